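#' Specification of an idealized two-leaflet bilayer frame
#'
#' Describes a pseudo-lipid bilayer used to exercise the membrane analytics
#' with known ground truth: two lattices of pseudo-lipids (one charged head
#' pair at ±0.05 nm about each leaflet plane, the +q head on the
#' water-facing side of both leaflets so the bilayer is mirror-symmetric,
#' and neutral tail beads toward the midplane), bulk water above and below,
#' and optional transmembrane
#' cylindrical water pores. Pseudo-lipids capture only what the metrics
#' measure — charge, label and position geometry — not lipid chemistry.
#'
#' @param box Box edges `c(Lx, Ly, Lz)` (nm).
#' @param leaflet_z Leaflet plane heights `c(z_lower, z_upper)` (nm), inside
#'   the box.
#' @param lipids_per_leaflet Pseudo-lipids per leaflet.
#' @param head_charges Charges `c(+q, -q)` of the head pair (e); must sum
#'   to 0 so frames are neutral by construction.
#' @param tail_beads Neutral tail beads per lipid (toward the midplane).
#' @param water_density Bulk water number density (nm^-3, default 33.3).
#' @param pores List of pores, each `list(center = c(x, y), radius = r)`;
#'   radii must stay below a quarter of the smaller lateral edge and pores
#'   must not overlap (periodic distance).
#' @param jitter_sd Gaussian positional jitter sd applied to lipid beads
#'   (nm).
#' @param seed Integer seed; the frame is bit-reproducible given the spec.
#' @return A validated `bilayer_spec` list.
#' @export
bilayer_spec <- function(box = c(10, 10, 12), leaflet_z = c(4.5, 7.5),
                         lipids_per_leaflet = 400L,
                         head_charges = c(0.5, -0.5), tail_beads = 3L,
                         water_density = 33.3, pores = list(),
                         jitter_sd = 0.05, seed = 1L) {
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("invalid box", call. = FALSE)
  if (length(leaflet_z) != 2L || leaflet_z[1] >= leaflet_z[2] ||
      leaflet_z[1] <= 0 || leaflet_z[2] >= box[3]) {
    stop("leaflet_z must satisfy 0 < z_lower < z_upper < Lz", call. = FALSE)
  }
  if (water_density <= 0) stop("water_density must be positive", call. = FALSE)
  if (abs(sum(head_charges)) > 1e-12) {
    stop("head_charges must sum to zero", call. = FALSE)
  }
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  rmax <- min(box[1], box[2]) / 4
  for (p in pores) {
    if (is.null(p$center) || is.null(p$radius) || length(p$center) != 2L) {
      stop("each pore needs center = c(x, y) and radius", call. = FALSE)
    }
    if (p$radius <= 0 || p$radius >= rmax) {
      stop(sprintf("pore radius must lie in (0, %.3f)", rmax), call. = FALSE)
    }
  }
  if (length(pores) > 1L) {
    for (i in seq_len(length(pores) - 1L)) for (j in (i + 1L):length(pores)) {
      d <- .periodic_xy_dist(pores[[i]]$center, pores[[j]]$center, box[1:2])
      if (d < pores[[i]]$radius + pores[[j]]$radius) {
        stop(sprintf("pores %d and %d overlap", i, j), call. = FALSE)
      }
    }
  }
  structure(list(box = box, leaflet_z = as.numeric(leaflet_z),
                 lipids_per_leaflet = as.integer(lipids_per_leaflet),
                 head_charges = as.numeric(head_charges),
                 tail_beads = as.integer(tail_beads),
                 water_density = water_density, pores = pores,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "bilayer_spec")
}

.periodic_xy_dist <- function(a, b, L) {
  d <- abs(a - b)
  d <- pmin(d, L - d)
  sqrt(sum(d^2))
}

#' Generate an idealized bilayer particle frame with ground truth
#'
#' Builds the frame described by a [bilayer_spec()]: leaflet lattices of
#' pseudo-lipids with jitter, bulk water slabs on both sides, and water
#' cylinders through planted pores (lipids inside a pore cylinder are
#' removed). The net frame charge is exactly zero because heads come in
#' ±q pairs. The returned ground truth carries the exact leaflet planes,
#' pore geometry and densities for parameter-recovery tests.
#'
#' @param spec A [bilayer_spec()].
#' @param time Optional frame timestamp (ns).
#' @return A list with `frame` (a [particle_frame()]) and `ground_truth`
#'   (leaflet planes, pore list, densities and counts).
#' @export
#' @examples
#' bf <- make_bilayer_frame(bilayer_spec(pores = list(
#'   list(center = c(5, 5), radius = 1))))
#' leaflet_bounds(bf$frame)
make_bilayer_frame <- function(spec, time = NA_real_) {
  stopifnot(inherits(spec, "bilayer_spec"))
  withr::with_seed(spec$seed, .build_bilayer(spec, time))
}

.build_bilayer <- function(spec, time) {
  Lx <- spec$box[1]; Ly <- spec$box[2]; Lz <- spec$box[3]
  zl <- spec$leaflet_z[1]; zu <- spec$leaflet_z[2]
  mid <- (zl + zu) / 2
  n <- spec$lipids_per_leaflet
  ng <- ceiling(sqrt(n))
  gx <- (rep(seq_len(ng), each = ng)[seq_len(n)] - 0.5) * Lx / ng
  gy <- (rep(seq_len(ng), times = ng)[seq_len(n)] - 0.5) * Ly / ng
  in_pore <- rep(FALSE, n)
  for (p in spec$pores) {
    d <- vapply(seq_len(n), function(k)
      .periodic_xy_dist(c(gx[k], gy[k]), p$center, c(Lx, Ly)), numeric(1))
    in_pore <- in_pore | d < p$radius
  }
  gx <- gx[!in_pore]; gy <- gy[!in_pore]
  n_kept <- length(gx)

  pos <- list(); chg <- list(); lab <- list()
  add <- function(x, y, z, q, l) {
    pos[[length(pos) + 1L]] <<- cbind(x, y, z)
    chg[[length(chg) + 1L]] <<- rep(q, length(x))
    lab[[length(lab) + 1L]] <<- rep(l, length(x))
  }
  tail_gap <- (zu - zl) / 2 - 0.2
  for (leaf in c(zl, zu)) {
    dir_in <- if (leaf < mid) 1 else -1
    # +q head on the water-facing side of each leaflet: the two dipole
    # layers mirror and the bilayer is symmetric about the midplane
    add(gx, gy, rep(leaf - dir_in * 0.05, n_kept), spec$head_charges[1],
        "HEAD+")
    add(gx, gy, rep(leaf + dir_in * 0.05, n_kept), spec$head_charges[2],
        "HEAD-")
    for (k in seq_len(spec$tail_beads)) {
      zb <- leaf + dir_in * (0.1 + k * tail_gap / (spec$tail_beads + 1))
      add(gx, gy, rep(zb, n_kept), 0, "TAIL")
    }
  }
  lipid_pos <- do.call(rbind, pos)
  lipid_pos <- lipid_pos + matrix(stats::rnorm(length(lipid_pos),
                                               sd = spec$jitter_sd),
                                  ncol = 3L)

  water_margin <- 0.3
  wpos <- list()
  slab_water <- function(z0, z1) {
    vol <- Lx * Ly * (z1 - z0)
    nw <- round(spec$water_density * vol)
    if (nw < 1) return(NULL)
    cbind(stats::runif(nw, 0, Lx), stats::runif(nw, 0, Ly),
          stats::runif(nw, z0, z1))
  }
  wpos$below <- slab_water(0, zl - water_margin)
  wpos$above <- slab_water(zu + water_margin, Lz)
  n_pore_water <- 0L
  for (p in spec$pores) {
    vol <- pi * p$radius^2 * (zu - zl)
    nw <- round(spec$water_density * vol)
    if (nw < 1) next
    rr <- p$radius * sqrt(stats::runif(nw))
    th <- stats::runif(nw, 0, 2 * pi)
    wpos[[length(wpos) + 1L]] <- cbind(p$center[1] + rr * cos(th),
                                       p$center[2] + rr * sin(th),
                                       stats::runif(nw, zl, zu))
    n_pore_water <- n_pore_water + nw
  }
  water_pos <- do.call(rbind, wpos)

  positions <- rbind(lipid_pos, water_pos)
  charges <- c(do.call(c, chg), rep(0, nrow(water_pos)))
  labels <- c(do.call(c, lab), rep("WATER", nrow(water_pos)))
  frame <- particle_frame(positions, charges, labels, box = spec$box,
                          time = time)
  list(frame = frame,
       ground_truth = list(
         leaflet_z = spec$leaflet_z,
         pores = spec$pores,
         water_density = spec$water_density,
         n_lipids_removed = n - n_kept,
         n_pore_water = n_pore_water,
         jitter_sd = spec$jitter_sd))
}

#' Generate a parallel-plate charged-slab frame (electrostatics oracle)
#'
#' Two uniformly scattered sheets of point charges with surface charge
#' densities `+sigma` and `-sigma` (e nm^-2), centered about the box
#' midplane with the given separation. The parallel-plate closed form
#' predicts a transmembrane potential of exactly `sigma * separation` in
#' reduced units, independent of how finely each sheet is discretized,
#' making this frame the analytic oracle for the potential pipeline.
#'
#' @param sigma Surface charge density (e nm^-2).
#' @param separation Sheet separation (nm), below `Lz / 2`.
#' @param box Box edges (nm).
#' @param particles_per_sheet Point charges per sheet (default 400).
#' @param seed Integer seed for the lateral scatter.
#' @return A [particle_frame()] with labels `"SHEET+"`, `"SHEET-"`.
#' @export
make_charged_slab_frame <- function(sigma, separation, box = c(10, 10, 10),
                                    particles_per_sheet = 400L, seed = 1L) {
  box <- as.numeric(box)
  if (separation <= 0 || separation >= box[3] / 2) {
    stop("separation must lie in (0, Lz / 2)", call. = FALSE)
  }
  if (particles_per_sheet < 1L) {
    stop("particles_per_sheet must be >= 1", call. = FALSE)
  }
  z_lo <- (box[3] - separation) / 2
  z_hi <- (box[3] + separation) / 2
  q <- sigma * box[1] * box[2] / particles_per_sheet
  withr::with_seed(as.integer(seed), {
    xy <- cbind(stats::runif(2L * particles_per_sheet, 0, box[1]),
                stats::runif(2L * particles_per_sheet, 0, box[2]))
    z <- rep(c(z_lo, z_hi), each = particles_per_sheet)
    particle_frame(cbind(xy, z),
                   rep(c(q, -q), each = particles_per_sheet),
                   rep(c("SHEET+", "SHEET-"), each = particles_per_sheet),
                   box = box)
  })
}

#' Specification of the generative PEF dose-response dataset
#'
#' Encodes the mechanistic narrative of PEF electroporation as a small
#' generative model over a pulse-strength x pulse-width design grid:
#' pulse strength above a threshold sets the latent pore number
#' \eqn{N = a_N \max(0, E - E_{thr})}; pulse width sets the latent
#' large-pore fraction \eqn{S = logistic(a_S (\log_{10} w - c_S))}; the
#' small-dye uptake rate saturates with N, the large-dye uptake rate with
#' N S, and fusion is linear in both rates with the large-pore coefficient
#' dominating by construction. Noise is added before clipping rates to
#' \[0, 100\] (extreme-dose rows are therefore heteroscedastic).
#'
#' @param strengths Field-strength grid (kV/cm).
#' @param widths_ns Pulse-width grid (ns).
#' @param n_replicates Rows per grid point.
#' @param e_threshold Poration threshold (kV/cm).
#' @param a_n Pore-number slope (per kV/cm above threshold).
#' @param a_s,s_center Large-pore logistic slope and center (log10 ns).
#' @param k_y,k_p Saturation rates of the YP and PI links.
#' @param beta0,beta_small,beta_large Fusion coefficients (intercept, per
#'   YP %, per PI %); `beta_large > beta_small` is required, encoding the
#'   dominance of large-pore formation in fusion.
#' @param yp_sd,pi_sd,fusion_sd Gaussian noise sds (all >= 0).
#' @param seed Integer seed.
#' @return A validated `pef_response_spec` list.
#' @export
pef_response_spec <- function(strengths = c(0, 0.4, 0.8, 1.2, 1.6, 2.0, 2.4),
                              widths_ns = c(200, 1000, 10000, 40000),
                              n_replicates = 1L,
                              e_threshold = 0.4, a_n = 2,
                              a_s = 1.5, s_center = 3.5,
                              k_y = 1.0, k_p = 0.6,
                              beta0 = 0.3, beta_small = 0.02,
                              beta_large = 0.15,
                              yp_sd = 3, pi_sd = 3, fusion_sd = 0.5,
                              seed = 1L) {
  if (!length(strengths) || !length(widths_ns)) {
    stop("strength and width grids must be non-empty", call. = FALSE)
  }
  if (any(widths_ns <= 0)) stop("pulse widths must be positive", call. = FALSE)
  if (any(c(yp_sd, pi_sd, fusion_sd) < 0)) {
    stop("noise sds must be >= 0", call. = FALSE)
  }
  if (beta_large <= beta_small) {
    stop("beta_large must exceed beta_small", call. = FALSE)
  }
  structure(list(strengths = as.numeric(strengths),
                 widths_ns = as.numeric(widths_ns),
                 n_replicates = as.integer(n_replicates),
                 e_threshold = e_threshold, a_n = a_n,
                 a_s = a_s, s_center = s_center, k_y = k_y, k_p = k_p,
                 beta0 = beta0, beta_small = beta_small,
                 beta_large = beta_large, yp_sd = yp_sd, pi_sd = pi_sd,
                 fusion_sd = fusion_sd, seed = as.integer(seed)),
            class = "pef_response_spec")
}

#' Generate a synthetic PEF dose-response sample table with ground truth
#'
#' Draws one sample table row per design-grid point (times replicates) from
#' the generative model of [pef_response_spec()]. Pre-noise dye-uptake
#' rates are monotone non-decreasing in field strength at fixed width. The
#' ground truth stores every latent (pore number, large-pore fraction,
#' noiseless rates) and the generative coefficients, so downstream fits can
#' be checked for parameter recovery — in particular, a PLS fit of fusion
#' on (YP, PI) must weight the large-pore proxy (PI) more heavily,
#' recovering `beta_large > beta_small`.
#'
#' @param spec A [pef_response_spec()].
#' @return A list with `table` (a [sample_table]) and `ground_truth`.
#' @export
#' @examples
#' ds <- make_pef_response_dataset(pef_response_spec(seed = 7))
#' head(ds$table)
make_pef_response_dataset <- function(spec) {
  stopifnot(inherits(spec, "pef_response_spec"))
  grid <- expand.grid(rep = seq_len(spec$n_replicates),
                      strength = spec$strengths, width = spec$widths_ns,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  N <- spec$a_n * pmax(0, grid$strength - spec$e_threshold)
  S <- stats::plogis(spec$a_s * (log10(grid$width) - spec$s_center))
  yp0 <- 100 * (2 * stats::plogis(spec$k_y * N) - 1)
  pi0 <- 100 * (2 * stats::plogis(spec$k_p * N * S) - 1)
  withr::with_seed(spec$seed, {
    yp <- pmin(100, pmax(0, yp0 + stats::rnorm(n, sd = spec$yp_sd)))
    pi_rate <- pmin(100, pmax(0, pi0 + stats::rnorm(n, sd = spec$pi_sd)))
    fusion <- pmax(0, spec$beta0 + spec$beta_small * yp +
                     spec$beta_large * pi_rate +
                     stats::rnorm(n, sd = spec$fusion_sd))
  })
  ids <- sprintf("W_%gns_E_%.1f", grid$width, grid$strength)
  if (spec$n_replicates > 1L) ids <- sprintf("%s_r%d", ids, grid$rep)
  table <- data.frame(sample_id = ids,
                      pulse_width_ns = grid$width,
                      field_strength_kv_cm = grid$strength,
                      yp_rate = yp, pi_rate = pi_rate, fusion_rate = fusion,
                      role = "unassigned", stringsAsFactors = FALSE)
  validate_sample_table(table)
  list(table = table,
       ground_truth = list(pore_number = N, large_pore_fraction = S,
                           yp_noiseless = yp0, pi_noiseless = pi0,
                           coefficients = spec[c("beta0", "beta_small",
                                                 "beta_large")],
                           spec = spec))
}
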