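#' Axis profiles: binned quantities along the membrane normal
#'
#' An `axis_profile` stores a quantity binned along one box axis — the
#' charge density \eqn{\rho(z)} in e nm\eqn{^{-3}} or the electrostatic
#' potential \eqn{\phi(z)} in reduced units — on uniform half-open bins
#' `[edge_i, edge_{i+1})`.
#'
#' @param bin_edges Monotone numeric vector of bin edges (nm), uniform width.
#' @param values Numeric vector, one per bin.
#' @param kind `"charge_density"` or `"potential"`.
#' @param axis Which axis the profile runs along (`"x"`, `"y"`, `"z"`).
#' @return An object of class `axis_profile`.
#' @export
axis_profile <- function(bin_edges, values, kind = c("charge_density",
                                                     "potential"),
                         axis = "z") {
  kind <- match.arg(kind)
  bin_edges <- as.numeric(bin_edges)
  values <- as.numeric(values)
  if (length(values) != length(bin_edges) - 1L) {
    stop("need length(values) == length(bin_edges) - 1", call. = FALSE)
  }
  widths <- diff(bin_edges)
  if (any(widths <= 0)) stop("bin edges must be strictly increasing",
                             call. = FALSE)
  if (max(widths) - min(widths) > 1e-12 * max(widths)) {
    stop("bins must be uniform", call. = FALSE)
  }
  structure(list(bin_edges = bin_edges, values = values, kind = kind,
                 axis = match.arg(axis, c("x", "y", "z")),
                 phi0 = 0, eps0 = 1),
            class = "axis_profile")
}

#' @export
print.axis_profile <- function(x, ...) {
  cat(sprintf("axis_profile (%s) along %s: %d bins of %.4g nm on [%g, %g]\n",
              x$kind, x$axis, length(x$values), diff(x$bin_edges)[1],
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Bin centers of an axis profile
#' @param profile An `axis_profile`.
#' @return Numeric vector of bin centers (nm).
#' @export
profile_centers <- function(profile) {
  e <- profile$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

.axis_index <- function(axis) match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))

#' Charge-density profile along the membrane normal
#'
#' Sums per-particle charges in uniform slices along the chosen axis and
#' divides by the slice volume, giving \eqn{\rho} in e nm\eqn{^{-3}}. The
#' profile integrates back to the total frame charge exactly:
#' `sum(values) * Lx * Ly * bin_width` equals `sum(frame$charges)`.
#'
#' @param frame A [particle_frame()].
#' @param bin_width Slice thickness (nm, default 0.1). If it does not divide
#'   the box edge to within one part in 1e6, the trailing partial slice is
#'   folded into the last bin with a warning.
#' @param axis Membrane normal (default `"z"`).
#' @return An `axis_profile` of kind `"charge_density"`.
#' @export
#' @examples
#' f <- make_charged_slab_frame(sigma = 0.2, separation = 3,
#'                              box = c(10, 10, 10), seed = 1)
#' rho <- charge_density_profile(f, bin_width = 0.1)
charge_density_profile <- function(frame, bin_width = 0.1, axis = "z") {
  stopifnot(inherits(frame, "particle_frame"))
  if (nrow(frame$positions) == 0L) stop("empty frame", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  ax <- .axis_index(axis)
  L <- frame$box[ax]
  nb_exact <- L / bin_width
  nb <- floor(nb_exact + 1e-9)
  if (nb < 1L) stop("bin_width exceeds the box edge", call. = FALSE)
  if (abs(nb_exact - nb) > 1e-6 * nb_exact) {
    warning(sprintf(
      "bin_width %g does not divide box edge %g; folding the trailing %.4g nm into the last bin",
      bin_width, L, L - nb * bin_width))
  }
  z <- frame$positions[, ax]
  idx <- pmin(floor(z / bin_width) + 1L, nb)
  sums <- numeric(nb)
  agg <- rowsum(frame$charges, idx)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  area <- prod(frame$box[-ax])
  axis_profile(seq(0, nb * bin_width, length.out = nb + 1L),
               sums / (area * bin_width), kind = "charge_density",
               axis = axis)
}

#' Electrostatic potential by double integration of the charge density
#'
#' Solves the 1-D Poisson equation in reduced units
#' (\eqn{\epsilon_0 = 1}, charges in e, lengths in nm):
#' \deqn{\phi(z) = -\frac{1}{\epsilon_0}\int_0^z\int_0^{z'} \rho(z'')\,dz''\,dz'}
#' by cumulative double integration from the lower box edge, with the gauge
#' \eqn{\phi_0 = \phi(0) = 0}. The bin density is treated as piecewise
#' constant, for which the double integral is evaluated exactly (each fully
#' traversed slice contributes as a charge sheet at its center). Reported
#' values are the potential at bin centers. No periodic or dipole correction
#' is applied: for a frame with net dipole the potentials at the two box
#' edges legitimately differ.
#'
#' @param density An `axis_profile` of kind `"charge_density"`.
#' @return An `axis_profile` of kind `"potential"` (reduced units) on the
#'   same bins.
#' @export
potential_profile <- function(density) {
  stopifnot(inherits(density, "axis_profile"))
  if (density$kind != "charge_density") {
    stop("input profile must be of kind 'charge_density'", call. = FALSE)
  }
  rho <- density$values
  dz <- diff(density$bin_edges)[1]
  centers <- profile_centers(density)
  nb <- length(rho)
  s0 <- c(0, cumsum(rho)[-nb])            # charge/dz of fully traversed bins
  m0 <- c(0, cumsum(rho * centers)[-nb])  # their first moments
  phi <- -(dz * (centers * s0 - m0) + rho * dz^2 / 8) / density$eps0
  out <- axis_profile(density$bin_edges, phi, kind = "potential",
                      axis = density$axis)
  out
}

#' Transmembrane potential imbalance
#'
#' The transmembrane potential is the mean potential over a bulk-water
#' region above the membrane minus the mean over a bulk-water region below:
#' \eqn{\Delta\phi = \langle\phi\rangle_{upper} - \langle\phi\rangle_{lower}}
#' (reduced units).
#'
#' @param potential An `axis_profile` of kind `"potential"`.
#' @param water_region_lower,water_region_upper Length-2 numeric intervals
#'   (nm) along the profile axis, both lying in bulk water.
#' @param leaflet_bounds Optional `(z_lower, z_upper)` leaflet positions;
#'   when supplied, regions overlapping the membrane slab raise an error.
#' @return The scalar \eqn{\Delta\phi}.
#' @export
transmembrane_potential <- function(potential, water_region_lower,
                                    water_region_upper,
                                    leaflet_bounds = NULL) {
  stopifnot(inherits(potential, "axis_profile"))
  if (potential$kind != "potential") {
    stop("input profile must be of kind 'potential'", call. = FALSE)
  }
  chk <- function(reg, nm) {
    if (length(reg) != 2L || reg[1] >= reg[2]) {
      stop(nm, " must be an interval c(lo, hi) with lo < hi", call. = FALSE)
    }
    if (!is.null(leaflet_bounds) &&
        reg[2] > leaflet_bounds[1] && reg[1] < leaflet_bounds[2]) {
      stop(nm, " overlaps the membrane slab [",
           leaflet_bounds[1], ", ", leaflet_bounds[2], "]", call. = FALSE)
    }
  }
  chk(water_region_lower, "water_region_lower")
  chk(water_region_upper, "water_region_upper")
  if (water_region_lower[2] > water_region_upper[1]) {
    stop("lower region must lie entirely below the upper region", call. = FALSE)
  }
  centers <- profile_centers(potential)
  lo <- centers >= water_region_lower[1] & centers <= water_region_lower[2]
  hi <- centers >= water_region_upper[1] & centers <= water_region_upper[2]
  if (!any(lo) || !any(hi)) {
    stop("a water region contains no profile bins", call. = FALSE)
  }
  mean(potential$values[hi]) - mean(potential$values[lo])
}

#' Locate the two leaflet planes from headgroup particles
#'
#' Splits the z-coordinates of head-labeled particles into two groups by a
#' 1-D two-cluster k-means and returns the mean z of each group (lower
#' first). Intended for bilayers whose slab does not straddle the periodic
#' z-boundary. If the two clusters are not separated by at least four pooled
#' within-cluster standard deviations — e.g. a single flat sheet, or a
#' pore-collapsed membrane — an error advises supplying bounds manually.
#'
#' @param frame A [particle_frame()].
#' @param head_labels Labels counted as headgroups
#'   (default `c("HEAD+", "HEAD-")`).
#' @return Numeric `c(z_lower_leaflet, z_upper_leaflet)` (nm).
#' @export
leaflet_bounds <- function(frame, head_labels = c("HEAD+", "HEAD-")) {
  stopifnot(inherits(frame, "particle_frame"))
  z <- frame$positions[frame$labels %in% head_labels, 3L]
  if (length(z) < 2L) {
    stop("need at least one head particle per leaflet", call. = FALSE)
  }
  centers0 <- stats::quantile(z, c(0.25, 0.75), names = FALSE)
  if (diff(centers0) < 1e-12) centers0 <- centers0 + c(-1e-9, 1e-9)
  km <- stats::kmeans(z, centers = matrix(centers0, ncol = 1L))
  if (any(km$size == 0L)) {
    stop("head particles form a single cluster; supply leaflet bounds manually",
         call. = FALSE)
  }
  mu <- sort(as.numeric(km$centers))
  pooled_sd <- sqrt(sum(km$withinss) / length(z))
  if (diff(mu) < 4 * pooled_sd) {
    stop("head particles form a single cluster; supply leaflet bounds manually",
         call. = FALSE)
  }
  mu
}

#' Write / read an axis profile as two-column CSV
#'
#' The CSV has a `#`-prefixed metadata header line (kind, axis, bin width)
#' followed by `bin_center,value` rows.
#'
#' @param profile An `axis_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "axis_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s axis=%s bin_width=%.17g edge0=%.17g",
                     profile$kind, profile$axis, diff(profile$bin_edges)[1],
                     profile$bin_edges[1]), con)
  writeLines("bin_center,value", con)
  writeLines(sprintf("%.17g,%.17g", profile_centers(profile),
                     profile$values), con)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path)
  meta_line <- lines[grepl("^#", lines)][1]
  get_meta <- function(key) {
    sub(sprintf(".*%s=([^ ]+).*", key), "\\1", meta_line)
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  bw <- as.numeric(get_meta("bin_width"))
  edge0 <- as.numeric(get_meta("edge0"))
  edges <- c(edge0, df$bin_center + bw / 2)
  axis_profile(edges, df$value, kind = get_meta("kind"),
               axis = get_meta("axis"))
}
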