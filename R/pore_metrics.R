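#' Inter-leaflet water count and volume
#'
#' The volume of electroporation pores is tracked by the amount of water
#' residing between the two lipid leaflets: the count of water-labeled
#' particles with z strictly inside the leaflet bounds, converted to volume
#' by a per-molecule volume constant (default 0.030 nm³, ambient liquid
#' water).
#'
#' @param frame A [particle_frame()].
#' @param bounds `c(z_lower, z_upper)` leaflet positions (nm), e.g. from
#'   [leaflet_bounds()].
#' @param water_volume_per_particle Volume per water particle (nm³).
#' @param water_label Label identifying water particles.
#' @return A list with `count` and `volume` (nm³).
#' @export
interleaflet_water_volume <- function(frame, bounds,
                                      water_volume_per_particle = 0.030,
                                      water_label = "WATER") {
  stopifnot(inherits(frame, "particle_frame"))
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    stop("bounds must be c(z_lower, z_upper) with z_lower < z_upper",
         call. = FALSE)
  }
  z <- frame$positions[frame$labels == water_label, 3L]
  count <- sum(z > bounds[1] & z < bounds[2])
  list(count = count, volume = count * water_volume_per_particle)
}

.pore_slab <- function(bounds, slab_fraction) {
  mid <- mean(bounds)
  half <- diff(bounds) * slab_fraction / 2
  c(mid - half, mid + half)
}

# periodic 4-neighborhood connected components on an nx x ny occupancy grid
.label_periodic <- function(occ) {
  nx <- nrow(occ); ny <- ncol(occ)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  for (j0 in seq_len(ny)) for (i0 in seq_len(nx)) {
    if (!occ[i0, j0] || lab[i0, j0]) next
    cur <- cur + 1L
    queue <- matrix(c(i0, j0), ncol = 2L)
    lab[i0, j0] <- cur
    while (nrow(queue)) {
      i <- queue[1L, 1L]; j <- queue[1L, 2L]
      queue <- queue[-1L, , drop = FALSE]
      nb <- rbind(c(i %% nx + 1L, j), c((i - 2L) %% nx + 1L, j),
                  c(i, j %% ny + 1L), c(i, (j - 2L) %% ny + 1L))
      for (k in 1:4) {
        ii <- nb[k, 1L]; jj <- nb[k, 2L]
        if (occ[ii, jj] && !lab[ii, jj]) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

# periodic (circular) mean of coordinates in [0, L)
.periodic_mean <- function(x, L) {
  theta <- 2 * pi * x / L
  m <- atan2(mean(sin(theta)), mean(cos(theta)))
  (m %% (2 * pi)) * L / (2 * pi)
}

#' Count and size membrane pores by periodic grid labeling
#'
#' Water particles inside the central slab of the inter-leaflet gap are
#' binned onto a 2-D x-y occupancy grid; occupied cells are grouped by
#' 4-neighborhood connected components with periodic wrap in x and y, so a
#' pore straddling the box boundary is counted once. Components smaller than
#' `min_cells` cells are discarded as stray water. Each surviving component
#' is one pore with area `n_cells * cell area`, water count, volume
#' (count times the per-molecule volume constant) and a periodic-mean
#' centroid.
#'
#' @param frame A [particle_frame()].
#' @param bounds `c(z_lower, z_upper)` leaflet positions (nm).
#' @param cell_size Requested grid cell edge (nm); the actual cell edge is
#'   the box edge divided by the nearest integer cell count. Must not exceed
#'   half the smaller lateral box edge.
#' @param min_cells Minimum component size in cells (default 2).
#' @param water_volume_per_particle Volume per water particle (nm³).
#' @param slab_fraction Central fraction of the inter-leaflet gap used for
#'   pore detection (default 0.5), so headgroup-adjacent water does not
#'   trigger false pores.
#' @param water_label Label identifying water particles.
#' @return An object of class `pore_report`: `frame_time`,
#'   `water_count_between_leaflets`, `pore_volume` (total inter-leaflet
#'   water volume), `n_pores`, and `pores`, a data frame with one row per
#'   pore (`pore_id`, `n_cells`, `area`, `water_count`, `volume`,
#'   `centroid_x`, `centroid_y`).
#' @export
count_pores <- function(frame, bounds, cell_size = 0.4, min_cells = 2L,
                        water_volume_per_particle = 0.030,
                        slab_fraction = 0.5, water_label = "WATER") {
  stopifnot(inherits(frame, "particle_frame"))
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  Lx <- frame$box[1]; Ly <- frame$box[2]
  if (cell_size > min(Lx, Ly) / 2) {
    stop("cell_size must not exceed half the smaller lateral box edge",
         call. = FALSE)
  }
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    stop("bounds must be c(z_lower, z_upper) with z_lower < z_upper",
         call. = FALSE)
  }
  iw <- interleaflet_water_volume(frame, bounds, water_volume_per_particle,
                                  water_label)
  slab <- .pore_slab(bounds, slab_fraction)
  keep <- frame$labels == water_label &
    frame$positions[, 3L] > slab[1] & frame$positions[, 3L] < slab[2]
  x <- frame$positions[keep, 1L]; y <- frame$positions[keep, 2L]
  nx <- max(1L, as.integer(round(Lx / cell_size)))
  ny <- max(1L, as.integer(round(Ly / cell_size)))
  cellx <- Lx / nx; celly <- Ly / ny
  pores <- data.frame(pore_id = integer(), n_cells = integer(),
                      area = numeric(), water_count = integer(),
                      volume = numeric(), centroid_x = numeric(),
                      centroid_y = numeric())
  if (length(x)) {
    ix <- pmin(floor(x / cellx) + 1L, nx)
    iy <- pmin(floor(y / celly) + 1L, ny)
    counts <- matrix(0L, nx, ny)
    for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
    lab <- .label_periodic(counts > 0L)
    comp_ids <- setdiff(unique(as.integer(lab)), 0L)
    pid <- 0L
    for (cid in comp_ids) {
      cells <- which(lab == cid)
      if (length(cells) < min_cells) next
      pid <- pid + 1L
      in_comp <- lab[cbind(ix, iy)] == cid
      pores <- rbind(pores, data.frame(
        pore_id = pid, n_cells = length(cells),
        area = length(cells) * cellx * celly,
        water_count = sum(in_comp),
        volume = sum(in_comp) * water_volume_per_particle,
        centroid_x = .periodic_mean(x[in_comp], Lx),
        centroid_y = .periodic_mean(y[in_comp], Ly)))
    }
  }
  structure(list(frame_time = frame$time,
                 water_count_between_leaflets = iw$count,
                 pore_volume = iw$volume,
                 n_pores = nrow(pores), pores = pores,
                 cell_size = c(cellx, celly)),
            class = "pore_report")
}

#' @export
print.pore_report <- function(x, ...) {
  cat(sprintf(
    "pore_report%s: %d pore(s), %d water between leaflets (%.3f nm^3)\n",
    if (is.na(x$frame_time)) "" else sprintf(" (t = %g ns)", x$frame_time),
    x$n_pores, x$water_count_between_leaflets, x$pore_volume))
  if (x$n_pores) print(x$pores, row.names = FALSE)
  invisible(x)
}

#' Pore metrics over a frame sequence
#'
#' Applies [interleaflet_water_volume()] and [count_pores()] to each frame
#' of a trajectory-like sequence. Leaflet bounds are either recomputed per
#' frame (`bounds_policy = "per_frame"`) or located once on the first frame
#' and frozen (`"frozen"`); explicit bounds may also be supplied. Reports
#' are ordered by frame time (input order for untimed frames).
#'
#' @param frames List of [particle_frame()] objects.
#' @param bounds_policy `"per_frame"`, `"frozen"`, or `"manual"` (then
#'   `bounds` must be given).
#' @param bounds Explicit `c(z_lower, z_upper)` for `"manual"`.
#' @param head_labels Passed to [leaflet_bounds()].
#' @param ... Passed to [count_pores()].
#' @return A list of `pore_report`s, ordered by frame time.
#' @export
pore_timeseries <- function(frames, bounds_policy = c("per_frame", "frozen",
                                                      "manual"),
                            bounds = NULL, head_labels = c("HEAD+", "HEAD-"),
                            ...) {
  bounds_policy <- match.arg(bounds_policy)
  if (!length(frames)) stop("need at least one frame", call. = FALSE)
  if (bounds_policy == "manual" && is.null(bounds)) {
    stop("bounds_policy = 'manual' requires explicit bounds", call. = FALSE)
  }
  if (bounds_policy == "frozen") {
    bounds <- leaflet_bounds(frames[[1L]], head_labels)
  }
  reports <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    reports[[i]] <- tryCatch({
      b <- if (bounds_policy == "per_frame")
        leaflet_bounds(frames[[i]], head_labels) else bounds
      count_pores(frames[[i]], bounds = b, ...)
    }, error = function(e) {
      stop(sprintf("frame %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
  }
  times <- vapply(reports, function(r) r$frame_time, numeric(1))
  if (!anyNA(times)) reports <- reports[order(times)]
  reports
}

#' Write a list of pore reports as tidy CSV
#'
#' One row per frame for frame-level quantities, followed by one row per
#' pore (frame-level columns repeated).
#'
#' @param reports A list of `pore_report`s (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pore_report_csv <- function(reports, path) {
  if (inherits(reports, "pore_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    base <- data.frame(frame_time = r$frame_time, n_pores = r$n_pores,
                       water_count = r$water_count_between_leaflets,
                       pore_volume = r$pore_volume)
    if (r$n_pores == 0L) {
      cbind(base, data.frame(pore_id = NA_integer_, area = NA_real_,
                             volume = NA_real_, centroid_x = NA_real_,
                             centroid_y = NA_real_))
    } else {
      cbind(base[rep(1L, r$n_pores), , drop = FALSE],
            r$pores[, c("pore_id", "area", "volume", "centroid_x",
                        "centroid_y")])
    }
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
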