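pore_spec <- function(pores, seed = 30, water_density = 33.3, ...) {
  bilayer_spec(box = c(12, 12, 12), leaflet_z = c(4.5, 7.5),
               lipids_per_leaflet = 576, water_density = water_density,
               pores = pores, seed = seed, ...)
}

test_that("an intact bilayer has no inter-leaflet water and no pores", {
  bf <- make_bilayer_frame(pore_spec(list()))
  b <- leaflet_bounds(bf$frame)
  iw <- interleaflet_water_volume(bf$frame, b)
  expect_equal(iw$count, 0)
  expect_equal(iw$volume, 0)
  pr <- count_pores(bf$frame, b)
  expect_equal(pr$n_pores, 0)
})

test_that("a planted cylindrical pore's water volume matches pi r^2 h", {
  bf <- make_bilayer_frame(pore_spec(list(list(center = c(6, 6),
                                               radius = 1))))
  b <- leaflet_bounds(bf$frame)
  iw <- interleaflet_water_volume(bf$frame, b,
                                  water_volume_per_particle = 0.030)
  analytic <- pi * 1^2 * 3
  expect_equal(iw$volume, analytic, tolerance = 0.05 * analytic)
  # report-level bookkeeping: pore_volume = water count x volume constant
  pr <- count_pores(bf$frame, b)
  expect_equal(pr$pore_volume, pr$water_count_between_leaflets * 0.030,
               tolerance = 1e-12)
  expect_equal(pr$n_pores, 1)
})

test_that("doubling the planted pore radius quadruples the water volume", {
  vols <- vapply(c(1, 2), function(r) {
    bf <- make_bilayer_frame(pore_spec(list(list(center = c(6, 6),
                                                 radius = r))))
    interleaflet_water_volume(bf$frame, leaflet_bounds(bf$frame))$volume
  }, numeric(1))
  expect_equal(vols[2] / vols[1], 4, tolerance = 0.1 * 4)
})

test_that("well-separated planted pores are counted exactly with centroids", {
  pores <- list(list(center = c(2.5, 2.5), radius = 0.8),
                list(center = c(8.5, 2.5), radius = 0.8),
                list(center = c(5.5, 8.5), radius = 0.8))
  bf <- make_bilayer_frame(pore_spec(pores))
  b <- leaflet_bounds(bf$frame)
  pr <- count_pores(bf$frame, b, cell_size = 0.4)
  expect_equal(pr$n_pores, 3)
  # each recovered centroid lies within one cell of a planted center
  for (p in pores) {
    d <- apply(pr$pores[, c("centroid_x", "centroid_y")], 1, function(cc)
      sqrt(sum(pmin(abs(cc - p$center), 12 - abs(cc - p$center))^2)))
    expect_lt(min(d), 0.4 + 1e-9)
  }
})

test_that("a pore straddling the periodic boundary is counted once", {
  bf <- make_bilayer_frame(pore_spec(list(list(center = c(0, 6),
                                               radius = 1))))
  b <- leaflet_bounds(bf$frame)
  pr <- count_pores(bf$frame, b, cell_size = 0.4)
  expect_equal(pr$n_pores, 1)
  # independent oracle: non-periodic labeling of a 2x2 tiled grid
  expect_equal(pr$n_pores,
               periodic_pore_count_oracle(bf$frame, b, cell_size = 0.4))
  # centroid maps back to the planted center modulo the box
  cx <- pr$pores$centroid_x
  expect_lt(min(abs(cx), 12 - abs(cx)), 0.4 + 1e-9)
  expect_lt(abs(pr$pores$centroid_y - 6), 0.4 + 1e-9)
})

test_that("grid labeling agrees with the tiled-flood-fill oracle off-boundary", {
  pores <- list(list(center = c(3, 3), radius = 1),
                list(center = c(9, 9), radius = 0.7))
  bf <- make_bilayer_frame(pore_spec(pores))
  b <- leaflet_bounds(bf$frame)
  for (cs in c(0.3, 0.4, 0.6)) {
    expect_equal(count_pores(bf$frame, b, cell_size = cs)$n_pores,
                 periodic_pore_count_oracle(bf$frame, b, cell_size = cs))
  }
})

test_that("pore outputs are invariant to particle order and x-y translation", {
  bf <- make_bilayer_frame(pore_spec(list(list(center = c(2, 6),
                                               radius = 1))))
  f <- bf$frame
  b <- leaflet_bounds(f)
  pr <- count_pores(f, b)
  # permute particle order
  perm <- withr::with_seed(31, sample.int(nrow(f$positions)))
  fp <- particle_frame(f$positions[perm, ], f$charges[perm], f$labels[perm],
                       f$box)
  prp <- count_pores(fp, b)
  expect_equal(prp$n_pores, pr$n_pores)
  expect_equal(prp$pore_volume, pr$pore_volume)
  expect_equal(sort(prp$pores$volume), sort(pr$pores$volume))
  # rigid x-y translation with wrap; shift by whole grid cells so the
  # occupancy pattern translates exactly
  shift <- c(2.0, 3.2, 0)
  ft <- particle_frame(sweep(f$positions, 2, shift, "+"), f$charges,
                       f$labels, f$box)
  prt <- count_pores(ft, b, cell_size = 0.4)
  pr04 <- count_pores(f, b, cell_size = 0.4)
  expect_equal(prt$n_pores, pr04$n_pores)
  expect_equal(sum(prt$pores$volume), sum(pr04$pores$volume))
  expect_equal((prt$pores$centroid_x - shift[1]) %% 12,
               pr04$pores$centroid_x %% 12, tolerance = 1e-6)
})

test_that("refining the grid changes a large pore's area by < 10%", {
  # dense water keeps interior cells occupied at the finer grid, so the
  # comparison probes discretization, not sampling sparsity
  bf <- make_bilayer_frame(pore_spec(list(list(center = c(6, 6),
                                               radius = 2)),
                                     water_density = 80))
  b <- leaflet_bounds(bf$frame)
  a1 <- count_pores(bf$frame, b, cell_size = 0.4)$pores$area
  a2 <- count_pores(bf$frame, b, cell_size = 0.2)$pores$area
  expect_lt(abs(a2 - a1) / a1, 0.10)
})

test_that("pore volumes add up to the slab water bookkeeping identity", {
  bf <- make_bilayer_frame(pore_spec(list(list(center = c(3, 3), radius = 1),
                                          list(center = c(9, 9),
                                               radius = 0.8))))
  f <- bf$frame
  b <- leaflet_bounds(f)
  pr <- count_pores(f, b, min_cells = 1)
  # with min_cells = 1 every slab water particle belongs to some component
  slab <- b[1] + diff(b) * 0.25
  slab_hi <- b[2] - diff(b) * 0.25
  n_slab <- sum(f$labels == "WATER" & f$positions[, 3] > slab &
                  f$positions[, 3] < slab_hi)
  expect_equal(sum(pr$pores$water_count), n_slab)
  expect_equal(sum(pr$pores$volume), n_slab * 0.030, tolerance = 1e-12)
})

test_that("invalid pore-metric inputs are rejected", {
  bf <- make_bilayer_frame(pore_spec(list()))
  b <- leaflet_bounds(bf$frame)
  expect_error(interleaflet_water_volume(bf$frame, rev(b)), "z_lower")
  expect_error(count_pores(bf$frame, b, cell_size = 7), "half the smaller")
})

test_that("a growing-then-plateauing pore schedule is recovered in order", {
  radii <- c(0.5, 0.7, 0.9, 1.1, 1.3, 1.3, 1.3, 1.3)
  frames <- lapply(seq_along(radii), function(i) {
    make_bilayer_frame(pore_spec(list(list(center = c(6, 6),
                                           radius = radii[i])),
                                 seed = 40 + i), time = i * 0.5)$frame
  })
  reports <- pore_timeseries(frames, bounds_policy = "per_frame")
  vols <- vapply(reports, function(r) r$pore_volume, numeric(1))
  expect_gt(cor(vols, radii^2, method = "spearman"), 0.9)
  # non-decreasing up to counting noise, then flat
  expect_true(all(diff(vols[1:5]) > 0))
  plateau <- vols[5:8]
  expect_lt(max(plateau) - min(plateau), 3 * sqrt(mean(plateau) / 0.030) * 0.030)
})

test_that("two jitter seeds of the same schedule agree within counting noise", {
  vol_for_seed <- function(s) {
    bf <- make_bilayer_frame(pore_spec(list(list(center = c(6, 6),
                                                 radius = 1)), seed = s))
    interleaflet_water_volume(bf$frame, leaflet_bounds(bf$frame))$volume
  }
  v1 <- vol_for_seed(50); v2 <- vol_for_seed(51)
  count_sd <- sqrt(v1 / 0.030) * 0.030  # Poisson-scale counting noise
  expect_lt(abs(v1 - v2), 3 * count_sd)
})

test_that("constant frames give a constant time series", {
  f <- make_bilayer_frame(pore_spec(list(list(center = c(6, 6),
                                              radius = 1))), time = 0)$frame
  frames <- list(f, particle_frame(f$positions, f$charges, f$labels, f$box,
                                   time = 1))
  reports <- pore_timeseries(frames, bounds_policy = "frozen")
  expect_equal(reports[[1]]$pore_volume, reports[[2]]$pore_volume)
  expect_equal(reports[[1]]$n_pores, reports[[2]]$n_pores)
})
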