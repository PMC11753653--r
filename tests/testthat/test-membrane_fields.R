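test_that("charge binning is exact for a single point charge", {
  f <- particle_frame(rbind(c(5, 5, 2.05)), charges = 1, labels = "Q",
                      box = c(10, 10, 10))
  rho <- charge_density_profile(f, bin_width = 0.1)
  expect_equal(length(rho$values), 100)
  hit <- which(rho$values != 0)
  expect_equal(hit, 21)  # bin [2.0, 2.1)
  expect_equal(rho$values[hit], 1 / (10 * 10 * 0.1))
})

test_that("neutral frames give identically zero density and potential", {
  bf <- make_bilayer_frame(bilayer_spec(head_charges = c(0, 0),
                                        lipids_per_leaflet = 36,
                                        water_density = 3, seed = 4))
  rho <- charge_density_profile(bf$frame)
  expect_true(all(rho$values == 0))
  phi <- potential_profile(rho)
  expect_true(all(phi$values == 0))
})

test_that("density profiles conserve total charge", {
  frames <- list(
    make_charged_slab_frame(0.3, 2, seed = 5),
    make_bilayer_frame(bilayer_spec(lipids_per_leaflet = 64,
                                    water_density = 5, seed = 6))$frame)
  for (f in frames) {
    for (bw in c(0.05, 0.1, 0.25)) {
      rho <- charge_density_profile(f, bin_width = bw)
      integral <- sum(rho$values) * f$box[1] * f$box[2] * bw
      expect_equal(integral, sum(f$charges), tolerance = 1e-9)
    }
  }
  # planted sheet: integral over the sheet region recovers sigma * area
  sl <- make_charged_slab_frame(0.5, 4, box = c(8, 8, 10), seed = 7)
  rho <- charge_density_profile(sl, bin_width = 0.1)
  centers <- profile_centers(rho)
  lower_sheet <- centers < 5
  q_lower <- sum(rho$values[lower_sheet]) * 8 * 8 * 0.1
  expect_equal(q_lower, 0.5 * 8 * 8, tolerance = 1e-9)
})

test_that("the potential gauge fixes phi = 0 at the lower box edge", {
  f <- make_charged_slab_frame(0.2, 3, seed = 8)
  phi <- potential_profile(charge_density_profile(f, 0.1))
  # every bin below the first charge is exactly zero, including bin 1
  expect_equal(phi$values[1], 0)
  first_charged <- min(which(charge_density_profile(f, 0.1)$values != 0))
  expect_true(all(phi$values[seq_len(first_charged - 1)] == 0))
})

test_that("parallel-plate frames match the closed form |dphi| = sigma * d", {
  for (case in list(c(0.2, 3), c(0.1, 2), c(0.4, 1.5))) {
    sigma <- case[1]; d <- case[2]
    f <- make_charged_slab_frame(sigma, d, box = c(10, 10, 10), seed = 9)
    phi <- potential_profile(charge_density_profile(f, bin_width = 0.1))
    lo <- c(0, (10 - d) / 2 - 0.5)
    hi <- c((10 + d) / 2 + 0.5, 10)
    dphi <- transmembrane_potential(phi, lo, hi)
    expect_equal(abs(dphi), sigma * d, tolerance = 0.02 * sigma * d)
  }
})

test_that("potential superposition holds to near machine precision", {
  f1 <- make_charged_slab_frame(0.2, 3, seed = 10)
  f2 <- make_charged_slab_frame(0.15, 4.5, seed = 11)
  r1 <- charge_density_profile(f1, 0.1)
  r2 <- charge_density_profile(f2, 0.1)
  sum_profile <- axis_profile(r1$bin_edges, r1$values + r2$values,
                              kind = "charge_density")
  phi_sum <- potential_profile(sum_profile)
  expect_equal(phi_sum$values,
               potential_profile(r1)$values + potential_profile(r2)$values,
               tolerance = 1e-10)
})

test_that("transmembrane potential scales monotonically with sheet charge", {
  dphi <- vapply(c(0.1, 0.2, 0.4), function(sigma) {
    f <- make_charged_slab_frame(sigma, 3, seed = 12)
    phi <- potential_profile(charge_density_profile(f, 0.1))
    transmembrane_potential(phi, c(0, 3), c(7, 10))
  }, numeric(1))
  expect_true(all(diff(abs(dphi)) > 0))
})

test_that("reflecting a frame through the box midplane negates dphi", {
  bf <- make_bilayer_frame(bilayer_spec(lipids_per_leaflet = 100,
                                        water_density = 8, seed = 13,
                                        head_charges = c(0.7, -0.7)))
  f <- bf$frame
  # break the mirror symmetry so dphi is nonzero: add a dipole pair
  # (at generic z, off the bin edges, where half-open binning mirrors cleanly)
  f2 <- particle_frame(rbind(f$positions, c(5, 5, 2.03), c(5, 5, 9.48)),
                       c(f$charges, 2, -2), c(f$labels, "ION", "ION"),
                       f$box)
  mirrored <- particle_frame(
    cbind(f2$positions[, 1], f2$positions[, 2],
          f2$box[3] - f2$positions[, 3]),
    f2$charges, f2$labels, f2$box)
  reg_lo <- c(0.5, 3.0); reg_hi <- c(9.0, 11.5)
  d1 <- transmembrane_potential(
    potential_profile(charge_density_profile(f2, 0.1)), reg_lo, reg_hi)
  d2 <- transmembrane_potential(
    potential_profile(charge_density_profile(mirrored, 0.1)),
    c(f2$box[3] - reg_hi[2], f2$box[3] - reg_hi[1]),
    c(f2$box[3] - reg_lo[2], f2$box[3] - reg_lo[1]))
  expect_gt(abs(d1), 1e-3)
  expect_equal(d1 + d2, 0, tolerance = 1e-9)
})

test_that("halving the bin width changes the slab-oracle dphi by < 1%", {
  f <- make_charged_slab_frame(0.2, 3, seed = 14)
  d <- vapply(c(0.1, 0.05), function(bw) {
    transmembrane_potential(
      potential_profile(charge_density_profile(f, bw)), c(0, 3), c(7, 10))
  }, numeric(1))
  expect_lt(abs(d[2] - d[1]) / abs(d[1]), 0.01)
})

test_that("a symmetric neutral bilayer has negligible mean dphi", {
  # averaged over three independent frames: head-group jitter leaves a
  # small random dipole imbalance in any single configuration
  dphi <- vapply(1:3, function(s) {
    bf <- make_bilayer_frame(bilayer_spec(seed = s))
    phi <- potential_profile(charge_density_profile(bf$frame, 0.1))
    b <- leaflet_bounds(bf$frame)
    transmembrane_potential(phi, c(0.5, b[1] - 1), c(b[2] + 1, 11.5),
                            leaflet_bounds = b)
  }, numeric(1))
  expect_lt(abs(mean(dphi)), 0.01)
})

test_that("water regions overlapping the membrane slab are rejected", {
  f <- make_charged_slab_frame(0.2, 3, seed = 16)
  phi <- potential_profile(charge_density_profile(f, 0.1))
  expect_error(
    transmembrane_potential(phi, c(0, 4), c(7, 10),
                            leaflet_bounds = c(3.5, 6.5)),
    "overlaps the membrane slab")
  expect_error(transmembrane_potential(phi, c(5, 4), c(7, 10)), "interval")
})

test_that("non-uniform bins are rejected by the potential integrator", {
  expect_error(axis_profile(c(0, 1, 3), c(1, 1), kind = "charge_density"),
               "uniform")
  rho <- charge_density_profile(make_charged_slab_frame(0.1, 2, seed = 1),
                                0.1)
  phi <- potential_profile(rho)
  expect_error(potential_profile(phi), "charge_density")
})

test_that("leaflet bounds recover the generator's leaflet planes", {
  spec <- bilayer_spec(leaflet_z = c(4.0, 7.0), lipids_per_leaflet = 400,
                       water_density = 2, jitter_sd = 0.05, seed = 17)
  bf <- make_bilayer_frame(spec)
  b <- leaflet_bounds(bf$frame)
  tol <- 2 * spec$jitter_sd / sqrt(400)
  expect_equal(b[1], 4.0, tolerance = 3 * tol + 1e-3)
  expect_equal(b[2], 7.0, tolerance = 3 * tol + 1e-3)
})

test_that("leaflet bounds are equivariant under a rigid z-shift", {
  bf <- make_bilayer_frame(bilayer_spec(lipids_per_leaflet = 100,
                                        water_density = 2, seed = 18))
  b0 <- leaflet_bounds(bf$frame)
  shift <- 1.5  # keeps the slab off the periodic boundary
  f2 <- particle_frame(sweep(bf$frame$positions, 2, c(0, 0, shift), "+"),
                       bf$frame$charges, bf$frame$labels, bf$frame$box)
  expect_equal(leaflet_bounds(f2), b0 + shift, tolerance = 1e-9)
})

test_that("a single flat head sheet is rejected as unsplittable", {
  n <- 100
  pos <- cbind(runif(n, 0, 10), runif(n, 0, 10), rnorm(n, 5, 0.05))
  f <- particle_frame(pos, rep(0, n), rep("HEAD+", n), c(10, 10, 10))
  expect_error(leaflet_bounds(f), "manually")
})

test_that("profiles round-trip through their CSV representation", {
  f <- make_charged_slab_frame(0.2, 3, seed = 19)
  rho <- charge_density_profile(f, 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(rho, path)
  back <- read_profile_csv(path)
  expect_equal(back$values, rho$values, tolerance = 1e-12)
  expect_equal(back$kind, "charge_density")
  expect_equal(profile_centers(back), profile_centers(rho), tolerance = 1e-12)
})
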