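test_that("walk steps have the diffusion-derived standard deviation", {
  cfg <- tiny_cfg()
  set.seed(5)
  w <- simulate_walk(cfg, D = 1)
  steps <- diff(w)
  # sigma = sqrt(2 * D * dt_fine) = 0.2 um at D = 1, dt = 20 us
  expect_equal(sd(as.vector(steps)), 0.2, tolerance = 0.02)
  expect_equal(colMeans(steps), c(0, 0, 0), tolerance = 0.02)
  w0 <- simulate_walk(cfg, D = 0)
  expect_true(all(w0 == 0))
})

test_that("mean squared displacement follows the 3-D diffusion law", {
  cfg <- tiny_cfg()
  set.seed(6)
  msd <- replicate(300, sum(simulate_walk(cfg, D = 1)[401, ]^2))
  # final position after t = 8 ms: E|X|^2 = 6 D t = 48 um^2 (se ~ 4.7%)
  expect_equal(mean(msd), 48, tolerance = 0.2)
})

test_that("static single-cylinder phase matches the closed form", {
  cfg <- tiny_cfg()
  n_fine <- qboldsim:::.cfg_counts(cfg)$n_fine
  basis <- test_basis()
  # r = 2 Rc, theta = 90 deg, phi = 0: kernel = 0.25, so each 2 ms bin
  # accrues 2*pi*gamma*B0*(1-Y)*Hct*dchi * 0.25 * 2e-3 = 0.108913 rad
  fx <- single_cylinder_fixture(Rc = 5, r = 10, theta = pi / 2, phi = 0)
  walk <- matrix(rep(fx$point, each = n_fine + 1), n_fine + 1, 3)
  ph <- accrue_phase(walk, fx$system, basis, cfg)
  expect_equal(ph, rep(0.1089127, 4), tolerance = 1e-5)
  # axis parallel to B0: sin^2(theta) = 0
  fx0 <- single_cylinder_fixture(Rc = 5, r = 10, theta = 0, phi = 0)
  walk0 <- matrix(rep(fx0$point, each = n_fine + 1), n_fine + 1, 3)
  expect_equal(accrue_phase(walk0, fx0$system, basis, cfg), rep(0, 4))
  # phi = 45 deg: cos(2 phi) = 0
  fx45 <- single_cylinder_fixture(Rc = 5, r = 10, theta = pi / 2,
                                  phi = pi / 4)
  walk45 <- matrix(rep(fx45$point, each = n_fine + 1), n_fine + 1, 3)
  expect_equal(accrue_phase(walk45, fx45$system, basis, cfg), rep(0, 4),
               tolerance = 1e-12)
})

test_that("phase is exactly linear in 1 - Y", {
  cfg <- tiny_cfg()
  sys <- small_system(seed = 31)
  set.seed(32)
  walk <- simulate_walk(cfg, D = 0.1)
  walk <- walk + rep(c(30, 0, 0), each = nrow(walk))
  ph1 <- accrue_phase(walk, sys, test_basis(Y = 0.6), cfg)
  ph2 <- accrue_phase(walk, sys, test_basis(Y = 0.2), cfg)
  expect_equal(ph2, 2 * ph1, tolerance = 1e-12)
})

test_that("proximity refinement is consistent with an all-fine evaluation", {
  cfg_coarse <- tiny_cfg()
  cfg_fine <- walk_config(dt_fine = 0.02, dt_coarse = 0.02, dt_store = 2,
                          duration = 8, n_protons_total = 20,
                          n_protons_keep = 10)
  basis <- test_basis()
  fx <- single_cylinder_fixture(Rc = 5, r = 12, theta = pi / 3, phi = 0.4)
  # proximal walk (r ~ 12 < 5 Rc): every interval is refined to the fine
  # grid, so both configurations evaluate identical positions
  set.seed(33)
  walk <- simulate_walk(cfg_coarse, D = 0.1)
  walk <- walk + rep(fx$point, each = nrow(walk))
  expect_equal(accrue_phase(walk, fx$system, basis, cfg_coarse),
               accrue_phase(walk, fx$system, basis, cfg_fine),
               tolerance = 1e-9)
  # distant static proton: coarse and fine grids see the same position
  fx_far <- single_cylinder_fixture(Rc = 5, r = 40, theta = pi / 3,
                                    phi = 0.4)
  wstat <- matrix(rep(fx_far$point, each = nrow(walk)), nrow(walk), 3)
  expect_equal(accrue_phase(wstat, fx_far$system, basis, cfg_coarse),
               accrue_phase(wstat, fx_far$system, basis, cfg_fine),
               tolerance = 1e-9)
})

test_that("vessel entry is detected and entered protons carry no phase", {
  cfg <- tiny_cfg()
  n_fine <- qboldsim:::.cfg_counts(cfg)$n_fine
  # cylinder axis along x (theta = pi/2); perpendicular plane is y-z
  fx <- single_cylinder_fixture(Rc = 5, r = 20, theta = pi / 2, phi = 0)
  # straight-line walk crossing the cylinder interior perpendicular to it
  tpath <- seq(-20, 20, length.out = n_fine + 1)
  crossing <- cbind(0, tpath, 0)
  expect_true(detect_entry(crossing, fx$system, cfg))
  expect_error(accrue_phase(crossing, fx$system, test_basis(), cfg),
               "entered")
  # distant static proton never enters
  far <- matrix(rep(c(0, 40, 0), each = n_fine + 1), n_fine + 1, 3)
  expect_false(detect_entry(far, fx$system, cfg))
  # a proton starting inside the vessel is flagged immediately
  inside <- matrix(rep(c(0, 1, 0), each = n_fine + 1), n_fine + 1, 3)
  expect_true(detect_entry(inside, fx$system, cfg))
})

test_that("populations are reproducible and archives round-trip exactly", {
  cfg <- walk_config(duration = 20, n_protons_total = 30,
                     n_protons_keep = 10)
  a1 <- run_population(5, 0.02, cfg, seed = 77, Rs = 80)
  a2 <- run_population(5, 0.02, cfg, seed = 77, Rs = 80)
  expect_identical(a1$increments, a2$increments)
  expect_identical(a1$n_discarded, a2$n_discarded)
  expect_equal(dim(a1$increments), c(10, 10))
  expect_true(all(is.finite(a1$increments)))
  path <- tempfile(fileext = ".rds")
  write_archive(a1, path)
  expect_identical(read_archive(path)$increments, a1$increments)
})

test_that("a population without enough clean protons signals an error", {
  cfg <- walk_config(duration = 20, n_protons_total = 4,
                     n_protons_keep = 4)
  expect_error(run_population(5, 0.5, cfg, seed = 3, Rs = 20),
               "clean protons")
})
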