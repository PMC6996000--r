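test_that("protocol timings map to the expected storage-grid indices", {
  idx <- qboldsim:::.protocol_indices(
    sequence_protocol("ASE", tE = 80, tau = 16), 16, 2, 60)
  expect_identical(idx$m, 16L)   # (80 - 16) / (2 * 2)
  expect_identical(idx$n, 40L)   # 80 / 2
  idx <- qboldsim:::.protocol_indices(
    sequence_protocol("GESSE", tSE = 60, tau = 4), 4, 2, 60)
  expect_identical(idx$m, 15L)   # 60 / (2 * 2)
  expect_identical(idx$n, 32L)   # (60 + 4) / 2
  # off-grid timings are rejected, never interpolated
  expect_error(qboldsim:::.protocol_indices(
    sequence_protocol("ASE", tE = 80, tau = 3), 3, 2, 60), "storage grid")
  expect_error(qboldsim:::.protocol_indices(
    sequence_protocol("ASE", tE = 80, tau = 16), 16, 2, 30),
    "beyond the archived")
})

test_that("static protons recombine to phi(tau) = -omega * tau", {
  cfg <- walk_config(duration = 120)
  omega <- c(0.02, -0.013, 0.005)
  arch <- static_phase_archive(omega, cfg)
  prot <- sequence_protocol("ASE", tE = 80, tau = c(-16, 0, 16, 40))
  phi <- recombine(arch, prot)
  expect_equal(phi, outer(omega, -c(-16, 0, 16, 40)), tolerance = 1e-12)
})

test_that("ASE signal from static protons is exactly symmetric in tau", {
  arch <- static_phase_archive(seq(-0.05, 0.05, length.out = 41))
  tau <- seq(-60, 60, 12)
  prot <- sequence_protocol("ASE", tE = 60, tau = tau)
  s <- extravascular_signal(arch, prot)
  expect_equal(s$magnitude, rev(s$magnitude), tolerance = 1e-12)
  expect_equal(s$magnitude[tau == 0], 1)  # full refocusing at the echo
})

test_that("oxygenation scaling is exact and the nominal target is a no-op", {
  arch <- small_archive()
  prot <- sequence_protocol("ASE", tE = 60, tau = seq(-40, 40, 8))
  s_nom <- extravascular_signal(arch, prot)
  s_same <- extravascular_signal(arch, prot, Y_target = arch$basis$Y)
  expect_identical(s_nom$magnitude, s_same$magnitude)
  # scaling to Y = 1 removes all susceptibility dephasing
  s_oxy <- extravascular_signal(arch, prot, Y_target = 1)
  expect_equal(s_oxy$magnitude, rep(1, length(prot$tau)))
  # deoxygenation only deepens the attenuation
  s_deoxy <- extravascular_signal(arch, prot, Y_target = 0.3)
  expect_true(all(s_deoxy$magnitude <= s_nom$magnitude + 1e-12))
})

test_that("a single proton always has unit magnitude", {
  arch <- static_phase_archive(0.037)
  prot <- sequence_protocol("ASE", tE = 60, tau = seq(-60, 60, 12))
  s <- extravascular_signal(arch, prot)
  expect_equal(s$magnitude, rep(1, length(prot$tau)))
})

test_that("volume scaling follows the log-magnitude rule", {
  arch <- small_archive()
  prot <- sequence_protocol("ASE", tE = 60, tau = seq(0, 40, 8))
  s <- extravascular_signal(arch, prot)
  expect_equal(scale_volume(s, 0.03, 0.03)$magnitude, s$magnitude)
  expect_equal(scale_volume(s, 0.03, 0.06)$magnitude, s$magnitude^2,
               tolerance = 1e-12)
  s_t2 <- extravascular_signal(arch, prot, T2_t = 80, apply_t2 = TRUE)
  expect_error(scale_volume(s_t2, 0.03, 0.06), "T2")
})

test_that("multi-radius combination is a pointwise product", {
  arch <- small_archive()
  prot <- sequence_protocol("ASE", tE = 60, tau = seq(0, 40, 8))
  s <- extravascular_signal(arch, prot)
  expect_equal(combine_radii(list(s))$magnitude, s$magnitude)
  # two copies at Vf each equal one copy at 2 Vf
  both <- combine_radii(list(s, s))
  expect_equal(both$magnitude, scale_volume(s, arch$Vf, 2 * arch$Vf)$magnitude,
               tolerance = 1e-12)
  expect_true(all(both$magnitude <= s$magnitude))
  prot2 <- sequence_protocol("ASE", tE = 60, tau = seq(0, 32, 8))
  s2 <- extravascular_signal(arch, prot2)
  expect_error(combine_radii(list(s, s2)), "grids")
})

test_that("total signal interpolates between compartments", {
  arch <- small_archive()
  prot <- sequence_protocol("ASE", tE = 60, tau = seq(0, 40, 8))
  ev <- extravascular_signal(arch, prot, T2_t = 80, apply_t2 = TRUE)
  iv <- intravascular_signal(prot, blood_params_from(0.6))
  expect_equal(total_signal(ev, iv, 0)$magnitude, ev$magnitude)
  expect_equal(total_signal(ev, iv, 1)$magnitude, iv$magnitude)
  tot <- total_signal(ev, iv, 0.03)
  expect_true(all(abs(tot$magnitude - ev$magnitude) <=
                    0.03 * abs(iv$magnitude - ev$magnitude) + 1e-12))
})

test_that("diffusion changes map to equivalent radii", {
  expect_equal(equivalent_radius(5, 1, 2), 5 * sqrt(2), tolerance = 1e-12)
  expect_identical(equivalent_radius(7.3, 1.4, 1.4), 7.3)
  # grey-matter upper diffusivity 1.09 um^2/ms: +4.4% radius
  expect_equal(100 * (equivalent_radius(1, 1, 1.09) - 1), 4.4,
               tolerance = 0.01)
})

test_that("ASE symmetry survives diffusion within Monte Carlo error", {
  arch <- small_archive()
  tau <- seq(-48, 48, 8)
  prot <- sequence_protocol("ASE", tE = 60, tau = tau)
  s <- extravascular_signal(arch, prot)
  # P = 150 protons: allow a 2% asymmetry band
  expect_lt(max(abs(s$magnitude - rev(s$magnitude))), 0.02)
})

test_that("GESSE with diffusion shifts signal towards negative tau", {
  arch <- small_archive()
  tau <- seq(8, 24, 8)  # |tau| <= tSE/2 keeps acquisition after refocusing
  gp <- sequence_protocol("GESSE", tSE = 60, tau = c(-tau, tau))
  s <- extravascular_signal(arch, gp)
  neg <- s$magnitude[seq_along(tau)]
  pos <- s$magnitude[length(tau) + seq_along(tau)]
  # at Rc = 5 um diffusion makes the pre-echo signal exceed the post-echo
  expect_gt(mean(neg - pos), 0)
})

test_that("signal curves round-trip through CSV and JSON", {
  arch <- small_archive()
  prot <- sequence_protocol("ASE", tE = 60, tau = seq(0, 40, 8))
  s <- extravascular_signal(arch, prot)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".json")
  write_signal_curve(s, p1, "csv")
  write_signal_curve(s, p2, "json")
  b1 <- read_signal_curve(p1, "csv")
  b2 <- read_signal_curve(p2, "json")
  expect_equal(b1$magnitude, s$magnitude, tolerance = 1e-12)
  expect_equal(b2$magnitude, s$magnitude, tolerance = 1e-12)
  expect_identical(attr(b1, "compartment"), "extravascular")
  expect_identical(attr(b2, "t2_applied"), FALSE)
})

test_that("diffusion-radius equivalence is an exact rescaling of the model", {
  # scaling space by sqrt(k) and D by k leaves the dimensionless field
  # kernel and every seeded draw invariant, so tau_D-equivalent
  # populations on one master seed are identical, not merely close
  cfg <- walk_config(duration = 20, n_protons_total = 40,
                     n_protons_keep = 20)
  p1 <- default_params()                 # D = 1
  a1 <- run_population(20, 0.03, cfg, p1, seed = 61)
  p2 <- default_params(); p2$blood$D <- 2
  a2 <- run_population(equivalent_radius(20, 1, 2), 0.03, cfg, p2,
                       seed = 61)
  expect_equal(a2$increments, a1$increments, tolerance = 1e-12)
  expect_identical(a2$n_discarded, a1$n_discarded)
})
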