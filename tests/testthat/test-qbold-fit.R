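test_that("the SDR R2' relation and its inverse are consistent", {
  expect_equal(sdr_r2p(0, 0.03, 0.4), 0)
  expect_equal(sdr_r2p(0.4, 0.06, 0.4), 2 * sdr_r2p(0.4, 0.03, 0.4))
  expect_equal(sdr_r2p(0.4, 0.03, 0.4), 4.3565, tolerance = 1e-4)
  # round trip through the OEF inversion is exact
  r2p <- sdr_r2p(0.37, 0.021, 0.43)
  expect_equal(oef_from_fit(r2p, 0.021, 0.43), 0.37, tolerance = 1e-12)
  expect_equal(oef_from_fit(4.3565, 0.03, 0.4), 0.40, tolerance = 1e-4)
  expect_equal(oef_from_fit(0, 0.03, 0.4), 0)
  expect_error(oef_from_fit(4, 0, 0.4), "undefined")
})

test_that("the forward model switches regimes at 1.5 V0 / R2p", {
  S0 <- 1; R2 <- 12.5; R2p <- 4.3565; V0 <- 0.03
  expect_equal(sdr_signal(0, 80, S0, R2, R2p, V0), S0 * exp(-0.08 * R2))
  # threshold ~ 10.33 ms for these parameters
  thr <- 1.5 * V0 / R2p * 1000
  expect_equal(thr, 10.33, tolerance = 1e-3)
  s_lo <- sdr_signal(thr - 0.5, 80, S0, R2, R2p, V0)
  expect_equal(log(s_lo) - log(S0 * exp(-0.08 * R2)),
               -0.3 * ((thr - 0.5) / 1000)^2 * R2p^2 / V0)
  # beyond the threshold the log-signal is linear in tau with slope -R2p
  s1 <- sdr_signal(20, 80, S0, R2, R2p, V0)
  s2 <- sdr_signal(50, 80, S0, R2, R2p, V0)
  expect_equal(log(s2) - log(s1), -R2p * 0.030, tolerance = 1e-12)
})

test_that("the estimator recovers ideal SDR curves exactly", {
  prot <- protocol_ase80()
  for (pars in list(c(4.3565, 0.03), c(2.2, 0.01), c(6.8, 0.05))) {
    curve <- ideal_sdr_curve(R2p = pars[1], V0 = pars[2], protocol = prot)
    est <- fit_qbold(curve)
    expect_equal(est$R2p, pars[1], tolerance = 1e-10)
    expect_equal(est$DBV, pars[2], tolerance = 1e-10)
    expect_equal(percentage_error_dbv(est$DBV, pars[2]), 0,
                 tolerance = 1e-7)
  }
})

test_that("fits are invariant to overall signal scaling", {
  prot <- protocol_ase80()
  curve <- ideal_sdr_curve(R2p = 4.3565, V0 = 0.03, protocol = prot)
  scaled <- curve
  scaled$magnitude <- curve$magnitude * 7.3
  e1 <- fit_qbold(curve); e2 <- fit_qbold(scaled)
  expect_equal(e2$R2p, e1$R2p, tolerance = 1e-10)
  expect_equal(e2$DBV, e1$DBV, tolerance = 1e-10)
})

test_that("a flat curve yields zero R2' and zero DBV", {
  prot <- protocol_ase80()
  est <- fit_qbold(data.frame(tau = prot$tau,
                              magnitude = rep(0.5, length(prot$tau))))
  expect_equal(est$R2p, 0, tolerance = 1e-12)
  expect_equal(est$DBV, 0, tolerance = 1e-12)
})

test_that("DBV always equals the intercept gap and the echo row is exact", {
  prot <- protocol_ase80()
  set.seed(9)
  # noisy, model-violating curve: the identities must still hold
  mag <- exp(-0.002 * prot$tau - 0.2 + rnorm(length(prot$tau), sd = 0.02))
  est <- fit_qbold(data.frame(tau = prot$tau, magnitude = mag))
  expect_equal(est$DBV, est$ln_S_extrap0 - est$ln_S_meas0,
               tolerance = 1e-12)
  expect_equal(est$ln_S_meas0, log(mag[prot$tau == 0]), tolerance = 1e-12)
  expect_true(is.finite(est$se_R2p) && is.finite(est$se_DBV))
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_qbold(data.frame(tau = c(4, 20, 40),
                                    magnitude = c(1, 0.9, 0.8))),
               "tau = 0")
  expect_error(fit_qbold(data.frame(tau = c(0, 20), magnitude = c(1, 0.9))),
               "at least two")
  expect_error(fit_qbold(data.frame(tau = c(0, 20, 40),
                                    magnitude = c(1, -0.9, 0.8))),
               "non-positive")
})

test_that("DBV decomposition sums exactly and vanishes at the reference", {
  prot <- protocol_ase80()
  mk <- function(r2p, v0, atten) {
    m <- sdr_signal(prot$tau, 80, 1, 12.5, r2p, v0)
    m[prot$tau == 0] <- m[prot$tau == 0] * exp(-atten)
    data.frame(tau = prot$tau, magnitude = m)
  }
  curves <- list("20" = mk(4, 0.03, 0.03), "1000" = mk(4.36, 0.03, 0))
  ests <- lapply(curves, fit_qbold)
  dec <- decompose_dbv(curves, ests, 1000)
  expect_equal(dec$attenuation_term[dec$radius == 1000], 0)
  expect_equal(dec$attenuation_term + dec$intercept_term,
               dec$apparent_dbv, tolerance = 1e-12)
  expect_equal(dec$attenuation_term[dec$radius == 20], 0.03,
               tolerance = 1e-10)
  expect_error(decompose_dbv(curves, ests, 77), "reference")
})

test_that("estimates serialize to JSON", {
  est <- fit_qbold(ideal_sdr_curve(4.3565, 0.03, protocol = protocol_ase80()))
  path <- tempfile(fileext = ".json")
  write_estimate(est, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$R2p, est$R2p, tolerance = 1e-12)
  expect_equal(back$DBV, est$DBV, tolerance = 1e-12)
})
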