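# Event kinetics: the logistic distance effect, activity decay, regimen
# probabilities, the RMSD objective and the calibration fitters.

test_that("logistic solution honours its boundary conditions and the ODE", {
  p <- logistic_params(K = 0.4, r = 0.02, phi0 = 0.02)
  expect_equal(logistic_phi(0, p), 0.02)
  expect_lt(abs(logistic_phi(2000, p) - 0.4), 1e-6)
  expect_error(logistic_phi(-1, p), "non-negative")
  expect_error(logistic_params(K = 0, r = 0.1, phi0 = 0.2), "\\(0, 1\\]")
  expect_error(logistic_params(K = 0.5, r = -1, phi0 = 0.2), "positive")

  set.seed(21)
  for (i in 1:10) {
    K <- runif(1, 0.1, 1)
    phi0 <- runif(1, 0.01, 0.9)
    r <- runif(1, 0.002, 0.05)
    pp <- logistic_params(K = K, r = r, phi0 = phi0)
    sol <- deSolve::lsoda(
      y = c(phi = phi0), times = c(0, 150),
      func = function(t, y, parms) list(r * y * (1 - y / K)),
      rtol = 1e-12, atol = 1e-12
    )
    expect_lt(abs(logistic_phi(150, pp) - sol[2, "phi"]), 1e-8)
  }
})

test_that("activity decay starts at one and halves at eleven days", {
  p <- decay_params()
  expect_equal(zeta(0, p), 1)
  expect_equal(zeta(11, p), 0.5)
  t <- seq(0, 30, by = 0.5)
  expect_true(all(diff(zeta(t, p)) < 0))
  expect_error(zeta(-1, p), "non-negative")
  # printed decay-constant magnitude is available as a switch
  expect_equal(zeta(1, decay_params(lambda = 0.06)), exp(-0.06))
})

test_that("regimen probabilities collapse to the analytic limits", {
  cp <- control_params()
  mit <- default_mitosis_logistic()
  apop <- default_apoptosis_logistic()
  dk <- decay_params()
  d <- c(0, 50, 150, 400, 900)
  expect_equal(p_mitosis("Control", d, 3), rep(0.4, 5))
  expect_equal(p_apoptosis("Control", d, 3), rep(0.1, 5))
  # zeta = 1 at t = 0: exactly the distance profile
  expect_lt(max(abs(p_mitosis("Rad223", d, 0) - logistic_phi(d, mit))), 1e-12)
  expect_lt(max(abs(p_apoptosis("Rad223", d, 0) - logistic_phi(d, apop))), 1e-12)
  # at the bone interface on day 0 apoptosis is quadrupled
  expect_equal(p_apoptosis("Rad223", 0, 0), 0.4)
  # zeta -> 0: the control rates
  expect_lt(max(abs(p_mitosis("Rad223", d, 1e6) - cp$alpha1)), 1e-12)
  expect_lt(max(abs(p_apoptosis("Rad223", d, 1e6) - cp$alpha2)), 1e-12)
})

test_that("therapy is strongest near the bone and early", {
  d <- seq(0, 600, by = 10)
  t <- seq(0, 15, by = 0.5)
  for (tt in c(0, 4, 10)) {
    expect_true(all(diff(p_mitosis("Rad223", d, tt)) >= 0))
    expect_true(all(diff(p_apoptosis("Rad223", d, tt)) <= 0))
  }
  for (dd in c(20, 100, 300)) {
    expect_true(all(diff(p_mitosis("Rad223", dd, t)) >= 0))
    expect_true(all(diff(p_apoptosis("Rad223", dd, t)) <= 0))
  }
  expect_true(all(p_mitosis("Rad223", d, 0) > 0 &
                  p_mitosis("Rad223", d, 0) <= 1))
})

test_that("an apoptosis floor below the control rate is rejected with diagnostics", {
  bad <- logistic_params(K = 0.05, r = 0.01, phi0 = 0.4) # falls below alpha2
  expect_error(p_apoptosis("Rad223", 1500, 0, apoptosis = bad), "phi_apop")
  expect_error(control_params(0.95, 0.15), "exceeds 1")
})

test_that("compiled and R kinetics agree", {
  p <- osteosim:::params_to_cpp(sim_params(), "Rad223")
  for (d in c(0, 35, 120, 400)) {
    for (t in c(0, 2.5, 11)) {
      v <- osteosim:::cpp_event_probs(d, t, p)
      expect_equal(unname(v["p_mit"]), p_mitosis("Rad223", d, t), tolerance = 1e-12)
      expect_equal(unname(v["p_apop"]), p_apoptosis("Rad223", d, t), tolerance = 1e-12)
    }
  }
})

test_that("rmsd has a canonical and a literal per-point mode", {
  expect_equal(rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsd(c(1, 2, 3), c(1, 2, 3), "literal"), 0)
  expect_equal(rmsd(0.7, 0.2), 0.5)
  expect_equal(rmsd(0.7, 0.2, "literal"), 0.5)
  expect_equal(rmsd(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_equal(rmsd(c(3, 4), c(0, 0), "literal"), 7 / sqrt(2))
  expect_error(rmsd(numeric(0), numeric(0)), "empty")
  expect_error(rmsd(1:3, 1:2), "lengths differ")
})

test_that("fixture generator is exact at zero noise and reproducible", {
  truth <- logistic_params(K = 0.8, r = 0.01, phi0 = 0.2)
  s0 <- generate_calibration_fixture(truth, n = 15, noise_sd = 0, seed = 4)
  expect_equal(s0$y, logistic_phi(s0$x, truth))
  expect_equal(range(s0$x), c(0, 500))
  s1 <- generate_calibration_fixture(truth, n = 15, noise_sd = 0.05, seed = 9)
  s2 <- generate_calibration_fixture(truth, n = 15, noise_sd = 0.05, seed = 9)
  expect_identical(s1, s2)
  dk <- decay_params()
  sd0 <- generate_calibration_fixture(dk, n = 10, noise_sd = 0, seed = 1)
  expect_equal(range(sd0$x), c(0, 15))
  expect_equal(sd0$y, zeta(sd0$x, dk))
})

test_that("fixture noise is centred for a mid-range truth", {
  truth <- logistic_params(K = 0.75, r = 0.01, phi0 = 0.25)
  set.seed(31)
  res <- replicate(400, {
    s <- generate_calibration_fixture(truth, n = 20, noise_sd = 0.05)
    mean(s$y - logistic_phi(s$x, truth))
  })
  se <- sd(res) / sqrt(length(res))
  expect_lt(abs(mean(res)), 3 * se + 1e-4)
})

test_that("logistic fit recovers noise-free truth within one percent", {
  truth <- logistic_params(K = 0.4, r = 0.02, phi0 = 0.02)
  s <- generate_calibration_fixture(truth, n = 20, noise_sd = 0, seed = 5)
  fit <- fit_logistic(s, seed = 17)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$params$K / truth$K - 1), 0.01)
  expect_lt(abs(fit$params$r / truth$r - 1), 0.01)
  expect_lt(abs(fit$params$phi0 / truth$phi0 - 1), 0.01)
  expect_lt(fit$rmsd, 1e-4)
  # the decreasing branch is recovered too
  truth2 <- default_apoptosis_logistic()
  s2 <- generate_calibration_fixture(truth2, n = 20, noise_sd = 0, seed = 6)
  fit2 <- fit_logistic(s2, seed = 18)
  expect_lt(abs(fit2$params$phi0 / truth2$phi0 - 1), 0.01)
  expect_lt(abs(fit2$params$K / truth2$K - 1), 0.01)
})

test_that("degenerate calibration tables give a flagged flat fit", {
  flat <- tibble::tibble(x = c(0, 100, 200, 300), y = rep(0.3, 4))
  expect_warning(fit <- fit_logistic(flat), "flat")
  expect_true(fit$degenerate)
  expect_equal(fit$rmsd, 0)
  expect_error(fit_logistic(tibble::tibble(x = c(0, 0, 0), y = c(0.1, 0.2, 0.3))),
               "distinct distances")
  expect_warning(fd <- fit_decay(tibble::tibble(x = c(0, 0), y = c(1, 0.9))),
                 "degenerate")
  expect_true(fd$degenerate)
})

test_that("decay fit recovers the half-life", {
  truth <- decay_params()
  s <- generate_calibration_fixture(truth, n = 12, noise_sd = 0, seed = 8)
  fit <- fit_decay(s, seed = 19)
  expect_lt(abs(fit$params$lambda / truth$lambda - 1), 0.01)
  expect_lt(abs(fit$params$R0 / truth$R0 - 1), 0.01)
  expect_equal(fit$half_life, log(2) / fit$params$lambda)
  expect_lt(abs(fit$half_life - 11), 0.2)
  expect_equal(glance(fit)$degenerate, FALSE)
  expect_equal(tidy(fit)$term, c("R0", "lambda", "half_life"))
})

test_that("noisy fits stay within twice the noise level", {
  truth <- logistic_params(K = 0.4, r = 0.02, phi0 = 0.02)
  set.seed(23)
  for (i in 1:5) {
    s <- generate_calibration_fixture(truth, n = 20, noise_sd = 0.02)
    fit <- fit_logistic(s, seed = i)
    expect_lte(fit$rmsd, 0.04)
  }
})
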