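# Event kinetics: control probabilities, the logistic distance effect of
# Radium-223, exponential activity decay, the RMSD objective, and calibration
# of the logistic / decay models by seeded global search plus local
# refinement. A fixture generator produces synthetic calibration tables.

#' Control-regimen event probabilities
#'
#' Daily mitosis and apoptosis probabilities of an untreated cell, uniform
#' across the lesion.
#'
#' @param alpha1 Daily mitosis probability (default 0.4).
#' @param alpha2 Daily apoptosis probability (default 0.1).
#' @return A `control_params` object.
#' @export
control_params <- function(alpha1 = 0.4, alpha2 = 0.1) {
  if (alpha1 < 0 || alpha2 < 0) abort("alpha1 and alpha2 must be non-negative")
  if (alpha1 + alpha2 > 1) {
    abort(sprintf("alpha1 + alpha2 = %.3f exceeds 1; a cell has one fate per cycle",
                  alpha1 + alpha2))
  }
  structure(list(alpha1 = alpha1, alpha2 = alpha2), class = "control_params")
}

#' Logistic distance-effect parameters
#'
#' Parameters of the logistic solution `phi(d)` describing the day-0 effect
#' of Radium-223 as a function of distance from the bone interface.
#'
#' @param K Asymptote (probability, far from bone).
#' @param r Rate per micrometre.
#' @param phi0 Value at distance zero (at the bone interface).
#' @return A `logistic_params` object.
#' @export
logistic_params <- function(K, r, phi0) {
  if (K <= 0 || K > 1 || phi0 <= 0 || phi0 > 1) {
    abort("K and phi0 must lie in (0, 1]")
  }
  if (r <= 0) abort("rate r must be positive")
  structure(list(K = K, r = r, phi0 = phi0), class = "logistic_params")
}

#' Default mitosis distance effect
#'
#' Near the bone mitosis is almost abolished (phi0 = 0.02); far from the bone
#' it recovers the control rate (K = alpha1 = 0.4), with the transition in
#' the 100-300 um band (r = 0.02 per um) so that the therapeutic effect is
#' essentially lost beyond ~400 um.
#' @return A `logistic_params` object.
#' @export
default_mitosis_logistic <- function() logistic_params(K = 0.4, r = 0.02, phi0 = 0.02)

#' Default apoptosis distance effect
#'
#' Near the bone apoptosis is almost quadrupled relative to control
#' (phi0 = 0.4 = 4 * alpha2); far from the bone it decays to the control rate
#' (K = alpha2 = 0.1). The rate is anchored on the loss of any therapeutic
#' effect beyond 400 um: r = 0.005 per um puts phi_apop(400) within about
#' 10% of alpha2. (The decreasing branch of the logistic steepens towards
#' d = 0, so its rate must be much smaller than the mitotic one for the
#' transition to span the same distance band.)
#' @return A `logistic_params` object.
#' @export
default_apoptosis_logistic <- function() logistic_params(K = 0.1, r = 0.005, phi0 = 0.4)

#' Radium-223 activity decay parameters
#'
#' Activity is 1 at administration and decays exponentially; the default rate
#' `ln(2) / 11` per day encodes the 11-day half-life. Pass `lambda = 0.06`
#' for the printed decay-constant magnitude instead.
#'
#' @param R0 Initial activity in (0, 1]; default 1.
#' @param lambda Decay rate per day; default `log(2) / 11` (about 0.063).
#' @return A `decay_params` object.
#' @export
decay_params <- function(R0 = 1, lambda = log(2) / 11) {
  if (R0 <= 0 || R0 > 1) abort("R0 must lie in (0, 1]")
  if (lambda <= 0) abort("decay rate lambda must be positive")
  structure(list(R0 = R0, lambda = lambda), class = "decay_params")
}

#' Logistic distance effect
#'
#' Closed-form solution of the logistic growth equation
#' `phi'(d) = r * phi(d) * (1 - phi(d) / K)` with `phi(0) = phi0`:
#' `phi(d) = K / (1 + ((K - phi0) / phi0) * exp(-r d))`. Monotone from
#' `phi0` at the bone interface towards the asymptote `K`.
#'
#' @param d Distance from the bone interface in micrometres (vectorised,
#'   non-negative).
#' @param p A [logistic_params()] object.
#' @return Probabilities in (0, 1].
#' @export
logistic_phi <- function(d, p) {
  stopifnot(inherits(p, "logistic_params"))
  if (any(d < 0)) abort("distance d must be non-negative")
  p$K / (1 + ((p$K - p$phi0) / p$phi0) * exp(-p$r * d))
}

#' Radium-223 activity at time t
#'
#' @param t Time since administration in days (vectorised, non-negative).
#' @param p A [decay_params()] object.
#' @return Activity fraction `R0 * exp(-lambda t)`, strictly decreasing.
#' @export
#' @examples
#' zeta(0, decay_params())   # 1
#' zeta(11, decay_params())  # 0.5 (half-life)
zeta <- function(t, p = decay_params()) {
  stopifnot(inherits(p, "decay_params"))
  if (any(t < 0)) abort("time t must be non-negative")
  p$R0 * exp(-p$lambda * t)
}

#' Mitosis probability of a cell
#'
#' Control: the uniform daily probability `alpha1`. Radium-223: the
#' activity-modulated interpolation
#' `alpha1 / (1 + (alpha1 / phi_mit(d_min) - 1) * zeta(t))`, which equals
#' `phi_mit(d_min)` at administration (`zeta = 1`) and relaxes to `alpha1`
#' as the activity decays.
#'
#' @param regimen `"Control"` or `"Rad223"`.
#' @param d_min Minimum distance from the cell to the bone, micrometres
#'   (vectorised).
#' @param t Time since administration, days.
#' @param control A [control_params()] object.
#' @param mitosis A [logistic_params()] object for the mitotic distance effect.
#' @param decay A [decay_params()] object.
#' @return Probability in (0, 1].
#' @export
p_mitosis <- function(regimen, d_min, t, control = control_params(),
                      mitosis = default_mitosis_logistic(),
                      decay = decay_params()) {
  regimen <- match.arg(regimen, c("Control", "Rad223"))
  if (any(d_min < 0) || any(t < 0)) abort("d_min and t must be non-negative")
  if (regimen == "Control") {
    return(rep(control$alpha1, length.out = max(length(d_min), length(t))))
  }
  if (control$alpha1 == 0) {
    return(rep(0, length.out = max(length(d_min), length(t))))
  }
  phi <- logistic_phi(d_min, mitosis)
  control$alpha1 / (1 + (control$alpha1 / phi - 1) * zeta(t, decay))
}

#' Apoptosis probability of a cell
#'
#' Control: the uniform daily probability `alpha2`. Radium-223:
#' `alpha2 / (1 - (1 - alpha2 / phi_apop(d_min)) * zeta(t))`, equal to
#' `phi_apop(d_min)` at administration and relaxing to `alpha2` as the
#' activity decays. Requires `phi_apop(d) >= alpha2` so the denominator stays
#' in (0, 1].
#'
#' @inheritParams p_mitosis
#' @param apoptosis A [logistic_params()] object for the apoptotic distance
#'   effect.
#' @return Probability in `[alpha2, phi_apop(0)]`.
#' @export
p_apoptosis <- function(regimen, d_min, t, control = control_params(),
                        apoptosis = default_apoptosis_logistic(),
                        decay = decay_params()) {
  regimen <- match.arg(regimen, c("Control", "Rad223"))
  if (any(d_min < 0) || any(t < 0)) abort("d_min and t must be non-negative")
  if (regimen == "Control") {
    return(rep(control$alpha2, length.out = max(length(d_min), length(t))))
  }
  if (control$alpha2 == 0) {
    return(rep(0, length.out = max(length(d_min), length(t))))
  }
  phi <- logistic_phi(d_min, apoptosis)
  if (any(phi < control$alpha2 - 1e-12)) {
    abort(sprintf(
      paste0("phi_apop(d) = %.4f falls below alpha2 = %.3f at d = %.1f um; ",
             "the apoptotic distance effect must stay >= alpha2 so the ",
             "denominator of the treated apoptosis probability stays in (0, 1]"),
      min(phi), control$alpha2, d_min[which.min(phi)]
    ))
  }
  den <- 1 - (1 - control$alpha2 / phi) * zeta(t, decay)
  control$alpha2 / den
}

#' Root mean square deviation between model and data
#'
#' The default mode is the canonical RMSD, `sqrt(mean((model - observed)^2))`.
#' The `"literal"` mode reproduces the printed per-point form,
#' `sum(sqrt((1/N) * (model - observed)^2)) = sum(|model - observed|) / sqrt(N)`.
#'
#' @param model,observed Numeric vectors of equal length (>= 1).
#' @param mode `"rms"` (default) or `"literal"`.
#' @return Non-negative scalar.
#' @export
rmsd <- function(model, observed, mode = c("rms", "literal")) {
  mode <- match.arg(mode)
  if (length(model) == 0) abort("empty input")
  if (length(model) != length(observed)) abort("model and observed lengths differ")
  if (mode == "rms") sqrt(mean((model - observed)^2))
  else sum(abs(model - observed)) / sqrt(length(model))
}

# seeded differential evolution (rand/1/bin) over a box, then nlminb polish
de_optimize <- function(fn, lower, upper, pop = 40L, gens = 150L,
                        f_weight = 0.7, crossover = 0.9) {
  d <- length(lower)
  x <- matrix(runif(pop * d, lower, upper), nrow = pop, ncol = d, byrow = TRUE)
  fx <- apply(x, 1, fn)
  for (g in seq_len(gens)) {
    for (i in seq_len(pop)) {
      idx <- sample(setdiff(seq_len(pop), i), 3)
      v <- x[idx[1], ] + f_weight * (x[idx[2], ] - x[idx[3], ])
      v <- pmin(pmax(v, lower), upper)
      cross <- runif(d) < crossover
      cross[sample(d, 1)] <- TRUE
      u <- ifelse(cross, v, x[i, ])
      fu <- fn(u)
      if (fu <= fx[i]) {
        x[i, ] <- u
        fx[i] <- fu
      }
    }
  }
  best <- which.min(fx)
  fit <- nlminb(x[best, ], fn, lower = lower, upper = upper)
  if (fit$objective <= fx[best]) {
    list(par = fit$par, value = fit$objective)
  } else {
    list(par = x[best, ], value = fx[best])
  }
}

check_samples <- function(samples) {
  if (!all(c("x", "y") %in% names(samples))) {
    abort("calibration samples need columns `x` and `y`")
  }
  if (any(samples$x < 0)) abort("sample x values must be non-negative")
  if (any(samples$y < 0 | samples$y > 1)) abort("sample y values must lie in [0, 1]")
  samples
}

#' Fit the logistic distance effect to calibration samples
#'
#' Minimises the RMSD between the closed-form logistic and the samples over
#' (K, r, phi0) by a seeded differential-evolution global search followed by
#' local refinement.
#'
#' @param samples A data frame with columns `x` (distance, micrometres) and
#'   `y` (observed fraction in `[0, 1]`); at least 3 rows spanning at least 2
#'   distinct distances.
#' @param objective `"rms"` (canonical RMSD, default) or `"literal"`.
#' @param seed Optional integer seed for the search.
#' @return A `logistic_fit`: fitted [logistic_params()], final RMSD, the
#'   objective mode, and a `degenerate` flag (set, with a warning, when all
#'   responses are equal and a flat fit is returned).
#' @export
fit_logistic <- function(samples, objective = c("rms", "literal"), seed = NULL) {
  objective <- match.arg(objective)
  samples <- check_samples(samples)
  if (nrow(samples) < 3 || length(unique(samples$x)) < 2) {
    abort("need >= 3 samples spanning >= 2 distinct distances")
  }
  if (!is.null(seed)) set.seed(seed)
  x <- samples$x
  y <- samples$y
  if (sd(y) == 0) {
    warn("all responses equal; returning a flat logistic fit")
    level <- max(y[1], 1e-6)
    params <- logistic_params(K = level, r = 1e-4, phi0 = level)
    return(structure(
      list(params = params, rmsd = rmsd(rep(level, length(y)), y, objective),
           objective = objective, degenerate = TRUE, n = length(y)),
      class = "logistic_fit"
    ))
  }
  obj <- function(theta) {
    phi <- theta[1] / (1 + ((theta[1] - theta[3]) / theta[3]) * exp(-theta[2] * x))
    rmsd(phi, y, objective)
  }
  res <- de_optimize(obj, lower = c(1e-3, 1e-4, 1e-3), upper = c(1, 0.5, 1))
  params <- logistic_params(K = res$par[1], r = res$par[2], phi0 = res$par[3])
  structure(
    list(params = params, rmsd = res$value, objective = objective,
         degenerate = FALSE, n = length(y)),
    class = "logistic_fit"
  )
}

#' Fit the exponential activity decay to calibration samples
#'
#' Least-RMSD fit of `R0 * exp(-lambda t)` over (R0, lambda), seeded from a
#' log-linear regression and refined by bounded minimisation with random
#' multi-starts.
#'
#' @param samples A data frame with columns `x` (time, days, >= 0) and `y`
#'   (activity fraction); at least 2 rows.
#' @param objective `"rms"` or `"literal"`.
#' @param seed Optional integer seed.
#' @return A `decay_fit` with fitted [decay_params()], final RMSD, the
#'   implied half-life `ln(2) / lambda` (days), and a `degenerate` flag.
#' @export
fit_decay <- function(samples, objective = c("rms", "literal"), seed = NULL) {
  objective <- match.arg(objective)
  samples <- check_samples(samples)
  if (nrow(samples) < 2) abort("need >= 2 samples")
  if (!is.null(seed)) set.seed(seed)
  x <- samples$x
  y <- samples$y
  if (length(unique(x)) < 2 || sd(y) == 0) {
    warn("degenerate decay samples; returning a flat fit")
    level <- min(max(mean(y), 1e-6), 1)
    params <- decay_params(R0 = level, lambda = 1e-6)
    return(structure(
      list(params = params, rmsd = rmsd(rep(level, length(y)), y, objective),
           half_life = log(2) / params$lambda, objective = objective,
           degenerate = TRUE, n = length(y)),
      class = "decay_fit"
    ))
  }
  obj <- function(theta) rmsd(theta[1] * exp(-theta[2] * x), y, objective)
  lower <- c(1e-6, 1e-6)
  upper <- c(1, 5)
  starts <- list()
  pos <- y > 0
  if (sum(pos) >= 2 && length(unique(x[pos])) >= 2) {
    ll <- lm(log(y[pos]) ~ x[pos])
    starts[[1]] <- pmin(pmax(c(exp(coef(ll)[1]), -coef(ll)[2]), lower), upper)
  }
  for (i in seq_len(5)) starts[[length(starts) + 1]] <- runif(2, lower, upper)
  fits <- lapply(starts, function(s) nlminb(s, obj, lower = lower, upper = upper))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  params <- decay_params(R0 = best$par[1], lambda = best$par[2])
  structure(
    list(params = params, rmsd = best$objective,
         half_life = log(2) / params$lambda, objective = objective,
         degenerate = FALSE, n = length(y)),
    class = "decay_fit"
  )
}

#' Generate a synthetic calibration table
#'
#' Emulates the intravital-microscopy summaries used to calibrate the model:
#' a logistic-in-distance response sampled over 0-500 micrometres, or an
#' exponential-in-time activity sampled over 0-15 days, with additive
#' Gaussian noise truncated to `[0, 1]`.
#'
#' @param truth A [logistic_params()] or [decay_params()] object.
#' @param n Number of samples (>= 1).
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @param seed Optional integer seed.
#' @param x_max Upper end of the sampling grid; defaults to 500 (micrometres)
#'   for a logistic truth and 15 (days) for a decay truth.
#' @return A tibble with columns `x` and `y`.
#' @export
generate_calibration_fixture <- function(truth, n = 20, noise_sd = 0.02,
                                         seed = NULL, x_max = NULL) {
  if (n < 1) abort("n must be >= 1")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(truth, "logistic_params")) {
    if (is.null(x_max)) x_max <- 500
    x <- seq(0, x_max, length.out = n)
    mu <- logistic_phi(x, truth)
  } else if (inherits(truth, "decay_params")) {
    if (is.null(x_max)) x_max <- 15
    x <- seq(0, x_max, length.out = n)
    mu <- zeta(x, truth)
  } else {
    abort("truth must be logistic_params or decay_params")
  }
  y <- pmin(pmax(mu + rnorm(n, 0, noise_sd), 0), 1)
  tibble(x = x, y = y)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> K = %.4f, r = %.4f /um, phi0 = %.4f | RMSD (%s) = %.3g%s\n",
    x$params$K, x$params$r, x$params$phi0, x$objective, x$rmsd,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> R0 = %.4f, lambda = %.4f /day (half-life %.2f d) | RMSD (%s) = %.3g%s\n",
    x$params$R0, x$params$lambda, x$half_life, x$objective, x$rmsd,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = c("K", "r", "phi0"),
         estimate = c(x$params$K, x$params$r, x$params$phi0))
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("R0", "lambda", "half_life"),
         estimate = c(x$params$R0, x$params$lambda, x$half_life))
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(rmsd = x$rmsd, objective = x$objective, degenerate = x$degenerate,
         n = x$n)
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble(rmsd = x$rmsd, objective = x$objective, degenerate = x$degenerate,
         n = x$n)
}

#' @export
autoplot.logistic_fit <- function(object, samples = NULL, ...) {
  d <- seq(0, 500, length.out = 200)
  df <- tibble(x = d, y = logistic_phi(d, object$params))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "distance from bone (um)", y = "response fraction") +
    ggplot2::theme_minimal()
  if (!is.null(samples)) {
    p <- p + ggplot2::geom_point(data = samples, ggplot2::aes(x = .data$x, y = .data$y))
  }
  p
}
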