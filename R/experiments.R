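# Ensemble statistics and the four analyses: replicate-count selection by
# coefficient of variation, one-at-a-time sensitivity scan, NRMSE validation
# statistic, regimen comparison and the distance-dependence study.

#' Run an ensemble of independent simulations
#'
#' Member i runs with seed `base_seed + i - 1`. Eradicated members contribute
#' zero tumour size from eradication onward; boundary-arrested members are
#' retained (carrying their last size forward) but flagged.
#'
#' @param lesion A [lesion_config()].
#' @param config An [engine_config()].
#' @param params A [sim_params()] bundle.
#' @param m Number of independent simulations (>= 1).
#' @param base_seed Integer seed of the first member.
#' @return A `sim_ensemble`: sizes matrix (`m` x hours+1), normalized sizes,
#'   statuses, seeds and configuration echo.
#' @export
run_ensemble <- function(lesion, config = engine_config(),
                         params = sim_params(), m = 20, base_seed = 1) {
  stopifnot(m >= 1)
  h <- config$t_hours + 1L
  sizes <- matrix(0, nrow = m, ncol = h)
  statuses <- character(m)
  init <- NA_real_
  for (i in seq_len(m)) {
    traj <- run_simulation(lesion, config, params, seed = base_seed + i - 1L)
    k <- nrow(traj)
    sizes[i, seq_len(k)] <- traj$n_tumour
    st <- attr(traj, "status")
    statuses[i] <- st
    if (k < h) {
      # eradicated runs stay at zero; arrested runs carry the last size
      sizes[i, (k + 1L):h] <- if (st == "eradicated") 0 else traj$n_tumour[k]
    }
    init <- attr(traj, "initial_size")
  }
  structure(
    list(
      sizes = sizes,
      normalized = sizes / init,
      initial_size = init,
      statuses = statuses,
      seeds = base_seed + seq_len(m) - 1L,
      m = m,
      time_h = 0:(h - 1L),
      lesion = lesion, config = config, params = params
    ),
    class = "sim_ensemble"
  )
}

#' Mean trend of an ensemble
#'
#' @param ensemble A `sim_ensemble`.
#' @param normalized Return sizes divided by the initial size?
#' @return A tibble with `time_h`, `day`, `mean_size`.
#' @export
ensemble_mean <- function(ensemble, normalized = TRUE) {
  s <- if (normalized) ensemble$normalized else ensemble$sizes
  tibble(
    time_h = ensemble$time_h,
    day = ensemble$time_h / 24,
    mean_size = colMeans(s)
  )
}

#' @export
print.sim_ensemble <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<sim_ensemble> %d x [%d x %d] %s runs: mean final normalized %.3f (sd %.3f), eradicated %.1f%%\n",
    x$m, x$lesion$a_tumor, x$lesion$b_tumor, x$config$regimen,
    g$mean_final_norm, g$sd_final_norm, g$eradication_pct
  ))
  invisible(x)
}

#' @export
tidy.sim_ensemble <- function(x, ...) {
  m <- x$m
  h <- length(x$time_h)
  tibble(
    member = rep(seq_len(m), each = h),
    time_h = rep(x$time_h, times = m),
    day = rep(x$time_h / 24, times = m),
    n_tumour = as.vector(t(x$sizes)),
    normalized = as.vector(t(x$normalized)),
    status = rep(x$statuses, each = h)
  )
}

#' @export
glance.sim_ensemble <- function(x, ...) {
  fin <- x$normalized[, ncol(x$normalized)]
  erad <- mean(x$statuses == "eradicated")
  tibble(
    m = x$m,
    mean_final_norm = mean(fin),
    sd_final_norm = sd(fin),
    eradication_pct = 100 * erad,
    eradication_se = 100 * sqrt(erad * (1 - erad) / x$m),
    arrest_fraction = mean(x$statuses == "boundary_arrest")
  )
}

#' @export
autoplot.sim_ensemble <- function(object, max_members = 50, ...) {
  df <- tidy(object) %>% filter(.data$member <= max_members)
  mu <- ensemble_mean(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$normalized,
                                   group = .data$member)) +
    ggplot2::geom_line(alpha = 0.25, colour = "grey60") +
    ggplot2::geom_line(data = mu, ggplot2::aes(y = .data$mean_size, group = NULL),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "time (days)", y = "tumour size (normalized)") +
    ggplot2::theme_minimal()
}

#' Ensemble coefficient of variation
#'
#' For each member the root-mean-square deviation of its trajectory from the
#' ensemble mean trend is computed over all hourly points; the coefficient of
#' variation is the average of these deviations divided by the time-averaged
#' mean trend, as a percentage.
#'
#' @param ensemble A `sim_ensemble` (or a members-by-time numeric matrix).
#' @return C_V in percent.
#' @export
coefficient_of_variation <- function(ensemble) {
  s <- if (inherits(ensemble, "sim_ensemble")) ensemble$sizes else ensemble
  if (nrow(s) < 2) abort("coefficient of variation needs M >= 2 members")
  mu <- colMeans(s)
  sigma_i <- sqrt(rowMeans((s - rep(mu, each = nrow(s)))^2))
  100 * mean(sigma_i) / mean(mu)
}

#' Choose the replicate count by the C_V criterion
#'
#' Runs ensembles of increasing size and returns the smallest candidate M
#' whose coefficient of variation does not exceed the threshold. Members are
#' shared across candidates (candidate M uses the first M members of the
#' largest ensemble).
#'
#' @param lesion A [lesion_config()].
#' @param config An [engine_config()].
#' @param params A [sim_params()] bundle.
#' @param candidate_m Candidate replicate counts (default 10..100 by 10).
#' @param threshold C_V threshold in percent (default 2).
#' @param base_seed Integer seed of the first member.
#' @return A list: chosen `m`, `table` of (m, cv), and `warning` (TRUE when
#'   no candidate meets the threshold and the largest is returned).
#' @export
choose_M <- function(lesion, config = engine_config(), params = sim_params(),
                     candidate_m = seq(10, 100, by = 10), threshold = 2,
                     base_seed = 1) {
  if (length(candidate_m) == 0) abort("no candidate M values")
  candidate_m <- sort(unique(as.integer(candidate_m)))
  ens <- run_ensemble(lesion, config, params, m = max(candidate_m),
                      base_seed = base_seed)
  cv <- vapply(candidate_m, function(m) {
    coefficient_of_variation(ens$sizes[seq_len(m), , drop = FALSE])
  }, numeric(1))
  tab <- tibble(m = candidate_m, cv = cv)
  ok <- which(cv <= threshold)
  if (length(ok) > 0) {
    list(m = candidate_m[ok[1]], table = tab, warning = FALSE)
  } else {
    warn(sprintf("no candidate M reaches C_V <= %.3g%%; returning the largest",
                 threshold))
    list(m = max(candidate_m), table = tab, warning = TRUE)
  }
}

#' One-at-a-time perturbation vector
#'
#' Eleven values spanning -50% to +50% of the coefficient in 10% steps.
#'
#' @param alpha The coefficient's default value.
#' @return Numeric vector of length 11.
#' @export
#' @examples
#' perturbation_vector(0.4) # 0.20, 0.24, ..., 0.60
perturbation_vector <- function(alpha) alpha * seq(0.5, 1.5, by = 0.1)

#' Mono-parametric sensitivity scan
#'
#' One coefficient at a time is varied over its perturbation vector while the
#' other is held at its default; for each value an M-run Control ensemble is
#' run and the mean final tumour size is normalized on the baseline output
#' (alpha1 = 0.4, alpha2 = 0.1).
#'
#' @param coefficients Which coefficients to scan.
#' @param lesion A [lesion_config()] (default the `[8 x 7]` lesion).
#' @param m Replicates per value (default 20).
#' @param base_seed Integer seed.
#' @param config An [engine_config()]; the scan is run under its regimen
#'   (Control by default).
#' @param params Baseline [sim_params()].
#' @return A tibble: `coefficient`, `value`, `pct_change`, `mean_final_norm`,
#'   `normalized_output` (baseline = 1).
#' @export
sensitivity_scan <- function(coefficients = c("alpha1", "alpha2"),
                             lesion = lesion_config(8, 7), m = 20,
                             base_seed = 1, config = engine_config("Control"),
                             params = sim_params()) {
  coefficients <- match.arg(coefficients, c("alpha1", "alpha2"),
                            several.ok = TRUE)
  baseline <- run_ensemble(lesion, config, params, m = m,
                           base_seed = base_seed)
  base_mean <- glance(baseline)$mean_final_norm
  rows <- list()
  seed_off <- 1000L
  for (coef in coefficients) {
    vals <- perturbation_vector(params$control[[coef]])
    for (v in vals) {
      cp <- params$control
      cp[[coef]] <- v
      pert <- sim_params(control_params(cp$alpha1, cp$alpha2),
                         params$mitosis, params$apoptosis, params$decay)
      ens <- run_ensemble(lesion, config, pert, m = m,
                          base_seed = base_seed + seed_off)
      seed_off <- seed_off + 1000L
      rows[[length(rows) + 1]] <- tibble(
        coefficient = coef, value = v,
        pct_change = 100 * (v / params$control[[coef]] - 1),
        mean_final_norm = glance(ens)$mean_final_norm
      )
    }
  }
  bind_rows(rows) %>%
    mutate(normalized_output = .data$mean_final_norm / base_mean)
}

#' Normalized root-mean-square error between model and observed series
#'
#' `NRMSE = 100 / mean(x_m) * sqrt(sum((x_m - x_d)^2) / L)`, the validation
#' statistic comparing the model's normalized growth curve, sampled at the
#' observation days, to an observed normalized curve.
#'
#' @param x_m Model normalized sizes at the observation days.
#' @param x_d Observed normalized sizes at the same days.
#' @return NRMSE in percent.
#' @export
nrmse <- function(x_m, x_d) {
  if (length(x_m) != length(x_d)) abort("series lengths differ")
  if (length(x_m) < 1) abort("empty series")
  100 / mean(x_m) * sqrt(mean((x_m - x_d)^2))
}

#' Sample an ensemble mean trend at observation days
#'
#' @param ensemble A `sim_ensemble`.
#' @param days Observation days (default 0, 2, 5, 9, 12, 15).
#' @return A tibble with `day` and `x_m` (mean normalized size).
#' @export
sample_at_days <- function(ensemble, days = c(0, 2, 5, 9, 12, 15)) {
  mu <- ensemble_mean(ensemble)
  idx <- match(round(days * 24), mu$time_h)
  if (anyNA(idx)) abort("observation day outside the simulated follow-up")
  tibble(day = days, x_m = mu$mean_size[idx])
}

#' Compare Control and Radium-223 regimens
#'
#' Runs matched ensembles under both regimens and quantifies the therapy
#' effect on the last day of follow-up: the fold decrease (ratio of mean
#' final normalized sizes), the normalized difference (their subtraction),
#' and the eradication percentage of the treated ensemble with a binomial
#' standard error.
#'
#' @param lesion A [lesion_config()].
#' @param m Replicates per regimen.
#' @param base_seed Integer seed (treated ensemble uses `base_seed + m`).
#' @param params A [sim_params()] bundle.
#' @param follow_up_days Follow-up time in days.
#' @param daughter_clock_mode Passed to [engine_config()].
#' @return A `regimen_comparison`: one-row tibble with the control and
#'   treated means, `fold_decrease`, `normalized_difference`,
#'   `eradication_pct`, `eradication_se`, plus the two ensembles as
#'   attributes.
#' @export
compare_regimens <- function(lesion, m = 20, base_seed = 1,
                             params = sim_params(), follow_up_days = 15,
                             daughter_clock_mode = "zero") {
  ctrl <- run_ensemble(
    lesion,
    engine_config("Control", follow_up_days,
                  daughter_clock_mode = daughter_clock_mode),
    params, m = m, base_seed = base_seed
  )
  rad <- run_ensemble(
    lesion,
    engine_config("Rad223", follow_up_days,
                  daughter_clock_mode = daughter_clock_mode),
    params, m = m, base_seed = base_seed + m
  )
  gc_ <- glance(ctrl)
  gr <- glance(rad)
  fold <- if (gr$mean_final_norm == 0) Inf else
    gc_$mean_final_norm / gr$mean_final_norm
  out <- tibble(
    a_tumor = lesion$a_tumor, b_tumor = lesion$b_tumor,
    margin_thickness = lesion$margin_thickness, m = m,
    mean_final_norm_control = gc_$mean_final_norm,
    mean_final_norm_rad223 = gr$mean_final_norm,
    fold_decrease = fold,
    normalized_difference = gc_$mean_final_norm - gr$mean_final_norm,
    eradication_pct = gr$eradication_pct,
    eradication_se = gr$eradication_se
  )
  structure(out, class = c("regimen_comparison", class(out)),
            control = ctrl, rad223 = rad)
}

#' @export
autoplot.regimen_comparison <- function(object, ...) {
  df <- bind_rows(
    ensemble_mean(attr(object, "control")) %>% mutate(regimen = "Control"),
    ensemble_mean(attr(object, "rad223")) %>% mutate(regimen = "Rad223")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$mean_size,
                                   colour = .data$regimen)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "time (days)", y = "mean tumour size (normalized)") +
    ggplot2::theme_minimal()
}

#' Distance-dependence study
#'
#' Re-runs the treated lesion with increasing initial margin thickness
#' (lattice pixels), displacing the tumour from the bone interface where the
#' radioisotope accumulates. Thickness w corresponds to roughly `w * delta`
#' micrometres (1, 5, 10, 15, 20 px = about 21, 104, 208, 313, 417 um, i.e.
#' distance bins R1-R5). A Control ensemble provides the reference mean.
#'
#' @param lesion A [lesion_config()]; its own `margin_thickness` is ignored.
#' @param thicknesses Margin thicknesses in pixels.
#' @param m Replicates per condition.
#' @param base_seed Integer seed.
#' @param params A [sim_params()] bundle.
#' @param follow_up_days Follow-up in days.
#' @return A tibble with one row per thickness: `margin_thickness`,
#'   `distance_um`, `mean_final_norm`, `normalized_difference` (Control minus
#'   treated), `eradication_pct`, `eradication_se`.
#' @export
distance_study <- function(lesion, thicknesses = c(1, 5, 10, 15, 20), m = 20,
                           base_seed = 1, params = sim_params(),
                           follow_up_days = 15) {
  ctrl <- run_ensemble(
    lesion_config(lesion$a_tumor, lesion$b_tumor, lesion$n,
                  margin_thickness = thicknesses[1]),
    engine_config("Control", follow_up_days), params,
    m = m, base_seed = base_seed
  )
  ctrl_mean <- glance(ctrl)$mean_final_norm
  rows <- purrr::imap(thicknesses, function(w, i) {
    les <- lesion_config(lesion$a_tumor, lesion$b_tumor, lesion$n,
                         margin_thickness = w)
    ens <- run_ensemble(les, engine_config("Rad223", follow_up_days), params,
                        m = m, base_seed = base_seed + i * m)
    g <- glance(ens)
    tibble(
      margin_thickness = w,
      distance_um = w * hex_delta(),
      mean_final_norm = g$mean_final_norm,
      normalized_difference = ctrl_mean - g$mean_final_norm,
      eradication_pct = g$eradication_pct,
      eradication_se = g$eradication_se
    )
  })
  out <- bind_rows(rows)
  structure(out, class = c("distance_study", class(out)),
            control_mean = ctrl_mean)
}
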