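# The hourly simulation loop: clock-gated Monte-Carlo event assessment, the
# four event-execution cases (edge/interior mitosis and apoptosis) with
# minimum-distance-path shifts, bone digestion, edge smoothing, and
# termination handling. The loop itself runs in compiled code; every
# operation is also exposed step-wise for testing.

STATUS_LEVELS <- c("running", "time_elapsed", "eradicated", "boundary_arrest")

status_from_code <- function(code) STATUS_LEVELS[code + 1L]

#' Engine configuration
#'
#' @param regimen `"Control"` (untreated) or `"Rad223"`.
#' @param follow_up_days Follow-up time T in days (default 15; simulated in
#'   whole hours).
#' @param dt_hours Simulation time step; fixed at 1 hour.
#' @param t_cell_hours Cell-cycle span gating event eligibility (24 hours).
#' @param daughter_clock_mode Clock given to a newborn cell: `"zero"`
#'   (default; the daughter completes a full 24-hour cycle before its first
#'   event, honouring the cell-cycle cadence) or `"random"` (uniform in
#'   1..24 hours, mirroring the randomized initialization; makes the first
#'   daughter cycle shorter and growth measurably faster).
#' @return An `engine_config` object.
#' @export
engine_config <- function(regimen = c("Control", "Rad223"),
                          follow_up_days = 15,
                          dt_hours = 1L,
                          t_cell_hours = 24L,
                          daughter_clock_mode = c("zero", "random")) {
  regimen <- match.arg(regimen)
  daughter_clock_mode <- match.arg(daughter_clock_mode)
  if (dt_hours != 1L) abort("the engine advances in 1-hour steps")
  if (t_cell_hours %% dt_hours != 0) abort("dt must divide the cell-cycle span")
  t_hours <- follow_up_days * 24
  if (abs(t_hours - round(t_hours)) > 1e-9) {
    abort("follow_up_days must correspond to a whole number of hours")
  }
  structure(
    list(regimen = regimen, follow_up_days = follow_up_days,
         t_hours = as.integer(round(t_hours)), dt_hours = 1L,
         t_cell_hours = as.integer(t_cell_hours),
         daughter_clock_mode = daughter_clock_mode),
    class = "engine_config"
  )
}

#' Kinetic parameter bundle for a simulation
#'
#' @param control A [control_params()] object.
#' @param mitosis A [logistic_params()] object for the mitotic distance effect.
#' @param apoptosis A [logistic_params()] object for the apoptotic distance
#'   effect.
#' @param decay A [decay_params()] object.
#' @return A `sim_params` object.
#' @export
sim_params <- function(control = control_params(),
                       mitosis = default_mitosis_logistic(),
                       apoptosis = default_apoptosis_logistic(),
                       decay = decay_params()) {
  stopifnot(inherits(control, "control_params"),
            inherits(mitosis, "logistic_params"),
            inherits(apoptosis, "logistic_params"),
            inherits(decay, "decay_params"))
  structure(
    list(control = control, mitosis = mitosis, apoptosis = apoptosis,
         decay = decay),
    class = "sim_params"
  )
}

# flatten params for the compiled engine
params_to_cpp <- function(params, regimen, daughter_clock_mode = "zero") {
  list(
    alpha1 = params$control$alpha1, alpha2 = params$control$alpha2,
    mit_K = params$mitosis$K, mit_r = params$mitosis$r,
    mit_phi0 = params$mitosis$phi0,
    apop_K = params$apoptosis$K, apop_r = params$apoptosis$r,
    apop_phi0 = params$apoptosis$phi0,
    R0 = params$decay$R0, lambda = params$decay$lambda,
    delta = hex_delta(),
    rad = identical(regimen, "Rad223"),
    daughter_mode = if (identical(daughter_clock_mode, "zero")) 1L else 0L
  )
}

# p_mit + p_apop must stay <= 1 for every reachable (d, t); checked over a
# sweep of distances and activity levels at run start
validate_probabilities <- function(params, regimen, t_hours) {
  if (regimen == "Control") {
    tot <- params$control$alpha1 + params$control$alpha2
    if (tot > 1) abort(sprintf("p_mit + p_apop = %.3f > 1", tot))
    return(invisible(TRUE))
  }
  d <- seq(0, 2000, by = 5)
  for (t in seq(0, t_hours / 24, length.out = 41)) {
    pm <- p_mitosis("Rad223", d, t, params$control, params$mitosis, params$decay)
    pa <- p_apoptosis("Rad223", d, t, params$control, params$apoptosis, params$decay)
    if (any(pm + pa > 1 + 1e-12)) {
      abort(sprintf(
        "p_mit + p_apop reaches %.3f > 1 at d = %.0f um, t = %.2f d",
        max(pm + pa), d[which.max(pm + pa)], t
      ))
    }
  }
  invisible(TRUE)
}

#' Assess the hourly event mask
#'
#' For every event-eligible cell (internal clock at 24 hours or beyond) one
#' uniform number is drawn and compared with the apoptosis band first:
#' `u < p_apop` marks the cell apoptotic, `u < p_apop + p_mit` mitotic,
#' otherwise it stays quiescent. Probabilities are evaluated at the cell's
#' current minimum distance to bone and the given time. The state is not
#' modified.
#'
#' @param state A `lattice_state`.
#' @param params A [sim_params()] bundle.
#' @param t_days Time since treatment start in days.
#' @param regimen `"Control"` or `"Rad223"`.
#' @return A tibble with one row per eligible cell: `q`, `r`, `status`
#'   (factor: quiescent, mitotic, apoptotic).
#' @export
assess_events <- function(state, params, t_days,
                          regimen = c("Control", "Rad223")) {
  regimen <- match.arg(regimen)
  stopifnot(inherits(state, "lattice_state"))
  validate_probabilities(params, regimen, t_hours = max(1, t_days * 24))
  res <- cpp_assess(state$label, state$clock,
                    params_to_cpp(params, regimen), t_days)
  tibble(
    q = res$q, r = res$r,
    status = factor(c("quiescent", "mitotic", "apoptotic")[res$status + 1L],
                    levels = c("quiescent", "mitotic", "apoptotic"))
  )
}

#' Execute a mitosis
#'
#' An edge cell (at least one non-tumour neighbour) deploys its daughter on a
#' uniformly chosen non-tumour neighbour, which then digests the surrounding
#' bone. An interior cell shifts every tumour cell on a minimum distance path
#' to the nearest bone site one step outward, places the daughter on the
#' vacated site next to the mother, and the outermost displaced cell digests
#' the bone around its new margin position.
#'
#' @param state A `lattice_state`.
#' @param q,r Coordinates of the mitotic mother cell.
#' @param daughter_clock_mode `"random"` or `"zero"`.
#' @return The updated `lattice_state` (tumour count + 1).
#' @export
execute_mitosis <- function(state, q, r, daughter_clock_mode = "zero") {
  stopifnot(inherits(state, "lattice_state"))
  p <- params_to_cpp(sim_params(), "Control", daughter_clock_mode)
  res <- cpp_execute_mitosis(state$label, state$clock, q, r, p)
  state$label <- res$label
  state$clock <- res$clock
  state$status <- status_from_code(res$status)
  state
}

#' Execute an apoptosis
#'
#' An edge cell vacates its site, which becomes margin permanently. For an
#' interior cell the tumour cells on a minimum distance path to the nearest
#' non-tumour site shift one step inward to fill the vacancy, and the outer
#' terminal site of the path becomes margin.
#'
#' @param state A `lattice_state`.
#' @param q,r Coordinates of the apoptotic cell.
#' @return The updated `lattice_state` (tumour count - 1).
#' @export
execute_apoptosis <- function(state, q, r) {
  stopifnot(inherits(state, "lattice_state"))
  res <- cpp_execute_apoptosis(state$label, state$clock, q, r)
  state$label <- res$label
  state$clock <- res$clock
  state$status <- if (!any(res$label == LBL_TUMOUR)) "eradicated"
                  else status_from_code(res$status)
  state
}

#' Smooth the tumour edge
#'
#' Repeatedly, in randomized order, every tumour cell with more than three
#' non-tumour neighbours is swapped with the non-tumour neighbour that itself
#' has the fewest non-tumour neighbours (ties broken by distance to the
#' tumour centroid, then uniformly at random), and the margin is
#' re-established, until no such cell remains or an iteration cap of ten
#' times the tumour perimeter is reached.
#'
#' @param state A `lattice_state`.
#' @return The updated `lattice_state`, with attribute `cap_hit` (logical).
#' @export
smooth_edges <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  res <- cpp_smooth(state$label, state$clock)
  state$label <- res$label
  state$clock <- res$clock
  attr(state, "cap_hit") <- res$cap_hit
  state
}

#' Advance the simulation by one hour
#'
#' Clocks tick; eligible cells are assessed; the assessed events are executed
#' in one uniformly shuffled sequence against the mutating state; edges are
#' smoothed; termination is checked (time elapsed, eradication, or tumour /
#' margin contact with the grid border, which arrests the run).
#'
#' @param state A `lattice_state`.
#' @param config An [engine_config()].
#' @param params A [sim_params()] bundle.
#' @return The updated `lattice_state` with `time_h` advanced and a
#'   `last_step` field: executed mitoses/apoptoses and smoothing-cap flag.
#' @export
sim_step <- function(state, config = engine_config(), params = sim_params()) {
  stopifnot(inherits(state, "lattice_state"), inherits(config, "engine_config"))
  if (state$status != "running") return(state)
  t_hour <- state$time_h + 1L
  p <- params_to_cpp(params, config$regimen, config$daughter_clock_mode)
  res <- cpp_step(state$label, state$clock, p, t_hour)
  state$label <- res$label
  state$clock <- res$clock
  state$time_h <- t_hour
  state$status <- if (res$status == 0L && t_hour >= config$t_hours) {
    "time_elapsed"
  } else {
    status_from_code(res$status)
  }
  state$last_step <- list(n_mitoses = res$n_mit, n_apoptoses = res$n_apop,
                          cap_hit = res$cap_hit)
  state
}

#' Run a full simulation
#'
#' Initializes the lesion (unless an existing state is supplied) and runs the
#' hourly loop to the follow-up time, eradication, or boundary arrest.
#'
#' @param lesion A [lesion_config()] or an initialized `lattice_state`.
#' @param config An [engine_config()].
#' @param params A [sim_params()] bundle.
#' @param seed Optional integer seed covering initialization and dynamics.
#' @param snapshot_every Record a label-matrix snapshot every this many hours
#'   (0 = none).
#' @param keep_state Return the final lattice state in the result.
#' @return A `sim_trajectory`: a tibble with columns `time_h`, `day`,
#'   `n_tumour`, `n_margin`, `n_bone`, `n_mitoses`, `n_apoptoses`, with
#'   attributes `status`, `initial_size`, `seed`, `cap_hits`, `config`,
#'   `params`, and optionally `final_state` / `snapshots`.
#' @export
#' @examples
#' traj <- run_simulation(lesion_config(2, 1), engine_config("Control"),
#'                        seed = 1)
#' glance(traj)
run_simulation <- function(lesion, config = engine_config(),
                           params = sim_params(), seed = NULL,
                           snapshot_every = 0L, keep_state = FALSE) {
  stopifnot(inherits(config, "engine_config"))
  validate_probabilities(params, config$regimen, config$t_hours)
  if (!is.null(seed)) set.seed(seed)
  state <- if (inherits(lesion, "lattice_state")) lesion
           else initialize_lesion(lesion)
  p <- params_to_cpp(params, config$regimen, config$daughter_clock_mode)
  res <- cpp_run(state$label, state$clock, p, config$t_hours,
                 as.integer(snapshot_every))
  rows <- seq_len(res$t_end + 1L)
  counts <- res$counts[rows, , drop = FALSE]
  traj <- tibble(
    time_h = rows - 1L,
    day = (rows - 1L) / 24,
    n_tumour = counts[, 1], n_margin = counts[, 2], n_bone = counts[, 3],
    n_mitoses = counts[, 4], n_apoptoses = counts[, 5]
  )
  traj$n_mitoses[1] <- NA_integer_
  traj$n_apoptoses[1] <- NA_integer_
  structure(
    traj,
    class = c("sim_trajectory", class(traj)),
    status = status_from_code(res$status),
    initial_size = counts[1, 1],
    seed = seed,
    cap_hits = res$cap_hits,
    config = config,
    params = params,
    lesion = if (inherits(lesion, "lattice_state")) lesion$config else lesion,
    final_state = if (keep_state) {
      new_lattice_state(res$label, res$clock, time_h = res$t_end,
                        status = status_from_code(res$status),
                        config = if (inherits(lesion, "lattice_state"))
                          lesion$config else lesion)
    },
    snapshots = if (snapshot_every > 0) {
      list(labels = res$snapshots, times = res$snapshot_times)
    }
  )
}

#' @export
glance.sim_trajectory <- function(x, ...) {
  init <- attr(x, "initial_size")
  final <- x$n_tumour[nrow(x)]
  tibble(
    initial_size = init,
    final_size = final,
    final_normalized = final / init,
    hours = x$time_h[nrow(x)],
    status = attr(x, "status"),
    cap_hits = attr(x, "cap_hits")
  )
}

#' @export
tidy.sim_trajectory <- function(x, ...) {
  tibble(time_h = x$time_h, day = x$day, n_tumour = x$n_tumour,
         normalized = x$n_tumour / attr(x, "initial_size"))
}

#' @export
autoplot.sim_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$normalized)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (days)", y = "tumour size (normalized)",
                  title = sprintf("%s run (%s)",
                                  attr(object, "config")$regimen,
                                  attr(object, "status"))) +
    ggplot2::theme_minimal()
}
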