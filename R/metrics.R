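#' Settling time of the reach
#'
#' Time from target disclosure until the real joint angle first enters the
#' band `|theta - theta_T| < tol` and stays inside it for at least `dwell`
#' seconds. Returns `NA_real_` (not an error) if the trajectory never
#' settles; a trajectory already inside the band at disclosure has settling
#' time 0.
#'
#' The tolerance and dwell are conventions of this package (the settling band
#' is not part of the model); they are exposed so coarser arrival criteria
#' (for example 0.1 rad, roughly the visible end of the movement) can be used.
#'
#' @param traj An `aif_trajectory`.
#' @param theta_T Target angle (rad); defaults to the trajectory's scenario
#'   target.
#' @param tol Half-width of the settling band (rad).
#' @param dwell Minimum time the angle must remain inside the band (s).
#' @param t_T Disclosure time (s); defaults to the scenario's event time.
#' @return Settling time in seconds, or `NA_real_`.
#' @export
reach_time <- function(traj, theta_T = NULL, tol = 0.02, dwell = 1,
                       t_T = NULL) {
  stopifnot(inherits(traj, "aif_trajectory"),
            is_scalar_finite(tol), tol > 0,
            is_scalar_finite(dwell), dwell >= 0)
  sc <- attr(traj, "scenario")
  if (is.null(theta_T)) theta_T <- sc$events$target$theta
  if (is.null(t_T)) t_T <- sc$events$target$time
  if (is.null(theta_T) || is.null(t_T))
    stop("trajectory has no target event; give theta_T and t_T explicitly",
         call. = FALSE)
  dt <- traj$t[2L] - traj$t[1L]
  eligible <- traj$t >= t_T - 1e-12
  inband <- eligible & (abs(traj$theta - theta_T) < tol)
  need <- max(1L, as.integer(round(dwell / dt)))
  # first sample from which the band holds for `need` consecutive samples
  r <- rle(inband)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0L) return(NA_real_)
  traj$t[starts[ok[1L]]] - t_T
}

#' Time-window mean of a logged field
#'
#' Arithmetic mean of one trajectory column over `from <= t < to` (the final
#' sample at `t = to` is included when `to` is the end of the run).
#'
#' @param traj An `aif_trajectory`.
#' @param field Column name.
#' @param from,to Window bounds (s), `0 <= from < to <= t_sim`.
#' @return Scalar mean.
#' @export
window_mean <- function(traj, field, from, to) {
  stopifnot(inherits(traj, "aif_trajectory"),
            is.character(field), length(field) == 1L,
            is_scalar_finite(from), is_scalar_finite(to), from >= 0, from < to)
  if (!field %in% names(traj))
    stop("unknown trajectory field: ", field, call. = FALSE)
  t_end <- traj$t[nrow(traj)]
  if (to > t_end + 1e-12)
    stop("window extends past the end of the trajectory", call. = FALSE)
  sel <- traj$t >= from - 1e-12 &
    (traj$t < to - 1e-12 | (abs(to - t_end) < 1e-12 & traj$t <= to + 1e-12))
  if (!any(sel)) stop("empty window", call. = FALSE)
  mean(traj[[field]][sel])
}

#' Cancellation of the two action components
#'
#' At the mixed-conflict steady state the proprioceptive and visual
#' contributions to action pull in opposite directions and suppress the net
#' action. This index quantifies that:
#' \deqn{CI = \frac{|k_{A,p}\bar a_p + k_{A,v}\bar a_v|}
#'                 {|k_{A,p}\bar a_p| + |k_{A,v}\bar a_v|} \in [0, 1],}
#' where the bars are window means of the logged gradient components. 0 means
#' perfect cancellation, 1 means fully aligned components. Returns `NaN` if
#' both weighted components average exactly to zero.
#'
#' @inheritParams window_mean
#' @param k_A Action-gain pair; defaults to the trajectory's scenario gains.
#' @return Scalar in `[0, 1]` (or `NaN` for a degenerate window).
#' @export
cancellation_index <- function(traj, from, to, k_A = NULL) {
  stopifnot(inherits(traj, "aif_trajectory"))
  if (is.null(k_A)) k_A <- attr(traj, "scenario")$gains$k_A
  p <- k_A[1L] * window_mean(traj, "a_prop", from, to)
  v <- k_A[2L] * window_mean(traj, "a_vis", from, to)
  abs(p + v) / (abs(p) + abs(v))
}

#' Summary metrics of one run
#'
#' Collapses a trajectory into the quantities the analyses are phrased in:
#' settling time, steady-state angle, the real- versus inferred-velocity
#' magnitudes (whose dissociation marks conflict-driven movement), the
#' residual model-dynamics error, and the action cancellation index. The
#' steady-state window is the final `steady_window` seconds of the run.
#'
#' @param traj An `aif_trajectory`.
#' @param tol,dwell Settling-band parameters passed to [reach_time()] (used
#'   only when the scenario has a target event).
#' @param steady_window Length of the terminal averaging window (s).
#' @return A one-row data frame with columns `scenario`, `seed`,
#'   `reach_time`, `steady_theta`, `mean_abs_real_velocity`,
#'   `mean_abs_inferred_velocity`, `mean_eps_m2`, `cancellation_index`.
#' @export
summarize_run <- function(traj, tol = 0.02, dwell = 1, steady_window = 5) {
  stopifnot(inherits(traj, "aif_trajectory"))
  sc <- attr(traj, "scenario")
  t_end <- traj$t[nrow(traj)]
  from <- max(0, t_end - steady_window)
  rt <- if (!is.null(sc$events$target))
    reach_time(traj, tol = tol, dwell = dwell) else NA_real_
  # velocity dissociation window: from the first event (if any) to the end
  ev_t <- c(sc$events$target$time, sc$events$illusion$time)
  w0 <- if (length(ev_t)) min(ev_t) else 0
  data.frame(
    scenario = sc$name,
    seed = attr(traj, "seed"),
    reach_time = rt,
    steady_theta = window_mean(traj, "theta", from, t_end),
    mean_abs_real_velocity =
      mean(abs(traj$theta_prime[traj$t >= w0 - 1e-12])),
    mean_abs_inferred_velocity =
      mean(abs(traj$mu_theta_prime[traj$t >= w0 - 1e-12])),
    mean_eps_m2 = window_mean(traj, "eps_m2", from, t_end),
    cancellation_index = cancellation_index(traj, from, t_end),
    stringsAsFactors = FALSE
  )
}

#' Run a scenario over several seeds and aggregate
#'
#' @param scenario An `aif_scenario`.
#' @param seeds Integer vector of seeds, one run each.
#' @param ... Passed to [summarize_run()].
#' @return A data frame with one row per seed (the columns of
#'   [summarize_run()]).
#' @export
summarize_seeds <- function(scenario, seeds = 1:10, ...) {
  stopifnot(inherits(scenario, "aif_scenario"), length(seeds) >= 1L)
  do.call(rbind, lapply(seeds, function(s) {
    summarize_run(run_simulation(scenario, seed = s), ...)
  }))
}
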