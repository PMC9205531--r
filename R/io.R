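#' Write and read scenario configurations
#'
#' Scenarios serialize to nested YAML. `write_scenario_config()` writes the
#' full resolved configuration; `read_scenario_config()` rebuilds a scenario
#' through the constructors, so every constraint is re-checked and unknown
#' keys are rejected by name. A config file may instead contain just
#' `scenario: <builder name>` plus builder arguments, in which case the named
#' builder supplies all remaining defaults (an empty override set yields the
#' builder's exact default scenario).
#'
#' @param scenario An `aif_scenario`.
#' @param path File path.
#' @return `read_scenario_config()` returns an `aif_scenario`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "aif_scenario"))
  x <- list(
    name = scenario$name,
    theta0 = scenario$theta0,
    theta_vr0 = scenario$theta_vr0,
    process = unclass(scenario$process),
    model = unclass(scenario$model),
    gains = unclass(scenario$gains),
    source = Filter(Negate(is.null), unclass(scenario$source)),
    events = scenario$events,
    loop = unclass(scenario$loop)[c("t_sim", "dt", "sigma_acc",
                                    "divergence_bound")]
  )
  yaml::write_yaml(Filter(Negate(is.null), x), path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  if (is.null(x)) x <- list()
  if (!is.null(x$scenario)) {
    builder <- switch(x$scenario,
                      reach = scenario_reach,
                      rhi = scenario_rhi,
                      virtual_reach = scenario_virtual_reach,
                      stop("unknown scenario name: ", x$scenario,
                           call. = FALSE))
    args <- x[setdiff(names(x), "scenario")]
    bad <- setdiff(names(args), names(formals(builder)))
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    return(do.call(builder, args))
  }
  known <- c("name", "theta0", "theta_vr0", "process", "model", "gains",
             "source", "events", "loop")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  check_keys <- function(lst, fn, label) {
    bad <- setdiff(names(lst), names(formals(fn)))
    if (length(bad))
      stop("unknown ", label, " key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    lst
  }
  lp <- x$loop %||% list()
  bad_lp <- setdiff(names(lp), c("t_sim", "dt", "sigma_acc",
                                 "divergence_bound"))
  if (length(bad_lp))
    stop("unknown loop key(s): ", paste(bad_lp, collapse = ", "),
         call. = FALSE)
  gn <- x$gains %||% list()
  structure(list(
    name = x$name %||% "custom",
    theta0 = x$theta0 %||% 0,
    theta_vr0 = x$theta_vr0,
    process = do.call(process_params,
                      check_keys(x$process %||% list(), process_params,
                                 "process")),
    model = do.call(model_params,
                    check_keys(x$model %||% list(), model_params, "model")),
    gains = gains(k_mu = unlist(gn$k_mu %||% c(0.1, 0.01, 0.001)),
                  k_A = unlist(gn$k_A %||% c(0.3, 0.3))),
    source = do.call(visual_source,
                     check_keys(x$source %||% list(mode = "real_hand"),
                                visual_source, "source")),
    events = x$events %||% list(target = NULL, illusion = NULL),
    loop = do.call(loop_config, lp)
  ), class = "aif_scenario")
}

#' Write and read trajectory tables
#'
#' Trajectories are stored as plain tab-separated text with a header row (one
#' row per time point), chosen over a binary format so runs can be diffed.
#' The run metadata (full scenario configuration and seed) is written
#' alongside as `<path>.meta.yaml`; `read_trajectory()` re-attaches it when
#' present.
#'
#' @param traj An `aif_trajectory`.
#' @param path Output file path.
#' @return `read_trajectory()` returns an `aif_trajectory`;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "aif_trajectory"))
  utils::write.table(as.data.frame(traj), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(seed = attr(traj, "seed"))
  write_scenario_config(attr(traj, "scenario"),
                        paste0(path, ".scenario.yaml"))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- utils::read.table(path, header = TRUE, sep = "\t")
  class(traj) <- c("aif_trajectory", "data.frame")
  sc_path <- paste0(path, ".scenario.yaml")
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(sc_path))
    attr(traj, "scenario") <- read_scenario_config(sc_path)
  if (file.exists(meta_path))
    attr(traj, "seed") <- yaml::read_yaml(meta_path)$seed
  traj
}

#' Write a run manifest
#'
#' Records everything needed to regenerate a batch byte-for-byte: the full
#' resolved scenario, the seed list, the output paths and the package
#' version.
#'
#' @param scenario An `aif_scenario`.
#' @param seeds Integer vector of seeds.
#' @param outputs Character vector of output paths.
#' @param path Manifest path (JSON).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(scenario, seeds, outputs, path) {
  stopifnot(inherits(scenario, "aif_scenario"))
  manifest <- list(
    package = "activereach",
    version = as.character(utils::packageVersion("activereach")),
    scenario = scenario$name,
    config = list(
      theta0 = scenario$theta0,
      process = unclass(scenario$process),
      model = unclass(scenario$model),
      gains = unclass(scenario$gains),
      source = Filter(Negate(is.null), unclass(scenario$source)),
      events = scenario$events,
      loop = unclass(scenario$loop)
    ),
    seeds = as.integer(seeds),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Panel plot of one trajectory
#'
#' Stacks the standard diagnostic panels: real and inferred joint angle (with
#' the target, if any), real and inferred velocity, action, the three
#' prediction errors, and the two action-gradient components.
#'
#' @param traj An `aif_trajectory` (possibly re-read from disk).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj) {
  stopifnot(inherits(traj, "aif_trajectory"))
  panels <- list(
    `joint angle (rad)` = data.frame(
      t = rep(traj$t, 2),
      value = c(traj$theta, traj$mu_theta),
      series = rep(c("real", "inferred"), each = nrow(traj))),
    `velocity (rad/s)` = data.frame(
      t = rep(traj$t, 2),
      value = c(traj$theta_prime, traj$mu_theta_prime),
      series = rep(c("real", "inferred"), each = nrow(traj))),
    `action (rad/s^2)` = data.frame(t = traj$t, value = traj$A,
                                    series = "action"),
    `prediction errors` = data.frame(
      t = rep(traj$t, 3),
      value = c(traj$eps_p, traj$eps_v_norm, traj$eps_m2),
      series = rep(c("proprioceptive", "visual |.|", "model"),
                   each = nrow(traj))),
    `action components` = data.frame(
      t = rep(traj$t, 2),
      value = c(traj$a_prop, traj$a_vis),
      series = rep(c("proprioceptive", "visual"), each = nrow(traj)))
  )
  long <- do.call(rbind, Map(function(d, nm) {
    d$panel <- nm
    d
  }, panels, names(panels)))
  long$panel <- factor(long$panel, levels = names(panels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.placement = "outside",
                   legend.position = "bottom")
}

#' Velocity overlay across velocity gains
#'
#' Real (solid) and inferred (dashed) joint-angle velocities from a gain
#' sweep, one colour per gain: the real profiles fan out with the gain while
#' the inferred profiles nearly coincide.
#'
#' @param sweep An `aif_gain_sweep` from [sweep_velocity_gains()].
#' @return A ggplot object.
#' @export
plot_velocity_overlay <- function(sweep) {
  stopifnot(inherits(sweep, "aif_gain_sweep"))
  gains_v <- attr(sweep, "gain_values")
  long <- do.call(rbind, Map(function(traj, g) {
    data.frame(t = rep(traj$t, 2),
               value = c(traj$theta_prime, traj$mu_theta_prime),
               kind = rep(c("real", "inferred"), each = nrow(traj)),
               gain = g)
  }, sweep, gains_v))
  long$gain <- factor(long$gain)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$gain,
                                     linetype = .data$kind)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_linetype_manual(values = c(real = "solid",
                                              inferred = "dashed")) +
    ggplot2::labs(x = "time (s)", y = "joint velocity (rad/s)",
                  colour = "velocity gain", linetype = NULL) +
    ggplot2::theme_minimal()
}
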