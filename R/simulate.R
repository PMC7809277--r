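#' Simulation configuration
#'
#' Full parameterisation of a run. Defaults follow the reference setup: 490
#' individuals, mean degree 10, 1000 timesteps, the seven-bin certainty
#' scheme, opinion drift of at most `0.1 * epsilon` for gate-closed
#' individuals and certainty drift of at most 0.1.
#'
#' @param epsilon confidence threshold, in \[0, 1\]; smaller values mean
#'   stronger homophily. Applied as an absolute opinion-distance cutoff on the
#'   \[-1, 1\] opinion axis, so `epsilon = 1` spans half the axis.
#' @param n population size (default 490); must be a multiple of the number
#'   of certainty bins.
#' @param k mean degree of the per-timestep interaction network (default 10).
#' @param events an [event_process()], or `NULL` for no events.
#' @param timesteps horizon T; the run records conflict at t = 0..T.
#' @param seed integer seed; the whole run is reproducible from it.
#' @param drift_scale opinion-drift scale (default 0.1; drift magnitude is
#'   uniform on \[0, drift_scale * epsilon\]).
#' @param certainty_drift certainty-drift scale (default 0.1).
#' @param drift_all drift every individual's opinion (default: only
#'   gate-closed individuals drift).
#' @param gate_mode see [social_step()].
#' @param network_method see [sample_network()].
#' @param scheme a [certainty_scheme()].
#' @param store_opinions keep the full n x (T+1) opinion trajectory (off by
#'   default to keep sweep memory flat).
#' @return An object of class `siem_config`.
#' @export
siem_config <- function(epsilon, n = 490L, k = 10, events = NULL,
                        timesteps = 1000L, seed = 1L,
                        drift_scale = 0.1, certainty_drift = 0.1,
                        drift_all = FALSE,
                        gate_mode = c("interaction_set", "neighbors"),
                        network_method = c("gnp", "regular"),
                        scheme = certainty_scheme(),
                        store_opinions = FALSE) {
  gate_mode <- match.arg(gate_mode)
  network_method <- match.arg(network_method)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || is.na(epsilon) ||
      epsilon < 0 || epsilon > 1)
    stop("`epsilon` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(timesteps) || length(timesteps) != 1 || timesteps < 0 ||
      timesteps != round(timesteps))
    stop("`timesteps` must be a non-negative integer", call. = FALSE)
  if (!is.null(events) && !inherits(events, "siem_event_process"))
    stop("`events` must be NULL or an event_process object", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || n <= 0 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  if (as.integer(n) %% scheme$n_bins != 0L)
    stop(sprintf("`n` must be a multiple of the number of certainty bins (%d)",
                 scheme$n_bins), call. = FALSE)
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k > n - 1)
    stop(sprintf("`k` must lie in [0, %d]", as.integer(n) - 1L), call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("`seed` must be an integer", call. = FALSE)
  structure(list(epsilon = epsilon, n = as.integer(n), k = k, events = events,
                 timesteps = as.integer(timesteps), seed = as.integer(seed),
                 drift_scale = drift_scale, certainty_drift = certainty_drift,
                 drift_all = isTRUE(drift_all), gate_mode = gate_mode,
                 network_method = network_method, scheme = scheme,
                 store_opinions = isTRUE(store_opinions)),
            class = "siem_config")
}

#' Advance the simulation by one timestep
#'
#' Executes the per-timestep workflow, in order: (1) a fresh random network is
#' sampled; (2) all opinions are updated synchronously by the certainty-gated
#' bounded-confidence rule; (3) certainties relax toward their baselines and
#' drift; (4) a new event may spawn, and every currently active event is
#' applied to the population in start order, each with fresh per-individual
#' weights.
#'
#' @param state a `siem_population`.
#' @param config a `siem_config`.
#' @param active_events list of `siem_event`s still running from earlier
#'   timesteps.
#' @param t timestep index being computed.
#' @return A list with `state`, `active_events` (still active after `t`), and
#'   `spawned` (events that started at `t`).
#' @export
step <- function(state, config, active_events = list(), t = 1L) {
  net <- sample_network(config$n, config$k, method = config$network_method)
  state <- social_step(state, net, config$epsilon,
                       drift_scale = config$drift_scale,
                       drift_all = config$drift_all,
                       gate_mode = config$gate_mode)
  state <- certainty_step(state, drift_scale = config$certainty_drift)
  spawned <- list()
  if (!is.null(config$events)) {
    spawned <- spawn_events(config$events, t)
    active_events <- c(active_events, spawned)
    active_events <- Filter(function(ev) event_active(ev, t), active_events)
    for (ev in active_events) {
      state <- apply_event(state, ev, config$epsilon)
    }
  }
  list(state = state,
       active_events = Filter(function(ev) event_active(ev, t + 1L),
                              active_events),
       spawned = spawned)
}

#' Run a full simulation
#'
#' Seeds the random number generator, initializes the population, iterates
#' [step()] over the horizon and records the conflict level (population
#' standard deviation of opinions) at every timestep, together with a log of
#' all events. Identical `(config, seed)` give bit-identical results.
#'
#' @param config a [siem_config()].
#' @param quiet suppress progress messages (default `TRUE`; when `FALSE`, a
#'   line is written to stderr every 100 timesteps).
#' @return An object of class `siem_run`: list with `conflict` (numeric,
#'   length `timesteps + 1`, `conflict[t + 1]` is the conflict at timestep t),
#'   `events` (data frame `start, duration, strength, opinion`), `opinions`
#'   (final opinion vector, or full n x (T+1) matrix when
#'   `store_opinions = TRUE`), `state` (final population), `config`.
#' @examples
#' run <- run_simulation(siem_config(epsilon = 0.9, n = 14, timesteps = 50))
#' tail(run$conflict, 1)
#' @export
run_simulation <- function(config, quiet = TRUE) {
  if (!inherits(config, "siem_config"))
    stop("`config` must be a siem_config object", call. = FALSE)
  set.seed(config$seed)
  state <- init_population(config$n, config$scheme)
  T <- config$timesteps
  conflict_series <- numeric(T + 1L)
  conflict_series[1L] <- conflict(state$opinions)
  trajectory <- NULL
  if (config$store_opinions) {
    trajectory <- matrix(NA_real_, nrow = config$n, ncol = T + 1L)
    trajectory[, 1L] <- state$opinions
  }
  all_events <- list()
  active <- list()
  for (t in seq_len(T)) {
    out <- step(state, config, active, t)
    state <- out$state
    active <- out$active_events
    all_events <- c(all_events, out$spawned)
    conflict_series[t + 1L] <- conflict(state$opinions)
    if (config$store_opinions) trajectory[, t + 1L] <- state$opinions
    if (!quiet && t %% 100L == 0L)
      message(sprintf("t = %d / %d, conflict = %.3f", t, T,
                      conflict_series[t + 1L]))
  }
  structure(list(conflict = conflict_series,
                 events = event_log(all_events),
                 opinions = if (config$store_opinions) trajectory
                            else state$opinions,
                 state = state,
                 config = config),
            class = "siem_run")
}

#' @export
print.siem_run <- function(x, ...) {
  T <- x$config$timesteps
  cat(sprintf("<siem_run> n = %d, epsilon = %g, %d timesteps, seed %d\n",
              x$config$n, x$config$epsilon, T, x$config$seed))
  cat(sprintf("  conflict: start %.3f, end %.3f; %d events\n",
              x$conflict[1], x$conflict[T + 1L], nrow(x$events)))
  invisible(x)
}
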