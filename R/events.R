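#' Stochastic event process parameters
#'
#' External events are time-bounded happenings (disasters, rulings, news
#' releases) that carry an effective opinion and an influencing strength and
#' can act on every eligible individual in the same timestep. The process is
#' parameterised by the probability `frequency` that a new event starts in any
#' timestep, a mean duration `duration` (timesteps), and a mean strength
#' `strength`; individual events vary stochastically around these means.
#'
#' @param frequency probability of a new event per timestep, in \[0, 1\].
#' @param duration mean event duration in timesteps, >= 0; realized durations
#'   are uniform on \[0, 2 * duration\], rounded, with a floor of 1.
#' @param strength mean event strength, in \[0.2, 0.8\]; realized strengths
#'   are uniform on \[strength - 0.2, strength + 0.2\] so they stay in
#'   \[0, 1\].
#' @param sign_mode `"random"` (default): each event's effective opinion is
#'   +strength or -strength with equal probability; `"positive"`: always
#'   +strength.
#' @return An object of class `siem_event_process`.
#' @export
event_process <- function(frequency, duration, strength,
                          sign_mode = c("random", "positive")) {
  sign_mode <- match.arg(sign_mode)
  stopifnot(is.numeric(frequency), length(frequency) == 1,
            is.numeric(duration), length(duration) == 1,
            is.numeric(strength), length(strength) == 1)
  if (is.na(frequency) || frequency < 0 || frequency > 1)
    stop("event `frequency` must lie in [0, 1]", call. = FALSE)
  if (is.na(duration) || duration < 0)
    stop("event `duration` must be >= 0", call. = FALSE)
  if (is.na(strength) || strength < 0.2 || strength > 0.8)
    stop("mean event `strength` must lie in [0.2, 0.8]", call. = FALSE)
  structure(list(frequency = frequency, duration = duration,
                 strength = strength, sign_mode = sign_mode),
            class = "siem_event_process")
}

#' Spawn new events for one timestep
#'
#' With probability `params$frequency` a single event starts at `t`, with
#' strength uniform on \[strength - 0.2, strength + 0.2\], duration uniform on
#' \[0, 2 * duration\] rounded to whole timesteps (minimum 1), and effective
#' opinion `sign * strength` per `sign_mode`.
#'
#' @param params a [event_process()].
#' @param t current timestep index.
#' @return A list of 0 or 1 `siem_event` objects (fields `start`, `duration`,
#'   `strength`, `opinion`).
#' @export
spawn_events <- function(params, t) {
  stopifnot(inherits(params, "siem_event_process"))
  if (stats::runif(1) >= params$frequency) return(list())
  strength <- stats::runif(1, params$strength - 0.2, params$strength + 0.2)
  dur <- max(1L, as.integer(round(stats::runif(1, 0, 2 * params$duration))))
  sgn <- if (params$sign_mode == "random") sample(c(-1, 1), 1) else 1
  list(structure(list(start = as.integer(t), duration = dur,
                      strength = strength, opinion = sgn * strength),
                 class = "siem_event"))
}

#' Is an event active at timestep t?
#' @param event a `siem_event`.
#' @param t timestep index.
#' @return `TRUE` while `start <= t < start + duration`.
#' @export
event_active <- function(event, t) {
  t >= event$start && t < event$start + event$duration
}

# Deterministic core of event influence, given the per-individual weights W.
# Eligible individuals (certainty <= event strength AND opinion strictly
# within epsilon of the event's opinion) move a fraction W of the way toward
# the event's opinion; everyone else is untouched.
apply_event_core <- function(opinions, certainties, event_opinion,
                             event_strength, epsilon, W) {
  eligible <- certainties <= event_strength &
    abs(opinions - event_opinion) < epsilon
  opinions[eligible] <- opinions[eligible] +
    W[eligible] * (event_opinion - opinions[eligible])
  pmin(pmax(opinions, -1), 1)
}

#' Apply an active event to the population
#'
#' Every individual whose certainty does not exceed the event's strength and
#' whose opinion lies strictly within the confidence threshold of the event's
#' opinion moves toward that opinion by an independent random fraction W
#' uniform on \[0, 1\], drawn per individual. The move is convex, so no one
#' crosses the event's opinion; all eligible individuals are exposed in the
#' same timestep.
#'
#' @param state a `siem_population`.
#' @param event a `siem_event`.
#' @param epsilon confidence threshold (shared with interpersonal influence).
#' @return The state with updated `opinions`.
#' @export
apply_event <- function(state, event, epsilon) {
  stopifnot(inherits(state, "siem_population"), inherits(event, "siem_event"))
  W <- stats::runif(state$n)
  state$opinions <- apply_event_core(state$opinions, state$certainties,
                                     event$opinion, event$strength,
                                     epsilon, W)
  state
}

#' @export
print.siem_event <- function(x, ...) {
  cat(sprintf("<siem_event> start %d, duration %d, strength %.3f, opinion %+.3f\n",
              x$start, x$duration, x$strength, x$opinion))
  invisible(x)
}

# Event log as a data frame (one row per event, possibly zero rows).
event_log <- function(events) {
  if (!length(events)) {
    return(data.frame(start = integer(), duration = integer(),
                      strength = numeric(), opinion = numeric()))
  }
  data.frame(start = vapply(events, `[[`, integer(1), "start"),
             duration = vapply(events, `[[`, integer(1), "duration"),
             strength = vapply(events, `[[`, numeric(1), "strength"),
             opinion = vapply(events, `[[`, numeric(1), "opinion"))
}
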