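#' Conflict level of an opinion distribution
#'
#' Conflict is summarised as the population standard deviation (divisor n) of
#' opinions, so a uniform distribution on \[-1, 1\] has conflict
#' 1/sqrt(3) = 0.577 in the large-n limit and a half/half split at -1 and +1
#' has conflict 1.
#'
#' @param opinions numeric vector of at least 2 opinions.
#' @return Conflict level, in \[0, 1\] for opinions in \[-1, 1\].
#' @examples
#' conflict(c(-1, -1, 1, 1))  # 1
#' @export
conflict <- function(opinions) {
  if (!is.numeric(opinions) || length(opinions) < 2)
    stop("`opinions` must contain at least 2 values", call. = FALSE)
  sqrt(mean((opinions - mean(opinions))^2))
}

#' Long-term mean conflict of a run
#'
#' Arithmetic mean of the conflict series over an inclusive timestep window,
#' by default \[500, 1000\] (the series is statistically steady well before
#' t = 500 under the default horizon).
#'
#' @param run a `siem_run`.
#' @param window integer vector `c(first, last)` of timesteps, inclusive.
#' @return Mean conflict over the window.
#' @export
long_term_conflict <- function(run, window = c(500, 1000)) {
  stopifnot(inherits(run, "siem_run"), length(window) == 2,
            window[1] <= window[2], window[1] >= 0)
  if (window[2] > run$config$timesteps)
    stop(sprintf("window [%d, %d] exceeds the run horizon (%d timesteps)",
                 window[1], window[2], run$config$timesteps), call. = FALSE)
  mean(run$conflict[(window[1]:window[2]) + 1L])
}

#' Empirical conflict relationship coefficients
#'
#' Coefficients of the closed-form relationship between long-term conflict,
#' homophily and event exposure:
#' `conflict = slope * (1 - epsilon) * [intercept + E_s * (E_f * E_d)^exponent]`.
#'
#' @param slope leading slope (default 0.75).
#' @param intercept event-free term inside the bracket (default 0.44).
#' @param exponent exposure power (default 0.08).
#' @return An object of class `conflict_relation`.
#' @export
conflict_relation <- function(slope = 0.75, intercept = 0.44,
                              exponent = 0.08) {
  structure(list(slope = slope, intercept = intercept, exponent = exponent),
            class = "conflict_relation")
}

# Bracketed predictor P = (1 - eps) * [b + E_s * (E_f E_d)^c], with the
# no-event limit (exposure = 0) defined as P = (1 - eps) * b so the
# relationship is continuous at zero exposure.
relation_predictor <- function(epsilon, strength, exposure,
                               relation = conflict_relation()) {
  term <- ifelse(exposure > 0, strength * exposure^relation$exponent, 0)
  (1 - epsilon) * (relation$intercept + term)
}

#' Predict long-term conflict from the empirical relationship
#'
#' Evaluates the closed-form relationship
#' `slope * (1 - epsilon) * [intercept + strength * exposure^exponent]`, where
#' `exposure = frequency * duration` of the event process. The no-event case
#' (`exposure = 0`) takes the event term as exactly 0, so the prediction is
#' continuous from rare, short events down to none. Vectorised over the
#' numeric arguments.
#'
#' @param epsilon confidence threshold in \[0, 1\].
#' @param strength mean event strength (ignored when `exposure` is 0).
#' @param exposure product of event frequency and mean duration, >= 0.
#' @param relation a [conflict_relation()].
#' @return Predicted long-term conflict.
#' @examples
#' predict_conflict(0.2)                             # no events: 0.264
#' predict_conflict(0.2, strength = 0.5, exposure = 1)  # 0.564
#' @export
predict_conflict <- function(epsilon, strength = 0, exposure = 0,
                             relation = conflict_relation()) {
  stopifnot(all(epsilon >= 0 & epsilon <= 1), all(exposure >= 0))
  relation$slope * relation_predictor(epsilon, strength, exposure, relation)
}

#' Default parameter-sweep grid
#'
#' Seventeen configurations spanning the standard one-at-a-time sweeps:
#' confidence threshold 0.1-0.9 under events of mean strength 0.5, event
#' strength 0.2-0.8, event frequency 0.01-0.5 and event duration 1-50, all
#' around the reference point epsilon = 0.2, strength 0.5, frequency 0.1,
#' duration 10.
#'
#' @return Data frame with columns `label`, `epsilon`, `strength`,
#'   `frequency`, `duration`.
#' @export
default_sweep_grid <- function() {
  rbind(
    data.frame(label = "epsilon", epsilon = c(0.1, 0.3, 0.5, 0.7, 0.9),
               strength = 0.5, frequency = 0.1, duration = 10),
    data.frame(label = "strength", epsilon = 0.2,
               strength = c(0.2, 0.4, 0.6, 0.8), frequency = 0.1,
               duration = 10),
    data.frame(label = "frequency", epsilon = 0.2, strength = 0.5,
               frequency = c(0.01, 0.05, 0.2, 0.5), duration = 10),
    data.frame(label = "duration", epsilon = 0.2, strength = 0.5,
               frequency = 0.1, duration = c(1, 5, 20, 50))
  )
}

#' Run a parameter sweep
#'
#' Runs every configuration in `grid` for `repeats` seeds, records the mean
#' and standard deviation of long-term conflict across seeds, and attaches
#' the closed-form predictor
#' `P = (1 - epsilon) * [intercept + strength * (frequency * duration)^exponent]`
#' for each row.
#'
#' @param grid data frame with columns `epsilon`, `strength`, `frequency`,
#'   `duration` (a `frequency` or `duration` of 0 means no events), and
#'   optionally `label`; see [default_sweep_grid()].
#' @param repeats number of independent seeds per configuration (>= 1).
#' @param window long-term averaging window passed to
#'   [long_term_conflict()].
#' @param base_seed seeds used are `base_seed + 0 .. repeats - 1`, offset per
#'   configuration so no two cells share a seed.
#' @param n,k,timesteps simulation size parameters applied to every cell.
#' @param relation a [conflict_relation()] for the predictor column.
#' @param quiet suppress per-configuration progress lines.
#' @return A `siem_sweep` data frame: one row per configuration with
#'   `mean_conflict`, `sd_conflict`, `predictor` and `repeats` added.
#' @export
run_sweep <- function(grid, repeats = 5, window = c(500, 1000),
                      base_seed = 1L, n = 490L, k = 10, timesteps = 1000L,
                      relation = conflict_relation(), quiet = TRUE) {
  stopifnot(is.data.frame(grid), repeats >= 1)
  needed <- c("epsilon", "strength", "frequency", "duration")
  missing_cols <- setdiff(needed, names(grid))
  if (length(missing_cols))
    stop("`grid` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"label" %in% names(grid))
    grid$label <- if (nrow(grid)) paste0("config", seq_len(nrow(grid)))
                  else character()
  out <- grid[, c("label", needed)]
  out$repeats <- if (nrow(grid)) as.integer(repeats) else integer()
  out$mean_conflict <- numeric(nrow(grid))
  out$sd_conflict <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    has_events <- grid$frequency[i] > 0 && grid$duration[i] > 0
    ev <- if (has_events)
      event_process(grid$frequency[i], grid$duration[i], grid$strength[i])
    vals <- vapply(seq_len(repeats), function(r) {
      cfg <- siem_config(epsilon = grid$epsilon[i], n = n, k = k, events = ev,
                         timesteps = timesteps,
                         seed = base_seed + (i - 1L) * repeats + (r - 1L))
      long_term_conflict(run_simulation(cfg), window)
    }, numeric(1))
    out$mean_conflict[i] <- mean(vals)
    out$sd_conflict[i] <- stats::sd(vals)
    if (!quiet)
      message(sprintf("[%d/%d] %s: eps=%.2g Es=%.2g Ef=%.2g Ed=%.2g -> %.3f",
                      i, nrow(grid), grid$label[i], grid$epsilon[i],
                      grid$strength[i], grid$frequency[i], grid$duration[i],
                      out$mean_conflict[i]))
  }
  out$predictor <- relation_predictor(out$epsilon, out$strength,
                                      out$frequency * out$duration, relation)
  class(out) <- c("siem_sweep", "data.frame")
  out
}

#' Correlate a sweep with the empirical relationship
#'
#' Pearson correlation between simulated long-term mean conflict and the
#' closed-form predictor across the sweep, the least-squares slope of the
#' through-origin regression of simulated conflict on the predictor, and the
#' two-sided p-value of the correlation.
#'
#' @param sweep a `siem_sweep` (or any data frame with `mean_conflict` and
#'   `predictor` columns).
#' @return List with `r`, `slope`, `p_value` and `n`.
#' @export
fit_relation <- function(sweep) {
  stopifnot(is.data.frame(sweep),
            all(c("mean_conflict", "predictor") %in% names(sweep)))
  y <- sweep$mean_conflict
  P <- sweep$predictor
  if (length(y) < 3)
    stop("at least 3 sweep rows are needed to fit the relationship",
         call. = FALSE)
  if (stats::sd(P) == 0)
    stop("the predictor is constant across the sweep; correlation undefined",
         call. = FALSE)
  ct <- stats::cor.test(y, P)
  list(r = unname(ct$estimate),
       slope = sum(P * y) / sum(P^2),
       p_value = ct$p.value,
       n = length(y))
}
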