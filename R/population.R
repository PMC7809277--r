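#' Certainty allocation scheme
#'
#' Describes how baseline certainties are allocated at initialization:
#' individuals are split evenly across a set of overlapping certainty bins and
#' each draws a baseline uniformly within its bin. The default scheme uses the
#' seven overlapping ranges 0.0-0.4, 0.1-0.5, ..., 0.6-1.0, which produces an
#' approximately bell-shaped certainty distribution centred on 0.5.
#'
#' @param bin_lower numeric vector of bin lower bounds (default
#'   `seq(0, 0.6, by = 0.1)`).
#' @param bin_width common width of every bin (default 0.4).
#' @return An object of class `certainty_scheme`.
#' @export
certainty_scheme <- function(bin_lower = seq(0, 0.6, by = 0.1),
                             bin_width = 0.4) {
  stopifnot(is.numeric(bin_lower), length(bin_lower) >= 1,
            !is.unsorted(bin_lower),
            is.numeric(bin_width), length(bin_width) == 1, bin_width > 0)
  if (any(bin_lower < 0) || any(bin_lower + bin_width > 1))
    stop("certainty bins must lie within [0, 1]", call. = FALSE)
  structure(list(bin_lower = bin_lower, bin_width = bin_width,
                 n_bins = length(bin_lower)),
            class = "certainty_scheme")
}

#' Initialize a population
#'
#' Draws opinions independently and uniformly on \[-1, 1\] and allocates
#' `n / n_bins` individuals at random to each certainty bin of `scheme`, with
#' baseline certainty uniform within the bin. Current certainties start equal
#' to the baselines. Uses R's global random number stream.
#'
#' @param n population size; must be a positive multiple of the number of bins.
#' @param scheme a [certainty_scheme()].
#' @return An object of class `siem_population`: a list with elements
#'   `opinions`, `certainties`, `baseline_certainties`, `bins` (the bin index
#'   each individual was allocated to) and `n`.
#' @examples
#' set.seed(1)
#' pop <- init_population(490)
#' mean(pop$baseline_certainties)  # close to 0.5
#' @export
init_population <- function(n, scheme = certainty_scheme()) {
  if (!inherits(scheme, "certainty_scheme"))
    stop("`scheme` must be a certainty_scheme object", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n <= 0 || n != round(n))
    stop("`n` must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (n %% scheme$n_bins != 0L)
    stop(sprintf("`n` must be a multiple of the number of certainty bins (%d)",
                 scheme$n_bins), call. = FALSE)
  per_bin <- n %/% scheme$n_bins
  opinions <- stats::runif(n, -1, 1)
  bins <- sample(rep.int(seq_len(scheme$n_bins), per_bin))
  lower <- scheme$bin_lower[bins]
  baseline <- stats::runif(n, lower, lower + scheme$bin_width)
  structure(list(opinions = opinions,
                 certainties = baseline,
                 baseline_certainties = baseline,
                 bins = bins,
                 n = n),
            class = "siem_population")
}

validate_population <- function(state) {
  stopifnot(inherits(state, "siem_population"))
  with(state, {
    stopifnot(length(opinions) == n, length(certainties) == n,
              length(baseline_certainties) == n,
              all(opinions >= -1 & opinions <= 1),
              all(certainties >= 0 & certainties <= 1),
              all(baseline_certainties >= 0 & baseline_certainties <= 1))
  })
  invisible(state)
}

# Deterministic core of the certainty update, given the random draws:
# u = uniform(0,1) fraction of the gap to baseline; v = drift magnitude;
# s = drift sign (+1/-1). Result clipped to [0, 1].
certainty_core <- function(certainties, baselines, u, v, s) {
  c2 <- certainties + u * (baselines - certainties) + s * v
  pmin(pmax(c2, 0), 1)
}

#' Advance certainties by one timestep
#'
#' Each certainty moves toward its baseline by a uniform random fraction of the
#' remaining gap (so it never overshoots), then receives a small random drift
#' of magnitude uniform on \[0, `drift_scale`\] with random sign, and is
#' clipped to \[0, 1\]. Baselines are never modified.
#'
#' @param state a `siem_population`.
#' @param drift_scale upper bound of the drift magnitude (default 0.1).
#' @return The state with updated `certainties`.
#' @export
certainty_step <- function(state, drift_scale = 0.1) {
  stopifnot(inherits(state, "siem_population"),
            is.numeric(drift_scale), drift_scale >= 0)
  n <- state$n
  u <- stats::runif(n)
  v <- stats::runif(n, 0, drift_scale)
  s <- sample(c(-1, 1), n, replace = TRUE)
  state$certainties <- certainty_core(state$certainties,
                                      state$baseline_certainties, u, v, s)
  state
}

#' @export
print.siem_population <- function(x, ...) {
  cat(sprintf("<siem_population> n = %d\n", x$n))
  cat(sprintf("  opinions   : mean %.3f, sd %.3f\n",
              mean(x$opinions), stats::sd(x$opinions)))
  cat(sprintf("  certainties: mean %.3f, sd %.3f\n",
              mean(x$certainties), stats::sd(x$certainties)))
  invisible(x)
}
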