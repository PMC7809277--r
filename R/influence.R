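#' Bounded-confidence interaction set
#'
#' The set of contacts whose opinions an individual can take in: itself plus
#' every network neighbor whose opinion lies strictly within the confidence
#' threshold `epsilon` of its own.
#'
#' @param i individual index (1-based).
#' @param opinions numeric vector of current opinions.
#' @param neighbors integer vector of network neighbors of `i` (excluding `i`).
#' @param epsilon confidence threshold (absolute opinion distance, >= 0).
#' @return Sorted integer vector of indices, always containing `i`.
#' @examples
#' interaction_set(1, c(0, 0.1, 0.5), neighbors = c(2, 3), epsilon = 0.2)
#' @export
interaction_set <- function(i, opinions, neighbors, epsilon) {
  stopifnot(length(i) == 1, epsilon >= 0)
  neighbors <- setdiff(as.integer(neighbors), i)
  within <- neighbors[abs(opinions[neighbors] - opinions[i]) < epsilon]
  sort(c(as.integer(i), within))
}

# Deterministic core of the certainty-gated bounded-confidence update.
#
# For each individual i: I_i = {i} + within-threshold neighbors. If the gate is
# open (C_i <= gate average), the new opinion is the unweighted mean of
# opinions over I_i; otherwise the opinion persists plus the supplied signed
# drift. `drift` is the full signed drift vector (one value per individual);
# which individuals it reaches depends on `drift_all`. All updates are
# synchronous and the result is clipped to [-1, 1].
#
# gate_mode "interaction_set": gate average is mean certainty over I_i
# including self. gate_mode "neighbors": mean certainty over linked neighbors
# excluding self (closed when there are none).
social_update_core <- function(opinions, certainties, edges, epsilon, drift,
                               drift_all = FALSE,
                               gate_mode = c("interaction_set", "neighbors")) {
  gate_mode <- match.arg(gate_mode)
  n <- length(opinions)
  stopifnot(length(certainties) == n, length(drift) == n, epsilon >= 0)

  from <- c(edges[, 1], edges[, 2])
  to <- c(edges[, 2], edges[, 1])
  keep <- abs(opinions[from] - opinions[to]) < epsilon
  fk <- from[keep]
  tk <- to[keep]

  count_in <- tabulate(fk, nbins = n)          # within-threshold neighbors
  sum_o <- numeric(n)
  sum_c_in <- numeric(n)
  if (length(fk)) {
    agg <- rowsum(cbind(opinions[tk], certainties[tk]), fk, reorder = FALSE)
    ix <- as.integer(rownames(agg))
    sum_o[ix] <- agg[, 1]
    sum_c_in[ix] <- agg[, 2]
  }
  size_i <- count_in + 1L                      # |I_i|, self included
  mean_opinion <- (sum_o + opinions) / size_i

  if (gate_mode == "interaction_set") {
    gate_avg <- (sum_c_in + certainties) / size_i
    open <- certainties <= gate_avg
  } else {
    deg <- tabulate(from, nbins = n)
    sum_c_nb <- numeric(n)
    if (length(from)) {
      agg2 <- rowsum(certainties[to], from, reorder = FALSE)
      sum_c_nb[as.integer(rownames(agg2))] <- agg2[, 1]
    }
    open <- deg > 0L & certainties <= sum_c_nb / pmax(deg, 1L)
  }

  out <- ifelse(open, mean_opinion, opinions + drift)
  if (drift_all) out[open] <- out[open] + drift[open]
  pmin(pmax(out, -1), 1)
}

#' Certainty-gated social influence step
#'
#' Synchronously updates every opinion from the current opinion and certainty
#' vectors. An individual whose certainty does not exceed the average certainty
#' of its bounded-confidence interaction set adopts the unweighted mean opinion
#' of that set; a more-certain individual ignores social influence and its
#' opinion drifts by a random amount, uniform on \[0, `drift_scale * epsilon`\]
#' with random sign. Opinions are clipped to \[-1, 1\].
#'
#' @param state a `siem_population`.
#' @param net a `siem_network` over the same individuals.
#' @param epsilon confidence threshold.
#' @param drift_scale drift magnitude as a fraction of `epsilon` (default 0.1,
#'   so drift is always small relative to the confidence threshold).
#' @param drift_all if `TRUE`, the drift is also added to socially updated
#'   opinions (by default only gate-closed individuals drift).
#' @param gate_mode `"interaction_set"` (gate average includes self, over the
#'   within-threshold set; default) or `"neighbors"` (average over all linked
#'   neighbors, excluding self).
#' @return The state with updated `opinions`.
#' @export
social_step <- function(state, net, epsilon, drift_scale = 0.1,
                        drift_all = FALSE,
                        gate_mode = c("interaction_set", "neighbors")) {
  stopifnot(inherits(state, "siem_population"), inherits(net, "siem_network"),
            net$n == state$n)
  gate_mode <- match.arg(gate_mode)
  n <- state$n
  drift <- stats::runif(n, 0, drift_scale * epsilon) *
    sample(c(-1, 1), n, replace = TRUE)
  state$opinions <- social_update_core(state$opinions, state$certainties,
                                       net$edges, epsilon, drift,
                                       drift_all = drift_all,
                                       gate_mode = gate_mode)
  state
}
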