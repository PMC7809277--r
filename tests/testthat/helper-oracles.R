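# Scalar brute-force evaluators of the update rules, written independently of
# the vectorized engine: plain loops over individuals applying the decision
# rules literally. Used to pin the engine's behaviour exactly.

brute_neighbors <- function(i, edges) {
  c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])
}

brute_interaction_set <- function(i, opinions, neighbors, epsilon) {
  within <- neighbors[abs(opinions[neighbors] - opinions[i]) < epsilon]
  sort(c(i, within))
}

brute_social <- function(opinions, certainties, edges, epsilon, drift,
                         drift_all = FALSE, gate_mode = "interaction_set") {
  n <- length(opinions)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- brute_neighbors(i, edges)
    I <- brute_interaction_set(i, opinions, nb, epsilon)
    open <- if (gate_mode == "interaction_set") {
      certainties[i] <= mean(certainties[I])
    } else {
      length(nb) > 0 && certainties[i] <= mean(certainties[nb])
    }
    out[i] <- if (open) mean(opinions[I]) else opinions[i] + drift[i]
    if (drift_all && open) out[i] <- out[i] + drift[i]
  }
  pmin(pmax(out, -1), 1)
}

brute_event <- function(opinions, certainties, event_opinion, event_strength,
                        epsilon, W) {
  for (i in seq_along(opinions)) {
    if (certainties[i] <= event_strength &&
        abs(opinions[i] - event_opinion) < epsilon) {
      opinions[i] <- opinions[i] + W[i] * (event_opinion - opinions[i])
    }
  }
  pmin(pmax(opinions, -1), 1)
}

# Random small test instance: n nodes, each pair linked with probability
# edge_p, opinions uniform on [-1, 1], certainties uniform on [0, 1].
random_instance <- function(n, edge_p = 0.4) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < edge_p
  list(opinions = stats::runif(n, -1, 1),
       certainties = stats::runif(n),
       edges = unname(pairs[keep, , drop = FALSE]))
}

# Small population object built by hand (bypasses init_population).
manual_population <- function(opinions, certainties,
                              baselines = certainties) {
  structure(list(opinions = opinions, certainties = certainties,
                 baseline_certainties = baselines,
                 bins = rep(1L, length(opinions)),
                 n = length(opinions)),
            class = "siem_population")
}
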