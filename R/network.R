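#' Sample a fresh interaction network
#'
#' Draws the random undirected graph of potential influence links for one
#' timestep. The default sampler is an Erdős–Rényi graph G(n, p) with
#' p = k / (n - 1), so the expected mean degree is `k`; `method = "regular"`
#' draws a random k-regular graph instead (exact degree, requires integer `k`
#' with `n * k` even). Sampling is delegated to igraph and consumes R's global
#' random number stream, so draws are reproducible under `set.seed()`.
#'
#' @param n number of nodes (>= 2).
#' @param k target mean degree, in \[0, n - 1\].
#' @param method `"gnp"` (default, expected degree) or `"regular"` (exact
#'   degree).
#' @return An object of class `siem_network`: a list with `n`, `k`, and
#'   `edges`, an m x 2 integer matrix of node pairs (1-based, i < j).
#' @examples
#' set.seed(1)
#' net <- sample_network(490, 10)
#' mean(degrees(net))  # close to 10
#' @export
sample_network <- function(n, k, method = c("gnp", "regular")) {
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n))
    stop("`n` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 0 || k > n - 1)
    stop(sprintf("`k` must lie in [0, %d] for n = %d", as.integer(n) - 1L,
                 as.integer(n)), call. = FALSE)
  n <- as.integer(n)
  if (method == "gnp") {
    g <- igraph::sample_gnp(n, k / (n - 1))
  } else {
    if (k != round(k) || (n * k) %% 2 != 0)
      stop("`regular` sampling needs integer `k` with n * k even",
           call. = FALSE)
    g <- igraph::sample_k_regular(n, as.integer(k))
  }
  edges <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(edges) <- "integer"
  structure(list(n = n, k = k, edges = edges), class = "siem_network")
}

#' Node degrees of an interaction network
#' @param net a `siem_network`.
#' @return Integer vector of length `net$n`.
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "siem_network"))
  tabulate(net$edges, nbins = net$n)
}

#' Write a network as a plain-text edge list
#'
#' Two tab-separated columns of 0-based node indices, one edge per line; a
#' debugging aid.
#'
#' @param net a `siem_network`.
#' @param path output file path.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "siem_network"))
  utils::write.table(net$edges - 1L, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Directed expansion of the edge list: each undirected edge {a, b} becomes
# a->b and b->a, so per-node neighbor aggregation is a single grouped sum.
directed_edges <- function(net) {
  e <- net$edges
  cbind(from = c(e[, 1], e[, 2]), to = c(e[, 2], e[, 1]))
}

#' @export
print.siem_network <- function(x, ...) {
  cat(sprintf("<siem_network> n = %d, %d edges (target mean degree %g)\n",
              x$n, nrow(x$edges), x$k))
  invisible(x)
}
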