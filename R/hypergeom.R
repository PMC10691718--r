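#' Probability that two viruses share at least c protein clusters
#'
#' Tail probability of the hypergeometric law used to decide whether two
#' viruses are similar enough to be linked in the heterogeneous graph.
#' Virus A carries `a` protein clusters and virus B carries `b`, both drawn
#' from a universe of `n` distinct clusters observed across all viruses.
#' Under the null that B's clusters are a uniform random subset, the number
#' of clusters shared with A is `X ~ Hypergeometric(N = n, K = a, draws = b)`
#' and the returned value is
#' \deqn{P(X \ge c) = \sum_{i=c}^{\min(a,b)} \binom{a}{i}\binom{n-a}{b-i} / \binom{n}{b}.}
#' A small probability means the observed overlap `c` is unlikely by chance,
#' i.e. the viruses are genuinely related.
#'
#' The computation delegates to [stats::phyper()] (survival form), which
#' works in log space internally, so large universes do not overflow.
#'
#' @param a,b Cluster counts of the two viruses (order does not matter).
#' @param c Observed number of shared clusters; the tail starts here.
#' @param n Size of the cluster universe (total distinct clusters).
#' @return Probability in `[0, 1]`, vectorized over its arguments.
#' @examples
#' shared_cluster_prob(a = 5, b = 3, c = 3, n = 10) # == choose(5,3)/choose(10,3)
#' @seealso [build_v2v_edges()] which applies the threshold `tau1`.
#' @export
shared_cluster_prob <- function(a, b, c, n) {
  if (any(n < 1)) {
    stop("cluster universe size 'n' must be >= 1")
  }
  if (any(a < 0) || any(b < 0) || any(a > n) || any(b > n)) {
    stop("'a' and 'b' must lie in [0, n]")
  }
  if (any(c < 0) || any(c > pmin(a, b))) {
    stop("'c' must lie in [0, min(a, b)]")
  }
  # P(X >= c) with X ~ Hypergeom(white = a, black = n - a, drawn = b)
  stats::phyper(c - 1, m = a, n = n - a, k = b, lower.tail = FALSE)
}
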