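#' Xavier-uniform initialization of the embedding table
#'
#' Draws every entry i.i.d. from `U(-s, s)` with `s = sqrt(6 / (r + d))`,
#' treating the table as an `r x d` weight matrix (`r` = number of nodes).
#'
#' @param r Number of rows (virus + prokaryote nodes).
#' @param d Embedding dimension.
#' @param seed Optional integer seed; when given, the draw is deterministic
#'   and the RNG state is restored afterwards.
#' @return An `r x d` numeric matrix.
#' @export
init_embeddings <- function(r, d, seed = NULL) {
  stopifnot(r >= 1, d >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  bound <- sqrt(6 / (r + d))
  matrix(stats::runif(r * d, -bound, bound), r, d)
}

#' Sample one unobserved prokaryote per positive training pair
#'
#' For each (virus, host) training pair, draws a negative prokaryote
#' uniformly from the prokaryotes with no observed training interaction
#' with that virus. Intended to be called afresh every epoch.
#'
#' @param pos Integer matrix with columns `v` (virus row index into the
#'   embedding table) and `p` (prokaryote row index).
#' @param prokaryote_rows Integer vector of all prokaryote row indices.
#' @return Integer matrix with columns `v`, `p`, `q` (negative).
#'   Consumes the R RNG stream.
#' @export
sample_negatives <- function(pos, prokaryote_rows) {
  stopifnot(is.matrix(pos), ncol(pos) >= 2)
  hosts_of <- split(pos[, 2], pos[, 1])
  q <- integer(nrow(pos))
  for (t in seq_len(nrow(pos))) {
    v <- pos[t, 1]
    cand <- setdiff(prokaryote_rows, hosts_of[[as.character(v)]])
    if (!length(cand)) {
      stop("virus with row index ", v,
           " interacts with every prokaryote; cannot sample a negative")
    }
    q[t] <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  }
  cbind(v = pos[, 1], p = pos[, 2], q = q)
}

#' Bayesian personalized ranking loss over (v, p+, q-) triples
#'
#' `sum_t -log sigma(s_vp - s_vq)` with `s_vp = h_v . h_p` the dot-product
#' preference score: each observed host `p` is pushed above the sampled
#' non-host `q` for the same virus.
#'
#' @param H Final embedding matrix (one row per node).
#' @param triples Integer matrix with columns `v`, `p`, `q` of row indices.
#' @param grad If `TRUE`, attach the analytic gradient with respect to `H`
#'   as attribute `"gradient"`.
#' @return Scalar loss (sum over triples), strictly positive.
#' @export
bpr_loss <- function(H, triples, grad = FALSE) {
  if (!nrow(triples)) stop("triples must be nonempty")
  v <- triples[, 1]; p <- triples[, 2]; q <- triples[, 3]
  s <- rowSums(H[v, , drop = FALSE] * (H[p, , drop = FALSE] - H[q, , drop = FALSE]))
  # -log sigma(s) = log(1 + exp(-s)), computed stably
  loss <- sum(ifelse(s > 0, log1p(exp(-s)), -s + log1p(exp(s))))
  if (grad) {
    g <- stats::plogis(s) - 1            # d(-log sigma(s))/ds
    G <- matrix(0, nrow(H), ncol(H))
    gv <- g * (H[p, , drop = FALSE] - H[q, , drop = FALSE])
    gp <- g * H[v, , drop = FALSE]
    for (t in seq_along(v)) {
      G[v[t], ] <- G[v[t], ] + gv[t, ]
      G[p[t], ] <- G[p[t], ] + gp[t, ]
      G[q[t], ] <- G[q[t], ] - gp[t, ]
    }
    attr(loss, "gradient") <- G
  }
  loss
}

#' InfoNCE contrastive loss between two views
#'
#' Rows of both views are L2-normalized, then each node's view-1 vector is
#' scored against every node's view-2 vector at temperature `rho`; the loss
#' is the per-node cross-entropy of the matching pair against all nodes
#' (the positive is part of the denominator, so the loss is >= 0).
#' Log-sum-exp is computed with max subtraction for stability. Zero-norm
#' rows cannot be normalized and are excluded with a warning.
#'
#' @param H1,H2 Equally shaped view matrices (one row per node).
#' @param rho Temperature (> 0).
#' @param grad If `TRUE`, attach gradients with respect to the
#'   *unnormalized* `H1` and `H2` as attributes `"gradient1"`, `"gradient2"`.
#' @return Scalar loss (sum over usable nodes).
#' @export
infonce_loss <- function(H1, H2, rho, grad = FALSE) {
  stopifnot(all(dim(H1) == dim(H2)), rho > 0)
  n1 <- sqrt(rowSums(H1^2)); n2 <- sqrt(rowSums(H2^2))
  keep <- n1 > 0 & n2 > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-norm row(s) excluded from the contrastive loss")
  }
  idx <- which(keep)
  if (!length(idx)) {
    loss <- 0
    if (grad) {
      attr(loss, "gradient1") <- matrix(0, nrow(H1), ncol(H1))
      attr(loss, "gradient2") <- matrix(0, nrow(H1), ncol(H1))
    }
    return(loss)
  }
  Z1 <- H1[idx, , drop = FALSE] / n1[idx]
  Z2 <- H2[idx, , drop = FALSE] / n2[idx]
  S <- tcrossprod(Z1, Z2) / rho
  m <- apply(S, 1, max)
  lse <- m + log(rowSums(exp(S - m)))
  loss <- sum(lse - diag(S))
  if (grad) {
    P <- exp(S - lse)                    # row-softmax
    A <- P; diag(A) <- diag(A) - 1       # dLoss/dS
    dZ1 <- (A %*% Z2) / rho
    dZ2 <- (crossprod(A, Z1)) / rho
    # back through row normalization z = h / |h|
    unnorm <- function(dZ, Z, nrm) (dZ - rowSums(dZ * Z) * Z) / nrm
    G1 <- matrix(0, nrow(H1), ncol(H1))
    G2 <- matrix(0, nrow(H1), ncol(H1))
    G1[idx, ] <- unnorm(dZ1, Z1, n1[idx])
    G2[idx, ] <- unnorm(dZ2, Z2, n2[idx])
    attr(loss, "gradient1") <- G1
    attr(loss, "gradient2") <- G2
  }
  loss
}
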