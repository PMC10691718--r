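#' One light-graph-convolution step (matrix form)
#'
#' Applies the normalized operator once: `H_{k+1} = A_norm %*% H_k`.
#' There is no feature transform, nonlinearity, or self-loop: a node's new
#' representation is the degree-normalized sum of its neighbours' current
#' representations only.
#'
#' @param A_norm Sparse normalized operator from [normalized_operator()].
#' @param H Numeric matrix, one row per node, rows in graph node order.
#' @return Matrix of the same shape as `H`.
#' @export
propagate_matrix <- function(A_norm, H) {
  if (nrow(H) != nrow(A_norm)) stop("row count of H must match the operator")
  out <- as.matrix(A_norm %*% H)
  dimnames(out) <- dimnames(H)
  out
}

#' One light-graph-convolution step (per-node message-passing form)
#'
#' Reference implementation of the same update as [propagate_matrix()],
#' written as explicit per-edge messages with the per-edge normalization
#' `1 / sqrt(deg(u) * deg(w))`. Virus rows aggregate over both their virus
#' and prokaryote neighbours; prokaryote rows aggregate over their virus
#' neighbours only (there are no prokaryote-prokaryote edges). Exists as a
#' readable oracle for the matrix form; the matrix form is used in training.
#'
#' @param g A `"phg_graph"`.
#' @param H Numeric matrix, rows in `g$nodes` order.
#' @return Matrix of the same shape as `H`.
#' @export
propagate_node_form <- function(g, H) {
  stopifnot(inherits(g, "phg_graph"))
  if (nrow(H) != length(g$nodes)) stop("row count of H must match the graph")
  d <- g$degree
  out <- matrix(0, nrow(H), ncol(H), dimnames = dimnames(H))
  add_msgs <- function(from, to) {
    for (e in seq_along(from)) {
      u <- from[e]; w <- to[e]
      norm <- 1 / sqrt(d[u] * d[w])
      out[u, ] <<- out[u, ] + norm * H[w, ]
      out[w, ] <<- out[w, ] + norm * H[u, ]
    }
  }
  if (!is.null(g$v2v) && nrow(g$v2v)) {
    add_msgs(match(as.character(g$v2v$virus1), g$nodes),
             match(as.character(g$v2v$virus2), g$nodes))
  }
  if (!is.null(g$v2p) && nrow(g$v2p)) {
    add_msgs(match(as.character(g$v2p$virus_id), g$nodes),
             match(as.character(g$v2p$prokaryote_id), g$nodes))
  }
  out
}

#' Combine per-layer embeddings into the final representation
#'
#' Unweighted mean of the layer-1..K states; the trainable layer-0 table is
#' deliberately excluded.
#'
#' @param layer_states Non-empty list of equally shaped matrices `H(1..K)`.
#' @return Their elementwise mean.
#' @export
layer_combine <- function(layer_states) {
  if (!length(layer_states)) stop("layer_states must be non-empty")
  Reduce(`+`, layer_states) / length(layer_states)
}

#' Sample a sign-aligned noise matrix for contrastive views
#'
#' For each node `i`, draws `psi_bar ~ U(0,1)^d`, rescales it to unit L2
#' norm, multiplies by `epsilon`, and aligns it with the node's current
#' representation by an elementwise product with `sign(h_i)`. The resulting
#' vector has L2 norm exactly `epsilon` whenever `h_i` has no zero entries
#' (zero coordinates receive zero noise, so the norm can fall below
#' `epsilon` on such rows), and every coordinate satisfies
#' `psi[i,d] * h[i,d] >= 0`.
#'
#' @param H_ref Matrix whose signs the noise is aligned to.
#' @param epsilon Noise magnitude (>= 0).
#' @return Noise matrix of the same shape as `H_ref`. Consumes the R RNG
#'   stream; seed via `set.seed()` for reproducibility.
#' @export
sample_noise <- function(H_ref, epsilon) {
  stopifnot(epsilon >= 0)
  if (epsilon == 0) return(array(0, dim(H_ref)))
  d <- ncol(H_ref)
  psi_bar <- matrix(stats::runif(nrow(H_ref) * d), nrow(H_ref), d)
  nrm <- sqrt(rowSums(psi_bar^2))
  psi_bar <- psi_bar / nrm * epsilon
  psi_bar * sign(H_ref)
}

#' Encode node embeddings by K rounds of light graph convolution
#'
#' Computes `H(k) = A_norm %*% H(k-1)` for `k = 1..K` starting from the
#' trainable table `H0`, and the final embedding as the mean of layers
#' 1..K (equivalently `(1/K) * sum_k A_norm^k %*% H0`).
#'
#' @param A_norm Normalized operator.
#' @param H0 Layer-0 embedding matrix, rows in node order.
#' @param K Number of propagation layers (>= 1).
#' @return List with `layer_states` (list of K matrices) and `final`.
#' @export
encode <- function(A_norm, H0, K) {
  stopifnot(K >= 1)
  layers <- vector("list", K)
  H <- as.matrix(H0)
  for (k in seq_len(K)) {
    H <- propagate_matrix(A_norm, H)
    layers[[k]] <- H
  }
  list(layer_states = layers, final = layer_combine(layers))
}

#' Encode one noise-perturbed view
#'
#' Runs the perturbed recursion `H'(k) = A_norm %*% H'(k-1) + psi(k)` with
#' `H'(0) = H0` (the input table itself is never perturbed) and returns the
#' mean of the perturbed layers 1..K. Each layer draws an independent noise
#' matrix via [sample_noise()], sign-aligned to that layer's pre-noise
#' propagated state. With `epsilon = 0` the result equals [encode()]
#' bit-for-bit. Call twice (with the RNG advancing) to obtain the two
#' contrastive views.
#'
#' @inheritParams encode
#' @param epsilon Noise magnitude.
#' @return List with `layer_states` and `final` for the perturbed view.
#' @export
encode_perturbed <- function(A_norm, H0, K, epsilon) {
  stopifnot(K >= 1, epsilon >= 0)
  layers <- vector("list", K)
  H <- as.matrix(H0)
  for (k in seq_len(K)) {
    H <- propagate_matrix(A_norm, H)
    H <- H + sample_noise(H, epsilon)
    layers[[k]] <- H
  }
  list(layer_states = layers, final = layer_combine(layers))
}
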