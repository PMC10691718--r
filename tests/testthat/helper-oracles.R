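# Independent oracles and toy-graph builders shared across the suite.

# Exhaustive enumeration oracle for the shared-cluster tail probability:
# virus A holds clusters {1..a}; enumerate every b-subset of {1..n} and
# count those overlapping A in at least c elements. Independent of phyper.
enum_shared_prob <- function(a, b, c, n) {
  if (b == 0) return(as.numeric(c == 0))
  subsets <- utils::combn(n, b)
  mean(colSums(subsets <= a) >= c)
}

# Random heterogeneous graph with edge probabilities p_vv / p_vp.
# Uses the current RNG stream; wrap in withr::with_seed or set.seed.
random_hetero_graph <- function(nv, np, p_vv = 0.2, p_vp = 0.3) {
  viruses <- sprintf("v%03d", seq_len(nv))
  proks <- sprintf("p%03d", seq_len(np))
  vv <- t(utils::combn(nv, 2))
  keep <- stats::runif(nrow(vv)) < p_vv
  v2v <- data.frame(virus1 = viruses[vv[keep, 1]],
                    virus2 = viruses[vv[keep, 2]],
                    stringsAsFactors = FALSE)
  vp <- expand.grid(v = seq_len(nv), p = seq_len(np))
  keep <- stats::runif(nrow(vp)) < p_vp
  v2p <- data.frame(virus_id = viruses[vp$v[keep]],
                    prokaryote_id = proks[vp$p[keep]],
                    stringsAsFactors = FALSE)
  suppressWarnings(assemble_graph(v2v, v2p, viruses, proks))
}

# Two-node graph (one virus, one prokaryote, one edge): A_norm = [[0,1],[1,0]]
two_node_graph <- function() {
  suppressWarnings(assemble_graph(
    v2v = NULL,
    v2p = data.frame(virus_id = "v1", prokaryote_id = "p1"),
    viruses = "v1", prokaryotes = "p1"))
}

# Deterministic-negative training toy: 2 blocks x viruses, one prokaryote
# per block, so each virus has exactly one possible negative host.
deterministic_negative_ecosystem <- function(seed = 1) {
  make_ecosystem(ecosystem_params(blocks = 2, viruses_per_block = 5,
                                  prokaryotes_per_block = 1, holdout = 0.2,
                                  fn_blast = 0, fn_crispr = 0, fp_blast = 0,
                                  seed = seed))
}

# Pairwise AUC of positive (virus, true host) scores against all other
# (virus, prokaryote) scores for the same viruses.
ranking_auc <- function(scores, pairs) {
  pos <- mapply(function(v, p) scores[v, p],
                as.character(pairs$virus_id),
                as.character(pairs$prokaryote_id))
  neg <- unlist(lapply(seq_len(nrow(pairs)), function(i) {
    v <- as.character(pairs$virus_id[i])
    scores[v, setdiff(colnames(scores), as.character(pairs$prokaryote_id[i]))]
  }))
  cmp <- outer(pos, neg, `-`)
  mean((cmp > 0) + 0.5 * (cmp == 0))
}
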