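#' Dot-product host preference scores
#'
#' `score[v, p] = h_v . h_p` on the final embeddings. Optionally mapped
#' through the logistic sigmoid for reporting; the sigmoid is strictly
#' monotone, so it never changes any ranking.
#'
#' @param H Final embedding matrix with node ids as row names (e.g.
#'   `coef(fit)`).
#' @param virus_ids,prokaryote_ids Character vectors of node ids to score.
#' @param sigmoid Map scores through `1/(1+exp(-s))`.
#' @return Numeric matrix, viruses in rows, prokaryotes in columns.
#' @export
score_hosts <- function(H, virus_ids, prokaryote_ids, sigmoid = FALSE) {
  miss <- setdiff(c(virus_ids, prokaryote_ids), rownames(H))
  if (length(miss)) stop("unknown node id(s): ", paste(utils::head(miss, 5), collapse = ", "))
  S <- tcrossprod(H[virus_ids, , drop = FALSE], H[prokaryote_ids, , drop = FALSE])
  dimnames(S) <- list(virus_ids, prokaryote_ids)
  if (sigmoid) S <- stats::plogis(S)
  S
}

#' Rank candidate hosts for each virus
#'
#' Sorts each virus's scores in descending order; ties are broken
#' lexicographically by prokaryote id, so rankings are deterministic.
#'
#' @param scores Score matrix from [score_hosts()] (viruses x prokaryotes).
#' @param k Truncate each ranking to the top `k` hosts (default: all).
#' @return A list of class `"host_ranking"`: per virus a data.frame with
#'   `prokaryote_id`, `score`, `rank`.
#' @export
rank_hosts <- function(scores, k = ncol(scores)) {
  stopifnot(k >= 1)
  proks <- colnames(scores)
  out <- lapply(rownames(scores), function(v) {
    s <- scores[v, ]
    ord <- order(-s, proks)
    n <- min(k, length(ord))
    data.frame(prokaryote_id = proks[ord][seq_len(n)],
               score = unname(s[ord][seq_len(n)]),
               rank = seq_len(n), stringsAsFactors = FALSE)
  })
  names(out) <- rownames(scores)
  class(out) <- "host_ranking"
  out
}

#' @method print host_ranking
#' @export
print.host_ranking <- function(x, n = 3, ...) {
  cat(sprintf("Host rankings for %d virus(es)\n", length(x)))
  for (v in utils::head(names(x), n)) {
    top <- x[[v]][1, ]
    cat(sprintf("  %s -> %s (score %.4f)%s\n", v, top$prokaryote_id, top$score,
                if (nrow(x[[v]]) > 1) sprintf(" [+%d more]", nrow(x[[v]]) - 1) else ""))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' Predict host rankings from a fitted model
#'
#' @param object A `"phagehost"` fit.
#' @param virus_ids Viruses to query (default: all virus nodes).
#' @param k Top-k cutoff (default 5, the usual host-range report size).
#' @param type `"ranking"` (default) for a [rank_hosts()] object, or
#'   `"scores"` for the raw score matrix over all prokaryotes.
#' @param sigmoid Report sigmoid-mapped scores (rank-preserving).
#' @param ... Unused.
#' @export
predict.phagehost <- function(object, virus_ids = NULL, k = 5,
                              type = c("ranking", "scores"),
                              sigmoid = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(virus_ids)) virus_ids <- object$graph$viruses
  H <- coef(object)
  S <- score_hosts(H, virus_ids, object$graph$prokaryotes, sigmoid = sigmoid)
  if (type == "scores") return(S)
  rank_hosts(S, k = k)
}

taxon_of <- function(ids, taxonomy, level) {
  m <- match(ids, taxonomy$prokaryote_id)
  if (anyNA(m)) {
    stop("missing taxonomy row for prokaryote(s): ",
         paste(utils::head(ids[is.na(m)], 5), collapse = ", "))
  }
  as.character(taxonomy[[level]][m])
}

#' Top-1 host prediction accuracy at a taxonomic rank
#'
#' A virus's prediction is counted correct when its top-ranked prokaryote
#' has the same taxon, at the requested rank, as any of the virus's known
#' hosts in `test_pairs`. Returns the fraction of correct viruses.
#'
#' @param rankings A `"host_ranking"` object covering every test virus.
#' @param test_pairs Data.frame with `virus_id`, `prokaryote_id` of
#'   held-out true interactions (a virus may have several rows).
#' @param taxonomy Data.frame with columns `prokaryote_id`, `species`,
#'   `genus`, `family`.
#' @param level One of `"species"`, `"genus"`, `"family"`.
#' @return Fraction in `[0, 1]`, with attribute `"per_virus"` (named
#'   logical vector).
#' @export
accuracy_at_rank <- function(rankings, test_pairs, taxonomy,
                             level = c("species", "genus", "family")) {
  level <- match.arg(level)
  test_viruses <- unique(as.character(test_pairs$virus_id))
  miss <- setdiff(test_viruses, names(rankings))
  if (length(miss)) stop("no ranking for test virus(es): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  correct <- vapply(test_viruses, function(v) {
    pred <- rankings[[v]]$prokaryote_id[1]
    truth <- as.character(test_pairs$prokaryote_id[test_pairs$virus_id == v])
    taxon_of(pred, taxonomy, level) %in% taxon_of(truth, taxonomy, level)
  }, logical(1))
  structure(mean(correct), per_virus = correct)
}

#' Species-level accuracy binned by similarity to the training set
#'
#' Stratifies test viruses by a precomputed per-virus similarity value
#' (typically each test virus's maximum genome similarity to any training
#' virus) and reports per-bin species-level top-1 accuracy.
#'
#' @param rankings A `"host_ranking"` object.
#' @param test_pairs Held-out true interactions.
#' @param taxonomy Taxonomy table (see [accuracy_at_rank()]).
#' @param similarity Named numeric vector: one value per test virus.
#' @param thresholds Increasing numeric cut points; bins are the intervals
#'   between consecutive values (left-closed, right-open; last bin closed).
#' @param level Taxonomic rank (default species).
#' @return Data.frame with `bin`, `lower`, `upper`, `n`, `accuracy`
#'   (`NA` for empty bins).
#' @export
evaluate_binned <- function(rankings, test_pairs, taxonomy, similarity,
                            thresholds, level = "species") {
  test_viruses <- unique(as.character(test_pairs$virus_id))
  miss <- setdiff(test_viruses, names(similarity))
  if (length(miss)) stop("missing similarity value for: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  stopifnot(length(thresholds) >= 2, !is.unsorted(thresholds))
  nb <- length(thresholds) - 1
  lo <- thresholds[-length(thresholds)]
  hi <- thresholds[-1]
  res <- lapply(seq_len(nb), function(b) {
    sim <- similarity[test_viruses]
    inb <- sim >= lo[b] & (if (b == nb) sim <= hi[b] else sim < hi[b])
    vs <- test_viruses[inb]
    if (!length(vs)) {
      return(data.frame(bin = b, lower = lo[b], upper = hi[b],
                        n = 0L, accuracy = NA_real_))
    }
    tp <- test_pairs[test_pairs$virus_id %in% vs, , drop = FALSE]
    acc <- as.numeric(accuracy_at_rank(rankings, tp, taxonomy, level))
    data.frame(bin = b, lower = lo[b], upper = hi[b],
               n = length(vs), accuracy = acc)
  })
  do.call(rbind, res)
}
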