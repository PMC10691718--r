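#' Graph-construction thresholds
#'
#' @param tau1 Probability cutoff for virus-virus edges: two viruses are
#'   linked when [shared_cluster_prob()] of their observed overlap is
#'   strictly below `tau1`. Default 0.01.
#' @param tau2 BLASTN E-value cutoff for virus-prokaryote edges (strict
#'   `<` comparison). Default 1e-5.
#' @return A list of class `"graph_params"`.
#' @export
graph_params <- function(tau1 = 0.01, tau2 = 1e-5) {
  stopifnot(is.numeric(tau1), length(tau1) == 1, tau1 > 0, tau1 <= 1,
            is.numeric(tau2), length(tau2) == 1, tau2 > 0)
  structure(list(tau1 = tau1, tau2 = tau2), class = "graph_params")
}

#' Build virus-virus edges from protein-cluster profiles
#'
#' Links two viruses when the chance of their observed protein-cluster
#' overlap under the hypergeometric null is below `tau1`. Pairs with an
#' empty intersection are never linked (their tail probability is exactly 1),
#' so only overlapping pairs are tested.
#'
#' @param profiles Cluster profiles as returned by [cluster_profiles()]:
#'   a list with `virus_ids`, a list `clusters` of character vectors, and
#'   the universe size `n`.
#' @param params A [graph_params()] object.
#' @return A data.frame with columns `virus1`, `virus2` (each unordered
#'   pair once, `virus1 < virus2` lexicographically), `shared` and `prob`.
#' @export
build_v2v_edges <- function(profiles, params = graph_params()) {
  stopifnot(inherits(params, "graph_params"))
  ids <- profiles$virus_ids
  if (anyDuplicated(ids)) {
    stop("duplicate virus_id in cluster profiles: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  nv <- length(ids)
  if (nv < 2) stop("need at least 2 virus profiles")
  n <- profiles$n
  sizes <- lengths(profiles$clusters)

  # sparse virus x cluster incidence; crossprod gives pairwise intersections
  univ <- sort(unique(unlist(profiles$clusters, use.names = FALSE)))
  if (length(univ) > n) stop("profiles reference more clusters than the universe size")
  i <- rep.int(seq_len(nv), sizes)
  j <- match(unlist(profiles$clusters, use.names = FALSE), univ)
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(nv, length(univ)))
  ov <- Matrix::tcrossprod(M)
  ov <- as(Matrix::triu(ov, k = 1), "TsparseMatrix")
  if (length(ov@x) == 0L) {
    return(data.frame(virus1 = character(), virus2 = character(),
                      shared = integer(), prob = numeric()))
  }
  vi <- ov@i + 1L
  vj <- ov@j + 1L
  shared <- as.integer(ov@x)
  prob <- shared_cluster_prob(sizes[vi], sizes[vj], shared, n)
  keep <- prob < params$tau1
  id1 <- ids[vi][keep]
  id2 <- ids[vj][keep]
  swap <- id1 > id2
  tmp <- id1[swap]; id1[swap] <- id2[swap]; id2[swap] <- tmp
  out <- data.frame(virus1 = id1, virus2 = id2,
                    shared = shared[keep], prob = prob[keep],
                    stringsAsFactors = FALSE)
  out[order(out$virus1, out$virus2), , drop = FALSE]
}

#' Assemble per-virus cluster profiles from a long cluster table
#'
#' @param clusters A data.frame with columns `virus_id` and `cluster_id`
#'   (a `protein_id` column, if present, is ignored beyond membership).
#' @param universe_size Optional override of the cluster-universe size;
#'   defaults to the number of distinct clusters observed in the table.
#' @return A list with `virus_ids`, `clusters` (list of unique cluster-id
#'   vectors) and universe size `n`.
#' @export
cluster_profiles <- function(clusters, universe_size = NULL) {
  stopifnot(all(c("virus_id", "cluster_id") %in% names(clusters)))
  sets <- lapply(split(as.character(clusters$cluster_id),
                       as.character(clusters$virus_id)), unique)
  n <- length(unique(as.character(clusters$cluster_id)))
  if (!is.null(universe_size)) {
    if (universe_size < n) stop("universe_size smaller than observed cluster count")
    n <- as.integer(universe_size)
  }
  list(virus_ids = names(sets), clusters = unname(sets), n = n)
}

#' Build virus-prokaryote edges from alignment and interaction evidence
#'
#' An edge is created when any of three evidence sources supports the pair:
#' a CRISPR-spacer hit, a BLASTN alignment with E-value strictly below
#' `tau2`, or a known interaction from the training split. A pair appears
#' once regardless of how many sources support it; per-source provenance
#' flags are kept for reporting.
#'
#' @param blast Data.frame of BLAST tabular (outfmt 6) hits with at least
#'   `qseqid` (virus), `sseqid` (prokaryote) and `evalue`; when a pair has
#'   several HSPs the minimum E-value is used. May be `NULL` or empty.
#' @param crispr Data.frame with columns `prokaryote_id`, `virus_id`
#'   (already filtered hits). May be `NULL` or empty.
#' @param known Data.frame with columns `virus_id`, `prokaryote_id` of
#'   training-split interactions only; the caller must not pass test pairs.
#' @param viruses,prokaryotes Character vectors of registered node ids used
#'   to validate every row.
#' @param params A [graph_params()] object (supplies `tau2`).
#' @return Data.frame with `virus_id`, `prokaryote_id` and logical
#'   provenance columns `crispr`, `blast`, `known`.
#' @export
build_v2p_edges <- function(blast = NULL, crispr = NULL, known = NULL,
                            viruses, prokaryotes, params = graph_params()) {
  stopifnot(inherits(params, "graph_params"))
  check_ids <- function(df, vcol, pcol, what) {
    bad_v <- !(df[[vcol]] %in% viruses)
    bad_p <- !(df[[pcol]] %in% prokaryotes)
    if (any(bad_v)) {
      stop(sprintf("%s row %d: unknown virus id '%s'", what,
                   which(bad_v)[1], df[[vcol]][which(bad_v)[1]]))
    }
    if (any(bad_p)) {
      stop(sprintf("%s row %d: unknown prokaryote id '%s'", what,
                   which(bad_p)[1], df[[pcol]][which(bad_p)[1]]))
    }
  }
  pairs <- list()
  if (!is.null(blast) && nrow(blast)) {
    check_ids(blast, "qseqid", "sseqid", "blast")
    key <- paste(blast$qseqid, blast$sseqid, sep = "\r")
    emin <- tapply(blast$evalue, key, min)
    hit <- names(emin)[emin < params$tau2]
    if (length(hit)) {
      sp <- strsplit(hit, "\r", fixed = TRUE)
      pairs$blast <- data.frame(virus_id = vapply(sp, `[`, "", 1),
                                prokaryote_id = vapply(sp, `[`, "", 2),
                                src = "blast", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(crispr) && nrow(crispr)) {
    check_ids(crispr, "virus_id", "prokaryote_id", "crispr")
    pairs$crispr <- data.frame(virus_id = as.character(crispr$virus_id),
                               prokaryote_id = as.character(crispr$prokaryote_id),
                               src = "crispr", stringsAsFactors = FALSE)
  }
  if (!is.null(known) && nrow(known)) {
    check_ids(known, "virus_id", "prokaryote_id", "known")
    pairs$known <- data.frame(virus_id = as.character(known$virus_id),
                              prokaryote_id = as.character(known$prokaryote_id),
                              src = "known", stringsAsFactors = FALSE)
  }
  if (!length(pairs)) {
    return(data.frame(virus_id = character(), prokaryote_id = character(),
                      crispr = logical(), blast = logical(), known = logical()))
  }
  all <- do.call(rbind, pairs)
  key <- paste(all$virus_id, all$prokaryote_id, sep = "\r")
  uk <- sort(unique(key))
  out <- data.frame(
    virus_id = vapply(strsplit(uk, "\r", fixed = TRUE), `[`, "", 1),
    prokaryote_id = vapply(strsplit(uk, "\r", fixed = TRUE), `[`, "", 2),
    crispr = uk %in% key[all$src == "crispr"],
    blast = uk %in% key[all$src == "blast"],
    known = uk %in% key[all$src == "known"],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble the virus-prokaryote heterogeneous graph
#'
#' Builds the symmetric block adjacency
#' \deqn{A = \begin{pmatrix} R_{vv} & R_{vp} \\ R_{vp}^T & 0 \end{pmatrix}}
#' with viruses first, then prokaryotes; the prokaryote-prokaryote block is
#' structurally zero (prokaryotes exchange messages only through viruses).
#' Node order is lexicographic within each class, so construction is
#' reproducible bit-for-bit.
#'
#' @param v2v Data.frame of virus-virus edges (columns `virus1`, `virus2`),
#'   e.g. from [build_v2v_edges()]. May be empty.
#' @param v2p Data.frame of virus-prokaryote edges (columns `virus_id`,
#'   `prokaryote_id`), e.g. from [build_v2p_edges()]. May be empty.
#' @param viruses,prokaryotes Character vectors registering every node;
#'   nodes without edges are kept (and reported as isolated).
#' @return An object of class `"phg_graph"`: list with `viruses`,
#'   `prokaryotes`, `nodes` (ordered ids), sparse adjacency `A`, degree
#'   vector `degree`, the edge tables, and `isolated` node ids.
#' @export
assemble_graph <- function(v2v, v2p, viruses, prokaryotes) {
  viruses <- sort(unique(as.character(viruses)))
  prokaryotes <- sort(unique(as.character(prokaryotes)))
  if (length(intersect(viruses, prokaryotes))) {
    stop("virus and prokaryote id sets overlap")
  }
  nodes <- c(viruses, prokaryotes)
  nn <- length(nodes)
  idx <- function(id, what) {
    m <- match(id, nodes)
    if (anyNA(m)) stop("unregistered ", what, " id: ", id[which(is.na(m))[1]])
    m
  }
  ii <- integer(0); jj <- integer(0)
  if (!is.null(v2v) && nrow(v2v)) {
    a <- idx(as.character(v2v$virus1), "virus")
    b <- idx(as.character(v2v$virus2), "virus")
    if (any(a == b)) stop("self-loop virus pair not allowed")
    if (any(a > length(viruses)) || any(b > length(viruses))) {
      stop("v2v edge references a prokaryote id")
    }
    ii <- c(ii, a, b); jj <- c(jj, b, a)
  }
  if (!is.null(v2p) && nrow(v2p)) {
    a <- idx(as.character(v2p$virus_id), "virus")
    b <- idx(as.character(v2p$prokaryote_id), "prokaryote")
    if (any(a > length(viruses))) stop("v2p edge: virus column holds a prokaryote id")
    if (any(b <= length(viruses))) stop("v2p edge: prokaryote column holds a virus id")
    ii <- c(ii, a, b); jj <- c(jj, b, a)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nn, nn),
                            dimnames = list(nodes, nodes), use.last.ij = TRUE)
  A <- methods::as(A, "generalMatrix")
  deg <- Matrix::rowSums(A)
  isolated <- nodes[deg == 0]
  if (length(isolated)) {
    warning(length(isolated), " isolated node(s) with no edges: ",
            paste(utils::head(isolated, 5), collapse = ", "),
            if (length(isolated) > 5) ", ..." else "")
  }
  structure(list(viruses = viruses, prokaryotes = prokaryotes, nodes = nodes,
                 A = A, degree = deg, v2v = v2v, v2p = v2p,
                 isolated = isolated),
            class = "phg_graph")
}

#' @method print phg_graph
#' @export
print.phg_graph <- function(x, ...) {
  cat("Virus-prokaryote heterogeneous graph\n")
  cat(sprintf("  %d viruses, %d prokaryotes\n",
              length(x$viruses), length(x$prokaryotes)))
  cat(sprintf("  %d virus-virus edges, %d virus-prokaryote edges\n",
              if (is.null(x$v2v)) 0L else nrow(x$v2v),
              if (is.null(x$v2p)) 0L else nrow(x$v2p)))
  if (length(x$isolated)) {
    cat(sprintf("  %d isolated node(s)\n", length(x$isolated)))
  }
  invisible(x)
}

#' Symmetrically normalized propagation operator
#'
#' Returns \eqn{\tilde A = D^{-1/2} A D^{-1/2}}, the operator applied at
#' every light-graph-convolution layer. Each edge `(u, w)` carries weight
#' \eqn{1/\sqrt{d_u d_w}}; rows and columns of zero-degree nodes are zero
#' (an isolated node neither emits nor receives messages).
#'
#' @param g A `"phg_graph"` from [assemble_graph()].
#' @return A sparse symmetric matrix of the same dimension as `g$A`.
#' @export
normalized_operator <- function(g) {
  stopifnot(inherits(g, "phg_graph"))
  d <- g$degree
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  An <- Matrix::Diagonal(x = dinv) %*% g$A %*% Matrix::Diagonal(x = dinv)
  dimnames(An) <- dimnames(g$A)
  An
}

#' One-line build report for a graph
#'
#' @param g A `"phg_graph"`.
#' @return A list (JSON-serializable) of node/edge counts per evidence
#'   type and the isolated-node list.
#' @export
graph_report <- function(g) {
  stopifnot(inherits(g, "phg_graph"))
  v2p <- g$v2p
  list(
    n_viruses = length(g$viruses),
    n_prokaryotes = length(g$prokaryotes),
    n_v2v_edges = if (is.null(g$v2v)) 0L else nrow(g$v2v),
    n_v2p_edges = if (is.null(v2p)) 0L else nrow(v2p),
    n_v2p_crispr = if (is.null(v2p) || !nrow(v2p)) 0L else sum(v2p$crispr),
    n_v2p_blast = if (is.null(v2p) || !nrow(v2p)) 0L else sum(v2p$blast),
    n_v2p_known = if (is.null(v2p) || !nrow(v2p)) 0L else sum(v2p$known),
    isolated = as.list(g$isolated)
  )
}
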