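#' Parameters of the planted-block synthetic ecosystem
#'
#' Describes a toy phage-host ecosystem with block structure: viruses of a
#' block share a signature set of protein clusters (so the hypergeometric
#' test links them) and infect that block's prokaryotes; alignment evidence
#' concentrates within blocks, with configurable false negatives and
#' spurious cross-block hits.
#'
#' @param blocks Number of host blocks.
#' @param viruses_per_block,prokaryotes_per_block Nodes per block.
#' @param universe Total number of distinct protein clusters.
#' @param signature Signature clusters reserved per block (disjoint
#'   across blocks).
#' @param sig_per_virus Signature clusters carried by each virus.
#' @param bg_per_virus Background clusters (drawn from the shared pool)
#'   carried by each virus.
#' @param holdout Fraction of each block's viruses whose true pair is
#'   moved to the test split (the viruses stay in the graph, linked only
#'   through similarity and alignment evidence).
#' @param fn_blast,fn_crispr Per-true-pair probability that the BLAST /
#'   CRISPR evidence row is *not* emitted.
#' @param fp_blast Per cross-block (virus, prokaryote) probability of a
#'   spurious BLAST row; its E-value is drawn log-uniformly over
#'   `1e-8..1e2`, so some spurious rows pass a `tau2 = 1e-5` threshold and
#'   some do not.
#' @param preset `"small"` (4 x 5 viruses), `"medium"` (4 x 10, the
#'   default study condition) or `"sparse"` (weak-evidence regime: fewer
#'   signature clusters, most alignment evidence missing). Explicit
#'   arguments override the preset.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list of class `"ecosystem_params"`.
#' @export
ecosystem_params <- function(blocks = 4L, viruses_per_block = 10L,
                             prokaryotes_per_block = 2L, universe = 200L,
                             signature = 15L, sig_per_virus = 12L,
                             bg_per_virus = 3L, holdout = 0.2,
                             fn_blast = 0.2, fn_crispr = 0.5,
                             fp_blast = 0.02,
                             preset = c("medium", "small", "sparse"),
                             seed = 1L) {
  preset <- match.arg(preset)
  p <- as.list(environment())
  p$preset <- preset
  if (preset == "small" && missing(viruses_per_block)) p$viruses_per_block <- 5L
  if (preset == "sparse") {
    if (missing(signature)) p$signature <- 8L
    if (missing(sig_per_virus)) p$sig_per_virus <- 5L
    if (missing(bg_per_virus)) p$bg_per_virus <- 3L
    if (missing(fn_blast)) p$fn_blast <- 0.6
    if (missing(fn_crispr)) p$fn_crispr <- 0.85
  }
  stopifnot(p$blocks >= 1, p$viruses_per_block >= 1,
            p$prokaryotes_per_block >= 1, p$holdout > 0 || p$holdout == 0,
            p$holdout < 1, p$fn_blast >= 0, p$fn_blast <= 1,
            p$fn_crispr >= 0, p$fn_crispr <= 1, p$fp_blast >= 0,
            p$fp_blast <= 1, p$sig_per_virus <= p$signature)
  if (p$blocks * p$signature > p$universe) {
    stop("signature clusters exceed the universe: blocks * signature > universe")
  }
  structure(p, class = "ecosystem_params")
}

#' Generate a synthetic planted-block phage-host ecosystem
#'
#' Emits every table the pipeline consumes: a long protein-cluster table,
#' BLAST outfmt-6 and CRISPR evidence, train/test interaction splits, a
#' balanced 3-level taxonomy (one species per block, genera grouping two
#' blocks, families grouping four) and the ground-truth pairing. Each
#' virus carries mostly its block's signature clusters plus a few
#' background clusters, and truly interacts with exactly one prokaryote of
#' its block.
#'
#' @param params An [ecosystem_params()] object.
#' @return A list with `clusters`, `blast`, `crispr`, `train_pairs`,
#'   `test_pairs`, `taxonomy`, `truth`, `viruses`, `prokaryotes`, `params`.
#'   Deterministic given `params$seed`; the caller's RNG state is restored.
#' @export
make_ecosystem <- function(params = ecosystem_params()) {
  stopifnot(inherits(params, "ecosystem_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)

  B <- params$blocks
  vb <- params$viruses_per_block
  pb <- params$prokaryotes_per_block
  viruses <- sprintf("virus_%02d_%02d", rep(seq_len(B), each = vb),
                     rep(seq_len(vb), B))
  prokaryotes <- sprintf("prok_%02d_%02d", rep(seq_len(B), each = pb),
                         rep(seq_len(pb), B))
  v_block <- rep(seq_len(B), each = vb)
  p_block <- rep(seq_len(B), each = pb)
  cluster_ids <- sprintf("PC_%04d", seq_len(params$universe))
  sig_sets <- split(cluster_ids[seq_len(B * params$signature)],
                    rep(seq_len(B), each = params$signature))
  background <- cluster_ids[-seq_len(B * params$signature)]

  cl_rows <- lapply(seq_along(viruses), function(i) {
    b <- v_block[i]
    sig <- sample(sig_sets[[b]], params$sig_per_virus)
    bg <- if (params$bg_per_virus > 0 && length(background)) {
      sample(background, min(params$bg_per_virus, length(background)))
    } else character()
    cl <- c(sig, bg)
    data.frame(virus_id = viruses[i],
               protein_id = sprintf("%s_p%02d", viruses[i], seq_along(cl)),
               cluster_id = cl, stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, cl_rows)

  # one true host per virus, inside its own block
  host_idx <- vapply(v_block, function(b) {
    cands <- which(p_block == b)
    if (length(cands) == 1L) cands else cands[sample.int(length(cands), 1L)]
  }, integer(1))
  truth <- data.frame(virus_id = viruses, prokaryote_id = prokaryotes[host_idx],
                      block = v_block, split = "train", stringsAsFactors = FALSE)
  for (b in seq_len(B)) {
    in_b <- which(v_block == b)
    n_test <- round(params$holdout * length(in_b))
    if (n_test > 0) {
      test_vs <- sample(in_b, n_test)
      truth$split[test_vs] <- "test"
    }
  }
  train_pairs <- truth[truth$split == "train", c("virus_id", "prokaryote_id")]
  test_pairs <- truth[truth$split == "test", c("virus_id", "prokaryote_id")]
  rownames(train_pairs) <- rownames(test_pairs) <- NULL

  # alignment evidence around true pairs (emitted independently of split)
  blast_rows <- list(); crispr_rows <- list()
  for (i in seq_along(viruses)) {
    p <- truth$prokaryote_id[i]
    if (stats::runif(1) > params$fn_blast) {
      len <- sample(200:2000, 1)
      qs <- sample(1:5000, 1)
      blast_rows[[length(blast_rows) + 1L]] <- data.frame(
        qseqid = viruses[i], sseqid = p,
        pident = round(stats::runif(1, 85, 100), 2), length = len,
        mismatch = sample(0:20, 1), gapopen = sample(0:3, 1),
        qstart = qs, qend = qs + len - 1, sstart = 1000, send = 1000 + len - 1,
        evalue = 10^stats::runif(1, -50, -10),
        bitscore = round(stats::runif(1, 100, 2000), 1),
        stringsAsFactors = FALSE)
    }
    if (stats::runif(1) > params$fn_crispr) {
      crispr_rows[[length(crispr_rows) + 1L]] <- data.frame(
        prokaryote_id = p, virus_id = viruses[i],
        spacer_id = sprintf("%s_sp%02d", p, i), mismatches = 0L,
        coverage = 1.0, stringsAsFactors = FALSE)
    }
  }
  # spurious cross-block BLAST rows; e-values straddle typical tau2
  for (i in seq_along(viruses)) {
    for (j in seq_along(prokaryotes)) {
      if (p_block[j] != v_block[i] && stats::runif(1) < params$fp_blast) {
        len <- sample(50:500, 1)
        blast_rows[[length(blast_rows) + 1L]] <- data.frame(
          qseqid = viruses[i], sseqid = prokaryotes[j],
          pident = round(stats::runif(1, 70, 95), 2), length = len,
          mismatch = sample(5:50, 1), gapopen = sample(0:5, 1),
          qstart = 1, qend = len, sstart = 1, send = len,
          evalue = 10^stats::runif(1, -8, 2),
          bitscore = round(stats::runif(1, 30, 200), 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_blast <- data.frame(qseqid = character(), sseqid = character(),
                            pident = numeric(), length = integer(),
                            mismatch = integer(), gapopen = integer(),
                            qstart = integer(), qend = integer(),
                            sstart = integer(), send = integer(),
                            evalue = numeric(), bitscore = numeric())
  blast <- if (length(blast_rows)) do.call(rbind, blast_rows) else empty_blast
  crispr <- if (length(crispr_rows)) do.call(rbind, crispr_rows) else
    data.frame(prokaryote_id = character(), virus_id = character(),
               spacer_id = character(), mismatches = integer(),
               coverage = numeric())

  taxonomy <- data.frame(
    prokaryote_id = prokaryotes,
    species = sprintf("Species_%02d", p_block),
    genus = sprintf("Genus_%02d", ceiling(p_block / 2)),
    family = sprintf("Family_%02d", ceiling(p_block / 4)),
    stringsAsFactors = FALSE)

  list(clusters = clusters, blast = blast, crispr = crispr,
       train_pairs = train_pairs, test_pairs = test_pairs,
       taxonomy = taxonomy, truth = truth,
       viruses = viruses, prokaryotes = prokaryotes, params = params)
}

#' Build the heterogeneous graph of a synthetic ecosystem
#'
#' Convenience wrapper: cluster profiles -> virus-virus edges, evidence
#' tables -> virus-prokaryote edges (training interactions only), then
#' [assemble_graph()] over all registered nodes.
#'
#' @param eco Output of [make_ecosystem()].
#' @param params A [graph_params()] object.
#' @param quiet Suppress the isolated-node warning (they are expected in
#'   sparse regimes).
#' @return A `"phg_graph"`.
#' @export
ecosystem_graph <- function(eco, params = graph_params(), quiet = FALSE) {
  profiles <- cluster_profiles(eco$clusters)
  v2v <- build_v2v_edges(profiles, params)
  v2p <- build_v2p_edges(blast = eco$blast, crispr = eco$crispr,
                         known = eco$train_pairs,
                         viruses = eco$viruses, prokaryotes = eco$prokaryotes,
                         params = params)
  if (quiet) {
    suppressWarnings(assemble_graph(v2v, v2p, eco$viruses, eco$prokaryotes))
  } else {
    assemble_graph(v2v, v2p, eco$viruses, eco$prokaryotes)
  }
}

#' Random nucleotide sequences for fragmentation experiments
#'
#' @param n Number of sequences.
#' @param min_len,max_len Length range (uniform).
#' @param seed Optional seed (RNG state restored).
#' @return A [Biostrings::DNAStringSet] named `contig_00001...`.
#' @export
random_genomes <- function(n, min_len = 6000L, max_len = 60000L, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  lens <- sample(min_len:max_len, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("contig_%05d", seq_len(n))
  out
}

#' Fragment viral contigs into fixed-length windows
#'
#' For each repeat, cuts one uniformly positioned window of `length` bases
#' out of every input sequence; sequences shorter than the window are
#' skipped with a warning. Used to probe prediction robustness on short
#' contigs (e.g. 1 kbp / 2 kbp / 5 kbp fragments drawn repeatedly).
#'
#' @param fasta A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param length Window length in bases (>= 1).
#' @param repeats Number of independent repeats (default 10).
#' @param seed Optional seed (RNG state restored).
#' @return A list of `repeats` `DNAStringSet`s; fragment names are
#'   `<source>|rep<r>|<start>-<end>` (1-based, inclusive).
#' @export
fragment_contigs <- function(fasta, length, repeats = 10L, seed = NULL) {
  stopifnot(length >= 1, repeats >= 1)
  if (is.character(fasta)) fasta <- Biostrings::readDNAStringSet(fasta)
  if (!methods::is(fasta, "DNAStringSet")) {
    stop("'fasta' must be a DNAStringSet or a FASTA file path")
  }
  if (!base::length(fasta)) stop("empty FASTA input")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  widths <- Biostrings::width(fasta)
  short <- widths < length
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than ", length,
            " bp skipped: ", paste(utils::head(names(fasta)[short], 3),
                                   collapse = ", "),
            if (sum(short) > 3) ", ..." else "")
  }
  keep <- which(!short)
  lapply(seq_len(repeats), function(r) {
    starts <- vapply(widths[keep], function(w) {
      if (w == length) 1L else sample.int(w - length + 1L, 1L)
    }, integer(1))
    frags <- Biostrings::subseq(fasta[keep], start = starts,
                                width = length)
    names(frags) <- sprintf("%s|rep%d|%d-%d", names(fasta)[keep], r,
                            starts, starts + length - 1L)
    frags
  })
}
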