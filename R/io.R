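read_tsv_checked <- function(path, required, what, header = TRUE,
                             col.names = NULL) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- if (is.null(col.names)) {
    utils::read.delim(path, header = header, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")
  } else {
    utils::read.delim(path, header = header, sep = "\t", col.names = col.names,
                      stringsAsFactors = FALSE, quote = "")
  }
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write the protein-cluster membership table
#'
#' Tab-delimited with a header line; columns `virus_id`, `protein_id`,
#' `cluster_id`.
#'
#' @param path File path.
#' @return `read_cluster_table()` a data.frame; writers return `path`
#'   invisibly.
#' @export
read_cluster_table <- function(path) {
  df <- read_tsv_checked(path, c("virus_id", "protein_id", "cluster_id"),
                         "cluster table")
  df
}

#' @rdname read_cluster_table
#' @param clusters Data.frame to write.
#' @export
write_cluster_table <- function(clusters, path) write_tsv(clusters, path)

blast6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read / write BLAST tabular output (outfmt 6)
#'
#' Headerless, 12 tab-delimited columns (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`). Rows with a
#' different field count raise an error naming the offending line.
#'
#' @param path File path.
#' @return A data.frame with the 12 standard columns.
#' @export
read_blast_outfmt6 <- function(path) {
  if (!file.exists(path)) stop("BLAST file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character()), 12), blast6_cols))
    return(out)
  }
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf != 12)
  if (length(bad)) {
    stop(sprintf("BLAST outfmt-6 file %s: line %d has %d field(s), expected 12",
                 path, bad[1], nf[bad[1]]))
  }
  df <- utils::read.delim(text = lines, header = FALSE, sep = "\t",
                          col.names = blast6_cols, stringsAsFactors = FALSE,
                          quote = "")
  df
}

#' @rdname read_blast_outfmt6
#' @param hits Data.frame with the 12 outfmt-6 columns.
#' @export
write_blast_outfmt6 <- function(hits, path) {
  miss <- setdiff(blast6_cols, names(hits))
  if (length(miss)) stop("missing outfmt-6 column(s): ", paste(miss, collapse = ", "))
  utils::write.table(hits[, blast6_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write the CRISPR-spacer hit table
#'
#' Tab-delimited with header; requires columns `prokaryote_id` (the
#' spacer-carrying prokaryote) and `virus_id`; extra hit-quality columns
#' pass through. The table is taken as already-filtered evidence.
#'
#' @param path File path.
#' @export
read_crispr_table <- function(path) {
  read_tsv_checked(path, c("prokaryote_id", "virus_id"), "CRISPR table")
}

#' @rdname read_crispr_table
#' @param hits Data.frame to write.
#' @export
write_crispr_table <- function(hits, path) write_tsv(hits, path)

#' Read / write virus-prokaryote interaction pair tables
#'
#' Tab-delimited with header; columns `virus_id`, `prokaryote_id`.
#'
#' @param path File path.
#' @export
read_pairs <- function(path) {
  read_tsv_checked(path, c("virus_id", "prokaryote_id"), "pairs table")
}

#' @rdname read_pairs
#' @param pairs Data.frame to write.
#' @export
write_pairs <- function(pairs, path) {
  write_tsv(pairs[, c("virus_id", "prokaryote_id")], path)
}

#' Read / write the prokaryote taxonomy lineage table
#'
#' Tab-delimited with header; columns `prokaryote_id`, `species`, `genus`,
#' `family`. Duplicate prokaryote ids are an error.
#'
#' @param path File path.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_checked(path, c("prokaryote_id", "species", "genus", "family"),
                         "taxonomy table")
  if (anyDuplicated(df$prokaryote_id)) {
    stop("duplicate prokaryote_id in taxonomy: ",
         df$prokaryote_id[duplicated(df$prokaryote_id)][1])
  }
  df
}

#' @rdname read_taxonomy
#' @param taxonomy Data.frame to write.
#' @export
write_taxonomy <- function(taxonomy, path) write_tsv(taxonomy, path)

#' Write / read a graph archive directory
#'
#' Persists a `"phg_graph"` as plain text: `nodes.tsv` (id, type),
#' `v2v_edges.tsv`, `v2p_edges.tsv` (with provenance flags), the adjacency
#' in MatrixMarket coordinate format (`adjacency.mtx`) and a JSON build
#' report. `read_graph_archive()` reconstructs the graph from the node and
#' edge lists and verifies it against the stored adjacency.
#'
#' @param g A `"phg_graph"`.
#' @param dir Directory (created if needed).
#' @return The directory (writer) or a `"phg_graph"` (reader).
#' @export
write_graph_archive <- function(g, dir) {
  stopifnot(inherits(g, "phg_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(node_id = g$nodes,
                       type = rep(c("virus", "prokaryote"),
                                  c(length(g$viruses), length(g$prokaryotes)))),
            file.path(dir, "nodes.tsv"))
  v2v <- g$v2v
  if (is.null(v2v) || !nrow(v2v)) {
    v2v <- data.frame(virus1 = character(), virus2 = character())
  }
  write_tsv(v2v, file.path(dir, "v2v_edges.tsv"))
  v2p <- g$v2p
  if (is.null(v2p) || !nrow(v2p)) {
    v2p <- data.frame(virus_id = character(), prokaryote_id = character(),
                      crispr = logical(), blast = logical(), known = logical())
  }
  write_tsv(v2p, file.path(dir, "v2p_edges.tsv"))
  Matrix::writeMM(methods::as(g$A, "CsparseMatrix"),
                  file.path(dir, "adjacency.mtx"))
  jsonlite::write_json(graph_report(g), file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_graph_archive
#' @export
read_graph_archive <- function(dir) {
  nodes <- read_tsv_checked(file.path(dir, "nodes.tsv"),
                            c("node_id", "type"), "nodes")
  v2v <- read_tsv_checked(file.path(dir, "v2v_edges.tsv"),
                          c("virus1", "virus2"), "v2v edges")
  v2p <- read_tsv_checked(file.path(dir, "v2p_edges.tsv"),
                          c("virus_id", "prokaryote_id"), "v2p edges")
  g <- suppressWarnings(assemble_graph(
    v2v, v2p,
    viruses = nodes$node_id[nodes$type == "virus"],
    prokaryotes = nodes$node_id[nodes$type == "prokaryote"]))
  A_stored <- Matrix::readMM(file.path(dir, "adjacency.mtx"))
  # MatrixMarket round-trips may come back as pattern/symmetric classes
  A_stored <- methods::as(methods::as(A_stored, "dMatrix"), "generalMatrix")
  if (!all(dim(A_stored) == dim(g$A)) || max(abs(g$A - A_stored)) > 0) {
    stop("graph archive ", dir, ": adjacency does not match edge lists")
  }
  g
}

#' Write / read an embedding table
#'
#' Tab-delimited text: first column `node_id`, then `e1..ed` embedding
#' coordinates at full double precision.
#'
#' @param H Numeric matrix with node ids as row names.
#' @param path File path.
#' @export
write_embeddings <- function(H, path) {
  stopifnot(!is.null(rownames(H)))
  df <- data.frame(node_id = rownames(H),
                   format(as.data.frame(H), digits = 17, trim = TRUE,
                          scientific = TRUE),
                   stringsAsFactors = FALSE)
  names(df) <- c("node_id", sprintf("e%d", seq_len(ncol(H))))
  write_tsv(df, path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- read_tsv_checked(path, "node_id", "embeddings")
  H <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(H) <- "double"
  rownames(H) <- df$node_id
  colnames(H) <- NULL
  H
}

#' Write / read a host-ranking report
#'
#' TSV form: columns `virus_id`, `rank`, `prokaryote_id`, `score`.
#' JSON form: one object per virus with its ranked host list.
#'
#' @param rankings A `"host_ranking"` object.
#' @param path Output path.
#' @export
write_ranking_tsv <- function(rankings, path) {
  stopifnot(inherits(rankings, "host_ranking"))
  rows <- lapply(names(rankings), function(v) {
    data.frame(virus_id = v, rank = rankings[[v]]$rank,
               prokaryote_id = rankings[[v]]$prokaryote_id,
               score = sprintf("%.10g", rankings[[v]]$score),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_ranking_tsv
#' @export
read_ranking_tsv <- function(path) {
  df <- read_tsv_checked(path, c("virus_id", "rank", "prokaryote_id", "score"),
                         "ranking report")
  out <- lapply(split(df, df$virus_id), function(d) {
    d <- d[order(d$rank), ]
    data.frame(prokaryote_id = d$prokaryote_id, score = as.numeric(d$score),
               rank = d$rank, stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- out[unique(df$virus_id)]
  class(out) <- "host_ranking"
  out
}

#' @rdname write_ranking_tsv
#' @export
write_ranking_json <- function(rankings, path) {
  stopifnot(inherits(rankings, "host_ranking"))
  jsonlite::write_json(unclass(rankings), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bundle and serialize a run configuration
#'
#' Merges graph thresholds, training control, options and file paths into
#' one JSON-serializable record carrying the seed and a content hash, so
#' every output directory documents exactly how it was produced.
#'
#' @param params A [graph_params()] object.
#' @param control A [phagehost_control()] object.
#' @param paths,options Named lists, free-form.
#' @return A list of class `"run_config"` with a `config_hash` field.
#' @export
run_config <- function(params = graph_params(),
                       control = phagehost_control(),
                       paths = list(), options = list()) {
  cfg <- list(graph = unclass(params), train = unclass(control),
              options = options, paths = paths, seed = control$seed)
  cfg$config_hash <- content_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE))
  structure(cfg, class = "run_config")
}

# deterministic polynomial hash (base 131 mod 2^31-1) over UTF-8 bytes;
# exact in double arithmetic since intermediate values stay below 2^53
content_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @rdname run_config
#' @param cfg A `"run_config"`.
#' @param path Output JSON path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
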