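make_profiles <- function(sets, n) {
  list(virus_ids = names(sets), clusters = unname(sets), n = n)
}

test_that("virus-virus edges follow the hypergeometric threshold", {
  # two fully overlapping profiles in a large universe: strong link
  pr <- make_profiles(list(A = c("c1", "c2"), B = c("c1", "c2")), 100)
  e <- build_v2v_edges(pr, graph_params(tau1 = 0.01))
  expect_equal(nrow(e), 1)
  expect_equal(e$virus1, "A"); expect_equal(e$virus2, "B")
  expect_equal(e$prob, 1 / choose(100, 2), tolerance = 1e-12)

  # single shared cluster in a tiny universe: P(>=1) = 5/6, no edge
  pr <- make_profiles(list(A = c("c1", "c2"), B = c("c1", "c3")), 4)
  expect_equal(nrow(build_v2v_edges(pr, graph_params(tau1 = 0.5))), 0)

  # disjoint profiles are never linked, any tau1
  pr <- make_profiles(list(A = c("c1"), B = c("c2")), 50)
  expect_equal(nrow(build_v2v_edges(pr, graph_params(tau1 = 1))), 0)

  expect_error(build_v2v_edges(make_profiles(list(A = "c1"), 5)), "at least 2")
  pr <- make_profiles(list(A = "c1", A = "c1"), 5)
  expect_error(build_v2v_edges(pr), "duplicate")
})

test_that("lowering tau1 never adds virus-virus edges", {
  set.seed(42)
  sets <- lapply(1:12, function(i) {
    sample(sprintf("c%02d", 1:30), sample(5:12, 1))
  })
  names(sets) <- sprintf("V%02d", 1:12)
  pr <- make_profiles(sets, 30)
  taus <- c(0.5, 0.1, 0.01, 0.001)
  edges <- lapply(taus, function(t) {
    e <- build_v2v_edges(pr, graph_params(tau1 = t))
    paste(e$virus1, e$virus2)
  })
  for (i in seq_along(taus)[-1]) {
    expect_true(all(edges[[i]] %in% edges[[i - 1]]))
  }
})

test_that("virus-prokaryote edges union three evidence sources with provenance", {
  vs <- c("v1", "v2"); ps <- c("p1", "p2")
  gp <- graph_params(tau2 = 1e-5)
  empty <- build_v2p_edges(viruses = vs, prokaryotes = ps, params = gp)
  expect_equal(nrow(empty), 0)

  # E-value exactly at tau2 is excluded (strict inequality)
  bl <- data.frame(qseqid = c("v1", "v1"), sseqid = c("p1", "p2"),
                   evalue = c(1e-5, 0.9e-5))
  e <- build_v2p_edges(blast = bl, viruses = vs, prokaryotes = ps, params = gp)
  expect_equal(e$prokaryote_id, "p2")

  # same pair via crispr and known: one edge, both flags
  cr <- data.frame(prokaryote_id = "p1", virus_id = "v1")
  kn <- data.frame(virus_id = "v1", prokaryote_id = "p1")
  e <- build_v2p_edges(crispr = cr, known = kn, viruses = vs, prokaryotes = ps,
                       params = gp)
  expect_equal(nrow(e), 1)
  expect_true(e$crispr && e$known && !e$blast)

  # multiple HSPs: the per-pair minimum e-value decides
  bl <- data.frame(qseqid = c("v2", "v2"), sseqid = c("p1", "p1"),
                   evalue = c(1, 1e-9))
  e <- build_v2p_edges(blast = bl, viruses = vs, prokaryotes = ps, params = gp)
  expect_equal(nrow(e), 1)

  # unknown id errors name the row
  bad <- data.frame(qseqid = "vX", sseqid = "p1", evalue = 0)
  expect_error(build_v2p_edges(blast = bad, viruses = vs, prokaryotes = ps),
               "row 1.*vX")
})

test_that("raising tau2 never removes virus-prokaryote edges", {
  set.seed(7)
  bl <- data.frame(qseqid = sample(c("v1", "v2"), 30, TRUE),
                   sseqid = sample(c("p1", "p2", "p3"), 30, TRUE),
                   evalue = 10^stats::runif(30, -12, 0))
  for (pair in list(c(1e-8, 1e-5), c(1e-5, 1e-3))) {
    e_lo <- build_v2p_edges(blast = bl, viruses = c("v1", "v2"),
                            prokaryotes = c("p1", "p2", "p3"),
                            params = graph_params(tau2 = pair[1]))
    e_hi <- build_v2p_edges(blast = bl, viruses = c("v1", "v2"),
                            prokaryotes = c("p1", "p2", "p3"),
                            params = graph_params(tau2 = pair[2]))
    expect_true(all(paste(e_lo$virus_id, e_lo$prokaryote_id) %in%
                      paste(e_hi$virus_id, e_hi$prokaryote_id)))
  }
})

test_that("assembled adjacency has the documented block structure", {
  g <- two_node_graph()
  expect_equal(as.matrix(g$A), matrix(c(0, 1, 1, 0), 2,
                                      dimnames = list(g$nodes, g$nodes)))
  expect_equal(unname(g$degree), c(1, 1))

  # 2 viruses with a v2v edge plus one v2p edge from virus 1 -> degrees 2,1,1
  g <- suppressWarnings(assemble_graph(
    v2v = data.frame(virus1 = "v1", virus2 = "v2"),
    v2p = data.frame(virus_id = "v1", prokaryote_id = "p1"),
    viruses = c("v1", "v2"), prokaryotes = "p1"))
  expect_equal(unname(g$degree), c(2, 1, 1))
  A <- as.matrix(g$A)
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) == 0))

  # edgeless graph: all-zero adjacency, isolated nodes flagged
  expect_warning(
    g0 <- assemble_graph(NULL, NULL, c("v1", "v2"), "p1"),
    "isolated")
  expect_equal(sum(g0$A), 0)
  expect_setequal(g0$isolated, c("v1", "v2", "p1"))
})

test_that("prokaryote-prokaryote block is structurally zero on random graphs", {
  set.seed(11)
  for (i in 1:10) {
    g <- random_hetero_graph(sample(3:20, 1), sample(2:10, 1))
    V <- length(g$viruses)
    pp <- as.matrix(g$A[(V + 1):length(g$nodes), (V + 1):length(g$nodes)])
    expect_equal(sum(abs(pp)), 0)
    expect_equal(unname(g$degree), unname(Matrix::rowSums(g$A)))
  }
})

test_that("normalized operator weights equal 1/sqrt(du*dw) edge by edge", {
  # star: one virus linked to 4 prokaryotes -> every edge weight 1/2
  g <- suppressWarnings(assemble_graph(
    NULL, data.frame(virus_id = "v1", prokaryote_id = sprintf("p%d", 1:4)),
    viruses = "v1", prokaryotes = sprintf("p%d", 1:4)))
  An <- normalized_operator(g)
  expect_equal(unname(An["v1", sprintf("p%d", 1:4)]), rep(0.5, 4))

  set.seed(23)
  for (i in 1:10) {
    g <- random_hetero_graph(sample(5:25, 1), sample(3:12, 1))
    An <- as.matrix(normalized_operator(g))
    A <- as.matrix(g$A)
    d <- g$degree
    for (u in seq_along(g$nodes)) {
      for (w in which(A[u, ] != 0)) {
        expect_equal(An[u, w], unname(1 / sqrt(d[u] * d[w])), tolerance = 1e-15)
      }
    }
    expect_true(isSymmetric(An))
  }
})

test_that("normalized operator zeroes isolated nodes and is a contraction", {
  expect_warning(
    g <- assemble_graph(NULL,
                        data.frame(virus_id = "v1", prokaryote_id = "p1"),
                        viruses = c("v1", "v2"), prokaryotes = "p1"),
    "isolated")
  An <- as.matrix(normalized_operator(g))
  expect_equal(An["v2", ], c(v1 = 0, v2 = 0, p1 = 0))
  expect_equal(An[, "v2"], c(v1 = 0, v2 = 0, p1 = 0))

  # spectral radius <= 1 (eigen decomposition as the oracle)
  set.seed(31)
  for (i in 1:10) {
    g <- random_hetero_graph(sample(10:40, 1), sample(5:10, 1))
    An <- as.matrix(normalized_operator(g))
    expect_lte(max(abs(eigen(An, symmetric = TRUE,
                             only.values = TRUE)$values)), 1 + 1e-10)
  }
})

test_that("graph report counts nodes and edges per evidence type", {
  vs <- c("v1", "v2"); ps <- c("p1", "p2")
  v2p <- build_v2p_edges(
    blast = data.frame(qseqid = "v1", sseqid = "p1", evalue = 1e-9),
    crispr = data.frame(prokaryote_id = "p2", virus_id = "v1"),
    known = data.frame(virus_id = "v2", prokaryote_id = "p1"),
    viruses = vs, prokaryotes = ps)
  g <- assemble_graph(data.frame(virus1 = "v1", virus2 = "v2"), v2p, vs, ps)
  rep <- graph_report(g)
  expect_equal(rep$n_v2v_edges, 1)
  expect_equal(rep$n_v2p_edges, 3)
  expect_equal(rep$n_v2p_blast, 1)
  expect_equal(rep$n_v2p_crispr, 1)
  expect_equal(rep$n_v2p_known, 1)
})
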