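toy_taxonomy <- data.frame(
  prokaryote_id = c("p1", "p2", "p3", "p4"),
  species = c("s1", "s2", "s2b", "s3"),
  genus = c("g1", "g2", "g2", "g3"),
  family = c("f1", "f2", "f2", "f2"),
  stringsAsFactors = FALSE)

test_that("host scores are dot products; sigmoid preserves ranks", {
  H <- rbind(v1 = c(1, 0), v2 = c(0.5, 0.5), p1 = c(0.6, 0.8), p2 = c(1, 0))
  S <- score_hosts(H, c("v1", "v2"), c("p1", "p2"))
  expect_equal(S["v1", "p1"], 0.6)
  expect_equal(S["v1", "p2"], 1)
  expect_equal(S["v2", "p1"], 0.7)
  # identical vectors score their squared norm; orthogonal vectors zero
  expect_equal(score_hosts(H, "v1", "p2")[1, 1], 1)
  H2 <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(score_hosts(H2, "a", "b")[1, 1], 0)
  expect_error(score_hosts(H, "vX", "p1"), "unknown node")

  Ssig <- score_hosts(H, c("v1", "v2"), c("p1", "p2"), sigmoid = TRUE)
  expect_equal(Ssig, stats::plogis(S))
  for (v in rownames(S)) {
    expect_equal(order(-S[v, ]), order(-Ssig[v, ]))
  }
})

test_that("rank_hosts sorts descending with lexicographic tie-break", {
  S <- matrix(c(0.2, 0.9, 0.2, 0.5), 1,
              dimnames = list("v1", c("pB", "pA", "pD", "pC")))
  rk <- rank_hosts(S)
  expect_equal(rk$v1$prokaryote_id, c("pA", "pC", "pB", "pD"))
  expect_equal(rk$v1$score, c(0.9, 0.5, 0.2, 0.2))
  expect_equal(rk$v1$rank, 1:4)

  # all-equal scores: pure lexicographic order; k beyond P gives full list
  S0 <- matrix(1, 1, 4, dimnames = list("v1", c("pC", "pA", "pD", "pB")))
  expect_equal(rank_hosts(S0, k = 99)$v1$prokaryote_id,
               c("pA", "pB", "pC", "pD"))
  expect_equal(nrow(rank_hosts(S0, k = 2)$v1), 2)

  # permutation property and agreement with a reference sort
  set.seed(61)
  S <- matrix(stats::rnorm(3 * 15), 3, 15,
              dimnames = list(sprintf("v%d", 1:3), sprintf("q%02d", 1:15)))
  rk <- rank_hosts(S)
  for (v in rownames(S)) {
    expect_setequal(rk[[v]]$prokaryote_id, colnames(S))
    expect_equal(rk[[v]]$score, sort(S[v, ], decreasing = TRUE),
                 ignore_attr = TRUE)
  }
})

test_that("accuracy at rank follows the taxonomy containment rules", {
  rankings <- structure(list(
    vA = data.frame(prokaryote_id = c("p1", "p2"), score = c(2, 1), rank = 1:2),
    vB = data.frame(prokaryote_id = c("p3", "p1"), score = c(2, 1), rank = 1:2),
    vC = data.frame(prokaryote_id = c("p4", "p1"), score = c(2, 1), rank = 1:2),
    vD = data.frame(prokaryote_id = c("p1", "p4"), score = c(2, 1), rank = 1:2)
  ), class = "host_ranking")
  tp <- data.frame(virus_id = c("vA", "vB", "vC", "vD"),
                   prokaryote_id = c("p1", "p2", "p4", "p1"))
  # vA, vC, vD exact; vB predicts p3 (species s2b) vs truth p2 (s2):
  # wrong species, same genus
  expect_equal(as.numeric(accuracy_at_rank(rankings, tp, toy_taxonomy,
                                           "species")), 0.75)
  expect_equal(as.numeric(accuracy_at_rank(rankings, tp, toy_taxonomy,
                                           "genus")), 1)
  expect_equal(as.numeric(accuracy_at_rank(rankings, tp, toy_taxonomy,
                                           "family")), 1)

  # multi-host virus: matching any known host's taxon counts
  tp2 <- data.frame(virus_id = c("vB", "vB"), prokaryote_id = c("p2", "p3"))
  expect_equal(as.numeric(accuracy_at_rank(rankings, tp2, toy_taxonomy,
                                           "species")), 1)

  expect_error(accuracy_at_rank(rankings,
                                data.frame(virus_id = "vZ",
                                           prokaryote_id = "p1"),
                                toy_taxonomy), "no ranking")
  bad_tax <- toy_taxonomy[1:2, ]
  expect_error(accuracy_at_rank(rankings, tp, bad_tax), "missing taxonomy")
})

test_that("accuracy is monotone from species to genus to family", {
  set.seed(71)
  eco <- make_ecosystem(ecosystem_params(seed = 71))
  proks <- eco$prokaryotes
  for (i in 1:10) {
    rankings <- structure(lapply(unique(eco$test_pairs$virus_id), function(v) {
      data.frame(prokaryote_id = sample(proks), score = sort(stats::runif(length(proks)), TRUE),
                 rank = seq_along(proks))
    }), class = "host_ranking")
    names(rankings) <- unique(eco$test_pairs$virus_id)
    accs <- sapply(c("species", "genus", "family"), function(lv) {
      as.numeric(accuracy_at_rank(rankings, eco$test_pairs, eco$taxonomy, lv))
    })
    expect_true(accs["species"] <= accs["genus"] &&
                  accs["genus"] <= accs["family"])
  }
})

test_that("similarity binning stratifies accuracy correctly", {
  rankings <- structure(list(
    vA = data.frame(prokaryote_id = "p1", score = 1, rank = 1),
    vB = data.frame(prokaryote_id = "p3", score = 1, rank = 1),
    vC = data.frame(prokaryote_id = "p4", score = 1, rank = 1),
    vD = data.frame(prokaryote_id = "p2", score = 1, rank = 1)
  ), class = "host_ranking")
  tp <- data.frame(virus_id = c("vA", "vB", "vC", "vD"),
                   prokaryote_id = c("p1", "p2", "p4", "p4"))
  sim <- c(vA = 0.1, vB = 0.3, vC = 0.8, vD = 0.9)

  # one bin covering everything reduces to plain accuracy
  tab <- evaluate_binned(rankings, tp, toy_taxonomy, sim, c(0, 1))
  expect_equal(tab$n, 4L)
  expect_equal(tab$accuracy,
               as.numeric(accuracy_at_rank(rankings, tp, toy_taxonomy,
                                           "species")))

  # hand-checked two-bin split: low bin {vA correct, vB wrong} = 0.5,
  # high bin {vC correct, vD wrong} = 0.5
  tab <- evaluate_binned(rankings, tp, toy_taxonomy, sim, c(0, 0.5, 1))
  expect_equal(tab$n, c(2L, 2L))
  expect_equal(tab$accuracy, c(0.5, 0.5))

  # empty bin reports n = 0 and NA accuracy
  tab <- evaluate_binned(rankings, tp, toy_taxonomy, sim, c(0, 0.05, 0.5, 1))
  expect_equal(tab$n[1], 0L)
  expect_true(is.na(tab$accuracy[1]))

  expect_error(evaluate_binned(rankings, tp, toy_taxonomy,
                               sim[c("vA", "vB")], c(0, 1)),
               "missing similarity")
})

test_that("predict method returns rankings aligned with score matrices", {
  eco <- make_ecosystem(ecosystem_params(preset = "small", seed = 2))
  g <- ecosystem_graph(eco, quiet = TRUE)
  fit <- phagehost(g, eco$train_pairs,
                   control = phagehost_control(d = 16, epochs = 20, seed = 2))
  vs <- unique(eco$test_pairs$virus_id)
  S <- predict(fit, virus_ids = vs, type = "scores")
  rk <- predict(fit, virus_ids = vs, k = 3)
  expect_equal(dim(S), c(length(vs), length(eco$prokaryotes)))
  for (v in vs) {
    expect_equal(rk[[v]]$prokaryote_id[1],
                 colnames(S)[order(-S[v, ], colnames(S))[1]])
    expect_equal(nrow(rk[[v]]), 3)
  }
})
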