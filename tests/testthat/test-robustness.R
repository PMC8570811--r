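test_that("Jeffreys interval boundary conventions and symmetry hold", {
  expect_identical(jeffreys_interval(0, 10)$low, 0)
  expect_identical(jeffreys_interval(10, 10)$high, 1)
  j <- jeffreys_interval(5, 10)
  expect_equal(j$low + j$high, 1, tolerance = 1e-9)   # Beta(5.5, 5.5) symmetry
  expect_error(jeffreys_interval(11, 10), "k <= n")
  expect_error(jeffreys_interval(1, 0), "k <= n")
})

test_that("Jeffreys endpoints invert the Beta CDF (bisection oracle)", {
  invert <- function(target, k, n) {
    lo <- 0; hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (pbeta(mid, k + 0.5, n - k + 0.5) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (kn in list(c(20, 100), c(3, 17), c(250, 400))) {
    j <- jeffreys_interval(kn[1], kn[2])
    expect_equal(j$low, invert(0.025, kn[1], kn[2]), tolerance = 1e-8)
    expect_equal(j$high, invert(0.975, kn[1], kn[2]), tolerance = 1e-8)
  }
})

test_that("Jeffreys interval width shrinks with n and coverage is near nominal", {
  widths <- sapply(c(20, 80, 320, 1280), function(n) {
    j <- jeffreys_interval(round(0.3 * n), n)
    j$high - j$low
  })
  expect_true(all(diff(widths) < 0))

  set.seed(2024)
  p_true <- 0.3; n <- 60
  k <- rbinom(10000, n, p_true)
  covered <- vapply(k, function(ki) {
    j <- jeffreys_interval(ki, n)
    j$low <= p_true && p_true <= j$high
  }, logical(1))
  expect_gt(mean(covered), 0.93)
  expect_lt(mean(covered), 0.97)
})

test_that("fragility index agrees with the exhaustive linear-scan oracle", {
  set.seed(99)
  tested <- 0
  while (tested < 60) {
    a <- sample(5:60, 1); b <- sample(0:80, 1)
    c_ <- sample(0:40, 1); d <- sample(50:400, 1)
    t <- contingency_table(a, b, c_, d)
    thr <- 1e-3
    if (fisher_right_tail(t) >= thr) next
    tested <- tested + 1
    fr <- fragility_index(t, threshold = thr)
    r_star <- oracle_fragility_scan(a, b, c_, d, thr)
    if (!fr$capped) {
      expect_identical(fr$index, r_star)
    } else {
      # cap reached: the true crossing (if any) lies beyond r_max
      expect_true(is.na(r_star) || r_star > fr$r_max)
    }
    # p-sequence over removals is non-decreasing
    rs <- 0:fr$index
    ps <- sapply(rs, function(r) fisher_right_tail(
      contingency_table(a - r, b, c_, d)))
    expect_true(all(diff(ps) >= -1e-12))
  }
})

test_that("fragility handles borderline, robust and growing-support cases", {
  # permissive mode on a non-significant table: nothing to remove
  t_ns <- contingency_table(3, 10, 10, 40)
  expect_gt(fisher_right_tail(t_ns), 1e-6)
  expect_identical(fragility_index(t_ns, permissive = TRUE)$index, 0L)
  expect_error(fragility_index(t_ns), "significant")

  # overwhelming association stays under threshold through the whole cap
  t_rob <- contingency_table(500, 100, 200, 9200)
  fr <- fragility_index(t_rob, threshold = 1e-6)
  expect_true(fr$capped)
  expect_identical(fr$index, fr$r_max)

  # adding one supporting article never makes an association more fragile
  set.seed(5)
  checked <- 0
  while (checked < 25) {
    a <- sample(10:40, 1); b <- sample(0:30, 1)
    c_ <- sample(0:20, 1); d <- sample(100:400, 1)
    t <- contingency_table(a, b, c_, d)
    if (fisher_right_tail(t) >= 1e-4) next
    checked <- checked + 1
    f0 <- fragility_index(t, threshold = 1e-4)
    f1 <- fragility_index(contingency_table(a + 1, b, c_, d),
                          threshold = 1e-4)
    if (!f0$capped && !f1$capped) expect_gte(f1$index, f0$index)
  }
})

test_that("supporting corpus is the propagated intersection (cell a)", {
  kg <- tiny_kg()
  idx <- build_corpus_index(kg)
  sc <- supporting_corpus(idx, "compound:CID5793", "mesh:D044882")
  expect_identical(sc, sort(intersect(idx$propagated[["compound:CID5793"]],
                                      idx$propagated[["mesh:D044882"]])))
  t <- build_contingency(idx, "compound:CID5793", "mesh:D044882")
  expect_identical(length(sc), t$a)
  expect_identical(supporting_corpus(idx, "compound:CID962", "mesh:D044882"),
                   character())
})

test_that("a propagated family corpus is the union over its child diseases", {
  # compound linked only to two specific diseases; the family association
  # is carried by the union of their articles
  kg <- knowledge_graph(
    articles = paste0("a", 1:12),
    compounds = "compound:CID9651",
    descriptors = data.frame(
      id = c("mesh:Dfam", "mesh:Dang", "mesh:Dinf"),
      tree_number = c("C14.280.647", "C14.280.647.250", "C14.280.647.500")),
    discusses = data.frame(article = paste0("a", 1:6),
                           compound = "compound:CID9651"),
    subject_terms = data.frame(
      article = c("a1", "a2", "a3", "a4", "a9"),
      descriptor = c("mesh:Dang", "mesh:Dang", "mesh:Dinf", "mesh:Dinf",
                     "mesh:Dang")))
  idx <- build_corpus_index(kg)
  expect_identical(supporting_corpus(idx, "compound:CID9651", "mesh:Dfam"),
                   c("a1", "a2", "a3", "a4"))
})

test_that("importance scores follow the tf-idf formula and rank specific terms", {
  # 10-article corpus, descriptor on 5 of them, global explicit corpus 100
  # within a universe of 10000: tf = 0.5, idf = ln(100), score = tf * idf
  arts <- sprintf("b%05d", 1:10000)
  corpus <- arts[1:10]
  kg <- knowledge_graph(
    articles = arts,
    descriptors = data.frame(id = c("mesh:Dq", "mesh:Dubiq"),
                             tree_number = c("C01.100", "C01.200")),
    subject_terms = rbind(
      data.frame(article = arts[1:100], descriptor = "mesh:Dq"),
      data.frame(article = arts, descriptor = "mesh:Dubiq")))
  # mesh:Dq marks arts 1..100 but only 5 of the 10 corpus articles
  kg$subject_terms <- kg$subject_terms[
    !(kg$subject_terms$descriptor == "mesh:Dq" &
        kg$subject_terms$article %in% arts[6:10]), ]
  idx <- build_corpus_index(kg)
  prof <- importance_scores(corpus, kg, idx)
  rq <- prof[prof$mesh_id == "mesh:Dq", ]
  expect_equal(rq$tf, 0.5)
  expect_equal(rq$idf, log(10000 / 95), tolerance = 1e-12)
  expect_equal(rq$score, rq$tf * rq$idf, tolerance = 1e-12)
  # a descriptor covering the whole universe has idf = 0, score = 0,
  # despite tf = 1 in the corpus
  ru <- prof[prof$mesh_id == "mesh:Dubiq", ]
  expect_equal(ru$tf, 1)
  expect_equal(ru$score, 0)
  expect_lt(ru$score, rq$score)
  expect_error(importance_scores(character(), kg, idx), "empty")
})

test_that("importance scores are invariant to article order and exclude queries", {
  kg <- tiny_kg()
  idx <- build_corpus_index(kg)
  corpus <- supporting_corpus(idx, "compound:CID5793", "mesh:D044882")
  p1 <- importance_scores(corpus, kg, idx)
  p2 <- importance_scores(rev(corpus), kg, idx)
  expect_identical(p1, p2)
  p3 <- importance_scores(corpus, kg, idx,
                          exclude = c("compound:CID5793", "mesh:D003924"))
  expect_false("mesh:D003924" %in% p3$mesh_id)
})
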