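test_that("contingency construction is exact set arithmetic", {
  idx <- structure(list(
    explicit = list(), N = 10L, use_propagation = TRUE,
    propagated = list("compound:CID1" = paste0("a", 1:5),
                      "mesh:D1" = paste0("a", 6:8))),
    class = "corpus_index")
  t <- build_contingency(idx, "compound:CID1", "mesh:D1")
  expect_identical(c(t$a, t$b, t$c, t$d), c(0L, 5L, 3L, 2L))

  for (seed in 1:20) {
    set.seed(seed)
    N <- 50L
    ca <- sample(paste0("a", 1:N), sample(N, 1))
    ma <- sample(paste0("a", 1:N), sample(N, 1))
    idx$propagated <- list("compound:CID1" = ca, "mesh:D1" = ma)
    idx$N <- N
    t <- build_contingency(idx, "compound:CID1", "mesh:D1")
    expect_identical(t$a, length(intersect(ca, ma)))
    expect_identical(t$b, length(setdiff(ca, ma)))
    expect_identical(t$c, length(setdiff(ma, ca)))
    expect_identical(t$N, N)
  }
})

test_that("right-tailed Fisher p matches exhaustive enumeration and is monotone in a", {
  expect_equal(fisher_right_tail(contingency_table(0, 5, 3, 2)), 1)
  expect_equal(fisher_right_tail(contingency_table(3, 1, 1, 3)), 17 / 70,
               tolerance = 1e-12)
  # random tables vs the exact-coefficient oracle
  set.seed(42)
  for (i in 1:50) {
    cells <- as.integer(sample(0:12, 4, replace = TRUE))
    p <- fisher_right_tail(do.call(contingency_table, as.list(cells)))
    expect_equal(p, do.call(oracle_fisher, as.list(cells)), tolerance = 1e-12)
  }
  # fixing margins, increasing a strictly decreases p
  base <- c(n_chem = 12L, n_mesh = 9L, N = 40L)
  ps <- sapply(1:9, function(a) {
    fisher_right_tail(contingency_table(a, base["n_chem"] - a,
                                        base["n_mesh"] - a,
                                        base["N"] - base["n_chem"] - base["n_mesh"] + a))
  })
  expect_true(all(diff(ps) < 0))
})

test_that("large-universe tables keep a stable hypergeometric tail", {
  # ~1e7-article universe: the tail must neither overflow nor lose the scale
  p_mid <- fisher_right_tail(contingency_table(700, 99300, 49300, 9850700))
  expect_gt(p_mid, 0); expect_lt(p_mid, 1e-10)
  p_deep <- fisher_right_tail(contingency_table(1500, 98500, 48500, 9851500))
  expect_gt(p_deep, 0); expect_lt(p_deep, 1e-250)
  expect_equal(fisher_right_tail(contingency_table(0, 95000, 45000, 9860000)), 1)
})

test_that("odds ratio applies the Haldane-Anscombe correction at zero cells", {
  expect_equal(as.numeric(odds_ratio(contingency_table(3, 1, 1, 3))), 9)
  expect_false(attr(odds_ratio(contingency_table(3, 1, 1, 3)), "corrected"))
  expect_equal(as.numeric(odds_ratio(contingency_table(7, 7, 7, 7))), 1)
  or0 <- odds_ratio(contingency_table(0, 5, 3, 2))
  expect_true(attr(or0, "corrected"))
  expect_equal(as.numeric(or0), (0.5 * 2.5) / (5.5 * 3.5), tolerance = 1e-12)
})

test_that("chi-squared equals the Pearson cell-wise oracle, 0 on empty margins", {
  expect_equal(chi_squared(contingency_table(10, 10, 10, 10)), 0)
  expect_equal(chi_squared(contingency_table(20, 10, 10, 20)), 20 / 3,
               tolerance = 1e-12)
  expect_equal(chi_squared(contingency_table(0, 0, 5, 5)), 0)
  set.seed(7)
  for (i in 1:25) {
    cells <- as.integer(sample(0:30, 4, replace = TRUE))
    t <- do.call(contingency_table, as.list(cells))
    obs <- matrix(cells, 2, 2, byrow = TRUE)
    expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    oracle <- if (any(expected == 0)) 0 else sum((obs - expected)^2 / expected)
    expect_equal(chi_squared(t), oracle, tolerance = 1e-10)
  }
})

test_that("BH q-values reproduce the naive step-up and dominate p element-wise", {
  expect_equal(bh_qvalues(c(0.001, 0.01, 0.02, 0.04)),
               c(0.004, 0.02, 0.08 / 3, 0.04), tolerance = 1e-12)
  expect_identical(bh_qvalues(numeric()), numeric())
  expect_equal(bh_qvalues(0.37), 0.37)
  expect_equal(bh_qvalues(rep(0.2, 5)), rep(0.2, 5))
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_qvalues(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("candidate pairs respect category, class-size and support filters", {
  kg <- tiny_kg()
  idx <- build_corpus_index(kg)
  cand <- enumerate_candidate_pairs(kg, idx, enrichment_config())
  # exhaustive oracle: every chem x allowed-mesh pair with joint articles
  chems <- c(kg$compounds, unique(kg$classes$id))
  meshes <- unique(kg$descriptors$id)
  expected <- 0L
  for (ch in chems) for (d in meshes) {
    if (cooccurrence(idx, ch, d) >= 1) expected <- expected + 1L
  }
  expect_identical(nrow(cand), expected)
  expect_true(all(cand$support >= 1))

  # category filter: a descriptor living only under tree E is dropped
  kgE <- tiny_kg()
  kgE$descriptors$tree_number[kgE$descriptors$id == "mesh:D006262"] <- "E01.100"
  idxE <- build_corpus_index(kgE)
  candE <- enumerate_candidate_pairs(kgE, idxE, enrichment_config())
  expect_false("mesh:D006262" %in% candE$mesh)

  # class-size cap: a class at the cap is excluded, below it is kept
  capped <- enumerate_candidate_pairs(kg, idx,
                                      enrichment_config(class_size_cap = 1))
  expect_false(any(entity_kind(capped$chem) == "chemical_class"))
})

test_that("run_enrichment flags a strongly planted pair and only related pairs", {
  sim <- generate_synthetic_kg(synthetic_config(
    planted = data.frame(chem = 1, mesh = 1, lambda = 20), seed = 101))
  rec <- run_enrichment(sim$kg)
  planted_row <- rec[rec$chem_id == sim$truth$chem & rec$mesh_id == sim$truth$mesh, ]
  expect_true(planted_row$significant)
  expect_gt(planted_row$odds_ratio, 5)
  out <- evaluate_recovery(rec, sim$truth, sim$kg)
  expect_identical(out$power, 1)
  expect_identical(out$fdp, 0)
  # q >= p and the significance flag is exactly the q-threshold rule
  expect_true(all(rec$q_value >= rec$p_value - 1e-15))
  expect_identical(rec$significant, rec$q_value < 1e-6)
  # deterministic ordering: descending chi2, ties by ids
  expect_true(all(diff(rec$chi2) <= 0))
})

test_that("a vacuous threshold marks every tested pair significant", {
  kg <- tiny_kg()
  rec <- run_enrichment(kg, enrichment_config(q_threshold = 1))
  expect_gt(nrow(rec), 0)
  expect_true(all(rec$significant))
})

test_that("per-entity-kind BH adjusts compound and class families separately", {
  sim <- generate_synthetic_kg(synthetic_config(seed = 5))
  recg <- run_enrichment(sim$kg, enrichment_config())
  reck <- run_enrichment(sim$kg, enrichment_config(bh_scope = "per-entity-kind"))
  key <- paste(reck$chem_id, reck$mesh_id)
  for (kind in unique(entity_kind(reck$chem_id))) {
    sel <- entity_kind(reck$chem_id) == kind
    expect_equal(reck$q_value[sel], oracle_bh(reck$p_value[sel]),
                 tolerance = 1e-12)
  }
  # p-values identical across scopes, only the adjustment family changes
  expect_equal(reck$p_value[order(key)],
               recg$p_value[order(paste(recg$chem_id, recg$mesh_id))])
})

test_that("propagation comparison yields novel pairs with zero explicit support", {
  # signal planted at a leaf pair; ancestors only associate via propagation
  sim <- generate_synthetic_kg(synthetic_config(
    planted = data.frame(chem = 1, mesh = 1, lambda = 25), seed = 31))
  without <- run_enrichment(sim$kg, enrichment_config(use_propagation = FALSE))
  with <- run_enrichment(sim$kg, enrichment_config())
  cmp <- compare_association_sets(without, with)
  expect_gt(nrow(cmp$novel), 0)
  # every novel pair has empty explicit co-occurrence
  idx0 <- build_corpus_index(sim$kg, use_propagation = FALSE)
  for (i in seq_len(nrow(cmp$novel))) {
    expect_identical(cooccurrence(idx0, cmp$novel$chem_id[i],
                                  cmp$novel$mesh_id[i]), 0L)
  }
})

test_that("mesh-mesh mode tests unordered descriptor pairs once", {
  kg <- tiny_kg()
  rec <- run_enrichment(kg, enrichment_config(mesh_mesh = TRUE,
                                              q_threshold = 1))
  mm <- rec[entity_kind(rec$chem_id) == "mesh_descriptor", ]
  expect_gt(nrow(mm), 0)
  expect_true(all(mm$chem_id < mm$mesh_id))
  expect_identical(anyDuplicated(paste(mm$chem_id, mm$mesh_id)), 0L)
})
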