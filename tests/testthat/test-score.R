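pair_keys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# probability tables used to instantiate the worked example numerically
EXAMPLE_TABLES <- list(
  c("1" = 0.2, "2" = 0.5, "3" = 0.7),
  c("1" = 0.05, "2" = 0.3, "3" = 0.9),
  c("1" = 0.5, "2" = 0.5, "3" = 0.5)
)

test_that("worked five-node example: s0 = 1 and total = 1 + P(2) + P(3)P(1)", {
  toy <- fig_toy()
  expect_equal(shared_count(toy$g, "i", "j"), 1)
  for (p in EXAMPLE_TABLES) {
    bank <- manual_calibration_bank(p)
    s <- sn_score(toy$g, bank, "i", "j", shared_counts = toy$counts)
    expect_equal(s$s0, 1)
    expect_equal(s$s1, unname(p["2"]))
    expect_equal(s$s2, unname(p["3"] * p["1"]))
    expect_equal(s$total, unname(1 + p["2"] + p["3"] * p["1"]))
    # symmetric in the pair
    s_rev <- sn_score(toy$g, bank, "j", "i", shared_counts = toy$counts)
    expect_equal(s_rev$total, s$total)
    expect_equal(c(s_rev$s0, s_rev$s1, s_rev$s2), c(s$s0, s$s1, s$s2))
  }
})

test_that("shared counts match set intersection on toys and random graphs", {
  g0 <- pharm_graph(triangle_edges()[0, ],
    nodes = tibble::tibble(id = c("D1", "X1"), kind = c("drug", "disease")))
  expect_equal(shared_count(g0, "D1", "X1"), 0)

  g <- small_graph(seed = 31)
  kind_of <- oracle_kind_map(g)
  ids <- g$nodes$id
  for (i in sample(ids, 8)) {
    for (j in sample(setdiff(ids, i), 8)) {
      expect_equal(shared_count(g, i, j), oracle_shared_count(g$edges, i, j))
    }
  }
  expect_error(shared_count(g, ids[1], ids[1]), class = "sns_domain_error")
})

test_that("link weights: real links weigh 1, virtual links weigh P(shared count)", {
  bank <- manual_calibration_bank(c("1" = 0.2, "2" = 0.5))
  # D1 directly linked to P1 -> weight 1
  g <- pharm_graph(triangle_edges())
  expect_equal(link_weight(g, bank, "D1", "P1"), 1)

  # virtual pair with no shared neighbor -> P(0) = 0
  g2 <- pharm_graph(tibble::tibble(
    source_id = c("D1", "D2"), source_kind = "drug",
    target_id = c("P1", "P2"), target_kind = "protein"
  ))
  expect_equal(link_weight(g2, bank, "D1", "P2"), 0)

  # virtual pair mediated by two bridges -> P(2)
  g3 <- pharm_graph(tibble::tibble(
    source_id = c("D1", "D1", "Pa", "Pb"),
    source_kind = c("drug", "drug", "protein", "protein"),
    target_id = c("Pa", "Pb", "X1", "X1"),
    target_kind = c("protein", "protein", "disease", "disease")
  ))
  expect_equal(link_weight(g3, bank, "D1", "X1"), 0.5)
})

test_that("decomposition equals the full weight-matrix oracle on random graphs", {
  for (seed in c(1, 8)) {
    g <- small_graph(seed = seed, n_drugs = 6, n_proteins = 12, n_diseases = 6)
    bank <- calibrate_graph(g)
    ids <- g$nodes$id
    kind_of <- oracle_kind_map(g)
    pairs <- expand.grid(i = ids[kind_of[ids] == "drug"],
      j = ids[kind_of[ids] == "disease"], stringsAsFactors = FALSE)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]
      s <- sn_score(g, bank, i, j)
      expect_score_equal(s, oracle_score(g, bank, i, j))
    }
  }
})

test_that("simple mode is the bare count; extended dominates; P = 0 collapses them", {
  g <- small_graph(seed = 17)
  bank <- calibrate_graph(g)
  zero <- zero_bank()
  kind_of <- oracle_kind_map(g)
  drugs <- g$nodes$id[kind_of[g$nodes$id] == "drug"]
  diseases <- g$nodes$id[kind_of[g$nodes$id] == "disease"]
  for (i in sample(drugs, 5)) {
    for (j in sample(diseases, 5)) {
      simple <- sn_score(g, NULL, i, j, mode = "simple")
      expect_equal(simple$total, shared_count(g, i, j))
      expect_equal(simple$s1 + simple$s2, 0)
      ext <- sn_score(g, bank, i, j)
      expect_gte(ext$total, simple$total)
      collapsed <- sn_score(g, zero, i, j)
      expect_equal(collapsed$total, simple$total)
    }
  }
})

test_that("leave-one-out equals scoring the physically edge-deleted graph", {
  for (seed in c(4, 23)) {
    g <- small_graph(seed = seed, n_drugs = 6, n_proteins = 10, n_diseases = 6)
    bank <- calibrate_graph(g)
    cross <- g$edges[g$edges$category != "protein_protein", ]
    for (r in seq_len(nrow(cross))) {
      i <- cross$from[r]; j <- cross$to[r]
      loo <- sn_score(g, bank, i, j, leave_one_out = TRUE)
      direct <- sn_score(delete_edge(g, i, j), bank, i, j)
      expect_equal(loo$s0, direct$s0)
      expect_equal(loo$s1, direct$s1)
      expect_equal(loo$s2, direct$s2)
      expect_equal(loo$total, direct$total)
    }
    # leave-one-out on an unconnected pair is a no-op
    neg <- sample_negatives(g, "drug_disease", 3, seed = 1)
    for (r in seq_len(nrow(neg))) {
      expect_equal(
        sn_score(g, bank, neg$from[r], neg$to[r], leave_one_out = TRUE)$total,
        sn_score(g, bank, neg$from[r], neg$to[r])$total
      )
    }
  }
})

test_that("with a frozen calibration, adding a bridge edge raises the pair score", {
  g <- small_graph(seed = 12)
  bank <- calibrate_graph(g, policy = "fitted") # monotone P
  kind_of <- oracle_kind_map(g)
  # find (drug i, disease j, protein k) with k linked to i but not to j
  found <- FALSE
  for (r in which(g$edges$category == "drug_protein")) {
    i <- g$edges$from[r]; k <- g$edges$to[r]
    for (j in g$nodes$id[kind_of[g$nodes$id] == "disease"]) {
      if (!has_edge(g, k, j) && !has_edge(g, i, j)) {
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
  before <- sn_score(g, bank, i, j)$total
  edges2 <- dplyr::bind_rows(tidy(g)[, 1:4] %>%
    rlang::set_names(c("source_id", "target_id", "source_kind", "target_kind")) %>%
    dplyr::select("source_id", "source_kind", "target_id", "target_kind"),
    tibble::tibble(source_id = k, source_kind = "protein",
      target_id = j, target_kind = "disease"))
  g2 <- pharm_graph(edges2, nodes = g$nodes)
  after <- sn_score(g2, bank, i, j)$total
  expect_gt(after, before)
})

test_that("batch scoring agrees with pairwise calls and handles edge cases", {
  g <- small_graph(seed = 27, n_drugs = 6, n_proteins = 10, n_diseases = 6)
  bank <- calibrate_graph(g)
  batch <- score_all_pairs(g, bank, "drug_disease")
  expect_gt(nrow(batch), 0)
  for (r in sample(nrow(batch), min(12, nrow(batch)))) {
    s <- sn_score(g, bank, batch$from[r], batch$to[r],
      leave_one_out = batch$connected[r])
    expect_equal(batch$total[r], s$total)
    expect_equal(batch$s0[r], s$s0)
  }
  # every connected pair of the category appears
  dd <- g$edges[g$edges$category == "drug_disease", ]
  expect_true(all(pair_keys(dd$from, dd$to) %in% pair_keys(batch$from, batch$to)))
  # deterministic order
  expect_identical(batch, score_all_pairs(g, bank, "drug_disease"))

  # triangle: exactly one drug_disease row
  tri <- pharm_graph(triangle_edges())
  tbank <- manual_calibration_bank(c("1" = 0.2))
  expect_equal(nrow(score_all_pairs(tri, tbank, "drug_disease")), 1)

  # edgeless graph: empty result
  g0 <- pharm_graph(triangle_edges()[0, ],
    nodes = tibble::tibble(id = c("D1", "X1"), kind = c("drug", "disease")))
  expect_equal(nrow(score_all_pairs(g0, tbank, "drug_disease")), 0)
})

test_that("scoring rejects invalid pairs and missing calibration", {
  g <- small_graph(seed = 2)
  drugs <- g$nodes$id[oracle_kind_map(g)[g$nodes$id] == "drug"]
  expect_error(sn_score(g, NULL, drugs[1], drugs[1]), class = "sns_domain_error")
  expect_error(sn_score(g, NULL, drugs[1], drugs[2]), class = "sns_validation_error")
  expect_error(sn_score(g, NULL, drugs[1], "missing"), class = "sns_lookup_error")
  expect_error(sn_score(g, NULL, drugs[1], g$nodes$id[g$nodes$kind == "disease"][1]),
    class = "sns_calibration_missing")
})
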