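# Fixture builders and independent brute-force oracles. The oracles work
# straight off the edge table (never the package's adjacency structures or
# matrix products) so they are a second, independent route to every result.

triangle_edges <- function() {
  tibble::tibble(
    source_id = c("D1", "P1", "D1"),
    source_kind = c("drug", "protein", "drug"),
    target_id = c("P1", "X1", "X1"),
    target_kind = c("protein", "disease", "disease")
  )
}

# five-node configuration of the worked example: bridge m real on both sides,
# k real only to j, l real to neither; the surrounding-network shared counts
# (i,k) = 2, (i,l) = 3, (l,j) = 1 are injected
fig_toy <- function() {
  g <- pharm_graph(
    tibble::tibble(
      source_id = c("i", "m", "k"),
      source_kind = c("drug", "protein", "protein"),
      target_id = c("m", "j", "j"),
      target_kind = c("protein", "disease", "disease")
    ),
    nodes = tibble::tibble(id = "l", kind = "protein")
  )
  list(g = g, counts = c("i|k" = 2, "i|l" = 3, "j|l" = 1))
}

small_graph <- function(seed, n_drugs = 8, n_proteins = 16, n_diseases = 8,
                        n_modules = 2, p_within = 0.5, p_between = 0.08) {
  generate_network(synth_params(
    n_drugs = n_drugs, n_proteins = n_proteins, n_diseases = n_diseases,
    n_modules = n_modules, p_within = p_within, p_between = p_between,
    pp_within = p_within, pp_between = p_between, seed = seed
  ))$graph
}

oracle_neighbors <- function(edges, v) {
  sort(unique(c(edges$to[edges$from == v], edges$from[edges$to == v])))
}

oracle_shared_count <- function(edges, i, j, kinds = NULL, kind_of = NULL) {
  shared <- intersect(oracle_neighbors(edges, i), oracle_neighbors(edges, j))
  if (!is.null(kinds)) shared <- shared[kind_of[shared] %in% kinds]
  length(shared)
}

oracle_kind_map <- function(g) stats::setNames(g$nodes$kind, g$nodes$id)

# O(N^2) double loop over all cross-kind pairs of a category
oracle_shared_table <- function(g, category, bridge_kinds = NULL) {
  kind_of <- oracle_kind_map(g)
  kinds <- switch(category,
    drug_protein = c("drug", "protein"),
    protein_disease = c("protein", "disease"),
    drug_disease = c("drug", "disease")
  )
  left <- g$nodes$id[g$nodes$kind == kinds[1]]
  right <- g$nodes$id[g$nodes$kind == kinds[2]]
  edges <- g$edges
  edge_keys <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "|")
  rows <- list()
  for (i in left) {
    for (j in right) {
      n <- oracle_shared_count(edges, i, j, bridge_kinds, kind_of)
      conn <- paste(min(i, j), max(i, j), sep = "|") %in% edge_keys
      rows[[length(rows) + 1L]] <- c(n = n, conn = as.integer(conn))
    }
  }
  m <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(total = rep(1, nrow(m)), connected = m[, "conn"]),
    by = list(n = m[, "n"]), FUN = sum)
  agg[order(agg$n), ]
}

# weight of one (possibly virtual) link under a calibration bank
oracle_weight <- function(g, bank, x, y, kind_of, edge_keys) {
  if (paste(min(x, y), max(x, y), sep = "|") %in% edge_keys) return(1)
  k1 <- kind_of[[x]]; k2 <- kind_of[[y]]
  pair <- sort(c(k1, k2))
  cat <- if (k1 == k2) {
    if (k1 == "protein") attr(bank, "pp_weight_category") else NA_character_
  } else if (setequal(pair, c("drug", "protein"))) "drug_protein"
  else if (setequal(pair, c("disease", "protein"))) "protein_disease"
  else "drug_disease"
  if (is.na(cat)) return(0)
  n <- oracle_shared_count(g$edges, x, y, attr(bank, "bridge_kinds"), kind_of)
  connection_probability(bank[[cat]], n)
}

# full-weight-matrix evaluation of one pair: sum over every other node k of
# W_ik * W_kj, split into the s0/s1/s2 terms
oracle_score <- function(g, bank, i, j, leave_one_out = FALSE) {
  edges <- g$edges
  if (leave_one_out) {
    keep <- !((edges$from == i & edges$to == j) | (edges$from == j & edges$to == i))
    edges <- edges[keep, ]
  }
  g2 <- g
  g2$edges <- edges
  kind_of <- oracle_kind_map(g)
  edge_keys <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "|")
  s0 <- 0; s1 <- 0; s2 <- 0
  for (k in setdiff(g$nodes$id, c(i, j))) {
    a_ik <- paste(min(i, k), max(i, k), sep = "|") %in% edge_keys
    a_kj <- paste(min(k, j), max(k, j), sep = "|") %in% edge_keys
    w_ik <- oracle_weight(g2, bank, i, k, kind_of, edge_keys)
    w_kj <- oracle_weight(g2, bank, k, j, kind_of, edge_keys)
    if (a_ik && a_kj) s0 <- s0 + 1
    else if (a_ik || a_kj) s1 <- s1 + w_ik * w_kj
    else s2 <- s2 + w_ik * w_kj
  }
  list(s0 = s0, s1 = s1, s2 = s2, total = s0 + s1 + s2)
}

expect_score_equal <- function(s, oracle, tol = 1e-9) {
  expect_equal(s$s0, oracle$s0, tolerance = tol)
  expect_equal(s$s1, oracle$s1, tolerance = tol)
  expect_equal(s$s2, oracle$s2, tolerance = tol)
  expect_equal(s$total, oracle$total, tolerance = tol)
}

# Bernoulli-sampled shared-count table from a known logistic truth
simulated_table <- function(a, b, ns = 1:8, pairs_per_n = 2500, seed = 42,
                            category = "drug_disease") {
  withr::with_seed(seed, {
    p_true <- 1 / (1 + exp(a + b * ns))
    connected <- rbinom(length(ns), size = pairs_per_n, prob = p_true)
    structure(
      list(
        category = category,
        rows = tibble::tibble(
          n = c(0L, ns),
          pairs_total = c(pairs_per_n, rep(pairs_per_n, length(ns))),
          pairs_connected = c(0, connected)
        )
      ),
      class = "sns_shared_table"
    )
  })
}

zero_bank <- function() manual_calibration_bank(c("1" = 0))
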