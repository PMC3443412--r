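test_that("shared-count distribution matches hand-derived tallies on toys", {
  # triangle D1-P1-X1-D1 plus an isolated drug D2: the (D1, X1) pair shares
  # P1 (n = 1, connected); the (D2, X1) pair shares nothing (n = 0)
  g <- pharm_graph(triangle_edges(), nodes = tibble::tibble(id = "D2", kind = "drug"))
  tab <- count_shared_distribution(g, "drug_disease")
  expect_equal(tab$rows$n, c(0L, 1L))
  expect_equal(tab$rows$pairs_total, c(1, 1))
  expect_equal(tab$rows$pairs_connected, c(0, 1))

  # edgeless graph: a single n = 0 row counted by complement
  g0 <- pharm_graph(triangle_edges()[0, ],
    nodes = tibble::tibble(id = c("D1", "P1", "X1"),
      kind = c("drug", "protein", "disease")))
  tab0 <- count_shared_distribution(g0, "drug_disease")
  expect_equal(tab0$rows, tibble::tibble(n = 0L, pairs_total = 1, pairs_connected = 0))

  expect_error(count_shared_distribution(g, "protein_protein"),
    class = "sns_unsupported_category")
})

test_that("shared-count distribution equals the O(N^2) pair-scan oracle", {
  for (seed in c(2, 5, 13)) {
    g <- small_graph(seed = seed) # 32 nodes
    for (category in c("drug_protein", "protein_disease", "drug_disease")) {
      tab <- count_shared_distribution(g, category)
      oracle <- oracle_shared_table(g, category)
      expect_equal(tab$rows$n, oracle$n)
      expect_equal(tab$rows$pairs_total, oracle$total)
      expect_equal(tab$rows$pairs_connected, oracle$connected)
      # consistency: totals sum to the number of cross-kind pairs
      kinds <- strsplit(category, "_")[[1]]
      expect_equal(sum(tab$rows$pairs_total),
        sum(g$nodes$kind == kinds[1]) * sum(g$nodes$kind == kinds[2]))
      expect_true(all(tab$rows$pairs_connected <= tab$rows$pairs_total))
    }
    # restricted bridge kinds agree with the restricted oracle
    tabp <- count_shared_distribution(g, "drug_disease", bridge_kinds = "protein")
    oraclep <- oracle_shared_table(g, "drug_disease", bridge_kinds = "protein")
    expect_equal(tabp$rows$pairs_total, oraclep$total)
    expect_equal(tabp$rows$pairs_connected, oraclep$connected)
  }
})

test_that("empirical probability is the per-n connected fraction, zero at n = 0", {
  tab <- structure(list(category = "drug_disease",
    rows = tibble::tibble(n = c(0L, 2L, 3L), pairs_total = c(10, 4, 5),
      pairs_connected = c(0, 1, 5))), class = "sns_shared_table")
  expect_equal(empirical_probability(tab, 0), 0)
  expect_equal(empirical_probability(tab, 2), 0.25)
  expect_equal(empirical_probability(tab, 3), 1.0) # all connected: upper bound
  expect_true(is.na(empirical_probability(tab, 7))) # unobserved
  expect_error(empirical_probability(tab, -1), class = "sns_domain_error")
})

test_that("logistic fit recovers known parameters from Bernoulli tables", {
  tab <- simulated_table(a = 2, b = -1, ns = 1:8, pairs_per_n = 2500, seed = 42)
  fit <- fit_connection_probability(tab)
  expect_lt(abs(fit$a - 2), 0.1)
  expect_lt(abs(fit$b - (-1)), 0.1)
  expect_lt(fit$b, 0)
})

test_that("degenerate calibration tables raise typed fit errors", {
  flat <- structure(list(category = "drug_disease",
    rows = tibble::tibble(n = 0:5,
      pairs_total = c(100, rep(100, 5)),
      pairs_connected = c(0, rep(50, 5)))), class = "sns_shared_table")
  expect_error(fit_connection_probability(flat), class = "sns_monotonicity_error")

  two_rows <- structure(list(category = "drug_disease",
    rows = tibble::tibble(n = c(0L, 1L, 2L), pairs_total = c(5, 10, 10),
      pairs_connected = c(0, 2, 5))), class = "sns_shared_table")
  expect_error(fit_connection_probability(two_rows), class = "sns_fit_error")

  none_connected <- structure(list(category = "drug_disease",
    rows = tibble::tibble(n = 0:4, pairs_total = rep(50, 5),
      pairs_connected = rep(0, 5))), class = "sns_shared_table")
  expect_error(fit_connection_probability(none_connected), class = "sns_fit_error")
})

test_that("connection probability honours the evaluation policy", {
  tab <- simulated_table(a = 2, b = -1, ns = c(1:4, 6L), pairs_per_n = 2000, seed = 9)
  fit <- fit_connection_probability(tab)

  hybrid <- structure(list(category = "drug_disease", table = tab, fit = fit,
    policy = "hybrid"), class = "sns_calibration")
  fitted <- structure(list(category = "drug_disease", table = tab, fit = fit,
    policy = "fitted"), class = "sns_calibration")
  empirical <- structure(list(category = "drug_disease", table = tab, fit = NULL,
    policy = "empirical"), class = "sns_calibration")

  # P(0) = 0 under every policy
  for (cp in list(hybrid, fitted, empirical)) {
    expect_identical(connection_probability(cp, 0L), 0)
  }
  # hybrid: observed n -> empirical ratio; unobserved n -> fitted curve
  expect_equal(connection_probability(hybrid, 2L), empirical_probability(tab, 2L))
  expect_equal(connection_probability(hybrid, 5L), logistic_eval(fit, 5))
  expect_equal(connection_probability(hybrid, 12L), logistic_eval(fit, 12))
  # fitted: the curve everywhere (n > 0)
  expect_equal(connection_probability(fitted, c(1L, 5L)), logistic_eval(fit, c(1, 5)))
  # empirical: unobserved -> 0
  expect_equal(connection_probability(empirical, 5L), 0)
  # range invariant
  ns <- 0:20
  for (cp in list(hybrid, fitted, empirical)) {
    p <- connection_probability(cp, ns)
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_error(connection_probability(hybrid, -2L), class = "sns_domain_error")
})

test_that("whole-graph calibration produces one calibration per cross category", {
  g <- generate_network(synth_params(n_drugs = 20, n_proteins = 40, n_diseases = 20,
    n_modules = 2, seed = 4))$graph
  bank <- calibrate_graph(g)
  expect_s3_class(bank, "sns_calibration_bank")
  expect_named(unclass(bank), c("drug_protein", "protein_disease", "drug_disease"))
  gl <- glance(bank)
  expect_true(all(gl$policy %in% c("hybrid", "empirical")))
  expect_true(all(is.na(gl$b) | gl$b < 0))
})

test_that("score normalizer recovers a known logistic and is monotone", {
  withr::with_seed(7, {
    score <- runif(20000, 0, 10)
    connected <- runif(20000) < 1 / (1 + exp(2 - 1 * score))
  })
  fit <- calibrate_score_normalizer(
    tibble::tibble(score = score, connected = connected), bins = 25)
  expect_lt(abs(fit$a - 2), 0.1)
  expect_lt(abs(fit$b - (-1)), 0.1)

  s <- sort(runif(50, 0, 10))
  norm <- normalize_scores(fit, s)
  expect_true(all(diff(norm) >= 0))
  expect_true(all(norm > 0 & norm < 1))

  expect_error(
    calibrate_score_normalizer(tibble::tibble(score = runif(100), connected = FALSE)),
    class = "sns_fit_error"
  )
})

test_that("calibration banks survive a JSON round trip", {
  g <- small_graph(seed = 21)
  bank <- calibrate_graph(g)
  path <- withr::local_tempfile(fileext = ".json")
  calibration_to_json(bank, path)
  bank2 <- calibration_from_json(path)
  for (cc in names(bank)) {
    expect_equal(
      connection_probability(bank2[[cc]], 0:12),
      connection_probability(bank[[cc]], 0:12)
    )
  }
  expect_equal(attr(bank2, "pp_weight_category"), attr(bank, "pp_weight_category"))

  manual <- manual_calibration_bank(c("1" = 0.2, "2" = 0.5, "3" = 0.7))
  p2 <- withr::local_tempfile(fileext = ".json")
  calibration_to_json(manual, p2)
  manual2 <- calibration_from_json(p2)
  expect_equal(
    connection_probability(manual2$drug_disease, 0:4),
    c(0, 0.2, 0.5, 0.7, 0)
  )
})
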