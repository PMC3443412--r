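CALIBRATED_CATEGORIES <- c("drug_protein", "protein_disease", "drug_disease")

#' Shared-neighbor count distribution for one link category
#'
#' Scans every unordered cross-kind node pair of the category and tallies its
#' shared-neighbor count `n` into `pairs_total[n]`, and additionally into
#' `pairs_connected[n]` when the pair is directly linked. The ratio
#' `pairs_connected / pairs_total` at each `n` is the empirical connection
#' probability P(n). Pairs with `n = 0` are obtained by complement arithmetic
#' (all cross-kind pairs minus pairs with `n >= 1`), never enumerated, so the
#' scan stays sparse.
#'
#' Shared neighbors may be of any node kind adjacent to both endpoints unless
#' `bridge_kinds` restricts them; protein–protein links therefore contribute
#' bridging proteins.
#'
#' @param g a [pharm_graph()]
#' @param category one of `drug_protein`, `protein_disease`, `drug_disease`.
#'   The protein–protein category is not calibrated.
#' @param bridge_kinds optional kinds allowed as shared neighbors
#' @return an `sns_shared_table`: the category plus a tibble with columns
#'   `n`, `pairs_total`, `pairs_connected`
#' @export
count_shared_distribution <- function(g, category, bridge_kinds = NULL) {
  if (identical(category, "protein_protein")) {
    abort("protein_protein pairs are not calibrated; only the three cross-kind categories are",
      class = "sns_unsupported_category")
  }
  if (!category %in% CALIBRATED_CATEGORIES) {
    abort(paste0("unknown link category: ", category), class = "sns_validation_error")
  }
  kinds <- category_kinds(category)
  rows_idx <- which(g$nodes$kind == kinds[1])
  cols_idx <- which(g$nodes$kind == kinds[2])
  n_pairs <- length(rows_idx) * length(cols_idx)

  S0 <- shared_count_matrix(g, bridge_kinds)
  S0sub <- S0[rows_idx, cols_idx, drop = FALSE]
  entries <- Matrix::summary(methods::as(S0sub, "TsparseMatrix"))
  entries <- entries[entries$x > 0, , drop = FALSE]
  total_tab <- table(as.integer(entries$x))

  cat_edges <- g$edges[g$edges$category == category, ]
  if (nrow(cat_edges) > 0) {
    n_conn <- as.integer(S0[cbind(cat_edges$from, cat_edges$to)])
    conn_tab <- table(n_conn)
  } else {
    conn_tab <- table(integer(0))
  }

  ns <- sort(unique(c(0L, as.integer(names(total_tab)), as.integer(names(conn_tab)))))
  pairs_total <- vapply(ns, function(k) {
    if (k == 0L) n_pairs - nrow(entries) else as.integer(total_tab[as.character(k)])
  }, double(1))
  pairs_connected <- vapply(ns, function(k) {
    v <- conn_tab[as.character(k)]
    if (is.na(v)) 0 else as.double(v)
  }, double(1))

  structure(
    list(
      category = category,
      rows = tibble(n = ns, pairs_total = pairs_total, pairs_connected = pairs_connected)
    ),
    class = "sns_shared_table"
  )
}

#' @method print sns_shared_table
#' @export
print.sns_shared_table <- function(x, ...) {
  cat("<sns_shared_table> category:", x$category, "\n")
  print(x$rows)
  invisible(x)
}

#' Empirical connection probability at a given shared count
#'
#' P(n) is the fraction of directly connected pairs among all pairs sharing
#' exactly `n` neighbors; P(0) is 0 by definition. For an `n >= 1` never
#' observed in the table the probability is unknown and `NA` is returned.
#'
#' @param table an `sns_shared_table` from [count_shared_distribution()]
#' @param n non-negative integer shared count (vectorized)
#' @return numeric vector of probabilities (`NA` where unobserved)
#' @export
empirical_probability <- function(table, n) {
  if (any(n < 0)) abort("shared count must be non-negative", class = "sns_domain_error")
  rows <- table$rows
  idx <- match(n, rows$n)
  out <- ifelse(!is.na(idx) & rows$pairs_total[idx] > 0,
    rows$pairs_connected[idx] / rows$pairs_total[idx], NA_real_)
  out[n == 0] <- 0
  out
}

# weighted least-squares fit of f(x) = 1 / (1 + exp(a + b x)) to points
# (x, p) with weights w; deterministic start a = -logit(rate), b = -1
fit_logistic_points <- function(x, p, w, label = "logistic fit") {
  keep <- w > 0
  x <- x[keep]; p <- p[keep]; w <- w[keep]
  if (length(x) < 3) {
    abort(paste0(label, " needs at least 3 points with positive weight; got ", length(x)),
      class = "sns_fit_error")
  }
  if (sum(p * w) <= 0) {
    abort(paste0(label, ": no connected pairs (no positive class)"), class = "sns_fit_error")
  }
  # a flat or decreasing trend can only fit with b >= 0; reject it up front
  # (the numeric fit may not even start on such data)
  xm <- sum(w * x) / sum(w)
  pm <- sum(w * p) / sum(w)
  slope <- sum(w * (x - xm) * (p - pm)) / sum(w * (x - xm)^2)
  if (slope <= 1e-10) {
    abort(paste0(label, ": connection probability does not increase with the predictor",
      " (weighted slope ", signif(slope, 3), "); refusing a non-monotone fit"),
      class = "sns_monotonicity_error")
  }
  rate <- min(max(sum(p * w) / sum(w), 1e-6), 1 - 1e-6)
  start <- list(a = -stats::qlogis(rate), b = -1)
  dat <- data.frame(x = x, p = p)
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ 1 / (1 + exp(a + b * x)),
      data = dat, start = start, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste0(label, " did not converge: ", conditionMessage(e)),
        class = "sns_fit_error")
    }
  )
  cf <- stats::coef(fit)
  if (cf[["b"]] >= -1e-8) {
    abort(paste0(label, ": fitted b = ", signif(cf[["b"]], 3),
      " is not negative; connection probability must increase with shared count"),
      class = "sns_monotonicity_error")
  }
  structure(
    list(
      a = unname(cf[["a"]]), b = unname(cf[["b"]]),
      deviance = sum(w * stats::residuals(fit)^2),
      n_points = length(x)
    ),
    class = "sns_logistic"
  )
}

#' Fit the connecting-probability function
#'
#' Fits the logistic curve `f(x) = 1 / (1 + exp(a + b x))` to the empirical
#' points `(n, P(n))` for `n >= 1`, each weighted by the number of pairs
#' observed at that count, by weighted least squares with a deterministic
#' start. A fit with `b >= 0` (connection probability not increasing with
#' shared count) is rejected; callers fall back to the empirical policy.
#'
#' @param table an `sns_shared_table`
#' @return an `sns_logistic` with elements `a`, `b`, `deviance`, `n_points`
#' @export
fit_connection_probability <- function(table) {
  rows <- table$rows[table$rows$n >= 1 & table$rows$pairs_total > 0, ]
  fit <- fit_logistic_points(
    x = rows$n,
    p = rows$pairs_connected / rows$pairs_total,
    w = rows$pairs_total,
    label = paste0("connection-probability fit (", table$category, ")")
  )
  fit$category <- table$category
  fit
}

#' Evaluate a fitted logistic curve
#' @param fit an `sns_logistic`
#' @param x numeric vector
#' @return `1 / (1 + exp(a + b x))`
#' @export
logistic_eval <- function(fit, x) {
  1 / (1 + exp(fit$a + fit$b * x))
}

#' @method print sns_logistic
#' @export
print.sns_logistic <- function(x, ...) {
  cat("<sns_logistic> f(x) = 1/(1 + exp(a + b x)), a =", signif(x$a, 4),
    ", b =", signif(x$b, 4), "\n")
  invisible(x)
}

new_calibration <- function(category, table, fit, policy) {
  structure(list(category = category, table = table, fit = fit, policy = policy),
    class = "sns_calibration")
}

#' Connection probability under a calibration policy
#'
#' Evaluates P(n) for a calibrated category. P(0) = 0 under every policy.
#' Policy `"hybrid"` (the default produced by [calibrate_graph()]) uses the
#' empirical ratio where `n` was observed and the fitted logistic elsewhere;
#' `"fitted"` always uses the curve; `"empirical"` returns 0 where `n` was
#' never observed; `"manual"` looks up an injected table.
#'
#' @param cp an `sns_calibration`
#' @param n non-negative integer vector of shared counts
#' @return numeric vector of probabilities in `[0, 1]`
#' @export
connection_probability <- function(cp, n) {
  if (any(n < 0)) abort("shared count must be non-negative", class = "sns_domain_error")
  out <- numeric(length(n))
  pos <- n > 0
  if (!any(pos)) return(out)
  policy <- cp$policy
  if (policy == "manual") {
    v <- cp$table[as.character(n[pos])]
    v[is.na(v)] <- 0
    out[pos] <- unname(v)
    return(out)
  }
  emp <- empirical_probability(cp$table, n[pos])
  if (policy == "empirical") {
    emp[is.na(emp)] <- 0
    out[pos] <- emp
  } else if (policy == "fitted") {
    if (is.null(cp$fit)) abort("no fitted curve in calibration", class = "sns_calibration_missing")
    out[pos] <- logistic_eval(cp$fit, n[pos])
  } else if (policy == "hybrid") {
    fill <- is.na(emp)
    if (any(fill)) {
      emp[fill] <- if (is.null(cp$fit)) 0 else logistic_eval(cp$fit, n[pos][fill])
    }
    out[pos] <- emp
  } else {
    abort(paste0("unknown calibration policy: ", policy), class = "sns_validation_error")
  }
  out
}

#' @method print sns_calibration
#' @export
print.sns_calibration <- function(x, ...) {
  cat("<sns_calibration> category:", x$category, " policy:", x$policy, "\n")
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Calibrate connection probabilities for a whole graph
#'
#' Runs [count_shared_distribution()] and [fit_connection_probability()] for
#' each of the three cross-kind link categories and returns the bank of
#' per-category calibrations consumed by the scoring functions. The data are
#' calibrated per category because link counts are far from evenly
#' distributed across categories, so a shared count carries different
#' evidence in each. When a category's logistic fit fails (too few points,
#' or a non-increasing fit) that category falls back to the `"empirical"`
#' policy with a warning.
#'
#' @param g a [pharm_graph()]
#' @param policy `"hybrid"` (default), `"fitted"` or `"empirical"`
#' @param bridge_kinds optional kinds allowed as shared neighbors
#' @param pp_weight_category category whose calibration stands in for virtual
#'   protein–protein links when scoring (no P(n) is calibrated for the
#'   protein–protein category itself)
#' @return an `sns_calibration_bank` (named list of `sns_calibration`)
#' @export
calibrate_graph <- function(g, policy = c("hybrid", "fitted", "empirical"),
                            bridge_kinds = NULL,
                            pp_weight_category = "protein_disease") {
  policy <- match.arg(policy)
  stopifnot(pp_weight_category %in% CALIBRATED_CATEGORIES)
  bank <- lapply(CALIBRATED_CATEGORIES, function(cc) {
    tab <- count_shared_distribution(g, cc, bridge_kinds)
    fit <- tryCatch(fit_connection_probability(tab), error = function(e) {
      warn(paste0("calibration fit failed for ", cc, " (", conditionMessage(e),
        "); falling back to empirical policy"))
      NULL
    })
    pol <- if (is.null(fit) && policy != "empirical") "empirical" else policy
    new_calibration(cc, tab, fit, pol)
  })
  names(bank) <- CALIBRATED_CATEGORIES
  structure(bank,
    class = "sns_calibration_bank",
    bridge_kinds = bridge_kinds,
    pp_weight_category = pp_weight_category
  )
}

#' Build a calibration from a hand-specified probability table
#'
#' Injects known P(n) values instead of estimating them from a graph. Useful
#' for worked examples and for reusing probabilities frozen on a larger
#' network than the one being scored.
#'
#' @param category link category the table applies to
#' @param p named numeric vector: names are shared counts `n`, values P(n)
#' @return an `sns_calibration` with policy `"manual"`
#' @export
manual_calibration <- function(category, p) {
  stopifnot(is.numeric(p), !is.null(names(p)), all(p >= 0 & p <= 1))
  new_calibration(category, p, fit = NULL, policy = "manual")
}

#' @rdname manual_calibration
#' @param pp_weight_category see [calibrate_graph()]
#' @return `manual_calibration_bank()`: an `sns_calibration_bank` using the
#'   same table for every calibrated category
#' @export
manual_calibration_bank <- function(p, pp_weight_category = "protein_disease") {
  bank <- lapply(CALIBRATED_CATEGORIES, manual_calibration, p = p)
  names(bank) <- CALIBRATED_CATEGORIES
  structure(bank,
    class = "sns_calibration_bank",
    bridge_kinds = NULL,
    pp_weight_category = pp_weight_category
  )
}

#' Fit the score normalizer
#'
#' The raw shared neighborhood score has no upper bound and its scale differs
#' across link categories, so equal raw scores do not mean equal connection
#' odds. The normalizer maps a raw score to a probability-like value in
#' (0, 1) by binning scored pairs of known connection status, computing the
#' fraction connected per bin, and fitting the same logistic family against
#' the bin midpoints (weighted by bin occupancy).
#'
#' @param scores data frame with numeric column `score` and logical column
#'   `connected`, e.g. a [score_all_pairs()] result
#' @param bins number of equal-width score bins (default 20)
#' @return an `sns_logistic` with a `bin_edges` attribute; apply it with
#'   [normalize_scores()]
#' @export
calibrate_score_normalizer <- function(scores, bins = 20) {
  stopifnot(all(c("score", "connected") %in% names(scores)))
  s <- scores$score
  y <- as.logical(scores$connected)
  if (!any(y)) {
    abort("score normalizer: no connected pairs (no positive class)", class = "sns_fit_error")
  }
  edges <- seq(min(s), max(s), length.out = bins + 1)
  if (edges[1] == edges[length(edges)]) {
    abort("score normalizer: all scores identical", class = "sns_fit_error")
  }
  bin <- cut(s, breaks = edges, include.lowest = TRUE, labels = FALSE)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- tapply(y, bin, length)
  p <- tapply(y, bin, mean)
  used <- as.integer(names(w))
  fit <- fit_logistic_points(mids[used], as.numeric(p), as.numeric(w),
    label = "score normalizer")
  attr(fit, "bin_edges") <- edges
  fit
}

#' Normalize raw scores through a fitted normalizer
#'
#' Monotone increasing map into (0, 1); preserves the ranking of raw scores.
#' @param fit an `sns_logistic` from [calibrate_score_normalizer()]
#' @param score numeric vector of raw scores
#' @return numeric vector in (0, 1)
#' @export
normalize_scores <- function(fit, score) {
  logistic_eval(fit, score)
}

# ---- broom-style methods ----------------------------------------------------

#' @method tidy sns_shared_table
#' @export
tidy.sns_shared_table <- function(x, ...) {
  mutate(x$rows,
    category = x$category,
    p_empirical = empirical_probability(x, .data$n),
    .before = 1
  )
}

#' @method tidy sns_calibration
#' @export
tidy.sns_calibration <- function(x, ...) {
  if (x$policy == "manual") {
    tab <- tibble(category = x$category, n = as.integer(names(x$table)),
      p_empirical = unname(x$table))
  } else {
    tab <- tidy(x$table)
  }
  tab$p_policy <- connection_probability(x, tab$n)
  if (!is.null(x$fit)) tab$p_fitted <- logistic_eval(x$fit, tab$n)
  tab
}

#' @method glance sns_calibration
#' @export
glance.sns_calibration <- function(x, ...) {
  tibble(
    category = x$category,
    policy = x$policy,
    a = if (is.null(x$fit)) NA_real_ else x$fit$a,
    b = if (is.null(x$fit)) NA_real_ else x$fit$b,
    deviance = if (is.null(x$fit)) NA_real_ else x$fit$deviance,
    n_points = if (is.null(x$fit)) NA_integer_ else x$fit$n_points
  )
}

#' @method tidy sns_calibration_bank
#' @export
tidy.sns_calibration_bank <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy)
}

#' @method glance sns_calibration_bank
#' @export
glance.sns_calibration_bank <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance)
}

#' @method print sns_calibration_bank
#' @export
print.sns_calibration_bank <- function(x, ...) {
  cat("<sns_calibration_bank>\n")
  print(glance(x))
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

#' Serialize a calibration bank to JSON
#'
#' Writes the per-category empirical tables, fitted parameters and policies
#' so that a calibration frozen on one graph can be reused on another.
#' @param bank an `sns_calibration_bank`
#' @param path file path
#' @return `path`, invisibly
#' @export
calibration_to_json <- function(bank, path) {
  doc <- list(
    pp_weight_category = attr(bank, "pp_weight_category"),
    bridge_kinds = attr(bank, "bridge_kinds"),
    categories = lapply(unclass(bank), function(cp) {
      list(
        category = cp$category,
        policy = cp$policy,
        table = if (cp$policy == "manual") {
          list(n = as.integer(names(cp$table)), p = unname(cp$table))
        } else {
          as.list(cp$table$rows)
        },
        fit = if (is.null(cp$fit)) NULL else cp$fit[c("a", "b", "deviance", "n_points")]
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname calibration_to_json
#' @return `calibration_from_json()`: an `sns_calibration_bank`
#' @export
calibration_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  bank <- lapply(doc$categories, function(cp) {
    fit <- NULL
    if (!is.null(cp$fit) && length(cp$fit) > 0) {
      fit <- structure(as.list(cp$fit), class = "sns_logistic")
      fit$category <- cp$category
    }
    tab <- if (identical(cp$policy, "manual")) {
      setNames(cp$table$p, as.character(cp$table$n))
    } else {
      structure(list(category = cp$category, rows = as_tibble(cp$table)),
        class = "sns_shared_table")
    }
    new_calibration(cp$category, tab, fit, cp$policy)
  })
  names(bank) <- vapply(bank, function(cp) cp$category, character(1))
  structure(bank[CALIBRATED_CATEGORIES],
    class = "sns_calibration_bank",
    bridge_kinds = doc$bridge_kinds,
    pp_weight_category = doc$pp_weight_category
  )
}
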