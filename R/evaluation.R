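#' Sample unconnected node pairs
#'
#' Draws a uniform sample without replacement from the unordered cross-kind
#' pairs of the category that carry no direct link, reproducibly by seed.
#' Pairs listed in `exclude` (e.g. held-out positives of a
#' [split_links()] holdout) are never returned.
#'
#' @param g a [pharm_graph()]
#' @param category link category
#' @param size number of pairs to draw
#' @param seed integer seed
#' @param exclude optional tibble of pairs (`from`, `to`) to exclude
#' @return tibble with columns `from`, `to`
#' @export
sample_negatives <- function(g, category, size, seed = 1, exclude = NULL) {
  stopifnot(category %in% LINK_CATEGORIES)
  kinds <- category_kinds(category)
  left <- sort(g$nodes$id[g$nodes$kind == kinds[1]])
  right <- sort(g$nodes$id[g$nodes$kind == kinds[2]])
  if (kinds[1] == kinds[2]) {
    pairs <- utils::combn(left, 2)
    all_pairs <- tibble(from = pairs[1, ], to = pairs[2, ])
  } else {
    all_pairs <- tibble(
      from = rep(left, each = length(right)),
      to = rep(right, times = length(left))
    )
  }
  edge_keys <- pair_key(g$edges$from, g$edges$to)
  drop <- pair_key(all_pairs$from, all_pairs$to) %in% edge_keys
  if (!is.null(exclude) && nrow(exclude) > 0) {
    drop <- drop | pair_key(all_pairs$from, all_pairs$to) %in%
      pair_key(exclude$from, exclude$to)
  }
  pool <- all_pairs[!drop, ]
  if (size > nrow(pool)) {
    abort(paste0("requested ", size, " negatives but only ", nrow(pool),
      " unconnected pairs exist"), class = "sns_size_error")
  }
  withr::local_seed(seed)
  picked <- sort(sample.int(nrow(pool), size))
  pool[picked, ]
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Compare shared-count distributions of connected and unconnected pairs
#'
#' The premise of shared-neighborhood scoring is that directly connected
#' pairs share more neighbors than unconnected pairs. This test compares the
#' shared-count distribution of all connected pairs of a category against a
#' seeded uniform sample of unconnected pairs with the two-sample
#' Kolmogorov–Smirnov test. Both the two-sided p-value and the one-sided
#' p-value in the direction "connected stochastically larger" are reported.
#'
#' @param g a [pharm_graph()]
#' @param category link category with at least one connected pair
#' @param negative_sample_size unconnected pairs to sample; the default uses
#'   every unconnected pair of the category (capped at 50000), mirroring the
#'   full-distribution comparison the method's validation is based on
#' @param seed integer seed for the negative sample
#' @param bridge_kinds optional kinds allowed as shared neighbors
#' @return an `sns_ks` with the statistic, the two p-values, the sample
#'   sizes and the two count vectors
#' @export
ks_compare <- function(g, category, negative_sample_size = NULL, seed = 1,
                       bridge_kinds = NULL) {
  stopifnot(category %in% LINK_CATEGORIES)
  edges <- g$edges[g$edges$category == category, ]
  if (nrow(edges) == 0) {
    abort(paste0("no connected pairs in category ", category),
      class = "sns_insufficient_data")
  }
  if (is.null(negative_sample_size)) {
    kinds <- category_kinds(category)
    n_all <- if (kinds[1] == kinds[2]) {
      n1 <- sum(g$nodes$kind == kinds[1])
      n1 * (n1 - 1) / 2
    } else {
      sum(g$nodes$kind == kinds[1]) * sum(g$nodes$kind == kinds[2])
    }
    negative_sample_size <- min(n_all - nrow(edges), 50000L)
  }
  S0 <- shared_count_matrix(g, bridge_kinds)
  connected <- as.numeric(S0[cbind(edges$from, edges$to)])
  neg <- sample_negatives(g, category, negative_sample_size, seed = seed)
  unconnected <- as.numeric(S0[cbind(neg$from, neg$to)])

  two <- suppressWarnings(ks.test(connected, unconnected))
  one <- suppressWarnings(ks.test(connected, unconnected, alternative = "less"))
  structure(
    list(
      category = category,
      statistic = unname(two$statistic),
      p_value = two$p.value,
      p_one_sided = one$p.value,
      n_connected = length(connected),
      n_unconnected = length(unconnected),
      connected_counts = connected,
      unconnected_counts = unconnected,
      seed = seed
    ),
    class = "sns_ks"
  )
}

#' @method print sns_ks
#' @export
print.sns_ks <- function(x, ...) {
  cat("<sns_ks> category:", x$category, "\n")
  cat("  D =", signif(x$statistic, 4), " two-sided p =", format(x$p_value, digits = 4),
    " one-sided p =", format(x$p_one_sided, digits = 4), "\n")
  cat("  n connected:", x$n_connected, " n unconnected:", x$n_unconnected, "\n")
  invisible(x)
}

#' @method glance sns_ks
#' @export
glance.sns_ks <- function(x, ...) {
  tibble(
    category = x$category, statistic = x$statistic, p_value = x$p_value,
    p_one_sided = x$p_one_sided, n_connected = x$n_connected,
    n_unconnected = x$n_unconnected
  )
}

#' @method tidy sns_ks
#' @export
tidy.sns_ks <- function(x, ...) {
  bind_rows(
    tibble(connected = TRUE, shared_count = x$connected_counts),
    tibble(connected = FALSE, shared_count = x$unconnected_counts)
  )
}

#' ROC curve and AUC from scores and labels
#'
#' AUC is computed by the rank statistic (Mann–Whitney with midranks for
#' ties; ties are abundant in simple-mode integer scores, so this choice is
#' observable). The curve is a threshold sweep over distinct score values,
#' grouping tied scores, and its trapezoidal area equals the rank AUC.
#'
#' @param scores numeric vector
#' @param labels logical (or 0/1) vector, `TRUE` for positives
#' @return an `sns_roc` with `auc`, `curve` (tibble `threshold`, `fpr`,
#'   `tpr`), `n_pos`, `n_neg`
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC needs at least one positive and one negative label",
      class = "sns_degenerate_labels")
  }
  r <- rank(scores) # midranks
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- cumsum(table(factor(s, levels = unique(s)))) # tie-group boundaries
  tpr <- c(0, cumsum(y)[last] / n_pos, 1)
  fpr <- c(0, cumsum(!y)[last] / n_neg, 1)
  curve <- tibble(
    threshold = c(Inf, unique(s), -Inf),
    fpr = as.numeric(fpr), tpr = as.numeric(tpr)
  )
  structure(
    list(auc = auc, curve = distinct(curve, .data$fpr, .data$tpr, .keep_all = TRUE),
      n_pos = n_pos, n_neg = n_neg),
    class = "sns_roc"
  )
}

#' @method print sns_roc
#' @export
print.sns_roc <- function(x, ...) {
  cat("<sns_roc> AUC =", signif(x$auc, 4), " (", x$n_pos, "positives,",
    x$n_neg, "negatives )\n")
  invisible(x)
}

#' @method glance sns_roc
#' @export
glance.sns_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @method tidy sns_roc
#' @export
tidy.sns_roc <- function(x, ...) x$curve

#' Simple versus extended scoring on one category
#'
#' Evaluates both forms of the score as link predictors: the positives are
#' the category's existing links, scored leave-one-out; the negatives are a
#' seeded equal-size sample of unconnected pairs, scored on the intact
#' graph. Both modes are evaluated on exactly the same pair set — the simple
#' score is the `s0` column of the extended decomposition — and summarized
#' as ROC curves, plus the relative AUC improvement in percent.
#'
#' @param g a [pharm_graph()]
#' @param cp_bank an `sns_calibration_bank`
#' @param category link category
#' @param seed integer seed for the negative sample
#' @param n_negatives number of negatives (default `min(#positives, 50000)`)
#' @return an `sns_mode_comparison`: list with `simple` and `extended`
#'   (`sns_roc`), `improvement` (percent), `category`, `scores` (the scored
#'   pair table), `seed`
#' @export
compare_simple_extended <- function(g, cp_bank, category, seed = 1,
                                    n_negatives = NULL) {
  stopifnot(category %in% LINK_CATEGORIES)
  edges <- g$edges[g$edges$category == category, ]
  if (nrow(edges) == 0) {
    abort(paste0("no positives in category ", category), class = "sns_insufficient_data")
  }
  if (is.null(n_negatives)) n_negatives <- min(nrow(edges), 50000L)
  neg <- sample_negatives(g, category, n_negatives, seed = seed)

  ctx <- score_context(g, cp_bank)
  score_set <- function(pairs, loo) {
    purrr::map2_dfr(pairs$from, pairs$to, function(i, j) {
      res <- score_pair_impl(ctx, i, j, "extended", loo)
      tibble(from = i, to = j, s0 = res$s0,
        total = res$s0 + res$s1 + res$s2, connected = res$connected)
    })
  }
  scored <- bind_rows(
    mutate(score_set(edges[, c("from", "to")], loo = TRUE), label = TRUE),
    mutate(score_set(neg, loo = FALSE), label = FALSE)
  )
  roc_simple <- roc_auc(scored$s0, scored$label)
  roc_extended <- roc_auc(scored$total, scored$label)
  structure(
    list(
      category = category,
      simple = roc_simple,
      extended = roc_extended,
      improvement = (roc_extended$auc - roc_simple$auc) / roc_simple$auc * 100,
      scores = scored,
      seed = seed
    ),
    class = "sns_mode_comparison"
  )
}

#' @method print sns_mode_comparison
#' @export
print.sns_mode_comparison <- function(x, ...) {
  cat("<sns_mode_comparison> category:", x$category, "\n")
  cat("  AUC simple   =", signif(x$simple$auc, 4), "\n")
  cat("  AUC extended =", signif(x$extended$auc, 4),
    " (", sprintf("%+.1f%%", x$improvement), ")\n")
  invisible(x)
}

#' @method glance sns_mode_comparison
#' @export
glance.sns_mode_comparison <- function(x, ...) {
  tibble(
    category = x$category,
    auc_simple = x$simple$auc,
    auc_extended = x$extended$auc,
    improvement_pct = x$improvement,
    n_pos = x$simple$n_pos,
    n_neg = x$simple$n_neg
  )
}

#' @method tidy sns_mode_comparison
#' @export
tidy.sns_mode_comparison <- function(x, ...) {
  bind_rows(
    mutate(x$simple$curve, mode = "simple"),
    mutate(x$extended$curve, mode = "extended")
  )
}
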