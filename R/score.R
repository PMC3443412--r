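# category whose calibration supplies P(n) for a virtual link between kinds
# k1 and k2; NA means the weight is identically zero (drug-drug and
# disease-disease pairs have no link category, hence no connected pairs and
# an empirical connection probability of zero)
weight_category <- function(kind1, kind2, pp_proxy) {
  out <- category_for_kinds(kind1, kind2)
  pp <- !is.na(out) & out == "protein_protein"
  out[pp] <- pp_proxy
  out
}

#' Shared-neighbor count of a node pair
#'
#' The number of nodes directly linked to both `i` and `j` (the 0th-order
#' score, "Shared Nodes Count"). A direct link between `i` and `j` never
#' contributes. `bridge_kinds` optionally restricts which kinds may act as
#' shared neighbors.
#'
#' @param g a [pharm_graph()]
#' @param i,j distinct node ids
#' @param bridge_kinds optional character vector of kinds
#' @return integer count
#' @export
shared_count <- function(g, i, j, bridge_kinds = NULL) {
  if (identical(i, j)) abort("shared_count needs two distinct nodes", class = "sns_domain_error")
  assert_node(g, i)
  assert_node(g, j)
  shared <- intersect(g$adj[[i]], g$adj[[j]])
  if (!is.null(bridge_kinds)) {
    kind_of <- node_kind_map(g)
    shared <- shared[kind_of[shared] %in% bridge_kinds]
  }
  length(shared)
}

#' Weight of a (real or virtual) link
#'
#' A directly connected pair has weight 1. An unconnected ("virtual") pair is
#' weighted by the calibrated connection probability P(n) of its shared
#' count, taken from the calibration of the kind pair's link category
#' (virtual protein–protein links use the proxy category recorded in the
#' bank; drug–drug and disease–disease pairs weigh 0).
#'
#' @param g a [pharm_graph()]
#' @param cp_bank an `sns_calibration_bank`
#' @param i,k distinct node ids
#' @return numeric scalar in `[0, 1]`
#' @export
link_weight <- function(g, cp_bank, i, k) {
  if (identical(i, k)) abort("link_weight needs two distinct nodes", class = "sns_domain_error")
  assert_node(g, i)
  assert_node(g, k)
  if (has_edge(g, i, k)) return(1)
  kind_of <- node_kind_map(g)
  cat <- weight_category(kind_of[[i]], kind_of[[k]], attr(cp_bank, "pp_weight_category"))
  if (is.na(cat)) return(0)
  cp <- cp_bank[[cat]]
  if (is.null(cp)) {
    abort(paste0("no calibration for category ", cat), class = "sns_calibration_missing")
  }
  n <- shared_count(g, i, k, attr(cp_bank, "bridge_kinds"))
  connection_probability(cp, n)
}

# precomputed per-graph context shared by batch scoring
score_context <- function(g, cp_bank) {
  list(
    g = g,
    bank = cp_bank,
    kind_of = node_kind_map(g),
    bridge_kinds = if (is.null(cp_bank)) NULL else attr(cp_bank, "bridge_kinds"),
    pp_proxy = if (is.null(cp_bank)) "protein_disease" else attr(cp_bank, "pp_weight_category"),
    S0 = shared_count_matrix(g, if (is.null(cp_bank)) NULL else attr(cp_bank, "bridge_kinds"))
  )
}

# nodes reachable from v in <= 2 hops (excluding v), under optional edge mask
two_hop_reach <- function(adj, v, drop = NULL) {
  n1 <- adj[[v]]
  if (!is.null(drop)) n1 <- setdiff(n1, drop)
  setdiff(union(n1, unlist(adj[n1], use.names = FALSE)), v)
}

# probability-weighted values for virtual pairs anchored at `anchor`
virtual_weights <- function(ctx, anchor_kind, k_ids, s_vals) {
  out <- numeric(length(k_ids))
  if (length(k_ids) == 0) return(out)
  kinds <- ctx$kind_of[k_ids]
  cats <- weight_category(rep(anchor_kind, length(k_ids)), kinds, ctx$pp_proxy)
  for (cat in unique(cats[!is.na(cats)])) {
    cp <- ctx$bank[[cat]]
    if (is.null(cp)) {
      abort(paste0("no calibration for category ", cat), class = "sns_calibration_missing")
    }
    sel <- !is.na(cats) & cats == cat
    out[sel] <- connection_probability(cp, s_vals[sel])
  }
  out
}

# core per-pair evaluation; returns list with decomposition and per-bridge rows
score_pair_impl <- function(ctx, i, j, mode, leave_one_out, detail = FALSE,
                            shared_counts = NULL) {
  g <- ctx$g
  connected <- has_edge(g, i, j)
  loo <- leave_one_out && connected
  adj_i <- g$adj[[i]]
  adj_j <- g$adj[[j]]
  if (loo) {
    adj_i <- setdiff(adj_i, j)
    adj_j <- setdiff(adj_j, i)
  }

  if (mode == "simple") {
    shared <- intersect(adj_i, adj_j)
    if (!is.null(ctx$bridge_kinds)) {
      shared <- shared[ctx$kind_of[shared] %in% ctx$bridge_kinds]
    }
    s0 <- length(shared)
    bridges <- if (detail) {
      tibble(k = shared, kind = unname(ctx$kind_of[shared]),
        a_ik = TRUE, a_kj = TRUE, w_ik = 1, w_kj = 1,
        product = rep(1, s0), term = rep("s0", s0))
    } else NULL
    return(list(s0 = s0, s1 = 0, s2 = 0, connected = connected, bridges = bridges))
  }

  # candidate bridges: k with W_ik > 0 and W_kj > 0 is only possible within
  # two hops of both endpoints (P(0) = 0); an injected shared-count table can
  # assert counts from a surrounding network, so then all nodes are candidates
  if (is.null(shared_counts)) {
    cand <- intersect(
      two_hop_reach(g$adj, i, drop = if (loo) j else NULL),
      two_hop_reach(g$adj, j, drop = if (loo) i else NULL)
    )
  } else {
    cand <- g$nodes$id
  }
  cand <- sort(setdiff(cand, c(i, j)))
  if (length(cand) == 0) {
    return(list(s0 = 0, s1 = 0, s2 = 0, connected = connected,
      bridges = if (detail) empty_bridges() else NULL))
  }

  a_ik <- cand %in% adj_i
  a_kj <- cand %in% adj_j

  # shared counts for the virtual anchors, from the frozen matrix with the
  # leave-one-out correction (removing edge i-j drops j from N(i), so s_ik
  # loses one iff k is adjacent to j, and symmetrically)
  s_ik <- as.numeric(ctx$S0[, i])[match(cand, g$nodes$id)]
  s_kj <- as.numeric(ctx$S0[, j])[match(cand, g$nodes$id)]
  if (loo) {
    s_ik <- s_ik - as.numeric(cand %in% g$adj[[j]])
    s_kj <- s_kj - as.numeric(cand %in% g$adj[[i]])
  }
  if (!is.null(shared_counts)) {
    over_ik <- shared_counts[paste(pmin(i, cand), pmax(i, cand), sep = "|")]
    over_kj <- shared_counts[paste(pmin(j, cand), pmax(j, cand), sep = "|")]
    s_ik[!is.na(over_ik)] <- over_ik[!is.na(over_ik)]
    s_kj[!is.na(over_kj)] <- over_kj[!is.na(over_kj)]
  }

  w_ik <- rep(1, length(cand))
  w_kj <- rep(1, length(cand))
  kind_i <- ctx$kind_of[[i]]
  kind_j <- ctx$kind_of[[j]]
  w_ik[!a_ik] <- virtual_weights(ctx, kind_i, cand[!a_ik], s_ik[!a_ik])
  w_kj[!a_kj] <- virtual_weights(ctx, kind_j, cand[!a_kj], s_kj[!a_kj])

  s0 <- sum(a_ik & a_kj)
  s1 <- sum(w_kj[a_ik & !a_kj]) + sum(w_ik[!a_ik & a_kj])
  s2 <- sum(w_ik[!a_ik & !a_kj] * w_kj[!a_ik & !a_kj])

  bridges <- NULL
  if (detail) {
    product <- w_ik * w_kj
    term <- ifelse(a_ik & a_kj, "s0", ifelse(!a_ik & !a_kj, "s2", "s1"))
    keep <- product > 0
    bridges <- tibble(
      k = cand[keep], kind = unname(ctx$kind_of[cand[keep]]),
      a_ik = a_ik[keep], a_kj = a_kj[keep],
      w_ik = w_ik[keep], w_kj = w_kj[keep],
      product = product[keep], term = term[keep]
    )
  }
  list(s0 = s0, s1 = s1, s2 = s2, connected = connected, bridges = bridges)
}

empty_bridges <- function() {
  tibble(k = character(0), kind = character(0), a_ik = logical(0), a_kj = logical(0),
    w_ik = numeric(0), w_kj = numeric(0), product = numeric(0), term = character(0))
}

#' Shared neighborhood score of one node pair
#'
#' Computes the score decomposition `s0 + s1 + s2` for a pair: `s0` counts
#' bridges linked directly to both endpoints ("Shared Nodes Count"); `s1`
#' sums the probability weight of bridges linked directly to one endpoint
#' and virtually to the other; `s2` sums the weight products of bridges
#' virtual on both sides. Equivalently, the total is the sum over bridge
#' nodes `k` of `W_ik * W_kj` with real links weighing 1 and virtual links
#' weighing the calibrated P(shared count). `mode = "simple"` returns the
#' bare count (`s1 = s2 = 0`).
#'
#' With `leave_one_out = TRUE` a directly connected pair is scored as if its
#' own edge were absent — the edge is removed before every term, including
#' the shared counts inside the weights — so the score of a known link does
#' not depend on that link's presence.
#'
#' @param g a [pharm_graph()]
#' @param cp_bank an `sns_calibration_bank` (may be `NULL` for simple mode)
#' @param i,j distinct node ids whose kinds form a link category
#' @param mode `"extended"` (default) or `"simple"`
#' @param leave_one_out logical
#' @param normalizer optional `sns_logistic` from
#'   [calibrate_score_normalizer()]; fills the `normalized` field
#' @param shared_counts optional named numeric vector overriding shared
#'   counts for weight computation, names `"a|b"` with `a < b`; used when
#'   counts were frozen on a larger network than the scored subgraph
#' @param detail keep the per-bridge breakdown (needed by
#'   [explain_candidate()])
#' @return an `sns_score` with fields `s0`, `s1`, `s2`, `total`,
#'   `normalized`, `mode`, `leave_one_out`, `connected`
#' @examples
#' g <- pharm_graph(tibble::tibble(
#'   source_id = c("D1", "P1", "D1"), source_kind = c("drug", "protein", "drug"),
#'   target_id = c("P1", "X1", "X1"), target_kind = c("protein", "disease", "disease")
#' ))
#' bank <- manual_calibration_bank(c("1" = 0.2, "2" = 0.5))
#' sn_score(g, bank, "D1", "X1", leave_one_out = TRUE)
#' @export
sn_score <- function(g, cp_bank, i, j, mode = c("extended", "simple"),
                     leave_one_out = FALSE, normalizer = NULL,
                     shared_counts = NULL, detail = FALSE) {
  mode <- match.arg(mode)
  if (identical(i, j)) abort("sn_score needs two distinct nodes", class = "sns_domain_error")
  assert_node(g, i)
  assert_node(g, j)
  kind_of <- node_kind_map(g)
  category <- category_for_kinds(kind_of[[i]], kind_of[[j]])
  if (is.na(category)) {
    abort(paste0("pair (", i, ", ", j, ") has kinds (", kind_of[[i]], ", ", kind_of[[j]],
      ") which form no link category"), class = "sns_validation_error")
  }
  if (mode == "extended" && is.null(cp_bank)) {
    abort("extended mode needs a calibration bank", class = "sns_calibration_missing")
  }
  ctx <- score_context(g, cp_bank)
  res <- score_pair_impl(ctx, i, j, mode, leave_one_out, detail = detail,
    shared_counts = shared_counts)
  new_sns_score(i, j, kind_of, category, res, mode, leave_one_out, normalizer)
}

new_sns_score <- function(i, j, kind_of, category, res, mode, leave_one_out, normalizer) {
  total <- res$s0 + res$s1 + res$s2
  structure(
    list(
      i = i, j = j, kind_i = unname(kind_of[[i]]), kind_j = unname(kind_of[[j]]),
      category = category,
      s0 = res$s0, s1 = res$s1, s2 = res$s2, total = total,
      normalized = if (is.null(normalizer)) NA_real_ else normalize_scores(normalizer, total),
      connected = res$connected,
      mode = mode, leave_one_out = leave_one_out,
      bridges = res$bridges
    ),
    class = "sns_score"
  )
}

#' @method print sns_score
#' @export
print.sns_score <- function(x, ...) {
  cat("<sns_score> (", x$i, ", ", x$j, ") [", x$category, ", ", x$mode,
    if (x$leave_one_out) ", leave-one-out" else "", "]\n", sep = "")
  cat("  s0 =", x$s0, " s1 =", signif(x$s1, 6), " s2 =", signif(x$s2, 6),
    " total =", signif(x$total, 6), "\n")
  if (!is.na(x$normalized)) cat("  normalized =", signif(x$normalized, 6), "\n")
  invisible(x)
}

#' @method tidy sns_score
#' @export
tidy.sns_score <- function(x, ...) {
  tibble(
    from = x$i, to = x$j, category = x$category,
    s0 = x$s0, s1 = x$s1, s2 = x$s2, total = x$total,
    normalized = x$normalized, connected = x$connected,
    mode = x$mode, leave_one_out = x$leave_one_out
  )
}

#' Score every node pair of a link category
#'
#' Batch driver over all unordered cross-kind pairs of the category. Pairs
#' with a zero score and no direct link are dropped from the result; directly
#' connected pairs are always kept and, when
#' `leave_one_out_for_connected = TRUE` (the default), are scored with their
#' own edge removed. Rows are emitted in deterministic sorted order.
#'
#' @inheritParams sn_score
#' @param category one of the four link categories
#' @param leave_one_out_for_connected score connected pairs leave-one-out
#' @return tibble with columns `from`, `to`, `category`, `s0`, `s1`, `s2`,
#'   `total`, `normalized`, `connected`, `mode`
#' @export
score_all_pairs <- function(g, cp_bank, category, mode = c("extended", "simple"),
                            leave_one_out_for_connected = TRUE, normalizer = NULL) {
  mode <- match.arg(mode)
  if (!category %in% LINK_CATEGORIES) {
    abort(paste0("unknown link category: ", category), class = "sns_validation_error")
  }
  if (mode == "extended" && is.null(cp_bank)) {
    abort("extended mode needs a calibration bank", class = "sns_calibration_missing")
  }
  kinds <- category_kinds(category)
  left <- sort(g$nodes$id[g$nodes$kind == kinds[1]])
  right <- sort(g$nodes$id[g$nodes$kind == kinds[2]])
  if (length(left) == 0 || length(right) == 0) return(empty_score_table())
  if (kinds[1] == kinds[2]) {
    pairs <- utils::combn(left, 2)
    from <- pairs[1, ]; to <- pairs[2, ]
  } else {
    from <- rep(left, each = length(right))
    to <- rep(right, times = length(left))
  }
  ctx <- score_context(g, cp_bank)
  kind_of <- ctx$kind_of
  rows <- purrr::map2(from, to, function(i, j) {
    res <- score_pair_impl(ctx, i, j, mode, leave_one_out_for_connected)
    if (!res$connected && res$s0 + res$s1 + res$s2 == 0) return(NULL)
    total <- res$s0 + res$s1 + res$s2
    tibble(
      from = i, to = j, category = category,
      s0 = res$s0, s1 = res$s1, s2 = res$s2, total = total,
      normalized = if (is.null(normalizer)) NA_real_ else normalize_scores(normalizer, total),
      connected = res$connected, mode = mode
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty_score_table())
  arrange(out, .data$from, .data$to)
}

empty_score_table <- function() {
  tibble(
    from = character(0), to = character(0), category = character(0),
    s0 = numeric(0), s1 = numeric(0), s2 = numeric(0), total = numeric(0),
    normalized = numeric(0), connected = logical(0), mode = character(0)
  )
}

#' Score table columns expected by downstream helpers
#'
#' [score_all_pairs()] emits `total` as the raw score; helpers that need a
#' single `score` column (e.g. [calibrate_score_normalizer()]) can use this
#' adapter to pick raw or normalized scores.
#' @param scored a [score_all_pairs()] result
#' @param space `"raw"` or `"normalized"`
#' @return the same tibble with an added `score` column
#' @export
score_column <- function(scored, space = c("raw", "normalized")) {
  space <- match.arg(space)
  scored$score <- if (space == "raw") scored$total else scored$normalized
  scored
}
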