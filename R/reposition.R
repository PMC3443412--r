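#' Proteins associated with a disease class
#'
#' Returns every protein with a direct protein–disease link to any node of
#' the class (e.g. all cancer-term descriptors). These are the "class target
#' proteins" the candidate filter requires a drug to hit directly.
#'
#' @param g a [pharm_graph()]
#' @param disease_class character vector of disease node ids
#' @return sorted character vector of protein ids
#' @export
class_proteins <- function(g, disease_class) {
  if (length(disease_class) == 0) return(character(0))
  kind_of <- node_kind_map(g)
  for (d in disease_class) {
    assert_node(g, d)
    if (kind_of[[d]] != "disease") {
      abort(paste0(d, " is not a disease node"), class = "sns_validation_error")
    }
  }
  sort(unique(unlist(lapply(disease_class, function(d) {
    graph_neighbors(g, d, kinds = "protein")
  }), use.names = FALSE)))
}

#' Repositioning candidates for a disease query
#'
#' Scores every drug against the query disease(s) with the extended shared
#' neighborhood score and applies the four selection criteria of the
#' repositioning pipeline:
#'
#' 1. the score exceeds `threshold` *and* the pair's Shared Nodes Count
#'    satisfies the `max_shared` constraint (default 0: the pair must be
#'    supported purely by indirect first/second-order evidence);
#' 2. the drug is on the approved-drug list;
#' 3. the drug has no existing drug–disease link to *any* node of the
#'    disease class (it is a genuinely novel indication for the class);
#' 4. the drug has at least one direct drug–protein link to a class target
#'    protein (see [class_proteins()]).
#'
#' Drugs already linked to the query disease itself are never candidates.
#' Records are ranked by score (descending, ties broken by drug id) and
#' carry their supporting bridge paths for explanation.
#'
#' @param g a [pharm_graph()]
#' @param cp_bank an `sns_calibration_bank`
#' @param diseases character vector of query disease ids
#' @param approved character vector of approved drug ids (see
#'   [read_drug_list()])
#' @param disease_class character vector of disease ids forming the broader
#'   class used by criteria 3 and 4; defaults to the query itself
#' @param threshold minimum score, exclusive (default 0.004)
#' @param max_shared maximum allowed Shared Nodes Count (default 0)
#' @param score_space `"normalized"` (requires `normalizer`) or `"raw"`
#' @param normalizer optional `sns_logistic` from
#'   [calibrate_score_normalizer()]
#' @return an `sns_candidates` tibble: `drug`, `disease`, `score` (in the
#'   chosen space), `total`, `normalized`, `shared_count`, the four
#'   criterion flags, and a list-column `paths` of supporting bridges
#' @export
find_candidates <- function(g, cp_bank, diseases, approved,
                            disease_class = diseases,
                            threshold = 0.004, max_shared = 0,
                            score_space = c("normalized", "raw"),
                            normalizer = NULL) {
  score_space <- match.arg(score_space)
  if (score_space == "normalized" && is.null(normalizer)) {
    abort("score_space = \"normalized\" needs a fitted normalizer; pass normalizer = ",
      class = "sns_validation_error")
  }
  if (length(approved) == 0) {
    warn("empty approved-drug list: no candidate can pass criterion 2")
  }
  kind_of <- node_kind_map(g)
  for (d in unique(c(diseases, disease_class))) assert_node(g, d)
  targets <- class_proteins(g, disease_class)
  drugs <- sort(g$nodes$id[g$nodes$kind == "drug"])
  ctx <- score_context(g, cp_bank)

  rows <- list()
  for (dis in diseases) {
    for (drug in drugs) {
      if (has_edge(g, drug, dis)) next # existing indication, not a candidate
      res <- score_pair_impl(ctx, drug, dis, "extended", leave_one_out = FALSE,
        detail = TRUE)
      total <- res$s0 + res$s1 + res$s2
      normalized <- if (is.null(normalizer)) NA_real_ else normalize_scores(normalizer, total)
      score <- if (score_space == "raw") total else normalized
      class_links <- intersect(g$adj[[drug]], disease_class)
      rows[[length(rows) + 1L]] <- tibble(
        drug = drug, disease = dis,
        score = score, total = total, normalized = normalized,
        shared_count = res$s0,
        pass_score = score > threshold & res$s0 <= max_shared,
        approved = drug %in% approved,
        novel_indication = length(class_links) == 0,
        target_linked = length(intersect(g$adj[[drug]], targets)) > 0,
        paths = list(res$bridges)
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0) {
    out <- out %>%
      filter(.data$pass_score, .data$approved, .data$novel_indication, .data$target_linked) %>%
      arrange(dplyr::desc(.data$score), .data$drug, .data$disease)
  }
  structure(out, class = c("sns_candidates", class(tibble())),
    threshold = threshold, max_shared = max_shared, score_space = score_space,
    disease_class = disease_class, approved = approved)
}

#' Supporting paths of one candidate
#'
#' Expands a candidate's bridge table into human-readable
#' drug–bridge–disease paths with per-path weight products and the score
#' term (`s0`/`s1`/`s2`) each belongs to. The products sum to the
#' candidate's raw score.
#'
#' @param candidates an `sns_candidates` table from [find_candidates()]
#' @param drug,disease ids selecting one record
#' @return tibble `drug`, `bridge`, `bridge_kind`, `disease`, `w_ik`,
#'   `w_kj`, `product`, `term`
#' @export
explain_candidate <- function(candidates, drug, disease) {
  hit <- which(candidates$drug == drug & candidates$disease == disease)
  if (length(hit) != 1) {
    abort(paste0("no candidate record for (", drug, ", ", disease, ")"),
      class = "sns_lookup_error")
  }
  b <- candidates$paths[[hit]]
  tibble(
    drug = drug, bridge = b$k, bridge_kind = b$kind, disease = disease,
    w_ik = b$w_ik, w_kj = b$w_kj, product = b$product, term = b$term
  ) %>% arrange(dplyr::desc(.data$product), .data$bridge)
}

#' Independently re-check emitted candidates
#'
#' Post-hoc audit: re-derives each of the four criteria for every emitted
#' record straight from the graph and the filter settings stored on the
#' candidate table, without reusing the pipeline's own flags. Returns one
#' row per record with the re-checked flags and an `ok` conjunction; any
#' `FALSE` indicates a filter defect.
#'
#' @param candidates an `sns_candidates` table
#' @param g the graph the candidates were derived from
#' @return tibble of re-checked flags
#' @export
audit_candidates <- function(candidates, g) {
  threshold <- attr(candidates, "threshold")
  max_shared <- attr(candidates, "max_shared")
  space <- attr(candidates, "score_space")
  disease_class <- attr(candidates, "disease_class")
  approved <- attr(candidates, "approved")
  targets <- class_proteins(g, disease_class)
  purrr::pmap_dfr(
    list(candidates$drug, candidates$disease, candidates$score),
    function(drug, dis, score) {
      s0 <- shared_count(g, drug, dis)
      tibble(
        drug = drug, disease = dis,
        chk_score = score > threshold && s0 <= max_shared,
        chk_approved = drug %in% approved,
        chk_novel = length(intersect(g$adj[[drug]], disease_class)) == 0,
        chk_target = length(intersect(g$adj[[drug]], targets)) > 0,
        chk_not_linked = !has_edge(g, drug, dis)
      ) %>% mutate(ok = .data$chk_score & .data$chk_approved & .data$chk_novel &
          .data$chk_target & .data$chk_not_linked)
    }
  )
}
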