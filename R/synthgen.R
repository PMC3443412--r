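#' Parameters for the planted-community network generator
#'
#' The generator emulates the one statistical property the shared
#' neighborhood score relies on: directly connected pairs share more
#' neighbors than unconnected pairs. Nodes of each kind are assigned to
#' latent modules; pairs inside a module link with probability `p_within`,
#' pairs across modules with the background probability `p_between`, per
#' category. Drug–disease links are generated sparser (`p_within` and
#' `p_between` scaled by `dd_scale`) to mirror the strong relative scarcity
#' of curated drug–disease links compared to drug–protein links in real
#' pharmacological networks — a shape emulation, not a numeric target.
#'
#' @param n_drugs,n_proteins,n_diseases node counts per kind
#' @param n_modules number of latent modules (communities)
#' @param p_within within-module link probability for cross-kind categories
#' @param p_between background link probability for cross-kind categories
#' @param pp_within,pp_between protein–protein link probabilities
#' @param dd_scale multiplier applied to the drug–disease probabilities
#' @param seed integer seed; the whole graph is drawn from one seeded stream
#' @return a `synth_params` list
#' @export
synth_params <- function(n_drugs = 60, n_proteins = 120, n_diseases = 60,
                         n_modules = 6, p_within = 0.25, p_between = 0.01,
                         pp_within = 0.25, pp_between = 0.01,
                         dd_scale = 0.5, seed = 1) {
  p <- list(
    n_drugs = as.integer(n_drugs), n_proteins = as.integer(n_proteins),
    n_diseases = as.integer(n_diseases), n_modules = as.integer(n_modules),
    p_within = p_within, p_between = p_between,
    pp_within = pp_within, pp_between = pp_between,
    dd_scale = dd_scale, seed = as.integer(seed)
  )
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  counts <- c(p$n_drugs, p$n_proteins, p$n_diseases, p$n_modules)
  if (any(counts < 1)) {
    abort("node and module counts must be >= 1", class = "sns_validation_error")
  }
  if (p$n_modules > min(p$n_drugs, p$n_proteins, p$n_diseases)) {
    abort("n_modules may not exceed the smallest kind count", class = "sns_validation_error")
  }
  probs <- c(p$p_within, p$p_between, p$pp_within, p$pp_between)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "sns_validation_error")
  }
  if (p$p_between > p$p_within || p$pp_between > p$pp_within) {
    abort("background probability must not exceed the within-module probability",
      class = "sns_validation_error")
  }
  if (p$dd_scale < 0 || p$dd_scale * p$p_within > 1) {
    abort("dd_scale out of range", class = "sns_validation_error")
  }
  invisible(p)
}

# independent Bernoulli links between two id vectors given module labels
sample_bipartite <- function(ids1, mod1, kind1, ids2, mod2, kind2, p_in, p_out) {
  same <- outer(mod1, mod2, "==")
  hit <- which(matrix(stats::runif(length(same)), nrow(same)) < ifelse(same, p_in, p_out),
    arr.ind = TRUE)
  tibble(
    source_id = ids1[hit[, 1]], source_kind = kind1,
    target_id = ids2[hit[, 2]], target_kind = kind2
  )
}

#' Generate a planted-community tripartite network
#'
#' Draws a drug–protein–disease graph (plus protein–protein interactions)
#' from the module structure described in [synth_params()]. All randomness
#' comes from one stream seeded with `params$seed`, and sampling happens in
#' a fixed documented order (drug–protein, protein–disease, drug–disease,
#' protein–protein), so output is reproducible byte for byte. Setting
#' `p_within = p_between` yields an unstructured Erdős–Rényi-style null
#' model.
#'
#' @param params a [synth_params()] list
#' @return list with `graph` (a [pharm_graph()], all nodes registered even
#'   if isolated) and `modules` (tibble `id`, `kind`, `module` of the
#'   ground-truth assignments)
#' @export
generate_network <- function(params) {
  validate_synth_params(params)
  withr::local_seed(params$seed)

  drugs <- sprintf("D%03d", seq_len(params$n_drugs))
  prots <- sprintf("P%03d", seq_len(params$n_proteins))
  dis <- sprintf("X%03d", seq_len(params$n_diseases))
  m_d <- sample.int(params$n_modules, params$n_drugs, replace = TRUE)
  m_p <- sample.int(params$n_modules, params$n_proteins, replace = TRUE)
  m_x <- sample.int(params$n_modules, params$n_diseases, replace = TRUE)

  edges <- bind_rows(
    sample_bipartite(drugs, m_d, "drug", prots, m_p, "protein",
      params$p_within, params$p_between),
    sample_bipartite(prots, m_p, "protein", dis, m_x, "disease",
      params$p_within, params$p_between),
    sample_bipartite(drugs, m_d, "drug", dis, m_x, "disease",
      params$p_within * params$dd_scale, params$p_between * params$dd_scale),
    {
      pp <- sample_bipartite(prots, m_p, "protein", prots, m_p, "protein",
        params$pp_within, params$pp_between)
      pp[pp$source_id < pp$target_id, ] # upper triangle: no loops, one draw per pair
    }
  )
  nodes <- tibble(
    id = c(drugs, prots, dis),
    kind = rep(c("drug", "protein", "disease"),
      c(params$n_drugs, params$n_proteins, params$n_diseases)),
    namespace = "synthetic"
  )
  list(
    graph = pharm_graph(edges, nodes = nodes),
    modules = tibble(id = nodes$id, kind = nodes$kind, module = c(m_d, m_p, m_x))
  )
}

#' Hold out links for evaluation
#'
#' Removes a random fraction of one category's edges from a copy of the
#' graph (the held-out positives) and samples an unconnected-pair negative
#' set of `negatives_per_positive` times that size. Negatives are
#' unconnected in the *original* graph, so they can never coincide with a
#' held-out positive.
#'
#' @param g a [pharm_graph()]
#' @param category link category to split (needs at least 10 edges)
#' @param fraction fraction of edges to hold out, in (0, 1); `ceiling` is
#'   applied to the edge count
#' @param negatives_per_positive negatives sampled per held-out positive
#' @param seed integer seed
#' @return an `sns_holdout`: list with `train` (graph), `positives`,
#'   `negatives` (tibbles `from`, `to`), `category`, `fraction`, `seed`
#' @export
split_links <- function(g, category, fraction, negatives_per_positive = 1, seed = 1) {
  stopifnot(category %in% LINK_CATEGORIES)
  if (fraction <= 0 || fraction >= 1) {
    abort("fraction must lie strictly between 0 and 1", class = "sns_validation_error")
  }
  idx <- which(g$edges$category == category)
  if (length(idx) < 10) {
    abort(paste0("category ", category, " has fewer than 10 edges"),
      class = "sns_insufficient_data")
  }
  n_hold <- ceiling(fraction * length(idx))
  withr::local_seed(seed)
  hold <- sort(sample(idx, n_hold))
  positives <- g$edges[hold, c("from", "to")]

  train <- g
  train$edges <- g$edges[-hold, ]
  train$adj <- build_adjacency(train$edges, g$nodes$id)

  negatives <- sample_negatives(g, category,
    size = negatives_per_positive * n_hold,
    seed = sample.int(.Machine$integer.max, 1))

  structure(
    list(train = train, positives = positives, negatives = negatives,
      category = category, fraction = fraction, seed = seed),
    class = "sns_holdout"
  )
}

#' @method print sns_holdout
#' @export
print.sns_holdout <- function(x, ...) {
  cat("<sns_holdout> category:", x$category, " fraction:", x$fraction, "\n")
  cat("  held-out positives:", nrow(x$positives),
    " negatives:", nrow(x$negatives), "\n")
  invisible(x)
}
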