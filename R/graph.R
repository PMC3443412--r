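NODE_KINDS <- c("drug", "protein", "disease")

#' Namespaces understood for node identifiers
#'
#' Real identifiers come from PubChem (compounds), Entrez Gene (proteins) and
#' MeSH (disease descriptors); generated networks use the `synthetic`
#' namespace so they can never be mistaken for curated ontology ids.
#' @keywords internal
NODE_NAMESPACES <- c("pubchem_cid", "entrez_gene", "mesh_descriptor", "synthetic")

NAMESPACE_KIND <- c(
  pubchem_cid = "drug",
  entrez_gene = "protein",
  mesh_descriptor = "disease"
)

LINK_CATEGORIES <- c("drug_protein", "protein_disease", "drug_disease", "protein_protein")

# kind pair -> link category; drug+drug and disease+disease have no category
category_for_kinds <- function(kind1, kind2) {
  key <- paste(pmin(kind1, kind2), pmax(kind1, kind2), sep = "+")
  lookup <- c(
    "drug+protein" = "drug_protein",
    "disease+protein" = "protein_disease",
    "disease+drug" = "drug_disease",
    "drug+disease" = "drug_disease",
    "protein+protein" = "protein_protein"
  )
  unname(lookup[key])
}

#' Kinds at the two ends of a link category
#' @param category one of the four link categories
#' @return character vector of length 2 (first kind, second kind)
#' @keywords internal
category_kinds <- function(category) {
  switch(category,
    drug_protein = c("drug", "protein"),
    protein_disease = c("protein", "disease"),
    drug_disease = c("drug", "disease"),
    protein_protein = c("protein", "protein"),
    abort(paste0("unknown link category: ", category), class = "sns_validation_error")
  )
}

# canonical endpoint order inside an edge row: drug < protein < disease, then id
kind_rank <- c(drug = 1L, protein = 2L, disease = 3L)

#' Construct a tripartite pharmacological graph
#'
#' Builds the package's central data structure from a tidy edge table: an
#' undirected simple graph over drug, protein and disease nodes with four
#' typed link categories (drug–protein, protein–disease, drug–disease,
#' protein–protein). Duplicate rows collapse to a single edge whose
#' `source_tag` becomes the sorted union of the duplicates' tags. Edge
#' categories are inferred from the endpoint kinds; a drug–drug or
#' disease–disease row is rejected.
#'
#' @param edges data frame with columns `source_id`, `source_kind`,
#'   `target_id`, `target_kind` and optionally `source_tag`.
#' @param nodes optional data frame with columns `id`, `kind` and optionally
#'   `namespace`, used to register isolated nodes and namespaces.
#' @return an object of class `pharm_graph` with components `nodes` (tibble:
#'   `id`, `kind`, `namespace`), `edges` (tibble: `from`, `to`, `category`,
#'   `source_tag`) and a named adjacency list.
#' @examples
#' g <- pharm_graph(tibble::tibble(
#'   source_id = c("D1", "P1", "D1"),
#'   source_kind = c("drug", "protein", "drug"),
#'   target_id = c("P1", "X1", "X1"),
#'   target_kind = c("protein", "disease", "disease")
#' ))
#' glance(g)
#' @export
pharm_graph <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  required <- c("source_id", "source_kind", "target_id", "target_kind")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    abort(paste0("edge table lacks column(s): ", paste(missing_cols, collapse = ", ")),
      class = "sns_validation_error")
  }
  if (!"source_tag" %in% names(edges)) edges$source_tag <- NA_character_
  edges <- edges[, c(required, "source_tag")]

  for (col in required) edges[[col]] <- as.character(edges[[col]])
  check_ids(c(edges$source_id, edges$target_id))
  bad_kind <- !(edges$source_kind %in% NODE_KINDS) | !(edges$target_kind %in% NODE_KINDS)
  if (any(bad_kind)) {
    abort(paste0("unknown node kind in edge row(s): ",
      paste(which(bad_kind), collapse = ", ")), class = "sns_parse_error")
  }
  loops <- edges$source_id == edges$target_id
  if (any(loops)) {
    abort(paste0("self-loop in edge row(s): ", paste(which(loops), collapse = ", ")),
      class = "sns_validation_error")
  }
  cat_vec <- category_for_kinds(edges$source_kind, edges$target_kind)
  if (anyNA(cat_vec)) {
    bad <- which(is.na(cat_vec))
    abort(paste0(
      "forbidden endpoint kinds (no drug-drug or disease-disease links) in edge row(s): ",
      paste(bad, collapse = ", ")), class = "sns_validation_error")
  }

  # canonical orientation: drug < protein < disease, ties by id
  flip <- kind_rank[edges$source_kind] > kind_rank[edges$target_kind] |
    (edges$source_kind == edges$target_kind & edges$source_id > edges$target_id)
  from <- ifelse(flip, edges$target_id, edges$source_id)
  to <- ifelse(flip, edges$source_id, edges$target_id)
  from_kind <- ifelse(flip, edges$target_kind, edges$source_kind)
  to_kind <- ifelse(flip, edges$source_kind, edges$target_kind)

  etab <- tibble(
    from = as.character(from), from_kind = as.character(from_kind),
    to = as.character(to), to_kind = as.character(to_kind),
    category = as.character(cat_vec), source_tag = edges$source_tag
  )
  etab <- etab %>%
    group_by(.data$from, .data$from_kind, .data$to, .data$to_kind, .data$category) %>%
    summarise(source_tag = collapse_tags(.data$source_tag), .groups = "drop") %>%
    arrange(.data$category, .data$from, .data$to)

  node_tab <- tibble(
    id = as.character(c(etab$from, etab$to)),
    kind = as.character(c(etab$from_kind, etab$to_kind))
  )
  if (!is.null(nodes)) {
    nodes <- as_tibble(nodes)
    if (!all(c("id", "kind") %in% names(nodes))) {
      abort("node table needs columns id and kind", class = "sns_validation_error")
    }
    extra <- tibble(id = as.character(nodes$id), kind = as.character(nodes$kind))
    if (!all(extra$kind %in% NODE_KINDS)) {
      abort("unknown node kind in node table", class = "sns_validation_error")
    }
    node_tab <- bind_rows(node_tab, extra)
  }
  node_tab <- distinct(node_tab, .data$id, .data$kind)
  dup <- node_tab$id[duplicated(node_tab$id)]
  if (length(dup) > 0) {
    abort(paste0(
      "node id(s) used with more than one kind: ", paste(unique(dup), collapse = ", "),
      "; namespace-qualify ids (e.g. \"CID:5543\") to disambiguate"),
      class = "sns_validation_error")
  }
  ns <- namespace_for(node_tab, nodes)
  node_tab <- arrange(mutate(node_tab, namespace = ns), .data$kind, .data$id)

  g <- structure(
    list(
      nodes = node_tab,
      edges = etab[, c("from", "to", "category", "source_tag")],
      adj = build_adjacency(etab, node_tab$id)
    ),
    class = "pharm_graph"
  )
  g
}

check_ids <- function(ids) {
  bad <- is.na(ids) | ids == "" | grepl("[[:space:]]", ids)
  if (any(bad)) {
    abort(paste0("empty or whitespace-containing node id in edge row(s): ",
      paste(unique(((which(bad) - 1L) %% (length(ids) / 2)) + 1L), collapse = ", ")),
      class = "sns_parse_error")
  }
  invisible(TRUE)
}

collapse_tags <- function(tags) {
  tags <- unique(unlist(strsplit(tags[!is.na(tags)], ";", fixed = TRUE)))
  if (length(tags) == 0) NA_character_ else paste(sort(tags), collapse = ";")
}

namespace_for <- function(node_tab, nodes) {
  ns <- rep("synthetic", nrow(node_tab))
  if (!is.null(nodes) && "namespace" %in% names(nodes)) {
    idx <- match(node_tab$id, as.character(nodes$id))
    given <- as.character(nodes$namespace)[idx]
    ok <- !is.na(given)
    if (any(ok & !(given %in% NODE_NAMESPACES))) {
      abort("unknown namespace in node table", class = "sns_validation_error")
    }
    mismatch <- ok & given %in% names(NAMESPACE_KIND) &
      NAMESPACE_KIND[given] != node_tab$kind
    if (any(mismatch, na.rm = TRUE)) {
      abort("namespace implies a different kind than declared", class = "sns_validation_error")
    }
    ns[ok] <- given[ok]
  }
  ns
}

build_adjacency <- function(etab, ids) {
  adj <- setNames(vector("list", length(ids)), ids)
  if (nrow(etab) > 0) {
    ends <- c(etab$from, etab$to)
    other <- c(etab$to, etab$from)
    spl <- split(other, ends)
    spl <- lapply(spl, function(x) sort(unique(x)))
    adj[names(spl)] <- spl
  }
  empty <- vapply(adj, is.null, logical(1))
  adj[empty] <- list(character(0))
  adj
}

#' @method print pharm_graph
#' @export
print.pharm_graph <- function(x, ...) {
  nk <- table(factor(x$nodes$kind, levels = NODE_KINDS))
  ec <- table(factor(x$edges$category, levels = LINK_CATEGORIES))
  cat("<pharm_graph> ", nrow(x$nodes), " nodes (",
    paste(paste0(nk, " ", names(nk)), collapse = ", "), "), ",
    nrow(x$edges), " edges\n", sep = "")
  for (cc in LINK_CATEGORIES) cat("  ", cc, ": ", ec[[cc]], "\n", sep = "")
  invisible(x)
}

#' @method tidy pharm_graph
#' @export
tidy.pharm_graph <- function(x, ...) {
  kind_of <- node_kind_map(x)
  mutate(x$edges,
    from_kind = unname(kind_of[.data$from]),
    to_kind = unname(kind_of[.data$to]),
    .after = "to"
  )
}

#' @method glance pharm_graph
#' @export
glance.pharm_graph <- function(x, ...) {
  ec <- table(factor(x$edges$category, levels = LINK_CATEGORIES))
  tibble(
    n_nodes = nrow(x$nodes),
    n_drugs = sum(x$nodes$kind == "drug"),
    n_proteins = sum(x$nodes$kind == "protein"),
    n_diseases = sum(x$nodes$kind == "disease"),
    n_edges = nrow(x$edges),
    n_drug_protein = as.integer(ec[["drug_protein"]]),
    n_protein_disease = as.integer(ec[["protein_disease"]]),
    n_drug_disease = as.integer(ec[["drug_disease"]]),
    n_protein_protein = as.integer(ec[["protein_protein"]])
  )
}

node_kind_map <- function(g) setNames(g$nodes$kind, g$nodes$id)

assert_node <- function(g, id) {
  if (!id %in% g$nodes$id) {
    abort(paste0("unknown node: ", id), class = "sns_lookup_error")
  }
  invisible(TRUE)
}

#' Test whether two nodes are directly linked
#' @param g a [pharm_graph()]
#' @param i,j node ids
#' @return logical scalar
#' @export
has_edge <- function(g, i, j) {
  j %in% g$adj[[i]]
}

#' Neighbors of a node
#'
#' @param g a [pharm_graph()]
#' @param id node id
#' @param kinds optional character vector restricting the returned nodes to
#'   the given kinds
#' @return sorted character vector of neighbor ids (never contains `id`)
#' @export
graph_neighbors <- function(g, id, kinds = NULL) {
  assert_node(g, id)
  nb <- g$adj[[id]]
  if (!is.null(kinds)) {
    kind_of <- node_kind_map(g)
    nb <- nb[kind_of[nb] %in% kinds]
  }
  nb
}

#' Shortest path between two nodes
#'
#' Unweighted breadth-first shortest path. When several shortest paths exist
#' the lexicographically smallest node sequence is returned, so the result is
#' deterministic.
#'
#' @param g a [pharm_graph()]
#' @param from,to node ids
#' @return character vector of node ids from `from` to `to`, or `NULL` when
#'   the nodes are in different components
#' @export
graph_shortest_path <- function(g, from, to) {
  assert_node(g, from)
  assert_node(g, to)
  if (from == to) return(from)
  dist <- bfs_distances(g$adj, to)
  if (is.na(dist[[from]])) return(NULL)
  path <- from
  cur <- from
  while (cur != to) {
    nb <- g$adj[[cur]]
    nxt <- nb[!is.na(dist[nb]) & dist[nb] == dist[[cur]] - 1L]
    cur <- min(nxt) # adjacency is sorted; min = lexicographic tie-break
    path <- c(path, cur)
  }
  path
}

bfs_distances <- function(adj, src) {
  dist <- setNames(rep(NA_integer_, length(adj)), names(adj))
  dist[[src]] <- 0L
  frontier <- src
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Delete one edge from a graph
#'
#' Returns a copy of the graph with the edge between `i` and `j` removed
#' (nodes are kept). Used by the leave-one-out machinery and handy for
#' what-if queries.
#' @inheritParams has_edge
#' @return a `pharm_graph`
#' @export
delete_edge <- function(g, i, j) {
  assert_node(g, i)
  assert_node(g, j)
  if (!has_edge(g, i, j)) {
    abort(paste0("no edge between ", i, " and ", j), class = "sns_lookup_error")
  }
  keep <- !((g$edges$from == i & g$edges$to == j) | (g$edges$from == j & g$edges$to == i))
  g$edges <- g$edges[keep, ]
  g$adj[[i]] <- setdiff(g$adj[[i]], j)
  g$adj[[j]] <- setdiff(g$adj[[j]], i)
  g
}

# ---- matrix views -----------------------------------------------------------

node_index <- function(g) setNames(seq_len(nrow(g$nodes)), g$nodes$id)

adjacency_matrix <- function(g) {
  idx <- node_index(g)
  n <- length(idx)
  i <- idx[g$edges$from]
  j <- idx[g$edges$to]
  Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = 1,
    dims = c(n, n), dimnames = list(names(idx), names(idx))
  )
}

# S0[i, j] = number of shared neighbors of i and j (optionally only bridges of
# the given kinds). The direct i-j edge never contributes (no self-loops).
shared_count_matrix <- function(g, bridge_kinds = NULL) {
  A <- adjacency_matrix(g)
  if (is.null(bridge_kinds)) {
    A %*% A
  } else {
    keep <- g$nodes$kind %in% bridge_kinds
    A[, keep, drop = FALSE] %*% A[keep, , drop = FALSE]
  }
}

# ---- I/O --------------------------------------------------------------------

#' Read a typed edge list
#'
#' Reads the package's canonical TSV format: header
#' `source_id  source_kind  target_id  target_kind  [source_tag]`, one edge
#' per row. Duplicate rows collapse; row order never affects the resulting
#' graph.
#'
#' @param path file path
#' @return a [pharm_graph()]
#' @export
read_edge_list <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  required <- c("source_id", "source_kind", "target_id", "target_kind")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("edge list ", path, " lacks column(s): ",
      paste(missing_cols, collapse = ", ")), class = "sns_parse_error")
  }
  incomplete <- which(apply(is.na(raw[, required]) | raw[, required] == "", 1, any))
  if (length(incomplete) > 0) {
    abort(paste0("malformed row(s) (missing fields) at line ",
      paste(incomplete + 1L, collapse = ", "), " of ", path),
      class = "sns_parse_error")
  }
  pharm_graph(raw)
}

#' Write a typed edge list
#'
#' Inverse of [read_edge_list()]: the written file reloads to an identical
#' graph (same nodes, edges and categories). Rows are emitted in a stable
#' sorted order. Isolated nodes are not representable in an edge list and are
#' dropped with a warning.
#'
#' @param g a [pharm_graph()]
#' @param path file path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(g, path) {
  iso <- setdiff(g$nodes$id, unique(c(g$edges$from, g$edges$to)))
  if (length(iso) > 0) {
    warn(paste0(length(iso), " isolated node(s) not representable in an edge list"))
  }
  kind_of <- node_kind_map(g)
  out <- tibble(
    source_id = g$edges$from,
    source_kind = unname(kind_of[g$edges$from]),
    target_id = g$edges$to,
    target_kind = unname(kind_of[g$edges$to]),
    source_tag = g$edges$source_tag
  ) %>% arrange(.data$source_kind, .data$source_id, .data$target_kind, .data$target_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a SIF-style interaction file
#'
#' Three columns, `node<TAB>category<TAB>node`, for import into network
#' visualization tools.
#' @inheritParams write_edge_list
#' @return `path`, invisibly
#' @export
write_sif <- function(g, path) {
  out <- tibble(a = g$edges$from, category = g$edges$category, b = g$edges$to)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read an identifier list
#'
#' One identifier per line, blank lines and `#` comments ignored. Used for
#' the approved-drug filter of [find_candidates()].
#' @param path file path
#' @return character vector
#' @export
read_drug_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x[x != "" & !startsWith(x, "#")]
}
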