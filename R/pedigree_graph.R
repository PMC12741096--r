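#' Build the population pedigree graph from a trio table
#'
#' Constructs a mixed graph over all individuals: directed parental edges
#' (parent -> child, tagged with the role `father` or `mother`) plus one
#' undirected-by-convention full-sibling edge per pair of individuals sharing
#' both (non-missing) parents. Parents that are referenced but have no row of
#' their own are added as founder nodes. Individuals with no parents,
#' children, or siblings are kept as isolated nodes. Every non-ID column of
#' the table (sex included) is attached verbatim as a node attribute.
#'
#' The graph is an igraph object (directed; sibling edges are stored once per
#' unordered pair and all neighbourhood/distance operations in this package
#' traverse every edge in both directions). Edge attributes: `type`
#' (`"parental"` or `"sibling"`) and `role` (`"father"`, `"mother"`, or `NA`
#' for sibling edges). Monozygotic twins get no special treatment: they are
#' full siblings.
#'
#' @param table A trio table (see [read_trios()], [trio_table()]).
#' @param attributes Optional data frame of additional per-individual
#'   attributes with an `id` column; attributes for IDs absent from the graph
#'   raise one collected warning, not an error.
#' @return A `pedigree_graph` (subclass of `igraph`).
#' @examples
#' trios <- trio_table(c("c1", "c2", "f1", "m1"),
#'                     dad_id = c("f1", "f1", NA, NA),
#'                     mom_id = c("m1", "m1", NA, NA))
#' g <- prepare_graph(trios)
#' igraph::ecount(g)  # 4 parental + 1 sibling edge
#' @seealso [graph_to_trio()], [get_family_graphs()], [get_kinship()]
#' @export
prepare_graph <- function(table, attributes = NULL) {
  validate_trios(table)
  ids <- as.character(table$id)
  nodes <- unique(c(ids,
                    table$dad_id[!is.na(table$dad_id)],
                    table$mom_id[!is.na(table$mom_id)]))

  dad_ok <- !is.na(table$dad_id)
  mom_ok <- !is.na(table$mom_id)
  par_edges <- tibble::tibble(
    from = c(table$dad_id[dad_ok], table$mom_id[mom_ok]),
    to = c(ids[dad_ok], ids[mom_ok]),
    type = "parental",
    role = c(rep("father", sum(dad_ok)), rep("mother", sum(mom_ok)))
  )
  sib_edges <- full_sibling_pairs(table)

  edges <- rbind(par_edges, sib_edges)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))

  cyc <- parental_cycle(g)
  if (!is.null(cyc)) {
    stop("cyclic parentage: ", paste(cyc, collapse = " -> "),
         " -> ", cyc[1], call. = FALSE)
  }

  attr_cols <- setdiff(names(table), .trio_id_cols)
  for (col in attr_cols) {
    vals <- rep(NA, length(nodes))
    vals[match(ids, nodes)] <- table[[col]]
    g <- igraph::set_vertex_attr(g, col, value = vals)
  }
  if (!is.null(attributes)) {
    if (!"id" %in% names(attributes)) {
      stop("`attributes` must have an 'id' column", call. = FALSE)
    }
    unknown <- setdiff(attributes$id, nodes)
    if (length(unknown)) {
      warning("attributes for unknown ID(s) ignored: ",
              paste(head(unknown, 10L), collapse = ", "), call. = FALSE)
    }
    keep <- attributes$id %in% nodes
    idx <- match(attributes$id[keep], nodes)
    for (col in setdiff(names(attributes), "id")) {
      vals <- igraph::vertex_attr(g, col) %||% rep(NA, length(nodes))
      vals[idx] <- attributes[[col]][keep]
      g <- igraph::set_vertex_attr(g, col, value = vals)
    }
  }
  class(g) <- unique(c("pedigree_graph", class(g)))
  g
}

# All unordered full-sibling pairs of a trio table: both parents shared and
# non-missing. One row per pair, lexicographic orientation.
full_sibling_pairs <- function(table) {
  kids <- table[!is.na(table$dad_id) & !is.na(table$mom_id), ]
  if (!nrow(kids)) {
    return(tibble::tibble(from = character(), to = character(),
                          type = character(), role = character()))
  }
  sibships <- split(kids$id, paste(kids$dad_id, kids$mom_id, sep = "\r"))
  pairs <- lapply(sibships, function(s) {
    if (length(s) < 2L) return(NULL)
    s <- sort(s)
    t(utils::combn(s, 2L))
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) {
    return(tibble::tibble(from = character(), to = character(),
                          type = character(), role = character()))
  }
  tibble::tibble(from = pairs[, 1L], to = pairs[, 2L],
                 type = "sibling", role = NA_character_)
}

# Returns NULL if the parental edges form a DAG, otherwise one witness cycle
# (vector of node names). Non-trivial strongly connected components of the
# parental subgraph contain all directed cycles.
parental_cycle <- function(g) {
  pg <- parental_subgraph(g)
  if (igraph::is_dag(pg)) return(NULL)
  comp <- igraph::components(pg, mode = "strong")
  big <- which(comp$csize > 1L)[1]
  members <- igraph::V(pg)$name[comp$membership == big]
  sub <- igraph::induced_subgraph(pg, members)
  # walk the component until a node repeats, then cut out the loop
  walk <- igraph::V(sub)$name[1]
  repeat {
    nxt <- igraph::neighbors(sub, walk[length(walk)], mode = "out")$name[1]
    if (nxt %in% walk) {
      return(walk[seq(match(nxt, walk), length(walk))])
    }
    walk <- c(walk, nxt)
  }
}

parental_subgraph <- function(g) {
  igraph::subgraph_from_edges(g, igraph::E(g)[igraph::E(g)$type == "parental"],
                              delete.vertices = FALSE)
}

# Edge table of parental edges: tibble(parent, child, role)
parental_edge_table <- function(g) {
  e <- igraph::as_data_frame(g, what = "edges")
  e <- e[e$type == "parental", , drop = FALSE]
  tibble::tibble(parent = e$from, child = e$to, role = e$role)
}

sibling_edge_table <- function(g) {
  e <- igraph::as_data_frame(g, what = "edges")
  e <- e[e$type == "sibling", , drop = FALSE]
  tibble::tibble(a = e$from, b = e$to)
}

#' Validate the invariants of a pedigree graph
#'
#' Reports, without erroring: directed cycles among parental edges, children
#' with more than one father-role or mother-role in-edge, and sibling edges
#' that disagree with the full-sibling rule (a sibling edge must exist exactly
#' between pairs with identical, non-missing father and mother).
#'
#' @param graph A pedigree graph.
#' @return A tibble with columns `check` and `detail`, one row per violation;
#'   zero rows if and only if all invariants hold.
#' @export
validate_graph <- function(graph) {
  report <- list()
  add <- function(check, detail) {
    report[[length(report) + 1L]] <<- tibble::tibble(check = check,
                                                     detail = detail)
  }
  cyc <- parental_cycle(graph)
  if (!is.null(cyc)) {
    add("parental_cycle", paste(c(cyc, cyc[1]), collapse = " -> "))
  }
  pe <- parental_edge_table(graph)
  if (nrow(pe)) {
    per_role <- dplyr::count(pe, .data$child, .data$role)
    bad <- per_role[per_role$n > 1L, ]
    for (i in seq_len(nrow(bad))) {
      add("duplicate_parent_role",
          paste0("child '", bad$child[i], "' has ", bad$n[i], " ",
                 bad$role[i], "-role parents"))
    }
  }
  # recompute the expected sibling pairs from the parental edges
  wide <- tidyr::pivot_wider(pe, id_cols = "child", names_from = "role",
                             values_from = "parent",
                             values_fn = function(x) x[1])
  if (!"father" %in% names(wide)) wide$father <- NA_character_
  if (!"mother" %in% names(wide)) wide$mother <- NA_character_
  expected <- full_sibling_pairs(tibble::tibble(
    id = wide$child, dad_id = wide$father, mom_id = wide$mother))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  exp_keys <- key(expected$from, expected$to)
  se <- sibling_edge_table(graph)
  got_keys <- key(se$a, se$b)
  for (k in setdiff(got_keys, exp_keys)) {
    add("spurious_sibling_edge",
        paste0("sibling edge between non-full-siblings: ",
               gsub("\r", " -- ", k)))
  }
  for (k in setdiff(exp_keys, got_keys)) {
    add("missing_sibling_edge",
        paste0("full siblings without sibling edge: ",
               gsub("\r", " -- ", k)))
  }
  dup <- unique(got_keys[duplicated(got_keys)])
  for (k in dup) {
    add("duplicate_sibling_edge", gsub("\r", " -- ", k))
  }
  if (!length(report)) {
    return(tibble::tibble(check = character(), detail = character()))
  }
  dplyr::bind_rows(report)
}

#' Serialize / load a pedigree graph as edge-list + node-attribute TSV
#'
#' `write_graph_tsv()` writes `<prefix>_edges.tsv` (source, target, edge_type,
#' role) and `<prefix>_nodes.tsv` (id + one column per node attribute);
#' `read_graph_tsv()` loads them back losslessly.
#'
#' @param graph A pedigree graph.
#' @param prefix Path prefix for the two files.
#' @return `write_graph_tsv()`: the two paths, invisibly. `read_graph_tsv()`:
#'   a `pedigree_graph`.
#' @export
write_graph_tsv <- function(graph, prefix) {
  e <- igraph::as_data_frame(graph, what = "edges")
  names(e)[names(e) == "type"] <- "edge_type"
  v <- igraph::as_data_frame(graph, what = "vertices")
  names(v)[names(v) == "name"] <- "id"
  ep <- paste0(prefix, "_edges.tsv")
  np <- paste0(prefix, "_nodes.tsv")
  readr::write_tsv(e, ep, na = "NA", progress = FALSE)
  readr::write_tsv(v, np, na = "NA", progress = FALSE)
  invisible(c(edges = ep, nodes = np))
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(prefix) {
  e <- readr::read_tsv(paste0(prefix, "_edges.tsv"),
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE, show_col_types = FALSE)
  v <- readr::read_tsv(paste0(prefix, "_nodes.tsv"),
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE, show_col_types = FALSE)
  names(e)[names(e) == "edge_type"] <- "type"
  names(v)[names(v) == "id"] <- "name"
  g <- igraph::graph_from_data_frame(e, directed = TRUE, vertices = v)
  class(g) <- unique(c("pedigree_graph", class(g)))
  g
}
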