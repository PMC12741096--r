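#' Extract the degree-n family graph of each proband
#'
#' For every proband, takes the neighbourhood (ego) graph of all individuals
#' within graph distance `degree` of the proband, ignoring edge direction and
#' counting sibling edges as one step. On loop-free pedigrees this distance
#' coincides with the classical degree of relatedness (parent 1, grandparent /
#' half-sibling / avuncular 2, first cousin 3, ...). Probands may appear as
#' members of each other's families. Node attributes are preserved in the
#' subgraphs.
#'
#' Non-blood neighbours (e.g. the co-parent of a proband's child, two
#' undirected steps away) are members under plain neighbourhood semantics;
#' set `blood_only = TRUE` to drop members with no genealogical path to the
#' proband (path-counting kinship 0; see [genealogical_distance()]).
#'
#' @param graph A pedigree graph from [prepare_graph()].
#' @param proband_ids Character vector of node names to centre families on.
#' @param degree Positive integer: maximum graph distance to include.
#' @param blood_only Drop members with no genealogical path to the proband.
#' @return A named list of `family_graph` objects (names = proband IDs), each
#'   a list with elements `proband_id`, `members` (tibble `member_id`,
#'   `degree`, sorted by degree then ID), and `graph` (the induced subgraph).
#' @examples
#' trios <- trio_table(c("c1", "c2", "f1", "m1"),
#'                     dad_id = c("f1", "f1", NA, NA),
#'                     mom_id = c("m1", "m1", NA, NA))
#' g <- prepare_graph(trios)
#' fams <- get_family_graphs(g, "c1", degree = 1)
#' fams[["c1"]]$members
#' @export
get_family_graphs <- function(graph, proband_ids, degree,
                              blood_only = FALSE) {
  stopifnot(inherits(graph, "igraph"))
  proband_ids <- as.character(proband_ids)
  if (!length(proband_ids)) return(stats::setNames(list(), character()))
  if (!is.numeric(degree) || length(degree) != 1L || degree < 1 ||
      degree != round(degree)) {
    stop("`degree` must be a positive integer", call. = FALSE)
  }
  unknown <- setdiff(proband_ids, igraph::V(graph)$name)
  if (length(unknown)) {
    stop("unknown proband ID(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  egos <- igraph::make_ego_graph(graph, order = degree, nodes = proband_ids,
                                 mode = "all")
  fams <- Map(function(pid, sub) {
    # within the distance-n ball, in-ball shortest paths equal global ones
    dm <- igraph::distances(sub, v = pid, mode = "all")
    d <- stats::setNames(dm[1, ], colnames(dm))
    members <- tibble::tibble(member_id = names(d),
                              degree = as.integer(d))
    if (blood_only) {
      keep <- vapply(members$member_id, function(m) {
        is.finite(genealogical_distance(sub, pid, m))
      }, logical(1))
      members <- members[keep, ]
      sub <- igraph::induced_subgraph(sub, members$member_id)
    }
    members <- dplyr::arrange(members, .data$degree, .data$member_id)
    structure(list(proband_id = pid, members = members, graph = sub),
              class = "family_graph")
  }, proband_ids, egos)
  stats::setNames(fams, proband_ids)
}

#' @export
print.family_graph <- function(x, ...) {
  cat("<family_graph> proband:", x$proband_id,
      "|", nrow(x$members), "members, max degree",
      max(x$members$degree), "\n")
  print(x$members, ...)
  invisible(x)
}

#' Long-format membership table of extracted families
#'
#' @param families A list of `family_graph` objects from
#'   [get_family_graphs()].
#' @return A tibble with one row per (proband, member) pair — the proband
#'   itself included at degree 0 — with columns `proband_id`, `member_id`,
#'   `degree`.
#' @export
membership_table <- function(families) {
  if (!length(families)) {
    return(tibble::tibble(proband_id = character(), member_id = character(),
                          degree = integer()))
  }
  dplyr::bind_rows(lapply(families, function(f) {
    tibble::tibble(proband_id = f$proband_id,
                   member_id = f$members$member_id,
                   degree = f$members$degree)
  }))
}
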