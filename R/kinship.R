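#' Shortest genealogical distance between two individuals
#'
#' The distance d underlying the path-counting kinship estimator
#' `0.5^d * C`. A genealogically valid path ascends from `i` through
#' child-to-parent links, optionally crosses exactly one full-sibling edge at
#' its apex, then descends to `j`; it must pass through a most recent common
#' ancestor configuration. Raw undirected graph distance is deliberately not
#' used: it would assign spurious kinship to affines (e.g. two co-parents are
#' two undirected steps apart through their child, but that path descends
#' before ascending and carries no shared ancestry).
#'
#' Concretely, d is the minimum over
#' \itemize{
#'   \item common ancestors `a` (self included) of `up_i(a) + up_j(a)`, and
#'   \item full-sibling edges `s -- t` with `s` an ancestor-or-self of `i` and
#'     `t` an ancestor-or-self of `j`, of `up_i(s) + 1 + up_j(t)`.
#' }
#'
#' @param graph A pedigree graph.
#' @param i,j Node names.
#' @return A non-negative integer distance (0 for `i == j`), or `Inf` when no
#'   genealogical path exists.
#' @examples
#' trios <- trio_table(c("c1", "c2", "f1", "m1"),
#'                     dad_id = c("f1", "f1", NA, NA),
#'                     mom_id = c("m1", "m1", NA, NA))
#' g <- prepare_graph(trios)
#' genealogical_distance(g, "c1", "f1")  # parent-child: 1
#' genealogical_distance(g, "c1", "c2")  # full siblings: 1 (sibling edge)
#' @seealso [get_kinship()]
#' @export
genealogical_distance <- function(graph, i, j) {
  ids <- igraph::V(graph)$name
  unknown <- setdiff(c(i, j), ids)
  if (length(unknown)) {
    stop("unknown ID(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (i == j) return(0L)
  maps <- ancestor_maps(graph, c(i, j))
  mi <- maps[[i]]
  mj <- maps[[j]]
  d <- Inf
  common <- intersect(names(mi), names(mj))
  if (length(common)) d <- min(d, mi[common] + mj[common])
  sib <- sibling_edge_table(graph)
  if (nrow(sib)) {
    for (k in seq_len(nrow(sib))) {
      s <- sib$a[k]; t <- sib$b[k]
      if (s %in% names(mi) && t %in% names(mj)) {
        d <- min(d, mi[[s]] + 1 + mj[[t]])
      }
      if (t %in% names(mi) && s %in% names(mj)) {
        d <- min(d, mi[[t]] + 1 + mj[[s]])
      }
    }
  }
  if (is.finite(d)) as.integer(d) else Inf
}

# For each requested node, the named integer vector of up-distances to every
# ancestor-or-self (self = 0). Multiple ascending paths to the same ancestor
# keep the minimum. BFS over child -> parent adjacency.
ancestor_maps <- function(graph, nodes = igraph::V(graph)$name) {
  pe <- parental_edge_table(graph)
  parents_of <- split(pe$parent, pe$child)
  lapply(stats::setNames(nodes, nodes), function(x) {
    dist <- c(stats::setNames(0L, x))
    frontier <- x
    step <- 0L
    while (length(frontier)) {
      step <- step + 1L
      nxt <- unique(unlist(parents_of[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, names(dist))
      if (!length(nxt)) break
      dist <- c(dist, stats::setNames(rep(step, length(nxt)), nxt))
      frontier <- nxt
    }
    dist
  })
}

#' Kinship matrix by path counting
#'
#' Computes, for every pair of individuals in a (neighbourhood) graph, the
#' kinship-by-path-counting estimate `C * 0.5^d`, where d is the shortest
#' genealogical distance of [genealogical_distance()] and `C` is a constant
#' (default 1; it may represent, e.g., the heritability of a phenotype).
#' Pairs with no genealogical path get 0; the diagonal is `C`.
#'
#' On loop-free pedigrees (no pair related through two distinct ancestral
#' couples) `0.5^d` equals twice the classical kinship coefficient. Under
#' pedigree loops it is a lower bound (double first cousins: 0.125 vs the
#' classical 0.25), and the estimator is not inbreeding-aware: the diagonal
#' stays at `C` regardless of ancestral consanguinity. Distances are taken
#' within the supplied graph; if a neighbourhood subgraph truncates a
#' connecting ancestor, the truncated connection does not contribute.
#'
#' @param graph A pedigree graph or a `family_graph` (its subgraph is used).
#' @param C Positive scale constant applied to every entry.
#' @param output `"dense"` for a base matrix with ID dimnames, or
#'   `"sparse_triplets"` for a long tibble (`id_1`, `id_2`, `kinship`) of the
#'   nonzero upper triangle plus the diagonal (structural zeros absent:
#'   population graphs are mostly unrelated pairs).
#' @return A symmetric numeric matrix, or a triplet tibble.
#' @examples
#' trios <- trio_table(c("c1", "c2", "f1", "m1"),
#'                     dad_id = c("f1", "f1", NA, NA),
#'                     mom_id = c("m1", "m1", NA, NA))
#' g <- prepare_graph(trios)
#' get_kinship(g)["c1", "f1"]  # 0.5
#' @export
get_kinship <- function(graph, C = 1,
                        output = c("dense", "sparse_triplets")) {
  output <- match.arg(output)
  if (inherits(graph, "family_graph")) graph <- graph$graph
  stopifnot(inherits(graph, "igraph"))
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    stop("`C` must be a positive number", call. = FALSE)
  }
  ids <- igraph::V(graph)$name
  d <- pairwise_genealogical_distances(graph)
  if (output == "dense") {
    n <- length(ids)
    mat <- matrix(0, n, n, dimnames = list(ids, ids))
    if (nrow(d)) {
      i <- match(d$id_1, ids)
      j <- match(d$id_2, ids)
      mat[cbind(i, j)] <- C * 0.5^d$distance
      mat[cbind(j, i)] <- C * 0.5^d$distance
    }
    diag(mat) <- C
    mat
  } else {
    out <- tibble::tibble(id_1 = c(ids, d$id_1),
                          id_2 = c(ids, d$id_2),
                          kinship = c(rep(C, length(ids)), C * 0.5^d$distance))
    dplyr::arrange(out, .data$id_1, .data$id_2)
  }
}

# All finite pairwise genealogical distances of a graph as a tibble
# (id_1, id_2, distance), upper triangle only (id_1 < id_2).
# Strategy: per-node ancestor maps inverted to per-ancestor descendant lists;
# each shared ancestor a contributes candidates up_i(a) + up_j(a) for all
# descendant pairs, each sibling edge s--t contributes
# up_i(s) + 1 + up_j(t) for descendants i of s, j of t; group-min wins.
pairwise_genealogical_distances <- function(graph) {
  ids <- igraph::V(graph)$name
  maps <- ancestor_maps(graph, ids)
  desc_id <- rep(ids, lengths(maps))
  anc_id <- unlist(lapply(maps, names), use.names = FALSE)
  up <- unlist(maps, use.names = FALSE)
  by_anc <- split(seq_along(anc_id), anc_id)

  cand_i <- vector("list", 0L)
  cand_j <- vector("list", 0L)
  cand_d <- vector("list", 0L)
  push <- function(i, j, d) {
    keep <- i != j
    cand_i[[length(cand_i) + 1L]] <<- pmin(i[keep], j[keep])
    cand_j[[length(cand_j) + 1L]] <<- pmax(i[keep], j[keep])
    cand_d[[length(cand_d) + 1L]] <<- d[keep]
  }
  for (rows in by_anc) {
    if (length(rows) < 2L) next
    di <- up[rows]
    nd <- desc_id[rows]
    pair <- utils::combn(seq_along(rows), 2L)
    push(nd[pair[1L, ]], nd[pair[2L, ]], di[pair[1L, ]] + di[pair[2L, ]])
  }
  sib <- sibling_edge_table(graph)
  for (k in seq_len(nrow(sib))) {
    rs <- by_anc[[sib$a[k]]]
    rt <- by_anc[[sib$b[k]]]
    if (is.null(rs) || is.null(rt)) next
    grid_s <- rep(seq_along(rs), times = length(rt))
    grid_t <- rep(seq_along(rt), each = length(rs))
    push(desc_id[rs][grid_s], desc_id[rt][grid_t],
         up[rs][grid_s] + 1L + up[rt][grid_t])
  }
  if (!length(cand_i)) {
    return(tibble::tibble(id_1 = character(), id_2 = character(),
                          distance = integer()))
  }
  cand <- tibble::tibble(id_1 = unlist(cand_i), id_2 = unlist(cand_j),
                         distance = unlist(cand_d))
  dplyr::summarise(dplyr::group_by(cand, .data$id_1, .data$id_2),
                   distance = min(.data$distance), .groups = "drop")
}

#' Write a kinship matrix to disk
#'
#' @param kin A dense kinship matrix or triplet tibble from [get_kinship()].
#' @param path Output path.
#' @return `path`, invisibly. Dense matrices are written as CSV with an ID
#'   header column; triplet tibbles as TSV (`id_1`, `id_2`, `kinship`).
#' @export
write_kinship <- function(kin, path) {
  if (is.matrix(kin)) {
    out <- data.frame(id = rownames(kin), kin, check.names = FALSE)
    readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  } else {
    readr::write_tsv(kin, path, progress = FALSE)
  }
  invisible(path)
}
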