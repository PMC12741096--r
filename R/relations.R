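#' Label a relationship from its MRCA configuration
#'
#' A consanguine relationship is characterised by the generations `up` from
#' the proband to the most recent common ancestor (MRCA), the generations
#' `down` from the relative to the MRCA, and whether the connection is full
#' (through a full-sibling pair / both parents at the apex) or half (through
#' a single shared ancestor). The code taxonomy:
#'
#' \itemize{
#'   \item `(0,0)` Self; `(u,0)` ancestors `Pa`, `GPa`, `GGPa`, ... (one `G`
#'     prepended per extra generation); `(0,v)` descendants `Ch`, `GCh`, ...
#'   \item `(1,1)` siblings `Sib` / `HSib`.
#'   \item `(u,1)`, u >= 2: piblings (parent's sibling, i.e. aunts/uncles)
#'     `Pib`, `GPib`, `GGPib`, ...; `(1,v)`, v >= 2: niblings (sibling's
#'     child) `Nib`, `GNib`, ...
#'   \item `(u,v)`, u,v >= 2: cousins of order `min(u,v) - 1` with removal
#'     `|u - v|`: `1C`, `2C`, `1C2R` (first cousin twice removed), ...
#' }
#' Half relations take an `H` prefix. The implied degree of relatedness is
#' `up + down - 1` for full collateral relations (the sibling edge at the
#' apex saves a step) and `up + down` otherwise.
#'
#' @param up,down Non-negative integers: generations to the MRCA on the
#'   proband's and the relative's side.
#' @param fullness `"full"`, `"half"`, or `"not_applicable"` (lineal
#'   relations and self).
#' @return A tibble row: `up`, `down`, `fullness`, `code`, `description`,
#'   `degree`.
#' @examples
#' classify_pair(0, 1)             # Ch (child)
#' classify_pair(2, 1, "full")     # Pib (pibling: aunt/uncle)
#' classify_pair(2, 4, "full")     # 1C2R (first cousin twice removed)
#' @export
classify_pair <- function(up, down,
                          fullness = c("not_applicable", "full", "half")) {
  fullness <- match.arg(fullness)
  if (!is.numeric(up) || !is.numeric(down) || length(up) != 1L ||
      length(down) != 1L || is.na(up) || is.na(down) ||
      up < 0 || down < 0 || up != round(up) || down != round(down)) {
    stop("`up` and `down` must be single non-negative integers",
         call. = FALSE)
  }
  up <- as.integer(up); down <- as.integer(down)
  half <- identical(fullness, "half")
  collateral <- up >= 1L && down >= 1L
  degree <- if (collateral && !half) up + down - 1L else up + down
  greats <- function(n) strrep("G", n)
  if (up == 0L && down == 0L) {
    code <- "Self"; desc <- "self"
  } else if (down == 0L) {
    code <- switch(as.character(up), "1" = "Pa", "2" = "GPa",
                   paste0(greats(up - 2L), "GPa"))
    desc <- switch(as.character(up), "1" = "parent", "2" = "grandparent",
                   paste0(strrep("great-", up - 2L), "grandparent"))
  } else if (up == 0L) {
    code <- switch(as.character(down), "1" = "Ch", "2" = "GCh",
                   paste0(greats(down - 2L), "GCh"))
    desc <- switch(as.character(down), "1" = "child", "2" = "grandchild",
                   paste0(strrep("great-", down - 2L), "grandchild"))
  } else if (up == 1L && down == 1L) {
    code <- "Sib"; desc <- "sibling"
  } else if (down == 1L) {
    code <- if (up == 2L) "Pib" else paste0(greats(up - 3L), "GPib")
    desc <- if (up == 2L) "pibling (parent's sibling)" else
      paste0(strrep("great-", up - 3L), "grand-pibling")
  } else if (up == 1L) {
    code <- if (down == 2L) "Nib" else paste0(greats(down - 3L), "GNib")
    desc <- if (down == 2L) "nibling (sibling's child)" else
      paste0(strrep("great-", down - 3L), "grand-nibling")
  } else {
    order <- min(up, down) - 1L
    removal <- abs(up - down)
    code <- if (removal == 0L) paste0(order, "C") else
      paste0(order, "C", removal, "R")
    ord_word <- c("first", "second", "third", "fourth", "fifth",
                  "sixth")[min(order, 6L)]
    desc <- paste0(ord_word, " cousin",
                   if (removal == 1L) " once removed"
                   else if (removal == 2L) " twice removed"
                   else if (removal > 2L) paste0(" ", removal,
                                                 " times removed"))
  }
  if (half && collateral) {
    code <- paste0("H", code)
    desc <- paste("half", desc)
  }
  tibble::tibble(up = up, down = down, fullness = fullness,
                 code = code, description = desc, degree = degree)
}

# Enumerate all MRCA configurations between proband i and member j within a
# graph and return the chosen one: minimal implied degree, ties broken toward
# the more horizontal relation (larger min(up, down)), then full before half.
# Returns NULL when no configuration exists (affines / unrelated).
mrca_configuration <- function(mi, mj, sib) {
  cfg <- list()
  common <- intersect(names(mi), names(mj))
  for (a in common) {
    u <- mi[[a]]; v <- mj[[a]]
    cfg[[length(cfg) + 1L]] <- c(u, v, 0L)   # 0 = ancestor route (half)
  }
  if (nrow(sib)) {
    for (k in seq_len(nrow(sib))) {
      s <- sib$a[k]; t <- sib$b[k]
      if (s %in% names(mi) && t %in% names(mj)) {
        cfg[[length(cfg) + 1L]] <- c(mi[[s]] + 1L, mj[[t]] + 1L, 1L)
      }
      if (t %in% names(mi) && s %in% names(mj)) {
        cfg[[length(cfg) + 1L]] <- c(mi[[t]] + 1L, mj[[s]] + 1L, 1L)
      }
    }
  }
  if (!length(cfg)) return(NULL)
  m <- do.call(rbind, cfg)
  u <- m[, 1L]; v <- m[, 2L]; full <- m[, 3L] == 1L
  lineal <- u == 0L | v == 0L
  degree <- ifelse(full & !lineal, u + v - 1L, u + v)
  horiz <- pmin(u, v)
  ord <- order(degree, -horiz, -full, u, v)[1L]
  list(up = u[ord], down = v[ord],
       fullness = if (lineal[ord] || (u[ord] == 0L && v[ord] == 0L))
         "not_applicable" else if (full[ord]) "full" else "half",
       degree = degree[ord])
}

#' Label every member of a family graph relative to its proband
#'
#' For each member, all MRCA configurations (shared-ancestor routes and
#' full-sibling-bridged routes, as in [genealogical_distance()]) are
#' enumerated; the configuration with minimal implied degree is selected,
#' ties broken toward the more horizontal relation (larger `min(up, down)`).
#' A connection through a full-sibling pair at the apex is `full`; through a
#' single shared ancestor, `half`. Members with no configuration — affines
#' such as the co-parent of the proband's child — are labelled `Unrelated`.
#' Configurations ascending more than `max_up` generations on the proband's
#' side, or of implied degree above `max_degree`, are bucketed as `Distant`:
#' the labelling favours horizontal relations identifiable from the
#' great-great-great-great-grandparents of a proband down, so it is not
#' exhaustive past the fifth degree and assigns no named relation past the
#' ninth.
#'
#' When the graph carries a `sex` attribute, descriptions (not codes) are
#' sex-specialised for near relations (mother/father, aunt/uncle, ...).
#'
#' @param family A `family_graph` from [get_family_graphs()].
#' @param max_up Cap on proband-side ascent for named labels (default 6).
#' @param max_degree Cap on implied degree for named labels (default 9).
#' @return A tibble with one row per member: `proband_id`, `member_id`,
#'   `up`, `down`, `fullness`, `code`, `description`, `degree`.
#' @examples
#' trios <- trio_table(c("c1", "c2", "f1", "m1"),
#'                     dad_id = c("f1", "f1", NA, NA),
#'                     mom_id = c("m1", "m1", NA, NA),
#'                     sex = c("male", "female", "male", "female"))
#' g <- prepare_graph(trios)
#' fam <- get_family_graphs(g, "c1", degree = 1)[["c1"]]
#' get_relations(fam)
#' @export
get_relations <- function(family, max_up = 6L, max_degree = 9L) {
  stopifnot(inherits(family, "family_graph"))
  g <- family$graph
  pid <- family$proband_id
  ids <- family$members$member_id
  maps <- ancestor_maps(g, igraph::V(g)$name)
  sib <- sibling_edge_table(g)
  sexes <- if ("sex" %in% igraph::vertex_attr_names(g)) {
    stats::setNames(igraph::V(g)$sex, igraph::V(g)$name)
  } else NULL
  rows <- lapply(ids, function(m) {
    if (m == pid) {
      lab <- classify_pair(0L, 0L, "not_applicable")
    } else {
      cfg <- mrca_configuration(maps[[pid]], maps[[m]], sib)
      if (is.null(cfg)) {
        lab <- tibble::tibble(up = NA_integer_, down = NA_integer_,
                              fullness = "not_applicable",
                              code = "Unrelated",
                              description = "no genealogical path",
                              degree = NA_integer_)
      } else if (cfg$up > max_up || cfg$degree > max_degree) {
        lab <- tibble::tibble(up = cfg$up, down = cfg$down,
                              fullness = cfg$fullness, code = "Distant",
                              description = "beyond labelling range",
                              degree = cfg$degree)
      } else {
        lab <- classify_pair(cfg$up, cfg$down, cfg$fullness)
      }
    }
    lab$description <- sex_specialise(lab$code, lab$description,
                                      if (is.null(sexes)) NA_character_
                                      else sexes[[m]])
    tibble::tibble(proband_id = pid, member_id = m, lab)
  })
  dplyr::bind_rows(rows)
}

# Sex-specialised wording for the nearest relations; codes stay sex-neutral.
sex_specialise <- function(code, description, sex) {
  if (is.na(sex) || !sex %in% c("female", "male")) return(description)
  word <- switch(code,
    Pa = c(female = "mother", male = "father"),
    Ch = c(female = "daughter", male = "son"),
    Sib = c(female = "sister", male = "brother"),
    HSib = c(female = "half sister", male = "half brother"),
    GPa = c(female = "grandmother", male = "grandfather"),
    GCh = c(female = "granddaughter", male = "grandson"),
    Pib = c(female = "aunt", male = "uncle"),
    Nib = c(female = "niece", male = "nephew"),
    HPib = c(female = "half aunt", male = "half uncle"),
    HNib = c(female = "half niece", male = "half nephew"),
    NULL)
  if (is.null(word)) description else unname(word[sex])
}
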