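#' Read a trio table from delimited text or PLINK .fam
#'
#' A trio table holds one row per individual: the individual's own ID plus the
#' IDs of the father and the mother. Parents referenced without a row of their
#' own are legal (register data routinely truncate ascending lineages); they
#' become founder nodes at graph construction time. All IDs are coerced to
#' character on ingest and any ID matching one of `missing_codes` becomes `NA`.
#'
#' @param path Path to the input file.
#' @param format One of `"csv"`, `"tsv"`, `"plink_fam"`. PLINK `.fam` files are
#'   whitespace-delimited with columns FID IID PAT MAT SEX PHENO and no header;
#'   SEX is recoded 1 = male, 2 = female, other = unknown, and FID/PHENO are
#'   carried as attribute columns `fid` and `pheno`.
#' @param missing_codes Character vector of strings treated as missing parent
#'   IDs. Default `c("", "NA", "0")`: `"0"` is the PLINK convention but may be
#'   a legitimate ID in other registries, hence configurable.
#' @param id_cols Named character vector mapping the roles `id`, `dad_id`,
#'   `mom_id` (and optionally `sex`) to column names in the file. Ignored for
#'   `plink_fam`.
#' @return A `trio_tbl`: a tibble with columns `id`, `dad_id`, `mom_id`,
#'   optionally `sex` (`"female"`, `"male"`, `"unknown"`), and every other
#'   input column carried verbatim as a character attribute column. The
#'   configured missing codes are stored in the `"missing_codes"` attribute.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,dad_id,mom_id", "c1,f1,m1", "f1,0,0", "m1,0,0"), tf)
#' read_trios(tf, format = "csv")
#' @seealso [write_trios()], [validate_trios()], [prepare_graph()]
#' @export
read_trios <- function(path,
                       format = c("csv", "tsv", "plink_fam"),
                       missing_codes = c("", "NA", "0"),
                       id_cols = c(id = "id", dad_id = "dad_id",
                                   mom_id = "mom_id", sex = "sex")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("trio file does not exist: ", path, call. = FALSE)
  }
  if (format == "plink_fam") {
    raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                             col.names = c("fid", "id", "dad_id", "mom_id",
                                           "sex_code", "pheno"))
    tbl <- tibble::tibble(
      id = raw$id,
      dad_id = raw$dad_id,
      mom_id = raw$mom_id,
      sex = dplyr::case_match(raw$sex_code,
                              "1" ~ "male", "2" ~ "female",
                              .default = "unknown"),
      fid = raw$fid,
      pheno = raw$pheno
    )
  } else {
    delim <- if (format == "csv") "," else "\t"
    raw <- readr::read_delim(path, delim = delim,
                             col_types = readr::cols(.default = readr::col_character()),
                             na = character(), progress = FALSE,
                             show_col_types = FALSE)
    for (role in c("id", "dad_id", "mom_id")) {
      col <- unname(id_cols[role])
      if (is.na(col) || !col %in% names(raw)) {
        stop("required column '", col, "' (", role, ") not found in ", path,
             call. = FALSE)
      }
    }
    raw <- dplyr::rename(raw, dplyr::all_of(
      id_cols[!is.na(id_cols) & id_cols %in% names(raw)]))
    tbl <- dplyr::relocate(raw, dplyr::any_of(c(.trio_id_cols, "sex")))
  }
  tbl$dad_id[tbl$dad_id %in% missing_codes] <- NA_character_
  tbl$mom_id[tbl$mom_id %in% missing_codes] <- NA_character_
  if ("sex" %in% names(tbl)) {
    tbl$sex[is.na(tbl$sex) | !tbl$sex %in% c("female", "male")] <- "unknown"
  }
  new_trio_tbl(tbl, missing_codes = missing_codes)
}

#' Construct a trio table from vectors or a data frame
#'
#' @param x A data frame with columns `id`, `dad_id`, `mom_id` (plus optional
#'   `sex` and attribute columns), or a character vector of individual IDs.
#' @param dad_id,mom_id Parent IDs (recycled `NA` allowed) when `x` is a
#'   character vector.
#' @param sex Optional sex codes (`"female"`, `"male"`, `"unknown"`).
#' @param missing_codes Strings mapped to `NA` in the parent columns.
#' @param ... Further equal-length attribute columns when `x` is a vector.
#' @return A validated `trio_tbl`.
#' @examples
#' trio_table(c("c1", "f1", "m1"),
#'            dad_id = c("f1", NA, NA),
#'            mom_id = c("m1", NA, NA),
#'            sex = c("female", "male", "female"))
#' @export
trio_table <- function(x, dad_id = NULL, mom_id = NULL, sex = NULL,
                       missing_codes = c("", "NA", "0"), ...) {
  if (is.data.frame(x)) {
    tbl <- tibble::as_tibble(x)
  } else {
    tbl <- tibble::tibble(id = as.character(x),
                          dad_id = as.character(dad_id),
                          mom_id = as.character(mom_id))
    if (!is.null(sex)) tbl$sex <- as.character(sex)
    extra <- list(...)
    for (nm in names(extra)) tbl[[nm]] <- extra[[nm]]
  }
  missing <- setdiff(.trio_id_cols, names(tbl))
  if (length(missing)) {
    stop("trio table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in .trio_id_cols) tbl[[col]] <- as.character(tbl[[col]])
  tbl$dad_id[tbl$dad_id %in% missing_codes] <- NA_character_
  tbl$mom_id[tbl$mom_id %in% missing_codes] <- NA_character_
  new_trio_tbl(tbl, missing_codes = missing_codes)
}

new_trio_tbl <- function(tbl, missing_codes) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "missing_codes") <- missing_codes
  class(tbl) <- unique(c("trio_tbl", class(tbl)))
  validate_trios(tbl)
  tbl
}

#' Validate a trio table
#'
#' Checks the structural invariants of trio data: IDs are non-missing and
#' unique, no individual is recorded as their own parent, and father and
#' mother differ unless both are missing.
#'
#' @param table A trio table (see [trio_table()]).
#' @return `table`, invisibly, if valid; otherwise an error describing every
#'   violated invariant, listing the offending IDs.
#' @export
validate_trios <- function(table) {
  problems <- character()
  if (anyNA(table$id) || any(table$id == "")) {
    problems <- c(problems, "individual_id is missing for some rows")
  }
  dup <- unique(table$id[duplicated(table$id)])
  if (length(dup)) {
    problems <- c(problems,
                  paste0("duplicate individual_id: ",
                         paste(head(dup, 10L), collapse = ", ")))
  }
  self_par <- table$id[!is.na(table$dad_id) & table$id == table$dad_id |
                         !is.na(table$mom_id) & table$id == table$mom_id]
  if (length(self_par)) {
    problems <- c(problems,
                  paste0("self-parentage for: ",
                         paste(head(unique(self_par), 10L), collapse = ", ")))
  }
  same_par <- table$id[!is.na(table$dad_id) & !is.na(table$mom_id) &
                         table$dad_id == table$mom_id]
  if (length(same_par)) {
    problems <- c(problems,
                  paste0("father_id equals mother_id for: ",
                         paste(head(unique(same_par), 10L), collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid trio table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(table)
}

#' Write a trio table to delimited text or PLINK .fam
#'
#' Missing parent IDs are written as the first configured missing code of the
#' table (`"0"` for PLINK output regardless). `read_trios(write_trios(x))` is
#' the identity for csv/tsv.
#'
#' @param table A trio table.
#' @param path Output path.
#' @param format One of `"csv"`, `"tsv"`, `"plink_fam"`. PLINK output writes
#'   FID IID PAT MAT SEX PHENO; FID comes from a `fid` column when present
#'   (otherwise the individual ID), PHENO from a `pheno` column (otherwise
#'   `-9`), and unknown sex is written as `0`.
#' @return `path`, invisibly.
#' @export
write_trios <- function(table, path, format = c("csv", "tsv", "plink_fam")) {
  format <- match.arg(format)
  validate_trios(table)
  if (format == "plink_fam") {
    sex_code <- if ("sex" %in% names(table)) {
      dplyr::case_match(table$sex, "male" ~ "1", "female" ~ "2", .default = "0")
    } else rep("0", nrow(table))
    out <- data.frame(
      fid = if ("fid" %in% names(table)) table$fid else table$id,
      iid = table$id,
      pat = ifelse(is.na(table$dad_id), "0", table$dad_id),
      mat = ifelse(is.na(table$mom_id), "0", table$mom_id),
      sex = sex_code,
      pheno = if ("pheno" %in% names(table)) table$pheno else rep("-9", nrow(table))
    )
    utils::write.table(out, path, quote = FALSE, sep = " ",
                       row.names = FALSE, col.names = FALSE)
  } else {
    na_code <- (attr(table, "missing_codes") %||% c("", "NA", "0"))[1]
    out <- as.data.frame(table)
    readr::write_delim(out, path, delim = if (format == "csv") "," else "\t",
                       na = na_code, progress = FALSE)
  }
  invisible(path)
}

#' Reconstruct a trio table from a pedigree graph
#'
#' Inverts [prepare_graph()]: every node becomes one record whose `dad_id` is
#' its unique male parent and `mom_id` its unique female parent. This requires
#' a `sex` attribute on every node that has children. Sibling edges are
#' ignored (they are derivable from shared parents), and nodes without
#' parental in-edges become founders with both parents missing. Node
#' attributes are carried back as columns.
#'
#' @param graph A pedigree graph from [prepare_graph()].
#' @param on_ambiguity What to do when a parent's sex is unknown:
#'   `"error"` (default; silent data loss is worse than a loud failure) or
#'   `"set_missing"` (drop that parent link, leaving the slot `NA`).
#' @return A `trio_tbl`, one row per node, in graph vertex order.
#' @examples
#' trios <- trio_table(c("c1", "f1", "m1"),
#'                     dad_id = c("f1", NA, NA), mom_id = c("m1", NA, NA),
#'                     sex = c("male", "male", "female"))
#' g <- prepare_graph(trios)
#' graph_to_trio(g)
#' @export
graph_to_trio <- function(graph, on_ambiguity = c("error", "set_missing")) {
  on_ambiguity <- match.arg(on_ambiguity)
  stopifnot(inherits(graph, "igraph"))
  ids <- igraph::V(graph)$name
  sex <- if ("sex" %in% igraph::vertex_attr_names(graph)) {
    igraph::V(graph)$sex
  } else rep(NA_character_, length(ids))
  pe <- parental_edge_table(graph)
  dad <- setNames(rep(NA_character_, length(ids)), ids)
  mom <- dad
  for (child in unique(pe$child)) {
    parents <- pe$parent[pe$child == child]
    psex <- sex[match(parents, ids)]
    unknown <- parents[is.na(psex) | !psex %in% c("female", "male")]
    if (length(unknown)) {
      if (on_ambiguity == "error") {
        stop("parent(s) without known sex: ",
             paste(unknown, collapse = ", "),
             "; set on_ambiguity = \"set_missing\" to drop these links",
             call. = FALSE)
      }
      parents <- setdiff(parents, unknown)
      psex <- sex[match(parents, ids)]
    }
    if (sum(psex == "male") > 1L || sum(psex == "female") > 1L) {
      stop("child '", child, "' has two same-sex parents", call. = FALSE)
    }
    if (any(psex == "male")) dad[child] <- parents[psex == "male"]
    if (any(psex == "female")) mom[child] <- parents[psex == "female"]
  }
  tbl <- tibble::tibble(id = ids, dad_id = unname(dad), mom_id = unname(mom))
  for (attr_name in setdiff(igraph::vertex_attr_names(graph), "name")) {
    tbl[[attr_name]] <- igraph::vertex_attr(graph, attr_name)
  }
  new_trio_tbl(tbl, missing_codes = c("", "NA", "0"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
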