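#' Canonical relation-code universe
#'
#' All named codes reachable from MRCA configurations with proband ascent
#' `up <= max_up` and implied degree `<= max_degree` (full variants for
#' collaterals, plus `HSib`), with their grid coordinates. This is the code
#' set rendered by [relation_grid_figure()].
#'
#' @param max_up,max_degree Caps as in [get_relations()].
#' @return A tibble: `code`, `up`, `down`, `fullness`, `degree`.
#' @export
relation_codes <- function(max_up = 6L, max_degree = 9L) {
  grid <- expand.grid(up = 0:max_up, down = 0:12)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    u <- grid$up[k]; v <- grid$down[k]
    if (u == 0L && v == 0L) return(NULL)
    fullness <- if (u >= 1L && v >= 1L) "full" else "not_applicable"
    lab <- classify_pair(u, v, fullness)
    if (lab$degree > max_degree) return(NULL)
    lab[, c("code", "up", "down", "fullness", "degree")]
  })
  full <- dplyr::bind_rows(rows)
  # cousin codes are symmetric in (up, down); keep the up <= down cell
  full <- dplyr::arrange(full, .data$code, .data$up)
  full <- dplyr::distinct(full, .data$code, .keep_all = TRUE)
  full <- dplyr::arrange(full, .data$up, .data$down)
  hsib <- classify_pair(1L, 1L, "half")[, c("code", "up", "down",
                                            "fullness", "degree")]
  dplyr::bind_rows(full, hsib)
}

#' Aggregate relation labels across probands
#'
#' Counts each relation code over a table of labelled relatives (the row-bound
#' output of [get_relations()] across probands) and reports, per code, the
#' total and the average per proband. `Self` rows are excluded from counting;
#' every canonical code absent from the table gets total 0.
#'
#' @param relations A tibble with at least a `code` column (output of
#'   [get_relations()], possibly row-bound over many probands).
#' @param n_probands Number of probands the table covers (>= 1).
#' @param codes Optional tibble of codes to report (default
#'   [relation_codes()] plus any code observed in `relations`).
#' @return A `relation_summary` tibble: `code`, `up`, `down`, `total`,
#'   `mean_per_proband`, with `n_probands` stored as an attribute. Means are
#'   exact; rendering rounds to 3 decimals.
#' @examples
#' # 22 piblings over 426 probands -> mean 0.052
#' rel <- tibble::tibble(code = rep("Pib", 22))
#' subset(relation_summary(rel, 426), code == "Pib")
#' @export
relation_summary <- function(relations, n_probands, codes = NULL) {
  if (!is.numeric(n_probands) || length(n_probands) != 1L || n_probands < 1) {
    stop("`n_probands` must be a positive integer", call. = FALSE)
  }
  if (is.null(codes)) codes <- relation_codes()
  counted <- relations[relations$code != "Self", , drop = FALSE]
  tallies <- dplyr::count(counted, .data$code, name = "total")
  extra <- setdiff(tallies$code, codes$code)
  if (length(extra)) {
    codes <- dplyr::bind_rows(
      codes,
      tibble::tibble(code = extra, up = NA_integer_, down = NA_integer_,
                     fullness = NA_character_, degree = NA_integer_))
  }
  out <- dplyr::left_join(codes[, c("code", "up", "down")], tallies,
                          by = "code")
  out$total <- ifelse(is.na(out$total), 0L, out$total)
  out$mean_per_proband <- out$total / n_probands
  out <- tibble::as_tibble(out)
  attr(out, "n_probands") <- as.integer(n_probands)
  class(out) <- unique(c("relation_summary", class(out)))
  out
}

#' Render the relation summary as a consanguinity-chart grid
#'
#' Draws one cell per named relation code on a grid indexed by generations up
#' (rows, proband at the origin) and generations down (columns), each cell
#' showing `CODE total (mean)` with the mean rounded to 3 decimals — the
#' classical consanguinity-chart layout. `Unrelated` and `Distant` buckets
#' are reported by [relation_summary()] but omitted from the figure. The
#' layout is deterministic for a fixed summary.
#'
#' @param summary A `relation_summary`.
#' @param path Output file; the extension selects the device (`.png` or
#'   `.svg`). `NULL` returns the ggplot object without writing.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly when written to `path`.
#' @export
relation_grid_figure <- function(summary, path = NULL,
                                 width = 10, height = 6) {
  cells <- summary[!is.na(summary$up) &
                     !summary$code %in% c("Unrelated", "Distant", "Self"),
                   , drop = FALSE]
  cells$label <- sprintf("%s\n%d (%.3f)", cells$code, cells$total,
                         cells$mean_per_proband)
  p <- ggplot2::ggplot(cells,
                       ggplot2::aes(x = .data$down, y = -.data$up)) +
    ggplot2::geom_tile(fill = "grey95", colour = "grey40",
                       width = 0.95, height = 0.95) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.6,
                       lineheight = 0.9) +
    ggplot2::scale_x_continuous(breaks = 0:max(cells$down),
                                name = "generations down from MRCA") +
    ggplot2::scale_y_continuous(breaks = -(0:max(cells$up)),
                                labels = 0:max(cells$up),
                                name = "generations up to MRCA") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Relations per proband",
                  subtitle = sprintf("code  total (mean per proband); n = %d probands",
                                     attr(summary, "n_probands") %||% NA_integer_)) +
    ggplot2::theme_minimal()
  if (is.null(path)) return(p)
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else {
    stop("unsupported figure format: .", ext, " (use .png or .svg)",
         call. = FALSE)
  }
  on.exit(grDevices::dev.off())
  print(p)
  invisible(p)
}

#' Write a relation summary as TSV
#'
#' @param summary A `relation_summary`.
#' @param path Output path.
#' @return `path`, invisibly. Means are rounded to 3 decimals in the file.
#' @export
write_relation_summary <- function(summary, path) {
  out <- tibble::as_tibble(summary)
  out$mean_per_proband <- round(out$mean_per_proband, 3L)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
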