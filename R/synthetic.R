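#' Simulate a seeded random pedigree as a trio table
#'
#' Generates a generation-structured population: `n_founder_couples` unrelated
#' founder couples each draw a sibship size from a zero-truncated Poisson
#' (mean parameter `sibship_lambda`); every child of a non-final generation
#' founds a couple, and with probability `half_sib_rate` a parent re-partners
#' once with a new unrelated partner and produces a second sibship (creating
#' half-siblings). Mate choice controls pedigree loops:
#'
#' \itemize{
#'   \item `loop_free = TRUE` (default): every mate is a newly created,
#'     unrelated immigrant, so no pair of individuals is related through two
#'     distinct ancestral couples — the regime where path-counting kinship
#'     equals twice the classical kinship coefficient exactly.
#'   \item `loop_free = FALSE`: with probability 0.3 a child instead marries
#'     another child of the same generation from a different sibship, which
#'     can create loops (e.g. double first cousins).
#' }
#'
#' IDs encode generation and birth order (`g<generation>_i<index>`;
#' immigrant spouses `g<generation>_s<index>`) for debuggability. Identical
#' configurations (including `seed`) produce identical tables. The model
#' aims at structural variety for testing, not human demography.
#'
#' @param n_founder_couples Positive integer.
#' @param n_generations Positive integer: number of offspring generations.
#' @param sibship_lambda Poisson mean (> 0) for sibship sizes, zero-truncated.
#' @param half_sib_rate Probability in \[0, 1\] that a parent re-partners.
#' @param loop_free Forbid mate choice between relatives (see above).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `trio_tbl` with columns `id`, `dad_id`, `mom_id`, `sex`, and
#'   `generation`.
#' @examples
#' ped <- make_random_pedigree(n_founder_couples = 3, n_generations = 2,
#'                             sibship_lambda = 2, seed = 1)
#' nrow(ped)
#' @export
make_random_pedigree <- function(n_founder_couples,
                                 n_generations,
                                 sibship_lambda = 2.4,
                                 half_sib_rate = 0.1,
                                 loop_free = TRUE,
                                 seed = 1L) {
  if (!is.numeric(n_founder_couples) || n_founder_couples < 1 ||
      n_founder_couples != round(n_founder_couples)) {
    stop("`n_founder_couples` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_generations) || n_generations < 1 ||
      n_generations != round(n_generations)) {
    stop("`n_generations` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(sibship_lambda) || sibship_lambda <= 0) {
    stop("`sibship_lambda` must be > 0", call. = FALSE)
  }
  if (!is.numeric(half_sib_rate) || half_sib_rate < 0 || half_sib_rate > 1) {
    stop("`half_sib_rate` must be a probability", call. = FALSE)
  }
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  on.exit(.Random.seed_restore(old), add = TRUE)

  rows <- list()
  n_spouse <- 0L
  add_row <- function(id, dad, mom, sex, gen) {
    rows[[length(rows) + 1L]] <<- list(id = id, dad_id = dad, mom_id = mom,
                                       sex = sex, generation = gen)
  }
  new_spouse <- function(gen, sex) {
    n_spouse <<- n_spouse + 1L
    id <- sprintf("g%d_s%d", gen, n_spouse)
    add_row(id, NA_character_, NA_character_, sex, gen)
    id
  }

  # founder generation 0
  couples <- lapply(seq_len(n_founder_couples), function(k) {
    dad <- sprintf("g0_i%d", 2L * k - 1L)
    mom <- sprintf("g0_i%d", 2L * k)
    add_row(dad, NA_character_, NA_character_, "male", 0L)
    add_row(mom, NA_character_, NA_character_, "female", 0L)
    list(dad = dad, mom = mom)
  })

  for (gen in seq_len(n_generations)) {
    kids <- list()   # (id, sex, sibship index) per child born this generation
    n_kid <- 0L
    breed <- function(dad, mom, sibship) {
      size <- rztpois(1L, sibship_lambda)
      for (b in seq_len(size)) {
        n_kid <<- n_kid + 1L
        id <- sprintf("g%d_i%d", gen, n_kid)
        sex <- if (rbinom(1L, 1L, 0.5) == 1L) "female" else "male"
        add_row(id, dad, mom, sex, gen)
        kids[[length(kids) + 1L]] <<- list(id = id, sex = sex,
                                           sibship = sibship)
      }
    }
    for (ci in seq_along(couples)) {
      cp <- couples[[ci]]
      breed(cp$dad, cp$mom, ci)
      if (runif(1L) < half_sib_rate) {
        # one parent re-partners with a new unrelated partner
        if (runif(1L) < 0.5) {
          breed(cp$dad, new_spouse(gen - 1L, "female"), ci)
        } else {
          breed(new_spouse(gen - 1L, "male"), cp$mom, ci)
        }
      }
    }
    if (gen == n_generations) break
    # children found the next generation's couples
    couples <- list()
    taken <- rep(FALSE, length(kids))
    for (ki in seq_along(kids)) {
      if (taken[ki]) next
      kid <- kids[[ki]]
      mate_id <- NULL
      if (!loop_free && runif(1L) < 0.3) {
        free <- which(!taken & seq_along(kids) > ki &
                        vapply(kids, function(k) k$sibship != kid$sibship &&
                                 k$sex != kid$sex, logical(1)))
        if (length(free)) {
          pick <- free[sample.int(length(free), 1L)]
          taken[pick] <- TRUE
          mate_id <- kids[[pick]]$id
        }
      }
      if (is.null(mate_id)) {
        mate_id <- new_spouse(gen, if (kid$sex == "male") "female" else "male")
      }
      taken[ki] <- TRUE
      couples[[length(couples) + 1L]] <-
        if (kid$sex == "male") list(dad = kid$id, mom = mate_id)
        else list(dad = mate_id, mom = kid$id)
    }
  }
  tbl <- dplyr::bind_rows(rows)
  tbl$generation <- as.character(tbl$generation)
  new_trio_tbl(tbl, missing_codes = c("", "NA", "0"))
}

# zero-truncated Poisson via inverse CDF on U(P(X=0), 1); deterministic
# under set.seed and never returns 0
rztpois <- function(n, lambda) {
  p0 <- exp(-lambda)
  qpois(p0 + runif(n) * (1 - p0), lambda)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Canonical hand-built fixture families
#'
#' Small pedigrees with hand-verified expectations, used throughout the test
#' suite and handy as worked examples:
#'
#' \describe{
#'   \item{nuclear}{two parents, two full-sibling children.}
#'   \item{half_sib}{one mother, two fathers, two maternal half-siblings.}
#'   \item{four_generation}{16 individuals spanning great-grandparents,
#'     grandparents, piblings, first cousins, a parent's cousin (first cousin
#'     once removed), and a paternal half-sibling of the proband `p`.}
#'   \item{double_first_cousins}{two sibling pairs intermarry; their children
#'     are double first cousins — the canonical pedigree loop on which
#'     path-counting kinship (0.125) undershoots the classical coefficient
#'     (0.25).}
#'   \item{isolated_individuals}{a trio plus three singletons.}
#' }
#'
#' Each element carries the trio table (`trios`) and a sidecar tibble
#' (`expected`) of hand-verified assertions: `id1` (proband), `id2`,
#' `distance` (genealogical), `kinship` (path-counting, C = 1; 0 for no
#' path), and `label` (relation code of `id2` relative to `id1`).
#'
#' @return A named list of `list(trios, expected)` fixtures.
#' @export
canonical_fixtures <- function() {
  fx <- list()

  fx$nuclear <- list(
    trios = trio_table(
      c("c1", "c2", "f1", "m1"),
      dad_id = c("f1", "f1", NA, NA),
      mom_id = c("m1", "m1", NA, NA),
      sex = c("male", "female", "male", "female")),
    expected = tibble::tribble(
      ~id1, ~id2, ~distance, ~kinship, ~label,
      "c1", "f1", 1, 0.5, "Pa",
      "c1", "m1", 1, 0.5, "Pa",
      "c1", "c2", 1, 0.5, "Sib",
      "f1", "c1", 1, 0.5, "Ch",
      "f1", "m1", Inf, 0, "Unrelated"))

  fx$half_sib <- list(
    trios = trio_table(
      c("c1", "c2", "f1", "f2", "m1"),
      dad_id = c("f1", "f2", NA, NA, NA),
      mom_id = c("m1", "m1", NA, NA, NA),
      sex = c("male", "male", "male", "male", "female")),
    expected = tibble::tribble(
      ~id1, ~id2, ~distance, ~kinship, ~label,
      "c1", "c2", 2, 0.25, "HSib",
      "c1", "m1", 1, 0.5, "Pa",
      "c1", "f2", Inf, 0, "Unrelated",
      "f1", "f2", Inf, 0, "Unrelated"))

  # generation 1: ggf x ggm (proband's paternal great-grandparents)
  # generation 2: their children gf (grandfather) and gpib (grand-pibling),
  #   spouses gm, gpib_sp
  # generation 3: fa (father) + pib (pibling) from gf x gm; pc (parent's
  #   cousin) from gpib x gpib_sp; spouses mo, pib_sp, step
  # generation 4: p (proband) + sib from fa x mo; hsib from fa x step;
  #   cous (first cousin) from pib x pib_sp
  fx$four_generation <- list(
    trios = trio_table(
      c("ggf", "ggm", "gf", "gpib", "gm", "gpib_sp",
        "fa", "pib", "pc", "mo", "pib_sp", "step",
        "p", "sib", "hsib", "cous"),
      dad_id = c(NA, NA, "ggf", "ggf", NA, NA,
                 "gf", "gf", "gpib", NA, NA, NA,
                 "fa", "fa", "fa", "pib"),
      mom_id = c(NA, NA, "ggm", "ggm", NA, NA,
                 "gm", "gm", "gpib_sp", NA, NA, NA,
                 "mo", "mo", "step", "pib_sp"),
      sex = c("male", "female", "male", "male", "female", "female",
              "male", "male", "female", "female", "female", "female",
              "male", "female", "male", "female")),
    expected = tibble::tribble(
      ~id1, ~id2, ~distance, ~kinship, ~label,
      "p", "fa", 1, 0.5, "Pa",
      "p", "sib", 1, 0.5, "Sib",
      "p", "hsib", 2, 0.25, "HSib",
      "p", "gf", 2, 0.25, "GPa",
      "p", "pib", 2, 0.25, "Pib",
      "p", "ggf", 3, 0.125, "GGPa",
      "p", "cous", 3, 0.125, "1C",
      "p", "gpib", 3, 0.125, "GPib",
      "p", "pc", 4, 0.0625, "1C1R",
      "pib", "p", 2, 0.25, "Nib",
      "gf", "p", 2, 0.25, "GCh",
      "p", "mo", 1, 0.5, "Pa",
      "p", "step", Inf, 0, "Unrelated"))

  # sibling pair a1/a2 marries sibling pair b1/b2; c1 and c2 are double
  # first cousins: two distinct ancestral couples connect them
  fx$double_first_cousins <- list(
    trios = trio_table(
      c("fa", "ma", "fb", "mb", "a1", "a2", "b1", "b2", "c1", "c2"),
      dad_id = c(NA, NA, NA, NA, "fa", "fa", "fb", "fb", "a1", "a2"),
      mom_id = c(NA, NA, NA, NA, "ma", "ma", "mb", "mb", "b1", "b2"),
      sex = c("male", "female", "male", "female",
              "male", "male", "female", "female", "male", "female")),
    expected = tibble::tribble(
      ~id1, ~id2, ~distance, ~kinship, ~label,
      "c1", "c2", 3, 0.125, "1C",
      "c1", "a2", 2, 0.25, "Pib",
      "c1", "fa", 2, 0.25, "GPa"))

  fx$isolated_individuals <- list(
    trios = trio_table(
      c("c1", "f1", "m1", "x1", "x2", "x3"),
      dad_id = c("f1", NA, NA, NA, NA, NA),
      mom_id = c("m1", NA, NA, NA, NA, NA),
      sex = c("female", "male", "female", "unknown", "male", "female")),
    expected = tibble::tribble(
      ~id1, ~id2, ~distance, ~kinship, ~label,
      "c1", "f1", 1, 0.5, "Pa",
      "x1", "x2", Inf, 0, "Unrelated"))

  fx
}
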