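test_that("classify_pair reproduces the standard consanguinity codes", {
  cases <- list(
    list(0, 1, "not_applicable", "Ch", 1L),
    list(1, 0, "not_applicable", "Pa", 1L),
    list(2, 0, "not_applicable", "GPa", 2L),
    list(3, 0, "not_applicable", "GGPa", 3L),
    list(6, 0, "not_applicable", "GGGGGPa", 6L),  # great^4-grandparent
    list(0, 3, "not_applicable", "GGCh", 3L),
    list(1, 1, "full", "Sib", 1L),
    list(1, 1, "half", "HSib", 2L),
    list(2, 1, "full", "Pib", 2L),
    list(3, 1, "full", "GPib", 3L),
    list(4, 1, "full", "GGPib", 4L),
    list(1, 2, "full", "Nib", 2L),
    list(1, 3, "full", "GNib", 3L),
    list(2, 2, "full", "1C", 3L),
    list(3, 3, "full", "2C", 5L),
    list(2, 4, "full", "1C2R", 5L),   # first cousin twice removed
    list(4, 2, "full", "1C2R", 5L),   # same code in both directions
    list(2, 2, "half", "H1C", 4L),
    list(2, 1, "half", "HPib", 3L))
  for (cs in cases) {
    lab <- classify_pair(cs[[1]], cs[[2]], cs[[3]])
    expect_equal(lab$code, cs[[4]],
                 info = paste(cs[[1]], cs[[2]], cs[[3]]))
    expect_equal(lab$degree, cs[[5]],
                 info = paste(cs[[1]], cs[[2]], cs[[3]]))
  }
  expect_error(classify_pair(-1, 0), "non-negative")
  expect_error(classify_pair(1, 0.5), "non-negative")
})

test_that("classify_pair is total on the 0..6 grid with consistent degrees", {
  seen <- character()
  for (u in 0:6) for (v in 0:6) {
    for (f in c("full", "half")) {
      if ((u == 0 || v == 0) && f == "half") next
      lab <- classify_pair(u, v, if (u == 0 || v == 0) "not_applicable" else f)
      expect_true(nzchar(lab$code))
      full_collateral <- u >= 1 && v >= 1 && f == "full"
      expect_equal(lab$degree,
                   if (full_collateral) u + v - 1L else u + v)
      seen <- c(seen, paste(u, v, lab$fullness, lab$code))
      if (u == 0 || v == 0) break
    }
  }
  # codes uniquely determined by (up, down, fullness): no two grid points
  # share a (u, v, fullness) with different codes
  keys <- unique(seen)
  tags <- sub(" [^ ]+$", "", keys)
  expect_equal(anyDuplicated(tags), 0L)
})

test_that("get_relations labels the nuclear family with sexed descriptions", {
  g <- prepare_graph(canonical_fixtures()$nuclear$trios)
  fam <- get_family_graphs(g, "c1", degree = 1)[["c1"]]
  rel <- get_relations(fam)
  by_id <- function(m) rel[rel$member_id == m, ]
  expect_equal(by_id("f1")$code, "Pa")
  expect_equal(by_id("f1")$description, "father")
  expect_equal(by_id("m1")$description, "mother")
  expect_equal(by_id("c2")$code, "Sib")
  expect_equal(by_id("c2")$description, "sister")
  expect_equal(by_id("c1")$code, "Self")
})

test_that("the four-generation fixture is labelled as its sidecar says", {
  fx <- canonical_fixtures()$four_generation
  g <- prepare_graph(fx$trios)
  fams <- get_family_graphs(g, unique(fx$expected$id1), degree = 6)
  for (k in seq_len(nrow(fx$expected))) {
    e <- fx$expected[k, ]
    rel <- get_relations(fams[[e$id1]])
    expect_equal(rel$code[rel$member_id == e$id2], e$label,
                 info = paste(e$id1, "->", e$id2))
  }
})

test_that("affines in the neighbourhood are labelled Unrelated", {
  tbl <- trio_table(c("kid", "pa", "ma"),
                    dad_id = c("pa", NA, NA), mom_id = c("ma", NA, NA),
                    sex = c("male", "male", "female"))
  fam <- get_family_graphs(prepare_graph(tbl), "pa", degree = 2)[["pa"]]
  rel <- get_relations(fam)
  expect_equal(rel$code[rel$member_id == "ma"], "Unrelated")
  expect_equal(rel$code[rel$member_id == "kid"], "Ch")
})

test_that("relations beyond the ascent and degree caps become Distant", {
  deep <- chain_pedigree(8)
  fam <- get_family_graphs(prepare_graph(deep), "x8", degree = 8)[["x8"]]
  rel <- get_relations(fam)
  # x8's 7- and 8-generation ancestors exceed the up <= 6 cap
  expect_equal(rel$code[rel$member_id == "x0"], "Distant")
  expect_equal(rel$code[rel$member_id == "x1"], "Distant")
  expect_equal(rel$code[rel$member_id == "x2"], "GGGGGPa")
  # deep descendants stay named: only proband-side ascent is capped at 6
  fam0 <- get_family_graphs(prepare_graph(deep), "x0", degree = 8)[["x0"]]
  rel0 <- get_relations(fam0)
  expect_equal(rel0$code[rel0$member_id == "x8"], "GGGGGGGCh")
  # a tighter cap demotes more of the chain
  rel_tight <- get_relations(fam, max_up = 2)
  expect_equal(rel_tight$code[rel_tight$member_id == "x5"], "Distant")
})

test_that("labels are reciprocal on random loop-free pedigrees", {
  mirror <- function(code) {
    # ancestors <-> descendants, piblings <-> niblings, cousins fixed
    swaps <- c(Pa = "Ch", Ch = "Pa", GPa = "GCh", GCh = "GPa",
               Sib = "Sib", HSib = "HSib")
    if (code %in% names(swaps)) return(unname(swaps[code]))
    if (grepl("Pib$", code)) return(sub("Pib$", "Nib", code))
    if (grepl("Nib$", code)) return(sub("Nib$", "Pib", code))
    if (grepl("^G+Pa$", code)) return(sub("Pa$", "Ch", code))
    if (grepl("^G+Ch$", code)) return(sub("Ch$", "Pa", code))
    code  # cousin codes are symmetric
  }
  for (trios in random_pedigrees(3, seed0 = 55)) {
    g <- prepare_graph(trios)
    probands <- trios$id[seq(1, nrow(trios), length.out = 5)]
    fams <- get_family_graphs(g, trios$id, degree = 3)
    rel <- dplyr::bind_rows(lapply(fams[probands], get_relations))
    rel <- rel[!rel$code %in% c("Self", "Unrelated", "Distant") &
                 rel$member_id %in% trios$id, ]
    for (k in seq_len(nrow(rel))) {
      back <- get_relations(fams[[rel$member_id[k]]])
      back_code <- back$code[back$member_id == rel$proband_id[k]]
      expect_equal(back_code, mirror(rel$code[k]),
                   info = paste(rel$proband_id[k], "<->", rel$member_id[k],
                                rel$code[k]))
    }
  }
})

test_that("label-implied degree equals the family-graph degree on loop-free
           pedigrees", {
  for (trios in random_pedigrees(3, seed0 = 77)) {
    g <- prepare_graph(trios)
    probands <- trios$id[seq(1, nrow(trios), length.out = 4)]
    fams <- get_family_graphs(g, probands, degree = 4)
    for (pid in probands) {
      rel <- get_relations(fams[[pid]])
      mem <- fams[[pid]]$members
      merged <- merge(rel, mem, by = "member_id")
      named <- !merged$code %in% c("Unrelated", "Distant")
      expect_equal(merged$degree.x[named], merged$degree.y[named])
    }
  }
})

test_that("the half-sib fixture separates full from half relations", {
  fx <- canonical_fixtures()$half_sib
  fam <- get_family_graphs(prepare_graph(fx$trios), "c1", 2)[["c1"]]
  rel <- get_relations(fam)
  expect_equal(rel$fullness[rel$member_id == "c2"], "half")
  expect_equal(rel$code[rel$member_id == "c2"], "HSib")
  g2 <- prepare_graph(canonical_fixtures()$nuclear$trios)
  rel2 <- get_relations(get_family_graphs(g2, "c1", 1)[["c1"]])
  expect_equal(rel2$fullness[rel2$member_id == "c2"], "full")
})
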