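test_that("read_trios ingests delimited trio tables with missing codes", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,dad_id,mom_id", "c1,f1,m1", "f1,0,0", "m1,0,0"), tf)
  tbl <- read_trios(tf, format = "csv", missing_codes = "0")
  expect_s3_class(tbl, "trio_tbl")
  expect_equal(tbl$id, c("c1", "f1", "m1"))  # row order preserved
  expect_true(all(is.na(tbl$dad_id[2:3])))   # founders
  expect_equal(tbl$dad_id[1], "f1")
  expect_type(tbl$id, "character")

  # custom column names and tsv
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("IID\tPAT\tMAT", "c1\tf1\tNA"), tf2)
  tbl2 <- read_trios(tf2, format = "tsv",
                     id_cols = c(id = "IID", dad_id = "PAT", mom_id = "MAT"))
  expect_equal(tbl2$id, "c1")
  expect_true(is.na(tbl2$mom_id))
})

test_that("read_trios rejects malformed input with named diagnostics", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,father,mom_id", "a,b,c"), tf)
  expect_error(read_trios(tf, format = "csv"), "dad_id")

  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,dad_id,mom_id", "a,b,b"), tf2)
  expect_error(read_trios(tf2, format = "csv"), "father_id equals mother_id")

  tf3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,dad_id,mom_id", "a,NA,NA", "a,NA,NA"), tf3)
  expect_error(read_trios(tf3, format = "csv"), "duplicate individual_id.*a")

  tf4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,dad_id,mom_id", "a,a,m"), tf4)
  expect_error(read_trios(tf4, format = "csv"), "self-parentage.*a")

  expect_error(read_trios(file.path(tempdir(), "nope.csv"), format = "csv"),
               "does not exist")
})

test_that("PLINK .fam dialect maps sex codes and carries FID/PHENO", {
  tf <- withr::local_tempfile(fileext = ".fam")
  writeLines(c("FAM1 c1 f1 m1 2 -9",
               "FAM1 f1 0 0 1 -9",
               "FAM1 m1 0 0 0 2"), tf)
  tbl <- read_trios(tf, format = "plink_fam")
  expect_equal(tbl$sex, c("female", "male", "unknown"))
  expect_equal(tbl$fid, rep("FAM1", 3))
  expect_equal(tbl$pheno, c("-9", "-9", "2"))
  expect_true(is.na(tbl$dad_id[2]))

  # unknown sex writes back as SEX code 0
  out <- withr::local_tempfile(fileext = ".fam")
  write_trios(tbl, out, format = "plink_fam")
  reread <- read_trios(out, format = "plink_fam")
  expect_equal(reread$sex, tbl$sex)
  expect_equal(strsplit(readLines(out)[3], " ")[[1]][5], "0")
})

test_that("write_trios / read_trios round-trip on csv and tsv", {
  fx <- canonical_fixtures()
  for (fmt in c("csv", "tsv")) {
    for (name in names(fx)) {
      tbl <- fx[[name]]$trios
      out <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_trios(tbl, out, format = fmt)
      back <- read_trios(out, format = fmt)
      expect_equal(tibble::as_tibble(back), tibble::as_tibble(tbl),
                   info = paste(name, fmt))
    }
  }
  # empty table -> header-only file
  empty <- trio_table(tibble::tibble(id = character(), dad_id = character(),
                                     mom_id = character()))
  out <- withr::local_tempfile(fileext = ".csv")
  write_trios(empty, out, format = "csv")
  expect_equal(readLines(out), "id,dad_id,mom_id")
  expect_equal(nrow(read_trios(out, format = "csv")), 0L)
})

test_that("attribute columns are carried verbatim without coercion", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,dad_id,mom_id,status,score",
               "c1,f1,m1,case,00123", "f1,NA,NA,control,7"), tf)
  tbl <- read_trios(tf, format = "csv")
  expect_equal(tbl$score, c("00123", "7"))  # leading zeros preserved
  g <- prepare_graph(tbl)
  expect_equal(igraph::V(g)$status[match("c1", igraph::V(g)$name)], "case")
})

test_that("graph_to_trio inverts prepare_graph on sexed tables", {
  fx <- canonical_fixtures()
  for (name in names(fx)) {
    tbl <- fx[[name]]$trios
    back <- graph_to_trio(prepare_graph(tbl))
    ord <- match(tbl$id, back$id)
    expect_equal(back$dad_id[ord], tbl$dad_id, info = name)
    expect_equal(back$mom_id[ord], tbl$mom_id, info = name)
    expect_equal(back$sex[ord], tbl$sex, info = name)
  }
})

test_that("graph_to_trio handles unsexed parents per on_ambiguity", {
  tbl <- trio_table(c("c", "p1", "p2"),
                    dad_id = c("p1", NA, NA), mom_id = c("p2", NA, NA),
                    sex = c("male", "unknown", "female"))
  g <- prepare_graph(tbl)
  expect_error(graph_to_trio(g), "p1")
  relaxed <- graph_to_trio(g, on_ambiguity = "set_missing")
  expect_true(is.na(relaxed$dad_id[relaxed$id == "c"]))
  expect_equal(relaxed$mom_id[relaxed$id == "c"], "p2")
})

test_that("graph_to_trio rejects two same-sex parents and handles isolates", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("p1", "p2"), to = c("c", "c"),
               type = "parental", role = c("father", "father")),
    vertices = data.frame(name = c("c", "p1", "p2"),
                          sex = c("male", "male", "male")))
  expect_error(graph_to_trio(g), "two same-sex parents")

  lone <- igraph::make_empty_graph() + igraph::vertex("solo", sex = "female")
  tbl <- graph_to_trio(lone)
  expect_equal(nrow(tbl), 1L)
  expect_true(is.na(tbl$dad_id) && is.na(tbl$mom_id))
})
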