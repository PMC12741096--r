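# Shared fixture builders for the test suite.

# nuclear family extended with all four grandparents and a maternal
# half-sibling, for degree-2 neighbourhood checks
extended_nuclear <- function() {
  trio_table(
    c("c1", "c2", "f1", "m1", "pgf", "pgm", "mgf", "mgm", "hs", "f2"),
    dad_id = c("f1", "f1", "pgf", "mgf", NA, NA, NA, NA, "f2", NA),
    mom_id = c("m1", "m1", "pgm", "mgm", NA, NA, NA, NA, "m1", NA),
    sex = c("male", "female", "male", "female", "male", "female",
            "male", "female", "male", "male"))
}

# a pure descent line founder -> ... -> last, n_links parent-child links
chain_pedigree <- function(n_links) {
  ids <- paste0("x", 0:n_links)
  trio_table(ids,
             dad_id = c(NA, ids[1:n_links]),
             mom_id = rep(NA_character_, n_links + 1),
             sex = rep("male", n_links + 1))
}

# battery of seeded random pedigrees for property-style tests; parameter
# rotation keeps every pedigree well under 200 individuals
random_pedigrees <- function(n = 10, loop_free = TRUE, seed0 = 100) {
  lapply(seq_len(n), function(k) {
    gens <- 2 + (k %% 2)
    make_random_pedigree(
      n_founder_couples = if (gens == 3) 2 else 3 + (k %% 4),
      n_generations = gens,
      sibship_lambda = 1.4 + 0.15 * (k %% 4),
      half_sib_rate = 0.15,
      loop_free = loop_free,
      seed = seed0 + k)
  })
}
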