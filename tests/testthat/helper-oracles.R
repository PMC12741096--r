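# Independent oracles built straight from trio records (no igraph, none of
# the package's graph machinery), used to cross-check the implementation.

# Classical recursive kinship matrix phi over all individuals of a trio
# table (referenced-but-unlisted parents included as founders):
#   phi(i,j) = 1/2 (phi(father(i), j) + phi(mother(i), j)),  j not below i
#   phi(i,i) = 1/2 (1 + phi(father(i), mother(i)))
# with missing-parent terms 0 and founders mutually unrelated. Processing in
# depth order guarantees the "j is not a descendant of i" side condition.
oracle_kinship <- function(trios) {
  ids <- unique(c(trios$id,
                  trios$dad_id[!is.na(trios$dad_id)],
                  trios$mom_id[!is.na(trios$mom_id)]))
  n <- length(ids)
  dad <- match(trios$dad_id[match(ids, trios$id)], ids)
  mom <- match(trios$mom_id[match(ids, trios$id)], ids)

  depth <- rep(0L, n)
  repeat {
    new_depth <- pmax(
      ifelse(is.na(dad), 0L, depth[ifelse(is.na(dad), 1L, dad)] + 1L),
      ifelse(is.na(mom), 0L, depth[ifelse(is.na(mom), 1L, mom)] + 1L))
    if (identical(new_depth, depth)) break
    depth <- new_depth
  }
  ord <- order(depth)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  done <- integer()
  for (i in ord) {
    fi <- dad[i]; mi <- mom[i]
    if (length(done)) {
      row <- 0.5 * ((if (is.na(fi)) 0 else K[fi, done]) +
                      (if (is.na(mi)) 0 else K[mi, done]))
      K[i, done] <- row
      K[done, i] <- row
    }
    inb <- if (is.na(fi) || is.na(mi)) 0 else K[fi, mi]
    K[i, i] <- 0.5 * (1 + inb)
    done <- c(done, i)
  }
  K
}

# Brute-force breadth-first search over the mixed pedigree relation:
# parent-child links (both directions) plus full-sibling links, from the raw
# trio rows. Returns named integer distances of every individual within
# `degree` of `proband`.
oracle_bfs <- function(trios, proband, degree) {
  ids <- unique(c(trios$id,
                  trios$dad_id[!is.na(trios$dad_id)],
                  trios$mom_id[!is.na(trios$mom_id)]))
  adj <- lapply(stats::setNames(vector("list", length(ids)), ids),
                function(x) character())
  link <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  for (r in seq_len(nrow(trios))) {
    if (!is.na(trios$dad_id[r])) link(trios$id[r], trios$dad_id[r])
    if (!is.na(trios$mom_id[r])) link(trios$id[r], trios$mom_id[r])
  }
  both <- !is.na(trios$dad_id) & !is.na(trios$mom_id)
  sibships <- split(trios$id[both],
                    paste(trios$dad_id[both], trios$mom_id[both]))
  for (s in sibships) {
    if (length(s) < 2) next
    prs <- utils::combn(s, 2)
    for (k in seq_len(ncol(prs))) link(prs[1, k], prs[2, k])
  }
  dist <- stats::setNames(0L, proband)
  frontier <- proband
  for (step in seq_len(degree)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                   names(dist))
    if (!length(nxt)) break
    dist <- c(dist, stats::setNames(rep(step, length(nxt)), nxt))
    frontier <- nxt
  }
  dist
}
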