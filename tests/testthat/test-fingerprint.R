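occ_row <- function(id, motif, start, score = 10) {
  tibble::tibble(id = id, motif = motif, start = start, score = score)
}

test_that("fingerprints order motifs by occurrence position", {
  recs <- new_seqset("s1", strrep("A", 200))
  occ <- occ_row("s1", c(2L, 4L, 3L, 1L), c(10L, 60L, 130L, 170L))
  fp <- build_fingerprints(recs, occ)
  expect_equal(fp$fingerprint[[1]], c(2L, 4L, 3L, 1L))
  expect_equal(fp$pattern_key, "2-4-3-1")
  # input order is irrelevant
  fp2 <- build_fingerprints(recs, occ[c(3, 1, 4, 2), ])
  expect_equal(fp, fp2)
  # no occurrences -> empty fingerprint
  fp0 <- build_fingerprints(recs, occ[0, ])
  expect_equal(fp0$fingerprint[[1]], integer(0))
  expect_equal(fp0$pattern_key, "")
  # unknown ids are rejected
  expect_error(build_fingerprints(recs, occ_row("zz", 1L, 0L)), "unknown")
})

test_that("ZOOPS semantics keep only the best occurrence per motif", {
  recs <- new_seqset("s1", strrep("A", 100))
  occ <- occ_row("s1", c(1L, 1L, 2L), c(50L, 5L, 20L), score = c(12, 8, 9))
  fp <- build_fingerprints(recs, occ)
  expect_equal(fp$fingerprint[[1]], c(2L, 1L))  # best motif-1 hit is at 50
})

test_that("group_patterns ranks by count and partitions the set", {
  recs <- new_seqset(sprintf("s%02d", 1:10), rep(strrep("A", 50), 10))
  keys <- c(rep(list(c(1L, 2L)), 6), rep(list(c(2L, 1L)), 3), list(1L))
  occ <- dplyr::bind_rows(lapply(1:10, function(i) {
    occ_row(recs$id[i], keys[[i]], seq(0, by = 10,
                                       length.out = length(keys[[i]])))
  }))
  fp <- build_fingerprints(recs, occ)
  g <- group_patterns(fp, family_suffix = "x")
  expect_equal(g$pattern, c("1x", "2x", "3x"))
  expect_equal(g$count, c(6L, 3L, 1L))
  expect_equal(sum(g$count), 10L)
  expect_equal(sum(g$fraction), 1)
  expect_setequal(unlist(g$members), recs$id)
  # identical fingerprints in one group only
  expect_equal(g$pattern_key, c("1-2", "2-1", "1"))
  expect_error(group_patterns(dplyr::bind_rows(fp, fp[1, ])), "duplicate")
})

test_that("group ids are stable under input shuffling", {
  recs <- new_seqset(sprintf("s%02d", 1:9), rep(strrep("A", 50), 9))
  keys <- c(rep(list(c(1L, 2L)), 5), rep(list(2L), 4))
  occ <- dplyr::bind_rows(lapply(1:9, function(i) {
    occ_row(recs$id[i], keys[[i]], seq(0, by = 10,
                                       length.out = length(keys[[i]])))
  }))
  fp <- build_fingerprints(recs, occ)
  g1 <- group_patterns(fp)
  g2 <- group_patterns(fp[sample(9), ])
  expect_equal(g1$pattern_key, g2$pattern_key)
  expect_equal(g1$fraction, g2$fraction)
})

test_that("prevalence counts fractions with the fingerprint denominator", {
  recs <- new_seqset(sprintf("s%02d", 1:51), rep(strrep("A", 50), 51))
  occ <- dplyr::bind_rows(
    lapply(1:51, function(i) occ_row(recs$id[i], 1L, 0L)),
    lapply(1:46, function(i) occ_row(recs$id[i], 2L, 20L))
  )
  fp <- build_fingerprints(recs, occ)
  prev <- prevalence_table(fp, motifs = 1:3)
  expect_equal(prev$prevalence, c(1, 46 / 51, 0))
  expect_equal(round(100 * prev$prevalence[2], 1), 90.2)
})

test_that("the full pipeline recovers a planted pattern partition", {
  withr::with_seed(81, {
    cons <- replicate(4, random_motif_consensus(8))
  })
  make <- function(ranks, n, seed) {
    generate_family_set(family_spec(
      "background", n = n, length_range = c(130, 160),
      motif_plan = lapply(ranks, function(k) {
        list(consensus = cons[k], prevalence = 1)
      }), seed = seed))
  }
  sets <- list(make(1:4, 20, 31), make(1:3, 18, 32), make(1:2, 12, 33))
  records <- dplyr::bind_rows(lapply(seq_along(sets), function(i) {
    r <- sets[[i]]$records
    r$id <- paste0("g", i, "_", r$id)
    r
  }))
  truth_groups <- split(records$id, rep(1:3, c(20, 18, 12)))
  ms <- discover_motifs(records, seed = 34, n_shuffles = 29)
  occ <- scan_motifs(ms, records)
  fp <- build_fingerprints(records, occ)
  groups <- group_patterns(fp, "c")
  expect_equal(nrow(groups), 3)
  expect_equal(sort(groups$count, decreasing = TRUE), c(20L, 18L, 12L))
  got <- lapply(groups$members, sort)
  want <- lapply(truth_groups, sort)
  expect_setequal(got, unname(want))
})
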