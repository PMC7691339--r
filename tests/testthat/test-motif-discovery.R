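test_that("a strongly planted motif is recovered with its sites", {
  withr::with_seed(71, m1 <- random_motif_consensus(8))
  set <- generate_family_set(family_spec(
    "csp", n = 20, length_range = c(120, 150),
    motif_plan = list(list(consensus = m1, prevalence = 1)), seed = 17))
  ms <- discover_motifs(set$records, seed = 18, n_shuffles = 29)
  expect_gte(length(ms$models), 1)
  expect_equal(ms$models[[1]]$consensus, m1)
  # site recall at exact planted offsets
  occ <- scan_motifs(ms$models[[1]], set$records)
  planted <- set$truth$motifs
  hit <- dplyr::semi_join(planted, occ, by = c("id", "start"))
  expect_gte(nrow(hit) / nrow(planted), 0.9)
  # prevalence of the top motif across fingerprints is 1
  fp <- build_fingerprints(set$records, scan_motifs(ms, set$records))
  prev <- prevalence_table(fp)
  expect_equal(prev$prevalence[prev$motif == 1], 1)
})

test_that("identical sequences give a degenerate first motif", {
  withr::with_seed(72, base <- random_protein(60, cys_freq = 0.05))
  recs <- new_seqset(sprintf("c%02d", 1:20), rep(base, 20))
  ms <- discover_motifs(recs, seed = 3, n_shuffles = 19)
  expect_gte(length(ms$models), 1)
  m <- ms$models[[1]]
  expect_true(all(apply(m$ppm, 1, max) >= 0.95))
})

test_that("featureless sequences yield no significant motifs", {
  runs_with_motifs <- 0
  for (s in 1:20) {
    recs <- withr::with_seed(200 + s, new_seqset(
      sprintf("n%02d", 1:15),
      vapply(1:15, function(i) random_protein(50, cys_freq = 0.05),
             character(1))))
    ms <- discover_motifs(recs, minw = 6, maxw = 8, seed = 300 + s,
                          n_shuffles = 99)
    if (length(ms$models) > 0) runs_with_motifs <- runs_with_motifs + 1
  }
  expect_lte(runs_with_motifs, 1)  # >= 95% of 20 runs clean
})

test_that("shuffle-null significance hits its floor for a planted motif", {
  withr::with_seed(73, m1 <- random_motif_consensus(8))
  set <- generate_family_set(family_spec(
    "csp", n = 8, length_range = c(50, 60),
    motif_plan = list(list(consensus = m1, prevalence = 1)), seed = 19))
  fit <- em_zoops(set$records, 8, start_point = m1)
  p <- motif_significance(fit, set$records, n_shuffles = 999, seed = 7)
  expect_equal(p, 1 / 1000)
})

test_that("significance is calibrated on null data", {
  withr::with_seed(74, base <- new_seqset(
    sprintf("b%02d", 1:10),
    vapply(1:10, function(i) random_protein(60, cys_freq = 0.05),
           character(1))))
  over_05 <- 0
  for (trial in 1:10) {
    shuf <- withr::with_seed(400 + trial, cysmotif:::.shuffle_records(base))
    enc <- cysmotif:::.encode_set(shuf)
    b <- cysmotif:::.background_freq(enc)
    model <- withr::with_seed(500 + trial, cysmotif:::.best_model_for_width(
      enc, 7, b, cysmotif:::.default_policy()))
    p <- motif_significance(model, shuf, n_shuffles = 49, seed = 600 + trial)
    if (p > 0.05) over_05 <- over_05 + 1
  }
  expect_gte(over_05, 9)
})

test_that("scanning scores and thresholds behave as defined", {
  withr::with_seed(75, cons <- random_motif_consensus(8))
  model <- consensus_model(cons)
  lo <- log2(model$ppm) - log2(0.05)
  max_bits <- sum(apply(lo, 1, max))
  # the consensus window scores the per-column maximum sum
  rec <- new_seqset("x", paste0(strrep("G", 20), cons, strrep("G", 20)))
  occ <- scan_motifs(model, rec)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$start, 20L)
  expect_equal(occ$score, max_bits)
  # a background-only record gives no hit at the 60% threshold
  withr::with_seed(76, bgrec <- new_seqset("bg", random_protein(100)))
  expect_equal(nrow(scan_motifs(model, bgrec)), 0)
  # masked spans are never reported
  masked <- rec
  masked$residues <- paste0(strrep("G", 20),
                            paste0("XX", substr(cons, 3, 8)),
                            strrep("G", 20))
  expect_equal(nrow(scan_motifs(model, masked)), 0)
})

test_that("later motifs never overlap the masked spans of earlier ones", {
  withr::with_seed(77, {
    m1 <- random_motif_consensus(8)
    m2 <- random_motif_consensus(8)
  })
  set <- generate_family_set(family_spec(
    "csp", n = 15, length_range = c(120, 150),
    motif_plan = list(list(consensus = m1, prevalence = 1),
                      list(consensus = m2, prevalence = 1)), seed = 20))
  ms <- discover_motifs(set$records, seed = 21, n_shuffles = 29)
  expect_gte(length(ms$models), 2)
  occ <- scan_motifs(ms, set$records)
  spans <- occ |>
    dplyr::mutate(end = start + width) |>
    dplyr::arrange(id, start)
  overlaps <- spans |>
    dplyr::group_by(id) |>
    dplyr::summarise(bad = any(start[-1] < end[-dplyr::n()]))
  expect_false(any(overlaps$bad))
})
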