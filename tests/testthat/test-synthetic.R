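test_that("generation is reproducible and anchors honour gap bounds", {
  spec <- family_spec("classic_obp", n = 10, seed = 4)
  a <- generate_family_set(spec)
  b <- generate_family_set(spec)
  expect_identical(a, b)

  gaps_ok <- a$truth$anchors |>
    dplyr::group_by(id) |>
    dplyr::summarise(ok = all(diff(position) - 1 >= c(23, 3, 36, 8, 8)) &&
                       all(diff(position) - 1 <= c(44, 3, 43, 12, 8)))
  expect_true(all(gaps_ok$ok))
  # anchor residues really are cysteines
  for (i in 1:10) {
    pos <- a$truth$anchors$position[a$truth$anchors$id == a$records$id[i]]
    ch <- strsplit(a$records$residues[i], "")[[1]]
    expect_true(all(ch[pos + 1] == "C"))
    # and no stray cysteines outside anchors (suppressed background)
    expect_equal(sum(ch == "C"), length(pos))
  }
})

test_that("CSP records carry exactly the four planted anchor cysteines", {
  set <- generate_family_set(family_spec("csp", n = 5, seed = 2))
  counts <- set$truth$anchors |> dplyr::count(id)
  expect_true(all(counts$n == 4))
  expect_true(all(vapply(strsplit(set$records$residues, ""),
                         function(ch) sum(ch == "C"), numeric(1)) == 4))
})

test_that("motif prevalence is exact and sites score above threshold", {
  withr::with_seed(14, {
    plan <- list(
      list(consensus = random_motif_consensus(8), prevalence = 1),
      list(consensus = random_motif_consensus(8), prevalence = 46 / 51)
    )
  })
  set <- generate_family_set(family_spec("minusc_obp", n = 51,
                                         motif_plan = plan, seed = 6))
  by_motif <- set$truth$motifs |> dplyr::count(motif)
  expect_equal(by_motif$n, c(51L, 46L))
  # each planted site scores above its own model's scanning threshold
  for (k in 1:2) {
    model <- consensus_model(plan[[k]]$consensus)
    occ <- scan_motifs(model, set$records)
    planted <- set$truth$motifs[set$truth$motifs$motif == k, ]
    found <- dplyr::semi_join(planted, occ,
                              by = c("id", "start"))
    expect_equal(nrow(found), nrow(planted))
  }
})

test_that("motifs are planted left-to-right and never overlap anchors", {
  withr::with_seed(15, {
    plan <- lapply(1:3, function(k) list(consensus = random_motif_consensus(8),
                                         prevalence = 1))
  })
  set <- generate_family_set(family_spec("csp", n = 12, motif_plan = plan,
                                         seed = 8))
  for (i in set$records$id) {
    m <- set$truth$motifs[set$truth$motifs$id == i, ]
    m <- m[order(m$motif), ]
    expect_true(all(diff(m$start) >= m$width[-nrow(m)]))  # ordered, disjoint
    anchors <- set$truth$anchors$position[set$truth$anchors$id == i]
    covered <- unlist(Map(seq, m$start, m$start + m$width - 1))
    expect_length(intersect(anchors, covered), 0)
  }
})

test_that("infeasible placements error before emission", {
  big <- list(list(consensus = strrep("W", 60), prevalence = 1))
  spec <- family_spec("csp", n = 2, length_range = c(40, 45),
                      motif_plan = big, seed = 1)
  expect_error(generate_family_set(spec), "infeasible")
  expect_error(family_spec("csp", n = 2, length_range = c(10, 20)),
               "scaffold span")
})

test_that("transcript length arithmetic and determinism hold", {
  p <- new_seqset("p", "MK")
  tx <- generate_transcript(p, utr5 = 0, utr3 = 0, seed = 5)
  # ATG (encoding the M) + 1 codon + stop
  expect_equal(nchar(tx$transcript$residues), 9)
  expect_true(startsWith(tx$transcript$residues, "ATG"))
  tx2 <- generate_transcript(p, utr5 = 0, utr3 = 0, seed = 5)
  expect_identical(tx, tx2)
  tx3 <- generate_transcript(p, utr5 = 0, utr3 = 0, seed = 6)
  expect_false(identical(tx$transcript$residues, tx3$transcript$residues))
})

test_that("labelled trees are binary over the record ids", {
  ids <- sprintf("s%d", 1:4)
  tr <- generate_labeled_tree(ids, seed = 3)
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(tr$Nnode, 3)
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.rooted(tr))
  expect_setequal(tr$tip.label, ids)
  expect_error(generate_labeled_tree(c("a", "a", "b")), "duplicate")
})
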