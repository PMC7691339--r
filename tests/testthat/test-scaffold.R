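make_scaffold_seq <- function(gaps, residue = "C", fill = "A",
                              lead = 0, trail = 0) {
  body <- paste0(residue,
                 paste0(vapply(gaps, function(g) strrep(fill, g),
                               character(1)), residue, collapse = ""))
  paste0(strrep(fill, lead), body, strrep(fill, trail))
}

test_that("match_scaffold finds the forced CSP match", {
  s <- new_seqset("x", make_scaffold_seq(c(6, 18, 2), lead = 0, trail = 4))
  m <- match_scaffold(s, csp_pattern())
  expect_equal(nrow(m), 1)
  expect_equal(m$anchor_positions[[1]], c(0L, 7L, 26L, 29L))
  expect_equal(c(m$start, m$end), c(0L, 30L))
  # no cysteines, no match
  none <- new_seqset("y", strrep("AKLM", 20))
  expect_equal(nrow(match_scaffold(none, csp_pattern())), 0)
})

test_that("match_scaffold equals the brute-force enumeration oracle", {
  withr::with_seed(33, {
    patterns <- list(obp_classic_pattern(), obp_minusc_pattern(),
                     csp_pattern())
    for (rep in 1:100) {
      s <- random_protein(sample(60:120, 1), cys_freq = 0.1)
      for (p in patterns) {
        got <- match_scaffold(new_seqset("r", s), p)
        want <- oracle_match_scaffold(s, p)
        expect_equal(nrow(got), length(want))
        if (length(want) > 0) {
          expect_equal(got$anchor_positions, want)
        }
      }
    }
  })
})

test_that("gap bounds are sharp: one residue in or out destroys the match", {
  p <- obp_classic_pattern()
  lo <- p$anchors$gap_min[-1]
  hi <- p$anchors$gap_max[-1]
  at_lo <- new_seqset("lo", make_scaffold_seq(lo))
  at_hi <- new_seqset("hi", make_scaffold_seq(hi))
  expect_equal(nrow(match_scaffold(at_lo, p)), 1)
  expect_equal(nrow(match_scaffold(at_hi, p)), 1)
  # shrink the first variable gap below its minimum
  under <- new_seqset("u", make_scaffold_seq(c(lo[1] - 1, lo[-1])))
  expect_equal(nrow(match_scaffold(under, p)), 0)
  # grow it past its maximum
  over <- new_seqset("o", make_scaffold_seq(c(hi[1] + 1, hi[-1])))
  expect_equal(nrow(match_scaffold(over, p)), 0)
})

test_that("classify_obp applies the subclass rules with precedence", {
  gaps <- c(30, 3, 40, 10, 8)
  classic <- make_scaffold_seq(gaps, lead = 5, trail = 12)
  out <- classify_obp(new_seqset("c1", classic))
  expect_equal(out$family, "obp")
  expect_equal(out$subclass, "classic")

  # remove C2 and C5 -> minus-C
  ch <- strsplit(classic, "", fixed = TRUE)[[1]]
  pos <- which(ch == "C")
  ch[pos[c(2, 5)]] <- "A"
  minus <- paste(ch, collapse = "")
  outm <- classify_obp(new_seqset("m1", minus))
  expect_equal(outm$subclass, "minus-C")
  expect_equal(outm$total_cys, 4L)

  # classic + 7 extra downstream cysteines + trailing proline -> plus-C
  plus <- paste0(classic, strrep("AC", 7), "AAP")
  outp <- classify_obp(new_seqset("p1", plus))
  expect_equal(outp$subclass, "plus-C")
  # without the proline the call stays classic
  noP <- paste0(classic, strrep("AC", 7), "AA")
  expect_equal(classify_obp(new_seqset("p2", noP))$subclass, "classic")

  # no scaffold at all -> unclassified
  expect_equal(classify_obp(new_seqset("u", strrep("AKL", 40)))$family,
               "unclassified")
})

test_that("every sequence receives exactly one subclass", {
  withr::with_seed(55, {
    seqs <- new_seqset(sprintf("r%03d", 1:120),
                       vapply(1:120, function(i) {
                         random_protein(sample(80:160, 1), cys_freq = 0.12)
                       }, character(1)))
    calls <- classify_obp(seqs)
    expect_equal(nrow(calls), 120)
    expect_false(anyDuplicated(calls$id) > 0)
    expect_true(all(calls$subclass[calls$family == "obp"] %in%
                      c("classic", "minus-C", "plus-C")))
    expect_true(all(is.na(calls$subclass[calls$family == "unclassified"])))
  })
})

test_that("classify_csp calls the four-cysteine scaffold", {
  set <- generate_family_set(family_spec("csp", n = 8, seed = 21))
  out <- classify_csp(set$records)
  expect_true(all(out$family == "csp"))
  expect_true(all(out$total_cys == 4))
  expect_equal(classify_csp(new_seqset("u", strrep("AKL", 40)))$family,
               "unclassified")
})

test_that("clean synthetic families produce an identity confusion matrix", {
  withr::with_seed(77, {
    fams <- c("classic_obp", "minusc_obp", "plusc_obp", "csp", "snmp")
    calls <- lapply(fams, function(f) {
      set <- generate_family_set(family_spec(f, n = 12,
                                             seed = match(f, fams)))
      obp <- classify_obp(set$records)
      csp <- classify_csp(set$records)
      snmp <- classify_snmp(set$records)
      got <- dplyr::case_when(
        f == "classic_obp" ~ all(obp$subclass == "classic"),
        f == "minusc_obp" ~ all(obp$subclass == "minus-C"),
        f == "plusc_obp" ~ all(obp$subclass == "plus-C"),
        f == "csp" ~ all(csp$family == "csp"),
        f == "snmp" ~ all(snmp$family == "snmp")
      )
      expect_true(got, label = paste("identity calls for", f))
      # cross-family: OBP families must not call as SNMP and vice versa
      if (f != "snmp") expect_true(all(snmp$family == "unclassified"))
      if (f == "snmp") expect_true(all(obp$family == "unclassified"))
    })
  })
})
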