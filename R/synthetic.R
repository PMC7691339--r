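# Seeded generator for labelled synthetic chemosensory protein families:
# conserved-cysteine scaffolds planted at the family's printed spacings,
# ungapped motifs planted at configured prevalences in rank (left-to-
# right) order, hydrophobic terminal stretches for the SNMP topology,
# and transcripts embedding reverse-translated ORFs between stop-
# disrupted UTRs. Every set is emitted together with a ground-truth
# record of what was planted, so downstream recovery is checkable.

.default_length_range <- list(
  classic_obp = c(130L, 160L),
  minusc_obp  = c(150L, 190L),
  plusc_obp   = c(180L, 230L),
  csp         = c(120L, 150L),
  snmp        = c(430L, 520L),
  background  = c(100L, 200L)
)

.family_scaffold <- function(family) {
  switch(family,
    classic_obp = obp_classic_pattern(),
    minusc_obp  = obp_minusc_pattern(),
    plusc_obp   = obp_classic_pattern(),
    csp         = csp_pattern(),
    snmp        = NULL,
    background  = NULL
  )
}

#' Background residue frequencies for the generator
#'
#' Uniform over the 20 amino acids, with configurable down-weighting of
#' cysteine (so stray cysteines cannot confound conserved-Cys subclass
#' truth labels) and, for membrane-protein loops, of the strongly
#' hydrophobic residues I/L/V/F (so stray hydrophobic windows cannot
#' confound the two-segment transmembrane truth).
#'
#' @param cys_weight Relative weight of `C` (default 0).
#' @param hydrophobic_weight Relative weight of each of I, L, V, F
#'   (default 1; the SNMP family spec sets 0).
#' @return Named probability vector over [AA_ALPHABET], summing to 1.
#' @export
synthetic_background <- function(cys_weight = 0, hydrophobic_weight = 1) {
  w <- setNames(rep(1, 20), AA_ALPHABET)
  w["C"] <- cys_weight
  w[c("I", "L", "V", "F")] <- hydrophobic_weight
  w / sum(w)
}

#' Specify a synthetic protein family
#'
#' Bundles everything [generate_family_set()] needs: the family scaffold,
#' sequence-length range, background composition, a motif plan and (for
#' SNMPs) a transmembrane plan.
#'
#' @param family One of `"classic_obp"`, `"minusc_obp"`, `"plusc_obp"`,
#'   `"csp"`, `"snmp"`, or `"background"` (no scaffold and no
#'   transmembrane plan: plain background plus any planted motifs, the
#'   neutral substrate for motif-recovery checks).
#' @param n Number of sequences.
#' @param length_range Length bounds in residues; family-specific
#'   defaults span the lengths reported for each family.
#' @param background Residue frequency vector over [AA_ALPHABET]; default
#'   [synthetic_background()] with cysteine suppressed (and I/L/V/F
#'   suppressed for `snmp`).
#' @param motif_plan List of motifs to plant, each a list with
#'   `consensus` (ungapped residue string) and `prevalence` in `[0,1]`.
#'   Rank is list order; motifs are planted left-to-right by rank.
#'   Carrier records are a deterministic seeded choice of exactly
#'   `round(prevalence * n)` records per motif.
#' @param tm_plan For `snmp`: list with `n_segments` (always 2) and
#'   `segment_length` (default 25), planting poly-hydrophobic (I/L/V/F)
#'   stretches near both termini.
#' @param plusc_extras For `plusc_obp`: list with `n_extra` cysteines
#'   planted after C6 (default 7, the archetype count) and `spacer`
#'   bounds between them (default `c(1, 6)`; the spacings are not
#'   standardised, so uniform draws keep the generator honest), plus a
#'   trailing proline.
#' @param seed Integer seed; identical spec and seed give identical
#'   output.
#' @return A `family_spec` list.
#' @export
family_spec <- function(family = c("classic_obp", "minusc_obp", "plusc_obp",
                                   "csp", "snmp", "background"),
                        n, length_range = NULL, background = NULL,
                        motif_plan = list(), tm_plan = NULL,
                        plusc_extras = list(n_extra = 7L, spacer = c(1L, 6L)),
                        seed = 1L) {
  family <- match.arg(family)
  length_range <- length_range %||% .default_length_range[[family]]
  background <- background %||% synthetic_background(
    hydrophobic_weight = if (family == "snmp") 0 else 1
  )
  if (abs(sum(background) - 1) > 1e-9) abort("background must sum to 1")
  if (length(motif_plan) > 0) {
    prev <- map_dbl(motif_plan, "prevalence")
    if (any(prev < 0 | prev > 1)) abort("prevalences must lie in [0, 1]")
  }
  if (family == "snmp" && is.null(tm_plan)) {
    tm_plan <- list(n_segments = 2L, segment_length = 25L)
  }
  scaffold <- .family_scaffold(family)
  if (!is.null(scaffold) && length_range[2] < scaffold_max_span(scaffold)) {
    abort(sprintf(
      "length_range upper bound %d cannot hold the maximal scaffold span %d",
      length_range[2], scaffold_max_span(scaffold)
    ))
  }
  structure(list(family = family, n = as.integer(n),
                 length_range = as.integer(length_range),
                 background = background, scaffold = scaffold,
                 motif_plan = motif_plan, tm_plan = tm_plan,
                 plusc_extras = plusc_extras, seed = as.integer(seed)),
            class = "family_spec")
}

#' Draw a random motif consensus string
#'
#' Letters are drawn from `background`, so planted motifs share the
#' composition of the sequences they are planted in (apart from being
#' identical across sites, which is what makes them motifs).
#'
#' @param width Motif width in residues.
#' @param background Residue frequency vector (default
#'   [synthetic_background()]).
#' @return A residue string of length `width`.
#' @export
random_motif_consensus <- function(width, background = synthetic_background()) {
  paste(sample(AA_ALPHABET, width, replace = TRUE, prob = background),
        collapse = "")
}

# sample() treats a length-1 numeric vector as 1:x; these helpers draw
# safely from the given set regardless of its length.
.sample1 <- function(x) x[sample.int(length(x), 1L)]
.shuffle <- function(x) x[sample.int(length(x))]

# Random background string of length n (vector of chars).
.bg_chars <- function(n, background) {
  sample(AA_ALPHABET, n, replace = TRUE, prob = background)
}

# Backtracking placement of motif windows in rank order: window j must
# start at or after the end of window j-1, avoid anchor positions and
# blocked spans. Returns 0-based starts or NULL when infeasible.
.place_motifs <- function(L, widths, anchor_pos0, blocked) {
  blocked_mask <- rep(FALSE, L)
  for (b in blocked) if (length(b)) blocked_mask[seq(b[1] + 1L, b[2])] <- TRUE
  anchor_mask <- rep(FALSE, L)
  anchor_mask[anchor_pos0 + 1L] <- TRUE
  feasible <- function(s0, w) {
    idx <- seq(s0 + 1L, s0 + w)
    !any(anchor_mask[idx]) && !any(blocked_mask[idx])
  }
  rec <- function(j, min_start) {
    if (j > length(widths)) return(integer(0))
    w <- widths[j]
    cand <- min_start:(L - w)
    if (length(cand) == 0 || min_start > L - w) return(NULL)
    cand <- cand[vapply(cand, feasible, logical(1), w = w)]
    if (length(cand) == 0) return(NULL)
    for (s0 in .shuffle(cand)) {
      rest <- rec(j + 1L, s0 + w)
      if (!is.null(rest)) return(c(s0, rest))
    }
    NULL
  }
  rec(1L, 0L)
}

#' Generate a labelled synthetic protein family
#'
#' Each record carries exactly one scaffold instance (spacers drawn
#' uniformly within the pattern's gap bounds), planted motifs
#' overwriting background at non-anchor positions in rank order for the
#' deterministic carrier fraction, and (for SNMPs) poly-hydrophobic
#' stretches near both termini. The same spec and seed reproduce the set
#' byte for byte.
#'
#' @param spec A [family_spec()].
#' @return A list with `records` (sequence tibble) and `truth`, a list
#'   of tibbles: `labels` (`id`, `family`), `anchors` (`id`, `anchor`,
#'   `position`, 0-based), `motifs` (`id`, `motif` rank, `consensus`,
#'   `start`, `width`) and `tm` (`id`, `segment`, `start`, `end`).
#' @export
generate_family_set <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(spec$seed, .generate_family_set_impl(spec))
}

.generate_family_set_impl <- function(spec) {
  n <- spec$n
  ids <- sprintf("%s_%03d", spec$family, seq_len(n))
  # deterministic carriers per motif: seeded shuffle, first round(p*n)
  carriers <- map(spec$motif_plan, function(m) {
    k <- round(m$prevalence * n)
    sort(sample.int(n, n)[seq_len(k)])
  })
  anchors_rows <- list(); motif_rows <- list(); tm_rows <- list()
  residues <- character(n)
  for (i in seq_len(n)) {
    L <- .sample1(seq(spec$length_range[1], spec$length_range[2]))
    chars <- .bg_chars(L, spec$background)
    anchor_pos0 <- integer(0)
    blocked <- list()
    if (!is.null(spec$scaffold)) {
      a <- spec$scaffold$anchors
      gaps <- map_int(seq_len(nrow(a)), function(k) {
        if (k == 1) 0L else as.integer(.sample1(seq(a$gap_min[k], a$gap_max[k])))
      })
      rel <- cumsum(gaps + 1L) - 1L  # 0-based relative anchor offsets
      span <- rel[length(rel)] + 1L
      extras_pos <- integer(0)
      extra_span <- 0L
      if (spec$family == "plusc_obp") {
        ne <- spec$plusc_extras$n_extra
        sp <- spec$plusc_extras$spacer
        esp <- as.integer(seq(sp[1], sp[2])[sample.int(sp[2] - sp[1] + 1L, ne + 1L, replace = TRUE)])
        extras_rel <- span - 1L + cumsum(esp + 1L)  # ne cysteines + proline
        extra_span <- extras_rel[length(extras_rel)] + 1L - span
        extras_pos <- extras_rel
      }
      total_span <- span + extra_span
      if (total_span > L) abort(sprintf(
        "infeasible placement: scaffold span %d exceeds length %d (record %s)",
        total_span, L, ids[i]
      ))
      offset <- .sample1(0:(L - total_span))
      pos0 <- rel + offset
      chars[pos0 + 1L] <- a$residue
      if (length(extras_pos) > 0) {
        extras_abs <- extras_pos + offset
        ne <- spec$plusc_extras$n_extra
        chars[extras_abs[seq_len(ne)] + 1L] <- "C"
        chars[extras_abs[ne + 1L] + 1L] <- "P"
        anchor_pos0 <- c(pos0, extras_abs)
      } else {
        anchor_pos0 <- pos0
      }
      anchors_rows[[i]] <- tibble(id = ids[i],
                                  anchor = seq_along(anchor_pos0),
                                  position = as.integer(anchor_pos0))
    }
    if (!is.null(spec$tm_plan)) {
      sl <- spec$tm_plan$segment_length
      s1 <- .sample1(2:10)
      s2_end <- L - .sample1(2:10)
      segs <- list(c(s1, s1 + sl), c(s2_end - sl, s2_end))
      for (k in seq_along(segs)) {
        sp <- segs[[k]]
        chars[seq(sp[1] + 1L, sp[2])] <-
          sample(c("I", "L", "V", "F"), sl, replace = TRUE)
      }
      blocked <- segs
      tm_rows[[i]] <- tibble(id = ids[i], segment = seq_along(segs),
                             start = map_int(segs, function(s) as.integer(s[1])),
                             end = map_int(segs, function(s) as.integer(s[2])))
    }
    planted <- which(map_dbl(seq_along(carriers),
                             function(m) i %in% carriers[[m]]) > 0)
    if (length(planted) > 0) {
      widths <- map_int(spec$motif_plan[planted],
                        function(m) nchar(m$consensus))
      starts <- .place_motifs(L, widths, anchor_pos0, blocked)
      if (is.null(starts)) abort(sprintf(
        "infeasible placement: motifs do not fit in record %s (length %d)",
        ids[i], L
      ))
      for (k in seq_along(planted)) {
        m <- spec$motif_plan[[planted[k]]]
        idx <- seq(starts[k] + 1L, starts[k] + widths[k])
        chars[idx] <- strsplit(m$consensus, "", fixed = TRUE)[[1]]
      }
      motif_rows[[length(motif_rows) + 1L]] <- tibble(
        id = ids[i], motif = planted,
        consensus = map_chr(spec$motif_plan[planted], "consensus"),
        start = as.integer(starts), width = widths
      )
    }
    residues[i] <- paste(chars, collapse = "")
  }
  records <- new_seqset(ids, residues,
                        description = paste("synthetic", spec$family))
  truth <- list(
    labels = tibble(id = ids, family = spec$family),
    anchors = bind_rows(anchors_rows),
    motifs = if (length(motif_rows)) bind_rows(motif_rows) else
      tibble(id = character(), motif = integer(), consensus = character(),
             start = integer(), width = integer()),
    tm = if (length(tm_rows)) bind_rows(tm_rows) else
      tibble(id = character(), segment = integer(), start = integer(),
             end = integer())
  )
  list(records = records, truth = truth)
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# Codons per amino acid, from the standard genetic code.
.aa_codons <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), gc)
    }
    tab
  }
})

# Random UTR of length n with stop codons injected in all three frames
# roughly every 30 nt, so no spurious long ORF can span it.
.random_utr <- function(n) {
  if (n == 0) return("")
  chars <- sample(DNA_ALPHABET, n, replace = TRUE)
  for (off in 0:2) {
    starts <- seq(off, n - 3, by = 30)
    for (s in starts) {
      chars[(s + 1):(s + 3)] <- strsplit(sample(.STOP_CODONS, 1), "")[[1]]
    }
  }
  paste(chars, collapse = "")
}

# An 11-nt cassette with stop codons at offsets 0, 4 and 8 covers all
# three frame phases; placed at the UTR side of each ORF boundary it
# prevents off-frame reads of the coding region from running on into
# the UTRs.
.STOP_CASSETTE <- "TAAATAAATAA"

.stop_cassette_end <- function(utr) {
  n <- nchar(utr)
  if (n < 11) return(utr)
  paste0(substr(utr, 1, n - 11), .STOP_CASSETTE)
}

.stop_cassette_start <- function(utr) {
  n <- nchar(utr)
  if (n < 11) return(utr)
  paste0(.STOP_CASSETTE, substr(utr, 12, n))
}

#' Reverse-translate a protein into a synthetic transcript
#'
#' Emits `5'UTR + ATG + codons + stop + 3'UTR` (on the minus strand, the
#' reverse complement of that construct). The leading methionine of the
#' protein is encoded by the start ATG; codons are drawn uniformly among
#' synonyms; UTRs carry in-frame stops in all three frames so no
#' spurious ORF longer than ~10 residues can arise outside the planted
#' one.
#'
#' @param protein One-row sequence tibble (or any row-subsettable
#'   sequence tibble; the first row is used).
#' @param utr5,utr3 UTR lengths in nucleotides.
#' @param strand `"+"` or `"-"`.
#' @param seed Integer seed.
#' @return A list with `transcript` (one-row DNA sequence tibble) and
#'   `truth`: `nt_start`, `nt_end` (0-based half-open, forward strand,
#'   stop codon included), `frame` and `protein` (the encoded residue
#'   string, leading ATG methionine included).
#' @export
generate_transcript <- function(protein, utr5 = 60, utr3 = 60,
                                strand = c("+", "-"), seed = 1L) {
  strand <- match.arg(strand)
  res <- protein$residues[1]
  id <- protein$id[1]
  withr::with_seed(seed, {
    aa <- strsplit(res, "", fixed = TRUE)[[1]]
    body_aa <- if (aa[1] == "M") aa[-1] else aa
    codons <- map_chr(body_aa, function(a) {
      cands <- .aa_codons()[[a]]
      if (is.null(cands)) abort(paste0("cannot reverse-translate residue ", a))
      .sample1(cands)
    })
    orf <- paste0("ATG", paste(codons, collapse = ""),
                  sample(.STOP_CODONS, 1))
    u5 <- .stop_cassette_end(.random_utr(utr5))
    u3 <- .stop_cassette_start(.random_utr(utr3))
    plus <- paste0(u5, orf, u3)
    L <- nchar(plus)
    orf_start <- utr5
    orf_end <- utr5 + nchar(orf)
    encoded <- paste(c("M", body_aa), collapse = "")
    if (strand == "+") {
      out_seq <- plus
      nt_start <- orf_start; nt_end <- orf_end
      frame <- orf_start %% 3 + 1L
    } else {
      out_seq <- revcomp(plus)
      nt_start <- L - orf_end; nt_end <- L - orf_start
      frame <- -(orf_start %% 3 + 1L)
    }
    tx_id <- paste0(id, "_tx")
    list(
      transcript = new_seqset(tx_id, out_seq,
                              description = paste0("synthetic transcript (",
                                                   strand, ")"),
                              alphabet = "dna"),
      truth = tibble(id = tx_id, source = id,
                     nt_start = as.integer(nt_start),
                     nt_end = as.integer(nt_end),
                     frame = as.integer(frame), protein = encoded)
    )
  })
}

.random_join_newick <- function(labels) {
  nodes <- labels
  while (length(nodes) > 1) {
    pick <- sample(length(nodes), 2)
    joined <- paste0("(", nodes[pick[1]], ":1,", nodes[pick[2]], ":1)")
    nodes <- c(nodes[-pick], joined)
  }
  nodes
}

#' Generate a random labelled binary tree over record IDs
#'
#' Builds a rooted binary tree whose leaves are the record IDs. IDs
#' sharing a label are clustered into one subtree (so pattern labels are
#' clade-coherent by construction), and the label subtrees are joined at
#' random.
#'
#' @param ids Character vector of unique record IDs.
#' @param labels One label per ID (default: all one group).
#' @param seed Integer seed.
#' @return An [ape::read.tree()] `phylo` object with `length(ids)` leaves.
#' @export
generate_labeled_tree <- function(ids, labels = rep("g1", length(ids)),
                                  seed = 1L) {
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate record ID(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  stopifnot(length(labels) == length(ids))
  withr::with_seed(seed, {
    subtrees <- map_chr(split(ids, labels), .random_join_newick)
    txt <- paste0(.random_join_newick(unname(subtrees)), ";")
    ape::read.tree(text = txt)
  })
}
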