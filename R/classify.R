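# Family and subclass calling from scaffold matches and the hydropathy
# screen. Subclass precedence for OBPs is plus-C > classic > minus-C:
# every classic match is also compatible with the 4-anchor minus-C
# profile (a subset of its cysteines), and the plus-C subclass is the
# classic scaffold with extras, so precedence keeps the calls mutually
# exclusive.

.empty_call <- function() {
  tibble(id = character(), family = character(), subclass = character(),
         n_matches = integer(), anchor_positions = list(),
         total_cys = integer(), tm_segments = integer())
}

count_cys <- function(residues) {
  map_int(strsplit(residues, "", fixed = TRUE),
          function(ch) sum(ch == "C"))
}

#' Classify proteins into OBP subclasses
#'
#' Calls each sequence as `plus-C`, `classic`, `minus-C` or leaves it
#' unclassified, using conserved-cysteine scaffold matching:
#' * plus-C: a classic scaffold match with at least `extra_cys_min`
#'   cysteines after C6 and a proline after the last of them;
#' * classic: a classic scaffold match without the plus-C extras;
#' * minus-C: a match to the 4-anchor pattern derived from the classic
#'   scaffold by deleting C2 and C5, and no classic match.
#'
#' @param seqs Sequence tibble (columns `id`, `residues`).
#' @param classic,minusc Scaffold patterns; defaults are the shipped
#'   profiles [obp_classic_pattern()] and [obp_minusc_pattern()].
#' @param extra_cys_min Minimum extra cysteines for a plus-C call
#'   (default 4).
#' @return Tibble with columns `id`, `family` (`"obp"` or
#'   `"unclassified"`), `subclass`, `n_matches`, `anchor_positions`
#'   (list-column; first match, `NULL` when unclassified) and
#'   `total_cys`.
#' @export
classify_obp <- function(seqs, classic = obp_classic_pattern(),
                         minusc = obp_minusc_pattern(), extra_cys_min = 4) {
  rows <- map2(seqs$id, seqs$residues, function(id, res) {
    classic_hits <- match_scaffold_one(res, classic)
    if (length(classic_hits) > 0) {
      plusc <- map_dbl(classic_hits, function(h) {
        has_plusc_extras(res, h, min_extra = extra_cys_min)
      })
      sub <- if (any(plusc > 0)) "plus-C" else "classic"
      best <- if (any(plusc > 0)) classic_hits[[which(plusc > 0)[1]]] else classic_hits[[1]]
      return(tibble(id = id, family = "obp", subclass = sub,
                    n_matches = length(classic_hits),
                    anchor_positions = list(best),
                    total_cys = count_cys(res)))
    }
    minusc_hits <- match_scaffold_one(res, minusc)
    if (length(minusc_hits) > 0) {
      return(tibble(id = id, family = "obp", subclass = "minus-C",
                    n_matches = length(minusc_hits),
                    anchor_positions = list(minusc_hits[[1]]),
                    total_cys = count_cys(res)))
    }
    tibble(id = id, family = "unclassified", subclass = NA_character_,
           n_matches = 0L, anchor_positions = list(NULL),
           total_cys = count_cys(res))
  })
  bind_rows(rows)
}

#' Classify proteins as chemosensory proteins (CSPs)
#'
#' A sequence is called `csp` when the four-cysteine CSP scaffold
#' matches anywhere in the sequence.
#'
#' @param seqs Sequence tibble (columns `id`, `residues`).
#' @param pattern CSP scaffold; default [csp_pattern()].
#' @return Tibble with columns `id`, `family` (`"csp"` or
#'   `"unclassified"`), `n_matches`, `anchor_positions`, `total_cys`.
#' @export
classify_csp <- function(seqs, pattern = csp_pattern()) {
  rows <- map2(seqs$id, seqs$residues, function(id, res) {
    hits <- match_scaffold_one(res, pattern)
    tibble(
      id = id,
      family = if (length(hits) > 0) "csp" else "unclassified",
      n_matches = length(hits),
      anchor_positions = list(if (length(hits) > 0) hits[[1]] else NULL),
      total_cys = count_cys(res)
    )
  })
  bind_rows(rows)
}

#' Classify proteins by the SNMP two-transmembrane topology
#'
#' A sequence is called `snmp` when the hydropathy screen finds exactly
#' two candidate transmembrane segments, the first starting within the
#' N-terminal quarter, the second ending within the C-terminal quarter,
#' separated by a loop of at least `min_loop` residues (the large
#' extracellular domain characteristic of the CD36 family).
#'
#' Subfamily (SNMP1 vs SNMP2) is not called: that distinction is resolved
#' by phylogeny, not by topology.
#'
#' @param seqs Sequence tibble (columns `id`, `residues`).
#' @param window,threshold Hydropathy screen parameters, see
#'   [predict_tm_segments()].
#' @param min_loop Minimum inter-segment loop length in residues
#'   (default 100).
#' @return Tibble with columns `id`, `family` (`"snmp"` or
#'   `"unclassified"`), `tm_segments` (count), `loop_length`
#'   (`NA` unless exactly two segments), `total_cys`.
#' @export
classify_snmp <- function(seqs, window = 19, threshold = 1.6, min_loop = 100) {
  segs <- predict_tm_segments(seqs, window = window, threshold = threshold)
  rows <- map2(seqs$id, seqs$residues, function(id, res) {
    s <- segs[segs$id == id, ]
    n <- nchar(res)
    loop <- NA_integer_
    ok <- FALSE
    if (nrow(s) == 2) {
      loop <- s$start[2] - s$end[1]
      ok <- s$start[1] < ceiling(n / 4) &&
        s$end[2] > n - ceiling(n / 4) &&
        loop >= min_loop
    }
    tibble(id = id, family = if (ok) "snmp" else "unclassified",
           tm_segments = nrow(s), loop_length = loop,
           total_cys = count_cys(res))
  })
  bind_rows(rows)
}

#' Classify a sequence set for one chemosensory family
#'
#' Dispatches to [classify_obp()], [classify_csp()] or [classify_snmp()]
#' and returns a uniform call table.
#'
#' @param seqs Sequence tibble (columns `id`, `residues`).
#' @param family `"obp"`, `"csp"` or `"snmp"`.
#' @param ... Passed to the family classifier.
#' @return The classifier's tibble, see the family functions.
#' @export
classify_sequences <- function(seqs, family = c("obp", "csp", "snmp"), ...) {
  family <- match.arg(family)
  switch(family,
    obp = classify_obp(seqs, ...),
    csp = classify_csp(seqs, ...),
    snmp = classify_snmp(seqs, ...)
  )
}
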