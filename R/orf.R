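# Six-frame stop-to-stop ORF extraction with a minimum-length filter.
# Coordinates are 0-based half-open on the forward strand; the span of an
# ORF includes its terminating stop codon when one is present. An ORF
# that runs off the end of the sequence without a stop is reported with
# `has_stop = FALSE` (transcript fragments are common in de novo
# assemblies).

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

translate_codons <- function(codons) {
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"  # any codon containing N (or partial)
  unname(aa)
}

revcomp <- function(dna) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(dna, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

.frame_order <- c(1L, 2L, 3L, -1L, -2L, -3L)

# ORFs for one oriented string; coordinates local to that orientation.
.orfs_one_strand <- function(seqstr, frame_offsets, min_len, require_start) {
  n <- nchar(seqstr)
  out <- list()
  for (off in frame_offsets) {
    ncod <- (n - off) %/% 3
    if (ncod < 1) next
    starts <- off + 3L * (seq_len(ncod) - 1L)  # 0-based codon starts
    codons <- substring(seqstr, starts + 1L, starts + 3L)
    aa <- translate_codons(codons)
    is_stop <- aa == "*"
    # stretch boundaries: indices of codons between stops
    grp <- cumsum(c(TRUE, is_stop[-ncod]))
    for (g in split(seq_len(ncod), grp)) {
      g <- g[!is_stop[g]]
      if (length(g) == 0) next
      has_stop <- (g[length(g)] < ncod) && is_stop[g[length(g)] + 1L]
      if (require_start) {
        atg <- which(codons[g] == "ATG")
        if (length(atg) == 0) next
        g <- g[atg[1]:length(g)]
      }
      if (length(g) < min_len) next
      nt_start <- starts[g[1]]
      nt_end <- starts[g[length(g)]] + 3L + if (has_stop) 3L else 0L
      out[[length(out) + 1L]] <- list(
        frame_offset = off,
        nt_start = nt_start, nt_end = nt_end,
        protein = paste(aa[g], collapse = ""),
        has_start_codon = codons[g[1]] == "ATG",
        has_stop = has_stop
      )
    }
  }
  out
}

#' Find open reading frames in all six frames
#'
#' Enumerates maximal stop-to-stop ORFs on both strands whose translated
#' length meets `min_len`. With `require_start = TRUE`, each ORF is
#' trimmed to its first ATG and re-filtered. Codons containing `N`
#' translate to `X`.
#'
#' @param dna Sequence tibble of DNA records (columns `id`, `residues`).
#' @param min_len Minimum protein length in residues (default 100, the
#'   conventional minimum for coding-region prediction).
#' @param require_start Trim ORFs to the first ATG (default `FALSE`,
#'   i.e. stop-to-stop).
#' @return Tibble with columns `id`, `frame` (+1..+3, -1..-3), `nt_start`,
#'   `nt_end` (0-based half-open, forward strand; the span includes the
#'   terminating stop codon when present), `protein`, `has_start_codon`,
#'   `has_stop`. Rows are sorted per input record by descending protein
#'   length, ties broken by frame (+1 before -3) then `nt_start`.
#' @export
#' @examples
#' find_orfs(new_seqset("t", "ATGAAATAA", alphabet = "dna"), min_len = 1)
find_orfs <- function(dna, min_len = 100, require_start = FALSE) {
  bad <- regexpr(.alphabet_regex$dna, dna$residues)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf("record '%s' is not DNA (offending character at position %d)",
                  dna$id[i], bad[i]))
  }
  rows <- map2(dna$id, dna$residues, function(id, seqstr) {
    n <- nchar(seqstr)
    fwd <- .orfs_one_strand(seqstr, 0:2, min_len, require_start)
    rev <- .orfs_one_strand(revcomp(seqstr), 0:2, min_len, require_start)
    fwd <- map(fwd, function(o) {
      o$frame <- o$frame_offset + 1L
      o
    })
    rev <- map(rev, function(o) {
      o$frame <- -(o$frame_offset + 1L)
      # mirror [s, e) on the reverse complement back to forward coords
      s <- o$nt_start
      o$nt_start <- n - o$nt_end
      o$nt_end <- n - s
      o
    })
    orfs <- c(fwd, rev)
    if (length(orfs) == 0) return(NULL)
    tbl <- tibble(
      id = id,
      frame = map_int(orfs, "frame"),
      nt_start = map_int(orfs, "nt_start"),
      nt_end = map_int(orfs, "nt_end"),
      protein = map_chr(orfs, "protein"),
      has_start_codon = map_dbl(orfs, "has_start_codon") > 0,
      has_stop = map_dbl(orfs, "has_stop") > 0
    )
    tbl[order(-nchar(tbl$protein), match(tbl$frame, .frame_order),
              tbl$nt_start), ]
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(id = character(), frame = integer(), nt_start = integer(),
                  nt_end = integer(), protein = character(),
                  has_start_codon = logical(), has_stop = logical())
  }
  out
}

#' Longest ORF per record
#'
#' @inheritParams find_orfs
#' @return Tibble with at most one row per input record: the longest ORF
#'   under [find_orfs()]'s ordering. Records without a qualifying ORF are
#'   absent.
#' @export
longest_orf <- function(dna, min_len = 100, require_start = FALSE) {
  orfs <- find_orfs(dna, min_len = min_len, require_start = require_start)
  orfs |>
    group_by(.data$id) |>
    filter(row_number() == 1L) |>
    ungroup()
}
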