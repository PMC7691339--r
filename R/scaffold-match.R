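# Scaffold matching: depth-first enumeration of anchor-position tuples
# satisfying residue identity and bounded spacer gaps.

# All matches for one residue string. Returns a list of 0-based integer
# vectors in lexicographic order of positions.
match_scaffold_one <- function(residues, pattern) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  a <- pattern$anchors
  k <- nrow(a)
  # candidate positions per anchor (1-based here)
  cand <- lapply(a$residue, function(r) which(chars == r))
  if (any(lengths(cand) == 0)) return(list())
  out <- list()
  recurse <- function(level, positions) {
    if (level > k) {
      out[[length(out) + 1L]] <<- positions - 1L  # 0-based
      return(invisible())
    }
    prev <- positions[level - 1L]
    lo <- prev + a$gap_min[level] + 1L
    hi <- prev + a$gap_max[level] + 1L
    for (p in cand[[level]]) {
      if (p < lo) next
      if (p > hi) break
      recurse(level + 1L, c(positions, p))
    }
  }
  for (p0 in cand[[1]]) recurse(2L, p0)
  out
}

#' Match a conserved-residue scaffold pattern against protein sequences
#'
#' Enumerates, for each sequence, every tuple of anchor positions that
#' satisfies the pattern's residue and gap constraints, in lexicographic
#' order of positions. Coordinates are 0-based; `start`/`end` is the
#' half-open span from the first anchor to one past the last.
#'
#' @param seqs Sequence tibble (columns `id`, `residues`) as returned by
#'   [read_fasta()] or [new_seqset()].
#' @param pattern A [scaffold_pattern()].
#' @return Tibble with one row per match: `id`, `pattern`, `match`
#'   (1-based match index within the sequence), `anchor_positions`
#'   (list-column of 0-based integer vectors), `start`, `end`. Sequences
#'   without a match contribute no rows.
#' @export
#' @examples
#' s <- new_seqset("x", paste0("C", strrep("A", 6), "C", strrep("A", 18), "C", "AA", "C"))
#' match_scaffold(s, csp_pattern())
match_scaffold <- function(seqs, pattern) {
  stopifnot(inherits(pattern, "scaffold_pattern"))
  rows <- map2(seqs$id, seqs$residues, function(id, res) {
    hits <- match_scaffold_one(res, pattern)
    if (length(hits) == 0) return(NULL)
    tibble(
      id = id, pattern = pattern$name, match = seq_along(hits),
      anchor_positions = hits,
      start = map_int(hits, function(h) h[1]),
      end = map_int(hits, function(h) h[length(h)] + 1L)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(id = character(), pattern = character(), match = integer(),
                  anchor_positions = list(), start = integer(), end = integer())
  }
  out
}

# Does any classic match carry the plus-C extras (>= min_extra cysteines
# strictly after the final anchor, with a proline after the last one)?
has_plusc_extras <- function(residues, anchor_positions, min_extra = 4) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  last_anchor <- anchor_positions[length(anchor_positions)] + 1L  # 1-based
  extra_c <- which(chars == "C")
  extra_c <- extra_c[extra_c > last_anchor]
  if (length(extra_c) < min_extra) return(FALSE)
  any(which(chars == "P") > max(extra_c))
}
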