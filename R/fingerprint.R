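# Motif-pattern fingerprints: the ordered (left-to-right) list of
# motifs present in each sequence, and the frequency-ranked grouping of
# identical fingerprints into numbered patterns (e.g. "3c" = the third
# most frequent pattern of the classic set).

#' Build per-sequence motif fingerprints
#'
#' Orders each sequence's motif occurrences by start position. Under
#' ZOOPS semantics each motif is present at most once per sequence; if
#' several occurrences of one motif survive the scan (possible after
#' manual threshold lowering), only the best-scoring one is kept.
#'
#' @param records Sequence tibble (all sequences appear in the output,
#'   including those with no occurrence, as empty fingerprints).
#' @param occurrences Occurrence tibble from [scan_motifs()] (columns
#'   `id`, `motif`, `start`, `score`).
#' @return Tibble with columns `id`, `fingerprint` (list-column of
#'   integer motif ids ordered by start) and `pattern_key` (the
#'   fingerprint as a `-`-separated string, e.g. `"2-4-3-1"`; empty
#'   fingerprints give `""`).
#' @export
build_fingerprints <- function(records, occurrences) {
  stray <- setdiff(occurrences$id, records$id)
  if (length(stray) > 0) {
    abort(paste0("occurrences for unknown sequence id(s): ",
                 paste(unique(stray), collapse = ", ")))
  }
  occ <- occurrences
  if (nrow(occ) > 0) {
    occ <- occ |>
      group_by(.data$id, .data$motif) |>
      filter(.data$score == max(.data$score)) |>
      filter(row_number() == 1L) |>
      ungroup()
  }
  # non-overlap sanity (the scanner guarantees this within a motif;
  # across motifs masking does)
  chk <- occ |> arrange(.data$id, .data$start)
  fp <- map(records$id, function(i) {
    o <- chk[chk$id == i, ]
    o <- o[order(o$start), ]
    as.integer(o$motif)
  })
  tibble(
    id = records$id,
    fingerprint = fp,
    pattern_key = map_chr(fp, paste, collapse = "-")
  )
}

#' Group identical fingerprints into numbered motif patterns
#'
#' Sequences sharing an identical ordered motif list form one pattern.
#' Patterns are numbered by descending member count (ties broken by the
#' input order of their first member) and suffixed by the family letter,
#' e.g. `1c`, `2c`, ... for a classic-OBP set.
#'
#' @param fingerprints Tibble from [build_fingerprints()].
#' @param family_suffix Pattern-id suffix (e.g. `"c"`, `"m"`, `"p"`;
#'   default `""`).
#' @return Tibble with columns `pattern` (e.g. `"1c"`), `pattern_key`,
#'   `count`, `fraction` (of all fingerprints; fractions sum to 1) and
#'   `members` (list-column of sequence ids).
#' @export
group_patterns <- function(fingerprints, family_suffix = "") {
  if (anyDuplicated(fingerprints$id)) {
    abort("duplicate sequence ids in fingerprints")
  }
  n <- nrow(fingerprints)
  grp <- fingerprints |>
    mutate(.ord = row_number()) |>
    group_by(.data$pattern_key) |>
    summarise(count = n(), first_seen = min(.data$.ord),
              members = list(.data$id), .groups = "drop") |>
    arrange(desc(.data$count), .data$first_seen)
  grp |>
    mutate(pattern = paste0(row_number(), family_suffix),
           fraction = .data$count / n) |>
    select("pattern", "pattern_key", "count", "fraction", "members")
}

#' Per-motif prevalence across fingerprints
#'
#' @param fingerprints Tibble from [build_fingerprints()].
#' @param motifs Optional integer vector of motif ids to report; motifs
#'   in `motifs` but absent from every fingerprint get prevalence 0.
#'   Default: the motifs observed in the fingerprints.
#' @return Tibble with columns `motif` and `prevalence` (fraction of
#'   fingerprints containing the motif, denominator = number of
#'   fingerprints).
#' @export
prevalence_table <- function(fingerprints, motifs = NULL) {
  denom <- max(nrow(fingerprints), 1L)
  present <- fingerprints |>
    select("id", "fingerprint") |>
    tidyr::unnest_longer("fingerprint", values_to = "motif") |>
    filter(!is.na(.data$motif)) |>
    dplyr::distinct(.data$id, .data$motif) |>
    count(.data$motif)
  motifs <- motifs %||% present$motif
  tibble(motif = as.integer(sort(motifs))) |>
    left_join(present, by = "motif") |>
    mutate(prevalence = dplyr::coalesce(.data$n, 0L) / denom) |>
    select("motif", "prevalence")
}
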