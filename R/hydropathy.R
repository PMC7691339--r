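# Kyte-Doolittle sliding-window hydropathy screen. This is an in-house
# heuristic stand-in for a dedicated transmembrane-topology predictor:
# it flags candidate membrane-spanning stretches as runs of windows whose
# mean hydropathy clears a threshold, which is sufficient to recognise
# the two-terminal-helix SNMP layout.

#' Sliding-window mean Kyte-Doolittle hydropathy
#'
#' @param residues A single protein sequence string.
#' @param window Odd window length in residues (default 19, the classical
#'   transmembrane-helix span).
#' @return Numeric vector of length `nchar(residues) - window + 1`; entry
#'   `i` is the mean hydropathy of the window starting at 0-based
#'   position `i - 1`.
#' @export
hydropathy_profile <- function(residues, window = 19) {
  n <- nchar(residues)
  if (window %% 2 == 0) abort("window must be odd")
  if (window > n) abort(sprintf("window (%d) exceeds sequence length (%d)", window, n))
  kd <- unname(KYTE_DOOLITTLE[strsplit(residues, "", fixed = TRUE)[[1]]])
  kd[is.na(kd)] <- 0  # X contributes neutrally
  cs <- c(0, cumsum(kd))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' Predict candidate transmembrane segments by hydropathy
#'
#' Maximal runs of window starts whose mean Kyte-Doolittle hydropathy is
#' at or above `threshold` are merged into segments spanning the union of
#' their windows.
#'
#' @param seqs Sequence tibble (columns `id`, `residues`).
#' @param window Odd window length (default 19).
#' @param threshold Mean-hydropathy cutoff (default 1.6).
#' @return Tibble with columns `id`, `segment`, `start`, `end` (0-based
#'   half-open) and `mean_hydropathy` (the best window mean in the run).
#' @export
predict_tm_segments <- function(seqs, window = 19, threshold = 1.6) {
  rows <- map2(seqs$id, seqs$residues, function(id, res) {
    prof <- hydropathy_profile(res, window)
    hot <- which(prof >= threshold)
    if (length(hot) == 0) return(NULL)
    run_id <- cumsum(c(1L, diff(hot) > 1L))
    runs <- split(hot, run_id)
    tibble(
      id = id, segment = seq_along(runs),
      start = map_int(runs, function(r) r[1] - 1L),
      end = map_int(runs, function(r) r[length(r)] - 1L + window),
      mean_hydropathy = map_dbl(runs, function(r) max(prof[r]))
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(id = character(), segment = integer(), start = integer(),
                  end = integer(), mean_hydropathy = double())
  }
  out
}
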