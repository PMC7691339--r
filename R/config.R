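# Run configuration: one validated bundle of the tunable parameters of
# a family analysis, loadable from YAML with flag-style overrides.

.family_motif_defaults <- list(
  obp  = list(motif_minw = 6L, motif_maxw = 10L, motif_n = 8L),
  csp  = list(motif_minw = 6L, motif_maxw = 10L, motif_n = 8L),
  snmp = list(motif_minw = 45L, motif_maxw = 95L, motif_n = 10L)
)

#' Build a validated run configuration
#'
#' Defaults follow the family conventions: OBP/CSP motif widths 6-10
#' with up to 8 motifs, SNMP widths 45-95 with up to 10, significance
#' threshold 1e-4, ORF minimum 100 residues, hydropathy window 19 at
#' threshold 1.6.
#'
#' @param family `"obp"`, `"csp"` or `"snmp"`.
#' @param orf_min_len Minimum ORF length in residues.
#' @param orf_min_unit `"residues"` or `"nt"`; with `"nt"` the minimum
#'   is interpreted as nucleotides and divided by 3.
#' @param motif_minw,motif_maxw,motif_n Motif discovery parameters.
#' @param motif_p_threshold Motif significance threshold.
#' @param tm_window,tm_threshold Hydropathy screen parameters.
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(family = c("obp", "csp", "snmp"),
                       orf_min_len = 100L, orf_min_unit = c("residues", "nt"),
                       motif_minw = NULL, motif_maxw = NULL, motif_n = NULL,
                       motif_p_threshold = 1e-4,
                       tm_window = 19L, tm_threshold = 1.6, seed = 1L) {
  family <- match.arg(family)
  orf_min_unit <- match.arg(orf_min_unit)
  d <- .family_motif_defaults[[family]]
  cfg <- list(
    family = family,
    orf_min_len = as.integer(orf_min_len),
    orf_min_unit = orf_min_unit,
    motif_minw = as.integer(motif_minw %||% d$motif_minw),
    motif_maxw = as.integer(motif_maxw %||% d$motif_maxw),
    motif_n = as.integer(motif_n %||% d$motif_n),
    motif_p_threshold = motif_p_threshold,
    tm_window = as.integer(tm_window),
    tm_threshold = tm_threshold,
    seed = as.integer(seed)
  )
  if (cfg$orf_min_len < 1) abort("orf_min_len must be >= 1")
  if (cfg$motif_minw > cfg$motif_maxw) abort("motif_minw must be <= motif_maxw")
  if (cfg$motif_n < 1) abort("motif_n must be >= 1")
  if (cfg$motif_p_threshold <= 0 || cfg$motif_p_threshold >= 1) {
    abort("motif_p_threshold must be in (0, 1)")
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML, with overrides
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @param ... Named overrides taking precedence over the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  cfg <- modifyList(cfg, list(...))
  do.call(run_config, cfg)
}

#' Effective ORF minimum in residues
#'
#' @param cfg A `run_config`.
#' @return Integer residue minimum (nucleotide minima are divided by 3,
#'   rounded up).
#' @export
orf_min_residues <- function(cfg) {
  if (cfg$orf_min_unit == "nt") as.integer(ceiling(cfg$orf_min_len / 3))
  else cfg$orf_min_len
}
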