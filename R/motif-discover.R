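# Greedy de novo motif discovery: per round, ZOOPS-EM from seeded starts
# across candidate widths, width selection by LLR per free parameter,
# empirical shuffle-null significance, then masking of the accepted
# motif's occurrences before the next round.

# Deterministic-given-RNG-state search for the best model at one width.
# Candidate seeds are the distinct window subsequences (capped at
# n_starts, preferring repeated subsequences — a repeated exact word is
# the strongest cheap signal of a shared motif); the top n_score by the
# LLR of their initial model are kept, and full EM runs only from the
# top n_refine.
.best_model_for_width <- function(enc, w, b, policy) {
  wd <- .window_data(enc, w)
  if (is.null(wd)) return(NULL)
  # collision-safe numeric fingerprint of each window row
  key <- as.vector(wd$W %*% runif(w))
  first <- which(!duplicated(key))
  mult <- tabulate(match(key, key[first]))  # aligned with `first`
  ord <- first[order(-mult, runif(length(first)))]
  cand <- ord[seq_len(min(policy$n_starts, length(ord)))]
  logb <- log(b)
  n_score <- min(policy$n_score, length(cand))
  init_llr <- vapply(cand[seq_len(n_score)], function(j) {
    theta0 <- .theta_from_seed(wd$W[j, ])
    lr <- log(theta0) - rep(logb, each = w)
    .zoops_estep(wd, lr, 0.5)$llr
  }, numeric(1))
  top <- cand[seq_len(n_score)][order(init_llr, decreasing = TRUE)][
    seq_len(min(policy$n_refine, n_score))]
  best <- NULL
  for (j in top) {
    m <- .em_run(wd, .theta_from_seed(wd$W[j, ]), 0.5, b,
                 policy$pseudo_frac, policy$tol, policy$max_iter)
    if (is.null(best) || m$llr > best$llr) best <- m
  }
  best
}

.default_policy <- function(n_starts = 200, n_score = 30, n_refine = 3,
                            pseudo_frac = 0.01, tol = 1e-6,
                            max_iter = 200) {
  list(n_starts = n_starts, n_score = n_score, n_refine = n_refine,
       pseudo_frac = pseudo_frac, tol = tol, max_iter = max_iter)
}

# Shuffle residues within each sequence (masked X positions shuffle too).
.shuffle_records <- function(records) {
  records$residues <- vapply(records$residues, function(res) {
    ch <- strsplit(res, "", fixed = TRUE)[[1]]
    paste(ch[sample.int(length(ch))], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  records
}

# Encoded-level shuffle; per-sequence residue counts (hence the
# background) are invariant under it.
.shuffle_enc <- function(enc) {
  lapply(enc, function(x) x[sample.int(length(x))])
}

# Best width-normalised LLR across widths on one dataset; the statistic
# both the observed search and the shuffle null maximise.
.best_over_widths <- function(enc, b, widths, policy) {
  best <- NULL
  for (w in widths) {
    m <- .best_model_for_width(enc, w, b, policy)
    if (is.null(m)) next
    m$score <- m$llr / (19 * w)
    if (is.null(best) || m$score > best$score) best <- m
  }
  best
}

#' Empirical shuffle-null significance of a motif model
#'
#' The observed statistic is the model's LLR. For each of `n_shuffles`
#' datasets obtained by shuffling residues within each sequence, the
#' width-`w` motif search is re-run with the same seeding and refinement
#' policy used to fit the model, and
#' `p = (1 + #\{shuffled best-LLR >= observed\}) / (1 + n_shuffles)`.
#' The smallest attainable p is therefore `1 / (1 + n_shuffles)`.
#'
#' @param model A `motif_model` from [em_zoops()] or [discover_motifs()].
#' @param records The sequence tibble the model was fitted on.
#' @param n_shuffles Number of shuffled datasets (default 999).
#' @param seed Integer seed for the shuffles.
#' @return The p-value, in `(0, 1]`.
#' @export
motif_significance <- function(model, records, n_shuffles = 999, seed = 1L) {
  if (n_shuffles < 1) abort("n_shuffles must be >= 1")
  policy <- model$policy %||% .default_policy()
  withr::with_seed(seed, {
    enc0 <- .encode_set(records)
    b <- .background_freq(enc0)
    null_llr <- vapply(seq_len(n_shuffles), function(s) {
      m <- .best_model_for_width(.shuffle_enc(enc0), model$width, b, policy)
      if (is.null(m)) -Inf else m$llr
    }, numeric(1))
    (1 + sum(null_llr >= model$llr)) / (1 + n_shuffles)
  })
}

#' Discover ungapped motifs by iterative ZOOPS-EM with masking
#'
#' Greedy discovery: each round fits ZOOPS-EM models from seeded starts
#' at every width in `seq(minw, maxw, by = width_step)`, keeps the model
#' with the best LLR per free parameter (`llr / (19 w)`), tests it
#' against an empirical shuffle null, and stops when the motif is not
#' significant or `nmotifs` have been accepted. Occurrences of each
#' accepted motif are masked (replaced by `X`, excluded from candidate
#' sites) before the next round. Motifs are numbered by discovery rank.
#'
#' The shuffle null is computed once per run on the input set: for each
#' shuffled dataset the same width-search is run and its best
#' width-normalised LLR recorded; each round's motif is then referred to
#' this null sample. Because later rounds search masked (signal-depleted)
#' data against a null built from the full data, the test is, if
#' anything, conservative for them. A motif whose empirical p sits at
#' the attainable floor `1/(1 + n_shuffles)` (no shuffled dataset
#' reached its score) is accepted even when `p_threshold` is below the
#' floor, since the floor is the strongest statement the empirical test
#' can make.
#'
#' @param records Protein sequence tibble (>= 2 records, all at least
#'   `maxw` long).
#' @param minw,maxw Motif width bounds (defaults 6 and 10).
#' @param nmotifs Maximum number of motifs (default 8).
#' @param p_threshold Significance threshold (default 1e-4).
#' @param seed Integer seed governing seed sampling and shuffles.
#' @param n_shuffles Shuffled datasets for the run's null (default 99).
#' @param width_step Step of the width grid (default 1).
#' @param n_starts,n_score,n_refine Seeding policy: up to `n_starts`
#'   distinct candidate seed subsequences (repeated words first), the
#'   top `n_score` scored by initial LLR, full EM from the top
#'   `n_refine`.
#' @param scan_threshold_frac Fraction of a motif's maximum attainable
#'   log-odds used as its masking/scanning threshold (default 0.6).
#' @return A `motif_set`: list with `models` (list of `motif_model`,
#'   each with `significance` filled in), `background`, `n_records`, and
#'   the parameters of the run. `tidy()` gives the motif table,
#'   `glance()` the run summary, [scan_motifs()] the occurrences.
#' @export
discover_motifs <- function(records, minw = 6, maxw = 10, nmotifs = 8,
                            p_threshold = 1e-4, seed = 1L,
                            n_shuffles = 99, width_step = 1,
                            n_starts = 200, n_score = 30, n_refine = 3,
                            scan_threshold_frac = 0.6) {
  if (nrow(records) < 2) abort("need at least 2 records")
  if (minw > maxw) abort("minw must be <= maxw")
  if (nmotifs < 1) abort("nmotifs must be >= 1")
  if (p_threshold <= 0 || p_threshold >= 1) abort("p_threshold must be in (0, 1)")
  short <- nchar(records$residues) < minw
  if (any(short)) {
    abort(paste0("records shorter than minw: ",
                 paste(records$id[short], collapse = ", ")))
  }
  widths <- seq(as.integer(minw), as.integer(maxw), by = as.integer(width_step))
  policy <- .default_policy(n_starts = n_starts, n_score = n_score,
                            n_refine = n_refine)
  withr::with_seed(seed, {
    work <- records
    enc <- .encode_set(work)
    b <- .background_freq(enc)
    null_scores <- vapply(seq_len(n_shuffles), function(s) {
      m <- .best_over_widths(.shuffle_enc(enc), b, widths, policy)
      if (is.null(m)) -Inf else m$score
    }, numeric(1))
    p_floor <- 1 / (1 + n_shuffles)
    accept_at <- max(p_threshold, p_floor)
    models <- list()
    repeat {
      if (length(models) >= nmotifs) break
      cand <- .best_over_widths(enc, b, widths, policy)
      if (is.null(cand)) break
      p <- (1 + sum(null_scores >= cand$score)) / (1 + n_shuffles)
      cand$significance <- p
      cand$policy <- policy
      if (p > accept_at) break
      cand$rank <- length(models) + 1L
      models[[cand$rank]] <- cand
      occ <- .scan_model(cand, work, scan_threshold_frac)
      work <- .mask_occurrences(work, occ, cand$width)
      enc <- .encode_set(work)
    }
    structure(list(
      models = models, background = b, n_records = nrow(records),
      params = list(minw = minw, maxw = maxw, nmotifs = nmotifs,
                    p_threshold = p_threshold, seed = seed,
                    n_shuffles = n_shuffles, width_step = width_step,
                    scan_threshold_frac = scan_threshold_frac),
      null_scores = null_scores
    ), class = "motif_set")
  })
}

#' @export
print.motif_set <- function(x, ...) {
  cat("<motif_set>", length(x$models), "motif(s) over", x$n_records,
      "records\n")
  if (length(x$models) > 0) print(tidy(x))
  invisible(x)
}

# Log-odds (bits) occurrence scan of one model against one record set;
# greedy non-overlapping selection by descending score.
.scan_model <- function(model, records, threshold_frac = 0.6,
                        threshold_bits = NULL) {
  w <- model$width
  lo <- log2(model$ppm) - rep(log2(model$background), each = w)
  max_bits <- sum(apply(lo, 1, max))
  thr <- threshold_bits %||% (threshold_frac * max_bits)
  rows <- map2(records$id, records$residues, function(id, res) {
    x <- encode_protein(res)
    if (length(x) < w) return(NULL)
    e <- embed(x, w)[, w:1, drop = FALSE]
    ok <- rowSums(is.na(e)) == 0
    if (!any(ok)) return(NULL)
    s <- .window_scores(e[ok, , drop = FALSE], lo)
    starts <- which(ok)[s >= thr]
    sc <- s[s >= thr]
    if (length(starts) == 0) return(NULL)
    keep <- logical(0)
    taken <- integer(0)
    for (j in order(sc, decreasing = TRUE)) {
      span <- starts[j]:(starts[j] + w - 1L)
      if (!any(span %in% taken)) {
        keep <- c(keep, j)
        taken <- c(taken, span)
      }
    }
    tibble(id = id, start = starts[keep] - 1L, score = sc[keep])
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(id = character(), start = integer(), score = double())
  }
  arrange(out, .data$id, .data$start)
}

.mask_occurrences <- function(records, occ, w) {
  for (r in seq_len(nrow(occ))) {
    i <- which(records$id == occ$id[r])
    res <- strsplit(records$residues[i], "", fixed = TRUE)[[1]]
    res[(occ$start[r] + 1L):(occ$start[r] + w)] <- "X"
    records$residues[i] <- paste(res, collapse = "")
  }
  records
}

#' Scan sequences for occurrences of a motif
#'
#' Scores every window by summed log-odds (position probabilities vs
#' background, in bits) and reports windows at or above the threshold,
#' greedily selected to be non-overlapping in descending score order.
#'
#' @param model A `motif_model`, or a `motif_set` (all motifs scanned).
#' @param records Protein sequence tibble.
#' @param threshold_frac Threshold as a fraction of the motif's maximum
#'   attainable score (default 0.6); ignored when `threshold_bits` is
#'   given.
#' @param threshold_bits Absolute threshold in bits.
#' @return Tibble with columns `motif` (discovery rank; 1 for a bare
#'   model), `id`, `start` (0-based), `score` (bits).
#' @export
scan_motifs <- function(model, records, threshold_frac = 0.6,
                        threshold_bits = NULL) {
  models <- if (inherits(model, "motif_set")) model$models else list(model)
  rows <- imap(models, function(m, k) {
    occ <- .scan_model(m, records, threshold_frac, threshold_bits)
    if (nrow(occ) == 0) return(NULL)
    mutate(occ, motif = m$rank %||% k, width = m$width, .before = 1)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(motif = integer(), width = integer(), id = character(),
                  start = integer(), score = double())
  }
  out
}

#' Write a motif set in MEME minimal motif format
#'
#' @param motifs A `motif_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", ""),
             con)
  bg <- sprintf("%s %.6f", names(motifs$background), motifs$background)
  writeLines(c("Background letter frequencies",
               paste(bg, collapse = " "), ""), con)
  for (k in seq_along(motifs$models)) {
    m <- motifs$models[[k]]
    writeLines(sprintf("MOTIF %d %s", k, m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 20 w= %d nsites= %.0f E= %g",
      m$width, max(1, round(m$n_sites)), m$significance
    ), con)
    apply(m$ppm, 1, function(row) {
      writeLines(paste(sprintf("%.6f", row), collapse = " "), con)
    })
    writeLines("", con)
  }
  invisible(path)
}
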