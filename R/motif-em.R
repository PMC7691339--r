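# ZOOPS (zero-or-one occurrence per sequence) expectation-maximization
# for one fixed-width ungapped motif. Internal representation: sequences
# integer-encoded over the 20-letter alphabet, with NA marking masked or
# unknown (X) positions; candidate site windows containing NA are
# excluded from the site set, which is how iterative masking removes
# already-discovered occurrences from later rounds.

.encode_set <- function(records) {
  lapply(records$residues, encode_protein)
}

# Window data for width w: W is an (n_windows x w) integer matrix of
# residue codes (NA-free rows only), seq_idx maps each row to its source
# sequence, m counts valid windows per sequence.
.window_data <- function(enc, w) {
  mats <- list(); idx <- list()
  for (i in seq_along(enc)) {
    x <- enc[[i]]
    L <- length(x)
    if (L < w) next
    e <- embed(x, w)[, w:1, drop = FALSE]
    ok <- rowSums(is.na(e)) == 0
    if (!any(ok)) next
    mats[[length(mats) + 1L]] <- e[ok, , drop = FALSE]
    idx[[length(idx) + 1L]] <- list(i = i, starts = which(ok))
  }
  if (length(mats) == 0) return(NULL)
  W <- do.call(rbind, mats)
  seq_idx <- unlist(lapply(idx, function(z) rep(z$i, length(z$starts))))
  starts <- unlist(lapply(idx, function(z) z$starts))
  tab <- tabulate(seq_idx, nbins = length(enc))
  # one-hot indicator of (position-in-window, letter) per window row:
  # window scores and site-weighted counts are then single sparse
  # matrix-vector products
  N <- nrow(W)
  S <- Matrix::sparseMatrix(
    i = rep(seq_len(N), w),
    j = as.vector((rep(seq_len(w), each = N) - 1L) * 20L + W),
    x = 1, dims = c(N, 20L * w)
  )
  G <- Matrix::sparseMatrix(i = seq_idx, j = seq_len(N), x = 1,
                            dims = c(length(enc), N))
  list(W = W, S = S, G = G, seq_idx = seq_idx, starts = starts, m = tab,
       present = which(tab > 0L), n_seq = length(enc))
}

# Background from unmasked residues, add-one smoothed.
.background_freq <- function(enc) {
  counts <- tabulate(unlist(enc), nbins = 20)
  b <- (counts + 1) / (sum(counts) + 20)
  setNames(b, AA_ALPHABET)
}

# Sum of per-position log terms for every window row: scores[j] =
# sum_k M[k, W[j, k]].
.window_scores <- function(W, M) {
  s <- numeric(nrow(W))
  for (k in seq_len(ncol(W))) s <- s + M[k, W[, k]]
  unname(s)
}

# Same, through the prebuilt sparse indicator.
.window_scores_sp <- function(wd, M) {
  as.vector(wd$S %*% as.vector(t(M)))
}

# Data log-likelihood ratio (vs background-only) and per-window site
# posteriors for given parameters. Fully vectorised: a single global
# max-shift keeps exp() in range for any width.
.zoops_estep <- function(wd, log_ratio, gamma) {
  s <- .window_scores_sp(wd, log_ratio)
  mx <- max(s)
  sexp <- exp(s - mx)
  present <- wd$present
  Sg <- as.vector(wd$G %*% sexp)[present]             # sum_j lr_ij, shifted
  m <- wd$m[present]
  logS <- mx + log(Sg)
  a1 <- log1p(-gamma)
  a2 <- log(gamma / m) + logS
  mab <- pmax(a1, a2)
  logden <- mab + log(exp(a1 - mab) + exp(a2 - mab))  # per-sequence denom
  q <- numeric(wd$n_seq)
  q[present] <- exp(a2 - logden)
  full <- numeric(wd$n_seq)
  full[present] <- log(gamma / m) - logden
  z <- exp(full[wd$seq_idx] + s)
  list(llr = sum(logden), z = z, q = q)
}

.zoops_mstep <- function(wd, z, b, pseudo_frac = 0.01) {
  w <- ncol(wd$W)
  cf <- as.vector(Matrix::crossprod(wd$S, z))     # (position, letter) counts
  theta <- t(matrix(cf, nrow = 20)) + rep(pseudo_frac * b, each = w)
  dimnames(theta) <- list(NULL, AA_ALPHABET)
  theta / rowSums(theta)
}

.theta_from_seed <- function(codes, conf = 0.5) {
  w <- length(codes)
  theta <- matrix((1 - conf) / 19, nrow = w, ncol = 20,
                  dimnames = list(NULL, AA_ALPHABET))
  theta[cbind(seq_len(w), codes)] <- conf
  theta
}

.consensus_string <- function(ppm) {
  paste(AA_ALPHABET[apply(ppm, 1, which.max)], collapse = "")
}

.new_motif_model <- function(ppm, background, gamma, n_sites, llr,
                             converged, iterations, llr_trace,
                             policy = NULL) {
  structure(list(
    width = nrow(ppm), ppm = ppm, background = background, gamma = gamma,
    n_sites = n_sites, llr = llr, converged = converged,
    iterations = iterations, llr_trace = llr_trace,
    consensus = .consensus_string(ppm), significance = NA_real_,
    policy = policy
  ), class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> width", x$width, "consensus", x$consensus, "\n",
      sprintf(" llr = %.2f nats, n_sites = %.1f, gamma = %.3f%s\n",
              x$llr, x$n_sites, x$gamma,
              if (!x$converged) " (not converged)" else ""))
  if (!is.na(x$significance)) cat("  p =", format(x$significance), "\n")
  invisible(x)
}

# Core EM loop on prepared window data.
.em_run <- function(wd, theta0, gamma0, b, pseudo_frac = 0.01,
                    tol = 1e-6, max_iter = 500) {
  logb <- log(b)
  theta <- theta0
  gamma <- gamma0
  llr_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    lr <- log(theta) - rep(logb, each = nrow(theta))
    e <- .zoops_estep(wd, lr, gamma)
    trace[it] <- e$llr
    if (is.finite(llr_prev) &&
        abs(e$llr - llr_prev) <= tol * (abs(llr_prev) + 1)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    llr_prev <- e$llr
    theta <- .zoops_mstep(wd, e$z, b, pseudo_frac)
    gamma <- min(max(mean(e$q[wd$present]), 1e-6), 1 - 1e-6)
  }
  .new_motif_model(theta, b, gamma, n_sites = sum(e$q), llr = e$llr,
                   converged = converged, iterations = it,
                   llr_trace = trace)
}

#' Fit one ZOOPS motif model by expectation-maximization
#'
#' Zero-or-one-occurrence-per-sequence EM for an ungapped fixed-width
#' motif: each sequence contributes at most one site, with a fitted
#' per-sequence site probability. Iterates until the relative
#' log-likelihood-ratio improvement drops below `tol` or `max_iter`
#' is reached (the model is then returned with `converged = FALSE`,
#' not an error).
#'
#' @param records Protein sequence tibble. `X` residues are treated as
#'   masked and excluded from candidate sites.
#' @param w Motif width.
#' @param start_point A width-`w` seed subsequence string, or a
#'   `w x 20` starting probability matrix.
#' @param pseudo_frac Pseudocount per cell, as a fraction of the
#'   background frequency (default 0.01).
#' @param tol Relative LLR convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @return A `motif_model`: `ppm` (position probability matrix, rows sum
#'   to 1), `background`, `gamma` (site prior), `n_sites` (expected site
#'   count), `llr` (nats, vs the background-only model), `llr_trace`,
#'   `consensus`, convergence flags.
#' @export
em_zoops <- function(records, w, start_point, pseudo_frac = 0.01,
                     tol = 1e-6, max_iter = 500) {
  enc <- .encode_set(records)
  short <- nchar(records$residues) < w
  if (any(short)) {
    abort(paste0("records shorter than width ", w, ": ",
                 paste(records$id[short], collapse = ", ")))
  }
  wd <- .window_data(enc, w)
  if (is.null(wd)) abort("no unmasked windows available")
  b <- .background_freq(enc)
  if (is.character(start_point)) {
    codes <- encode_protein(start_point)
    if (length(codes) != w || anyNA(codes)) {
      abort("start_point string must be a width-w sequence over the amino-acid alphabet")
    }
    theta0 <- .theta_from_seed(codes)
  } else {
    theta0 <- as.matrix(start_point)
    stopifnot(nrow(theta0) == w, ncol(theta0) == 20)
    colnames(theta0) <- AA_ALPHABET
  }
  .em_run(wd, theta0, 0.5, b, pseudo_frac, tol, max_iter)
}
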