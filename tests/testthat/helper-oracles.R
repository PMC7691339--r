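# Independent brute-force oracles. These deliberately share no code with
# the implementation: combination enumeration for scaffold matching,
# codon-by-codon interval enumeration for ORFs, direct window means for
# hydropathy.

# Every anchor-position tuple satisfying a scaffold pattern, by filtering
# all combinations of anchor-residue positions.
oracle_match_scaffold <- function(residues, pattern) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  a <- pattern$anchors
  k <- nrow(a)
  pos_sets <- lapply(a$residue, function(r) which(chars == r))
  if (any(lengths(pos_sets) == 0)) return(list())
  combos <- expand.grid(pos_sets, KEEP.OUT.ATTRS = FALSE)
  keep <- rep(TRUE, nrow(combos))
  for (j in 2:k) {
    gap <- combos[[j]] - combos[[j - 1]] - 1L
    keep <- keep & gap >= a$gap_min[j] & gap <= a$gap_max[j]
  }
  combos <- combos[keep, , drop = FALSE]
  if (nrow(combos) == 0) return(list())
  res <- lapply(seq_len(nrow(combos)), function(i) {
    as.integer(unlist(combos[i, ])) - 1L
  })
  # lexicographic order of position tuples
  ord <- do.call(order, as.data.frame(do.call(rbind, res)))
  res[ord]
}

oracle_translate <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  if (is.null(aa) || is.na(aa)) "X" else aa
}

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# All stop-to-stop ORFs on both strands: walk each frame codon by codon,
# cut at stops, keep stretches of >= min_len translatable codons.
oracle_orfs <- function(seqstr, min_len, require_start = FALSE) {
  res <- list()
  L <- nchar(seqstr)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seqstr else oracle_revcomp(seqstr)
    for (off in 0:2) {
      i <- off + 1
      run <- list()
      flush <- function(run, ended_by_stop) {
        if (length(run) == 0) return(invisible())
        aa <- vapply(run, function(r) r$aa, character(1))
        starts <- vapply(run, function(r) r$start, numeric(1))
        if (require_start) {
          m <- which(vapply(run, function(r) r$codon == "ATG", logical(1)))
          if (length(m) == 0) return(invisible())
          aa <- aa[m[1]:length(aa)]
          starts <- starts[m[1]:length(starts)]
        }
        if (length(aa) < min_len) return(invisible())
        s0 <- starts[1] - 1
        e0 <- starts[length(starts)] + 2 + if (ended_by_stop) 3 else 0
        if (strand == "-") {
          tmp <- L - e0
          e0 <- L - s0
          s0 <- tmp
        }
        res[[length(res) + 1]] <<- list(
          frame = if (strand == "+") off + 1L else -(off + 1L),
          nt_start = as.integer(s0), nt_end = as.integer(e0),
          protein = paste(aa, collapse = ""),
          has_stop = ended_by_stop
        )
      }
      while (i + 2 <= nchar(s)) {
        codon <- substr(s, i, i + 2)
        aa <- oracle_translate(codon)
        if (aa == "*") {
          flush(run, TRUE)
          run <- list()
        } else {
          run[[length(run) + 1]] <- list(aa = aa, start = i, codon = codon)
        }
        i <- i + 3
      }
      flush(run, FALSE)
    }
  }
  res
}

oracle_hydropathy <- function(residues, window) {
  kd <- cysmotif::KYTE_DOOLITTLE
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(ch)
  vapply(seq_len(n - window + 1), function(i) {
    v <- kd[ch[i:(i + window - 1)]]
    v[is.na(v)] <- 0
    mean(v)
  }, numeric(1))
}

# Random protein sequence with controlled cysteine frequency.
random_protein <- function(len, cys_freq = 0.1) {
  others <- setdiff(cysmotif::AA_ALPHABET, "C")
  p <- c(cys_freq, rep((1 - cys_freq) / 19, 19))
  paste(sample(c("C", others), len, replace = TRUE, prob = p),
        collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# A bare motif_model carrying an (almost) deterministic consensus PPM,
# for scanning planted sites without running EM.
consensus_model <- function(consensus, conf = 0.9) {
  codes <- match(strsplit(consensus, "", fixed = TRUE)[[1]],
                 cysmotif::AA_ALPHABET)
  w <- length(codes)
  ppm <- matrix((1 - conf) / 19, nrow = w, ncol = 20,
                dimnames = list(NULL, cysmotif::AA_ALPHABET))
  ppm[cbind(seq_len(w), codes)] <- conf
  structure(list(width = w, ppm = ppm,
                 background = setNames(rep(0.05, 20), cysmotif::AA_ALPHABET),
                 consensus = consensus, rank = 1L),
            class = "motif_model")
}
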