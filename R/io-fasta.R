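# FASTA input/output. Parsing is delegated to Biostrings; validation of
# IDs and residues against the declared alphabet is done here so that
# errors name the offending record and position.

#' Read a FASTA file into a sequence tibble
#'
#' The ID is the header token up to the first whitespace; the remainder of
#' the header line becomes the description. Residues are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`. Residues outside the declared
#'   alphabet (beyond `X` for protein, `N` for DNA) are an error.
#' @return A tibble with columns `id`, `residues`, `description`, one row
#'   per record, in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "MKC"), tf)
#' read_fasta(tf)
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (file.size(path) == 0) abort(paste0("empty FASTA file: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no FASTA records in: ", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  new_seqset(ids, seqs, desc, alphabet = alphabet)
}

#' Construct a validated sequence tibble
#'
#' @param id Character vector of unique, non-empty record IDs.
#' @param residues Character vector of sequences (upper-cased on input).
#' @param description Optional character vector of free-text descriptions.
#' @param alphabet `"protein"` or `"dna"`.
#' @return A tibble with columns `id`, `residues`, `description`.
#' @export
new_seqset <- function(id, residues, description = "",
                       alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  residues <- toupper(residues)
  if (any(!nzchar(id))) abort("sequence IDs must be non-empty")
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence ID(s): ", paste(dup, collapse = ", ")))
  }
  if (any(!nzchar(residues))) {
    abort(paste0("empty sequence for ID(s): ",
                 paste(id[!nzchar(residues)], collapse = ", ")))
  }
  bad <- regexpr(.alphabet_regex[[alphabet]], residues)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf(
      "illegal %s residue '%s' in record '%s' at position %d",
      alphabet, substr(residues[i], bad[i], bad[i]), id[i], bad[i]
    ))
  }
  tibble(id = as.character(id), residues = residues,
         description = rep_len(as.character(description), length(id)))
}

#' Write a sequence tibble to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, path))` returns
#' `x` for any valid sequence set.
#'
#' @param seqs Tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for residues (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(width >= 1)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) abort(paste0("cannot write: ", path)))
  on.exit(close(con))
  if (nrow(seqs) == 0) return(invisible(path))
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  desc <- rep_len(desc, nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    header <- if (nzchar(desc[i])) paste(seqs$id[i], desc[i]) else seqs$id[i]
    body <- gsub(sprintf("(.{%d})", width), "\\1\n", seqs$residues[i])
    writeLines(c(paste0(">", header), sub("\n$", "", body)), con)
  }
  invisible(path)
}
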