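# Newick tree input with the validation the pipeline needs: leaf labels
# must be unique (they are joined against sequence IDs downstream) and a
# malformed file should fail with the offset of the imbalance, not deep
# inside ape.

#' Read a single-tree newick file
#'
#' @param path Path to a newick file containing one tree.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      abort(sprintf("newick parse error: unmatched ')' at offset %d", i))
    }
  }
  if (depth > 0L) {
    abort(sprintf(
      "newick parse error: %d unclosed '(' at end of input (length %d)",
      depth, length(chars)
    ))
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) abort(paste0("newick parse error in: ", path))
  if (inherits(tree, "multiPhylo")) {
    abort(paste0("expected a single tree, found ", length(tree), ": ", path))
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    abort(paste0("duplicate leaf label(s): ", paste(dup, collapse = ", ")))
  }
  tree
}
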