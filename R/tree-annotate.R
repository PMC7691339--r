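# Placing motif-pattern assignments on a phylogenetic tree: per-leaf
# colorstrip annotations (iTOL DATASET_COLORSTRIP format) and a
# clade-homogeneity summary quantifying how well patterns track clades.

.pattern_palette <- c(
  "#e6194b", "#3cb44b", "#ffe119", "#4363d8", "#f58231", "#911eb4",
  "#46f0f0", "#f032e6", "#bcf60c", "#fabebe", "#008080", "#e6beff",
  "#9a6324", "#fffac8", "#800000", "#aaffc3"
)

#' Deterministic pattern-to-color mapping
#'
#' Colors are assigned by pattern rank from a fixed palette; beyond the
#' palette size the assignment wraps (with a warning), keeping output
#' diffable across runs.
#'
#' @param patterns Character vector of pattern ids in rank order.
#' @return Named character vector of hex colors.
#' @export
pattern_colors <- function(patterns) {
  if (length(patterns) > length(.pattern_palette)) {
    warn(sprintf("more patterns (%d) than palette colors (%d); colors wrap",
                 length(patterns), length(.pattern_palette)))
  }
  idx <- (seq_along(patterns) - 1L) %% length(.pattern_palette) + 1L
  setNames(.pattern_palette[idx], patterns)
}

#' Annotate tree leaves with motif patterns
#'
#' Joins pattern-group membership onto the leaves of a tree. Leaves not
#' covered by any pattern group produce a warning and are omitted from
#' the annotation (the tree itself is untouched).
#'
#' @param tree A `phylo` object (see [read_newick()]).
#' @param pattern_groups Tibble from [group_patterns()] (columns
#'   `pattern`, `members`).
#' @return Tibble with columns `leaf`, `pattern`, `color`, one row per
#'   covered leaf.
#' @export
annotate_leaves <- function(tree, pattern_groups) {
  membership <- pattern_groups |>
    select("pattern", "members") |>
    tidyr::unnest_longer("members", values_to = "leaf")
  colors <- pattern_colors(pattern_groups$pattern)
  ann <- tibble(leaf = tree$tip.label) |>
    left_join(membership, by = "leaf")
  missing <- ann$leaf[is.na(ann$pattern)]
  if (length(missing) > 0) {
    warn(paste0("leaves without a pattern assignment: ",
                paste(missing, collapse = ", ")))
  }
  ann |>
    filter(!is.na(.data$pattern)) |>
    mutate(color = unname(colors[.data$pattern])) |>
    select("leaf", "pattern", "color")
}

#' Write leaf annotations as an iTOL colorstrip dataset
#'
#' Emits a `DATASET_COLORSTRIP` text block consumable by iTOL;
#' [read_itol_colorstrip()] round-trips it.
#'
#' @param annotations Tibble from [annotate_leaves()].
#' @param path Output path.
#' @param dataset_label Dataset label shown in iTOL (default
#'   `"motif patterns"`).
#' @return `path`, invisibly.
#' @export
write_itol_colorstrip <- function(annotations, path,
                                  dataset_label = "motif patterns") {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "DATASET_COLORSTRIP",
    "SEPARATOR TAB",
    paste0("DATASET_LABEL\t", dataset_label),
    "COLOR\t#888888",
    "DATA"
  ), con)
  writeLines(paste(annotations$leaf, annotations$color, annotations$pattern,
                   sep = "\t"), con)
  invisible(path)
}

#' Read back an iTOL colorstrip dataset written by this package
#'
#' @param path Path to a file from [write_itol_colorstrip()].
#' @return Tibble with columns `leaf`, `pattern`, `color`.
#' @export
read_itol_colorstrip <- function(path) {
  lines <- readLines(path)
  start <- match("DATA", lines)
  if (is.na(start)) abort("no DATA section found")
  body <- lines[-seq_len(start)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(tibble(leaf = character(), pattern = character(),
                  color = character()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  tibble(
    leaf = map_chr(parts, 1),
    pattern = map_chr(parts, 3),
    color = map_chr(parts, 2)
  )
}

#' Clade homogeneity of pattern annotations
#'
#' For every internal node with at least two annotated descendant
#' leaves, reports the majority pattern and its fraction of the node's
#' annotated leaves. The root's homogeneity equals the global
#' majority-pattern fraction; values near 1 throughout indicate that
#' motif patterns track clades.
#'
#' @param tree A `phylo` object.
#' @param annotations Tibble from [annotate_leaves()].
#' @return Tibble with columns `node` (ape node number), `n_leaves`
#'   (annotated leaves under the node), `majority_pattern`,
#'   `homogeneity`.
#' @export
clade_homogeneity <- function(tree, annotations) {
  ntip <- length(tree$tip.label)
  pat <- setNames(annotations$pattern, annotations$leaf)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  desc <- phangorn::Descendants(tree, nodes, type = "tips")
  rows <- map2(nodes, desc, function(node, tips) {
    labs <- tree$tip.label[tips]
    p <- pat[labs]
    p <- p[!is.na(p)]
    if (length(p) < 2) return(NULL)
    tab <- sort(table(p), decreasing = TRUE)
    tibble(node = node, n_leaves = length(p),
           majority_pattern = names(tab)[1],
           homogeneity = as.numeric(tab[1]) / length(p))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(node = integer(), n_leaves = integer(),
                  majority_pattern = character(), homogeneity = double())
  }
  out
}
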