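# broom-style tidiers and ggplot2 plot methods for the fitted objects.

#' Tidy a discovered motif set
#'
#' @param x A `motif_set` from [discover_motifs()].
#' @param ... Unused.
#' @return One row per motif: `motif` (rank), `width`, `consensus`,
#'   `n_sites`, `llr`, `p_value`, `converged`.
#' @method tidy motif_set
#' @export
tidy.motif_set <- function(x, ...) {
  if (length(x$models) == 0) {
    return(tibble(motif = integer(), width = integer(),
                  consensus = character(), n_sites = double(),
                  llr = double(), p_value = double(),
                  converged = logical()))
  }
  tibble(
    motif = map_int(x$models, function(m) as.integer(m$rank)),
    width = map_int(x$models, function(m) as.integer(m$width)),
    consensus = map_chr(x$models, "consensus"),
    n_sites = map_dbl(x$models, "n_sites"),
    llr = map_dbl(x$models, "llr"),
    p_value = map_dbl(x$models, "significance"),
    converged = map_dbl(x$models, "converged") > 0
  )
}

#' Summarise a motif discovery run
#'
#' @param x A `motif_set`.
#' @param ... Unused.
#' @return A one-row tibble: `n_motifs`, `n_records`, `minw`, `maxw`,
#'   `p_threshold`, `n_shuffles`, `seed`.
#' @method glance motif_set
#' @export
glance.motif_set <- function(x, ...) {
  tibble(
    n_motifs = length(x$models), n_records = x$n_records,
    minw = x$params$minw, maxw = x$params$maxw,
    p_threshold = x$params$p_threshold,
    n_shuffles = x$params$n_shuffles, seed = x$params$seed
  )
}

# Per-column information content (bits) of a position probability matrix.
.ppm_ic <- function(ppm) {
  apply(ppm, 1, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
}

#' Information-content logo plot of discovered motifs
#'
#' A simple sequence-logo-style panel per motif: letters at each column
#' scaled by their share of the column's information content.
#'
#' @param object A `motif_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motif_set
#' @export
autoplot.motif_set <- function(object, ...) {
  df <- bind_rows(imap(object$models, function(m, k) {
    ic <- .ppm_ic(m$ppm)
    bind_rows(lapply(seq_len(m$width), function(pos) {
      p <- m$ppm[pos, ]
      top <- sort(p, decreasing = TRUE)[1:3]
      h <- ic[pos] * top / sum(top)
      tibble(motif = paste0("motif ", m$rank %||% k), position = pos,
             letter = names(top), height = as.numeric(h),
             y = cumsum(as.numeric(h)) - as.numeric(h) / 2)
    }))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$y)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter,
                                    size = .data$height),
                       show.legend = FALSE) +
    ggplot2::facet_wrap(~motif, scales = "free_x") +
    ggplot2::scale_size_continuous(range = c(1, 6)) +
    ggplot2::labs(x = "position", y = "information (bits, stacked)") +
    ggplot2::theme_minimal()
}

#' Motif-pattern map of a sequence set
#'
#' Draws each sequence as a horizontal line with its motif occurrences
#' as numbered boxes, ordered by pattern group — the classical
#' motif-location figure for a protein family.
#'
#' @param records Sequence tibble.
#' @param occurrences Tibble from [scan_motifs()].
#' @return A ggplot object.
#' @export
plot_motif_map <- function(records, occurrences) {
  lens <- tibble(id = records$id, len = nchar(records$residues)) |>
    mutate(y = dplyr::row_number())
  occ <- occurrences |>
    left_join(lens, by = "id")
  if (!"width" %in% names(occ)) occ$width <- 8L
  ggplot2::ggplot(lens) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$len,
                                       y = .data$y, yend = .data$y),
                          color = "grey70") +
    ggplot2::geom_rect(
      data = occ,
      ggplot2::aes(xmin = .data$start, xmax = .data$start + .data$width,
                   ymin = .data$y - 0.35, ymax = .data$y + 0.35,
                   fill = factor(.data$motif))
    ) +
    ggplot2::geom_text(
      data = occ,
      ggplot2::aes(x = .data$start + .data$width / 2, y = .data$y,
                   label = .data$motif), size = 2.5
    ) +
    ggplot2::scale_y_continuous(breaks = lens$y, labels = lens$id) +
    ggplot2::labs(x = "residue position", y = NULL, fill = "motif") +
    ggplot2::theme_minimal()
}

#' Hydropathy profile plot
#'
#' @param records Sequence tibble.
#' @param window,threshold See [hydropathy_profile()].
#' @return A ggplot object with one panel per sequence and the
#'   transmembrane threshold as a dashed line.
#' @export
plot_hydropathy <- function(records, window = 19, threshold = 1.6) {
  df <- bind_rows(map2(records$id, records$residues, function(id, res) {
    prof <- hydropathy_profile(res, window)
    tibble(id = id, position = seq_along(prof) - 1L, hydropathy = prof)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$hydropathy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~id) +
    ggplot2::labs(x = "window start (0-based)",
                  y = "mean Kyte-Doolittle hydropathy") +
    ggplot2::theme_minimal()
}
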