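#' Genome-wide coordinates for a Manhattan plot of window shares
#'
#' Lays the chromosomes end to end and places each window at its midpoint on
#' the cumulative axis. This table is also the plot's test surface: the
#' shares column sums to 1.
#'
#' @param windows A [window_variance()] table.
#' @return Tibble `window_id`, `chromosome`, `midpoint_bp`, `cumulative_bp`,
#'   `variance_share`.
#' @export
manhattan_table <- function(windows) {
  stopifnot(is.data.frame(windows), nrow(windows) > 0)
  chrs <- unique(windows$chromosome)
  span <- vapply(chrs, function(ch) max(windows$stop_bp[windows$chromosome == ch]),
                 numeric(1))
  offset <- setNames(c(0, cumsum(as.numeric(span)))[seq_along(chrs)], chrs)
  mid <- (windows$start_bp + windows$stop_bp) / 2
  tibble::tibble(window_id = windows$window_id,
                 chromosome = windows$chromosome,
                 midpoint_bp = mid,
                 cumulative_bp = mid + offset[windows$chromosome],
                 variance_share = windows$variance_share)
}

#' Manhattan plot of the variance share per SNP window
#'
#' One point per window at its cumulative genome position, with alternating
#' chromosome shading; the y axis is the proportion of genetic variance
#' absorbed by the window (all windows sum to 1).
#'
#' @param windows A [window_variance()] table.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(windows) {
  mt <- manhattan_table(windows)
  chrs <- unique(mt$chromosome)
  mt$shade <- factor(match(mt$chromosome, chrs) %% 2)
  breaks <- vapply(split(mt$cumulative_bp, factor(mt$chromosome, levels = chrs)),
                   function(x) mean(range(x)), numeric(1))
  ggplot2::ggplot(mt, ggplot2::aes(x = .data$cumulative_bp,
                                   y = .data$variance_share,
                                   colour = .data$shade)) +
    ggplot2::geom_point(size = 0.9, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue4")) +
    ggplot2::scale_x_continuous(breaks = unname(breaks), labels = chrs) +
    ggplot2::labs(x = "chromosome",
                  y = "proportion of genetic variance per window") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank())
}

#' Render the Manhattan plot and its TSV twin
#'
#' @param windows A [window_variance()] table.
#' @param prefix Output prefix: writes `<prefix>.tsv` and (when a graphics
#'   device is available) `<prefix>.png`.
#' @return The manhattan table, invisibly.
#' @export
render_manhattan <- function(windows, prefix) {
  mt <- manhattan_table(windows)
  utils::write.table(as.data.frame(mt), paste0(prefix, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ok <- tryCatch({
    ggplot2::ggsave(paste0(prefix, ".png"), plot_manhattan(windows),
                    width = 9, height = 3.2, dpi = 150)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) warn("PNG device unavailable; wrote the TSV twin only")
  invisible(mt)
}
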