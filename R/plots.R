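#' Bar chart of arm-selection categories
#'
#' Shows the fraction of pre-miRNAs in each of the five arm-selection
#' categories.
#'
#' @param premirnas Arm-profiled pre-miRNA tibble (from [arm_profile()]).
#' @return A ggplot object.
#' @export
plot_arm_categories <- function(premirnas) {
  lvls <- c("5P_only", "3P_only", "5P_dominant", "3P_dominant", "equal")
  d <- dplyr::count(dplyr::filter(premirnas,
                                  .data$arm_category %in% lvls),
                    .data$arm_category)
  d$frac <- d$n / sum(d$n)
  d$arm_category <- factor(d$arm_category, levels = lvls)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$arm_category, y = .data$frac)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "arm-selection category",
                  y = "fraction of pre-miRNAs") +
    ggplot2::theme_minimal()
}

#' Box plot of expression by conservation quarter
#'
#' The quartile box plot of log10 expression with adjacent-pair Welch t-test
#' p-values in the subtitle.
#'
#' @param object A `conservation_expression` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_expression <- function(object, ...) {
  d <- object$data
  subtitle <- paste(sprintf("%s: p=%.3g", object$tests$pair,
                            object$tests$p_value), collapse = "   ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$quartile,
                                  y = .data$log_expression)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = "conservation quarter (ascending conservation level)",
                  y = "log10 expression level", subtitle = subtitle) +
    ggplot2::theme_minimal()
}

#' IsomiR stack plot of one pre-miRNA
#'
#' Draws the precursor span, its terminal loop when known, and every isomiR
#' as a segment scaled by copy number -- the per-candidate view of read
#' stacks on the two hairpin arms.
#'
#' @param premirnas Pre-miRNA tibble.
#' @param id `premirna_id` (or annotated `mirna_id`) to draw.
#' @return A ggplot object.
#' @export
plot_isomir_stack <- function(premirnas, id) {
  row <- premirnas[premirnas$premirna_id == id |
                     (!is.null(premirnas$mirna_id) &
                        premirnas$mirna_id == id), , drop = FALSE]
  if (nrow(row) == 0) abort(paste0("no pre-miRNA with id ", id))
  row <- row[1, ]
  iso <- row$isomirs[[1]]
  iso$y <- seq_len(nrow(iso))
  ggplot2::ggplot(iso) +
    ggplot2::annotate("rect", xmin = row$start, xmax = row$end,
                      ymin = 0.2, ymax = 0.5, fill = "grey80") +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start, xend = .data$end, y = .data$y, yend = .data$y,
      linewidth = .data$copy_number, color = .data$arm
    )) +
    ggplot2::scale_linewidth(range = c(0.5, 3)) +
    ggplot2::labs(title = paste0(row$premirna_id, " (", row$strand,
                                 " strand)"),
                  x = paste0(row$chrom, " position"), y = "isomiR") +
    ggplot2::theme_minimal()
}
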