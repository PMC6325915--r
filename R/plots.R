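#' Boxplot of RXE values by gene subgroup
#'
#' Distribution of per-sample RXE within each subgroup, with reference lines
#' at 0 (complete compensation) and -1 (no compensation).
#'
#' @param rxe_tbl Result of [compute_rxe()].
#' @return A ggplot object.
#' @export
plot_rxe_subgroups <- function(rxe_tbl) {
  ggplot2::ggplot(rxe_tbl, ggplot2::aes(x = .data$subgroup, y = .data$rxe)) +
    ggplot2::geom_boxplot(outlier.shape = NA, coef = 1.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "red") +
    ggplot2::geom_hline(yintercept = -1, linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = NULL, y = "RXE (log2 X:A mean TPM)")
}

#' Chromosome-level expression with RXE overlaid
#'
#' Per-autosome RGE distributions as boxplots with per-sample RXE drawn as
#' red points — the display used to judge whether X expression falls within
#' the autosomal band.
#'
#' @param rge_tbl Result of [compute_rge()].
#' @param rxe_tbl Optional result of [compute_rxe()] (a single subgroup) to
#'   overlay.
#' @return A ggplot object.
#' @export
plot_chromosome_expression <- function(rge_tbl, rxe_tbl = NULL) {
  rge_tbl$chromosome <- factor(
    rge_tbl$chromosome,
    levels = unique(rge_tbl$chromosome)
  )
  p <- ggplot2::ggplot(rge_tbl, ggplot2::aes(x = .data$chromosome, y = .data$rge)) +
    ggplot2::geom_boxplot(coef = 1.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "red") +
    ggplot2::labs(x = "autosome", y = "RGE (log2 vs other autosomes)")
  if (!is.null(rxe_tbl)) {
    p <- p + ggplot2::geom_point(
      data = mutate(rxe_tbl, chromosome = "X"),
      ggplot2::aes(x = .data$chromosome, y = .data$rxe),
      colour = "red", alpha = 0.7
    )
  }
  p
}
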