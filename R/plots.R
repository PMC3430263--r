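#' Plot a pocket set as a 2-D projection
#'
#' Projects pocket grid points (coloured by pocket id) and, optionally,
#' the protein atoms (grey) onto a coordinate plane. A quick visual check
#' that detected pockets sit where expected.
#'
#' @param object A `pocket_set` tibble.
#' @param structure Optional atom tibble drawn underneath.
#' @param plane Projection plane: `"xy"`, `"xz"` or `"yz"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pocket_set <- function(object, structure = NULL, plane = "xy", ...) {
  ax <- strsplit(match.arg(plane, c("xy", "xz", "yz")), "")[[1]]
  pts <- purrr::map2_dfr(object$grid_pts, object$pocket_id, function(m, id) {
    tibble::tibble(a = m[, ax[1]], b = m[, ax[2]],
                   pocket = factor(id))
  })
  p <- ggplot2::ggplot()
  if (!is.null(structure)) {
    poly <- polymer_atoms(structure)
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(a = poly[[ax[1]]], b = poly[[ax[2]]]),
      ggplot2::aes(x = .data$a, y = .data$b),
      colour = "grey80", size = 0.5
    )
  }
  p +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$a, y = .data$b,
                                     colour = .data$pocket),
                        size = 0.8, alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(ax[1], " (Å)"), y = paste0(ax[2], " (Å)"),
                  colour = "pocket") +
    ggplot2::theme_minimal()
}

#' Plot the Cross-Entropy optimisation trace
#'
#' Best objective value seen up to each stage; flat tails show the stall
#' phase that triggers convergence.
#'
#' @param object A `rank_aggregation` fit from [ce_aggregate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_aggregation <- function(object, ...) {
  df <- tibble::tibble(stage = seq_along(object$trace), phi = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$phi)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "CE stage", y = expression(Phi(delta))) +
    ggplot2::theme_minimal()
}

#' Bar chart of TOP-n success rates per ranking method
#'
#' @param summary Summary tibble from a `pipeline_report`
#'   (columns `method`, `top1`, `top3`).
#' @return A ggplot object.
#' @export
plot_success_rates <- function(summary) {
  df <- tidyr::pivot_longer(summary, c("top1", "top3"),
                            names_to = "depth", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$rate,
                                   fill = .data$depth)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "success rate", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
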