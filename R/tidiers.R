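#' @title Broom-style tidiers and plots
#' @name tidiers
#' @description
#' `tidy()` on an `fr_result` returns the long fragment-peak match table;
#' `glance()` a one-row run summary. `autoplot()` methods draw a peak-stem
#' spectrum (optionally annotated with matched fragment formulas) and a
#' ranked score plot with tied-rank clusters.
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @param x an `fr_result` from [rank_candidates()].
#' @param ... unused.
#' @return `tidy()`: tibble with one row per matched fragment-peak pair
#'   across candidates.
#' @method tidy fr_result
#' @export
tidy.fr_result <- function(x, ...) {
  dplyr::bind_rows(attr(x, "matches"), .id = "candidate_id")
}

#' @rdname tidiers
#' @return `glance()`: one-row tibble with candidate, peak, cluster counts
#'   and the best candidate's statistics.
#' @method glance fr_result
#' @export
glance.fr_result <- function(x, ...) {
  spec <- attr(x, "spectrum")
  tibble::tibble(
    n_candidates = nrow(x),
    n_peaks = if (!is.null(spec)) nrow(spec) else NA_integer_,
    n_clusters = length(unique(x$cluster)),
    top_score = max(x$score),
    n_tied_top = sum(x$score == max(x$score)),
    top_explained = x$n_peaks_explained[which.max(x$score)],
    mean_ppv = mean(ppv(x$n_matched_fragments, x$n_fragments))
  )
}

#' @rdname tidiers
#' @param object an `fr_spectrum` or `fr_result`.
#' @method autoplot fr_spectrum
#' @export
autoplot.fr_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
    ggplot2::labs(x = "m/z (Th)", y = "intensity",
                  title = paste0(attr(object, "ion_mode"),
                                 "-mode spectrum")) +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @param highlight optional candidate id drawn in a distinct colour
#'   (e.g. the known correct solution).
#' @method autoplot fr_result
#' @export
autoplot.fr_result <- function(object, highlight = NULL, ...) {
  df <- tibble::as_tibble(object)
  df$position <- seq_len(nrow(df))
  df$is_target <- !is.null(highlight) & df$id %in% highlight
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$cluster),
                                     shape = .data$is_target), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                guide = "none") +
    ggplot2::labs(x = "candidate (score order)", y = "score",
                  colour = "tied-rank cluster") +
    ggplot2::theme_minimal()
}
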