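#' 1-D intensity scatter for one channel page
#'
#' Droplet index against mean intensity, coloured by call, with the channel
#' threshold drawn when available — the standard dPCR 1-D scatter view.
#'
#' @param calls A `call_matrix` from [call_droplets()] (or any tibble with
#'   the page's `mean_`/`call_` columns).
#' @param channel Channel label.
#' @param temperature Temperature; default the lowest present.
#' @return A ggplot.
#' @export
plot_scatter_1d <- function(calls, channel, temperature = NULL) {
  temperature <- temperature %||% lowest_temp(calls, channel)
  mcol <- page_key(channel, temperature, "mean")
  ccol <- page_key(channel, temperature, "call")
  df <- tibble::tibble(index = seq_len(nrow(calls)),
                       intensity = calls[[mcol]],
                       call = if (ccol %in% names(calls)) calls[[ccol]] else FALSE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$intensity,
                                        colour = .data$call)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "#1f77b4")) +
    ggplot2::labs(x = "droplet", y = sprintf("%s @ %s degC (ADU)", channel, temperature),
                  colour = "positive") +
    ggplot2::theme_minimal()
  thr <- attr(calls, "thresholds")
  if (!is.null(thr) && channel %in% thr$channel) {
    p <- p + ggplot2::geom_hline(yintercept = thr$value[thr$channel == channel],
                                 linetype = 2, colour = "red3")
  }
  p
}

#' 2-D intensity scatter for a channel pair
#'
#' @param calls A `call_matrix`.
#' @param channel_x,channel_y Channel labels.
#' @param temperature Temperature; default the lowest present.
#' @return A ggplot.
#' @export
plot_scatter_2d <- function(calls, channel_x, channel_y, temperature = NULL) {
  temperature <- temperature %||% lowest_temp(calls, channel_x)
  cx <- page_key(channel_x, temperature, "mean")
  cy <- page_key(channel_y, temperature, "mean")
  callx <- calls[[page_key(channel_x, temperature, "call")]] %||% FALSE
  cally <- calls[[page_key(channel_y, temperature, "call")]] %||% FALSE
  df <- tibble::tibble(x = calls[[cx]], y = calls[[cy]],
                       cluster = paste0(ifelse(callx, "+", "-"), "/",
                                        ifelse(cally, "+", "-")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$cluster)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.7) +
    ggplot2::labs(x = sprintf("%s (ADU)", channel_x), y = sprintf("%s (ADU)", channel_y),
                  colour = sprintf("%s/%s", channel_x, channel_y)) +
    ggplot2::theme_minimal()
}

lowest_temp <- function(calls, channel) {
  cols <- grep(paste0("^mean_", channel, "_"), names(calls), value = TRUE)
  if (!length(cols)) stop("no intensity columns for channel ", channel, call. = FALSE)
  min(as.numeric(sub(paste0("^mean_", channel, "_"), "", cols)))
}

#' @describeIn plot_scatter_1d Faceted 1-D scatter across all pages of a
#'   call matrix.
#' @param object A `call_matrix`.
#' @param ... Unused.
#' @export
autoplot.call_matrix <- function(object, ...) {
  mcols <- grep("^mean_", names(object), value = TRUE)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("id", mcols)],
    dplyr::all_of(mcols), names_prefix = "mean_",
    names_to = "page", values_to = "intensity")
  long$index <- stats::ave(long$intensity, long$page, FUN = seq_along)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6, colour = "grey40") +
    ggplot2::facet_wrap(~page) +
    ggplot2::labs(x = "droplet", y = "mean intensity (ADU)") +
    ggplot2::theme_minimal()
}

#' Plot a stepwise-melting deconvolution
#'
#' Per-Tm-class concentration with bootstrap CI error bars.
#'
#' @param object A `dsma_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dsma_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$class <- sprintf("Tm %g degC", df$tm)
  v <- attr(object, "volume_nl") %||% 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$lambda)) +
    ggplot2::geom_col(fill = "#1f77b4", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "mean copies per droplet") +
    ggplot2::theme_minimal()
}
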