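#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Poisson quantification
#' @param x A `dpcr_quant` from [lambda_hat()].
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.dpcr_quant <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, se = x$se, ci_lo = x$ci[1], ci_hi = x$ci[2],
                 concentration = x$concentration,
                 sample_concentration = x$sample_concentration, flag = x$flag)
}

#' @rdname tidy.dpcr_quant
#' @export
glance.dpcr_quant <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_neg = x$n_neg,
                 n_pos = x$n_total - x$n_neg,
                 volume_nl = x$volume_nl, dilution = x$dilution, flag = x$flag)
}

#' @export
print.dpcr_quant <- function(x, ...) {
  cat(sprintf("<dpcr_quant> lambda = %.4g (SE %.3g), CI95 [%.4g, %.4g], %.4g copies/uL%s\n",
              x$lambda, x$se, x$ci[1], x$ci[2], x$concentration,
              if (x$flag != "none") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Tidy a CNV ratio result
#' @param x A `cnv_result` from [cnv_ratio()].
#' @param ... Unused.
#' @return One-row tibble with `ratio`, `ci_lo`, `ci_hi`, `call`.
#' @export
tidy.cnv_result <- function(x, ...) {
  tibble::tibble(ratio = x$ratio, ci_lo = x$ci[1], ci_hi = x$ci[2], call = x$call)
}

#' @export
print.cnv_result <- function(x, ...) {
  cat(sprintf("<cnv_result> ratio = %.3g, CI95 [%.3g, %.3g]: %s\n",
              x$ratio, x$ci[1], x$ci[2], x$call))
  invisible(x)
}

#' Tidy a VAF result
#' @param x A `vaf_result` from [vaf()].
#' @param ... Unused.
#' @return One-row tibble with `vaf` (percent), `ci_lo`, `ci_hi`.
#' @export
tidy.vaf_result <- function(x, ...) {
  tibble::tibble(vaf = x$vaf, ci_lo = x$ci[1], ci_hi = x$ci[2])
}

#' @export
print.vaf_result <- function(x, ...) {
  cat(sprintf("<vaf_result> VAF = %.4g%% , CI95 [%.4g, %.4g]\n",
              x$vaf, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Tidy a stepwise-melting deconvolution
#' @param x A `dsma_result` from [dsma_deconvolve()].
#' @param ... Unused.
#' @return A tibble, one row per Tm class.
#' @export
tidy.dsma_result <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @rdname tidy.dsma_result
#' @export
glance.dsma_result <- function(x, ...) {
  tibble::tibble(n_total = attr(x, "n_total"), n_classes = nrow(x),
                 lambda_cum_low = x$lambda_cum[1], any_clamped = any(x$clamped))
}
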