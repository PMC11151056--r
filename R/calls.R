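#' Automatic intensity threshold for one channel
#'
#' Estimates the positive/negative boundary from the intensity frequency
#' distribution. Primary method: kernel density estimate (Silverman
#' bandwidth); with two or more modes the threshold is the density minimum
#' between the two highest modes. Fallbacks: the two-means midpoint when the
#' clusters are separated by more than 4 pooled SDs, else a robust
#' single-population guard (median + 5 MAD) that treats the well as
#' all-negative — this prevents hallucinating positives in no-template
#' control wells.
#'
#' @param intensities Numeric vector of per-droplet mean intensities (ADU);
#'   at least 50 values.
#' @param channel Optional channel label carried into the result.
#' @param manual Manual override threshold; when given it is used verbatim.
#' @return A `dpcr_threshold` tibble: `channel`, `value`, `method`
#'   (`kde_valley` / `two_means` / `robust_mad` / `manual`), `modes_found`.
#' @export
auto_threshold <- function(intensities, channel = NA_character_, manual = NULL) {
  if (!is.null(manual)) {
    return(new_threshold(channel, manual, "manual", NA_integer_))
  }
  intensities <- intensities[is.finite(intensities)]
  if (length(intensities) < 50) {
    stop("need >= 50 intensity values to set a threshold", call. = FALSE)
  }
  den <- stats::density(intensities, bw = "nrd0", n = 512)
  y <- den$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  peaks <- peaks[y[peaks] >= 0.05 * max(y[peaks])]  # ignore negligible bumps
  modes_found <- length(peaks)
  if (modes_found >= 2) {
    top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
    valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1
    return(new_threshold(channel, den$x[valley], "kde_valley", modes_found))
  }
  if (diff(range(intensities)) > 0) {
    km <- stats::kmeans(intensities, centers = range(intensities), iter.max = 50)
    m <- sort(km$centers[, 1])
    pooled <- sqrt(mean(tapply(intensities, km$cluster, stats::var), na.rm = TRUE))
  } else {
    m <- c(0, 0); pooled <- NA_real_
  }
  if (is.finite(pooled) && pooled > 0 && (m[2] - m[1]) > 4 * pooled) {
    return(new_threshold(channel, mean(m), "two_means", modes_found))
  }
  new_threshold(channel,
                stats::median(intensities) + 5 * stats::mad(intensities),
                "robust_mad", modes_found)
}

new_threshold <- function(channel, value, method, modes_found) {
  structure(tibble::tibble(channel = channel, value = as.numeric(value),
                           method = method, modes_found = modes_found),
            class = c("dpcr_threshold", "tbl_df", "tbl", "data.frame"))
}

#' Classify droplet intensities against a threshold
#'
#' Positive iff strictly greater than the threshold, so a droplet exactly on
#' the boundary is called negative (conservative toward false positives).
#'
#' @param intensities Numeric vector.
#' @param threshold A [auto_threshold()] result or a single number.
#' @return Logical vector.
#' @export
classify <- function(intensities, threshold) {
  value <- if (is.numeric(threshold)) threshold else threshold$value
  intensities > value
}

#' Derive per-target presence from channel calls
#'
#' Applies each target's call rule at one imaging temperature: a `direct`
#' target is present iff its channel is positive; a `drop_off` target (mutant
#' detection with a wildtype probe) is present iff the reference (total
#' template) channel is positive AND the wildtype channel is negative.
#'
#' @param calls Tibble with `id` and logical `call_<channel>_<temperature>`
#'   columns (see [call_droplets()]), or plain logical channel columns named
#'   after the channels when `temperature` is `NULL`.
#' @param panel The [assay_panel()].
#' @param temperature Temperature whose calls to use; default the lowest
#'   panel temperature.
#' @return Tibble `id` + one logical `presence_<target>` column per target.
#' @export
apply_target_rules <- function(calls, panel, temperature = NULL) {
  stopifnot(inherits(panel, "assay_panel"))
  temperature <- temperature %||% min(panel$temperatures)
  chan_call <- function(ch) {
    col <- page_key(ch, temperature, "call")
    if (col %in% names(calls)) return(calls[[col]])
    if (ch %in% names(calls)) return(calls[[ch]])
    stop("call rule references channel with no call column: ", ch, call. = FALSE)
  }
  out <- tibble::tibble(id = calls$id)
  for (k in seq_len(nrow(panel$targets))) {
    t <- panel$targets[k, ]
    pres <- if (t$rule == "direct") {
      chan_call(t$channel)
    } else {
      chan_call(t$ref_channel) & !chan_call(t$wt_channel)
    }
    out[[paste0("presence_", t$name)]] <- pres
  }
  out
}

#' Enforce melting monotonicity across temperatures
#'
#' Fluorescence can only be lost as the temperature rises (probe-amplicon
#' duplexes dissociate above their Tm), so for any channel a droplet positive
#' at a higher temperature must be positive at every lower one. Droplets
#' violating this are physically inconsistent (noise flips) and are dropped
#' entirely, keeping the denominator N consistent across temperatures.
#'
#' @param calls Tibble with `id` and `call_<channel>_<temperature>` columns.
#' @param channels Channel labels present in `calls`.
#' @param temperatures Ascending imaging temperatures present in `calls`.
#' @return A list: `calls` (filtered tibble), `inconsistency_fraction`,
#'   `n_dropped`.
#' @export
monotone_filter <- function(calls, channels, temperatures) {
  temperatures <- sort(temperatures)
  if (length(temperatures) < 2) {
    return(list(calls = calls, inconsistency_fraction = 0, n_dropped = 0L))
  }
  bad <- rep(FALSE, nrow(calls))
  for (ch in channels) {
    for (j in seq_len(length(temperatures) - 1)) {
      lo <- calls[[page_key(ch, temperatures[j], "call")]]
      hi <- calls[[page_key(ch, temperatures[j + 1], "call")]]
      bad <- bad | (hi & !lo)
    }
  }
  list(calls = calls[!bad, , drop = FALSE],
       inconsistency_fraction = mean(bad),
       n_dropped = sum(bad))
}

#' Threshold and call every droplet of a well
#'
#' Estimates one threshold per channel on the lowest-temperature page (in a
#' stepwise-melting design that is where both populations exist; annealed
#' probes of one channel fluoresce identically across temperatures, so the
#' threshold is reused for that channel's other pages), classifies every
#' (channel, temperature) page, and applies the melting-monotonicity filter.
#'
#' @param call_table Unified intensity table from [build_call_table()] (or a
#'   truth-derived table) with `mean_<channel>_<temperature>` columns. Rows
#'   with `qc_status != "valid"` are excluded first when the column exists.
#' @param panel The [assay_panel()].
#' @param thresholds Optional named numeric vector of manual thresholds per
#'   channel.
#' @return A `call_matrix` tibble: `id`, the intensity columns, logical
#'   `call_*` columns, with attributes `thresholds` (tibble) and
#'   `inconsistency_fraction`.
#' @export
call_droplets <- function(call_table, panel, thresholds = NULL) {
  stopifnot(inherits(panel, "assay_panel"))
  tab <- call_table
  if ("qc_status" %in% names(tab)) tab <- tab[tab$qc_status == "valid", , drop = FALSE]
  t_low <- min(panel$temperatures)
  thr <- purrr::map_dfr(panel$channels, function(ch) {
    auto_threshold(tab[[page_key(ch, t_low, "mean")]], channel = ch,
                   manual = if (!is.null(thresholds) && ch %in% names(thresholds))
                     thresholds[[ch]] else NULL)
  })
  for (ch in panel$channels) {
    tval <- thr$value[thr$channel == ch]
    for (temp in panel$temperatures) {
      tab[[page_key(ch, temp, "call")]] <-
        classify(tab[[page_key(ch, temp, "mean")]], tval)
    }
  }
  mf <- monotone_filter(tab, panel$channels, panel$temperatures)
  out <- mf$calls
  attr(out, "thresholds") <- thr
  attr(out, "inconsistency_fraction") <- mf$inconsistency_fraction
  class(out) <- c("call_matrix", class(out))
  out
}
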