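#' Analyze one well image set end to end
#'
#' Runs the full computational chain on one well: per-page droplet detection
#' -> feature measurement -> registration to a reference page ->
#' QC filtering -> thresholding and calling -> Poisson quantification.
#' Channels carrying a single Tm class are quantified from per-target
#' presence at the lowest imaging temperature; channels carrying several Tm
#' classes are deconvolved by stepwise melting ([dsma_deconvolve()]).
#'
#' @param well A `pmda_well` or `image_set`.
#' @param panel The [assay_panel()].
#' @param params Detection parameters ([detect_params()]).
#' @param qc QC rules ([qc_rules()]).
#' @param thresholds Optional named manual thresholds per channel.
#' @param volume_nl Droplet volume for concentrations, nL.
#' @param dilution Dilution factor D.
#' @param n_theoretical Theoretical partition count (for the utilization
#'   rate); `NA` to skip.
#' @param seed Seed for the bootstrap SEs.
#' @return A `well_result` list: `droplets` (QC'ed unified table), `calls`
#'   (call matrix), `thresholds`, `quant` (per-target tibble), `dsma`
#'   (per-channel deconvolutions), `summary` (one-row tibble).
#' @export
analyze_well <- function(well, panel, params = NULL, qc = qc_rules(),
                         thresholds = NULL, volume_nl = 1.0, dilution = 1.0,
                         n_theoretical = NA_real_, seed = 1L) {
  stopifnot(inherits(panel, "assay_panel"))
  shape <- dim(well$pages[[1]])
  params <- params %||% detect_params()
  page_records <- detect_well(well, params)
  t_low <- min(panel$temperatures)
  reference <- page_key(panel$channels[1], t_low)
  ct <- build_call_table(page_records, reference = reference)
  dropped <- attr(ct, "dropped_fraction")
  ct <- qc_filter(ct, qc, image_shape = shape)
  cm <- call_droplets(ct, panel, thresholds = thresholds)
  n_valid <- nrow(cm)

  pres <- apply_target_rules(cm, panel, temperature = t_low)
  quant <- list(); dsma <- list()
  for (ch in panel$channels) {
    tms <- sort(unique(panel$targets$tm[panel$targets$channel == ch]))
    if (length(tms) >= 2) {
      counts <- purrr::map_dfr(panel$temperatures, function(temp) {
        calls <- cm[[page_key(ch, temp, "call")]]
        partition_counts(length(calls), sum(!calls), temperature = temp)
      })
      ds <- dsma_deconvolve(counts, tms, volume_nl = volume_nl,
                            dilution = dilution, seed = seed)
      dsma[[ch]] <- ds
      for (k in seq_len(nrow(ds))) {
        tname <- panel$targets$name[panel$targets$channel == ch &
                                      panel$targets$tm == ds$tm[k]]
        quant[[tname]] <- tibble::tibble(
          target = tname, channel = ch, tm = ds$tm[k], method = "dsma",
          n_total = attr(ds, "n_total"), n_pos = NA_integer_,
          lambda = ds$lambda[k], se = ds$se[k],
          ci_lo = ds$ci_lo[k], ci_hi = ds$ci_hi[k],
          concentration = to_concentration(ds$lambda[k], volume_nl, 1),
          sample_concentration = ds$concentration[k],
          flag = if (ds$clamped[k]) "clamped" else "none")
      }
    }
  }
  single <- panel$targets[!panel$targets$name %in% names(quant), ]
  for (k in seq_len(nrow(single))) {
    t <- single[k, ]
    p <- pres[[paste0("presence_", t$name)]]
    q <- lambda_hat(partition_counts(length(p), sum(!p)),
                    volume_nl = volume_nl, dilution = dilution)
    quant[[t$name]] <- tibble::tibble(
      target = t$name, channel = t$channel, tm = t$tm, method = "poisson",
      n_total = q$n_total, n_pos = q$n_total - q$n_neg,
      lambda = q$lambda, se = q$se, ci_lo = q$ci[1], ci_hi = q$ci[2],
      concentration = q$concentration,
      sample_concentration = q$sample_concentration, flag = q$flag)
  }
  quant <- dplyr::bind_rows(quant)

  util <- if (!is.na(n_theoretical)) {
    partition_utilization(n_valid, n_theoretical)$percent
  } else NA_real_
  summary <- tibble::tibble(
    n_detected = attr(ct, "n_reference") %||% nrow(ct),
    n_matched = nrow(ct), dropped_fraction = dropped,
    n_valid = n_valid,
    n_rejected = sum(ct$qc_status == "rejected"),
    inconsistency_fraction = attr(cm, "inconsistency_fraction"),
    utilization_pct = util
  )
  structure(list(droplets = ct, calls = cm,
                 thresholds = attr(cm, "thresholds"), quant = quant,
                 dsma = dsma, summary = summary),
            class = "well_result")
}

#' @export
print.well_result <- function(x, ...) {
  cat(sprintf("<well_result> %d valid droplet(s); %d target(s)\n",
              x$summary$n_valid, nrow(x$quant)))
  print(x$quant)
  invisible(x)
}

#' Run the full pipeline over a plate layout
#'
#' For every well in the layout: load (or take) its image set, run
#' [analyze_well()], and collect per-target results. Wells sharing a
#' `replicate_group` are additionally pooled per target (component-wise
#' count sums, then one Poisson estimate on the pooled counts). A failure in
#' one well is recorded and the run continues.
#'
#' @param layout Layout tibble ([read_layout()]) or CSV path.
#' @param images Named list of wells (`pmda_well`/`image_set` objects or TIFF
#'   paths), keyed by well id, or a directory containing `<well>.tif`.
#' @param panels Named list of [assay_panel()] objects keyed by panel name
#'   (or a single panel used for all wells).
#' @param out_dir Output directory for droplet tables, call/scatter data,
#'   results JSON and the run log; `NULL` writes nothing.
#' @param volume_nl Droplet volume, nL.
#' @param params,qc,thresholds,seed Passed to [analyze_well()].
#' @return A tibble of per-well, per-target results with attributes
#'   `pooled` (per replicate-group tibble), `summaries`, `errors` (named
#'   character), and `results` (list of `well_result`).
#' @export
run_pipeline <- function(layout, images, panels, out_dir = NULL,
                         volume_nl = 1.0, params = NULL, qc = qc_rules(),
                         thresholds = NULL, seed = 1L) {
  if (is.character(layout)) layout <- read_layout(layout)
  if (inherits(panels, "assay_panel")) {
    panels <- stats::setNames(rep(list(panels), length(unique(layout$panel))),
                              unique(layout$panel))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- character()
  results <- list(); errors <- character(); rows <- list(); summaries <- list()
  for (k in seq_len(nrow(layout))) {
    wid <- layout$well[k]
    res <- tryCatch({
      well <- fetch_well(images, wid)
      panel <- panels[[layout$panel[k]]]
      if (is.null(panel)) stop("well ", wid, " references undefined panel: ", layout$panel[k])
      analyze_well(well, panel, params = params, qc = qc,
                   thresholds = thresholds, volume_nl = volume_nl,
                   dilution = layout$dilution[k],
                   n_theoretical = layout$n_theoretical[k] %||% NA_real_,
                   seed = seed)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[wid] <- conditionMessage(res)
      log_lines <- c(log_lines, sprintf("well %s: ERROR %s", wid, errors[wid]))
      next
    }
    results[[wid]] <- res
    summaries[[wid]] <- dplyr::bind_cols(tibble::tibble(well = wid), res$summary)
    rows[[wid]] <- dplyr::bind_cols(
      tibble::tibble(well = wid, sample = layout$sample[k],
                     replicate_group = layout$replicate_group[k] %||% layout$sample[k]),
      res$quant)
    log_lines <- c(log_lines, sprintf(
      "well %s: %d valid / %d detected droplets, %d rejected, %.2f%% dropped in registration",
      wid, res$summary$n_valid, res$summary$n_detected, res$summary$n_rejected,
      100 * res$summary$dropped_fraction))
    if (!is.null(out_dir)) {
      write_droplet_table(res$calls, file.path(out_dir, paste0(wid, "_droplets.csv")))
    }
  }
  out <- dplyr::bind_rows(rows)

  pooled <- tibble::tibble()
  if (nrow(out)) {
    pooled <- out |>
      dplyr::filter(.data$method == "poisson") |>
      dplyr::group_by(.data$replicate_group, .data$target) |>
      dplyr::group_modify(function(d, g) {
        q <- lambda_hat(partition_counts(sum(d$n_total), sum(d$n_total - d$n_pos)),
                        volume_nl = volume_nl)
        tibble::tibble(n_wells = nrow(d), n_total = q$n_total,
                       lambda = q$lambda, se = q$se,
                       concentration = q$concentration, flag = q$flag)
      }) |>
      dplyr::ungroup()
  }
  if (!is.null(out_dir)) {
    write_results_json(list(per_well = out, pooled = pooled),
                       file.path(out_dir, "results.json"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  attr(out, "pooled") <- pooled
  attr(out, "summaries") <- dplyr::bind_rows(summaries)
  attr(out, "errors") <- errors
  attr(out, "results") <- results
  out
}

fetch_well <- function(images, wid) {
  w <- if (is.character(images) && length(images) == 1 && dir.exists(images)) {
    file.path(images, paste0(wid, ".tif"))
  } else {
    images[[wid]]
  }
  if (is.null(w)) stop("no image set for well ", wid, call. = FALSE)
  if (is.character(w)) w <- read_image_set(w)
  w
}
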