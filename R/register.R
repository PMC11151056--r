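#' Estimate the translation between two droplet record sets
#'
#' Changing fluorescence filters (or re-imaging after a temperature step)
#' shifts the whole field by a few pixels. The shift is estimated from the
#' droplet centres themselves: each reference centre takes its nearest target
#' centre within `search_radius`, the translation is the component-wise
#' median of the displacement vectors, and the match + median is repeated
#' once with the first estimate applied (two iterations; exact for integer
#' shifts of identical sets).
#'
#' @param ref,tgt Record tibbles with `x`, `y` (px).
#' @param search_radius Maximum displacement considered, px; default half the
#'   median droplet radius of `ref` when a `diameter` column exists, else 10.
#' @return A `shift_estimate`: tibble with `dx`, `dy` (target relative to
#'   reference), `n_support`, `residual_mad`.
#' @export
estimate_shift <- function(ref, tgt, search_radius = NULL) {
  if (!nrow(ref) || !nrow(tgt)) stop("both record sets must be non-empty", call. = FALSE)
  search_radius <- search_radius %||% default_radius(ref)
  dx <- 0; dy <- 0
  for (pass in 1:2) {
    nn <- nearest_within(ref$x, ref$y, tgt$x - dx, tgt$y - dy, search_radius)
    ok <- !is.na(nn)
    if (sum(ok) < 3) {
      stop(sprintf("only %d supporting displacement vector(s); need >= 3", sum(ok)),
           call. = FALSE)
    }
    dx <- dx + stats::median(tgt$x[nn[ok]] - dx - ref$x[ok]) + 0
    dy <- dy + stats::median(tgt$y[nn[ok]] - dy - ref$y[ok]) + 0
  }
  resid <- sqrt((tgt$x[nn[ok]] - ref$x[ok] - dx)^2 + (tgt$y[nn[ok]] - ref$y[ok] - dy)^2)
  structure(tibble::tibble(dx = dx, dy = dy, n_support = sum(ok),
                           residual_mad = stats::mad(resid, center = 0)),
            class = c("shift_estimate", "tbl_df", "tbl", "data.frame"))
}

# 0.5 x the median droplet radius: below the close-packing centre distance,
# so a shifted droplet cannot be captured by its neighbour
default_radius <- function(records) {
  if ("diameter" %in% names(records) && nrow(records)) {
    0.5 * stats::median(records$diameter) / 2
  } else 10
}

# nearest b-point index within radius for each a-point (NA when none)
nearest_within <- function(ax, ay, bx, by, r) {
  pairs <- cross_pairs(ax, ay, bx, by, r)
  out <- rep(NA_integer_, length(ax))
  if (!nrow(pairs)) return(out)
  pairs <- pairs[order(pairs$i, pairs$dist, pairs$j), ]
  first <- !duplicated(pairs$i)
  out[pairs$i[first]] <- pairs$j[first]
  out
}

#' Match droplets between a reference and a shifted target set
#'
#' Greedy nearest-neighbour matching after removing the estimated shift.
#' Candidate pairs within `radius` are sorted by distance, ties broken by
#' lower target id, and assigned one-to-one, so the mapping is injective in
#' both directions.
#'
#' @param ref,tgt Record tibbles with `id`, `x`, `y`.
#' @param shift A [estimate_shift()] result (or list with `dx`, `dy`).
#' @param radius Maximum residual distance for a match, px.
#' @return A `correspondence` list: `matched` (tibble `ref_id`, `tgt_id`,
#'   `dist`), `unmatched_reference`, `unmatched_target`.
#' @export
match_records <- function(ref, tgt, shift = list(dx = 0, dy = 0), radius = NULL) {
  radius <- radius %||% default_radius(ref)
  if (radius <= 0) stop("`radius` must be > 0", call. = FALSE)
  tx <- tgt$x - shift$dx; ty <- tgt$y - shift$dy
  pairs <- cross_pairs(ref$x, ref$y, tx, ty, radius)
  matched_i <- integer(); matched_j <- integer(); matched_d <- numeric()
  if (nrow(pairs)) {
    pairs <- pairs[order(pairs$dist, tgt$id[pairs$j]), ]
    used_i <- logical(nrow(ref)); used_j <- logical(nrow(tgt))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (!used_i[i] && !used_j[j]) {
        used_i[i] <- TRUE; used_j[j] <- TRUE
        matched_i <- c(matched_i, i); matched_j <- c(matched_j, j)
        matched_d <- c(matched_d, pairs$dist[k])
      }
    }
  }
  structure(list(
    matched = tibble::tibble(ref_id = ref$id[matched_i], tgt_id = tgt$id[matched_j],
                             dist = matched_d),
    unmatched_reference = setdiff(ref$id, ref$id[matched_i]),
    unmatched_target = setdiff(tgt$id, tgt$id[matched_j])
  ), class = "correspondence")
}

#' Build one per-droplet intensity table across all pages
#'
#' Designates one page as the reference identity set, registers every other
#' required page to it ([estimate_shift()] + [match_records()]), and keeps
#' only droplets matched on every page, so a single common denominator N of
#' droplets underlies all temperatures — which the stepwise-melting
#' arithmetic requires. Each retained droplet carries that page's measured
#' mean intensity.
#'
#' @param page_records Named list of per-page record tibbles (see
#'   [detect_well()]); each must carry its own `mean_<page>` column.
#' @param reference Name of the reference page; default the first.
#' @param required Pages that every retained droplet must appear on; default
#'   all pages.
#' @param radius Match radius, px (default half the median droplet radius).
#' @return A tibble (one row per retained droplet, reference geometry and QC
#'   columns if present, plus all `mean_*` columns) with attributes
#'   `dropped_fraction`, `n_reference`, and `shifts` (per-page tibble).
#' @export
build_call_table <- function(page_records, reference = NULL, required = NULL,
                             radius = NULL) {
  stopifnot(is.list(page_records), length(page_records) >= 1)
  reference <- reference %||% names(page_records)[1]
  if (!reference %in% names(page_records)) {
    stop("reference page not present: ", reference, call. = FALSE)
  }
  required <- required %||% names(page_records)
  missing <- setdiff(required, names(page_records))
  if (length(missing)) stop("required page(s) absent: ", paste(missing, collapse = ", "), call. = FALSE)
  ref <- page_records[[reference]]
  out <- ref
  shifts <- list()
  for (pg in setdiff(required, reference)) {
    tgt <- page_records[[pg]]
    sh <- estimate_shift(ref, tgt, search_radius = radius %||% default_radius(ref))
    co <- match_records(ref, tgt, sh, radius = radius %||% default_radius(ref))
    shifts[[pg]] <- tibble::tibble(page = pg, dx = sh$dx, dy = sh$dy,
                                   n_support = sh$n_support)
    mcol <- paste0("mean_", pg)
    val <- rep(NA_real_, nrow(ref))
    val[match(co$matched$ref_id, ref$id)] <- tgt[[mcol]][match(co$matched$tgt_id, tgt$id)]
    out[[mcol]] <- val
  }
  mean_cols <- paste0("mean_", required)
  keep <- stats::complete.cases(out[, mean_cols, drop = FALSE])
  res <- out[keep, , drop = FALSE]
  attr(res, "dropped_fraction") <- 1 - nrow(res) / nrow(ref)
  attr(res, "n_reference") <- nrow(ref)
  attr(res, "shifts") <- dplyr::bind_rows(shifts)
  res
}
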