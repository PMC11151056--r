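#' Gaussian prefilter
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian SD in px; `0` returns the input unchanged.
#' @return Smoothed matrix.
#' @export
preprocess <- function(image, sigma = 2) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(image)
  as.matrix(EBImage::gblur(image, sigma = sigma))
}

#' Detection parameters
#'
#' @param expected_diameter Expected droplet diameter, px.
#' @param min_diameter,max_diameter Equivalent-diameter gate applied to
#'   segmented objects; defaults scale with `expected_diameter`.
#' @param sigma Gaussian prefilter SD, px.
#' @return A list of validated parameters.
#' @export
detect_params <- function(expected_diameter = 31,
                          min_diameter = 0.4 * expected_diameter,
                          max_diameter = 2.5 * expected_diameter,
                          sigma = 2) {
  if (min_diameter >= max_diameter) {
    stop("`min_diameter` must be < `max_diameter`", call. = FALSE)
  }
  list(expected_diameter = expected_diameter, min_diameter = min_diameter,
       max_diameter = max_diameter, sigma = sigma)
}

#' Detect droplets in a 2-D fluorescence image
#'
#' The reference backend is classical and fully deterministic: Gaussian smooth
#' -> global Otsu threshold -> fill holes -> distance transform -> watershed
#' split of touching objects -> equivalent-diameter gate. It serves as a
#' reproducible oracle; a learned segmenter may be plugged in behind the same
#' contract (same inputs, same record schema, same fixture metrics).
#'
#' @param image Numeric matrix (droplets brighter than background).
#' @param params See [detect_params()].
#' @return A list: `labels` (integer label matrix) and `records` (tibble with
#'   `id`, `x`, `y`, `diameter`, `area`, `perimeter`, `circularity`).
#' @export
detect <- function(image, params = detect_params()) {
  if (!is.matrix(image) || !length(image)) {
    return(list(labels = matrix(0L, 0, 0), records = empty_records()))
  }
  sm <- preprocess(image, params$sigma)
  rng <- range(sm)
  if (diff(rng) == 0) {  # degenerate (blank/constant) image: nothing to find
    return(list(labels = matrix(0L, nrow(image), ncol(image)), records = empty_records()))
  }
  norm <- (sm - rng[1]) / diff(rng)
  thr <- foreground_threshold(norm)
  mask <- EBImage::fillHull(norm > thr$mid)
  dm <- EBImage::distmap(mask)
  ext <- max(1, round(0.3 * params$expected_diameter))  # min seed separation 0.6 d
  labels <- EBImage::watershed(dm, tolerance = 1, ext = ext)
  labels <- matrix(as.integer(labels), nrow(image), ncol(image))
  recs <- measure_shapes(labels, norm, edge_sigma = max(params$sigma, 0.5),
                         thr_global = thr$mid)
  keep <- recs$diameter >= params$min_diameter & recs$diameter <= params$max_diameter
  dropped <- recs$id[!keep]
  if (length(dropped)) labels[labels %in% dropped] <- 0L
  recs <- recs[keep, , drop = FALSE]
  # compact label ids to 1..n
  if (nrow(recs)) {
    relab <- integer(max(recs$id))
    relab[recs$id] <- seq_len(nrow(recs))
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
    recs$id <- seq_len(nrow(recs))
  }
  list(labels = labels, records = recs)
}

# Global foreground threshold for droplet arrays. Histograms are typically
# trimodal (background / negative droplets / positive droplets), which breaks
# plain Otsu: it splits negatives from positives and loses every negative
# droplet. Instead threshold at the midpoint between the background mode (the
# lowest-intensity mode) and the next population mode: a Gaussian-blurred
# disk edge crosses that midpoint exactly at the true boundary, so measured
# droplet sizes are unbiased. Otsu is the fallback for unimodal histograms.
foreground_threshold <- function(norm) {
  v <- as.vector(norm)
  if (length(v) > 2e5) v <- v[seq(1, length(v), length.out = 2e5)]
  den <- stats::density(v, n = 512)
  y <- den$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  peaks <- peaks[y[peaks] >= 0.02 * max(y[peaks])]
  if (length(peaks) >= 2) {
    return(list(mid = (den$x[peaks[1]] + den$x[peaks[2]]) / 2))
  }
  list(mid = EBImage::otsu(EBImage::Image(norm), range = c(0, 1)))
}

empty_records <- function() {
  tibble::tibble(id = integer(), x = numeric(), y = numeric(),
                 diameter = numeric(), area = numeric(), perimeter = numeric(),
                 circularity = numeric())
}

# perimeter from the 8-connected contour chain (EBImage perimeters
# under-count; chain step lengths track true perimeters within a few %)
chain_perimeters <- function(labels, ids) {
  oc <- EBImage::ocontour(EBImage::Image(labels))
  out <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    pts <- oc[[ids[k]]]
    if (is.null(pts) || nrow(pts) < 2) { out[k] <- 4; next }
    d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
    out[k] <- sum(sqrt(rowSums(d^2)))
  }
  out
}

# shape + centroid measurement for all labels present in the mask.
# When `edge_sigma` and `thr_global` are given (the detector's Gaussian
# prefilter SD and global threshold), the equivalent radius is corrected by
# inverting the blurred edge profile: a disk of plateau V over background B
# crosses the level t at radius r0 - sigma * qnorm((t - B)/(V - B)), so the
# mask radius is debiased per object regardless of how bright or dim the
# object is relative to the population. Without these arguments the raw
# mask area is used (appropriate for sharp, unblurred masks).
measure_shapes <- function(labels, weight_image, edge_sigma = 0,
                           thr_global = NULL) {
  idx <- which(labels > 0L)
  if (!length(idx)) return(empty_records())
  lab <- labels[idx]
  nr <- nrow(labels)
  y <- (idx - 1L) %% nr          # row - 1
  x <- (idx - 1L) %/% nr         # col - 1
  w <- pmax(weight_image[idx], 1e-9)
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)
  area <- as.numeric(tabulate(f))
  sw <- as.numeric(tapply(w, f, sum))
  cx <- as.numeric(tapply(w * x, f, sum)) / sw
  cy <- as.numeric(tapply(w * y, f, sum)) / sw
  per <- chain_perimeters(labels, ids)

  r_eq <- sqrt(area / pi)
  if (edge_sigma > 0 && !is.null(thr_global)) {
    bg_px <- weight_image[labels == 0L]
    bg <- if (length(bg_px)) stats::median(bg_px) else min(weight_image)
    plateau <- as.numeric(tapply(weight_image[idx], f, stats::median))
    q <- (thr_global - bg) / pmax(plateau - bg, 1e-9)
    z <- stats::qnorm(pmin(pmax(q, 0.01), 0.99))
    r_eq <- pmax(r_eq + edge_sigma * pmin(pmax(z, -2.5), 2.5), 0.5)
  }

  tibble::tibble(
    id = ids, x = cx, y = cy,
    diameter = 2 * r_eq, area = area, perimeter = per,
    circularity = pmin(4 * pi * area / per^2, 1.1)
  )
}

#' Measure per-droplet features on every image page
#'
#' Adds one `mean_<channel>_<temperature>` column per page: the mean of the
#' page's pixels inside the droplet's label mask.
#'
#' @param labels Integer label matrix.
#' @param pages Named list of matrices sharing the label geometry (names are
#'   `<channel>_<temperature>` page keys).
#' @param weight_image Image used for the intensity-weighted centroid;
#'   defaults to the pixel-wise max over `pages`.
#' @param ids Optional label ids that must be present; a missing id is an
#'   error.
#' @return A tibble of records with shape features and per-page means.
#' @export
measure_features <- function(labels, pages, weight_image = NULL, ids = NULL) {
  stopifnot(is.list(pages), length(pages) >= 1)
  for (p in pages) {
    if (!identical(dim(p), dim(labels))) {
      stop("pages and label mask must share geometry", call. = FALSE)
    }
  }
  weight_image <- weight_image %||% Reduce(pmax, pages)
  recs <- measure_shapes(labels, weight_image)
  if (!is.null(ids)) {
    missing <- setdiff(ids, recs$id)
    if (length(missing)) {
      stop("label(s) absent from mask: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (!nrow(recs)) {
    for (nm in names(pages)) recs[[paste0("mean_", nm)]] <- numeric()
    return(recs)
  }
  idx <- which(labels > 0L)
  f <- factor(labels[idx], levels = recs$id)
  for (nm in names(pages)) {
    recs[[paste0("mean_", nm)]] <- as.numeric(tapply(pages[[nm]][idx], f, mean))
  }
  recs
}

#' QC rules for droplet filtering
#'
#' @param size_tol Relative diameter tolerance `a`: droplets outside
#'   `[(1-a), (1+a)] * median diameter` are rejected.
#' @param min_circularity Minimum circularity (`4 pi A / P^2`).
#' @param overlap_factor Pairs closer than `overlap_factor * (r_i + r_j)` are
#'   both rejected; the default 0.9 lets tangent droplets pass since close
#'   packing is normal in a monolayer array.
#' @param edge_margin Margin from the image border, px; `NULL` = expected
#'   droplet radius (median diameter / 2).
#' @return A list of rules.
#' @export
qc_rules <- function(size_tol = 0.25, min_circularity = 0.85,
                     overlap_factor = 0.9, edge_margin = NULL) {
  list(size_tol = size_tol, min_circularity = min_circularity,
       overlap_factor = overlap_factor, edge_margin = edge_margin)
}

# grid-bucketed close-pair search: returns pairs (i, j, dist) with dist <= r
close_pairs <- function(x, y, r) {
  n <- length(x)
  if (n < 2) return(tibble::tibble(i = integer(), j = integer(), dist = numeric()))
  cell <- max(r, 1e-6)
  cx <- floor(x / cell); cy <- floor(y / cell)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  out_i <- integer(); out_j <- integer()
  for (b in names(buckets)) {
    ij <- as.integer(strsplit(b, " ")[[1]])
    cand <- unlist(buckets[paste(rep(ij[1] + -1:1, each = 3), ij[2] + -1:1)],
                   use.names = FALSE)
    pts <- buckets[[b]]
    for (i in pts) {
      js <- cand[cand > i]
      if (!length(js)) next
      d2 <- (x[js] - x[i])^2 + (y[js] - y[i])^2
      hit <- js[d2 <= r^2]
      out_i <- c(out_i, rep(i, length(hit))); out_j <- c(out_j, hit)
    }
  }
  tibble::tibble(i = out_i, j = out_j,
                 dist = sqrt((x[out_j] - x[out_i])^2 + (y[out_j] - y[out_i])^2))
}

#' Apply QC rules to detected droplets
#'
#' Flags the artifact classes the assay must exclude: oversized droplets
#' (e.g. coalesced pairs at 1.26x the singleton diameter), undersized
#' fragments, irregular objects (debris), overlapping pairs, and droplets
#' touching the image border. One reason is reported per droplet, in the
#' priority order oversized > undersized > irregular > overlap > edge.
#'
#' @param records Tibble from [detect()]/[measure_features()].
#' @param rules See [qc_rules()].
#' @param image_shape `c(rows, cols)` of the source image (needed for the
#'   edge rule; skipped when absent).
#' @return `records` with `qc_status` (`"valid"`/`"rejected"`) and
#'   `qc_reason` columns.
#' @export
qc_filter <- function(records, rules = qc_rules(), image_shape = NULL) {
  if (!nrow(records)) stop("no droplet records to filter", call. = FALSE)
  med <- stats::median(records$diameter)
  reason <- rep(NA_character_, nrow(records))
  mark <- function(cond, why) reason <<- ifelse(is.na(reason) & cond, why, reason)
  mark(records$diameter > (1 + rules$size_tol) * med, "oversized")
  mark(records$diameter < (1 - rules$size_tol) * med, "undersized")
  mark(records$circularity < rules$min_circularity, "irregular")
  rad <- records$diameter / 2
  cp <- close_pairs(records$x, records$y, 2 * rules$overlap_factor * max(rad))
  if (nrow(cp)) {
    bad <- cp$dist < rules$overlap_factor * (rad[cp$i] + rad[cp$j])
    ov <- unique(c(cp$i[bad], cp$j[bad]))
    cond <- rep(FALSE, nrow(records)); cond[ov] <- TRUE
    mark(cond, "overlap")
  }
  if (!is.null(image_shape)) {
    m <- rules$edge_margin %||% (med / 2)
    mark(records$x < m | records$y < m |
           records$x > image_shape[2] - 1 - m | records$y > image_shape[1] - 1 - m,
         "edge")
  }
  records$qc_status <- ifelse(is.na(reason), "valid", "rejected")
  records$qc_reason <- ifelse(is.na(reason), "none", reason)
  records
}

#' Score detections against ground truth
#'
#' Greedy nearest-neighbour matching: candidate (prediction, truth) pairs
#' within `match_radius` are sorted by distance (ties broken by lower
#' prediction id) and matched one-to-one.
#'
#' @param records Predicted records (`x`, `y`, `id`).
#' @param truth Ground-truth table (`x`, `y`).
#' @param match_radius Maximum centre distance for a match, px.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `undefined_precision` (TRUE when there were no predictions).
#' @export
evaluate_detection <- function(records, truth, match_radius = 5) {
  if (match_radius <= 0) stop("`match_radius` must be > 0", call. = FALSE)
  np <- nrow(records); nt <- nrow(truth)
  tp <- 0L
  if (np > 0 && nt > 0) {
    pairs <- cross_pairs(records$x, records$y, truth$x, truth$y, match_radius)
    pairs <- pairs[order(pairs$dist, records$id[pairs$i]), , drop = FALSE]
    used_p <- logical(np); used_t <- logical(nt)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (!used_p[i] && !used_t[j]) { used_p[i] <- TRUE; used_t[j] <- TRUE; tp <- tp + 1L }
    }
  }
  fp <- np - tp; fn <- nt - tp
  precision <- if (np > 0) tp / np else 0
  recall <- if (nt > 0) tp / nt else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, undefined_precision = np == 0)
}

# all pairs (i from set A, j from set B) within radius, grid-bucketed
cross_pairs <- function(ax, ay, bx, by, r) {
  cell <- max(r, 1e-6)
  bkey <- paste(floor(bx / cell), floor(by / cell))
  buckets <- split(seq_along(bx), bkey)
  out_i <- integer(); out_j <- integer(); out_d <- numeric()
  acx <- floor(ax / cell); acy <- floor(ay / cell)
  for (i in seq_along(ax)) {
    cand <- unlist(buckets[paste(rep(acx[i] + -1:1, each = 3), acy[i] + -1:1)],
                   use.names = FALSE)
    if (!length(cand)) next
    d2 <- (bx[cand] - ax[i])^2 + (by[cand] - ay[i])^2
    hit <- d2 <= r^2
    if (any(hit)) {
      out_i <- c(out_i, rep(i, sum(hit)))
      out_j <- c(out_j, cand[hit])
      out_d <- c(out_d, sqrt(d2[hit]))
    }
  }
  tibble::tibble(i = out_i, j = out_j, dist = out_d)
}

#' Detect and measure droplets on every page of a well
#'
#' Runs the reference detector independently on each (channel, temperature)
#' page and returns per-page record tables ready for registration.
#'
#' @param well A `pmda_well` or `image_set` (list with `pages` + `index`).
#' @param params See [detect_params()].
#' @return Named list of per-page tibbles (detection records with per-page
#'   mean intensity of that page).
#' @export
detect_well <- function(well, params = detect_params()) {
  out <- list()
  for (k in seq_len(nrow(well$index))) {
    pg <- well$index$page[k]
    det <- detect(well$pages[[pg]], params)
    recs <- det$records
    if (nrow(recs)) {
      idx <- which(det$labels > 0L)
      f <- factor(det$labels[idx], levels = recs$id)
      recs[[paste0("mean_", pg)]] <- as.numeric(tapply(well$pages[[pg]][idx], f, mean))
    } else {
      recs[[paste0("mean_", pg)]] <- numeric()
    }
    out[[pg]] <- recs
  }
  out
}
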