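#' Sphere-equivalent droplet diameter
#'
#' Droplets in a monolayer are spherical; a volume `v` nL corresponds to a
#' diameter `(6 v * 1e6 / pi)^(1/3)` um (1 nL = 1e6 um^3), e.g. 124.07 um for
#' 1 nL, about 31 px at 4 um/px.
#'
#' @param volume_nl Droplet volume(s), nL.
#' @param pixel_scale um per pixel; `NULL` returns the diameter in um.
#' @return Diameter(s) in px (or um).
#' @export
droplet_diameter <- function(volume_nl, pixel_scale = NULL) {
  d_um <- (6 * volume_nl * 1e6 / pi)^(1 / 3)
  if (is.null(pixel_scale)) d_um else d_um / pixel_scale
}

# pixel-center convention: x = column - 1, y = row - 1 (0-based, origin top-left)
disk_indices <- function(cx, cy, r, shape) {
  rows <- max(1L, floor(cy - r) + 1L):min(shape[1], ceiling(cy + r) + 1L)
  cols <- max(1L, floor(cx - r) + 1L):min(shape[2], ceiling(cx + r) + 1L)
  dy2 <- (rows - 1 - cy)^2
  dx2 <- (cols - 1 - cx)^2
  inside <- outer(dy2, dx2, "+") <= r^2
  ij <- which(inside, arr.ind = TRUE)
  (cols[ij[, 2]] - 1L) * shape[1] + rows[ij[, 1]]
}

ellipse_indices <- function(cx, cy, a, b, theta, shape) {
  r <- max(a, b)
  rows <- max(1L, floor(cy - r) + 1L):min(shape[1], ceiling(cy + r) + 1L)
  cols <- max(1L, floor(cx - r) + 1L):min(shape[2], ceiling(cx + r) + 1L)
  g <- expand.grid(row = rows, col = cols)
  dx <- g$col - 1 - cx
  dy <- g$row - 1 - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  (g$col[keep] - 1L) * shape[1] + g$row[keep]
}

# jittered hexagonal close packing; guarantees pairwise gap >= `gap` px.
# `n_extra` reserves additional sites (e.g. for artifacts injected later) and
# `dmax_extra` widens the pitch so oversized objects still fit their site.
place_droplets <- function(diameters_px, shape, gap = 2, jitter = 1.5,
                           n_extra = 0, dmax_extra = NULL) {
  n <- length(diameters_px) + n_extra
  dmax <- max(diameters_px, dmax_extra)
  pitch <- dmax + gap + 2 * sqrt(2) * jitter
  margin <- dmax / 2 + jitter + 2
  xs <- seq(margin, shape[2] - 1 - margin, by = pitch)
  ys <- seq(margin, shape[1] - 1 - margin, by = pitch * sqrt(3) / 2)
  if (!length(xs) || !length(ys) || length(xs) * length(ys) < n) {
    need <- ceiling(sqrt(n * pitch^2 * sqrt(3) / 2)) + ceiling(2 * margin + pitch)
    stop(sprintf("image %d x %d px cannot hold %d droplets at pitch %.1f px; need about %d x %d px",
                 shape[1], shape[2], n, pitch, need, need), call. = FALSE)
  }
  sites <- expand.grid(y = seq_along(ys), x = seq_along(xs))
  sx <- xs[sites$x] + ifelse(sites$y %% 2 == 0, pitch / 2, 0)
  sy <- ys[sites$y]
  ok <- sx <= shape[2] - 1 - margin
  sx <- sx[ok]; sy <- sy[ok]
  if (length(sx) < n) {
    stop(sprintf("image too small for %d droplets after hex staggering", n), call. = FALSE)
  }
  pick <- sample.int(length(sx), n)
  tibble::tibble(
    x = sx[pick] + stats::runif(n, -jitter, jitter),
    y = sy[pick] + stats::runif(n, -jitter, jitter)
  )
}

page_shift <- function(cfg, channel, temperature) {
  cs <- cfg$channel_shifts
  if (is.null(cs)) return(c(dx = 0, dy = 0))
  row <- cs[cs$channel == channel & cs$temperature == temperature, ]
  if (nrow(row) == 0) return(c(dx = 0, dy = 0))
  c(dx = row$dx[[1]], dy = row$dy[[1]])
}

#' Render a synthetic well into multichannel, multi-temperature images
#'
#' Places the droplets of an occupancy table as non-overlapping disks on a
#' jittered hexagonal lattice (close-packed monolayers are the geometry of a
#' PMDA) and renders one 16-bit grayscale page per (channel, temperature).
#' Each page applies its configured translation, emulating the pixel shifts
#' introduced by changing fluorescence filters. Pixel values are the
#' population mean for the droplet's true call plus additive Gaussian noise,
#' clipped to the bit depth. The label mask and a droplet-level ground-truth
#' table are attached.
#'
#' @param occ Occupancy table from [draw_occupancies()].
#' @param panel The [assay_panel()].
#' @param cfg The [sim_config()] used to draw `occ`.
#' @param truth Optional precomputed [true_call_matrix()]; computed if `NULL`.
#' @return A `pmda_well` object: `pages` (named list of matrices), `index`
#'   (tibble: page, channel, temperature, dx, dy), `labels` (integer matrix),
#'   `truth` (droplet table with positions, copies, calls, artifact_class),
#'   plus `cfg` and `panel`.
#' @export
render_well <- function(occ, panel, cfg, truth = NULL) {
  stopifnot(inherits(panel, "assay_panel"), inherits(cfg, "sim_config"))
  if (is.null(truth)) truth <- true_call_matrix(occ, panel)
  n <- nrow(occ)
  shape <- cfg$image_shape
  d_px <- droplet_diameter(occ$volume_nl, cfg$pixel_scale)

  set.seed(cfg$seed + 2L)
  n_lattice_art <- sum(round(cfg$artifact_rates[c("coalesced", "debris")] * n))
  pos <- place_droplets(
    d_px, shape, n_extra = n_lattice_art,
    dmax_extra = if (n_lattice_art > 0) max(d_px) * 2^(1 / 3) else NULL)
  spare <- pos[-seq_len(n), , drop = FALSE]
  pos <- pos[seq_len(n), , drop = FALSE]

  imod <- cfg$intensity %||% intensity_model(panel$channels)
  maxval <- 2^cfg$bit_depth - 1

  labels <- matrix(0L, shape[1], shape[2])
  idx_list <- vector("list", n)
  for (i in seq_len(n)) {
    idx_list[[i]] <- disk_indices(pos$x[i], pos$y[i], d_px[i] / 2, shape)
    labels[idx_list[[i]]] <- i
  }

  index <- tidyr::expand_grid(channel = panel$channels,
                              temperature = panel$temperatures)
  index$page <- page_key(index$channel, index$temperature)
  index$dx <- 0; index$dy <- 0

  set.seed(cfg$seed + 3L)
  mu <- list()  # per page: per-droplet population mean
  for (k in seq_len(nrow(index))) {
    ch <- index$channel[k]; temp <- index$temperature[k]
    m <- imod[imod$channel == ch, ]
    if (nrow(m) == 0) m <- intensity_model(ch)
    call <- truth[[page_key(ch, temp, "call")]]
    vals <- stats::rnorm(n, m$neg_mean, m$neg_sd)
    if (any(call)) {
      posval <- stats::rnorm(sum(call), m$pos_mean, m$pos_sd)
      if (m$rain_fraction > 0) {
        rain <- stats::runif(sum(call)) < m$rain_fraction
        posval[rain] <- stats::runif(sum(rain), m$neg_mean, m$pos_mean)
      }
      vals[call] <- posval
    }
    mu[[index$page[k]]] <- vals
  }

  pages <- list()
  for (k in seq_len(nrow(index))) {
    ch <- index$channel[k]; temp <- index$temperature[k]
    sh <- page_shift(cfg, ch, temp)
    index$dx[k] <- sh[["dx"]]; index$dy[k] <- sh[["dy"]]
    img <- matrix(cfg$background_mean, shape[1], shape[2])
    vals <- mu[[index$page[k]]]
    if (sh[["dx"]] == 0 && sh[["dy"]] == 0) {
      for (i in seq_len(n)) img[idx_list[[i]]] <- vals[i]
    } else {
      for (i in seq_len(n)) {
        idx <- disk_indices(pos$x[i] + sh[["dx"]], pos$y[i] + sh[["dy"]],
                            d_px[i] / 2, shape)
        img[idx] <- vals[i]
      }
    }
    set.seed(cfg$seed + 4L + 7L * k)
    if (cfg$noise_sd > 0) img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
    img <- round(pmin(pmax(img, 0), maxval))
    pages[[index$page[k]]] <- img
  }

  truth_tab <- dplyr::bind_cols(
    tibble::tibble(id = occ$id, x = pos$x, y = pos$y, diameter_px = d_px),
    occ[setdiff(names(occ), "id")],
    truth[setdiff(names(truth), "id")]
  )
  truth_tab$artifact_class <- NA_character_

  structure(list(pages = pages, index = index, labels = labels,
                 truth = truth_tab, cfg = cfg, panel = panel, spare = spare),
            class = "pmda_well")
}

#' @export
print.pmda_well <- function(x, ...) {
  cat(sprintf("<pmda_well> %d droplet(s) (%d artifact(s)), %d page(s) of %d x %d px\n",
              sum(is.na(x$truth$artifact_class)),
              sum(!is.na(x$truth$artifact_class)),
              length(x$pages), nrow(x$pages[[1]]), ncol(x$pages[[1]])))
  invisible(x)
}

#' Inject artifact objects into a rendered well
#'
#' Adds the object classes a droplet QC stage must reject: coalesced droplets
#' (single disks of twice the nominal volume, diameter 2^(1/3) = 1.26x a
#' singleton), debris (high-eccentricity 4:1 elliptical blobs, mask
#' circularity < 0.6), and edge-clipped droplets (disks centred within a
#' radius of the image border). Counts are `round(rate * n_droplets)` per
#' class. All injected objects are appended to the label mask and the
#' ground-truth table with their `artifact_class` set.
#'
#' @param well A `pmda_well` from [render_well()].
#' @param rates Named fractions; defaults to `well$cfg$artifact_rates`.
#' @return The modified `pmda_well`. With all rates zero the input is
#'   returned unchanged.
#' @export
inject_artifacts <- function(well, rates = NULL) {
  stopifnot(inherits(well, "pmda_well"))
  cfg <- well$cfg
  rates0 <- c(coalesced = 0, debris = 0, edge_clip = 0)
  rates <- rates %||% cfg$artifact_rates
  rates0[names(rates)] <- rates
  rates <- rates0
  n_art <- round(rates * cfg$n_droplets)
  if (sum(n_art) == 0) return(well)

  shape <- cfg$image_shape
  imod <- cfg$intensity %||% intensity_model(well$panel$channels)
  maxval <- 2^cfg$bit_depth - 1
  d1 <- droplet_diameter(cfg$volume_mean, cfg$pixel_scale)
  ex <- well$truth$x; ey <- well$truth$y
  next_id <- max(well$truth$id) + 1L

  set.seed(cfg$seed + 5L)
  spare <- well$spare %||% tibble::tibble(x = numeric(), y = numeric())
  free_spot <- function(r_need, edge = FALSE) {
    if (!edge && nrow(spare) > 0) {  # lattice sites reserved at render time
      p <- c(spare$x[1], spare$y[1])
      spare <<- spare[-1, , drop = FALSE]
      return(p)
    }
    margin <- if (edge) 0 else r_need + 2
    for (try in 1:300) {
      if (edge) {
        side <- sample.int(4L, 1L)
        off <- stats::runif(1, 1, r_need * 0.8)  # centre within a radius of the border
        along <- stats::runif(1, r_need, shape[2] - 1 - r_need)
        p <- switch(side,
                    c(along, off), c(along, shape[1] - 1 - off),
                    c(off, stats::runif(1, r_need, shape[1] - 1 - r_need)),
                    c(shape[2] - 1 - off, stats::runif(1, r_need, shape[1] - 1 - r_need)))
      } else {
        p <- c(stats::runif(1, margin, shape[2] - 1 - margin),
               stats::runif(1, margin, shape[1] - 1 - margin))
      }
      if (!length(ex) || min((ex - p[1])^2 + (ey - p[2])^2) > (r_need + d1 / 2 + 2)^2) {
        return(p)
      }
    }
    NULL
  }

  new_rows <- list()
  paint <- function(idx) {
    for (k in seq_len(nrow(well$index))) {
      ch <- well$index$channel[k]
      m <- imod[imod$channel == ch, ]
      if (nrow(m) == 0) m <- intensity_model(ch)
      val <- stats::rnorm(1, m$neg_mean, m$neg_sd)
      pg <- well$index$page[k]
      sh <- c(well$index$dx[k], well$index$dy[k])
      # apply the page shift by shifting the painted linear indices
      if (sh[1] != 0 || sh[2] != 0) {
        rr <- ((idx - 1L) %% shape[1]) + round(sh[2])
        cc <- ((idx - 1L) %/% shape[1]) + round(sh[1])
        ok <- rr >= 0 & rr < shape[1] & cc >= 0 & cc < shape[2]
        idx2 <- cc[ok] * shape[1] + rr[ok] + 1L
      } else idx2 <- idx
      well$pages[[pg]][idx2] <<- round(pmin(pmax(
        val + stats::rnorm(length(idx2), 0, cfg$noise_sd), 0), maxval))
    }
  }
  add_object <- function(idx, x, y, d_eq, class) {
    well$labels[idx] <<- next_id
    paint(idx)
    row <- well$truth[1, ]
    row[1, ] <- NA
    row$id <- next_id; row$x <- x; row$y <- y; row$diameter_px <- d_eq
    row$artifact_class <- class
    for (cc in grep("^call_", names(row))) row[[cc]] <- FALSE
    new_rows[[length(new_rows) + 1L]] <<- row
    ex <<- c(ex, x); ey <<- c(ey, y)
    next_id <<- next_id + 1L
  }

  for (j in seq_len(n_art[["coalesced"]])) {
    d <- d1 * 2^(1 / 3)  # volume doubles when two droplets merge
    p <- free_spot(d / 2); if (is.null(p)) next
    add_object(disk_indices(p[1], p[2], d / 2, shape), p[1], p[2], d, "coalesced")
  }
  for (j in seq_len(n_art[["debris"]])) {
    a <- d1 * 0.8; b <- a / 4
    p <- free_spot(a); if (is.null(p)) next
    theta <- stats::runif(1, 0, pi)
    idx <- ellipse_indices(p[1], p[2], a, b, theta, shape)
    add_object(idx, p[1], p[2], 2 * sqrt(length(idx) / pi), "debris")
  }
  for (j in seq_len(n_art[["edge_clip"]])) {
    p <- free_spot(d1 / 2, edge = TRUE); if (is.null(p)) next
    idx <- disk_indices(p[1], p[2], d1 / 2, shape)
    if (!length(idx)) next
    add_object(idx, p[1], p[2], d1, "edge_clip")
  }

  if (length(new_rows)) well$truth <- dplyr::bind_rows(well$truth, new_rows)
  well$spare <- spare
  well
}

#' Maximum-intensity projection across channels at one temperature
#'
#' Droplets negative in one channel may be positive in another; detection on
#' the projection finds them all.
#'
#' @param well A `pmda_well` (or any object with `pages` + `index`).
#' @param temperature Imaging temperature; default the lowest in the index.
#' @return A matrix.
#' @export
max_projection <- function(well, temperature = NULL) {
  temperature <- temperature %||% min(well$index$temperature)
  keys <- well$index$page[well$index$temperature == temperature]
  if (!length(keys)) stop("no pages at temperature ", temperature, call. = FALSE)
  Reduce(pmax, well$pages[keys])
}

#' Standard synthetic detection fixture
#'
#' A single-channel well rendered at a given signal-to-noise ratio
#' (`SNR = (negative droplet mean - background) / pixel noise SD`, i.e. the
#' contrast of the hardest objects to find) with an optional artifact load
#' split evenly across the three artifact classes.
#'
#' @param snr Signal-to-noise ratio of negative droplets over background.
#' @param artifact_rate Total artifact fraction (split across classes).
#' @param n_droplets Number of droplets.
#' @param concentration Target concentration, copies/uL droplet phase.
#' @param seed Master seed.
#' @return A `pmda_well` with artifacts injected.
#' @export
standard_fixture <- function(snr = 10, artifact_rate = 0, n_droplets = 500,
                             concentration = 360, seed = 1L) {
  panel <- assay_panel(target_spec("T1", "FAM", 73), "FAM", 58)
  pitch <- (if (artifact_rate > 0) 31 * 2^(1 / 3) else 31) + 7
  side <- ceiling(sqrt(n_droplets * (1 + artifact_rate) * pitch^2 * sqrt(3) / 2)) + 90
  cfg <- sim_config(
    concentrations = c(T1 = concentration), n_droplets = n_droplets,
    image_shape = c(side, side), noise_sd = 1500 / snr,
    artifact_rates = c(coalesced = artifact_rate / 3, debris = artifact_rate / 3,
                       edge_clip = artifact_rate / 3),
    seed = seed
  )
  occ <- draw_occupancies(panel, cfg)
  inject_artifacts(render_well(occ, panel, cfg))
}
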