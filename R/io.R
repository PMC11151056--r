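#' Write a well's image pages as a multi-page 16-bit TIFF
#'
#' Pages are written channel-major, temperature-minor. Each page's TIFF
#' `description` tag carries a JSON object with `channel`, `temperature`,
#' `dx`, `dy`, `bit_depth`; the same page index is also written to a sidecar
#' `<path>.pages.json`.
#'
#' @param well A `pmda_well` or `image_set` (list with `pages`, `index`).
#' @param path Output TIFF path.
#' @param bit_depth Bit depth (default from the object or 16).
#' @return `path`, invisibly.
#' @export
write_image_set <- function(well, path, bit_depth = NULL) {
  bit_depth <- bit_depth %||% well$cfg$bit_depth %||% well$bit_depth %||% 16L
  maxval <- 2^bit_depth - 1
  pages <- lapply(seq_len(nrow(well$index)), function(k) {
    img <- well$pages[[well$index$page[k]]] / maxval
    attr(img, "description") <- jsonlite::toJSON(list(
      channel = well$index$channel[k], temperature = well$index$temperature[k],
      dx = well$index$dx[k] %||% 0, dy = well$index$dy[k] %||% 0,
      bit_depth = bit_depth), auto_unbox = TRUE)
    img
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(well$index[, c("page", "channel", "temperature", "dx", "dy")],
                       paste0(path, ".pages.json"), digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF in the package's page dialect
#'
#' Page metadata is taken from each page's `description` tag (JSON with
#' `channel` and `temperature`); when the tags are absent the sidecar
#' `<path>.pages.json` is used. A page with neither is a dialect error.
#'
#' @param path TIFF path.
#' @return An `image_set`: list with `pages` (named list of integer-valued
#'   matrices in ADU), `index` (tibble: page, channel, temperature, dx, dy),
#'   `bit_depth`.
#' @export
read_image_set <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  raw <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  sidecar <- paste0(path, ".pages.json")
  side <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  bit_depth <- 16L
  meta <- vector("list", length(raw))
  for (k in seq_along(raw)) {
    desc <- attr(raw[[k]], "description")
    info <- NULL
    if (!is.null(desc) && nzchar(desc)) {
      info <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
    }
    if (is.null(info) && !is.null(side) && k <= nrow(side)) info <- as.list(side[k, ])
    if (is.null(info) || is.null(info$channel) || is.null(info$temperature)) {
      stop(sprintf("page %d: missing channel/temperature tags (not in the expected TIFF dialect)", k),
           call. = FALSE)
    }
    if (length(dim(raw[[k]])) > 2) {
      stop(sprintf("page %d is not grayscale", k), call. = FALSE)
    }
    if (!is.null(info$bit_depth)) bit_depth <- as.integer(info$bit_depth)
    meta[[k]] <- tibble::tibble(channel = as.character(info$channel),
                                temperature = as.numeric(info$temperature),
                                dx = as.numeric(info$dx %||% 0),
                                dy = as.numeric(info$dy %||% 0))
  }
  index <- dplyr::bind_rows(meta)
  index$page <- page_key(index$channel, index$temperature)
  pages <- list()
  maxval <- 2^bit_depth - 1
  for (k in seq_along(raw)) {
    m <- raw[[k]]
    attributes(m) <- list(dim = dim(m))
    pages[[index$page[k]]] <- round(m * maxval)
  }
  structure(list(pages = pages,
                 index = index[, c("page", "channel", "temperature", "dx", "dy")],
                 bit_depth = bit_depth),
            class = "image_set")
}

#' Write / read the integer label mask as 16-bit TIFF
#' @param labels Integer matrix of droplet labels (0 = background).
#' @param path TIFF path.
#' @return `path` / the label matrix.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write / read the ground-truth droplet table
#' @param truth Truth tibble from a `pmda_well`.
#' @param path CSV path.
#' @return `path` / a tibble.
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a droplet table CSV
#'
#' Canonical column order: `id, x_px, y_px, diameter_px, circularity,
#' qc_status, qc_reason`, then the `mean_<channel>_<temperature>` columns
#' (and any `call_*` columns, making the file directly usable as 1-D/2-D
#' scatter-plot data).
#'
#' @param records Droplet records (unified call table or per-page records).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_droplet_table <- function(records, path) {
  out <- tibble::as_tibble(records)
  ren <- c(x_px = "x", y_px = "y", diameter_px = "diameter")
  for (nm in names(ren)) {
    if (ren[[nm]] %in% names(out)) names(out)[names(out) == ren[[nm]]] <- nm
  }
  if (!"qc_status" %in% names(out)) out$qc_status <- "valid"
  if (!"qc_reason" %in% names(out)) out$qc_reason <- "none"
  lead <- intersect(c("id", "x_px", "y_px", "diameter_px", "circularity",
                      "qc_status", "qc_reason"), names(out))
  rest <- c(grep("^mean_", names(out), value = TRUE),
            grep("^call_", names(out), value = TRUE))
  readr::write_csv(out[, c(lead, rest)], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_droplet_table
#' @export
read_droplet_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  ren <- c(x = "x_px", y = "y_px", diameter = "diameter_px")
  for (nm in names(ren)) {
    if (ren[[nm]] %in% names(out)) names(out)[names(out) == ren[[nm]]] <- nm
  }
  out
}

#' Write results to versioned JSON
#' @param results A list or tibble of results.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(list(schema_version = "1.0", results = results), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
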