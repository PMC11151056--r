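#' Define a single assay target
#'
#' A target is one amplifiable species read out on one fluorophore channel at
#' one melting-temperature (Tm) class. Targets sharing a channel are separated
#' by Tm during stepwise melting imaging: the probe-amplicon duplex fluoresces
#' only at imaging temperatures strictly below its Tm.
#'
#' @param name Target name (e.g. `"HER2"`, `"L858R"`).
#' @param channel Fluorophore channel label (e.g. `"FAM"`, `"ROX"`).
#' @param tm Melting temperature of the probe-amplicon duplex, in deg C.
#' @param rule Call rule: `"direct"` (presence = channel positive) or
#'   `"drop_off"` (presence = reference channel positive AND wildtype channel
#'   negative; used for mutant detection with a wildtype probe).
#' @param ref_channel,wt_channel Channels referenced by a `"drop_off"` rule.
#' @return A one-row tibble describing the target.
#' @export
target_spec <- function(name, channel, tm, rule = c("direct", "drop_off"),
                        ref_channel = NA_character_, wt_channel = NA_character_) {
  rule <- match.arg(rule)
  if (!is.numeric(tm) || length(tm) != 1 || is.na(tm) || tm <= 0) {
    stop("`tm` must be a single positive temperature in deg C", call. = FALSE)
  }
  if (rule == "drop_off" && (is.na(ref_channel) || is.na(wt_channel))) {
    stop("a drop_off rule needs `ref_channel` and `wt_channel`", call. = FALSE)
  }
  tibble::tibble(
    name = as.character(name), channel = as.character(channel), tm = as.numeric(tm),
    rule = rule, ref_channel = as.character(ref_channel),
    wt_channel = as.character(wt_channel)
  )
}

#' Assemble and validate an assay panel
#'
#' A panel binds targets to the instrument configuration: the ordered
#' fluorophore channels that will be imaged and the ascending imaging
#' temperatures. The fluorophore x Tm code space bounds the number of targets
#' that can be multiplexed: at most `#channels * #Tm classes`.
#'
#' @param targets A tibble of targets, usually `dplyr::bind_rows()` of
#'   [target_spec()] calls.
#' @param channels Ordered character vector of channel labels.
#' @param temperatures Strictly increasing numeric vector of imaging
#'   temperatures, deg C.
#' @return An `assay_panel` object (list with `targets`, `channels`,
#'   `temperatures`).
#' @examples
#' panel <- assay_panel(
#'   rbind(
#'     target_spec("T790M", "FAM", 73),
#'     target_spec("L858R", "FAM", 63)
#'   ),
#'   channels = "FAM", temperatures = c(58, 68)
#' )
#' @export
assay_panel <- function(targets, channels, temperatures) {
  targets <- tibble::as_tibble(targets)
  needed <- c("name", "channel", "tm", "rule")
  if (!all(needed %in% names(targets))) {
    stop("`targets` must have columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!"ref_channel" %in% names(targets)) targets$ref_channel <- NA_character_
  if (!"wt_channel" %in% names(targets)) targets$wt_channel <- NA_character_
  channels <- as.character(channels)
  temperatures <- sort_check_temps(temperatures)
  if (anyDuplicated(channels)) stop("duplicate channel labels", call. = FALSE)
  if (anyDuplicated(targets$name)) stop("duplicate target names", call. = FALSE)
  if (any(targets$tm <= 0)) stop("all `tm` must be > 0", call. = FALSE)
  n_tm <- length(unique(targets$tm))
  capacity <- length(channels) * max(n_tm, 1L)
  if (nrow(targets) > capacity) {
    stop(sprintf("panel holds %d targets but the fluorophore x Tm code space only has %d codes",
                 nrow(targets), capacity), call. = FALSE)
  }
  if (anyDuplicated(targets[, c("channel", "tm")])) {
    stop("(channel, tm) pairs must be unique within a panel", call. = FALSE)
  }
  bad <- setdiff(targets$channel, channels)
  if (length(bad)) {
    stop("target channel(s) not in panel channels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  refs <- stats::na.omit(c(targets$ref_channel, targets$wt_channel))
  bad <- setdiff(refs, channels)
  if (length(bad)) {
    stop("rule references undefined channel(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(targets = targets, channels = channels, temperatures = temperatures),
    class = "assay_panel"
  )
}

sort_check_temps <- function(temperatures) {
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 1 || any(is.na(temperatures)) || any(temperatures <= 0)) {
    stop("`temperatures` must be positive, deg C", call. = FALSE)
  }
  if (is.unsorted(temperatures, strictly = TRUE)) {
    stop("`temperatures` must be strictly increasing", call. = FALSE)
  }
  temperatures
}

#' @export
print.assay_panel <- function(x, ...) {
  cat(sprintf("<assay_panel> %d target(s), channels: %s, temperatures: %s degC\n",
              nrow(x$targets), paste(x$channels, collapse = "/"),
              paste(x$temperatures, collapse = "/")))
  print(x$targets)
  invisible(x)
}

#' Read an assay panel from a YAML file
#'
#' The schema mirrors [assay_panel()]: top-level keys `channels`,
#' `temperatures`, and `targets` (each with `name`, `channel`, `tm`, `rule`,
#' and for drop_off rules `ref_channel` and `wt_channel`). Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path Path to the YAML file.
#' @return An [assay_panel()] object.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc) || !length(doc)) stop("empty panel file: ", path, call. = FALSE)
  extra <- setdiff(names(doc), c("channels", "temperatures", "targets"))
  if (length(extra)) stop("unknown panel key(s): ", paste(extra, collapse = ", "), call. = FALSE)
  if (is.null(doc$targets) || !length(doc$targets)) stop("panel has no targets", call. = FALSE)
  targets <- purrr::map_dfr(doc$targets, function(t) {
    extra <- setdiff(names(t), c("name", "channel", "tm", "rule", "ref_channel", "wt_channel"))
    if (length(extra)) stop("unknown target key(s): ", paste(extra, collapse = ", "), call. = FALSE)
    target_spec(t$name, t$channel, t$tm, rule = t$rule %||% "direct",
                ref_channel = t$ref_channel %||% NA_character_,
                wt_channel = t$wt_channel %||% NA_character_)
  })
  assay_panel(targets, channels = unlist(doc$channels),
              temperatures = unlist(doc$temperatures))
}

#' Write an assay panel to YAML
#' @param panel An [assay_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "assay_panel"))
  tl <- purrr::pmap(panel$targets, function(name, channel, tm, rule, ref_channel, wt_channel) {
    out <- list(name = name, channel = channel, tm = tm, rule = rule)
    if (!is.na(ref_channel)) out$ref_channel <- ref_channel
    if (!is.na(wt_channel)) out$wt_channel <- wt_channel
    out
  })
  yaml::write_yaml(list(channels = as.list(panel$channels),
                        temperatures = as.list(panel$temperatures),
                        targets = tl), path)
  invisible(path)
}

#' Read a plate layout
#'
#' A layout maps SLAS-style wells (row letter + two-digit column, e.g. `A01`)
#' to sample names, panels, dilution factors, theoretical partition counts,
#' and replicate groups. Columns: `well`, `sample`, `panel`, `dilution`,
#' `n_theoretical`, `replicate_group` (last two optional).
#'
#' @param path CSV file path.
#' @return A tibble, one row per well.
#' @export
read_layout <- function(path) {
  lay <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("well", "sample", "panel", "dilution")
  missing <- setdiff(needed, names(lay))
  if (length(missing)) stop("layout missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(lay$well)) stop("duplicate well ids in layout", call. = FALSE)
  if (!all(grepl("^[A-P][0-9]{2}$", lay$well))) {
    stop("well ids must be SLAS-style, e.g. A01", call. = FALSE)
  }
  if (any(lay$dilution <= 0)) stop("dilution factors must be > 0", call. = FALSE)
  if (!"n_theoretical" %in% names(lay)) lay$n_theoretical <- NA_real_
  if (!"replicate_group" %in% names(lay)) lay$replicate_group <- lay$sample
  tibble::as_tibble(lay)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
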