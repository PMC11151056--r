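#' Default per-channel intensity model
#'
#' Mean droplet intensities in ADU for negative and positive droplets, their
#' droplet-to-droplet standard deviations, and the fraction of "rain"
#' (intermediate-intensity positives). One row per channel.
#'
#' @param channels Channel labels.
#' @param neg_mean,neg_sd,pos_mean,pos_sd Population means/SDs in ADU.
#' @param rain_fraction Fraction of positive droplets drawn uniformly between
#'   the negative and positive means.
#' @return A tibble with one row per channel.
#' @export
intensity_model <- function(channels, neg_mean = 2000, neg_sd = 100,
                            pos_mean = 8000, pos_sd = 300, rain_fraction = 0) {
  tibble::tibble(channel = as.character(channels),
                 neg_mean = neg_mean, neg_sd = neg_sd,
                 pos_mean = pos_mean, pos_sd = pos_sd,
                 rain_fraction = rain_fraction)
}

#' Simulation configuration for one synthetic well
#'
#' Defaults emulate the instrument the package models: about 20 000 droplets
#' per well of nominal 1 nL (measured mean 1.010 nL with volume CV 3.46%),
#' imaged at 4 um/px so a 1 nL droplet spans about 31 px. A full 20 000-droplet
#' well does not fit one 2048 x 2048 frame at that scale; render it as four
#' tiles of ~5000 droplets, or work at the occupancy level where no image is
#' needed.
#'
#' @param concentrations Named numeric vector, copies/uL in the droplet phase,
#'   one entry per panel target.
#' @param n_droplets Number of droplets in the well.
#' @param volume_mean,volume_cv Mean droplet volume (nL) and coefficient of
#'   variation (fraction). Volumes are drawn from a log-normal law with this
#'   mean and CV (log-normal guarantees positivity).
#' @param pixel_scale Image scale, um/px.
#' @param image_shape Image size, `c(rows, cols)` px.
#' @param bit_depth Camera bit depth; intensities are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param intensity Per-channel intensity model, see [intensity_model()].
#' @param background_mean Background (oil) level, ADU.
#' @param noise_sd Per-pixel additive Gaussian noise SD, ADU.
#' @param artifact_rates Named fractions `c(coalesced=, debris=, edge_clip=)`
#'   of `n_droplets` to inject as artifacts.
#' @param channel_shifts Tibble with columns `channel`, `temperature`, `dx`,
#'   `dy` giving the translation (px) applied to each page, emulating pixel
#'   shifts from fluorescence filter changes. `NULL` = no shift.
#' @param seed Master seed. Sub-stages use fixed offsets from it: occupancies
#'   +1, placement +2, intensity populations +3, pixel noise +4, artifacts +5.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(concentrations,
                       n_droplets = 20000,
                       volume_mean = 1.010, volume_cv = 0.0346,
                       pixel_scale = 4, image_shape = c(2048, 2048),
                       bit_depth = 16,
                       intensity = NULL,
                       background_mean = 500, noise_sd = 150,
                       artifact_rates = c(coalesced = 0, debris = 0, edge_clip = 0),
                       channel_shifts = NULL,
                       seed = 1L) {
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))) {
    stop("`concentrations` must be named by target", call. = FALSE)
  }
  if (any(concentrations < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (n_droplets < 0) stop("`n_droplets` must be >= 0", call. = FALSE)
  if (volume_mean <= 0) stop("`volume_mean` must be > 0", call. = FALSE)
  if (volume_cv < 0 || volume_cv >= 1) stop("`volume_cv` must be in [0, 1)", call. = FALSE)
  rates <- c(coalesced = 0, debris = 0, edge_clip = 0)
  rates[names(artifact_rates)] <- artifact_rates
  if (any(rates < 0 | rates > 1)) stop("artifact rates must be in [0, 1]", call. = FALSE)
  structure(
    list(concentrations = concentrations, n_droplets = as.integer(n_droplets),
         volume_mean = volume_mean, volume_cv = volume_cv,
         pixel_scale = pixel_scale, image_shape = as.integer(image_shape),
         bit_depth = as.integer(bit_depth), intensity = intensity,
         background_mean = background_mean, noise_sd = noise_sd,
         artifact_rates = rates, channel_shifts = channel_shifts,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Draw per-droplet volumes and target copy numbers
#'
#' Droplet volumes follow a log-normal law with the configured mean and CV;
#' copy numbers per target are independent Poisson draws with mean
#' `lambda_i,t = c_t * v_i * 1e-3` (c in copies/uL, v in nL), the partitioning
#' model underlying all digital PCR quantification.
#'
#' @param panel An [assay_panel()]; every target must have a concentration in
#'   `cfg$concentrations`.
#' @param cfg A [sim_config()].
#' @return A tibble with `id`, `volume_nl`, and one `copies_<target>` column
#'   per target.
#' @export
draw_occupancies <- function(panel, cfg) {
  stopifnot(inherits(panel, "assay_panel"), inherits(cfg, "sim_config"))
  if (cfg$n_droplets == 0) stop("empty well: `n_droplets` is 0", call. = FALSE)
  missing <- setdiff(panel$targets$name, names(cfg$concentrations))
  if (length(missing)) {
    stop("no concentration for target(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- cfg$n_droplets
  set.seed(cfg$seed + 1L)
  if (cfg$volume_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$volume_cv^2))
    meanlog <- log(cfg$volume_mean) - sdlog^2 / 2
    v <- stats::rlnorm(n, meanlog, sdlog)
  } else {
    v <- rep(cfg$volume_mean, n)
  }
  occ <- tibble::tibble(id = seq_len(n), volume_nl = v)
  for (t in panel$targets$name) {
    occ[[paste0("copies_", t)]] <- stats::rpois(n, cfg$concentrations[[t]] * v * 1e-3)
  }
  occ
}

#' Ground-truth channel calls at one imaging temperature
#'
#' A channel is positive in a droplet iff the droplet carries at least one
#' copy of some target on that channel whose melting temperature is strictly
#' above the imaging temperature; probe-amplicon duplexes of lower-Tm targets
#' are dissociated and quenched.
#'
#' @param occ Occupancy table from [draw_occupancies()].
#' @param panel The [assay_panel()].
#' @param temperature Imaging temperature, deg C.
#' @return A tibble `id` + one logical column per panel channel.
#' @export
true_calls <- function(occ, panel, temperature) {
  stopifnot(inherits(panel, "assay_panel"))
  if (temperature <= 0) stop("`temperature` must be > 0", call. = FALSE)
  out <- tibble::tibble(id = occ$id)
  for (ch in panel$channels) {
    on_ch <- panel$targets[panel$targets$channel == ch & panel$targets$tm > temperature, ]
    if (nrow(on_ch) == 0) {
      out[[ch]] <- rep(FALSE, nrow(occ))
    } else {
      cols <- paste0("copies_", on_ch$name)
      out[[ch]] <- rowSums(as.matrix(occ[, cols, drop = FALSE])) >= 1
    }
  }
  out
}

#' Ground-truth call matrix over all panel temperatures
#'
#' @inheritParams true_calls
#' @return A tibble `id` + logical `call_<channel>_<temperature>` columns.
#' @export
true_call_matrix <- function(occ, panel) {
  out <- tibble::tibble(id = occ$id)
  for (temp in panel$temperatures) {
    tc <- true_calls(occ, panel, temp)
    for (ch in panel$channels) out[[page_key(ch, temp, "call")]] <- tc[[ch]]
  }
  out
}

#' Build a dilution series of configurations
#'
#' Scales every target concentration by each factor and derives a distinct,
#' deterministic seed per member so replicate wells are independent yet
#' reproducible.
#'
#' @param base A [sim_config()].
#' @param factors Positive dilution factors (1 = undiluted).
#' @return A list of `sim_config` objects, one per factor.
#' @export
make_dilution_series <- function(base, factors) {
  stopifnot(inherits(base, "sim_config"))
  if (!length(factors)) stop("`factors` must be non-empty", call. = FALSE)
  if (any(factors <= 0)) stop("`factors` must be > 0", call. = FALSE)
  purrr::imap(as.list(factors), function(f, i) {
    cfg <- base
    cfg$concentrations <- base$concentrations * f
    cfg$seed <- base$seed + 101L * (i - 1L)
    cfg
  })
}

# canonical page / column naming: <prefix>_<channel>_<temperature>
page_key <- function(channel, temperature, prefix = NULL) {
  key <- paste0(channel, "_", format(temperature, trim = TRUE))
  if (is.null(prefix)) key else paste0(prefix, "_", key)
}
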