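#' Partition counts for one target or channel state
#'
#' @param n_total Number of valid analyzed droplets.
#' @param n_neg Number of negative droplets among them.
#' @param temperature Optional temperature label, deg C.
#' @return A validated one-row tibble.
#' @export
partition_counts <- function(n_total, n_neg, temperature = NA_real_) {
  if (n_total <= 0) stop("`n_total` must be > 0", call. = FALSE)
  if (n_neg < 0 || n_neg > n_total) stop("`n_neg` must be in [0, n_total]", call. = FALSE)
  tibble::tibble(n_total = as.integer(n_total), n_neg = as.integer(n_neg),
                 temperature = temperature)
}

#' Poisson estimate of mean copies per droplet
#'
#' The digital PCR estimator: with `N` droplets of which `n_neg` are
#' negative, `lambda_hat = -ln(n_neg / N)` mean copies per droplet. The
#' standard error is the delta-method value
#' `sqrt((N - n_neg) / (N * n_neg))` with a 95% CI `lambda_hat +/- 1.96 SE`;
#' for extreme counts (fewer than 10 negatives or 10 positives) the CI is
#' instead the Wilson interval on the negative fraction transformed through
#' `-ln`. A saturated well (no negatives) reports the lower bound
#' `-ln(1 / (N + 1))` with a `saturated` flag; an all-negative well reports 0
#' with an `empty` flag.
#'
#' @param counts A [partition_counts()] row (or list with `n_total`,
#'   `n_neg`).
#' @param volume_nl Mean droplet volume used for the concentration, nL
#'   (nominal 1.000 by default; override with a measured mean).
#' @param dilution Dilution factor D relating droplet-phase to sample
#'   concentration.
#' @return A `dpcr_quant` object (list): `n_total`, `n_neg`, `lambda`, `se`,
#'   `ci` (lo, hi), `concentration` and `sample_concentration` (copies/uL),
#'   `volume_nl`, `dilution`, `flag` (`"none"`/`"empty"`/`"saturated"`).
#' @export
lambda_hat <- function(counts, volume_nl = 1.0, dilution = 1.0) {
  N <- counts$n_total; k <- counts$n_neg
  if (is.null(N) || N <= 0) stop("`n_total` must be > 0", call. = FALSE)
  flag <- "none"
  if (k == 0) {
    flag <- "saturated"
    lam <- -log(1 / (N + 1))  # lower bound, not a point estimate
    se <- NA_real_
    ci <- c(lam, Inf)
  } else {
    lam <- -log(k / N)
    se <- sqrt((N - k) / (N * as.numeric(k)))
    if (k == N) {
      flag <- "empty"
      ci <- c(0, -log(wilson_interval(k, N)[1]))
    } else if (k < 10 || (N - k) < 10) {
      w <- wilson_interval(k, N)
      ci <- c(-log(w[2]), -log(w[1]))
    } else {
      ci <- lam + c(-1.96, 1.96) * se
    }
  }
  structure(list(n_total = N, n_neg = k, lambda = lam, se = se,
                 ci = ci, volume_nl = volume_nl, dilution = dilution,
                 concentration = to_concentration(lam, volume_nl, 1),
                 sample_concentration = to_concentration(lam, volume_nl, dilution),
                 flag = flag),
            class = "dpcr_quant")
}

wilson_interval <- function(k, n, z = 1.96) {
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(centre - half, 1 / (n + 1)), min(centre + half, 1 - 1e-12))
}

#' Convert mean copies per droplet to a concentration
#'
#' `c = lambda / (v * 1e-3)` copies/uL for a droplet volume `v` nL
#' (1 nL = 1e-3 uL); the sample concentration multiplies by the dilution
#' factor D.
#'
#' @param lambda Mean copies per droplet.
#' @param volume_nl Droplet volume, nL.
#' @param dilution Dilution factor.
#' @return Concentration in copies/uL.
#' @export
to_concentration <- function(lambda, volume_nl = 1.0, dilution = 1.0) {
  if (volume_nl <= 0) stop("`volume_nl` must be > 0", call. = FALSE)
  if (dilution <= 0) stop("`dilution` must be > 0", call. = FALSE)
  lambda / (volume_nl * 1e-3) * dilution
}

#' Pool replicate wells
#'
#' Component-wise sums of the counts; the pooled lambda is then computed on
#' the summed counts (per-well results are kept separately by the caller).
#'
#' @param counts_list List of [partition_counts()] rows for the same target.
#' @return A pooled [partition_counts()] row.
#' @export
pool_replicates <- function(counts_list) {
  if (!length(counts_list)) stop("no replicate wells to pool", call. = FALSE)
  partition_counts(sum(purrr::map_dbl(counts_list, "n_total")),
                   sum(purrr::map_dbl(counts_list, "n_neg")),
                   temperature = counts_list[[1]]$temperature)
}

#' Partition utilization rate
#'
#' The ratio of analyzed partitions to the theoretical partition count, as a
#' percentage (e.g. 19 946 / 20 000 = 99.73%).
#'
#' @param n_analyzed Analyzed (valid) partitions.
#' @param n_theoretical Theoretical partitions for the well.
#' @return One-row tibble: `percent`, `flagged` (TRUE when analyzed exceeds
#'   theoretical; the value is reported unclipped).
#' @export
partition_utilization <- function(n_analyzed, n_theoretical) {
  if (n_analyzed <= 0 || n_theoretical <= 0) {
    stop("partition counts must be > 0", call. = FALSE)
  }
  tibble::tibble(percent = 100 * n_analyzed / n_theoretical,
                 flagged = n_analyzed > n_theoretical)
}

#' Copy-number-variation ratio of two quantifications
#'
#' `R = c_target / c_reference` with a delta-method CI on `ln R`
#' (`var(ln R) = (SE_t / lambda_t)^2 + (SE_r / lambda_r)^2`). The call uses
#' the clinical decision thresholds: `R >= 2.0` amplified, `R < 1.5` normal;
#' the gap `[1.5, 2.0)` is reported as equivocal rather than silently
#' rounded to either side.
#'
#' @param q_target,q_ref [lambda_hat()] results for the target (e.g. HER2)
#'   and reference (e.g. CEP17) assays.
#' @return A `cnv_result` list: `ratio`, `ci`, `call`.
#' @export
cnv_ratio <- function(q_target, q_ref) {
  if (q_ref$concentration <= 0) stop("reference concentration is 0: ratio undefined", call. = FALSE)
  R <- q_target$concentration / q_ref$concentration
  var_ln <- (q_target$se / q_target$lambda)^2 + (q_ref$se / q_ref$lambda)^2
  ci <- if (is.finite(var_ln)) R * exp(c(-1.96, 1.96) * sqrt(var_ln)) else c(NA_real_, NA_real_)
  call <- if (R >= 2.0) "amplified" else if (R < 1.5) "normal" else "equivocal"
  structure(list(ratio = R, ci = ci, call = call), class = "cnv_result")
}

#' Variant allele frequency from mutant and total quantifications
#'
#' `VAF = 100 * c_mutant / c_total` percent, with a delta-method CI on the
#' log ratio, clipped to `[0, 100]`.
#'
#' @param q_mut,q_total [lambda_hat()] results for the mutant target and the
#'   total-template channel.
#' @return A `vaf_result` list: `vaf` (percent), `ci`, `detected` is left to
#'   [detect_call()].
#' @export
vaf <- function(q_mut, q_total) {
  if (q_total$concentration <= 0) stop("total concentration must be > 0", call. = FALSE)
  if (q_mut$concentration > q_total$concentration) {
    stop("mutant concentration exceeds total: inconsistent channels", call. = FALSE)
  }
  f <- 100 * q_mut$concentration / q_total$concentration
  if (q_mut$lambda > 0 && is.finite(q_mut$se)) {
    var_ln <- (q_mut$se / q_mut$lambda)^2 + (q_total$se / q_total$lambda)^2
    ci <- pmin(pmax(f * exp(c(-1.96, 1.96) * sqrt(var_ln)), 0), 100)
  } else {
    ci <- c(0, NA_real_)
  }
  structure(list(vaf = f, ci = ci), class = "vaf_result")
}

#' Mutation detection call
#'
#' A mutant is called detected when at least `k_min` mutant-positive droplets
#' are observed and the no-template control is clean.
#'
#' @param n_pos_mut Mutant-positive droplet count in the sample well.
#' @param n_pos_ntc Positive droplet count in the NTC well.
#' @param k_min Minimum positives required (default 3).
#' @return One-row tibble: `detected`, `contamination`.
#' @export
detect_call <- function(n_pos_mut, n_pos_ntc, k_min = 3) {
  if (k_min < 1) stop("`k_min` must be >= 1", call. = FALSE)
  tibble::tibble(detected = n_pos_mut >= k_min && n_pos_ntc == 0,
                 contamination = n_pos_ntc > 0)
}

#' Fluorophore x Tm encoding capacity
#'
#' Stepwise melting multiplies the fluorophore space by the number of
#' resolvable Tm classes: `capacity = n_fluorophores * n_tm`. Alongside one
#' reference code, `capacity - 1` variants are resolvable (e.g. 4 probes x
#' 2 temperatures = 8 codes = 7 variants + reference).
#'
#' @param n_fluor Number of fluorophore channels.
#' @param n_tm Number of melting-temperature classes.
#' @return One-row tibble: `codes`, `variant_slots`.
#' @export
encoding_capacity <- function(n_fluor, n_tm) {
  if (n_fluor < 1 || n_tm < 1) stop("both dimensions must be >= 1", call. = FALSE)
  tibble::tibble(codes = n_fluor * n_tm, variant_slots = n_fluor * n_tm - 1)
}

#' Percent agreement between two qualitative methods
#'
#' From the 2x2 table of a reference method vs a test method:
#' overall percent agreement `OPA = 100 (a + d) / n`, positive percent
#' agreement `PPA = 100 a / (a + b)`, negative percent agreement
#' `NPA = 100 d / (c + d)`.
#'
#' @param a Both positive. @param b Reference positive, test negative.
#' @param c_ Reference negative, test positive. @param d Both negative.
#' @return One-row tibble: `opa`, `ppa`, `npa` (percent; `NA` when the
#'   corresponding margin is empty).
#' @export
agreement_stats <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  if (n <= 0) stop("empty agreement table", call. = FALSE)
  tibble::tibble(
    opa = 100 * (a + d) / n,
    ppa = if (a + b > 0) 100 * a / (a + b) else NA_real_,
    npa = if (c_ + d > 0) 100 * d / (c_ + d) else NA_real_
  )
}
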