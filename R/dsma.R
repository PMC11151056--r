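#' Deconvolve Tm classes from stepwise-melting counts on one channel
#'
#' In a stepwise melting design, targets on one fluorophore channel are
#' separated by melting temperature: a class with Tm `tm_j` fluoresces only
#' at imaging temperatures strictly below `tm_j`. With ascending imaging
#' temperatures `t_1 < ... < t_J` and one Tm class per temperature step, the
#' cumulative Poisson load visible at `t_j` is
#' `lambda_cum(t_j) = -ln(n_neg(t_j) / N)`, summing the classes still
#' annealed there. The per-class loads follow by differencing:
#' `lambda_J = lambda_cum(t_J)` for the highest-Tm class and
#' `lambda_j = lambda_cum(t_j) - lambda_cum(t_{j+1})` below it. Sampling
#' noise can make a difference slightly negative near `lambda ~ 0`; such
#' values are clamped to zero and flagged rather than erroring.
#'
#' Because every temperature is imaged on the same droplets, the cumulative
#' estimates are dependent and closed-form SEs would be wrong; SEs come from
#' a seeded parametric bootstrap over droplets (per-class positivity
#' resampled as independent Bernoulli fields via a multinomial over the
#' 2^J class-status combinations), `B` replicates.
#'
#' @param counts Tibble with columns `temperature`, `n_total`, `n_neg`, one
#'   row per imaging temperature of one channel. `n_total` must be identical
#'   across rows (guaranteed when the table comes from [build_call_table()] +
#'   [call_droplets()]).
#' @param tm_ladder Ascending Tm values, one class per imaging temperature;
#'   class j must satisfy `t_j < tm_j <= t_{j+1}`.
#' @param volume_nl,dilution Passed to [to_concentration()].
#' @param B Bootstrap replicates (default 200).
#' @param seed Bootstrap seed.
#' @return A `dsma_result` tibble, one row per class: `tm`, `temperature`,
#'   `lambda_cum`, `lambda`, `se`, `ci_lo`, `ci_hi`, `concentration`,
#'   `clamped`; attribute `n_total`.
#' @export
dsma_deconvolve <- function(counts, tm_ladder, volume_nl = 1.0, dilution = 1.0,
                            B = 200, seed = 1L) {
  counts <- dplyr::arrange(tibble::as_tibble(counts), .data$temperature)
  J <- nrow(counts)
  if (J < 1) stop("no temperature rows", call. = FALSE)
  if (length(unique(counts$n_total)) != 1) {
    stop("n_total differs across temperatures; build a unified droplet table first (build_call_table)",
         call. = FALSE)
  }
  if (length(tm_ladder) != J) {
    stop("`tm_ladder` must have one Tm class per imaging temperature", call. = FALSE)
  }
  tm_ladder <- sort(tm_ladder)
  if (any(tm_ladder <= counts$temperature)) {
    stop("each Tm class must melt above its imaging temperature", call. = FALSE)
  }
  if (J >= 2 && any(tm_ladder[-J] > counts$temperature[-1])) {
    stop("class j must be quenched at the next imaging temperature (tm_j <= t_{j+1})",
         call. = FALSE)
  }
  if (any(counts$n_neg == 0)) {
    stop("saturated well (no negative droplets) at some temperature; dilute and re-run",
         call. = FALSE)
  }
  N <- counts$n_total[1]
  lam_cum <- -log(counts$n_neg / N)
  deconv <- function(lc) {
    lam <- c(-diff(lc), lc[J])
    list(lambda = pmax(lam, 0), clamped = lam < 0)
  }
  est <- deconv(lam_cum)

  set.seed(seed)
  boot <- matrix(NA_real_, B, J)
  p_pos <- 1 - exp(-est$lambda)  # per-class positive probability per droplet
  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), J)))
  probs <- apply(combos, 1, function(s) prod(ifelse(s, p_pos, 1 - p_pos)))
  for (b in seq_len(B)) {
    cnt <- as.vector(stats::rmultinom(1, N, probs))
    neg_b <- vapply(seq_len(J), function(j) {
      # negative at t_j iff no class with tm > t_j is positive (classes j..J)
      sum(cnt[rowSums(combos[, j:J, drop = FALSE]) == 0])
    }, numeric(1))
    neg_b <- pmax(neg_b, 1)  # guard log(0) in pathological resamples
    boot[b, ] <- deconv(-log(neg_b / N))$lambda
  }
  se <- apply(boot, 2, stats::sd)
  ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))

  structure(tibble::tibble(
    tm = tm_ladder, temperature = counts$temperature,
    lambda_cum = lam_cum, lambda = est$lambda, se = se,
    ci_lo = ci[1, ], ci_hi = ci[2, ],
    concentration = to_concentration(est$lambda, volume_nl, dilution),
    clamped = est$clamped
  ), n_total = N, class = c("dsma_result", "tbl_df", "tbl", "data.frame"))
}
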