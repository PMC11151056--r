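test_that("lambda estimator matches the closed form on the worked counts", {
  q <- lambda_hat(partition_counts(10000, 3679))
  expect_equal(q$lambda, 1.0000, tolerance = 1e-4)
  expect_equal(q$se, 0.0131, tolerance = 1e-2)
  expect_equal(q$ci, q$lambda + c(-1.96, 1.96) * q$se)
  # parametric bootstrap cross-check of the delta-method SE
  set.seed(41)
  boot <- replicate(10000, -log(rbinom(1, 10000, 3679 / 10000) / 10000))
  expect_equal(sd(boot), q$se, tolerance = 0.05)
})

test_that("empty and saturated wells are flagged, not silently valued", {
  q <- lambda_hat(partition_counts(1000, 1000))
  expect_equal(q$lambda, 0)
  expect_equal(q$flag, "empty")
  q <- lambda_hat(partition_counts(1000, 0))
  expect_equal(q$flag, "saturated")
  expect_equal(q$lambda, -log(1 / 1001))  # reported as a lower bound
  expect_error(partition_counts(0, 0), "> 0")
})

test_that("lambda is strictly decreasing in the negative count", {
  lams <- purrr::map_dbl(seq(100, 900, by = 100),
                         ~ lambda_hat(partition_counts(1000, .x))$lambda)
  expect_true(all(diff(lams) < 0))
})

test_that("extreme counts switch to the Wilson-based interval", {
  q <- lambda_hat(partition_counts(10000, 4))
  expect_true(all(is.finite(q$ci)))
  expect_lt(q$ci[1], q$lambda)
  expect_gt(q$ci[2], q$lambda)
  # Wilson interval is asymmetric near the boundary
  expect_false(isTRUE(all.equal(q$lambda - q$ci[1], q$ci[2] - q$lambda)))
})

test_that("unit conversion to copies/uL", {
  expect_equal(to_concentration(1.0, 1.0, 1), 1000)
  expect_equal(to_concentration(0, 5, 7), 0)
  expect_equal(to_concentration(1.0, 0.85, 2), 2352.9, tolerance = 1e-4)
  expect_error(to_concentration(1, 0), "> 0")
  expect_error(to_concentration(1, 1, -1), "> 0")
})

test_that("replicate pooling sums counts and shrinks the SE by sqrt(k)", {
  w <- partition_counts(10000, 3679)
  pooled <- pool_replicates(rep(list(w), 4))
  expect_equal(pooled$n_total, 40000)
  expect_equal(lambda_hat(pooled)$lambda, lambda_hat(w)$lambda)
  expect_equal(lambda_hat(pooled)$se, lambda_hat(w)$se / 2, tolerance = 1e-10)
  # order invariance
  a <- partition_counts(9000, 2000); b <- partition_counts(11000, 5000)
  expect_identical(pool_replicates(list(a, b)), pool_replicates(list(b, a)))
  expect_error(pool_replicates(list()), "no replicate")
})

test_that("partition utilization matches the reporting convention", {
  expect_equal(partition_utilization(19946, 20000)$percent, 99.73)
  expect_equal(partition_utilization(10000, 10000)$percent, 100)
  expect_equal(partition_utilization(9800, 10000)$percent, 98.0)
  over <- partition_utilization(20100, 20000)
  expect_true(over$flagged)
  expect_equal(over$percent, 100.5)  # flagged, never clipped
})

test_that("CNV ratio calls follow the 2.0 / 1.5 decision thresholds", {
  q <- function(c_) { # quant stub with concentration c_ and tiny SE
    structure(list(lambda = c_ / 1000, se = c_ / 1e6, concentration = c_),
              class = "dpcr_quant")
  }
  expect_equal(cnv_ratio(q(2200), q(1000))$call, "amplified")
  expect_equal(cnv_ratio(q(2200), q(1000))$ratio, 2.2)
  expect_equal(cnv_ratio(q(1000), q(1000))$call, "normal")
  expect_equal(cnv_ratio(q(1700), q(1000))$call, "equivocal")
  self <- cnv_ratio(q(1234), q(1234))
  expect_identical(self$ratio, 1)
  expect_error(cnv_ratio(q(1), q(0)), "undefined")
})

test_that("CNV ratio of a well against itself is exactly 1", {
  q <- lambda_hat(partition_counts(8000, 3000))
  expect_identical(cnv_ratio(q, q)$ratio, 1)
})

test_that("VAF is the mutant fraction of total, in percent", {
  q <- function(c_) structure(list(lambda = c_ / 1000, se = sqrt(c_) / 1000,
                                   concentration = c_), class = "dpcr_quant")
  expect_equal(vaf(q(1), q(1000))$vaf, 0.1)
  expect_equal(vaf(q(0), q(1000))$vaf, 0)
  expect_equal(vaf(q(50), q(1000))$vaf, 5.0)
  expect_error(vaf(q(1100), q(1000)), "exceeds")
})

test_that("mutation detection needs k_min positives and a clean NTC", {
  expect_true(detect_call(5, 0, 3)$detected)
  expect_false(detect_call(2, 0, 3)$detected)
  res <- detect_call(5, 1, 3)
  expect_false(res$detected)
  expect_true(res$contamination)
  expect_error(detect_call(5, 0, 0), ">= 1")
})

test_that("encoding capacity is the fluorophore x Tm product", {
  expect_equal(unlist(encoding_capacity(4, 2)), c(codes = 8, variant_slots = 7))
  expect_equal(encoding_capacity(1, 1)$codes, 1)
  expect_equal(encoding_capacity(6, 3)$codes, 18)
})

test_that("agreement statistics match brute-force recomputation", {
  a <- agreement_stats(13, 2, 0, 15)
  expect_equal(a$opa, 100 * 28 / 30)
  expect_equal(round(a$opa, 1), 93.3)
  expect_equal(round(a$ppa, 1), 86.7)
  expect_equal(a$npa, 100)
  p <- agreement_stats(10, 0, 0, 10)
  expect_equal(c(p$opa, p$ppa, p$npa), c(100, 100, 100))
  # brute force from a per-sample call list
  set.seed(51)
  ref <- runif(200) < 0.5; test <- ifelse(runif(200) < 0.9, ref, !ref)
  bf <- agreement_stats(sum(ref & test), sum(ref & !test),
                        sum(!ref & test), sum(!ref & !test))
  expect_equal(bf$opa, 100 * mean(ref == test))
  expect_equal(bf$ppa, 100 * mean(test[ref]))
  expect_equal(bf$npa, 100 * mean(!test[!ref]))
  expect_true(is.na(agreement_stats(0, 0, 3, 7)$ppa))
})

test_that("estimator recovery and CI coverage on simulated wells", {
  # occupancy-level wells at fixed 1 nL so the estimand is exactly lambda
  panel <- mono_panel()
  for (lam in c(0.1, 1)) {
    ests <- purrr::map_dbl(1:60, function(s) {
      cfg <- sim_config(c(T1 = lam * 1000), n_droplets = 20000, volume_mean = 1,
                        volume_cv = 0, seed = 7000 + s)
      occ <- draw_occupancies(panel, cfg)
      lambda_hat(partition_counts(20000, sum(occ$copies_T1 == 0)))$lambda
    })
    se1 <- sqrt((exp(lam) - 1) / 20000)
    expect_lt(abs(mean(ests) - lam), 3 * se1 / sqrt(60))
  }
})
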