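test_that("threshold separates a clear mixture with <0.1% misclassification", {
  for (s in 1:20) {
    set.seed(s)
    pos <- runif(5000) < 0.3
    x <- ifelse(pos, rnorm(5000, 8000, 300), rnorm(5000, 2000, 100))
    thr <- auto_threshold(x)
    expect_gt(thr$value, 2500)
    expect_lt(thr$value, 7000)
    expect_lt(mean(classify(x, thr) != pos), 0.001)
  }
})

test_that("all-negative wells fall back to the single-population guard", {
  set.seed(11)
  x <- rnorm(3000, 2000, 100)
  thr <- auto_threshold(x)
  expect_equal(thr$method, "robust_mad")
  expect_equal(sum(classify(x, thr)), 0)
})

test_that("sparse positives are still split by the two-means fallback", {
  set.seed(12)
  x <- c(rnorm(9970, 2000, 100), rnorm(30, 8000, 300))  # 0.3% positive
  thr <- auto_threshold(x)
  expect_true(thr$method %in% c("two_means", "kde_valley"))
  expect_equal(sum(classify(x, thr)), sum(x > thr$value))
  expect_equal(sum(classify(x, thr) & x < 5000), 0)
  expect_equal(sum(!classify(x, thr) & x > 5000), 0)
})

test_that("manual thresholds are used verbatim; small wells error", {
  thr <- auto_threshold(rnorm(100), manual = 4321)
  expect_equal(thr$method, "manual")
  expect_equal(thr$value, 4321)
  expect_error(auto_threshold(rnorm(49)), "50")
})

test_that("classification is strictly greater-than", {
  expect_false(classify(5, 5))
  expect_true(classify(5 + 1e-9, 5))
  x <- c(1, 2, 3, 4, 5)
  expect_equal(classify(x, 3), x > 3)
  expect_true(all(!classify(c(1, 2), 10)))
})

test_that("kde threshold is scale-equivariant", {
  set.seed(13)
  x <- c(rnorm(2000, 2000, 100), rnorm(1000, 8000, 300))
  t1 <- auto_threshold(x)
  t3 <- auto_threshold(3 * x)
  expect_equal(t1$method, "kde_valley")
  expect_equal(t3$value / t1$value, 3, tolerance = 0.02)
})

test_that("drop-off rule matches its truth table; direct is the identity", {
  panel <- assay_panel(
    rbind(target_spec("TOT", "ROX", 73),
          target_spec("MUT", "ROX", 73.5, rule = "drop_off",
                      ref_channel = "ROX", wt_channel = "HEX"),
          target_spec("WT", "HEX", 73)),
    c("ROX", "HEX"), 58)
  combos <- tidyr::expand_grid(ROX = c(FALSE, TRUE), HEX = c(FALSE, TRUE))
  calls <- dplyr::bind_cols(tibble::tibble(id = 1:4), combos)
  pres <- apply_target_rules(calls, panel)
  expect_equal(pres$presence_TOT, combos$ROX)                  # direct = identity
  expect_equal(pres$presence_MUT, combos$ROX & !combos$HEX)    # only (T, F)
  expect_equal(sum(pres$presence_MUT), 1)
  # brute-force re-evaluation per droplet
  expect_equal(pres$presence_MUT,
               purrr::map_lgl(1:4, ~ combos$ROX[.x] && !combos$HEX[.x]))
})

test_that("rules referencing missing channels error", {
  panel <- assay_panel(target_spec("A", "FAM", 73), "FAM", 58)
  expect_error(apply_target_rules(tibble::tibble(id = 1), panel),
               "no call column")
})

test_that("monotone filter drops physically inconsistent droplets", {
  mk <- function(lo, hi) tibble::tibble(id = seq_along(lo),
                                        call_FAM_58 = lo, call_FAM_68 = hi)
  ok <- mk(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  res <- monotone_filter(ok, "FAM", c(58, 68))
  expect_identical(res$calls, ok)
  expect_equal(res$inconsistency_fraction, 0)

  bad <- mk(c(rep(TRUE, 99), FALSE), c(rep(FALSE, 99), TRUE))
  res <- monotone_filter(bad, "FAM", c(58, 68))
  expect_equal(res$n_dropped, 1)
  expect_equal(res$inconsistency_fraction, 0.01)
  expect_false(100 %in% res$calls$id)
})

test_that("noise-flip inconsistencies appear at the injected rate", {
  set.seed(21)
  n <- 20000; flip <- 0.005
  lo <- runif(n) < 0.4
  hi <- lo & (runif(n) < 0.5)          # consistent melting calls
  flips <- runif(n) < flip
  hi2 <- ifelse(flips, !hi, hi)        # symmetric call noise at the high T
  res <- monotone_filter(tibble::tibble(id = 1:n, call_FAM_58 = lo,
                                        call_FAM_68 = hi2), "FAM", c(58, 68))
  # droplets flipped to positive-at-68 while negative-at-58 are the violators
  expected <- flip * mean(!lo)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(res$inconsistency_fraction - expected), 3 * se + 1e-9)
})

test_that("simulated wells are called with <0.5% channel error", {
  panel <- dual_tm_panel()
  cfg <- sim_config(c(LOW = 400, HIGH = 400), n_droplets = 300,
                    image_shape = c(700, 700), seed = 31)
  occ <- draw_occupancies(panel, cfg)
  well <- render_well(occ, panel, cfg)
  res <- analyze_well(well, panel)
  truth <- well$truth
  co <- match_records(truth, tibble::as_tibble(res$calls), radius = 4)
  expect_gt(nrow(co$matched), 250)
  it <- match(co$matched$ref_id, truth$id)
  ic <- match(co$matched$tgt_id, res$calls$id)
  for (col in c("call_FAM_58", "call_FAM_68")) {
    expect_lt(mean(truth[[col]][it] != res$calls[[col]][ic]), 0.005)
  }
})
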