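test_that("two-temperature deconvolution matches the closed form", {
  counts <- rbind(partition_counts(10000, 3679, 58),
                  partition_counts(10000, 6065, 68))
  ds <- dsma_deconvolve(counts, c(63, 73), seed = 1)
  expect_equal(ds$lambda_cum, c(1.0000, 0.5001), tolerance = 1e-4)
  expect_equal(ds$lambda, c(0.500, 0.500), tolerance = 1e-3)
  expect_false(any(ds$clamped))
  # independent cross-check: simulate occupancies at 0.5/0.5 and recover
  panel <- dual_tm_panel()
  cfg <- sim_config(c(LOW = 500, HIGH = 500), n_droplets = 20000,
                    volume_mean = 1, volume_cv = 0, seed = 99)
  occ <- draw_occupancies(panel, cfg)
  ds2 <- dsma_deconvolve(channel_counts(occ, panel, "FAM"), c(63, 73), seed = 2)
  expect_lt(abs(ds2$lambda[1] - 0.5), 3 * ds2$se[1])
  expect_lt(abs(ds2$lambda[2] - 0.5), 3 * ds2$se[2])
})

test_that("class lambdas sum exactly to the cumulative low-T lambda", {
  for (s in 1:10) {
    set.seed(s)
    N <- 5000
    n68 <- sample(2000:4500, 1)
    n58 <- sample(1000:n68, 1)  # melting monotonicity: n_neg rises with T
    ds <- dsma_deconvolve(rbind(partition_counts(N, n58, 58),
                                partition_counts(N, n68, 68)),
                          c(63, 73), B = 10, seed = s)
    expect_equal(sum(ds$lambda), ds$lambda_cum[1], tolerance = 1e-12)
  }
})

test_that("equal negatives give a zero low-Tm class; inversions clamp", {
  ds <- dsma_deconvolve(rbind(partition_counts(8000, 4000, 58),
                              partition_counts(8000, 4000, 68)),
                        c(63, 73), B = 10, seed = 1)
  expect_equal(ds$lambda[1], 0)
  expect_false(ds$clamped[1])

  ds <- dsma_deconvolve(rbind(partition_counts(8000, 4100, 58),
                              partition_counts(8000, 4000, 68)),
                        c(63, 73), B = 10, seed = 1)
  expect_equal(ds$lambda[1], 0)
  expect_true(ds$clamped[1])
  expect_false(ds$clamped[2])
})

test_that("inconsistent denominators and saturation are refused", {
  expect_error(dsma_deconvolve(rbind(partition_counts(8000, 4000, 58),
                                     partition_counts(8100, 4000, 68)),
                               c(63, 73)), "build_call_table")
  expect_error(dsma_deconvolve(rbind(partition_counts(8000, 0, 58),
                                     partition_counts(8000, 10, 68)),
                               c(63, 73)), "saturated")
  expect_error(dsma_deconvolve(partition_counts(8000, 100, 58), c(50)),
               "melt above")
})

test_that("three-class ladders deconvolve with conservation", {
  # lambda = 0.3 / 0.5 / 0.2 visible cumulatively at 55 / 65 / 75 degC
  N <- 20000
  lam <- c(0.3, 0.5, 0.2)
  cum <- rev(cumsum(rev(lam)))
  set.seed(61)
  # joint droplet simulation: class positivity independent per droplet
  pos <- sapply(lam, function(l) rpois(N, l) > 0)
  n_neg <- sapply(1:3, function(j) sum(rowSums(pos[, j:3, drop = FALSE]) == 0))
  ds <- dsma_deconvolve(tibble::tibble(temperature = c(55, 65, 75),
                                       n_total = N, n_neg = n_neg),
                        tm_ladder = c(60, 70, 80), B = 50, seed = 3)
  expect_equal(sum(ds$lambda), ds$lambda_cum[1], tolerance = 1e-12)
  for (j in 1:3) expect_lt(abs(ds$lambda[j] - lam[j]), 4 * ds$se[j])
})

test_that("bootstrap SEs are reproducible and scale like 1/sqrt(N)", {
  counts <- function(N) rbind(partition_counts(N, round(N * exp(-1)), 58),
                              partition_counts(N, round(N * exp(-0.5)), 68))
  a <- dsma_deconvolve(counts(20000), c(63, 73), seed = 7)
  b <- dsma_deconvolve(counts(20000), c(63, 73), seed = 7)
  expect_identical(a$se, b$se)
  small <- dsma_deconvolve(counts(2000), c(63, 73), seed = 7)
  expect_gt(small$se[1] / a$se[1], 2)  # ~ sqrt(10) expected
})
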