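make_disk_image <- function(shape, cx, cy, r, fg = 5000, bg = 500, noise = 0,
                            seed = 1) {
  set.seed(seed)
  img <- matrix(bg, shape[1], shape[2])
  for (row in 1:shape[1]) for (col in 1:shape[2]) {
    if ((col - 1 - cx)^2 + (row - 1 - cy)^2 <= r^2) img[row, col] <- fg
  }
  if (noise > 0) img <- img + rnorm(length(img), 0, noise)
  img
}

test_that("Gaussian prefilter: identity at sigma 0, smoothing reduces noise", {
  img <- matrix(runif(100 * 100), 100, 100)
  expect_identical(preprocess(img, 0), img)
  const <- matrix(7, 50, 50)
  expect_equal(preprocess(const, 3), const, tolerance = 1e-6)
  set.seed(1)
  noisy <- matrix(rnorm(200 * 200), 200, 200)
  expect_lt(sd(preprocess(noisy, 2)), sd(noisy))
})

test_that("detector finds nothing in blank images and one disk exactly", {
  expect_equal(nrow(detect(matrix(500, 200, 200))$records), 0)
  img <- make_disk_image(c(150, 150), cx = 70, cy = 60, r = 15,
                         noise = 450, seed = 2)  # SNR 10
  det <- detect(img, detect_params(expected_diameter = 30))
  expect_equal(nrow(det$records), 1)
  expect_lt(abs(det$records$x - 70), 0.5)
  expect_lt(abs(det$records$y - 60), 0.5)
  expect_error(detect_params(expected_diameter = 30, min_diameter = 40,
                             max_diameter = 30), "min_diameter")
})

test_that("detector meets the fixture contract (500 droplets, SNR 10)", {
  well <- standard_fixture(snr = 10, artifact_rate = 0, n_droplets = 500, seed = 21)
  det <- detect(max_projection(well), detect_params(expected_diameter = 31))
  m <- evaluate_detection(det$records, well$truth, match_radius = 5)
  expect_gte(m$precision, 0.99)
  expect_gte(m$recall, 0.99)
})

test_that("feature measurement is exact on uniform disks", {
  img <- make_disk_image(c(120, 120), cx = 60, cy = 60, r = 14)
  det <- detect(img, detect_params(expected_diameter = 28, sigma = 0))
  pages <- list(FAM_58 = img, ROX_58 = matrix(1234, 120, 120))
  recs <- measure_features(det$labels, pages)
  expect_equal(recs$mean_FAM_58, 5000)      # uniform fill measured exactly
  expect_equal(recs$mean_ROX_58, 1234)      # per-page means independent
  expect_gte(recs$circularity, 0.9)         # ideal disk, d >= 20 px
  expect_error(measure_features(det$labels, pages, ids = 99), "absent")
  expect_error(measure_features(det$labels, list(FAM = matrix(0, 2, 2))),
               "geometry")
})

test_that("QC passes homogeneous wells and rejects each artifact class", {
  well <- standard_fixture(snr = 10, artifact_rate = 0, n_droplets = 200, seed = 5)
  recs <- measure_features(well$labels, well$pages)
  qc <- qc_filter(recs, qc_rules(), image_shape = dim(well$labels))
  expect_true(all(qc$qc_status == "valid"))

  well <- standard_fixture(snr = 10, artifact_rate = 0.06, n_droplets = 200, seed = 7)
  recs <- measure_features(well$labels, well$pages)
  qc <- qc_filter(recs, qc_rules(), image_shape = dim(well$labels))
  truth <- well$truth
  reason_of <- function(class) {
    ids <- truth$id[!is.na(truth$artifact_class) & truth$artifact_class == class]
    qc$qc_reason[qc$id %in% ids]
  }
  # coalesced: 1.26x diameter exceeds the (1 + 0.25) x median gate
  expect_true(all(reason_of("coalesced") == "oversized"))
  expect_true(all(reason_of("debris") == "irregular"))
  # clipped disks can fail the size or shape gate before the border rule fires
  expect_true(all(reason_of("edge_clip") %in% c("edge", "undersized", "irregular")))
  # conservation: every droplet is either valid or rejected
  expect_equal(sum(qc$qc_status == "valid") + sum(qc$qc_status == "rejected"),
               nrow(recs))
  expect_error(qc_filter(recs[0, ]), "no droplet")
})

test_that("detection scoring counts greedy one-to-one matches", {
  truth <- tibble::tibble(x = seq(10, 100, by = 10), y = 5)
  perfect <- tibble::tibble(id = 1:10, x = truth$x, y = truth$y)
  m <- evaluate_detection(perfect, truth, 3)
  expect_equal(c(m$precision, m$recall), c(1, 1))

  none <- evaluate_detection(perfect[0, ], truth, 3)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)
  expect_true(none$undefined_precision)

  spurious <- dplyr::bind_rows(perfect, tibble::tibble(id = 11, x = 200, y = 200))
  m <- evaluate_detection(spurious, truth, 3)
  expect_equal(m$precision, 10 / 11, tolerance = 1e-12)
  expect_equal(m$fp, 1)
})

test_that("the reference detector is deterministic", {
  well <- standard_fixture(snr = 5, artifact_rate = 0, n_droplets = 100, seed = 9)
  img <- max_projection(well)
  expect_identical(detect(img), detect(img))
})
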