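test_that("a 1 nL droplet maps to a 124.07 um disk", {
  expect_equal(droplet_diameter(1.0), (6e6 / pi)^(1 / 3), tolerance = 1e-12)
  expect_equal(droplet_diameter(1.0), 124.07, tolerance = 1e-4)
  expect_equal(droplet_diameter(1.0, pixel_scale = 4), 124.07 / 4, tolerance = 1e-4)
})

test_that("a noiseless singleton renders at its sampled centre", {
  panel <- mono_panel()
  cfg <- sim_config(c(T1 = 0), n_droplets = 1, image_shape = c(120, 120),
                    noise_sd = 0, seed = 4)
  occ <- draw_occupancies(panel, cfg)
  well <- render_well(occ, panel, cfg)
  idx <- which(well$labels == 1)
  y <- (idx - 1) %% 120; x <- (idx - 1) %/% 120
  expect_lt(abs(mean(x) - well$truth$x), 0.5)
  expect_lt(abs(mean(y) - well$truth$y), 0.5)
  # mask diameter matches the sphere-equivalent diameter
  expect_equal(2 * sqrt(length(idx) / pi), well$truth$diameter_px, tolerance = 0.05)
})

test_that("a configured page shift moves the cross-correlation peak", {
  panel <- assay_panel(target_spec("T1", "FAM", 73), c("FAM", "ROX"), 58)
  shifts <- tibble::tibble(channel = "ROX", temperature = 58, dx = 3, dy = -2)
  cfg <- sim_config(c(T1 = 400), n_droplets = 60, image_shape = c(360, 360),
                    noise_sd = 0, channel_shifts = shifts, seed = 6)
  occ <- draw_occupancies(panel, cfg)
  well <- render_well(occ, panel, cfg)
  a <- well$pages[["FAM_58"]]; b <- well$pages[["ROX_58"]]
  # FFT cross-correlation as an independent oracle for the displacement
  fa <- fft(a - mean(a)); fb <- fft(b - mean(b))
  cc <- Re(fft(Conj(fa) * fb, inverse = TRUE))
  peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(k, n) ifelse(k - 1 > n / 2, k - 1 - n, k - 1)
  expect_equal(wrap(peak[["col"]], 360), 3)   # dx (columns)
  expect_equal(wrap(peak[["row"]], 360), -2)  # dy (rows)
})

test_that("rendering conserves droplet count in the label mask", {
  well <- standard_fixture(snr = 10, artifact_rate = 0.05, n_droplets = 120, seed = 8)
  n_art <- sum(!is.na(well$truth$artifact_class))
  expect_gt(n_art, 0)
  expect_equal(sort(unique(as.vector(well$labels[well$labels > 0]))),
               seq_len(120 + n_art))
  expect_equal(nrow(well$truth), 120 + n_art)
})

test_that("artifact injection with zero rates is the identity", {
  panel <- mono_panel()
  cfg <- sim_config(c(T1 = 300), n_droplets = 50, image_shape = c(300, 300), seed = 2)
  well <- render_well(draw_occupancies(panel, cfg), panel, cfg)
  expect_identical(inject_artifacts(well, c(coalesced = 0, debris = 0, edge_clip = 0)),
                   well)
})

test_that("coalesced droplets are 1.26x singletons; debris is irregular", {
  well <- standard_fixture(snr = 10, artifact_rate = 0.06, n_droplets = 150, seed = 12)
  truth <- well$truth
  d1 <- droplet_diameter(well$cfg$volume_mean, well$cfg$pixel_scale)
  co <- truth[!is.na(truth$artifact_class) & truth$artifact_class == "coalesced", ]
  expect_gt(nrow(co), 0)
  expect_equal(co$diameter_px / d1, rep(2^(1 / 3), nrow(co)), tolerance = 0.02)
  # circularity of debris truth masks, measured on the rendered mask itself
  de <- truth[!is.na(truth$artifact_class) & truth$artifact_class == "debris", ]
  expect_gt(nrow(de), 0)
  shapes <- measure_features(well$labels, well$pages[1])
  expect_true(all(shapes$circularity[shapes$id %in% de$id] < 0.6))
})

test_that("rendering is bit-reproducible under a fixed seed", {
  panel <- mono_panel()
  cfg <- sim_config(c(T1 = 500), n_droplets = 40, image_shape = c(280, 280), seed = 33)
  occ <- draw_occupancies(panel, cfg)
  w1 <- render_well(occ, panel, cfg)
  w2 <- render_well(occ, panel, cfg)
  expect_identical(w1$pages, w2$pages)
  expect_identical(w1$truth, w2$truth)
})

test_that("an overfull well raises a geometry error naming a size", {
  panel <- mono_panel()
  cfg <- sim_config(c(T1 = 0), n_droplets = 500, image_shape = c(200, 200), seed = 1)
  occ <- draw_occupancies(panel, cfg)
  expect_error(render_well(occ, panel, cfg), "cannot hold .* need about")
})
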