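test_that("phantom generation is a pure function of the seed", {
  sp <- tiny_phantom(seed = 5)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$mask, b$truth$mask)
  expect_true(all(a$image$pixels >= 0 & a$image$pixels <= 1))
  # truth regions live inside the tissue band, none touch the borders
  expect_gt(sum(a$truth$mask), 0)
  expect_false(any(a$truth$mask[c(1, nrow(a$truth$mask)), ]))
})

test_that("speckle follows the Poisson count-noise contract", {
  # high-lambda limit: noise vanishes
  hi <- generate_phantom(phantom_spec(height_px = 120, width_px = 160,
                                      n_regions = 0, noise_lambda = 1e9,
                                      seed = 2))
  expect_lt(max(abs(hi$image$pixels - hi$clean)), 1e-3)

  # variance ~ clean/lambda at clean levels where [0,1] clipping is negligible
  lam <- 5
  ph <- generate_phantom(phantom_spec(n_regions = 0, noise_lambda = lam, seed = 3))
  resid <- ph$image$pixels - ph$clean
  sel <- abs(ph$clean - 0.25) < 0.01  # deep band, ~8e4 pixels
  expect_gt(sum(sel), 1e4)
  expect_equal(var(resid[sel]), mean(ph$clean[sel]) / lam, tolerance = 0.1)
  # mean preservation
  expect_equal(mean(ph$image$pixels[sel]), mean(ph$clean[sel]), tolerance = 0.01)
})

test_that("the identity annotator reproduces the truth exactly", {
  ph <- generate_phantom(tiny_phantom(seed = 7))
  ident <- rater_profile("id", "expert")
  out <- simulate_annotator(ph$truth, ph$image, ident, seed = 1)
  expect_identical(out$mask, ph$truth$mask)
  # total omission
  misser <- rater_profile("m", "junior", miss_rate = 1)
  out2 <- simulate_annotator(ph$truth, ph$image, misser, seed = 1)
  expect_identical(sum(out2$mask), 0L)
})

test_that("a +2 px boundary bias dilates a disc to the predicted IoU", {
  tr <- annotation_mask(disc_mask(100, 100, 50, 50, 20), "d", "truth")
  img <- bscan(matrix(0.5, 100, 100), "d")
  out <- simulate_annotator(tr, img, rater_profile("b", "junior",
                                                   boundary_bias_px = 2),
                            seed = 3)
  expect_true(all(tr$mask[!out$mask] == FALSE))  # pure dilation: superset
  iou <- sum(out$mask & tr$mask) / sum(out$mask | tr$mask)
  expect_equal(iou, 400 / 484, tolerance = 0.03)  # r^2/(r+2)^2, rasterised
})

test_that("expected IoU degrades monotonically in each error parameter", {
  tr <- annotation_mask(disc_mask(120, 120, 60, 60, 18) |
                          disc_mask(120, 120, 40, 90, 10), "d", "truth")
  img <- bscan(matrix(0.5, 120, 120), "d")
  mean_iou <- function(profile) {
    mean(vapply(1:20, function(s) {
      out <- simulate_annotator(tr, img, profile, seed = s)
      sum(out$mask & tr$mask) / sum(out$mask | tr$mask)
    }, numeric(1)))
  }
  for (param in c("boundary_bias_px", "jitter_sd_px", "miss_rate")) {
    levels <- switch(param, boundary_bias_px = c(0, 2, 4),
                     jitter_sd_px = c(0, 2, 4), miss_rate = c(0, 0.3, 0.8))
    ious <- vapply(levels, function(v) {
      args <- list(rater_id = "x", tier = "junior")
      args[[param]] <- v
      mean_iou(do.call(rater_profile, args))
    }, numeric(1))
    expect_true(all(diff(ious) < 0), label = paste("monotone in", param))
  }
})

test_that("positive bias brightens the annotated area (oversegmentation signature)", {
  ph <- generate_phantom(tiny_phantom(seed = 9, noise_lambda = 40))
  over <- rater_profile("ov", "junior", boundary_bias_px = 3)
  means <- vapply(1:10, function(s) {
    out <- simulate_annotator(ph$truth, ph$image, over, seed = s)
    c(mean(ph$image$pixels[out$mask]), mean(ph$image$pixels[ph$truth$mask]))
  }, numeric(2))
  expect_gt(mean(means[1, ]), mean(means[2, ]))
})

test_that("study generation is deterministic and stable under adding raters", {
  specs <- lapply(1:2, function(i) tiny_phantom(seed = NULL, n_regions = 3))
  profs <- default_rater_profiles()[c("Ex1", "Jr1")]
  s1 <- generate_study(specs, profs, rounds = 2, seed = 77)
  s2 <- generate_study(specs, profs, rounds = 2, seed = 77)
  expect_identical(s1$masks, s2$masks)
  expect_identical(s1$images, s2$images)
  expect_length(s1$masks, 2 * 2 * 2)  # images x raters x rounds
  expect_length(s1$truth, 2)

  # adding a rater must not change the existing raters' masks
  s3 <- generate_study(specs, default_rater_profiles()[c("Ex1", "Jr1", "Jr2")],
                       rounds = 2, seed = 77)
  key <- function(m) sprintf("%s_%s_%d", m$image_id, m$rater_id, m$round_id)
  m1 <- setNames(s1$masks, vapply(s1$masks, key, character(1)))
  m3 <- setNames(s3$masks, vapply(s3$masks, key, character(1)))
  expect_true(all(vapply(names(m1), function(k)
    identical(m1[[k]]$mask, m3[[k]]$mask), logical(1))))

  # single-round raters contribute only round 1
  s4 <- generate_study(specs, profs, rounds = 2, seed = 77,
                       single_round_raters = "Ex1")
  expect_length(s4$masks, 2 * 1 + 2 * 2)
  expect_error(generate_study(specs, profs, rounds = 0, seed = 1), "rounds")
})

test_that("a written study loads back equal through the manifest", {
  dir <- withr::local_tempdir()
  st <- generate_study(lapply(1:2, function(i) tiny_phantom(NULL, 3)),
                       default_rater_profiles()[c("Ex1", "Ex2")],
                       rounds = 1, seed = 5)
  write_study(st, dir)
  back <- load_study(load_manifest(file.path(dir, "manifest.json")))
  expect_identical(names(back$images), names(st$images))
  for (img in names(st$images))
    expect_lt(max(abs(back$images[[img]]$pixels - st$images[[img]]$pixels)),
              1 / 255 + 1e-12)
  key <- function(m) sprintf("%s_%s_%d", m$image_id, m$rater_id, m$round_id)
  bm <- setNames(back$masks, vapply(back$masks, key, character(1)))
  for (m in st$masks) expect_identical(bm[[key(m)]]$mask, m$mask)
})
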