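test_that("connected components follow 8-connectivity with deterministic order", {
  m <- matrix(FALSE, 10, 12)
  m[2:4, 2:4] <- TRUE
  m[7:9, 8:10] <- TRUE
  regs <- connected_regions(m)
  expect_length(regs, 2)
  expect_identical(vapply(regs, `[[`, integer(1), "area_px"), c(9L, 9L))
  expect_identical(regs[[1]]$region_id, 1L)  # top-left block first
  expect_lt(regs[[1]]$centroid[["row"]], regs[[2]]$centroid[["row"]])

  # squares touching only diagonally merge under 8- but not 4-connectivity
  d <- matrix(FALSE, 8, 8)
  d[2:3, 2:3] <- TRUE; d[4:5, 4:5] <- TRUE
  expect_length(connected_regions(d, 8), 1)
  expect_length(connected_regions(d, 4), 2)

  # full image is one region; empty mask none
  full <- matrix(TRUE, 6, 7)
  expect_identical(connected_regions(full)[[1]]$area_px, 42L)
  expect_length(connected_regions(matrix(FALSE, 5, 5)), 0)
})

test_that("labelling agrees with brute-force flood fill on random masks", {
  set.seed(51)
  for (i in 1:8) {
    m <- random_mask(15, 15, p = runif(1, 0.2, 0.6))
    for (conn in c(8L, 4L)) {
      regs <- connected_regions(m, conn)
      bf <- brute_components(m, conn)
      expect_length(regs, max(bf))
      # same partition: every package region maps to exactly one brute label
      for (reg in regs) expect_length(unique(bf[reg$pixels]), 1)
    }
  }
})

test_that("boundary bands have the expected geometry", {
  # 5x5 solid square away from borders: 16 inner, 24 outer
  m <- matrix(FALSE, 20, 20); m[8:12, 8:12] <- TRUE
  b <- boundary_bands(connected_regions(m)[[1]])
  expect_length(b$inner_band, 16)
  expect_length(b$outer_band, 24)
  # 1x1 region: inner is the pixel, outer its 8 neighbours
  m2 <- matrix(FALSE, 7, 7); m2[4, 4] <- TRUE
  b2 <- boundary_bands(connected_regions(m2)[[1]])
  expect_identical(b2$inner_band, which(m2))
  expect_length(b2$outer_band, 8)
  # at the image corner the outer band is clipped
  m3 <- matrix(FALSE, 7, 7); m3[1, 1] <- TRUE
  expect_length(boundary_bands(connected_regions(m3)[[1]])$outer_band, 3)
})

test_that("band geometry invariants hold and match neighbour-scan oracle", {
  set.seed(52)
  for (i in 1:6) {
    m <- random_mask(14, 14, 0.35)
    regs <- connected_regions(m)
    for (reg in regs) {
      b <- boundary_bands(reg)
      rm <- matrix(FALSE, 14, 14); rm[reg$pixels] <- TRUE
      expect_true(all(b$inner_band %in% reg$pixels))
      expect_false(any(b$outer_band %in% which(m)))  # outer never touches mask
      bf <- brute_bands(rm)
      expect_setequal(b$inner_band, bf$inner)
      expect_setequal(b$outer_band, bf$outer)
    }
  }
})

test_that("boundary intensity contrast reflects annotation accuracy", {
  # constant image: no contrast
  img0 <- bscan(matrix(0.5, 30, 30), "c")
  m <- matrix(FALSE, 30, 30); m[10:20, 10:20] <- TRUE
  reg <- connected_regions(m)[[1]]
  expect_equal(boundary_intensity_stats(img0, reg)$diff_outer_inner, 0)

  # dark disc in bright tissue, exact annotation: diff near the full contrast
  px <- matrix(0.5, 60, 60)
  dm <- disc_mask(60, 60, 30, 30, 12)
  px[dm] <- 0.05
  img <- bscan(px, "d")
  exact <- boundary_intensity_stats(img, connected_regions(dm)[[1]])
  expect_equal(exact$diff_outer_inner, 0.45, tolerance = 0.02)
  expect_equal(exact$mean_region, 0.05, tolerance = 0.01)

  # oversegmented annotation (dilated beyond the disc) has smaller contrast
  dil <- disc_mask(60, 60, 30, 30, 15)
  over <- boundary_intensity_stats(img, connected_regions(dil)[[1]])
  expect_lt(over$diff_outer_inner, exact$diff_outer_inner)
  expect_gt(over$mean_region, exact$mean_region)
})

test_that("zone assignment converts lateral distance with the X scaling", {
  img <- bscan(matrix(0.5, 428, 732), "z", scale_x_um = 10.5)
  reg_at <- function(col) structure(list(centroid = c(row = 200, col = col),
                                         dim = c(428L, 732L)),
                                    class = "annotated_region")
  centre <- 732 / 2 + 1  # 0-based centre column width/2, in 1-based coords
  expect_identical(zone_of(reg_at(centre), img), 1L)
  expect_identical(zone_of(reg_at(centre + 40), img), 1L)   # 0.42 mm
  expect_identical(zone_of(reg_at(centre + 100), img), 2L)  # 1.05 mm
  expect_identical(zone_of(reg_at(centre + 200), img), 3L)  # 2.10 mm
  expect_true(is.na(zone_of(reg_at(centre + 300), img)))    # 3.15 mm
  # zones partition: every centroid falls in exactly one of 1,2,3,none
  set.seed(53)
  cols <- runif(50, 1, 732)
  zs <- vapply(cols, function(cc) {
    z <- zone_of(reg_at(cc), img)
    if (is.na(z)) 4L else z
  }, integer(1))
  expect_true(all(zs %in% 1:4))
  expect_length(zs, 50)
})

test_that("noise groups use half-open bins at the shared endpoints", {
  expect_identical(noise_group(4.88), "low")
  expect_identical(noise_group(19.99), "low")
  expect_identical(noise_group(20), "medium")
  expect_identical(noise_group(39.99), "medium")
  expect_identical(noise_group(40), "high")
  expect_identical(noise_group(80.76), "high")
  expect_error(noise_group(0), "positive")
})

test_that("lambda estimation orders noise levels and rejects flat images", {
  ord_ok <- 0
  for (s in 1:5) {
    lo <- generate_phantom(tiny_phantom(seed = s, noise_lambda = 5))
    hi <- generate_phantom(tiny_phantom(seed = s + 100, noise_lambda = 40))
    if (estimate_noise_lambda(lo$image)$lambda_hat <
        estimate_noise_lambda(hi$image)$lambda_hat) ord_ok <- ord_ok + 1
  }
  expect_gte(ord_ok, 5)
  expect_error(estimate_noise_lambda(bscan(matrix(0.5, 64, 64), "flat")),
               "no noise signal")
})
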