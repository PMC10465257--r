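test_that("confusion counting matches a brute-force double loop", {
  set.seed(21)
  for (i in 1:5) {
    p <- random_mask(50, 50); r <- random_mask(50, 50)
    cc <- confusion_counts(p, r)
    bf <- brute_confusion(p, r)
    expect_identical(cc$TP, bf$TP)
    expect_identical(cc$TN, bf$TN)
    expect_identical(cc$FP, bf$FP)
    expect_identical(cc$FN, bf$FN)
  }
  # identity and complement edge cases
  r <- matrix(TRUE, 10, 10)
  cc <- confusion_counts(!r, r)
  expect_identical(c(cc$TP, cc$FN, cc$FP, cc$TN), c(0L, 100L, 0L, 0L))
  expect_error(confusion_counts(random_mask(3, 3), random_mask(4, 3)),
               "not aligned")
  # window restricts the tallies
  w <- matrix(FALSE, 10, 10); w[1:5, ] <- TRUE
  cc2 <- confusion_counts(r, r, window = w)
  expect_identical(cc2$TP + cc2$TN + cc2$FP + cc2$FN, 50L)
})

test_that("hand-worked coefficient examples are reproduced", {
  c1 <- confusion(TP = 40, TN = 40, FP = 10, FN = 10)
  k1 <- cohens_kappa(c1)
  expect_equal(unname(k1), c(0.6, 0.8, 0.5))
  a1 <- gwets_ac1(c1, "annotator_marginal")
  expect_equal(a1[["pe"]], 0.5)
  expect_equal(a1[["ac1"]], 0.6)
  expect_equal(gwets_ac1(c1, "standard")[["ac1"]], 0.6)  # symmetric marginals

  c2 <- confusion(TP = 90, TN = 5, FP = 3, FN = 2)
  k2 <- cohens_kappa(c2)
  expect_equal(k2[["pe"]], 0.8612)
  expect_equal(k2[["kappa"]], (0.95 - 0.8612) / (1 - 0.8612))
  a2p <- gwets_ac1(c2, "annotator_marginal")
  expect_equal(a2p[["pe"]], 0.93^2 + 0.07^2)
  expect_equal(a2p[["ac1"]], (0.95 - 0.8698) / (1 - 0.8698))
  a2s <- gwets_ac1(c2, "standard")
  expect_equal(a2s[["pe"]], 2 * 0.925 * 0.075)
  expect_equal(a2s[["ac1"]], (0.95 - 0.13875) / (1 - 0.13875))
})

test_that("degenerate denominators yield undefined (NA), never 0 or 1", {
  c0 <- confusion(TP = 0, TN = 100, FP = 0, FN = 0)
  ov <- overlap_metrics(c0)
  expect_true(all(is.na(ov[c("iou", "dsc", "tpr", "precision")])))
  expect_equal(ov[["tnr"]], 1)
  # pe = 1: kappa/AC1 undefined
  expect_true(is.na(cohens_kappa(c0)[["kappa"]]))
  expect_true(is.na(gwets_ac1(c0)[["ac1"]]))
  expect_error(cohens_kappa(confusion(0, 0, 0, 0)), "at least one pixel")
})

test_that("kappa is symmetric in pred/ref; annotator-marginal AC1 is not", {
  set.seed(31)
  found_asym <- FALSE
  for (i in 1:10) {
    p <- random_mask(30, 30, 0.2); r <- random_mask(30, 30, 0.4)
    a <- confusion_counts(p, r)
    b <- confusion_counts(r, p)
    expect_equal(cohens_kappa(a)[["kappa"]], cohens_kappa(b)[["kappa"]],
                 tolerance = 1e-12)
    expect_equal(gwets_ac1(a, "standard")[["ac1"]],
                 gwets_ac1(b, "standard")[["ac1"]], tolerance = 1e-12)
    if (abs(gwets_ac1(a)[["ac1"]] - gwets_ac1(b)[["ac1"]]) > 1e-6)
      found_asym <- TRUE
  }
  expect_true(found_asym)
})

test_that("perfect agreement forces every defined coefficient to 1", {
  set.seed(32)
  m <- random_mask(20, 20, 0.3)
  cc <- confusion_counts(m, m)
  sc <- agreement_scores(cc)
  expect_equal(sc$po, 1)
  expect_equal(sc$kappa, 1)
  expect_equal(sc$ac1_annotator, 1)
  expect_equal(sc$ac1_standard, 1)
  expect_equal(sc$iou, 1)
})

test_that("chance-corrected coefficients order by their chance terms at fixed po", {
  # (po - pe)/(1 - pe) is decreasing in pe when po < 1, so on imbalanced
  # masks the annotator-marginal AC1 sits below kappa iff its pe is larger
  set.seed(33)
  for (i in 1:10) {
    r <- matrix(FALSE, 40, 40); r[sample(1600, 40)] <- TRUE   # ~97% background
    p <- r; flips <- sample(1600, 30); p[flips] <- !p[flips]  # imperfect overlap
    cc <- confusion_counts(p, r)
    k <- cohens_kappa(cc); a <- gwets_ac1(cc, "annotator_marginal")
    if (a[["pe"]] > k[["pe"]]) expect_lt(a[["ac1"]], k[["kappa"]])
    if (a[["pe"]] < k[["pe"]]) expect_gt(a[["ac1"]], k[["kappa"]])
  }
})

test_that("kappa interpretation bands match the conventional cut points", {
  expect_identical(kappa_category(0.94), "almost-perfect")
  expect_identical(kappa_category(0.56), "moderate")
  expect_identical(kappa_category(0), "none")
  expect_identical(kappa_category(-0.3), "none")
  expect_identical(kappa_category(0.1), "none-to-slight")
  expect_identical(kappa_category(0.3), "fair")
  expect_identical(kappa_category(0.7), "substantial")
  expect_identical(kappa_category(0.81), "almost-perfect")
  expect_error(kappa_category(1.2), "must lie")
})

test_that("pairwise matrices equal per-pair brute-force computation", {
  set.seed(34)
  imgs <- list(a = bscan(matrix(0.5, 12, 12), "a"),
               b = bscan(matrix(0.5, 12, 12), "b"))
  raters <- c("r1", "r2", "r3")
  masks <- list()
  for (img in names(imgs)) for (r in raters)
    masks[[length(masks) + 1]] <- annotation_mask(random_mask(12, 12), img, r, 1)
  study <- structure(list(images = imgs, masks = masks,
                          rater_tiers = setNames(rep("expert", 3), raters),
                          consensus_raters = raters),
                     class = "annot_study")
  for (coef in c("kappa", "ac1_annotator", "ac1_standard")) {
    mat <- pairwise_matrix(study, coef, round = 1)
    expect_true(isSymmetric(mat$values))
    expect_equal(unname(diag(mat$values)), rep(1, 3))
    for (i in 1:2) for (j in (i + 1):3) {
      # pooled counts over both images, recomputed by brute force
      tots <- list(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
      for (img in names(imgs)) {
        mi <- Filter(function(m) m$rater_id == raters[i] && m$image_id == img, masks)[[1]]
        mj <- Filter(function(m) m$rater_id == raters[j] && m$image_id == img, masks)[[1]]
        bf <- brute_confusion(mi$mask, mj$mask)
        for (f in names(tots)) tots[[f]] <- tots[[f]] + bf[[f]]
      }
      bm <- brute_metrics(tots)
      want <- switch(coef, kappa = bm$kappa, ac1_annotator = bm$ac1_annotator,
                     ac1_standard = bm$ac1_standard)
      expect_equal(mat$values[i, j], want, tolerance = 1e-12)
    }
  }
  # identical raters give off-diagonal 1
  same <- lapply(names(imgs), function(img) {
    m <- random_mask(12, 12)
    lapply(c("r1", "r2"), function(r) annotation_mask(m, img, r, 1))
  })
  study2 <- structure(list(images = imgs, masks = do.call(c, same),
                           rater_tiers = c(r1 = "expert", r2 = "expert"),
                           consensus_raters = c("r1", "r2")),
                      class = "annot_study")
  expect_equal(pairwise_matrix(study2, "kappa", 1)$values["r1", "r2"], 1)
})

test_that("pooled counts across images equal the sum of per-image counts", {
  set.seed(35)
  p1 <- random_mask(9, 9); r1 <- random_mask(9, 9)
  p2 <- random_mask(9, 9); r2 <- random_mask(9, 9)
  ca <- confusion_counts(p1, r1); cb <- confusion_counts(p2, r2)
  cc <- confusion_counts(rbind(p1, p2), rbind(r1, r2))
  expect_identical(cc$TP, ca$TP + cb$TP)
  expect_identical(cc$FN, ca$FN + cb$FN)
})
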