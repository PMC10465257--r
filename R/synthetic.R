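#' Specification of an OCT-like phantom B-scan
#'
#' Describes a synthetic B-scan: a layered tissue background (dark vitreous
#' above, a brighter tissue band, a dimmer deep band below, joined by
#' smooth ramps and a gentle vertical gradient), elliptical fluid regions
#' that are much darker than tissue ("minimally reflective"), and Poisson
#' count noise: a noisy pixel is \eqn{Poisson(\lambda c)/\lambda} around
#' its clean value \eqn{c}, clipped to \[0, 1\]. Smaller \eqn{\lambda}
#' means stronger speckle; \eqn{\lambda} is identifiable from the
#' variance/mean slope of flat patches.
#'
#' @param height_px,width_px Image size in pixels (defaults 428 x 732).
#' @param scale_x_um,scale_y_um Microns per pixel (defaults 10.5, 3.8).
#' @param n_regions Number of fluid ellipses to place (overlaps merge).
#' @param region_axes_um Range of ellipse semi-axes in microns; axes are
#'   drawn uniformly from this range, so regions are round in physical
#'   space despite anisotropic pixels.
#' @param tissue_intensity Mean intensity of the central tissue band.
#' @param fluid_intensity Mean intensity inside fluid regions; must be
#'   below `tissue_intensity`.
#' @param noise_lambda Poisson shape parameter of the speckle.
#' @param seed Integer seed making generation a pure function of the spec;
#'   `NULL` lets [generate_study] derive one.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(height_px = 428L, width_px = 732L,
                         scale_x_um = 10.5, scale_y_um = 3.8,
                         n_regions = 12L, region_axes_um = c(30, 150),
                         tissue_intensity = 0.5, fluid_intensity = 0.05,
                         noise_lambda = 20, seed = NULL) {
  if (fluid_intensity >= tissue_intensity)
    stopf("fluid must be darker than tissue (fluid_intensity < tissue_intensity)")
  if (noise_lambda <= 0) stopf("noise_lambda must be positive")
  if (n_regions < 0) stopf("n_regions must be nonnegative")
  structure(list(height_px = as.integer(height_px), width_px = as.integer(width_px),
                 scale_x_um = scale_x_um, scale_y_um = scale_y_um,
                 n_regions = as.integer(n_regions), region_axes_um = region_axes_um,
                 tissue_intensity = tissue_intensity,
                 fluid_intensity = fluid_intensity,
                 noise_lambda = noise_lambda, seed = seed),
            class = "phantom_spec")
}

# Smooth step from 0 to 1 over [lo, hi] (cosine ramp).
smoothstep <- function(x, lo, hi) {
  t <- clip01((x - lo) / (hi - lo))
  (1 - cos(pi * t)) / 2
}

# Clean (noise-free) layered background for a phantom, rows x cols.
clean_background <- function(spec) {
  H <- spec$height_px; W <- spec$width_px
  rows <- seq_len(H)
  t1 <- 0.22 * H; t2 <- 0.72 * H; w <- 0.03 * H
  vitreous <- 0.16 * spec$tissue_intensity
  deep <- 0.50 * spec$tissue_intensity
  # gentle vertical gradient inside the tissue band (+6% top to -6% bottom)
  grad <- 1 + 0.06 * (1 - 2 * clip01((rows - t1) / (t2 - t1)))
  tissue <- spec$tissue_intensity * grad
  up <- smoothstep(rows, t1 - w, t1 + w)     # vitreous -> tissue
  down <- smoothstep(rows, t2 - w, t2 + w)   # tissue -> deep
  profile <- vitreous * (1 - up) + tissue * up * (1 - down) + deep * down
  matrix(profile, nrow = H, ncol = W)
}

# Rows of the tissue band interior where fluid regions may be placed.
tissue_band_rows <- function(spec) {
  H <- spec$height_px
  c(ceiling(0.22 * H + 0.03 * H), floor(0.72 * H - 0.03 * H))
}

# Rasterise an ellipse given in physical (micron) coordinates.
ellipse_mask <- function(H, W, centre_rc, a_um, b_um, sx, sy) {
  cr <- centre_rc[1]; cc <- centre_rc[2]
  rpx <- ceiling(b_um / sy); cpx <- ceiling(a_um / sx)
  rr <- max(1, floor(cr - rpx)):min(H, ceiling(cr + rpx))
  cc2 <- max(1, floor(cc - cpx)):min(W, ceiling(cc + cpx))
  dy <- (rr - cr) * sy
  dx <- (cc2 - cc) * sx
  inside <- outer(dy^2 / b_um^2, dx^2 / a_um^2, `+`) <= 1
  list(rows = rr, cols = cc2, inside = inside)
}

#' Generate a phantom B-scan with known fluid-region truth
#'
#' Fluid ellipses are placed by rejection sampling inside the central
#' tissue band (so every true region sits in tissue); overlapping ellipses
#' merge into one truth region. The clean image is lightly blurred (to give
#' annotations a realistic soft edge) and Poisson count noise of the
#' requested shape parameter is applied. Generation is a pure function of
#' `spec$seed`.
#'
#' @param spec A [phantom_spec] (with a non-NULL seed).
#' @return List with `image` (a [bscan]) and `truth` (an
#'   [annotation_mask] with rater_id `"truth"`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(spec$seed)) stopf("phantom_spec needs a seed for generation")
  with_seed(spec$seed, {
    H <- spec$height_px; W <- spec$width_px
    clean <- clean_background(spec)
    truth <- matrix(FALSE, H, W)
    band <- tissue_band_rows(spec)
    ax <- spec$region_axes_um
    placed <- 0L
    attempts <- 0L
    while (placed < spec$n_regions) {
      attempts <- attempts + 1L
      if (attempts > 200L * max(1L, spec$n_regions))
        stopf("could not place %d regions inside the tissue band", spec$n_regions)
      a_um <- stats::runif(1, ax[1], ax[2])
      b_um <- stats::runif(1, ax[1], ax[2])
      rpx <- b_um / spec$scale_y_um
      cpx <- a_um / spec$scale_x_um
      if (band[1] + rpx + 1 > band[2] - rpx - 1) next
      cr <- stats::runif(1, band[1] + rpx + 1, band[2] - rpx - 1)
      cc <- stats::runif(1, cpx + 2, W - cpx - 1)
      e <- ellipse_mask(H, W, c(cr, cc), a_um, b_um, spec$scale_x_um, spec$scale_y_um)
      truth[e$rows, e$cols] <- truth[e$rows, e$cols] | e$inside
      placed <- placed + 1L
    }
    clean[truth] <- spec$fluid_intensity
    # soften edges so annotation boundaries see a realistic intensity ramp
    clean <- EBImage::filter2(clean, EBImage::makeBrush(5, "gaussian", sigma = 0.7))
    clean <- clip01(clean)
    lam <- spec$noise_lambda
    noisy <- stats::rpois(length(clean), lam * clean) / lam
    noisy <- clip01(matrix(noisy, H, W))
    img_id <- sprintf("phantom_seed%d", spec$seed)
    list(image = bscan(noisy, image_id = img_id,
                       scale_x_um = spec$scale_x_um, scale_y_um = spec$scale_y_um),
         truth = annotation_mask(truth, image_id = img_id,
                                 rater_id = "truth", round_id = 1L),
         clean = clean)
  })
}

#' Simulated annotator profile
#'
#' Parameterises the error model of one simulated rater. Experienced
#' raters have small boundary bias and jitter; juniors oversegment
#' (positive bias pushes the annotation boundary outward into tissue) and
#' degrade towards the image periphery (`zone_decay` multiplies jitter and
#' miss probability once per zone step outward from the centre).
#'
#' @param rater_id Identifier.
#' @param tier `"expert"` or `"junior"`.
#' @param boundary_bias_px Signed boundary shift in pixels; positive
#'   dilates (oversegments), negative erodes.
#' @param jitter_sd_px SD of a smooth random radial boundary perturbation.
#' @param miss_rate Probability of omitting a true region entirely.
#' @param spurious_rate Expected number of spurious (false) small regions
#'   per image.
#' @param zone_decay Multiplier (>= 1) applied to jitter and miss rate per
#'   zone step away from the centre.
#' @return A `rater_profile` object.
#' @export
rater_profile <- function(rater_id, tier = c("expert", "junior"),
                          boundary_bias_px = 0, jitter_sd_px = 0,
                          miss_rate = 0, spurious_rate = 0, zone_decay = 1) {
  tier <- match.arg(tier)
  if (miss_rate < 0 || miss_rate > 1) stopf("miss_rate must be in [0, 1]")
  if (jitter_sd_px < 0) stopf("jitter_sd_px must be nonnegative")
  if (spurious_rate < 0) stopf("spurious_rate must be nonnegative")
  if (zone_decay < 1) stopf("zone_decay must be >= 1")
  structure(list(rater_id = as.character(rater_id), tier = tier,
                 boundary_bias_px = boundary_bias_px, jitter_sd_px = jitter_sd_px,
                 miss_rate = miss_rate, spurious_rate = spurious_rate,
                 zone_decay = zone_decay),
            class = "rater_profile")
}

#' Default simulated rater panel
#'
#' Two experts and three juniors whose error parameters place synthetic
#' studies in the qualitative regime of multi-rater OCT annotation
#' studies: near-faithful experts (mean IoU well above 0.8) and
#' oversegmenting juniors (positive boundary bias, zone-dependent jitter
#' and misses, mean IoU around 0.4-0.6). These are presets, not calibrated
#' estimates of any particular clinician.
#'
#' @return Named list of [rater_profile] objects (Ex1, Ex2, Jr1, Jr2, Jr3).
#' @export
default_rater_profiles <- function() {
  profs <- list(
    rater_profile("Ex1", "expert", boundary_bias_px = 0.2, jitter_sd_px = 0.5,
                  miss_rate = 0.02, spurious_rate = 0.2, zone_decay = 1.0),
    rater_profile("Ex2", "expert", boundary_bias_px = 0.3, jitter_sd_px = 0.6,
                  miss_rate = 0.03, spurious_rate = 0.3, zone_decay = 1.05),
    rater_profile("Jr1", "junior", boundary_bias_px = 1.5, jitter_sd_px = 1.5,
                  miss_rate = 0.10, spurious_rate = 1.0, zone_decay = 1.6),
    rater_profile("Jr2", "junior", boundary_bias_px = 2.5, jitter_sd_px = 2.0,
                  miss_rate = 0.20, spurious_rate = 1.5, zone_decay = 1.8),
    rater_profile("Jr3", "junior", boundary_bias_px = 1.8, jitter_sd_px = 1.8,
                  miss_rate = 0.15, spurious_rate = 1.2, zone_decay = 1.7))
  stats::setNames(profs, vapply(profs, `[[`, character(1), "rater_id"))
}

# Smooth unit-variance random field via bilinear upsampling of coarse
# Gaussian noise (grid spacing in pixels).
smooth_field <- function(nr, nc, spacing = 6) {
  gr <- max(2L, ceiling(nr / spacing) + 1L)
  gc <- max(2L, ceiling(nc / spacing) + 1L)
  g <- matrix(stats::rnorm(gr * gc), gr, gc)
  ri <- seq(1, gr, length.out = nr)
  ci <- seq(1, gc, length.out = nc)
  r0 <- pmin(floor(ri), gr - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), gc - 1L); fc <- ci - c0
  up <- matrix(0, nr, nc)
  for (jj in seq_len(nc)) {
    j0 <- c0[jj]; w <- fc[jj]
    colA <- (1 - fr) * g[r0, j0] + fr * g[r0 + 1L, j0]
    colB <- (1 - fr) * g[r0, j0 + 1L] + fr * g[r0 + 1L, j0 + 1L]
    up[, jj] <- (1 - w) * colA + w * colB
  }
  s <- stats::sd(up)
  if (s > 0) up / s else up
}

#' Simulate one rater's annotation of a phantom
#'
#' Each true region is independently dropped with probability
#' `miss_rate * f` (`f` the zone factor `zone_decay^(zone-1)`, regions
#' beyond zone 3 use the zone-3 exponent plus one); surviving regions have
#' their boundary moved by `boundary_bias_px` (as a Euclidean
#' signed-distance offset: positive bias dilates, negative erodes) plus a
#' smooth random radial jitter of SD `jitter_sd_px * f`. Finally,
#' `Poisson(spurious_rate)` small spurious regions are added adjacent to
#' true regions (or in the tissue band if there are none). The result is a
#' valid binary mask; with an all-zero profile the annotator reproduces
#' the truth exactly.
#'
#' @param truth Truth [annotation_mask].
#' @param image The [bscan] the truth lies on.
#' @param profile A [rater_profile].
#' @param seed Integer seed.
#' @param round_id Round tag of the produced mask.
#' @return An [annotation_mask] tagged with the profile's rater_id.
#' @export
simulate_annotator <- function(truth, image, profile, seed, round_id = 1L) {
  stopifnot(inherits(truth, "annotation_mask"), inherits(image, "bscan"),
            inherits(profile, "rater_profile"))
  with_seed(seed, {
    d <- dim(truth$mask)
    out <- matrix(FALSE, d[1], d[2])
    regions <- connected_regions(truth$mask)
    zspec <- zone_spec()
    for (reg in regions) {
      z <- zone_of(reg, image, zspec)
      expo <- if (is.na(z)) 3 else z - 1
      f <- profile$zone_decay^expo
      if (stats::runif(1) < min(1, profile$miss_rate * f)) next
      bias <- profile$boundary_bias_px
      jit <- profile$jitter_sd_px * f
      if (bias == 0 && jit == 0) {
        out[reg$pixels] <- TRUE
        next
      }
      pad <- as.integer(ceiling(abs(bias) + 4 * jit + 2))
      bb <- reg$bbox
      r1 <- max(1L, bb[["row1"]] - pad); r2 <- min(d[1], bb[["row2"]] + pad)
      c1 <- max(1L, bb[["col1"]] - pad); c2 <- min(d[2], bb[["col2"]] + pad)
      sub <- matrix(0, r2 - r1 + 1L, c2 - c1 + 1L)
      rows <- ((reg$pixels - 1L) %% d[1]) + 1L
      cols <- ((reg$pixels - 1L) %/% d[1]) + 1L
      sub[cbind(rows - r1 + 1L, cols - c1 + 1L)] <- 1
      sdist <- EBImage::distmap(1 - sub) - EBImage::distmap(sub)
      offset <- bias
      if (jit > 0) offset <- offset + jit * smooth_field(nrow(sub), ncol(sub))
      keep <- sdist <= offset
      out[r1:r2, c1:c2] <- out[r1:r2, c1:c2] | keep
    }
    n_sp <- stats::rpois(1, profile$spurious_rate)
    if (n_sp > 0) {
      band <- c(round(0.3 * d[1]), round(0.65 * d[1]))
      for (k in seq_len(n_sp)) {
        a_px <- stats::runif(1, 2, 5)
        b_px <- stats::runif(1, 2, 5)
        if (length(regions)) {
          reg <- regions[[sample.int(length(regions), 1)]]
          theta <- stats::runif(1, 0, 2 * pi)
          rad <- sqrt(reg$area_px / pi) * 1.5 + max(a_px, b_px) + 2
          cr <- reg$centroid[["row"]] + rad * sin(theta)
          cc <- reg$centroid[["col"]] + rad * cos(theta)
        } else {
          cr <- stats::runif(1, band[1], band[2])
          cc <- stats::runif(1, 10, d[2] - 10)
        }
        cr <- clip01(cr, 5, d[1] - 5); cc <- clip01(cc, 5, d[2] - 5)
        e <- ellipse_mask(d[1], d[2], c(cr, cc), a_px, b_px, 1, 1)
        out[e$rows, e$cols] <- out[e$rows, e$cols] | e$inside
      }
    }
    annotation_mask(out, image_id = truth$image_id,
                    rater_id = profile$rater_id, round_id = round_id)
  })
}

#' Default phantom panel for a synthetic study
#'
#' Ten phantoms whose speckle parameters span the observed clinical range
#' (about 5 to 80) with five low-noise, three medium-noise and two
#' high-noise scans, mirroring the noise-group distribution of the
#' emulated study design.
#'
#' @param n_images Number of phantoms (default 10; lambdas recycle).
#' @param n_regions Fluid regions per phantom.
#' @return List of [phantom_spec] objects (seeds unset; derived by
#'   [generate_study]).
#' @export
default_phantom_specs <- function(n_images = 10L, n_regions = 12L) {
  lambdas <- rep_len(c(5, 8, 10, 12, 15, 25, 30, 35, 50, 80), n_images)
  lapply(seq_len(n_images), function(i)
    phantom_spec(n_regions = n_regions, noise_lambda = lambdas[i]))
}

#' Generate a full synthetic annotation study
#'
#' Builds phantoms and simulated rater masks for every (image, rater,
#' round) cell. Every random draw flows from the root seed through a
#' deterministic per-(image, rater, round) hash, so adding a rater or an
#' image never changes the other masks, and two calls with the same seed
#' produce identical studies. Rounds are independent draws of the same
#' rater profile (round effects, if any, must be injected by passing
#' per-round profiles).
#'
#' @param phantom_specs List of [phantom_spec] (default
#'   [default_phantom_specs]).
#' @param profiles List of [rater_profile] (default
#'   [default_rater_profiles]).
#' @param rounds Number of annotation rounds (>= 1).
#' @param seed Root integer seed.
#' @param single_round_raters Rater ids that annotate only in round 1
#'   (e.g. a senior expert who grades once while everyone else grades
#'   twice); their round-1 masks stand in wherever a later round is
#'   required downstream.
#' @return A `synthetic_study` (an `annot_study` with an extra `truth`
#'   channel): fields `images`, `truth`, `masks`, `rater_tiers`,
#'   `consensus_raters` (the expert-tier raters).
#' @export
generate_study <- function(phantom_specs = default_phantom_specs(),
                           profiles = default_rater_profiles(),
                           rounds = 2L, seed = 1L,
                           single_round_raters = character()) {
  if (rounds < 1) stopf("rounds must be >= 1")
  if (!length(phantom_specs) || !length(profiles))
    stopf("need at least one phantom spec and one rater profile")
  images <- list(); truth <- list(); masks <- list()
  for (i in seq_along(phantom_specs)) {
    spec <- phantom_specs[[i]]
    image_id <- sprintf("img%02d", i)
    if (is.null(spec$seed)) spec$seed <- derive_seed(seed, "phantom", image_id)
    ph <- generate_phantom(spec)
    ph$image$image_id <- image_id
    ph$truth$image_id <- image_id
    images[[image_id]] <- ph$image
    truth[[image_id]] <- ph$truth
    for (p in profiles) {
      n_rounds <- if (p$rater_id %in% single_round_raters) 1L else rounds
      for (r in seq_len(n_rounds)) {
        sub <- derive_seed(seed, image_id, p$rater_id, r)
        masks[[length(masks) + 1L]] <-
          simulate_annotator(ph$truth, ph$image, p, seed = sub, round_id = r)
      }
    }
  }
  tiers <- vapply(profiles, `[[`, character(1), "tier")
  names(tiers) <- vapply(profiles, `[[`, character(1), "rater_id")
  structure(list(images = images, truth = truth, masks = masks,
                 rater_tiers = tiers,
                 consensus_raters = names(tiers)[tiers == "expert"],
                 seed = as.integer(seed)),
            class = c("synthetic_study", "annot_study"))
}

#' Write a synthetic study to disk as PNGs plus a manifest
#'
#' Images are written as 8-bit greyscale PNG, truth and rater masks as
#' 0/255 PNG, and a canonical JSON manifest ties them together, so the
#' disk-based pipeline can be exercised end to end on synthetic data.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  imgs <- data.frame(image_id = character(), path = character(),
                     scale_x_um = numeric(), scale_y_um = numeric())
  for (img in study$images) {
    p <- file.path("images", paste0(img$image_id, ".png"))
    write_png(img, file.path(dir, p))
    imgs <- rbind(imgs, data.frame(image_id = img$image_id, path = p,
                                   scale_x_um = img$scale_x_um,
                                   scale_y_um = img$scale_y_um))
  }
  for (tr in study$truth)
    write_png(tr, file.path(dir, "masks", paste0(tr$image_id, "_truth.png")))
  recs <- data.frame(image_id = character(), rater_id = character(),
                     round_id = integer(), path = character())
  for (m in study$masks) {
    p <- file.path("masks", sprintf("%s_%s_r%d.png", m$image_id, m$rater_id, m$round_id))
    write_png(m, file.path(dir, p))
    recs <- rbind(recs, data.frame(image_id = m$image_id, rater_id = m$rater_id,
                                   round_id = m$round_id, path = p))
  }
  manifest <- study_manifest(imgs, recs, study$rater_tiers,
                             study$consensus_raters, base_dir = dir)
  write_manifest(manifest, file.path(dir, "manifest.json"))
  invisible(file.path(dir, "manifest.json"))
}
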