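#' Evaluation configuration
#'
#' Collects the tunable constants of the evaluation pipeline in one place.
#'
#' @param consensus_rule Vote rule for the ground truth (see
#'   [majority_vote]).
#' @param connectivity Connected-component connectivity (8 or 4).
#' @param window_margin_px Margin of the per-region evaluation window.
#' @param zone_cuts_mm Zone cut points in mm.
#' @param noise_cuts Lambda cut points separating low/medium/high noise.
#' @param reuse_single_round Whether a single-round rater's masks stand in
#'   for the missing round in pairwise matrices.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(consensus_rule = "strict_majority", connectivity = 8L,
                      window_margin_px = 10L, zone_cuts_mm = c(0.5, 1.5, 3.0),
                      noise_cuts = c(20, 40), reuse_single_round = TRUE) {
  structure(list(consensus_rule = consensus_rule,
                 connectivity = as.integer(connectivity),
                 window_margin_px = as.integer(window_margin_px),
                 zone_cuts_mm = zone_cuts_mm, noise_cuts = noise_cuts,
                 reuse_single_round = reuse_single_round),
            class = "qc_config")
}

#' Evaluate a full annotation study
#'
#' Runs the whole pipeline: builds the majority-vote ground truth from the
#' consensus raters' last rounds, scores every (rater, round) against it in
#' both aggregation modes (pixel counts pooled over images, and the mean of
#' per-region metrics), computes pairwise inter-rater agreement matrices
#' (Cohen's kappa and both AC1 variants) per round, estimates each image's
#' speckle parameter, stratifies last-round per-region IoU by retinal zone
#' and noise group, and summarises annotation boundary intensities per
#' rater. Deterministic given the study and configuration.
#'
#' @param study An `annot_study` (from [load_study] or [generate_study]).
#' @param config A [qc_config].
#' @return An object of class `annotqc_results`; see the fields
#'   `per_rater_round`, `matrices`, `noise_table`, `strat_zone`,
#'   `strat_noise`, `intensity`, `region_detail`, `round_delta`,
#'   `provenance`.
#' @export
evaluate_study <- function(study, config = qc_config()) {
  stopifnot(inherits(study, "annot_study"))
  consensus <- build_ground_truth(study, rule = config$consensus_rule)
  raters <- names(study$rater_tiers)
  # decompose each consensus mask once; zones and boundary-intensity stats
  # of consensus regions do not depend on the rater, so cache them too
  cons_cache <- lapply(names(study$images), function(img) {
    regs <- connected_regions(consensus[[img]]$mask, config$connectivity)
    lab <- matrix(0L, nrow(consensus[[img]]$mask), ncol(consensus[[img]]$mask))
    for (reg in regs) lab[reg$pixels] <- reg$region_id
    bst <- lapply(regs, function(reg)
      boundary_intensity_stats(study$images[[img]], reg))
    list(regions = regs, lab = lab, bstats = bst)
  })
  names(cons_cache) <- names(study$images)
  rounds_of <- function(r)
    sort(unique(vapply(Filter(function(m) m$rater_id == r, study$masks),
                       `[[`, integer(1), "round_id")))
  max_round <- max(vapply(study$masks, `[[`, integer(1), "round_id"))

  per_rows <- list()
  region_detail <- list()
  for (r in raters) {
    tier <- study$rater_tiers[[r]]
    for (rd in rounds_of(r)) {
      rmasks <- masks_for(study, r, round = rd)
      pooled <- NULL
      n_areas <- 0L
      n_fp_areas <- 0L
      for (img in names(study$images)) {
        m <- rmasks[[img]]
        if (is.null(m)) stopf("rater '%s' round %d missing image '%s'", r, rd, img)
        cc <- confusion_counts(m, consensus[[img]])
        pooled <- if (is.null(pooled)) cc else add_counts(pooled, cc)
        cache <- cons_cache[[img]]
        tab <- per_region_metrics_impl(m$mask, cache$regions, cache$lab,
                                       image = study$images[[img]],
                                       window_margin_px = config$window_margin_px,
                                       connectivity = config$connectivity,
                                       intensity_cache = cache$bstats)
        n_areas <- n_areas + attr(tab, "n_pred_areas")
        n_fp_areas <- n_fp_areas + attr(tab, "n_unmatched_pred")
        if (nrow(tab)) {
          tab$image_id <- img
          tab$rater_id <- r
          tab$round_id <- rd
          tab$tier <- tier
          region_detail[[length(region_detail) + 1L]] <- tab
        }
      }
      sc <- agreement_scores(pooled)
      per_rows[[length(per_rows) + 1L]] <- cbind(
        data.frame(rater_id = r, tier = tier, round_id = rd,
                   mode = "pooled", n_areas = n_areas, n_fp_areas = n_fp_areas),
        sc)
    }
  }
  region_detail <- if (length(region_detail)) do.call(rbind, region_detail) else
    stop("study has no consensus regions to evaluate", call. = FALSE)

  # per-region-mean aggregation mode (undefined values excluded from means)
  for (r in raters) {
    tier <- study$rater_tiers[[r]]
    for (rd in rounds_of(r)) {
      sel <- region_detail$rater_id == r & region_detail$round_id == rd
      sub <- region_detail[sel, ]
      mcols <- c("iou", "dsc", "tnr", "tpr", "precision", "kappa",
                 "ac1_annotator", "ac1_standard", "po", "pe_kappa", "pe_ac1")
      means <- vapply(mcols, function(cn) mean(sub[[cn]], na.rm = TRUE), numeric(1))
      per_rows[[length(per_rows) + 1L]] <- cbind(
        data.frame(rater_id = r, tier = tier, round_id = rd,
                   mode = "per_region_mean",
                   n_areas = per_rows[[which(vapply(per_rows, function(x)
                     x$rater_id == r && x$round_id == rd && x$mode == "pooled",
                     logical(1)))[1]]]$n_areas,
                   n_fp_areas = NA_integer_),
        as.data.frame(as.list(means)))
    }
  }
  per_rater_round <- do.call(rbind, per_rows)
  rownames(per_rater_round) <- NULL

  matrices <- list()
  for (coef in c("kappa", "ac1_annotator", "ac1_standard")) {
    for (rd in seq_len(max_round)) {
      matrices[[sprintf("%s_round%d", coef, rd)]] <-
        pairwise_matrix(study, coefficient = coef, round = rd,
                        reuse_single_round = config$reuse_single_round)
    }
  }

  noise_table <- do.call(rbind, lapply(names(study$images), function(img) {
    est <- estimate_noise_lambda(study$images[[img]])
    data.frame(image_id = img, lambda_hat = est$lambda_hat, group = est$group)
  }))

  # last-round region detail, annotated with noise group, for stratification
  last_rd <- stats::aggregate(round_id ~ rater_id, region_detail, max)
  last_key <- paste(last_rd$rater_id, last_rd$round_id)
  detail_last <- region_detail[paste(region_detail$rater_id,
                                     region_detail$round_id) %in% last_key, ]
  detail_last$noise_group <- noise_table$group[match(detail_last$image_id,
                                                     noise_table$image_id)]
  strat_zone <- stratified_quality(detail_last, "zone")
  strat_noise <- stratified_quality(detail_last, "noise_group")

  # boundary intensities of each rater's own last-round annotations
  intensity <- list()
  for (r in raters) {
    rmasks <- masks_for(study, r, last_round = TRUE)
    stats_list <- list()
    for (img in names(rmasks)) {
      regs <- connected_regions(rmasks[[img]]$mask, config$connectivity)
      for (reg in regs)
        stats_list[[length(stats_list) + 1L]] <-
          boundary_intensity_stats(study$images[[img]], reg)
    }
    if (length(stats_list)) {
      st <- do.call(rbind, stats_list)
      intensity[[length(intensity) + 1L]] <- data.frame(
        rater_id = r, tier = study$rater_tiers[[r]],
        mean_outer = mean(st$mean_outer, na.rm = TRUE),
        mean_inner = mean(st$mean_inner, na.rm = TRUE),
        mean_region = mean(st$mean_region, na.rm = TRUE),
        diff_outer_inner = mean(st$diff_outer_inner, na.rm = TRUE),
        n_regions = nrow(st))
    }
  }
  intensity <- do.call(rbind, intensity)

  res <- structure(
    list(per_rater_round = per_rater_round, matrices = matrices,
         noise_table = noise_table, strat_zone = strat_zone,
         strat_noise = strat_noise, intensity = intensity,
         region_detail = region_detail,
         provenance = list(consensus_rule = config$consensus_rule,
                           config = unclass(config),
                           n_images = length(study$images),
                           raters = raters,
                           consensus_raters = study$consensus_raters,
                           seed = study$seed %||% NA)),
    class = "annotqc_results")
  res$round_delta <- round_delta(res)
  res
}

#' Round-over-round metric deltas
#'
#' For every rater with two annotation rounds, the signed change
#' (round 2 minus round 1) of IoU, DSC, TNR, TPR and precision in the
#' pooled aggregation mode, plus the tally of increased / same / decreased
#' cells over the rater-by-metric grid. Equality is judged at 4 decimal
#' places, the conventional display precision of such tables.
#'
#' @param results An `annotqc_results` object.
#' @param mode Aggregation mode to difference (default `"pooled"`).
#' @return List with `deltas` (data.frame rater x metric) and `tally`
#'   (named counts summing to the grid size); both empty for single-round
#'   studies.
#' @export
round_delta <- function(results, mode = "pooled") {
  tab <- results$per_rater_round
  tab <- tab[tab$mode == mode, ]
  metrics <- c("iou", "dsc", "tnr", "tpr", "precision")
  two_round <- intersect(unique(tab$rater_id[tab$round_id == 1L]),
                         unique(tab$rater_id[tab$round_id == 2L]))
  if (!length(two_round))
    return(list(deltas = data.frame(), tally = c(increased = 0L, same = 0L,
                                                 decreased = 0L)))
  rows <- list()
  for (r in two_round) {
    r1 <- tab[tab$rater_id == r & tab$round_id == 1L, ]
    r2 <- tab[tab$rater_id == r & tab$round_id == 2L, ]
    for (mname in metrics) {
      d <- round(r2[[mname]] - r1[[mname]], 4)
      rows[[length(rows) + 1L]] <- data.frame(
        rater_id = r, metric = mname, delta = r2[[mname]] - r1[[mname]],
        direction = if (is.na(d)) NA_character_
                    else if (d > 0) "increased" else if (d < 0) "decreased" else "same")
    }
  }
  deltas <- do.call(rbind, rows)
  tally <- c(increased = sum(deltas$direction == "increased", na.rm = TRUE),
             same = sum(deltas$direction == "same", na.rm = TRUE),
             decreased = sum(deltas$direction == "decreased", na.rm = TRUE))
  list(deltas = deltas, tally = tally)
}

#' @export
print.annotqc_results <- function(x, ...) {
  cat(sprintf("<annotqc_results> %d images, raters: %s (consensus: %s, rule %s)\n",
              x$provenance$n_images, paste(x$provenance$raters, collapse = ", "),
              paste(x$provenance$consensus_raters, collapse = ", "),
              x$provenance$consensus_rule))
  pooled <- x$per_rater_round[x$per_rater_round$mode == "pooled", ]
  print(pooled[, c("rater_id", "tier", "round_id", "iou", "dsc", "tnr", "tpr",
                   "precision", "n_areas")], digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.annotqc_results <- function(object, ...) {
  x <- object
  pooled <- x$per_rater_round[x$per_rater_round$mode == "pooled", ]
  by_tier <- stats::aggregate(iou ~ tier, pooled, mean)
  k1 <- x$matrices[["kappa_round1"]]
  cat("Annotation-quality study summary\n")
  cat(sprintf("  images: %d   raters: %d   consensus rule: %s\n",
              x$provenance$n_images, length(x$provenance$raters),
              x$provenance$consensus_rule))
  for (i in seq_len(nrow(by_tier)))
    cat(sprintf("  mean pooled IoU (%s): %.4f\n", by_tier$tier[i], by_tier$iou[i]))
  if (!is.null(k1))
    cat(sprintf("  mean off-diagonal kappa, round 1: %.4f\n", k1$mean_off_diagonal))
  if (!is.null(x$intensity)) {
    ag <- stats::aggregate(diff_outer_inner ~ tier, x$intensity, mean)
    for (i in seq_len(nrow(ag)))
      cat(sprintf("  mean outer-inner intensity diff (%s): %.4f\n",
                  ag$tier[i], ag$diff_outer_inner[i]))
  }
  cat(sprintf("  round deltas: %d increased / %d same / %d decreased\n",
              x$round_delta$tally[["increased"]], x$round_delta$tally[["same"]],
              x$round_delta$tally[["decreased"]]))
  invisible(x)
}

#' @export
plot.annotqc_results <- function(x, which = c("iou", "kappa"), ...) {
  which <- match.arg(which)
  if (which == "iou") {
    det <- x$region_detail
    graphics::boxplot(iou ~ rater_id, data = det,
                      ylab = "per-region IoU", xlab = "rater", ...)
  } else {
    m <- x$matrices[["kappa_round1"]]$values
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m, axes = FALSE,
                    xlab = "", ylab = "", zlim = c(0, 1), ...)
    graphics::axis(1, seq_len(nrow(m)), rownames(m))
    graphics::axis(2, seq_len(ncol(m)), colnames(m))
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits the per-rater tables (both aggregation modes), agreement matrices,
#' noise table, stratified tables, intensity summary and a machine-readable
#' JSON summary; optionally diagnostic plots (agreement heatmap and
#' per-region IoU box plot) as PNG.
#'
#' @param results An `annotqc_results`.
#' @param dir Output directory, created if needed.
#' @param plots Whether to render PNG figures.
#' @return `dir`, invisibly.
#' @export
render_report <- function(results, dir, plots = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(results$per_rater_round, file.path(dir, "per_rater_round.csv"))
  write_table(results$noise_table, file.path(dir, "noise.csv"))
  write_table(results$strat_zone, file.path(dir, "stratified_zone.csv"))
  write_table(results$strat_noise, file.path(dir, "stratified_noise.csv"))
  write_table(results$intensity, file.path(dir, "intensity.csv"))
  if (!is.null(results$round_delta$deltas) && nrow(results$round_delta$deltas))
    write_table(results$round_delta$deltas, file.path(dir, "round_delta.csv"))
  for (nm in names(results$matrices)) {
    m <- results$matrices[[nm]]$values
    write_table(cbind(data.frame(rater_id = rownames(m)), as.data.frame(m)),
                file.path(dir, sprintf("matrix_%s.csv", nm)))
  }
  summary_obj <- list(
    per_rater_round = results$per_rater_round,
    intensity = results$intensity,
    noise = results$noise_table,
    strat_zone = results$strat_zone,
    strat_noise = results$strat_noise,
    round_delta_tally = as.list(results$round_delta$tally),
    matrices = lapply(results$matrices, function(m) {
      list(coefficient = m$coefficient, round = m$round,
           rater_ids = m$rater_ids, values = m$values,
           mean_off_diagonal = m$mean_off_diagonal)
    }),
    provenance = results$provenance)
  jsonlite::write_json(summary_obj, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", matrix = "rowmajor")
  if (plots) {
    grDevices::png(file.path(dir, "kappa_round1.png"), 600, 500)
    plot(results, which = "kappa", main = "Pairwise kappa, round 1")
    grDevices::dev.off()
    grDevices::png(file.path(dir, "iou_by_rater.png"), 700, 500)
    plot(results, which = "iou", main = "Per-region IoU by rater")
    grDevices::dev.off()
  }
  invisible(dir)
}
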