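#' Headline quantities of an evaluated study
#'
#' Condenses an `annotqc_results` object into the study-level quantities of
#' interest: tier-level pooled IoU, zone-1 vs zone-3 per-region IoU by
#' tier, the per-region IoU range across noise groups, tier-level boundary
#' intensity statistics, and the expert-expert versus expert-junior kappa
#' contrast (round 1, pooled pixels).
#'
#' @param results An `annotqc_results` from [evaluate_study].
#' @return Named list of scalars; entries are `NA` when the study lacks
#'   the corresponding stratum.
#' @export
headline_metrics <- function(results) {
  pooled <- results$per_rater_round[results$per_rater_round$mode == "pooled", ]
  tier_iou <- function(ti) mean(pooled$iou[pooled$tier == ti], na.rm = TRUE)
  sz <- results$strat_zone
  zone_iou <- function(ti, z) {
    v <- sz$mean_iou[sz$tier == ti & sz$zone == as.character(z)]
    if (length(v)) v else NA_real_
  }
  sn <- results$strat_noise
  noise_range <- function(ti) {
    v <- sn$mean_iou[sn$tier == ti & sn$n > 0]
    if (length(v) > 1) max(v) - min(v) else NA_real_
  }
  it <- results$intensity
  tier_int <- function(ti, col) mean(it[[col]][it$tier == ti], na.rm = TRUE)
  km <- results$matrices[["kappa_round1"]]$values
  tiers <- results$per_rater_round$tier[match(rownames(km),
                                              results$per_rater_round$rater_id)]
  ex <- which(tiers == "expert"); jr <- which(tiers == "junior")
  kappa_exex <- if (length(ex) >= 2) mean(km[ex, ex][upper.tri(km[ex, ex])]) else NA_real_
  kappa_exjr <- if (length(ex) && length(jr)) mean(km[ex, jr, drop = FALSE]) else NA_real_
  list(expert_iou = tier_iou("expert"), junior_iou = tier_iou("junior"),
       expert_zone1_iou = zone_iou("expert", 1),
       expert_zone3_iou = zone_iou("expert", 3),
       junior_zone1_iou = zone_iou("junior", 1),
       junior_zone3_iou = zone_iou("junior", 3),
       expert_noise_iou_range = noise_range("expert"),
       junior_noise_iou_range = noise_range("junior"),
       expert_boundary_diff = tier_int("expert", "diff_outer_inner"),
       junior_boundary_diff = tier_int("junior", "diff_outer_inner"),
       expert_region_intensity = tier_int("expert", "mean_region"),
       junior_region_intensity = tier_int("junior", "mean_region"),
       kappa_expert_expert = kappa_exex,
       kappa_expert_junior = kappa_exjr,
       total_areas = sum(pooled$n_areas))
}
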