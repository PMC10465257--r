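#' Per-region agreement metrics against a consensus mask
#'
#' The consensus mask is decomposed into connected regions. Each rater
#' component is matched to the consensus region it overlaps most; for every
#' consensus region the confusion counts are then computed inside an
#' evaluation window (the region's bounding box dilated by
#' `window_margin_px`, excluding pixels of other consensus regions), with
#' the rater's matched components as the prediction. The window keeps
#' per-region specificity well defined without letting distant background
#' dominate. Rater components overlapping no consensus region are the
#' rater's false-positive areas and are reported in the attributes.
#'
#' @param pred Rater [annotation_mask] (or logical matrix).
#' @param consensus `consensus_mask` (or [annotation_mask]/logical matrix)
#'   to evaluate against.
#' @param image Optional [bscan]; when supplied each region also gets its
#'   zone (see [zone_of]) and boundary-intensity statistics.
#' @param window_margin_px Margin added around each region's bounding box.
#' @param connectivity Component connectivity (default 8).
#' @return Data.frame with one row per consensus region: `region_id`,
#'   `area_px`, `zone`, the overlap metrics, and (with `image`) the
#'   boundary intensity columns. Attributes `n_pred_areas` (count of the
#'   rater's annotated areas) and `n_unmatched_pred` (false-positive
#'   areas).
#' @export
per_region_metrics <- function(pred, consensus, image = NULL,
                               window_margin_px = 10L, connectivity = 8L) {
  p <- as_mask_matrix(pred)
  r <- as_mask_matrix(consensus)
  if (!identical(dim(p), dim(r))) stopf("pred and consensus are not aligned")
  cons_regions <- connected_regions(r, connectivity)
  cons_lab <- matrix(0L, nrow(r), ncol(r))
  for (reg in cons_regions) cons_lab[reg$pixels] <- reg$region_id
  per_region_metrics_impl(p, cons_regions, cons_lab, image = image,
                          window_margin_px = window_margin_px,
                          connectivity = connectivity)
}

# Workhorse: consensus decomposition precomputed, prediction supplied as a
# logical matrix. All work happens on window crops for speed.
per_region_metrics_impl <- function(p, cons_regions, cons_lab, image = NULL,
                                    window_margin_px = 10L, connectivity = 8L,
                                    intensity_cache = NULL) {
  d <- dim(cons_lab)
  pred_regions <- connected_regions(p, connectivity)
  pred_lab <- matrix(0L, d[1], d[2])
  for (reg in pred_regions) pred_lab[reg$pixels] <- reg$region_id

  # match each rater component to the consensus region it overlaps most
  match_of <- integer(length(pred_regions))
  for (i in seq_along(pred_regions)) {
    hits <- cons_lab[pred_regions[[i]]$pixels]
    hits <- hits[hits > 0L]
    match_of[i] <- if (length(hits)) as.integer(names(which.max(table(hits)))) else 0L
  }

  m <- as.integer(window_margin_px)
  rows_out <- vector("list", length(cons_regions))
  for (reg in cons_regions) {
    bb <- reg$bbox
    wr <- max(1L, bb[["row1"]] - m):min(d[1], bb[["row2"]] + m)
    wc <- max(1L, bb[["col1"]] - m):min(d[2], bb[["col2"]] + m)
    cl <- cons_lab[wr, wc]
    pl <- pred_lab[wr, wc]
    win <- cl == 0L | cl == reg$region_id     # other consensus regions excluded
    comp_ids <- which(match_of == reg$region_id)
    pv <- (pl %in% comp_ids) & win
    rv <- (cl == reg$region_id) & win
    cells <- tabulate(1L + pv[win] + 2L * rv[win], nbins = 4L)
    cc <- confusion(cells[4L], cells[1L], cells[2L], cells[3L])
    row <- cbind(data.frame(region_id = reg$region_id, area_px = reg$area_px),
                 agreement_scores(cc))
    if (!is.null(image)) {
      row$zone <- zone_of(reg, image)
      bstats <- if (!is.null(intensity_cache)) intensity_cache[[reg$region_id]]
                else boundary_intensity_stats(image, reg)
      row <- cbind(row, bstats)
    }
    rows_out[[reg$region_id]] <- row
  }
  out <- if (length(rows_out)) do.call(rbind, rows_out) else
    data.frame(region_id = integer(), area_px = integer())
  attr(out, "n_pred_areas") <- length(pred_regions)
  attr(out, "n_unmatched_pred") <- sum(match_of == 0L)
  out
}

#' Stratified annotation quality
#'
#' Aggregates per-region IoU by rater tier and a stratum (retinal zone or
#' image noise group), reporting mean, SD and region count per cell.
#' Undefined metric values are excluded and the exclusion count reported.
#'
#' @param region_table Data.frame of per-region results carrying columns
#'   `tier`, `iou`, and the stratum column.
#' @param stratum Column name to stratify by (`"zone"` or
#'   `"noise_group"`).
#' @return Data.frame with columns `tier`, stratum, `mean_iou`, `sd_iou`,
#'   `n`, `n_undefined` (cells with no regions keep `n = 0` and NA
#'   statistics).
#' @export
stratified_quality <- function(region_table, stratum = c("zone", "noise_group")) {
  stratum <- match.arg(stratum)
  if (!all(c("tier", "iou", stratum) %in% names(region_table)))
    stopf("region table lacks required columns (tier, iou, %s)", stratum)
  tiers <- c("expert", "junior")
  levels_s <- if (stratum == "zone") c(1L, 2L, 3L, NA) else c("low", "medium", "high")
  out <- list()
  for (ti in tiers) {
    for (sv in levels_s) {
      sel <- region_table$tier == ti &
        (if (is.na(sv)) is.na(region_table[[stratum]])
         else !is.na(region_table[[stratum]]) & region_table[[stratum]] == sv)
      vals <- region_table$iou[sel]
      n_undef <- sum(is.na(vals))
      vals <- vals[!is.na(vals)]
      out[[length(out) + 1L]] <- data.frame(
        tier = ti, stratum = if (is.na(sv)) "none" else as.character(sv),
        mean_iou = if (length(vals)) mean(vals) else NA_real_,
        sd_iou = if (length(vals) > 1) stats::sd(vals) else NA_real_,
        n = length(vals), n_undefined = n_undef)
    }
  }
  out <- do.call(rbind, out)
  names(out)[2] <- stratum
  out
}
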