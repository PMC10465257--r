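#' Pixel-level confusion counts between a mask and a reference
#'
#' Tallies TP/TN/FP/FN pixels, optionally restricted to an evaluation
#' window. These counts are the hub every agreement metric derives from.
#'
#' @param pred Logical matrix or [annotation_mask]: the annotation under
#'   evaluation.
#' @param ref Logical matrix, [annotation_mask] or `consensus_mask`: the
#'   reference (ground truth).
#' @param window Optional logical matrix; only its `TRUE` pixels enter the
#'   tallies (default: the whole image).
#' @return An object of class `confusion_counts` with integer fields
#'   `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, ref, window = NULL) {
  p <- as_mask_matrix(pred)
  r <- as_mask_matrix(ref)
  if (!identical(dim(p), dim(r)))
    stopf("pred (%d x %d) and ref (%d x %d) are not aligned",
          nrow(p), ncol(p), nrow(r), ncol(r))
  if (!is.null(window)) {
    w <- as_mask_matrix(window)
    if (!identical(dim(w), dim(p))) stopf("window is not aligned to the masks")
    p <- p[w]
    r <- r[w]
  }
  # single-pass tally of the 4 cells: 1=TN, 2=FP, 3=FN, 4=TP
  cells <- tabulate(1L + p + 2L * r, nbins = 4L)
  structure(list(TP = cells[4L], TN = cells[1L], FP = cells[2L], FN = cells[3L]),
            class = "confusion_counts")
}

#' Construct confusion counts directly
#' @param TP,TN,FP,FN Nonnegative pixel counts.
#' @return A `confusion_counts` object.
#' @export
confusion <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stopf("confusion counts must be nonnegative")
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (N=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

# Internal: add confusion counts (pooling across images).
add_counts <- function(a, b) {
  confusion(a$TP + b$TP, a$TN + b$TN, a$FP + b$FP, a$FN + b$FN)
}

as_mask_matrix <- function(x) {
  if (inherits(x, c("annotation_mask", "consensus_mask"))) x$mask
  else if (is.logical(x) && is.matrix(x)) x
  else if (is.numeric(x) && is.matrix(x)) x != 0
  else stopf("expected a logical matrix or an annotation/consensus mask")
}

ratio_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' Overlap metrics from confusion counts
#'
#' Evaluates the five overlap metrics: IoU = TP/(TP+FP+FN),
#' DSC = 2TP/(2TP+FP+FN), TNR = TN/(TN+FP), TPR = TP/(TP+FN) and
#' precision = TP/(TP+FP). A metric whose denominator is zero is undefined
#' and returned as `NA`, never coerced to 0 or 1.
#'
#' @param c A `confusion_counts` object.
#' @return Named numeric vector `iou, dsc, tnr, tpr, precision` (NA where
#'   undefined).
#' @export
overlap_metrics <- function(c) {
  TP <- as.numeric(c$TP); TN <- as.numeric(c$TN)
  FP <- as.numeric(c$FP); FN <- as.numeric(c$FN)
  c(iou = ratio_or_na(TP, TP + FP + FN),
    dsc = ratio_or_na(2 * TP, 2 * TP + FP + FN),
    tnr = ratio_or_na(TN, TN + FP),
    tpr = ratio_or_na(TP, TP + FN),
    precision = ratio_or_na(TP, TP + FP))
}

#' Cohen's kappa from confusion counts
#'
#' Chance-corrected agreement with observed agreement
#' \eqn{p_o = (TP+TN)/N} and chance agreement from both raters' marginals,
#' \eqn{p_e = [(TP+FN)(TP+FP) + (FP+TN)(FN+TN)]/N^2}; then
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)}. When \eqn{p_e = 1} (both marginals
#' degenerate and equal) kappa is undefined and returned as `NA`.
#'
#' @param c A `confusion_counts` object with N > 0.
#' @return Named numeric vector `kappa, po, pe`.
#' @export
cohens_kappa <- function(c) {
  TP <- as.numeric(c$TP); TN <- as.numeric(c$TN)
  FP <- as.numeric(c$FP); FN <- as.numeric(c$FN)
  N <- TP + TN + FP + FN
  if (N == 0) stopf("kappa needs at least one pixel")
  po <- (TP + TN) / N
  pe <- ((TP + FN) * (TP + FP) + (FP + TN) * (FN + TN)) / N^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  c(kappa = kappa, po = po, pe = pe)
}

#' Verbal agreement band for a kappa value
#'
#' Maps kappa to the conventional interpretation bands: no agreement for
#' \eqn{\kappa \le 0}, then none-to-slight (0.01-0.20), fair (0.21-0.40),
#' moderate (0.41-0.60), substantial (0.61-0.80) and almost perfect
#' (0.81-1.00).
#'
#' @param kappa Value in \[-1, 1\].
#' @return One of `"none"`, `"none-to-slight"`, `"fair"`, `"moderate"`,
#'   `"substantial"`, `"almost-perfect"`.
#' @export
kappa_category <- function(kappa) {
  if (is.na(kappa) || kappa < -1 || kappa > 1)
    stopf("kappa must lie in [-1, 1]")
  if (kappa <= 0) "none"
  else if (kappa <= 0.20) "none-to-slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost-perfect"
}

#' Gwet's AC1 from confusion counts, in two variants
#'
#' Both variants share the kappa structure \eqn{(p_o - p_e)/(1 - p_e)} and
#' differ only in the chance term. The `"annotator_marginal"` variant takes
#' \eqn{p_e = p_+^2 + p_-^2} with \eqn{p_+ = (TP+FP)/N} and
#' \eqn{p_- = (FN+TN)/N}: both probabilities come from the annotator-side
#' marginal only, which makes this variant asymmetric in the two raters.
#' The `"standard"` variant uses Gwet's published chance term
#' \eqn{p_e = 2\pi(1-\pi)} with \eqn{\pi} the mean of the two raters'
#' positive-rate marginals, and is symmetric. The two can differ
#' substantially on imbalanced masks; both are always reported.
#'
#' @param c A `confusion_counts` object with N > 0.
#' @param variant `"annotator_marginal"` (default, used for replication of
#'   the study design this package emulates) or `"standard"`.
#' @return Named numeric vector `ac1, po, pe` (`ac1` is NA when
#'   \eqn{p_e = 1}).
#' @export
gwets_ac1 <- function(c, variant = c("annotator_marginal", "standard")) {
  variant <- match.arg(variant)
  TP <- as.numeric(c$TP); TN <- as.numeric(c$TN)
  FP <- as.numeric(c$FP); FN <- as.numeric(c$FN)
  N <- TP + TN + FP + FN
  if (N == 0) stopf("AC1 needs at least one pixel")
  po <- (TP + TN) / N
  if (variant == "annotator_marginal") {
    p_pos <- (TP + FP) / N
    p_neg <- (FN + TN) / N
    pe <- p_pos^2 + p_neg^2
  } else {
    pi_bar <- ((TP + FP) / N + (TP + FN) / N) / 2
    pe <- 2 * pi_bar * (1 - pi_bar)
  }
  ac1 <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  c(ac1 = ac1, po = po, pe = pe)
}

#' All agreement scores from one confusion table
#'
#' @param c A `confusion_counts` object.
#' @return One-row data.frame with the overlap metrics, kappa, both AC1
#'   variants, and the observed/chance agreement terms.
#' @export
agreement_scores <- function(c) {
  ov <- overlap_metrics(c)
  ka <- cohens_kappa(c)
  a1 <- gwets_ac1(c, "annotator_marginal")
  a2 <- gwets_ac1(c, "standard")
  data.frame(iou = ov[["iou"]], dsc = ov[["dsc"]], tnr = ov[["tnr"]],
             tpr = ov[["tpr"]], precision = ov[["precision"]],
             kappa = ka[["kappa"]], ac1_annotator = a1[["ac1"]],
             ac1_standard = a2[["ac1"]],
             po = ka[["po"]], pe_kappa = ka[["pe"]], pe_ac1 = a1[["pe"]])
}

#' Pairwise inter-rater agreement matrix
#'
#' For every rater pair, confusion counts are pooled over all images of a
#' round (pixels pooled, the default aggregation) and the chosen coefficient
#' is computed. Raters missing the requested round reuse their other
#' round's masks when `reuse_single_round = TRUE`, mirroring designs where
#' a single-round rater's annotations stand in for both rounds.
#'
#' The annotator-marginal AC1 variant is not symmetric in (pred, ref); for
#' the matrix each unordered pair is computed once with the
#' earlier-listed rater as annotator, and mirrored.
#'
#' @param study An `annot_study`.
#' @param coefficient `"kappa"`, `"ac1_annotator"` or `"ac1_standard"`.
#' @param round Round number (1 or 2).
#' @param reuse_single_round Fall back to the other round when a rater has
#'   no mask for `round`.
#' @return An `agreement_matrix`: list with `rater_ids`, `values`
#'   (symmetric matrix, unit diagonal), `coefficient`, `round`,
#'   `mean_off_diagonal`.
#' @export
pairwise_matrix <- function(study, coefficient = c("kappa", "ac1_annotator", "ac1_standard"),
                            round = 1L, reuse_single_round = TRUE) {
  coefficient <- match.arg(coefficient)
  raters <- names(study$rater_tiers)
  nr <- length(raters)
  per_rater <- lapply(raters, function(r) {
    got <- masks_for(study, r, round = round)
    if (length(got) < length(study$images) && reuse_single_round) {
      fall <- masks_for(study, r, last_round = TRUE)
      for (img in setdiff(names(study$images), names(got))) got[[img]] <- fall[[img]]
    }
    missing <- setdiff(names(study$images), names(got))
    if (length(missing))
      stopf("rater '%s' has no round-%d mask for image(s) %s and no fallback",
            r, round, paste(missing, collapse = ", "))
    got
  })
  names(per_rater) <- raters
  coeff_fun <- switch(coefficient,
    kappa = function(cc) cohens_kappa(cc)[["kappa"]],
    ac1_annotator = function(cc) gwets_ac1(cc, "annotator_marginal")[["ac1"]],
    ac1_standard = function(cc) gwets_ac1(cc, "standard")[["ac1"]])
  vals <- diag(1, nr)
  dimnames(vals) <- list(raters, raters)
  for (i in seq_len(nr)) {
    for (j in seq_len(nr)) {
      if (j <= i) next
      pooled <- NULL
      for (img in names(study$images)) {
        cc <- confusion_counts(per_rater[[i]][[img]], per_rater[[j]][[img]])
        pooled <- if (is.null(pooled)) cc else add_counts(pooled, cc)
      }
      vals[i, j] <- vals[j, i] <- coeff_fun(pooled)
    }
  }
  off <- vals[upper.tri(vals)]
  structure(list(rater_ids = raters, values = vals, coefficient = coefficient,
                 round = as.integer(round),
                 mean_off_diagonal = mean(off, na.rm = TRUE)),
            class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("<agreement_matrix> %s, round %d (mean off-diagonal %.4f)\n",
              x$coefficient, x$round, x$mean_off_diagonal))
  print(round(x$values, digits))
  invisible(x)
}
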