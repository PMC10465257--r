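#' Pixelwise majority-vote consensus of rater masks
#'
#' Fuses aligned binary masks into one consensus mask. Two tie rules are
#' provided because a two-rater "majority" is otherwise ambiguous:
#' `strict_majority` marks a pixel positive when positive votes exceed half
#' the panel (for two raters this is the intersection: a ground-truth pixel
#' is one both experts marked); `at_least_half` marks it positive when votes
#' reach half (the union for two raters). Every report records the rule used.
#'
#' @param masks List of [annotation_mask] objects for a single image.
#' @param rule `"strict_majority"` (default) or `"at_least_half"`.
#' @return An object of class `consensus_mask` with fields `image_id`,
#'   `mask`, `n_voters`, `rule`.
#' @export
majority_vote <- function(masks, rule = c("strict_majority", "at_least_half")) {
  rule <- match.arg(rule)
  if (length(masks) < 1) stopf("majority_vote needs at least one mask")
  ids <- unique(vapply(masks, function(m) m$image_id, character(1)))
  if (length(ids) != 1)
    stopf("masks from different images cannot be fused: %s",
          paste(ids, collapse = ", "))
  dims <- vapply(masks, function(m) dim(m$mask), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("masks for image '%s' have mismatched shapes", ids)
  n <- length(masks)
  votes <- Reduce(`+`, lapply(masks, function(m) m$mask * 1L))
  fused <- if (rule == "strict_majority") votes > n / 2 else votes >= n / 2
  structure(list(image_id = ids, mask = fused, n_voters = n, rule = rule),
            class = "consensus_mask")
}

#' @export
print.consensus_mask <- function(x, ...) {
  cat(sprintf("<consensus_mask '%s'> %d voters, rule %s, %d positive px\n",
              x$image_id, x$n_voters, x$rule, sum(x$mask)))
  invisible(x)
}

#' Build ground-truth consensus masks for a study
#'
#' For every image, each consensus-panel rater contributes their
#' highest-numbered round (a rater with a single round contributes that
#' round), and the masks are fused with [majority_vote].
#'
#' @param study An `annot_study` (see [load_study] or [generate_study]).
#' @param rule Vote rule passed to [majority_vote].
#' @return Named list of `consensus_mask`, keyed by image_id.
#' @export
build_ground_truth <- function(study, rule = "strict_majority") {
  raters <- study$consensus_raters
  if (length(raters) < 1) stopf("study declares no consensus raters")
  per_rater <- lapply(raters, function(r) masks_for(study, r, last_round = TRUE))
  names(per_rater) <- raters
  out <- list()
  for (img in names(study$images)) {
    masks <- lapply(raters, function(r) per_rater[[r]][[img]])
    missing <- raters[vapply(masks, is.null, logical(1))]
    if (length(missing))
      stopf("consensus rater(s) %s have no mask for image '%s'",
            paste(missing, collapse = ", "), img)
    out[[img]] <- majority_vote(masks, rule = rule)
  }
  out
}
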