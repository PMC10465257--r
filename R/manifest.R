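#' Study manifest: images x raters x rounds
#'
#' The manifest is the study design as data: which images exist (with their
#' per-image physical scaling), which (image, rater, round) mask files were
#' collected, each rater's experience tier, and which raters form the
#' consensus (ground-truth) panel.
#'
#' @param images Data.frame with columns `image_id`, `path`, `scale_x_um`,
#'   `scale_y_um`.
#' @param masks Data.frame with columns `image_id`, `rater_id`, `round_id`,
#'   `path`.
#' @param rater_tiers Named character vector mapping rater_id to
#'   `"expert"` or `"junior"`.
#' @param consensus_raters Character vector of rater ids fused into the
#'   ground truth; must be a subset of the declared raters.
#' @param base_dir Directory that relative file paths resolve against.
#' @return An object of class `study_manifest`.
#' @export
study_manifest <- function(images, masks, rater_tiers, consensus_raters,
                           base_dir = ".") {
  images <- as.data.frame(images, stringsAsFactors = FALSE)
  masks <- as.data.frame(masks, stringsAsFactors = FALSE)
  need_i <- c("image_id", "path", "scale_x_um", "scale_y_um")
  need_m <- c("image_id", "rater_id", "round_id", "path")
  if (!all(need_i %in% names(images)))
    stopf("images table must have columns: %s", paste(need_i, collapse = ", "))
  if (nrow(masks) > 0 && !all(need_m %in% names(masks)))
    stopf("masks table must have columns: %s", paste(need_m, collapse = ", "))
  if (nrow(masks) == 0)
    masks <- data.frame(image_id = character(), rater_id = character(),
                        round_id = integer(), path = character(),
                        stringsAsFactors = FALSE)
  masks$round_id <- as.integer(masks$round_id)

  if (anyDuplicated(images$image_id))
    stopf("duplicate image_id in manifest: %s",
          paste(unique(images$image_id[duplicated(images$image_id)]), collapse = ", "))
  if (any(images$scale_x_um <= 0) || any(images$scale_y_um <= 0))
    stopf("image scaling must be positive")
  dangling <- setdiff(masks$image_id, images$image_id)
  if (length(dangling))
    stopf("mask references undeclared image(s): %s", paste(dangling, collapse = ", "))
  key <- paste(masks$image_id, masks$rater_id, masks$round_id)
  if (anyDuplicated(key))
    stopf("duplicate (image, rater, round) record(s): %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  if (nrow(masks) > 0 && !all(masks$round_id %in% c(1L, 2L)))
    stopf("round_id must be 1 or 2")
  raters <- unique(masks$rater_id)
  tiers <- unlist(rater_tiers)
  if (!all(raters %in% names(tiers)))
    stopf("rater_tiers missing entries for: %s",
          paste(setdiff(raters, names(tiers)), collapse = ", "))
  if (!all(tiers %in% c("expert", "junior")))
    stopf("rater tiers must be 'expert' or 'junior'")
  consensus_raters <- as.character(consensus_raters)
  if (length(raters) && !all(consensus_raters %in% raters))
    stopf("consensus rater(s) not among declared raters: %s",
          paste(setdiff(consensus_raters, raters), collapse = ", "))

  structure(
    list(images = images, masks = masks, rater_tiers = tiers,
         consensus_raters = consensus_raters, base_dir = base_dir),
    class = "study_manifest")
}

#' @export
print.study_manifest <- function(x, ...) {
  cat(sprintf("<study_manifest> %d images, %d masks, %d raters (%d consensus)\n",
              nrow(x$images), nrow(x$masks),
              length(unique(x$masks$rater_id)), length(x$consensus_raters)))
  invisible(x)
}

#' Load and validate a study manifest from JSON or CSV
#'
#' JSON is the canonical format: an object with `images`, `masks`,
#' `rater_tiers` and `consensus_raters` fields. A flat CSV dialect is
#' accepted as a convenience, one row per mask record with columns
#' `image_id, image_path, scale_x_um, scale_y_um, rater_id, round_id,
#' mask_path, tier, consensus` (consensus: TRUE for panel raters).
#' Referential integrity (no dangling image references, no duplicate
#' (image, rater, round), consensus panel a subset of raters) is enforced.
#'
#' @param path Manifest file (.json or .csv).
#' @return A [study_manifest]; relative paths resolve against the manifest's
#'   directory.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  base_dir <- dirname(normalizePath(path))
  if (ext == "json") {
    m <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    tiers <- unlist(m$rater_tiers)
    study_manifest(m$images, m$masks %||% data.frame(), tiers,
                   m$consensus_raters %||% character(), base_dir = base_dir)
  } else if (ext == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    images <- unique(tab[, c("image_id", "image_path", "scale_x_um", "scale_y_um")])
    names(images)[2] <- "path"
    masks <- tab[, c("image_id", "rater_id", "round_id", "mask_path")]
    names(masks)[4] <- "path"
    tiers_tab <- unique(tab[, c("rater_id", "tier")])
    tiers <- stats::setNames(tiers_tab$tier, tiers_tab$rater_id)
    consensus <- unique(tab$rater_id[as.logical(tab$consensus)])
    study_manifest(images, masks, tiers, consensus, base_dir = base_dir)
  } else stopf("unsupported manifest format: %s", ext)
}

#' Write a study manifest to canonical JSON
#'
#' @param manifest A [study_manifest].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "study_manifest"))
  obj <- list(images = manifest$images, masks = manifest$masks,
              rater_tiers = as.list(manifest$rater_tiers),
              consensus_raters = manifest$consensus_raters)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load every image and mask referenced by a manifest
#'
#' @param manifest A [study_manifest].
#' @return An `annot_study`: list with `images` (named list of [bscan]),
#'   `masks` (list of [annotation_mask]), `rater_tiers`, `consensus_raters`.
#' @export
load_study <- function(manifest) {
  stopifnot(inherits(manifest, "study_manifest"))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(manifest$base_dir, p))
  images <- list()
  for (i in seq_len(nrow(manifest$images))) {
    rec <- manifest$images[i, ]
    images[[rec$image_id]] <- read_image(resolve(rec$path),
                                         scale_x_um = rec$scale_x_um,
                                         scale_y_um = rec$scale_y_um,
                                         image_id = rec$image_id)
  }
  masks <- vector("list", nrow(manifest$masks))
  for (i in seq_len(nrow(manifest$masks))) {
    rec <- manifest$masks[i, ]
    masks[[i]] <- read_mask(resolve(rec$path), images[[rec$image_id]],
                            rater_id = rec$rater_id, round_id = rec$round_id)
  }
  structure(list(images = images, masks = masks,
                 rater_tiers = manifest$rater_tiers,
                 consensus_raters = manifest$consensus_raters),
            class = "annot_study")
}

#' @export
print.annot_study <- function(x, ...) {
  cat(sprintf("<annot_study> %d images, %d masks, raters: %s\n",
              length(x$images), length(x$masks),
              paste(names(x$rater_tiers), collapse = ", ")))
  invisible(x)
}

# Internal: retrieve masks for (rater, round) across images, as a named list
# keyed by image_id. With last_round = TRUE, a rater lacking the requested
# round falls back to their highest available round (single-round raters
# contribute that round wherever "last round" is required).
masks_for <- function(study, rater, round = NULL, last_round = FALSE) {
  out <- list()
  for (m in study$masks) {
    if (m$rater_id != rater) next
    cur <- out[[m$image_id]]
    if (last_round) {
      if (is.null(cur) || m$round_id > cur$round_id) out[[m$image_id]] <- m
    } else if (m$round_id == round) out[[m$image_id]] <- m
  }
  out
}
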