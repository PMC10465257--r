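# Connected-component machinery and per-region geometry.

# 8-connected labelling. EBImage::bwlabel is 4-connected; labels that touch
# across a diagonal are merged with a union-find pass, then relabelled
# consecutively in top-left (row-major) order of each component's first pixel.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n > 0 && connectivity == 8L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonals
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonals
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(n)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      root <- vapply(seq_len(n), find, integer(1))
      fg <- lab > 0L
      lab[fg] <- root[lab[fg]]
    }
  }
  # relabel 1..k by row-major order of first appearance
  fg_idx <- which(lab > 0L)
  if (length(fg_idx) == 0) return(lab)
  nr <- nrow(lab)
  rowmajor <- ((fg_idx - 1L) %% nr) * ncol(lab) + ((fg_idx - 1L) %/% nr)
  o <- order(rowmajor)
  first_seen <- !duplicated(lab[fg_idx][o])
  new_id <- integer(max(lab))
  new_id[lab[fg_idx][o][first_seen]] <- seq_len(sum(first_seen))
  lab[fg_idx] <- new_id[lab[fg_idx]]
  lab
}

#' Decompose a mask into connected annotated regions
#'
#' Freehand annotation strokes are treated as 8-connected by default (two
#' pixels touching only diagonally belong to one region); 4-connectivity is
#' available for comparison. Regions are numbered deterministically, first
#' annotated pixel in row-major (top-left) order first.
#'
#' @param mask Logical matrix or [annotation_mask].
#' @param connectivity 8 (default) or 4.
#' @return List of `annotated_region` objects, each with `region_id`,
#'   `pixels` (linear indices into the mask), `area_px`, `centroid`
#'   (row, col), `bbox` (row1, row2, col1, col2).
#' @export
connected_regions <- function(mask, connectivity = 8L) {
  m <- as_mask_matrix(mask)
  lab <- label_components(m, as.integer(connectivity))
  k <- max(lab)
  if (k == 0) return(list())
  nr <- nrow(m)
  idx_by_lab <- split(which(lab > 0L), lab[lab > 0L])
  lapply(seq_len(k), function(i) {
    idx <- idx_by_lab[[as.character(i)]]
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    structure(list(region_id = i, pixels = idx, area_px = length(idx),
                   centroid = c(row = mean(rows), col = mean(cols)),
                   bbox = c(row1 = min(rows), row2 = max(rows),
                            col1 = min(cols), col2 = max(cols)),
                   dim = dim(m)),
              class = "annotated_region")
  })
}

#' @export
print.annotated_region <- function(x, ...) {
  cat(sprintf("<annotated_region %d> area %d px, centroid (%.1f, %.1f)\n",
              x$region_id, x$area_px, x$centroid[1], x$centroid[2]))
  invisible(x)
}

# Internal: materialise a region as a logical matrix of the full image shape.
region_matrix <- function(region) {
  m <- matrix(FALSE, region$dim[1], region$dim[2])
  m[region$pixels] <- TRUE
  m
}

#' One-pixel boundary bands of a region
#'
#' The inner band is the set of region pixels with at least one background
#' 8-neighbour (the region minus its erosion by a 3x3 square); the outer
#' band is the set of background pixels with at least one region
#' 8-neighbour (the 3x3 dilation minus the region), clipped at the image
#' borders. These are the 1-px shells immediately inside and outside the
#' annotation edge.
#'
#' @param region An `annotated_region` from [connected_regions].
#' @return List with `outer_band` and `inner_band`, linear pixel indices.
#' @export
boundary_bands <- function(region) {
  d <- region$dim
  bb <- region$bbox
  # work on a 1-px padded crop so dilation near the bbox is correct;
  # pixels outside the image do not exist, so the pad is clipped afterwards
  r1 <- max(1L, bb[["row1"]] - 1L); r2 <- min(d[1], bb[["row2"]] + 1L)
  c1 <- max(1L, bb[["col1"]] - 1L); c2 <- min(d[2], bb[["col2"]] + 1L)
  sub <- matrix(FALSE, r2 - r1 + 1L, c2 - c1 + 1L)
  rows <- ((region$pixels - 1L) %% d[1]) + 1L
  cols <- ((region$pixels - 1L) %/% d[1]) + 1L
  sub[cbind(rows - r1 + 1L, cols - c1 + 1L)] <- TRUE
  brush <- matrix(1, 3, 3)
  er <- EBImage::erode(sub * 1, brush) > 0
  di <- EBImage::dilate(sub * 1, brush) > 0
  inner <- sub & !er
  outer <- di & !sub
  to_full <- function(w) {
    ij <- which(w, arr.ind = TRUE)
    (ij[, 2] + c1 - 2L) * d[1] + (ij[, 1] + r1 - 1L)
  }
  list(outer_band = as.integer(to_full(outer)),
       inner_band = as.integer(to_full(inner)))
}

#' Boundary and region intensity statistics
#'
#' Mean normalised intensity over the outer band, the inner band and the
#' whole region, and the outer-minus-inner difference. Fluid regions are
#' darker than surrounding tissue, so an accurate annotation has a bright
#' outer band and a dark inner band: a larger difference indicates a more
#' accurate boundary, and oversegmentation (annotation spilling into
#' tissue) shrinks it.
#'
#' @param image A [bscan] (normalised intensities).
#' @param region An `annotated_region` on that image.
#' @return One-row data.frame: `mean_outer`, `mean_inner`, `mean_region`,
#'   `diff_outer_inner` (NA if the outer band is empty, e.g. a region
#'   filling the whole image).
#' @export
boundary_intensity_stats <- function(image, region) {
  stopifnot(inherits(image, "bscan"))
  if (!identical(region$dim, dim(image$pixels)))
    stopf("region does not belong to image '%s'", image$image_id)
  bands <- boundary_bands(region)
  mean_outer <- if (length(bands$outer_band)) mean(image$pixels[bands$outer_band]) else NA_real_
  mean_inner <- if (length(bands$inner_band)) mean(image$pixels[bands$inner_band]) else NA_real_
  data.frame(mean_outer = mean_outer, mean_inner = mean_inner,
             mean_region = mean(image$pixels[region$pixels]),
             diff_outer_inner = mean_outer - mean_inner)
}

#' Retinal zone specification
#'
#' Zones are horizontal bands at increasing lateral distance from the
#' geometric centre column of the B-scan: zone 1 within `boundaries_mm[1]`,
#' zone 2 up to `boundaries_mm[2]`, zone 3 up to `boundaries_mm[3]`;
#' regions farther out fall in no zone and are reported separately.
#'
#' @param boundaries_mm Strictly increasing positive cut points in mm
#'   (default 0.5, 1.5, 3.0).
#' @return A `zone_spec` object.
#' @export
zone_spec <- function(boundaries_mm = c(0.5, 1.5, 3.0)) {
  if (length(boundaries_mm) != 3 || any(diff(boundaries_mm) <= 0) ||
      boundaries_mm[1] <= 0)
    stopf("zone boundaries must be 3 strictly increasing positive cut points")
  structure(list(boundaries_mm = boundaries_mm), class = "zone_spec")
}

#' Zone of a region
#'
#' The region is assigned by its centroid: the lateral distance from the
#' image centre column, converted to mm with the image's X scaling, is
#' binned against the zone cut points (half-open bins; a region straddling
#' a cut belongs to its centroid's zone).
#'
#' @param region An `annotated_region`.
#' @param image The [bscan] the region lies on (supplies width and X scale).
#' @param spec A [zone_spec].
#' @return Integer 1, 2 or 3, or `NA` for regions beyond the outermost cut.
#' @export
zone_of <- function(region, image, spec = zone_spec()) {
  stopifnot(inherits(image, "bscan"))
  w <- ncol(image$pixels)
  col0 <- region$centroid[["col"]] - 1  # 0-based pixel-centre coordinate
  d_mm <- abs(col0 - w / 2) * image$scale_x_um / 1000
  b <- spec$boundaries_mm
  if (d_mm < b[1]) 1L
  else if (d_mm < b[2]) 2L
  else if (d_mm < b[3]) 3L
  else NA_integer_
}
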