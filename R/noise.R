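#' Estimate the Poisson speckle shape parameter of a B-scan
#'
#' OCT speckle is modelled as count noise: an observed pixel is
#' \eqn{Poisson(\lambda c)/\lambda} around its clean value \eqn{c}, so the
#' local noise variance is proportional to the local mean with slope
#' \eqn{1/\lambda}. The estimator partitions the image into small tiles,
#' computes each tile's sample mean and sample variance, and takes
#' \eqn{\hat\lambda} as the reciprocal of the median variance/mean ratio
#' across tiles. The median makes the estimate robust to the minority of
#' tiles that straddle anatomical edges (whose variance is dominated by
#' structure, not noise). The contract is recovery of the generating
#' \eqn{\lambda} on phantoms, not a particular numeric path.
#'
#' @param image A [bscan].
#' @param tile_px Tile side in pixels (default 8).
#' @return A `noise_estimate`: list with `lambda_hat` and `group`
#'   (see [noise_group]).
#' @export
estimate_noise_lambda <- function(image, tile_px = 8L) {
  stopifnot(inherits(image, "bscan"))
  px <- image$pixels
  nr <- (nrow(px) %/% tile_px) * tile_px
  nc <- (ncol(px) %/% tile_px) * tile_px
  if (nr < tile_px || nc < tile_px) stopf("image smaller than one tile")
  px <- px[seq_len(nr), seq_len(nc)]
  # reshape into tile_px^2 x n_tiles columns
  a <- array(px, dim = c(tile_px, nr / tile_px, tile_px, nc / tile_px))
  a <- aperm(a, c(1, 3, 2, 4))
  dim(a) <- c(tile_px * tile_px, (nr / tile_px) * (nc / tile_px))
  m <- colMeans(a)
  v <- colMeans(a^2) - m^2
  v <- v * (nrow(a) / (nrow(a) - 1))  # unbiased
  keep <- m > 1e-3
  if (!any(keep)) stopf("image carries no intensity signal")
  ratio <- stats::median(v[keep] / m[keep])
  if (ratio <= 0)
    stopf("no noise signal detected (constant or noise-free image)")
  lambda_hat <- 1 / ratio
  structure(list(lambda_hat = lambda_hat, group = noise_group(lambda_hat)),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> lambda_hat = %.3f (%s noise)\n",
              x$lambda_hat, x$group))
  invisible(x)
}

#' Noise group for an estimated lambda
#'
#' Bins the speckle shape parameter into low / medium / high noise groups.
#' The conventional cut points 20 and 40 are shared endpoints; they are
#' resolved as half-open intervals \[0, 20) low, \[20, 40) medium and
#' \[40, Inf) high, so 20 is medium and 40 is high.
#'
#' @param lambda_hat Positive estimate of the shape parameter.
#' @param cuts Two increasing positive cut points (default 20, 40).
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
noise_group <- function(lambda_hat, cuts = c(20, 40)) {
  if (is.na(lambda_hat) || lambda_hat <= 0)
    stopf("lambda_hat must be positive")
  if (lambda_hat < cuts[1]) "low" else if (lambda_hat < cuts[2]) "medium" else "high"
}
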