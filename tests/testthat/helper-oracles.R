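# Independent brute-force oracles, deliberately written as plain pixel loops
# so they share no code path with the package implementation.

brute_confusion <- function(pred, ref) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; r <- ref[i, j]
      if (p && r) tp <- tp + 1L
      else if (!p && !r) tn <- tn + 1L
      else if (p && !r) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

brute_metrics <- function(ct) {
  TP <- ct$TP; TN <- ct$TN; FP <- ct$FP; FN <- ct$FN
  N <- TP + TN + FP + FN
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  po <- (TP + TN) / N
  pe_k <- ((TP + FN) * (TP + FP) + (FP + TN) * (FN + TN)) / N^2
  ppos <- (TP + FP) / N; pneg <- (FN + TN) / N
  pe_a <- ppos^2 + pneg^2
  pibar <- ((TP + FP) / N + (TP + FN) / N) / 2
  pe_s <- 2 * pibar * (1 - pibar)
  list(iou = div(TP, TP + FP + FN),
       dsc = div(2 * TP, 2 * TP + FP + FN),
       tnr = div(TN, TN + FP),
       tpr = div(TP, TP + FN),
       precision = div(TP, TP + FP),
       kappa = if (pe_k == 1) NA_real_ else (po - pe_k) / (1 - pe_k),
       ac1_annotator = if (pe_a == 1) NA_real_ else (po - pe_a) / (1 - pe_a),
       ac1_standard = if (pe_s == 1) NA_real_ else (po - pe_s) / (1 - pe_s))
}

# Flood-fill labelling by explicit neighbour scanning (8- or 4-connectivity).
brute_components <- function(mask, connectivity = 8L) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nb <- if (connectivity == 8L)
    rbind(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else rbind(c(-1,0), c(0,-1), c(0,1), c(1,0))
  k <- 0L
  for (sj in seq_len(ncol(mask))) for (si in seq_len(nrow(mask))) {
    if (!mask[si, sj] || lab[si, sj] != 0L) next
    k <- k + 1L
    queue <- list(c(si, sj)); lab[si, sj] <- k
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (d in seq_len(nrow(nb))) {
        ii <- cur[1] + nb[d, 1]; jj <- cur[2] + nb[d, 2]
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- k
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# 1-px boundary bands by explicit neighbour scanning.
brute_bands <- function(region_mask) {
  inner <- outer_ <- matrix(FALSE, nrow(region_mask), ncol(region_mask))
  for (i in seq_len(nrow(region_mask))) for (j in seq_len(ncol(region_mask))) {
    has_bg_nb <- FALSE; has_fg_nb <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nrow(region_mask) || jj < 1 || jj > ncol(region_mask)) next
      if (region_mask[ii, jj]) has_fg_nb <- TRUE else has_bg_nb <- TRUE
    }
    if (region_mask[i, j] && has_bg_nb) inner[i, j] <- TRUE
    if (!region_mask[i, j] && has_fg_nb) outer_[i, j] <- TRUE
  }
  list(inner = which(inner), outer = which(outer_))
}

random_mask <- function(nr, nc, p = 0.3) matrix(runif(nr * nc) < p, nr, nc)

# Small raster disc, TRUE inside radius r around (ci, cj).
disc_mask <- function(nr, nc, ci, cj, r) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if ((i - ci)^2 + (j - cj)^2 <= r^2) m[i, j] <- TRUE
  m
}

# Small fast phantom spec for unit tests.
tiny_phantom <- function(seed, n_regions = 4L, noise_lambda = 20,
                         height = 160L, width = 240L) {
  phantom_spec(height_px = height, width_px = width, n_regions = n_regions,
               region_axes_um = c(30, 80), noise_lambda = noise_lambda,
               seed = seed)
}
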