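#' @include AllClasses.R
NULL

#' Contrast enhancement and despeckling
#'
#' Linear percentile stretch saturating `saturationFraction` of the pixels
#' at each tail (mapping the low percentile to 0 and the high percentile
#' to 1, clamping outside), followed by a median-filter despeckle that
#' removes isolated single-pixel spikes.
#'
#' @param img 2-D numeric matrix (single channel).
#' @param saturationFraction fraction saturated at each tail,
#'   default 0.003.
#' @param despeckleRadius median filter radius (px), default 1; 0 skips
#'   despeckling.
#' @return numeric matrix in [0, 1].
#' @export
preprocessImage <- function(img, saturationFraction = 0.003,
                            despeckleRadius = 1) {
  if (length(dim(img)) != 2L) stop("image must be a 2-D single-channel matrix")
  q <- stats::quantile(img, c(saturationFraction, 1 - saturationFraction),
                       names = FALSE)
  if (q[2] - q[1] < .Machine$double.eps) return(matrix(0, nrow(img), ncol(img)))
  out <- pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
  if (despeckleRadius >= 1)
    out <- as.matrix(EBImage::medianFilter(out, as.integer(despeckleRadius)))
  out
}

# 8-connected labelling: 4-connected labels merged across diagonals
.label8 <- function(bin) {
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(lab), nrow(bin), ncol(bin))
  n <- max(lab)
  if (n < 2L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a <- c(lab[-H, -W], lab[-H, -1])   # pixel
  b <- c(lab[-1, -1], lab[-1, -W])   # its down-right / down-left neighbour
  keep <- a > 0L & b > 0L & a != b
  pairs <- unique(cbind(a[keep], b[keep]))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    i <- find(pairs[k, 1]); j <- find(pairs[k, 2])
    if (i != j) parent[max(i, j)] <- min(i, j)
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

#' Segment mitochondrial particles within a cell
#'
#' Global thresholding (Otsu by default, guarded by a robust noise floor
#' of `median + noiseFloorK * MAD` so that blank images yield no
#' detections), restriction to the cell mask, 8-connected component
#' labelling, manual-correction exclusions, and the area filter that
#' removes particles with area less than or equal to `areaCutoff`
#' (default 3 calibrated units, the false-positive filter). Both threshold
#' candidates are data-relative, so segmentation is invariant to uniform
#' intensity scaling.
#'
#' @param img enhanced image from [preprocessImage()] (values in [0, 1]).
#' @param cellMask logical matrix delineating the cell of interest.
#' @param thresholdMethod `"otsu"` (Otsu with noise floor) or `"floor"`
#'   (noise floor only).
#' @param exclusionList integer ids of particles to drop (the
#'   reproducible stand-in for the macro's manual false-positive
#'   correction).
#' @param pixelSize physical pixel size; areas are reported in
#'   `pixelSize^2` units (1 = pixel^2).
#' @param areaCutoff exclusion cutoff in calibrated area units, default 3
#'   (inclusive: area <= cutoff is removed).
#' @param noiseFloorK noise-floor multiplier, default 5.
#' @param imageId identifier stored in the result.
#' @return A [ParticleSet-class]; the label image is attached as
#'   attribute `"labels"`.
#' @export
segmentParticles <- function(img, cellMask,
                             thresholdMethod = c("otsu", "floor"),
                             exclusionList = integer(0), pixelSize = 1,
                             areaCutoff = 3, noiseFloorK = 5,
                             imageId = "image") {
  thresholdMethod <- match.arg(thresholdMethod)
  if (!identical(dim(img), dim(cellMask)))
    stop("cell mask must have the same shape as the image")
  if (!any(cellMask)) stop("empty cell mask")
  floorThr <- stats::median(img) + noiseFloorK * stats::mad(img)
  rng <- range(img)   # data-relative histogram keeps Otsu scale-invariant
  thr <- if (thresholdMethod == "otsu" && diff(rng) > 0)
    max(EBImage::otsu(EBImage::Image(img), range = rng), floorThr)
  else floorThr
  bin <- img > thr & cellMask
  lab <- .label8(bin)
  n <- max(lab)
  ids <- seq_len(n)
  px <- tabulate(lab, nbins = n)
  idx <- which(lab > 0L, arr.ind = TRUE)
  cx <- vapply(split(idx[, 2], lab[lab > 0L]), mean, numeric(1))
  cy <- vapply(split(idx[, 1], lab[lab > 0L]), mean, numeric(1))
  all <- data.frame(id = ids, area = px * pixelSize^2,
                    x = as.numeric(cx), y = as.numeric(cy))
  reason <- rep(NA_character_, n)
  reason[all$id %in% exclusionList] <- "manual exclusion"
  small <- is.na(reason) & all$area <= areaCutoff
  reason[small] <- sprintf("area <= %g", areaCutoff)
  keepRows <- is.na(reason)
  ps <- new("ParticleSet",
            particles = all[keepRows, , drop = FALSE],
            excluded = cbind(all[!keepRows, c("id", "area"), drop = FALSE],
                             reason = reason[!keepRows]),
            cellArea = sum(cellMask) * pixelSize^2,
            areaCutoff = areaCutoff, imageId = imageId)
  attr(ps, "labels") <- lab
  ps
}

#' Per-cell morphology metrics
#'
#' Mean particle area, particle count per cell area, and total particle
#' area per cell area (as a percentage) over the retained particles of a
#' cell.
#'
#' @param particleSet a [ParticleSet-class].
#' @return one-row data.frame (`mean_area`, `count_per_area`,
#'   `area_fraction_pct`); `mean_area` is `NA` for an empty set.
#' @export
cellMetrics <- function(particleSet) {
  stopifnot(is(particleSet, "ParticleSet"))
  p <- particles(particleSet)
  ca <- cellArea(particleSet)
  data.frame(
    mean_area = if (nrow(p)) mean(p$area) else NA_real_,
    count_per_area = nrow(p) / ca,
    area_fraction_pct = if (nrow(p)) 100 * sum(p$area) / ca else 0
  )
}

#' Aggregate per-cell metrics to coverslips and conditions
#'
#' Follows the study design of the imaging experiment: three randomly
#' chosen cells per coverslip are averaged, and the per-coverslip means
#' (four coverslips per condition) are summarized per condition as
#' mean +/- SD.
#'
#' @param cells data.frame with columns `condition`, `coverslip`, and one
#'   or more numeric metric columns (e.g. the output of [cellMetrics()]
#'   with design labels added).
#' @param expectedCells cells expected per coverslip, default 3; a
#'   deviating coverslip triggers a warning and uses the available cells.
#' @return list with `coverslip` (per-coverslip means and `n_cells`) and
#'   `condition` (per-condition `mean_*`, `sd_*`, `n` over coverslips).
#' @export
aggregateReplicates <- function(cells, expectedCells = 3) {
  stopifnot(all(c("condition", "coverslip") %in% names(cells)))
  metrics <- setdiff(names(cells), c("condition", "coverslip", "cell"))
  sp <- split(cells, list(cells$condition, cells$coverslip), drop = TRUE)
  cov <- do.call(rbind, lapply(sp, function(d) {
    if (nrow(d) != expectedCells)
      warning(sprintf("coverslip %s (%s) has %d cells, expected %d",
                      d$coverslip[1], d$condition[1], nrow(d), expectedCells))
    out <- data.frame(condition = d$condition[1], coverslip = d$coverslip[1],
                      n_cells = nrow(d))
    for (m in metrics) out[[m]] <- mean(d[[m]], na.rm = TRUE)
    out
  }))
  rownames(cov) <- NULL
  cond <- do.call(rbind, lapply(split(cov, cov$condition), function(d) {
    out <- data.frame(condition = d$condition[1], n = nrow(d))
    for (m in metrics) {
      out[[paste0("mean_", m)]] <- mean(d[[m]])
      out[[paste0("sd_", m)]] <- stats::sd(d[[m]])
    }
    out
  }))
  rownames(cond) <- NULL
  list(coverslip = cov, condition = cond)
}
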