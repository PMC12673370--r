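#' @include AllClasses.R
NULL

#' Ground truth for a synthetic mitochondrial image
#'
#' Parameters of the image generator: rod-like particles (blurred
#' capsules) placed inside an elliptical cell mask, with a controllable
#' degree of fusion. `fusionDegree` f merges `round(f * (count - 1))`
#' rods onto existing particles by attaching them end-to-end with zero
#' pixel overlap (pixel-conserving), so f = 0 gives `count` separated
#' particles and f = 1 a single connected chain.
#'
#' @param count number of rods, >= 0.
#' @param fusionDegree fusion degree in [0, 1], default 0.
#' @param canvas image size `c(rows, cols)`, default c(256, 256).
#' @param cellRadii ellipse radii (px) of the cell mask, default c(100, 85).
#' @param rodLength range (px) of rod lengths, default c(9, 15).
#' @param rodRadius rod half-width (px), default 1.6.
#' @param snr peak amplitude of a particle in units of the background
#'   noise SD, default 8.
#' @param background background intensity (counts, Poisson), default 100.
#' @param readNoiseSd Gaussian read noise SD (counts), default 3.
#' @return list of class `ImageGroundTruth`.
#' @export
imageGroundTruth <- function(count, fusionDegree = 0, canvas = c(256, 256),
                             cellRadii = c(100, 85), rodLength = c(9, 15),
                             rodRadius = 1.6, snr = 8, background = 100,
                             readNoiseSd = 3) {
  stopifnot(count >= 0, fusionDegree >= 0, fusionDegree <= 1,
            all(canvas >= 32), rodRadius > 0, snr > 0, background > 0)
  structure(list(count = count, fusionDegree = fusionDegree,
                 canvas = canvas, cellRadii = cellRadii,
                 rodLength = rodLength, rodRadius = rodRadius, snr = snr,
                 background = background, readNoiseSd = readNoiseSd),
            class = "ImageGroundTruth")
}

# pixel indices (column-major) of a capsule of radius r around segment
# p1 -> p2; coordinates are (x = column, y = row)
.capsulePixels <- function(p1, p2, r, dim) {
  H <- dim[1]; W <- dim[2]
  xr <- max(1, floor(min(p1[1], p2[1]) - r)):min(W, ceiling(max(p1[1], p2[1]) + r))
  yr <- max(1, floor(min(p1[2], p2[2]) - r)):min(H, ceiling(max(p1[2], p2[2]) + r))
  if (!length(xr) || !length(yr)) return(integer(0))
  g <- expand.grid(y = yr, x = xr)
  v <- p2 - p1
  vv <- sum(v * v)
  t <- if (vv < 1e-12) rep(0, nrow(g)) else
    pmin(pmax(((g$x - p1[1]) * v[1] + (g$y - p1[2]) * v[2]) / vv, 0), 1)
  dx <- g$x - (p1[1] + t * v[1]); dy <- g$y - (p1[2] + t * v[2])
  keep <- dx * dx + dy * dy <= r * r
  as.integer((g$x[keep] - 1L) * H + g$y[keep])
}

.dilateIdx <- function(idx, dim, radius = 2L) {
  H <- dim[1]
  x <- (idx - 1L) %/% H + 1L; y <- (idx - 1L) %% H + 1L
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  xx <- pmin(pmax(rep(x, each = nrow(off)) + off$dx, 1L), dim[2])
  yy <- pmin(pmax(rep(y, each = nrow(off)) + off$dy, 1L), dim[1])
  unique((xx - 1L) * H + yy)
}

#' Render a synthetic mitochondrial fluorescence image
#'
#' Draws rod-shaped particles as Gaussian-blurred capsules inside an
#' elliptical cell mask, applies Poisson photon noise plus Gaussian read
#' noise, and returns the intensity image together with the ground-truth
#' label image. Fused rods are attached end-to-end without pixel overlap,
#' so the total particle area is conserved under fusion while the
#' component count drops.
#'
#' @param truth an [imageGroundTruth()].
#' @param seed optional integer seed.
#' @return list with `image` (numeric matrix, counts), `labels` (integer
#'   matrix, 0 = background), `cellMask` (logical matrix), `areas`
#'   (true pixel area per component) and `truth`.
#' @export
#' @examples
#' im <- renderCellImage(imageGroundTruth(10, canvas = c(128, 128),
#'                                        cellRadii = c(50, 40)), seed = 1)
#' max(im$labels)
renderCellImage <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "ImageGroundTruth"))
  if (!is.null(seed)) set.seed(seed)
  H <- truth$canvas[1]; W <- truth$canvas[2]
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  cellMask <- ((xs - cx) / truth$cellRadii[1])^2 +
    ((ys - cy) / truth$cellRadii[2])^2 <= 1

  occ <- matrix(0L, H, W)        # component id per pixel
  near <- matrix(FALSE, H, W)    # keep-out zone for separated placement
  comps <- list()
  r <- truth$rodRadius
  n <- truth$count
  nMerge <- if (n > 1) round(truth$fusionDegree * (n - 1)) else 0L
  nSingle <- n - nMerge

  placeSingle <- function() {
    for (try in 1:300) {
      L <- stats::runif(1, truth$rodLength[1], truth$rodLength[2])
      th <- stats::runif(1, 0, pi)
      c0 <- c(stats::runif(1, cx - truth$cellRadii[1], cx + truth$cellRadii[1]),
              stats::runif(1, cy - truth$cellRadii[2], cy + truth$cellRadii[2]))
      d <- c(cos(th), sin(th))
      pix <- .capsulePixels(c0 - L / 2 * d, c0 + L / 2 * d, r, c(H, W))
      if (!length(pix)) next
      if (all(cellMask[pix]) && !any(near[pix])) return(pix)
    }
    stop("cannot place particle without overlap; reduce count or fusion 0 crowding")
  }

  attachRod <- function(ci) {
    anchor <- comps[[ci]][sample.int(length(comps[[ci]]), 1)]
    ax <- (anchor - 1L) %/% H + 1L; ay <- (anchor - 1L) %% H + 1L
    for (try in 1:60) {
      L <- stats::runif(1, truth$rodLength[1], truth$rodLength[2])
      th <- stats::runif(1, 0, 2 * pi)
      d <- c(cos(th), sin(th))
      prev <- NULL
      ok <- FALSE
      for (k in 0:ceiling(L + 2 * r + 4)) {
        p1 <- c(ax, ay) + k * d
        pix <- .capsulePixels(p1, p1 + L * d, r, c(H, W))
        if (!length(pix) || !all(cellMask[pix])) break
        other <- occ[pix] != 0L & occ[pix] != ci
        if (any(other)) break
        overlap <- occ[pix] == ci
        if (!any(overlap)) {
          # disjoint: accept if still 8-connected to the target chain
          nb <- .dilateIdx(pix, c(H, W), 1L)
          if (any(occ[nb] == ci)) return(pix)
          # pushed past the diagonal gap: fall back to minimal overlap
          if (!is.null(prev)) return(prev[occ[prev] == 0L])
          break
        }
        prev <- pix
      }
    }
    stop("cannot attach fused particle; cell too crowded")
  }

  mergeTargets <- if (nMerge > 0 && nSingle >= 1)
    sample.int(nSingle, nMerge, replace = TRUE) else integer(0)

  for (i in seq_len(nSingle)) {
    pix <- placeSingle()
    comps[[length(comps) + 1L]] <- pix
    occ[pix] <- length(comps)
    near[.dilateIdx(pix, c(H, W), 2L)] <- TRUE
  }
  for (i in seq_len(nMerge)) {
    ci <- if (length(comps)) mergeTargets[i] else {
      comps[[1]] <- placeSingle(); occ[comps[[1]]] <- 1L; 1L
    }
    pix <- attachRod(ci)
    comps[[ci]] <- c(comps[[ci]], pix)
    occ[pix] <- ci
    near[.dilateIdx(pix, c(H, W), 2L)] <- TRUE
  }

  list(image = .renderIntensity(occ, truth), labels = occ,
       cellMask = cellMask, areas = lengths(comps), truth = truth)
}

.renderIntensity <- function(occ, truth) {
  H <- nrow(occ); W <- ncol(occ)
  mask01 <- matrix(0, H, W)
  mask01[occ > 0L] <- 1
  blur <- if (any(mask01 > 0)) EBImage::gblur(mask01, sigma = 0.7) else mask01
  amp <- truth$snr * sqrt(truth$background + truth$readNoiseSd^2)
  lambda <- truth$background + amp * blur
  matrix(stats::rpois(H * W, lambda) +
           stats::rnorm(H * W, 0, truth$readNoiseSd), H, W)
}

#' Fuse particles of a rendered image, conserving pixels
#'
#' Merges components of an already rendered synthetic image by
#' translating one particle until it touches another (8-connected, zero
#' pixel overlap whenever the grid allows it), then re-draws the
#' intensity image from the updated label image. Each merge reduces the
#' component count by exactly one while conserving the total particle
#' area, providing the paired fused/unfused comparison used to validate
#' that morphometry reports an unchanged area fraction with a reduced
#' count under fusion.
#'
#' @param rendered output of [renderCellImage()].
#' @param merges number of merge operations.
#' @param seed optional integer seed.
#' @return the rendered list with updated `image`, `labels` and `areas`.
#' @export
fuseParticles <- function(rendered, merges, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  occ <- rendered$labels
  H <- nrow(occ); W <- ncol(occ)
  for (mi in seq_len(merges)) {
    ids <- sort(unique(occ[occ > 0L]))
    if (length(ids) < 2L) break
    done <- FALSE
    for (try in 1:20) {
      B <- sample(ids, 1)
      A <- sample(setdiff(ids, B), 1)
      bIdx <- which(occ == B)
      aIdx <- which(occ == A)
      bx <- (bIdx - 1L) %/% H + 1L; by <- (bIdx - 1L) %% H + 1L
      d <- c(mean((aIdx - 1L) %/% H + 1L) - mean(bx),
             mean((aIdx - 1L) %% H + 1L) - mean(by))
      if (sum(d^2) < 1e-9) next
      d <- d / sqrt(sum(d^2))
      occ[bIdx] <- 0L
      prev <- bIdx
      placed <- FALSE
      for (k in seq_len(max(H, W))) {
        nx <- bx + round(k * d[1]); ny <- by + round(k * d[2])
        if (any(nx < 1L | nx > W | ny < 1L | ny > H)) break
        nIdx <- (nx - 1L) * H + ny
        if (!all(rendered$cellMask[nIdx])) break
        hit <- occ[nIdx]
        if (any(hit > 0L)) {
          target <- hit[hit > 0L][1]
          nb <- .dilateIdx(prev, c(H, W), 1L)
          if (any(occ[nb] == target)) {
            occ[prev] <- target            # touching, zero overlap
          } else {
            occ[nIdx[hit == 0L]] <- target # minimal-overlap fallback
          }
          placed <- TRUE
          break
        }
        prev <- nIdx
      }
      if (placed) { done <- TRUE; break }
      occ[bIdx] <- B                       # restore and retry another pair
    }
    if (!done) stop("could not fuse particles: cell too sparse or crowded")
  }
  ids <- sort(unique(occ[occ > 0L]))
  occ[occ > 0L] <- match(occ[occ > 0L], ids)
  rendered$labels <- occ
  rendered$areas <- tabulate(occ, nbins = max(occ))
  rendered$image <- .renderIntensity(occ, rendered$truth)
  rendered
}
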