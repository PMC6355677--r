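# Renders plant-like synthetic RGB views whose foreground masks contain an
# exactly specified pixel count. Plants are composed of axis-aligned
# rectangles at least 3 px thick (stem, leaves, base), which makes the mask
# invariant under a 3x3 morphological opening, so the default segmentation
# recovers the area exactly on clean images.

#' Rendering parameters for synthetic views
#'
#' @param width,height canvas size in pixels.
#' @param topFraction top-view projected area as a fraction of the side-view
#'   area (erect habits project less from above).
#' @param noiseSd standard deviation (8-bit counts) of Gaussian pixel noise
#'   added to all channels; 0 gives clean images with a strict
#'   excess-green-separable palette.
#' @return A named list of render parameters.
#' @export
renderParams <- function(width = 640, height = 640, topFraction = 0.3,
                         noiseSd = 0) {
  stopifnot(width >= 16, height >= 16, topFraction > 0, noiseSd >= 0)
  list(width = as.integer(width), height = as.integer(height),
       topFraction = topFraction, noiseSd = noiseSd)
}

# Exact-area plant silhouette: a 3-px-wide stem with 3-px-tall leaf
# rectangles branching alternately left and right, plus a 4-row base piece
# absorbing the area residue modulo 3. Areas below 30 px fall back to a
# compact quasi-disc (still exact, but too small to be plant-shaped).
.plantMask <- function(n, H, W) {
  mask <- matrix(FALSE, H, W)
  if (n == 0) return(mask)
  if (n > H * W) stop("requested area exceeds canvas")
  if (n < 30) {
    cy <- ceiling(H / 2); cx <- ceiling(W / 2)
    iy <- rep(seq_len(H), times = W); ix <- rep(seq_len(W), each = H)
    d <- (iy - cy)^2 + (ix - cx)^2
    ord <- order(d, iy, ix)[seq_len(n)]
    mask[cbind(iy[ord], ix[ord])] <- TRUE
    return(mask)
  }
  r3 <- n %% 3
  w0 <- c(3L, 4L, 5L)[r3 + 1L]
  baseA <- if (r3 == 0) 0L else 4L * w0
  m <- n - baseA                      # multiple of 3 by construction
  cx <- floor(W / 2) - 1L             # stem columns cx..cx+2
  yBase <- H - 5L                     # stem bottom row
  maxStem <- yBase - 4L
  h <- min(m %/% 3L, maxStem)
  if (h < 3) { h <- 3L }              # m >= 9 guarantees this fits
  rem <- m - 3L * h
  # stem
  mask[(yBase - h + 1L):yBase, cx:(cx + 2L)] <- TRUE
  # base piece below the stem
  if (baseA > 0)
    mask[(yBase + 1L):(yBase + 4L), cx:(cx + w0 - 1L)] <- TRUE
  # leaves: 3-row bands every 4 rows, alternating sides
  if (rem > 0) {
    L <- rem %/% 3L
    maxLeft <- cx - 3L
    maxRight <- W - (cx + 2L) - 2L
    bands <- seq(yBase - h + 1L, yBase - 2L, by = 4L)
    slots <- as.vector(rbind(
      paste0("L", bands), paste0("R", bands)))
    for (s in slots) {
      if (L <= 0) break
      side <- substr(s, 1, 1)
      yb <- as.integer(substr(s, 2, 10))
      maxw <- if (side == "L") maxLeft else maxRight
      if (maxw < 3) next
      w <- min(maxw, L)
      if (L - w > 0 && L - w < 3) w <- L - 3L  # keep the next leaf >= 3 wide
      if (w < 3) next
      if (side == "L") mask[yb:(yb + 2L), (cx - w):(cx - 1L)] <- TRUE
      else mask[yb:(yb + 2L), (cx + 3L):(cx + 2L + w)] <- TRUE
      L <- L - w
    }
    if (L > 0) stop("requested area exceeds renderable capacity of canvas")
  }
  stopifnot(sum(mask) == n)
  mask
}

.paintView <- function(mask, noiseSd) {
  H <- nrow(mask); W <- ncol(mask)
  nFg <- sum(mask)
  nBg <- H * W - nFg
  R <- G <- B <- matrix(0, H, W)
  # background: neutral gray with a slight blue cast (excess green <= 0)
  g <- stats::runif(nBg, 100, 140)
  d <- stats::runif(nBg, 0, 30)
  R[!mask] <- g; G[!mask] <- g; B[!mask] <- g + d
  if (nFg > 0) {
    # foreground: green-dominant jitter; 2G - R - B lies in [160, 240], a
    # compact mode far from the background's [-30, 0] so the excess-green
    # histogram stays cleanly bimodal even under strong channel noise
    # (sigma = 10 per channel perturbs the index by sd ~24.5; the valley
    # margin is ~6.5 sd on either side)
    fg <- stats::runif(nFg, 160, 255)
    G[mask] <- fg
    R[mask] <- fg - 120 + stats::runif(nFg, 0, 40)
    B[mask] <- fg - 120 + stats::runif(nFg, 0, 40)
  }
  img <- array(0, dim = c(H, W, 3))
  img[, , 1] <- R; img[, , 2] <- G; img[, , 3] <- B
  if (noiseSd > 0)
    img <- img + array(stats::rnorm(length(img), 0, noiseSd), dim = dim(img))
  img <- round(pmin(pmax(img, 0), 255))
  img
}

#' Render the three orthogonal views of one plant
#'
#' Produces side-0, side-90 and top RGB images together with ground-truth
#' binary masks. Each side-view mask contains exactly `trueArea` foreground
#' pixels; the top view contains `round(topFraction * trueArea)`. In clean
#' mode (`noiseSd = 0`) every foreground pixel satisfies `2G - R - B > 0`
#' and every background pixel `2G - R - B <= 0`, so excess-green
#' segmentation can recover the mask exactly.
#'
#' @param trueArea requested foreground area of the side views (pixels).
#' @param rp render parameters from [renderParams()].
#' @param seed integer seed controlling stroke layout and colour jitter.
#' @return A list with elements `images` (named list of H x W x 3 arrays
#'   with 8-bit values) and `masks` (named list of logical matrices), names
#'   `side0`, `side90`, `top`.
#' @examples
#' rv <- renderViews(1234, renderParams(width = 128, height = 128), seed = 1)
#' sum(rv$masks$side0)  # exactly 1234
#' @export
renderViews <- function(trueArea, rp = renderParams(), seed = NULL) {
  trueArea <- round(trueArea)
  if (trueArea < 0) stop("'trueArea' must be >= 0")
  if (trueArea > rp$width * rp$height)
    stop("requested area exceeds canvas")
  .withSeed(seed, {
    areas <- c(side0 = trueArea, side90 = trueArea,
               top = round(rp$topFraction * trueArea))
    masks <- lapply(areas, .plantMask, H = rp$height, W = rp$width)
    images <- lapply(masks, .paintView, noiseSd = rp$noiseSd)
    list(images = images, masks = masks)
  })
}
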