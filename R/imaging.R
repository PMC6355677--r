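# Plant-background segmentation of RGB views: excess-green index, Otsu or
# fixed thresholding, morphological opening and small-component removal.
# The greenness index and threshold stand in for the (undisclosed)
# commercial platform pipeline; defaults follow common greenhouse practice.

#' Excess-green index of an RGB image
#'
#' Computes the per-pixel greenness index `2G - R - B` in a signed range.
#' Vegetation is strongly positive, neutral gray is zero, and soil or
#' bluish backgrounds are negative, which makes the index a robust basis
#' for thresholding greenhouse imagery.
#'
#' @param image H x W x 3 numeric array, channels in R,G,B order. Values in
#'   `[0, 1]` are rescaled to 8-bit; values in `[0, 255]` are used as-is.
#' @return Numeric H x W matrix of index values in `[-510, 510]`.
#' @examples
#' px <- array(c(50, 200, 30) / 255, dim = c(1, 1, 3))
#' excessGreen(px)  # 320
#' @export
excessGreen <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("'image' must be an H x W x 3 array")
  img <- image * (if (max(image) <= 1) 255 else 1)
  2 * img[, , 2] - img[, , 1] - img[, , 3]
}

# Histogram threshold on the integer excess-green range [-510, 510]:
# Otsu's between-class variance criterion with neighborhood valley
# emphasis, i.e. weighted by one minus the histogram mass within `window`
# bins of the candidate. The weight steers the optimum into the empty
# valley between modes when the foreground class is small and noise has
# broadened the background mode (where the classic criterion drifts into
# the majority mode); on a cleanly bimodal histogram the valley has zero
# mass and the choice coincides with classic Otsu.
.otsuThreshold <- function(exg, window = 25L) {
  v <- pmin(pmax(round(exg), -510), 510)
  p <- tabulate(v + 511L, nbins = 1021L)
  p <- p / sum(p)
  vals <- -510:510
  omega <- cumsum(p)
  mu <- cumsum(p * vals)
  muT <- mu[1021L]
  sb <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  idx <- seq_len(1021L)
  lo <- pmax(idx - window, 1L)
  hi <- pmin(idx + window, 1021L)
  nbhdMass <- omega[hi] - c(0, omega)[lo]
  vals[which.max((1 - nbhdMass) * sb)]
}

#' Segmentation parameters
#'
#' @param threshold "otsu" (adaptive: Otsu's criterion with neighborhood
#'   valley emphasis on the excess-green histogram) or "fixed".
#' @param fixedThreshold threshold in excess-green units used when
#'   `threshold = "fixed"`; pixels strictly above it are foreground.
#' @param minComponentPx connected components smaller than this are removed
#'   (fragmented wheat tillers stay above it; sensor specks fall below).
#' @param openingRadius radius of the square structuring element of the
#'   morphological opening (0 disables it).
#' @return A named list of segmentation parameters.
#' @export
segmentationParams <- function(threshold = c("otsu", "fixed"),
                               fixedThreshold = 0, minComponentPx = 25,
                               openingRadius = 1) {
  stopifnot(minComponentPx >= 0, openingRadius >= 0)
  list(threshold = match.arg(threshold),
       fixedThreshold = fixedThreshold,
       minComponentPx = as.integer(minComponentPx),
       openingRadius = as.integer(openingRadius))
}

#' Segment the plant in one RGB view
#'
#' Thresholds the excess-green index, applies a morphological opening and
#' removes connected components below the minimum size, returning the
#' foreground mask and pixel count. All-background and all-foreground
#' results are valid; an image whose index map is constant yields an empty
#' mask (there is no information to split on).
#'
#' @param image H x W x 3 numeric RGB array (see [excessGreen()]).
#' @param params segmentation parameters from [segmentationParams()].
#' @return A [SegmentationResult-class].
#' @examples
#' rv <- renderViews(1234, renderParams(width = 128, height = 128), seed = 1)
#' segmentView(rv$images$side0)@pixelCount  # 1234
#' @export
segmentView <- function(image, params = segmentationParams()) {
  exg <- excessGreen(image)
  if (!length(exg)) stop("empty image")
  rng <- range(exg)
  if (params$threshold == "fixed") {
    th <- params$fixedThreshold
  } else if (rng[1] == rng[2]) {
    th <- rng[2]  # constant index map: empty mask by convention
  } else {
    th <- .otsuThreshold(exg)
  }
  mask <- exg > th
  if (params$openingRadius > 0 && any(mask)) {
    k <- EBImage::makeBrush(2L * params$openingRadius + 1L, shape = "box")
    mask <- EBImage::opening(mask * 1, k) > 0
  }
  nKept <- 0L
  if (any(mask)) {
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab)
    keep <- which(sizes >= params$minComponentPx)
    nKept <- length(keep)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  new("SegmentationResult", mask = mask, pixelCount = as.integer(sum(mask)),
      thresholdUsed = as.numeric(th), nComponentsKept = nKept)
}

#' Read an RGB view image from PNG or TIFF
#'
#' @param path file path; format chosen by extension.
#' @return H x W x 3 numeric array with 8-bit values.
#' @export
readViewImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF images")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  img * 255
}

#' Segment a directory of rendered views into a pixel-count table
#'
#' Reads the `images.csv` manifest of an image directory (as written by
#' [generateExperiment()]), segments every listed view and assembles one
#' row of side-0, side-90 and top-view counts per (plant, day). Keys with a
#' missing view (absent file) are skipped with a warning naming the gap.
#'
#' @param imageDir directory containing view images and `images.csv`
#'   (columns plant_id, day, view, file).
#' @param params segmentation parameters from [segmentationParams()].
#' @return data.frame with columns plant_id, day, s0, s90, top, threshold.
#' @export
countSeries <- function(imageDir, params = segmentationParams()) {
  manifestPath <- file.path(imageDir, "images.csv")
  if (!file.exists(manifestPath))
    stop("no images.csv manifest under ", imageDir)
  man <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  key3 <- paste(man$plant_id, man$day, man$view)
  if (anyDuplicated(key3))
    stop("duplicate (plant, day, view) entries in manifest: ",
         paste(unique(key3[duplicated(key3)]), collapse = "; "))
  man$path <- file.path(imageDir, man$file)
  man$ok <- file.exists(man$path)

  keys <- unique(man[, c("plant_id", "day")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- man[man$plant_id == keys$plant_id[i] & man$day == keys$day[i], ]
    views <- c("side0", "side90", "top")
    present <- views %in% sel$view[sel$ok]
    if (!all(present)) {
      warning(sprintf("plant %s day %s: missing view(s) %s; row skipped",
                      keys$plant_id[i], keys$day[i],
                      paste(views[!present], collapse = ", ")))
      next
    }
    cnt <- th <- numeric(3)
    for (v in seq_along(views)) {
      sr <- segmentView(
        readViewImage(sel$path[sel$view == views[v]]), params)
      cnt[v] <- sr@pixelCount
      th[v] <- sr@thresholdUsed
    }
    rows[[i]] <- data.frame(plant_id = keys$plant_id[i], day = keys$day[i],
                            s0 = cnt[1], s90 = cnt[2], top = cnt[3],
                            threshold = mean(th))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(plant_id = character(), day = numeric(),
                      s0 = numeric(), s90 = numeric(), top = numeric(),
                      threshold = numeric())
  rownames(out) <- NULL
  out
}
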