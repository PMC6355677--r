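# Gravimetric water budget: interval evapotranspiration from pot-weight
# logs, bare-soil evaporation correction, cumulative transpiration, WUE
# (biovolume gained per gram of water used) and its drought-to-control
# ratio with the green/red heatmap classification.

#' Per-interval evapotranspiration losses from a weight log
#'
#' Consecutive-weighing bookkeeping: the loss attributed to the interval
#' ending at day `i` is the post-irrigation weight of the previous weighing
#' minus the pre-irrigation weight of the current one. Negative losses
#' (scale noise or condensation) are clipped to zero and flagged.
#'
#' @param weights data.frame with columns pot_id, day, weight_pre_g,
#'   weight_post_g (one or more pots).
#' @return data.frame with columns pot_id, day (interval end), loss_g,
#'   clipped.
#' @examples
#' w <- data.frame(pot_id = "p", day = c(0, 2),
#'                 weight_pre_g = c(1200, 1150),
#'                 weight_post_g = c(1200, 1190))
#' intervalLosses(w)$loss_g  # 50
#' @export
intervalLosses <- function(weights) {
  out <- lapply(split(weights, weights$pot_id), function(w) {
    if (nrow(w) < 2)
      stop("pot ", w$pot_id[1], ": need at least two weighings")
    if (is.unsorted(w$day, strictly = TRUE))
      stop("pot ", w$pot_id[1], ": weighing days must be strictly increasing")
    loss <- w$weight_post_g[-nrow(w)] - w$weight_pre_g[-1]
    clipped <- loss < 0
    data.frame(pot_id = w$pot_id[-1], day = w$day[-1],
               loss_g = pmax(loss, 0), clipped = clipped)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean bare-soil evaporation per weighing interval
#'
#' Averages the interval losses of all plant-free pots, giving the
#' evaporation baseline that is subtracted from whole-pot losses to isolate
#' transpiration. With no bare pots (the wheat trial carries none) the
#' baseline is zero everywhere and a warning is raised: whole-pot
#' evapotranspiration is then used as the water term.
#'
#' @param weights full weight log including an `is_bare` column.
#' @param days weighing-day grid used when no bare pots exist.
#' @return data.frame with columns day, evap_g.
#' @export
evaporationBaseline <- function(weights, days = NULL) {
  bare <- weights[weights$is_bare, ]
  if (!nrow(bare)) {
    if (is.null(days)) days <- sort(unique(weights$day))
    warning("no bare pots: evaporation baseline set to zero")
    return(data.frame(day = days[-1], evap_g = 0))
  }
  losses <- intervalLosses(bare)
  grids <- split(losses$day, losses$pot_id)
  if (length(unique(lapply(grids, unname))) > 1)
    stop("bare pots have misaligned weighing days")
  out <- stats::aggregate(loss_g ~ day, data = losses, FUN = mean)
  names(out)[2] <- "evap_g"
  out[order(out$day), ]
}

#' Cumulative transpiration per pot
#'
#' In `subtract_evap` mode the per-interval transpiration is
#' `max(loss - evap, 0)`; in `evapotranspiration` mode the raw whole-pot
#' loss is used (evaporation and transpiration together). Either series is
#' cumulated per pot, giving a non-negative, non-decreasing water-use
#' series.
#'
#' @param losses per-interval losses from [intervalLosses()].
#' @param evap evaporation baseline from [evaporationBaseline()].
#' @param mode "subtract_evap" or "evapotranspiration".
#' @return data.frame with columns pot_id, day, transp_g, cum_transp_g.
#' @export
cumulativeTranspiration <- function(losses, evap,
                                    mode = c("subtract_evap",
                                             "evapotranspiration")) {
  mode <- match.arg(mode)
  m <- merge(losses, evap, by = "day", all.x = TRUE)
  if (anyNA(m$evap_g))
    stop("evaporation baseline does not cover all loss intervals")
  m <- m[order(m$pot_id, m$day), ]
  m$transp_g <- if (mode == "subtract_evap")
    pmax(m$loss_g - m$evap_g, 0) else m$loss_g
  m$cum_transp_g <- stats::ave(m$transp_g, m$pot_id, FUN = cumsum)
  rownames(m) <- NULL
  m[, c("pot_id", "day", "transp_g", "cum_transp_g")]
}

#' Water Use Efficiency over a period
#'
#' `WUE = (DB_tn - DB_t0) / sum(Tr)`: biovolume gained per gram of water
#' transpired between the reference day and the current day. Negative
#' values (biovolume shrinking under late drought) are reported as-is.
#'
#' @param dbT0,dbTn DB at the reference and current day (vectorised).
#' @param cumTranspiration cumulative water use (g) over the period, > 0.
#' @param id optional identifiers used in error messages.
#' @return Numeric WUE vector (pixels per gram).
#' @examples
#' computeWUE(100, 1100, 500)  # 2
#' @export
computeWUE <- function(dbT0, dbTn, cumTranspiration, id = NULL) {
  bad <- cumTranspiration <= 0
  if (any(bad)) {
    who <- if (!is.null(id)) paste(id[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop("zero or negative cumulative transpiration for: ", who)
  }
  (dbTn - dbT0) / cumTranspiration
}

#' Per-cell WUE time series for an experiment
#'
#' Combines plant-level DB records with the pot water budget: per plant,
#' WUE at day `t > t0` is the DB gain since `t0` divided by the cumulative
#' transpiration since `t0`; plant-level values are then averaged per
#' (genotype, treatment, day).
#'
#' @param traits plant-level DB records from [dbSeries()] (`$traits`).
#' @param weights pot weight log (with `is_bare`, pot_id matching plant_id).
#' @param t0 reference day (wheat: the stress-imposition day; tomato: 0 DAT).
#' @param mode water-term mode, see [cumulativeTranspiration()]; default
#'   subtracts the bare-pot baseline when bare pots exist and falls back to
#'   whole-pot evapotranspiration otherwise.
#' @return List with `plants` (plant-level WUE records) and `cells`
#'   (mean WUE per genotype, treatment, day).
#' @export
wueSeries <- function(traits, weights, t0, mode = NULL) {
  hasBare <- any(weights$is_bare)
  if (is.null(mode))
    mode <- if (hasBare) "subtract_evap" else "evapotranspiration"
  losses <- intervalLosses(weights[!weights$is_bare, ])
  evap <- if (hasBare) evaporationBaseline(weights)
          else suppressWarnings(evaporationBaseline(weights))
  ct <- cumulativeTranspiration(losses, evap, mode)
  ct <- ct[ct$day > t0, ]
  # re-zero the cumulative series at t0
  off <- stats::ave(ct$cum_transp_g - ct$transp_g, ct$pot_id,
                    FUN = function(v) v[1])
  ct$cum_transp_g <- ct$cum_transp_g - off

  db0 <- traits[traits$day == t0, c("plant_id", "db")]
  if (!nrow(db0)) stop("no DB records at reference day t0 = ", t0)
  names(db0)[2] <- "db0"
  m <- merge(traits[traits$day > t0, ], db0, by = "plant_id")
  m <- merge(m, ct, by.x = c("plant_id", "day"),
             by.y = c("pot_id", "day"))
  m$wue <- computeWUE(m$db0, m$db, m$cum_transp_g, id = m$plant_id)
  plants <- m[order(m$genotype, m$treatment, m$replicate, m$day),
              c("plant_id", "genotype", "treatment", "replicate", "day",
                "wue")]
  rownames(plants) <- NULL
  cells <- stats::aggregate(wue ~ genotype + treatment + day, data = plants,
                            FUN = mean)
  names(cells)[4] <- "mean_wue"
  cells <- cells[order(cells$genotype, cells$treatment, cells$day), ]
  rownames(cells) <- NULL
  list(plants = plants, cells = cells)
}

#' WUE ratio and heatmap class
#'
#' Ratio of stressed over control WUE. The class boundary is closed on the
#' green side: ratios >= 1 (efficiency maintained under stress) are green,
#' ratios < 1 (efficiency lost) are red. A zero control WUE flags the
#' record as missing rather than erroring.
#'
#' @param wueStress,wueControl WUE values (vectorised).
#' @return data.frame with columns wue_ratio and heat_class.
#' @examples
#' wueRatio(1.32, 1)$heat_class  # "green"
#' wueRatio(0.52, 1)$heat_class  # "red"
#' @export
wueRatio <- function(wueStress, wueControl) {
  ratio <- ifelse(wueControl == 0, NA_real_, wueStress / wueControl)
  data.frame(wue_ratio = ratio, heat_class = heatClass(ratio))
}

#' Heatmap class of a WUE (or DB) ratio
#'
#' @param ratio numeric ratio vector.
#' @return "green" where ratio >= 1, "red" where < 1, NA where missing.
#' @export
heatClass <- function(ratio) {
  ifelse(is.na(ratio), NA_character_, ifelse(ratio >= 1, "green", "red"))
}

#' Per-genotype WUE-ratio table
#'
#' @param cells cell-level WUE from [wueSeries()] (`$cells`).
#' @param control label of the control treatment.
#' @return Long data.frame: genotype, day, wue_ratio, heat_class.
#' @export
wueRatioTable <- function(cells, control = "control") {
  ctl <- cells[cells$treatment == control, ]
  trt <- cells[cells$treatment != control, ]
  if (!nrow(ctl)) stop("control treatment '", control, "' not found")
  m <- merge(trt, ctl[, c("genotype", "day", "mean_wue")],
             by = c("genotype", "day"), suffixes = c("", "_ctl"))
  out <- cbind(m[, c("genotype", "day")],
               wueRatio(m$mean_wue, m$mean_wue_ctl))
  out <- out[order(out$genotype, out$day), ]
  rownames(out) <- NULL
  out
}

#' Export the WUE-ratio heatmap matrices
#'
#' Writes the genotype x day ratio matrix and the matching green/red class
#' matrix as CSV (genotypes as rows in design order, days as columns;
#' missing cells are empty fields). A PNG heatmap is drawn as a convenience
#' when `plotFile` is given and the pheatmap package is available; the CSVs
#' are the contract.
#'
#' @param ratioTab long table from [wueRatioTable()].
#' @param file path of the ratio-matrix CSV.
#' @param classFile optional path of the class-matrix CSV.
#' @param plotFile optional path of a PNG heatmap.
#' @param rowOrder optional genotype row order.
#' @return The ratio matrix data.frame, invisibly.
#' @export
exportHeatmap <- function(ratioTab, file, classFile = NULL, plotFile = NULL,
                          rowOrder = NULL) {
  if (!nrow(ratioTab)) stop("empty WUE-ratio table")
  ratio <- toDayMatrix(ratioTab, "wue_ratio", rowOrder)
  utils::write.csv(ratio, file, row.names = FALSE, na = "")
  if (!is.null(classFile)) {
    cls <- toDayMatrix(ratioTab, "heat_class", rowOrder)
    utils::write.csv(cls, classFile, row.names = FALSE, na = "")
  }
  if (!is.null(plotFile) && requireNamespace("pheatmap", quietly = TRUE)) {
    m <- as.matrix(ratio[, -1])
    rownames(m) <- ratio$genotype
    grDevices::png(plotFile, width = 900, height = 600)
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE)
    grDevices::dev.off()
  }
  invisible(ratio)
}
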