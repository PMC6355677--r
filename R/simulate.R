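# Seeded simulation of pot-phenotyping experiments: logistic growth under a
# piecewise stress factor, gravimetric water budgets, and factorial bundles.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.logistic <- function(t, K, r, tMid) K / (1 + exp(-r * (t - tMid)))

# Mean growth trajectory. Before the stress-onset day s the curve is the
# plain logistic; from s on, the logistic ODE dA/dt = r' A (1 - A/K') is
# re-initialised at the onset value A_s with K' = K f, r' = r f, whose closed
# form is K' / (1 + ((K' - A_s)/A_s) exp(-r'(t - s))). The branch is
# continuous at s and, when A_s > K f, declines toward the reduced carrying
# capacity — the drought-decline pattern. f = 1 reduces analytically to the
# unstressed curve.
.growthMean <- function(K, r, tMid, f, s, t) {
  pre <- .logistic(t, K, r, tMid)
  if (f == 1 || !is.finite(s) || all(t < s)) return(pre)
  As <- .logistic(s, K, r, tMid)
  K2 <- K * f
  r2 <- r * f
  post <- K2 / (1 + ((K2 - As) / As) * exp(-r2 * (t - s)))
  ifelse(t < s, pre, post)
}

.lognormNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog) - sdlog^2 / 2) # mean-one multiplicative noise
}

#' Simulate one plant's projected-area growth trajectory
#'
#' Evaluates the piecewise logistic growth model of [GrowthParams-class] at
#' the requested days and applies mean-one multiplicative lognormal noise
#' with the configured coefficient of variation. The stressed branch restarts
#' the logistic dynamics at the stress-onset value under the reduced carrying
#' capacity `K * treatmentFactor` and rate `r * treatmentFactor`, so the
#' series is continuous at the changeover and declines when the plant had
#' outgrown the stressed capacity.
#'
#' @param params a [GrowthParams-class] object.
#' @param days strictly increasing numeric vector of day indices.
#' @param seed integer seed; identical seeds give identical series.
#' @return Numeric vector of realised projected areas (pixels), named by day.
#' @examples
#' gp <- GrowthParams(K = 1e5, r = 0.15, tMid = 70,
#'                    treatmentFactor = 0.7, stressStartDay = 104)
#' a <- simulateGrowth(gp, seq(55, 147, 2), seed = 1)
#' @export
simulateGrowth <- function(params, days, seed = NULL) {
  stopifnot(is(params, "GrowthParams"))
  validObject(params)
  if (!length(days)) stop("'days' must be non-empty")
  if (any(diff(days) <= 0)) stop("'days' must be strictly increasing")
  mu <- .growthMean(params@K, params@r, params@tMid,
                    params@treatmentFactor, params@stressStartDay, days)
  eps <- .withSeed(seed, .lognormNoise(length(days), params@cvNoise))
  stats::setNames(mu * eps, days)
}

#' Simulate a pot-weight series with irrigation events
#'
#' Gravimetric bookkeeping between weighings: over each interval the pot
#' loses `evapRate * dt` grams to soil evaporation plus
#' `transpCoeff * meanArea * dt` grams to transpiration (trapezoidal mean of
#' the projected area at the interval endpoints); at each weighing the pot is
#' re-watered to `targetFraction * fcWeight`. Losses that would push the pot
#' below the dry-soil floor (`dryFloorFraction * fcWeight`) are truncated
#' proportionally across both components and flagged. True per-interval
#' evaporation and transpiration are stored alongside the recorded weights
#' so recovery can be checked.
#'
#' @param area numeric vector of projected areas aligned to `days`
#'   (use zeros for a bare pot).
#' @param days strictly increasing weighing days.
#' @param wp a [WaterParams-class] object.
#' @param seed integer seed for the weighing noise.
#' @param noiseSd standard deviation (g) of Gaussian noise added to the
#'   recorded pre-irrigation weights; 0 disables it.
#' @return data.frame with columns day, weight_pre_g, weight_post_g,
#'   evap_true_g, transp_true_g, truncated.
#' @export
simulateWaterSeries <- function(area, days, wp, seed = NULL, noiseSd = 0) {
  stopifnot(is(wp, "WaterParams"))
  validObject(wp)
  if (length(area) != length(days))
    stop("'area' and 'days' must be aligned")
  if (any(diff(days) <= 0)) stop("'days' must be strictly increasing")
  n <- length(days)
  target <- wp@targetFraction * wp@fcWeight
  floorW <- wp@dryFloorFraction * wp@fcWeight
  pre <- post <- rep(target, n)
  evap <- transp <- numeric(n)
  trunc <- logical(n)
  noise <- .withSeed(seed, if (noiseSd > 0) stats::rnorm(n, 0, noiseSd)
                           else numeric(n))
  for (i in seq_len(n)[-1]) {
    dt <- days[i] - days[i - 1]
    e <- wp@evapRate * dt
    tr <- wp@transpCoeff * mean(area[c(i - 1, i)]) * dt
    loss <- e + tr
    avail <- max(post[i - 1] - floorW, 0)
    if (loss > avail) {
      sc <- if (loss > 0) avail / loss else 0
      e <- e * sc
      tr <- tr * sc
      loss <- avail
      trunc[i] <- TRUE
    }
    evap[i] <- e
    transp[i] <- tr
    pre[i] <- post[i - 1] - loss + noise[i]
  }
  data.frame(day = days, weight_pre_g = pre, weight_post_g = post,
             evap_true_g = evap, transp_true_g = transp, truncated = trunc)
}

#' Generate a complete synthetic phenotyping experiment
#'
#' Builds a seeded [PhenoExperiment-class] bundle for a factorial design:
#' per-plant realised growth trajectories, the resulting three-view pixel
#' counts, pot-weight logs for plant and bare-soil pots, and ground-truth
#' tables (realised projected area and the proportional fresh weight).
#' Optionally renders and writes per-view PNG images with ground-truth masks.
#'
#' Noise streams are keyed by (genotype, replicate): the control and stressed
#' series of the same replicate share one multiplicative noise draw, making
#' the stressed trajectory the exact counterfactual of its control partner.
#' Treatment contrasts before stress onset are therefore exactly zero while
#' replicate-to-replicate variation is preserved.
#'
#' @param design an [ExperimentDesign-class]. The first treatment is the
#'   control (growth factor 1); later treatments use each genotype's
#'   `treatment_factor`.
#' @param growth data.frame with one row per genotype and columns
#'   genotype, K, r, t_mid, treatment_factor, cv_noise.
#' @param wp a [WaterParams-class], or a named list of them keyed by
#'   treatment (bare pots use the first treatment's parameters).
#' @param seed integer seed; the bundle is fully deterministic given it.
#' @param stressStartDay day stress is imposed (`Inf` for none).
#' @param withImages render PNG images and masks under `outDir`.
#' @param outDir output directory for manifests and images (required when
#'   `withImages = TRUE`).
#' @param rp render parameters from [renderParams()]; its `topFraction` also
#'   fixes the top-view count when no images are rendered.
#' @param weightNoiseSd Gaussian sd (g) on recorded pot weights.
#' @param freshWeightCoeff fresh weight per unit projected area (g/pixel)
#'   linking the digital trait to the destructive-harvest ground truth.
#' @return A [PhenoExperiment-class] bundle.
#' @examples
#' des <- ExperimentDesign(c("g1", "g2"), c("control", "drought"),
#'                         replicates = 3, timepoints = seq(55, 147, 2))
#' gr <- data.frame(genotype = c("g1", "g2"), K = c(14e4, 16e4), r = 0.12,
#'                  t_mid = 70, treatment_factor = c(0.6, 0.9),
#'                  cv_noise = 0.05)
#' pe <- generateExperiment(des, gr, WaterParams(1200, 0.95, 5, 3e-4),
#'                          seed = 1, stressStartDay = 104)
#' @export
generateExperiment <- function(design, growth, wp, seed,
                               stressStartDay = Inf,
                               withImages = FALSE, outDir = NULL,
                               rp = renderParams(), weightNoiseSd = 0,
                               freshWeightCoeff = 2e-4) {
  stopifnot(is(design, "ExperimentDesign"))
  validObject(design)
  if (anyDuplicated(growth$genotype))
    stop("duplicate genotype rows in growth table")
  miss <- setdiff(design@genotypes, growth$genotype)
  if (length(miss))
    stop("growth table misses genotypes: ", paste(miss, collapse = ", "))
  if (withImages && is.null(outDir))
    stop("'outDir' is required when withImages = TRUE")
  if (is(wp, "WaterParams"))
    wp <- stats::setNames(rep(list(wp), length(design@treatments)),
                          design@treatments)
  if (!all(design@treatments %in% names(wp)))
    stop("water parameters missing for some treatments")

  tp <- design@timepoints
  nd <- length(tp)
  wi <- wp[[design@treatments[1]]]@weighInterval
  weighKeep <- ((tp - tp[1]) %% wi) == 0
  weighKeep[1] <- TRUE

  gens <- design@genotypes
  trts <- design@treatments
  reps <- design@replicates
  nPlants <- length(gens) * length(trts) * reps

  res <- .withSeed(seed, {
    # one noise stream per (genotype, replicate), shared across treatments
    eps <- list()
    for (g in gens) {
      cv <- growth$cv_noise[growth$genotype == g]
      for (k in seq_len(reps))
        eps[[paste(g, k)]] <- .lognormNoise(nd, cv)
    }
    waterSeeds <- sample.int(.Machine$integer.max,
                             nPlants + design@nBarePots)
    renderSeeds <- if (withImages)
      sample.int(.Machine$integer.max, nPlants * nd) else integer()
    list(eps = eps, waterSeeds = waterSeeds, renderSeeds = renderSeeds)
  })

  plants <- truth <- counts <- weights <- list()
  ip <- 0L
  for (g in gens) {
    gr <- growth[growth$genotype == g, ]
    for (tr in trts) {
      f <- if (tr == trts[1]) 1 else gr$treatment_factor
      mu <- .growthMean(gr$K, gr$r, gr$t_mid, f, stressStartDay, tp)
      for (k in seq_len(reps)) {
        ip <- ip + 1L
        pid <- paste(g, tr, k, sep = "_")
        area <- mu * res$eps[[paste(g, k)]]
        a0 <- round(area)
        plants[[ip]] <- data.frame(plant_id = pid, pot_id = pid,
                                   genotype = g, treatment = tr,
                                   replicate = k)
        truth[[ip]] <- data.frame(plant_id = pid, day = tp, true_area = area,
                                  fresh_weight_g = freshWeightCoeff * area)
        counts[[ip]] <- data.frame(plant_id = pid, day = tp, s0 = a0,
                                   s90 = a0, top = round(rp$topFraction * a0))
        ws <- simulateWaterSeries(area[weighKeep], tp[weighKeep], wp[[tr]],
                                  seed = res$waterSeeds[ip],
                                  noiseSd = weightNoiseSd)
        weights[[ip]] <- cbind(pot_id = pid, ws, is_bare = FALSE,
                               fc_weight = wp[[tr]]@fcWeight)
      }
    }
  }
  wpBare <- wp[[trts[1]]]
  for (b in seq_len(design@nBarePots)) {
    pid <- paste0("bare_", b)
    ws <- simulateWaterSeries(numeric(sum(weighKeep)), tp[weighKeep], wpBare,
                              seed = res$waterSeeds[nPlants + b],
                              noiseSd = weightNoiseSd)
    weights[[nPlants + b]] <- cbind(pot_id = pid, ws, is_bare = TRUE,
                                    fc_weight = wpBare@fcWeight)
  }

  pe <- new("PhenoExperiment",
    design = design, growth = growth,
    plants = do.call(rbind, plants), truth = do.call(rbind, truth),
    counts = do.call(rbind, counts), weights = do.call(rbind, weights),
    imageDir = "", seed = as.integer(seed)
  )
  rownames(pe@truth) <- rownames(pe@counts) <- rownames(pe@weights) <- NULL

  if (!is.null(outDir)) {
    if (withImages) {
      pe@imageDir <- file.path(outDir, "images")
      .renderBundleImages(pe, outDir, rp, res$renderSeeds)
    }
    writeBundle(pe, outDir)
  }
  validObject(pe)
  pe
}

.renderBundleImages <- function(pe, outDir, rp, renderSeeds) {
  imgDir <- file.path(outDir, "images")
  mskDir <- file.path(outDir, "masks")
  dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(mskDir, recursive = TRUE, showWarnings = FALSE)
  cnt <- pe@counts
  manifest <- vector("list", nrow(cnt) * 3L)
  m <- 0L
  for (i in seq_len(nrow(cnt))) {
    rv <- renderViews(cnt$s0[i], rp, seed = renderSeeds[i])
    for (v in c("side0", "side90", "top")) {
      fn <- sprintf("%s_%s_%s.png", cnt$plant_id[i], cnt$day[i], v)
      png::writePNG(rv$images[[v]] / 255, file.path(imgDir, fn))
      png::writePNG(rv$masks[[v]] * 1, file.path(mskDir, fn))
      m <- m + 1L
      manifest[[m]] <- data.frame(plant_id = cnt$plant_id[i],
                                  day = cnt$day[i], view = v, file = fn)
    }
  }
  utils::write.csv(do.call(rbind, manifest),
                   file.path(imgDir, "images.csv"), row.names = FALSE)
  invisible(NULL)
}

#' Write a bundle's manifest CSVs
#'
#' Writes plants.csv, counts.csv, weights.csv and truth.csv under `dir`.
#'
#' @param pe a [PhenoExperiment-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(pe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(pe@plants, file.path(dir, "plants.csv"), row.names = FALSE)
  utils::write.csv(pe@counts, file.path(dir, "counts.csv"), row.names = FALSE)
  utils::write.csv(pe@weights, file.path(dir, "weights.csv"),
                   row.names = FALSE)
  utils::write.csv(pe@truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
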