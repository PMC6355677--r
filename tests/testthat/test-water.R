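# Water-budget reconstruction: losses, evaporation baseline, cumulative
# transpiration, WUE and its ratio/classification.

test_that("interval losses difference consecutive weighings", {
  w <- data.frame(pot_id = "p", day = c(0, 2, 4),
                  weight_pre_g = c(1200, 1150, 1190),
                  weight_post_g = c(1200, 1190, 1190))
  l <- intervalLosses(w)
  expect_equal(l$loss_g, c(50, 0))
  expect_false(any(l$clipped))
  # negative loss (scale noise) clips to zero with a flag
  w2 <- transform(w, weight_pre_g = c(1200, 1250, 1190))
  l2 <- intervalLosses(w2)
  expect_equal(l2$loss_g[1], 0)
  expect_true(l2$clipped[1])
  expect_error(intervalLosses(transform(w, day = c(0, 4, 2))),
               "strictly increasing")
  expect_error(intervalLosses(w[1, ]), "two weighings")
})

test_that("evaporation baseline averages bare pots", {
  days <- c(0, 2, 4)
  mk <- function(id, losses) data.frame(
    pot_id = id, day = days,
    weight_pre_g = c(1260, 1260 - losses[1], 1260 - losses[2]),
    weight_post_g = 1260, is_bare = TRUE)
  w <- rbind(mk("b1", c(8, 8)), mk("b2", c(8, 8)), mk("b3", c(8, 8)))
  ev <- evaporationBaseline(w)
  expect_equal(ev$evap_g, c(8, 8))
  # heterogeneous pots: arithmetic mean against a hand computation
  w2 <- rbind(mk("b1", c(6, 10)), mk("b2", c(12, 2)))
  ev2 <- evaporationBaseline(w2)
  expect_equal(ev2$evap_g, c((6 + 12) / 2, (10 + 2) / 2))
  # no bare pots: zeros with a warning
  wplant <- transform(mk("p1", c(5, 5)), is_bare = FALSE)
  expect_warning(ev3 <- evaporationBaseline(wplant), "no bare pots")
  expect_equal(ev3$evap_g, c(0, 0))
  # misaligned bare-pot days abort
  w3 <- rbind(mk("b1", c(8, 8)),
              transform(mk("b2", c(8, 8)), day = c(0, 3, 4)))
  expect_error(evaporationBaseline(w3), "misaligned")
})

test_that("cumulative transpiration follows the selected mode", {
  losses <- data.frame(pot_id = "p", day = c(2, 4), loss_g = c(50, 60),
                       clipped = FALSE)
  evap <- data.frame(day = c(2, 4), evap_g = c(10, 10))
  ct <- cumulativeTranspiration(losses, evap, "subtract_evap")
  expect_equal(ct$cum_transp_g, c(40, 90))
  ct2 <- cumulativeTranspiration(losses, evap, "evapotranspiration")
  expect_equal(ct2$cum_transp_g, c(50, 110))
  # evaporation exceeding losses clips to zero transpiration
  evapBig <- data.frame(day = c(2, 4), evap_g = c(100, 100))
  ct3 <- cumulativeTranspiration(losses, evapBig, "subtract_evap")
  expect_equal(ct3$cum_transp_g, c(0, 0))
  expect_error(cumulativeTranspiration(losses, evap[1, ], "subtract_evap"),
               "cover")
})

test_that("cumulative transpiration is non-negative and non-decreasing", {
  pe <- presetExperiment("tomato_rwm", seed = 4, weightNoiseSd = 1)
  w <- weightTable(pe)
  ct <- cumulativeTranspiration(intervalLosses(w[!w$is_bare, ]),
                                evaporationBaseline(w), "subtract_evap")
  for (s in split(ct$cum_transp_g, ct$pot_id)) {
    expect_true(all(s >= 0))
    expect_true(all(diff(s) >= 0))
  }
})

test_that("noise-free losses reproduce the generator ground truth", {
  pe <- presetExperiment("tomato_rwm", seed = 9)
  w <- weightTable(pe)
  losses <- intervalLosses(w)
  truth <- w[w$day > 0, ]
  m <- merge(losses, truth, by = c("pot_id", "day"))
  expect_equal(m$loss_g, m$evap_true_g + m$transp_true_g,
               tolerance = 1e-12)
  # subtract_evap mode recovers per-pot true transpiration
  ct <- cumulativeTranspiration(intervalLosses(w[!w$is_bare, ]),
                                evaporationBaseline(w), "subtract_evap")
  m2 <- merge(ct, truth, by = c("pot_id", "day"))
  m2 <- m2[order(m2$pot_id, m2$day), ]
  byPot <- split(m2, m2$pot_id)
  for (p in byPot)
    expect_equal(p$cum_transp_g, cumsum(p$transp_true_g), tolerance = 1e-9)
})

test_that("WUE is biovolume gain per gram of water", {
  expect_equal(computeWUE(100, 1100, 500), 2)
  expect_equal(computeWUE(500, 500, 123), 0)
  expect_equal(computeWUE(1100, 100, 500), -2)  # shrinkage reported as-is
  expect_error(computeWUE(1, 2, 0, id = "potX"), "potX")
})

test_that("wueSeries matches the closed-form area-per-water ratio", {
  # one unstressed plant, no noise: WUE(t) = (DB_t - DB_t0) / sum Tr
  des <- tinyDesign(genotypes = "gA", treatments = "control",
                    replicates = 1L, timepoints = seq(0, 20, 2))
  gr <- data.frame(genotype = "gA", K = 5e4, r = 0.3, t_mid = 10,
                   treatment_factor = 1, cv_noise = 0)
  wp <- WaterParams(1800, 0.7, evapRate = 0, transpCoeff = 5e-4)
  pe <- generateExperiment(des, gr, wp, seed = 1)
  ds <- dbSeries(countTable(pe), plantTable(pe))
  ws <- suppressWarnings(
    wueSeries(ds$traits, weightTable(pe), t0 = 0,
              mode = "subtract_evap"))
  w <- weightTable(pe)
  tr <- ds$traits
  for (d in c(10, 20)) {
    expected <- (tr$db[tr$day == d] - tr$db[tr$day == 0]) /
      sum(w$transp_true_g[w$day <= d])
    expect_equal(ws$plants$wue[ws$plants$day == d], expected,
                 tolerance = 1e-9)
  }
})

test_that("WUE ratio classifies the published heatmap boundaries", {
  expect_equal(wueRatio(2, 2)$wue_ratio, 1)
  expect_identical(wueRatio(2, 2)$heat_class, "green")
  expect_identical(wueRatio(1.32, 1)$heat_class, "green")
  expect_identical(wueRatio(0.52, 1)$heat_class, "red")
  z <- wueRatio(1, 0)
  expect_true(is.na(z$wue_ratio))
  expect_true(is.na(z$heat_class))
})

test_that("an arm ratioed against itself is exactly 1 at all time points", {
  pe <- tinyBundle(seed = 6, cv_noise = 0.05)
  ds <- dbSeries(countTable(pe), plantTable(pe))
  ws <- suppressWarnings(wueSeries(ds$traits, weightTable(pe), t0 = 55))
  cells <- ws$cells
  self <- wueRatio(cells$mean_wue, cells$mean_wue)
  expect_true(all(self$wue_ratio == 1))
  expect_true(all(self$heat_class == "green"))
})

test_that("a stronger stress factor lowers the end-of-run WUE ratio", {
  pe <- tinyBundle(seed = 8, cv_noise = 0)   # factors 0.6 (gA) and 0.9 (gB)
  ds <- dbSeries(countTable(pe), plantTable(pe))
  ws <- suppressWarnings(wueSeries(ds$traits, weightTable(pe), t0 = 55))
  wrt <- wueRatioTable(ws$cells, control = "control")
  endDay <- max(wrt$day)
  rA <- wrt$wue_ratio[wrt$genotype == "gA" & wrt$day == endDay]
  rB <- wrt$wue_ratio[wrt$genotype == "gB" & wrt$day == endDay]
  expect_lt(rA, rB)
  expect_lt(rA, 1)
})

test_that("exportHeatmap writes genotype-by-day matrices with gaps empty", {
  tab <- expand.grid(genotype = c("g1", "g2", "g3"), day = c(1, 2, 3, 4))
  tab$wue_ratio <- runif(nrow(tab), 0.5, 1.3)
  tab$heat_class <- heatClass(tab$wue_ratio)
  tab <- tab[-5, ]  # knock out one cell
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ratio.csv")
  cf <- file.path(dir, "class.csv")
  m <- exportHeatmap(tab, f, classFile = cf, rowOrder = c("g3", "g2", "g1"))
  expect_identical(dim(m), c(3L, 5L))
  re <- read.csv(f)
  expect_identical(re$genotype, c("g3", "g2", "g1"))
  expect_true(is.na(re$day_2[re$genotype == "g2"]))  # missing, not zero
  # cells equal the ratio table keyed identically
  for (i in sample(nrow(tab), 5)) {
    expect_equal(re[re$genotype == tab$genotype[i],
                    paste0("day_", tab$day[i])],
                 tab$wue_ratio[i], tolerance = 1e-12)
  }
  expect_error(exportHeatmap(tab[0, ], f), "empty")
})
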