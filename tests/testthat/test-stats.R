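# ANOVA decompositions, Duncan's range test and linear fits against
# independent oracles.

# Brute-force two-way sums of squares from cell/marginal means.
bruteTwoWay <- function(y, g, t) {
  g <- factor(g); t <- factor(t)
  n <- table(g, t)[1, 1]
  gm <- mean(y)
  tm <- tapply(y, t, mean)
  gmn <- tapply(y, g, mean)
  cm <- tapply(y, list(g, t), mean)
  ssT <- n * nlevels(g) * sum((tm - gm)^2)
  ssG <- n * nlevels(t) * sum((gmn - gm)^2)
  ssGT <- n * sum((cm - outer(gmn, rep(1, nlevels(t))) -
                   outer(rep(1, nlevels(g)), tm) + gm)^2)
  ssE <- sum((y - cm[cbind(g, t)])^2)
  c(treatment = ssT, genotype = ssG, interaction = ssGT, residual = ssE)
}

test_that("the 2x2x2 worked table decomposes to F = (9, 4, 1)", {
  d <- data.frame(g = rep(c("G1", "G1", "G2", "G2"), each = 2),
                  t = rep(c("C", "D", "C", "D"), each = 2),
                  y = c(10, 12, 6, 8, 11, 13, 9, 11))
  a <- anovaTwoWay(d$y, d$g, d$t)
  expect_equal(a$f[a$effect == "treatment"], 9)
  expect_equal(a$f[a$effect == "genotype"], 4)
  expect_equal(a$f[a$effect == "interaction"], 1)
  expect_equal(a$sumsq, c(18, 8, 2, 8))
})

test_that("equal cell means give near-zero F and p near one", {
  d <- expand.grid(rep = 1:2, g = c("G1", "G2"), t = c("C", "D"))
  d$y <- 10 + c(-1, 1)[d$rep]           # same mean, within-cell variance > 0
  a <- anovaTwoWay(d$y, d$g, d$t)
  expect_true(all(a$f[1:3] < 1e-20))
  expect_true(all(a$p[1:3] > 0.999))
})

test_that("two-way SS matches brute-force recomputation on random tables", {
  set.seed(12)
  for (i in 1:30) {
    ng <- sample(2:5, 1); nt <- sample(2:3, 1); n <- sample(2:4, 1)
    d <- expand.grid(rep = seq_len(n), g = paste0("g", seq_len(ng)),
                     t = paste0("t", seq_len(nt)))
    d$y <- rnorm(nrow(d), mean = 10 * as.integer(d$g))
    a <- anovaTwoWay(d$y, d$g, d$t)
    ss <- bruteTwoWay(d$y, d$g, d$t)
    expect_equal(a$sumsq, unname(ss[a$effect]), tolerance = 1e-8)
    # effect + residual SS sum to the total
    expect_equal(sum(a$sumsq), sum((d$y - mean(d$y))^2), tolerance = 1e-8)
  }
})

test_that("unbalanced or singleton layouts are rejected with cell names", {
  d <- expand.grid(rep = 1:2, g = c("G1", "G2"), t = c("C", "D"))
  d$y <- rnorm(8)
  expect_error(anovaTwoWay(d$y[-1], d$g[-1], d$t[-1]), "G1:C")
  d1 <- d[c(1, 3, 5, 7), ]
  expect_error(anovaTwoWay(d1$y, d1$g, d1$t), "balanced")
})

test_that("F is invariant to shifting and scaling the response", {
  set.seed(5)
  d <- expand.grid(rep = 1:3, g = c("a", "b", "c"), t = c("C", "D"))
  d$y <- rnorm(nrow(d), mean = (d$t == "D") * 2)
  f0 <- anovaTwoWay(d$y, d$g, d$t)$f
  f1 <- anovaTwoWay(d$y + 100, d$g, d$t)$f
  f2 <- anovaTwoWay(d$y * 7, d$g, d$t)$f
  expect_equal(f0, f1, tolerance = 1e-9)
  expect_equal(f0, f2, tolerance = 1e-9)
})

test_that("one-way ANOVA matches the hand decomposition and t-squared", {
  # {1,2,3} vs {4,5,6}: between SS 13.5 on 1 df, within SS 4 on 4 df
  a <- anovaOneWay(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(a$meansq[1], 13.5)
  expect_equal(a$meansq[2], 1)
  expect_equal(a$f[1], 13.5)
  # identical groups: F = 0
  a0 <- anovaOneWay(rep(c(1, 2), 2), rep(c("a", "b"), each = 2))
  expect_equal(a0$f[1], 0)
  # two-group F equals the pooled-variance t statistic squared
  set.seed(8)
  y <- rnorm(20); g <- rep(c("a", "b"), each = 10)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(anovaOneWay(y, g)$f[1], unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_error(anovaOneWay(1:3, c("a", "a", "b")), "fewer than 2")
  expect_error(anovaOneWay(1:3, rep("a", 3)), "two groups")
})

test_that("Duncan's test letters separate according to critical ranges", {
  set.seed(3)
  mk <- function(means, sd, n) {
    y <- unlist(lapply(means, function(m) m + sd * scale(rnorm(n))))
    list(y = as.numeric(y), g = rep(paste0("g", seq_along(means)), each = n))
  }
  # identical means: one letter
  d0 <- list(y = rep(c(5, 6, 7), 3), g = rep(c("a", "b", "c"), each = 3))
  m0 <- duncanMRT(d0$y, d0$g)
  expect_true(all(m0$letters == "a"))
  # huge separation: distinct letters in mean order
  d1 <- mk(c(1000, 10), 0.1, 5)
  m1 <- duncanMRT(d1$y, d1$g)
  expect_identical(m1$letters, c("a", "b"))
  expect_identical(m1$group, c("g1", "g2"))
})

test_that("Duncan letters agree with a from-scratch range computation", {
  # exact group means 20, 19.8, 10 with within-group sd 0.5, n = 5
  set.seed(14)
  base <- as.numeric(scale(rnorm(5))) * 0.5
  y <- c(base + 20, base + 19.8, base + 10)
  g <- rep(c("A", "B", "C"), each = 5)
  m <- duncanMRT(y, g, alpha = 0.05)
  # oracle: protection level 1-(1-a)^(p-1) quantiles of the studentized range
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / 12
  se <- sqrt(mse / 5)
  r2 <- qtukey(0.95, 2, 12) * se
  r3 <- qtukey(0.95^2, 3, 12) * se
  expect_lt(20 - 19.8, r2)        # A, B not separated
  expect_gt(20 - 10, r3)          # A, C separated
  expect_gt(19.8 - 10, r2)        # B, C separated
  expect_identical(m$letters, c("a", "a", "b"))
  expect_equal(attr(m, "mse"), mse, tolerance = 1e-12)
})

test_that("Duncan letters are transitive-consistent on random layouts", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(3:7, 1)
    y <- rnorm(k * 4, mean = rep(runif(k, 0, 3), each = 4))
    m <- duncanMRT(y, rep(paste0("g", 1:k), each = 4))
    for (l in unique(unlist(strsplit(m$letters, "")))) {
      has <- grepl(l, m$letters)
      expect_true(all(diff(which(has)) == 1))  # contiguous block of means
    }
  }
})

test_that("unequal group sizes fall back to the harmonic mean with a flag", {
  y <- c(rnorm(4, 0), rnorm(6, 10))
  g <- rep(c("a", "b"), c(4, 6))
  expect_warning(m <- duncanMRT(y, g), "harmonic")
  expect_true(attr(m, "harmonic_n_used"))
})

test_that("linear fits reproduce closed-form correlation values", {
  f <- suppressWarnings(linearFit(1:10, 2 * (1:10)))  # exact fit
  expect_equal(f$slope, 2)
  expect_equal(f$r2, 1)
  f2 <- linearFit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(f2$r2, 27 / 28, tolerance = 1e-12)
  # joint permutation invariance
  set.seed(2)
  x <- rnorm(15); y <- 2 * x + rnorm(15)
  p <- sample(15)
  expect_equal(linearFit(x, y), linearFit(x[p], y[p]), tolerance = 1e-12)
  expect_error(linearFit(rep(1, 5), rnorm(5)), "constant")
  fc <- linearFit(1:5, rep(3, 5))
  expect_equal(fc$r2, 0)
  expect_equal(fc$p, 1)
})

test_that("day-wise treatment F is flat before stress and large after", {
  nSig <- 0; nNull <- 0; runs <- 10
  for (s in seq_len(runs)) {
    pe <- generateExperiment(
      wheatDesign(4), wheatGrowthTable(4), wheatWaterParams(),
      seed = 1000 + s, stressStartDay = 104)
    ds <- dbSeries(countTable(pe), plantTable(pe))
    sub <- ds$traits[ds$traits$day %in% c(55, 75, 103, 147), ]
    rep_ <- anovaByDay(sub)
    pre <- rep_$p_treatment[rep_$day < 104]
    nNull <- nNull + all(pre > 0.05)
    nSig <- nSig + (rep_$p_treatment[rep_$day == 147] < 0.001)
  }
  expect_identical(nNull, runs)
  expect_identical(nSig, runs)
})
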