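# Statistical layer: per-day two-way genotype-by-treatment ANOVA, one-way
# ANOVA feeding Duncan's new multiple range test, and ordinary linear
# correlation. Model fitting goes through base aov()/lm(); Duncan's range
# test is implemented here from studentized-range quantiles.

.anovaTable <- function(fit, effects) {
  s <- summary(fit)[[1]]
  rn <- trimws(rownames(s))
  out <- data.frame(
    effect = c(effects, "residual"),
    df = s$Df,
    sumsq = s$`Sum Sq`,
    meansq = s$`Mean Sq`,
    f = s$`F value`,
    p = s$`Pr(>F)`
  )
  rownames(out) <- NULL
  stopifnot(length(rn) == nrow(out))
  out
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Decomposes a balanced genotype x treatment layout into treatment,
#' genotype and interaction effects tested against the residual mean
#' square. Only balanced designs with at least two replicates per cell are
#' accepted: the published designs are balanced and this sidesteps the
#' sums-of-squares-type ambiguity of unbalanced factorials.
#'
#' @param values numeric response (e.g. DB at one day).
#' @param genotype,treatment factors (or coercible) of the same length.
#' @return data.frame with one row per effect (`treatment`, `genotype`,
#'   `interaction`, `residual`) and columns df, sumsq, meansq, f, p.
#' @examples
#' d <- expand.grid(rep = 1:2, g = c("G1", "G2"), t = c("C", "D"))
#' y <- c(10, 12, 11, 13, 6, 8, 9, 11)
#' anovaTwoWay(y, d$g, d$t)
#' @export
anovaTwoWay <- function(values, genotype, treatment) {
  genotype <- factor(genotype)
  treatment <- factor(treatment)
  stopifnot(length(values) == length(genotype),
            length(values) == length(treatment))
  cellN <- table(genotype, treatment)
  if (any(cellN < 2) || length(unique(as.vector(cellN))) != 1) {
    bad <- which(cellN < 2 | cellN != max(cellN), arr.ind = TRUE)
    lab <- apply(bad, 1, function(i)
      paste0(rownames(cellN)[i[1]], ":", colnames(cellN)[i[2]],
             " (n=", cellN[i[1], i[2]], ")"))
    stop("design must be balanced with >= 2 replicates per cell; ",
         "offending cells: ", paste(utils::head(lab, 6), collapse = ", "))
  }
  fit <- stats::aov(values ~ treatment * genotype)
  .anovaTable(fit, c("treatment", "genotype", "interaction"))
}

#' One-way ANOVA
#'
#' @param values numeric response.
#' @param group group labels; at least two groups of at least two
#'   observations each.
#' @return data.frame with rows `group` and `residual` and columns df,
#'   sumsq, meansq, f, p.
#' @export
anovaOneWay <- function(values, group) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  n <- table(group)
  if (length(n) < 2) stop("need at least two groups")
  if (any(n < 2))
    stop("groups with fewer than 2 observations: ",
         paste(names(n)[n < 2], collapse = ", "))
  fit <- stats::aov(values ~ group)
  .anovaTable(fit, "group")
}

# Studentized-range quantile. qtukey's own inversion can fail to converge
# for many means at the low protection levels Duncan's test uses; fall back
# to bisecting the (monotone, reliable) ptukey distribution function.
.qrange <- function(pr, nMeans, df) {
  q <- suppressWarnings(stats::qtukey(pr, nMeans, df))
  if (is.finite(q)) return(q)
  stats::uniroot(function(x) stats::ptukey(x, nMeans, df) - pr,
                 c(1e-8, 500), tol = 1e-6)$root
}

#' Duncan's new multiple range test
#'
#' Ranks group means after a one-way ANOVA and assigns compact letter
#' codes. Means are sorted in decreasing order; the least significant range
#' for a span of p means is `q * sqrt(MSE / n)` where `q` is the
#' studentized-range quantile at Duncan's protection level
#' `1 - (1 - alpha)^(p - 1)`, and letters are assigned by the standard
#' underlining procedure (maximal non-significant stretches share a
#' letter). Unequal group sizes are handled through the harmonic mean n and
#' flagged.
#'
#' @param values numeric response.
#' @param group group labels.
#' @param alpha per-comparison significance level (default 0.05).
#' @return data.frame with columns group, mean, n, letters, sorted by
#'   decreasing mean, with attributes `mse`, `df`, `alpha`,
#'   `harmonic_n_used`.
#' @examples
#' v <- c(rnorm(5, 20, 0.5), rnorm(5, 19.8, 0.5), rnorm(5, 10, 0.5))
#' duncanMRT(v, rep(c("a", "b", "c"), each = 5))
#' @export
duncanMRT <- function(values, group, alpha = 0.05) {
  aov1 <- anovaOneWay(values, group)
  mse <- aov1$meansq[aov1$effect == "residual"]
  dfe <- aov1$df[aov1$effect == "residual"]
  if (dfe < 1) stop("residual degrees of freedom < 1")
  group <- factor(group)
  means <- tapply(values, group, mean)
  ns <- tapply(values, group, length)
  unequal <- length(unique(ns)) > 1
  nh <- if (unequal) length(ns) / sum(1 / ns) else ns[1]
  if (unequal)
    warning("unequal group sizes: harmonic mean n = ", signif(nh, 4),
            " used for critical ranges")
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  se <- sqrt(mse / nh)
  # critical range for a span of p means
  crit <- vapply(seq_len(k), function(p) {
    if (p < 2) return(0)
    .qrange((1 - alpha)^(p - 1), p, dfe) * se
  }, numeric(1))

  # reach(i): furthest mean still inside a non-significant stretch with i
  reach <- integer(k)
  for (i in seq_len(k)) {
    reach[i] <- i
    for (j in seq(i, k)) {
      if (m[i] - m[j] <= crit[j - i + 1]) reach[i] <- j
    }
  }
  # keep only maximal stretches: [i, reach(i)] is contained in an earlier
  # stretch exactly when some j < i reaches at least as far
  keep <- reach > c(-1L, cummax(reach)[-k])
  iv <- cbind(start = seq_len(k)[keep], end = reach[keep])
  letters_ <- rep("", k)
  for (li in seq_len(nrow(iv))) {
    rng <- iv[li, 1]:iv[li, 2]
    letters_[rng] <- paste0(letters_[rng], letters[li])
  }
  out <- data.frame(group = names(m), mean = as.numeric(m),
                    n = as.integer(ns[ord]), letters = letters_)
  rownames(out) <- NULL
  attr(out, "mse") <- mse
  attr(out, "df") <- dfe
  attr(out, "alpha") <- alpha
  attr(out, "harmonic_n_used") <- unequal
  out
}

#' Ordinary least-squares linear fit
#'
#' @param x,y numeric vectors of equal length >= 3; `x` must vary.
#' @return data.frame with columns slope, intercept, r2, p, n. `r2` is the
#'   squared Pearson correlation; `p` is the two-sided slope test. A
#'   constant `y` yields slope 0, r2 = 0, p = 1.
#' @examples
#' linearFit(c(1, 2, 3), c(1, 2, 4))$r2  # 27/28
#' @export
linearFit <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("'x' is constant")
  if (stats::var(y) == 0)
    return(data.frame(slope = 0, intercept = mean(y), r2 = 0, p = 1,
                      n = length(x)))
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  data.frame(slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r2 = s$r.squared,
             p = s$coefficients[2, 4],
             n = length(x))
}

#' Per-day two-way ANOVA report
#'
#' Fits one genotype x treatment ANOVA per imaging day (day-wise models;
#' no repeated-measures structure is assumed) and tabulates F and p per
#' effect alongside the per-treatment DB means.
#'
#' @param traits plant-level DB records from [dbSeries()].
#' @return data.frame with one row per day: mean DB per treatment, then
#'   f/p for treatment, genotype and interaction.
#' @export
anovaByDay <- function(traits) {
  days <- sort(unique(traits$day))
  trts <- sort(unique(traits$treatment))
  rows <- lapply(days, function(d) {
    td <- traits[traits$day == d, ]
    a <- anovaTwoWay(td$db, td$genotype, td$treatment)
    mts <- tapply(td$db, td$treatment, mean)[trts]
    r <- data.frame(day = d)
    for (tr in trts) r[[paste0("mean_db_", tr)]] <- mts[[tr]]
    for (ef in c("treatment", "genotype", "interaction")) {
      r[[paste0("f_", ef)]] <- a$f[a$effect == ef]
      r[[paste0("p_", ef)]] <- a$p[a$effect == ef]
    }
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
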