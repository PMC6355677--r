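# Digital Biovolume: the pixel-based proxy for above-ground plant mass
# combining two side views additively with a logarithmic top-view term,
# plus its treated-to-control ratio time series.

#' Compute the Digital Biovolume
#'
#' `DB = s0 + s90 + log(top / topDivisor)` from the foreground pixel sums of
#' the two side views and the top view. The trait is proportional to the
#' aerial mass of the plant; the log term contributes a few units against
#' side sums in the tens of thousands, so it is numerically negligible but
#' kept for fidelity to the published trait definition. A zero top-view
#' count (e.g. before emergence) either drops the log term
#' (`zeroTopPolicy = "omit_term"`, flagged via the `"omitted"` attribute)
#' or raises an error.
#'
#' @param s0,s90,top non-negative pixel sums (vectorised).
#' @param cfg a [DBConfig-class].
#' @return Numeric vector of DB values, with attribute `omitted` giving the
#'   indices where the log term was dropped.
#' @examples
#' computeDB(100, 200, 3)            # 300: log(3/3) = 0
#' computeDB(50000, 60000, 3000)     # 110000 + log(1000)
#' @export
computeDB <- function(s0, s90, top, cfg = DBConfig()) {
  stopifnot(is(cfg, "DBConfig"))
  if (any(s0 < 0) || any(s90 < 0) || any(top < 0))
    stop("pixel counts must be >= 0")
  n <- max(length(s0), length(s90), length(top))
  s0 <- rep_len(s0, n); s90 <- rep_len(s90, n); top <- rep_len(top, n)
  zero <- top == 0
  if (any(zero) && cfg@zeroTopPolicy == "error")
    stop("top-view count is zero at ", sum(zero), " record(s)")
  lg <- numeric(n)
  lg[!zero] <- log(top[!zero] / cfg@topDivisor, base = cfg@logBase)
  db <- s0 + s90 + lg
  attr(db, "omitted") <- which(zero)
  db
}

#' Plant-level DB records and per-cell summaries
#'
#' Joins a pixel-count table to the plant metadata, computes DB per
#' (plant, day) and aggregates means, standard deviations and replicate
#' counts per (genotype, treatment, day) cell. Missing replicates reduce
#' `n`; nothing is imputed, and a single replicate reports a missing sd.
#'
#' @param counts data.frame with columns plant_id, day, s0, s90, top.
#' @param plants data.frame with columns plant_id, genotype, treatment,
#'   replicate.
#' @param cfg a [DBConfig-class].
#' @return List with `traits` (plant-level records) and `summary`
#'   (cell-level mean_db, sd_db, n).
#' @export
dbSeries <- function(counts, plants, cfg = DBConfig()) {
  unknown <- setdiff(counts$plant_id, plants$plant_id)
  if (length(unknown))
    stop("unknown plant_id in counts: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  traits <- merge(counts, plants[, c("plant_id", "genotype", "treatment",
                                     "replicate")],
                  by = "plant_id", sort = FALSE)
  traits$db <- as.numeric(computeDB(traits$s0, traits$s90, traits$top, cfg))
  traits <- traits[order(traits$genotype, traits$treatment,
                         traits$replicate, traits$day),
                   c("plant_id", "genotype", "treatment", "replicate",
                     "day", "db")]
  rownames(traits) <- NULL
  agg <- function(f) stats::aggregate(
    db ~ genotype + treatment + day, data = traits, FUN = f)
  s <- agg(mean)
  names(s)[names(s) == "db"] <- "mean_db"
  s$sd_db <- agg(function(v) if (length(v) > 1) stats::sd(v) else NA_real_)$db
  s$n <- agg(length)$db
  s <- s[order(s$genotype, s$treatment, s$day), ]
  rownames(s) <- NULL
  list(traits = traits, summary = s)
}

#' Digital Biovolume Ratio of treated over control means
#'
#' @param treatedMean,controlMean cell-mean DB values (vectorised).
#' @return Numeric ratio vector.
#' @examples
#' computeDBR(70, 100)  # 0.7
#' @export
computeDBR <- function(treatedMean, controlMean) {
  if (any(controlMean <= 0))
    stop("control mean DB must be > 0 to form a ratio")
  treatedMean / controlMean
}

#' DBR time-series table
#'
#' Forms the treated-to-control DB ratio per genotype (comparing treatment
#' levels against the control treatment) or per arm (comparing genotypes
#' against a control arm within one treatment), per day.
#'
#' @param summary cell-level summary from [dbSeries()].
#' @param compare "treatment" (wheat-style: each non-control treatment vs
#'   the control treatment, per genotype) or "genotype" (tomato-style: each
#'   arm vs the control arm).
#' @param control label of the control treatment or arm.
#' @return Long data.frame with columns genotype, treatment (or arm), day,
#'   dbr.
#' @export
dbrTable <- function(summary, compare = c("treatment", "genotype"),
                     control) {
  compare <- match.arg(compare)
  if (compare == "treatment") {
    ctl <- summary[summary$treatment == control, ]
    trt <- summary[summary$treatment != control, ]
    if (!nrow(ctl)) stop("control treatment '", control, "' not found")
    m <- merge(trt, ctl[, c("genotype", "day", "mean_db")],
               by = c("genotype", "day"), suffixes = c("", "_ctl"))
    m$dbr <- computeDBR(m$mean_db, m$mean_db_ctl)
    out <- m[order(m$genotype, m$treatment, m$day),
             c("genotype", "treatment", "day", "dbr")]
  } else {
    ctl <- summary[summary$genotype == control, ]
    if (!nrow(ctl)) stop("control arm '", control, "' not found")
    # the control arm is kept (self-ratio exactly 1)
    m <- merge(summary, ctl[, c("treatment", "day", "mean_db")],
               by = c("treatment", "day"), suffixes = c("", "_ctl"))
    m$dbr <- computeDBR(m$mean_db, m$mean_db_ctl)
    out <- m[order(m$genotype, m$day),
             c("genotype", "treatment", "day", "dbr")]
  }
  rownames(out) <- NULL
  out
}

#' Pivot a long (genotype, day, value) table into a genotype x day matrix
#'
#' @param tab long data.frame.
#' @param value name of the value column.
#' @param rowOrder optional genotype ordering (e.g. design order).
#' @return data.frame matrix with genotypes as rows and days as columns;
#'   missing cells are NA.
#' @export
toDayMatrix <- function(tab, value = "dbr", rowOrder = NULL) {
  if (!nrow(tab)) stop("empty table")
  tab$genotype <- as.character(tab$genotype)
  wide <- stats::reshape(
    tab[, c("genotype", "day", value)],
    idvar = "genotype", timevar = "day", direction = "wide")
  names(wide) <- sub(paste0("^", value, "\\."), "day_", names(wide))
  if (!is.null(rowOrder))
    wide <- wide[match(intersect(rowOrder, wide$genotype), wide$genotype), ]
  rownames(wide) <- NULL
  wide
}
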