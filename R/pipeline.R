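# Pipeline orchestration: YAML config, input validation, staged execution
# (segment -> traits -> water -> stats) and deterministic CSV outputs.

.writeCsv <- function(df, path, cfg = NULL) {
  if (!is.null(cfg)) {
    hdr <- sprintf("# phenovol config_hash=%s seed=%s",
                   cfg$config_hash, cfg$seed)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(
      df, path, sep = ",", row.names = FALSE, col.names = TRUE,
      append = TRUE, qmethod = "double", na = ""))
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

.readCsv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

.configHash <- function(cfg) {
  # stable content hash without external digest dependencies
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  raw <- utf8ToInt(s)
  h <- 5381
  for (b in raw) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble a pipeline configuration
#'
#' @param inputDir directory holding plants.csv, counts.csv (or an images/
#'   subdirectory with a manifest), weights.csv and optionally truth.csv.
#' @param outputDir directory the pipeline writes to.
#' @param t0 reference day for WUE (wheat: stress-imposition day).
#' @param controlTreatment label of the control treatment.
#' @param dbConfig a [DBConfig-class].
#' @param segParams segmentation parameters from [segmentationParams()].
#' @param waterMode water-term mode, or NULL for the bare-pot-driven
#'   default (see [wueSeries()]).
#' @param mrtDay day at which the Duncan ranking is computed (default: the
#'   last day).
#' @param mrtOn response ranked by the Duncan test: "db" or "dbr".
#' @param compare DBR comparison axis, see [dbrTable()].
#' @param controlArm control arm label when `compare = "genotype"`.
#' @param seed seed recorded in output headers.
#' @return A named list with class "pipelineConfig".
#' @export
pipelineConfig <- function(inputDir, outputDir, t0,
                           controlTreatment = "control",
                           dbConfig = DBConfig(),
                           segParams = segmentationParams(),
                           waterMode = NULL, mrtDay = NULL, mrtOn = "db",
                           compare = "treatment", controlArm = NULL,
                           seed = 0L) {
  cfg <- list(inputDir = inputDir, outputDir = outputDir, t0 = t0,
              controlTreatment = controlTreatment, dbConfig = dbConfig,
              segParams = segParams, waterMode = waterMode,
              mrtDay = mrtDay, mrtOn = mrtOn, compare = compare,
              controlArm = controlArm, seed = seed)
  cfg$config_hash <- .configHash(cfg[setdiff(names(cfg), "config_hash")])
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching [pipelineConfig()] arguments
#'   (db_config and seg_params as nested mappings).
#' @return A "pipelineConfig" list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  dbc <- do.call(DBConfig, as.list(y$db_config))
  sp <- do.call(segmentationParams, as.list(y$seg_params))
  pipelineConfig(
    inputDir = y$input_dir, outputDir = y$output_dir, t0 = y$t0,
    controlTreatment = if (is.null(y$control_treatment)) "control"
                       else y$control_treatment,
    dbConfig = dbc, segParams = sp,
    waterMode = y$water_mode, mrtDay = y$mrt_day,
    mrtOn = if (is.null(y$mrt_on)) "db" else y$mrt_on,
    compare = if (is.null(y$compare)) "treatment" else y$compare,
    controlArm = y$control_arm,
    seed = if (is.null(y$seed)) 0L else y$seed
  )
}

#' Validate pipeline inputs
#'
#' Report-only checks of the input CSVs: schema presence, key uniqueness,
#' weight sanity (positive, post >= pre on irrigation days), day alignment
#' of the weight log, and view completeness of an image manifest. Inputs
#' are never modified.
#'
#' @param inputDir input directory (see [pipelineConfig()]).
#' @return data.frame QC report with columns severity, file, row, message;
#'   zero rows means no findings.
#' @export
validateInputs <- function(inputDir) {
  findings <- list()
  add <- function(severity, file, row, message)
    findings[[length(findings) + 1]] <<-
      data.frame(severity = severity, file = file, row = row,
                 message = message)

  pf <- file.path(inputDir, "plants.csv")
  if (!file.exists(pf)) {
    add("error", "plants.csv", NA, "file missing")
  } else {
    plants <- .readCsv(pf)
    need <- c("plant_id", "genotype", "treatment", "replicate")
    miss <- setdiff(need, names(plants))
    if (length(miss))
      add("error", "plants.csv", NA,
          paste("missing columns:", paste(miss, collapse = ", ")))
    else if (anyDuplicated(plants$plant_id))
      add("error", "plants.csv",
          paste(which(duplicated(plants$plant_id)), collapse = ","),
          "duplicate plant_id")
  }

  cf <- file.path(inputDir, "counts.csv")
  if (file.exists(cf)) {
    cnt <- .readCsv(cf)
    key <- paste(cnt$plant_id, cnt$day)
    if (anyDuplicated(key))
      add("error", "counts.csv",
          paste(which(duplicated(key)), collapse = ","),
          "duplicate (plant_id, day)")
    for (col in c("s0", "s90", "top"))
      if (col %in% names(cnt) && any(cnt[[col]] < 0))
        add("error", "counts.csv",
            paste(which(cnt[[col]] < 0), collapse = ","),
            paste("negative", col))
  }

  mf <- file.path(inputDir, "images", "images.csv")
  if (file.exists(mf)) {
    man <- .readCsv(mf)
    key3 <- paste(man$plant_id, man$day, man$view)
    if (anyDuplicated(key3))
      add("error", "images/images.csv",
          paste(which(duplicated(key3)), collapse = ","),
          "duplicate (plant_id, day, view)")
    missing <- !file.exists(file.path(inputDir, "images", man$file))
    if (any(missing))
      add("warning", "images/images.csv",
          paste(which(missing), collapse = ","),
          paste("missing image files:",
                paste(utils::head(man$file[missing], 5), collapse = ", ")))
  }

  wf <- file.path(inputDir, "weights.csv")
  if (!file.exists(wf)) {
    add("error", "weights.csv", NA, "file missing")
  } else {
    w <- .readCsv(wf)
    if (any(w$weight_pre_g <= 0 | w$weight_post_g <= 0))
      add("error", "weights.csv",
          paste(which(w$weight_pre_g <= 0 | w$weight_post_g <= 0),
                collapse = ","),
          "non-positive weight")
    bad <- w$weight_post_g < w$weight_pre_g
    if (any(bad))
      add("warning", "weights.csv", paste(which(bad), collapse = ","),
          "post-irrigation weight below pre-irrigation weight")
    grids <- split(w$day, w$pot_id)
    if (any(vapply(grids, function(d) is.unsorted(d, strictly = TRUE),
                   logical(1))))
      add("error", "weights.csv", NA, "unsorted or duplicated weighing days")
  }

  if (!length(findings))
    return(data.frame(severity = character(), file = character(),
                      row = character(), message = character()))
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}

#' Run the full phenotyping pipeline
#'
#' Executes the stages in order — segmentation (or pre-computed counts),
#' Digital Biovolume traits and ratios, water budget and WUE, per-day ANOVA
#' and Duncan ranking — and writes the standard output CSVs (counts.csv,
#' traits.csv, traits_summary.csv, dbr.csv, wue.csv, wue_ratio_matrix.csv,
#' heat_class_matrix.csv, anova_report.csv, mrt_report.csv, fits.csv,
#' qc_report.csv), each carrying a header comment with the config hash and
#' seed. Reruns on identical inputs are byte-identical. Warnings are
#' logged; schema errors abort.
#'
#' @param cfg a configuration from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return Invisible list of the in-memory stage results.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipelineConfig"))
  ind <- cfg$inputDir
  outd <- cfg$outputDir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outd, "run.log")
  logLines <- character()
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    logLines <<- c(logLines, msg)
  }
  say("phenovol run: config ", cfg$config_hash, ", seed ", cfg$seed)

  qc <- validateInputs(ind)
  if (any(qc$severity == "error"))
    stop("input validation failed:\n",
         paste(apply(qc[qc$severity == "error", ], 1, paste,
                     collapse = " | "), collapse = "\n"))
  plants <- .readCsv(file.path(ind, "plants.csv"))

  # stage 1: counts
  imgDir <- file.path(ind, "images")
  counts <- withCallingHandlers(
    if (file.exists(file.path(imgDir, "images.csv"))) {
      say("stage segment: segmenting views under ", imgDir)
      countSeries(imgDir, cfg$segParams)
    } else {
      say("stage segment: using precomputed counts.csv")
      .readCsv(file.path(ind, "counts.csv"))
    },
    warning = function(w) {
      logLines <<- c(logLines, paste("WARNING:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  .writeCsv(counts, file.path(outd, "counts.csv"), cfg)

  # stage 2: traits
  say("stage traits: computing DB for ", nrow(counts), " records")
  ds <- dbSeries(counts, plants, cfg$dbConfig)
  .writeCsv(ds$traits, file.path(outd, "traits.csv"), cfg)
  .writeCsv(ds$summary, file.path(outd, "traits_summary.csv"), cfg)
  dbr <- if (cfg$compare == "genotype")
    dbrTable(ds$summary, "genotype", cfg$controlArm)
  else
    dbrTable(ds$summary, "treatment", cfg$controlTreatment)
  .writeCsv(dbr, file.path(outd, "dbr.csv"), cfg)

  # stage 3: water budget
  weights <- .readCsv(file.path(ind, "weights.csv"))
  say("stage water: ", length(unique(weights$pot_id)), " pots, t0 = ",
      cfg$t0)
  wue <- withCallingHandlers(
    wueSeries(ds$traits, weights, t0 = cfg$t0, mode = cfg$waterMode),
    warning = function(w) {
      logLines <<- c(logLines, paste("WARNING:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  .writeCsv(wue$cells, file.path(outd, "wue.csv"), cfg)
  multiTreatment <- length(unique(plants$treatment)) > 1
  if (multiTreatment) {
    wrt <- wueRatioTable(wue$cells, cfg$controlTreatment)
    rowOrder <- unique(plants$genotype)
    exportHeatmap(wrt, file.path(outd, "wue_ratio_matrix.csv"),
                  classFile = file.path(outd, "heat_class_matrix.csv"),
                  rowOrder = rowOrder)
  }

  # stage 4: statistics
  say("stage stats: per-day ANOVA and ranking")
  anova <- if (multiTreatment) anovaByDay(ds$traits) else NULL
  if (!is.null(anova)) .writeCsv(anova, file.path(outd, "anova_report.csv"),
                                 cfg)
  mrtDay <- if (is.null(cfg$mrtDay)) max(ds$traits$day) else cfg$mrtDay
  td <- ds$traits[ds$traits$day == mrtDay, ]
  mrt <- duncanMRT(td$db, td$genotype)
  mrt <- cbind(day = mrtDay, mrt)
  .writeCsv(mrt, file.path(outd, "mrt_report.csv"), cfg)

  fits <- NULL
  tf <- file.path(ind, "truth.csv")
  if (file.exists(tf)) {
    truth <- .readCsv(tf)
    m <- merge(ds$traits, truth, by = c("plant_id", "day"))
    if (nrow(m) >= 3 && "fresh_weight_g" %in% names(m)) {
      fits <- linearFit(m$fresh_weight_g, m$db)
      fits <- cbind(x = "fresh_weight_g", y = "db", fits)
      .writeCsv(fits, file.path(outd, "fits.csv"), cfg)
    }
  }

  .writeCsv(qc, file.path(outd, "qc_report.csv"), cfg)
  writeLines(logLines, logFile)
  invisible(list(counts = counts, traits = ds$traits,
                 summary = ds$summary, dbr = dbr, wue = wue,
                 anova = anova, mrt = mrt, fits = fits, qc = qc))
}
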