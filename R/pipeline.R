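# End-to-end orchestration: phantom + cohort simulation -> delineation ->
# features -> reference uptake -> cohort statistics, with a reproducible
# manifest. One global seed fans out deterministically to per-stage seeds so
# stages can be re-run in isolation.

#' @keywords internal
#' @noRd
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}

# FNV-1a over the serialized config; a stable content fingerprint for the
# manifest without external digest dependencies.
#' @keywords internal
#' @noRd
configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Assemble a pipeline run configuration
#'
#' @param outputDir directory for all artifacts.
#' @param seed global seed; every stage derives its own seed from it.
#' @param stages stages to run, a subset of `"simulate"`, `"segment"`,
#'   `"features"`, `"refuptake"`, `"stats"` (imaging stages require
#'   `"simulate"` in the same run).
#' @param nPhantoms number of phantom images for the imaging stages.
#' @param phantom a [PhantomSpec-class] template (its seed is re-derived per
#'   phantom).
#' @param cohort a [CohortSpec-class] (its seed is re-derived from the global
#'   seed); ignored when `cohortFile` is given.
#' @param cohortFile optional CSV of an existing cohort (stats-only runs).
#' @param segmentation a [SegmentationConfig-class].
#' @param histogram a [HistogramConfig-class].
#' @param alpha univariate screening threshold.
#' @param covCutoff,slrCutoff stratification cutoffs (defaults 0.25, 0.83).
#' @param writeVolumes also write each phantom volume/masks as NIfTI.
#' @return a `petromicsRunConfig` list.
#' @export
runConfig <- function(outputDir = tempfile("petromics_run_"),
                      seed = 1L,
                      stages = c("simulate", "segment", "features",
                                 "refuptake", "stats"),
                      nPhantoms = 5L,
                      phantom = phantomSpec(),
                      cohort = cohortSpec(),
                      cohortFile = NULL,
                      segmentation = segmentationConfig(),
                      histogram = histogramConfig(),
                      alpha = 0.05,
                      covCutoff = 0.25, slrCutoff = 0.83,
                      writeVolumes = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(cohortFile) && !file.exists(cohortFile))
    stop("cohortFile does not exist: ", cohortFile)
  structure(list(outputDir = outputDir, seed = as.integer(seed),
                 stages = stages, nPhantoms = as.integer(nPhantoms),
                 phantom = phantom, cohort = cohort, cohortFile = cohortFile,
                 segmentation = segmentation, histogram = histogram,
                 alpha = alpha, covCutoff = covCutoff, slrCutoff = slrCutoff,
                 writeVolumes = writeVolumes),
            class = "petromicsRunConfig")
}

#' @keywords internal
#' @noRd
analysisCandidates <- function() {
  c("age_years", "sex_man", "loc_right_colon", "loc_rectum", "cea_ge5",
    "tumor_size_cm", "grade_high", "lvi_present", "stage_iii_iv",
    "adjuvant_yes", "max_suv", "mtv_cm3", "tlg_g", "mean_suv", "median_suv",
    "cov_suv", "kurtosis", "skewness", "entropy", "uniformity", "bm_suv",
    "blr", "spleen_suv", "slr")
}

#' @keywords internal
#' @noRd
imagingFeatureNames <- function() {
  c("max_suv", "mtv_cm3", "tlg_g", "mean_suv", "median_suv", "cov_suv",
    "kurtosis", "skewness", "entropy", "uniformity", "bm_suv", "blr",
    "spleen_suv", "slr")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in order and writes: `phantom_features.csv`
#' (per-phantom delineation, tumor features and reference uptake, with ground
#' truth), `cohort.csv`, `stats.json` (feature-grade tests, tumor-grade
#' comparisons, univariate/multivariate Cox, ROC cutoffs, Kaplan-Meier with
#' log-rank, stratified recurrence table), text tables mirroring the
#' feature-by-grade / survival / recurrence layouts, KM curves (PDF + step
#' CSV), and `manifest.json` (package version, seeds, config fingerprint,
#' artifact list). A failing stage aborts with its name; partial outputs are
#' kept under a `failed/` marker file. Identical config + seed give identical
#' numeric outputs.
#'
#' @param config a [runConfig()] list.
#' @return list with elements `phantoms` (data.frame or NULL), `cohort`,
#'   `stats`, `manifest`; artifacts under `config$outputDir`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "petromicsRunConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  log <- list()
  stageGuard <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      marker <- file.path(config$outputDir, "failed")
      writeLines(sprintf("stage '%s' failed: %s", stage,
                         conditionMessage(e)), marker)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  phantomTab <- NULL
  if (all(c("simulate", "segment") %in% config$stages)) {
    phantomTab <- stageGuard("segment+features+refuptake", {
      rows <- lapply(seq_len(config$nPhantoms), function(k) {
        ps <- config$phantom
        ps@seed <- childSeed(config$seed, k)
        ph <- generatePhantom(ps)
        if (config$writeVolumes)
          writePhantom(ph, file.path(config$outputDir, "phantoms"),
                       sprintf("phantom_%03d", k))
        row <- data.frame(phantom = k, seed = ps@seed,
                          true_mtv_cm3 = ph$truth@trueTumorVolumeCm3,
                          true_mean_suv = ps@tumorMean,
                          true_cov = ps@tumorTextureSD / ps@tumorMean)
        if ("segment" %in% config$stages) {
          del <- delineateTumor(ph$volume, ps@tumorCenter,
                                config$segmentation,
                                organMasks = ph$truth@organMasks)
          row$threshold <- del@threshold
          row$iterations <- del@iterations
          row$converged <- del@converged
          if ("features" %in% config$stages) {
            fv <- featureVector(tumorFeatures(ph$volume, del@mask,
                                              config$histogram))
            row <- cbind(row, as.data.frame(t(fv)))
          }
          if ("refuptake" %in% config$stages) {
            os <- ps@organSpecs
            vert <- as.matrix(os[grepl("^vertebra_", os$label),
                                 c("cx", "cy", "cz")])
            ru <- referenceUptake(
              ph$volume,
              liverCenterMM = as.numeric(os[os$label == "liver",
                                            c("cx", "cy", "cz")]),
              spleenCenterMM = as.numeric(os[os$label == "spleen",
                                             c("cx", "cy", "cz")]),
              vertebralCentersMM = vert)
            row <- cbind(row, as.data.frame(t(featureVector(ru))))
          }
        }
        row
      })
      do.call(rbind, rows)
    })
    pf <- file.path(config$outputDir, "phantom_features.csv")
    utils::write.csv(phantomTab, pf, row.names = FALSE)
    artifacts <- c(artifacts, pf)
    log$phantoms <- nrow(phantomTab)
  }

  cohort <- NULL
  if ("simulate" %in% config$stages || !is.null(config$cohortFile)) {
    cohort <- stageGuard("simulate", {
      if (!is.null(config$cohortFile)) readCohort(config$cohortFile)
      else {
        cs <- config$cohort
        cs@seed <- childSeed(config$seed, 0L)
        generateCohort(cs)
      }
    })
    cf <- file.path(config$outputDir, "cohort.csv")
    writeCohort(cohort, cf)
    artifacts <- c(artifacts, cf)
  }

  stats <- NULL
  if ("stats" %in% config$stages) {
    if (is.null(cohort)) stop("stats stage requires a cohort (simulate stage or cohortFile)")
    stats <- stageGuard("stats", {
      runCohortStats(cohort, alpha = config$alpha,
                     covCutoff = config$covCutoff,
                     slrCutoff = config$slrCutoff,
                     outputDir = config$outputDir)
    })
    artifacts <- c(artifacts, attr(stats, "artifacts"))
  }

  manifest <- list(
    package = "petromics",
    version = as.character(utils::packageVersion("petromics")),
    seed = config$seed,
    config_hash = configHash(config[setdiff(names(config), "outputDir")]),
    stages = config$stages,
    artifacts = basename(artifacts),
    log = log
  )
  mf <- file.path(config$outputDir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  list(phantoms = phantomTab, cohort = cohort, stats = stats,
       manifest = manifest)
}

#' Cohort statistics stage: feature-grade tests, survival models, tables
#'
#' @param cohort cohort data.frame.
#' @param alpha univariate screening threshold.
#' @param covCutoff,slrCutoff stratification cutoffs.
#' @param outputDir where to write `stats.json`, the text tables and KM
#'   outputs; NULL to skip writing.
#' @return nested list of results (invisibly written as JSON), with attribute
#'   `artifacts`.
#' @export
runCohortStats <- function(cohort, alpha = 0.05, covCutoff = 0.25,
                           slrCutoff = 0.83, outputDir = NULL) {
  markers <- intersect(c("cd4", "cd8", "cd163", "il6", "mmp11"), names(cohort))
  feats <- intersect(imagingFeatureNames(), names(cohort))

  # feature-by-grade rank tests (the feature-grade correlation table)
  gradeTests <- list()
  for (mk in markers) {
    for (f in feats) {
      kw <- kruskalWallisByGrade(cohort, f, mk)
      tier <- if (kw$p < 0.05) "significant"
              else if (kw$p < 0.10) "borderline" else "ns"
      rec <- list(feature = f, marker = mk, H = kw$H, df = kw$df, p = kw$p,
                  tier = tier,
                  medians = as.list(tapply(cohort[[f]], cohort[[mk]],
                                           stats::median, na.rm = TRUE)))
      if (kw$p < 0.05)
        rec$dunn <- dunnPosthoc(cohort, f, mk)
      gradeTests[[paste(mk, f, sep = ".")]] <- rec
    }
  }

  gradeComparison <- NULL
  if ("tumor_grade" %in% names(cohort) &&
      length(unique(cohort$tumor_grade)) == 2L) {
    gradeComparison <- lapply(feats, function(f) {
      mw <- mannWhitney(cohort, f, "tumor_grade")
      list(feature = f, U = mw$U, p = mw$p, method = mw$method)
    })
  }

  candidates <- intersect(analysisCandidates(), names(prepareCovariates(cohort)))
  screened <- univariateScreen(cohort, candidates, alpha = alpha)
  multivariate <- if (length(screened) >= 1L) coxFit(cohort, screened) else NULL

  cutCov <- rocCutoff(cohort, "cov_suv")
  cutSlr <- rocCutoff(cohort, "slr")

  kmCov <- kmLogrank(cohort, ifelse(cohort$cov_suv > covCutoff,
                                    "high_cov", "low_cov"))
  kmSlr <- kmLogrank(cohort, ifelse(cohort$slr >= slrCutoff,
                                    "high_slr", "low_slr"))
  strat <- recurrenceStratTable(cohort, covCutoff, slrCutoff)

  res <- list(
    n = nrow(cohort),
    feature_grade_tests = gradeTests,
    tumor_grade_comparison = gradeComparison,
    univariate = as.list(as.data.frame(attr(screened, "table"))),
    selected_covariates = as.character(screened),
    multivariate = if (is.null(multivariate)) NULL
                   else as.list(as.data.frame(multivariate)),
    roc_cutoffs = list(cov_suv = cutCov, slr = cutSlr),
    km = list(cov_suv = list(survival_at_60 = as.list(kmCov$survivalAtQuery),
                             chisq = kmCov$chisq, p = kmCov$p),
              slr = list(survival_at_60 = as.list(kmSlr$survivalAtQuery),
                         chisq = kmSlr$chisq, p = kmSlr$p)),
    recurrence_table = as.list(as.data.frame(strat))
  )

  artifacts <- character(0)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    sj <- file.path(outputDir, "stats.json")
    jsonlite::write_json(res, sj, auto_unbox = TRUE, digits = NA,
                         null = "null")
    artifacts <- c(artifacts, sj)
    artifacts <- c(artifacts,
                   writeStatsTables(res, cohort, outputDir),
                   writeKMOutputs(kmCov, kmSlr, outputDir))
  }
  attr(res, "artifacts") <- artifacts
  res
}

#' @keywords internal
#' @noRd
writeStatsTables <- function(res, cohort, outputDir) {
  paths <- character(0)
  # feature-by-grade table, significant + borderline rows only
  lines <- c("feature\tmarker\tmedian_g0\tmedian_g1\tmedian_g2\tp\ttier")
  for (rec in res$feature_grade_tests) {
    if (rec$tier == "ns") next
    med <- unlist(rec$medians)
    lines <- c(lines, sprintf("%s\t%s\t%.4g\t%.4g\t%.4g\t%.4g\t%s",
                              rec$feature, rec$marker, med[1], med[2], med[3],
                              rec$p, rec$tier))
  }
  p1 <- file.path(outputDir, "table_feature_by_grade.tsv")
  writeLines(lines, p1); paths <- c(paths, p1)

  # survival analysis table
  lines <- c("term\tanalysis\tcoef\thazard_ratio\tci_lower\tci_upper\tp")
  uni <- res$univariate
  for (i in seq_along(uni$term)) {
    lines <- c(lines, sprintf("%s\tunivariate\t%.4g\t%.4g\t%.4g\t%.4g\t%.4g",
                              uni$term[i], uni$coef[i], uni$hazard_ratio[i],
                              uni$ci_lower[i], uni$ci_upper[i], uni$p[i]))
  }
  mv <- res$multivariate
  if (!is.null(mv)) {
    for (i in seq_along(mv$term)) {
      lines <- c(lines,
                 sprintf("%s\tmultivariate\t%.4g\t%.4g\t%.4g\t%.4g\t%.4g",
                         mv$term[i], mv$coef[i], mv$hazard_ratio[i],
                         mv$ci_lower[i], mv$ci_upper[i], mv$p[i]))
    }
  }
  p2 <- file.path(outputDir, "table_survival.tsv")
  writeLines(lines, p2); paths <- c(paths, p2)

  # recurrence stratification table
  rt <- as.data.frame(res$recurrence_table)
  lines <- c("stage_group\timaging_group\tevents\ttotal\trate_percent")
  for (i in seq_len(nrow(rt))) {
    rate <- if (is.na(rt$rate_percent[i])) "-" else sprintf("%.1f", rt$rate_percent[i])
    lines <- c(lines, sprintf("%s\t%s\t%d\t%d\t%s", rt$stage_group[i],
                              rt$imaging_group[i], rt$events[i], rt$total[i],
                              rate))
  }
  p3 <- file.path(outputDir, "table_recurrence.tsv")
  writeLines(lines, p3); paths <- c(paths, p3)
  paths
}

#' @keywords internal
#' @noRd
writeKMOutputs <- function(kmCov, kmSlr, outputDir) {
  paths <- character(0)
  for (nm in c("cov_suv", "slr")) {
    km <- if (nm == "cov_suv") kmCov else kmSlr
    step <- do.call(rbind, lapply(names(km$curves), function(gp) {
      cbind(group = gp, km$curves[[gp]])
    }))
    pc <- file.path(outputDir, paste0("km_", nm, ".csv"))
    utils::write.csv(step, pc, row.names = FALSE)
    pp <- file.path(outputDir, paste0("km_", nm, ".pdf"))
    grDevices::pdf(pp, width = 6, height = 5)
    plotKM(km, main = paste("Recurrence-free survival by", nm))
    grDevices::dev.off()
    paths <- c(paths, pc, pp)
  }
  paths
}

#' Plot Kaplan-Meier curves from a kmLogrank result
#'
#' @param km result of [kmLogrank()].
#' @param main plot title.
#' @return NULL, invisibly.
#' @export
plotKM <- function(km, main = "Recurrence-free survival") {
  cols <- seq_along(km$curves)
  maxT <- max(vapply(km$curves, function(cv) max(cv$time), numeric(1)))
  graphics::plot(NA, xlim = c(0, maxT), ylim = c(0, 1),
                 xlab = "Months", ylab = "RFS probability", main = main)
  for (i in seq_along(km$curves)) {
    cv <- km$curves[[i]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$survival)), col = cols[i],
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = names(km$curves), col = cols,
                   lty = 1, bty = "n")
  if (!is.null(km$p))
    graphics::mtext(sprintf("log-rank p = %.3g", km$p), side = 3, line = 0,
                    cex = 0.8)
  invisible(NULL)
}
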