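# End-to-end orchestration: simulate (or load) -> preprocess -> quantify ->
# fit/validate -> stratify -> correlate, with a run manifest recording
# configuration and output checksums. Deterministic for a fixed config.

default_config <- function() {
  list(
    simulate = list(n_patients = 50, male_frac = 0.66,
                    subgroup_props = c(full = 0.64, weakA = 0.19,
                                       weakB = 0.17),
                    n_points = 10000),
    input = NULL,                       # alternatively: spectra/clinical paths
    grid = list(upper = 9.0, lower = 0.5, width = 0.002),
    water = WATER_WINDOW,
    reference = list(window = c(1.3, 1.7), target = 1.48),
    model = list(n_orth = 2, n_folds = 7, n_perm = 199),
    seed = NULL,
    outdir = NULL)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read a pipeline configuration
#'
#' Reads a YAML file (or takes a list) and fills unspecified fields with
#' the package defaults. A seed is mandatory whenever a stochastic stage
#' (simulation or permutation testing) is enabled.
#'
#' @param config path to a YAML file, or a named list.
#' @return the completed configuration list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(cfg$simulate))
    cfg$simulate$subgroup_props <- unlist(cfg$simulate$subgroup_props)
  stochastic <- !is.null(cfg$simulate) ||
    (!is.null(cfg$model$n_perm) && cfg$model$n_perm > 0)
  if (stochastic && is.null(cfg$seed))
    stop("config must provide a seed: simulation and/or permutation ",
         "testing is enabled")
  if (is.null(cfg$outdir)) stop("config must provide an outdir")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> reference -> bucket -> water exclusion ->
#' Pareto scaling -> OPLS-DA fit, cross-validation, permutation testing and
#' CV-ANOVA -> panel quantification -> mixing stratification -> paired
#' test battery -> response correlation, writing every stage output
#' under \code{outdir} plus a \code{manifest.json} with md5 checksums.
#' Rerunning with the same configuration reproduces the outputs.
#'
#' @param config YAML path or list, see \code{\link{readRunConfig}}.
#' @return invisibly, a list with the bucket table, metabolite table,
#'   model, validation results, trajectories, battery, correlations and
#'   the manifest.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$simulate)) {
    spec <- cohortSpec(n_patients = cfg$simulate$n_patients,
                       male_frac = cfg$simulate$male_frac,
                       subgroup_props = cfg$simulate$subgroup_props,
                       n_points = cfg$simulate$n_points,
                       seed = cfg$seed)
    cohort <- generateCohort(spec)
    spectra <- cohort$spectra
    clinical <- cohort$clinical
    write.csv(cohort$labels, file.path(cfg$outdir, "labels.csv"),
              row.names = FALSE)
  } else {
    files <- list.files(cfg$input$spectra, full.names = TRUE,
                        pattern = "\\.(tsv|txt|dx|jdx)$")
    spectra <- lapply(files, function(f) {
      meta <- strsplit(sub("\\.[^.]+$", "", basename(f)), "_")[[1]]
      reader <- if (grepl("\\.(dx|jdx)$", f)) readJCAMP else readSpectrum
      reader(f, sampleID = paste(meta[1], meta[2], sep = "_"),
             patientID = meta[1], timepoint = meta[2], channel = meta[3])
    })
    names(spectra) <- vapply(spectra, function(s)
      paste0(s@sampleID, "_", s@channel), character(1))
    clinical <- read.csv(cfg$input$clinical, stringsAsFactors = FALSE,
                         colClasses = c(cT = "character",
                                        cN = "character",
                                        yT = "character",
                                        yN = "character"))
    cohort <- NULL
  }

  is_cpmg <- vapply(spectra, function(s) s@channel == "CPMG", logical(1))
  referenced <- lapply(spectra, function(s) {
    if (s@channel != "CPMG") return(s)
    referenceToAlanine(s, window = cfg$reference$window,
                       target = cfg$reference$target)
  })

  grid <- bucketGrid(cfg$grid$upper, cfg$grid$lower, cfg$grid$width)
  bt <- buildBucketTable(referenced[is_cpmg], grid)
  bt <- excludeWater(bt, cfg$water)
  X <- paretoScale(bucketMatrix(bt))
  y <- SummarizedExperiment::colData(bt)$timepoint
  if (length(unique(y)) < 2 || sum(retainedBuckets(bt)) == 0)
    stop("cannot fit: need two classes and at least one retained bucket")

  model <- fitOplsda(X, y, n_orth = cfg$model$n_orth)
  cv <- crossValidate(X, y, n_orth = cfg$model$n_orth,
                      n_folds = cfg$model$n_folds)
  anova <- cvAnova(cv)
  perm <- if (cfg$model$n_perm > 0)
    permutationTest(X, y, n_orth = cfg$model$n_orth,
                    n_perm = cfg$model$n_perm, seed = cfg$seed,
                    n_folds = cfg$model$n_folds) else NULL
  pred <- predict(model, X)
  mct <- misclassificationTable(pred$class, y)

  metab <- quantifyPanel(referenced)
  cd <- SummarizedExperiment::colData(bt)
  # stratify on cross-validated predicted scores: training scores are
  # biased toward each sample's own label, which masks mixing
  traj <- detectMixing(cv$yhat_cv - 0.5, cd$timepoint, cd$patientID)
  groups <- merge(traj[, c("patient", "stratum")],
                  clinical[, c("patient", "sex")], by = "patient")
  battery <- pairedBattery(metab, groups)
  correlations <- correlateResponse(metab, clinical,
                                    strata = traj[, c("patient", "stratum")])

  # stage outputs
  out <- function(x, f) {
    write.csv(x, file.path(cfg$outdir, f), row.names = FALSE)
  }
  out(clinical, "clinical.csv")
  out(metaboliteLong(metab), "metabolites.csv")
  out(data.frame(sampleID = cd$sampleID, patientID = cd$patientID,
                 timepoint = cd$timepoint, t1 = scores(model),
                 yhat_cv = cv$yhat_cv, orthoScores(model)), "scores.csv")
  out(traj, "trajectories.csv")
  out(battery, "battery.csv")
  out(correlations, "correlations.csv")
  out(sLineData(model, bucketPPM(bt)), "sline.csv")
  writeOplsdaJSON(model, file.path(cfg$outdir, "model.json"))
  validation <- list(
    Q2 = cv$Q2, cv_anova = anova[c("F", "df1", "df2", "p")],
    permutation = if (!is.null(perm))
      list(p = as.list(perm$p), n_perm = perm$n_perm) else NULL,
    misclassification = mct,
    diagnostics = as.list(diagnostics(model)))
  jsonlite::write_json(validation, file.path(cfg$outdir, "validation.json"),
                       digits = NA, auto_unbox = TRUE)

  grDevices::png(file.path(cfg$outdir, "scores.png"), 800, 600)
  plotScores(model, cd$timepoint)
  grDevices::dev.off()
  grDevices::png(file.path(cfg$outdir, "sline.png"), 1000, 500)
  plotSLine(sLineData(model, bucketPPM(bt)))
  grDevices::dev.off()

  files <- setdiff(list.files(cfg$outdir), "manifest.json")
  manifest <- list(
    config = cfg,
    outputs = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(cfg$outdir, f)))))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(bucket_table = bt, metabolites = metab, model = model,
                 cv = cv, cv_anova = anova, permutation = perm,
                 misclassification = mct, trajectories = traj,
                 battery = battery, correlations = correlations,
                 clinical = clinical, cohort = cohort,
                 manifest = manifest))
}

#' Diagnostic plots
#'
#' \code{plotScores}: predictive score t[1] against the first orthogonal
#' score, colored by class. \code{plotSLine}: per-bucket covariance with
#' t[1] against ppm (axis reversed), colored by |p(corr)|.
#' \code{plotTrajectories}: pre -> post t[1] per patient, colored by
#' stratum.
#'
#' @param model an \code{\linkS4class{OplsdaModel}}.
#' @param classes per-sample class labels.
#' @param sline data.frame from \code{\link{sLineData}}.
#' @param traj data.frame from \code{\link{detectMixing}}.
#' @return invisibly, NULL; called for the plot side effect.
#' @name pipeline-plots
NULL

#' @rdname pipeline-plots
#' @export
plotScores <- function(model, classes) {
  to <- if (ncol(orthoScores(model)) > 0) orthoScores(model)[, 1]
        else rep(0, length(scores(model)))
  cls <- factor(classes)
  graphics::plot(scores(model), to, col = as.integer(cls), pch = 19,
                 xlab = "t[1] (predictive)", ylab = "t[o1] (orthogonal)",
                 main = "OPLS-DA scores")
  graphics::abline(v = 0, lty = 2, col = "grey")
  graphics::legend("topright", legend = levels(cls),
                   col = seq_len(nlevels(cls)), pch = 19)
  invisible(NULL)
}

#' @rdname pipeline-plots
#' @export
plotSLine <- function(sline) {
  pal <- grDevices::colorRampPalette(c("grey80", "orange", "red"))(100)
  idx <- pmax(1, ceiling(abs(sline$pcorr) * 100))
  graphics::plot(sline$ppm, sline$cov, type = "h", col = pal[idx],
                 xlim = rev(range(sline$ppm)),
                 xlab = "ppm", ylab = "cov(X, t[1])",
                 main = "s-line (colored by |p(corr)|)")
  invisible(NULL)
}

#' @rdname pipeline-plots
#' @export
plotTrajectories <- function(traj) {
  cols <- c(Grey = "grey50", Red = "red3", Green = "green4")
  graphics::plot(NA, xlim = range(c(traj$pre_t1, traj$post_t1)),
                 ylim = c(0.5, nrow(traj) + 0.5),
                 xlab = "t[1]", ylab = "patient",
                 main = "pre -> post score trajectories")
  graphics::abline(v = 0, lty = 2)
  for (i in seq_len(nrow(traj)))
    graphics::arrows(traj$pre_t1[i], i, traj$post_t1[i], i,
                     length = 0.05, col = cols[as.character(traj$stratum[i])])
  invisible(NULL)
}
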