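## Cohort-level orchestration: configuration, a synthetic-cohort
## writer (the stand-in for an imaging session), and the full
## reflectance -> vascular maps -> metabolic endpoints -> regional
## statistics pipeline with deterministic, machine-readable outputs.

#' Pipeline run configuration
#'
#' Defaults follow the acquisition and analysis conventions: four
#' imaging wavelengths (540/560/580/610 nm), a 20% reflectance
#' standard, a per-pixel R-squared acceptance threshold of 0.9,
#' endpoint times of 60 min (2-NBDG) and 80 min (TMRE), a 3x3
#' local-range window and a 10-px registration search radius.
#'
#' @param wavelengths imaging wavelengths, nm.
#' @param standardReflectance reflectance-standard reflectance.
#' @param r2Threshold NNLS acceptance threshold.
#' @param endpointTimes named vector, minutes post-injection.
#' @param window local-range window (odd, >= 3).
#' @param maxShift registration search radius, px.
#' @param dilate vessel-mask dilation radius for the analysis mask, px.
#' @param noiseCv generator noise CV used by [simulateCohort()].
#' @param seed base seed for generators.
#' @param background,extinction optics used for the design matrix (and
#'   by the cohort generator).
#' @return A named list of class `run_config`.
#' @export
runConfig <- function(wavelengths = c(540, 560, 580, 610),
                      standardReflectance = 0.20,
                      r2Threshold = 0.9,
                      endpointTimes = c(NBDG = 60, TMRE = 80),
                      window = 3L, maxShift = 10L, dilate = 1L,
                      noiseCv = 0.01, seed = 1L,
                      background = defaultTongueBackground(wavelengths),
                      extinction = builtinExtinctionTable(wavelengths)) {
  structure(list(wavelengths = wavelengths,
                 standardReflectance = standardReflectance,
                 r2Threshold = r2Threshold,
                 endpointTimes = endpointTimes, window = window,
                 maxShift = maxShift, dilate = dilate,
                 noiseCv = noiseCv, seed = as.integer(seed),
                 background = background, extinction = extinction),
            class = "run_config")
}

#' Write a synthetic imaging cohort to disk
#'
#' Generates `nNormal` normal and `nTumor` tumor-like scenes, renders
#' the multispectral reflectance stack and both fluorescence uptake
#' series for each, and writes images, masks, truth tables and a
#' cohort manifest to `outDir`. This is the synthetic stand-in for an
#' imaging session: downstream, [runPipeline()] consumes the manifest
#' exactly as it would for real acquisitions.
#'
#' @param outDir output directory (created if needed).
#' @param nNormal,nTumor group sizes.
#' @param size scene side length, px (>= 64).
#' @param seed base seed; every animal derives its own stream.
#' @param config a [runConfig()].
#' @return Path to the manifest YAML, invisibly.
#' @export
simulateCohort <- function(outDir, nNormal = 5L, nTumor = 5L,
                           size = 128L, seed = 1L,
                           config = runConfig(seed = seed)) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  animals <- list()
  groups <- c(rep("normal", nNormal), rep("tumor", nTumor))
  truthRows <- list()
  for (i in seq_along(groups)) {
    grp <- groups[i]
    id <- sprintf("%s%02d", grp, sum(groups[seq_len(i)] == grp))
    aSeed <- deriveSeed(seed, i)
    scene <- simulateTongueScene(size, size, tumorLike = grp == "tumor",
                                 seed = aSeed)
    stack <- renderReflectance(scene, config$background,
                               config$extinction,
                               noiseCv = config$noiseCv, seed = aSeed)
    paths <- list(
      stack = file.path(outDir, paste0(id, "_stack.nii.gz")),
      nbdg = file.path(outDir, paste0(id, "_nbdg.nii.gz")),
      tmre = file.path(outDir, paste0(id, "_tmre.nii.gz")),
      reflectance_mask = file.path(outDir, paste0(id, "_vessel.png")),
      fluor_mask = file.path(outDir, paste0(id, "_vessel_fluor.png")))
    writeSpectralStack(stack, paths$stack)
    writeFluorSeries(
      simulateFluorSeries(scene, "NBDG", noiseCv = config$noiseCv,
                          seed = aSeed), paths$nbdg)
    writeFluorSeries(
      simulateFluorSeries(scene, "TMRE", noiseCv = config$noiseCv,
                          seed = aSeed), paths$tmre)
    writeMask(scene@vesselMask, paths$reflectance_mask)
    writeMask(scene@vesselMask, paths$fluor_mask)
    animals[[i]] <- c(list(id = id, group = grp), paths)
    truthRows[[i]] <- data.frame(
      id = id, group = grp,
      meanStO2True = mean(scene@stO2True, na.rm = TRUE),
      meanTHbTrue = mean((scene@cHbO2True +
                            scene@cHbTrue)[scene@vesselMask]),
      seed = aSeed)
  }
  utils::write.csv(do.call(rbind, truthRows),
                   file.path(outDir, "truth.csv"), row.names = FALSE)
  manifest <- file.path(outDir, "manifest.yaml")
  yaml::write_yaml(list(seed = as.integer(seed), size = as.integer(size),
                        animals = animals), manifest)
  invisible(manifest)
}

.stage <- function(id, stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("animal %s, stage %s: %s", id, stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline over a cohort
#'
#' For every animal in the manifest: unmix the reflectance stack into
#' chromophore and vascular maps, extract both fluorescence endpoint
#' maps with co-registration and vessel exclusion, compute uptake
#' kinetics, local-range heterogeneity maps and the four-group
#' metabolic clustering, and summarize every parameter over the nine
#' nonants. Then compare groups per parameter (Student's t on pooled
#' nonant means) and correlate the six vascular-metabolic parameter
#' pairs per group (after global-max normalization of THb and the
#' metabolic intensities). All outputs are deterministic given the
#' manifest.
#'
#' Outputs under `outDir`: per-animal parameter maps
#' (`<id>_<param>.nii.gz`), kinetic-curve and cluster-count CSVs, a
#' tidy `nonant_summary.csv` (one row per animal x nonant x
#' parameter), `statistics.json` (group comparisons, correlations)
#' and `provenance.json` (config hash, seeds, versions).
#'
#' @param manifest manifest path (YAML) from [simulateCohort()], or
#'   the equivalent list.
#' @param outDir results directory (created if needed).
#' @param config a [runConfig()].
#' @return Invisibly, a list with `nonants` (the tidy summary data
#'   frame) and `statistics` (the statistics list).
#' @export
runPipeline <- function(manifest, outDir, config = runConfig()) {
  if (is.character(manifest)) {
    manifestPath <- manifest
    manifest <- yaml::read_yaml(manifest)
  } else manifestPath <- NA_character_
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  design <- buildDesignMatrix(config$wavelengths, config$background,
                              config$extinction)
  nonantRows <- list()
  for (an in manifest$animals) {
    id <- an$id
    stack <- .stage(id, "read_stack", readSpectralStack(an$stack))
    reflMask <- .stage(id, "read_masks", readMask(an$reflectance_mask))
    fluorMask <- .stage(id, "read_masks", readMask(an$fluor_mask))
    chrom <- .stage(id, "unmix", {
      unmixStack(computeAbsorbance(stack), design,
                 r2Threshold = config$r2Threshold)
    })
    vasc <- .stage(id, "vascular_maps", makeVascularMaps(chrom, reflMask))
    endpoints <- list()
    for (probe in c("NBDG", "TMRE")) {
      series <- .stage(id, paste0("read_", tolower(probe)),
                       readFluorSeries(an[[tolower(probe)]]))
      series <- subtractBackground(series)
      ep <- .stage(id, paste0("endpoint_", tolower(probe)), {
        shift <- registerShift(
          series@frames[, , dim(series@frames)[3L]],
          stack@frames[, , 2L], maxShift = config$maxShift)
        amask <- buildAnalysisMask(reflMask, fluorMask, shift,
                                   dilate = config$dilate)
        curve <- uptakeKinetics(series, amask)
        utils::write.csv(curve,
                         file.path(outDir, sprintf("%s_%s_kinetics.csv",
                                                   id, tolower(probe))),
                         row.names = FALSE)
        endpointMap(series, amask,
                    endpointTime = config$endpointTimes[[probe]])
      })
      endpoints[[probe]] <- ep
    }
    het <- .stage(id, "heterogeneity", {
      lrN <- localRangeMap(endpoints$NBDG@image, config$window)
      lrT <- localRangeMap(endpoints$TMRE@image, config$window)
      cl <- mergeClusters(binarizeByGlobalMean(endpoints$NBDG),
                          binarizeByGlobalMean(endpoints$TMRE))
      utils::write.csv(clusterCounts(cl),
                       file.path(outDir,
                                 sprintf("%s_cluster_counts.csv", id)),
                       row.names = FALSE)
      list(lrN = lrN, lrT = lrT)
    })
    maps <- list(
      StO2 = list(map = vasc@StO2, units = "fraction"),
      THb = list(map = vasc@THb, units = "indicator (M cm)"),
      Hb = list(map = vasc@Hb, units = "indicator (M cm)"),
      HbO2 = list(map = vasc@HbO2, units = "indicator (M cm)"),
      NBDG60 = list(map = endpoints$NBDG@image,
                    units = "background-subtracted counts"),
      TMRE80 = list(map = endpoints$TMRE@image,
                    units = "background-subtracted counts"),
      localRangeNBDG = list(map = het$lrN$image, units = "counts"),
      localRangeTMRE = list(map = het$lrT$image, units = "counts"))
    part <- nonantPartition(nrow(vasc@StO2), ncol(vasc@StO2))
    for (param in names(maps)) {
      writeMap(maps[[param]]$map,
               file.path(outDir, sprintf("%s_%s.nii.gz", id, param)),
               parameter = param, units = maps[[param]]$units)
      nm <- nonantMeans(maps[[param]]$map, partition = part)
      nm$id <- id; nm$group <- an$group; nm$parameter <- param
      nonantRows[[length(nonantRows) + 1L]] <- nm
    }
  }
  nonants <- do.call(rbind, nonantRows)
  nonants <- nonants[, c("id", "group", "parameter", "nonant", "mean",
                         "nValid")]
  utils::write.csv(nonants, file.path(outDir, "nonant_summary.csv"),
                   row.names = FALSE)
  statistics <- .cohortStatistics(nonants)
  jsonlite::write_json(statistics, file.path(outDir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  provenance <- list(
    package = "mpfm",
    version = as.character(utils::packageVersion("mpfm")),
    manifest = if (!is.na(manifestPath))
      unname(tools::md5sum(manifestPath)) else NA,
    config_hash = .configHash(config),
    seed = manifest$seed,
    conventions = list(
      indexing = "0-based, half-open nonant ranges, row-major",
      masks = "1 = vessel", missing = "NaN",
      cluster_codes = paste("1=lowNBDG/lowTMRE 2=lowNBDG/highTMRE",
                            "3=highNBDG/lowTMRE 4=highNBDG/highTMRE")))
  jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(nonants = nonants, statistics = statistics))
}

## Pooled-nonant group comparisons and the six per-group
## vascular-metabolic correlations (THb and metabolic intensities
## normalized to their global maximum across both groups first).
.cohortStatistics <- function(nonants) {
  getValues <- function(param, group) {
    v <- nonants[nonants$parameter == param & nonants$group == group,
                 c("id", "nonant", "mean")]
    v[order(v$id, v$nonant), ]
  }
  params <- unique(nonants$parameter)
  groupComparisons <- list()
  for (param in params) {
    n <- getValues(param, "normal"); t <- getValues(param, "tumor")
    if (sum(!is.na(n$mean)) < 2L || sum(!is.na(t$mean)) < 2L) next
    groupComparisons[[param]] <- compareGroups(n$mean, t$mean)
  }
  normalized <- nonants
  for (param in c("THb", "NBDG60", "TMRE80")) {
    sel <- normalized$parameter == param
    if (any(sel))
      normalized$mean[sel] <- normalizeGlobalMax(normalized$mean[sel])
  }
  pairs <- list(c("StO2", "THb"), c("NBDG60", "TMRE80"),
                c("TMRE80", "StO2"), c("NBDG60", "StO2"),
                c("TMRE80", "THb"), c("NBDG60", "THb"))
  correlations <- list()
  for (group in c("normal", "tumor")) {
    byPair <- list()
    for (p in pairs) {
      vx <- normalized[normalized$parameter == p[1L] &
                         normalized$group == group, ]
      vy <- normalized[normalized$parameter == p[2L] &
                         normalized$group == group, ]
      vx <- vx[order(vx$id, vx$nonant), ]
      vy <- vy[order(vy$id, vy$nonant), ]
      res <- tryCatch(correlateNonants(vx$mean, vy$mean),
                      error = function(e) NULL)
      if (!is.null(res))
        byPair[[paste(p, collapse = "_vs_")]] <- res
    }
    correlations[[group]] <- byPair
  }
  list(groupComparisons = groupComparisons,
       correlations = correlations)
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}
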