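# End-to-end pipeline orchestration: configuration with the study defaults,
# stage execution with fail-fast context, artifact output and a run manifest.

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: 4 mm implant offset
#' thickness, 70% target porosity, 50 N over 200 mm^2 static load, and a
#' synthetic phantom standing in for the patient CT.
#'
#' @param seed master seed; stage seeds are derived from it
#' @return nested configuration list
#' @export
defaultConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(outerRadii = c(90, 70, 60), shellThickness = 6,
                   asymmetryAmplitude = 0,
                   defectCenter = c(-65, 15, 39), defectRadius = 30),
    ct = list(spacing = 0.8, boneHU = 1200, backgroundHU = -1000, noiseSD = 30),
    segmentation = list(lowerHU = 226, upperHU = Inf, smoothIterations = 10),
    reconstruction = list(wrapVoxel = 0.8, booleanVoxel = 0.5),
    implant = list(thickness = 4, rimWidth = 6, cellSize = 2.5,
                   targetPorosity = 0.70, screwDiameter = 2,
                   shellVoxel = 0.3, latticeVoxel = 0.15),
    fea = list(voxelSize = 1.5, fixedSlabHeight = 5, totalLoad = 50,
               loadArea = 200),
    fitting = list(manufacturingAmplitude = 0.33, correlationLength = 15,
                   scanDensity = 0.5, scanNoiseSD = 0.05,
                   scanPoseAngleDeg = 10, scanPoseTranslation = c(8, 5, 3),
                   nSample = 20000, roiDilation = 5),
    vas = list(nExperts = 10, nReplicates = 5, mean = 3.66, sd = 0.5,
               mu0 = 3, alpha = 0.05)
  )
}

#' Validate a pipeline configuration
#'
#' Schema and range checks; called by [runPipeline()] before any compute.
#'
#' @param config configuration list (see [defaultConfig()])
#' @return the config, invisibly, or an error
#' @export
validateConfig <- function(config) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("config: ", msg, call. = FALSE)
  chk(is.list(config), "must be a list")
  needed <- c("seed", "phantom", "ct", "segmentation", "reconstruction",
              "implant", "fea", "fitting", "vas")
  chk(all(needed %in% names(config)),
      paste("missing sections:", paste(setdiff(needed, names(config)), collapse = ", ")))
  ph <- config$phantom
  chk(length(ph$outerRadii) == 3 && all(ph$outerRadii > 0), "phantom radii invalid")
  chk(ph$shellThickness > 0 && ph$shellThickness < min(ph$outerRadii),
      "phantom shell thickness invalid")
  chk(ph$defectRadius > 0, "defect radius must be positive")
  chk(config$ct$spacing > 0, "CT spacing must be positive")
  imp <- config$implant
  chk(imp$targetPorosity > 0 && imp$targetPorosity < 1,
      "targetPorosity must be a fraction in (0, 1)")
  chk(imp$thickness > 0, "implant thickness must be positive")
  chk(imp$rimWidth >= 0, "rimWidth must be >= 0")
  chk(config$fea$totalLoad >= 0 && config$fea$loadArea > 0, "FEA load settings invalid")
  chk(config$vas$mean >= 1 && config$vas$mean <= 5, "VAS mean must be in [1, 5]")
  chk(config$vas$sd >= 0, "VAS sd must be >= 0")
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Values merge over [defaultConfig()]; the result is validated.
#'
#' @param path YAML file
#' @return configuration list
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(defaultConfig(), user)
  validateConfig(config)
  config
}

.stageLog <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

.runStage <- function(stage, verbose, expr) {
  t0 <- proc.time()[3]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  .stageLog(verbose, stage, "done in %.1f s", proc.time()[3] - t0)
  out
}

#' Run the complete implant pipeline
#'
#' Executes phantom generation, CT synthesis, segmentation, defect
#' creation, mirror reconstruction, porous implant design, the FE strength
#' check and the fitting-accuracy analysis; optionally writes all stage
#' artifacts (STL / NIfTI / XYZ / CSV / VTK / JSON) and returns the run
#' manifest.
#'
#' @param config configuration list (see [defaultConfig()])
#' @param outDir output directory for artifacts (`NULL` = keep in memory)
#' @param verbose per-stage progress messages
#' @return manifest list: `config`, `version`, `metrics`, `artifacts` and
#'   per-stage outputs in `$objects`
#' @export
runPipeline <- function(config = defaultConfig(), outDir = NULL, verbose = TRUE) {
  validateConfig(config)
  seed <- as.integer(config$seed)
  artifacts <- character(0)
  saveMesh <- function(mesh, name) {
    if (!is.null(outDir)) {
      path <- file.path(outDir, paste0(name, ".stl"))
      writeSTL(mesh, path)
      artifacts[[name]] <<- path
    }
  }
  if (!is.null(outDir) && !dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  ph <- config$phantom
  spec <- PhantomSpec(outerRadii = ph$outerRadii, shellThickness = ph$shellThickness,
                      asymmetryAmplitude = ph$asymmetryAmplitude,
                      defectCenter = ph$defectCenter, defectRadius = ph$defectRadius,
                      seed = seed)
  clean <- .runStage("phantom", verbose, makeSkullPhantom(spec))
  saveMesh(clean, "phantom_clean")

  ct <- .runStage("ct", verbose, voxelizeToCT(
    clean, spacing = config$ct$spacing, boneHU = config$ct$boneHU,
    backgroundHU = config$ct$backgroundHU, noiseSD = config$ct$noiseSD,
    seed = seed + 1L))
  if (!is.null(outDir)) {
    path <- file.path(outDir, "ct_volume.nii.gz")
    writeVolumeNIfTI(ct, path)
    artifacts[["ct_volume"]] <- path
  }

  segSkull <- .runStage("segment", verbose, {
    mask <- thresholdSegment(ct, lower = config$segmentation$lowerHU,
                             upper = config$segmentation$upperHU)
    mask <- regionGrow(mask, "largest")
    maskToMesh(mask, smoothIterations = config$segmentation$smoothIterations)
  })
  saveMesh(segSkull, "skull_segmented")

  defective <- .runStage("defect", verbose, carveDefect(
    segSkull, ph$defectCenter, ph$defectRadius,
    voxel = config$reconstruction$booleanVoxel))
  saveMesh(defective, "skull_defective")

  recon <- .runStage("reconstruct", verbose, reconstructSkull(
    defective, wrapVoxel = config$reconstruction$wrapVoxel))
  saveMesh(recon$defectFree, "skull_reconstructed")
  saveMesh(recon$template, "implant_template")

  imp <- config$implant
  model <- .runStage("design", verbose, designImplant(
    recon$template, recon$defectFree, thickness = imp$thickness,
    rimWidth = imp$rimWidth, cellSize = imp$cellSize,
    targetPorosity = imp$targetPorosity, screwDiameter = imp$screwDiameter,
    voxel = imp$shellVoxel, latticeVoxel = imp$latticeVoxel))
  design <- attr(model, "design")
  saveMesh(model@solidRim, "implant_rim")
  saveMesh(model@porousCore, "implant_core")
  saveMesh(model@scaffold, "implant_scaffold")

  poreStats <- .runStage("pore_metrology", verbose, measurePoreDiameter(
    model@scaffold, model@porousCore, nSamples = 5, seed = seed + 2L))

  implantSolid <- .runStage("implant_solid", verbose, mergeAndWrap(
    list(model@solidRim, model@porousCore), wrapVoxel = imp$shellVoxel,
    closingRadius = 1L))
  saveMesh(implantSolid, "implant_solid")

  feaCfg <- config$fea
  feaOut <- .runStage("fea", verbose, {
    fem <- buildFEModel(defective, implantSolid, voxelSize = feaCfg$voxelSize)
    fem <- applyBCs(fem, fixedSlabHeight = feaCfg$fixedSlabHeight,
                    totalLoad = feaCfg$totalLoad, loadArea = feaCfg$loadArea)
    res <- solveLinearStatic(fem)
    list(model = fem, result = res, summary = summarizeFEA(res, fem))
  })
  if (!is.null(outDir)) {
    path <- file.path(outDir, "fea_result.vtk")
    writeVTK(feaOut$model, feaOut$result, path)
    artifacts[["fea_result"]] <- path
  }

  fit <- config$fitting
  fitting <- .runStage("fitting", verbose, {
    fabricated <- simulateManufacturing(recon$defectFree,
                                        amplitude = fit$manufacturingAmplitude,
                                        correlationLength = fit$correlationLength,
                                        seed = seed + 3L)
    ang <- fit$scanPoseAngleDeg * pi / 180
    pose <- RigidTransform(rbind(c(cos(ang), -sin(ang), 0),
                                 c(sin(ang), cos(ang), 0),
                                 c(0, 0, 1)), fit$scanPoseTranslation)
    cloud <- simulateScan(fabricated, pointsPerMm2 = fit$scanDensity,
                          noiseSD = fit$scanNoiseSD, pose = pose, seed = seed + 4L)
    ali <- bestFitAlign(cloud, segSkull)
    report <- decomposeAccuracy(segSkull, recon$defectFree, ali$aligned,
                                nSample = fit$nSample, seed = seed + 5L)
    roi <- rbind(ph$defectCenter - ph$defectRadius - fit$roiDilation,
                 ph$defectCenter + ph$defectRadius + fit$roiDilation)
    report@roiDeviation <- as.numeric(roiDeviation(ali$aligned, segSkull, roi))
    # gaps between the implant's outer opening and the cavity opening,
    # both taken on the skull's outer table
    implantOpening <- extractOuterSurface(implantSolid, recon$defectFree)
    cavityOpening <- extractOuterSurface(recon$template, recon$defectFree)
    gaps <- gapAnalysis(implantOpening, cavityOpening)
    list(cloud = cloud, alignment = ali, report = report, gaps = gaps)
  })
  if (!is.null(outDir)) {
    path <- file.path(outDir, "scan_cloud.xyz")
    writeXYZ(fitting$cloud, path)
    artifacts[["scan_cloud"]] <- path
  }

  vasCfg <- config$vas
  vas <- .runStage("vas", verbose, {
    scores <- simulateVAS(vasCfg$nExperts, vasCfg$nReplicates, vasCfg$mean,
                          vasCfg$sd, seed = seed + 6L)
    list(scores = scores, test = masTest(scores, mu0 = vasCfg$mu0,
                                         alpha = vasCfg$alpha))
  })
  if (!is.null(outDir)) {
    path <- file.path(outDir, "vas_scores.csv")
    writeVASTable(vas$scores, path)
    artifacts[["vas_scores"]] <- path
  }

  metrics <- list(
    corePorosityPercent = design$corePorosityPercent,
    implantPorosityPercent = design$implantPorosityPercent,
    V1 = design$V1, V2 = design$V2,
    strutRadius = design$strutRadius,
    poreDiameterMeanUm = poreStats$mean,
    poreDiameterSamplesUm = poreStats$samples,
    maxVonMisesMPa = feaOut$result@maxVonMises,
    implantMaxVonMisesMPa = with(feaOut$summary$regions,
                                 maxVonMises[label == "implant"]),
    maxDeformationMm = feaOut$result@maxDisplacement,
    equilibriumResidual = feaOut$result@reactionResidual,
    feaPass = feaOut$summary$pass,
    modelingAccuracyMm = fitting$report@modelingComponent,
    manufacturingAccuracyMm = fitting$report@manufacturingComponent,
    totalAccuracyMm = fitting$report@totalAsSum,
    totalAccuracyDirectMm = fitting$report@totalDirect,
    roiDeviationMm = fitting$report@roiDeviation,
    alignmentRMSmm = fitting$alignment$rms,
    gapXmm = unname(fitting$gaps@gap["x"]),
    gapYmm = unname(fitting$gaps@gap["y"]),
    implantExtentXmm = unname(fitting$gaps@implantExtent["x"]),
    implantExtentYmm = unname(fitting$gaps@implantExtent["y"]),
    mas = vas$test@mas,
    masT = vas$test@tStatistic,
    masP = vas$test@pValue,
    masRejectNull = vas$test@rejectNull
  )

  manifest <- list(
    version = as.character(utils::packageVersion("cranioforge")),
    seed = seed,
    config = config,
    metrics = metrics,
    artifacts = as.list(artifacts),
    checksums = if (length(artifacts)) as.list(tools::md5sum(unlist(artifacts))) else list()
  )
  if (!is.null(outDir)) {
    jsonlite::write_json(manifest[c("version", "seed", "metrics", "artifacts",
                                    "checksums")],
                         file.path(outDir, "manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  manifest$objects <- list(clean = clean, segmented = segSkull,
                           defective = defective, reconstruction = recon,
                           implant = model, implantSolid = implantSolid,
                           fea = feaOut, fitting = fitting, vas = vas)
  invisible(manifest)
}
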