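# Fitting-accuracy analysis: best-fit (ICP) alignment, signed surface
# deviation, the outward-deviation statistic, accuracy decomposition into
# modeling + manufacturing components, gap analysis, and the one-sample
# t-test on expert aesthetic scores.

#' Best-fit alignment of a point cloud to a reference mesh
#'
#' Coarse pre-alignment (centroids + principal axes, choosing the proper
#' sign combination with the lowest residual) followed by point-to-surface
#' iterative closest point with point-to-plane rigid updates, which do not
#' stall on tangential sliding the way point-to-point updates do on smooth
#' surfaces.
#'
#' @param test n x 3 point cloud
#' @param reference a [TriMesh-class]
#' @param maxIter,tol iteration controls (tol on the RMS change, mm)
#' @param preAlign run the coarse stage (disable when already roughly aligned)
#' @param sanityRMS flag (warning) when the final RMS exceeds this bound
#' @return list: `transform` (the [RigidTransform-class] applied to `test`),
#'   `aligned` (transformed points), `rms` (mm), `iterations`
#' @export
bestFitAlign <- function(test, reference, maxIter = 60, tol = 1e-9,
                         preAlign = TRUE, sanityRMS = 5) {
  test <- as.matrix(test)
  if (nrow(test) < 3) stop("at least 3 points required for alignment")
  Rtot <- diag(3)
  ttot <- c(0, 0, 0)
  cur <- test
  qh <- cpp_mesh_query_build(reference@vertices, reference@faces)
  if (preAlign) {
    refPts <- sampleSurface(reference, min(5000, max(1000, nrow(test))), seed = 7L)
    ct <- colMeans(cur)
    cr <- colMeans(refPts)
    Vt <- prcomp(cur)$rotation
    Vr <- prcomp(refPts)$rotation
    best <- NULL
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      s3 <- det(Vr %*% diag(c(s1, s2, 1)) %*% t(Vt))
      R0 <- Vr %*% diag(c(s1, s2, sign(s3))) %*% t(Vt)
      if (det(R0) < 0) next
      t0 <- cr - as.vector(R0 %*% ct)
      moved <- sweep(cur %*% t(R0), 2, t0, "+")
      sub <- moved[seq(1, nrow(moved), length.out = min(500, nrow(moved))), , drop = FALSE]
      rms <- sqrt(mean(cpp_mesh_query(qh, sub)$distance^2))
      if (is.null(best) || rms < best$rms) best <- list(R = R0, t = t0, rms = rms)
    }
    Rtot <- best$R
    ttot <- best$t
    cur <- sweep(cur %*% t(Rtot), 2, ttot, "+")
  }
  faceNormals <- .faceGeometry(reference)$normal
  rmsPrev <- Inf
  iterations <- 0L
  for (it in seq_len(maxIter)) {
    iterations <- it
    cp <- cpp_mesh_query(qh, cur)
    rms <- sqrt(mean(cp$distance^2))
    m <- faceNormals[cp$face, , drop = FALSE]
    e <- rowSums(m * (cur - cp$point))
    J <- cbind(cur[, 2] * m[, 3] - cur[, 3] * m[, 2],
               cur[, 3] * m[, 1] - cur[, 1] * m[, 3],
               cur[, 1] * m[, 2] - cur[, 2] * m[, 1],
               m)
    x <- tryCatch(solve(crossprod(J) + 1e-10 * diag(6), -crossprod(J, e)),
                  error = function(err) rep(0, 6))
    omega <- x[1:3]
    th <- sqrt(sum(omega^2))
    Rm <- if (th < 1e-15) diag(3) else {
      k <- omega / th
      K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
      diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    }
    cur <- sweep(cur %*% t(Rm), 2, x[4:6], "+")
    Rtot <- Rm %*% Rtot
    ttot <- as.vector(Rm %*% ttot) + x[4:6]
    if (abs(rmsPrev - rms) < tol) break
    rmsPrev <- rms
  }
  rms <- sqrt(mean(cpp_mesh_query(qh, cur)$distance^2))
  if (rms > sanityRMS)
    warning(sprintf("alignment RMS %.2f mm exceeds the sanity bound %.2f mm", rms,
                    sanityRMS))
  list(transform = RigidTransform(Rtot, ttot), aligned = cur, rms = rms,
       iterations = iterations)
}

#' Signed point-to-surface deviation
#'
#' Distance from each test point to the nearest reference surface point,
#' positive when the test point lies outside the reference solid (exact
#' ray-parity sign for watertight references).
#'
#' @param test n x 3 points, or a [TriMesh-class] (sampled with `nSample`
#'   area-uniform points)
#' @param reference watertight [TriMesh-class]
#' @param nSample samples when `test` is a mesh
#' @param seed sampling seed
#' @return numeric vector of signed distances (mm); the evaluated points
#'   are attached as attribute `"points"`
#' @export
signedDeviation <- function(test, reference, nSample = 20000, seed = 1L) {
  pts <- if (is(test, "TriMesh")) {
    p <- sampleSurface(test, nSample, seed = seed)
    unclass(p)[seq_len(nrow(p)), , drop = FALSE]
  } else as.matrix(test)
  res <- distanceToMesh(pts, reference, signed = TRUE)
  out <- res$distance
  attr(out, "points") <- pts
  out
}

#' Mean outward deviation
#'
#' The fitting-accuracy statistic: the mean of the strictly positive
#' (outward) signed deviations; points at or inside the reference are
#' excluded.  When nothing lies outside, returns 0 with attribute
#' `noPositive = TRUE`.
#'
#' @param devs signed deviations (mm), e.g. from [signedDeviation()]
#' @return mean outward deviation (mm); attribute `fractionPositive`
#' @export
meanOutwardDeviation <- function(devs) {
  if (!length(devs)) stop("empty deviation vector")
  pos <- devs[devs > 0]
  out <- if (length(pos)) mean(pos) else 0
  attr(out, "fractionPositive") <- length(pos) / length(devs)
  if (!length(pos)) attr(out, "noPositive") <- TRUE
  out
}

#' Outward deviation restricted to a region of interest
#'
#' @param test points or mesh (as in [signedDeviation()])
#' @param reference watertight [TriMesh-class]
#' @param roi 2 x 3 matrix: rows are the lower and upper corners of the
#'   ROI box (mm)
#' @param ... passed to [signedDeviation()]
#' @return mean outward deviation within the ROI (mm)
#' @export
roiDeviation <- function(test, reference, roi, ...) {
  devs <- signedDeviation(test, reference, ...)
  pts <- attr(devs, "points")
  roi <- as.matrix(roi)
  inRoi <- pts[, 1] >= roi[1, 1] & pts[, 1] <= roi[2, 1] &
    pts[, 2] >= roi[1, 2] & pts[, 2] <= roi[2, 2] &
    pts[, 3] >= roi[1, 3] & pts[, 3] <= roi[2, 3]
  if (!any(inRoi)) stop("ROI contains no test points")
  meanOutwardDeviation(devs[inRoi])
}

#' Decompose total fitting accuracy into modeling + manufacturing parts
#'
#' The modeling component is the mean outward deviation of the designed
#' reconstruction against the clean reference; the manufacturing component
#' that of the scanned (fabricated) surface against the design.  The total
#' is reported both as the sum of the components (the decomposition
#' convention) and as the directly measured scanned-vs-clean deviation.
#'
#' @param clean clean reference skull [TriMesh-class]
#' @param designed designed reconstruction [TriMesh-class]
#' @param scanned scanned surface: points or [TriMesh-class], aligned to
#'   `clean`
#' @param nSample samples per comparison
#' @param seed sampling seed
#' @param sanity error when mean absolute deviation exceeds this (mm) --
#'   catches misaligned inputs
#' @return a [DeviationReport-class]
#' @export
decomposeAccuracy <- function(clean, designed, scanned, nSample = 20000,
                              seed = 1L, sanity = 10) {
  devModel <- signedDeviation(designed, clean, nSample = nSample, seed = seed)
  devManuf <- signedDeviation(scanned, designed, nSample = nSample, seed = seed + 1L)
  devTotal <- signedDeviation(scanned, clean, nSample = nSample, seed = seed + 2L)
  if (mean(abs(devTotal)) > sanity)
    stop("mean absolute deviation ", sprintf("%.1f", mean(abs(devTotal))),
         " mm; inputs appear misaligned")
  modeling <- as.numeric(meanOutwardDeviation(devModel))
  manufacturing <- as.numeric(meanOutwardDeviation(devManuf))
  total <- as.numeric(meanOutwardDeviation(devTotal))
  new("DeviationReport",
      meanOutward = total,
      meanSigned = mean(devTotal),
      fractionPositive = attr(meanOutwardDeviation(devTotal), "fractionPositive"),
      modelingComponent = modeling,
      manufacturingComponent = manufacturing,
      totalAsSum = modeling + manufacturing,
      totalDirect = total,
      roiDeviation = NA_real_,
      deviations = as.numeric(devTotal))
}

#' Gap analysis between implant and cavity
#'
#' Axis-aligned extents (widths) of the implant and of the defect-cavity
#' opening, and the per-axis gap, cavity minus implant.
#'
#' @param implant implant [TriMesh-class]
#' @param cavity cavity-opening [TriMesh-class] (e.g. the implant template
#'   in the skull frame)
#' @return a [GapReport-class]
#' @export
gapAnalysis <- function(implant, cavity) {
  if (nFaces(cavity) == 0) stop("cavity mesh is empty")
  if (nFaces(implant) == 0) stop("implant mesh is empty")
  ei <- apply(implant@vertices[, 1:2, drop = FALSE], 2, function(v) diff(range(v)))
  ec <- apply(cavity@vertices[, 1:2, drop = FALSE], 2, function(v) diff(range(v)))
  names(ei) <- names(ec) <- c("x", "y")
  new("GapReport", implantExtent = ei, cavityExtent = ec, gap = ec - ei)
}

#' One-sample t-test on the mean aesthetic score (MAS)
#'
#' One-sided test of H0: MAS <= mu0 against Ha: MAS > mu0.  The
#' observation unit is the per-expert mean across replicates (so n equals
#' the number of experts); `unit = "rating"` treats every rating as an
#' observation instead.
#'
#' @param scores experts x replicates integer matrix (1..5)
#' @param mu0 null value (default 3, "satisfactory")
#' @param alpha significance level
#' @param unit "expert" (default) or "rating"
#' @return a [MASResult-class]
#' @export
masTest <- function(scores, mu0 = 3, alpha = 0.05, unit = c("expert", "rating")) {
  unit <- match.arg(unit)
  scores <- as.matrix(scores)
  if (any(scores < 1 | scores > 5)) stop("scores must lie in 1..5")
  x <- if (unit == "expert") rowMeans(scores) else as.vector(scores)
  n <- length(x)
  if (n < 2) stop("at least 2 observations required")
  mas <- mean(x)
  s <- sd(x)
  if (s == 0) {
    reject <- (mas > mu0) && alpha > 0
    return(new("MASResult", mas = mas, tStatistic = NA_real_, pValue = NA_real_,
               rejectNull = reject, n = as.integer(n), alpha = alpha, mu0 = mu0,
               degenerate = TRUE))
  }
  t <- (mas - mu0) / (s / sqrt(n))
  p <- pt(t, df = n - 1, lower.tail = FALSE)
  new("MASResult", mas = mas, tStatistic = t, pValue = p,
      rejectNull = p < alpha, n = as.integer(n), alpha = alpha, mu0 = mu0,
      degenerate = FALSE)
}

setMethod("show", "DeviationReport", function(object) {
  cat(sprintf("DeviationReport (mm): total %.4f (sum %.4f) = modeling %.4f + manufacturing %.4f\n",
              object@totalDirect, object@totalAsSum, object@modelingComponent,
              object@manufacturingComponent))
  cat(sprintf("  mean signed %.4f, fraction outward %.2f", object@meanSigned,
              object@fractionPositive))
  if (!is.na(object@roiDeviation)) cat(sprintf(", ROI %.4f", object@roiDeviation))
  cat("\n")
})

setMethod("show", "GapReport", function(object) {
  cat(sprintf("GapReport (mm): implant %.2f x %.2f, cavity %.2f x %.2f, gaps (%.3f, %.3f)\n",
              object@implantExtent[1], object@implantExtent[2],
              object@cavityExtent[1], object@cavityExtent[2],
              object@gap[1], object@gap[2]))
})

setMethod("show", "MASResult", function(object) {
  cat(sprintf("MAS = %.2f (n = %d): ", object@mas, object@n))
  if (object@degenerate) {
    cat("zero variance; decision by direct comparison: ")
  } else {
    cat(sprintf("t = %.3f, one-sided p = %.4g: ", object@tStatistic, object@pValue))
  }
  cat(if (object@rejectNull) "reject H0 (MAS > mu0)\n" else "cannot reject H0\n")
})
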