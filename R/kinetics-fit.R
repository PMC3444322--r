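#' @include kinetics-forward.R
NULL

#' Fit cerebral blood flow from a dynamic [15O]H2O scan
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) of the one-tissue
#' Kety model to the frame-averaged tissue curve, estimating flow and,
#' optionally, the partition coefficient and an additional tracer-arrival
#' delay relative to the recorded arterial input.  Frames are weighted by
#' their duration.
#'
#' @param scan a [DynamicScan-class] with tracer `"H2O"` and an AIF attached
#' @param fitLambda fit the partition coefficient (default) or fix it
#' @param fitDelay fit a regional arrival delay (default) or fix it at 0
#' @param lambda fixed/starting value of the partition coefficient (mL/mL)
#' @param startCbf starting value for CBF (mL/min/100 mL)
#' @param voxel row of the activity matrix to fit (ROI scans have one row)
#' @param dt internal integration step (s)
#' @return a list with elements `cbf` (mL/min/100 mL), `lambda`, `delay`
#'   (s), `converged`, `rss`, and `message`.  A degenerate or
#'   non-convergent fit is returned flagged (`converged = FALSE`, `cbf =
#'   NA`) with a warning, never as a silent zero.
#' @examples
#' sch <- defaultFrameSchedule("H2O")
#' scan <- simulateH2oTac(32, 0.9, aifModel(), sch[, 1], sch[, 2])
#' fitCBF(scan)$cbf
#' @export
fitCBF <- function(scan, fitLambda = TRUE, fitDelay = TRUE, lambda = 0.9,
                   startCbf = 40, voxel = 1L, dt = .GRID_DT) {
  stopifnot(is(scan, "DynamicScan"))
  if (tracer(scan) != "H2O") stop("fitCBF needs an H2O scan")
  if (length(scan@aif) < 1) stop("scan carries no arterial input model")
  obs <- as.numeric(activity(scan)[voxel, ])
  if (all(obs == 0) || !any(is.finite(obs))) {
    warning("degenerate (all-zero) tissue curve; CBF fit flagged")
    return(list(cbf = NA_real_, lambda = NA_real_, delay = NA_real_,
                converged = FALSE, rss = NA_real_,
                message = "degenerate tissue curve"))
  }
  fs <- frameStart(scan)
  fd <- frameDuration(scan)
  tg <- .modelGrid(fs, fd, dt)
  ca <- sampleAIF(scan@aif[[1]], tg)
  w <- sqrt(fd / mean(fd))

  predict <- function(cbf, lam, d) {
    cas <- if (d == 0) ca else
      stats::approx(tg, ca, xout = tg - d, rule = 2, yleft = 0)$y
    f <- .flowPerSec(cbf)
    tac <- f * .tissueConv(cas, f / lam, tg, dt)
    .frameAverage(tg, tac, fs, fd)
  }

  par0 <- c(cbf = startCbf)
  lower <- c(cbf = 0.1)
  upper <- c(cbf = 200)
  if (fitLambda) {
    par0 <- c(par0, lambda = lambda)
    lower <- c(lower, lambda = 0.5)
    upper <- c(upper, lambda = 1.2)
  }
  if (fitDelay) {
    par0 <- c(par0, delay = 0)
    lower <- c(lower, delay = -10)
    upper <- c(upper, delay = 10)
  }
  resid <- function(p) {
    lam <- if (fitLambda) p[["lambda"]] else lambda
    d <- if (fitDelay) p[["delay"]] else 0
    w * (predict(p[["cbf"]], lam, d) - obs)
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, maxfev = 2000,
                              ftol = 1e-10, ptol = 1e-10))
  ok <- fit$info %in% 1:4 && is.finite(fit$par[["cbf"]])
  if (!ok) warning("CBF fit did not converge: ", fit$message)
  list(cbf = if (ok) unname(fit$par[["cbf"]]) else NA_real_,
       lambda = if (fitLambda) unname(fit$par[["lambda"]]) else lambda,
       delay = if (fitDelay) unname(fit$par[["delay"]]) else 0,
       converged = ok, rss = sum(fit$fvec^2), message = fit$message)
}

#' Fit the oxygen extraction fraction from a dynamic [15O]O2 scan
#'
#' With flow and blood volume fixed (from the water and carbon monoxide
#' studies) the oxygen model is linear in the extraction fraction `E`:
#' \deqn{C(t) = E \, X(t) + B(t), \quad
#'  X = f(C_{a,O_2} \otimes e^{-k_2 t}) - 0.835 V_b R_{Hct} C_{a,O_2},
#'  \quad B = f (C_{a,w} \otimes e^{-k_2 t}) + V_b R_{Hct} C_{a,O_2},}
#' so `E` is obtained by weighted linear least squares on the frame
#' averages.
#'
#' @param scan a [DynamicScan-class] with tracer `"O2"` and both the
#'   whole-blood O2 and recirculating-water input curves attached
#' @param cbf fixed cerebral blood flow (mL/min/100 mL)
#' @param cbv fixed cerebral blood volume (mL/100 mL)
#' @param lambda partition coefficient (mL/mL)
#' @param rHct small-to-large-vessel haematocrit ratio
#' @param voxel row of the activity matrix to fit
#' @param dt internal integration step (s)
#' @return a list with `oef` (percent), `flagged` (TRUE when the estimated
#'   extraction fraction falls outside `[0, 1.5]`), and `rss`
#' @examples
#' sch <- defaultFrameSchedule("O2")
#' aifs <- list(o2 = aifModel(amplitude = 25), water = aifModel(
#'   amplitude = 8, delay = 30, shape = 2, timeToPeak = 40))
#' scan <- simulateO2Tac(0.45, 32, 3.2, 0.9, aifs$o2, aifs$water,
#'                       sch[, 1], sch[, 2])
#' fitOEF(scan, cbf = 32, cbv = 3.2)$oef
#' @export
fitOEF <- function(scan, cbf, cbv, lambda = 0.9, rHct = .R_HCT_DEFAULT,
                   voxel = 1L, dt = .GRID_DT) {
  stopifnot(is(scan, "DynamicScan"))
  if (tracer(scan) != "O2") stop("fitOEF needs an O2 scan")
  if (!all(c("o2", "water") %in% names(scan@aif)))
    stop("missing whole-blood O2 or recirculating-water input curve")
  obs <- as.numeric(activity(scan)[voxel, ])
  fs <- frameStart(scan)
  fd <- frameDuration(scan)
  tg <- .modelGrid(fs, fd, dt)
  caO2 <- sampleAIF(scan@aif[["o2"]], tg)
  caW <- sampleAIF(scan@aif[["water"]], tg)
  f <- .flowPerSec(cbf)
  k2 <- f / lambda
  vb <- cbv / 100
  convO2 <- .tissueConv(caO2, k2, tg, dt)
  convW <- .tissueConv(caW, k2, tg, dt)
  xFrames <- .frameAverage(tg, f * convO2 - .O2_VASC_CORR * vb * rHct * caO2,
                           fs, fd)
  bFrames <- .frameAverage(tg, f * convW + vb * rHct * caO2, fs, fd)
  w <- fd / mean(fd)
  denom <- sum(w * xFrames^2)
  if (denom <= 0) stop("degenerate O2 design: zero extraction signal")
  e <- sum(w * xFrames * (obs - bFrames)) / denom
  flagged <- e < 0 || e > 1.5
  if (flagged)
    warning(sprintf("extraction fraction %.3f outside [0, 1.5]; flagged", e))
  rss <- sum(w * (obs - bFrames - e * xFrames)^2)
  list(oef = 100 * e, flagged = flagged, rss = rss)
}

#' Compute cerebral blood volume from a [15O]CO scan
#'
#' Equilibrium blood-volume equation
#' \deqn{CBV = 100 \, C_{tissue} / (R_{Hct} \, C_{blood}),}
#' with tissue and whole-blood activities averaged over the equilibrium
#' frames (duration weighted).
#'
#' @param scan a [DynamicScan-class] with tracer `"CO"`
#' @param bloodActivity whole-blood activity: either per-frame values or a
#'   single equilibrium value (kBq/mL); defaults to frame averages of the
#'   scan's blood input model
#' @param rHct small-to-large-vessel haematocrit ratio
#' @param frames indices of the equilibrium frames to use (default all)
#' @param voxel row of the activity matrix to use
#' @return CBV in mL/100 mL
#' @examples
#' computeCBV(dynamicScan("CO", c(0, 120, 240), rep(120, 3),
#'                        rep(0.0272 * 30, 3)), bloodActivity = 30)  # 3.2
#' @export
computeCBV <- function(scan, bloodActivity = NULL, rHct = .R_HCT_DEFAULT,
                       frames = NULL, voxel = 1L) {
  stopifnot(is(scan, "DynamicScan"))
  if (tracer(scan) != "CO") stop("computeCBV needs a CO scan")
  if (is.null(frames)) frames <- seq_len(nFrames(scan))
  fs <- frameStart(scan)[frames]
  fd <- frameDuration(scan)[frames]
  if (is.null(bloodActivity)) {
    if (length(scan@aif) < 1)
      stop("no blood activity supplied and no blood input model attached")
    tg <- .modelGrid(frameStart(scan), frameDuration(scan))
    cb <- .frameAverage(tg, sampleAIF(scan@aif[[1]], tg), fs, fd)
  } else if (length(bloodActivity) == 1) {
    cb <- rep(bloodActivity, length(frames))
  } else {
    cb <- bloodActivity[frames]
  }
  w <- fd / sum(fd)
  meanBlood <- sum(w * cb)
  if (meanBlood <= 0) stop("blood activity must be positive")
  meanTissue <- sum(w * as.numeric(activity(scan)[voxel, frames]))
  100 * meanTissue / (rHct * meanBlood)
}

#' Voxelwise parametric CBF/OEF/CBV maps from phantom scans
#'
#' Applies the scalar fits voxel by voxel to co-registered multi-voxel H2O,
#' O2 and CO scans, honouring an infarct mask: masked voxels are fitted as
#' `NA` and excluded from the region summary.  If every voxel of the region
#' is masked the summary is flagged unavailable rather than returned as a
#' number.
#'
#' @param scanH2o,scanO2,scanCo [DynamicScan-class] objects with one row
#'   per voxel (identical voxel counts)
#' @param infarctMask logical vector (or array), `TRUE` for voxels to
#'   exclude; `NULL` for no exclusion
#' @param fitLambda,fitDelay passed to [fitCBF()]
#' @param rHct small-to-large-vessel haematocrit ratio
#' @return a list with `maps` (data.frame: voxel, masked, cbf, lambda, cbv,
#'   oef, converged) and `roiSummary` (list with mean cbf/cbv/oef over
#'   unmasked voxels, `nVoxels`, and `available`)
#' @export
fitParametricMaps <- function(scanH2o, scanO2, scanCo, infarctMask = NULL,
                              fitLambda = TRUE, fitDelay = FALSE,
                              rHct = .R_HCT_DEFAULT) {
  nv <- nrow(activity(scanH2o))
  if (nrow(activity(scanO2)) != nv || nrow(activity(scanCo)) != nv)
    stop("scans disagree on the number of voxels")
  if (is.null(infarctMask)) infarctMask <- rep(FALSE, nv)
  infarctMask <- as.logical(infarctMask)
  if (length(infarctMask) != nv)
    stop("infarct mask does not match the voxel grid")
  maps <- data.frame(voxel = seq_len(nv), masked = infarctMask,
                     cbf = NA_real_, lambda = NA_real_, cbv = NA_real_,
                     oef = NA_real_, converged = FALSE)
  for (v in which(!infarctMask)) {
    fh <- fitCBF(scanH2o, fitLambda = fitLambda, fitDelay = fitDelay,
                 voxel = v)
    if (!fh$converged) next
    cbv <- computeCBV(scanCo, rHct = rHct, voxel = v)
    fo <- fitOEF(scanO2, cbf = fh$cbf, cbv = cbv, lambda = fh$lambda,
                 rHct = rHct, voxel = v)
    maps$cbf[v] <- fh$cbf
    maps$lambda[v] <- fh$lambda
    maps$cbv[v] <- cbv
    maps$oef[v] <- fo$oef
    maps$converged[v] <- TRUE
  }
  keep <- maps$converged
  roi <- if (!any(keep)) {
    list(available = FALSE, nVoxels = 0L,
         cbf = NA_real_, cbv = NA_real_, oef = NA_real_)
  } else {
    list(available = TRUE, nVoxels = sum(keep),
         cbf = mean(maps$cbf[keep]), cbv = mean(maps$cbv[keep]),
         oef = mean(maps$oef[keep]))
  }
  list(maps = maps, roiSummary = roi)
}
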