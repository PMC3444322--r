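#' @include kinetics-forward.R
NULL

#' Forward-simulate voxel phantom scans
#'
#' Builds co-registered multi-voxel H2O, O2 and CO scans from per-voxel
#' true parameter arrays, for exercising the voxelwise fit mode without
#' patient data.  Arrays of any (identical) shape are accepted; the shape
#' is preserved in a `dim3` attribute on the activity matrices.
#'
#' @param cbf,cbv,oef numeric arrays of true values (identical shape);
#'   `oef` in percent
#' @param lambda partition coefficient, scalar or array
#' @param aifs named list with AIF models `h2o`, `o2`, `water`, `co` (as
#'   produced by the cohort generator); any missing entry falls back to a
#'   default model
#' @param noiseScale per-frame Gaussian noise scale (0 = noiseless), as in
#'   the cohort generator
#' @return named list of three multi-voxel [DynamicScan-class] objects
#'   (`H2O`, `O2`, `CO`)
#' @seealso [fitParametricMaps()]
#' @export
simulatePhantomScans <- function(cbf, cbv, oef, lambda = 0.9,
                                 aifs = NULL, noiseScale = 0) {
  shape <- dim(cbf)
  if (is.null(shape)) shape <- length(cbf)
  stopifnot(length(cbv) == length(cbf), length(oef) == length(cbf))
  lambda <- rep_len(lambda, length(cbf))
  if (is.null(aifs)) aifs <- list()
  h2o <- if (!is.null(aifs$h2o)) aifs$h2o else aifModel()
  o2 <- if (!is.null(aifs$o2)) aifs$o2 else
    aifModel(amplitude = 25, shape = 2.5, timeToPeak = 10)
  water <- if (!is.null(aifs$water)) aifs$water else
    aifModel(amplitude = 7.5, delay = 40, shape = 2, timeToPeak = 40)
  co <- if (!is.null(aifs$co)) aifs$co else
    aifModel(amplitude = 30, delay = 20, shape = 1.2, timeToPeak = 150)
  schH <- defaultFrameSchedule("H2O")
  schO <- defaultFrameSchedule("O2")
  schC <- defaultFrameSchedule("CO")
  actH <- t(sapply(seq_along(cbf), function(v) as.numeric(activity(
    simulateH2oTac(cbf[v], lambda[v], h2o, schH[, 1], schH[, 2])))))
  actO <- t(sapply(seq_along(cbf), function(v) as.numeric(activity(
    simulateO2Tac(oef[v] / 100, cbf[v], cbv[v], lambda[v], o2, water,
                  schO[, 1], schO[, 2])))))
  actC <- t(sapply(seq_along(cbf), function(v) as.numeric(activity(
    simulateCoTac(cbv[v], co, schC[, 1], schC[, 2])))))
  mk <- function(tr, act, sch, aifList, o2c = numeric()) {
    attr(act, "dim3") <- shape
    s <- dynamicScan(tr, sch[, 1], sch[, 2], act, aif = aifList,
                     o2Content = o2c)
    if (noiseScale > 0) s <- .addFrameNoise(s, "gaussian_frame", noiseScale)
    s
  }
  list(H2O = mk("H2O", actH, schH, list(blood = h2o)),
       O2 = mk("O2", actO, schO, list(o2 = o2, water = water), 0.18),
       CO = mk("CO", actC, schC, list(blood = co)))
}

#' Write a parametric map as NIfTI
#'
#' Thin wrapper over `RNifti` (Suggests) for exporting voxel maps; the
#' map vector is reshaped with the supplied grid shape.
#'
#' @param values numeric vector of voxel values
#' @param shape integer grid shape, e.g. `c(4, 4, 2)`
#' @param file output `.nii` path
#' @return `file`, invisibly
#' @export
writeMapNifti <- function(values, shape, file) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  arr <- array(values, dim = shape)
  RNifti::writeNifti(RNifti::asNifti(arr), file)
  invisible(file)
}
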