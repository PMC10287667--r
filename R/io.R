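#' @include AllClasses.R accessors.R
NULL

#' Construct a cohort table
#'
#' @param subjectID character vector of unique ids.
#' @param age numeric gestational ages (weeks).
#' @param motion optional named list of motion-trace arrays
#'   (parameters x stacks x timepoints), one per subject.
#' @return a validated [CohortTable-class].
#' @export
cohortTable <- function(subjectID, age, motion = list()) {
  new("CohortTable", subjectID = as.character(subjectID),
      age = as.numeric(age), motion = motion)
}

#' Read a cohort table from TSV
#'
#' The file must contain columns `subject_id` and `age` (gestational weeks).
#' Row order is preserved.
#'
#' @param path path to a tab-separated file.
#' @return a validated [CohortTable-class].
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  tab <- tryCatch(read.delim(path, sep = "\t", stringsAsFactors = FALSE),
                  error = function(e) stop("cohort schema error: ", conditionMessage(e)))
  if (nrow(tab) == 0L || !all(c("subject_id", "age") %in% colnames(tab)))
    stop("cohort schema error: need non-empty TSV with columns subject_id, age")
  age <- suppressWarnings(as.numeric(tab$age))
  if (anyNA(age)) stop("cohort parse error: non-numeric age")
  cohortTable(tab$subject_id, age)
}

#' Write a cohort table to TSV
#'
#' @param cohort a [CohortTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  write.table(data.frame(subject_id = cohort@subjectID, age = cohort@age),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a mask from a logical/numeric 3D array
#'
#' In-mask voxels are ordered lexicographically on their (x, y, z) lattice
#' index; this order is the single source of truth for every N-length vector
#' in the package.
#'
#' @param maskArray 3D array; nonzero entries are in-mask.
#' @param voxelSize numeric length-3 voxel size in mm.
#' @param mirror logical; compute homologous contralateral pairing by
#'   reflection about the mid-plane of the first axis.
#' @return a [GridMask-class].
#' @export
gridMask <- function(maskArray, voxelSize = c(2.2, 2.2, 2.2), mirror = FALSE) {
  stopifnot(length(dim(maskArray)) == 3L)
  idx <- which(maskArray != 0, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  coords <- matrix(as.integer(idx[ord, , drop = FALSE]), ncol = 3)
  m <- new("GridMask", coords = coords, dims = as.integer(dim(maskArray)),
           voxelSize = as.numeric(voxelSize))
  if (mirror) m <- computeMirrorPairs(m)
  m
}

#' Read a binary mask from a NIfTI file
#'
#' @param path NIfTI file with nonzero in-mask voxels.
#' @param mirror see [gridMask()].
#' @return a [GridMask-class] with voxel size taken from the header.
#' @export
readMask <- function(path, mirror = FALSE) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  gridMask(array(as.numeric(img), dim(img)[1:3]), voxelSize = vs,
           mirror = mirror)
}

#' Attach homologous contralateral voxel pairing to a mask
#'
#' Pairs voxel (x, y, z) with (dim_x + 1 - x, y, z); the pairing is an
#' involution and is NA where the reflected voxel is outside the mask.
#'
#' @param mask a [GridMask-class].
#' @return the mask with its `mirrorPair` slot filled.
#' @export
computeMirrorPairs <- function(mask) {
  co <- mask@coords
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  reflected <- cbind(mask@dims[1] + 1L - co[, 1], co[, 2], co[, 3])
  mp <- match(key(reflected), key(co))
  mask@mirrorPair <- as.integer(mp)
  validObject(mask)
  mask
}

#' Convert between mask-order vectors and full-grid volumes
#'
#' @param v numeric N-length vector in mask voxel order.
#' @param mask a [GridMask-class].
#' @param fill value for out-of-mask voxels.
#' @return `vectorToVolume`: a 3D array; `volumeToVector`: an N-length vector.
#' @export
vectorToVolume <- function(v, mask, fill = 0) {
  vol <- array(fill, mask@dims)
  vol[mask@coords] <- v
  vol
}

#' @rdname vectorToVolume
#' @param vol a 3D array on the mask grid.
#' @export
volumeToVector <- function(vol, mask) {
  vol[mask@coords]
}

#' Read a masked 4D series from a NIfTI file
#'
#' Returns the N x T matrix of in-mask voxel timecourses in mask voxel order,
#' which is deterministic and identical across subjects.
#'
#' @param path 4D NIfTI file on the mask grid.
#' @param mask a [GridMask-class].
#' @param subjectID subject identifier to record.
#' @return a [MaskedSeries-class].
#' @export
readMaskedSeries <- function(path, mask, subjectID = basename(path)) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("alignment error: expected a 4D image")
  if (!identical(as.integer(d[1:3]), mask@dims))
    stop("alignment error: image grid ", paste(d[1:3], collapse = "x"),
         " does not match mask grid ", paste(mask@dims, collapse = "x"))
  arr <- array(as.numeric(img), d)
  n <- nrow(mask@coords)
  dat <- matrix(NA_real_, n, d[4])
  flat <- matrix(arr, prod(d[1:3]), d[4])
  lin <- (mask@coords[, 3] - 1L) * (d[1] * d[2]) +
         (mask@coords[, 2] - 1L) * d[1] + mask@coords[, 1]
  dat[] <- flat[lin, ]
  if (anyNA(dat) || !all(is.finite(dat)))
    stop("data error: non-finite values inside the mask")
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  new("MaskedSeries", subjectID = subjectID, data = dat, tr = tr)
}

#' Write a masked series to a 4D NIfTI file
#'
#' @param series a [MaskedSeries-class].
#' @param mask the [GridMask-class] the series lives on.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeMaskedSeries <- function(series, mask, path) {
  d <- c(mask@dims, ncol(series@data))
  arr <- array(0, d)
  lin <- (mask@coords[, 3] - 1L) * (d[1] * d[2]) +
         (mask@coords[, 2] - 1L) * d[1] + mask@coords[, 1]
  flat <- matrix(arr, prod(d[1:3]), d[4])
  flat[lin, ] <- series@data
  img <- RNifti::asNifti(array(flat, d))
  RNifti::pixdim(img) <- c(mask@voxelSize, series@tr)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write a spatial map set to a 4D NIfTI file
#'
#' One volume per component; out-of-mask voxels are written as 0. Values
#' round-trip losslessly through [readMapSet()] at stored precision.
#'
#' @param mapSet a [SpatialMapSet-class] (M >= 1 maps).
#' @param mask the [GridMask-class] the maps live on.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMapSet <- function(mapSet, mask, path) {
  m <- mapSet@maps
  if (nrow(m) < 1L) stop("empty-set error: no maps to write")
  if (!all(is.finite(m))) stop("data error: non-finite map values")
  d <- c(mask@dims, nrow(m))
  flat <- matrix(0, prod(mask@dims), nrow(m))
  lin <- (mask@coords[, 3] - 1L) * (d[1] * d[2]) +
         (mask@coords[, 2] - 1L) * d[1] + mask@coords[, 1]
  flat[lin, ] <- t(m)
  img <- RNifti::asNifti(array(flat, d))
  RNifti::pixdim(img) <- c(mask@voxelSize, 1)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a spatial map set from a 4D NIfTI file
#'
#' @param path 4D NIfTI file written by [writeMapSet()].
#' @param mask the [GridMask-class] the maps live on.
#' @param kind map-set kind to record.
#' @return a [SpatialMapSet-class].
#' @export
readMapSet <- function(path, mask, kind = "matnet") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || !identical(as.integer(d[1:3]), mask@dims))
    stop("alignment error: map grid does not match mask grid")
  flat <- matrix(array(as.numeric(img), d), prod(d[1:3]), d[4])
  lin <- (mask@coords[, 3] - 1L) * (d[1] * d[2]) +
         (mask@coords[, 2] - 1L) * d[1] + mask@coords[, 1]
  new("SpatialMapSet", maps = t(flat[lin, , drop = FALSE]),
      mixing = matrix(0, 0, 0), kind = kind)
}

#' Persist a maturational dense connectome with provenance metadata
#'
#' Dense N x N matrices are stored as a single serialised object carrying the
#' mask fingerprint and design degrees of freedom, so downstream stages can
#' verify provenance before factorising.
#'
#' @param m a [MaturationalDense-class].
#' @param mask the [GridMask-class] used to build it.
#' @param path output path (.rds).
#' @return `path`, invisibly.
#' @export
writeDense <- function(m, mask, path) {
  obj <- list(tValues = m@tValues, beta = m@beta, df = m@df,
              thresholded = m@thresholded, degenerate = m@degenerate,
              maskFingerprint = fingerprint(mask@coords))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a maturational dense connectome saved by [writeDense()]
#'
#' @param path input path.
#' @param mask optional [GridMask-class]; when given, the stored mask
#'   fingerprint is checked against it.
#' @return a [MaturationalDense-class].
#' @export
readDense <- function(path, mask = NULL) {
  obj <- readRDS(path)
  if (!is.null(mask) && !identical(obj$maskFingerprint, fingerprint(mask@coords)))
    stop("provenance error: stored connectome was built on a different mask")
  new("MaturationalDense", tValues = obj$tValues, beta = obj$beta,
      df = obj$df, thresholded = obj$thresholded, degenerate = obj$degenerate)
}

#' Spatially smooth a masked series with a Gaussian kernel
#'
#' Optional pre-stage operation: each volume is unfolded to the full grid,
#' convolved with a separable Gaussian (sigma derived from the FWHM), and
#' re-masked. Synthetic data may already embed smoothness, so this is applied
#' only when configured.
#'
#' @param series a [MaskedSeries-class].
#' @param mask the [GridMask-class] the series lives on.
#' @param fwhm kernel full width at half maximum in mm (default 3).
#' @return a smoothed [MaskedSeries-class].
#' @export
smoothSeries <- function(series, mask, fwhm = 3) {
  sig <- fwhmToSigmaVox(fwhm, mask@voxelSize)
  out <- series@data
  for (t in seq_len(ncol(out))) {
    vol <- vectorToVolume(series@data[, t], mask)
    out[, t] <- volumeToVector(smoothVolume(vol, sig), mask)
  }
  new("MaskedSeries", subjectID = series@subjectID, data = out,
      tr = series@tr)
}
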