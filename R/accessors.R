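#' @include AllClasses.R
NULL

#' Accessors for matnets classes
#'
#' Small generic accessors so downstream code never reaches into slots.
#'
#' @param x an object from this package.
#' @return The requested component; see individual class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setGeneric("nMaps", function(x) standardGeneric("nMaps"))
#' @rdname accessors
#' @export
setGeneric("maps", function(x) standardGeneric("maps"))
#' @rdname accessors
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))
#' @rdname accessors
#' @export
setGeneric("subjectIDs", function(x) standardGeneric("subjectIDs"))
#' @rdname accessors
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))
#' @rdname accessors
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setGeneric("voxelCoords", function(x) standardGeneric("voxelCoords"))
#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setMethod("nVoxels", "GridMask", function(x) nrow(x@coords))
#' @rdname accessors
#' @export
setMethod("nVoxels", "MaskedSeries", function(x) nrow(x@data))
#' @rdname accessors
#' @export
setMethod("nVoxels", "SpatialMapSet", function(x) ncol(x@maps))
#' @rdname accessors
#' @export
setMethod("nSubjects", "CohortTable", function(x) length(x@subjectID))
#' @rdname accessors
#' @export
setMethod("nMaps", "SpatialMapSet", function(x) nrow(x@maps))
#' @rdname accessors
#' @export
setMethod("maps", "SpatialMapSet", function(x) x@maps)
#' @rdname accessors
#' @export
setMethod("maps", "HubMaps", function(x) x@maps)
#' @rdname accessors
#' @export
setMethod("ages", "CohortTable", function(x) x@age)
#' @rdname accessors
#' @export
setMethod("subjectIDs", "CohortTable", function(x) x@subjectID)
#' @rdname accessors
#' @export
setMethod("tValues", "MaturationalDense", function(x) x@tValues)
#' @rdname accessors
#' @export
setMethod("tValues", "AgeEffectMaps", function(x) x@tMaps)
#' @rdname accessors
#' @export
setMethod("seriesData", "MaskedSeries", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelCoords", "GridMask", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("groupLabels", "GroupPartition", function(x) x@labels)

#' Voxel-wise mm coordinates of a mask
#'
#' Lattice coordinates scaled by voxel size; used for parcellation and
#' distance computations.
#'
#' @param mask a [GridMask-class].
#' @return numeric N x 3 matrix of mm coordinates.
#' @export
mmCoords <- function(mask) {
  stopifnot(is(mask, "GridMask"))
  sweep(mask@coords, 2, mask@voxelSize, "*")
}

#' Flag voxels with zero temporal variance
#'
#' @param x a [MaskedSeries-class].
#' @param tol numeric tolerance on the temporal standard deviation.
#' @return logical vector, one entry per voxel.
#' @export
zeroVarianceVoxels <- function(x, tol = 1e-12) {
  stopifnot(is(x, "MaskedSeries"))
  mu <- rowMeans(x@data)
  sqrt(rowMeans((x@data - mu)^2)) < tol
}

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable: K = %d subjects, age %.1f-%.1f weeks%s\n",
              length(object@subjectID), min(object@age), max(object@age),
              if (length(object@motion)) ", with motion traces" else ""))
})

setMethod("show", "GridMask", function(object) {
  cat(sprintf("GridMask: N = %d voxels on %s grid, voxel %s mm%s\n",
              nrow(object@coords), paste(object@dims, collapse = "x"),
              paste(format(object@voxelSize, digits = 3), collapse = "x"),
              if (length(object@mirrorPair)) ", mirror-paired" else ""))
})

setMethod("show", "MaskedSeries", function(object) {
  cat(sprintf("MaskedSeries '%s': %d voxels x %d timepoints (TR = %gs)\n",
              object@subjectID, nrow(object@data), ncol(object@data),
              object@tr))
})

setMethod("show", "MaturationalDense", function(object) {
  cat(sprintf("MaturationalDense: %d x %d t-values, df = %d%s\n",
              nrow(object@tValues), ncol(object@tValues), object@df,
              if (object@thresholded) ", thresholded at 0" else ""))
})

setMethod("show", "SpatialMapSet", function(object) {
  cat(sprintf("SpatialMapSet (%s): M = %d maps over N = %d voxels\n",
              object@kind, nrow(object@maps), ncol(object@maps)))
})

setMethod("show", "MatnetConnectome", function(object) {
  cat(sprintf("MatnetConnectome: %d x %d\n",
              nrow(object@corr), ncol(object@corr)))
})

setMethod("show", "GroupPartition", function(object) {
  cat(sprintf("GroupPartition: G = %d groups, sizes [%s]\n", object@nGroups,
              paste(table(object@labels), collapse = ", ")))
})

setMethod("show", "CouplingTrajectory", function(object) {
  cat(sprintf(
    "CouplingTrajectory: %d subjects, polynomial order %d (BIC-selected)\n",
    nrow(object@table), object@order))
})
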