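#' Accessors for image containers
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `bValues()` returns the b values of a stack, `getVolume()` the volume at
#' one b value, `mapValues()` / `validMask()` the value and validity arrays
#' of a parameter or index map, `mapKind()` its kind, and `cutoffUsed()` the
#' cutoff(s) an index map was built with.
#'
#' @param object a DWIStack, ParameterMap or IndexMap.
#' @param b a b value present in the stack (for `getVolume`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))

#' @rdname accessors
#' @export
setGeneric("getVolume", function(object, b) standardGeneric("getVolume"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("mapKind", function(object) standardGeneric("mapKind"))

#' @rdname accessors
#' @export
setGeneric("cutoffUsed", function(object) standardGeneric("cutoffUsed"))

#' @rdname accessors
#' @export
setMethod("bValues", "DWIStack", function(object) object@bValues)

#' @rdname accessors
#' @export
setMethod("getVolume", "DWIStack", function(object, b) {
    i <- match(b, object@bValues)
    if (is.na(i))
        stop("stack has no b = ", b, " volume (available: ",
             paste(object@bValues, collapse = ", "), ")")
    object@volumes[[i]]
})

#' @rdname accessors
#' @export
setMethod("mapValues", "ParameterMap", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("mapValues", "IndexMap", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("validMask", "ParameterMap", function(object) object@valid)

#' @rdname accessors
#' @export
setMethod("validMask", "IndexMap", function(object) object@valid)

#' @rdname accessors
#' @export
setMethod("mapKind", "ParameterMap", function(object) object@kind)

#' @rdname accessors
#' @export
setMethod("mapKind", "IndexMap", function(object) object@kind)

#' @rdname accessors
#' @export
setMethod("cutoffUsed", "IndexMap", function(object) object@cutoff)

#' @rdname accessors
#' @param value replacement validity mask
#' @export
analysedVoxels <- function(roi) roi@voxels & !roi@exclusion

#' ROI constructor
#'
#' Build an [ROIMask-class] from a logical membership array (or voxel index
#' matrix) and an optional exclusion array.
#'
#' @param lesionID character identifier.
#' @param voxels logical array, or an n x 3 integer matrix of voxel indices
#'   (1-based) together with `dim`.
#' @param exclusion optional logical array (default: nothing excluded).
#' @param dim grid dimensions, required when `voxels` is an index matrix.
#' @return An [ROIMask-class].
#' @export
ROIMask <- function(lesionID, voxels, exclusion = NULL, dim = NULL) {
    if (is.matrix(voxels)) {
        stopifnot(!is.null(dim), ncol(voxels) == 3L)
        arr <- array(FALSE, dim)
        arr[voxels] <- TRUE
        voxels <- arr
    }
    if (is.null(exclusion)) exclusion <- array(FALSE, dim(voxels))
    new("ROIMask", lesionID = as.character(lesionID), voxels = voxels,
        exclusion = exclusion)
}
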