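#' @import methods
NULL

#' Multi-b-value diffusion-weighted image stack
#'
#' Holds one co-registered scalar volume per diffusion weighting (b value).
#' All volumes must share the same grid and the b values must be strictly
#' increasing. Mapping with the simplified IVIM approximations requires the
#' stack to contain b = 0, 50 and 800 s/mm^2; additional b values (e.g. 250)
#' may be present and are ignored by the estimators.
#'
#' @slot bValues numeric vector of b values in s/mm^2, strictly increasing.
#' @slot volumes list of 3-D numeric arrays, one per b value, identical dims.
#' @slot spacing numeric length-3 voxel spacing in mm.
#'
#' @seealso [simulateDWI()], [computeDprime()], [computeADC()]
#' @export
setClass("DWIStack",
    representation(bValues = "numeric", volumes = "list", spacing = "numeric"),
    prototype(spacing = c(1, 1, 1)))

setValidity("DWIStack", function(object) {
    msg <- character()
    if (length(object@bValues) != length(object@volumes))
        msg <- c(msg, "one volume per b value required")
    if (any(object@bValues < 0)) msg <- c(msg, "b values must be >= 0")
    if (is.unsorted(object@bValues, strictly = TRUE))
        msg <- c(msg, "b values must be strictly increasing")
    dims <- lapply(object@volumes, dim)
    if (length(dims) > 1L && !all(vapply(dims, identical, logical(1), dims[[1]])))
        msg <- c(msg, "all volumes must share the same grid")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be three positive numbers")
    if (length(msg)) msg else TRUE
})

#' Voxel-wise IVIM parameter map
#'
#' A single scalar map of kind \code{"Dprime"}, \code{"fprime"} or
#' \code{"ADC"} plus a validity mask. Values are held in internal SI-like
#' units (mm^2/s for Dprime/ADC, unitless for fprime); the conventional
#' display scalings (x1e-6 mm^2/s, x1e-3) are applied only at I/O and in
#' printed summaries. Voxels where the estimator is undefined (non-positive
#' signals) are flagged invalid rather than clamped.
#'
#' @slot kind character, one of "Dprime", "fprime", "ADC".
#' @slot values 3-D numeric array.
#' @slot valid 3-D logical array, same dims as values.
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @export
setClass("ParameterMap",
    representation(kind = "character", values = "array", valid = "array",
                   spacing = "numeric"),
    prototype(spacing = c(1, 1, 1)))

setValidity("ParameterMap", function(object) {
    msg <- character()
    if (!object@kind %in% c("Dprime", "fprime", "ADC"))
        msg <- c(msg, "kind must be Dprime, fprime or ADC")
    if (!identical(dim(object@values), dim(object@valid)))
        msg <- c(msg, "values and valid must share dims")
    if (!is.logical(object@valid))
        msg <- c(msg, "valid must be logical")
    v <- object@values[object@valid]
    if (length(v) && any(!is.finite(v)))
        msg <- c(msg, "values must be finite wherever valid")
    if (length(msg)) msg else TRUE
})

#' Two-colour binary index map
#'
#' Voxel values are exactly 0 (green, benign-like) or 100 (red,
#' malignant-like), produced by thresholding a parameter map at a cutoff
#' (strictly-less comparison) or by combining two index maps. The validity
#' mask is inherited from the source parameter map(s); invalid voxels carry
#' no colour.
#'
#' @slot kind character, one of "I_D", "I_f", "I_ADC", "I_Df".
#' @slot values 3-D numeric array with entries in {0, 100}.
#' @slot valid 3-D logical array.
#' @slot cutoff named numeric, the cutoff(s) that produced the map
#'   (internal units).
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @export
setClass("IndexMap",
    representation(kind = "character", values = "array", valid = "array",
                   cutoff = "numeric", spacing = "numeric"),
    prototype(spacing = c(1, 1, 1)))

setValidity("IndexMap", function(object) {
    msg <- character()
    if (!object@kind %in% c("I_D", "I_f", "I_ADC", "I_Df"))
        msg <- c(msg, "kind must be I_D, I_f, I_ADC or I_Df")
    if (!identical(dim(object@values), dim(object@valid)))
        msg <- c(msg, "values and valid must share dims")
    v <- object@values[object@valid]
    if (length(v) && !all(v %in% c(0, 100)))
        msg <- c(msg, "valid voxel values must be exactly 0 or 100")
    if (length(msg)) msg else TRUE
})

#' Region of interest for one lesion
#'
#' A voxel set for one lesion (conventionally a 2-D ROI on a single
#' representative slice, as in routine liver DWI reading) with an optional
#' exclusion subset (necrosis / cystic components / scars removed from
#' analysis). The analysed set is the voxel set minus the exclusion and must
#' be non-empty.
#'
#' @slot lesionID character identifier.
#' @slot voxels 3-D logical array marking ROI membership.
#' @slot exclusion 3-D logical array, subset of voxels, removed from analysis.
#' @export
setClass("ROIMask",
    representation(lesionID = "character", voxels = "array",
                   exclusion = "array"))

setValidity("ROIMask", function(object) {
    msg <- character()
    if (!identical(dim(object@voxels), dim(object@exclusion)))
        msg <- c(msg, "voxels and exclusion must share dims")
    if (any(object@exclusion & !object@voxels))
        msg <- c(msg, "exclusion must be a subset of the ROI voxel set")
    if (!any(object@voxels & !object@exclusion))
        msg <- c(msg, "analysed set (voxels minus exclusion) must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Synthetic phantom scene with per-voxel ground truth
#'
#' Ground truth for the DWI simulator: a label volume (0 = outside body,
#' 1 = liver background, >= 2 numbered lesions), per-voxel true IVIM
#' parameters (S0, D, f, D*), and a lesion table recording class, centre,
#' radius and the lesion-level parameter draws.
#'
#' @slot labels 3-D integer array of region labels.
#' @slot S0,D,f,Dstar 3-D numeric arrays of true per-voxel parameters.
#' @slot lesionTable data.frame with one row per lesion (lesion_id, class,
#'   centre, radius, lesion-level D/f/Dstar means, voxel count).
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @export
setClass("PhantomScene",
    representation(labels = "array", S0 = "array", D = "array", f = "array",
                   Dstar = "array", lesionTable = "data.frame",
                   spacing = "numeric"),
    prototype(spacing = c(1, 1, 1)))

setValidity("PhantomScene", function(object) {
    msg <- character()
    dm <- dim(object@labels)
    for (nm in c("S0", "D", "f", "Dstar"))
        if (!identical(dim(slot(object, nm)), dm))
            msg <- c(msg, sprintf("%s grid must match labels", nm))
    inside <- object@labels != 0L
    if (any(inside)) {
        if (any(object@S0[inside] <= 0)) msg <- c(msg, "S0 must be > 0 inside body")
        if (any(object@D[inside] < 0)) msg <- c(msg, "D must be >= 0")
        fi <- object@f[inside]
        if (any(fi < 0 | fi >= 1)) msg <- c(msg, "f must be in [0, 1)")
        if (any(object@Dstar[inside] < object@D[inside]))
            msg <- c(msg, "Dstar must be >= D")
    }
    lab <- setdiff(sort(unique(as.integer(object@labels))), c(0L, 1L))
    if (!all(lab %in% object@lesionTable$label))
        msg <- c(msg, "every lesion label needs a lesionTable entry")
    if (length(msg)) msg else TRUE
})

#' Cutoff set for index-map construction
#'
#' The three cutoffs used to binarise D', f' and ADC maps, in internal units
#' (mm^2/s, unitless). \code{provenance} records where they came from
#' ("published defaults" or a derivation run id).
#'
#' @slot cD,cF,cADC positive numeric cutoffs.
#' @slot provenance character free text.
#' @export
setClass("CutoffSet",
    representation(cD = "numeric", cF = "numeric", cADC = "numeric",
                   provenance = "character"))

setValidity("CutoffSet", function(object) {
    if (any(c(object@cD, object@cF, object@cADC) <= 0))
        "all cutoffs must be > 0" else TRUE
})

#' Published default cutoffs
#'
#' The reference cutoffs for the simplified-IVIM liver workflow:
#' D' 1529.4e-6 mm^2/s (haemangioma vs other), f' 114.5e-3 (FNH vs other),
#' ADC 1338.5e-6 mm^2/s (benign vs malignant). The published reference
#' values report the f' cutoff inconsistently as 114.4e-3 and 114.5e-3;
#' the tabulated 114.5e-3 is shipped here and the discrepancy is
#' deliberate, not resolved silently.
#'
#' @return A [CutoffSet-class] object.
#' @examples
#' referenceCutoffs()
#' @export
referenceCutoffs <- function() {
    new("CutoffSet", cD = 1529.4e-6, cF = 114.5e-3, cADC = 1338.5e-6,
        provenance = "published defaults")
}

setMethod("show", "DWIStack", function(object) {
    cat("DWIStack:", paste(object@bValues, collapse = ", "),
        "s/mm^2 |", paste(dim(object@volumes[[1]]), collapse = "x"),
        "voxels\n")
})

setMethod("show", "ParameterMap", function(object) {
    v <- object@values[object@valid]
    sc <- if (object@kind == "fprime") 1e3 else 1e6
    un <- if (object@kind == "fprime") "x1e-3" else "x1e-6 mm^2/s"
    cat(sprintf("ParameterMap %s: %s voxels, %d valid; mean %.1f %s\n",
        object@kind, paste(dim(object@values), collapse = "x"),
        sum(object@valid), mean(v) * sc, un))
})

setMethod("show", "IndexMap", function(object) {
    v <- object@values[object@valid]
    cat(sprintf("IndexMap %s: %d valid voxels, %.1f%% red\n", object@kind,
        sum(object@valid), if (length(v)) mean(v) else NA_real_))
})

setMethod("show", "PhantomScene", function(object) {
    cat(sprintf("PhantomScene: %s grid, %d lesions, %d body voxels\n",
        paste(dim(object@labels), collapse = "x"),
        nrow(object@lesionTable), sum(object@labels != 0L)))
})

setMethod("show", "CutoffSet", function(object) {
    cat(sprintf(
        "CutoffSet (%s): D' %.1f x1e-6 mm^2/s, f' %.1f x1e-3, ADC %.1f x1e-6 mm^2/s\n",
        object@provenance, object@cD * 1e6, object@cF * 1e3, object@cADC * 1e6))
})
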