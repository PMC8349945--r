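## ROI-level analysis: map means, percent-red, the translucent-
## hyperintensity display mask, the necrosis/cyst/scar exclusion mask,
## lesion-level malignancy calls, and the visual-judgment surrogate.
## The visual/manual steps of routine reading are replaced by mask
## arithmetic with declared k*SD conventions.

#' ROI mean of a parameter or index map
#'
#' Arithmetic mean over the analysed voxels of the ROI (voxel set minus
#' exclusion subset) that are valid in the map. For an index map the mean
#' equals 100 times the red-voxel fraction ("percent-red").
#'
#' @param map a [ParameterMap-class] or [IndexMap-class].
#' @param roi an [ROIMask-class] on the same grid.
#' @return scalar mean (internal units; percent for index maps).
#' @export
roiMean <- function(map, roi) {
    stopifnot(is(roi, "ROIMask"))
    sel <- analysedVoxels(roi) & validMask(map)
    if (!any(sel))
        stop("ROI '", roi@lesionID,
             "': no valid voxels left after exclusion")
    mean(mapValues(map)[sel])
}

#' Translucent-hyperintensity display mask from the b-800 image
#'
#' Voxels whose b-800 signal exceeds the reference-region mean by more than
#' `kSD` reference standard deviations; used to restrict visual assessment
#' to vital (cellular) tumour tissue, which is hyperintense at b = 800.
#' If the reference region is degenerate (zero SD), the rule falls back to
#' a strict `> mean` comparison with a warning.
#'
#' @param b800 3-D array.
#' @param refMask logical 3-D array sampling normal liver.
#' @param kSD threshold offset in reference SDs (default 2).
#' @return logical 3-D array.
#' @export
hyperintensityMask <- function(b800, refMask, kSD = 2) {
    stopifnot(identical(dim(b800), dim(refMask)), any(refMask))
    m <- mean(b800[refMask])
    s <- stats::sd(b800[refMask])
    if (!is.finite(s) || s == 0) {
        warning("degenerate reference region (sd = 0); using strict > mean")
        return(b800 > m)
    }
    b800 > m + kSD * s
}

#' Necrosis / cyst / scar exclusion mask within an ROI
#'
#' Flags, inside the ROI, voxels that are hyperintense on the b-0 image
#' and/or hypointense on the b-800 image -- the fluid-like pattern of
#' central necrosis, cystic components and scars. Thresholds are k*SD
#' offsets from the ROI-interior statistics: excluded if
#' b0 > median(b0_ROI) + kSD * sd(b0_ROI) or
#' b800 < median(b800_ROI) - kSD * sd(b800_ROI).
#' With `robust = TRUE` the SD is replaced by the MAD.
#'
#' @param b0,b800 3-D arrays on the ROI grid.
#' @param roi an [ROIMask-class].
#' @param kSD threshold offset (default 2).
#' @param robust use median/MAD statistics (default FALSE).
#' @return logical 3-D array, always a subset of the ROI voxel set; may be
#'   empty.
#' @export
exclusionMask <- function(b0, b800, roi, kSD = 2, robust = FALSE) {
    stopifnot(is(roi, "ROIMask"), identical(dim(b0), dim(roi@voxels)),
              identical(dim(b800), dim(roi@voxels)))
    inroi <- roi@voxels
    spread <- if (robust) stats::mad else stats::sd
    m0 <- stats::median(b0[inroi]);   s0 <- spread(b0[inroi])
    m8 <- stats::median(b800[inroi]); s8 <- spread(b800[inroi])
    if (!is.finite(s0)) s0 <- 0
    if (!is.finite(s8)) s8 <- 0
    excl <- inroi & ((b0 > m0 + kSD * s0) | (b800 < m8 - kSD * s8))
    excl
}

#' Attach an exclusion mask to an ROI
#'
#' Convenience wrapper: computes [exclusionMask()] and returns a copy of
#' the ROI with that exclusion applied.
#'
#' @inheritParams exclusionMask
#' @return an [ROIMask-class] with the exclusion subset set.
#' @export
applyExclusion <- function(roi, b0, b800, kSD = 2, robust = FALSE) {
    excl <- exclusionMask(b0, b800, roi, kSD, robust)
    if (!any(roi@voxels & !excl))
        stop("ROI '", roi@lesionID, "': exclusion would empty the ROI")
    new("ROIMask", lesionID = roi@lesionID, voxels = roi@voxels,
        exclusion = excl)
}

#' Lesion-level malignancy call from ROI statistics
#'
#' Decision rules of the quantitative workflow:
#' \describe{
#'   \item{Df_means}{malignant iff the ROI-mean D' and f' are both below
#'     their cutoffs (the combined-parameter rule).}
#'   \item{adc_mean}{malignant iff the ROI-mean ADC is below the ADC cutoff.}
#'   \item{index_pct}{malignant iff the I_Df percent-red exceeds
#'     `pctCutoffDf` (default 50.2; a higher percentage indicates
#'     malignancy; ties are benign, mirroring the strict-less voxel rule).}
#'   \item{iadc_pct}{as index_pct for I_ADC with `pctCutoffADC`
#'     (default 53.4).}
#' }
#'
#' @param record one-row data.frame or list with the ROI means required by
#'   the rule: `mean_Dprime`/`mean_fprime` (internal units), `mean_ADC`,
#'   `pct_IDf`, `pct_IADC`.
#' @param cutoffs a [CutoffSet-class] (default [referenceCutoffs()]).
#' @param rule which decision rule to apply.
#' @param pctCutoffDf,pctCutoffADC percent-red cutoffs for the index rules.
#' @return `"malignant"` or `"benign"`.
#' @examples
#' classifyLesion(list(mean_Dprime = 1057e-6, mean_fprime = 63e-3))
#' @export
classifyLesion <- function(record, cutoffs = referenceCutoffs(),
                           rule = c("Df_means", "adc_mean", "index_pct",
                                    "iadc_pct"),
                           pctCutoffDf = 50.2, pctCutoffADC = 53.4) {
    rule <- match.arg(rule)
    need <- switch(rule,
        Df_means = c("mean_Dprime", "mean_fprime"),
        adc_mean = "mean_ADC",
        index_pct = "pct_IDf",
        iadc_pct = "pct_IADC")
    miss <- need[!vapply(need, function(k)
        !is.null(record[[k]]) && is.finite(record[[k]]), logical(1))]
    if (length(miss))
        stop("record is missing required ROI mean(s): ",
             paste(miss, collapse = ", "))
    mal <- switch(rule,
        Df_means = record$mean_Dprime < cutoffs@cD &&
                   record$mean_fprime < cutoffs@cF,
        adc_mean = record$mean_ADC < cutoffs@cADC,
        index_pct = record$pct_IDf > pctCutoffDf,
        iadc_pct = record$pct_IADC > pctCutoffADC)
    if (mal) "malignant" else "benign"
}

#' Four-point visual-judgment surrogate from red-voxel dominance
#'
#' Maps the percent-red of an index map within the assessed area to the
#' four-point reading scale: red voxels dominating definitely / slightly,
#' green dominating slightly / definitely. Only the 50% majority boundary
#' is anchored in the reading rule (more vs less than half the voxels red);
#' the definite/probable band edges (default 25/75) are a package
#' convention and configurable.
#'
#' Default bands: >= 75 definitely_malignant; (50, 75) probably_malignant;
#' (25, 50] probably_benign; <= 25 definitely_benign. The malignant call is
#' red_fraction > 50.
#'
#' @param redFraction percent of red voxels, in \[0, 100\].
#' @param bands numeric length-3 increasing band edges
#'   (default c(25, 50, 75)).
#' @return list with `rating` (factor on the four-point scale) and `call`
#'   ("malignant"/"benign").
#' @export
visualSurrogate <- function(redFraction, bands = c(25, 50, 75)) {
    if (!is.finite(redFraction) || redFraction < 0 || redFraction > 100)
        stop("redFraction must be in [0, 100]")
    stopifnot(length(bands) == 3L, !is.unsorted(bands, strictly = TRUE))
    levs <- c("definitely_benign", "probably_benign", "probably_malignant",
              "definitely_malignant")
    rating <- if (redFraction >= bands[3]) levs[4]
        else if (redFraction > bands[2]) levs[3]
        else if (redFraction > bands[1]) levs[2]
        else levs[1]
    list(rating = factor(rating, levels = levs),
         call = if (redFraction > bands[2]) "malignant" else "benign")
}
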