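## Lesion-level cohort simulation: many small ROIs pushed through the real
## forward model and estimators, without building full 3-D scenes. This is
## the engine behind cutoff derivation experiments.

#' Reference cohort composition
#'
#' Lesion counts per class of the 109-patient reference cohort (one
#' reference lesion per patient): 32 HCC, 8 CCC, 22 colorectal and 12
#' breast-cancer metastases, 23 haemangiomas, 12 FNHs.
#'
#' @return named integer vector of class counts.
#' @export
referenceLesionCounts <- function() {
    c(HCC = 32L, CCC = 8L, metastasis_CRC = 22L, metastasis_breast = 12L,
      haemangioma = 23L, FNH = 12L)
}

## Largest-remainder allocation of n lesions over the reference proportions;
## deterministic, so repeated cohorts differ only in parameter draws.
allocateClasses <- function(n, counts = referenceLesionCounts()) {
    p <- counts / sum(counts)
    base <- floor(n * p)
    rem <- n - sum(base)
    if (rem > 0) {
        frac <- n * p - base
        extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    rep(names(counts), times = base)
}

#' Simulate a lesion cohort through the estimation chain
#'
#' Draws `n` lesions (classes allocated deterministically in the reference
#' cohort proportions, see [referenceLesionCounts()]), gives each an ROI of
#' `roiVoxels` voxels whose true parameters are the lesion-level draw plus
#' a small within-lesion jitter, evaluates the forward model at
#' b = 0, 50, 800 s/mm^2, optionally adds Rician noise, and runs the actual
#' map estimators ([computeDprime()], [computeFprime()], [computeADC()]) to
#' obtain ROI-mean estimates per lesion. If a [CutoffSet-class] is supplied,
#' the two-colour index maps are also built voxel-wise and their percent-red
#' ROI means recorded.
#'
#' Internally the whole cohort is laid out as a single `roiVoxels x n x 1`
#' stack (one column per lesion), so the per-voxel code path is identical
#' to whole-volume mapping.
#'
#' @param n number of lesions.
#' @param seed integer seed.
#' @param specs class specs, default [defaultClassSpecs()].
#' @param counts class composition, default [referenceLesionCounts()].
#' @param roiVoxels voxels per lesion ROI (default 25, a typical 2-D ROI).
#' @param mode forward-model mode (default `"fully_dephased"`, where the
#'   estimators are exact).
#' @param sigma Rician noise SD (0 = noiseless).
#' @param withinLesionCV relative within-lesion SD for D and f.
#' @param cutoffs optional [CutoffSet-class]; adds index-map percent columns.
#' @return data.frame with one row per lesion: lesion_id, class, malignant,
#'   true_D, true_f, mean_Dprime, mean_fprime, mean_ADC (internal units)
#'   and, with cutoffs, pct_ID, pct_If, pct_IADC, pct_IDf.
#' @examples
#' head(simulateLesionCohort(20, seed = 1))
#' @export
simulateLesionCohort <- function(n, seed = 1, specs = defaultClassSpecs(),
                                 counts = referenceLesionCounts(),
                                 roiVoxels = 25,
                                 mode = c("fully_dephased", "biexponential"),
                                 sigma = 0, withinLesionCV = 0.03,
                                 cutoffs = NULL) {
    mode <- match.arg(mode)
    stopifnot(n >= 2, roiVoxels >= 1)
    set.seed(seed)
    classes <- allocateClasses(n, counts)

    les <- do.call(rbind, lapply(classes, function(cl)
        sampleClassParams(specs[[cl]], 1)))
    cv <- withinLesionCV
    vox <- function(mean, sd, lo, hi = Inf)
        matrix(rtruncnorm(roiVoxels * n,
                          rep(mean, each = roiVoxels),
                          rep(sd, each = roiVoxels), lo, hi),
               nrow = roiVoxels)
    ## per-voxel truths, one column per lesion
    Dv <- vox(les$D, cv * les$D, 1e-9)
    fv <- vox(les$f, cv * les$f, 0, 0.99)
    S0 <- vox(les$S0, cv * les$S0, 1)
    Dsv <- pmax(matrix(rep(les$Dstar, each = roiVoxels), nrow = roiVoxels), Dv)

    bvals <- c(0, 50, 800)
    vols <- lapply(bvals, function(b) {
        v <- forwardSignal(S0, Dv, fv, Dsv, b = b, mode = mode)
        if (sigma > 0) {
            g1 <- stats::rnorm(length(v), 0, sigma)
            g2 <- stats::rnorm(length(v), 0, sigma)
            v <- sqrt((v + g1)^2 + g2^2)
        }
        array(v, c(roiVoxels, n, 1))
    })
    stk <- new("DWIStack", bValues = bvals, volumes = vols)

    dp <- computeDprime(stk)
    fp <- computeFprime(stk, dp)
    adc <- computeADC(stk)

    colMean <- function(map) {
        v <- mapValues(map); v[!validMask(map)] <- NA
        colMeans(matrix(v, nrow = roiVoxels), na.rm = TRUE)
    }
    rec <- data.frame(
        lesion_id = sprintf("L%04d", seq_len(n)),
        class = classes,
        malignant = vapply(classes, function(cl)
            isTRUE(specs[[cl]]$malignant), logical(1)),
        true_D = les$D, true_f = les$f,
        mean_Dprime = colMean(dp),
        mean_fprime = colMean(fp),
        mean_ADC = colMean(adc),
        stringsAsFactors = FALSE)
    rownames(rec) <- NULL

    if (!is.null(cutoffs)) {
        iD <- binarizeMap(dp, cutoffs@cD)
        iF <- binarizeMap(fp, cutoffs@cF)
        iA <- binarizeMap(adc, cutoffs@cADC)
        iDf <- combineDf(iD, iF)
        rec$pct_ID <- colMean(iD)
        rec$pct_If <- colMean(iF)
        rec$pct_IADC <- colMean(iA)
        rec$pct_IDf <- colMean(iDf)
    }
    rec
}
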