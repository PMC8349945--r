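## Simplified IVIM parameter mapping from three b values (0, 50, 800 s/mm^2)
## using explicit approximations instead of biexponential fitting:
##   D'  = [ln S(50) - ln S(800)] / 750          (perfusion suppressed at b>=50)
##   f'  = 1 - S(50)/S(0) * exp(D' * 50)         (signal excess at b = 0)
##   ADC = [ln S(0) - ln S(800)] / 800
## Non-positive signals make a voxel invalid; nothing is floored or clamped,
## since silent clamping would fabricate diffusion values.

requireB <- function(stack, b) {
    miss <- setdiff(b, bValues(stack))
    if (length(miss))
        stop("stack is missing required b value(s): ",
             paste(miss, collapse = ", "))
}

#' Estimated diffusion coefficient map D'
#'
#' Voxel-wise \eqn{D' = [\ln S(b_{50}) - \ln S(b_{800})]/(b_{800}-b_{50})},
#' the monoexponential decay rate between b = 50 and b = 800 s/mm^2. With
#' perfusion largely suppressed above b = 50, D' approximates the true
#' diffusion coefficient. Voxels with non-positive S(50) or S(800) are
#' marked invalid.
#'
#' Extra b values in the stack (e.g. 250 s/mm^2) are ignored.
#'
#' @param stack a [DWIStack-class] containing b = 50 and 800.
#' @return A [ParameterMap-class] of kind "Dprime" (mm^2/s).
#' @examples
#' stk <- new("DWIStack", bValues = c(0, 50, 800),
#'            volumes = list(array(1000, c(2, 2, 1)),
#'                           array(900,  c(2, 2, 1)),
#'                           array(300,  c(2, 2, 1))))
#' mapValues(computeDprime(stk))[1]  # log(3)/750 = 1464.8e-6 mm^2/s
#' @export
computeDprime <- function(stack) {
    requireB(stack, c(50, 800))
    s50 <- getVolume(stack, 50)
    s800 <- getVolume(stack, 800)
    valid <- s50 > 0 & s800 > 0
    vals <- array(0, dim(s50))
    vals[valid] <- (log(s50[valid]) - log(s800[valid])) / 750
    new("ParameterMap", kind = "Dprime", values = vals, valid = valid,
        spacing = stack@spacing)
}

#' Estimated perfusion fraction map f'
#'
#' Voxel-wise \eqn{f' = 1 - S(b_{50})/S(b_0)\,\exp(D' b_{50})}: the relative
#' signal excess at b = 0 beyond the diffusion decay extrapolated back from
#' b = 50. Invalid where S(0) <= 0 or where D' is invalid. The raw value is
#' retained (it can fall below 0 under noise); validity is not affected by
#' sign, and no clipping to \[0, 1\] is applied -- downstream binarisation
#' handles any real value, and clipping would bias ROI means.
#'
#' @param stack a [DWIStack-class] containing b = 0 and 50.
#' @param dprime the D' map computed from the same stack (computed on the
#'   fly when NULL).
#' @return A [ParameterMap-class] of kind "fprime" (unitless).
#' @export
computeFprime <- function(stack, dprime = NULL) {
    requireB(stack, c(0, 50))
    if (is.null(dprime)) dprime <- computeDprime(stack)
    stopifnot(is(dprime, "ParameterMap"), mapKind(dprime) == "Dprime")
    s0 <- getVolume(stack, 0)
    s50 <- getVolume(stack, 50)
    if (!identical(dim(s0), dim(mapValues(dprime))))
        stop("grid mismatch between stack and D' map")
    valid <- s0 > 0 & validMask(dprime)
    dp <- mapValues(dprime)
    vals <- array(0, dim(s0))
    vals[valid] <- 1 - s50[valid] / s0[valid] * exp(dp[valid] * 50)
    new("ParameterMap", kind = "fprime", values = vals, valid = valid,
        spacing = stack@spacing)
}

#' Apparent diffusion coefficient map
#'
#' Voxel-wise \eqn{ADC = [\ln S(b_0) - \ln S(b_{800})]/(b_{800}-b_0)}, the
#' conventional monoexponential decay rate over the full b range. Same
#' validity rules as [computeDprime()].
#'
#' For every voxel valid in all three maps the algebraic identity
#' \eqn{ADC = D' - \ln(1 - f')/800} holds exactly (substitute the D' and f'
#' definitions); it is used as an internal consistency check.
#'
#' @param stack a [DWIStack-class] containing b = 0 and 800.
#' @return A [ParameterMap-class] of kind "ADC" (mm^2/s).
#' @export
computeADC <- function(stack) {
    requireB(stack, c(0, 800))
    s0 <- getVolume(stack, 0)
    s800 <- getVolume(stack, 800)
    valid <- s0 > 0 & s800 > 0
    vals <- array(0, dim(s0))
    vals[valid] <- (log(s0[valid]) - log(s800[valid])) / 800
    new("ParameterMap", kind = "ADC", values = vals, valid = valid,
        spacing = stack@spacing)
}

#' Compute all three simplified-IVIM maps
#'
#' Convenience wrapper returning D', f' and ADC maps from one stack.
#'
#' @param stack a [DWIStack-class] containing b = 0, 50 and 800.
#' @return named list with elements `Dprime`, `fprime`, `ADC`.
#' @export
computeMaps <- function(stack) {
    dp <- computeDprime(stack)
    list(Dprime = dp, fprime = computeFprime(stack, dp),
         ADC = computeADC(stack))
}
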