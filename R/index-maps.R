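## Two-colour index maps: threshold a parameter map at a cutoff (red = 100
## where the value is strictly below the cutoff, green = 0 otherwise),
## combine the D' and f' maps by voxel-wise AND, and render red/green
## overlays on the b-800 image.

indexKindFor <- c(Dprime = "I_D", fprime = "I_f", ADC = "I_ADC")

#' Binarise a parameter map into a two-colour index map
#'
#' A voxel is set to 100 (red, malignant-like) if its parameter value is
#' strictly lower than the cutoff, and to 0 (green, benign-like) otherwise;
#' ties at the cutoff are green. Invalid voxels stay invalid and carry no
#' colour.
#'
#' @param map a [ParameterMap-class].
#' @param cutoff positive scalar in the map's internal units (mm^2/s for
#'   Dprime/ADC, unitless for fprime).
#' @return An [IndexMap-class] of kind I_D, I_f or I_ADC.
#' @examples
#' m <- new("ParameterMap", kind = "Dprime",
#'          values = array(c(1076e-6, 1784e-6), c(2, 1, 1)),
#'          valid = array(TRUE, c(2, 1, 1)))
#' mapValues(binarizeMap(m, 1529.4e-6))  # 100 (red), 0 (green)
#' @export
binarizeMap <- function(map, cutoff) {
    stopifnot(is(map, "ParameterMap"))
    if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
        stop("cutoff must be a single positive number")
    valid <- validMask(map)
    vals <- array(0, dim(valid))
    vals[valid] <- ifelse(mapValues(map)[valid] < cutoff, 100, 0)
    cut <- c(cutoff); names(cut) <- mapKind(map)
    new("IndexMap", kind = indexKindFor[[mapKind(map)]], values = vals,
        valid = valid, cutoff = cut, spacing = map@spacing)
}

#' Combine the D' and f' index maps into I_Df
#'
#' A voxel of the combined map is 100 only if the corresponding voxels of
#' I_D and I_f are both 100 (diffusion and perfusion restriction in the
#' same voxel); otherwise 0. Equivalent to the voxel-wise minimum.
#' A voxel is invalid if it is invalid in either input.
#'
#' @param iD index map of kind "I_D".
#' @param iF index map of kind "I_f".
#' @return An [IndexMap-class] of kind "I_Df".
#' @export
combineDf <- function(iD, iF) {
    stopifnot(is(iD, "IndexMap"), is(iF, "IndexMap"))
    if (mapKind(iD) != "I_D" || mapKind(iF) != "I_f")
        stop("combineDf expects an I_D and an I_f map")
    if (!identical(dim(mapValues(iD)), dim(mapValues(iF))))
        stop("grid mismatch between I_D and I_f")
    valid <- validMask(iD) & validMask(iF)
    vals <- pmin(mapValues(iD), mapValues(iF))
    vals[!valid] <- 0
    new("IndexMap", kind = "I_Df", values = vals, valid = valid,
        cutoff = c(cutoffUsed(iD), cutoffUsed(iF)), spacing = iD@spacing)
}

## grayscale window by percentile range; returns values in [0, 1]
windowSlice <- function(sl, probs = c(0.01, 0.99)) {
    q <- stats::quantile(sl, probs, names = FALSE)
    if (q[2] <= q[1]) return(array(0, dim(sl)))
    pmin(pmax((sl - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Render a red/green index-map overlay on a b-800 slice
#'
#' Blends the windowed (1st-99th percentile) grayscale b-800 slice with
#' red (index value 100) and green (index value 0) inside `displayMask`;
#' outside the mask, and at invalid voxels, the b-800 image shows through
#' unmodified. `alpha = 0` reproduces the pure b-800 slice.
#'
#' @param index an [IndexMap-class].
#' @param b800 3-D array, the b = 800 volume on the same grid.
#' @param slice slice index (third dimension).
#' @param alpha blend factor in \[0, 1\] (default 0.4).
#' @param displayMask logical 3-D array restricting where colour is shown
#'   (e.g. the translucent-hyperintensity mask); default everywhere.
#' @return An H x W x 3 RGB array in \[0, 1\].
#' @seealso [writeOverlayPNG()]
#' @export
renderOverlay <- function(index, b800, slice, alpha = 0.4,
                          displayMask = NULL) {
    stopifnot(is(index, "IndexMap"))
    dm <- dim(mapValues(index))
    if (!identical(dm, dim(b800))) stop("index and b800 must share grid")
    if (slice < 1 || slice > dm[3]) stop("slice out of range")
    if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
    if (is.null(displayMask)) displayMask <- array(TRUE, dm)

    gray <- windowSlice(b800[, , slice])
    rgb <- array(rep(gray, 3), c(dm[1], dm[2], 3))
    m <- displayMask[, , slice] & validMask(index)[, , slice]
    red <- m & (mapValues(index)[, , slice] == 100)
    grn <- m & !red
    for (ch in 1:3) {
        plane <- rgb[, , ch]
        tint <- c(1, 0, 0)[ch] * red + c(0, 1, 0)[ch] * grn
        plane[m] <- (1 - alpha) * plane[m] + alpha * tint[m]
        rgb[, , ch] <- plane
    }
    rgb
}

#' Write an overlay slice to PNG
#'
#' @param index,b800,slice,alpha,displayMask as in [renderOverlay()].
#' @param path output PNG file path.
#' @return invisibly, the path.
#' @export
writeOverlayPNG <- function(index, b800, slice, path, alpha = 0.4,
                            displayMask = NULL) {
    rgb <- renderOverlay(index, b800, slice, alpha, displayMask)
    ## image rows run along y; transpose to raster orientation
    raster <- aperm(rgb, c(2, 1, 3))[dim(rgb)[2]:1, , , drop = FALSE]
    png::writePNG(raster, path)
    invisible(path)
}
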