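## Synthetic liver DWI phantom: class-labelled lesions, biexponential IVIM
## forward model, Rician noise. Geometry is abstract (elliptical-cylinder body, no
## anatomical atlas); its job is to give every downstream stage a ground
## truth, not to look like a liver.

#' Default lesion class specifications
#'
#' Returns the generator's per-class parameter distributions. The true
#' diffusion coefficient D and perfusion fraction f are matched to the
#' published lesion-group statistics of the simplified-IVIM liver cohort:
#' haemangiomas D 1784 +/- 314 x1e-6 mm^2/s, all other classes
#' 1076 +/- 184 x1e-6; FNHs f 164 +/- 58 x1e-3, all other classes
#' 63 +/- 35 x1e-3. D* (not estimated by the workflow, simulated only)
#' defaults to a uniform 10-100 x1e-3 mm^2/s range; S0 to 1000 +/- 100
#' signal units. Liver background uses D = 1.0e-3 mm^2/s, f = 0.10.
#'
#' Parameters are drawn per lesion from truncated normals (truncation at
#' physical bounds: D >= 0, 0 <= f < 1), so that lesion-level ROI means
#' reproduce the published between-lesion distributions.
#'
#' @return Named list of class specs, each a list with fields `class`,
#'   `malignant`, `D_mean`, `D_sd`, `f_mean`, `f_sd`, `Dstar_range`,
#'   `S0_mean`, `S0_sd` (internal units: mm^2/s, unitless, signal units).
#' @examples
#' defaultClassSpecs()[["haemangioma"]]$D_mean  # 1.784e-3 mm^2/s
#' @export
defaultClassSpecs <- function() {
    mk <- function(class, malignant, Dm, Ds, fm, fs) {
        list(class = class, malignant = malignant,
             D_mean = Dm, D_sd = Ds, f_mean = fm, f_sd = fs,
             Dstar_range = c(10e-3, 100e-3),
             S0_mean = 1000, S0_sd = 100)
    }
    specs <- list(
        HCC               = mk("HCC",               TRUE,  1076e-6, 184e-6,  63e-3, 35e-3),
        CCC               = mk("CCC",               TRUE,  1076e-6, 184e-6,  63e-3, 35e-3),
        metastasis_CRC    = mk("metastasis_CRC",    TRUE,  1076e-6, 184e-6,  63e-3, 35e-3),
        metastasis_breast = mk("metastasis_breast", TRUE,  1076e-6, 184e-6,  63e-3, 35e-3),
        haemangioma       = mk("haemangioma",       FALSE, 1784e-6, 314e-6,  63e-3, 35e-3),
        FNH               = mk("FNH",               FALSE, 1076e-6, 184e-6, 164e-3, 58e-3),
        liver_background  = mk("liver_background",  FALSE, 1000e-6, 100e-6, 100e-3, 20e-3)
    )
    specs
}

## Truncated-normal draw by inverse-CDF; deterministic under the current RNG
## stream. Degenerate sd = 0 returns the (clamped) mean.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
    if (all(sd <= 0)) return(pmin(pmax(rep(mean, length.out = n), lo), hi))
    plo <- stats::pnorm(lo, mean, sd)
    phi <- stats::pnorm(hi, mean, sd)
    stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## Mean of a normal(mu, sd) truncated to [lo, hi].
truncnormMean <- function(mu, sd, lo, hi = Inf) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    Z <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / Z
}

## Underlying mu such that the [lo, hi]-truncated normal with SD sd has the
## requested mean; keeps class means on target despite truncation at the
## physical bounds. Memoised (called per lesion).
.truncMuCache <- new.env(parent = emptyenv())
truncMuFor <- function(target, sd, lo, hi = Inf) {
    if (sd <= 0) return(target)
    if (stats::pnorm(lo, target, sd) < 1e-12 &&
        stats::pnorm(hi, target, sd) > 1 - 1e-12) return(target)
    key <- paste(target, sd, lo, hi)
    hit <- .truncMuCache[[key]]
    if (!is.null(hit)) return(hit)
    mu <- stats::uniroot(function(m) truncnormMean(m, sd, lo, hi) - target,
                         c(target - 4 * sd, target + sd), tol = 1e-12)$root
    .truncMuCache[[key]] <- mu
    mu
}

## Density of the mean-corrected truncated normal a class's lesion-level
## parameter follows; used to locate generative Youden optima analytically.
classDensity <- function(target, sd, lo, hi = Inf) {
    mu <- truncMuFor(target, sd, lo, hi)
    Z <- stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd)
    function(x) ifelse(x >= lo & x <= hi, stats::dnorm(x, mu, sd) / Z, 0)
}

#' Sample lesion-level IVIM parameters for a class
#'
#' Draws `n` independent lesion-level parameter sets (S0, D, f, Dstar) from
#' a class spec, using truncated normals for S0/D/f (D >= 1e-9 mm^2/s,
#' f in [0, 0.99], S0 >= 1) and a uniform draw over `Dstar_range` floored
#' at D (the pseudodiffusion coefficient cannot fall below the tissue
#' diffusion coefficient). The underlying Gaussian location is shifted so
#' the truncated distribution's mean equals the class target mean; without
#' this, truncation at 0 would bias the perfusion-fraction classes upward.
#'
#' @param spec one element of [defaultClassSpecs()].
#' @param n number of draws.
#' @return data.frame with columns S0, D, f, Dstar.
#' @export
sampleClassParams <- function(spec, n) {
    D <- rtruncnorm(n, truncMuFor(spec$D_mean, spec$D_sd, 1e-9),
                    spec$D_sd, lo = 1e-9)
    f <- rtruncnorm(n, truncMuFor(spec$f_mean, spec$f_sd, 0, 0.99),
                    spec$f_sd, lo = 0, hi = 0.99)
    S0 <- rtruncnorm(n, truncMuFor(spec$S0_mean, spec$S0_sd, 1),
                     spec$S0_sd, lo = 1)
    Dstar <- pmax(stats::runif(n, spec$Dstar_range[1], spec$Dstar_range[2]), D)
    data.frame(S0 = S0, D = D, f = f, Dstar = Dstar)
}

#' Biexponential IVIM forward signal model
#'
#' Signal intensity of the two-compartment IVIM model,
#' \deqn{S(b) = S_0\,[(1-f)\,e^{-bD} + f\,e^{-b(D+D^*)}]}{
#'   S(b) = S0 * ((1-f) exp(-b D) + f exp(-b (D+D*)))}
#' or, in `"fully_dephased"` mode, the idealised limit in which the
#' perfusion compartment contributes only at b = 0
#' (\eqn{S(0)=S_0}, \eqn{S(b>0)=S_0(1-f)e^{-bD}}). The fully dephased mode
#' is the regime the simplified estimators are exact in, and is used for
#' exact-recovery testing.
#'
#' All arguments are vectorised and recycled.
#'
#' @param S0 signal at b = 0 (arbitrary units, > 0).
#' @param D true diffusion coefficient (mm^2/s, >= 0).
#' @param f perfusion fraction (unitless, in \[0, 1)).
#' @param Dstar pseudodiffusion coefficient (mm^2/s, >= D); ignored in
#'   fully dephased mode.
#' @param b diffusion weighting (s/mm^2, >= 0).
#' @param mode `"biexponential"` (default) or `"fully_dephased"`.
#' @return numeric signal intensities.
#' @examples
#' forwardSignal(1000, 1.0e-3, 0.2, 50e-3, b = 50)          # 776.60
#' forwardSignal(1000, 1.0e-3, 0.2, b = 800,
#'               mode = "fully_dephased")                    # 800*exp(-0.8)
#' @export
forwardSignal <- function(S0, D, f, Dstar = 50e-3, b,
                          mode = c("biexponential", "fully_dephased")) {
    mode <- match.arg(mode)
    stopifnot(all(b >= 0))
    if (mode == "biexponential") {
        S0 * ((1 - f) * exp(-b * D) + f * exp(-b * (D + Dstar)))
    } else {
        res <- S0 * (1 - f) * exp(-b * D)
        bb <- b + 0 * res            # broadcast b to the result shape
        s0 <- S0 + 0 * res
        res[bb == 0] <- s0[bb == 0]
        res
    }
}

## Logical sphere on an integer grid: voxel centres within radius of centre.
sphereMask <- function(dm, centre, radius) {
    dx <- (seq_len(dm[1]) - centre[1])
    dy <- (seq_len(dm[2]) - centre[2])
    dz <- (seq_len(dm[3]) - centre[3])
    outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= radius^2
}

## Body = elliptical cylinder: full slice extent in z (an axial slab through
## the abdomen), elliptical cross-section in-plane; voxels outside are
## air/background with zero true signal.
bodyMask <- function(dm) {
    semi <- (dm[1:2] - 1) / 2
    cx <- (dm[1:2] + 1) / 2
    dx <- ((seq_len(dm[1]) - cx[1]) / semi[1])^2
    dy <- ((seq_len(dm[2]) - cx[2]) / semi[2])^2
    inplane <- outer(dx, dy, "+") <= 1
    array(rep(inplane, dm[3]), dm)
}

## Necrotic / cystic core parameters: free-fluid-like diffusion, essentially
## no perfusion, elevated S0 (fluid hyperintensity on b0).
coreParams <- list(D = 3.0e-3, f = 0.002, S0_factor = 2)

#' Build a synthetic phantom scene
#'
#' Places spherical lesions of the requested classes inside an
#' elliptical-cylinder body filled with liver background, and samples
#' per-voxel ground-truth
#' IVIM parameters. Each lesion draws its (D, f, Dstar, S0) centre from the
#' class distribution ([sampleClassParams()]); voxels within the lesion add
#' a small truncated-normal jitter (`withinLesionCV`, relative SD) so maps
#' are textured while ROI means stay on the lesion-level draw. Background
#' voxels are sampled independently from the background spec.
#'
#' Lesions with `core = TRUE` receive a central subregion (radius
#' `coreFrac` times the lesion radius) with free-fluid-like parameters
#' (high D, f near 0, elevated S0): bright on b0, dark on b800 -- the
#' necrosis/cyst/scar pattern the exclusion mask is meant to catch.
#'
#' @param dim integer grid dimensions, default c(64, 64, 16).
#' @param lesions data.frame with column `class` (names from
#'   [defaultClassSpecs()]) and `radius` (voxels, >= 1.5 so lesion
#'   diameters are at least 3 voxels); optional columns `x`, `y`, `z`
#'   (centre, otherwise placed randomly inside the body) and `core`
#'   (logical). NULL or 0 rows gives pure background.
#' @param seed integer seed; the same seed and config reproduce the scene
#'   exactly.
#' @param specs class specs, default [defaultClassSpecs()].
#' @param withinLesionCV relative within-lesion SD for D and f (default
#'   0.03; 0 gives perfectly homogeneous lesions).
#' @param coreFrac core radius as a fraction of lesion radius (default 0.5).
#' @param spacing voxel spacing in mm.
#' @return A [PhantomScene-class].
#' @examples
#' sc <- buildScene(dim = c(32, 32, 8),
#'                  lesions = data.frame(class = "HCC", radius = 4),
#'                  seed = 1)
#' sc
#' @export
buildScene <- function(dim = c(64, 64, 16), lesions = NULL, seed = 1,
                       specs = defaultClassSpecs(), withinLesionCV = 0.03,
                       coreFrac = 0.5, spacing = c(1, 1, 1)) {
    dm <- as.integer(dim)
    stopifnot(length(dm) == 3L, all(dm >= 4L))
    set.seed(seed)
    body <- bodyMask(dm)
    labels <- array(0L, dm)
    labels[body] <- 1L

    nles <- if (is.null(lesions)) 0L else nrow(lesions)
    if (nles > 0L) {
        stopifnot(all(lesions$class %in% names(specs)))
        if (any(lesions$radius < 1.5))
            stop("lesion radius must be >= 1.5 voxels (diameter >= 3)")
    }

    S0 <- array(0, dm); Dv <- array(0, dm); fv <- array(0, dm)
    Ds <- array(0, dm)
    bg <- specs$liver_background
    nb <- sum(body)
    bgp <- sampleClassParams(bg, nb)
    S0[body] <- bgp$S0; Dv[body] <- bgp$D; fv[body] <- bgp$f
    Ds[body] <- bgp$Dstar

    tab <- data.frame(lesion_id = character(), class = character(),
                      label = integer(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric(), n_voxels = integer(),
                      D = numeric(), f = numeric(), Dstar = numeric(),
                      malignant = logical(), has_core = logical(),
                      stringsAsFactors = FALSE)
    occupied <- array(FALSE, dm)
    for (i in seq_len(nles)) {
        cls <- lesions$class[i]
        r <- lesions$radius[i]
        hasCore <- isTRUE(lesions$core[i])
        fixed <- all(c("x", "y", "z") %in% names(lesions)) &&
            !any(is.na(c(lesions$x[i], lesions$y[i], lesions$z[i])))
        placed <- FALSE
        for (try in seq_len(if (fixed) 1L else 200L)) {
            ctr <- if (fixed) c(lesions$x[i], lesions$y[i], lesions$z[i])
                   else vapply(dm, function(d) {
                       lo <- min(1 + r, (d + 1) / 2)
                       hi <- max(d - r, (d + 1) / 2)
                       stats::runif(1, lo, hi)
                   }, numeric(1))
            m <- sphereMask(dm, ctr, r)
            if (!any(m)) next
            if (all(body[m]) && !any(occupied[m])) { placed <- TRUE; break }
        }
        if (!placed)
            stop("could not place lesion ", i, " (class ", cls,
                 ", radius ", r, ") inside the body grid")
        occupied <- occupied | m
        lp <- sampleClassParams(specs[[cls]], 1)
        nv <- sum(m)
        cv <- withinLesionCV
        Dv[m] <- rtruncnorm(nv, lp$D, cv * lp$D, lo = 1e-9)
        fv[m] <- rtruncnorm(nv, lp$f, cv * lp$f, lo = 0, hi = 0.99)
        S0[m] <- rtruncnorm(nv, lp$S0, cv * lp$S0, lo = 1)
        Ds[m] <- pmax(lp$Dstar, Dv[m])
        if (hasCore) {
            cm <- sphereMask(dm, ctr, coreFrac * r) & m
            Dv[cm] <- coreParams$D
            fv[cm] <- coreParams$f
            S0[cm] <- coreParams$S0_factor * lp$S0
            Ds[cm] <- pmax(Ds[cm], coreParams$D)
        }
        lab <- i + 1L
        labels[m] <- lab
        tab[i, ] <- list(sprintf("L%03d", i), cls, lab, ctr[1], ctr[2],
                         ctr[3], r, nv, lp$D, lp$f, lp$Dstar,
                         isTRUE(specs[[cls]]$malignant), hasCore)
    }
    new("PhantomScene", labels = labels, S0 = S0, D = Dv, f = fv,
        Dstar = Ds, lesionTable = tab, spacing = as.numeric(spacing))
}

#' Simulate a diffusion-weighted stack from a phantom scene
#'
#' Evaluates the forward model ([forwardSignal()]) voxel-wise at each
#' requested b value and optionally corrupts the magnitudes with Rician
#' noise: the noisy signal is \eqn{\sqrt{(S+g_1)^2 + g_2^2}} with
#' \eqn{g_1, g_2} independent zero-mean Gaussians of SD `sigma`, drawn
#' independently per voxel and per b-value volume. Voxels outside the body
#' have zero true signal (pure noise floor under Rician noise).
#'
#' `sliceShift` optionally shifts the highest-b volume by whole voxels
#' along the first axis, a crude stand-in for inter-scan motion
#' misalignment used in robustness tests; default 0 (off).
#'
#' @param scene a [PhantomScene-class].
#' @param bValues b values to simulate (s/mm^2); must include 0, 50, 800
#'   for downstream mapping.
#' @param mode forward-model mode, see [forwardSignal()].
#' @param noise `"none"` or `"rician"`.
#' @param sigma Rician noise SD in signal units (>= 0); 0 reproduces the
#'   noiseless forward model exactly.
#' @param seed integer seed for the noise draws.
#' @param sliceShift integer voxel shift applied to the max-b volume.
#' @return A [DWIStack-class].
#' @examples
#' sc <- buildScene(dim = c(16, 16, 4), seed = 1)
#' stk <- simulateDWI(sc, sigma = 0)
#' @export
simulateDWI <- function(scene, bValues = c(0, 50, 800),
                        mode = c("biexponential", "fully_dephased"),
                        noise = c("none", "rician"), sigma = 0, seed = 1,
                        sliceShift = 0L) {
    mode <- match.arg(mode)
    noise <- match.arg(noise)
    if (sigma < 0) stop("noise sigma must be >= 0")
    if (sigma > 0 && noise == "none") noise <- "rician"
    bValues <- sort(unique(bValues))
    dm <- dim(scene@labels)
    inside <- scene@labels != 0L
    set.seed(seed)
    vols <- lapply(bValues, function(b) {
        v <- array(0, dm)
        v[inside] <- forwardSignal(scene@S0[inside], scene@D[inside],
                                   scene@f[inside], scene@Dstar[inside],
                                   b = b, mode = mode)
        if (noise == "rician" && sigma > 0) {
            g1 <- array(stats::rnorm(prod(dm), 0, sigma), dm)
            g2 <- array(stats::rnorm(prod(dm), 0, sigma), dm)
            v <- sqrt((v + g1)^2 + g2^2)
        }
        v
    })
    if (sliceShift != 0L) {
        k <- length(vols)
        v <- vols[[k]]
        idx <- ((seq_len(dm[1]) - 1L - as.integer(sliceShift)) %% dm[1]) + 1L
        vols[[k]] <- v[idx, , , drop = FALSE]
    }
    new("DWIStack", bValues = bValues, volumes = vols,
        spacing = scene@spacing)
}
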