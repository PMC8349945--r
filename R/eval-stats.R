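## Statistical evaluation pipeline: empirical ROC with DeLong AUC variance,
## Youden-optimal cutoffs, paired/unpaired AUC comparison, normality-gated
## group tests, confusion-matrix metrics, and two-way random-effects ICC.
## ROC/Youden/DeLong are implemented from the defining formulas with
## documented deterministic tie-breaks so derived cutoffs are reproducible.

## Placement values (DeLong structural components) for oriented scores:
## psi(x, y) = 1 if x > y, 1/2 if x == y, 0 otherwise.
placements <- function(pos, neg) {
    cmp <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
    list(V10 = rowMeans(cmp), V01 = colMeans(cmp), auc = mean(cmp))
}

#' Empirical ROC analysis
#'
#' Builds the empirical ROC of a continuous marker against a binary truth.
#' The marker direction is explicit: with `"lower_is_positive"` (the
#' convention for diffusion parameters, where lower values indicate
#' malignancy) a case is called positive when its value falls below a
#' threshold; with `"higher_is_positive"` when it lies above.
#'
#' The AUC is the normalised Mann-Whitney statistic (mean over all
#' positive/negative pairs of the comparison score, ties counting 1/2),
#' identical to the trapezoidal area under the empirical curve. Its 95% CI
#' uses the DeLong structural-components variance,
#' var(AUC) = var(V10)/m + var(V01)/n for m positives and n negatives.
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' values, plus -Inf and +Inf, making derived cutoffs independent of sample
#' order.
#'
#' @param values numeric marker values, one per case.
#' @param labels logical (TRUE = positive) or factor/character coercible to
#'   logical via `positive`.
#' @param direction `"lower_is_positive"` or `"higher_is_positive"`.
#' @param positive when `labels` is not logical, the level counted positive.
#' @return object of class `"ivimROC"`: list with `values`, `labels`,
#'   `direction`, `thresholds`, `sens`, `spec`, `auc`, `auc_var`,
#'   `auc_ci95`, `n_pos`, `n_neg`, `V10`, `V01`.
#' @examples
#' r <- rocCurve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
#'               direction = "lower_is_positive")
#' r$auc  # 1: perfect separation
#' @export
rocCurve <- function(values, labels,
                     direction = c("lower_is_positive",
                                   "higher_is_positive"),
                     positive = NULL) {
    direction <- match.arg(direction)
    if (!is.logical(labels)) {
        if (is.null(positive))
            stop("supply `positive` when labels are not logical")
        labels <- labels == positive
    }
    stopifnot(length(values) == length(labels), all(is.finite(values)))
    if (!any(labels) || all(labels))
        stop("ROC needs at least one case in each class")

    flip <- if (direction == "lower_is_positive") -1 else 1
    pl <- placements(flip * values[labels], flip * values[!labels])
    m <- sum(labels); n <- sum(!labels)
    v <- stats::var(pl$V10) / m + stats::var(pl$V01) / n
    if (!is.finite(v)) v <- 0
    half <- stats::qnorm(0.975) * sqrt(v)

    u <- sort(unique(values))
    thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
    callPos <- function(t) if (direction == "lower_is_positive")
        values < t else values > t
    sens <- vapply(thr, function(t) mean(callPos(t)[labels]), numeric(1))
    spec <- vapply(thr, function(t) mean(!callPos(t)[!labels]), numeric(1))

    structure(list(values = values, labels = labels, direction = direction,
                   thresholds = thr, sens = sens, spec = spec,
                   auc = pl$auc, auc_var = v,
                   auc_ci95 = c(max(0, pl$auc - half), min(1, pl$auc + half)),
                   n_pos = m, n_neg = n, V10 = pl$V10, V01 = pl$V01),
              class = "ivimROC")
}

#' @export
print.ivimROC <- function(x, ...) {
    cat(sprintf("ROC: %d pos / %d neg, %s; AUC %.3f (95%% CI %.3f-%.3f)\n",
                x$n_pos, x$n_neg, x$direction, x$auc,
                x$auc_ci95[1], x$auc_ci95[2]))
    invisible(x)
}

#' Youden-optimal cutoff of an ROC curve
#'
#' Maximises the Youden index J = sensitivity + specificity - 1 over the
#' candidate thresholds of [rocCurve()]. Ties are broken deterministically:
#' among equal-J candidates the one with higher sensitivity wins (a
#' screening-oriented choice: prefer catching positives), then the smaller
#' threshold. Reported accuracy weights sensitivity and specificity by the
#' sample class prevalences.
#'
#' @param roc an `"ivimROC"` object.
#' @return list with `cutoff`, `J`, `sens`, `spec`, `acc`.
#' @examples
#' r <- rocCurve(c(0, 1, 2.5, 2, 3, 4), rep(c(TRUE, FALSE), each = 3),
#'               direction = "lower_is_positive")
#' youdenCutoff(r)$cutoff  # 2.75
#' @export
youdenCutoff <- function(roc) {
    stopifnot(inherits(roc, "ivimROC"))
    J <- roc$sens + roc$spec - 1
    ord <- order(-J, -roc$sens, roc$thresholds)
    i <- ord[1]
    acc <- (roc$sens[i] * roc$n_pos + roc$spec[i] * roc$n_neg) /
        (roc$n_pos + roc$n_neg)
    list(cutoff = roc$thresholds[i], J = J[i], sens = roc$sens[i],
         spec = roc$spec[i], acc = acc)
}

#' DeLong comparison of two AUCs
#'
#' Tests AUC_a = AUC_b with the DeLong structural-components estimator of
#' var(AUC_a - AUC_b). For paired markers (same cases underlying both ROC
#' curves, required: identical labels) the covariance of the placement
#' values is subtracted, var = var_a + var_b - 2 cov; for independent
#' samples the variances add. Two-sided normal p value.
#'
#' @param rocA,rocB `"ivimROC"` objects.
#' @param paired logical; TRUE when both markers were measured on the same
#'   cases in the same order.
#' @return list with `auc_a`, `auc_b`, `delta`, `var`, `z`, `p`.
#' @export
delongCompare <- function(rocA, rocB, paired = TRUE) {
    stopifnot(inherits(rocA, "ivimROC"), inherits(rocB, "ivimROC"))
    delta <- rocA$auc - rocB$auc
    if (paired) {
        if (!identical(rocA$labels, rocB$labels))
            stop("paired comparison requires identical cases and labels")
        cv <- stats::cov(rocA$V10, rocB$V10) / rocA$n_pos +
              stats::cov(rocA$V01, rocB$V01) / rocA$n_neg
        v <- rocA$auc_var + rocB$auc_var - 2 * cv
    } else {
        v <- rocA$auc_var + rocB$auc_var
    }
    if (v <= .Machine$double.eps^0.5) {
        z <- if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
    } else z <- delta / sqrt(v)
    list(auc_a = rocA$auc, auc_b = rocB$auc, delta = delta, var = v,
         z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk on each group at `alphaNormality`; if both pass, a
#' two-sided Welch t test, otherwise a Mann-Whitney U test (exact
#' enumeration when the combined sample size is at most 12 and there are no
#' ties, else the normal approximation with tie/continuity correction).
#' The normality gate engages only for groups of at least 4 observations
#' (Shapiro-Wilk has essentially no power below that); smaller or constant
#' groups fall through to the Mann-Whitney branch.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param alphaNormality gate level for Shapiro-Wilk (default 0.05).
#' @return list with `test` ("welch_t" or "mann_whitney"), `p`,
#'   `statistic`, `shapiro_p` (length 2, NA where not testable).
#' @examples
#' groupTest(c(1, 2, 3), c(4, 5, 6))$p  # exact Mann-Whitney: 0.1
#' @export
groupTest <- function(a, b, alphaNormality = 0.05) {
    if (length(a) < 2 || length(b) < 2)
        stop("each group needs at least 2 observations")
    swp <- vapply(list(a, b), function(x) {
        if (length(x) < 4 || length(unique(x)) == 1) return(NA_real_)
        tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
    }, numeric(1))
    normal <- all(!is.na(swp) & swp >= alphaNormality)
    if (normal) {
        tt <- stats::t.test(a, b, var.equal = FALSE)
        return(list(test = "welch_t", p = tt$p.value,
                    statistic = unname(tt$statistic), shapiro_p = swp))
    }
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- (length(a) + length(b) <= 12) && !ties
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    list(test = "mann_whitney", p = wt$p.value,
         statistic = unname(wt$statistic), shapiro_p = swp)
}

#' Sensitivity, specificity and accuracy from a confusion table
#'
#' Plain ratios: sens = TP/(TP+FN), spec = TN/(TN+FP),
#' acc = (TP+TN)/total. A zero denominator yields NA for the affected
#' metric, with its name returned in `undefined` (never a silent NaN).
#' Values are returned at full precision; round at display.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return list with `sens`, `spec`, `acc`, `undefined`.
#' @examples
#' confusionMetrics(tp = 72, fp = 3, tn = 32, fn = 2)  # 0.973/0.914/0.954
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
    cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
    stopifnot(all(cnt >= 0), all(cnt == round(cnt)))
    undef <- character()
    sens <- if (tp + fn > 0) tp / (tp + fn) else { undef <- c(undef, "sens"); NA_real_ }
    spec <- if (tn + fp > 0) tn / (tn + fp) else { undef <- c(undef, "spec"); NA_real_ }
    tot <- sum(cnt)
    acc <- if (tot > 0) (tp + tn) / tot else { undef <- c(undef, "acc"); NA_real_ }
    list(sens = sens, spec = spec, acc = acc, undefined = undef)
}

#' Pooled accuracy from published sensitivity/specificity and group sizes
#'
#' Reconstructs the implied confusion counts (TP = round(sens * nPos),
#' TN = round(spec * nNeg)) and returns the pooled accuracy
#' (TP + TN)/(nPos + nNeg). Useful for checking that tabulated
#' sens/spec/accuracy triples are arithmetically consistent.
#'
#' @param sens,spec proportions in \[0, 1\].
#' @param nPos,nNeg group sizes.
#' @return list with `tp`, `tn`, `acc`.
#' @export
poolAccuracy <- function(sens, spec, nPos, nNeg) {
    tp <- round(sens * nPos); tn <- round(spec * nNeg)
    list(tp = tp, tn = tn, acc = (tp + tn) / (nPos + nNeg))
}

#' Intraclass correlation coefficient, two-way random, absolute agreement
#'
#' Single-measure ICC(2,1) from the two-way ANOVA mean squares of a
#' complete subjects x raters matrix:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the row (subject), column
#' (rater) and residual mean squares. Absolute agreement: a constant shift
#' between raters lowers the coefficient. With `form = "consistency"` the
#' rater variance term is dropped (ICC(3,1)).
#'
#' @param ratings numeric matrix, subjects in rows, raters/sessions in
#'   columns; complete (no NA), >= 2 rows and >= 2 columns.
#' @param form "agreement" (default) or "consistency".
#' @return list with `icc`, `ms` (named mean squares), `undefined`
#'   (TRUE when between-subject variance is zero and the coefficient is
#'   undefined; icc is then NA).
#' @examples
#' m <- cbind(1:5, 1:5)
#' iccAgreement(m)$icc  # 1: perfect agreement
#' @export
iccAgreement <- function(ratings, form = c("agreement", "consistency")) {
    form <- match.arg(form)
    ratings <- as.matrix(ratings)
    if (anyNA(ratings)) stop("ICC requires a complete rating matrix")
    n <- nrow(ratings); k <- ncol(ratings)
    if (n < 2 || k < 2) stop("ICC needs >= 2 subjects and >= 2 raters")
    gm <- mean(ratings)
    SSR <- k * sum((rowMeans(ratings) - gm)^2)
    SSC <- n * sum((colMeans(ratings) - gm)^2)
    SST <- sum((ratings - gm)^2)
    SSE <- SST - SSR - SSC
    MSR <- SSR / (n - 1); MSC <- SSC / (k - 1)
    MSE <- SSE / ((n - 1) * (k - 1))
    ms <- c(MSR = MSR, MSC = MSC, MSE = MSE)
    denom <- if (form == "agreement")
        MSR + (k - 1) * MSE + k / n * (MSC - MSE)
    else MSR + (k - 1) * MSE
    if (denom <= .Machine$double.eps^0.5 && MSR <= .Machine$double.eps^0.5) {
        warning("zero between-subject variance; ICC undefined")
        return(list(icc = NA_real_, ms = ms, undefined = TRUE))
    }
    list(icc = (MSR - MSE) / denom, ms = ms, undefined = FALSE)
}

#' Derive parameter cutoffs from a lesion cohort
#'
#' Reproduces the cutoff-derivation strategy of the workflow on a lesion
#' record table: the D' cutoff separates haemangiomas from all other
#' lesions (haemangiomas have high diffusion), the f' cutoff separates
#' FNHs from all other lesions (FNHs have high perfusion fraction), and the
#' ADC cutoff separates benign from malignant lesions. Each is the
#' Youden-optimal threshold of the corresponding ROC with direction
#' lower-is-positive ("positive" = the non-high group).
#'
#' @param records data.frame as returned by [simulateLesionCohort()], with
#'   columns `class`, `malignant`, `mean_Dprime`, `mean_fprime`,
#'   `mean_ADC`.
#' @return A [CutoffSet-class] with provenance "derived".
#' @export
deriveCutoffs <- function(records) {
    need <- c("class", "malignant", "mean_Dprime", "mean_fprime", "mean_ADC")
    stopifnot(all(need %in% names(records)))
    rD <- rocCurve(records$mean_Dprime, records$class != "haemangioma",
                   direction = "lower_is_positive")
    rF <- rocCurve(records$mean_fprime, records$class != "FNH",
                   direction = "lower_is_positive")
    rA <- rocCurve(records$mean_ADC, records$malignant,
                   direction = "lower_is_positive")
    new("CutoffSet",
        cD = youdenCutoff(rD)$cutoff,
        cF = youdenCutoff(rF)$cutoff,
        cADC = youdenCutoff(rA)$cutoff,
        provenance = sprintf("derived from %d lesions", nrow(records)))
}

#' Population-optimal Youden cutoff between two generator classes
#'
#' For lesion-level parameters following the generator's mean-corrected
#' truncated normals, the large-sample Youden-optimal threshold is the
#' crossing point of the two class densities (where the derivative of
#' sens + spec vanishes). Located numerically between the class means.
#'
#' @param specLow,specHigh lists with `mean` and `sd` of the low and high
#'   class (internal units).
#' @param lo,hi truncation bounds used by the sampler.
#' @return scalar crossing point.
#' @export
generativeYoudenOptimum <- function(specLow, specHigh, lo = 0, hi = Inf) {
    dLow <- classDensity(specLow$mean, specLow$sd, lo, hi)
    dHigh <- classDensity(specHigh$mean, specHigh$sd, lo, hi)
    stats::uniroot(function(x) dLow(x) - dHigh(x),
                   c(specLow$mean, specHigh$mean), tol = 1e-12)$root
}
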