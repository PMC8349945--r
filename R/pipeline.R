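## End-to-end pipeline: phantom -> maps -> index maps -> ROI analysis ->
## evaluation, driven by one serialisable config. Stages never mutate
## upstream artifacts; each writes its own outputs under outDir (when
## given) so later stages can be rerun alone.

lesionsFromConfig <- function(scfg) {
    if (is.null(scfg$lesions) || length(scfg$lesions) == 0L) return(NULL)
    do.call(rbind, lapply(scfg$lesions, function(l)
        data.frame(class = l$class, radius = l$radius,
                   x = if (is.null(l$x)) NA_real_ else l$x,
                   y = if (is.null(l$y)) NA_real_ else l$y,
                   z = if (is.null(l$z)) NA_real_ else l$z,
                   core = isTRUE(l$core))))
}

## 2-D ROI on the representative slice through the lesion centre: the
## lesion's voxels on that slice, as in single-slice clinical reading.
lesionROI <- function(scene, row) {
    dm <- dim(scene@labels)
    sl <- max(1L, min(dm[3], round(row$z)))
    vox <- array(FALSE, dm)
    vox[, , sl] <- scene@labels[, , sl] == row$label
    if (!any(vox)) stop("lesion ", row$lesion_id,
                        " has no voxels on its central slice")
    ROIMask(row$lesion_id, vox)
}

#' Run the full simplified-IVIM pipeline on a phantom
#'
#' Executes phantom generation, parameter mapping, index-map construction,
#' ROI analysis and lesion classification in order, from a single
#' configuration ([defaultRunConfig()]). Cutoffs come either from the
#' published defaults (`cutoff_source: published_defaults`) or are derived on a
#' simulated lesion cohort (`cutoff_source: derive`, size
#' `derive$n_lesions`). ROIs are the lesion voxels on the slice through
#' each lesion's centre, with the necrosis/cyst/scar exclusion mask
#' applied; invalid-voxel counts per map are reported (quality problems
#' surface as numbers, not silent drops).
#'
#' `config$scene$specs_overrides` may carry per-class overrides of the
#' generator specs (e.g. zero-SD classes for controlled separability
#' experiments) and `config$scene$within_lesion_cv` the within-lesion
#' jitter; both remain plain serialisable values.
#'
#' @param config configuration list, see [defaultRunConfig()].
#' @param outDir optional output directory; when given, per-stage
#'   artifacts (NIfTI volumes, lesion CSV, summary JSON) are written.
#' @param verbose print stage progress.
#' @return list with `scene`, `stack`, `maps` (Dprime/fprime/ADC),
#'   `index` (I_D/I_f/I_ADC/I_Df), `cutoffs`, `records` (per-lesion
#'   data.frame incl. calls), `summary` (named list of counts and
#'   accuracies).
#' @examples
#' cfg <- defaultRunConfig(seed = 7)
#' cfg$scene$dim <- c(32, 32, 8)
#' cfg$scene$lesions <- list(list(class = "HCC", radius = 4),
#'                           list(class = "haemangioma", radius = 4))
#' res <- runPipeline(cfg)
#' res$summary$accuracy_Df_means
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL,
                        verbose = FALSE) {
    say <- function(...) if (verbose) message("[", ..., "]")
    stopifnot(is.list(config), !is.null(config$seed))
    if (!is.null(outDir))
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    say("phantom")
    specs <- defaultClassSpecs()
    for (cl in names(config$scene$specs_overrides))
        specs[[cl]] <- utils::modifyList(specs[[cl]],
                                         config$scene$specs_overrides[[cl]])
    cv <- if (is.null(config$scene$within_lesion_cv)) 0.03
          else config$scene$within_lesion_cv
    scene <- tryCatch(
        buildScene(dim = unlist(config$scene$dim),
                   lesions = lesionsFromConfig(config$scene),
                   seed = config$seed, specs = specs, withinLesionCV = cv),
        error = function(e) stop("stage phantom: ", conditionMessage(e)))
    sigma <- if (is.null(config$noise$sigma)) 0 else config$noise$sigma
    stack <- simulateDWI(scene, bValues = unlist(config$b_values),
                         mode = config$mode,
                         noise = if (sigma > 0) "rician" else "none",
                         sigma = sigma, seed = config$seed + 1L)
    if (!is.null(outDir)) {
        writeScene(scene, file.path(outDir, "phantom"))
        writeDWIStack(stack, file.path(outDir, "phantom"))
    }

    say("map")
    maps <- tryCatch(computeMaps(stack),
        error = function(e) stop("stage map: ", conditionMessage(e)))
    inside <- scene@labels != 0L
    invalidCounts <- vapply(maps, function(m)
        sum(!validMask(m) & inside), numeric(1))
    if (!is.null(outDir)) {
        writeParameterMap(maps$Dprime, file.path(outDir, "dprime"))
        writeParameterMap(maps$fprime, file.path(outDir, "fprime"))
        writeParameterMap(maps$ADC, file.path(outDir, "adc"))
    }

    say("index")
    cutoffs <- switch(config$cutoff_source,
        published_defaults = referenceCutoffs(),
        derive = deriveCutoffs(simulateLesionCohort(
            n = config$derive$n_lesions, seed = config$seed + 2L,
            roiVoxels = config$derive$roi_voxels)),
        stop("stage index: unknown cutoff_source '", config$cutoff_source, "'"))
    index <- list(I_D = binarizeMap(maps$Dprime, cutoffs@cD),
                  I_f = binarizeMap(maps$fprime, cutoffs@cF),
                  I_ADC = binarizeMap(maps$ADC, cutoffs@cADC))
    index$I_Df <- combineDf(index$I_D, index$I_f)
    if (!is.null(outDir))
        for (k in names(index))
            writeIndexMap(index[[k]], file.path(outDir, tolower(k)))

    say("roi")
    tab <- scene@lesionTable
    kEx <- if (is.null(config$thresholds$k_sd_exclude)) 2
           else config$thresholds$k_sd_exclude
    b0 <- getVolume(stack, 0); b800 <- getVolume(stack, 800)
    records <- NULL
    if (nrow(tab) > 0) {
        records <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
            roi <- lesionROI(scene, tab[i, ])
            excl <- exclusionMask(b0, b800, roi, kSD = kEx)
            if (any(roi@voxels & !excl))
                roi <- new("ROIMask", lesionID = roi@lesionID,
                           voxels = roi@voxels, exclusion = excl)
            data.frame(
                lesion_id = tab$lesion_id[i], class = tab$class[i],
                malignant = tab$malignant[i],
                n_voxels = sum(analysedVoxels(roi)),
                n_excluded = sum(roi@exclusion),
                mean_Dprime = roiMean(maps$Dprime, roi),
                mean_fprime = roiMean(maps$fprime, roi),
                mean_ADC = roiMean(maps$ADC, roi),
                pct_ID = roiMean(index$I_D, roi),
                pct_If = roiMean(index$I_f, roi),
                pct_IADC = roiMean(index$I_ADC, roi),
                pct_IDf = roiMean(index$I_Df, roi),
                stringsAsFactors = FALSE)
        }))
        rownames(records) <- NULL

        say("evaluate")
        records$call_Df_means <- vapply(seq_len(nrow(records)), function(i)
            classifyLesion(records[i, ], cutoffs, rule = "Df_means"),
            character(1))
        records$call_index_pct <- vapply(seq_len(nrow(records)), function(i)
            classifyLesion(records[i, ], cutoffs, rule = "index_pct"),
            character(1))
        records$call_adc_mean <- vapply(seq_len(nrow(records)), function(i)
            classifyLesion(records[i, ], cutoffs, rule = "adc_mean"),
            character(1))
        records$visual_rating <- vapply(seq_len(nrow(records)), function(i)
            as.character(visualSurrogate(records$pct_IDf[i])$rating),
            character(1))
    }

    truthCall <- ifelse(tab$malignant, "malignant", "benign")
    accOf <- function(col) if (is.null(records)) NA_real_
        else mean(records[[col]] == truthCall)
    summary <- list(
        n_lesions = nrow(tab),
        invalid_voxels = as.list(invalidCounts),
        cutoffs = list(cD = cutoffs@cD, cF = cutoffs@cF,
                       cADC = cutoffs@cADC,
                       provenance = cutoffs@provenance),
        accuracy_Df_means = accOf("call_Df_means"),
        accuracy_index_pct = accOf("call_index_pct"),
        accuracy_adc_mean = accOf("call_adc_mean"))
    if (any(invalidCounts > 0))
        warning("invalid voxels per map: ",
                paste(names(invalidCounts), invalidCounts, sep = "=",
                      collapse = ", "))

    if (!is.null(outDir)) {
        if (!is.null(records))
            writeLesionRecords(records, file.path(outDir, "lesions.csv"))
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(scene = scene, stack = stack, maps = maps, index = index,
         cutoffs = cutoffs, records = records, summary = summary)
}
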