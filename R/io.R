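## File formats. NIfTI is the canonical volume format (via RNifti), one
## volume per b value plus a JSON sidecar naming the b values; parameter
## maps as float NIfTI with a uint8 validity companion; index maps as uint8
## with 255 marking invalid voxels; lesion records as CSV in display units
## (D'/ADC x1e-6 mm^2/s, f' x1e-3, index maps in percent); run configs as
## YAML. Voxel indices are 0-based on disk only where a format demands it;
## in R everything is 1-based.

writeVol <- function(arr, path, spacing = c(1, 1, 1), datatype = "double") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path, datatype = datatype)
    invisible(path)
}

#' Write / read a DWI stack as NIfTI volumes plus JSON sidecar
#'
#' `writeDWIStack()` writes one `<prefix>_b<value>.nii.gz` per b value and
#' a `<prefix>_bvalues.json` sidecar listing the b values, file names and
#' voxel spacing. `readDWIStack()` reads that layout back; alternatively it
#' accepts any directory holding per-b NIfTI volumes with such a manifest.
#'
#' @param stack a [DWIStack-class].
#' @param dir output/input directory.
#' @param prefix file-name prefix (default "dwi").
#' @return `writeDWIStack`: invisibly, the sidecar path;
#'   `readDWIStack`: a [DWIStack-class].
#' @export
writeDWIStack <- function(stack, dir, prefix = "dwi") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- sprintf("%s_b%g.nii.gz", prefix, bValues(stack))
    for (i in seq_along(files))
        writeVol(stack@volumes[[i]], file.path(dir, files[i]), stack@spacing)
    sidecar <- file.path(dir, paste0(prefix, "_bvalues.json"))
    jsonlite::write_json(
        list(b_values = bValues(stack), files = files,
             spacing = stack@spacing),
        sidecar, auto_unbox = FALSE, digits = NA)
    invisible(sidecar)
}

#' @rdname writeDWIStack
#' @export
readDWIStack <- function(dir, prefix = "dwi") {
    sidecar <- file.path(dir, paste0(prefix, "_bvalues.json"))
    if (!file.exists(sidecar)) stop("no b-value manifest at ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    vols <- lapply(meta$files, function(fn) {
        v <- RNifti::readNifti(file.path(dir, fn))
        array(as.numeric(v), dim(v))
    })
    new("DWIStack", bValues = as.numeric(meta$b_values), volumes = vols,
        spacing = as.numeric(meta$spacing))
}

#' Write / read a parameter map as NIfTI
#'
#' Values are stored in display units (x1e-6 mm^2/s for Dprime/ADC,
#' x1e-3 for fprime) as float NIfTI; the validity mask goes to a uint8
#' companion `<path>_valid.nii.gz`. Reading restores internal units.
#'
#' @param map a [ParameterMap-class].
#' @param path output path without extension (e.g. "out/dprime").
#' @param kind map kind, needed by `readParameterMap` to undo the display
#'   scaling.
#' @return `writeParameterMap`: invisibly the value-volume path;
#'   `readParameterMap`: a [ParameterMap-class].
#' @export
writeParameterMap <- function(map, path) {
    sc <- if (mapKind(map) == "fprime") 1e3 else 1e6
    v <- mapValues(map) * sc
    v[!validMask(map)] <- 0
    writeVol(v, paste0(path, ".nii.gz"), map@spacing)
    writeVol(array(as.integer(validMask(map)), dim(v)),
             paste0(path, "_valid.nii.gz"), map@spacing, datatype = "uint8")
    invisible(paste0(path, ".nii.gz"))
}

#' @rdname writeParameterMap
#' @export
readParameterMap <- function(path, kind) {
    stopifnot(kind %in% c("Dprime", "fprime", "ADC"))
    sc <- if (kind == "fprime") 1e3 else 1e6
    v <- RNifti::readNifti(paste0(path, ".nii.gz"))
    valid <- RNifti::readNifti(paste0(path, "_valid.nii.gz"))
    new("ParameterMap", kind = kind,
        values = array(as.numeric(v) / sc, dim(v)),
        valid = array(as.integer(valid) == 1L, dim(v)))
}

#' Write an index map as uint8 NIfTI
#'
#' Voxel values 0 (green) and 100 (red); invalid voxels are stored as 255.
#'
#' @param index an [IndexMap-class].
#' @param path output path without extension.
#' @return invisibly, the written path.
#' @export
writeIndexMap <- function(index, path) {
    v <- mapValues(index)
    v[!validMask(index)] <- 255
    writeVol(array(as.integer(v), dim(v)), paste0(path, ".nii.gz"),
             index@spacing, datatype = "uint8")
    invisible(paste0(path, ".nii.gz"))
}

#' Write phantom ground truth
#'
#' Label volume as uint16 NIfTI plus the lesion table as CSV
#' (lesion id, class, centre, radius, lesion-level true D/f/Dstar, voxel
#' count, malignancy).
#'
#' @param scene a [PhantomScene-class].
#' @param dir output directory.
#' @return invisibly, the lesion-table path.
#' @export
writeScene <- function(scene, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeVol(scene@labels, file.path(dir, "labels.nii.gz"), scene@spacing,
             datatype = "uint16")
    path <- file.path(dir, "lesions.csv")
    utils::write.csv(scene@lesionTable, path, row.names = FALSE)
    invisible(path)
}

#' Write / read lesion records in display units
#'
#' The CSV carries D'/ADC columns in 1e-6 mm^2/s, f' in 1e-3 and index-map
#' percentages as-is (column names keep the internal names with a
#' `_x1e6` / `_x1e3` suffix documenting the scaling). Reading restores
#' internal units.
#'
#' @param records lesion record data.frame
#'   (see [simulateLesionCohort()]).
#' @param path CSV path.
#' @return `writeLesionRecords`: invisibly the path;
#'   `readLesionRecords`: the data.frame in internal units.
#' @export
writeLesionRecords <- function(records, path) {
    out <- records
    for (cl in intersect(c("mean_Dprime", "mean_ADC", "true_D"), names(out))) {
        out[[paste0(cl, "_x1e6")]] <- out[[cl]] * 1e6
        out[[cl]] <- NULL
    }
    for (cl in intersect(c("mean_fprime", "true_f"), names(out))) {
        out[[paste0(cl, "_x1e3")]] <- out[[cl]] * 1e3
        out[[cl]] <- NULL
    }
    utils::write.csv(out, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeLesionRecords
#' @export
readLesionRecords <- function(path) {
    rec <- utils::read.csv(path, stringsAsFactors = FALSE)
    for (cl in grep("_x1e6$", names(rec), value = TRUE)) {
        rec[[sub("_x1e6$", "", cl)]] <- rec[[cl]] / 1e6
        rec[[cl]] <- NULL
    }
    for (cl in grep("_x1e3$", names(rec), value = TRUE)) {
        rec[[sub("_x1e3$", "", cl)]] <- rec[[cl]] / 1e3
        rec[[cl]] <- NULL
    }
    rec
}

#' Default run configuration
#'
#' The full pipeline configuration as a plain named list, fully
#' serialisable to YAML: a run is reproducible from config + seed alone.
#'
#' @param seed integer master seed.
#' @return named list (see fields in the source).
#' @export
defaultRunConfig <- function(seed = 1) {
    list(
        seed = seed,
        b_values = c(0, 50, 800),
        scene = list(dim = c(64, 64, 16),
                     lesions = list(
                         list(class = "HCC", radius = 5),
                         list(class = "haemangioma", radius = 5),
                         list(class = "FNH", radius = 4))),
        mode = "biexponential",
        noise = list(model = "none", sigma = 0),
        cutoff_source = "published_defaults",
        derive = list(n_lesions = 500, roi_voxels = 25),
        thresholds = list(k_sd_hyper = 2, k_sd_exclude = 2),
        overlay = list(alpha = 0.4)
    )
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @return `readRunConfig`: the config list; `writeRunConfig`: invisibly
#'   the path.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}
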