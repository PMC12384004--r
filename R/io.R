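# NIfTI-1 volume I/O and cohort serialization.

#' Write an image or mask volume to NIfTI-1
#'
#' Volumes are stored as float64 and masks as uint8, so a read-back
#' round trip reproduces voxels and spacing exactly.
#'
#' @param volume an \linkS4class{ImageVolume} or
#'   \linkS4class{MaskVolume}.
#' @param path output file (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path) {
    stopifnot(is(volume, "ImageVolume"))
    img <- RNifti::asNifti(volume@voxels)
    RNifti::pixdim(img) <- volume@spacing
    dtype <- if (is(volume, "MaskVolume")) "uint8" else "double"
    tryCatch(RNifti::writeNifti(img, path, datatype = dtype),
             error = function(e)
                 stop("failed to write '", path, "': ",
                      conditionMessage(e)))
    invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path input file.
#' @param mask read as a \linkS4class{MaskVolume}?
#' @return An \linkS4class{ImageVolume} or \linkS4class{MaskVolume}
#'   with spacing taken from the header.
#' @export
readVolume <- function(path, mask = FALSE) {
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                    error = function(e)
                        stop("failed to read '", path, "': ",
                             conditionMessage(e)))
    v <- array(as.numeric(img), dim(img))
    sp <- RNifti::pixdim(img)[seq_len(3)]
    if (mask) MaskVolume(v, sp) else ImageVolume(v, sp)
}

#' Write a cohort to a directory
#'
#' Saves, per patient, the two phase volumes, the lung mask and every
#' GTV mask as NIfTI-1 files, plus one clinical CSV for the cohort with
#' the header \code{patient_id,cci,copd,smoking,age,dlco_baseline_pct,
#' dlco_post_pct} (empty field = missing post-treatment value).
#'
#' @param cohort a \linkS4class{RadiomicsCohort}.
#' @param directory output directory (created if needed).
#' @return Invisibly, the manifest data.frame (columns
#'   \code{patient_id}, \code{kind}, \code{path}); also written as
#'   \code{manifest.csv}.
#' @export
writeCohort <- function(cohort, directory) {
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(directory))
        stop("cannot create directory '", directory, "'")
    rows <- list()
    addRow <- function(pid, kind, path)
        rows[[length(rows) + 1]] <<- data.frame(
            patient_id = pid, kind = kind, path = path,
            stringsAsFactors = FALSE)
    for (p in cohort@patients) {
        pid <- p@patientId
        f0 <- file.path(directory, paste0(pid, "_phase0.nii.gz"))
        f50 <- file.path(directory, paste0(pid, "_phase50.nii.gz"))
        fl <- file.path(directory, paste0(pid, "_lungs.nii.gz"))
        writeVolume(p@phase0, f0);  addRow(pid, "phase0", f0)
        writeVolume(p@phase50, f50); addRow(pid, "phase50", f50)
        writeVolume(p@lungMask, fl); addRow(pid, "lung_mask", fl)
        for (l in seq_along(p@gtvMasks)) {
            fg <- file.path(directory,
                            sprintf("%s_gtv%02d.nii.gz", pid, l))
            writeVolume(p@gtvMasks[[l]], fg)
            addRow(pid, "gtv_mask", fg)
        }
    }
    clin <- cohort@clinical
    fcsv <- file.path(directory, "clinical.csv")
    write.csv(clin, fcsv, row.names = FALSE, na = "")
    addRow("", "clinical", fcsv)
    manifest <- do.call(rbind, rows)
    write.csv(manifest, file.path(directory, "manifest.csv"),
              row.names = FALSE)
    invisible(manifest)
}

#' Read a cohort back from a directory
#'
#' Reconstructs a \linkS4class{RadiomicsCohort} from the files written
#' by \code{\link{writeCohort}}.
#'
#' @param directory the cohort directory.
#' @return A \linkS4class{RadiomicsCohort} (latents and config are not
#'   serialized and come back empty).
#' @export
readCohort <- function(directory) {
    mpath <- file.path(directory, "manifest.csv")
    if (!file.exists(mpath)) stop("no manifest.csv in '", directory, "'")
    manifest <- read.csv(mpath, stringsAsFactors = FALSE)
    clin <- read.csv(file.path(directory, "clinical.csv"),
                     stringsAsFactors = FALSE)
    if (nrow(clin) > 0 && !"dlco_post_pct" %in% names(clin))
        clin$dlco_post_pct <- NA_real_
    patients <- lapply(seq_len(nrow(clin)), function(i) {
        pid <- clin$patient_id[i]
        sub <- manifest[manifest$patient_id == pid, ]
        getOne <- function(kind, mask = FALSE) {
            f <- sub$path[sub$kind == kind]
            stopifnot(length(f) >= 1)
            readVolume(f[1], mask = mask)
        }
        gtvPaths <- sub$path[sub$kind == "gtv_mask"]
        new("SyntheticPatient", patientId = pid,
            phase0 = getOne("phase0"), phase50 = getOne("phase50"),
            lungMask = getOne("lung_mask", mask = TRUE),
            gtvMasks = lapply(gtvPaths, readVolume, mask = TRUE),
            clinical = clin[i, , drop = FALSE])
    })
    new("RadiomicsCohort", patients = patients, clinical = clin,
        latents = data.frame(), config = NULL)
}

#' Write a feature table as CSV with a provenance sidecar
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param path CSV output path (patients x features, first column
#'   \code{patient_id}).
#' @param config optional extraction config stored as a JSON sidecar
#'   (\code{<path>.json}) for provenance.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(table, path, config = NULL) {
    m <- featureMatrix(table)
    df <- data.frame(patient_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE)
    if (!is.null(config)) {
        cfg <- config
        cfg$normalizationMap <- if (is.null(cfg$normalizationMap)) NULL
            else list(anchors = cfg$normalizationMap@anchors,
                      referenceValues = cfg$normalizationMap@referenceValues)
        jsonlite::write_json(cfg, paste0(path, ".json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(path)
}

#' Read a feature table written by \code{\link{writeFeatureTable}}
#'
#' @param path the CSV path.
#' @return A \linkS4class{FeatureTable}.
#' @export
readFeatureTable <- function(path) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$patient_id
    FeatureTable(m)
}
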