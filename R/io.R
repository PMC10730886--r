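# External interfaces: NIfTI volumes, participant TSV, ground-truth JSON.

#' Write a 3-D or 4-D array as NIfTI-1
#'
#' Integer arrays (atlas/sub-parcel labels) are stored as integer volumes,
#' numeric maps as float volumes.
#'
#' @param arr array to write
#' @param path output path (`.nii` / `.nii.gz`)
#' @param voxel_dims voxel dimensions in mm
#' @return the path, invisibly
#' @export
write_nifti_volume <- function(arr, path, voxel_dims = c(3, 3, 3.5)) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_dims, rep(1, length(dim(arr)) - 3L))
  dt <- if (is.integer(arr)) "int32" else "float64"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file
#' @param integer coerce to integer labels
#' @return array
#' @export
read_nifti_volume <- function(path, integer = FALSE) {
  a <- as.array(RNifti::readNifti(path))
  attributes(a) <- list(dim = dim(a))
  if (integer) storage.mode(a) <- "integer"
  a
}

#' Write the participant table as TSV
#'
#' Columns: subject_id, group, age, sex, mean_dvars, tiv, ace_r, pspr_s,
#' cbi_r.
#'
#' @param subjects participant table
#' @param path output TSV path
#' @return the path, invisibly
#' @export
write_participants_tsv <- function(subjects, path) {
  cols <- intersect(c("subject_id", "group", "age", "sex", "mean_dvars",
                      "tiv", "ace_r", "pspr_s", "cbi_r"), names(subjects))
  utils::write.table(subjects[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a participant TSV
#' @param path TSV path
#' @return data.frame with `group` and `sex` as factors
#' @export
read_participants_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("group" %in% names(d))
    d$group <- factor(d$group, levels = intersect(
      c("Control", "PSP", "CBS", "bvFTD"), unique(d$group)))
  if ("sex" %in% names(d)) d$sex <- factor(d$sex, levels = c("F", "M"))
  d
}

#' Write a synthetic study to disk
#'
#' Atlas and sub-parcel labels as integer NIfTI, PET maps as a 4-D float
#' NIfTI, participants as TSV, region/sub-parcel tables as TSV, and the
#' ground truth (loadings, coupling slopes, clinical coefficients) as JSON.
#' Per-subject fMRI volumes are written only when `fmri = TRUE` (they are
#' large and fully reproducible from the configuration seed).
#'
#' @param study a `sim_study`
#' @param dir output directory
#' @param fmri also write per-subject 4-D fMRI volumes
#' @return invisibly, the output directory
#' @export
write_study <- function(study, dir, fmri = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vd <- c(3, 3, 3.5)
  write_nifti_volume(study$atlas$labels, file.path(dir, "atlas.nii.gz"), vd)
  write_nifti_volume(study$subparcellation$labels,
                     file.path(dir, "subparcels.nii.gz"), vd)
  write_nifti_volume(study$pet$maps, file.path(dir, "pet_bpnd.nii.gz"), vd)
  write_participants_tsv(study$subjects, file.path(dir, "participants.tsv"))
  utils::write.table(study$atlas$region_table, file.path(dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$subparcellation$table,
                     file.path(dir, "subparcel_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- list(loadings = study$truth$loadings,
             coupling_slope = as.list(study$truth$coupling_slope),
             clinical = study$truth$clinical,
             seed = study$config$seed)
  writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = 12),
             file.path(dir, "ground_truth.json"))
  if (fmri) {
    for (s in seq_len(nrow(study$subjects))) {
      vol <- simulate_subject_fmri(study, s, voxelwise = TRUE)
      write_nifti_volume(vol, file.path(dir, sprintf(
        "%s_bold.nii.gz", study$subjects$subject_id[s])), vd)
    }
  }
  invisible(dir)
}
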