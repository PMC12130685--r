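#' Write a 3D/4D volume as NIfTI-1
#'
#' @param volume numeric array
#' @param path output path (`.nii` or `.nii.gz`)
#' @param voxel_size_mm isotropic spacing recorded in the header
#' @return the path, invisibly
#' @export
write_volume <- function(volume, path, voxel_size_mm = 1) {
  img <- RNifti::asNifti(volume * 1,
                         pixdim = rep(voxel_size_mm, min(3, length(dim(volume)))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file
#' @return numeric array
#' @export
read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim(v))
}

#' Write FSL-style bval/bvec text files
#'
#' One row of b-values; three rows of direction components.
#'
#' @param bvals,bvecs acquisition shells and directions
#' @param bval_path,bvec_path output paths
#' @return invisibly, the two paths
#' @export
write_bvals_bvecs <- function(bvals, bvecs, bval_path, bvec_path) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(as.matrix(bvecs)), 1, paste, collapse = " "), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read FSL-style bval/bvec text files
#'
#' @param bval_path,bvec_path input paths
#' @return list with `bvals` and n x 3 `bvecs`
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) == 3) bv <- t(bv)
  if (nrow(bv) != length(bvals)) stop_invalid("bvals/bvecs length mismatch")
  dimnames(bv) <- NULL
  list(bvals = bvals, bvecs = bv)
}

#' Write / read the echo-time JSON sidecar
#'
#' @param times_ms echo-preparation times (ms)
#' @param path JSON path
#' @return the path (write) or numeric vector (read)
#' @export
write_echo_times <- function(times_ms, path) {
  jsonlite::write_json(list(t2prep_times_ms = times_ms), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_echo_times
#' @export
read_echo_times <- function(path) {
  as.numeric(jsonlite::read_json(path, simplifyVector = TRUE)$t2prep_times_ms)
}

#' Write the biomarker table as CSV
#'
#' @param table biomarker table
#' @param path CSV path
#' @return the path, invisibly
#' @export
write_biomarker_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a biomarker table CSV
#'
#' @param path CSV path
#' @return data.frame of class `glymap_biomarker_table`
#' @export
read_biomarker_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("glymap_biomarker_table", "data.frame")
  tab
}
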