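#' Write a volume to NIfTI
#'
#' @param vol a [volume_image].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  im <- RNifti::asNifti(vol$values)
  RNifti::pixdim(im) <- vol$spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' Voxel spacing is taken from the NIfTI header.
#' @param path NIfTI file.
#' @param modality `"t1post"` or `"flair"`.
#' @return A [volume_image].
#' @export
read_volume <- function(path, modality) {
  im <- RNifti::readNifti(path)
  volume_image(array(as.numeric(im), dim = dim(im)),
               RNifti::pixdim(im)[1:3], modality)
}

#' Write a mask to NIfTI (0/1 encoded)
#' @param mask a [roi_mask].
#' @param spacing voxel spacing in mm.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, spacing, path) {
  stopifnot(inherits(mask, "roi_mask"))
  im <- RNifti::asNifti(array(as.integer(mask$mask), dim = dim(mask$mask)))
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a mask from NIfTI
#' @param path NIfTI file (nonzero = in mask).
#' @param role `"tumor"` or `"nawm"`.
#' @return A [roi_mask].
#' @export
read_mask <- function(path, role) {
  im <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(im) != 0, dim = dim(im)), role)
}

write_phantom_patient <- function(ph, dir, pid) {
  p <- function(suffix) file.path(dir, paste0(pid, "_", suffix, ".nii.gz"))
  write_volume(ph$t1post, p("t1post"))
  write_volume(ph$flair, p("flair"))
  write_mask(ph$tumor_t1post, ph$t1post$spacing, p("tumor_t1post"))
  write_mask(ph$tumor_flair, ph$flair$spacing, p("tumor_flair"))
  write_mask(ph$nawm, ph$t1post$spacing, p("nawm"))
  list(t1post_path = p("t1post"), flair_path = p("flair"),
       tumor_t1post_path = p("tumor_t1post"),
       tumor_flair_path = p("tumor_flair"), nawm_path = p("nawm"))
}

#' Read one patient record from a cohort manifest row
#'
#' @param row a single-row data.frame with `t1post_path`, `flair_path`,
#'   `tumor_t1post_path`, `tumor_flair_path` and `nawm_path` columns (as
#'   written by [generate_cohort()]).
#' @return Patient record usable by [extract_all()].
#' @export
read_patient <- function(row) {
  tumor_t1 <- read_mask(row$tumor_t1post_path, "tumor")
  nawm <- read_mask(row$nawm_path, "nawm")
  list(t1post = read_volume(row$t1post_path, "t1post"),
       flair = read_volume(row$flair_path, "flair"),
       tumor = tumor_t1, tumor_t1post = tumor_t1,
       tumor_flair = read_mask(row$tumor_flair_path, "tumor"),
       nawm = nawm)
}
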