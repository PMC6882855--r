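#' Construct a CT volume
#'
#' A \code{ct_volume} is a 3D scalar field of CT intensities with per-axis
#' voxel spacing in mm. Intensities are Hounsfield units (HU) before
#' \code{\link{normalize_hu}} and dimensionless values in [0, 1] afterwards.
#' Axis order is fixed internally as (x, y, z): the first two axes span the
#' axial plane, the third is the scanner z direction. The NIfTI affine, when
#' present, is carried through untouched.
#'
#' @param data 3D numeric array.
#' @param spacing numeric triple, voxel size in mm per axis (x, y, z).
#' @param affine optional 4x4 voxel-to-world matrix, passed through to output
#'   files unmodified.
#' @param normalized logical flag; \code{TRUE} once intensities have been
#'   mapped to [0, 1].
#' @return An object of class \code{ct_volume} with fields \code{data},
#'   \code{spacing}, \code{affine} and \code{normalized}.
#' @seealso \code{\link{read_volume}}, \code{\link{normalize_hu}}
#' @export
ct_volume <- function(data, spacing, affine = NULL, normalized = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("ct_volume: data must be a 3D array, got %s dimension(s)",
          paste(length(dim(data))))
  spacing <- check_triple(spacing, "spacing")
  if (normalized && (min(data) < 0 || max(data) > 1))
    stopf("ct_volume: normalized volume has values outside [0, 1]")
  structure(list(data = data, spacing = spacing, affine = affine,
                 normalized = isTRUE(normalized)),
            class = "ct_volume")
}

#' Construct a label volume
#'
#' A binary 3D mask sharing its paired CT volume's grid and spacing. The
#' \code{role} records what the mask delineates: the haemorrhage reference
#' standard, the cranial cavity (the prediction domain: brain, meninges,
#' ventricles, CSF — excluding skull), or a model prediction.
#'
#' @param data 3D array with values in \{0, 1\} (logical arrays are accepted
#'   and converted).
#' @param spacing numeric triple, voxel size in mm per axis.
#' @param role one of \code{"ich"}, \code{"cranial_cavity"},
#'   \code{"prediction"}.
#' @param affine optional 4x4 voxel-to-world matrix, passed through.
#' @return An object of class \code{label_volume}.
#' @export
label_volume <- function(data, spacing,
                         role = c("ich", "cranial_cavity", "prediction"),
                         affine = NULL) {
  role <- match.arg(role)
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("label_volume: data must be a 3D array")
  if (is.logical(data)) data <- array(as.numeric(data), dim(data))
  if (!all(data %in% c(0, 1)))
    stopf("label_volume: mask values must be 0 or 1")
  spacing <- check_triple(spacing, "spacing")
  structure(list(data = data, spacing = spacing, affine = affine, role = role),
            class = "label_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              if (x$normalized) "normalized [0,1]" else "Hounsfield units"))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume role=%s> %s voxels, %d foreground, spacing %s mm\n",
              x$role, paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' Read a CT volume from a NIfTI file
#'
#' Spacing is taken from the NIfTI \code{pixdim} header field; the affine
#' (qform/sform) is kept and passed through on write. Data are not modified.
#'
#' @param path path to a readable 3D NIfTI file (.nii or .nii.gz).
#' @return A \code{\link{ct_volume}}.
#' @export
read_volume <- function(path) {
  hdr <- read_nifti_checked(path)
  ct_volume(hdr$data, hdr$spacing, affine = hdr$affine, normalized = FALSE)
}

#' Read a binary mask from a NIfTI file
#'
#' @param path path to a readable 3D NIfTI file containing only 0/1 values.
#' @param role mask role, see \code{\link{label_volume}}.
#' @return A \code{\link{label_volume}}.
#' @export
read_mask <- function(path, role = c("ich", "cranial_cavity", "prediction")) {
  hdr <- read_nifti_checked(path)
  label_volume(hdr$data, hdr$spacing, role = match.arg(role),
               affine = hdr$affine)
}

read_nifti_checked <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stopf("cannot read NIfTI: file not found: %s", paste(path, collapse = ", "))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]  # degenerate 4th axis
  if (length(d) != 3L)
    stopf("expected 3D NIfTI data in %s, got %dD", path, length(dim(img)))
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stopf("non-positive voxel spacing (%s) in %s",
          paste(signif(sp, 3), collapse = ", "), path)
  aff <- tryCatch(structure(as.matrix(RNifti::xform(img)), dimnames = NULL),
                  error = function(e) NULL)
  list(data = array(as.numeric(img), d), spacing = as.numeric(sp),
       affine = aff)
}

#' Write a volume or mask to a NIfTI file
#'
#' @param vol a \code{\link{ct_volume}} or \code{\link{label_volume}}.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume") || inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$data)
  if (!is.null(vol$affine))
    img <- RNifti::`qform<-`(img, value = structure(vol$affine, code = 2L))
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Normalize CT intensities to [0, 1]
#'
#' Hounsfield values in [-200, 200] are mapped linearly onto [0, 1]; values
#' below and above the relevant range are set to the scaled minimum (0) and
#' maximum (1) respectively. The bounds map exactly: -200 HU -> 0,
#' +200 HU -> 1. Re-normalizing an already normalized volume is an error,
#' guarding against silent double scaling.
#'
#' @param vol an unnormalized \code{\link{ct_volume}}.
#' @return The normalized \code{ct_volume} (flag set).
#' @export
normalize_hu <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$normalized)
    stopf("normalize_hu: volume is already normalized")
  vol$data <- pmin(pmax((vol$data + 200) / 400, 0), 1)
  vol$normalized <- TRUE
  vol
}

#' Resample a volume or mask to a target voxel spacing
#'
#' Intensities are interpolated trilinearly; label masks use nearest-neighbour
#' interpolation so they remain binary. The output grid has
#' \code{round(dim * spacing / target)} voxels per axis, conserving physical
#' extent to within one target voxel. Voxel values are treated as point
#' samples at voxel centres.
#'
#' @param vol a \code{\link{ct_volume}} or \code{\link{label_volume}}.
#' @param target_spacing numeric triple, target voxel size in mm.
#' @return Same class as \code{vol}, on the new grid.
#' @export
resample <- function(vol, target_spacing) {
  target_spacing <- check_triple(target_spacing, "target_spacing")
  is_label <- inherits(vol, "label_volume")
  if (!is_label && !inherits(vol, "ct_volume"))
    stopf("resample: need a ct_volume or label_volume")
  d <- dim(vol$data)
  if (any(d < 2)) stopf("resample: degenerate axis (single voxel) in input")
  nd <- pmax(round(d * vol$spacing / target_spacing), 1L)
  if (any(nd < 2)) stopf("resample: target spacing collapses an axis to a single voxel")

  # Source (fractional) index of each target voxel centre, per axis.
  src <- lapply(1:3, function(a) {
    s <- ((seq_len(nd[a]) - 0.5) * target_spacing[a]) / vol$spacing[a] + 0.5
    pmin(pmax(s, 1), d[a])
  })
  if (is_label) {
    idx <- lapply(1:3, function(a) pmin(pmax(round(src[[a]]), 1L), d[a]))
    out <- vol$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    res <- vol
    res$data <- array(out, nd)
    res$spacing <- target_spacing
    return(res)
  }
  i0 <- lapply(1:3, function(a) pmin(pmax(floor(src[[a]]), 1L), d[a] - 1L))
  tfrac <- lapply(1:3, function(a) src[[a]] - i0[[a]])
  acc <- array(0, nd)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- outer(outer(if (cx) tfrac[[1]] else 1 - tfrac[[1]],
                     if (cy) tfrac[[2]] else 1 - tfrac[[2]]),
               if (cz) tfrac[[3]] else 1 - tfrac[[3]])
    acc <- acc + array(w, nd) *
      vol$data[i0[[1]] + cx, i0[[2]] + cy, i0[[3]] + cz, drop = FALSE]
  }
  res <- vol
  res$data <- acc
  res$spacing <- target_spacing
  if (res$normalized) res$data <- pmin(pmax(res$data, 0), 1)
  res
}
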