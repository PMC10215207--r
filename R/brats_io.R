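# BraTS-layout case handling: <root>/<case_id>/<case_id>_<modality>.nii[.gz]
# with modality in {flair, t1, t1ce, t2, seg}.

BRATS_MODALITIES <- c("flair", "t1", "t1ce", "t2")

#' Construct an MRI case
#'
#' Bundles the four co-registered modality volumes of one subject with an
#' optional ground-truth label volume.  All five volumes must share one
#' shape; label values must lie in \{0,1,2,3,4\} (3 marks a missing label
#' in the upstream annotation and is remapped to background downstream).
#'
#' @param flair,t1,t1ce,t2 3D numeric arrays of identical shape.
#' @param seg Optional 3D integer label volume, same shape.
#' @param case_id Subject identifier.
#' @param spacing Voxel size in mm per axis.
#' @return An object of class `mri_case`.
#' @export
mri_case <- function(flair, t1, t1ce, t2, seg = NULL,
                     case_id = "case", spacing = c(1, 1, 1)) {
  vols <- list(flair = flair, t1 = t1, t1ce = t1ce, t2 = t2)
  shp <- dim(flair)
  if (length(shp) != 3L) stop("modality volumes must be 3D arrays")
  for (m in names(vols)) {
    if (!identical(dim(vols[[m]]), shp)) {
      stop("shape mismatch: ", m, " has dims (",
           paste(dim(vols[[m]]), collapse = ","),
           ") but flair has (", paste(shp, collapse = ","), ")")
    }
  }
  if (!is.null(seg)) {
    if (!identical(dim(seg), shp)) {
      stop("shape mismatch: seg has dims (", paste(dim(seg), collapse = ","),
           ") but flair has (", paste(shp, collapse = ","), ")")
    }
    bad <- setdiff(unique(as.vector(seg)), c(0, 1, 2, 3, 4))
    if (length(bad) > 0) {
      stop("seg contains labels outside {0,1,2,3,4}: ",
           paste(bad, collapse = ", "))
    }
    if (any(seg == 3)) {
      warning("seg of case '", case_id,
              "' contains label 3 (missing label); it will be treated as background")
    }
  }
  structure(list(case_id = case_id, flair = flair, t1 = t1, t1ce = t1ce,
                 t2 = t2, seg = seg, shape = shp, spacing = spacing),
            class = "mri_case")
}

#' @export
print.mri_case <- function(x, ...) {
  cat("<mri_case> ", x$case_id, "  ", paste(x$shape, collapse = "x"),
      " voxels @ ", paste(x$spacing, collapse = "x"), " mm",
      if (is.null(x$seg)) "  (no labels)" else "  (labeled)", "\n", sep = "")
  invisible(x)
}

find_modality_file <- function(case_dir, suffix) {
  base <- basename(case_dir)
  cands <- file.path(case_dir, paste0(base, "_", suffix, c(".nii.gz", ".nii")))
  cands <- cands[file.exists(cands)]
  if (length(cands) == 0) return(NULL)
  cands[1]  # .nii.gz preferred when both exist
}

#' Load a BraTS-layout case directory
#'
#' Expects files `<case_id>_<modality>.nii[.gz]` for modalities flair,
#' t1, t1ce, t2 and optionally seg, where `case_id` is the directory
#' basename.  A missing image modality is an error naming the missing
#' suffix; a missing seg simply yields an unlabeled case.
#'
#' @param case_dir Path to the case directory.
#' @return An [mri_case] object.
#' @export
load_case <- function(case_dir) {
  if (!dir.exists(case_dir)) stop("case directory not found: ", case_dir)
  vols <- list()
  for (m in BRATS_MODALITIES) {
    f <- find_modality_file(case_dir, m)
    if (is.null(f)) stop("missing modality file with suffix '_", m,
                         "' in ", case_dir)
    vols[[m]] <- read_nifti(f)
  }
  segf <- find_modality_file(case_dir, "seg")
  seg <- if (is.null(segf)) NULL else read_nifti(segf)$data
  mri_case(flair = vols$flair$data, t1 = vols$t1$data,
           t1ce = vols$t1ce$data, t2 = vols$t2$data, seg = seg,
           case_id = basename(normalizePath(case_dir)),
           spacing = vols$flair$spacing)
}

#' Save one volume as NIfTI
#'
#' Thin wrapper around [write_nifti] used when emitting phantom cases and
#' predicted masks.
#'
#' @inheritParams write_nifti
#' @param volume 3D numeric array.
#' @export
save_volume <- function(volume, path, spacing = c(1, 1, 1),
                        create_dirs = FALSE) {
  write_nifti(volume, path, spacing = spacing, create_dirs = create_dirs)
}

#' Enumerate case directories under a root
#'
#' A subdirectory counts as a case when it contains a `*_flair.nii[.gz]`
#' file.  The result is lexicographically sorted, hence deterministic.
#'
#' @param root Dataset root directory.
#' @return Character vector of case directory paths.
#' @export
discover_cases <- function(root) {
  if (!dir.exists(root)) stop("dataset root not found: ", root)
  subs <- list.dirs(root, recursive = FALSE)
  keep <- vapply(subs, function(d) !is.null(find_modality_file(d, "flair")),
                 logical(1))
  sort(subs[keep])
}
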