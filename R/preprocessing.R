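# Intensity normalization, resampling to the network grid, derivation of
# the nested WT/TC/ET binary targets, and channel stacking.

#' Construct a modality stack
#'
#' 4-channel tensor of min-max normalized modalities in the fixed order
#' (Flair, T1, T1ce, T2), stored with dim `(4, D, H, W)`.
#'
#' @param data Numeric array of dim `(4, D, H, W)` with values in `[0,1]`.
#' @param case_id Subject identifier.
#' @export
modality_stack <- function(data, case_id = "case") {
  if (length(dim(data)) != 4L || dim(data)[1] != 4L)
    stop("modality_stack data must have dim (4, D, H, W)")
  if (min(data) < 0 || max(data) > 1)
    stop("modality_stack values must lie in [0, 1]")
  structure(list(data = data, case_id = case_id), class = "modality_stack")
}

#' Construct a mask stack
#'
#' 3-channel binary tensor in the fixed order (WT, TC, ET), stored with
#' dim `(3, D, H, W)`.  Enforces the voxelwise nesting ET <= TC <= WT that
#' follows from the label-set definitions.
#'
#' @param data Binary array of dim `(3, D, H, W)`.
#' @param case_id Subject identifier.
#' @export
mask_stack <- function(data, case_id = "case") {
  if (length(dim(data)) != 4L || dim(data)[1] != 3L)
    stop("mask_stack data must have dim (3, D, H, W)")
  if (!all(data %in% c(0, 1))) stop("mask_stack values must be binary")
  if (any(data[3, , , ] > data[2, , , ]) || any(data[2, , , ] > data[1, , , ]))
    stop("mask nesting violated: require ET <= TC <= WT voxelwise")
  structure(list(data = data, case_id = case_id), class = "mask_stack")
}

#' Min-max normalize a volume to [0, 1]
#'
#' `(v - min) / (max - min)` elementwise; a constant volume maps to all
#' zeros (the degenerate-range convention).  Applied per modality and per
#' case, since absolute MR intensities are not comparable across scans.
#'
#' @param volume Numeric array of finite values.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(volume) {
  if (!all(is.finite(volume))) stop("minmax_normalize: non-finite values in input")
  lo <- min(volume)
  hi <- max(volume)
  if (hi == lo) return(array(0, dim = dim(volume) %||% length(volume)))
  (volume - lo) / (hi - lo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resize a 3D volume
#'
#' Resamples to `target_shape` on an align-corners grid: trilinear
#' interpolation for images, nearest neighbour for label volumes (so the
#' output value set is a subset of the input's).  An identity target
#' shape returns the values unchanged in both modes.
#'
#' @param volume 3D numeric array.
#' @param target_shape Integer vector `(D, H, W)` of positive dims.
#' @param mode `"image"` (trilinear) or `"label"` (nearest neighbour).
#' @return Array of dim `target_shape`.
#' @export
resize_volume <- function(volume, target_shape, mode = c("image", "label")) {
  mode <- match.arg(mode)
  if (length(dim(volume)) != 3L) stop("resize_volume expects a 3D array")
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 1L))
    stop("target_shape must be three positive integers")
  if (identical(dim(volume), target_shape)) return(volume)
  if (mode == "image") {
    x <- array(volume, dim = c(1L, dim(volume)))
    out <- cpp_trilinear_fwd(x, target_shape)
    array(out, dim = target_shape)
  } else {
    src_idx <- function(n_in, n_out) {
      if (n_out == 1L) return(as.integer(round((n_in - 1) / 2)) + 1L)
      as.integer(round((0:(n_out - 1)) * (n_in - 1) / (n_out - 1))) + 1L
    }
    d <- dim(volume)
    volume[src_idx(d[1], target_shape[1]),
           src_idx(d[2], target_shape[2]),
           src_idx(d[3], target_shape[3]), drop = FALSE]
  }
}

#' Derive the nested WT/TC/ET binary masks from a label volume
#'
#' From the 4-valued expert labeling (0 background, 1 non-enhancing tumor
#' core, 2 peritumoral edema, 4 enhancing tumor): WT marks labels
#' \{1,2,4\}, TC marks \{1,4\}, ET marks \{4\}.  Label 3 ("missing
#' label") is treated as background with a warning.
#'
#' @param seg 3D integer label volume with values in \{0,1,2,3,4\}.
#' @param case_id Subject identifier carried onto the result.
#' @return A [mask_stack] of dim `(3, D, H, W)`.
#' @export
derive_masks <- function(seg, case_id = "case") {
  vals <- unique(as.vector(seg))
  bad <- setdiff(vals, c(0, 1, 2, 3, 4))
  if (length(bad) > 0)
    stop("seg contains labels outside {0,...,4}: ", paste(bad, collapse = ", "))
  if (3 %in% vals)
    warning("seg contains label 3 (missing label); treated as background")
  d <- dim(seg)
  out <- array(0, dim = c(3L, d))
  out[1, , , ] <- as.numeric(seg == 1 | seg == 2 | seg == 4)
  out[2, , , ] <- as.numeric(seg == 1 | seg == 4)
  out[3, , , ] <- as.numeric(seg == 4)
  mask_stack(out, case_id = case_id)
}

#' Preprocess one case to paired network tensors
#'
#' Each modality is min-max normalized, then trilinearly resized to
#' `target_shape`, then stacked in the fixed channel order (Flair, T1,
#' T1ce, T2).  If the case carries labels, seg is resized with nearest
#' neighbour first and the three masks are derived from the resized
#' labels, which keeps the three channels mutually consistent.
#'
#' @param case An [mri_case].
#' @param target_shape Network grid `(D, H, W)`, default `c(128,128,128)`.
#' @return List with elements `stack` ([modality_stack]) and `masks`
#'   ([mask_stack] or `NULL` for unlabeled cases).
#' @export
stack_case <- function(case, target_shape = c(128L, 128L, 128L)) {
  stopifnot(inherits(case, "mri_case"))
  target_shape <- as.integer(target_shape)
  img <- array(0, dim = c(4L, target_shape))
  mods <- list(case$flair, case$t1, case$t1ce, case$t2)
  for (i in seq_along(mods)) {
    img[i, , , ] <- resize_volume(minmax_normalize(mods[[i]]),
                                  target_shape, mode = "image")
  }
  # trilinear weights are convex, but guard against float round-off
  img[img < 0] <- 0
  img[img > 1] <- 1
  masks <- NULL
  if (!is.null(case$seg)) {
    seg_r <- resize_volume(case$seg, target_shape, mode = "label")
    masks <- derive_masks(seg_r, case_id = case$case_id)
  }
  list(stack = modality_stack(img, case_id = case$case_id), masks = masks)
}
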