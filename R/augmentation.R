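# In-plane rotation augmentation.  Rotations act on every axial slice
# (the plane of the first two array axes) about the slice center, with
# bilinear resampling for images and nearest neighbour for labels, and
# zero fill for regions rotated in from outside the field of view.

#' Define an augmentation plan
#'
#' The default plan holds four rotations evenly spread over the stated
#' \[-5, +15\] degree range, so each original case expands into five
#' training pairs (original + 4 rotated copies), reproducing the
#' 369 -> 1845 dataset expansion.
#'
#' @param angles_deg Nonzero rotation angles in degrees, each within
#'   \[-5, 15\].
#' @param include_original Keep the unrotated pair (default `TRUE`).
#' @return An object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(angles_deg = c(-5, 5, 10, 15),
                              include_original = TRUE) {
  if (any(angles_deg == 0)) stop("plan angles must be nonzero")
  if (any(angles_deg < -5 | angles_deg > 15))
    stop("plan angles must lie within [-5, 15] degrees")
  structure(list(angles_deg = angles_deg,
                 include_original = isTRUE(include_original)),
            class = "augmentation_plan")
}

#' Expansion factor of a plan
#' @param plan An [augmentation_plan].
#' @export
expansion_factor <- function(plan) {
  length(plan$angles_deg) + as.integer(plan$include_original)
}

# Precompute bilinear/nearest sampling of a rotated 2D grid, applied to
# all slices of a volume at once (the same in-plane transform for every
# axial slice).
rotate_slices <- function(volume, angle_deg, mode) {
  d <- dim(volume)
  nd <- d[1]; nh <- d[2]; ns <- d[3]
  theta <- angle_deg * pi / 180
  cx <- (nd + 1) / 2
  cy <- (nh + 1) / 2
  gi <- rep(seq_len(nd), times = nh) - cx
  gj <- rep(seq_len(nh), each = nd) - cy
  # inverse rotation: sample source at R(-theta) * (i,j)
  si <- cx + cos(theta) * gi + sin(theta) * gj
  sj <- cy - sin(theta) * gi + cos(theta) * gj
  m <- matrix(volume, nrow = nd * nh, ncol = ns)
  out <- matrix(0, nrow = nd * nh, ncol = ns)
  if (mode == "label") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= nd & rj >= 1 & rj <= nh
    out[ok, ] <- m[(rj[ok] - 1) * nd + ri[ok], ]
  } else {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    for (corner in 1:4) {
      right <- corner %in% c(2, 4)
      lower <- corner >= 3
      ci <- i0 + right
      cj <- j0 + lower
      w <- (if (right) fi else 1 - fi) * (if (lower) fj else 1 - fj)
      ok <- ci >= 1 & ci <= nd & cj >= 1 & cj <= nh & w > 0
      if (any(ok)) {
        out[ok, ] <- out[ok, ] + w[ok] * m[(cj[ok] - 1) * nd + ci[ok], ]
      }
    }
  }
  array(out, dim = d)
}

#' Rotate a volume in the axial plane
#'
#' @param volume 3D numeric array.
#' @param angle_deg Rotation angle in degrees, |angle| <= 180.
#' @param mode `"image"` (bilinear) or `"label"` (nearest neighbour).
#' @return Rotated array of identical shape; exposed corners are 0.
#' @export
rotate_volume <- function(volume, angle_deg, mode = c("image", "label")) {
  mode <- match.arg(mode)
  if (length(dim(volume)) != 3L) stop("rotate_volume expects a 3D array")
  if (!all(is.finite(volume))) stop("rotate_volume: non-finite values in input")
  if (abs(angle_deg) > 180) stop("|angle_deg| must be <= 180")
  if (angle_deg == 0) return(volume)
  rotate_slices(volume, angle_deg, mode)
}

#' Rotate a paired modality/mask stack
#'
#' Applies one angle to all 4 image channels (bilinear) and all 3 mask
#' channels (nearest neighbour).  Nearest-neighbour resampling uses the
#' same source voxel for every channel, so the ET <= TC <= WT nesting is
#' preserved exactly.
#'
#' @param stack A [modality_stack].
#' @param masks A [mask_stack] of matching spatial shape.
#' @param angle_deg Rotation angle in degrees.
#' @return List with rotated `stack` and `masks`.
#' @export
rotate_case <- function(stack, masks, angle_deg) {
  stopifnot(inherits(stack, "modality_stack"), inherits(masks, "mask_stack"))
  if (!identical(dim(stack$data)[-1], dim(masks$data)[-1]))
    stop("stack and masks have mismatched spatial shapes")
  img <- stack$data
  for (c in 1:4) {
    img[c, , , ] <- rotate_volume(stack$data[c, , , ], angle_deg, "image")
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  msk <- masks$data
  for (c in 1:3) {
    msk[c, , , ] <- rotate_volume(masks$data[c, , , ], angle_deg, "label")
  }
  list(stack = modality_stack(img, stack$case_id),
       masks = mask_stack(msk, masks$case_id))
}

#' Expand a dataset by rotation
#'
#' Deterministic, content-independent expansion: each original pair is
#' followed by its rotated copies in plan order, giving exactly
#' `length(cases) * expansion_factor(plan)` output pairs (with the
#' default plan: 369 cases -> 1845 pairs).
#'
#' @param cases List of `list(stack=, masks=)` pairs.
#' @param plan An [augmentation_plan].
#' @return List of `list(stack=, masks=)` pairs.
#' @export
expand_dataset <- function(cases, plan = augmentation_plan()) {
  if (!plan$include_original && length(plan$angles_deg) == 0)
    stop("plan produces no output")
  out <- vector("list", length(cases) * expansion_factor(plan))
  k <- 0L
  for (cs in cases) {
    if (plan$include_original) {
      k <- k + 1L
      out[[k]] <- cs
    }
    for (a in plan$angles_deg) {
      k <- k + 1L
      out[[k]] <- rotate_case(cs$stack, cs$masks, a)
    }
  }
  out
}
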