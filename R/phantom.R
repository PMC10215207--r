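# Synthetic brain phantoms in the BraTS layout: a smooth ellipsoidal
# "brain" on zero background carrying (with configurable probability) a
# nested spherical lesion — enhancing core (label 4), non-enhancing
# shell (label 1), edema shell (label 2) — rendered into four
# pseudo-modalities with distinct, fixed region contrasts plus Gaussian
# noise.  Geometry is deliberately idealized: the tests need mask
# algebra and learnable contrasts, not anatomical realism.

# region intensity table (rows: modality; cols: brain, edema, NET, ET).
# Chosen to mimic the qualitative contrast of real glioma MRI: edema
# brightest on Flair/T2, enhancing core brightest on T1ce.
PHANTOM_CONTRAST <- rbind(
  flair = c(brain = 0.35, ed = 0.90, net = 0.55, et = 0.60),
  t1    = c(brain = 0.60, ed = 0.35, net = 0.30, et = 0.45),
  t1ce  = c(brain = 0.40, ed = 0.35, net = 0.30, et = 0.95),
  t2    = c(brain = 0.40, ed = 0.80, net = 0.60, et = 0.70)
)

#' Phantom specification
#'
#' @param shape Voxel grid `(D, H, W)`; the default 32-cube keeps CPU
#'   training of the recovery experiment inside minutes, while the full
#'   240 x 240 x 155 BraTS grid is equally supported.
#' @param tumor_probability Probability that a case carries a lesion.
#' @param tumor_radius_range Outer (edema) radius range in voxels; the
#'   non-enhancing and enhancing radii are fixed fractions (2/3, 1/3) of
#'   the outer radius.  Must fit inside the brain ellipsoid.
#' @param noise_sigma Standard deviation of additive Gaussian intensity
#'   noise (intensities are on a 0-1 scale).
#' @param seed Seed making each phantom fully deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 32L), tumor_probability = 1,
                         tumor_radius_range = NULL, noise_sigma = 0.03,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("shape must be three dims of at least 8 voxels")
  if (is.null(tumor_radius_range)) {
    tumor_radius_range <- pmax(c(3, 4), round(c(0.16, 0.28) * min(shape)))
  }
  if (tumor_probability <= 0 || tumor_probability > 1)
    stop("tumor_probability must lie in (0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  semi <- 0.45 * shape
  if (max(tumor_radius_range) >= min(semi))
    stop("tumor radii exceed the brain ellipsoid for this shape")
  structure(list(shape = shape, tumor_probability = tumor_probability,
                 tumor_radius_range = tumor_radius_range,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom case
#'
#' Deterministic given `spec$seed`: the same spec yields voxel-identical
#' volumes.  The label volume uses the BraTS value convention
#' \{0, 1, 2, 4\} and by construction satisfies the ET within TC within
#' WT nesting with all three regions nonempty whenever a lesion is
#' present.
#'
#' @param spec A [phantom_spec].
#' @param case_id Identifier for the emitted case.
#' @return An [mri_case] with `seg` always present.
#' @export
generate_phantom <- function(spec = phantom_spec(), case_id = "phantom_001") {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  ctr <- (d + 1) / 2
  semi <- 0.45 * d
  gx <- (seq_len(d[1]) - ctr[1]) / semi[1]
  gy <- (seq_len(d[2]) - ctr[2]) / semi[2]
  gz <- (seq_len(d[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)  # ellipsoidal radius^2
  brain <- r2 <= 1

  seg <- array(0, dim = d)
  has_tumor <- runif(1) < spec$tumor_probability
  if (has_tumor) {
    rr <- spec$tumor_radius_range
    r_out <- runif(1, rr[1], rr[2])
    r_net <- max(2 / 3 * r_out, 2.0)
    r_et <- max(1 / 3 * r_out, 1.0)
    # rejection-sample a center whose outer sphere stays inside the brain
    ok <- FALSE
    for (try in 1:200) {
      cand <- ctr + (runif(3) - 0.5) * semi
      margin <- sqrt(sum(((cand - ctr) / semi)^2)) + r_out / min(semi)
      if (margin <= 0.98) { ok <- TRUE; break }
    }
    if (!ok) cand <- ctr
    dist2 <- outer(outer((seq_len(d[1]) - cand[1])^2,
                         (seq_len(d[2]) - cand[2])^2, `+`),
                   (seq_len(d[3]) - cand[3])^2, `+`)
    seg[dist2 <= r_out^2] <- 2
    seg[dist2 <= r_net^2] <- 1
    seg[dist2 <= r_et^2] <- 4
  }

  falloff <- 1 - 0.3 * pmin(r2, 1)   # mild radial shading keeps it smooth
  vols <- list()
  for (m in rownames(PHANTOM_CONTRAST)) {
    cc <- PHANTOM_CONTRAST[m, ]
    v <- array(0, dim = d)
    v[brain] <- cc[["brain"]] * falloff[brain]
    v[seg == 2] <- cc[["ed"]]
    v[seg == 1] <- cc[["net"]]
    v[seg == 4] <- cc[["et"]]
    if (spec$noise_sigma > 0) {
      noise <- array(rnorm(prod(d), sd = spec$noise_sigma), dim = d)
      v[brain] <- v[brain] + noise[brain]
    }
    v[v < 0] <- 0
    vols[[m]] <- v
  }
  mri_case(flair = vols$flair, t1 = vols$t1, t1ce = vols$t1ce, t2 = vols$t2,
           seg = seg, case_id = case_id, spacing = c(1, 1, 1))
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` BraTS-layout case directories (five compressed NIfTI files
#' each, labels included), seeding case `i` with `spec$seed + i`, and
#' returns the sorted directory paths — directly consumable by
#' [discover_cases] and [load_case].
#'
#' @param n Number of cases (>= 0).
#' @param spec A [phantom_spec]; its seed is the dataset base seed.
#' @param out_root Output directory (created if missing).
#' @return Sorted character vector of case directory paths.
#' @export
generate_dataset <- function(n, spec = phantom_spec(), out_root) {
  if (n < 0) stop("n must be >= 0")
  if (!dir.exists(out_root)) {
    ok <- dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output root: ", out_root)
  }
  paths <- character(n)
  for (i in seq_len(n)) {
    id <- sprintf("phantom_%04d", i)
    cspec <- spec
    cspec$seed <- spec$seed + i
    case <- generate_phantom(cspec, case_id = id)
    cdir <- file.path(out_root, id)
    dir.create(cdir, showWarnings = FALSE)
    for (m in c("flair", "t1", "t1ce", "t2", "seg")) {
      write_nifti(case[[m]], file.path(cdir, paste0(id, "_", m, ".nii.gz")),
                  spacing = case$spacing)
    }
    paths[i] <- cdir
  }
  sort(paths)
}
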