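# Synthetic contrast-enhancing tumor phantoms with known ground truth and
# auto-generated scribbles, so the whole segmentation + volumetry pipeline can
# be exercised and validated without patient data.

phantom_presets <- list(
  # ellipsoid semi-axes in mm, sized to span the tumor-volume range seen in
  # clinical pituitary adenoma series (about 0.76 to 15.3 cm^3)
  small  = c(5.7, 5.7, 5.7),    # ~0.78 cm^3
  medium = c(12, 11.5, 11),     # ~6.36 cm^3
  large  = c(16, 15.5, 14.7)    # ~15.27 cm^3
)

# evaluate expr with a private, seeded RNG stream; the caller's RNG state is
# left untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic tumor phantom
#'
#' An ellipsoidal, homogeneously contrast-enhancing "tumor" of known ground
#' truth inside a darker background volume, with independent Gaussian noise
#' added voxel-wise. The ground truth is the set of voxels whose centers lie
#' strictly inside the ellipsoid, which makes lattice-counting oracles exact.
#' Identical parameters and seed produce bit-identical output; the caller's
#' RNG state is not disturbed.
#'
#' @param preset `"small"`, `"medium"` or `"large"` — semi-axes presets
#'   spanning roughly 0.78 to 15.3 cm^3, the size regime of clinical pituitary
#'   adenoma series. Ignored when `radii` is given.
#' @param shape Grid extent in voxels (default 64^3).
#' @param spacing Voxel spacing in mm (default 1 mm isotropic).
#' @param center Tumor center in (possibly fractional) voxel indices; defaults
#'   to the grid center.
#' @param radii Ellipsoid semi-axes in mm (length 3), overriding `preset`.
#' @param intensity_tumor,intensity_background Noise-free intensities of the
#'   two compartments (must differ). The defaults give a gap of 100.
#' @param noise_sigma Standard deviation of the additive Gaussian noise
#'   (default 10, i.e. 10 percent of the default intensity gap).
#' @param seed Integer seed for the noise field.
#' @return A list with `image` (a [scalar_volume()]), `truth` (a binary
#'   [label_map()]) and `params` (the fully resolved parameter list).
#' @examples
#' ph <- make_phantom(preset = "small", shape = c(32, 32, 32), seed = 7)
#' label_volume(ph$truth, 1)$volume_mm3 # close to 4/3 pi 5.7^3
#' @export
make_phantom <- function(preset = c("medium", "small", "large"),
                         shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         center = NULL, radii = NULL,
                         intensity_tumor = 120, intensity_background = 20,
                         noise_sigma = 10, seed = 1) {
  if (is.null(radii)) {
    preset <- match.arg(preset)
    radii <- phantom_presets[[preset]]
  } else {
    preset <- "custom"
  }
  radii <- as.numeric(radii)
  stopifnot(length(radii) == 3L, all(radii > 0))
  geometry <- image_geometry(shape, spacing)
  shape <- geometry$shape
  spacing <- geometry$spacing
  if (is.null(center)) center <- (shape + 1) / 2
  center <- as.numeric(center)
  stopifnot(length(center) == 3L)
  if (intensity_tumor == intensity_background) {
    stop("tumor and background intensities must differ")
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0")
  }
  # squared normalized ellipsoid coordinate of every voxel center
  ax <- lapply(1:3, function(a) {
    ((seq_len(shape[a]) - center[a]) * spacing[a] / radii[a])^2
  })
  q <- outer(outer(ax[[1L]], ax[[2L]], "+"), ax[[3L]], "+")
  inside <- q < 1
  if (!any(inside)) stop("ellipsoid contains no voxel centers; enlarge radii")
  co <- which(inside, arr.ind = TRUE)
  if (any(apply(co, 2L, min) <= 1L) || any(apply(co, 2L, max) >= shape)) {
    stop("tumor touches the grid boundary; enlarge the grid or shrink the ",
         "radii (the background scribble shell must fit around the tumor)")
  }
  vals <- array(intensity_background, shape)
  vals[inside] <- intensity_tumor
  if (noise_sigma > 0) {
    noise <- with_seed(seed, stats::rnorm(prod(shape), sd = noise_sigma))
    vals <- vals + array(noise, shape)
  }
  truth <- mask_from_logical(inside, geometry, meaning = c("1" = "tumor"))
  list(image = scalar_volume(vals, geometry = geometry),
       truth = truth,
       params = list(preset = preset, shape = shape, spacing = spacing,
                     center = center, radii = radii,
                     intensity_tumor = intensity_tumor,
                     intensity_background = intensity_background,
                     noise_sigma = noise_sigma, seed = seed))
}

#' Auto-generate scribbles from a ground-truth mask
#'
#' Emulates the interactive initialization — an area painted inside the tumor
#' and a stroke outside it: the foreground scribble is the ground truth eroded
#' `fg_erosion` times; the background scribble is a shell at distance
#' `bg_offset` from the tumor, `bg_thickness` voxels thick (the dilation by
#' `bg_offset` minus the dilation by `bg_offset - bg_thickness`). By
#' construction the foreground scribble is contained in the ground truth and
#' the background scribble is disjoint from it.
#'
#' @param truth Binary `label_map` ground truth (nonempty).
#' @param fg_erosion Non-negative erosion count for the inner area (0 keeps
#'   the whole truth).
#' @param bg_offset Dilation count placing the outer shell (>= 1).
#' @param bg_thickness Shell thickness in dilation steps, `1 <= bg_thickness
#'   <= bg_offset`.
#' @param connectivity Structuring-element connectivity for the erosions and
#'   dilations (default 6).
#' @return A `scribble_set` (label 1 = foreground, 2 = background).
#' @export
make_scribbles <- function(truth, fg_erosion = 2L, bg_offset = 3L,
                           bg_thickness = 2L, connectivity = 6L) {
  gt <- logical_from_mask(truth)
  if (!any(gt)) stop("ground truth is empty")
  fg_erosion <- as.integer(fg_erosion)
  bg_offset <- as.integer(bg_offset)
  bg_thickness <- as.integer(bg_thickness)
  if (fg_erosion < 0L) stop("fg_erosion must be >= 0")
  if (bg_offset < 1L || bg_thickness < 1L || bg_thickness > bg_offset) {
    stop("need 1 <= bg_thickness <= bg_offset")
  }
  offs <- neighbor_offsets(connectivity)
  fg <- gt
  for (i in seq_len(fg_erosion)) fg <- binary_erode_once(fg, offs)
  if (!any(fg)) {
    stop("eroding the ground truth ", fg_erosion,
         " times empties the foreground scribble; use a smaller fg_erosion")
  }
  outer_ <- gt
  for (i in seq_len(bg_offset)) outer_ <- binary_dilate_once(outer_, offs)
  inner <- gt
  for (i in seq_len(bg_offset - bg_thickness)) {
    inner <- binary_dilate_once(inner, offs)
  }
  bg <- outer_ & !inner
  if (!any(bg)) {
    stop("background shell is empty (tumor fills the grid?)")
  }
  lab <- array(0L, dim(gt))
  lab[bg] <- 2L
  lab[fg] <- 1L
  as_scribbles(label_map(lab, geometry = truth$geometry,
                         meaning = c("1" = "tumor", "2" = "background")))
}
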