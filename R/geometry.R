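#' Image geometry of a 3D voxel grid
#'
#' Bundles the grid extent with its physical calibration: voxel counts per axis,
#' voxel spacing in millimetres, and a physical origin offset. Every volume and
#' label map in the package carries one, and all volumetry (mm^3 / cm^3) derives
#' from it: the volume of one voxel is the product of the three spacings.
#'
#' Voxel coordinates are 1-based R array indices in (i, j, k) order, mapped to
#' physical axes in file-header order. Direction/orientation matrices present in
#' NRRD or NIfTI headers are ignored by computation: every operation here is
#' grid-local, so patient orientation never enters.
#'
#' @param shape Integer vector of length 3, voxel counts per axis (all >= 1).
#' @param spacing Numeric vector of length 3, mm per voxel along each axis (> 0).
#' @param origin Numeric vector of length 3, physical offset in mm.
#' @return An object of class `"image_geometry"`.
#' @examples
#' g <- image_geometry(c(64, 64, 64))
#' voxel_volume(g) # 1 mm^3 for the 1 mm isotropic default
#' @export
image_geometry <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L)) {
    stop("shape must be 3 positive integers")
  }
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    stop("spacing must be 3 positive reals (mm)")
  }
  if (length(origin) != 3L || anyNA(origin)) {
    stop("origin must be 3 finite reals (mm)")
  }
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_geometry")
}

#' @rdname image_geometry
#' @param g An `image_geometry`.
#' @export
voxel_volume <- function(g) {
  stopifnot(inherits(g, "image_geometry"))
  prod(g$spacing)
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("<image_geometry> %s voxels @ (%s) mm, origin (%s)\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' 3D scalar volume (image)
#'
#' A real-valued intensity grid plus its [image_geometry()] — the in-memory form
#' of an MRI volume. Intensities must be finite everywhere.
#'
#' @param values Numeric 3D array of intensities.
#' @param spacing,origin Passed to [image_geometry()]; ignored when `geometry`
#'   is given.
#' @param geometry Optional `image_geometry` (must match `dim(values)`).
#' @return An object of class `"scalar_volume"` with fields `values`, `geometry`.
#' @export
scalar_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          geometry = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a 3D array")
  }
  if (!all(is.finite(values))) stop("all intensities must be finite")
  storage.mode(values) <- "double"
  if (is.null(geometry)) geometry <- image_geometry(dim(values), spacing, origin)
  if (!identical(as.integer(dim(values)), geometry$shape)) {
    stop("values extent does not match geometry shape")
  }
  structure(list(values = values, geometry = geometry), class = "scalar_volume")
}

#' 3D label map
#'
#' An integer-valued grid on the same geometry as an image: scribbles,
#' segmentations and ground truth all use this container. Label 0 is reserved
#' for "unlabeled / background"; every nonzero label present in the grid must
#' be named in `meaning`. The package-wide convention is label 1 = tumor
#' (foreground), label 2 = background, and binary masks are derived as
#' `labels == 1`.
#'
#' @param labels Integer 3D array of non-negative labels.
#' @param spacing,origin,geometry As in [scalar_volume()].
#' @param meaning Named character vector mapping label value (name) to class
#'   name, e.g. `c("1" = "tumor", "2" = "background")`.
#' @return An object of class `"label_map"` with fields `labels`, `geometry`,
#'   `meaning`.
#' @export
label_map <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      geometry = NULL,
                      meaning = c("1" = "tumor", "2" = "background")) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("labels must be a 3D array")
  }
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be non-negative integers")
  }
  storage.mode(labels) <- "integer"
  if (is.null(geometry)) geometry <- image_geometry(dim(labels), spacing, origin)
  if (!identical(as.integer(dim(labels)), geometry$shape)) {
    stop("labels extent does not match geometry shape")
  }
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(as.character(present), names(meaning))
  if (length(missing) > 0L) {
    stop("labels present but not named in `meaning`: ",
         paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, geometry = geometry, meaning = meaning),
            class = "label_map")
}

#' Scribble set: GrowCut seeds
#'
#' Validates a label map as a GrowCut initialization: values restricted to
#' \{0, 1, 2\} with 1 = foreground (tumor) and 2 = background, and at least one
#' voxel of each nonzero class — the automaton needs at least two competing
#' label classes to run.
#'
#' @param x A `label_map` (or integer 3D array, forwarded to [label_map()]).
#' @param ... Passed to [label_map()] when `x` is a bare array.
#' @return `x` with class `"scribble_set"` prepended.
#' @export
as_scribbles <- function(x, ...) {
  if (!inherits(x, "label_map")) x <- label_map(x, ...)
  vals <- unique(as.vector(x$labels))
  if (!all(vals %in% c(0L, 1L, 2L))) {
    stop("scribbles may only contain labels 0 (unlabeled), 1 (foreground), 2 (background)")
  }
  if (!any(x$labels == 1L)) {
    stop("scribbles contain no foreground (label 1) voxels; ",
         "GrowCut needs seeds of at least two classes")
  }
  if (!any(x$labels == 2L)) {
    stop("scribbles contain no background (label 2) voxels; ",
         "GrowCut needs seeds of at least two classes")
  }
  if (!inherits(x, "scribble_set")) class(x) <- c("scribble_set", class(x))
  x
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels @ (%s) mm; intensity range [%.4g, %.4g]\n",
              paste(x$geometry$shape, collapse = "x"),
              paste(format(x$geometry$spacing), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(factor(x$labels[x$labels > 0L]))
  lab <- if (length(tab) == 0L) "empty" else {
    paste(sprintf("%s (%s): %d", names(tab),
                  x$meaning[names(tab)], as.integer(tab)), collapse = "; ")
  }
  cat(sprintf("<%s> %s voxels @ (%s) mm; %s\n",
              class(x)[1L],
              paste(x$geometry$shape, collapse = "x"),
              paste(format(x$geometry$spacing), collapse = ", "),
              lab))
  invisible(x)
}

# geometry accessor working for volumes, label maps and bare geometries
geom_of <- function(x) {
  if (inherits(x, "image_geometry")) return(x)
  if (!is.null(x$geometry)) return(x$geometry)
  stop("object carries no image_geometry")
}

#' Check that two volumes live on the same grid
#'
#' Shapes must be identical and spacings agree within a relative tolerance of
#' 1e-4. Origins and orientation are not compared (all computation is
#' grid-local). Never mutates its inputs.
#'
#' @param a,b Objects carrying an `image_geometry` (volumes, label maps, or
#'   geometries).
#' @param strict If `TRUE`, raise an error describing both geometries instead
#'   of returning `FALSE`.
#' @param tol Relative spacing tolerance.
#' @return `TRUE` or `FALSE` (invisibly `TRUE` in strict mode).
#' @export
validate_geometry <- function(a, b, strict = FALSE, tol = 1e-4) {
  ga <- geom_of(a)
  gb <- geom_of(b)
  ok <- identical(ga$shape, gb$shape) &&
    all(abs(ga$spacing - gb$spacing) <= tol * pmax(ga$spacing, gb$spacing))
  if (!ok && strict) {
    stop(sprintf(
      "geometry mismatch: %s @ (%s) mm vs %s @ (%s) mm",
      paste(ga$shape, collapse = "x"), paste(format(ga$spacing), collapse = ", "),
      paste(gb$shape, collapse = "x"), paste(format(gb$spacing), collapse = ", ")))
  }
  if (strict) invisible(TRUE) else ok
}

#' Extract a binary mask for one label
#'
#' @param m A `label_map`.
#' @param label Label value defining the mask (default 1, the tumor class).
#' @return A binary `label_map` (labels in \{0, 1\}) on the same geometry.
#' @export
mask_of <- function(m, label = 1L) {
  stopifnot(inherits(m, "label_map"))
  lab <- array(0L, dim(m$labels))
  lab[m$labels == as.integer(label)] <- 1L
  nm <- m$meaning[as.character(label)]
  if (is.na(nm)) nm <- "mask"
  label_map(lab, geometry = m$geometry, meaning = c("1" = unname(nm)))
}

# coerce logical array -> binary label_map on a given geometry
mask_from_logical <- function(mask, geometry, meaning = c("1" = "tumor")) {
  if (length(meaning) != 1L || anyNA(meaning)) meaning <- c("1" = "tumor")
  names(meaning) <- "1"
  lab <- array(0L, dim(mask))
  lab[mask] <- 1L
  label_map(lab, geometry = geometry, meaning = meaning)
}

# logical array from a binary label_map; errors on non-binary input
logical_from_mask <- function(m) {
  stopifnot(inherits(m, "label_map"))
  if (!all(m$labels %in% c(0L, 1L))) {
    stop("mask must be binary (labels 0/1); found labels ",
         paste(setdiff(unique(as.vector(m$labels)), c(0L, 1L)), collapse = ", "))
  }
  m$labels == 1L
}
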