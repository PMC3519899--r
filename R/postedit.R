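# Morphological post-editing of binary segmentations: dilation, erosion and
# island removal, applied as an ordered sequence after visual inspection.

#' Binary dilation or erosion
#'
#' Classic binary morphology with the structuring element implied by the
#' connectivity — a 6-neighbor cross or the full 3x3x3 cube — iterated `radius`
#' times. Outside the grid counts as background, so erosion eats inward at the
#' image border. Geometry is preserved.
#'
#' @param mask A binary `label_map` (labels in \{0, 1\}).
#' @param op `"dilate"` or `"erode"`.
#' @param radius Positive integer; number of elementary iterations.
#' @param connectivity 6 or 26.
#' @return A binary `label_map`.
#' @export
morph_binary <- function(mask, op = c("dilate", "erode"), radius = 1L,
                         connectivity = 26L) {
  op <- match.arg(op)
  m <- logical_from_mask(mask)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("radius must be >= 1")
  offs <- neighbor_offsets(connectivity)
  f <- if (op == "dilate") binary_dilate_once else binary_erode_once
  for (i in seq_len(radius)) m <- f(m, offs)
  mask_from_logical(m, mask$geometry, meaning = mask$meaning["1"])
}

#' Remove small connected components ("islands")
#'
#' Connected components of the mask (under the given connectivity) smaller
#' than `min_size` voxels are zeroed; `min_size = "keep_largest"` retains only
#' the largest component, ties broken by the component appearing first in
#' lexicographic scan order. An empty mask passes through unchanged.
#'
#' @param mask A binary `label_map`.
#' @param min_size Positive integer voxel count, or `"keep_largest"`.
#' @param connectivity 6 or 26.
#' @return A binary `label_map` whose foreground is a subset of the input's.
#' @export
remove_islands <- function(mask, min_size = "keep_largest", connectivity = 26L) {
  m <- logical_from_mask(mask)
  if (!any(m)) return(mask)
  comp <- label_components(m, connectivity)
  sizes <- tabulate(comp[comp > 0L])
  keep <- if (identical(min_size, "keep_largest")) {
    which.max(sizes) # first maximal component in scan order
  } else {
    min_size <- as.integer(min_size)
    if (is.na(min_size) || min_size < 1L) {
      stop("min_size must be a positive integer or \"keep_largest\"")
    }
    which(sizes >= min_size)
  }
  mask_from_logical(array(comp %in% keep, dim(m)), mask$geometry,
                    meaning = mask$meaning["1"])
}

#' Describe one post-editing step
#'
#' @param op `"dilate"`, `"erode"` or `"remove_islands"`.
#' @param radius For dilate/erode: positive integer voxels.
#' @param connectivity 6 or 26.
#' @param min_size For remove_islands: positive integer or `"keep_largest"`.
#' @return An object of class `"postedit_step"`.
#' @export
postedit_step <- function(op = c("remove_islands", "dilate", "erode"),
                          radius = 1L, connectivity = 26L,
                          min_size = "keep_largest") {
  op <- match.arg(op)
  structure(list(op = op, radius = as.integer(radius),
                 connectivity = as.integer(connectivity),
                 min_size = min_size),
            class = "postedit_step")
}

#' @export
print.postedit_step <- function(x, ...) {
  detail <- if (x$op == "remove_islands") {
    paste0("min_size=", if (identical(x$min_size, "keep_largest"))
      "keep_largest" else x$min_size)
  } else {
    paste0("radius=", x$radius)
  }
  cat(sprintf("<postedit_step> %s (%s, %d-connectivity)\n", x$op, detail,
              x$connectivity))
  invisible(x)
}

#' Apply a post-editing sequence
#'
#' Applies the steps left to right; the empty sequence is the identity. The
#' voxel-count delta of every step is recorded in the `"postedit_log"`
#' attribute of the result (and echoed with `verbose = TRUE`).
#'
#' @param mask A binary `label_map`.
#' @param steps List of [postedit_step()] objects (a single step is accepted).
#' @param verbose Echo per-step voxel deltas via [message()].
#' @return The edited binary `label_map`.
#' @export
apply_postedit <- function(mask, steps = list(), verbose = FALSE) {
  if (inherits(steps, "postedit_step")) steps <- list(steps)
  out <- mask
  logical_from_mask(out) # validate binary even for the empty sequence
  log <- data.frame(step = character(0), voxels_before = integer(0),
                    voxels_after = integer(0))
  for (s in steps) {
    if (!inherits(s, "postedit_step")) stop("steps must be postedit_step objects")
    before <- sum(out$labels == 1L)
    out <- switch(s$op,
      dilate = morph_binary(out, "dilate", s$radius, s$connectivity),
      erode = morph_binary(out, "erode", s$radius, s$connectivity),
      remove_islands = remove_islands(out, s$min_size, s$connectivity)
    )
    after <- sum(out$labels == 1L)
    log <- rbind(log, data.frame(step = s$op, voxels_before = before,
                                 voxels_after = after))
    if (verbose) {
      message(sprintf("postedit %s: %d -> %d voxels (%+d)", s$op, before,
                      after, after - before))
    }
  }
  attr(out, "postedit_log") <- log
  out
}
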