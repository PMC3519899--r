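#' @export
print.growcut <- function(x, ...) {
  cat("GrowCut segmentation\n")
  cat(sprintf("  grid: %s voxels, ROI [%s]..[%s]\n",
              paste(x$label_map$geometry$shape, collapse = "x"),
              paste(x$roi$lower, collapse = ","),
              paste(x$roi$upper, collapse = ",")))
  cat(sprintf("  seeds: %d foreground, %d background; max_diff = %s\n",
              x$n_seeds[["foreground"]], x$n_seeds[["background"]],
              format(x$max_diff)))
  cat(sprintf("  %d iterations, %s\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  tab <- table(factor(x$label_map$labels[x$label_map$labels > 0L]))
  for (l in names(tab)) {
    cat(sprintf("  label %s (%s): %d voxels\n", l,
                x$label_map$meaning[[l]], as.integer(tab[[l]])))
  }
  invisible(x)
}

#' Summarize a GrowCut segmentation
#'
#' Per-label voxel counts and physical volumes (mm^3 and cm^3), plus the
#' convergence record.
#'
#' @param object A `"growcut"` fit.
#' @param ... Unused.
#' @return An object of class `"summary.growcut"`: a list with a per-label
#'   `table` (data frame), `iterations`, `converged` and `changed_trace`.
#' @export
summary.growcut <- function(object, ...) {
  m <- object$label_map
  vv <- voxel_volume(m$geometry)
  labs <- sort(unique(as.vector(m$labels[m$labels > 0L])))
  tab <- data.frame(
    label = labs,
    meaning = unname(m$meaning[as.character(labs)]),
    voxels = vapply(labs, function(l) sum(m$labels == l), integer(1)),
    stringsAsFactors = FALSE
  )
  tab$volume_mm3 <- tab$voxels * vv
  tab$volume_cm3 <- tab$volume_mm3 / 1000
  structure(list(table = tab, iterations = object$iterations,
                 converged = object$converged,
                 changed_trace = object$changed_trace,
                 voxel_volume_mm3 = vv),
            class = "summary.growcut")
}

#' @export
print.summary.growcut <- function(x, ...) {
  cat(sprintf("GrowCut segmentation: %d iterations, %s (voxel = %.4g mm^3)\n",
              x$iterations, if (x$converged) "converged" else "NOT converged",
              x$voxel_volume_mm3))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot a slice of a GrowCut segmentation
#'
#' Shows one axial (or caller-chosen axis) slice of the image with the
#' segmented foreground overlaid as a contour/tint.
#'
#' @param x A `"growcut"` fit.
#' @param image Optional `scalar_volume` to use as the underlay; if missing,
#'   only the labels are shown.
#' @param slice Slice index along `axis`; defaults to the slice with the most
#'   foreground voxels.
#' @param axis Slicing axis (1, 2 or 3; default 3).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the slice index plotted.
#' @export
plot.growcut <- function(x, image = NULL, slice = NULL, axis = 3L, ...) {
  lab <- x$label_map$labels
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)
  fg <- lab == 1L
  if (is.null(slice)) {
    counts <- apply(fg, axis, sum)
    slice <- which.max(counts)
  }
  take <- function(a) {
    switch(axis,
           a[slice, , , drop = TRUE],
           a[, slice, , drop = TRUE],
           a[, , slice, drop = TRUE])
  }
  if (!is.null(image)) {
    graphics::image(take(image$values), col = grDevices::gray.colors(128),
                    axes = FALSE, asp = 1,
                    main = sprintf("GrowCut labels, slice %d (axis %d)", slice, axis),
                    ...)
    sl <- take(lab)
    ov <- array(NA_real_, dim(sl))
    ov[sl == 1L] <- 1
    graphics::image(ov, col = grDevices::adjustcolor("green", 0.35), add = TRUE)
    sl2 <- ov
    sl2[is.na(sl2)] <- 0
    graphics::contour(sl2, levels = 0.5, add = TRUE, drawlabels = FALSE,
                      col = "green3")
  } else {
    graphics::image(take(lab), col = c("black", "green3", "yellow"),
                    axes = FALSE, asp = 1,
                    main = sprintf("GrowCut labels, slice %d (axis %d)", slice, axis),
                    ...)
  }
  invisible(slice)
}
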