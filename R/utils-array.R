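# Internal 3D array helpers shared by the automaton, morphology and phantom code.
# All arrays are plain R arrays in native (column-major, i-fastest) layout.

#' Neighbor offset table for a 3D connectivity
#'
#' Returns the fixed, documented offset ordering used everywhere in the package:
#' offsets are enumerated with the first axis varying fastest (the order produced
#' by `expand.grid(-1:1, -1:1, -1:1)` with the zero offset removed). Tie-breaking
#' in the GrowCut update rule picks the first maximal attacker in this order, so
#' the ordering is part of the determinism contract.
#'
#' @param connectivity 6 (face neighbors) or 26 (full 3x3x3 Moore neighborhood).
#' @return Integer matrix with one offset per row and columns (di, dj, dk).
#' @keywords internal
neighbor_offsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) {
    stop("connectivity must be 6 or 26, got ", connectivity)
  }
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1,
                             KEEP.OUT.ATTRS = FALSE))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g
}

# shift3d(a, d, fill)[p] == a[p + d] where in range, `fill` elsewhere.
# Used both to fetch neighbor values (attacker at p + d) and, with logical
# arrays, to implement structuring-element morphology.
shift3d <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- vector("list", 3L)
  dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dm[ax]
    dd <- d[ax]
    if (abs(dd) >= n) return(out)
    if (dd >= 0L) {
      dst[[ax]] <- seq_len(n - dd)
      src[[ax]] <- seq_len(n - dd) + dd
    } else {
      dst[[ax]] <- seq_len(n + dd) - dd
      src[[ax]] <- seq_len(n + dd)
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

# TRUE where at least one neighbor (per `offs`) of a TRUE voxel lies; equivalently
# one binary dilation step without the center.
neighbor_any <- function(mask, offs) {
  out <- array(FALSE, dim(mask))
  for (k in seq_len(nrow(offs))) {
    out <- out | shift3d(mask, offs[k, ], FALSE)
  }
  out
}

binary_dilate_once <- function(mask, offs) mask | neighbor_any(mask, offs)

binary_erode_once <- function(mask, offs) {
  out <- mask
  for (k in seq_len(nrow(offs))) {
    out <- out & shift3d(mask, offs[k, ], FALSE)
  }
  out
}

# Connected-component labelling by iterative minimum-index propagation.
# Components are numbered 1..k in order of their smallest linear index
# (lexicographic scan order in the native array layout), which fixes the
# keep_largest tie-break deterministically.
label_components <- function(mask, connectivity = 26L) {
  offs <- neighbor_offsets(connectivity)
  lab <- array(0, dim(mask))
  lab[mask] <- which(mask)
  repeat {
    prev <- lab
    for (k in seq_len(nrow(offs))) {
      sh <- shift3d(lab, offs[k, ], 0)
      upd <- mask & sh > 0 & sh < lab
      if (any(upd)) lab[upd] <- sh[upd]
    }
    if (identical(lab, prev)) break
  }
  reps <- sort(unique(lab[lab > 0]))
  out <- array(0L, dim(mask))
  out[mask] <- match(lab[mask], reps)
  out
}
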