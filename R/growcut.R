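#' GrowCut parameters
#'
#' Tuning knobs of the cellular automaton.
#'
#' @param neighborhood 26 (default, the classical 3D Moore neighborhood) or 6
#'   (face connectivity).
#' @param roi_margin Non-negative margin in voxels added around the bounding
#'   box of all scribbled voxels; the automaton runs only inside that box.
#' @param max_iterations Upper bound on synchronous iterations; normal exit is
#'   convergence (no voxel changed), the cap only guards against pathological
#'   float dithering.
#' @param max_diff_policy How the similarity normalizer `max_diff` is computed:
#'   `"neighbors"` (default) takes the maximum absolute intensity difference
#'   over all neighbor pairs inside the region of interest; `"range"` uses the
#'   intensity range (max minus min) of the region.
#' @return An object of class `"growcut_params"`.
#' @export
growcut_params <- function(neighborhood = 26L, roi_margin = 5L,
                           max_iterations = 500L,
                           max_diff_policy = c("neighbors", "range")) {
  neighborhood <- as.integer(neighborhood)
  if (!neighborhood %in% c(6L, 26L)) stop("neighborhood must be 6 or 26")
  roi_margin <- as.integer(roi_margin)
  if (is.na(roi_margin) || roi_margin < 0L) stop("roi_margin must be >= 0")
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L) {
    stop("max_iterations must be >= 1")
  }
  max_diff_policy <- match.arg(max_diff_policy)
  structure(list(neighborhood = neighborhood, roi_margin = roi_margin,
                 max_iterations = max_iterations,
                 max_diff_policy = max_diff_policy),
            class = "growcut_params")
}

#' GrowCut similarity weight
#'
#' The attack-weight kernel of the automaton: `g(c_p, c_q) = 1 - |c_p - c_q| /
#' max_diff`, i.e. 1 for identical intensities, 0 at the maximal observed
#' neighbor difference, linear in between. A degenerate constant image
#' (`max_diff = 0`) yields `g = 1` everywhere. Vectorised over its first two
#' arguments.
#'
#' @param c_p,c_q Intensities of the attacked and attacking voxel.
#' @param max_diff Non-negative normalizer; an error is raised if any
#'   `|c_p - c_q|` exceeds it (the normalizer was computed incorrectly
#'   upstream).
#' @return Weights in `[0, 1]`.
#' @examples
#' similarity_weight(100, 100, 50) # 1
#' similarity_weight(0, 25, 50)    # 0.5
#' @export
similarity_weight <- function(c_p, c_q, max_diff) {
  if (length(max_diff) != 1L || is.na(max_diff) || max_diff < 0) {
    stop("max_diff must be a single non-negative number")
  }
  d <- abs(c_p - c_q)
  if (any(d > max_diff)) {
    stop("intensity difference ", format(max(d)),
         " exceeds max_diff = ", format(max_diff),
         "; the similarity normalizer was computed incorrectly upstream")
  }
  if (max_diff == 0) return(rep(1, length(d)))
  1 - d / max_diff
}

#' Region of interest around the scribbles
#'
#' The axis-aligned bounding box of all nonzero scribble voxels, expanded by
#' `margin` voxels per axis and clipped to the image extent. A bounding box is
#' a superset of the convex hull of the scribbled voxels, so no labeled voxel
#' is ever excluded.
#'
#' @param scribbles A `scribble_set` (or any `label_map` with nonzero voxels).
#' @param margin Non-negative margin in voxels.
#' @param geometry Grid extent to clip against; defaults to the scribbles' own.
#' @return An object of class `"roi_box"` with 1-based inclusive `lower` and
#'   `upper` voxel indices.
#' @export
compute_roi <- function(scribbles, margin = 5L, geometry = NULL) {
  stopifnot(inherits(scribbles, "label_map"))
  if (is.null(geometry)) geometry <- scribbles$geometry
  margin <- as.integer(margin)
  if (is.na(margin) || margin < 0L) stop("margin must be >= 0")
  w <- which(scribbles$labels > 0L)
  if (length(w) == 0L) stop("cannot compute an ROI from empty scribbles")
  co <- arrayInd(w, dim(scribbles$labels))
  lower <- pmax(1L, apply(co, 2L, min) - margin)
  upper <- pmin(geometry$shape, apply(co, 2L, max) + margin)
  structure(list(lower = as.integer(lower), upper = as.integer(upper)),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> [%s] .. [%s] (%s voxels)\n",
              paste(x$lower, collapse = ", "),
              paste(x$upper, collapse = ", "),
              prod(x$upper - x$lower + 1L)))
  invisible(x)
}

#' Initialize the GrowCut automaton state
#'
#' Scribbled voxels receive their scribble label with full strength (theta = 1);
#' all other voxels are unlabeled with theta = 0. The active set is every voxel
#' adjacent to a seed; no voxel is saturated yet.
#'
#' @param image A `scalar_volume`.
#' @param scribbles A `scribble_set` on the same geometry.
#' @param params A [growcut_params()] (its neighborhood defines adjacency).
#' @return An object of class `"growcut_state"` with full-grid fields `labels`,
#'   `strength`, `saturated`, `active`.
#' @export
initialize_state <- function(image, scribbles, params = growcut_params()) {
  stopifnot(inherits(image, "scalar_volume"))
  scribbles <- as_scribbles(scribbles)
  validate_geometry(image, scribbles, strict = TRUE)
  offs <- neighbor_offsets(params$neighborhood)
  seeds <- scribbles$labels
  strength <- array(0, dim(seeds))
  strength[seeds > 0L] <- 1
  structure(list(labels = seeds,
                 strength = strength,
                 saturated = array(FALSE, dim(seeds)),
                 active = neighbor_any(seeds > 0L, offs),
                 geometry = image$geometry),
            class = "growcut_state")
}

# ---- internal engine ---------------------------------------------------------

# similarity normalizer over neighbor pairs of a (sub)volume
gc_max_diff <- function(vals, offs, policy) {
  if (policy == "range") return(max(vals) - min(vals))
  md <- 0
  for (k in seq_len(nrow(offs))) {
    sh <- shift3d(vals, offs[k, ], NA_real_)
    d <- suppressWarnings(max(abs(vals - sh), na.rm = TRUE))
    if (is.finite(d)) md <- max(md, d)
  }
  md
}

# per-offset similarity weight arrays, 0 where the neighbor is off-grid;
# computed once per segmentation and reused every iteration
gc_weights <- function(vals, offs, max_diff) {
  W <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    sh <- shift3d(vals, offs[k, ], NA_real_)
    d <- abs(vals - sh)
    w <- if (max_diff == 0) array(1, dim(vals)) else 1 - d / max_diff
    w[is.na(d)] <- 0
    W[[k]] <- w
  }
  W
}

# one synchronous sweep: all reads from the previous state; among equal-strength
# attackers the first in neighbor_offsets() order wins (strict > throughout)
gc_sweep <- function(labels, strength, W, offs, eligible) {
  best <- strength
  blab <- labels
  for (k in seq_along(W)) {
    a <- W[[k]] * shift3d(strength, offs[k, ], 0)
    upd <- a > best
    if (any(upd)) {
      l <- shift3d(labels, offs[k, ], 0L)
      best[upd] <- a[upd]
      blab[upd] <- l[upd]
    }
  }
  changed <- eligible & (best > strength)
  n <- sum(changed)
  if (n > 0L) {
    strength[changed] <- best[changed]
    labels[changed] <- blab[changed]
  }
  list(labels = labels, strength = strength, changed = changed,
       changed_count = n)
}

# full evolution loop on (sub)arrays; returns labels/strength plus bookkeeping
gc_run <- function(vals, seeds, params) {
  offs <- neighbor_offsets(params$neighborhood)
  md <- gc_max_diff(vals, offs, params$max_diff_policy)
  W <- gc_weights(vals, offs, md)
  labels <- seeds
  strength <- array(0, dim(vals))
  strength[seeds > 0L] <- 1
  saturated <- array(FALSE, dim(vals))
  active <- neighbor_any(seeds > 0L, offs)
  trace <- integer(0)
  converged <- FALSE
  it <- 0L
  while (it < params$max_iterations) {
    it <- it + 1L
    res <- gc_sweep(labels, strength, W, offs, active & !saturated)
    trace <- c(trace, res$changed_count)
    if (res$changed_count == 0L) {
      converged <- TRUE
      break
    }
    labels <- res$labels
    strength <- res$strength
    # theta = 1 voxels can never be conquered again; voxels with no changed
    # neighbor cannot see a stronger attack next iteration
    saturated <- saturated | strength >= 1
    active <- neighbor_any(res$changed, offs)
  }
  list(labels = labels, strength = strength, iterations = it,
       converged = converged, trace = trace, max_diff = md)
}

#' One synchronous GrowCut iteration
#'
#' Advances a [initialize_state()] state by a single synchronous step inside
#' `roi`: every active, unsaturated voxel is attacked by its strongest
#' neighbor (similarity weight times the neighbor's previous strength) and is
#' conquered when that attack strictly exceeds its own previous strength. All
#' reads use the previous state, so the result is order-independent and
#' deterministic.
#'
#' @param state A `"growcut_state"`.
#' @param image The `scalar_volume` being segmented.
#' @param roi A [compute_roi()] box, or `NULL` for the whole grid.
#' @param params A [growcut_params()].
#' @return A list with the advanced `state` and `changed_count`, the number of
#'   voxels whose label or strength changed.
#' @export
growcut_step <- function(state, image, roi = NULL, params = growcut_params()) {
  stopifnot(inherits(state, "growcut_state"), inherits(image, "scalar_volume"))
  dm <- dim(image$values)
  if (is.null(roi)) {
    roi <- structure(list(lower = c(1L, 1L, 1L), upper = as.integer(dm)),
                     class = "roi_box")
  }
  if (any(roi$lower < 1L) || any(roi$upper > dm) || any(roi$lower > roi$upper)) {
    stop("roi box does not lie inside the image extent")
  }
  ii <- roi$lower[1L]:roi$upper[1L]
  jj <- roi$lower[2L]:roi$upper[2L]
  kk <- roi$lower[3L]:roi$upper[3L]
  vals <- image$values[ii, jj, kk, drop = FALSE]
  offs <- neighbor_offsets(params$neighborhood)
  md <- gc_max_diff(vals, offs, params$max_diff_policy)
  W <- gc_weights(vals, offs, md)
  lab <- state$labels[ii, jj, kk, drop = FALSE]
  str <- state$strength[ii, jj, kk, drop = FALSE]
  eligible <- (state$active & !state$saturated)[ii, jj, kk, drop = FALSE]
  res <- gc_sweep(lab, str, W, offs, eligible)
  state$labels[ii, jj, kk] <- res$labels
  state$strength[ii, jj, kk] <- res$strength
  sat <- state$saturated[ii, jj, kk, drop = FALSE] | res$strength >= 1
  state$saturated[ii, jj, kk] <- sat
  act <- array(FALSE, dim(state$labels))
  act[ii, jj, kk] <- neighbor_any(res$changed, offs)
  state$active <- act
  list(state = state, changed_count = res$changed_count)
}

#' GrowCut segmentation
#'
#' Fits the GrowCut cellular automaton to an image from user scribbles.
#' Scribbled voxels are seeds with full strength; in each synchronous
#' iteration every unsaturated voxel adjacent to last iteration's changes is
#' attacked by its neighbors, an attack with weight
#' `similarity_weight(c_p, c_q, max_diff) * theta_q` conquering the voxel when
#' it strictly exceeds its current strength. Iteration stops when no voxel
#' changes.
#'
#' Three of the classic speed-ups are built in and provably do not change the
#' result: computation is restricted to the scribble bounding box plus margin
#' (the region of interest), neighbor similarity weights are precomputed once
#' and reused, and saturated voxels (full strength, or no changed neighbor)
#' are skipped. [growcut_reference()] runs the same automaton naively and is
#' used as the correctness oracle in the test suite.
#'
#' @param image A `scalar_volume`.
#' @param scribbles A `scribble_set` on the same grid: label 1 = foreground
#'   (tumor), label 2 = background.
#' @param params A [growcut_params()].
#' @param keep_strength Keep the final per-voxel strength field in the returned
#'   object (needed by some diagnostics; costs one double array).
#' @return An object of class `"growcut"` with components
#'   \describe{
#'     \item{label_map}{the segmentation as a [label_map()] (0 outside the ROI)}
#'     \item{strength}{final strength field (if `keep_strength`)}
#'     \item{iterations, converged, changed_trace}{evolution bookkeeping}
#'     \item{roi}{the [compute_roi()] box used}
#'     \item{max_diff}{the similarity normalizer used}
#'     \item{params, call}{inputs}
#'   }
#' @seealso [growcut_reference()], [apply_postedit()], [dice()]
#' @examples
#' ph <- make_phantom(preset = "small", shape = c(32, 32, 32), noise_sigma = 0,
#'                    seed = 1)
#' sc <- make_scribbles(ph$truth)
#' fit <- growcut(ph$image, sc)
#' fit
#' dice(mask_of(fit$label_map), ph$truth) # 1: noiseless phantom is recovered
#' @export
growcut <- function(image, scribbles, params = growcut_params(),
                    keep_strength = TRUE) {
  stopifnot(inherits(image, "scalar_volume"))
  scribbles <- as_scribbles(scribbles)
  validate_geometry(image, scribbles, strict = TRUE)
  if (!inherits(params, "growcut_params")) stop("params must be growcut_params()")
  roi <- compute_roi(scribbles, params$roi_margin, image$geometry)
  ii <- roi$lower[1L]:roi$upper[1L]
  jj <- roi$lower[2L]:roi$upper[2L]
  kk <- roi$lower[3L]:roi$upper[3L]
  r <- gc_run(image$values[ii, jj, kk, drop = FALSE],
              scribbles$labels[ii, jj, kk, drop = FALSE],
              params)
  if (!r$converged) {
    warning("GrowCut did not converge within ", params$max_iterations,
            " iterations; returning the partial labeling")
  }
  full <- array(0L, dim(image$values))
  full[ii, jj, kk] <- r$labels
  meaning <- scribbles$meaning
  if (is.null(meaning)) meaning <- c("1" = "tumor", "2" = "background")
  out <- list(
    label_map = label_map(full, geometry = image$geometry, meaning = meaning),
    strength = NULL,
    iterations = r$iterations,
    converged = r$converged,
    changed_trace = r$trace,
    roi = roi,
    max_diff = r$max_diff,
    n_seeds = c(foreground = sum(scribbles$labels == 1L),
                background = sum(scribbles$labels == 2L)),
    params = params,
    call = match.call()
  )
  if (keep_strength) {
    s <- array(0, dim(image$values))
    s[ii, jj, kk] <- r$strength
    out$strength <- s
  }
  structure(out, class = "growcut")
}

#' Naive GrowCut reference implementation (correctness oracle)
#'
#' Runs the identical automaton semantics with none of the speed-ups: every
#' voxel of the full grid is visited in every iteration, similarity weights
#' are recomputed on the fly, and no saturation or activity tracking is done.
#' On any input whose scribble bounding box plus margin covers the whole grid,
#' the result is voxel-for-voxel identical to [growcut()]; the test suite
#' checks this on randomized instances.
#'
#' @inheritParams growcut
#' @return A [label_map()] with the converged labels; attributes `iterations`
#'   and `converged` carry the evolution bookkeeping.
#' @export
growcut_reference <- function(image, scribbles, params = growcut_params()) {
  stopifnot(inherits(image, "scalar_volume"))
  scribbles <- as_scribbles(scribbles)
  validate_geometry(image, scribbles, strict = TRUE)
  vals <- as.double(image$values)
  dm <- dim(image$values)
  offs <- neighbor_offsets(params$neighborhood)
  md <- gc_max_diff(image$values, offs, params$max_diff_policy)
  n <- prod(dm)
  co <- arrayInd(seq_len(n), dm)
  K <- nrow(offs)
  nbr <- matrix(NA_integer_, n, K)
  for (k in seq_len(K)) {
    ni <- co[, 1L] + offs[k, 1L]
    nj <- co[, 2L] + offs[k, 2L]
    nk <- co[, 3L] + offs[k, 3L]
    ok <- ni >= 1L & ni <= dm[1L] & nj >= 1L & nj <= dm[2L] & nk >= 1L & nk <= dm[3L]
    idx <- rep(NA_integer_, n)
    idx[ok] <- ni[ok] + (nj[ok] - 1L) * dm[1L] + (nk[ok] - 1L) * dm[1L] * dm[2L]
    nbr[, k] <- idx
  }
  labels <- as.integer(scribbles$labels)
  strength <- double(n)
  strength[labels > 0L] <- 1
  it <- 0L
  converged <- FALSE
  while (it < params$max_iterations) {
    it <- it + 1L
    newl <- labels
    news <- strength
    nchg <- 0L
    for (p in seq_len(n)) {
      nb <- nbr[p, ]
      nb <- nb[!is.na(nb)]
      g <- if (md == 0) rep(1, length(nb)) else 1 - abs(vals[p] - vals[nb]) / md
      a <- g * strength[nb]
      i <- which.max(a)
      if (length(i) == 1L && a[i] > strength[p]) {
        news[p] <- a[i]
        newl[p] <- labels[nb[i]]
        nchg <- nchg + 1L
      }
    }
    if (nchg == 0L) {
      converged <- TRUE
      break
    }
    labels <- newl
    strength <- news
  }
  if (!converged) {
    warning("reference GrowCut did not converge within ", params$max_iterations,
            " iterations")
  }
  meaning <- scribbles$meaning
  if (is.null(meaning)) meaning <- c("1" = "tumor", "2" = "background")
  out <- label_map(array(labels, dm), geometry = image$geometry,
                   meaning = meaning)
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  out
}
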