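test_that("similarity_weight is linear and guards its normalizer", {
  expect_equal(similarity_weight(100, 100, 50), 1)
  expect_equal(similarity_weight(0, 50, 50), 0)
  expect_equal(similarity_weight(0, 25, 50), 0.5)
  expect_equal(similarity_weight(3, 7, 0 + 4), 0)
  # degenerate constant image: normalizer 0 means everything is similar
  expect_equal(similarity_weight(5, 5, 0), 1)
  expect_error(similarity_weight(0, 60, 50), "exceeds")
  expect_error(similarity_weight(1, 2, -1), "non-negative")
})

test_that("compute_roi is the clipped scribble bounding box plus margin", {
  lab <- array(0L, c(64, 64, 64))
  lab[11, 11, 11] <- 1L
  lab[21, 16, 13] <- 2L
  sc <- as_scribbles(label_map(lab))
  roi <- compute_roi(sc, margin = 5)
  expect_identical(roi$lower, c(6L, 6L, 6L))
  expect_identical(roi$upper, c(26L, 21L, 18L))
  lab2 <- array(0L, c(64, 64, 64))
  lab2[1, 1, 1] <- 1L
  lab2[2, 1, 1] <- 2L
  roi2 <- compute_roi(as_scribbles(label_map(lab2)), margin = 3)
  expect_identical(roi2$lower, c(1L, 1L, 1L)) # clipped at the origin
  expect_identical(roi2$upper, c(5L, 4L, 4L))
  lab3 <- array(0L, c(8, 8, 8))
  lab3[1, 1, 1] <- 1L
  lab3[8, 8, 8] <- 2L
  roi3 <- compute_roi(as_scribbles(label_map(lab3)), margin = 99)
  expect_identical(roi3$lower, c(1L, 1L, 1L)) # whole image
  expect_identical(roi3$upper, c(8L, 8L, 8L))
  expect_error(compute_roi(label_map(array(0L, c(4, 4, 4)))), "empty")
})

test_that("initialize_state seeds scribbles at full strength", {
  set.seed(41)
  inst <- random_instance(c(8, 8, 8), n_fg = 10L, n_bg = 20L)
  st <- initialize_state(inst$image, inst$scribbles)
  expect_identical(sum(st$strength == 1), 30L)
  expect_identical(st$labels, inst$scribbles$labels)
  expect_false(any(st$saturated))
  expect_true(all(st$strength >= 0 & st$strength <= 1))
  # every positive-strength voxel is labeled
  expect_true(all(st$labels[st$strength > 0] > 0L))
})

test_that("one synchronous step conquers exactly the seed neighborhood", {
  # constant 1x1x5 line: after one step both seed neighbors are conquered at
  # full strength, the middle voxel is still unlabeled
  inst <- line_instance(rep(50, 5))
  st <- initialize_state(inst$image, inst$scribbles)
  res <- growcut_step(st, inst$image)
  expect_identical(res$changed_count, 2L)
  expect_identical(as.vector(res$state$labels), c(1L, 1L, 0L, 2L, 2L))
  expect_equal(as.vector(res$state$strength), c(1, 1, 0, 1, 1))
})

test_that("line automata converge to the hand-simulated labelings", {
  # constant line: fronts meet at the middle voxel; the tie is broken by the
  # fixed neighbor order (negative offset first), so foreground wins it
  inst <- line_instance(rep(50, 5))
  fit <- growcut(inst$image, inst$scribbles)
  expect_identical(as.vector(fit$label_map$labels), c(1L, 1L, 1L, 2L, 2L))
  expect_true(fit$converged)
  ref <- growcut_reference(inst$image, inst$scribbles)
  expect_identical(ref$labels, fit$label_map$labels)
  # two-intensity line: zero similarity across the step blocks cross-boundary
  # attacks entirely
  inst2 <- line_instance(c(0, 0, 0, 100, 100, 100))
  fit2 <- growcut(inst2$image, inst2$scribbles)
  expect_identical(as.vector(fit2$label_map$labels),
                   c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(growcut_reference(inst2$image, inst2$scribbles)$labels,
                   fit2$label_map$labels)
})

test_that("a fully scribbled image is already converged", {
  vals <- array(runif(8), c(2, 2, 2))
  lab <- array(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), c(2, 2, 2))
  sc <- as_scribbles(label_map(lab))
  fit <- growcut(scalar_volume(vals), sc)
  expect_identical(fit$label_map$labels, lab)
  expect_identical(fit$iterations, 1L)
  expect_identical(fit$changed_trace, 0L)
})

test_that("scribbled voxels never change label or strength", {
  set.seed(7)
  for (rep in 1:5) {
    inst <- random_instance(c(10, 10, 10))
    fit <- growcut(inst$image, inst$scribbles,
                   growcut_params(roi_margin = 10))
    seeded <- inst$scribbles$labels > 0L
    expect_identical(fit$label_map$labels[seeded],
                     inst$scribbles$labels[seeded])
    expect_true(all(fit$strength[seeded] == 1))
  }
})

test_that("strength is non-decreasing across iterations (monotonicity)", {
  set.seed(11)
  inst <- random_instance(c(8, 8, 8))
  st <- initialize_state(inst$image, inst$scribbles)
  prev <- st$strength
  for (i in 1:30) {
    res <- growcut_step(st, inst$image)
    expect_true(all(res$state$strength >= prev))
    expect_true(all(res$state$strength <= 1))
    # every positive-strength voxel carries a label
    expect_true(all(res$state$labels[res$state$strength > 0] > 0L))
    if (res$changed_count == 0L) break
    prev <- res$state$strength
    st <- res$state
  }
  expect_identical(res$changed_count, 0L)
})

test_that("no voxel outside the ROI is ever labeled (ROI soundness)", {
  set.seed(13)
  vals <- array(runif(16^3, 0, 10), c(16, 16, 16)) # near-uniform: easy spread
  lab <- array(0L, c(16, 16, 16))
  lab[3, 3, 3] <- 1L
  lab[5, 5, 5] <- 2L
  sc <- as_scribbles(label_map(lab))
  fit <- growcut(scalar_volume(vals), sc, growcut_params(roi_margin = 2))
  roi <- fit$roi
  outside <- array(TRUE, c(16, 16, 16))
  outside[roi$lower[1]:roi$upper[1], roi$lower[2]:roi$upper[2],
          roi$lower[3]:roi$upper[3]] <- FALSE
  expect_true(all(fit$label_map$labels[outside] == 0L))
  expect_true(any(fit$label_map$labels[!outside] > 0L))
})

test_that("runs are deterministic: identical inputs give identical output", {
  set.seed(17)
  inst <- random_instance(c(9, 9, 9))
  f1 <- growcut(inst$image, inst$scribbles)
  f2 <- growcut(inst$image, inst$scribbles)
  expect_identical(f1$label_map$labels, f2$label_map$labels)
  expect_identical(f1$strength, f2$strength)
  expect_identical(f1$changed_trace, f2$changed_trace)
})

test_that("optimized and reference engines agree bit for bit (small oracle)", {
  set.seed(23)
  p <- growcut_params(roi_margin = 12) # ROI covers the full 12^3 grid
  for (rep in 1:10) {
    inst <- random_instance()
    fast <- growcut(inst$image, inst$scribbles, p, keep_strength = FALSE)
    ref <- growcut_reference(inst$image, inst$scribbles, p)
    expect_identical(fast$label_map$labels, ref$labels)
  }
})

test_that("6-connectivity is honored", {
  set.seed(29)
  inst <- random_instance(c(8, 8, 8))
  p <- growcut_params(neighborhood = 6, roi_margin = 8)
  fast <- growcut(inst$image, inst$scribbles, p, keep_strength = FALSE)
  ref <- growcut_reference(inst$image, inst$scribbles, p)
  expect_identical(fast$label_map$labels, ref$labels)
})

test_that("non-convergence within max_iterations warns and flags the fit", {
  inst <- line_instance(rep(1, 9))
  expect_warning(
    fit <- growcut(inst$image, inst$scribbles,
                   growcut_params(max_iterations = 1)),
    "converge"
  )
  expect_false(fit$converged)
  expect_identical(fit$iterations, 1L)
})

test_that("growcut fit methods print, summarize and plot", {
  ph <- make_phantom(preset = "small", shape = c(28, 28, 28), noise_sigma = 0,
                     seed = 2)
  fit <- growcut(ph$image, make_scribbles(ph$truth))
  expect_output(print(fit), "converged")
  s <- summary(fit)
  expect_s3_class(s, "summary.growcut")
  expect_equal(s$table$volume_mm3[s$table$label == 1],
               label_volume(ph$truth, 1)$volume_mm3)
  expect_output(print(s), "tumor")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, image = ph$image))
})
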