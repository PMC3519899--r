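test_that("elementary structuring elements behave classically", {
  single <- cuboid_mask(c(5, 5, 5), c(3, 3, 3), c(3, 3, 3))
  d6 <- morph_binary(single, "dilate", 1, 6)
  expect_identical(sum(d6$labels), 7L) # 6-neighbor cross
  d26 <- morph_binary(single, "dilate", 1, 26)
  expect_identical(sum(d26$labels), 27L) # full cube
  cube <- cuboid_mask(c(5, 5, 5), c(2, 2, 2), c(4, 4, 4))
  e <- morph_binary(cube, "erode", 1, 6)
  expect_identical(sum(e$labels), 1L)
  expect_identical(e$labels[3, 3, 3], 1L) # only the center survives
  gone <- morph_binary(single, "erode", 1, 6)
  expect_identical(sum(gone$labels), 0L) # a lone voxel is annihilated
})

test_that("morphology rejects non-binary input and preserves geometry", {
  lab <- array(0L, c(4, 4, 4))
  lab[1, 1, 1] <- 2L
  m <- label_map(lab)
  expect_error(morph_binary(m, "dilate"), "binary")
  msk <- cuboid_mask(c(6, 6, 6), c(2, 2, 2), c(3, 3, 3), c(0.5, 0.5, 2))
  out <- morph_binary(msk, "dilate", 1, 6)
  expect_identical(out$geometry, msk$geometry)
})

test_that("dilation is extensive, erosion anti-extensive, both monotone", {
  set.seed(31)
  for (rep in 1:5) {
    a <- array(runif(6^3) < 0.3, c(6, 6, 6))
    b <- a
    b[which(!b)[1:10]] <- TRUE # b is a strict superset of a
    ma <- as_mask(a)
    mb <- as_mask(b)
    for (conn in c(6, 26)) {
      da <- logical_from_mask(morph_binary(ma, "dilate", 1, conn))
      ea <- logical_from_mask(morph_binary(ma, "erode", 1, conn))
      expect_true(all(da[a])) # output contains input
      expect_true(all(!ea[!a])) # output inside input
      db <- logical_from_mask(morph_binary(mb, "dilate", 1, conn))
      eb <- logical_from_mask(morph_binary(mb, "erode", 1, conn))
      expect_true(all(db[da])) # monotone in the mask
      expect_true(all(eb[ea]))
    }
  }
})

test_that("remove_islands drops small components and keeps the largest", {
  a <- array(0L, c(10, 10, 10))
  a[2:6, 2:6, 2:3] <- 1L # 50 voxels
  a[9, 9, c(8, 9, 10)] <- 1L # 3 voxels
  m <- as_mask(a)
  out <- remove_islands(m, min_size = 10)
  expect_identical(sum(out$labels), 50L)
  out2 <- remove_islands(m, "keep_largest")
  expect_identical(sum(out2$labels), 50L)
  # single component: keep_largest is the identity
  one <- cuboid_mask(c(6, 6, 6), c(2, 2, 2), c(4, 4, 4))
  expect_identical(remove_islands(one, "keep_largest")$labels, one$labels)
  # empty mask passes through
  empty <- as_mask(array(0L, c(4, 4, 4)))
  expect_identical(remove_islands(empty, "keep_largest")$labels, empty$labels)
})

test_that("diagonal contact merges under 26- but not 6-connectivity", {
  a <- array(0L, c(5, 5, 5))
  a[1:2, 1:2, 1] <- 1L # component A: 4 voxels, first in scan order
  a[3:4, 3:4, 1] <- 1L # component B: 4 voxels, touches A only at a corner
  m <- as_mask(a)
  out26 <- remove_islands(m, "keep_largest", connectivity = 26)
  expect_identical(sum(out26$labels), 8L) # one merged component
  out6 <- remove_islands(m, "keep_largest", connectivity = 6)
  expect_identical(sum(out6$labels), 4L)
  expect_identical(out6$labels[1:2, 1:2, 1], matrix(1L, 2, 2)) # scan-order tie
})

test_that("remove_islands output is a subset and never splits a component", {
  set.seed(37)
  for (rep in 1:5) {
    a <- array(runif(8^3) < 0.25, c(8, 8, 8))
    m <- as_mask(a)
    out <- logical_from_mask(remove_islands(m, min_size = 3))
    expect_true(all(!out[!a]))
    comp_in <- growcutvol:::label_components(a, 26)
    comp_out <- growcutvol:::label_components(out, 26)
    # each surviving input component maps onto exactly one output component
    for (cid in setdiff(unique(comp_out[comp_out > 0]), 0)) {
      src <- unique(comp_in[comp_out == cid])
      expect_length(src, 1L)
      expect_identical(sum(comp_out == cid), sum(comp_in == src))
    }
  }
})

test_that("apply_postedit composes steps and the empty list is identity", {
  set.seed(43)
  a <- array(runif(7^3) < 0.3, c(7, 7, 7))
  m <- as_mask(a)
  expect_identical(apply_postedit(m, list())$labels, m$labels)
  # closing (dilate then erode, 6-conn) fixes a solid cube away from borders
  cube <- cuboid_mask(c(9, 9, 9), c(3, 3, 3), c(7, 7, 7))
  closed <- apply_postedit(cube, list(
    postedit_step("dilate", radius = 1, connectivity = 6),
    postedit_step("erode", radius = 1, connectivity = 6)
  ))
  expect_identical(closed$labels, cube$labels)
  log <- attr(closed, "postedit_log")
  expect_identical(nrow(log), 2L)
  expect_identical(log$voxels_after[2], sum(cube$labels == 1L))
  # speck removal restores a clean mask exactly
  speckled <- cube
  speckled$labels[1, 1, 1] <- 1L
  speckled$labels[9, 1, 1] <- 1L
  out <- apply_postedit(speckled, list(postedit_step("remove_islands")))
  expect_identical(out$labels, cube$labels)
})
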