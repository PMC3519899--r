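test_that("dice matches direct overlap counting", {
  cube <- cuboid_mask(c(10, 10, 10), c(2, 2, 2), c(5, 5, 5)) # 4^3 = 64 voxels
  expect_equal(dice(cube, cube), 1)
  shifted <- cuboid_mask(c(10, 10, 10), c(4, 2, 2), c(7, 5, 5))
  expect_equal(dice(cube, shifted), 0.5) # |A|=|B|=64, overlap 32
  disjoint <- cuboid_mask(c(10, 10, 10), c(7, 7, 7), c(9, 9, 9))
  expect_equal(dice(cube, disjoint), 0)
  empty <- as_mask(array(0L, c(10, 10, 10)))
  expect_equal(dice(empty, empty), 1) # both-empty convention
  expect_equal(dice(cube, empty), 0)
  expect_error(dice(cube, cuboid_mask(c(9, 9, 9), c(1, 1, 1), c(2, 2, 2))),
               "geometry mismatch")
})

test_that("dice is symmetric, bounded, and strictly drops with lost overlap", {
  set.seed(47)
  for (rep in 1:10) {
    a <- as_mask(array(runif(6^3) < 0.4, c(6, 6, 6)))
    b <- as_mask(array(runif(6^3) < 0.4, c(6, 6, 6)))
    d <- dice(a, b)
    expect_equal(d, dice(b, a))
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
  # move one overlapping voxel of b elsewhere: sizes fixed, overlap decreases
  a <- cuboid_mask(c(8, 8, 8), c(2, 2, 2), c(5, 5, 5))
  b <- cuboid_mask(c(8, 8, 8), c(2, 2, 2), c(5, 5, 5))
  b$labels[2, 2, 2] <- 0L
  b$labels[8, 8, 8] <- 1L
  expect_lt(dice(a, b), 1)
})

test_that("label_volume multiplies counts by the voxel volume", {
  m <- label_map(array(1L, c(10, 10, 10)))
  lv <- label_volume(m, 1)
  expect_identical(lv$voxels, 1000L)
  expect_equal(lv$volume_mm3, 1000)
  aniso <- label_map(array(1L, c(5162, 1, 1)), spacing = c(0.5, 0.5, 0.6))
  expect_equal(label_volume(aniso, 1)$volume_mm3, 774.3)
  empty <- label_map(array(0L, c(4, 4, 4)))
  expect_identical(label_volume(empty, 1)$voxels, 0L)
  expect_equal(label_volume(empty, 1)$volume_mm3, 0)
  expect_error(label_volume(m, 7), "not declared")
  # additivity over disjoint labels of a shared map
  two <- array(0L, c(6, 6, 6))
  two[1:2, , ] <- 1L
  two[5:6, , ] <- 2L
  tm <- label_map(two)
  expect_equal(label_volume(tm, 1)$volume_mm3 + label_volume(tm, 2)$volume_mm3,
               sum(two > 0) * 1)
})

test_that("summarize_stats uses the sample (n-1) standard deviation", {
  s <- summarize_stats(c(1, 2, 3, 4))
  expect_equal(s[["mean"]], 2.5)
  expect_equal(s[["sd"]], sqrt(sum((c(1, 2, 3, 4) - 2.5)^2) / 3))
  expect_equal(unname(summarize_stats(c(5, 5, 5))), c(5, 5, 5, 0))
  expect_error(summarize_stats(numeric(0)), "at least one")
  expect_true(is.na(summarize_stats(7)[["sd"]]))
})

test_that("geometric volume models reduce to their closed forms", {
  expect_equal(geometric_volume("spherical", d = 2), 4 * pi / 3)
  expect_equal(geometric_volume("mean_radius", r = c(1, 1, 1)), 4 * pi / 3)
  # ellipsoid with equal diameters collapses onto the spherical model
  for (d in c(0.5, 2, 13.7)) {
    expect_equal(geometric_volume("ellipsoid", a = d, b = d, c = d),
                 geometric_volume("spherical", d = d))
  }
  expect_equal(geometric_volume("caliper", a = 10, b = 4), 80)
  expect_error(geometric_volume("spherical"), "needs")
  expect_error(geometric_volume("ellipsoid", a = 1, b = 2), "needs")
})

test_that("macdonald_area matches brute-force geometry on rasterized shapes", {
  # single voxel: degenerate one-voxel-extent convention
  one <- macdonald_area(matrix(TRUE, 1, 1), c(1, 1))
  expect_equal(one$area_mm2, 1)
  # filled 20 x 10 mm rectangle at 0.5 mm: the largest diameter is the
  # diagonal sqrt(500) = 22.3607 mm
  rect <- matrix(TRUE, 41, 21)
  a <- macdonald_area(rect, c(0.5, 0.5))
  expect_equal(a$diameter_mm, sqrt(20^2 + 10^2), tolerance = 1e-12)
  # perpendicular extent of a w x h rectangle across its diagonal is
  # 2*w*h/diag; the product is then exactly w*h*2 = 400
  expect_equal(a$perpendicular_mm, 2 * 20 * 10 / sqrt(500), tolerance = 1e-12)
  expect_equal(a$area_mm2, 400, tolerance = 1e-9)
  # rasterized disk of diameter 20 mm: area within 5% of 400 mm^2
  xx <- ((1:81) - 41) * 0.5
  disk <- outer(xx, xx, function(x, y) x^2 + y^2) < 100
  ad <- macdonald_area(disk, c(0.5, 0.5))
  expect_equal(ad$area_mm2, 400, tolerance = 0.05)
  expect_error(macdonald_area(matrix(FALSE, 3, 3)), "empty")
})

test_that("macdonald_response applies the inclusive 50% reduction rule", {
  expect_true(macdonald_response(100, 50))
  expect_false(macdonald_response(100, 51))
  expect_true(macdonald_response(100, 0))
  expect_error(macdonald_response(0, 10), "> 0")
})

test_that("compare_pair fills a case record from volumes and dice", {
  cube <- cuboid_mask(c(10, 10, 10), c(2, 2, 2), c(5, 5, 5))
  rec <- compare_pair(cube, cube, "self")
  expect_equal(rec$dsc_percent, 100)
  expect_equal(rec$volume_manual_mm3, rec$volume_auto_mm3)
  shifted <- cuboid_mask(c(10, 10, 10), c(4, 2, 2), c(7, 5, 5))
  rec2 <- compare_pair(cube, shifted, "shift")
  expect_equal(rec2$dsc_percent, 50)
  expect_identical(rec2$voxels_manual, 64L)
  expect_identical(rec2$voxels_auto, 64L)
  disjoint <- cuboid_mask(c(10, 10, 10), c(8, 8, 8), c(9, 9, 9))
  expect_equal(compare_pair(cube, disjoint, "disj")$dsc_percent, 0)
})

test_that("study_report summarizes records in cm^3 with sample sd", {
  recs <- data.frame(
    case_id = c("a", "b"),
    volume_manual_mm3 = c(1000, 3000),
    volume_auto_mm3 = c(1500, 2500),
    voxels_manual = c(1000L, 3000L),
    voxels_auto = c(1500L, 2500L),
    dsc_percent = c(60, 80)
  )
  rep <- study_report(recs)
  s <- rep$summary
  expect_equal(s$dsc_percent[s$stat == "mean"], 70)
  expect_equal(s$dsc_percent[s$stat == "sd"], sqrt(200), tolerance = 1e-12)
  expect_equal(s$volume_manual_cm3[s$stat == "mean"], 2) # mm^3 -> cm^3
  expect_true(is.na(s$voxels_manual[s$stat == "sd"]))
  expect_error(study_report(recs[1, ]), "at least 2")
  # identical records collapse the spread to zero
  recs10 <- do.call(rbind, lapply(1:10, function(i) {
    r <- recs[1, ]
    r$case_id <- as.character(i)
    r
  }))
  r10 <- study_report(recs10)$summary
  expect_equal(r10$dsc_percent[r10$stat == "sd"], 0)
  expect_equal(r10$dsc_percent[r10$stat == "min"],
               r10$dsc_percent[r10$stat == "max"])
  expect_output(print(study_report(recs)), "Summary")
})
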