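test_that("3D labelling joins slices where 2D labelling keeps them apart", {
  m <- array(FALSE, c(9, 11, 11))
  co <- as.matrix(expand.grid(z = 1:9, y = 1:11, x = 1:11))
  inside <- (co[, 1] - 5)^2 + (co[, 2] - 6)^2 + (co[, 3] - 6)^2 <= 16
  m[co[inside, , drop = FALSE]] <- TRUE
  expect_equal(max(label_components(m, 3)), 1)
  expect_equal(max(label_components(m, 2)), 9)   # one label per slice
  expect_equal(max(label_components(array(FALSE, c(2, 5, 5)), 3)), 0)

  two <- array(FALSE, c(3, 10, 10))
  two[1:3, 2:3, 2:3] <- TRUE; two[1:3, 7:8, 7:8] <- TRUE
  expect_equal(max(label_components(two, 3)), 2)
})

test_that("diagonal contact merges under 26/8 connectivity but not under 6/4", {
  m <- array(FALSE, c(2, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE        # corner neighbours
  expect_equal(max(label_components(m, 3, connectivity = 26)), 1)
  expect_equal(max(label_components(m, 3, connectivity = 6)), 2)
})

test_that("lateral border clearing keeps z-face objects and interior objects", {
  lab <- array(0L, c(4, 12, 12))
  lab[2:3, 1:3, 4:6] <- 1L                       # touches y = 0 face
  lab[1, 5:7, 5:7] <- 2L                         # touches only top z-slice
  lab[2:3, 8:10, 8:10] <- 3L                     # interior
  out <- clear_lateral_border(lab)
  expect_equal(max(out), 2)                      # renumbered consecutively
  expect_equal(sum(out > 0), sum(lab == 2L) + sum(lab == 3L))
  expect_true(all(out[lab == 1L] == 0))
})

test_that("equivalent radius follows the sphere and circle formulas", {
  one <- array(0L, c(1, 3, 3)); one[1, 2, 2] <- 1L
  r3 <- measure_regions(one, c(1, 1, 1), dim_cell_radius = 3)
  expect_equal(r3$r_cal_um, (3 / (4 * pi))^(1 / 3), tolerance = 1e-12)
  # one-slice region of exactly pi um^2: r_cal (area mode) = 1 exactly
  npix <- 314159L
  lab <- array(0L, c(1, 320, 1000))
  lab[1, , ][seq_len(npix)] <- 1L
  r2 <- measure_regions(lab, c(sqrt(pi / npix), sqrt(pi / npix), 1),
                        dim_cell_radius = 2)
  expect_equal(r2$r_cal_um, 1.0, tolerance = 1e-5)
  # digitized 5-um sphere at 0.2 um spacing: within 2% of truth
  sph <- sphere_labels(5, 0.2)
  rs <- measure_regions(sph, c(0.2, 0.2, 0.2), dim_cell_radius = 3)
  expect_lt(abs(rs$r_cal_um - 5) / 5, 0.02)
})

test_that("volume mode and max-area mode can disagree for flat objects", {
  # an oblate object: 3 slices of a wide disk
  lab <- array(0L, c(3, 41, 41))
  for (z in 1:3) lab[z, , ][circle_mask(41, 41, 21, 21, 15)] <- 1L
  m3 <- measure_regions(lab, c(1, 1, 1), dim_cell_radius = 3)
  m2 <- measure_regions(lab, c(1, 1, 1), dim_cell_radius = 2)
  expect_equal(m2$r_cal_um, sqrt(m2$max_slice_area_um2 / pi))
  expect_equal(m3$r_cal_um, (3 * m3$volume_um3 / (4 * pi))^(1 / 3))
  expect_gt(m2$r_cal_um, m3$r_cal_um)
})

test_that("size bands classify inclusively with a gap between them", {
  rec <- data.frame(label = 1:5,
                    r_cal_um = c(1.5, 2.0, 3.0, 4.0, 6.5))
  cls <- classify_size(rec)$class
  expect_equal(cls, c("micronucleus", "micronucleus", "unclassified",
                      "nucleus", "nucleus"))
  expect_error(classify_size(rec, c(0.1, 2.0), c(1.5, 7.5)), "disjoint")
})

test_that("label edits delete, merge and split with voxel conservation", {
  lab <- array(0L, c(2, 20, 20))
  lab[1:2, 2:5, 2:5] <- 1L
  lab[1:2, 8:11, 8:11] <- 2L
  lab[1:2, 14:17, 14:17] <- 3L
  total <- sum(lab > 0)

  del <- edit_labels(lab, list(list(op = "delete", label = 2L)))
  expect_equal(max(del), 2)
  expect_equal(sum(del > 0), total - sum(lab == 2L))

  touching <- array(0L, c(1, 10, 10))
  touching[1, 2:5, 2:5] <- 1L; touching[1, 2:5, 6:9] <- 2L
  mrg <- edit_labels(touching, list(list(op = "merge", label = 1L, with = 2L)))
  expect_equal(max(mrg), 1)
  expect_equal(sum(mrg == 1L), sum(touching > 0))

  # dumbbell: two 7x7 lobes joined by a thin 1-px bridge
  db <- array(0L, c(1, 15, 25))
  db[1, 4:10, 3:9] <- 1L; db[1, 4:10, 17:23] <- 1L; db[1, 7, 10:16] <- 1L
  sp <- edit_labels(db, list(list(
    op = "split", label = 1L,
    seeds = rbind(c(1L, 7L, 6L), c(1L, 7L, 20L)))))
  expect_equal(max(sp), 2)
  expect_equal(sum(sp > 0), sum(db > 0))         # split conserves voxels
  lobe <- 7 * 7 + 7 / 2                          # lobe + half the bridge
  expect_lt(abs(sum(sp == 1L) - lobe) / lobe, 0.05)
  expect_lt(abs(sum(sp == 2L) - lobe) / lobe, 0.05)

  expect_error(edit_labels(lab, list(list(op = "delete", label = 9L))),
               "unknown label")
  expect_error(edit_labels(db, list(list(op = "split", label = 1L,
                                         seeds = rbind(c(1L, 1L, 1L),
                                                       c(1L, 7L, 6L))))),
               "outside label")
})

test_that("edit scripts parse channels, merges and seed lists", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("channel,op,label,with,seeds",
               "blue,delete,3,,",
               "blue,merge,1,2,",
               "red,split,4,,1 5 5; 1 9 9"), f)
  ed <- read_edit_script(f)
  expect_named(ed, c("blue", "red"))
  expect_equal(ed$blue[[2]]$with, 2L)
  expect_equal(ed$red[[1]]$seeds, rbind(c(1L, 5L, 5L), c(1L, 9L, 9L)))
})
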