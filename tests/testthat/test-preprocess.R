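test_that("bilateral smoothing is off at 0 and is a fixed point on constants", {
  img <- array(runif(4 * 20 * 20, 0, 255), dim = c(4, 20, 20))
  expect_identical(bilateral_smooth(img, 0, 2), img)
  expect_identical(bilateral_smooth(img, 100, 0), img)
  flat <- array(42, dim = c(1, 15, 15))
  expect_equal(bilateral_smooth(flat, 200, 1.5), flat)
})

test_that("bilateral smoothing reduces flat-region variance but keeps edges put", {
  set.seed(7)
  ny <- 40L; nx <- 40L
  clean <- matrix(50, ny, nx); clean[, 21:nx] <- 200
  noisy <- clean + matrix(rnorm(ny * nx, sd = 10), ny, nx)
  sm <- bilateral_smooth(noisy, degree_of_smoothing = 400, spatial_sigma = 2)
  # flat-region variance strictly reduced on both sides of the step
  expect_lt(var(as.numeric(sm[, 5:15])), var(as.numeric(noisy[, 5:15])))
  expect_lt(var(as.numeric(sm[, 26:36])), var(as.numeric(noisy[, 26:36])))
  # half-max (125) crossing per row stays within 1 pixel of the true edge
  edge <- apply(sm, 1, function(r) which(r >= 125)[1])
  expect_true(all(abs(edge - 21) <= 1))
})

test_that("manual thresholding matches direct counts", {
  ramp <- matrix(rep(0:255, each = 4), nrow = 4)      # 256 columns, 0..255
  expect_equal(sum(threshold_manual(ramp, 128)), 4 * 128)
  expect_true(all(threshold_manual(ramp, 0)))
  expect_false(any(threshold_manual(ramp, 256)))
})

test_that("adaptive threshold reduces to the global rule and kills flat input", {
  img <- array(10, dim = c(1, 50, 50)); img[1, 20:30, 20:30] <- 200
  m_local <- threshold_adaptive(img, 1, window = 65)   # window >= image
  expect_equal(sum(m_local), 11 * 11)
  expect_false(any(threshold_adaptive(array(7, c(1, 30, 30)))))
})

test_that("adaptive thresholding recovers dim objects that a global cut misses", {
  ny <- 40L; nx <- 160L
  bg <- matrix(rep(seq(20, 100, length.out = nx), each = ny), ny, nx)
  img <- bg
  for (cx in c(25, 80, 135))                   # equal contrast above local bg
    img[circle_mask(ny, nx, 20, cx, 7)] <- bg[20, cx] + 60
  n_comp <- function(mask) max(label_components(mask, 2))
  adaptive <- threshold_adaptive(array(img, c(1, ny, nx)), 1, window = 41)
  global <- threshold_adaptive(array(img, c(1, ny, nx)), 1, window = 999)
  expect_equal(n_comp(adaptive[1, , ]), 3)
  expect_lt(n_comp(global[1, , ]), 3)
})

test_that("raising the effective threshold never adds foreground", {
  set.seed(11)
  img <- array(10, dim = c(2, 60, 60))
  img[1, 10:25, 10:25] <- 180; img[2, 30:50, 20:45] <- 220
  img <- img + array(rnorm(length(img), sd = 8), dim = dim(img))
  m_hi <- threshold_adaptive(img, 1.0, 33)
  m_lo <- threshold_adaptive(img, 0.7, 33)
  expect_true(all(m_lo[m_hi]))                 # lower sensitivity is a superset
  t_lo <- threshold_manual(img, 100); t_hi <- threshold_manual(img, 150)
  expect_true(all(t_lo[t_hi]))
})

test_that("the global discriminant threshold agrees with an independent Otsu", {
  set.seed(5)
  vals <- round(c(rnorm(4000, 60, 12), rnorm(1200, 190, 15)))
  vals <- pmin(pmax(vals, 0), 255)
  img <- array(vals, dim = c(1, 52, 100))
  ours <- threshold_adaptive(img, 1, window = 999)
  t_ref <- EBImage::otsu(EBImage::Image(img[1, , ] / 255), range = c(0, 1),
                         levels = 256) * 255
  ref <- img[1, , ] > t_ref
  # same binarization up to the one-level inclusive/exclusive convention
  expect_lt(mean(ours[1, , ] != ref), 0.002)
})

test_that("morphological reconnection and denoising behave as closing/opening", {
  m <- matrix(FALSE, 20, 20)
  m[5:9, 4:8] <- TRUE; m[5:9, 10:14] <- TRUE    # 1-px gap between squares
  expect_identical(morph_reconnect(m, 0), m)
  expect_identical(morph_denoise(m, 0), m)
  joined <- morph_reconnect(m, 1)
  expect_equal(max(label_components(joined, 2)), 1)
  expect_gte(sum(joined), sum(m))               # closing never removes

  solid <- matrix(FALSE, 30, 30); solid[8:22, 8:22] <- TRUE
  expect_identical(morph_reconnect(solid, 2), solid)

  specks <- matrix(FALSE, 30, 30)
  specks[cbind(c(3, 10, 20), c(4, 15, 25))] <- TRUE
  expect_false(any(morph_denoise(specks, 1)))
  disk <- circle_mask(40, 40, 20, 20, 10)
  opened <- morph_denoise(disk, 2)
  expect_lte(sum(opened), sum(disk))            # opening never adds
  expect_lt(abs(sum(opened) - sum(disk)) / sum(disk), 0.05)
})
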