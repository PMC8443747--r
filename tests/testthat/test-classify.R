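test_that("overlap rate is the covered voxel fraction", {
  reg <- array(FALSE, c(2, 10, 50)); reg[1:2, , ] <- TRUE   # 1000 voxels
  other <- array(FALSE, c(2, 10, 50)); other[1, , ] <- TRUE # covers 500
  expect_equal(overlap_rate(reg, other), 0.5)
  expect_equal(overlap_rate(reg, reg), 1.0)
  expect_equal(overlap_rate(reg, array(FALSE, dim(reg))), 0.0)
  expect_error(overlap_rate(array(FALSE, c(1, 2, 2)), other), "empty")
})

test_that("overlap rate is invariant under xy upsampling of rectangles", {
  reg <- matrix(FALSE, 12, 16); reg[3:8, 3:12] <- TRUE
  oth <- matrix(FALSE, 12, 16); oth[5:10, 7:16] <- TRUE
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                      rep(seq_len(ncol(m)), each = 2)]
  expect_lt(abs(overlap_rate(reg, oth) - overlap_rate(up(reg), up(oth))),
            1e-6)
})

test_that("objective classification is inclusive at the threshold and partitions", {
  lab <- array(0L, c(1, 20, 100))
  lab[1, 1:10, 1:100] <- 1L                      # 1000-voxel region
  mk <- function(k) { g <- array(FALSE, c(1, 20, 100)); if (k > 0) g[1, 1:10, ][seq_len(k)] <- TRUE; g }
  reg <- measure_regions(lab, c(1, 1, 1))
  at <- classify_objective(reg, lab, green_mask = mk(500), rate_min = 0.5,
                           mode = "overlapped")
  below <- classify_objective(reg, lab, green_mask = mk(490), rate_min = 0.5,
                              mode = "overlapped")
  expect_true(at$is_objective)                   # exactly 0.5 counts
  expect_false(below$is_objective)               # 0.49 does not
  comp <- classify_objective(reg, lab, green_mask = mk(490), rate_min = 0.5,
                             mode = "non_overlapped")
  expect_true(comp$is_objective)                 # exact complement
  # partition property over a sweep of coverages
  for (k in c(0, 137, 500, 999, 1000)) {
    a <- classify_objective(reg, lab, green_mask = mk(k), rate_min = 0.5,
                            mode = "overlapped")$is_objective
    b <- classify_objective(reg, lab, green_mask = mk(k), rate_min = 0.5,
                            mode = "non_overlapped")$is_objective
    expect_true(xor(a, b))
  }
})

test_that("union overlap uses green-or-blue, not the max of the two", {
  lab <- array(0L, c(1, 10, 10)); lab[1, 1:10, 1:10] <- 1L  # 100 voxels
  g <- array(FALSE, c(1, 10, 10)); g[1, 1:3, ] <- TRUE      # 30 voxels
  b <- array(FALSE, c(1, 10, 10)); b[1, 4:6, ] <- TRUE      # 30 disjoint
  reg <- measure_regions(lab, c(1, 1, 1))
  out <- classify_objective(reg, lab, g, b, rate_min = 0.55, mode = "overlapped")
  expect_true(out$is_objective)                  # union 0.6 >= 0.55
  expect_equal(out$overlap_rate_green, 0.3)
  expect_equal(out$overlap_rate_blue, 0.3)
})

test_that("envelope status recovers an enveloped/naked phantom split exactly", {
  set.seed(3)
  nz <- 6L; ny <- 60L; nx <- 200L
  lab <- array(0L, c(nz, ny, nx))
  green <- array(FALSE, c(nz, ny, nx))
  truth <- logical(20)
  for (i in 1:20) {
    cy <- 10 + 20 * ((i - 1) %/% 10)
    cx <- 10 + 18 * ((i - 1) %% 10)
    lab[3:4, (cy - 2):(cy + 2), (cx - 2):(cx + 2)] <- i
    truth[i] <- i %% 2 == 0
    if (truth[i]) green[2:5, (cy - 3):(cy + 3), (cx - 3):(cx + 3)] <- TRUE
  }
  reg <- classify_size(measure_regions(lab, c(0.4, 0.4, 1)))
  expect_true(all(reg$class == "micronucleus"))
  st <- envelope_status(reg, lab, green, rate_min = 0.5)$envelope_status
  expect_equal(st == "positive", truth)          # 10/10 split recovered
  nost <- envelope_status(reg, lab, NULL)$envelope_status
  expect_true(all(nost == "not_applicable"))
})

test_that("summary counts match a disjoint phantom's ground truth", {
  expect_equal(unlist(summarize_counts(data.frame())),
               c(n_nuclei = 0, n_micronuclei = 0,
                 n_micronuclei_envelope_positive = 0,
                 n_micronuclei_envelope_negative = 0, n_objective = 0,
                 micronuclei_per_nucleus = NA))
  ph <- make_disjoint_phantom()
  res <- run_pipeline(ph$stack, mn_params(voxel_spacing = ph$stack$spacing))
  expect_equal(res$summary$n_nuclei, ph$counts$n_nuclei)
  expect_equal(res$summary$n_micronuclei, ph$counts$n_micronuclei)
  expect_equal(res$summary$n_micronuclei_envelope_positive,
               ph$counts$n_micronuclei_envelope_positive)
  expect_equal(res$summary$micronuclei_per_nucleus, 8 / 5)
})
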