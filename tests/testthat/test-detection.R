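test_that("fixed-threshold binarization follows the >= convention", {
  cfg <- detection_config("fixed", fixed_threshold = 1L)
  m <- binarize_channel(matrix(0L, 8, 8), "axon", cfg)
  expect_identical(positive_count(m), 0L)

  plane <- cbind(matrix(10L, 8, 4), matrix(200L, 8, 4))
  cfg100 <- detection_config("fixed", fixed_threshold = 100L)
  m <- binarize_channel(plane, "oligodendrocyte", cfg100)
  expect_identical(mm(m), plane >= 100L)
  # boundary: a pixel exactly at the threshold is foreground
  cfg200 <- detection_config("fixed", fixed_threshold = 200L)
  expect_identical(positive_count(binarize_channel(plane, "axon", cfg200)), 32L)
})

test_that("otsu threshold equals exhaustive between-class-variance search", {
  for (seed in 1:6) {
    set.seed(seed)
    plane <- matrix(as.integer(round(c(rnorm(600, 40, 12), rnorm(424, 180, 20)))),
                    32, 32)
    plane[plane < 0L] <- 0L; plane[plane > 255L] <- 255L
    expect_identical(otsu_threshold(plane, 256L), as.numeric(oracle_otsu(plane)))
  }
  # two-level plane: every separating threshold ties, lowest must win
  plane <- matrix(rep(c(10L, 200L), each = 32), 8, 8)
  expect_identical(otsu_threshold(plane, 256L), 11)
  expect_equal(oracle_otsu(plane), 11)
})

test_that("constant plane under otsu yields an empty mask with a warning", {
  cfg <- detection_config("otsu")
  expect_warning(m <- binarize_channel(matrix(7L, 8, 8), "nucleus", cfg),
                 "all-constant")
  expect_identical(positive_count(m), 0L)
})

test_that("cell bodies are the dilated nucleus-marker overlap", {
  cfg <- detection_config("fixed")
  nuc <- mask_from_coords(0:3, rep(1L, 4), 10, 10)
  mrk <- mask_from_coords(6:9, rep(8L, 4), 10, 10)
  expect_identical(positive_count(detect_cell_bodies(nuc, mrk, cfg)), 0L)
  expect_identical(mm(detect_cell_bodies(nuc, nuc, cfg)), mm(nuc))

  set.seed(11)
  a <- random_mask(15, 12, p = 0.3); b <- random_mask(15, 12, p = 0.3)
  expect_identical(mm(detect_cell_bodies(a, b, cfg)), oracle_and(a, b))

  cfg2 <- detection_config("fixed", cell_body_dilation_px = 2L)
  expect_identical(mm(detect_cell_bodies(a, b, cfg2)),
                   oracle_dilate(oracle_and(a, b), 2L))
  expect_error(detect_cell_bodies(nuc, random_mask(4, 4), cfg), "dimension mismatch")
})

bar_stack <- function() {
  # oligodendrocyte: horizontal bar rows 4-6; axon: vertical bar cols 4-6
  o <- matrix(0L, 16, 16); o[5:7, ] <- 200L
  a <- matrix(0L, 16, 16); a[, 5:7] <- 200L
  n <- matrix(0L, 16, 16)
  channel_stack(o, a, n)
}

test_that("candidates are the co-localized membrane overlap minus cell bodies", {
  cfg <- detection_config("fixed", fixed_threshold = 100L)
  cand <- detect_candidates(bar_stack(), cfg)
  expect_length(cand, 1L)
  # the 3x3 intersection block at rows 4-6 x cols 4-6 (0-based)
  expect_identical(positive_count(cand), 9L)
  xy <- mask_coords(cand[[1]])
  expect_true(all(xy$x %in% 4:6) && all(xy$y %in% 4:6))

  # area filter: 9 px < 10 removes the block entirely
  cfg10 <- detection_config("fixed", fixed_threshold = 100L,
                            min_component_area_px = 10L)
  expect_identical(positive_count(detect_candidates(bar_stack(), cfg10)), 0L)
  # 9 px >= 9 keeps it
  cfg9 <- detection_config("fixed", fixed_threshold = 100L,
                           min_component_area_px = 9L)
  expect_identical(positive_count(detect_candidates(bar_stack(), cfg9)), 9L)
})

test_that("empty axon signal or all-consumed cell bodies yield no candidates", {
  o <- matrix(200L, 12, 12); a <- matrix(0L, 12, 12); n <- matrix(0L, 12, 12)
  cfg <- detection_config("fixed", fixed_threshold = 100L)
  expect_identical(positive_count(detect_candidates(channel_stack(o, a, n), cfg)), 0L)
  # all-true nucleus and oligodendrocyte: everything is cell body
  full <- matrix(200L, 12, 12)
  expect_identical(positive_count(detect_candidates(channel_stack(full, full, full), cfg)),
                   0L)
})

test_that("component area filtering is monotone and candidates stay within both membrane masks", {
  for (seed in 1:4) {
    gen <- generate_stack(synth_config(width = 48L, height = 48L, depth = 2L,
                                       n_fibers = 3L, fiber_length_px = 25L,
                                       n_nuclei = 1L, nucleus_radius = 5L,
                                       n_distractors = 2L, seed = seed))
    cfg0 <- detection_config("fixed", fixed_threshold = 100L)
    cand <- detect_candidates(gen$stack, cfg0)
    for (zi in seq_along(cand)) {
      o <- gen$stack$channels$oligodendrocyte[[zi]] >= 100L
      a <- gen$stack$channels$axon[[zi]] >= 100L
      expect_true(all(!mm(cand[[zi]]) | (o & a)))
    }
    prev <- Inf
    for (area in c(0L, 4L, 8L, 16L, 64L)) {
      cfg <- detection_config("fixed", fixed_threshold = 100L,
                              min_component_area_px = area)
      n <- candidate_pixel_count(detect_candidates(gen$stack, cfg))
      expect_lte(n, prev)
      prev <- n
    }
  }
})

test_that("pixel counting is additive and matches a brute-force loop", {
  expect_identical(candidate_pixel_count(list()), 0L)
  a <- mask_from_coords(0:2, 0:2, 8, 8)
  b <- mask_from_coords(0:3, rep(4L, 4), 8, 8, z = 1L)
  expect_identical(candidate_pixel_count(list(a, b)), 7L)
  set.seed(5)
  ms <- lapply(0:2, function(z) random_mask(20, 20, z, 0.3))
  brute <- 0L
  for (m in ms) for (i in 1:20) for (j in 1:20) if (mm(m)[i, j]) brute <- brute + 1L
  expect_identical(candidate_pixel_count(ms), brute)
})
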