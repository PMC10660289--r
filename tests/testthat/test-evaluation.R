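test_that("confusion counts match a brute-force pixel loop", {
  pred <- mask_from_coords(c(0, 1, 2, 3), c(0, 0, 0, 3), 4, 4)
  gold <- mask_from_coords(c(0, 1, 2), c(0, 0, 0), 4, 4)
  cc <- confusion_counts(pred, gold)
  expect_identical(c(cc$tp, cc$fp, cc$fn), c(3L, 1L, 0L))
  expect_identical(cc$domain_size, 16L)
  brute <- oracle_confusion(list(pred), list(gold))
  expect_identical(c(cc$tp, cc$fp, cc$fn), c(brute$tp, brute$fp, brute$fn))

  set.seed(8)
  p <- lapply(0:1, function(z) random_mask(12, 10, z, 0.3))
  g <- lapply(0:1, function(z) random_mask(12, 10, z, 0.3))
  d <- lapply(0:1, function(z) random_mask(12, 10, z, 0.5))
  cc <- confusion_counts(p, g, d)
  brute <- oracle_confusion(p, g, d)
  expect_identical(c(cc$tp, cc$fp, cc$fn), c(brute$tp, brute$fp, brute$fn))
  expect_identical(cc$domain_size, positive_count(d))
})

test_that("perfect agreement and disjoint masks hit the count boundaries", {
  set.seed(9)
  m <- random_mask(10, 10, p = 0.3)
  cc <- confusion_counts(m, m)
  expect_identical(c(cc$fp, cc$fn), c(0L, 0L))
  a <- mask_from_coords(0:3, rep(0L, 4), 10, 10)
  b <- mask_from_coords(0:3, rep(5L, 4), 10, 10)
  expect_identical(confusion_counts(a, b)$tp, 0L)
  expect_error(confusion_counts(a, random_mask(5, 5)), "dimension mismatch")
})

test_that("precision is 100*tp/(tp+fp) and undefined when nothing was marked", {
  cc <- structure(list(tp = 3, fp = 1, fn = 0, domain_size = 16),
                  class = "confusion_counts")
  expect_equal(pixel_precision(cc), 75)
  cc$fp <- 0; cc$tp <- 7
  expect_equal(pixel_precision(cc), 100)
  cc$tp <- 0
  expect_error(pixel_precision(cc), class = "myelinGT_undefined_precision")
})

test_that("precision does not depend on z order or pixels outside the domain", {
  set.seed(10)
  p <- lapply(0:2, function(z) random_mask(15, 15, z, 0.25))
  g <- lapply(0:2, function(z) random_mask(15, 15, z, 0.25))
  d <- lapply(0:2, function(z) random_mask(15, 15, z, 0.6))
  base <- pixel_precision(confusion_counts(p, g, d))
  perm <- c(3, 1, 2)
  expect_equal(pixel_precision(confusion_counts(p[perm], g[perm], d[perm])), base)
  # add predictions strictly outside the domain: nothing changes
  p2 <- lapply(seq_along(p), function(k) {
    extra <- mm(p[[k]]) | !mm(d[[k]])
    binary_mask(extra, k - 1L)
  })
  expect_equal(pixel_precision(confusion_counts(p2, g, d)), base)
  # shrinking the domain never increases any count
  d_small <- lapply(seq_along(d), function(k)
    binary_mask(mm(d[[k]]) & random_mask(15, 15, p = 0.5), k - 1L))
  cc_big <- confusion_counts(p, g, d)
  cc_small <- confusion_counts(p, g, d_small)
  expect_lte(cc_small$tp, cc_big$tp)
  expect_lte(cc_small$fp, cc_big$fp)
  expect_lte(cc_small$fn, cc_big$fn)
})

test_that("predictions contained in gold score exactly 100", {
  g <- mask_from_coords(c(1:8, 1:8), c(rep(2L, 8), rep(5L, 8)), 12, 12)
  p <- mask_from_coords(2:5, rep(2L, 4), 12, 12)
  expect_identical(pixel_precision(confusion_counts(p, g)), 100)
})

test_that("averaging is unweighted and display rounding is half-up", {
  expect_equal(average_precision(c(50)), 50)
  expect_equal(average_precision(c(0, 100)), 50)
  expect_error(average_precision(numeric(0)), "empty")
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(-2.345, 2), -2.35)
  expect_equal(round_half_up(2.344, 2), 2.34)
})

test_that("reports average per annotator first, then across annotators", {
  cc <- function(tp, fp) structure(list(tp = tp, fp = fp, fn = 0, domain_size = 1000),
                                   class = "confusion_counts")
  rows <- list(
    list(image_id = "img1", annotator_id = "A", counts = cc(30, 70)),   # 30%
    list(image_id = "img2", annotator_id = "A", counts = cc(50, 50)),   # 50%
    list(image_id = "img1", annotator_id = "B", counts = cc(70, 30)))   # 70%
  rep <- build_report(rows)
  expect_equal(rep$rows$precision_percent, c(30, 50, 70))
  expect_equal(sort(rep$per_annotator$mean_precision_percent), c(40, 70))
  expect_equal(rep$overall, 55)          # mean of annotator means (paper-style)
  expect_equal(rep$overall_pooled, 50)   # mean over rows

  one <- build_report(list(list(image_id = "i", annotator_id = "A",
                                counts = cc(3, 1))))
  expect_equal(one$rows$precision_percent, 75)
  expect_equal(one$overall, 75)
})

test_that("undefined rows are excluded from averages with a warning", {
  cc <- function(tp, fp) structure(list(tp = tp, fp = fp, fn = 5, domain_size = 100),
                                   class = "confusion_counts")
  rows <- list(
    list(image_id = "img1", annotator_id = "A", counts = cc(0, 0)),
    list(image_id = "img2", annotator_id = "A", counts = cc(0, 0)),
    list(image_id = "img1", annotator_id = "B", counts = cc(60, 40)))
  expect_warning(rep <- build_report(rows), "undefined precision")
  expect_true(all(is.na(rep$rows$precision_percent[rep$rows$annotator_id == "A"])))
  expect_equal(rep$overall, 60)  # only B contributes
  path <- tempfile(fileext = ".csv")
  write_report_csv(rep, path)
  got <- utils::read.csv(path)
  expect_identical(names(got),
                   c("image_id", "annotator_id", "tp", "fp", "fn", "precision_percent"))
  expect_identical(nrow(got), 3L)
})

test_that("the gold standard is exactly the rasterized adjudicated set", {
  adj <- annotation_set(width = 20, height = 15, depth = 2, source = "adjudicator",
                        vectors = list(myelin_vector("g1", 0, rbind(c(3, 7), c(12, 7)))))
  expect_message(gold <- extract_gold_standard(list(), adj), NA)
  expect_length(gold, 2L)
  expect_identical(positive_count(gold[[1]]), 10L)
  expect_identical(positive_count(gold[[2]]), 0L)

  # empty adjudicated set: all-zero gold
  none <- extract_gold_standard(list(), annotation_set(width = 8, height = 8))
  expect_identical(positive_count(none), 0L)

  # composition with TIFF round trip
  path <- tempfile(fileext = ".tif")
  save_mask_tiff(gold, path)
  expect_true(mask_stack_equal(load_mask_tiff(path), gold))

  experts <- list(annotation_set(width = 5, height = 5, source = "e1"))
  expect_error(extract_gold_standard(experts, adj), "dimension mismatch")
})
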