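test_that("vector and set invariants are enforced at construction", {
  expect_error(myelin_vector("a", 0, rbind(c(1, 1)), thickness = 2L), "odd")
  expect_error(myelin_vector("a", 0, rbind(c(1, 1), c(1, 1))), "distinct")
  expect_error(myelin_vector("a", 0, matrix(0, 0, 2)), "n >= 1")
  expect_error(myelin_vector("", 0, rbind(c(1, 1))), "non-empty string")

  v1 <- myelin_vector("a", 0, rbind(c(1, 1)))
  expect_error(annotation_set(width = 10, height = 10, vectors = list(v1, v1)),
               "duplicate vector id")
  oob <- myelin_vector("b", 0, rbind(c(10, 0)))
  expect_error(annotation_set(width = 10, height = 10, vectors = list(oob)),
               "out-of-bounds")
  deep <- myelin_vector("c", 3, rbind(c(1, 1)))
  expect_error(annotation_set(width = 10, height = 10, depth = 3, vectors = list(deep)),
               "depth")
})

test_that("annotation JSON round trip is the identity, thickness byte-exact", {
  set.seed(99)
  for (rep in 1:5) {
    s <- random_annotation_set(n_vectors = 50L)
    path <- tempfile(fileext = ".iev.json")
    write_annotations(s, path)
    expect_sets_equal(read_annotations(path), s)
  }
  # empty set writes vectors:[]
  path <- tempfile(fileext = ".iev.json")
  write_annotations(annotation_set(width = 5, height = 5), path)
  expect_match(readLines(path, warn = FALSE), '"vectors":\\[\\]')
  expect_length(read_annotations(path)$vectors, 0L)
})

test_that("invalid annotation documents are rejected on read", {
  doc <- function(vec_json) {
    sprintf('{"format_version":1,"image_ref":"x","width":10,"height":10,"depth":1,"source":"e1","vectors":[%s]}',
            vec_json)
  }
  p <- tempfile(fileext = ".json")

  writeLines(doc('{"id":"v1","z":0,"thickness":3,"points":[[1,2],[3,4]]}'), p)
  s <- read_annotations(p)
  expect_identical(s$vectors[[1]]$thickness, 3L)
  expect_identical(s$vectors[[1]]$points, rbind(c(1L, 2L), c(3L, 4L)))

  writeLines(doc('{"id":"v1","z":0,"thickness":2,"points":[[1,2]]}'), p)
  expect_error(read_annotations(p), "odd")

  writeLines(doc('{"id":"v1","z":0,"thickness":1,"points":[[10,0]]}'), p)
  expect_error(read_annotations(p), "out-of-bounds")

  writeLines('{"image_ref":"x"}', p)
  expect_error(read_annotations(p), "missing field")
})

test_that("stroke rasterization follows Bresenham plus centred disk dilation", {
  v <- myelin_vector("p", 0, rbind(c(5, 5)))
  m <- rasterize_vector(v, 10, 10)
  expect_identical(mask_coords(m), data.frame(x = 5L, y = 5L))

  h <- myelin_vector("h", 0, rbind(c(0, 0), c(4, 0)))
  m <- rasterize_vector(h, 10, 10)
  expect_identical(positive_count(m), 5L)
  expect_setequal(mask_coords(m)$x, 0:4)
  expect_true(all(mask_coords(m)$y == 0L))

  # thick stroke equals the brute-force disk-stamping oracle
  for (thick in c(3L, 5L)) {
    seg <- myelin_vector("s", 0, rbind(c(2, 3), c(14, 9)), thickness = thick)
    m <- rasterize_vector(seg, 20, 20)
    path <- mm(rasterize_vector(myelin_vector("s1", 0, seg$points), 20, 20))
    idx <- which(path, arr.ind = TRUE)
    expect_identical(mm(m),
                     oracle_stamp(cbind(idx[, 2] - 1L, idx[, 1] - 1L), thick, 20, 20))
  }

  # diagonal line: one pixel per column
  d <- myelin_vector("d", 0, rbind(c(0, 0), c(6, 6)))
  expect_identical(positive_count(rasterize_vector(d, 10, 10)), 7L)
})

test_that("set rasterization has union semantics per z-section", {
  w <- 20L; h <- 20L
  a <- myelin_vector("a", 0, rbind(c(0, 0), c(5, 0)))
  b <- myelin_vector("b", 0, rbind(c(0, 5), c(5, 5)))
  cxy <- myelin_vector("c", 1, rbind(c(3, 0), c(3, 8)))
  s <- annotation_set(width = w, height = h, depth = 2, vectors = list(a, b, cxy))

  expect_identical(positive_count(rasterize_set(s, 0)), 12L)  # disjoint: additive
  expect_identical(positive_count(rasterize_set(s, 1)), 9L)
  empty_z <- annotation_set(width = w, height = h, depth = 2)
  expect_identical(positive_count(rasterize_set(empty_z, 0)), 0L)

  # overlapping vectors: union, checked against an explicit pixel-set union
  o1 <- myelin_vector("o1", 0, rbind(c(0, 2), c(9, 2)), thickness = 3L)
  o2 <- myelin_vector("o2", 0, rbind(c(4, 0), c(4, 9)), thickness = 3L)
  s2 <- annotation_set(width = 12, height = 12, vectors = list(o1, o2))
  u <- mm(rasterize_vector(o1, 12, 12)) | mm(rasterize_vector(o2, 12, 12))
  expect_identical(mm(rasterize_set(s2, 0)), u)
  expect_lt(positive_count(rasterize_set(s2, 0)),
            positive_count(rasterize_vector(o1, 12, 12)) +
            positive_count(rasterize_vector(o2, 12, 12)))
})

test_that("merging preserves both sets verbatim and never mutates them", {
  set.seed(4)
  a <- random_annotation_set(source = "expert1")
  b <- random_annotation_set(source = "expert2")
  a_before <- a
  m <- merge_sets(a, b)
  expect_sets_equal(extract_source(m, "expert1"), a_before)
  expect_sets_equal(extract_source(m, "expert2"), b)
  expect_sets_equal(a, a_before)
  expect_identical(sum(vapply(m$sets, function(s) length(s$vectors), integer(1))),
                   length(a$vectors) + length(b$vectors))

  empty <- annotation_set(width = a$width, height = a$height, depth = a$depth,
                          source = "nobody")
  m2 <- merge_sets(a, empty)
  expect_sets_equal(extract_source(m2, "expert1"), a_before)

  expect_error(merge_sets(a, a), "distinct")
  small <- annotation_set(width = 5, height = 5, source = "expert2")
  expect_error(merge_sets(a, small), "dimension mismatch")
  expect_error(extract_source(m, "expert9"), "unknown source")
})

test_that("edits delete, trim and draw exactly one vector", {
  v <- myelin_vector("v1", 0, rbind(c(0, 0), c(3, 0), c(6, 0), c(6, 3), c(6, 6)),
                     thickness = 3L)
  s <- annotation_set(width = 10, height = 10, vectors = list(v))

  expect_length(apply_edit(s, edit_delete("v1"))$vectors, 0L)
  expect_error(apply_edit(s, edit_delete("nope")), "unknown vector id")
  expect_error(apply_edit(s, edit_trim("v1", 0L)), "0 points")

  trimmed <- apply_edit(s, edit_trim("v1", 2L))
  expect_identical(nrow(trimmed$vectors[[1]]$points), 2L)
  full_px <- mm(rasterize_set(s, 0))
  trim_px <- mm(rasterize_set(trimmed, 0))
  expect_true(all(!trim_px | full_px))  # trimmed rasterization is a subset
  expect_lt(sum(trim_px), sum(full_px))

  drawn <- apply_edit(annotation_set(width = 10, height = 10),
                      edit_draw(myelin_vector("new", 0, rbind(c(1, 1)))))
  expect_length(drawn$vectors, 1L)
  # delete reduces the count by exactly one
  two <- apply_edit(drawn, edit_draw(myelin_vector("new2", 0, rbind(c(2, 2)))))
  expect_identical(length(apply_edit(two, edit_delete("new"))$vectors),
                   length(two$vectors) - 1L)
})

test_that("z-context returns the -1/0/+1 neighbourhood with empty stack ends", {
  vs <- list(myelin_vector("z0", 0, rbind(c(1, 1))),
             myelin_vector("z1a", 1, rbind(c(2, 2))),
             myelin_vector("z1b", 1, rbind(c(3, 3))),
             myelin_vector("z2", 2, rbind(c(4, 4))))
  s <- annotation_set(width = 10, height = 10, depth = 3, vectors = vs)

  ctx0 <- z_context(s, 0)
  expect_length(ctx0$below, 0L)
  expect_identical(vapply(ctx0$at, `[[`, character(1), "id"), "z0")
  expect_identical(sort(vapply(ctx0$above, `[[`, character(1), "id")), c("z1a", "z1b"))

  ctx1 <- z_context(s, 1)
  expect_identical(vapply(ctx1$below, `[[`, character(1), "id"), "z0")
  expect_identical(vapply(ctx1$above, `[[`, character(1), "id"), "z2")
  # interior lists match a direct per-z filter
  expect_identical(vapply(ctx1$at, `[[`, character(1), "id"),
                   vapply(Filter(function(v) v$z == 1, s$vectors), `[[`,
                          character(1), "id"))

  single <- annotation_set(width = 5, height = 5, depth = 1,
                           vectors = list(myelin_vector("only", 0, rbind(c(0, 0)))))
  ctx <- z_context(single, 0)
  expect_length(ctx$below, 0L)
  expect_length(ctx$above, 0L)
  expect_error(z_context(s, 3), "out of range")
})
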