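# Programmatic fixtures shared by several test files.

# write a list of integer planes as a grayscale TIFF, returning the path
write_gray_tiff <- function(planes, path = tempfile(fileext = ".tif"),
                            bits = 8L) {
  denom <- 2^bits - 1
  tiff::writeTIFF(lapply(planes, function(p) p / denom), path,
                  bits.per.sample = bits)
  path
}

random_mask <- function(width, height, z = 0L, p = 0.1) {
  binary_mask(matrix(runif(width * height) < p, height, width), z)
}

random_vector <- function(id, width, height, depth, source = "rand") {
  n <- sample(1:6, 1)
  pts <- matrix(0L, n, 2)
  pts[1, ] <- c(sample(0:(width - 1), 1), sample(0:(height - 1), 1))
  if (n > 1) {
    for (k in 2:n) {
      repeat {
        cand <- pmin(pmax(pts[k - 1, ] + sample(-3:3, 2, replace = TRUE), 0L),
                     c(width - 1L, height - 1L))
        if (any(cand != pts[k - 1, ])) break
      }
      pts[k, ] <- cand
    }
  }
  myelin_vector(id, z = sample(0:(depth - 1), 1), points = pts,
                thickness = sample(c(1L, 3L, 5L), 1), source = source)
}

random_annotation_set <- function(width = 40L, height = 30L, depth = 3L,
                                  n_vectors = 5L, source = "rand") {
  vs <- lapply(seq_len(n_vectors), function(i)
    random_vector(sprintf("v%03d", i), width, height, depth, source))
  annotation_set(image_ref = "fixture", width = width, height = height,
                 depth = depth, source = source, vectors = vs)
}

# annotation sets compared field by field (points byte-exact)
expect_sets_equal <- function(a, b) {
  expect_identical(a$image_ref, b$image_ref)
  expect_identical(c(a$width, a$height, a$depth), c(b$width, b$height, b$depth))
  expect_identical(a$source, b$source)
  expect_identical(length(a$vectors), length(b$vectors))
  for (k in seq_along(a$vectors)) {
    va <- a$vectors[[k]]; vb <- b$vectors[[k]]
    expect_identical(va$id, vb$id)
    expect_identical(va$z, vb$z)
    expect_identical(va$thickness, vb$thickness)
    expect_identical(va$source, vb$source)
    expect_identical(va$points, vb$points)
  }
}

mask_stack_equal <- function(a, b) {
  length(a) == length(b) &&
    all(mapply(function(x, y) identical(mm(x), mm(y)), a, b))
}
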