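# Independent brute-force oracles. These deliberately re-derive every
# quantity with plain loops / exhaustive search so they share no code
# path with the implementation they check.

mm <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# pixelwise AND by explicit double loop
oracle_and <- function(a, b) {
  a <- mm(a); b <- mm(b)
  out <- matrix(FALSE, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) out[i, j] <- isTRUE(a[i, j]) && isTRUE(b[i, j])
  }
  out
}

# binary dilation by a Euclidean disk, stamping offsets pixel by pixel
oracle_dilate <- function(m, r) {
  m <- mm(m)
  if (r <= 0) return(m)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!m[i, j]) next
      for (dy in -r:r) {
        for (dx in -r:r) {
          if (dx * dx + dy * dy > r * r) next
          ii <- i + dy; jj <- j + dx
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) out[ii, jj] <- TRUE
        }
      }
    }
  }
  out
}

# exhaustive-search Otsu: try every threshold t (pixel true iff >= t),
# compute between-class variance directly from the class members,
# first (lowest) maximum wins; NA for constant planes
oracle_otsu <- function(plane, n_levels = 256L) {
  v <- as.vector(plane)
  if (min(v) == max(v)) return(NA_real_)
  best_t <- NA_real_; best_var <- -Inf
  n <- length(v)
  for (t in 1:(n_levels - 1L)) {
    c0 <- v[v < t]; c1 <- v[v >= t]
    if (!length(c0) || !length(c1)) next
    w0 <- length(c0) / n; w1 <- length(c1) / n
    var_b <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (var_b > best_var + 1e-12) {
      best_var <- var_b
      best_t <- t
    }
  }
  best_t
}

# 8-connected flood-fill labelling with an explicit stack, then drop
# components with area < min_area
oracle_area_filter <- function(m, min_area) {
  m <- mm(m)
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  next_lab <- 0L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (!m[i, j] || lab[i, j] > 0L) next
      next_lab <- next_lab + 1L
      stack <- list(c(i, j))
      lab[i, j] <- next_lab
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dy in -1:1) {
          for (dx in -1:1) {
            if (dx == 0 && dy == 0) next
            ii <- p[1] + dy; jj <- p[2] + dx
            if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
                m[ii, jj] && lab[ii, jj] == 0L) {
              lab[ii, jj] <- next_lab
              stack[[length(stack) + 1L]] <- c(ii, jj)
            }
          }
        }
      }
    }
  }
  if (next_lab == 0L || min_area <= 0) return(m)
  areas <- tabulate(lab[lab > 0L], nbins = next_lab)
  out <- matrix(FALSE, h, w)
  for (k in which(areas >= min_area)) out[lab == k] <- TRUE
  out
}

# full detection chain re-derived from first principles
oracle_detect <- function(stack, cfg) {
  binz <- function(plane, role) {
    if (cfg$binarize_method == "fixed") {
      thr <- cfg$fixed_threshold[[role]]
    } else {
      thr <- oracle_otsu(plane, if (stack$bit_depth == 16L) 65536L else 256L)
      if (is.na(thr)) return(matrix(FALSE, nrow(plane), ncol(plane)))
    }
    plane >= thr
  }
  lapply(seq_len(stack$depth), function(zi) {
    o <- binz(stack$channels$oligodendrocyte[[zi]], "oligodendrocyte")
    a <- binz(stack$channels$axon[[zi]], "axon")
    n <- binz(stack$channels$nucleus[[zi]], "nucleus")
    marker <- if (cfg$cell_body_marker == "oligodendrocyte") o else a
    b <- oracle_dilate(oracle_and(n, marker), cfg$cell_body_dilation_px)
    cand <- o & !b & a
    oracle_area_filter(cand, cfg$min_component_area_px)
  })
}

# confusion counts by looping over every pixel of every section
oracle_confusion <- function(predicted, gold, domain = NULL) {
  tp <- fp <- fn <- 0L
  for (k in seq_along(predicted)) {
    p <- mm(predicted[[k]]); g <- mm(gold[[k]])
    d <- if (is.null(domain)) matrix(TRUE, nrow(p), ncol(p)) else mm(domain[[k]])
    for (i in seq_len(nrow(p))) {
      for (j in seq_len(ncol(p))) {
        if (!d[i, j]) next
        if (p[i, j] && g[i, j]) tp <- tp + 1L
        else if (p[i, j] && !g[i, j]) fp <- fp + 1L
        else if (!p[i, j] && g[i, j]) fn <- fn + 1L
      }
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

# disk-stamping oracle for stroke rasterization: stamp a Euclidean disk
# at every path pixel found by walking the segment the slow way
oracle_stamp <- function(path_px, thickness, width, height) {
  r <- (thickness - 1) / 2
  out <- matrix(FALSE, height, width)
  for (k in seq_len(nrow(path_px))) {
    for (dy in -r:r) {
      for (dx in -r:r) {
        if (dx * dx + dy * dy > r * r) next
        x <- path_px[k, 1] + dx; y <- path_px[k, 2] + dy
        if (x >= 0 && x < width && y >= 0 && y < height) out[y + 1, x + 1] <- TRUE
      }
    }
  }
  out
}
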