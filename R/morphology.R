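# Internal raster morphology shared by detection, rasterization and
# vectorization. Dilation and the Euclidean distance transform delegate to
# EBImage; 8-connected labelling and Zhang-Suen thinning are implemented
# here (EBImage::bwlabel is 4-connected and EBImage has no thinning).

# 0-based (dx, dy) offsets of the digital disk {d : dx^2 + dy^2 <= r^2}
disk_offsets <- function(r) {
  r <- as.integer(r)
  if (r <= 0L) return(matrix(0L, 1L, 2L, dimnames = list(NULL, c("dx", "dy"))))
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

disk_kernel <- function(r) {
  off <- disk_offsets(r)
  k <- matrix(0L, 2L * r + 1L, 2L * r + 1L)
  k[cbind(off[, "dy"] + r + 1L, off[, "dx"] + r + 1L)] <- 1L
  k
}

# binary dilation by a Euclidean disk of radius r (r = 0 is the identity)
dilate_mask <- function(m, r) {
  m <- as_mask_matrix(m)
  if (r <= 0L || !any(m)) return(m)
  EBImage::dilate(matrix(as.numeric(m), nrow(m)), disk_kernel(r)) > 0
}

# 8-connected component labelling: 4-connected bwlabel, then union-find
# across the two diagonal adjacency directions.
label_components8 <- function(m) {
  m <- as_mask_matrix(m)
  lab <- EBImage::bwlabel(matrix(as.numeric(m), nrow(m)))
  lab <- matrix(as.integer(round(lab)), nrow(m))
  nlab <- max(lab, 0L)
  if (nlab <= 1L || nrow(lab) < 2L || ncol(lab) < 2L) return(lab)
  parent <- seq_len(nlab)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  merge_pairs <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) return(invisible())
    for (k in which(sel)) {
      ra <- find_root(a[k]); rb <- find_root(b[k])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  nr <- nrow(lab); nc <- ncol(lab)
  merge_pairs(lab[-nr, -nc], lab[-1, -1])  # down-right diagonal
  merge_pairs(lab[-nr, -1], lab[-1, -nc])  # down-left diagonal
  roots <- vapply(seq_len(nlab), find_root, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

# drop 8-connected components with area < min_area (keep area >= min_area)
filter_small_components <- function(m, min_area) {
  m <- as_mask_matrix(m)
  if (min_area <= 0L || !any(m)) return(m)
  lab <- label_components8(m)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  matrix(lab %in% keep, nrow(m))
}

# Zhang-Suen morphological thinning to a 1-px, 8-connected skeleton.
# Neighbourhood labels follow the usual convention (p2 = north = y-1,
# clockwise to p9 = north-west); y is the matrix row.
thin_mask <- function(m) {
  m <- as_mask_matrix(m)
  nr <- nrow(m); nc <- ncol(m)
  img <- matrix(0L, nr + 2L, nc + 2L)
  img[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(m)
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p  <- img[ri, ci, drop = FALSE]
      p2 <- img[ri - 1L, ci, drop = FALSE]; p3 <- img[ri - 1L, ci + 1L, drop = FALSE]
      p4 <- img[ri, ci + 1L, drop = FALSE]; p5 <- img[ri + 1L, ci + 1L, drop = FALSE]
      p6 <- img[ri + 1L, ci, drop = FALSE]; p7 <- img[ri + 1L, ci - 1L, drop = FALSE]
      p8 <- img[ri, ci - 1L, drop = FALSE]; p9 <- img[ri - 1L, ci - 1L, drop = FALSE]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) + (p4 == 0L & p5 == 1L) +
           (p5 == 0L & p6 == 1L) + (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      del <- if (step == 1L) {
        p == 1L & b >= 2L & b <= 6L & a == 1L & p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        p == 1L & b >= 2L & b <= 6L & a == 1L & p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      if (any(del)) {
        changed <- TRUE
        p[del] <- 0L
        img[ri, ci] <- p
      }
    }
    if (!changed) break
  }
  img[ri, ci, drop = FALSE] > 0L
}

# Euclidean distance transform of the foreground, with the image border
# treated as background (EBImage::distmap alone treats it as foreground,
# which would give infinite distances on all-foreground planes).
distance_transform <- function(m) {
  m <- as_mask_matrix(m)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- as.numeric(m)
  d <- EBImage::distmap(pad, metric = "euclidean")
  matrix(as.numeric(d), nr + 2L, nc + 2L)[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}
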