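# Conversion of binary masks to centerline polylines. The decomposition:
#   1. Zhang-Suen thinning to a 1-px skeleton.
#   2. Skeleton split into maximal branch-free paths at junction pixels
#      (>= 3 skeleton neighbours, 8-connectivity). A junction pixel is
#      included as the terminal point of every incident path, so the union
#      of the paths covers the whole skeleton. Pure cycles are cut at their
#      lexicographically smallest pixel (x, then y).
#   3. Each path simplified: at tolerance 0, only interior points of
#      constant-direction runs are dropped (provably lossless: Bresenham
#      redraws exactly the dropped pixels); at tolerance > 0, classical
#      Douglas-Peucker (opt-in, lossy). Plain Douglas-Peucker at tol 0 is
#      NOT lossless: a point can sit exactly on its ancestor chord yet off
#      the segment joining the finally kept neighbours, so Bresenham would
#      redraw a different chain.
#   4. Per-path thickness = the odd integer nearest to the mean of the
#      per-pixel width estimate (2 * dt - 1) along the path, dt being the
#      Euclidean distance transform of the *input mask*; ties go to the
#      lower odd value. The centerline of an ideal band of width 2k+1 sits
#      at dt = k+1, so 2*dt - 1 recovers the width exactly; near skeleton
#      junctions dt reaches sqrt(2)..2 even on 1-px structures, and this
#      estimator (decision boundaries at half-integer mean dt) still maps
#      such paths to thickness 1, which "2 * mean(dt)" would not.

#' Douglas-Peucker polyline simplification
#'
#' Recursively keeps the point of maximal perpendicular distance from the
#' chord while that distance exceeds `tol`; endpoints are always kept.
#' With `tol = 0` only points lying exactly on the chord are removed.
#'
#' @param points an n x 2 numeric matrix of polyline vertices.
#' @param tol tolerance in pixels (>= 0).
#' @return the simplified subset of `points`, order preserved.
#' @export
douglas_peucker <- function(points, tol = 0) {
  n <- nrow(points)
  if (n <= 2L) return(points)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1L]; j <- rng[2L]
    if (j - i < 2L) next
    p0 <- points[i, ]; p1 <- points[j, ]
    mid <- (i + 1L):(j - 1L)
    dx <- p1[1L] - p0[1L]; dy <- p1[2L] - p0[2L]
    len <- sqrt(dx^2 + dy^2)
    if (len == 0) {
      d <- sqrt((points[mid, 1L] - p0[1L])^2 + (points[mid, 2L] - p0[2L])^2)
    } else {
      d <- abs(dx * (p0[2L] - points[mid, 2L]) - (p0[1L] - points[mid, 1L]) * dy) / len
    }
    k <- which.max(d)
    if (d[k] > tol) {
      idx <- mid[k]
      keep[idx] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, idx)
      stack[[length(stack) + 1L]] <- c(idx, j)
    }
  }
  points[keep, , drop = FALSE]
}

# drop interior points of maximal constant-step runs; for an 8-connected
# pixel chain this is exactly the set of removals that Bresenham re-draws
# losslessly
collapse_straight_runs <- function(points) {
  n <- nrow(points)
  if (n <= 2L) return(points)
  steps <- points[-1L, , drop = FALSE] - points[-n, , drop = FALSE]
  turn <- rowSums(steps[-1L, , drop = FALSE] != steps[-(n - 1L), , drop = FALSE]) > 0L
  points[c(TRUE, turn, TRUE), , drop = FALSE]
}

# 8-neighbour offsets (dx, dy)
neighbour_offsets <- cbind(dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
                           dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))

# order pixels lexicographically by (x, y)
lex_order <- function(px) order(px[, 1L], px[, 2L])

# Decompose a 1-px skeleton matrix into branch-free pixel paths.
# Returns a list of n x 2 integer matrices of 0-based (x, y) coordinates.
skeleton_paths <- function(skel) {
  skel <- as_mask_matrix(skel)
  h <- nrow(skel); w <- ncol(skel)
  coords <- mask_coords(binary_mask(skel))
  if (!nrow(coords)) return(list())
  px <- as.matrix(coords)                      # (x, y), 0-based
  id_of <- matrix(0L, h, w)
  id_of[cbind(px[, 2L] + 1L, px[, 1L] + 1L)] <- seq_len(nrow(px))
  neighbours <- function(i) {
    x <- px[i, 1L] + neighbour_offsets[, "dx"]
    y <- px[i, 2L] + neighbour_offsets[, "dy"]
    ok <- x >= 0L & x < w & y >= 0L & y < h
    ids <- id_of[cbind(y[ok] + 1L, x[ok] + 1L)]
    ids[ids > 0L]
  }
  nbr <- lapply(seq_len(nrow(px)), neighbours)
  deg <- lengths(nbr)
  is_junction <- deg >= 3L

  paths <- list()
  add_path <- function(ids) paths[[length(paths) + 1L]] <<- px[ids, , drop = FALSE]

  # chains and cycles among non-junction pixels
  visited <- is_junction                        # junctions handled separately
  walk_chain <- function(start, prev = 0L) {
    chain <- start
    visited[start] <<- TRUE
    cur <- start
    repeat {
      nxt <- setdiff(nbr[[cur]][!is_junction[nbr[[cur]]]], chain)
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      cur <- nxt[lex_order(px[nxt, , drop = FALSE])[1L]]
      visited[cur] <<- TRUE
      chain <- c(chain, cur)
    }
    chain
  }
  non_j <- which(!is_junction)
  # start chains at pixels with <= 1 non-junction neighbour (chain ends)
  nj_deg <- vapply(seq_along(nbr), function(i) sum(!is_junction[nbr[[i]]]), integer(1))
  ends <- non_j[nj_deg[non_j] <= 1L]
  for (e in ends[lex_order(px[ends, , drop = FALSE])]) {
    if (visited[e]) next
    chain <- walk_chain(e)
    # attach an adjacent junction (lexicographically smallest) at each end
    head_j <- nbr[[chain[1L]]][is_junction[nbr[[chain[1L]]]]]
    tail_j <- nbr[[chain[length(chain)]]][is_junction[nbr[[chain[length(chain)]]]]]
    if (length(head_j)) {
      head_j <- head_j[lex_order(px[head_j, , drop = FALSE])[1L]]
      chain <- c(head_j, chain)
    }
    if (length(tail_j)) {
      tail_j <- setdiff(tail_j, chain[1L])
      if (length(tail_j)) {
        tail_j <- tail_j[lex_order(px[tail_j, , drop = FALSE])[1L]]
        chain <- c(chain, tail_j)
      }
    }
    add_path(chain)
  }
  # remaining non-junction pixels belong to pure cycles: cut at the
  # lexicographically smallest pixel and close the loop
  for (s in non_j[lex_order(px[non_j, , drop = FALSE])]) {
    if (visited[s]) next
    chain <- walk_chain(s)
    if (length(chain) > 2L) chain <- c(chain, chain[1L])
    add_path(chain)
  }
  # junction pixels not yet covered by any path (junction clusters):
  # trace them greedily so every skeleton pixel is covered
  covered <- logical(nrow(px))
  for (p in paths) covered[id_of[cbind(p[, 2L] + 1L, p[, 1L] + 1L)]] <- TRUE
  left <- which(!covered)
  while (length(left)) {
    s <- left[lex_order(px[left, , drop = FALSE])[1L]]
    chain <- s
    covered[s] <- TRUE
    cur <- s
    repeat {
      nxt <- nbr[[cur]][!covered[nbr[[cur]]]]
      if (!length(nxt)) break
      cur <- nxt[lex_order(px[nxt, , drop = FALSE])[1L]]
      covered[cur] <- TRUE
      chain <- c(chain, cur)
    }
    add_path(chain)
    left <- which(!covered)
  }
  paths
}

#' Convert a binary mask to centerline vectors
#'
#' The mask is thinned to a 1-px skeleton, the skeleton is decomposed into
#' maximal branch-free paths split at junction pixels (>= 3 skeleton
#' neighbours, 8-connectivity), each path is simplified at `simplify_tol`
#' (0: lossless collapse of straight runs; > 0: Douglas-Peucker, which may
#' move the redrawn chain), and each path's thickness is estimated from
#' the Euclidean distance transform of the input mask: the odd integer
#' nearest to the path mean of `2 * dt - 1` (exact on ideal
#' constant-width bands). Ids are sequential and the source label is
#' `"converted"`.
#'
#' @param mask a [binary_mask()] (an empty mask yields an empty set).
#' @param simplify_tol simplification tolerance in pixels; the default 0
#'   is lossless for rasterization.
#' @param image_ref optional image reference recorded on the set.
#' @param depth depth recorded on the returned set; defaults to `z + 1`
#'   of the mask.
#' @return an [annotation_set()] with source `"converted"`.
#' @export
vectorize_mask <- function(mask, simplify_tol = 0, image_ref = "", depth = NULL) {
  z <- mask_z(mask)
  m <- as_mask_matrix(mask)
  if (is.null(depth)) depth <- z + 1L
  out <- annotation_set(image_ref = image_ref, width = ncol(m), height = nrow(m),
                        depth = depth, source = "converted")
  if (!any(m)) return(out)
  skel <- thin_mask(m)
  dt <- distance_transform(m)
  paths <- skeleton_paths(skel)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    thick <- nearest_odd(mean(2 * dt[cbind(p[, 2L] + 1L, p[, 1L] + 1L)] - 1))
    pts <- if (simplify_tol > 0) douglas_peucker(p, simplify_tol)
           else collapse_straight_runs(p)
    out <- append_vector(out, myelin_vector(id = sprintf("c%04d_z%d", i, z), z = z,
                                            points = pts, thickness = thick,
                                            source = "converted"))
  }
  out
}

# odd integer nearest to v, ties toward the lower odd value, minimum 1
# (the 1e-9 guards exact ties against floating-point drift in the mean)
nearest_odd <- function(v) {
  k <- ceiling((v - 1) / 2 - 0.5 - 1e-9)
  max(2L * as.integer(k) + 1L, 1L)
}

#' Replace a set's vectors with the conversion of a mask stack
#'
#' Conversion *overwrites*: the returned set contains only the converted
#' vectors, regardless of what the input set held, keeping the input
#' set's image metadata. This mirrors loading an externally produced
#' candidate mask over an annotation project.
#'
#' @param set an [annotation_set()] providing image dimensions/metadata.
#' @param masks a [binary_mask()] or list of them (one per z).
#' @param simplify_tol Douglas-Peucker tolerance in pixels.
#' @return a new [annotation_set()] with source `"converted"`.
#' @export
replace_with_converted <- function(set, masks, simplify_tol = 0) {
  if (inherits(masks, "binary_mask") || is.matrix(masks)) masks <- list(masks)
  for (m in masks) {
    if (!identical(dim(m), c(set$height, set$width)))
      stop("mask dimensions do not match the annotation set")
    if (mask_z(m) >= set$depth) stop("mask z exceeds the annotation set depth")
  }
  out <- annotation_set(image_ref = set$image_ref, width = set$width,
                        height = set$height, depth = set$depth,
                        source = "converted")
  k <- 0L
  for (m in masks) {
    conv <- vectorize_mask(m, simplify_tol, image_ref = set$image_ref,
                           depth = set$depth)
    for (v in conv$vectors) {
      k <- k + 1L
      out <- append_vector(out, myelin_vector(sprintf("c%04d", k), v$z, v$points,
                                              v$thickness, "converted"))
    }
  }
  out
}
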