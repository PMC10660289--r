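#' A single myelin stroke: polyline, thickness, z-section, provenance
#'
#' Strokes are recorded as ordered 0-based integer pixel coordinates.
#' Thickness is an odd positive integer so that the rendered stroke is a
#' centred disk sweep; even values are rejected, not rounded.
#'
#' @param id unique (within a set) string identifier.
#' @param z 0-based z-section index.
#' @param points an n x 2 matrix (or list of `[x, y]` pairs) of 0-based
#'   integer coordinates, n >= 1; consecutive points must be distinct.
#' @param thickness odd positive integer stroke width in pixels.
#' @param source annotator / source label.
#' @return an object of class `myelin_vector`.
#' @export
myelin_vector <- function(id, z, points, thickness = 1L, source = "manual") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  z <- as.integer(z)
  if (is.na(z) || z < 0L) stop("'z' must be a non-negative integer")
  if (is.list(points)) points <- do.call(rbind, lapply(points, as.numeric))
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 1L)
    stop("'points' must be an n x 2 matrix with n >= 1")
  if (any(is.na(points)) || any(points != round(points)))
    stop("points must be integer pixel coordinates")
  storage.mode(points) <- "integer"
  dimnames(points) <- NULL
  if (nrow(points) > 1L) {
    same <- rowSums(points[-1L, , drop = FALSE] ==
                    points[-nrow(points), , drop = FALSE]) == 2L
    if (any(same)) stop("consecutive points must be distinct")
  }
  thickness <- as.integer(thickness)
  if (is.na(thickness) || thickness < 1L || thickness %% 2L == 0L)
    stop("'thickness' must be an odd positive integer")
  structure(list(id = id, z = z, points = points, thickness = thickness,
                 source = as.character(source)),
            class = "myelin_vector")
}

#' An ordered collection of myelin vectors from one source
#'
#' @param image_ref free-text reference to the annotated image.
#' @param width,height,depth dimensions of that image (pixels, sections).
#' @param source default annotator / source label for the set.
#' @param vectors list of [myelin_vector()]s. Ids must be unique, every
#'   `z` must be `< depth`, and every point must lie in
#'   `[0, width) x [0, height)`.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(image_ref = "", width, height, depth = 1L,
                           source = "manual", vectors = list()) {
  width <- as.integer(width); height <- as.integer(height); depth <- as.integer(depth)
  if (any(is.na(c(width, height, depth))) || width < 1L || height < 1L || depth < 1L)
    stop("'width', 'height' and 'depth' must be positive integers")
  if (!is.list(vectors)) stop("'vectors' must be a list")
  set <- structure(list(image_ref = as.character(image_ref), width = width,
                        height = height, depth = depth,
                        source = as.character(source), vectors = list()),
                   class = "annotation_set")
  for (v in vectors) set <- append_vector(set, v)
  set
}

append_vector <- function(set, v) {
  if (!inherits(v, "myelin_vector")) stop("vectors must be myelin_vector objects")
  if (v$id %in% vector_ids(set)) stop(sprintf("duplicate vector id '%s'", v$id))
  if (v$z >= set$depth)
    stop(sprintf("vector '%s' has z=%d but the set has depth %d", v$id, v$z, set$depth))
  if (any(v$points[, 1L] < 0L) || any(v$points[, 1L] >= set$width) ||
      any(v$points[, 2L] < 0L) || any(v$points[, 2L] >= set$height))
    stop(sprintf("vector '%s' has out-of-bounds points (bounds are half-open: [0,%d) x [0,%d))",
                 v$id, set$width, set$height))
  set$vectors[[length(set$vectors) + 1L]] <- v
  set
}

#' Ids of the vectors in a set, in order
#' @param set an [annotation_set()].
#' @return character vector.
#' @export
vector_ids <- function(set) vapply(set$vectors, `[[`, character(1), "id")

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> source '%s', %d vector(s), canvas %d x %d x %d\n",
              x$source, length(x$vectors), x$width, x$height, x$depth))
  invisible(x)
}

#' @export
print.myelin_vector <- function(x, ...) {
  cat(sprintf("<myelin_vector> '%s' z=%d, %d point(s), thickness %d, source '%s'\n",
              x$id, x$z, nrow(x$points), x$thickness, x$source))
  invisible(x)
}

annotation_format_version <- 1L

#' Write an annotation set to its UTF-8 JSON file
#'
#' The on-disk document has the schema
#' `{format_version, image_ref, width, height, depth, source,
#' vectors: [{id, z, thickness, source, points: [[x, y], ...]}]}`
#' and is inverted exactly by [read_annotations()]. The conventional file
#' extension is `.iev.json`.
#'
#' @param set an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path) {
  if (!inherits(set, "annotation_set")) stop("'set' must be an annotation_set")
  if (anyDuplicated(vector_ids(set))) stop("duplicate vector id")  # defensive
  doc <- list(
    format_version = jsonlite::unbox(annotation_format_version),
    image_ref = jsonlite::unbox(set$image_ref),
    width = jsonlite::unbox(set$width),
    height = jsonlite::unbox(set$height),
    depth = jsonlite::unbox(set$depth),
    source = jsonlite::unbox(set$source),
    vectors = lapply(set$vectors, function(v) list(
      id = jsonlite::unbox(v$id),
      z = jsonlite::unbox(v$z),
      thickness = jsonlite::unbox(v$thickness),
      source = jsonlite::unbox(v$source),
      points = v$points
    ))
  )
  tryCatch(jsonlite::write_json(doc, path, digits = NA, pretty = FALSE),
           error = function(e) stop(sprintf("cannot write '%s': %s",
                                            path, conditionMessage(e))))
  invisible(path)
}

#' Read and validate an annotation set from JSON
#'
#' All invariants are re-checked on read: unique ids, odd thickness,
#' in-bounds points (half-open bounds), `z < depth`.
#'
#' @param path path to a file written by [write_annotations()].
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop(sprintf("cannot read '%s': %s",
                                                   path, conditionMessage(e))))
  need <- c("format_version", "image_ref", "width", "height", "depth",
            "source", "vectors")
  if (!all(need %in% names(doc)))
    stop(sprintf("'%s': missing field(s): %s", path,
                 paste(setdiff(need, names(doc)), collapse = ", ")))
  if (!identical(as.integer(doc$format_version), annotation_format_version))
    stop(sprintf("'%s': unsupported format_version %s", path, doc$format_version))
  vectors <- lapply(doc$vectors, function(v) {
    vneed <- c("id", "z", "thickness", "points")
    if (!all(vneed %in% names(v)))
      stop(sprintf("'%s': vector missing field(s): %s", path,
                   paste(setdiff(vneed, names(v)), collapse = ", ")))
    pts <- do.call(rbind, lapply(v$points, function(p) as.numeric(unlist(p))))
    myelin_vector(id = v$id, z = v$z, points = pts, thickness = v$thickness,
                  source = if (is.null(v$source)) doc$source else v$source)
  })
  annotation_set(image_ref = doc$image_ref, width = doc$width,
                 height = doc$height, depth = doc$depth,
                 source = doc$source, vectors = vectors)
}

# integer Bresenham line, endpoints inclusive; returns an n x 2 matrix
bresenham_segment <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); sx <- if (x0 < x1) 1L else -1L
  dy <- -abs(y1 - y0); sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  n <- max(abs(x1 - x0), abs(y1 - y0)) + 1L
  out <- matrix(0L, n, 2L)
  x <- x0; y <- y0
  for (k in seq_len(n)) {
    out[k, ] <- c(x, y)
    if (x == x1 && y == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x <- x + sx }
    if (e2 <= dx) { err <- err + dx; y <- y + sy }
  }
  out
}

# pixel chain of a whole polyline (duplicate junction pixels removed)
polyline_pixels <- function(points) {
  if (nrow(points) == 1L) return(points)
  segs <- lapply(seq_len(nrow(points) - 1L), function(i) {
    s <- bresenham_segment(points[i, 1L], points[i, 2L],
                           points[i + 1L, 1L], points[i + 1L, 2L])
    if (i > 1L) s <- s[-1L, , drop = FALSE]
    s
  })
  do.call(rbind, segs)
}

#' Rasterize one myelin vector onto a canvas
#'
#' The polyline is drawn segment by segment with Bresenham's line
#' algorithm; the resulting 1-px path is then dilated by a Euclidean disk
#' of radius `(thickness - 1) / 2`. A single-point vector stamps one disk.
#' Disk pixels falling outside the canvas are clipped.
#'
#' @param v a [myelin_vector()].
#' @param width,height canvas size in pixels.
#' @return a [binary_mask()] at the vector's z.
#' @export
rasterize_vector <- function(v, width, height) {
  if (!inherits(v, "myelin_vector")) stop("'v' must be a myelin_vector")
  path <- polyline_pixels(v$points)
  r <- (v$thickness - 1L) %/% 2L
  if (r > 0L) {
    off <- disk_offsets(r)
    path <- cbind(rep(path[, 1L], each = nrow(off)) + off[, "dx"],
                  rep(path[, 2L], each = nrow(off)) + off[, "dy"])
  }
  keep <- path[, 1L] >= 0L & path[, 1L] < width &
          path[, 2L] >= 0L & path[, 2L] < height
  path <- path[keep, , drop = FALSE]
  m <- matrix(FALSE, height, width)
  if (nrow(path)) m[cbind(path[, 2L] + 1L, path[, 1L] + 1L)] <- TRUE
  binary_mask(m, v$z)
}

#' Rasterize all vectors of a set at one z-section
#'
#' Union of [rasterize_vector()] over every vector with matching `z`.
#'
#' @param set an [annotation_set()].
#' @param z 0-based z-index.
#' @return a [binary_mask()].
#' @export
rasterize_set <- function(set, z) {
  m <- matrix(FALSE, set$height, set$width)
  for (v in set$vectors) {
    if (v$z == z) m <- m | as_mask_matrix(rasterize_vector(v, set$width, set$height))
  }
  binary_mask(m, z)
}

#' Rasterize a set at every z-section
#'
#' @param set an [annotation_set()].
#' @return list of [binary_mask()], z = 0 .. depth-1.
#' @export
rasterize_all <- function(set) {
  lapply(seq_len(set$depth) - 1L, function(z) rasterize_set(set, z))
}

#' Merge two annotation sets for side-by-side review
#'
#' The merged object preserves both sets verbatim (each vector keeps its
#' source); the inputs are never mutated, and [extract_source()] returns
#' the original set unchanged. Cross-source vector fusion is deliberately
#' not performed: editing operates on each source's set independently.
#'
#' @param a,b [annotation_set()]s with distinct `source` labels and equal
#'   image dimensions.
#' @return an object of class `merged_annotation`.
#' @export
merge_sets <- function(a, b) {
  if (!inherits(a, "annotation_set") || !inherits(b, "annotation_set"))
    stop("'a' and 'b' must be annotation_sets")
  if (identical(a$source, b$source))
    stop(sprintf("source labels must be distinct (both are '%s')", a$source))
  if (!identical(c(a$width, a$height, a$depth), c(b$width, b$height, b$depth)))
    stop("image dimension mismatch between sets")
  structure(list(sets = stats::setNames(list(a, b), c(a$source, b$source))),
            class = "merged_annotation")
}

#' Extract one source's set from a merged annotation
#'
#' @param merged a [merge_sets()] result.
#' @param source the source label to extract.
#' @return the original [annotation_set()].
#' @export
extract_source <- function(merged, source) {
  if (!inherits(merged, "merged_annotation")) stop("'merged' must be a merged_annotation")
  if (!source %in% names(merged$sets))
    stop(sprintf("unknown source '%s' (have: %s)", source,
                 paste(names(merged$sets), collapse = ", ")))
  merged$sets[[source]]
}

#' @export
print.merged_annotation <- function(x, ...) {
  cat(sprintf("<merged_annotation> sources: %s (%s vectors)\n",
              paste(names(x$sets), collapse = " + "),
              paste(vapply(x$sets, function(s) length(s$vectors), integer(1)),
                    collapse = " + ")))
  invisible(x)
}

#' Editing operations on annotation sets
#'
#' `edit_delete(id)` removes a vector, `edit_trim(id, keep)` truncates a
#' vector to its first `keep` points (at least 1), and `edit_draw(vector)`
#' appends a new vector. [apply_edit()] applies one edit and returns a new
#' set; all other vectors are untouched.
#'
#' @param id id of an existing vector.
#' @param keep number of leading points to keep (>= 1).
#' @param vector a [myelin_vector()] to append.
#' @return an edit object for [apply_edit()].
#' @export
edit_delete <- function(id) structure(list(type = "delete", id = id), class = "myelin_edit")

#' @rdname edit_delete
#' @export
edit_trim <- function(id, keep) structure(list(type = "trim", id = id,
                                               keep = as.integer(keep)),
                                          class = "myelin_edit")

#' @rdname edit_delete
#' @export
edit_draw <- function(vector) structure(list(type = "draw", vector = vector),
                                        class = "myelin_edit")

#' Apply a single edit to an annotation set
#'
#' @param set an [annotation_set()].
#' @param edit an [edit_delete()], [edit_trim()] or [edit_draw()] object.
#' @return the edited [annotation_set()] (the input is not mutated).
#' @export
apply_edit <- function(set, edit) {
  if (!inherits(edit, "myelin_edit")) stop("'edit' must be a myelin_edit")
  ids <- vector_ids(set)
  switch(edit$type,
    delete = {
      i <- match(edit$id, ids)
      if (is.na(i)) stop(sprintf("unknown vector id '%s'", edit$id))
      set$vectors[[i]] <- NULL
      set
    },
    trim = {
      i <- match(edit$id, ids)
      if (is.na(i)) stop(sprintf("unknown vector id '%s'", edit$id))
      if (edit$keep < 1L) stop("cannot trim a vector to 0 points")
      v <- set$vectors[[i]]
      k <- min(edit$keep, nrow(v$points))
      set$vectors[[i]] <- myelin_vector(v$id, v$z, v$points[seq_len(k), , drop = FALSE],
                                        v$thickness, v$source)
      set
    },
    draw = append_vector(set, edit$vector),
    stop("unknown edit type"))
}

#' Vectors at a z-section together with its two neighbours
#'
#' Returns the vectors at `z - 1`, `z` and `z + 1` as three read-only
#' lists; missing neighbours at the ends of the stack are empty lists.
#' This mirrors reviewing a section with its adjacent optical sections
#' visible (myelin wriggles across z, so context from the neighbouring
#' sections guides the annotator) without ever merging sections.
#'
#' @param set an [annotation_set()].
#' @param z 0-based z-index, `0 <= z < depth`.
#' @return a list with elements `below` (z-1), `at` (z), `above` (z+1).
#' @export
z_context <- function(set, z) {
  z <- as.integer(z)
  if (is.na(z) || z < 0L || z >= set$depth)
    stop(sprintf("z=%d out of range [0, %d)", z, set$depth))
  at_z <- function(zz) {
    if (zz < 0L || zz >= set$depth) return(list())
    Filter(function(v) v$z == zz, set$vectors)
  }
  list(below = at_z(z - 1L), at = at_z(z), above = at_z(z + 1L))
}
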