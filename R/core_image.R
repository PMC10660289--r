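#' Construct a binary mask for one z-section
#'
#' A `binary_mask` is a logical matrix (`height` rows, `width` columns)
#' tagged with the 0-based z-index of the optical section it belongs to.
#' Pixel `(x, y)` (0-based, x = column, y = row) is element
#' `[y + 1, x + 1]`.
#'
#' @param data a logical or numeric matrix; non-zero entries are foreground.
#' @param z 0-based z-section index.
#' @return an object of class `binary_mask`.
#' @seealso [mask_from_coords()], [mask_coords()], [positive_count()]
#' @export
binary_mask <- function(data, z = 0L) {
  if (!is.matrix(data)) stop("'data' must be a matrix")
  z <- as.integer(z)
  if (length(z) != 1L || is.na(z) || z < 0L) stop("'z' must be a single non-negative integer")
  m <- matrix(as.logical(data) & !is.na(data), nrow(data), ncol(data))
  structure(m, z = z, class = "binary_mask")
}

#' Build a binary mask from 0-based pixel coordinates
#'
#' @param x,y integer vectors of equal length, 0-based column/row positions.
#' @param width,height canvas size in pixels.
#' @param z 0-based z-index.
#' @return a [binary_mask()].
#' @export
mask_from_coords <- function(x, y, width, height, z = 0L) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) && (any(x < 0 | x >= width) || any(y < 0 | y >= height)))
    stop("pixel coordinates out of bounds")
  m <- matrix(FALSE, height, width)
  if (length(x)) m[cbind(y + 1L, x + 1L)] <- TRUE
  binary_mask(m, z)
}

#' Extract 0-based coordinates of the foreground pixels of a mask
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @return a data frame with integer columns `x` and `y`, ordered by
#'   column-major scan of the underlying matrix.
#' @export
mask_coords <- function(mask) {
  idx <- which(as_mask_matrix(mask), arr.ind = TRUE)
  data.frame(x = as.integer(idx[, 2L] - 1L), y = as.integer(idx[, 1L] - 1L))
}

#' Count foreground pixels
#'
#' Sums the number of `TRUE` pixels over a single mask or a (possibly
#' nested) list of masks, e.g. one list per z-section or one list of
#' per-image lists.
#'
#' @param masks a [binary_mask()], logical matrix, or list thereof.
#' @return integer pixel count.
#' @export
positive_count <- function(masks) {
  if (is.list(masks)) return(as.integer(sum(vapply(masks, positive_count, numeric(1)))))
  sum(as_mask_matrix(masks))
}

mask_z <- function(mask) {
  z <- attr(mask, "z")
  if (is.null(z)) 0L else as.integer(z)
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "binary_mask")) {
    attributes(mask) <- list(dim = dim(mask))
  } else if (!is.matrix(mask)) stop("expected a binary_mask or matrix")
  mask & !is.na(mask)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, z = %d, %d foreground pixel(s)\n",
              ncol(x), nrow(x), mask_z(x), positive_count(x)))
  invisible(x)
}

stack_roles <- c("oligodendrocyte", "axon", "nucleus")

#' Construct an aligned three-channel z-stack
#'
#' @param oligodendrocyte,axon,nucleus each a list of integer intensity
#'   matrices (one per z-section), or a single matrix for a one-section
#'   stack. All planes of all channels must share dimensions, and the
#'   three channels must have equal depth.
#' @param z_step_um optional physical z spacing in micrometres (e.g. 1 for
#'   1-um-thick optical sections).
#' @param bit_depth 8 or 16; inferred from the data range when `NULL`.
#' @return an object of class `channel_stack` with fields `width`,
#'   `height`, `depth`, `channels` (named list of plane lists),
#'   `bit_depth` and `z_step_um`.
#' @export
channel_stack <- function(oligodendrocyte, axon, nucleus, z_step_um = NULL,
                          bit_depth = NULL) {
  chans <- list(oligodendrocyte = oligodendrocyte, axon = axon, nucleus = nucleus)
  chans <- lapply(chans, function(ch) {
    if (is.matrix(ch)) ch <- list(ch)
    if (!is.list(ch) || !length(ch) || !all(vapply(ch, is.matrix, logical(1))))
      stop("each channel must be a matrix or non-empty list of matrices")
    lapply(ch, function(p) {
      storage.mode(p) <- "integer"
      p
    })
  })
  depths <- vapply(chans, length, integer(1))
  if (length(unique(depths)) != 1L)
    stop(sprintf("channel depth mismatch: oligodendrocyte=%d, axon=%d, nucleus=%d",
                 depths[1L], depths[2L], depths[3L]))
  dims <- unique(do.call(rbind, lapply(chans, function(ch)
    do.call(rbind, lapply(ch, dim)))))
  if (nrow(dims) != 1L) stop("channel plane dimension mismatch")
  vals <- unlist(chans, use.names = FALSE)
  if (any(is.na(vals)) || any(vals < 0L)) stop("intensities must be non-negative")
  if (is.null(bit_depth)) bit_depth <- if (max(vals, 0L) > 255L) 16L else 8L
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  structure(list(width = dims[1L, 2L], height = dims[1L, 1L],
                 depth = unname(depths[1L]), channels = chans,
                 bit_depth = as.integer(bit_depth), z_step_um = z_step_um),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %d x %d px, %d z-section(s), %d-bit\n",
              x$width, x$height, x$depth, x$bit_depth))
  if (!is.null(x$z_step_um)) cat(sprintf("  z step: %g um\n", x$z_step_um))
  for (role in stack_roles) {
    rng <- range(unlist(x$channels[[role]]))
    cat(sprintf("  %-16s intensity range [%d, %d]\n", role, rng[1L], rng[2L]))
  }
  invisible(x)
}

read_gray_pages <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read TIFF '%s': no such file", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop(sprintf("cannot read TIFF '%s': %s",
                                                     path, conditionMessage(e))))
  if (is.matrix(pages) || is.array(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(k) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L && dim(p)[3L] == 1L) p <- p[, , 1L]
    if (length(dim(p)) != 2L)
      stop(sprintf("page %d of '%s' is not grayscale (found %d sample(s) per pixel); channel identity is semantic, refusing to pick one",
                   k, path, if (length(dim(p)) == 3L) dim(p)[3L] else NA_integer_))
    storage.mode(p) <- "integer"
    p
  })
}

#' Load an aligned three-channel z-stack from per-channel TIFF files
#'
#' Page `k` of each file becomes z-section `k` (never reordered). The three
#' files must be single- or multi-page *grayscale* TIFFs with identical
#' page counts and dimensions; RGB pages are rejected rather than silently
#' reduced to one channel.
#'
#' @param oligo_path,axon_path,nucleus_path TIFF file paths; channel roles
#'   are assigned from argument position.
#' @param z_step_um optional z spacing in micrometres.
#' @return a [channel_stack()].
#' @export
load_stack <- function(oligo_path, axon_path, nucleus_path, z_step_um = NULL) {
  channel_stack(read_gray_pages(oligo_path),
                read_gray_pages(axon_path),
                read_gray_pages(nucleus_path),
                z_step_um = z_step_um)
}

#' Write per-z binary masks to an 8-bit TIFF
#'
#' One grayscale page per z-section, background 0 and foreground 255, so
#' [load_mask_tiff()] reproduces the masks exactly. Masks must share
#' dimensions and carry contiguous z-indices starting at 0; they are
#' written in z order.
#'
#' @param masks a [binary_mask()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_mask_tiff <- function(masks, path) {
  if (inherits(masks, "binary_mask") || is.matrix(masks)) masks <- list(masks)
  if (!length(masks)) stop("empty mask list")
  zs <- vapply(masks, mask_z, integer(1))
  if (anyDuplicated(zs) || !setequal(zs, seq_along(masks) - 1L))
    stop("mask z-indices must be contiguous from 0")
  masks <- masks[order(zs)]
  dims <- unique(do.call(rbind, lapply(masks, dim)))
  if (nrow(dims) != 1L) stop("masks must share width and height")
  pages <- lapply(masks, function(m) matrix(as.numeric(as_mask_matrix(m)), nrow(m)))
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 8L),
                 error = function(e) stop(sprintf("cannot write '%s': %s",
                                                  path, conditionMessage(e))))
  invisible(path)
}

#' Load per-z binary masks from a grayscale TIFF
#'
#' Any pixel value greater than zero is foreground; pages are returned in
#' file order as z-sections 0, 1, ...
#'
#' @param path TIFF file path.
#' @return a list of [binary_mask()], one per page.
#' @export
load_mask_tiff <- function(path) {
  pages <- read_gray_pages(path)
  lapply(seq_along(pages), function(k) binary_mask(pages[[k]] > 0L, z = k - 1L))
}

#' One-line summary of stack files (CLI `info` helper)
#'
#' @param oligo_path,axon_path,nucleus_path TIFF paths as for [load_stack()].
#' @return the loaded [channel_stack()], invisibly; prints its summary.
#' @export
stack_info <- function(oligo_path, axon_path, nucleus_path) {
  s <- load_stack(oligo_path, axon_path, nucleus_path)
  print(s)
  invisible(s)
}
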