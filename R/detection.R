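#' Configuration for candidate-myelin detection
#'
#' Holds the free parameters of the co-localization detector: how each
#' channel is binarized, how far detected cell bodies are dilated before
#' subtraction, and the minimum connected-component area kept. None of
#' these values is prescribed by the underlying study; they are explicit
#' user-set parameters.
#'
#' @param binarize_method `"otsu"` (default; per-section threshold
#'   maximizing between-class variance) or `"fixed"`.
#' @param fixed_threshold intensity threshold(s) used when
#'   `binarize_method = "fixed"`: a single value applied to every channel,
#'   or a named vector/list with entries `oligodendrocyte`, `axon`,
#'   `nucleus`. A pixel is foreground iff intensity >= threshold.
#' @param cell_body_dilation_px non-negative disk radius by which the
#'   nucleus-marker overlap is dilated before removal.
#' @param min_component_area_px 8-connected components of the candidate
#'   mask with area strictly below this are discarded.
#' @param cell_body_marker which membrane channel acts as the cellular
#'   marker whose overlap with nuclei defines cell bodies; defaults to
#'   the oligodendrocyte channel.
#' @return an object of class `detection_config`.
#' @export
detection_config <- function(binarize_method = c("otsu", "fixed"),
                             fixed_threshold = 128L,
                             cell_body_dilation_px = 0L,
                             min_component_area_px = 0L,
                             cell_body_marker = c("oligodendrocyte", "axon")) {
  binarize_method <- match.arg(binarize_method)
  cell_body_marker <- match.arg(cell_body_marker)
  thr <- unlist(fixed_threshold)
  if (is.null(names(thr))) {
    if (length(thr) != 1L) stop("unnamed 'fixed_threshold' must be a single value")
    thr <- c(oligodendrocyte = thr, axon = thr, nucleus = thr)
  }
  if (!all(stack_roles %in% names(thr)))
    stop("'fixed_threshold' must name all of: ", paste(stack_roles, collapse = ", "))
  thr <- thr[stack_roles]
  if (any(thr < 0)) stop("'fixed_threshold' must be >= 0")
  if (cell_body_dilation_px < 0L) stop("'cell_body_dilation_px' must be >= 0")
  if (min_component_area_px < 0L) stop("'min_component_area_px' must be >= 0")
  structure(list(binarize_method = binarize_method,
                 fixed_threshold = thr,
                 cell_body_dilation_px = as.integer(cell_body_dilation_px),
                 min_component_area_px = as.integer(min_component_area_px),
                 cell_body_marker = cell_body_marker),
            class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat("<detection_config>\n")
  cat("  binarize_method:      ", x$binarize_method, "\n")
  if (x$binarize_method == "fixed")
    cat("  fixed_threshold:      ",
        paste(sprintf("%s=%g", names(x$fixed_threshold), x$fixed_threshold),
              collapse = ", "), "\n")
  cat("  cell_body_dilation_px:", x$cell_body_dilation_px, "\n")
  cat("  min_component_area_px:", x$min_component_area_px, "\n")
  cat("  cell_body_marker:     ", x$cell_body_marker, "\n")
  invisible(x)
}

#' Otsu threshold of an integer intensity plane
#'
#' Chooses the threshold `t` maximizing the between-class variance of the
#' two classes `{intensity < t}` and `{intensity >= t}`, over all candidate
#' levels of the plane's dynamic range (256 levels for 8-bit data). Ties
#' are broken toward the lower threshold. Returns `NA` for an all-constant
#' plane, where no threshold separates two classes.
#'
#' @param plane integer matrix of non-negative intensities.
#' @param n_levels number of gray levels (256 or 65536); inferred from the
#'   data range when `NULL`.
#' @return the threshold as a single number, or `NA_real_`.
#' @export
otsu_threshold <- function(plane, n_levels = NULL) {
  v <- as.integer(plane)
  if (is.null(n_levels)) n_levels <- if (max(v) > 255L) 65536L else 256L
  if (max(v) >= n_levels) stop("intensities exceed the stated number of levels")
  if (min(v) == max(v)) return(NA_real_)
  h <- tabulate(v + 1L, nbins = n_levels)
  lev <- 0:(n_levels - 1L)
  cw <- cumsum(h)                 # pixels with intensity <= level
  cm <- cumsum(h * lev)
  total <- cw[n_levels]
  # threshold t = lev + 1: class0 = {< t} has cw[t] pixels, mass cm[t]
  t_cand <- which(cw > 0L & cw < total)  # both classes non-empty
  n0 <- cw[t_cand]
  n1 <- total - n0
  mu0 <- cm[t_cand] / n0
  mu1 <- (cm[n_levels] - cm[t_cand]) / n1
  sigma_b <- n0 * n1 * (mu0 - mu1)^2
  as.numeric(t_cand[which.max(sigma_b)])  # which.max takes the first (lowest) maximum
}

#' Binarize one channel plane
#'
#' With `method = "fixed"`, a pixel is foreground iff its intensity is at
#' least the configured per-role threshold. With `method = "otsu"`, the
#' threshold is chosen per z-section by [otsu_threshold()]; an all-constant
#' plane yields an empty mask with a warning.
#'
#' @param plane integer intensity matrix.
#' @param role one of `"oligodendrocyte"`, `"axon"`, `"nucleus"`.
#' @param cfg a [detection_config()].
#' @param z z-index recorded on the returned mask.
#' @param n_levels gray-level count passed to [otsu_threshold()].
#' @return a [binary_mask()].
#' @export
binarize_channel <- function(plane, role, cfg, z = 0L, n_levels = NULL) {
  role <- match.arg(role, stack_roles)
  if (cfg$binarize_method == "fixed") {
    thr <- cfg$fixed_threshold[[role]]
  } else {
    thr <- otsu_threshold(plane, n_levels)
    if (is.na(thr)) {
      warning(sprintf("all-constant %s plane at z=%d under otsu; returning empty mask",
                      role, z))
      return(binary_mask(matrix(FALSE, nrow(plane), ncol(plane)), z))
    }
  }
  binary_mask(plane >= thr, z)
}

#' Detect cell bodies as the dilated nucleus-marker overlap
#'
#' Cell bodies are defined as the pixelwise overlap of the nucleus mask
#' and the cellular-marker mask, dilated by a disk of radius
#' `cfg$cell_body_dilation_px`.
#'
#' @param nucleus_mask,marker_mask [binary_mask()]s of equal dimensions
#'   and z.
#' @param cfg a [detection_config()].
#' @return a [binary_mask()].
#' @export
detect_cell_bodies <- function(nucleus_mask, marker_mask, cfg) {
  if (!identical(dim(nucleus_mask), dim(marker_mask)))
    stop("mask dimension mismatch")
  if (mask_z(nucleus_mask) != mask_z(marker_mask))
    stop("mask z mismatch")
  ov <- as_mask_matrix(nucleus_mask) & as_mask_matrix(marker_mask)
  binary_mask(dilate_mask(ov, cfg$cell_body_dilation_px), mask_z(nucleus_mask))
}

#' Detect candidate myelin pixels in a z-stack
#'
#' Per z-section: binarize the three channels; remove cell bodies (the
#' dilated overlap of the nucleus mask with the cellular-marker mask) from
#' the oligodendrocyte mask; intersect the remainder with the axon mask;
#' finally drop 8-connected components with area below
#' `cfg$min_component_area_px`. Sections are processed independently; no
#' 3-D connectivity is used.
#'
#' @param stack a [channel_stack()].
#' @param cfg a [detection_config()].
#' @return a list of [binary_mask()], one per z-section.
#' @export
detect_candidates <- function(stack, cfg) {
  if (!inherits(stack, "channel_stack")) stop("'stack' must be a channel_stack")
  if (!inherits(cfg, "detection_config")) stop("'cfg' must be a detection_config")
  n_levels <- if (stack$bit_depth == 16L) 65536L else 256L
  lapply(seq_len(stack$depth) - 1L, function(z) {
    o <- binarize_channel(stack$channels$oligodendrocyte[[z + 1L]], "oligodendrocyte",
                          cfg, z, n_levels)
    a <- binarize_channel(stack$channels$axon[[z + 1L]], "axon", cfg, z, n_levels)
    n <- binarize_channel(stack$channels$nucleus[[z + 1L]], "nucleus", cfg, z, n_levels)
    marker <- if (cfg$cell_body_marker == "oligodendrocyte") o else a
    b <- detect_cell_bodies(n, marker, cfg)
    cand <- as_mask_matrix(o) & !as_mask_matrix(b) & as_mask_matrix(a)
    binary_mask(filter_small_components(cand, cfg$min_component_area_px), z)
  })
}

#' Total candidate pixel count over sections and images
#'
#' Convenience alias of [positive_count()] for reporting detector output
#' (the study-style "candidate myelin pixels on N images" total).
#'
#' @param masks mask, list of masks, or list of per-image mask lists.
#' @return integer total.
#' @export
candidate_pixel_count <- function(masks) positive_count(masks)
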