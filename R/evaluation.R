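#' Pixel confusion counts between a predicted and a gold mask stack
#'
#' Counts are computed pixelwise within an evaluation domain and summed
#' over z-sections. The domain is either `"all"` (whole image) or a mask
#' stack, typically the candidate-myelin mask so that annotators are
#' scored only on the pixels they were asked to adjudicate.
#'
#' @param predicted,gold a [binary_mask()] or list of them (one per z),
#'   with matching dimensions and depth.
#' @param domain `"all"` or a mask stack matching `predicted`.
#' @return an object of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn` and `domain_size`.
#' @export
confusion_counts <- function(predicted, gold, domain = "all") {
  predicted <- as_mask_list(predicted)
  gold <- as_mask_list(gold)
  if (length(predicted) != length(gold)) stop("depth mismatch between predicted and gold")
  use_domain <- !(is.character(domain) && identical(domain, "all"))
  if (use_domain) {
    domain <- as_mask_list(domain)
    if (length(domain) != length(predicted)) stop("depth mismatch with domain")
  }
  tp <- fp <- fn <- dsz <- 0L
  for (k in seq_along(predicted)) {
    p <- as_mask_matrix(predicted[[k]])
    g <- as_mask_matrix(gold[[k]])
    if (!identical(dim(p), dim(g))) stop("dimension mismatch between predicted and gold")
    d <- if (use_domain) {
      dm <- as_mask_matrix(domain[[k]])
      if (!identical(dim(dm), dim(p))) stop("dimension mismatch with domain")
      dm
    } else matrix(TRUE, nrow(p), ncol(p))
    tp <- tp + sum(p & g & d)
    fp <- fp + sum(p & !g & d)
    fn <- fn + sum(!p & g & d)
    dsz <- dsz + sum(d)
  }
  structure(list(tp = tp, fp = fp, fn = fn, domain_size = dsz),
            class = "confusion_counts")
}

as_mask_list <- function(x) {
  if (inherits(x, "binary_mask") || is.matrix(x)) list(x) else x
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d (domain %d px)\n",
              x$tp, x$fp, x$fn, x$domain_size))
  invisible(x)
}

#' Pixel precision as a percentage
#'
#' `100 * tp / (tp + fp)`: the fraction of marked pixels that are in the
#' gold standard. Undefined when no pixel was marked within the domain
#' (`tp + fp = 0`); that raises an error of class
#' `myelinGT_undefined_precision` rather than returning 0 or 100.
#'
#' @param counts a [confusion_counts()] object.
#' @return precision in percent.
#' @export
pixel_precision <- function(counts) {
  if (counts$tp + counts$fp == 0)
    stop(structure(class = c("myelinGT_undefined_precision", "error", "condition"),
                   list(message = "precision undefined: no predicted pixels in the evaluation domain (tp + fp = 0)",
                        call = sys.call(-1))))
  100 * counts$tp / (counts$tp + counts$fp)
}

#' Pixel recall as a percentage
#'
#' `100 * tp / (tp + fn)`. Computed for completeness; the study-style
#' report carries precision only.
#'
#' @param counts a [confusion_counts()] object.
#' @return recall in percent.
#' @export
pixel_recall <- function(counts) {
  if (counts$tp + counts$fn == 0)
    stop(structure(class = c("myelinGT_undefined_precision", "error", "condition"),
                   list(message = "recall undefined: no gold pixels in the evaluation domain (tp + fn = 0)",
                        call = sys.call(-1))))
  100 * counts$tp / (counts$tp + counts$fn)
}

#' Unweighted mean of precision percentages
#'
#' @param values non-empty numeric vector of percentages.
#' @return the arithmetic mean, at full precision (display rounding is
#'   applied by the report printer; see [round_half_up()]).
#' @export
average_precision <- function(values) {
  if (!length(values)) stop("cannot average an empty list of precisions")
  mean(values)
}

#' Round half away from zero
#'
#' Display rounding for report percentages. Base R's `round()` rounds
#' half to even; report values use the conventional half-up rule (e.g.
#' the mean of 36.23 and 60.54 prints as 48.39, not 48.38).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) * sign(x) / p
}

#' Rasterize an adjudicated annotation set into the gold-standard masks
#'
#' The gold standard is the adjudicated set rendered at every z-section.
#' The individual experts' sets are inputs for audit logging only: their
#' vector counts are reported so the adjudication provenance is on
#' record, but they do not affect the gold masks.
#'
#' @param expert_sets list of the experts' [annotation_set()]s (may be
#'   empty).
#' @param adjudicated the adjudicated [annotation_set()].
#' @return list of [binary_mask()], one per z.
#' @export
extract_gold_standard <- function(expert_sets, adjudicated) {
  if (!inherits(adjudicated, "annotation_set"))
    stop("'adjudicated' must be an annotation_set")
  for (s in expert_sets) {
    if (!identical(c(s$width, s$height, s$depth),
                   c(adjudicated$width, adjudicated$height, adjudicated$depth)))
      stop("dimension mismatch between an expert set and the adjudicated set")
    message(sprintf("gold standard audit: expert source '%s' contributed %d vector(s)",
                    s$source, length(s$vectors)))
  }
  rasterize_all(adjudicated)
}

#' Build a per-image, per-annotator precision report
#'
#' Each row receives its precision; each annotator is summarized by the
#' unweighted mean over that annotator's images; the overall figure is
#' the mean of the per-annotator averages ("paper-style" pooling of
#' Table-3 form), with the pooled per-row mean also reported. A row whose
#' precision is undefined (no marked pixel in the domain) is kept with
#' `NA`, excluded from all averages, and flagged with a warning.
#'
#' @param per_image_counts a non-empty list of entries
#'   `list(image_id =, annotator_id =, counts = confusion_counts)`.
#' @return an object of class `eval_report` with fields `rows` (data
#'   frame), `per_annotator` (data frame) and `overall` /
#'   `overall_pooled` (percent).
#' @export
build_report <- function(per_image_counts) {
  if (!length(per_image_counts)) stop("no confusion counts supplied")
  rows <- do.call(rbind, lapply(per_image_counts, function(e) {
    stopifnot(inherits(e$counts, "confusion_counts"))
    prec <- tryCatch(pixel_precision(e$counts),
                     myelinGT_undefined_precision = function(cond) NA_real_)
    data.frame(image_id = as.character(e$image_id),
               annotator_id = as.character(e$annotator_id),
               tp = e$counts$tp, fp = e$counts$fp, fn = e$counts$fn,
               precision_percent = prec,
               stringsAsFactors = FALSE)
  }))
  if (anyNA(rows$precision_percent))
    warning(sprintf("%d row(s) with undefined precision excluded from averages (no marked pixels in domain)",
                    sum(is.na(rows$precision_percent))))
  ann <- unique(rows$annotator_id)
  per_annotator <- do.call(rbind, lapply(ann, function(a) {
    v <- rows$precision_percent[rows$annotator_id == a]
    v <- v[!is.na(v)]
    data.frame(annotator_id = a,
               n_images = sum(rows$annotator_id == a),
               mean_precision_percent = if (length(v)) mean(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  ok <- !is.na(per_annotator$mean_precision_percent)
  overall <- if (any(ok)) mean(per_annotator$mean_precision_percent[ok]) else NA_real_
  pooled_vals <- rows$precision_percent[!is.na(rows$precision_percent)]
  overall_pooled <- if (length(pooled_vals)) mean(pooled_vals) else NA_real_
  structure(list(rows = rows, per_annotator = per_annotator,
                 overall = overall, overall_pooled = overall_pooled),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  shown <- x$rows
  shown$precision_percent <- round_half_up(shown$precision_percent, 2L)
  print(shown, row.names = FALSE)
  cat("per annotator:\n")
  pa <- x$per_annotator
  pa$mean_precision_percent <- round_half_up(pa$mean_precision_percent, 2L)
  print(pa, row.names = FALSE)
  cat(sprintf("overall average precision (paper-style, mean of annotator means): %.2f%%\n",
              round_half_up(x$overall, 2L)))
  cat(sprintf("overall average precision (pooled over rows): %.2f%%\n",
              round_half_up(x$overall_pooled, 2L)))
  invisible(x)
}

#' Write the report's rows to CSV
#'
#' Columns: `image_id, annotator_id, tp, fp, fn, precision_percent`
#' (precision at full precision; apply [round_half_up()] for display).
#'
#' @param report an [build_report()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(report$rows, path, row.names = FALSE)
  invisible(path)
}
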