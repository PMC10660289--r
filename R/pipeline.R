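# End-to-end headless workflow: detect -> vectorize -> adjudicate ->
# export_gold -> evaluate. A project is a JSON manifest of file paths;
# every stage reads and writes files, logs what it did (with md5 digests
# and pixel counts, so the study-style totals are always auditable) and
# is a pure function of its inputs: reruns produce byte-identical
# artifacts.

pipeline_stages <- c("detect", "vectorize", "adjudicate", "export_gold", "evaluate")

#' Create a project manifest
#'
#' All paths are stored as given; relative paths are resolved against the
#' manifest's directory when the project is read from disk, or against
#' `root` here.
#'
#' @param image_id identifier used in the evaluation report.
#' @param images named list/vector with `oligodendrocyte`, `axon`,
#'   `nucleus` TIFF paths.
#' @param detection a [detection_config()] (stored inline in the
#'   manifest).
#' @param candidates_path output TIFF for the candidate mask.
#' @param candidates_annotation_path output JSON for the vectorized
#'   candidates.
#' @param expert_annotation_paths named list of annotation JSON paths,
#'   one per annotator.
#' @param adjudicated_path annotation JSON produced by the adjudicating
#'   expert (an input to the pipeline; adjudication itself is human
#'   work).
#' @param gold_path output TIFF for the gold-standard mask.
#' @param report_path output CSV for the evaluation report.
#' @param domain either `"candidates"` (evaluate on candidate pixels
#'   only, when the candidate mask exists) or `"all"`.
#' @param simplify_tol Douglas-Peucker tolerance used by the vectorize
#'   stage.
#' @param log_path optional log file (log lines always go to stderr too).
#' @param root directory the relative paths live in.
#' @return an object of class `myelin_project`.
#' @export
myelin_project <- function(image_id, images, detection = detection_config(),
                           candidates_path = "candidates.tif",
                           candidates_annotation_path = "candidates.iev.json",
                           expert_annotation_paths = list(),
                           adjudicated_path = "adjudicated.iev.json",
                           gold_path = "gold.tif",
                           report_path = "report.csv",
                           domain = c("candidates", "all"),
                           simplify_tol = 0,
                           log_path = NULL,
                           root = ".") {
  images <- as.list(images)
  if (!all(stack_roles %in% names(images)))
    stop("'images' must name all of: ", paste(stack_roles, collapse = ", "))
  structure(list(image_id = as.character(image_id),
                 images = images[stack_roles],
                 detection = detection,
                 candidates_path = candidates_path,
                 candidates_annotation_path = candidates_annotation_path,
                 expert_annotation_paths = as.list(expert_annotation_paths),
                 adjudicated_path = adjudicated_path,
                 gold_path = gold_path,
                 report_path = report_path,
                 domain = match.arg(domain),
                 simplify_tol = simplify_tol,
                 log_path = log_path,
                 root = root),
            class = "myelin_project")
}

#' Write / read a project manifest as JSON
#'
#' @param project a [myelin_project()].
#' @param path manifest path; on read, relative project paths are
#'   resolved against the manifest's directory.
#' @return `write_project()`: `path` invisibly; `read_project()`: the
#'   [myelin_project()].
#' @export
write_project <- function(project, path) {
  doc <- unclass(project)
  doc$root <- NULL
  doc$detection <- unclass(doc$detection)
  doc$detection$fixed_threshold <- as.list(doc$detection$fixed_threshold)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_project
#' @export
read_project <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  det <- doc$detection
  detection <- detection_config(binarize_method = det$binarize_method,
                                fixed_threshold = unlist(det$fixed_threshold),
                                cell_body_dilation_px = det$cell_body_dilation_px,
                                min_component_area_px = det$min_component_area_px,
                                cell_body_marker = det$cell_body_marker)
  myelin_project(image_id = doc$image_id, images = as.list(doc$images),
                 detection = detection,
                 candidates_path = doc$candidates_path,
                 candidates_annotation_path = doc$candidates_annotation_path,
                 expert_annotation_paths = as.list(doc$expert_annotation_paths),
                 adjudicated_path = doc$adjudicated_path,
                 gold_path = doc$gold_path,
                 report_path = doc$report_path,
                 domain = doc$domain,
                 simplify_tol = doc$simplify_tol,
                 log_path = if (is.null(doc$log_path)) NULL else doc$log_path,
                 root = dirname(path))
}

proj_path <- function(project, p) {
  if (is.null(p)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(project$root, p)
}

log_line <- function(project, stage, fmt, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
  message(line)
  lp <- proj_path(project, project$log_path)
  if (!is.null(lp)) cat(line, "\n", file = lp, append = TRUE, sep = "")
  invisible(line)
}

digest_of <- function(path) unname(tools::md5sum(path))

require_artifact <- function(project, path, producer, what) {
  if (!file.exists(path))
    stop(sprintf("missing %s '%s': run stage '%s' first", what, path, producer))
  path
}

#' Run the ground-truth pipeline
#'
#' Executes the requested stages in the given order. Every stage writes
#' its artifact(s) and logs a line with input/output md5 digests and
#' pixel counts. A missing prerequisite raises an error naming the stage
#' that produces it. Given identical inputs the pipeline is
#' deterministic: reruns yield byte-identical artifacts.
#'
#' Stages:
#' * `detect`: load the channel stack, run [detect_candidates()], save
#'   the candidate mask TIFF.
#' * `vectorize`: convert the candidate mask to vectors
#'   ([vectorize_mask()] per section, overwrite semantics) and write the
#'   candidate annotation JSON.
#' * `adjudicate`: validate the adjudicated annotation file (produced by
#'   the adjudicating expert outside the pipeline) and log its digest.
#' * `export_gold`: rasterize the adjudicated set into the gold mask
#'   TIFF via [extract_gold_standard()].
#' * `evaluate`: score every expert annotation file against the gold
#'   mask (domain = candidate mask when `project$domain` is
#'   `"candidates"` and the candidate TIFF exists) and write the CSV
#'   report.
#'
#' @param project a [myelin_project()] or manifest path.
#' @param stages ordered subset of
#'   `c("detect", "vectorize", "adjudicate", "export_gold", "evaluate")`.
#' @return the [build_report()] result if `evaluate` ran, otherwise
#'   `NULL`, invisibly.
#' @export
run_pipeline <- function(project, stages = pipeline_stages) {
  if (is.character(project)) project <- read_project(project)
  if (!inherits(project, "myelin_project")) stop("'project' must be a myelin_project")
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  report <- NULL
  for (stage in stages) {
    report <- switch(stage,
      detect = { stage_detect(project); NULL },
      vectorize = { stage_vectorize(project); NULL },
      adjudicate = { stage_adjudicate(project); NULL },
      export_gold = { stage_export_gold(project); NULL },
      evaluate = stage_evaluate(project))
  }
  invisible(report)
}

stage_detect <- function(project) {
  paths <- vapply(project$images, function(p) proj_path(project, p), character(1))
  for (p in paths) {
    if (!file.exists(p))
      stop(sprintf("missing channel TIFF '%s': provide the input images", p))
  }
  stack <- load_stack(paths[["oligodendrocyte"]], paths[["axon"]], paths[["nucleus"]])
  cand <- detect_candidates(stack, project$detection)
  out <- proj_path(project, project$candidates_path)
  save_mask_tiff(cand, out)
  counts <- vapply(cand, positive_count, numeric(1))
  log_line(project, "detect",
           "inputs %s -> '%s' (md5 %s); candidate pixels per z: %s (total %d)",
           paste(substr(vapply(paths, digest_of, character(1)), 1L, 8L), collapse = "/"),
           out, substr(digest_of(out), 1L, 8L),
           paste(counts, collapse = ","), sum(counts))
  invisible(out)
}

stage_vectorize <- function(project) {
  cand_path <- require_artifact(project, proj_path(project, project$candidates_path),
                                "detect", "candidate mask")
  cand <- load_mask_tiff(cand_path)
  blank <- annotation_set(image_ref = project$image_id,
                          width = ncol(cand[[1L]]), height = nrow(cand[[1L]]),
                          depth = length(cand), source = "converted")
  converted <- replace_with_converted(blank, cand, project$simplify_tol)
  out <- proj_path(project, project$candidates_annotation_path)
  write_annotations(converted, out)
  log_line(project, "vectorize",
           "'%s' (md5 %s) -> '%s' (md5 %s); %d vector(s) from %d candidate pixel(s)",
           cand_path, substr(digest_of(cand_path), 1L, 8L),
           out, substr(digest_of(out), 1L, 8L),
           length(converted$vectors), positive_count(cand))
  invisible(out)
}

stage_adjudicate <- function(project) {
  adj_path <- proj_path(project, project$adjudicated_path)
  if (!file.exists(adj_path))
    stop(sprintf("missing adjudicated annotation file '%s': stage 'adjudicate' expects the adjudicating expert's markings (produced interactively, outside this pipeline)",
                 adj_path))
  adj <- read_annotations(adj_path)
  log_line(project, "adjudicate",
           "validated '%s' (md5 %s): source '%s', %d vector(s)",
           adj_path, substr(digest_of(adj_path), 1L, 8L),
           adj$source, length(adj$vectors))
  invisible(adj_path)
}

stage_export_gold <- function(project) {
  adj_path <- require_artifact(project, proj_path(project, project$adjudicated_path),
                               "adjudicate", "adjudicated annotation file")
  adj <- read_annotations(adj_path)
  experts <- lapply(project$expert_annotation_paths, function(p) {
    pp <- proj_path(project, p)
    if (file.exists(pp)) read_annotations(pp) else NULL
  })
  experts <- Filter(Negate(is.null), experts)
  gold <- withCallingHandlers(extract_gold_standard(experts, adj),
                              message = function(m) {
                                log_line(project, "export_gold", "%s",
                                         sub("\n$", "", conditionMessage(m)))
                                invokeRestart("muffleMessage")
                              })
  out <- proj_path(project, project$gold_path)
  save_mask_tiff(gold, out)
  log_line(project, "export_gold",
           "'%s' -> '%s' (md5 %s); gold pixels: %d",
           adj_path, out, substr(digest_of(out), 1L, 8L), positive_count(gold))
  invisible(out)
}

stage_evaluate <- function(project) {
  gold_path <- require_artifact(project, proj_path(project, project$gold_path),
                                "export_gold", "gold-standard mask")
  gold <- load_mask_tiff(gold_path)
  domain <- "all"
  if (identical(project$domain, "candidates")) {
    cand_path <- proj_path(project, project$candidates_path)
    if (file.exists(cand_path)) domain <- load_mask_tiff(cand_path)
    else log_line(project, "evaluate",
                  "candidate mask '%s' not found; evaluating on the whole image",
                  cand_path)
  }
  if (!length(project$expert_annotation_paths))
    stop("no expert annotation files configured; nothing to evaluate")
  entries <- lapply(names(project$expert_annotation_paths), function(ann) {
    p <- proj_path(project, project$expert_annotation_paths[[ann]])
    if (!file.exists(p))
      stop(sprintf("missing expert annotation file '%s' for annotator '%s'", p, ann))
    set <- read_annotations(p)
    pred <- rasterize_all(set)
    list(image_id = project$image_id, annotator_id = ann,
         counts = confusion_counts(pred, gold, domain))
  })
  report <- build_report(entries)
  out <- proj_path(project, project$report_path)
  write_report_csv(report, out)
  for (i in seq_len(nrow(report$rows))) {
    r <- report$rows[i, ]
    log_line(project, "evaluate",
             "image %s annotator %s: tp=%d fp=%d fn=%d precision=%s%%",
             r$image_id, r$annotator_id, r$tp, r$fp, r$fn,
             ifelse(is.na(r$precision_percent), "NA",
                    sprintf("%.2f", round_half_up(r$precision_percent, 2L))))
  }
  log_line(project, "evaluate", "report written to '%s' (md5 %s)",
           out, substr(digest_of(out), 1L, 8L))
  report
}
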