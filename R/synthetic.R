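# Seeded generator of fluorescent-like z-stacks with known myelin ground
# truth. Fibers are smoothed 2-D random walks that drift across adjacent
# z-sections; true fibers are co-drawn in both membrane channels with
# independent per-channel pixel dropout ("granular" staining an annotator
# must bridge); distractor fibers appear in only one membrane channel
# (false-positive sources); nuclei are filled disks with matching
# oligodendrocyte signal underneath (cell bodies). All randomness flows
# from the explicit seed; identical seeds give bit-identical output.

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Configuration of the synthetic stack generator
#'
#' Defaults describe a small but realistic field: a 256 x 256 px crop of
#' a confocal stack with 3 optical sections, a dozen wriggling fibers of
#' 3 px thickness, moderate staining granularity (15% pixel dropout per
#' channel), half a dozen nuclei and mild Gaussian sensor noise on an
#' 8-bit intensity scale.
#'
#' @param width,height,depth canvas size in pixels / z-sections.
#' @param n_fibers number of true (co-localized) myelin fibers.
#' @param fiber_thickness odd stroke width of fibers, px.
#' @param fiber_length_px number of unit steps per fiber walk.
#' @param step_sigma standard deviation of the per-step heading change
#'   (radians); larger values wriggle more.
#' @param z_drift_p per-step probability that a fiber drifts to an
#'   adjacent z-section (the across-z wriggle).
#' @param granularity_p probability that a fiber pixel is dropped in a
#'   given membrane channel (independently per channel), in `[0, 1]`.
#' @param n_distractors fibers drawn in only one membrane channel; these
#'   are false-positive sources and never contribute gold pixels.
#' @param n_nuclei number of nuclei (cell bodies).
#' @param nucleus_radius nucleus disk radius, px; must be smaller than
#'   half the smaller canvas side.
#' @param noise_sigma Gaussian noise standard deviation (intensity units).
#' @param fiber_intensity,background_intensity 8-bit intensities of
#'   structure and background.
#' @param seed integer RNG seed; same seed, same stack.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(width = 256L, height = 256L, depth = 3L,
                         n_fibers = 12L, fiber_thickness = 3L,
                         fiber_length_px = 80L, step_sigma = 0.25,
                         z_drift_p = 0.05, granularity_p = 0.15,
                         n_distractors = 6L, n_nuclei = 6L,
                         nucleus_radius = 8L, noise_sigma = 8,
                         fiber_intensity = 200L, background_intensity = 20L,
                         seed = 1L) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              depth = as.integer(depth), n_fibers = as.integer(n_fibers),
              fiber_thickness = as.integer(fiber_thickness),
              fiber_length_px = as.integer(fiber_length_px),
              step_sigma = step_sigma, z_drift_p = z_drift_p,
              granularity_p = granularity_p,
              n_distractors = as.integer(n_distractors),
              n_nuclei = as.integer(n_nuclei),
              nucleus_radius = as.integer(nucleus_radius),
              noise_sigma = noise_sigma,
              fiber_intensity = as.integer(fiber_intensity),
              background_intensity = as.integer(background_intensity),
              seed = as.integer(seed))
  with(cfg, {
    if (width < 1L || height < 1L || depth < 1L) stop("dimensions must be positive")
    if (fiber_thickness %% 2L == 0L || fiber_thickness < 1L)
      stop("'fiber_thickness' must be an odd positive integer")
    if (granularity_p < 0 || granularity_p > 1) stop("'granularity_p' must be in [0, 1]")
    if (z_drift_p < 0 || z_drift_p > 1) stop("'z_drift_p' must be in [0, 1]")
    if (n_nuclei > 0L && nucleus_radius >= min(width, height) / 2)
      stop("impossible geometry: 'nucleus_radius' must be < min(width, height) / 2")
    if (fiber_intensity > 255L || background_intensity > 255L)
      stop("intensities are 8-bit (<= 255)")
    if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  })
  structure(cfg, class = "synth_config")
}

# one smoothed random walk: n x 2 integer points (0-based), plus a z per point
fiber_walk <- function(cfg) {
  margin <- 2
  x <- runif(1, margin, cfg$width - 1 - margin)
  y <- runif(1, margin, cfg$height - 1 - margin)
  heading <- runif(1, 0, 2 * pi)
  z <- sample.int(cfg$depth, 1L) - 1L
  pts <- matrix(NA_integer_, cfg$fiber_length_px, 2L)
  zs <- integer(cfg$fiber_length_px)
  pts[1L, ] <- c(round(x), round(y)); zs[1L] <- z
  k <- 1L
  for (i in seq_len(cfg$fiber_length_px - 1L)) {
    heading <- heading + rnorm(1, 0, cfg$step_sigma)
    x <- x + cos(heading); y <- y + sin(heading)
    if (x < 0 || x > cfg$width - 1 || y < 0 || y > cfg$height - 1) break
    if (cfg$depth > 1L && runif(1) < cfg$z_drift_p) {
      z <- z + sample(c(-1L, 1L), 1L)
      z <- max(0L, min(cfg$depth - 1L, z))
    }
    p <- c(round(x), round(y))
    if (any(p != pts[k, ])) {
      k <- k + 1L
      pts[k, ] <- p
      zs[k] <- z
    } else {
      zs[k] <- z  # same pixel: keep the latest z
    }
  }
  list(points = pts[seq_len(k), , drop = FALSE], z = zs[seq_len(k)])
}

# split a walk into per-z runs, one myelin_vector per run
walk_to_vectors <- function(walk, thickness, source, id_prefix) {
  runs <- rle(walk$z)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- list()
  for (j in seq_along(starts)) {
    pts <- walk$points[starts[j]:ends[j], , drop = FALSE]
    # a run can revisit a pixel right at a z switch; drop exact repeats
    if (nrow(pts) > 1L) {
      same <- c(FALSE, rowSums(pts[-1L, , drop = FALSE] ==
                               pts[-nrow(pts), , drop = FALSE]) == 2L)
      pts <- pts[!same, , drop = FALSE]
    }
    out[[j]] <- myelin_vector(sprintf("%s_s%02d", id_prefix, j),
                              z = runs$values[j], points = pts,
                              thickness = thickness, source = source)
  }
  out
}

#' Generate a seeded synthetic stack with known ground truth
#'
#' Returns the three-channel stack, the gold masks (exactly the
#' rasterization of the gold vectors at every z), the gold vectors, and a
#' `bookkeeping` record of what else was drawn: per-channel distractor
#' masks and the cell-body masks. Nuclei are placed so their (slightly
#' dilated) disks avoid gold fibers, so cell-body removal during
#' detection never consumes true myelin; distractor pixels avoid gold and
#' cell bodies, but distractors of opposite channels may cross - those
#' crossings are exactly the detector's unavoidable false positives.
#'
#' @param cfg a [synth_config()].
#' @return a list with elements `stack` ([channel_stack()]), `gold` (list
#'   of [binary_mask()] per z), `gold_vectors` ([annotation_set()]) and
#'   `bookkeeping`.
#' @export
generate_stack <- function(cfg) {
  if (!inherits(cfg, "synth_config")) stop("'cfg' must be a synth_config")
  with_seed(cfg$seed, {
    w <- cfg$width; h <- cfg$height; d <- cfg$depth
    gold_set <- annotation_set(image_ref = sprintf("synthetic-seed%d", cfg$seed),
                               width = w, height = h, depth = d, source = "gold")
    for (i in seq_len(cfg$n_fibers)) {
      vs <- walk_to_vectors(fiber_walk(cfg), cfg$fiber_thickness, "gold",
                            sprintf("fiber%03d", i))
      for (v in vs) gold_set <- append_vector(gold_set, v)
    }
    gold <- rasterize_all(gold_set)
    gold_mat <- lapply(gold, as_mask_matrix)

    # nuclei: rejection-sample centres whose dilated disk avoids gold
    nuc_mat <- replicate(d, matrix(FALSE, h, w), simplify = FALSE)
    centres <- matrix(NA_real_, 0L, 2L)
    if (cfg$n_nuclei > 0L) {
      r <- cfg$nucleus_radius
      off <- disk_offsets(r)
      off_guard <- disk_offsets(r + 2L)
      placed <- 0L; tries <- 0L
      while (placed < cfg$n_nuclei && tries < 200L * cfg$n_nuclei) {
        tries <- tries + 1L
        cx <- round(runif(1, r, w - 1 - r)); cy <- round(runif(1, r, h - 1 - r))
        gx <- pmin(pmax(cx + off_guard[, "dx"], 0L), w - 1L)
        gy <- pmin(pmax(cy + off_guard[, "dy"], 0L), h - 1L)
        hit <- any(vapply(gold_mat, function(g) any(g[cbind(gy + 1L, gx + 1L)]),
                          logical(1)))
        if (hit) next
        placed <- placed + 1L
        centres <- rbind(centres, c(cx, cy))
        for (z in seq_len(d)) {
          nuc_mat[[z]][cbind(cy + off[, "dy"] + 1L, cx + off[, "dx"] + 1L)] <- TRUE
        }
      }
    }

    # distractors: single-channel fibers avoiding gold and cell bodies
    distr_mat <- list(
      oligodendrocyte = replicate(d, matrix(FALSE, h, w), simplify = FALSE),
      axon = replicate(d, matrix(FALSE, h, w), simplify = FALSE))
    if (cfg$n_distractors > 0L) {
      for (i in seq_len(cfg$n_distractors)) {
        chan <- if (i %% 2L == 1L) "oligodendrocyte" else "axon"
        vs <- walk_to_vectors(fiber_walk(cfg), cfg$fiber_thickness, "distractor",
                              sprintf("distr%03d", i))
        for (v in vs) {
          m <- as_mask_matrix(rasterize_vector(v, w, h))
          m <- m & !gold_mat[[v$z + 1L]] & !nuc_mat[[v$z + 1L]]
          distr_mat[[chan]][[v$z + 1L]] <- distr_mat[[chan]][[v$z + 1L]] | m
        }
      }
    }

    bg <- cfg$background_intensity; fg <- cfg$fiber_intensity
    drop_pixels <- function(m) {
      # independent per-channel dropout: granular staining
      if (cfg$granularity_p <= 0 || !any(m)) return(m)
      idx <- which(m)
      m[idx[runif(length(idx)) < cfg$granularity_p]] <- FALSE
      m
    }
    make_plane <- function(struct) {
      plane <- matrix(bg, h, w)
      plane[struct] <- fg
      if (cfg$noise_sigma > 0)
        plane <- plane + rnorm(length(plane), 0, cfg$noise_sigma)
      matrix(as.integer(pmin(pmax(round(plane), 0), 255)), h, w)
    }
    oligo <- axon <- nucleus <- vector("list", d)
    for (z in seq_len(d)) {
      oligo[[z]] <- make_plane(drop_pixels(gold_mat[[z]]) |
                               drop_pixels(distr_mat$oligodendrocyte[[z]]) |
                               nuc_mat[[z]])
      axon[[z]] <- make_plane(drop_pixels(gold_mat[[z]]) |
                              drop_pixels(distr_mat$axon[[z]]))
      nucleus[[z]] <- make_plane(nuc_mat[[z]])
    }
    stack <- channel_stack(oligo, axon, nucleus, z_step_um = 1, bit_depth = 8L)
    list(stack = stack,
         gold = gold,
         gold_vectors = gold_set,
         bookkeeping = list(
           config = cfg,
           nucleus_centres = centres,
           cell_body_masks = lapply(seq_len(d), function(z)
             binary_mask(nuc_mat[[z]], z - 1L)),
           distractor_masks = list(
             oligodendrocyte = lapply(seq_len(d), function(z)
               binary_mask(distr_mat$oligodendrocyte[[z]], z - 1L)),
             axon = lapply(seq_len(d), function(z)
               binary_mask(distr_mat$axon[[z]], z - 1L)))))
  })
}

#' Corrupt a gold annotation set with known error rates
#'
#' Simulates an imperfect annotator: each gold vector is deleted with
#' probability `fn_rate`, and spurious short strokes are added off-gold
#' until the fraction of annotated pixels lying outside the gold
#' rasterization reaches `fp_rate` in expectation. Spurious strokes are
#' fully disjoint from the gold mask (and from each other), so the
#' resulting precision against gold is `100 * (1 - fp_rate)` up to the
#' granularity of whole strokes. Deterministic per `seed`.
#'
#' @param gold_vectors the gold [annotation_set()].
#' @param fp_rate target fraction of annotated pixels outside gold, in
#'   `[0, 1)`.
#' @param fn_rate per-vector deletion probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param source source label of the simulated annotator.
#' @return an [annotation_set()].
#' @export
corrupt_annotation <- function(gold_vectors, fp_rate, fn_rate, seed,
                               source = "simulated_annotator") {
  if (fp_rate < 0 || fp_rate >= 1) stop("'fp_rate' must be in [0, 1)")
  if (fn_rate < 0 || fn_rate > 1) stop("'fn_rate' must be in [0, 1]")
  set <- gold_vectors
  with_seed(seed, {
    keep <- runif(length(set$vectors)) >= fn_rate
    kept <- set$vectors[keep]
    out <- annotation_set(image_ref = set$image_ref, width = set$width,
                          height = set$height, depth = set$depth,
                          source = source, vectors = kept)
    if (fp_rate > 0) {
      gold_full <- lapply(rasterize_all(set), as_mask_matrix)
      kept_masks <- lapply(rasterize_all(out), as_mask_matrix)
      n_kept <- sum(vapply(kept_masks, sum, numeric(1)))
      target <- round(n_kept * fp_rate / (1 - fp_rate))
      spur <- lapply(gold_full, function(m) matrix(FALSE, nrow(m), ncol(m)))
      added <- 0L; k <- 0L; tries <- 0L
      walk_cfg <- synth_config(width = set$width, height = set$height,
                               depth = set$depth, fiber_length_px = 10L,
                               step_sigma = 0.4, z_drift_p = 0,
                               n_nuclei = 0L, seed = seed)
      median_thick <- if (length(set$vectors))
        as.integer(median(vapply(set$vectors, `[[`, integer(1), "thickness")))
      else 1L
      if (median_thick %% 2L == 0L) median_thick <- median_thick + 1L
      while (added < target && tries < 50L * max(target, 1L)) {
        tries <- tries + 1L
        wk <- fiber_walk(walk_cfg)
        v <- myelin_vector("tmp", wk$z[1L], wk$points, median_thick, source)
        m <- as_mask_matrix(rasterize_vector(v, set$width, set$height))
        zi <- v$z + 1L
        if (any(m & gold_full[[zi]]) || any(m & spur[[zi]])) next
        k <- k + 1L
        out <- append_vector(out, myelin_vector(sprintf("fp%04d", k), v$z,
                                                v$points, median_thick, source))
        spur[[zi]] <- spur[[zi]] | m
        added <- added + sum(m)
      }
    }
    out
  })
}
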