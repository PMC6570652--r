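#' Synthetic-experiment configuration
#'
#' Describes the simulated world: a cell population with a ~10:1
#' non-engram:engram ratio, sessions A-F with the study's default durations
#' (learning 6 min; two NREM and one REM sleep windows of 1 min imaged each;
#' retrieval 3 min; different context 3 min) at 20 frames/s, background
#' calcium transients, planted co-active sub-ensembles whose presence across
#' sessions follows a configurable fate plan, and a reporter snapshot with one
#' blob per expressing (engram) cell.
#'
#' @param n_cells total number of cells (default 200).
#' @param engram_fraction fraction of cells that are engram cells (default 0.1).
#' @param n_engram_patterns,n_nonengram_patterns planted sub-ensembles per group.
#' @param pattern_size integer range `c(min, max)` of cells per pattern.
#' @param session_plan data.frame with columns `label`, `stage`, `duration_s`.
#' @param frame_rate_hz imaging rate (default 20).
#' @param event_rate_hz background transient rate per cell (Hz).
#' @param pattern_activation_rate_hz activation rate of each planted pattern.
#' @param participation_weights range `c(lo, hi)` in (0, 1] for per-member
#'   participation weights.
#' @param kernel calcium kernel `c(rise_s, decay_s)` (difference of
#'   exponentials, peak-normalized to 1).
#' @param amplitude global transient amplitude; `amp_jitter_sdlog` lognormal
#'   jitter applied per event.
#' @param amp_jitter_sdlog lognormal sd of per-event amplitude jitter.
#' @param noise_sd additive Gaussian noise sd on traces.
#' @param fate_plan list, one element per engram pattern, of session labels in
#'   which the pattern is active; `NULL` builds a default plan cycling
#'   aligned / isolated / mixed categories with [make_fate_plan()].
#' @param f_shared_fraction fraction of aligned patterns also active in the
#'   different-context session F (default 0.5).
#' @param nonengram_session_unique if `TRUE` (default) non-engram patterns are
#'   redrawn per session, so no structure is shared across sessions.
#' @param image_size snapshot size in pixels `c(rows, cols)`.
#' @param blob_sigma,blob_peak Gaussian blob sd (px) and peak intensity.
#' @param background,snapshot_noise_sd snapshot background level and noise sd.
#' @param seed integer RNG seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_cells = 200,
                         engram_fraction = 0.1,
                         n_engram_patterns = 4,
                         n_nonengram_patterns = 4,
                         pattern_size = c(4, 8),
                         session_plan = default_session_plan(),
                         frame_rate_hz = 20,
                         event_rate_hz = 0.05,
                         pattern_activation_rate_hz = 0.2,
                         participation_weights = c(0.5, 1),
                         kernel = c(rise_s = 0.1, decay_s = 0.8),
                         amplitude = 1,
                         amp_jitter_sdlog = 0.2,
                         noise_sd = 0.02,
                         fate_plan = NULL,
                         f_shared_fraction = 0.5,
                         nonengram_session_unique = TRUE,
                         image_size = c(400, 400),
                         blob_sigma = 3,
                         blob_peak = 2000,
                         background = 200,
                         snapshot_noise_sd = 40,
                         seed = 1L) {
  cfg <- as.list(environment())
  n_engram <- round(engram_fraction * n_cells)
  if (n_engram < max(pattern_size)) {
    stop("infeasible config: largest engram pattern (", max(pattern_size),
         ") exceeds engram group size (", n_engram, ")")
  }
  if (n_cells - n_engram < max(pattern_size) && n_nonengram_patterns > 0) {
    stop("infeasible config: pattern larger than non-engram group")
  }
  frames <- session_plan$duration_s * frame_rate_hz
  if (any(abs(frames - round(frames)) > 1e-9)) {
    stop("duration_s * frame_rate_hz must be integral for every session")
  }
  if (event_rate_hz < 0 || pattern_activation_rate_hz < 0 || noise_sd < 0) {
    stop("rates and noise_sd must be non-negative")
  }
  if (is.null(fate_plan)) {
    cats <- rep_len(c("aligned", "isolated", "mixed"), n_engram_patterns)
    cfg$fate_plan <- make_fate_plan(cats, f_shared_fraction)
  } else {
    if (length(fate_plan) != n_engram_patterns) {
      stop("fate_plan must have one entry per engram pattern")
    }
    cfg$fate_plan <- lapply(fate_plan, function(p) {
      p <- as.character(p)
      if (!all(p %in% VALID_LABELS)) stop("fate_plan labels must be A-F")
      if (!"A" %in% p) stop("every planted engram pattern must be active in A")
      p
    })
  }
  cfg$seed <- as.integer(seed)
  class(cfg) <- "synth_config"
  cfg
}

#' @rdname synth_config
#' @export
default_session_plan <- function() {
  data.frame(
    label = c("A", "B", "C", "D", "E", "F"),
    stage = c("awake", "NREM", "NREM", "REM", "awake", "awake"),
    duration_s = c(360, 60, 60, 60, 180, 180),
    stringsAsFactors = FALSE
  )
}

#' Build a fate plan from category names
#'
#' Categories map to session-presence sets: `aligned` patterns persist from
#' learning through sleep into retrieval (A, B, C, D, E); `isolated` patterns
#' appear only at learning (A); `mixed` patterns reappear at retrieval but not
#' during sleep (A, E). A fraction of aligned patterns is additionally active
#' in the different context F.
#'
#' @param categories character vector over
#'   `c("aligned", "isolated", "mixed")`, one per engram pattern.
#' @param f_shared_fraction fraction of aligned patterns also present in F.
#' @return List of session-label vectors.
#' @export
make_fate_plan <- function(categories, f_shared_fraction = 0.5) {
  stopifnot(all(categories %in% c("aligned", "isolated", "mixed")))
  plan <- lapply(categories, function(cat) {
    switch(cat,
           aligned = c("A", "B", "C", "D", "E"),
           isolated = "A",
           mixed = c("A", "E"))
  })
  ali <- which(categories == "aligned")
  if (length(ali)) {
    n_f <- floor(length(ali) * f_shared_fraction)
    for (i in head(ali, n_f)) plan[[i]] <- c(plan[[i]], "F")
  }
  plan
}

#' Discretized calcium kernel
#'
#' Difference of exponentials `exp(-t/decay) - exp(-t/rise)`, sampled at the
#' frame rate and normalized to peak 1; truncated where the decay falls below
#' 1e-3 of the peak.
#'
#' @param rise_s,decay_s rise and decay time constants in seconds.
#' @param frame_rate_hz sampling rate.
#' @return Numeric vector, `k[1]` at lag 0.
#' @export
calcium_kernel <- function(rise_s, decay_s, frame_rate_hz) {
  stopifnot(decay_s > rise_s, rise_s > 0)
  t_max <- decay_s * log(1000)
  t <- seq(0, t_max, by = 1 / frame_rate_hz)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)
}

# causal convolution of each row with kernel, same length as input
convolve_rows <- function(imp, kern) {
  nf <- ncol(imp)
  if (nf == 0 || nrow(imp) == 0) return(imp)
  out <- imp
  for (i in seq_len(nrow(imp))) {
    if (any(imp[i, ] != 0)) {
      out[i, ] <- stats::convolve(imp[i, ], rev(kern), type = "open")[seq_len(nf)]
    }
  }
  out
}

draw_pattern <- function(member_pool, n_cells, size_range, w_range) {
  size <- if (size_range[1] == size_range[2]) size_range[1] else
    sample(seq(size_range[1], size_range[2]), 1)
  members <- sample(member_pool, size)
  w <- runif(size, w_range[1], w_range[2])
  vec <- numeric(n_cells)
  vec[members] <- w
  list(members = members, weights = w, vector = vec / sqrt(sum(vec^2)))
}

#' Generate a full synthetic experiment
#'
#' Builds sessions A-F of cell x frame transient traces: background Poisson
#' events per cell plus planted pattern activations (member cells co-fire with
#' amplitudes proportional to their participation weights), convolved with the
#' calcium kernel, plus Gaussian noise, clipped at zero. Also returns complete
#' ground truth and a synthetic reporter snapshot with a blob per engram cell.
#'
#' @param cfg a [synth_config()].
#' @return List with elements `session_set` ([session_set()]), `ground_truth`
#'   (pattern vectors, activation times, fate labels, engram ids, background
#'   event counts) and `snapshot` (a [snapshot_image()]).
#' @export
generate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cells
  ids <- sprintf("c%03d", seq_len(n))
  n_engram <- round(cfg$engram_fraction * n)
  engram_idx <- sort(sample(n, n_engram))
  nonengram_idx <- setdiff(seq_len(n), engram_idx)

  centroids <- place_centroids(n, cfg$image_size,
                               min_sep = 4 * cfg$blob_sigma,
                               margin = 4 * cfg$blob_sigma)
  registry <- cell_registry(ids, x = centroids[, 1], y = centroids[, 2],
                            engram_flag = seq_len(n) %in% engram_idx)

  kern <- calcium_kernel(cfg$kernel[["rise_s"]], cfg$kernel[["decay_s"]],
                         cfg$frame_rate_hz)

  eng_patterns <- lapply(seq_len(cfg$n_engram_patterns), function(k) {
    draw_pattern(engram_idx, n, cfg$pattern_size, cfg$participation_weights)
  })
  fixed_noneng <- NULL
  if (!cfg$nonengram_session_unique && cfg$n_nonengram_patterns > 0) {
    fixed_noneng <- lapply(seq_len(cfg$n_nonengram_patterns), function(k) {
      draw_pattern(nonengram_idx, n, cfg$pattern_size, cfg$participation_weights)
    })
  }

  activation_times <- list()
  noneng_vectors <- list()
  bg_counts <- list()
  sessions <- vector("list", nrow(cfg$session_plan))

  for (si in seq_len(nrow(cfg$session_plan))) {
    lab <- cfg$session_plan$label[si]
    dur <- cfg$session_plan$duration_s[si]
    nf <- as.integer(round(dur * cfg$frame_rate_hz))
    imp <- matrix(0, n, nf)

    counts <- rpois(n, cfg$event_rate_hz * dur)
    bg_counts[[lab]] <- counts
    for (i in which(counts > 0)) {
      tt <- sample.int(nf, counts[i], replace = TRUE)
      amp <- cfg$amplitude * exp(rnorm(counts[i], 0, cfg$amp_jitter_sdlog))
      for (e in seq_along(tt)) imp[i, tt[e]] <- imp[i, tt[e]] + amp[e]
    }

    sess_noneng <- if (cfg$nonengram_session_unique && cfg$n_nonengram_patterns > 0) {
      lapply(seq_len(cfg$n_nonengram_patterns), function(k) {
        draw_pattern(nonengram_idx, n, cfg$pattern_size, cfg$participation_weights)
      })
    } else fixed_noneng
    noneng_vectors[[lab]] <- if (length(sess_noneng)) {
      do.call(cbind, lapply(sess_noneng, `[[`, "vector"))
    } else matrix(0, n, 0)

    pats <- c(
      lapply(seq_along(eng_patterns), function(k) {
        if (lab %in% cfg$fate_plan[[k]]) {
          c(eng_patterns[[k]], id = sprintf("engram_p%d", k))
        } else NULL
      }),
      lapply(seq_along(sess_noneng), function(k) {
        c(sess_noneng[[k]], id = sprintf("nonengram_%s_p%d", lab, k))
      })
    )
    for (p in pats) {
      if (is.null(p)) next
      n_act <- max(1L, rpois(1, cfg$pattern_activation_rate_hz * dur))
      tt <- sort(sample.int(nf, n_act, replace = TRUE))
      jit <- exp(rnorm(n_act, 0, cfg$amp_jitter_sdlog))
      for (e in seq_along(tt)) {
        imp[p$members, tt[e]] <- imp[p$members, tt[e]] +
          p$weights * cfg$amplitude * jit[e]
      }
      activation_times[[p$id]] <- c(activation_times[[p$id]],
                                    setNames(list((tt - 1) / cfg$frame_rate_hz), lab))
    }

    tr <- convolve_rows(imp, kern)
    if (cfg$noise_sd > 0) tr <- tr + matrix(rnorm(n * nf, 0, cfg$noise_sd), n, nf)
    tr <- pmax(tr, 0)
    dimnames(tr) <- list(ids, NULL)
    sessions[[si]] <- list(label = lab, stage = cfg$session_plan$stage[si],
                           frame_rate_hz = cfg$frame_rate_hz,
                           traces = trace_matrix(tr, normalized = TRUE))
  }

  fate <- data.frame(
    pattern = sprintf("engram_p%d", seq_along(eng_patterns)),
    category = vapply(cfg$fate_plan, function(p) {
      slept <- any(c("B", "C", "D") %in% p)
      retrieved <- "E" %in% p
      if (slept && retrieved) "aligned"
      else if (!slept && !retrieved) "isolated"
      else "mixed"
    }, ""),
    triplet = vapply(cfg$fate_plan, function(p) {
      paste0("+",
             if (any(c("B", "C", "D") %in% p)) "+" else "-",
             if ("E" %in% p) "+" else "-")
    }, ""),
    f_present = vapply(cfg$fate_plan, function(p) "F" %in% p, TRUE),
    stringsAsFactors = FALSE
  )

  ss <- session_set(sessions, registry)
  gt <- list(
    engram_pattern_vectors = do.call(cbind, lapply(eng_patterns, `[[`, "vector")),
    nonengram_pattern_vectors = noneng_vectors,
    activation_times = activation_times,
    fate_labels = fate,
    engram_ids = ids[engram_idx],
    background_event_counts = bg_counts,
    kernel = kern
  )
  if (!is.null(gt$engram_pattern_vectors)) {
    dimnames(gt$engram_pattern_vectors) <- list(ids, fate$pattern)
  }
  snap <- generate_snapshot(registry, gt$engram_ids, list(
    image_size = cfg$image_size, blob_sigma = cfg$blob_sigma,
    blob_peak = cfg$blob_peak, background = cfg$background,
    noise_sd = cfg$snapshot_noise_sd))
  list(session_set = ss, ground_truth = gt, snapshot = snap)
}

# rejection-sample centroids with a minimum separation; (x, y) = (col, row)
place_centroids <- function(n, image_size, min_sep, margin) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    x <- runif(1, margin, image_size[2] - margin)
    y <- runif(1, margin, image_size[1] - margin)
    if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= min_sep^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
    tries <- tries + 1L
    if (tries > 200L * n) stop("cannot place ", n, " centroids at min_sep ",
                               min_sep, " in ", paste(image_size, collapse = "x"))
  }
  cbind(x = xs, y = ys)
}

#' Generate a synthetic reporter snapshot
#'
#' 16-bit-range grayscale image: smooth background (constant plus a gentle
#' linear gradient) with an isotropic Gaussian blob at each expressing cell's
#' centroid, plus Gaussian noise, clipped at zero.
#'
#' @param registry a [cell_registry()] with centroids in snapshot coordinates.
#' @param expressing_ids cell ids that carry the reporter.
#' @param image_cfg list: `image_size`, `blob_sigma`, `blob_peak`,
#'   `background`, `noise_sd`.
#' @return A [snapshot_image()].
#' @export
generate_snapshot <- function(registry, expressing_ids, image_cfg) {
  sz <- image_cfg$image_size
  if (!all(expressing_ids %in% registry$cell_id)) {
    stop("expressing_ids not all present in registry")
  }
  rows <- sz[1]; cols <- sz[2]
  grad <- outer(seq_len(rows) / rows, seq_len(cols) / cols, "+") / 2
  img <- image_cfg$background * (0.9 + 0.2 * grad)
  sel <- registry[registry$cell_id %in% expressing_ids, , drop = FALSE]
  sig <- image_cfg$blob_sigma
  half <- ceiling(4 * sig)
  for (i in seq_len(nrow(sel))) {
    cx <- sel$x[i]; cy <- sel$y[i]
    if (cx < 1 || cx > cols || cy < 1 || cy > rows) {
      stop("centroid outside image bounds for cell ", sel$cell_id[i])
    }
    r0 <- max(1, floor(cy - half)); r1 <- min(rows, ceiling(cy + half))
    c0 <- max(1, floor(cx - half)); c1 <- min(cols, ceiling(cx + half))
    rr <- r0:r1; cc <- c0:c1
    blob <- image_cfg$blob_peak *
      exp(-(outer((rr - cy)^2, (cc - cx)^2, "+")) / (2 * sig^2))
    img[rr, cc] <- img[rr, cc] + blob
  }
  if (image_cfg$noise_sd > 0) {
    img <- img + matrix(rnorm(rows * cols, 0, image_cfg$noise_sd), rows, cols)
  }
  snapshot_image(pmax(round(img), 0))
}

#' Shuffle a trace matrix
#'
#' Shuffling control used by the overlap and matching-score nulls:
#' `timestamps` permutes time bins independently per cell (per-cell value
#' multisets preserved), `neuron_indices` permutes row identities (per-frame
#' population totals preserved), `both` composes the two.
#'
#' @param traces a [trace_matrix()] or plain cells x frames matrix.
#' @param mode one of `"timestamps"`, `"neuron_indices"`, `"both"`.
#' @param seed optional integer seed for reproducibility.
#' @return Same type as `traces`.
#' @export
shuffle_traces <- function(traces, mode = c("timestamps", "neuron_indices", "both"),
                           seed = NULL) {
  mode <- match.arg(mode)
  is_tm <- inherits(traces, "trace_matrix")
  v <- if (is_tm) traces$values else as.matrix(traces)
  if (!length(v)) stop("empty trace matrix")
  if (!is.null(seed)) set.seed(seed)
  if (mode %in% c("timestamps", "both")) {
    for (i in seq_len(nrow(v))) v[i, ] <- v[i, sample.int(ncol(v))]
  }
  if (mode %in% c("neuron_indices", "both")) {
    rn <- rownames(v)
    v <- v[sample.int(nrow(v)), , drop = FALSE]
    rownames(v) <- rn
  }
  if (is_tm) trace_matrix(v, normalized = traces$normalized) else v
}
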