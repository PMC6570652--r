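#' Sliding-window correlation matrices
#'
#' Pearson correlation between every cell pair within a 1 s window slid in
#' 200 ms steps (defaults). Cells with zero variance inside a window get 0
#' correlations by convention (and a 0 diagonal entry), so matrix shapes stay
#' stable.
#'
#' @param traces a [trace_matrix()] or cells x frames matrix.
#' @param frame_rate_hz frames per second.
#' @param window_s,step_s window length and step, in seconds; both must map to
#'   whole frame counts.
#' @return A `corr_window_series`: list with `matrices` (list of N x N
#'   correlation matrices), `midpoints` (seconds, window midpoints),
#'   `window_s`, `step_s`, `n_cells`.
#' @export
sliding_correlations <- function(traces, frame_rate_hz,
                                 window_s = 1.0, step_s = 0.2) {
  v <- if (inherits(traces, "trace_matrix")) traces$values else as.matrix(traces)
  w <- window_s * frame_rate_hz
  s <- step_s * frame_rate_hz
  if (abs(w - round(w)) > 1e-9 || abs(s - round(s)) > 1e-9) {
    stop("window_s and step_s must map to integer frame counts")
  }
  w <- as.integer(round(w)); s <- as.integer(round(s))
  nf <- ncol(v)
  if (nf < w) stop("trace too short for a ", window_s, " s window")
  starts <- seq(1L, nf - w + 1L, by = s)
  mats <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    seg <- v[, starts[k]:(starts[k] + w - 1L), drop = FALSE]
    sds <- apply(seg, 1, sd)
    C <- suppressWarnings(cor(t(seg)))
    C[!is.finite(C)] <- 0
    zero <- sds == 0
    C[zero, ] <- 0
    C[, zero] <- 0
    mats[[k]] <- C
  }
  structure(list(matrices = mats,
                 midpoints = (starts - 1 + (w - 1) / 2) / frame_rate_hz,
                 window_s = window_s, step_s = step_s, n_cells = nrow(v)),
            class = "corr_window_series")
}

#' Correlation-matrix overlap
#'
#' Overlap between the correlation structure at two window midpoints:
#' `M(t, t') = (1/(N(N-1))) * sum_{i != j} C_ij^t C_ij^{t'}` (both orders of
#' each pair counted). `M_total(t) = sum_{t'} M(t, t')` measures how often the
#' correlation pattern at `t` recurs over the analysis span, and
#' `repetition_sum` is its sum over `t`. The self term `t' = t` is included;
#' it cancels in group ratio comparisons.
#'
#' @param cw a `corr_window_series` from [sliding_correlations()].
#' @param span_s restrict to windows with midpoint `<= span_s` (default 60;
#'   `Inf` for all).
#' @return An `overlap_result`: list with `M`, `M_total`, `repetition_sum`,
#'   `midpoints`, `n_cells`.
#' @export
overlap_matrix <- function(cw, span_s = 60) {
  stopifnot(inherits(cw, "corr_window_series"))
  N <- cw$n_cells
  if (N < 2) stop("need at least 2 cells")
  keep <- which(cw$midpoints <= span_s)
  if (length(keep) < 2) stop("need at least 2 windows inside the span")
  # flatten each correlation matrix (diagonal zeroed) into a row
  X <- t(vapply(cw$matrices[keep], function(C) {
    diag(C) <- 0
    as.vector(C)
  }, numeric(N * N)))
  M <- (X %*% t(X)) / (N * (N - 1))
  M_total <- rowSums(M)
  structure(list(M = M, M_total = M_total, repetition_sum = sum(M_total),
                 midpoints = cw$midpoints[keep], n_cells = N),
            class = "overlap_result")
}

# full pipeline: traces -> repetition_sum over the span
repetition_sum_of <- function(traces, frame_rate_hz, window_s = 1, step_s = 0.2,
                              span_s = 60) {
  cw <- sliding_correlations(traces, frame_rate_hz, window_s, step_s)
  overlap_matrix(cw, span_s)$repetition_sum
}

#' Shuffle null for the repetition statistic
#'
#' Monte-Carlo null of `repetition_sum`: each resample applies an independent
#' per-cell time randomization (default circular shift, which preserves each
#' cell's autocorrelation while destroying cross-cell timing; `"permute"`
#' permutes bins per cell), recomputes the overlap pipeline and collects the
#' statistic.
#'
#' @param traces cells x frames matrix or [trace_matrix()].
#' @param frame_rate_hz frames per second.
#' @param n_shuffles number of resamples (study default 10000).
#' @param seed integer seed.
#' @param scope `"circular"` (default) or `"permute"`.
#' @param window_s,step_s,span_s forwarded to the overlap pipeline.
#' @return List with `null` (numeric vector), `observed`, `percentile` of the
#'   observed value in the null.
#' @export
overlap_shuffle_null <- function(traces, frame_rate_hz, n_shuffles = 10000,
                                 seed = NULL, scope = c("circular", "permute"),
                                 window_s = 1, step_s = 0.2, span_s = 60) {
  scope <- match.arg(scope)
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  v <- if (inherits(traces, "trace_matrix")) traces$values else as.matrix(traces)
  if (!is.null(seed)) set.seed(seed)
  observed <- repetition_sum_of(v, frame_rate_hz, window_s, step_s, span_s)
  nf <- ncol(v)
  null <- vapply(seq_len(n_shuffles), function(b) {
    sh <- v
    if (scope == "circular") {
      off <- sample.int(nf, nrow(v), replace = TRUE)
      for (i in seq_len(nrow(v))) {
        k <- off[i] %% nf
        if (k > 0) sh[i, ] <- v[i, c((nf - k + 1):nf, 1:(nf - k))]
      }
    } else {
      for (i in seq_len(nrow(v))) sh[i, ] <- v[i, sample.int(nf)]
    }
    repetition_sum_of(sh, frame_rate_hz, window_s, step_s, span_s)
  }, 0)
  list(null = null, observed = observed,
       percentile = mean(null < observed) * 100)
}

#' Per-group repetition report
#'
#' Repetition sums for the engram and non-engram groups of the learning
#' session, plus a shuffled-engram control, expressed relative to the
#' non-engram sum (the per-animal quantities behind the group-ratio figure).
#'
#' @param sset a [session_set()] containing session A.
#' @param labels named vector `cell_id -> "engram"/"non_engram"`.
#' @param n_shuffles shuffles for the engram null (default 1000).
#' @param seed integer seed.
#' @param span_s analysis span in seconds (default 60).
#' @param window_s,step_s window parameters.
#' @return List with per-group `repetition_sum`, `engram_ratio`,
#'   `shuffled_engram_ratio`, `null_percentile` (observed engram value's
#'   percentile in its shuffle null).
#' @export
repetition_report <- function(sset, labels, n_shuffles = 1000, seed = NULL,
                              span_s = 60, window_s = 1, step_s = 0.2) {
  stopifnot(inherits(sset, "session_set"))
  sessA <- get_session(sset, "A")
  g <- group_traces(sessA, sset$registry, labels)
  if (nrow(g$engram) < 2 || nrow(g$non_engram) < 2) {
    stop("each group needs at least 2 cells")
  }
  fr <- sessA$frame_rate_hz
  rs_e <- repetition_sum_of(g$engram, fr, window_s, step_s, span_s)
  rs_n <- repetition_sum_of(g$non_engram, fr, window_s, step_s, span_s)
  nul <- overlap_shuffle_null(g$engram, fr, n_shuffles = n_shuffles,
                              seed = seed, window_s = window_s,
                              step_s = step_s, span_s = span_s)
  list(repetition_sum = c(engram = rs_e, non_engram = rs_n,
                          shuffled_engram = mean(nul$null)),
       engram_ratio = rs_e / rs_n,
       shuffled_engram_ratio = mean(nul$null) / rs_n,
       null_percentile = nul$percentile)
}
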