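#' Factorize population activity into co-activation patterns
#'
#' Non-negative matrix factorization of the cells x frames data matrix `D`
#' into a cells x K pattern matrix `B` (each column one synchronously active
#' sub-ensemble) and a K x frames intensity matrix `H` (when each ensemble
#' activates and how strongly), minimizing the squared Frobenius cost
#' `E = sum((D - BH)^2)`. Each restart draws random non-negative initial
#' matrices, runs multiplicative (Lee-Seung) updates to near-convergence and
#' then a projected-gradient refinement; the restart with the lowest cost
#' wins. Negative entries of `D` (possible in dF/F) violate non-negativity
#' and are clipped at zero, with the clipped fraction recorded.
#'
#' @param D cells x frames matrix (or [trace_matrix()]).
#' @param K number of patterns (>= 1).
#' @param restarts random restarts (study-scale default 1000; use ~50 for
#'   desk-scale work).
#' @param seed optional integer seed (governs all restarts).
#' @param tol relative cost-decrease tolerance terminating the multiplicative
#'   phase.
#' @param max_iter cap on multiplicative iterations per restart.
#' @param pg_iter cap on projected-gradient refinement steps.
#' @return An `nmf_decomposition`: list with `B`, `H`, `E`, `K`, `D`,
#'   `restarts_used`, `cost_trace` (per-iteration cost of the winning
#'   restart), `clipped_fraction`, `seed`.
#' @export
nmf_factorize <- function(D, K, restarts = 1000, seed = NULL,
                          tol = 1e-6, max_iter = 200, pg_iter = 100) {
  v <- if (inherits(D, "trace_matrix")) D$values else as.matrix(D)
  if (K < 1) stop("K must be >= 1")
  if (K > min(dim(v))) stop("K exceeds min(cells, frames)")
  clipped <- mean(v < 0)
  if (clipped > 0) v <- pmax(v, 0)
  if (all(v == 0)) stop("all-zero data matrix")
  if (!is.null(seed)) set.seed(seed)
  fit <- .cpp_nmf(v, as.integer(K), as.integer(restarts),
                  as.integer(max_iter), tol, as.integer(pg_iter))
  structure(list(B = fit$B, H = fit$H, E = fit$E, K = K, D = v,
                 restarts_used = fit$restarts_used,
                 cost_trace = fit$cost_trace,
                 clipped_fraction = clipped, seed = seed),
            class = "nmf_decomposition")
}

#' @export
print.nmf_decomposition <- function(x, ...) {
  cat(sprintf("<nmf_decomposition> K = %d, %d cells x %d frames, E = %.4g\n",
              x$K, nrow(x$B), ncol(x$H), x$E))
  invisible(x)
}

#' Corrected Akaike information criterion for an NMF fit
#'
#' Gaussian-residual form:
#' `AICc = n * log(E/n) + 2p + 2p(p+1)/(n - p - 1)`, with `n` the number of
#' observed matrix entries (cells x frames) and `p` the parameter count of a
#' rank-K factorization. An `E` floor guards the `E -> 0` limit.
#'
#' @param E residual sum of squares.
#' @param n_obs number of observations (cells x frames).
#' @param n_params parameter count (see [select_num_patterns()] for the
#'   convention used).
#' @param e_floor lower guard on `E` (default 1e-12); flagged via attribute
#'   `floored` when it bites.
#' @return AICc value.
#' @export
aicc <- function(E, n_obs, n_params, e_floor = 1e-12) {
  if (n_obs <= n_params + 1) {
    stop("infeasible: n_obs must exceed n_params + 1")
  }
  floored <- E < e_floor
  E <- max(E, e_floor)
  structure(n_obs * log(E / n_obs) + 2 * n_params +
              2 * n_params * (n_params + 1) / (n_obs - n_params - 1),
            floored = floored)
}

#' Select the number of patterns by AICc
#'
#' Fits each candidate K with [nmf_factorize()], scores the best-of-restarts
#' cost with [aicc()] and returns the minimizer (ties go to the smaller K).
#' The parameter count is `p = K (N + T)` by default; `gauge = "minus1"`
#' uses `K (N + T - 1)`, discounting the per-pattern scale gauge.
#'
#' @param D cells x frames matrix.
#' @param k_range integer vector of candidate K.
#' @param restarts,seed,tol,max_iter,pg_iter forwarded to [nmf_factorize()].
#' @param gauge `"none"` (default) or `"minus1"` parameter-count convention.
#' @return A `model_selection`: list with `k_range`, `E`, `aicc`, `best_k`,
#'   `fit` (the winning decomposition), `infeasible` (K values skipped).
#' @export
select_num_patterns <- function(D, k_range, restarts = 50, seed = NULL,
                                tol = 1e-6, max_iter = 200, pg_iter = 100,
                                gauge = c("none", "minus1")) {
  gauge <- match.arg(gauge)
  v <- if (inherits(D, "trace_matrix")) D$values else as.matrix(D)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stop("empty k_range")
  if (!is.null(seed)) set.seed(seed)
  n_obs <- prod(dim(v))
  N <- nrow(v); Tt <- ncol(v)
  Es <- As <- rep(NA_real_, length(k_range))
  fits <- vector("list", length(k_range))
  infeasible <- logical(length(k_range))
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    p <- if (gauge == "none") K * (N + Tt) else K * (N + Tt - 1)
    if (K > min(N, Tt) || n_obs <= p + 1) {
      infeasible[i] <- TRUE
      next
    }
    fit <- nmf_factorize(v, K, restarts = restarts, tol = tol,
                         max_iter = max_iter, pg_iter = pg_iter)
    Es[i] <- fit$E
    As[i] <- as.numeric(aicc(fit$E, n_obs, p))
    fits[[i]] <- fit
  }
  if (all(infeasible)) stop("no feasible K in k_range")
  best_i <- which(As == min(As, na.rm = TRUE))[1]  # ties -> smallest K
  structure(list(k_range = k_range, E = Es, aicc = As,
                 best_k = k_range[best_i], fit = fits[[best_i]],
                 infeasible = k_range[infeasible]),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> K* = %d over {%s}\n", x$best_k,
              paste(x$k_range, collapse = ",")))
  invisible(x)
}

#' Normalize an NMF decomposition
#'
#' Rescales every pattern column of `B` to unit L2 norm and absorbs the scale
#' into the matching row of `H`, leaving the reconstruction `BH` unchanged.
#' All-zero pattern columns are dropped (with a warning) and `K` decremented.
#'
#' @param d an `nmf_decomposition`.
#' @return The normalized decomposition.
#' @export
normalize_patterns <- function(d) {
  stopifnot(inherits(d, "nmf_decomposition"))
  nrm <- sqrt(colSums(d$B^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero pattern column(s) dropped")
    d$B <- d$B[, !zero, drop = FALSE]
    d$H <- d$H[!zero, , drop = FALSE]
    nrm <- nrm[!zero]
    d$K <- ncol(d$B)
  }
  d$B <- sweep(d$B, 2, nrm, "/")
  d$H <- sweep(d$H, 1, nrm, "*")
  d
}

#' Fit pattern sets for every session and group
#'
#' Runs AICc model-order selection plus factorization separately for the
#' engram and non-engram cells of each session, returning unit-norm pattern
#' sets keyed `[[group]][[session]]` — the input shape the matching-score and
#' fate operations expect.
#'
#' @param sset a [session_set()].
#' @param labels named vector `cell_id -> "engram"/"non_engram"`.
#' @param k_range candidate pattern counts.
#' @param restarts,seed forwarded to [select_num_patterns()].
#' @param groups which cell groups to fit (default both).
#' @param ... further arguments to [select_num_patterns()].
#' @return List `patterns[[group]][[label]]` of cells x K unit-column
#'   matrices, with attribute `selection` holding each `model_selection`.
#' @export
fit_session_patterns <- function(sset, labels, k_range = 1:6, restarts = 50,
                                 seed = NULL,
                                 groups = c("engram", "non_engram"), ...) {
  stopifnot(inherits(sset, "session_set"))
  if (!is.null(seed)) set.seed(seed)
  groups <- match.arg(groups, several.ok = TRUE)
  out <- setNames(vector("list", length(groups)), groups)
  sel <- setNames(vector("list", length(groups)), groups)
  for (grp in groups) {
    out[[grp]] <- list()
    sel[[grp]] <- list()
    for (lab in names(sset$sessions)) {
      g <- group_traces(sset$sessions[[lab]], sset$registry, labels)[[grp]]
      ms <- select_num_patterns(g, k_range = k_range, restarts = restarts, ...)
      nd <- normalize_patterns(ms$fit)
      out[[grp]][[lab]] <- nd$B
      sel[[grp]][[lab]] <- ms
    }
  }
  attr(out, "selection") <- sel
  out
}
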