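#' Restricted Mahalanobis population-vector distance
#'
#' Distance between the population-activity distributions of two sessions for
#' one cell group. Frames are samples; the covariance is taken over the pooled
#' (union) sample with the pooled mean. With eigenpairs `(lambda_i, v_i)` of
#' that covariance, each eigendimension contributes
#' `s_i = (v_i' (mu_X - mu_Y))^2 / lambda_i`, and the distance is the square
#' root of the sum of the `dims` largest `s_i` — the maximum over a bijective
#' reordering of eigendimensions reduces to picking the largest terms.
#' Restricting to a fixed number of dimensions makes groups with different
#' cell counts comparable.
#'
#' @param X,Y frames x cells matrices (same cells, same order).
#' @param dims number of eigendimensions retained (default 10).
#' @param eigen_floor eigenvalues at or below this are excluded from
#'   candidacy; default `1e-10 * trace(cov)/ncol`.
#' @return Numeric distance with attributes `dims_used` (how many terms were
#'   summed) and `eigen_floor`.
#' @export
restricted_mahalanobis <- function(X, Y, dims = 10, eigen_floor = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must share the same cell set")
  if (nrow(X) < 2 || nrow(Y) < 2) stop("need >= 2 samples per session")
  pooled <- rbind(X, Y)
  C <- cov(pooled)
  if (is.null(eigen_floor)) {
    eigen_floor <- 1e-10 * sum(diag(C)) / ncol(C)
  }
  eg <- eigen(C, symmetric = TRUE)
  usable <- which(eg$values > eigen_floor)
  dmu <- colMeans(X) - colMeans(Y)
  s <- (as.numeric(crossprod(eg$vectors[, usable, drop = FALSE], dmu)))^2 /
    eg$values[usable]
  k <- min(dims, length(s))
  if (k < 1) {
    d <- 0
    k <- 0L
  } else {
    d <- sqrt(sum(sort(s, decreasing = TRUE)[seq_len(k)]))
  }
  structure(d, dims_used = k, eigen_floor = eigen_floor,
            truncated = k < dims)
}

#' Cross-session population-vector distance profile
#'
#' Restricted Mahalanobis distance of every session's population vectors to
#' the learning session (A), separately for the engram and non-engram groups,
#' plus the per-session non-engram minus engram difference.
#'
#' @param sset a [session_set()] containing session A.
#' @param labels named vector `cell_id -> "engram"/"non_engram"`.
#' @param dims eigendimensions retained (default 10).
#' @param bin_frames optional temporal binning of population vectors (frames
#'   per bin; default 1 = per-frame vectors).
#' @return A `pvd_result`: data.frame with columns `session`, `engram`,
#'   `non_engram`, `difference`, plus attribute `dims`.
#' @export
pvd_profile <- function(sset, labels, dims = 10, bin_frames = 1) {
  stopifnot(inherits(sset, "session_set"))
  if (!"A" %in% names(sset$sessions)) stop("missing session A")
  pv <- function(sess, group) {
    g <- group_traces(sess, sset$registry, labels)[[group]]
    m <- t(g)                                  # frames x cells
    if (bin_frames > 1) {
      nb <- nrow(m) %/% bin_frames
      m <- m[seq_len(nb * bin_frames), , drop = FALSE]
      grp <- rep(seq_len(nb), each = bin_frames)
      m <- rowsum(m, grp) / bin_frames
    }
    m
  }
  others <- setdiff(names(sset$sessions), "A")
  out <- data.frame(session = others, engram = NA_real_,
                    non_engram = NA_real_, stringsAsFactors = FALSE)
  for (grp in c("engram", "non_engram")) {
    A <- pv(get_session(sset, "A"), grp)
    for (r in seq_along(others)) {
      S <- pv(get_session(sset, others[r]), grp)
      out[[grp]][r] <- as.numeric(restricted_mahalanobis(S, A, dims = dims))
    }
  }
  out$difference <- out$non_engram - out$engram
  structure(out, dims = dims, class = c("pvd_result", "data.frame"))
}
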