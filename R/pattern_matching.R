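#' Cosine similarity between non-negative pattern vectors
#'
#' `v . w / (||v|| ||w||)`; for unit vectors this is the plain dot product.
#' Non-negative inputs give values in \[0, 1\].
#'
#' @param v,w numeric vectors of equal length, not all-zero.
#' @return Cosine similarity.
#' @export
cosine_sim <- function(v, w) {
  nv <- sqrt(sum(v^2)); nw <- sqrt(sum(w^2))
  if (nv == 0 || nw == 0) stop("zero vector in cosine similarity")
  sum(v * w) / (nv * nw)
}

# columnwise cosine matrix between two pattern matrices (cells x K each)
cosine_cross <- function(X, Y) {
  Xn <- sweep(X, 2, pmax(sqrt(colSums(X^2)), .Machine$double.eps), "/")
  Yn <- sweep(Y, 2, pmax(sqrt(colSums(Y^2)), .Machine$double.eps), "/")
  crossprod(Xn, Yn)
}

#' Matching score between two pattern sets
#'
#' Fraction of patterns in session X with at least one partner in session Y
#' whose cosine similarity strictly exceeds `c`:
#' `MS(X,Y) = (1/N_X) sum_i Theta[ sum_j Theta(v_i . v_j - c) - d ]`, with
#' `Theta` the strict step function and `d` any constant in (0, 1) (the inner
#' sum is an integer, so every such `d` is equivalent). Asymmetric in (X, Y).
#'
#' @param X,Y cells x K matrices of pattern columns (same cell ordering).
#' @param c cosine threshold (study value 0.6; strict: a cosine of exactly
#'   `c` does not count).
#' @param d step constant in (0, 1); default 0.5.
#' @return A `match_result`: list with `ms`, `n_x`, `matched` (logical per X
#'   pattern), `best_cosine`, `best_partner`, `c`, `d`.
#' @export
matching_score <- function(X, Y, c = 0.6, d = 0.5) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) < 1) stop("empty pattern set X")
  if (nrow(X) != nrow(Y)) stop("pattern sets must share the cell ordering")
  if (d <= 0 || d >= 1) stop("d must lie in (0, 1)")
  S <- cosine_cross(X, Y)
  inner <- rowSums(S > c)
  matched <- (inner - d) > 0
  best <- apply(S, 1, which.max)
  structure(list(ms = mean(matched), n_x = ncol(X), matched = matched,
                 best_cosine = S[cbind(seq_len(nrow(S)), best)],
                 best_partner = best, c = c, d = d),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> MS = %.3f (%d/%d patterns matched, c = %g)\n",
              x$ms, sum(x$matched), x$n_x, x$c))
  invisible(x)
}

#' Shuffle null and normalized matching score
#'
#' For each resample, both raw session matrices are shuffled in timestamps and
#' neuron indices, re-factorized with the same AICc K-selection procedure, and
#' the MS recomputed. Returns the observed MS, the shuffle mean/sd, and the
#' normalized MS (observed minus shuffle mean).
#'
#' @param D_X,D_Y raw cells x frames matrices of the two sessions (one cell
#'   group; shuffling precedes factorization).
#' @param k_range candidate K values for selection.
#' @param restarts NMF restarts per fit.
#' @param n_shuffles number of resamples (study value 40).
#' @param seed integer seed.
#' @param c,d matching-score parameters.
#' @param freeze_k if not `NULL`, skip per-shuffle K re-selection and use this
#'   fixed K instead.
#' @return List with `observed`, `shuffled` (vector), `shuffle_mean`,
#'   `shuffle_sd`, `normalized`.
#' @export
ms_shuffle_null <- function(D_X, D_Y, k_range = 1:6, restarts = 50,
                            n_shuffles = 40, seed = NULL, c = 0.6, d = 0.5,
                            freeze_k = NULL) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  fit_patterns <- function(M) {
    if (is.null(freeze_k)) {
      ms <- select_num_patterns(M, k_range = k_range, restarts = restarts)
      normalize_patterns(ms$fit)$B
    } else {
      normalize_patterns(nmf_factorize(M, freeze_k, restarts = restarts))$B
    }
  }
  obs <- matching_score(fit_patterns(D_X), fit_patterns(D_Y), c = c, d = d)$ms
  shuf <- vapply(seq_len(n_shuffles), function(b) {
    sx <- shuffle_traces(D_X, mode = "both")
    sy <- shuffle_traces(D_Y, mode = "both")
    matching_score(fit_patterns(sx), fit_patterns(sy), c = c, d = d)$ms
  }, 0)
  list(observed = obs, shuffled = shuf, shuffle_mean = mean(shuf),
       shuffle_sd = sd(shuf), normalized = obs - mean(shuf))
}

#' Matching-score profile across sessions
#'
#' `MS(A, S)` for every non-learning session S, per cell group, plus the
#' engram minus non-engram difference.
#'
#' @param patterns list `[[group]][[session]]` of cells x K unit-column
#'   pattern matrices (see [fit_session_patterns()]).
#' @param c cosine threshold (default 0.6; raise to e.g. 0.7 for the
#'   sensitivity variant).
#' @param d step constant.
#' @return data.frame with columns `session`, `engram`, `non_engram`,
#'   `difference`.
#' @export
ms_profile <- function(patterns, c = 0.6, d = 0.5) {
  for (grp in c("engram", "non_engram")) {
    if (is.null(patterns[[grp]]) || is.null(patterns[[grp]][["A"]])) {
      stop("missing session A pattern set for group ", grp)
    }
  }
  sess <- setdiff(names(patterns$engram), "A")
  out <- data.frame(session = sess, engram = NA_real_, non_engram = NA_real_,
                    stringsAsFactors = FALSE)
  for (grp in c("engram", "non_engram")) {
    A <- patterns[[grp]][["A"]]
    for (r in seq_along(sess)) {
      Y <- patterns[[grp]][[sess[r]]]
      if (is.null(Y)) stop("missing session ", sess[r], " for group ", grp)
      out[[grp]][r] <- matching_score(A, Y, c = c, d = d)$ms
    }
  }
  out$difference <- out$engram - out$non_engram
  out
}

#' Classify cross-session pattern fates
#'
#' Tracks every learning-session (A) pattern: it is "present" in a later
#' session iff some pattern there has cosine similarity strictly above `c`.
#' Fate triplets cover (learning, sleep, retrieval): sleep uses NREM (B or C)
#' in one variant and REM (D) in the other, mirroring the two figure panels.
#' `aligned` = persists through sleep into retrieval (`+++`); `isolated` =
#' learning only (`+--`); the two mixed triplets (`++-`, `+-+`) complete the
#' partition. F-context presence is reported alongside.
#'
#' @param patterns list `[[group]][[session]]` of pattern matrices.
#' @param c cosine threshold (default 0.6).
#' @return A `fate_table`: list with one data.frame per sleep variant
#'   (`NREM`, `REM`) carrying per-pattern rows (`group`, `pattern`, presence
#'   flags, `triplet`, `category`, `f_present`) and a `fractions` table of
#'   per-group category fractions (each group's fractions sum to 1).
#' @export
classify_fates <- function(patterns, c = 0.6) {
  need <- c("A", "E")
  groups <- intersect(c("engram", "non_engram"), names(patterns))
  if (!length(groups)) stop("patterns must carry an engram and/or non_engram group")
  for (grp in groups) {
    miss <- setdiff(need, names(patterns[[grp]]))
    if (length(miss)) stop("missing required session(s) ",
                           paste(miss, collapse = ","), " for ", grp)
  }
  has_nrem <- any(c("B", "C") %in% names(patterns$engram))
  has_rem <- "D" %in% names(patterns$engram)
  if (!has_nrem && !has_rem) stop("missing required sleep session (B/C or D)")

  present_in <- function(A, Y) {
    if (is.null(Y) || ncol(Y) == 0) return(rep(FALSE, ncol(A)))
    apply(cosine_cross(A, Y) > c, 1, any)
  }
  variant <- function(sleep_labels) {
    rows <- list()
    for (grp in groups) {
      A <- patterns[[grp]][["A"]]
      sleep <- rep(FALSE, ncol(A))
      for (sl in intersect(sleep_labels, names(patterns[[grp]]))) {
        sleep <- sleep | present_in(A, patterns[[grp]][[sl]])
      }
      retr <- present_in(A, patterns[[grp]][["E"]])
      fpr <- if ("F" %in% names(patterns[[grp]])) {
        present_in(A, patterns[[grp]][["F"]])
      } else rep(NA, ncol(A))
      triplet <- paste0("+", ifelse(sleep, "+", "-"), ifelse(retr, "+", "-"))
      category <- ifelse(sleep & retr, "aligned",
                         ifelse(!sleep & !retr, "isolated", "mixed"))
      rows[[grp]] <- data.frame(group = grp,
                                pattern = seq_len(ncol(A)),
                                sleep = sleep, retrieval = retr,
                                triplet = triplet, category = category,
                                f_present = fpr, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  variants <- list()
  if (has_nrem) variants$NREM <- variant(c("B", "C"))
  if (has_rem) variants$REM <- variant("D")

  fractions <- do.call(rbind, lapply(names(variants), function(vn) {
    df <- variants[[vn]]
    do.call(rbind, lapply(split(df, df$group), function(g) {
      tab <- table(factor(g$triplet, levels = c("+++", "++-", "+-+", "+--")))
      data.frame(variant = vn, group = g$group[1],
                 triplet = names(tab),
                 fraction = as.numeric(tab) / nrow(g),
                 count = as.integer(tab),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(fractions) <- NULL
  structure(c(variants, list(fractions = fractions)), class = "fate_table")
}

#' @export
print.fate_table <- function(x, ...) {
  cat("<fate_table>\n")
  print(x$fractions)
  invisible(x)
}

#' Cross-session pattern network
#'
#' Graph with one node per (session, pattern) and an edge between patterns of
#' *different* sessions whose cosine similarity strictly exceeds `c`.
#' Connected components summarize pattern lineages.
#'
#' @param patterns_by_session named list `[[session]]` of cells x K pattern
#'   matrices for one cell group.
#' @param c cosine threshold (default 0.6).
#' @return List with `graph` (igraph object), `edges` (data.frame
#'   src_session, src_pattern, dst_session, dst_pattern, cosine),
#'   `components` (membership vector).
#' @export
pattern_network <- function(patterns_by_session, c = 0.6) {
  sess <- names(patterns_by_session)
  if (length(sess) < 2) stop("need at least 2 sessions")
  nodes <- do.call(rbind, lapply(sess, function(s) {
    k <- ncol(patterns_by_session[[s]])
    if (k == 0) return(NULL)
    data.frame(session = s, pattern = seq_len(k),
               name = sprintf("%s_p%d", s, seq_len(k)),
               stringsAsFactors = FALSE)
  }))
  edges <- list()
  for (a in seq_along(sess)) for (b in seq_along(sess)) {
    if (b <= a) next
    S <- cosine_cross(patterns_by_session[[sess[a]]],
                      patterns_by_session[[sess[b]]])
    hit <- which(S > c, arr.ind = TRUE)
    if (nrow(hit)) {
      edges[[length(edges) + 1]] <- data.frame(
        src_session = sess[a], src_pattern = hit[, 1],
        dst_session = sess[b], dst_pattern = hit[, 2],
        cosine = S[hit], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(src_session = character(), src_pattern = integer(),
               dst_session = character(), dst_pattern = integer(),
               cosine = numeric(), stringsAsFactors = FALSE)
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes$name)
  if (nrow(edges)) {
    ename <- rbind(sprintf("%s_p%d", edges$src_session, edges$src_pattern),
                   sprintf("%s_p%d", edges$dst_session, edges$dst_pattern))
    g <- igraph::add_edges(g, as.vector(ename), cosine = edges$cosine)
  }
  comp <- igraph::components(g)$membership
  list(graph = g, edges = edges, components = comp)
}
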