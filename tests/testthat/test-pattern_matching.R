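test_that("cosine similarity basics", {
  expect_equal(cosine_sim(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_sim(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosine_sim(c(1, 1, 0) / sqrt(2), c(1, 0, 0)), 1 / sqrt(2))
  expect_error(cosine_sim(c(0, 0), c(1, 1)), "zero vector")
})

test_that("matching score: identity, hand case, disjoint sets, strict threshold", {
  set.seed(101)
  X <- matrix(runif(12 * 3), 12, 3)
  X <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  expect_equal(matching_score(X, X)$ms, 1)

  # two X patterns with best cosines {0.9, 0.4} to Y -> MS = 0.5
  e1 <- c(1, rep(0, 5)); e2 <- c(0, 1, rep(0, 4))
  x1 <- e1
  x2 <- e2
  y1 <- 0.9 * e1 + sqrt(1 - 0.81) * c(0, 0, 1, 0, 0, 0)
  y2 <- 0.4 * e2 + sqrt(1 - 0.16) * c(0, 0, 0, 1, 0, 0)
  ms <- matching_score(cbind(x1, x2), cbind(y1, y2))
  expect_equal(ms$ms, 0.5)
  expect_identical(unname(ms$matched), c(TRUE, FALSE))

  # disjoint supports -> 0
  A <- diag(6)[, 1:3]; B <- diag(6)[, 4:6]
  expect_equal(matching_score(A, B)$ms, 0)

  # a cosine of exactly c does not count (strict step function)
  v <- c(1, 0); w <- c(0.6, 0.8)   # cosine exactly 0.6
  expect_equal(matching_score(cbind(v), cbind(w), c = 0.6)$ms, 0)
  expect_equal(matching_score(cbind(v), cbind(w), c = 0.6 - 1e-9)$ms, 1)
})

test_that("MS lies in [0,1] and is non-increasing in c", {
  set.seed(102)
  X <- matrix(runif(20 * 5), 20, 5)
  Y <- matrix(runif(20 * 7), 20, 7)
  cs <- seq(0.1, 0.95, by = 0.05)
  mss <- vapply(cs, function(cc) matching_score(X, Y, c = cc)$ms, 0)
  expect_true(all(mss >= 0 & mss <= 1))
  expect_true(all(diff(mss) <= 0))
})

test_that("ms_profile reports per-session scores and differences", {
  set.seed(103)
  V <- matrix(runif(15 * 3), 15, 3)
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  pats <- list(engram = list(A = V, B = V, E = V),
               non_engram = list(A = V, B = V, E = V))
  prof <- ms_profile(pats)
  expect_equal(prof$engram, c(1, 1))
  expect_equal(prof$difference, c(0, 0))
  pats$non_engram$B <- diag(15)[, 1:3] # disjoint from V? not guaranteed; force
  pats$non_engram$A <- diag(15)[, 4:6]
  pats$non_engram$E <- diag(15)[, 7:9]
  prof2 <- ms_profile(pats)
  expect_equal(prof2$non_engram, c(0, 0))
  expect_error(ms_profile(list(engram = list(B = V))), "session A")
})

test_that("fate classification recovers planted categories exactly at high SNR", {
  # planted: 2 aligned, 2 isolated, 2 mixed engram patterns, no noise
  plan <- make_fate_plan(c("aligned", "aligned", "isolated", "isolated",
                           "mixed", "mixed"), f_shared_fraction = 0.5)
  cfg <- synth_config(
    n_cells = 40, engram_fraction = 1, n_engram_patterns = 6,
    n_nonengram_patterns = 0, pattern_size = c(5, 6),
    session_plan = data.frame(
      label = c("A", "B", "C", "D", "E", "F"),
      stage = c("awake", "NREM", "NREM", "REM", "awake", "awake"),
      duration_s = c(30, 15, 15, 15, 20, 20)),
    event_rate_hz = 0, pattern_activation_rate_hz = 0.3, noise_sd = 0,
    fate_plan = plan, image_size = c(300, 300), seed = 111)
  e <- generate_experiment(cfg)
  truth <- e$ground_truth$engram_pattern_vectors
  pats <- list(engram = lapply(names(e$session_set$sessions), function(lab) {
    keep <- vapply(cfg$fate_plan, function(p) lab %in% p, TRUE)
    truth[, keep, drop = FALSE]
  }))
  names(pats$engram) <- names(e$session_set$sessions)
  ft <- classify_fates(pats)
  got <- table(ft$NREM$category[ft$NREM$group == "engram"])
  expect_identical(as.integer(got[c("aligned", "isolated", "mixed")]),
                   c(2L, 2L, 2L))
  # triplet conventions
  expect_setequal(ft$NREM$triplet[ft$NREM$category == "aligned"], "+++")
  expect_setequal(ft$NREM$triplet[ft$NREM$category == "isolated"], "+--")
  # fractions partition session-A patterns
  fr <- ft$fractions
  for (vn in unique(fr$variant)) {
    expect_equal(sum(fr$fraction[fr$variant == vn & fr$group == "engram"]), 1)
  }
  # F presence follows the plan: 1 of 2 aligned patterns shared with F
  expect_identical(sum(ft$NREM$f_present[ft$NREM$group == "engram"]), 1L)
})

test_that("fate classification trivial cases", {
  v <- c(1, 0, 0, 0)
  pats <- list(engram = list(A = cbind(v), B = cbind(v), D = cbind(v),
                             E = cbind(v)),
               non_engram = list(A = cbind(c(0, 1, 0, 0)),
                                 B = cbind(c(0, 0, 1, 0)),
                                 D = cbind(c(0, 0, 1, 0)),
                                 E = cbind(c(0, 0, 0, 1))))
  ft <- classify_fates(pats)
  eng <- ft$NREM[ft$NREM$group == "engram", ]
  expect_identical(eng$triplet, "+++")
  expect_identical(eng$category, "aligned")
  non <- ft$REM[ft$REM$group == "non_engram", ]
  expect_identical(non$triplet, "+--")
  expect_identical(non$category, "isolated")
  expect_error(classify_fates(list(engram = list(A = cbind(v)))),
               "missing required")
})

test_that("pattern network edges, lineages and random-vector sparsity", {
  v <- c(1, 0, 0, 0, 0)
  reps <- list(A = cbind(v), B = cbind(v), D = cbind(v), E = cbind(v))
  net <- pattern_network(reps)
  expect_equal(nrow(net$edges), 6)  # all cross-session pairs of the same vector
  expect_equal(max(net$components), 1)

  disj <- list(A = cbind(diag(6)[, 1]), B = cbind(diag(6)[, 2]))
  net0 <- pattern_network(disj)
  expect_equal(nrow(net0$edges), 0)

  # random sparse non-negative unit vectors (the shape NMF emits) rarely
  # exceed c = 0.6 in high dimension; dense non-negative vectors would not
  # satisfy this (they concentrate near cosine 2/pi)
  set.seed(104)
  mk <- function(k) {
    m <- matrix(0, 60, k)
    for (j in seq_len(k)) m[sample(60, 6), j] <- runif(6, 0.5, 1)
    sweep(m, 2, sqrt(colSums(m^2)), "/")
  }
  netr <- pattern_network(list(A = mk(20), B = mk(20)))
  expect_lt(nrow(netr$edges) / 400, 0.05)
})

test_that("shuffle-null normalized MS separates shared from independent structure", {
  # two sessions sharing planted patterns
  cfg <- synth_config(
    n_cells = 24, engram_fraction = 1, n_engram_patterns = 2,
    n_nonengram_patterns = 0, pattern_size = c(5, 6),
    session_plan = tiny_session_plan(c("A", "E"), c("awake", "awake"),
                                     c(20, 20)),
    event_rate_hz = 0.02, pattern_activation_rate_hz = 0.3, noise_sd = 0.01,
    fate_plan = list(c("A", "E"), c("A", "E")), image_size = c(200, 200),
    seed = 105)
  e <- generate_experiment(cfg)
  DX <- session_traces(e, "A"); DY <- session_traces(e, "E")
  shared <- ms_shuffle_null(DX, DY, k_range = 1:3, restarts = 15,
                            n_shuffles = 5, seed = 9)
  expect_gt(shared$normalized, 0)
  expect_error(ms_shuffle_null(DX, DY, n_shuffles = 0), "n_shuffles")

  # sessions with no shared synchrony structure (background events only):
  # normalized MS within 2 shuffle SDs of zero
  cfg2 <- synth_config(
    n_cells = 30, engram_fraction = 0.2, n_engram_patterns = 1,
    n_nonengram_patterns = 0, pattern_size = c(4, 5),
    session_plan = tiny_session_plan(c("A", "E"), c("awake", "awake"),
                                     c(20, 20)),
    event_rate_hz = 0.2, pattern_activation_rate_hz = 0.3, noise_sd = 0.01,
    fate_plan = list("A"), image_size = c(220, 220), seed = 106)
  e2 <- generate_experiment(cfg2)
  lab2 <- truth_labels(e2)
  noneng <- names(lab2)[lab2 == "non_engram"]
  DX2 <- session_traces(e2, "A")[noneng, ]
  DY2 <- session_traces(e2, "E")[noneng, ]
  indep <- ms_shuffle_null(DX2, DY2, k_range = 1:3, restarts = 15,
                           n_shuffles = 5, seed = 10)
  expect_lte(abs(indep$normalized), 2 * max(indep$shuffle_sd, 0.05))
})
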