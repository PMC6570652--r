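test_that("exact rank-1 data is factorized to machine precision", {
  set.seed(91)
  b <- runif(15); h <- runif(120)
  D <- outer(b, h)
  f <- nmf_factorize(D, 1, restarts = 10, seed = 5)
  expect_lt(f$E / sum(D^2), 1e-8)
  expect_gt(cosine_sim(f$B[, 1], b), 0.999)
  # E bookkeeping agrees with recomputation
  expect_equal(f$E, sum((D - f$B %*% f$H)^2), tolerance = 1e-8)
})

test_that("cost trace is non-increasing on random instances", {
  set.seed(92)
  for (rep in 1:8) {
    D <- matrix(rexp(20 * 60), 20, 60)
    f <- nmf_factorize(D, sample(2:4, 1), restarts = 3, seed = rep)
    tr <- f$cost_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(head(tr, -1), 1e-12)))
  }
})

test_that("planted disjoint patterns are recovered at low noise", {
  set.seed(93)
  N <- 30; Tt <- 400; K <- 2
  B <- matrix(0, N, K)
  B[1:6, 1] <- runif(6, 0.5, 1); B[11:16, 2] <- runif(6, 0.5, 1)
  H <- matrix(0, K, Tt)
  for (k in 1:K) H[k, sample(Tt, 30)] <- runif(30, 0.5, 1.5)
  D <- pmax(B %*% H + matrix(rnorm(N * Tt, 0, 0.01), N, Tt), 0)
  f <- normalize_patterns(nmf_factorize(D, K, restarts = 50, seed = 3))
  S <- abs(crossprod(sweep(B, 2, sqrt(colSums(B^2)), "/"), f$B))
  # best assignment: each planted pattern has a recovered twin
  expect_true(all(apply(S, 1, max) > 0.99))
})

test_that("errors and guards", {
  expect_error(nmf_factorize(matrix(1, 4, 4), 0), "K")
  expect_error(nmf_factorize(matrix(1, 4, 4), 5), "exceeds")
  expect_error(nmf_factorize(matrix(0, 4, 4), 2), "all-zero")
  # negative entries are clipped and the fraction recorded
  D <- matrix(c(-1, 2, 3, 4, 5, 6), 2, 3)
  f <- nmf_factorize(D, 1, restarts = 2, seed = 1)
  expect_equal(f$clipped_fraction, 1 / 6)
})

test_that("aicc matches a hand evaluation and is monotone in p", {
  E <- 37.5; n <- 4000; p <- 120
  expect_equal(as.numeric(aicc(E, n, p)),
               n * log(E / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1))
  expect_gt(as.numeric(aicc(E, n, 2 * p)), as.numeric(aicc(E, n, p)))
  expect_error(aicc(1, 10, 20), "infeasible")
  # E -> 0 is guarded by the floor
  a0 <- aicc(0, n, p)
  expect_true(is.finite(as.numeric(a0)))
  expect_true(attr(a0, "floored"))
})

test_that("select_num_patterns: singleton range and penalty dominance on noise", {
  set.seed(94)
  D <- matrix(rexp(20 * 200), 20, 200)
  ms <- select_num_patterns(D, 3, restarts = 5, seed = 1)
  expect_identical(ms$best_k, 3L)
  picks <- vapply(1:5, function(s) {
    Dn <- matrix(rexp(20 * 200), 20, 200)
    select_num_patterns(Dn, 1:3, restarts = 10, seed = s)$best_k
  }, 0L)
  expect_gte(sum(picks == 1L), 3)  # smallest K wins on structureless data
  expect_error(select_num_patterns(matrix(1, 2, 2), 10:12), "no feasible K")
})

test_that("best-of-restarts cost is non-increasing in K", {
  set.seed(95)
  D <- matrix(rexp(15 * 100), 15, 100)
  Es <- vapply(1:4, function(K) nmf_factorize(D, K, restarts = 50,
                                              seed = 7)$E, 0)
  expect_true(all(diff(Es) <= 1e-6 * Es[-length(Es)]))
})

test_that("normalize_patterns is a gauge fix leaving BH unchanged", {
  set.seed(96)
  D <- matrix(rexp(12 * 50), 12, 50)
  f <- nmf_factorize(D, 3, restarts = 5, seed = 2)
  n1 <- normalize_patterns(f)
  expect_equal(unname(colSums(n1$B^2)), rep(1, 3), tolerance = 1e-12)
  expect_lt(max(abs(f$B %*% f$H - n1$B %*% n1$H)), 1e-10)
  # idempotent, and gauge transformations are undone
  n2 <- normalize_patterns(n1)
  expect_equal(n1$B, n2$B, tolerance = 1e-12)
  g <- f; g$B[, 2] <- g$B[, 2] * 7; g$H[2, ] <- g$H[2, ] / 7
  n3 <- normalize_patterns(g)
  expect_equal(n3$B, n1$B, tolerance = 1e-9)
  # zero column dropped with warning
  z <- f; z$B[, 1] <- 0
  expect_warning(nz <- normalize_patterns(z), "dropped")
  expect_identical(nz$K, 2L)
})

test_that("recovered intensities track planted activation strength", {
  cfg <- nmf_session_config(seed = 97, n_patterns = 2, n_cells = 24,
                            duration_s = 30, noise_sd = 0.01)
  e <- generate_experiment(cfg)
  D <- session_traces(e)
  f <- normalize_patterns(nmf_factorize(D, 2, restarts = 30, seed = 4))
  gt <- e$ground_truth
  kern <- gt$kernel
  for (k in 1:2) {
    # planted intensity = activation impulse train convolved with the kernel
    imp <- numeric(ncol(D))
    tt <- round(gt$activation_times[[paste0("engram_p", k)]]$A * 20) + 1
    imp[tt] <- 1
    planted <- stats::convolve(imp, rev(kern), type = "open")[seq_len(ncol(D))]
    cors <- vapply(1:2, function(j) cor(planted, f$H[j, ]), 0)
    expect_gt(max(cors), 0.8)
  }
})
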