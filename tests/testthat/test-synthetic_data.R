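test_that("generation is deterministic under the seed", {
  cfg <- tiny_config(seed = 11)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  for (lab in names(e1$session_set$sessions)) {
    expect_identical(e1$session_set$sessions[[lab]]$traces$values,
                     e2$session_set$sessions[[lab]]$traces$values)
  }
  expect_identical(e1$snapshot$pixels, e2$snapshot$pixels)
  expect_identical(e1$ground_truth$engram_ids, e2$ground_truth$engram_ids)
})

test_that("noiseless single activation reproduces weight x kernel exactly", {
  cfg <- synth_config(
    n_cells = 10, engram_fraction = 0.5, n_engram_patterns = 1,
    n_nonengram_patterns = 0, pattern_size = c(3, 3),
    session_plan = tiny_session_plan("A", "awake", 10),
    event_rate_hz = 0, pattern_activation_rate_hz = 0,  # forced to 1 activation
    noise_sd = 0, amp_jitter_sdlog = 0, fate_plan = list("A"),
    image_size = c(120, 120), seed = 5
  )
  e <- generate_experiment(cfg)
  tr <- session_traces(e)
  gt <- e$ground_truth
  act <- gt$activation_times$engram_p1$A
  expect_length(act, 1)
  t0 <- round(act * cfg$frame_rate_hz) + 1
  kern <- gt$kernel   # peak-normalized to 1, kern[1] = 0 at the event frame
  members <- which(gt$engram_pattern_vectors[, 1] > 0)
  scales <- numeric(length(members))
  for (mi in seq_along(members)) {
    trace <- tr[members[mi], ]
    span <- t0:min(ncol(tr), t0 + length(kern) - 1)
    scales[mi] <- max(trace)        # = weight, since max(kern) = 1
    expect_equal(unname(trace[span]),
                 scales[mi] * kern[seq_along(span)], tolerance = 1e-12)
    # FFT convolution leaves ~1e-16 residue where exact zeros are expected
    expect_lt(max(trace[setdiff(seq_along(trace), span)]), 1e-10)
  }
  # member amplitudes are proportional to the planted participation weights
  w <- gt$engram_pattern_vectors[members, 1]
  expect_equal(scales / scales[1], unname(w / w[1]), tolerance = 1e-12)
  nonmembers <- setdiff(seq_len(nrow(tr)), members)
  expect_true(all(tr[nonmembers, ] == 0))  # never convolved, exactly flat
})

test_that("planted pattern vectors are non-negative unit vectors consistent with fates", {
  e <- generate_experiment(tiny_config(seed = 21, n_engram_patterns = 3,
                                       session_plan = tiny_session_plan(
                                         c("A", "B", "E"),
                                         c("awake", "NREM", "awake"),
                                         c(10, 5, 5))))
  V <- e$ground_truth$engram_pattern_vectors
  expect_true(all(V >= 0))
  expect_equal(unname(colSums(V^2)), rep(1, ncol(V)))
  # a pattern present in a session has >= 1 activation there
  ft <- e$ground_truth$fate_labels
  at <- e$ground_truth$activation_times
  for (k in seq_len(nrow(ft))) {
    acts <- at[[ft$pattern[k]]]
    expect_true("A" %in% names(acts) && length(acts$A) >= 1)
  }
})

test_that("background event counts follow the Poisson rate", {
  rate <- 0.3; dur <- 20
  counts <- unlist(lapply(1:10, function(s) {
    cfg <- tiny_config(seed = 100 + s, event_rate_hz = rate,
                       n_engram_patterns = 2, n_nonengram_patterns = 0,
                       session_plan = tiny_session_plan("A", "awake", dur))
    generate_experiment(cfg)$ground_truth$background_event_counts$A
  }))
  mu <- rate * dur
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / length(counts)))
})

test_that("infeasible configs error", {
  expect_error(tiny_config(n_cells = 10, engram_fraction = 0.1,
                           pattern_size = c(3, 4)), "infeasible")
  expect_error(tiny_config(session_plan = tiny_session_plan("A", "awake", 0.025)),
               "integral")
})

test_that("shuffle_traces preserves the right marginals", {
  set.seed(9)
  v <- matrix(rexp(8 * 50), 8, 50, dimnames = list(paste0("c", 1:8), NULL))
  st <- shuffle_traces(v, "timestamps", seed = 1)
  for (i in 1:8) expect_equal(sort(st[i, ]), sort(v[i, ]))
  sn <- shuffle_traces(v, "neuron_indices", seed = 2)
  expect_equal(colSums(sn), colSums(v))
  expect_identical(rownames(sn), rownames(v))
  sb <- shuffle_traces(v, "both", seed = 3)
  expect_equal(sort(as.vector(sb)), sort(as.vector(v)))
  expect_error(shuffle_traces(matrix(numeric(0), 0, 0)), "empty")
})

test_that("time shuffling destroys planted repetition structure", {
  cfg <- tiny_config(seed = 31, n_cells = 12, engram_fraction = 1,
                     n_engram_patterns = 2, n_nonengram_patterns = 0,
                     pattern_size = c(4, 5),
                     fate_plan = list("A", "A"),
                     pattern_activation_rate_hz = 0.5,
                     session_plan = tiny_session_plan("A", "awake", 20))
  tr <- session_traces(generate_experiment(cfg))
  orig <- repetition_sum_of(tr, 20, span_s = Inf)
  nul <- overlap_shuffle_null(tr, 20, n_shuffles = 50, seed = 7, span_s = Inf)
  expect_gt(orig, quantile(nul$null, 0.95))
  sh <- shuffle_traces(tr, "timestamps", seed = 11)
  expect_lt(repetition_sum_of(sh, 20, span_s = Inf),
            quantile(nul$null, 0.999))
})
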