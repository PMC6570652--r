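# Small synthetic worlds shared across test files. All sizes are desk-scale;
# the generator defaults themselves are study-scale.

tiny_session_plan <- function(labels = c("A", "B"),
                              stages = c("awake", "NREM"),
                              duration_s = c(10, 5)) {
  data.frame(label = labels, stage = stages, duration_s = duration_s,
             stringsAsFactors = FALSE)
}

tiny_config <- function(seed = 1, ...) {
  args <- list(
    n_cells = 20, engram_fraction = 0.25, n_engram_patterns = 2,
    n_nonengram_patterns = 1, pattern_size = c(3, 4),
    session_plan = tiny_session_plan(),
    event_rate_hz = 0.05, pattern_activation_rate_hz = 0.3,
    noise_sd = 0.02, image_size = c(150, 150), seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

# single-session, engram-only world for NMF / model-order work
nmf_session_config <- function(seed, n_patterns = 3, n_cells = 40,
                               duration_s = 60, noise_sd = 0.005,
                               event_rate_hz = 0) {
  synth_config(
    n_cells = n_cells, engram_fraction = 1, n_engram_patterns = n_patterns,
    n_nonengram_patterns = 0, pattern_size = c(6, 10),
    session_plan = tiny_session_plan("A", "awake", duration_s),
    event_rate_hz = event_rate_hz, pattern_activation_rate_hz = 0.2,
    noise_sd = noise_sd, fate_plan = rep(list("A"), n_patterns),
    image_size = c(300, 300), seed = seed
  )
}

session_traces <- function(exp, label = "A") {
  exp$session_set$sessions[[label]]$traces$values
}

truth_labels <- function(exp) {
  reg <- exp$session_set$registry
  setNames(ifelse(reg$engram_flag, "engram", "non_engram"), reg$cell_id)
}

# brute-force overlap oracle: direct double loop over the definition
brute_overlap <- function(cw, a, b) {
  C1 <- cw$matrices[[a]]; C2 <- cw$matrices[[b]]
  N <- nrow(C1); s <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i != j) s <- s + C1[i, j] * C2[i, j]
  }
  s / (N * (N - 1))
}

# gaussian blob image helper
blob_image <- function(n, centres, sigma, peak, background = 10) {
  img <- matrix(background, n, n)
  for (k in seq_len(nrow(centres))) {
    img <- img + peak * outer(seq_len(n), seq_len(n), function(i, j) {
      exp(-((i - centres[k, 2])^2 + (j - centres[k, 1])^2) / (2 * sigma^2))
    })
  }
  snapshot_image(img)
}
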