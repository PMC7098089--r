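# shared in-code fixtures for the unit tests

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a deterministic toy genome built from a fixed RNG stream
toy_genome <- function(lens = c(chrA = 6000L, chrB = 4000L), seed = 99L) {
  set.seed(seed)
  vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
}

# a tiny untrained model stack (loop model over anchor + orientation),
# cheap enough for contract tests that only need a working forward pass
tiny_stack <- function(window = 96L, seed = 5L) {
  cfg <- model_config(anchor_length = window, rnn_window = 32L,
                      scale = 1 / 32, epochs = 2L, batch_size = 16L,
                      patience = 2L)
  cnn <- build_model("cnn_anchor", cfg, seed = seed)
  rnn <- build_model("rnn_anchor", cfg, seed = seed + 1L)
  anchor <- build_model("anchor", cfg, components = list(cnn = cnn, rnn = rnn),
                        seed = seed + 2L)
  orientation <- build_model("orientation", cfg,
                             components = list(anchor = anchor),
                             seed = seed + 3L)
  loop <- build_model("loop", cfg,
                      components = list(anchor = anchor,
                                        orientation = orientation),
                      seed = seed + 4L)
  list(cfg = cfg, cnn = cnn, rnn = rnn, anchor = anchor,
       orientation = orientation, loop = loop, window = window)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# independent average-precision oracle: walk the ranked list positive by
# positive (ties handled by grouping equal scores into one block)
ap_bruteforce <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  P <- sum(y)
  tp <- 0; n_seen <- 0; ap <- 0; i <- 1
  n <- length(y)
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1] == s[i]) j <- j + 1
    block_tp <- sum(y[i:j])
    tp <- tp + block_tp
    n_seen <- j
    ap <- ap + (block_tp / P) * (tp / n_seen)
    i <- j + 1
  }
  ap
}

# sorted-interpolation percentile oracle (type-7 convention, by hand)
percentile_bruteforce <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
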