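test_that("architectures expose the published layer widths at full scale", {
  cfg <- model_config()  # scale 1
  cnn <- build_model("cnn_anchor", cfg, seed = 1)
  expect_equal(dim(cnn$params$cnn$W1), c(17L * 5L, 256L))
  expect_length(cnn$params$cnn$Wd, 3L)
  expect_equal(dim(cnn$params$cnn$Wd[[1]]), c(5L * 256L, 512L))
  expect_equal(cfg$dilation_rates, c(1L, 3L, 7L))
  expect_equal(vapply(cnn$params$head$W, ncol, 0L), c(256L, 128L, 1L))

  rnn <- build_model("rnn_anchor", cfg, seed = 1)
  # two bidirectional layers of 64 units each: gate matrices are (in+64) x 256
  expect_equal(dim(rnn$params$rnn$W1f), c(5L + 64L, 4L * 64L))
  expect_equal(dim(rnn$params$rnn$W1b), c(5L + 64L, 4L * 64L))
  expect_equal(dim(rnn$params$rnn$W2f), c(3L * 64L, 4L * 64L))
  expect_equal(dim(rnn$params$rnn$W2b), c(3L * 64L, 4L * 64L))

  # shrinking `scale` shrinks widths, not topology
  small <- build_model("cnn_anchor", model_config(scale = 1 / 8), seed = 1)
  expect_equal(dim(small$params$cnn$W1), c(17L * 5L, 32L))
  expect_length(small$params$cnn$Wd, 3L)
  expect_length(small$params$head$W, 3L)
})

test_that("model composition requires its trained prerequisites", {
  cfg <- model_config(scale = 1 / 32, anchor_length = 96L, rnn_window = 32L)
  expect_error(build_model("anchor", cfg), "requires")
  expect_error(build_model("orientation", cfg), "requires")
  expect_error(build_model("loop", cfg), "requires")
})

test_that("forward passes are probabilistic, deterministic, and batch-stable", {
  st <- tiny_stack()
  set.seed(71)
  seqs <- vapply(1:7, function(i) random_seq(st$window), "")
  for (m in list(st$cnn, st$rnn, st$anchor)) {
    p <- predict(m, seqs)
    expect_true(all(p >= 0 & p <= 1))
    expect_identical(p, predict(m, seqs))                    # determinism
    one_by_one <- vapply(seqs, function(s) predict(m, s), 0, USE.NAMES = FALSE)
    expect_equal(p, one_by_one, tolerance = 1e-6)            # batching oracle
  }
  pl <- predict(st$loop, list(left = seqs[1:3], right = seqs[4:6]))
  expect_true(all(pl >= 0 & pl <= 1))

  # strand averaging is the mean of the two strand predictions
  pf <- predict(st$cnn, seqs)
  pr <- predict(st$cnn, vapply(seqs, reverse_complement, "", USE.NAMES = FALSE))
  expect_equal(predict(st$cnn, seqs, strand_average = TRUE), (pf + pr) / 2)
})

test_that("the RNN branch sees only the central window bases", {
  st <- tiny_stack()
  set.seed(73)
  core <- random_seq(st$cfg$rnn_window)
  flankA <- (st$window - st$cfg$rnn_window) / 2
  s1 <- paste0(random_seq(flankA), core, random_seq(flankA))
  s2 <- paste0(random_seq(flankA), core, random_seq(flankA))
  expect_equal(predict(st$rnn, s1), predict(st$rnn, s2))
})

test_that("saved models reload with bit-identical predictions", {
  st <- tiny_stack()
  set.seed(75)
  seqs <- vapply(1:5, function(i) random_seq(st$window), "")
  dir <- tempfile()
  save_model(st$anchor, dir)
  re <- load_model(dir)
  expect_identical(predict(re, seqs), predict(st$anchor, seqs))
  ldir <- tempfile()
  save_model(st$loop, ldir)
  lre <- load_model(ldir)
  expect_identical(predict(lre, list(left = seqs[1:2], right = seqs[3:4])),
                   predict(st$loop, list(left = seqs[1:2], right = seqs[3:4])))
})

test_that("analytic gradients agree with finite differences", {
  cfg <- model_config(anchor_length = 40L, rnn_window = 20L, scale = 1 / 32,
                      batch_size = 8L)
  set.seed(77)
  seqs <- vapply(1:8, function(i) random_seq(40, c("A", "C", "G", "T", "N")), "")
  y <- rep(c(1, 0), 4)
  codes <- insuloop:::encode_codes(seqs)
  opts <- insuloop:::cpp_opts(cfg, seed = 7, use_cnn = TRUE, use_rnn = TRUE,
                              train_trunks = TRUE)
  cnn <- build_model("cnn_anchor", cfg, seed = 3)
  rnn <- build_model("rnn_anchor", cfg, seed = 4)
  fdim <- 3L * cfg$dilated_filters + cfg$rnn_window * cfg$td_units
  params <- list(cnn = cnn$params$cnn, rnn = rnn$params$rnn,
                 head = insuloop:::with_seed(5, insuloop:::init_head_params(fdim, c(6L, 4L))))
  g <- insuloop:::cpp_seqmodel_loss_grads(params, codes, y, opts)

  fd_check <- function(path, n_checks = 3L, eps = 1e-3, tol = 0.08) {
    ga <- g; v <- params
    for (k in path) { ga <- ga[[k]]; v <- v[[k]] }
    set.seed(sum(unlist(lapply(path, function(x) sum(utf8ToInt(as.character(x)))))))
    idxs <- order(abs(ga), decreasing = TRUE)[seq_len(min(50, length(ga)))]
    idxs <- sample(idxs, min(n_checks, length(idxs)))
    for (idx in idxs) {
      perturb <- function(delta) {
        p2 <- params
        vv <- v; vv[idx] <- vv[idx] + delta
        if (length(path) == 2L) p2[[path[[1]]]][[path[[2]]]] <- vv
        else p2[[path[[1]]]][[path[[2]]]][[path[[3]]]] <- vv
        insuloop:::cpp_seqmodel_loss_grads(p2, codes, y, opts)$loss
      }
      num <- (perturb(eps) - perturb(-eps)) / (2 * eps)
      if (abs(num) > 1e-4)
        expect_equal(ga[idx], num, tolerance = tol)
    }
  }
  fd_check(list("head", "W", 1L))
  fd_check(list("head", "W", 3L))
  fd_check(list("cnn", "W1"))
  fd_check(list("cnn", "Wd", 2L))
  fd_check(list("cnn", "g2"))
  fd_check(list("rnn", "W1f"))
  fd_check(list("rnn", "W2b"))
  fd_check(list("rnn", "Wtd"))
})

test_that("training reduces loss on a linearly separable planted-motif task", {
  set.seed(79)
  mk <- function(n, planted) {
    vapply(seq_len(n), function(i) {
      s <- random_seq(120)
      if (planted) {
        at <- sample(30:80, 1)
        substr(s, at, at + 7) <- "GTACGCTG"
      }
      s
    }, "")
  }
  tr <- list(sequences = c(mk(60, TRUE), mk(60, FALSE)),
             labels = rep(1:0, each = 60))
  vl <- list(sequences = c(mk(16, TRUE), mk(16, FALSE)),
             labels = rep(1:0, each = 16))
  cfg <- model_config(anchor_length = 120L, rnn_window = 40L, scale = 1 / 16,
                      batch_size = 8L, patience = 15L, lr = 3e-3)
  m <- build_model("cnn_anchor", cfg, seed = 2)
  m <- train_model(m, tr, vl, seed = 3, epochs = 15L)
  h <- m$history$train_loss
  expect_true(m$trained)
  expect_lt(mean(tail(h, 3)), mean(head(h, 3)))
  expect_lt(min(h), 0.6)
  # history records one validation AP per epoch
  expect_length(m$history$val_ap, length(h))
})

test_that("training seeds make runs reproducible", {
  set.seed(81)
  seqs <- vapply(1:40, function(i) random_seq(64), "")
  y <- rep(c(1, 0), 20)
  cfg <- model_config(anchor_length = 64L, rnn_window = 32L, scale = 1 / 32,
                      batch_size = 8L)
  tr <- list(sequences = seqs, labels = y)
  m1 <- train_model(build_model("cnn_anchor", cfg, seed = 9), tr, tr,
                    seed = 4, epochs = 2L)
  m2 <- train_model(build_model("cnn_anchor", cfg, seed = 9), tr, tr,
                    seed = 4, epochs = 2L)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(predict(m1, seqs), predict(m2, seqs))
})
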