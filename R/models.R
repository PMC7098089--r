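# models: the five-model stack (CNN anchor, RNN anchor, combined anchor,
# anchor orientation, loop) over the compiled trunks in src/nn.cpp

#' Model configuration
#'
#' Architecture widths follow the published insulator-loop network: a first
#' convolution of 256 filters of size 17 x 5, three parallel dilated
#' convolutions (512 filters of size 5 x 1, dilation rates 1, 3, 7) whose
#' outputs are concatenated, batch normalization + leaky ReLU (slope 0.2) +
#' dropout 0.3 around each convolutional block, global max pooling; the RNN
#' branch is two stacked bidirectional LSTM layers of 64 units with dropout
#' 0.2 after each, a time-distributed linear map, and flattening. Dense
#' heads: (256, 128) for the single-branch and orientation models,
#' (512, 256) for the combined anchor and loop models. Loss is binary
#' cross-entropy minimized with RMSprop. `scale` multiplies every width
#' (filter/unit/node count) for desk-scale runs without changing the layer
#' topology.
#'
#' @param anchor_length standardized anchor length in bases.
#' @param rnn_window central window fed to the BiLSTM branch, in bases.
#' @param scale width multiplier in (0, 1].
#' @param td_units width of the time-distributed linear map (scaled).
#' @param leaky_slope negative slope of the leaky ReLU.
#' @param cnn_dropout,rnn_dropout dropout rates.
#' @param lr,rho,eps RMSprop learning rate, decay and epsilon.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss.
#' @return a list of class `insuloop_config`.
#' @export
model_config <- function(anchor_length = 4000L, rnn_window = 800L, scale = 1,
                         td_units = 32L, leaky_slope = 0.2, cnn_dropout = 0.3,
                         rnn_dropout = 0.2, lr = 1e-3, rho = 0.9, eps = 1e-7,
                         batch_size = 64L, epochs = 50L, patience = 5L) {
  stopifnot(rnn_window <= anchor_length, scale > 0, scale <= 1,
            cnn_dropout > 0, cnn_dropout < 1, rnn_dropout > 0, rnn_dropout < 1)
  sc <- function(x) pmax(1L, as.integer(round(x * scale)))
  structure(list(
    anchor_length = as.integer(anchor_length),
    rnn_window = as.integer(rnn_window),
    scale = scale,
    conv1_filters = sc(256), conv1_kernel = c(17L, 5L),
    dilated_filters = sc(512), dilated_kernel = c(5L, 1L),
    dilation_rates = c(1L, 3L, 7L),
    lstm_units = sc(64), lstm_layers = 2L, td_units = sc(td_units),
    dense_cnn_rnn = sc(c(256, 128)),
    dense_combined = sc(c(512, 256)),
    dense_orientation = sc(c(256, 128)),
    dense_loop = sc(c(512, 256)),
    leaky_slope = leaky_slope, cnn_dropout = cnn_dropout,
    rnn_dropout = rnn_dropout,
    loss = "binary_crossentropy", optimizer = "rmsprop",
    lr = lr, rho = rho, eps = eps,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    patience = as.integer(patience)
  ), class = "insuloop_config")
}

cpp_opts <- function(config, seed = 1L, use_cnn = TRUE, use_rnn = TRUE,
                     train_trunks = TRUE, epochs = NULL, head_dropout = 0,
                     verbose = FALSE) {
  list(epochs = as.integer(epochs %||% config$epochs),
       batch = config$batch_size, patience = config$patience,
       rnn_window = config$rnn_window, lr = config$lr, rho = config$rho,
       eps = config$eps, leaky = config$leaky_slope,
       drop_cnn = config$cnn_dropout, drop_rnn = config$rnn_dropout,
       drop_head = head_dropout,
       bn_mom = 0.9, bn_eps = 1e-5, seed = as.double(seed %% 2^31),
       use_cnn = use_cnn, use_rnn = use_rnn, train_trunks = train_trunks,
       verbose = verbose)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scale_features <- function(f, center, scale) {
  f <- sweep(f, 2, center)
  sweep(f, 2, scale, "/")
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

init_cnn_params <- function(config) {
  F1 <- config$conv1_filters; F2 <- config$dilated_filters
  list(W1 = glorot(17L * 5L, F1), b1 = numeric(F1),
       g1 = rep(1, F1), be1 = numeric(F1), rm1 = numeric(F1), rv1 = rep(1, F1),
       Wd = lapply(1:3, function(i) glorot(5L * F1, F2)),
       bd = lapply(1:3, function(i) numeric(F2)),
       g2 = rep(1, 3L * F2), be2 = numeric(3L * F2),
       rm2 = numeric(3L * F2), rv2 = rep(1, 3L * F2))
}

init_rnn_params <- function(config) {
  U <- config$lstm_units; D <- config$td_units
  cell <- function(cin) {
    W <- glorot(cin + U, 4L * U)
    b <- numeric(4L * U)
    b[(U + 1L):(2L * U)] <- 1  # forget-gate bias
    list(W = W, b = b)
  }
  c1f <- cell(5L); c1b <- cell(5L); c2f <- cell(2L * U); c2b <- cell(2L * U)
  list(W1f = c1f$W, b1f = c1f$b, W1b = c1b$W, b1b = c1b$b,
       W2f = c2f$W, b2f = c2f$b, W2b = c2b$W, b2b = c2b$b,
       Wtd = glorot(2L * U, D), btd = numeric(D))
}

init_head_params <- function(dims_in, hidden) {
  dims <- c(dims_in, hidden, 1L)
  list(W = lapply(seq_len(length(dims) - 1L),
                  function(j) glorot(dims[j], dims[j + 1L])),
       b = lapply(seq_len(length(dims) - 1L),
                  function(j) numeric(dims[j + 1L])))
}

cnn_feature_dim <- function(config) 3L * config$dilated_filters
rnn_feature_dim <- function(config) config$rnn_window * config$td_units

#' Build an (untrained) model of a given kind
#'
#' Kinds: `cnn_anchor` and `rnn_anchor` are the two single-branch anchor
#' classifiers; `anchor` combines the trained CNN and RNN branches (their
#' heads stripped, trunk outputs concatenated) under a new dense head;
#' `orientation` reuses the anchor model's trunks with a fresh head and
#' fine-tunes everything on the left-vs-right task; `loop` consumes a pair
#' of encoded anchors, applying the anchor and orientation feature
#' extractors to each side and feeding (left features, right features,
#' anchor probabilities, orientation probabilities) to a new dense head.
#'
#' @param kind one of `"cnn_anchor"`, `"rnn_anchor"`, `"anchor"`,
#'   `"orientation"`, `"loop"`.
#' @param config from [model_config()].
#' @param components named list of prerequisite trained models:
#'   `anchor` needs `cnn` and `rnn`; `orientation` needs `anchor`;
#'   `loop` needs `anchor` and `orientation`.
#' @param seed seed for parameter initialization.
#' @return an `insuloop_model` object.
#' @export
build_model <- function(kind = c("cnn_anchor", "rnn_anchor", "anchor",
                                 "orientation", "loop"),
                        config = model_config(), components = list(),
                        seed = 1L) {
  kind <- match.arg(kind)
  with_seed(seed, {
    params <- switch(kind,
      cnn_anchor = list(
        cnn = init_cnn_params(config),
        head = init_head_params(cnn_feature_dim(config), config$dense_cnn_rnn)),
      rnn_anchor = list(
        rnn = init_rnn_params(config),
        head = init_head_params(rnn_feature_dim(config), config$dense_cnn_rnn)),
      anchor = {
        need <- c("cnn", "rnn")
        if (!all(need %in% names(components)))
          stop("anchor model composition requires trained 'cnn' and 'rnn' components")
        list(cnn = components$cnn$params$cnn, rnn = components$rnn$params$rnn,
             head = init_head_params(cnn_feature_dim(config) + rnn_feature_dim(config),
                                     config$dense_combined))
      },
      orientation = {
        if (!"anchor" %in% names(components))
          stop("orientation model composition requires a trained 'anchor' component")
        list(cnn = components$anchor$params$cnn,
             rnn = components$anchor$params$rnn,
             head = init_head_params(cnn_feature_dim(config) + rnn_feature_dim(config),
                                     config$dense_orientation))
      },
      loop = {
        need <- c("anchor", "orientation")
        if (!all(need %in% names(components)))
          stop("loop model composition requires trained 'anchor' and 'orientation' components")
        # per side: the anchor and orientation models' penultimate dense
        # activations plus their two probability outputs
        fdim <- 2L * (utils::tail(config$dense_combined, 1L) +
                        utils::tail(config$dense_orientation, 1L) + 2L)
        list(head = init_head_params(fdim, config$dense_loop))
      })
    structure(list(kind = kind, params = params, config = config,
                   components = if (kind == "loop") components else NULL,
                   history = NULL, seed = seed, trained = FALSE),
              class = "insuloop_model")
  })
}

model_uses <- function(model) {
  switch(model$kind,
         cnn_anchor = c(cnn = TRUE, rnn = FALSE),
         rnn_anchor = c(cnn = FALSE, rnn = TRUE),
         c(cnn = TRUE, rnn = TRUE))
}

#' Train a model
#'
#' Minimizes binary cross-entropy with RMSprop; keeps the parameters of the
#' best-validation-loss epoch and records per-epoch training loss,
#' validation loss and validation average precision. For the combined
#' `anchor` model the pretrained trunks are frozen by default and only the
#' new head is fit (set `train_trunks = TRUE` to fine-tune); the
#' `orientation` model fine-tunes its trunks. The RNN branch always sees
#' only the `rnn_window` central bases of each sequence. Loop models are
#' trained on precomputed pair features (see [loop_features()]) with the
#' component models frozen.
#'
#' @param model from [build_model()].
#' @param train,val lists with `sequences` (character, equal lengths) and
#'   `labels` (0/1); for loop models, `features` (matrix) and `labels`.
#' @param seed training seed (shuffling, dropout).
#' @param epochs optional override of `config$epochs`.
#' @param train_trunks optional override of the per-kind default.
#' @param head_dropout dropout rate on the head input for head-only fits
#'   (frozen-trunk combined model and loop model); mirrors the dropout
#'   placed before the dense layers elsewhere in the network.
#' @param verbose print per-epoch progress.
#' @return the trained `insuloop_model` with `history` filled in.
#' @export
train_model <- function(model, train, val, seed = 1L, epochs = NULL,
                        train_trunks = NULL, head_dropout = 0,
                        verbose = FALSE) {
  config <- model$config
  uses <- if (model$kind == "loop") NULL else model_uses(model)
  tt <- train_trunks %||% (!model$kind %in% c("anchor", "loop"))
  if (model$kind == "loop" || !tt) {
    # head-only fit over frozen features, computed once
    opts <- cpp_opts(config, seed = seed, epochs = epochs,
                     head_dropout = head_dropout, verbose = verbose)
    if (model$kind == "loop") {
      Ftr <- train$features
      Fva <- val$features
    } else {
      fopts <- cpp_opts(config, use_cnn = uses[["cnn"]],
                        use_rnn = uses[["rnn"]])
      Ftr <- cpp_trunk_features(model$params, encode_codes(train$sequences),
                                fopts)
      Fva <- cpp_trunk_features(model$params, encode_codes(val$sequences),
                                fopts)
    }
    fit <- cpp_train_mlp(model$params$head, Ftr, as.numeric(train$labels),
                         Fva, as.numeric(val$labels), opts)
    model$params$head <- fit$params
    model$history <- fit$history
  } else {
    opts <- cpp_opts(config, seed = seed, use_cnn = uses[["cnn"]],
                     use_rnn = uses[["rnn"]], train_trunks = TRUE,
                     epochs = epochs, verbose = verbose)
    Xt <- encode_codes(train$sequences)
    Xv <- encode_codes(val$sequences)
    fit <- cpp_train_seqmodel(model$params, Xt, as.numeric(train$labels),
                              Xv, as.numeric(val$labels), opts)
    model$params <- fit$params
    model$history <- fit$history
  }
  model$trained <- TRUE
  model$seed <- seed
  model
}

#' Predict probabilities
#'
#' Deterministic for a saved model (evaluation mode: no dropout, running
#' batch-norm statistics). With `strand_average = TRUE` each sequence is
#' scored on both strands and the two probabilities averaged.
#'
#' @param object an `insuloop_model`.
#' @param newdata character vector of sequences (anchor kinds), or for loop
#'   models a list with `left` and `right` sequence vectors (or a
#'   precomputed `features` matrix).
#' @param strand_average average forward and reverse-complement predictions.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.insuloop_model <- function(object, newdata, strand_average = FALSE, ...) {
  if (object$kind == "loop") {
    feats <- if (is.matrix(newdata)) newdata
             else if (is.list(newdata) && !is.null(newdata$features)) newdata$features
             else loop_features(object, newdata$left, newdata$right)
    if (!is.null(object$feat_center))
      feats <- scale_features(feats, object$feat_center, object$feat_scale)
    return(as.numeric(cpp_predict_mlp(object$params$head, feats,
                                      object$config$leaky_slope)))
  }
  uses <- model_uses(object)
  opts <- cpp_opts(object$config, use_cnn = uses[["cnn"]], use_rnn = uses[["rnn"]])
  p <- as.numeric(cpp_predict_seqmodel(object$params, encode_codes(newdata), opts))
  if (strand_average) {
    rc <- vapply(newdata, reverse_complement, character(1), USE.NAMES = FALSE)
    p2 <- as.numeric(cpp_predict_seqmodel(object$params, encode_codes(rc), opts))
    p <- (p + p2) / 2
  }
  p
}

#' Trunk features (head input) of a sequence model
#'
#' @param model a trained `insuloop_model` of a sequence kind.
#' @param sequences character vector of equal-length sequences.
#' @return numeric matrix, one row per sequence.
#' @export
trunk_features <- function(model, sequences) {
  uses <- model_uses(model)
  opts <- cpp_opts(model$config, use_cnn = uses[["cnn"]], use_rnn = uses[["rnn"]])
  cpp_trunk_features(model$params, encode_codes(sequences), opts)
}

#' Pair features consumed by the loop model
#'
#' For each side (left, right window sequence) the trunk features are
#' passed through the anchor model's and the orientation model's dense
#' layers up to (excluding) the output layer, and the two probability
#' outputs are appended; the loop head sees
#' `[left embedding, right embedding]` where each side's embedding is
#' `[anchor dense features, orientation dense features, p_anchor,
#' p_orient]`.
#'
#' @param loop_model an `insuloop_model` of kind `loop` (holds the
#'   components), or a list with `anchor` and `orientation` models.
#' @param left,right character vectors of window sequences.
#' @return numeric feature matrix.
#' @export
loop_features <- function(loop_model, left, right) {
  comp <- if (inherits(loop_model, "insuloop_model")) loop_model$components
          else loop_model
  unname(cbind(side_features(comp, left), side_features(comp, right)))
}

# per-side embedding: penultimate dense activations of the anchor and
# orientation models plus their probability outputs
side_features <- function(components, seqs) {
  am <- components$anchor
  om <- components$orientation
  fa <- trunk_features(am, seqs)
  fo <- trunk_features(om, seqs)
  ea <- cpp_head_penult(am$params$head, fa, am$config$leaky_slope)
  eo <- cpp_head_penult(om$params$head, fo, om$config$leaky_slope)
  pa <- as.numeric(cpp_predict_mlp(am$params$head, fa, am$config$leaky_slope))
  po <- as.numeric(cpp_predict_mlp(om$params$head, fo, om$config$leaky_slope))
  unname(cbind(ea, eo, pa, po))
}

#' Save a trained model to a directory
#'
#' Writes the parameters, configuration, history and (for loop models) the
#' component models; [load_model()] restores an object whose predictions
#' are bit-identical to the original's.
#'
#' @param model an `insuloop_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  if (!is.null(model$history)) {
    h <- model$history
    utils::write.table(
      data.frame(epoch = seq_along(h$train_loss), train_loss = h$train_loss,
                 val_loss = h$val_loss, val_ap = h$val_ap),
      file.path(dir, "history.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  writeLines(paste0(model$kind, " (scale ", model$config$scale, ")"),
             file.path(dir, "architecture.txt"))
  invisible(dir)
}

#' Load a model saved with [save_model()]
#' @param dir directory written by [save_model()].
#' @return an `insuloop_model`.
#' @export
load_model <- function(dir) {
  readRDS(file.path(dir, "model.rds"))
}

#' @export
print.insuloop_model <- function(x, ...) {
  cat("<insuloop_model>", x$kind,
      if (x$trained) "(trained)" else "(untrained)", "\n")
  cat("  scale:", x$config$scale,
      " anchor_length:", x$config$anchor_length,
      " rnn_window:", x$config$rnn_window, "\n")
  if (!is.null(x$history))
    cat("  best epoch:", x$history$best_epoch,
        " val AP:", signif(x$history$val_ap[[x$history$best_epoch]], 3), "\n")
  invisible(x)
}
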