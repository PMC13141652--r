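#' Model specification for the FP-chimera classifier
#'
#' Three architecture families are available, all operating on a single
#' channel of `input_length` preprocessed current samples and emitting two
#' class scores (normal vs. FP chimera):
#'
#' * `resnet1d` (default): an initial 1D convolution (kernel
#'   `initial_kernel`, stride 2) followed by residual stages of 3-wide 1D
#'   convolutions (`channels[i]` filters, `blocks[i]` blocks per stage,
#'   stride-2 downsampling between stages), global average pooling and a
#'   linear head.
#' * `mlp`: fully connected layers with ReLU between; the published layer
#'   sizes are (20000, 4096), (4096, 64), (64, 2), i.e. `mlp_dims =
#'   c(4096, 64, 2)` at `input_length = 20000`.
#' * `vdcnn1d`: a deep plain convolutional stack whose first embedding layer
#'   is a 1D convolution with kernel size 3, with max-pool halving between
#'   stages.
#'
#' @param architecture One of `"resnet1d"`, `"mlp"`, `"vdcnn1d"`.
#' @param input_length Window length 2N fed to the model (default 20000).
#' @param channels Integer vector of stage widths (conv architectures).
#' @param blocks Residual blocks per stage (`resnet1d`).
#' @param initial_kernel Kernel of the initial convolution (`resnet1d`).
#' @param mlp_dims Output sizes of the linear layers (`mlp`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(architecture = c("resnet1d", "mlp", "vdcnn1d"),
                       input_length = 20000,
                       channels = c(16, 32, 64, 128),
                       blocks = rep(2L, length(channels)),
                       initial_kernel = 7,
                       mlp_dims = c(4096, 64, 2)) {
  architecture <- match.arg(architecture)
  stopifnot(input_length > 0, length(blocks) == length(channels))
  structure(list(type = architecture,
                 input_len = as.integer(input_length),
                 channels = as.integer(channels),
                 blocks = as.integer(blocks),
                 initial_kernel = as.integer(initial_kernel),
                 mlp_dims = as.integer(mlp_dims)),
            class = "model_spec")
}

#' Training configuration
#'
#' Defaults follow the published regime where stated (batch size 256, 30
#' epochs); the optimizer (Adam, learning rate 1e-3, no schedule) and the
#' cross-entropy loss are this package's documented choices.
#'
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialization and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 256, epochs = 30,
                         learning_rate = 1e-3, seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

#' Number of trainable parameters of a model specification
#'
#' Computed in closed form from the layer sizes (weights plus biases), so
#' even the full-size MLP — 20000x4096 + 4096x64 + 64x2 plus biases,
#' 82,186,434 parameters — is counted without being instantiated.
#'
#' @param spec A [model_spec()].
#' @return Parameter count (double, to hold large counts exactly).
#' @export
n_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  lin <- function(i, o) i * o + o
  conv <- function(ci, co, k) ci * k * co + co
  if (spec$type == "mlp") {
    dims <- c(spec$input_len, spec$mlp_dims)
    return(sum(vapply(seq_len(length(dims) - 1),
                      function(i) lin(dims[i], dims[i + 1]), 0)))
  }
  if (spec$type == "resnet1d") {
    total <- conv(1, spec$channels[1], spec$initial_kernel)
    cin <- spec$channels[1]
    for (st in seq_along(spec$channels)) {
      co <- spec$channels[st]
      for (bl in seq_len(spec$blocks[st])) {
        total <- total + conv(cin, co, 3) + conv(co, co, 3)
        proj <- (bl == 1L && st > 1L) || cin != co
        if (proj) total <- total + conv(cin, co, 1)
        cin <- co
      }
    }
    return(total + lin(cin, 2))
  }
  # vdcnn1d
  total <- conv(1, spec$channels[1], 3)
  cin <- spec$channels[1]
  for (st in seq_along(spec$channels)) {
    co <- spec$channels[st]
    total <- total + conv(cin, co, 3) + conv(co, co, 3)
    cin <- co
  }
  total + lin(cin, 2)
}

as_arch_list <- function(spec) {
  list(type = spec$type, input_len = spec$input_len,
       channels = spec$channels, blocks = spec$blocks,
       initial_kernel = spec$initial_kernel, mlp_dims = spec$mlp_dims)
}

#' Build a model with seeded initial weights
#'
#' Instantiates the architecture with He-normal initial weights drawn from a
#' seeded generator, so two builds with the same seed produce bit-identical
#' forward passes.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `nanochimera_model` (untrained weights).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  w <- cpp_init_net(as_arch_list(spec), as.integer(seed))
  structure(list(spec = spec, weights = w, seed = as.integer(seed),
                 n_parameters = n_parameters(spec), log = NULL,
                 trained = FALSE),
            class = "nanochimera_model")
}

#' @export
print.nanochimera_model <- function(x, ...) {
  cat(sprintf("<nanochimera_model %s, input %d, %s parameters%s>\n",
              x$spec$type, x$spec$input_len,
              format(x$n_parameters, big.mark = ","),
              if (isTRUE(x$trained)) ", trained" else ", untrained"))
  invisible(x)
}

#' Train the FP-chimera classifier
#'
#' Minimizes the two-class cross-entropy with Adam on the training split,
#' monitors validation accuracy each epoch, and keeps the weights of the
#' best-validation epoch. Fully deterministic for a fixed seed.
#'
#' @param spec A [model_spec()].
#' @param dataset A list with `train` and `val` as produced by
#'   [build_dataset()] (`x` matrix of windows, `y` 0/1 labels).
#' @param config A [train_config()].
#' @return A trained `nanochimera_model` carrying the training log.
#' @export
train_model <- function(spec, dataset, config = train_config()) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(dataset$val) || !length(dataset$val$y)) stop("validation set is empty")
  fit <- cpp_train_net(as_arch_list(spec),
                       dataset$train$x, as.integer(dataset$train$y),
                       dataset$val$x, as.integer(dataset$val$y),
                       config$epochs, config$batch_size,
                       config$learning_rate, config$seed)
  structure(list(spec = spec, weights = fit$weights, seed = config$seed,
                 n_parameters = n_parameters(spec), log = fit$log,
                 best_epoch = fit$best_epoch,
                 best_val_accuracy = fit$best_val_accuracy,
                 train_config = config, trained = TRUE),
            class = "nanochimera_model")
}

#' Predict FP-chimera probabilities for signal windows
#'
#' @param model A trained `nanochimera_model`.
#' @param x Matrix of windows (one per row) of the model's input length.
#' @return Numeric vector of class-1 (FP chimera) probabilities.
#' @export
predict_model <- function(model, x) {
  if (is.null(model$weights)) stop("model has no weights")
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$spec$input_len) {
    stop("window length ", ncol(x), " does not match model input ",
         model$spec$input_len)
  }
  p <- cpp_predict_net(as_arch_list(model$spec), model$weights, x, 256L)
  p[, 2]
}

#' Evaluate a classifier on a labelled test set
#'
#' Accuracy, precision, recall and F1 with FP chimera as the positive class,
#' plus the full ROC curve and its AUC from a sweep over the class-1 scores.
#' On a single-class test set the AUC is reported as `NA`.
#'
#' @param scores Class-1 probabilities (or a trained model given with `x`).
#' @param y True 0/1 labels.
#' @param threshold Decision threshold on the class-1 score (default 0.5).
#' @return A list: `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `confusion` (2x2 matrix), `roc` (`data.frame` of `fpr`, `tpr`).
#' @export
evaluate_scores <- function(scores, y, threshold = 0.5) {
  y <- as.integer(y)
  stopifnot(length(scores) == length(y))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  roc <- roc_curve(scores, y)
  list(accuracy = (tp + tn) / length(y), precision = precision,
       recall = recall, f1 = f1, auc = attr(roc, "auc"),
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(pred = c("fp_chimera", "normal"),
                                          truth = c("fp_chimera", "normal"))),
       roc = roc)
}

# Threshold-sweep ROC; AUC by trapezoid over unique score cutoffs.
roc_curve <- function(scores, y) {
  pos <- sum(y == 1)
  neg <- sum(y == 0)
  if (pos == 0 || neg == 0) {
    out <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
    attr(out, "auc") <- NA_real_
    return(out)
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  tp <- cumsum(ys == 1)
  fp <- cumsum(ys == 0)
  keep <- c(diff(ss) != 0, TRUE)  # one point per distinct threshold
  tpr <- c(0, tp[keep] / pos)
  fpr <- c(0, fp[keep] / neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- data.frame(fpr = fpr, tpr = tpr)
  attr(out, "auc") <- auc
  out
}

#' Evaluate a trained model on a test split
#'
#' @param model A trained `nanochimera_model`.
#' @param test A list with `x` and `y` (as in [build_dataset()] splits).
#' @param threshold Decision threshold.
#' @return See [evaluate_scores()].
#' @export
evaluate_model <- function(model, test, threshold = 0.5) {
  evaluate_scores(predict_model(model, test$x), test$y, threshold)
}

#' Classify candidate reads and filter a read set
#'
#' Applies the trained classifier to the breakpoint-centered window of every
#' candidate chimeric read and removes the reads predicted to be FP
#' chimeras. Reads the detector called normal — and candidate reads without
#' a signal trace, which are counted and reported — are always retained.
#'
#' @param model A trained `nanochimera_model`.
#' @param signals Named list of [raw_signal()] objects.
#' @param calls Call table from [classify_reads()].
#' @param read_lens Named vector of read lengths in bases.
#' @param config A [preprocess_config()] matching the model's input length.
#' @param threshold Decision threshold on the FP-chimera probability.
#' @return A list: `fp_ids` (read ids predicted FP chimera), `kept_ids`,
#'   `missing_signal` (candidate ids lacking a trace), `scores` (named
#'   probabilities for scored reads).
#' @export
classify_and_filter <- function(model, signals, calls, read_lens,
                                config = preprocess_config(),
                                threshold = 0.5) {
  if (2L * config$half_window_N != model$spec$input_len) {
    stop("preprocess window 2N does not match the model input length")
  }
  cand <- calls[calls$chimera_type != "normal", , drop = FALSE]
  missing <- cand$read_id[!(cand$read_id %in% names(signals))]
  cand <- cand[cand$read_id %in% names(signals), , drop = FALSE]
  fp_ids <- character()
  scores <- stats::setNames(numeric(0), character(0))
  if (nrow(cand)) {
    wins <- lapply(seq_len(nrow(cand)), function(i) {
      sig <- signals[[cand$read_id[i]]]
      bp <- breakpoint_to_signal_index(sig, cand$breakpoint[i],
                                       read_lens[[cand$read_id[i]]])
      extract_window(sig, bp, config, label = "fp_chimera")
    })
    x <- do.call(rbind, lapply(wins, `[[`, "values"))
    scores <- stats::setNames(predict_model(model, x), cand$read_id)
    fp_ids <- cand$read_id[scores >= threshold]
  }
  kept <- setdiff(calls$read_id, fp_ids)
  list(fp_ids = fp_ids, kept_ids = kept, missing_signal = missing,
       scores = scores)
}

#' Filter a FASTQ file by read id
#'
#' Writes a copy of the input FASTQ excluding the given read ids.
#'
#' @param fastq_in Input FASTQ path.
#' @param fastq_out Output FASTQ path.
#' @param drop_ids Character vector of read ids to remove.
#' @return Invisibly, the number of reads written.
#' @export
filter_fastq <- function(fastq_in, fastq_out, drop_ids) {
  reads <- Biostrings::readQualityScaledDNAStringSet(fastq_in)
  ids <- sub("\\s.*$", "", names(reads))
  keep <- !(ids %in% drop_ids)
  Biostrings::writeQualityScaledXStringSet(reads[keep], fastq_out)
  invisible(sum(keep))
}
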