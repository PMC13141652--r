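test_that("parameter counting matches the published MLP layer sizes", {
  spec <- model_spec("mlp", input_length = 20000, mlp_dims = c(4096, 64, 2))
  expect_equal(n_parameters(spec),
               20000 * 4096 + 4096 + 4096 * 64 + 64 + 64 * 2 + 2)
  expect_equal(n_parameters(spec), 82186434)
  # closed form agrees with the instantiated network on desk-scale models
  for (sp in list(model_spec("mlp", input_length = 200, mlp_dims = c(32, 2)),
                  model_spec("resnet1d", input_length = 400,
                             channels = c(4, 8), blocks = c(1, 2)),
                  model_spec("vdcnn1d", input_length = 400, channels = c(4, 8),
                             blocks = c(1, 1)))) {
    m <- build_model(sp, seed = 1)
    expect_equal(sum(vapply(m$weights, length, 0L)), n_parameters(sp))
  }
})

test_that("model building is seeded and shape-checked", {
  sp <- model_spec("resnet1d", input_length = 200, channels = c(4, 8),
                   blocks = c(1, 1))
  m1 <- build_model(sp, seed = 5)
  m2 <- build_model(sp, seed = 5)
  x <- matrix(rnorm(3 * 200), 3, 200)
  expect_identical(predict_model(m1, x), predict_model(m2, x))
  m3 <- build_model(sp, seed = 6)
  expect_false(identical(predict_model(m1, x), predict_model(m3, x)))
  expect_error(predict_model(m1, matrix(0, 2, 100)), "length")
})

test_that("evaluation metrics match their closed forms", {
  # confusion TP=90, FP=4, FN=10, TN=96
  scores <- c(rep(0.9, 90), rep(0.1, 10), rep(0.9, 4), rep(0.1, 96))
  y <- c(rep(1, 100), rep(0, 100))
  ev <- evaluate_scores(scores, y)
  expect_equal(ev$confusion["fp_chimera", "fp_chimera"], 90)
  expect_equal(round(ev$precision, 4), 0.9574)
  expect_equal(ev$recall, 0.9)
  expect_equal(round(ev$f1, 4), 0.9278)
  expect_equal(ev$f1, 2 * ev$precision * ev$recall / (ev$precision + ev$recall),
               tolerance = 1e-9)
  expect_equal(ev$accuracy, (90 + 96) / 200)
  # perfect separation and constant scores
  perf <- evaluate_scores(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$auc, 1)
  expect_equal(evaluate_scores(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)
  # single-class set: AUC undefined
  expect_true(is.na(evaluate_scores(runif(5), rep(1, 5))$auc))
})

test_that("AUC is invariant under monotone score transforms and matches pROC", {
  set.seed(42)
  y <- rbinom(300, 1, 0.5)
  scores <- runif(300) + 0.4 * y
  a1 <- evaluate_scores(scores, y)$auc
  a2 <- evaluate_scores(plogis(5 * scores - 2), y)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a1, ref, tolerance = 1e-9)
})

test_that("training separates window classes and is seed-deterministic", {
  # synthetic windows: positives carry a centred low-variance low-level dip
  set.seed(13)
  n <- 240; L <- 400
  mk <- function(pos) {
    x <- rnorm(L, 90, 10)
    if (pos) x[180:260] <- rnorm(81, 54, 0.2)
    as.numeric(scale(x))
  }
  y <- rep(c(1, 0), each = n / 2)
  X <- t(vapply(seq_len(n), function(i) mk(y[i] == 1), numeric(L)))
  idx <- rep(seq_len(10), length.out = n)
  ds <- list(train = list(x = X[idx > 2, ], y = y[idx > 2]),
             val = list(x = X[idx == 1, ], y = y[idx == 1]),
             test = list(x = X[idx == 2, ], y = y[idx == 2]))
  sp <- model_spec("resnet1d", input_length = L, channels = c(8, 16),
                   blocks = c(1, 1))
  cfg <- train_config(batch_size = 32, epochs = 6, seed = 3)
  fit <- train_model(sp, ds, cfg)
  expect_gte(evaluate_model(fit, ds$test)$accuracy, 0.95)
  # two runs under the same seed agree exactly
  fit2 <- train_model(sp, ds, cfg)
  expect_identical(fit$best_val_accuracy, fit2$best_val_accuracy)
  expect_identical(fit$weights[[1]], fit2$weights[[1]])
  # the training log tracks every epoch
  expect_equal(nrow(fit$log), 6L)
  expect_error(train_model(sp, list(train = ds$train,
                                    val = list(x = matrix(0, 0, L),
                                               y = integer())), cfg))
})

test_that("MLP and deep-CNN baselines also learn separable windows", {
  set.seed(17)
  L <- 200
  mk <- function(pos) {
    x <- rnorm(L, 90, 10)
    if (pos) x[80:130] <- rnorm(51, 54, 0.2)
    as.numeric(scale(x))
  }
  y <- rep(c(1, 0), 60)
  X <- t(vapply(seq_along(y), function(i) mk(y[i] == 1), numeric(L)))
  ds <- list(train = list(x = X[1:100, ], y = y[1:100]),
             val = list(x = X[101:120, ], y = y[101:120]))
  for (arch in c("mlp", "vdcnn1d")) {
    sp <- model_spec(arch, input_length = L, channels = c(4, 8),
                     blocks = c(1, 1), mlp_dims = c(64, 16, 2))
    fit <- train_model(sp, ds, train_config(batch_size = 20, epochs = 8, seed = 2))
    expect_gte(fit$best_val_accuracy, 0.9)
  }
})

test_that("classify_and_filter removes only predicted candidates", {
  sim <- simulate_run(sim_config(
    n_reads = 120, chimera_rates = c(inverted_repeat = 0.4, cross = 0, gapped = 0),
    p_smooth_chimera = 1, p_smooth_normal = 0, seed = 19))
  calls <- classify_reads(filter_mapq(sim$frags))
  pc <- preprocess_config(half_window_N = 500)
  truth <- sim$truth
  wins <- lapply(seq_len(nrow(truth)), function(i) {
    sig <- sim$signals[[truth$read_id[i]]]
    if (truth$true_type[i] != "normal") {
      extract_window(sig, truth$junction_sample[i], pc, label = "fp_chimera")
    } else extract_window(sig, NULL, pc, label = "normal", seed = 4)
  })
  ds <- build_dataset(wins, seed = 5)
  sp <- model_spec("resnet1d", input_length = 1000, channels = c(8, 16),
                   blocks = c(1, 1))
  fit <- train_model(sp, ds, train_config(batch_size = 32, epochs = 6, seed = 1))
  res <- classify_and_filter(fit, sim$signals, calls, sim$read_lens, pc)
  # non-candidates are always retained
  normals <- calls$read_id[calls$chimera_type == "normal"]
  expect_true(all(normals %in% res$kept_ids))
  expect_equal(sort(c(res$fp_ids, res$kept_ids)), sort(calls$read_id))
  # against simulator truth, filtering is near-perfect on this easy set
  truth_fp <- truth$read_id[truth$true_type != "normal"]
  recall <- length(intersect(res$fp_ids, truth_fp)) / length(truth_fp)
  expect_gte(recall, 0.9)
  # a candidate with no trace is reported and retained
  sig2 <- sim$signals
  drop_id <- calls$read_id[calls$chimera_type != "normal"][1]
  sig2[[drop_id]] <- NULL
  res2 <- classify_and_filter(fit, sig2, calls, sim$read_lens, pc)
  expect_equal(res2$missing_signal, drop_id)
  expect_true(drop_id %in% res2$kept_ids)
})
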