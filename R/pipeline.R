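#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations, input paths and the master seed
#' into one serializable object. `NULL` paths mean the corresponding inputs
#' are produced by the built-in simulator.
#'
#' @param paths Named list of input paths (`paf`/`sam`, `signals`,
#'   `reference`, `reads`), or `NULL` entries to simulate.
#' @param sim A [sim_config()] used when inputs are simulated.
#' @param detector A [detector_config()].
#' @param feature A [feature_config()].
#' @param preprocess A [preprocess_config()].
#' @param model A [model_spec()].
#' @param training A [train_config()].
#' @param sv List of SV-evaluation settings (`min_support`, `af_min`,
#'   `match_tolerance`, `af_values`).
#' @param seed Master seed; stage seeds are derived from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = list(),
                            sim = sim_config(),
                            detector = detector_config(),
                            feature = feature_config(),
                            preprocess = preprocess_config(),
                            model = model_spec(input_length = 2 * preprocess$half_window_N),
                            training = train_config(),
                            sv = list(min_support = 3, af_min = 0.02,
                                      match_tolerance = 500,
                                      af_values = seq(0.01, 0.08, by = 0.01)),
                            seed = 1L) {
  if (2L * preprocess$half_window_N != model$input_len) {
    stop("model input length must equal 2N of the preprocess config")
  }
  structure(list(paths = paths, sim = sim, detector = detector,
                 feature = feature, preprocess = preprocess, model = model,
                 training = training, sv = sv, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full FP-chimera filtering pipeline
#'
#' Chains the stages: (simulate or load inputs) -> chimera detection ->
#' smoothed-segment features -> window preprocessing -> classifier training
#' -> read filtering -> SV-error evaluation (raw vs filtered vs dose-matched
#' random-removal control). Stage outputs and a manifest (configs, seeds,
#' read counts in/out per stage) are written under `out_dir`. The SV stage
#' is skipped with a warning when the dataset yields no clean calls to
#' compare against.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created).
#' @return Invisibly, a list with the per-stage results (`calls`, `summary`,
#'   `features`, `prevalence`, `model`, `eval`, `filter`, `sv`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("ncrun")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message(sprintf("[%s] %s", name,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  # --- stage 1: inputs -------------------------------------------------
  if (length(config$paths) && !is.null(config$paths$paf)) {
    frags <- read_alignments(config$paths$paf)
    signals <- if (!is.null(config$paths$signals)) {
      read_signals(config$paths$signals)
    } else NULL
    reference <- if (!is.null(config$paths$reference)) {
      Biostrings::readDNAStringSet(config$paths$reference)
    } else NULL
    grouped <- group_by_read(frags)
    read_lens <- stats::setNames(grouped$reads$read_len, grouped$reads$read_id)
    truth <- NULL
    log_stage("input", n_fragments = nrow(frags),
              n_reads = length(read_lens), source = "files")
  } else {
    sim <- simulate_run(config$sim)
    frags <- sim$frags
    signals <- sim$signals
    reference <- sim$reference
    read_lens <- sim$read_lens
    truth <- sim$truth
    log_stage("input", n_fragments = nrow(frags),
              n_reads = length(read_lens), source = "simulated")
  }

  # --- stage 2: detection ----------------------------------------------
  frags_f <- filter_mapq(frags)
  ref_fetch <- if (!is.null(reference)) reference_accessor(reference) else NULL
  calls <- classify_reads(frags_f, config$detector, ref_fetch)
  summary <- summarize_chimeras(calls, read_lens)
  write_fragments_tsv(frags_f, file.path(out_dir, "fragments.tsv"))
  utils::write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("detect", n_reads = nrow(calls),
            n_chimeric = sum(calls$chimera_type != "normal"),
            fp_ratio = round(summary$fp_ratio, 4))

  features <- NULL
  prevalence <- NULL
  model <- NULL
  eval_report <- NULL
  filt <- NULL
  sv_res <- NULL

  if (!is.null(signals)) {
    # --- stage 3: smoothed-segment features ----------------------------
    anchors <- NULL
    if (!is.null(truth)) {
      anchors <- stats::setNames(
        ifelse(is.na(truth$junction_sample), truth$anchor_sample,
               truth$junction_sample), truth$read_id)
      anchors <- anchors[!is.na(anchors)]
    }
    features <- feature_reports(signals, calls, read_lens, config$feature,
                                anchors = anchors, seed = config$seed)
    prevalence <- smoothed_segment_prevalence(features)
    utils::write.table(features, file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("feature", n_reports = nrow(features),
              frac_chimeric = round(mean(
                features$has_smoothed_segment[features$chimera_type != "normal"]), 3))

    # --- stage 4: preprocessing ----------------------------------------
    labels <- if (!is.null(truth)) {
      stats::setNames(ifelse(truth$true_type == "normal", "normal",
                             "fp_chimera"), truth$read_id)
    } else {
      stats::setNames(ifelse(calls$chimera_type == "normal", "normal",
                             "fp_chimera"), calls$read_id)
    }
    windows <- lapply(calls$read_id, function(id) {
      sig <- signals[[id]]
      if (is.null(sig)) return(NULL)
      lab <- labels[[id]]
      bp <- if (lab == "fp_chimera") {
        i <- match(id, calls$read_id)
        breakpoint_to_signal_index(sig, calls$breakpoint[i], read_lens[[id]])
      } else NULL
      extract_window(sig, bp, config$preprocess, label = lab,
                     seed = config$seed)
    })
    windows <- Filter(Negate(is.null), windows)
    dataset <- build_dataset(windows, seed = config$seed)
    log_stage("preprocess", n_windows = length(windows),
              n_train = length(dataset$train$y), n_val = length(dataset$val$y),
              n_test = length(dataset$test$y))

    # --- stage 5: classifier -------------------------------------------
    model <- train_model(config$model, dataset, config$training)
    eval_report <- evaluate_model(model, dataset$test)
    log_stage("train", best_epoch = model$best_epoch,
              val_accuracy = round(model$best_val_accuracy, 4),
              test_accuracy = round(eval_report$accuracy, 4))

    # --- stage 6: filtering --------------------------------------------
    filt <- classify_and_filter(model, signals, calls, read_lens,
                                config$preprocess)
    writeLines(filt$fp_ids, file.path(out_dir, "fp_read_ids.txt"))
    log_stage("filter", n_candidates = sum(calls$chimera_type != "normal"),
              n_removed = length(filt$fp_ids),
              n_kept = length(filt$kept_ids))

    # --- stage 7: SV evaluation ----------------------------------------
    all_ids <- calls$read_id
    clean_ids <- if (!is.null(truth)) {
      truth$read_id[truth$true_type == "normal"]
    } else {
      setdiff(all_ids, calls$read_id[calls$chimera_type != "normal"])
    }
    control <- make_control(all_ids, length(filt$fp_ids), seed = config$seed)
    arms <- list(clean = clean_ids, raw = all_ids,
                 filtered = filt$kept_ids, control = control$kept_ids)
    caller <- function(fr, ids, af) {
      call_svs_from_fragments(fr, ids, min_support = config$sv$min_support,
                              af_min = af)
    }
    clean_calls <- caller(frags_f, clean_ids, config$sv$af_min)
    if (nrow(clean_calls) == 0 &&
        nrow(caller(frags_f, all_ids, config$sv$af_min)) == 0) {
      warning("sv-eval: no SV calls in any arm; stage skipped")
      log_stage("sv_eval", skipped = TRUE)
    } else {
      per_arm <- lapply(arms[c("raw", "filtered", "control")], function(ids) {
        compare_sv_sets(clean_calls, caller(frags_f, ids, config$sv$af_min),
                        match_tolerance = config$sv$match_tolerance)
      })
      scan <- mosaic_gradient_scan(frags_f, arms,
                                   af_values = config$sv$af_values,
                                   caller = function(fr, ids, af) caller(fr, ids, af),
                                   match_tolerance = config$sv$match_tolerance)
      sv_res <- list(clean_calls = clean_calls,
                     error_rates = vapply(per_arm, `[[`, 0, "error_rate"),
                     per_arm = per_arm, gradient = scan)
      utils::write.table(scan, file.path(out_dir, "sv_gradient.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage("sv_eval", n_clean = nrow(clean_calls),
                raw = round(sv_res$error_rates[["raw"]], 4),
                filtered = round(sv_res$error_rates[["filtered"]], 4),
                control = round(sv_res$error_rates[["control"]], 4))
    }
  }

  manifest$config <- serialize_config(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(calls = calls, summary = summary, features = features,
                 prevalence = prevalence, model = model, eval = eval_report,
                 filter = filt, sv = sv_res, manifest = manifest,
                 out_dir = out_dir))
}

# Flatten the nested configs to plain lists for the JSON manifest.
serialize_config <- function(config) {
  lapply(config, function(x) {
    if (is.list(x)) lapply(unclass(x), function(y) unclass(y)) else x
  })
}
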