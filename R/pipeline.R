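# End-to-end orchestration: simulate (or load) paired cases, extract and
# standardize isocenter slices, build augmentation cohorts, featurize,
# train the prediction heads, and evaluate on the held-out cases.

#' Pipeline run configuration
#'
#' Collects every knob of [run_pipeline()] with its default. The whole
#' configuration (plus the derived per-stage seeds) is serialized into the
#' run directory, so a run can be reproduced from its own audit trail.
#'
#' @param out_dir Output directory for manifests, predictions and metrics.
#' @param n Number of simulated cases (ignored when `input_manifest` given).
#' @param coverage_range Range the simulated coverage targets are drawn
#'   uniformly from (percent).
#' @param level Augmentation cohort level (1, 2 or 3), see [build_cohort()].
#' @param split_ratio Case-level training fraction.
#' @param seed Global seed; every stage derives its own sub-seed from it.
#' @param extractor `"randconv"` (default), `"vgg16"`, or a ready
#'   `feature_extractor` object.
#' @param regressor_variants Character subset of `c("rf", "dnn")`.
#' @param window CT intensity window for slice normalization.
#' @param noise_mean,noise_variance Augmentation noise parameters.
#' @param grid_shape,spacing,shrink Phantom geometry, see [generate_cohort()].
#' @param input_manifest Optional CSV path with columns `case_id`,
#'   `pre_path`, `post_path`, `tumor_path`, `ablation_path` pointing at
#'   registered NIfTI volumes/masks; when supplied these cases are used
#'   instead of simulated ones.
#' @param dnn_hidden Hidden-layer sizes when the `"dnn"` variant is trained.
#' @param keep_features Store the difference-vector matrix on the returned
#'   run object (rows aligned with its `pairs`); off by default because the
#'   matrix is large.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("slicecov_run_"),
                       n = 40, coverage_range = c(20, 100),
                       level = 1, split_ratio = 0.8, seed = 7L,
                       extractor = "randconv",
                       regressor_variants = "rf",
                       window = c(-160, 240),
                       noise_mean = 0.01, noise_variance = 0.001,
                       grid_shape = c(320, 320, 40),
                       spacing = c(1, 1, 5),
                       shrink = 1,
                       input_manifest = NULL,
                       dnn_hidden = c(4096L, 1024L),
                       keep_features = FALSE) {
  structure(
    list(out_dir = out_dir, n = n, coverage_range = coverage_range,
         level = level, split_ratio = split_ratio, seed = as.integer(seed),
         extractor = extractor, regressor_variants = regressor_variants,
         window = window, noise_mean = noise_mean,
         noise_variance = noise_variance, grid_shape = grid_shape,
         spacing = spacing, shrink = shrink,
         input_manifest = input_manifest, dnn_hidden = dnn_hidden,
         keep_features = keep_features),
    class = "run_config")
}

resolve_extractor <- function(extractor) {
  if (inherits(extractor, "feature_extractor")) return(extractor)
  switch(extractor,
         randconv = randconv_extractor(),
         vgg16 = vgg16_extractor(),
         stop_slicecov(paste0("Unknown extractor '", extractor, "'."),
                       "slicecov_config_error"))
}

load_cases_from_manifest <- function(path) {
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    for (col in c("pre_path", "post_path", "tumor_path", "ablation_path")) {
      if (!file.exists(row[[col]])) {
        stop_slicecov(
          sprintf("[load] case %s: missing input file '%s'.",
                  row$case_id, row[[col]]),
          "slicecov_missing_input")
      }
    }
    tumor <- read_label_volume(row$tumor_path)
    ablation <- read_label_volume(row$ablation_path)
    list(case_id = row$case_id,
         pre_volume = as.array(RNifti::readNifti(row$pre_path)),
         post_volume = as.array(RNifti::readNifti(row$post_path)),
         tumor_mask = tumor, ablation_mask = ablation,
         true_coverage = percent_tumor_coverage(tumor, ablation)$percent_coverage)
  })
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    # unwrap iteration wrappers (e.g. purrr's indexed errors) to the cause
    root <- e
    while (!inherits(root, "slicecov_error") && !is.null(root$parent)) {
      root <- root$parent
    }
    if (inherits(root, "slicecov_error")) stop(root)
    stop_slicecov(paste0("[", name, "] ", conditionMessage(e)),
                  "slicecov_stage_error")
  })
}

#' Run the slice-based coverage estimation pipeline end to end
#'
#' Stages, in order: simulate (or load) paired cases with ground-truth
#' coverage; extract and standardize both isocenter slices per case; split
#' cases 80:20; expand the training and testing sides into the requested
#' augmentation cohort; compute difference vectors; train the class
#' forest and the requested regressors on the training pairs; evaluate on
#' the held-out pairs. Every intermediate table is written as CSV into
#' `config$out_dir`, metrics as JSON; a rerun with the same configuration
#' reproduces the metrics file byte for byte (all backbones and forests
#' here are deterministic given the seed).
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Object of class `slicecov_run`: the cohort manifest, the pair
#'   table with splits, the prediction table, the
#'   [classification_report()] and [regression_report()]s on the test
#'   pairs, fitted models, and output paths.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed

  # Cases are rendered one at a time and reduced to their two standardized
  # slices immediately: full-resolution volumes never accumulate in memory.
  pairs <- if (!is.null(config$input_manifest)) {
    cases <- stage("load", load_cases_from_manifest(config$input_manifest))
    stage("slices", make_case_pairs(cases, window = config$window))
  } else {
    say("simulating ", config$n, " phantom cases")
    cohort <- stage("simulate", {
      targets <- withr::with_seed(
        sub_seed(seed, "targets"),
        stats::runif(config$n, config$coverage_range[1], config$coverage_range[2]))
      cohort <- generate_cohort(config$n, targets, seed = seed,
                                grid_shape = config$grid_shape,
                                spacing = config$spacing,
                                shrink = config$shrink)
      cohort[cohort$status == "ok", ]
    })
    say("extracting isocenter slices")
    stage("slices", dplyr::bind_rows(purrr::map(seq_len(nrow(cohort)), function(i) {
      case <- generate_case(cohort$spec[[i]], case_id = cohort$case_id[i])
      make_case_pairs(list(case), window = config$window)
    })))
  }

  split <- stage("split", split_cases(pairs$case_id, ratio = config$split_ratio,
                                      seed = sub_seed(seed, "split")))
  cohort_pairs <- stage("cohort", {
    dplyr::inner_join(
      build_cohort(pairs, level = config$level,
                   seed = sub_seed(seed, "augment"),
                   noise_mean = config$noise_mean,
                   noise_variance = config$noise_variance),
      split, by = "case_id")
  })

  say("extracting features for ", nrow(cohort_pairs), " pairs")
  extractor <- resolve_extractor(config$extractor)
  X <- stage("features", cohort_difference_matrix(cohort_pairs, extractor))

  is_train <- cohort_pairs$split == "train"
  y <- cohort_pairs$coverage

  say("training predictors")
  classifier <- stage("train", train_classifier(
    X[is_train, , drop = FALSE], class_of(y[is_train]),
    seed = sub_seed(seed, "classifier")))
  regressors <- stage("train", {
    out <- list()
    for (v in config$regressor_variants) {
      out[[v]] <- train_regressor(
        X[is_train, , drop = FALSE], y[is_train], variant = v,
        seed = sub_seed(seed, "regressor", v),
        hidden = config$dnn_hidden)
    }
    out
  })

  say("evaluating on held-out pairs")
  votes <- stage("predict", predict_class(classifier, X))
  predictions <- dplyr::bind_cols(
    cohort_pairs[, c("case_id", "split", "aug_tumor", "aug_ablation", "coverage")],
    tibble::tibble(class_true = class_of(y)), votes)
  for (v in names(regressors)) {
    predictions[[paste0("pred_", v)]] <- predict_coverage(regressors[[v]], X)
  }

  test <- predictions[predictions$split == "test", ]
  class_report <- stage("evaluate", classification_report(
    test$class_true, test$class_pred,
    test[, paste0("vote_", coverage_class_levels())]))
  reg_reports <- stage("evaluate", {
    lapply(regressors, function(m) NULL) -> out
    for (v in names(regressors)) {
      out[[v]] <- regression_report(test$coverage, test[[paste0("pred_", v)]])
    }
    out
  })

  paths <- write_run_outputs(config, pairs, cohort_pairs, predictions,
                             class_report, reg_reports, extractor)
  structure(
    list(config = config, split = split, pairs = cohort_pairs,
         predictions = predictions, classifier = classifier,
         regressors = regressors, class_report = class_report,
         reg_reports = reg_reports, extractor_id = extractor$id,
         features = if (isTRUE(config$keep_features)) X,
         paths = paths),
    class = "slicecov_run")
}

serializable_config <- function(config) {
  cfg <- unclass(config)
  if (inherits(cfg$extractor, "feature_extractor")) {
    cfg$extractor <- cfg$extractor$id
  }
  cfg
}

write_run_outputs <- function(config, pairs, cohort_pairs, predictions,
                              class_report, reg_reports, extractor) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  jsonlite::write_json(serializable_config(config), p("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(pairs[, c("case_id", "coverage")], p("cases.csv"),
                   row.names = FALSE)
  manifest <- cohort_pairs[, c("case_id", "split", "aug_tumor",
                               "aug_ablation", "coverage")]
  utils::write.csv(manifest, p("pairs.csv"), row.names = FALSE)
  pred_out <- predictions
  pred_out$class_true <- as.character(pred_out$class_true)
  pred_out$class_pred <- as.character(pred_out$class_pred)
  utils::write.csv(pred_out, p("predictions.csv"), row.names = FALSE)
  metrics <- list(
    extractor = extractor$id,
    classification = as.list(glance(class_report)),
    regression = lapply(reg_reports, function(r) as.list(glance(r))))
  jsonlite::write_json(metrics, p("metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(config = p("config.json"), cases = p("cases.csv"),
       pairs = p("pairs.csv"), predictions = p("predictions.csv"),
       metrics = p("metrics.json"))
}

#' @export
print.slicecov_run <- function(x, ...) {
  cat("<slicecov_run> ", nrow(x$pairs), " pairs (level ", x$config$level,
      "), extractor ", x$extractor_id, "\n", sep = "")
  print(x$class_report)
  for (v in names(x$reg_reports)) {
    cat(v, ": ", sep = "")
    print(x$reg_reports[[v]])
  }
  invisible(x)
}

#' Label-permutation baseline for a regressor
#'
#' Refits the forest regressor `n_permutations` times on permuted training
#' labels and records the held-out MAE of each null fit. The p-value is
#' `(1 + #{null MAE <= observed MAE}) / (n_permutations + 1)` — the
#' probability of doing at least as well with the coverage labels
#' scrambled.
#'
#' @param x_train,y_train Training difference vectors and coverages.
#' @param x_test,y_test Held-out pairs.
#' @param n_permutations Number of null refits (default 20).
#' @param seed Integer seed (drives both permutations and forest seeds).
#' @param variant Regressor variant passed to [train_regressor()].
#' @return List with `observed_mae`, `null_maes`, `p_value`.
#' @export
mae_permutation_test <- function(x_train, y_train, x_test, y_test,
                                 n_permutations = 20, seed = 1L,
                                 variant = "rf") {
  model <- train_regressor(x_train, y_train, variant = variant,
                           seed = sub_seed(seed, "perm-observed"))
  observed <- mean(abs(predict_coverage(model, x_test) - y_test))
  null_maes <- vapply(seq_len(n_permutations), function(b) {
    y_perm <- withr::with_seed(sub_seed(seed, "perm-labels", b),
                               sample(y_train))
    m <- train_regressor(x_train, y_perm, variant = variant,
                         seed = sub_seed(seed, "perm-fit", b))
    mean(abs(predict_coverage(m, x_test) - y_test))
  }, numeric(1))
  list(observed_mae = observed, null_maes = null_maes,
       p_value = (1 + sum(null_maes <= observed)) / (n_permutations + 1))
}
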