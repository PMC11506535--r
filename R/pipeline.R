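#' Configuration of an end-to-end diagnostic run
#'
#' Bundles every stage's parameters. All randomness in a run flows from
#' `seed` through named substreams (cohort, CNN, explainer, folds), so a
#' rerun with the same configuration reproduces every report exactly.
#'
#' @param cohort a [cohort_spec()] (its seed is re-derived from `seed`) or
#'   a directory path previously written by [write_cohort()].
#' @param threshold segmentation threshold, degC.
#' @param cnn a [cnn_config()]; its seed is re-derived per fold. The default
#'   input size matches the aspect of the default cohort's side-by-side
#'   composite (two 32x32 breasts), so no distortion is introduced and the
#'   explainer's masks map back to grid cells one-to-one.
#' @param n_segments,n_samples,kernel_width,ridge,top_k explainer settings
#'   (see [explain_instance()] and [critical_roi()]).
#' @param fill replacement value for switched-off segments during
#'   perturbation. The pipeline default is 0 — the background value of a
#'   segmented, scaled thermogram — so that "segment off" reads as "tissue
#'   removed" rather than painting gray blocks over the background.
#' @param weight_floor if no explanation segment weight exceeds this, the
#'   case is treated as "no critical region found" and factors fall back to
#'   the whole affected breast (the typical behavior on healthy cases).
#' @param n_bins,disc_method discretization settings (see [discretize()]).
#' @param alpha Laplace smoothing pseudo-count for the network CPTs.
#' @param variant_bn `"tan"` or `"nb"` network variant.
#' @param K number of cross-validation folds.
#' @param resubstitution if `TRUE`, the CNN prediction node of Model B uses
#'   a single CNN trained on all images (resubstitution predictions);
#'   default `FALSE` uses out-of-fold CNN predictions so the node carries
#'   no information about its own row's training.
#' @param seed master seed of the run.
#' @param outdir optional output directory for artifacts.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       threshold = 29,
                       cnn = cnn_config(input_size = c(32L, 64L, 1L)),
                       n_segments = 16L, n_samples = 150L,
                       kernel_width = 0.25, ridge = 1.0, top_k = 3L, fill = 0,
                       weight_floor = 0.05,
                       n_bins = 3L, disc_method = "equal_frequency",
                       alpha = 1, variant_bn = "tan",
                       K = 5L, resubstitution = FALSE,
                       seed = 1L, outdir = NULL) {
  cfg <- list(cohort = cohort, threshold = threshold, cnn = cnn,
              n_segments = as.integer(n_segments),
              n_samples = as.integer(n_samples),
              kernel_width = kernel_width, ridge = ridge,
              top_k = as.integer(top_k), fill = fill,
              weight_floor = weight_floor,
              n_bins = as.integer(n_bins), disc_method = disc_method,
              alpha = alpha, variant_bn = variant_bn,
              K = as.integer(K), resubstitution = isTRUE(resubstitution),
              seed = as.integer(seed), outdir = outdir)
  stopifnot(cfg$K >= 2L, cfg$top_k >= 1L, cfg$n_segments >= 2L)
  structure(cfg, class = "run_config")
}

combine_pair <- function(pair) {
  thermogram(cbind(pair$left$values, pair$right$values),
             mask = cbind(pair$left$mask, pair$right$mask),
             meta = pair$left$meta[setdiff(names(pair$left$meta),
                                           "laterality")])
}

# split a composite grid and assign roles; any empty half propagates
roles_of <- function(composite, record) {
  halves <- split_bilateral(composite)
  assign_roles(halves$left, halves$right, record)
}

#' Run the shared pipeline core: segmentation, CNN, explanation, factors
#'
#' Executes the per-patient stages once so that Model A and Model B can be
#' evaluated on the same artifacts: thresholds the grids, trains one CNN
#' per cross-validation fold (each patient's predictions and explanations
#' come from the CNN that never saw that patient), localizes the critical
#' ROI with the perturbation explainer, extracts the thermal factors
#' (affected side restricted to the critical ROI when one is found, whole
#' healthy breast otherwise), and assembles the modeling table.
#'
#' @param config a [run_config()].
#' @return A list with `records`, `table` (factor table + `CNN_prediction`
#'   column), `folds`, `cnn_prob`, `cnn_label`, `cnn_metrics`,
#'   `roi_fallbacks` (patients whose factors used the whole-breast
#'   fallback), and `config`.
#' @export
run_pipeline_core <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed_cohort <- derive_seed(config$seed, 1L, 11L)
  seed_cnn <- derive_seed(config$seed, 2L, 12L)
  seed_xai <- derive_seed(config$seed, 3L, 13L)
  seed_folds <- derive_seed(config$seed, 4L, 14L)

  cohort <- if (is.character(config$cohort)) {
    read_cohort(config$cohort)
  } else {
    spec <- config$cohort
    spec$seed <- seed_cohort
    generate_cohort(spec)
  }
  records <- cohort$records
  n <- nrow(records)
  if (n < config$K) stop("fewer patients than folds", call. = FALSE)

  stage <- function(what, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] patient %s: %s", what, id, conditionMessage(e)),
           call. = FALSE))
  }

  composites <- lapply(seq_len(n), function(i)
    stage("segmentation", records$patient_id[i], {
      pair <- cohort$pairs[[i]]
      threshold_segment(combine_pair(pair), config$threshold)
    }))
  images <- lapply(composites, preprocess_for_cnn, config = config$cnn)

  y <- as.integer(records$diagnosis)
  folds <- stratified_folds(y, config$K, seed_folds)

  cnn_prob <- numeric(n)
  roi_pairs <- vector("list", n)
  fallbacks <- character()

  resub_model <- NULL
  if (config$resubstitution) {
    cfg_all <- config$cnn; cfg_all$seed <- seed_cnn
    resub_model <- cnn_train(cnn_build(cfg_all), images, y)
  }

  for (k in seq_len(config$K)) {
    tr <- which(folds != k); te <- which(folds == k)
    cfg_k <- config$cnn
    cfg_k$seed <- derive_seed(seed_cnn, k, 0L)
    model_k <- cnn_train(cnn_build(cfg_k), images[tr], y[tr])
    cnn_prob[te] <- cnn_predict(model_k, images[te])$probability_sick
    predictor <- function(imgs) cnn_predict(model_k, imgs)$probability_sick
    for (i in te) {
      id <- records$patient_id[i]
      roi_pairs[[i]] <- stage("explanation", id, {
        roles <- roles_of(composites[[i]], records[i, ])
        img <- images[[i]]
        map <- segment_superpixels(img, config$n_segments)
        expl <- explain_instance(img, predictor, map,
                                 n_samples = config$n_samples,
                                 kernel_width = config$kernel_width,
                                 ridge = config$ridge, fill = config$fill,
                                 seed = derive_seed(seed_xai, i, 0L))
        affected <- roles$affected
        used_fallback <- TRUE
        if (max(expl$segment_weights) > config$weight_floor) {
          crit <- tryCatch({
            cg <- critical_roi(composites[[i]], expl, config$top_k)
            ch <- split_bilateral(cg)
            half <- if (roles$affected$laterality == "left") ch$left else ch$right
            if (sum(half$grid$mask) >= 2L) half else NULL
          }, thermotan_empty_segmentation = function(e) NULL)
          if (!is.null(crit)) {
            crit$role <- "affected"
            affected <- crit
            used_fallback <- FALSE
          }
        }
        if (used_fallback) fallbacks <<- c(fallbacks, id)
        list(affected = affected, healthy = roles$healthy,
             explanation_r2 = expl$r2)
      })
    }
  }
  cnn_label <- as.integer(cnn_prob >= 0.5)
  tab <- factor_table(records, roi_pairs)
  src <- if (config$resubstitution)
    cnn_predict(resub_model, images)$label else cnn_label
  tab$CNN_prediction <- src[match(tab$patient_id, records$patient_id)]
  list(records = records, table = tab, folds = folds,
       cnn_prob = cnn_prob, cnn_label = cnn_label,
       cnn_metrics = eight_metrics(cnn_label, cnn_prob, y),
       roi_fallbacks = fallbacks, config = config)
}

bn_learner <- function(config, drop_cols) {
  list(
    fit = function(train) {
      train <- train[, setdiff(names(train), drop_cols), drop = FALSE]
      d <- suppressWarnings(discretize(train, target = "diagnosis",
                                       n_bins = config$n_bins,
                                       method = config$disc_method))
      tan_fit(d$data, target = "diagnosis", variant = config$variant_bn,
              alpha = config$alpha, scheme = d$scheme)
    },
    predict = function(model, test) {
      predict(model, test)[["1"]]
    })
}

evaluate_bn <- function(core, include_cnn_node) {
  config <- core$config
  drop_cols <- c("patient_id", if (!include_cnn_node) "CNN_prediction")
  seed_folds <- derive_seed(config$seed, 4L, 14L)
  cv <- kfold(core$table, "diagnosis", config$K,
              bn_learner(config, drop_cols), seed = seed_folds)
  full <- core$table[, setdiff(names(core$table), drop_cols), drop = FALSE]
  d <- suppressWarnings(discretize(full, target = "diagnosis",
                                   n_bins = config$n_bins,
                                   method = config$disc_method))
  list(confusion = cv$confusion,
       performance = cv$performance,
       metrics = eight_metrics(cv$predicted, cv$prob, cv$truth),
       mi_report = mi_report(d$data, "diagnosis", raw = full),
       prob = cv$prob, predicted = cv$predicted, truth = cv$truth,
       folds = cv$folds)
}

write_run_artifacts <- function(result, core, name) {
  outdir <- core$config$outdir
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(core$table, file.path(outdir, "factor_table.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$mi_report),
                   file.path(outdir, sprintf("%s_mi_report.csv", name)),
                   row.names = FALSE)
  sink(file.path(outdir, sprintf("%s_report.txt", name)))
  print(result$confusion); print(result$performance)
  sink()
  jsonlite::write_json(
    list(overall_precision = result$confusion$overall_precision,
         misclassified = result$confusion$misclassified,
         roc_index = result$performance$roc_index,
         gini_index = result$performance$gini_index,
         metrics = as.list(result$metrics)),
    file.path(outdir, sprintf("%s_summary.json", name)),
    auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Run Model A: thermal factors + medical records
#'
#' The fully interpretable diagnostic model: a tree-augmented naive Bayes
#' network over the thermal factors (extracted from the explainer's
#' critical ROI, falling back to the whole affected breast) together with
#' age and last menstrual period, evaluated by stratified K-fold
#' cross-validation with per-fold discretization and CPT fitting.
#'
#' @param config a [run_config()].
#' @param core optionally, a precomputed [run_pipeline_core()] result (for
#'   paired Model A / Model B comparisons on identical artifacts).
#' @return A list of class `"model_report"`: `confusion`, `performance`,
#'   `metrics`, `mi_report`, `prob`, `predicted`, `truth`, `folds`, plus
#'   the pipeline `core`.
#' @export
run_model_a <- function(config, core = NULL) {
  if (is.null(core)) core <- run_pipeline_core(config)
  res <- evaluate_bn(core, include_cnn_node = FALSE)
  res$core <- core
  res$variant <- "A"
  class(res) <- "model_report"
  write_run_artifacts(res, core, "model_a")
  res
}

#' Run Model B: Model A plus the CNN prediction node
#'
#' Identical to [run_model_a()] but with the CNN's predicted label added to
#' the network's feature set. By default the label entering each row is the
#' out-of-fold CNN prediction, so the node never encodes information about
#' the row it describes; `resubstitution = TRUE` in the configuration
#' reproduces the optimistic variant where one CNN sees all images.
#'
#' @inheritParams run_model_a
#' @return A list of class `"model_report"`; its `mi_report` contains the
#'   `CNN_prediction` node.
#' @export
run_model_b <- function(config, core = NULL) {
  if (is.null(core)) core <- run_pipeline_core(config)
  res <- evaluate_bn(core, include_cnn_node = TRUE)
  res$core <- core
  res$variant <- "B"
  class(res) <- "model_report"
  write_run_artifacts(res, core, "model_b")
  res
}

#' Run Model A and Model B on the same pipeline artifacts
#'
#' @param config a [run_config()].
#' @return A list with elements `A` and `B` (each a `"model_report"`)
#'   sharing one [run_pipeline_core()] result.
#' @export
run_models <- function(config) {
  core <- run_pipeline_core(config)
  list(A = run_model_a(config, core), B = run_model_b(config, core))
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("== Model %s (%s, %d-fold CV, %d patients) ==\n",
              x$variant, toupper(x$core$config$variant_bn),
              x$core$config$K, length(x$truth)))
  print(x$confusion)
  print(x$performance)
  invisible(x)
}
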