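#' Default workflow configuration
#'
#' Returns the full configuration list used by [run_workflow()], with every
#' default made explicit so the copy stored alongside a run is
#' self-describing. Fields given in `...` (or as a list/YAML path via
#' `config`) override the defaults.
#'
#' @param config Optional list or path to a YAML file with overrides.
#' @param ... Named overrides taking precedence over `config`.
#' @return A validated configuration list.
#' @export
workflow_config <- function(config = NULL, ...) {
  defaults <- list(
    response = "fassif",
    dataset = NULL,            # NULL = bundled dataset
    descriptors = "synthetic", # path to CSV or "synthetic"
    synthetic = list(),        # overrides for synthetic_spec()
    cube_root = TRUE,
    skew_limit = 2,
    kurt_limit = 7,
    cv_groups = 7,
    vip_keep = 100,
    max_components = 5,
    component_threshold = 0.01,
    selection_tol = 1e-6,
    relocate = TRUE,
    pca_components = 2,
    augment = character(),
    seed = 1,
    out_dir = NULL
  )
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  overrides <- c(config %||% list(), list(...))
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  cfg$response <- match.arg(tolower(cfg$response), media_codes())
  if (!is.null(cfg$dataset) && !file.exists(cfg$dataset)) {
    abort(paste0("dataset file not found: ", cfg$dataset))
  }
  if (!identical(cfg$descriptors, "synthetic") && !file.exists(cfg$descriptors)) {
    abort(paste0("descriptor file not found: ", cfg$descriptors))
  }
  if (is.null(cfg$out_dir)) abort("config requires an out_dir")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

workflow_log <- function(lines, path) {
  cat(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), lines, "\n"),
      file = path, append = TRUE, sep = "")
}

#' Run the complete model-building workflow
#'
#' Orchestrates the published protocol end to end: load the solubility
#' dataset and descriptors, preprocess (cube root, normality screen,
#' autoscale), response-sorted split, PCA/DModX outlier relocation, VIP
#' truncation to the top descriptors, greedy backward elimination monitored
#' by cross-validated Q2, optional experimental augmentation, final model
#' summary and inter-medium correlations. Every stage writes an artifact into
#' the run directory together with a manifest and a log; re-running an
#' identical configuration reproduces identical outputs.
#'
#' With `descriptors = "synthetic"` the descriptor matrix and response are
#' produced by [generate_latent_dataset()] (the dataset table is then built
#' around the synthetic response) so the full pipeline can be exercised and
#' validated against known ground truth.
#'
#' @param config Configuration list, YAML path or the result of
#'   [workflow_config()].
#' @param ... Overrides forwarded to [workflow_config()].
#' @return Invisibly, a list with the split, selection trace, final model,
#'   summary table, correlation table, ground truth (synthetic runs) and the
#'   run directory.
#' @export
run_workflow <- function(config = NULL, ...) {
  cfg <- workflow_config(config, ...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  if (file.exists(log_path)) unlink(log_path)
  artifacts <- character()
  emit <- function(name) artifacts <<- c(artifacts, name)
  stage <- function(name, expr) {
    workflow_log(paste0("stage ", name, " started"), log_path)
    out <- tryCatch(expr, error = function(e) {
      workflow_log(paste0("stage ", name, " FAILED: ", conditionMessage(e)), log_path)
      abort(paste0("workflow stage '", name, "': ", conditionMessage(e)))
    })
    workflow_log(paste0("stage ", name, " done"), log_path)
    out
  }
  set.seed(cfg$seed, kind = "Mersenne-Twister")

  cfg_store <- cfg
  cfg_store$augment <- as.list(cfg$augment)
  yaml::write_yaml(cfg_store, file.path(cfg$out_dir, "config.yaml"))
  emit("config.yaml")

  truth <- NULL
  if (identical(cfg$descriptors, "synthetic")) {
    synth <- stage("load", {
      spec <- do.call(synthetic_spec, utils::modifyList(
        list(seed = cfg$seed), cfg$synthetic))
      generate_latent_dataset(spec)
    })
    truth <- synth$truth
    desc <- synth$x
    # wrap the synthetic response as a solubility table in the chosen medium
    y_sol <- pmin(pmax(synth$y - 4, -12), 0)
    ds <- tibble::tibble(name = names(y_sol), set = NA_character_,
                         mw = 400, logd65 = 3, psa = 100, rotb = 5,
                         logs_phb = NA_real_, logs_fassif = NA_real_,
                         logs_hif = NA_real_, tm_c = NA_real_)
    ds[[medium_column(cfg$response)]] <- unname(y_sol)
    if (cfg$response != "phb") {
      # emulate measured buffer solubility correlated with the response so
      # experimental augmentation can be exercised end to end
      ds$logs_phb <- pmin(pmax(unname(y_sol) + rnorm(length(y_sol), 0, 0.4),
                               -12), 0)
    }
  } else {
    ds <- stage("load", {
      if (is.null(cfg$dataset)) solubility_data() else load_solubility_data(cfg$dataset)
    })
    desc <- stage("load", load_descriptor_matrix(cfg$descriptors))
  }
  write_solubility_data(ds, file.path(cfg$out_dir, "dataset.csv"))
  emit("dataset.csv")

  resp_col <- medium_column(cfg$response)
  ds_mod <- ds[!is.na(ds[[resp_col]]), , drop = FALSE]
  y_all <- setNames(ds_mod[[resp_col]], ds_mod$name)
  desc_m <- as_descriptor_matrix(desc)
  absent <- setdiff(ds_mod$name, rownames(desc_m))
  if (length(absent) > 0) {
    abort(paste0("no descriptors for compound(s): ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  desc_m <- desc_m[ds_mod$name, , drop = FALSE]

  prep <- stage("preprocess", preprocess_descriptors(
    desc_m, cube_root = cfg$cube_root,
    skew_limit = cfg$skew_limit, kurt_limit = cfg$kurt_limit))
  yaml::write_yaml(list(
    cube_root = prep$state$cube_root_applied,
    retained = prep$state$retained,
    excluded_nonnormal = prep$excluded,
    dropped_constant = prep$state$dropped_constant,
    centers = as.list(round(prep$state$centers, 10)),
    scales = as.list(round(prep$state$scales, 10))
  ), file.path(cfg$out_dir, "preprocess_state.yaml"))
  emit("preprocess_state.yaml")

  split <- stage("split", sorted_thirds_split(ds_mod, cfg$response))
  if (cfg$relocate) {
    split <- stage("relocate", relocate_outliers(
      split, prep$data, k = cfg$pca_components))
  }
  split_tbl <- tibble::tibble(
    name = c(split$train, split$test),
    set = c(rep("Tr", length(split$train)), rep("Te", length(split$test)))
  )
  readr::write_csv(split_tbl, file.path(cfg$out_dir, "split.csv"))
  readr::write_csv(split$relocations, file.path(cfg$out_dir, "relocations.csv"))
  emit("split.csv"); emit("relocations.csv")

  xm <- as_descriptor_matrix(prep$data)
  x_train <- xm[split$train, , drop = FALSE]
  y_train <- y_all[split$train]
  x_trunc <- stage("truncate", truncate_top_vip(
    x_train, y_train, keep = cfg$vip_keep, groups = cfg$cv_groups))
  kept <- attr(x_trunc, "kept")
  workflow_log(paste0("VIP truncation kept ", length(kept), " descriptors"), log_path)

  trace <- stage("select", greedy_backward_selection(
    x_trunc, y_train, groups = cfg$cv_groups, max_a = cfg$max_components,
    threshold = cfg$component_threshold, tol = cfg$selection_tol))
  readr::write_csv(trace$steps, file.path(cfg$out_dir, "trace.csv"))
  emit("trace.csv")
  workflow_log(paste0("selection removed ", sum(trace$steps$accepted),
                      " descriptors: ",
                      paste(trace$steps$descriptor[trace$steps$accepted],
                            collapse = ", ")), log_path)

  x_sel <- as_descriptor_matrix(x_trunc)[, trace$final, drop = FALSE]
  y_sel <- y_train
  augment_summary <- NULL
  if (length(cfg$augment) > 0) {
    aug <- stage("augment", augment_experimental(
      x_sel, y_sel, ds_mod, which = cfg$augment, groups = cfg$cv_groups,
      max_a = cfg$max_components, threshold = cfg$component_threshold,
      tol = cfg$selection_tol))
    x_sel <- as_descriptor_matrix(aug$data)
    y_sel <- aug$y
    augment_summary <- aug$summary
    readr::write_csv(aug$summary, file.path(cfg$out_dir, "augmentation.csv"))
    emit("augmentation.csv")
  }

  model <- stage("model", {
    sel <- choose_components(x_sel, y_sel, max_a = cfg$max_components,
                             groups = cfg$cv_groups,
                             threshold = cfg$component_threshold)
    fit <- fit_pls(x_sel, y_sel, sel$ncomp)
    attr(fit, "q2") <- sel$q2
    fit
  })
  write_pls_model(model, file.path(cfg$out_dir, "model"))
  emit("model/")

  test_names <- intersect(split$test, rownames(xm))
  x_test <- xm[test_names, model$descriptors[model$descriptors %in% colnames(xm)],
               drop = FALSE]
  summary_tbl <- stage("summarize", {
    if (setequal(colnames(x_test), model$descriptors) && length(test_names) > 0) {
      build_model_summary(model, attr(model, "q2"),
                          x_test[, model$descriptors, drop = FALSE],
                          y_all[test_names],
                          id = paste0(cfg$response, "_pls"),
                          augmentations = cfg$augment)
    } else {
      build_model_summary(model, attr(model, "q2"),
                          id = paste0(cfg$response, "_pls"),
                          augmentations = cfg$augment)
    }
  })
  readr::write_csv(summary_tbl, file.path(cfg$out_dir, "summary.csv"))
  yaml::write_yaml(as.list(summary_tbl), file.path(cfg$out_dir, "summary.yaml"))
  emit("summary.csv"); emit("summary.yaml")

  correlations <- stage("correlate", {
    pairs <- utils::combn(media_codes(), 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      ok <- sum(!is.na(ds[[medium_column(pr[1])]]) &
                  !is.na(ds[[medium_column(pr[2])]])) >= 3
      if (!ok) return(NULL)
      stratified_correlation(ds, pr[1], pr[2])
    })
    dplyr::bind_rows(rows)
  })
  readr::write_csv(correlations, file.path(cfg$out_dir, "correlations.csv"))
  emit("correlations.csv")

  manifest <- list(
    config_md5 = unname(tools::md5sum(file.path(cfg$out_dir, "config.yaml"))),
    seed = cfg$seed,
    artifacts = artifacts
  )
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  workflow_log("workflow complete", log_path)

  invisible(list(config = cfg, dataset = ds, split = split, trace = trace,
                 model = model, summary = summary_tbl,
                 correlations = correlations, truth = truth,
                 run_dir = cfg$out_dir))
}

#' Serialise a PLS model to a plain-text bundle
#'
#' Writes the weights, loadings and scores as CSV and the scalar metadata
#' (component count, y-loadings, centres, training statistics) as YAML.
#'
#' @param model A `pls_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pls_model <- function(model, dir) {
  stopifnot(inherits(model, "pls_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- tibble::as_tibble(model$W); wt$descriptor <- model$descriptors
  pt <- tibble::as_tibble(model$P); pt$descriptor <- model$descriptors
  st <- tibble::as_tibble(model$scores); st$name <- rownames(model$scores)
  readr::write_csv(wt[, c("descriptor", setdiff(names(wt), "descriptor"))],
                   file.path(dir, "weights.csv"))
  readr::write_csv(pt[, c("descriptor", setdiff(names(pt), "descriptor"))],
                   file.path(dir, "x_loadings.csv"))
  readr::write_csv(st[, c("name", setdiff(names(st), "name"))],
                   file.path(dir, "scores.csv"))
  yaml::write_yaml(list(
    ncomp = model$ncomp,
    y_loadings = as.list(model$q),
    y_center = model$y_center,
    x_center = as.list(setNames(model$x_center, model$descriptors)),
    r2 = model$r2, rmse_tr = model$rmse_tr,
    n = model$n, p = model$p
  ), file.path(dir, "meta.yaml"), precision = 15)
  invisible(dir)
}

#' Read a PLS model bundle written by [write_pls_model()]
#'
#' Restores everything needed for prediction and VIP. The training descriptor
#' matrix is not serialised, so DModX against the training residuals is not
#' available on a restored model.
#'
#' @param dir Bundle directory.
#' @return A `pls_model`.
#' @export
read_pls_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  wt <- readr::read_csv(file.path(dir, "weights.csv"), show_col_types = FALSE)
  pt <- readr::read_csv(file.path(dir, "x_loadings.csv"), show_col_types = FALSE)
  st <- readr::read_csv(file.path(dir, "scores.csv"), show_col_types = FALSE)
  descriptors <- wt$descriptor
  W <- as.matrix(wt[-1]); P <- as.matrix(pt[-1])
  rownames(W) <- rownames(P) <- descriptors
  Tm <- as.matrix(st[-1]); rownames(Tm) <- st$name
  q <- unlist(meta$y_loadings)
  x_center <- unlist(meta$x_center)[descriptors]
  coef_full <- pls_coefficients(W, P, q, meta$ncomp)
  tt <- colSums(Tm^2)
  structure(
    list(ncomp = meta$ncomp, W = W, P = P, q = q, scores = Tm,
         coefficients = coef_full, x_center = x_center,
         y_center = meta$y_center, fitted = NULL, y = NULL,
         r2 = meta$r2, r2_cum = NULL, rmse_tr = meta$rmse_tr,
         ssy_comp = q^2 * tt, n = meta$n, p = meta$p,
         descriptors = descriptors, train_matrix = NULL),
    class = "pls_model"
  )
}

#' Tabular and graphical reports for a completed run
#'
#' Reads the artifacts of a [run_workflow()] directory and produces the
#' standard report set: observed-versus-predicted values for the training
#' set, the inter-medium correlation table, the selection trace and
#' solubility-range tables, each written as a CSV next to the run artifacts
#' and returned together with ggplot objects.
#'
#' @param run_dir A directory produced by [run_workflow()].
#' @return A list with `tables` (named list of tibbles) and `plots`
#'   (named list of ggplot objects).
#' @export
report_figures <- function(run_dir) {
  need <- c("dataset.csv", "summary.csv", "correlations.csv", "model", "split.csv")
  missing_art <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing_art) > 0) {
    abort(paste0("run directory lacks artifact(s): ",
                 paste(missing_art, collapse = ", ")))
  }
  ds <- load_solubility_data(file.path(run_dir, "dataset.csv"))
  correlations <- readr::read_csv(file.path(run_dir, "correlations.csv"),
                                  show_col_types = FALSE)
  split_tbl <- readr::read_csv(file.path(run_dir, "split.csv"),
                               show_col_types = FALSE)
  summary_tbl <- readr::read_csv(file.path(run_dir, "summary.csv"),
                                 show_col_types = FALSE)
  cfg <- yaml::read_yaml(file.path(run_dir, "config.yaml"))
  model <- read_pls_model(file.path(run_dir, "model"))

  resp_col <- medium_column(cfg$response)
  obs <- setNames(ds[[resp_col]], ds$name)
  scores_names <- rownames(model$scores)
  obs_pred <- tibble::tibble(
    name = scores_names,
    observed = unname(obs[scores_names]),
    predicted = drop(model$y_center + model$scores %*% model$q),
    set = split_tbl$set[match(scores_names, split_tbl$name)]
  )
  ranges <- dplyr::bind_rows(lapply(media_codes(), function(m) {
    v <- ds[[medium_column(m)]]
    if (all(is.na(v))) return(NULL)
    summarize_solubility(ds, m)
  }))
  tables <- list(observed_vs_predicted = obs_pred,
                 correlations = correlations,
                 summary = summary_tbl,
                 solubility_ranges = ranges)
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(run_dir, paste0("fig_", nm, ".csv")))
  }
  plots <- list(
    observed_vs_predicted = plot_observed_predicted(obs_pred),
    solubility_ranges = plot_solubility_ranges(ds)
  )
  if (nrow(correlations) > 0) {
    first <- correlations[1, ]
    plots$media_correlation <- plot_media_correlation(
      ds, first$medium_a, first$medium_b)
  }
  list(tables = tables, plots = plots)
}
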