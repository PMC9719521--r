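#' Bootstrap ridge-logistic classification
#'
#' Training and evaluation by bootstrap resampling: in each iteration a
#' bootstrap training set is drawn (by sample, or by patient so that
#' biological replicates never straddle the train/test split), features
#' are standardized on the training set, optionally reduced by PCA to
#' the components explaining a target variance fraction, the inverse
#' regularization strength C is chosen by 10-fold cross-validation on
#' the training set, a class-balanced ridge-penalized logistic model is
#' fitted, and the out-of-bag samples are scored. AUC and accuracy are
#' recorded per iteration; each sample's out-of-bag probabilities are
#' aggregated by their median.
#'
#' @name classifier
NULL

#' Bootstrap configuration
#'
#' @param n_iterations number of bootstrap iterations (default 1000).
#' @param seed master seed; per-iteration substreams are derived
#'   deterministically so any iteration is reproducible in isolation.
#' @param pca_variance_target fraction of variance the kept principal
#'   components must explain, or `NA` to skip PCA.
#' @param C_grid inverse regularization strengths searched by
#'   cross-validation.
#' @param cv_folds cross-validation folds.
#' @param resample_unit `"sample"` or `"patient"`.
#' @param first_timepoint_only when `TRUE`, out-of-bag metrics use only
#'   each patient's first-timepoint sample.
#' @return A list of class `BootstrapConfig`.
#' @export
bootstrap_config <- function(n_iterations = 1000, seed = 1,
                             pca_variance_target = NA,
                             C_grid = c(1e-3, 1e-2, 1e-1, 1, 10, 100),
                             cv_folds = 10,
                             resample_unit = c("sample", "patient"),
                             first_timepoint_only = FALSE) {
  resample_unit <- match.arg(resample_unit)
  stopifnot(n_iterations >= 1, length(C_grid) >= 1,
            is.na(pca_variance_target) ||
              (pca_variance_target > 0 && pca_variance_target <= 1))
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 pca_variance_target = pca_variance_target,
                 C_grid = sort(C_grid), cv_folds = as.integer(cv_folds),
                 resample_unit = resample_unit,
                 first_timepoint_only = first_timepoint_only),
            class = "BootstrapConfig")
}

#' Standardize features (fit on train, apply to test)
#'
#' Columns are scaled to mean 0 and population standard deviation 1
#' using parameters estimated on the training rows only. Zero-variance
#' columns are flagged and mapped to 0.
#'
#' @param train numeric matrix used to fit the scaling.
#' @param test optional matrix scaled with the training parameters.
#' @return List with `train`, `test` (or `NULL`), `center`, `scale`,
#'   `constant` (logical per column).
#' @export
standardize <- function(train, test = NULL) {
  center <- colMeans(train)
  scale <- apply(train, 2, sd_pop)
  constant <- scale == 0
  scale[constant] <- 1
  apply_std <- function(m) {
    out <- sweep(sweep(m, 2, center), 2, scale, "/")
    out[, constant] <- 0
    out
  }
  list(train = apply_std(train),
       test = if (is.null(test)) NULL else apply_std(test),
       center = center, scale = scale, constant = constant)
}

#' Draw one bootstrap train/test split
#'
#' Unit `"sample"`: n samples drawn with replacement form the training
#' multiset; undrawn samples are the test set. Unit `"patient"`:
#' patients are drawn with replacement and every sample of a drawn
#' patient enters the training set (with the patient's multiplicity);
#' the test set is the samples of undrawn patients, so no patient can
#' appear on both sides.
#'
#' @param metadata data.frame with one row per sample; needs
#'   `patient_id` for patient-level resampling.
#' @param resample_unit `"sample"` or `"patient"`.
#' @return List with `train` (row indices, with multiplicity) and
#'   `test` (row indices).
#' @export
bootstrap_split <- function(metadata, resample_unit = "sample") {
  n <- nrow(metadata)
  if (resample_unit == "sample") {
    train <- sample.int(n, n, replace = TRUE)
    test <- setdiff(seq_len(n), unique(train))
  } else {
    stopifnot("patient_id" %in% names(metadata))
    patients <- unique(metadata$patient_id)
    drawn <- sample(patients, length(patients), replace = TRUE)
    train <- unlist(lapply(drawn, function(p)
      which(metadata$patient_id == p)), use.names = FALSE)
    test <- which(!metadata$patient_id %in% drawn)
  }
  list(train = train, test = test)
}

#' PCA reduction fitted on training data
#'
#' Keeps the smallest number of leading components whose cumulative
#' explained variance reaches `variance_target`; the test set is
#' projected with the training basis only.
#'
#' @param train standardized training matrix.
#' @param test optional matrix projected with the training rotation.
#' @param variance_target fraction in `(0, 1]`.
#' @return List with `train`, `test`, `rotation`, `center`,
#'   `n_components`.
#' @export
pca_reduce <- function(train, test = NULL, variance_target = 0.8) {
  pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= variance_target - 1e-12)[1]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  proj <- function(m) sweep(m, 2, pc$center) %*% rot
  list(train = pc$x[, seq_len(k), drop = FALSE],
       test = if (is.null(test)) NULL else proj(test),
       rotation = rot, center = pc$center, n_components = k)
}

# class-balanced ridge logistic fit at one C; returns a predictor
fit_ridge_logistic <- function(x, y, C) {
  n <- nrow(x)
  w <- ifelse(y, n / (2 * sum(y)), n / (2 * sum(!y)))
  lambda <- 1 / (n * C)
  # small CV folds legitimately carry few observations per class;
  # glmnet's small-n advisory is expected there
  withCallingHandlers(
    glmnet::glmnet(x, factor(y, levels = c(FALSE, TRUE)),
                   family = "binomial", alpha = 0,
                   lambda = lambda, weights = w,
                   standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

predict_prob <- function(fit, x) {
  as.numeric(stats::predict(fit, newx = x, type = "response"))
}

# 10-fold CV over the C grid, selection metric AUC, ties toward the
# smallest C (strongest regularization)
select_C <- function(x, y, C_grid, folds = 10) {
  n <- nrow(x)
  folds <- min(folds, n)
  fold_id <- sample(rep_len(seq_len(folds), n))
  aucs <- vapply(C_grid, function(C) {
    preds <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2) next
      fit <- fit_ridge_logistic(x[tr, , drop = FALSE], y[tr], C)
      preds[!tr] <- predict_prob(fit, x[!tr, , drop = FALSE])
    }
    ok <- !is.na(preds)
    if (length(unique(y[ok])) < 2) return(NA_real_)
    auc_rank(y[ok], preds[ok])
  }, numeric(1))
  if (all(is.na(aucs))) return(min(C_grid))
  best <- which(aucs >= max(aucs, na.rm = TRUE) - 1e-12)
  min(C_grid[best])
}

#' Bootstrap training and evaluation
#'
#' @param fm a `FeatureMatrix` whose metadata carries a logical or
#'   two-level `label` column (and `patient_id` / `timepoint` when
#'   needed).
#' @param config a `BootstrapConfig`.
#' @return An object of class `BootstrapResult`: per-iteration `auc`,
#'   `accuracy` and `chosen_C`; per-sample out-of-bag probability lists
#'   and their medians; 95% CIs; the number of redrawn degenerate
#'   iterations.
#' @export
bootstrap_train_eval <- function(fm, config = bootstrap_config()) {
  stopifnot(inherits(fm, "FeatureMatrix"), inherits(config, "BootstrapConfig"))
  x <- fm$x
  y <- as_binary_label(fm$metadata$label)
  md <- fm$metadata
  eval_mask <- rep(TRUE, nrow(x))
  if (config$first_timepoint_only) {
    stopifnot(all(c("patient_id", "timepoint") %in% names(md)))
    first_tp <- stats::ave(md$timepoint, md$patient_id, FUN = min)
    eval_mask <- md$timepoint == first_tp
  }
  n_iter <- config$n_iterations
  auc <- numeric(n_iter); acc <- numeric(n_iter); chosen <- numeric(n_iter)
  oob <- vector("list", nrow(x))
  n_redrawn <- 0
  for (i in seq_len(n_iter)) {
    set.seed(sub_seed(config$seed, i))
    repeat {
      sp <- bootstrap_split(md, config$resample_unit)
      if (length(unique(y[sp$train])) == 2 &&
          length(sp$test) > 0 && sum(eval_mask[sp$test]) > 0) break
      n_redrawn <- n_redrawn + 1
    }
    std <- standardize(x[sp$train, , drop = FALSE],
                       x[sp$test, , drop = FALSE])
    xtr <- std$train; xte <- std$test
    if (!is.na(config$pca_variance_target)) {
      pr <- pca_reduce(xtr, xte, config$pca_variance_target)
      xtr <- pr$train; xte <- pr$test
    }
    C <- select_C(xtr, y[sp$train], config$C_grid, config$cv_folds)
    fit <- fit_ridge_logistic(xtr, y[sp$train], C)
    prob <- predict_prob(fit, xte)
    for (j in seq_along(sp$test))
      oob[[sp$test[j]]] <- c(oob[[sp$test[j]]], prob[j])
    ev <- eval_mask[sp$test]
    ye <- y[sp$test][ev]; pe <- prob[ev]
    auc[i] <- if (length(unique(ye)) == 2) auc_rank(ye, pe) else NA_real_
    acc[i] <- if (length(ye)) mean((pe >= 0.5) == ye) else NA_real_
    chosen[i] <- C
  }
  med <- vapply(oob, function(p) if (length(p)) stats::median(p) else NA_real_,
                numeric(1))
  ci <- function(v) stats::quantile(v[!is.na(v)], c(0.025, 0.975), names = FALSE)
  structure(list(auc = auc, accuracy = acc, chosen_C = chosen,
                 oob_probabilities = oob, median_probability = med,
                 auc_ci = ci(auc), accuracy_ci = ci(acc),
                 mean_auc = mean(auc, na.rm = TRUE),
                 mean_accuracy = mean(acc, na.rm = TRUE),
                 n_redrawn = n_redrawn, config = config,
                 labels = y, metadata = md),
            class = "BootstrapResult")
}

#' @export
print.BootstrapResult <- function(x, ...) {
  cat(sprintf(
    "BootstrapResult: %d iterations; AUC %.3f [%.3f, %.3f]; accuracy %.3f\n",
    length(x$auc), x$mean_auc, x$auc_ci[1], x$auc_ci[2], x$mean_accuracy))
  invisible(x)
}

as_binary_label <- function(label) {
  if (is.logical(label)) return(label)
  lv <- sort(unique(as.character(label)))
  if (length(lv) != 2) stop("label must have exactly two levels")
  as.character(label) == lv[2]
}

#' Finalize a model and apply it to a validation cohort
#'
#' Trains one final model on all training data using the regularization
#' strength most frequently chosen across the bootstrap iterations
#' (ties toward stronger regularization), with standardization and PCA
#' fitted on the full training set, then scores the validation cohort
#' and bootstraps its metrics for confidence intervals.
#'
#' @param fm_train the training `FeatureMatrix`.
#' @param boot a `BootstrapResult` from [bootstrap_train_eval()].
#' @param fm_validation the validation `FeatureMatrix` (same columns).
#' @param n_ci_boot bootstrap resamples for the validation CIs.
#' @return List with `model` (class `FinalModel`), `probabilities`,
#'   `auc`, `accuracy`, `auc_ci`, `accuracy_ci`.
#' @export
finalize_and_apply <- function(fm_train, boot, fm_validation,
                               n_ci_boot = 1000) {
  stopifnot(identical(colnames(fm_train$x), colnames(fm_validation$x)))
  cfg <- boot$config
  y <- as_binary_label(fm_train$metadata$label)
  set.seed(sub_seed(cfg$seed, 0L))
  C <- mode_smallest(boot$chosen_C)
  std <- standardize(fm_train$x, fm_validation$x)
  xtr <- std$train; xva <- std$test
  pca <- NULL
  if (!is.na(cfg$pca_variance_target)) {
    pca <- pca_reduce(xtr, xva, cfg$pca_variance_target)
    xtr <- pca$train; xva <- pca$test
  }
  fit <- fit_ridge_logistic(xtr, y, C)
  model <- structure(list(center = std$center, scale = std$scale,
                          constant = std$constant,
                          pca_rotation = pca$rotation,
                          pca_center = pca$center,
                          coefficients = as.numeric(stats::coef(fit)),
                          C = C, config = cfg,
                          feature_names = colnames(fm_train$x),
                          train_probabilities = predict_prob(fit, xtr)),
                     class = "FinalModel")
  prob <- predict_prob(fit, xva)
  yv <- as_binary_label(fm_validation$metadata$label)
  auc <- auc_rank(yv, prob)
  acc <- mean((prob >= 0.5) == yv)
  nv <- length(yv)
  boots <- vapply(seq_len(n_ci_boot), function(b) {
    set.seed(sub_seed(cfg$seed, 100000 + b))
    idx <- sample.int(nv, nv, replace = TRUE)
    c(auc = if (length(unique(yv[idx])) == 2) auc_rank(yv[idx], prob[idx])
            else NA_real_,
      acc = mean((prob[idx] >= 0.5) == yv[idx]))
  }, numeric(2))
  ci <- function(v) stats::quantile(v[!is.na(v)], c(0.025, 0.975), names = FALSE)
  list(model = model, probabilities = prob, auc = auc, accuracy = acc,
       auc_ci = ci(boots["auc", ]), accuracy_ci = ci(boots["acc", ]))
}

#' Apply a finalized model to new features
#'
#' @param model a `FinalModel`.
#' @param x numeric matrix with the model's feature columns.
#' @return Predicted probabilities of the positive class.
#' @export
predict_final <- function(model, x) {
  stopifnot(inherits(model, "FinalModel"),
            identical(colnames(x), model$feature_names))
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  z[, model$constant] <- 0
  if (!is.null(model$pca_rotation))
    z <- sweep(z, 2, model$pca_center) %*% model$pca_rotation
  eta <- model$coefficients[1] + z %*% model$coefficients[-1]
  as.numeric(1 / (1 + exp(-eta)))
}

#' Serialize a finalized model as JSON
#'
#' @param model a `FinalModel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_final_model <- function(model, path) {
  out <- list(center = model$center, scale = model$scale,
              constant = model$constant,
              pca_rotation = model$pca_rotation,
              pca_center = model$pca_center,
              coefficients = model$coefficients, C = model$C,
              feature_names = model$feature_names,
              config = unclass(model$config))
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
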