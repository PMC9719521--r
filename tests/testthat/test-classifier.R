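test_that("standardization fits on train only, population SD", {
  tr <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  te <- cbind(a = c(4, 0), b = c(7, 7))
  std <- standardize(tr, te)
  expect_equal(colMeans(std$train), c(a = 0, b = 0))
  expect_equal(apply(std$train[, 1, drop = FALSE], 2, function(x)
    sqrt(mean((x - mean(x))^2))), c(a = 1))
  # zero-variance column flagged and mapped to 0
  expect_true(std$constant["b"])
  expect_equal(std$test[, "b"], c(0, 0))
  # test rows scaled with train parameters only (sd_pop of 1:3)
  expect_equal(std$test[, "a"], (c(4, 0) - 2) / sqrt(2 / 3))
  # leakage check: refitting on test would change the output
  std_leak <- standardize(te)
  expect_false(isTRUE(all.equal(std$test[, "a"], std_leak$train[, "a"])))
})

test_that("bootstrap splits respect the resampling unit", {
  md <- data.frame(sample = paste0("s", 1:8),
                   label = rep(c("x", "y"), 4),
                   patient_id = rep(paste0("p", 1:4), each = 2))
  set.seed(41)
  for (i in 1:50) {
    sp <- bootstrap_split(md, "patient")
    train_pat <- unique(md$patient_id[sp$train])
    test_pat <- unique(md$patient_id[sp$test])
    # patient integrity: never on both sides
    expect_length(intersect(train_pat, test_pat), 0)
    # all samples of a drawn patient enter training together
    for (p in train_pat)
      expect_true(all(which(md$patient_id == p) %in% sp$train))
    # a patient drawn twice contributes its samples twice
    tab <- table(md$patient_id[sp$train]) / 2
    expect_true(all(tab == round(tab)))
  }
  # sample-unit out-of-bag fraction approaches 1/e
  set.seed(42)
  md_big <- data.frame(sample = paste0("s", 1:200),
                       patient_id = paste0("p", 1:200))
  oob <- mean(replicate(200, length(bootstrap_split(md_big, "sample")$test)))
  expect_lt(abs(oob / 200 - exp(-1)), 0.02)
})

test_that("PCA reduction keeps the target variance, train basis only", {
  # first component carrying 90% of the variance -> one component kept
  set.seed(43)
  n <- 400
  x <- cbind(rnorm(n, sd = 3), rnorm(n, sd = 1))
  x <- x %*% matrix(c(0.8, 0.6, -0.6, 0.8), 2)
  ev <- eigen(cov(x))$values
  expect_gt(ev[1] / sum(ev), 0.88)
  pr <- pca_reduce(x, variance_target = 0.8)
  expect_equal(pr$n_components, 1)

  # exactly isotropic 10-dim data, target 0.8 -> 8 components
  iso <- rbind(diag(10), -diag(10))
  expect_equal(pca_reduce(iso, variance_target = 0.8)$n_components, 8)

  # the test projection uses the train rotation only
  te <- matrix(rnorm(20), 10, 2)
  pr2 <- pca_reduce(x, te, variance_target = 0.8)
  expect_equal(pr2$test,
               sweep(te, 2, pr2$center) %*% pr2$rotation)
})

test_that("bootstrap training is deterministic and separates classes", {
  env <- load_scenarios()
  set.seed(45)
  n <- 40
  y <- rep(c(FALSE, TRUE), each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:4)))
  x[, 1] <- x[, 1] + ifelse(y, 3, 0)
  x[, 2] <- x[, 2] - ifelse(y, 3, 0)
  md <- data.frame(sample = rownames(x), label = ifelse(y, "b", "a"),
                   patient_id = rownames(x))
  fm <- structure(list(x = x, metadata = md), class = "FeatureMatrix")
  cfg <- bootstrap_config(n_iterations = 30, seed = 7)
  r1 <- bootstrap_train_eval(fm, cfg)
  expect_gte(r1$mean_auc, 0.95)
  expect_true(all(unlist(r1$oob_probabilities) >= 0 &
                    unlist(r1$oob_probabilities) <= 1))
  # positive-class median probability exceeds negative-class median
  expect_gt(median(r1$median_probability[y], na.rm = TRUE),
            median(r1$median_probability[!y], na.rm = TRUE))
  # identical seed -> bit-identical result
  r2 <- bootstrap_train_eval(fm, cfg)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$median_probability, r2$median_probability)
  expect_identical(r1$chosen_C, r2$chosen_C)

  # permuted labels -> chance-level AUC
  md_perm <- md
  set.seed(46)
  md_perm$label <- sample(md$label)
  fm_perm <- structure(list(x = x, metadata = md_perm),
                       class = "FeatureMatrix")
  r3 <- bootstrap_train_eval(fm_perm, bootstrap_config(n_iterations = 30,
                                                       seed = 7))
  expect_gt(r3$mean_auc, 0.3)
  expect_lt(r3$mean_auc, 0.7)
})

test_that("first-timepoint restriction limits metric samples", {
  set.seed(47)
  n <- 24
  pat <- rep(paste0("p", 1:(n / 2)), 2)        # two timepoints each
  y <- as.integer(sub("p", "", pat)) <= n / 4  # label per patient
  x <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:3)))
  x[, 1] <- x[, 1] + ifelse(y, 3, 0)
  x[, 2] <- x[, 2] - ifelse(y, 3, 0)
  md <- data.frame(sample = rownames(x), label = ifelse(y, "b", "a"),
                   patient_id = pat,
                   timepoint = rep(c(1, 2), each = n / 2))
  fm <- structure(list(x = x, metadata = md), class = "FeatureMatrix")
  cfg <- bootstrap_config(n_iterations = 10, seed = 9,
                          resample_unit = "patient",
                          first_timepoint_only = TRUE)
  r <- bootstrap_train_eval(fm, cfg)
  expect_true(all(is.finite(r$accuracy)))
  expect_gte(r$mean_accuracy, 0.7)
})

test_that("finalization freezes the modal C and ignores validation labels", {
  set.seed(49)
  n <- 50
  y <- rep(c(FALSE, TRUE), each = n / 2)
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(paste0("s", 1:n), paste0("f", 1:4)))
  x[, 2] <- x[, 2] + ifelse(y, 3, 0)
  x[, 3] <- x[, 3] - ifelse(y, 3, 0)
  md <- data.frame(sample = rownames(x), label = ifelse(y, "b", "a"),
                   patient_id = rownames(x))
  fm <- structure(list(x = x, metadata = md), class = "FeatureMatrix")
  boot <- bootstrap_train_eval(fm, bootstrap_config(n_iterations = 20,
                                                    seed = 5))
  # held-out separable cohort
  nv <- 30
  yv <- rep(c(FALSE, TRUE), each = nv / 2)
  xv <- matrix(rnorm(nv * 4), nv, 4,
               dimnames = list(paste0("v", 1:nv), paste0("f", 1:4)))
  xv[, 2] <- xv[, 2] + ifelse(yv, 3, 0)
  xv[, 3] <- xv[, 3] - ifelse(yv, 3, 0)
  mdv <- data.frame(sample = rownames(xv), label = ifelse(yv, "b", "a"),
                    patient_id = rownames(xv))
  fmv <- structure(list(x = xv, metadata = mdv), class = "FeatureMatrix")
  fin <- finalize_and_apply(fm, boot, fmv, n_ci_boot = 200)
  expect_gte(fin$auc, 0.95)
  expect_equal(fin$model$C, griffin:::mode_smallest(boot$chosen_C))
  # applying the model to its own training data reproduces the stored
  # training probabilities
  expect_equal(predict_final(fin$model, x),
               fin$model$train_probabilities, tolerance = 1e-9)
  # flipping validation labels changes neither model nor probabilities
  mdv2 <- mdv; mdv2$label <- rev(mdv$label)
  fmv2 <- structure(list(x = xv, metadata = mdv2), class = "FeatureMatrix")
  fin2 <- finalize_and_apply(fm, boot, fmv2, n_ci_boot = 200)
  expect_identical(fin2$model$coefficients, fin$model$coefficients)
  expect_identical(fin2$probabilities, fin$probabilities)
  # validation on the training cohort matches in-sample scoring
  fin3 <- finalize_and_apply(fm, boot, fm, n_ci_boot = 50)
  expect_equal(fin3$probabilities, fin3$model$train_probabilities,
               tolerance = 1e-9)
  # CI width shrinks with validation cohort size
  big <- 8
  xb <- do.call(rbind, replicate(big, xv, simplify = FALSE))
  rownames(xb) <- paste0("vb", seq_len(nv * big))
  mdb <- data.frame(sample = rownames(xb),
                    label = rep(mdv$label, big),
                    patient_id = rownames(xb))
  fmb <- structure(list(x = xb, metadata = mdb), class = "FeatureMatrix")
  finb <- finalize_and_apply(fm, boot, fmb, n_ci_boot = 200)
  expect_lt(diff(finb$auc_ci), diff(fin$auc_ci) + 1e-9)

  # JSON serialization round-trips the coefficients
  path <- tempfile(fileext = ".json")
  write_final_model(fin$model, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$coefficients, fin$model$coefficients)
  expect_equal(back$C, fin$model$C)
})
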