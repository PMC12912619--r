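# Staged classification from SUVR + network features: feature assembly,
# train-only standardization, univariate filtering, LASSO selection with
# 5-fold CV, six classifier families tuned by CV AUC, bootstrap CIs, and
# Monte-Carlo permutation-sampling Shapley attribution.

stage_order <- c(CN = 1L, EMCI = 2L, LMCI = 3L, AD = 4L)

classifier_families <- c("svm", "rf", "lr", "mlp", "xgb", "knn")

#' Assemble a namespaced feature matrix
#'
#' Concatenates per-subject SUVR values (`suvr.<roi>`), global network
#' metric AUCs (`global.<metric>`) and nodal metric AUCs
#' (`nodal.<metric>.<roi>`) into one matrix, restricted to the subjects of
#' a binary task. The positive class is the later disease stage.
#'
#' @param suvr A [suvr_matrix()].
#' @param net_features Result of [cohort_network_features()] on the same
#'   subjects (NULL to use SUVR features only).
#' @param groups Group label per subject (same order as `suvr`).
#' @param task Character vector of the two group labels, e.g. c("CN", "AD").
#' @param global_metrics Which global metrics to include (default: the
#'   eight reported global properties).
#' @return Object of class `feature_matrix`: list with `values`, `labels`
#'   (factor, positive level last), `subject_ids`, `split` (NA until
#'   [stratified_split()]), `scaling`.
#' @export
assemble_features <- function(suvr, net_features, groups, task,
                              global_metrics = c("average_degree", "cp",
                                                 "eglob", "eloc", "avg_bc",
                                                 "sigma", "lambda", "gamma")) {
  stopifnot(inherits(suvr, "suvr_matrix"), length(task) == 2L)
  groups <- as.character(groups)
  keep <- which(groups %in% task)
  if (length(keep) == 0L) stop_("no subjects in task groups %s", paste(task, collapse = "/"))
  ids <- suvr$subject_ids[keep]
  blocks <- list()
  sv <- suvr$values[keep, , drop = FALSE]
  colnames(sv) <- paste0("suvr.", colnames(sv))
  blocks$suvr <- sv
  if (!is.null(net_features)) {
    if (!is.null(net_features$global_auc)) {
      ga <- as.matrix(net_features$global_auc)[keep, global_metrics, drop = FALSE]
      colnames(ga) <- paste0("global.", colnames(ga))
      blocks$global <- ga
    }
    if (!is.null(net_features$nodal_auc)) {
      for (nm in names(net_features$nodal_auc)) {
        na_ <- net_features$nodal_auc[[nm]][keep, , drop = FALSE]
        colnames(na_) <- paste0("nodal.", nm, ".", colnames(na_))
        blocks[[paste0("nodal.", nm)]] <- na_
      }
    }
  }
  values <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(values))) stop_("duplicate feature names after assembly")
  all_na <- apply(values, 2L, function(v) all(is.na(v)))
  if (any(all_na)) {
    warn_("dropping feature(s) not computed for this cohort: %s",
          paste(colnames(values)[all_na], collapse = ", "))
    values <- values[, !all_na, drop = FALSE]
  }
  if (anyNA(values)) {
    bad <- unique(colnames(values)[which(is.na(values), arr.ind = TRUE)[, 2L]])
    stop_("missing values in features: %s", paste(head(bad, 5L), collapse = ", "))
  }
  ord <- task[order(stage_order[task])]
  labels <- factor(groups[keep], levels = ord)
  rownames(values) <- ids
  structure(list(values = values, labels = labels, subject_ids = ids,
                 task = ord, split = rep(NA_character_, length(ids)),
                 scaling = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d subjects x %d features (%s vs %s%s)\n",
              nrow(x$values), ncol(x$values), x$task[1L], x$task[2L],
              if (all(is.na(x$split))) "" else ", split assigned"))
  invisible(x)
}

#' Stratified train/test split
#'
#' Assigns round(train_fraction * n) subjects of each class to the training
#' set, preserving class proportions within one subject; disjoint and
#' exhaustive; deterministic under `seed`.
#'
#' @param fm A `feature_matrix`.
#' @param train_fraction Training share (default 0.7).
#' @param seed Integer seed.
#' @return The feature matrix with its `split` slot filled.
#' @export
stratified_split <- function(fm, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  split <- rep("test", length(fm$labels))
  with_seed(derive_seed(seed, "split"), {
    for (lev in levels(fm$labels)) {
      idx <- which(fm$labels == lev)
      if (length(idx) < 2L) stop_("class '%s' has fewer than 2 subjects", lev)
      n_train <- round(train_fraction * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      split[sample(idx, n_train)] <- "train"
    }
  })
  fm$split <- split
  fm
}

#' Standardize features with train-only parameters
#'
#' Column means and SDs are fit on the training split and applied to every
#' subject, so no test information leaks into the scaling.
#'
#' @param fm A split `feature_matrix`.
#' @return The feature matrix with standardized `values` and `scaling` set.
#' @export
standardize_features <- function(fm) {
  tr <- fm$split == "train"
  if (!any(tr)) stop_("no training subjects; run stratified_split first")
  center <- colMeans(fm$values[tr, , drop = FALSE])
  scale_ <- apply(fm$values[tr, , drop = FALSE], 2L, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  fm$values <- sweep(sweep(fm$values, 2L, center), 2L, scale_, "/")
  fm$scaling <- list(center = center, scale = scale_)
  fm
}

#' Univariate feature filter on the training split
#'
#' Keeps features whose training-split two-group comparison (normality-gated
#' t vs Mann-Whitney, as in [compare_groups()]) has p < alpha.
#'
#' @param fm A split `feature_matrix`.
#' @param alpha Retention threshold (default 0.05, uncorrected).
#' @return The reduced feature matrix; attribute `filter_record` documents
#'   every feature's test and p-value.
#' @export
univariate_filter <- function(fm, alpha = 0.05) {
  tr <- fm$split == "train"
  la <- fm$labels[tr]
  if (min(table(la)) < 3L) stop_("need >= 3 training subjects per class")
  xs <- fm$values[tr, , drop = FALSE]
  rec <- lapply(seq_len(ncol(xs)), function(j) {
    a <- xs[la == levels(la)[1L], j]; b <- xs[la == levels(la)[2L], j]
    if (sd(a) == 0 && sd(b) == 0)
      return(data.frame(feature = colnames(xs)[j], test = "none", p = 1))
    cmp <- compare_groups(a, b, corrected_alpha = alpha)
    data.frame(feature = colnames(xs)[j], test = cmp$test_used, p = cmp$p_value)
  })
  rec <- do.call(rbind, rec)
  keep <- rec$p < alpha
  if (!any(keep))
    stop_("no features pass the univariate filter at alpha = %g; raise alpha", alpha)
  fm$values <- fm$values[, keep, drop = FALSE]
  attr(fm, "filter_record") <- rec
  fm
}

stratified_foldid <- function(labels, k, seed) {
  foldid <- integer(length(labels))
  with_seed(derive_seed(seed, "folds"), {
    for (lev in levels(labels)) {
      idx <- sample(which(labels == lev))
      foldid[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  foldid
}

#' LASSO feature selection with k-fold cross-validation
#'
#' Fits an L1-penalized logistic path on the training split; lambda is
#' chosen by minimum mean cross-validated deviance over stratified folds,
#' and the features with nonzero coefficients at that lambda are returned.
#'
#' @param fm A split (and typically standardized/filtered) `feature_matrix`.
#' @param n_folds CV folds (default 5).
#' @param seed Integer seed (fold assignment).
#' @return List with `selected` (feature names), `lambda`, and the
#'   `cv.glmnet` fit.
#' @export
lasso_select <- function(fm, n_folds = 5L, seed = 1L) {
  tr <- fm$split == "train"
  x <- fm$values[tr, , drop = FALSE]
  y <- fm$labels[tr]
  if (ncol(x) < 2L)   # nothing left to shrink
    return(list(selected = colnames(x), lambda = NA_real_, fit = NULL))
  foldid <- stratified_foldid(y, n_folds, seed)
  if (any(tapply(y, foldid, function(v) length(unique(v))) < 2L))
    stop_("degenerate folds: a fold lacks one class; reduce n_folds")
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                          type.measure = "deviance")
  co <- coef(cv, s = "lambda.min")
  nz <- rownames(co)[which(co[, 1L] != 0)]
  selected <- setdiff(nz, "(Intercept)")
  if (length(selected) == 0L) {
    warn_("LASSO shrank every coefficient to zero; keeping the single best-scored feature")
    co1 <- coef(cv$glmnet.fit, s = min(cv$glmnet.fit$lambda))
    selected <- rownames(co1)[-1L][which.max(abs(co1[-1L, 1L]))]
  }
  list(selected = selected, lambda = cv$lambda.min, fit = cv)
}

default_tuning_grids <- function() {
  list(svm = expand.grid(cost = c(0.1, 1, 10), kernel = c("linear", "radial"),
                         stringsAsFactors = FALSE),
       rf = expand.grid(ntree = c(100, 500)),
       lr = data.frame(dummy = 1),
       mlp = expand.grid(size = c(16, 64), decay = c(0.01, 0.1)),
       xgb = expand.grid(max_depth = c(2, 3, 4), nrounds = 100, eta = 0.1),
       knn = expand.grid(k = c(3, 5, 7, 11)))
}

fit_family <- function(family, x, y, pars, seed) {
  with_seed(derive_seed(seed, paste0("fit_", family)), {
    pos <- levels(y)[2L]
    switch(family,
      svm = e1071::svm(x, y, kernel = pars$kernel, cost = pars$cost,
                       probability = TRUE),
      rf = randomForest::randomForest(x, y, ntree = pars$ntree),
      lr = suppressWarnings(glm(y01 ~ ., family = binomial(),
                                data = data.frame(y01 = as.integer(y == pos),
                                                  x, check.names = FALSE))),
      mlp = nnet::nnet(x, class.ind(y), size = pars$size, decay = pars$decay,
                       softmax = TRUE, maxit = 300, trace = FALSE,
                       MaxNWts = 50000),
      xgb = xgboost::xgboost(x, y, nrounds = pars$nrounds,
                             max_depth = pars$max_depth,
                             learning_rate = pars$eta, nthread = 1,
                             verbosity = 0),
      knn = list(x = x, y = y, k = pars$k),  # lazy learner: store train set
      stop_("unknown classifier family '%s'", family))
  })
}

class.ind <- function(y) {
  m <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

predict_prob <- function(model, family, x, levels_) {
  pos <- levels_[2L]
  switch(family,
    svm = {
      pr <- attr(predict(model, x, probability = TRUE), "probabilities")
      pr[, pos]
    },
    rf = predict(model, x, type = "prob")[, pos],
    lr = {
      p <- predict(model, newdata = data.frame(x, check.names = FALSE),
                   type = "response")
      unname(p)
    },
    mlp = predict(model, x)[, pos],
    xgb = as.numeric(predict(model, x)),
    knn = {
      pr <- class::knn(model$x, x, model$y, k = model$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == pos, p, 1 - p)
    })
}

binary_metrics <- function(y, prob, levels_, threshold = 0.5) {
  pos <- levels_[2L]; neg <- levels_[1L]
  pred <- ifelse(prob >= threshold, pos, neg)
  tp <- sum(pred == pos & y == pos); tn <- sum(pred == neg & y == neg)
  fp <- sum(pred == pos & y == neg); fn <- sum(pred == neg & y == pos)
  auc <- if (length(unique(y)) < 2L) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                   levels = levels_, direction = "<",
                                   quiet = TRUE)))
  c(accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = auc)
}

bootstrap_ci <- function(y, prob, levels_, n_boot, seed) {
  stats_boot <- matrix(NA_real_, n_boot, 4L)
  with_seed(derive_seed(seed, "boot"), {
    idx_by <- split(seq_along(y), y)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(idx_by, function(ii) sample(ii, replace = TRUE)),
                    use.names = FALSE)
      stats_boot[b, ] <- suppressMessages(binary_metrics(y[idx], prob[idx], levels_))
    }
  })
  lo <- apply(stats_boot, 2L, quantile, 0.025, na.rm = TRUE)
  hi <- apply(stats_boot, 2L, quantile, 0.975, na.rm = TRUE)
  list(low = setNames(lo, c("accuracy", "sensitivity", "specificity", "auc")),
       high = setNames(hi, c("accuracy", "sensitivity", "specificity", "auc")))
}

#' Train, tune and evaluate one classifier family
#'
#' Hyperparameters are tuned by mean cross-validated AUC on stratified
#' training folds (the test split is never touched during tuning); the best
#' configuration is refit on the full training split and evaluated on both
#' splits with stratified-bootstrap percentile 95% CIs.
#'
#' @param fm A split, standardized `feature_matrix` (restrict its columns to
#'   the selected features before calling, if selection was run).
#' @param family One of `"svm"`, `"rf"`, `"lr"`, `"mlp"`, `"xgb"`, `"knn"`.
#' @param tuning_grid data.frame of configurations (default: shipped grid).
#' @param n_folds CV folds for tuning.
#' @param n_boot Bootstrap resamples for the CIs (default 2000).
#' @param seed Integer seed.
#' @return Object of class `model_report`.
#' @export
train_evaluate <- function(fm, family = "lr", tuning_grid = NULL,
                           n_folds = 5L, n_boot = 2000L, seed = 1L) {
  family <- match.arg(family, classifier_families)
  grid <- tuning_grid %||% default_tuning_grids()[[family]]
  tr <- fm$split == "train"; te <- fm$split == "test"
  x_tr <- fm$values[tr, , drop = FALSE]; y_tr <- fm$labels[tr]
  x_te <- fm$values[te, , drop = FALSE]; y_te <- fm$labels[te]
  if (length(unique(y_te)) < 2L) stop_("test split contains a single class")
  levels_ <- levels(fm$labels)
  foldid <- stratified_foldid(y_tr, n_folds, seed)
  cv_auc <- rep(NA_real_, nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    pars <- grid[gidx, , drop = FALSE]
    aucs <- rep(NA_real_, n_folds)
    for (f in seq_len(n_folds)) {
      inf <- foldid != f
      if (!any(!inf) || length(unique(y_tr[inf])) < 2L) next
      fit <- fit_family(family, x_tr[inf, , drop = FALSE], y_tr[inf], pars,
                        seed = seed + f)
      pr <- predict_prob(fit, family, x_tr[!inf, , drop = FALSE], levels_)
      aucs[f] <- binary_metrics(y_tr[!inf], pr, levels_)["auc"]
    }
    cv_auc[gidx] <- if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE)
  }
  best <- if (all(is.na(cv_auc))) 1L else which.max(cv_auc)
  pars <- grid[best, , drop = FALSE]
  model <- fit_family(family, x_tr, y_tr, pars, seed = seed)
  reports <- list()
  for (split_name in c("train", "test")) {
    xx <- if (split_name == "train") x_tr else x_te
    yy <- if (split_name == "train") y_tr else y_te
    prob <- predict_prob(model, family, xx, levels_)
    pt <- binary_metrics(yy, prob, levels_)
    ci <- bootstrap_ci(yy, prob, levels_, n_boot, seed)
    reports[[split_name]] <- data.frame(
      split = split_name, metric = names(pt), value = unname(pt),
      ci_low = unname(ci$low[names(pt)]), ci_high = unname(ci$high[names(pt)]),
      stringsAsFactors = FALSE)
  }
  prob_te <- predict_prob(model, family, x_te, levels_)
  roc_obj <- pROC::roc(response = y_te, predictor = prob_te, levels = levels_,
                       direction = "<", quiet = TRUE)
  structure(list(task = fm$task, family = family,
                 hyperparameters = as.list(pars), cv_auc = cv_auc[best],
                 metrics = do.call(rbind, reports),
                 selected_features = colnames(fm$values),
                 roc = data.frame(fpr = 1 - roc_obj$specificities,
                                  tpr = roc_obj$sensitivities),
                 model = model, levels = levels_, seed = seed),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("%s vs %s [%s] (positive class: %s)\n", x$task[1L], x$task[2L],
              x$family, x$task[2L]))
  m <- x$metrics
  for (s in c("train", "test")) {
    ms <- m[m$split == s, ]
    cat(sprintf("  %-5s %s\n", s,
                paste(sprintf("%s %.3f (%.3f, %.3f)", ms$metric, ms$value,
                              ms$ci_low, ms$ci_high), collapse = "  ")))
  }
  invisible(x)
}

#' Monte-Carlo permutation-sampling Shapley attribution
#'
#' Estimates per-subject, per-feature Shapley values of the model's positive
#' class probability by permutation sampling: for each sampled feature
#' ordering, features are switched one by one from the background value to
#' the subject's value and the marginal change in prediction is credited to
#' the switched feature. With a single background vector the per-permutation
#' credits sum exactly to prediction minus baseline, so the efficiency
#' property holds for the averaged estimates up to Monte-Carlo noise.
#'
#' @param report A `model_report` (its fitted model is explained).
#' @param fm The `feature_matrix` the model was trained on (train split
#'   medians form the background).
#' @param subjects Indices of subjects to explain (default: the test split).
#' @param n_samples Permutations per subject.
#' @param seed Integer seed.
#' @return Object of class `attribution_report`: list with `values`
#'   (subjects x features Shapley matrix), `baseline`, `ranking` (features
#'   by decreasing mean absolute attribution).
#' @export
shapley_attribution <- function(report, fm, subjects = NULL, n_samples = 100L,
                                seed = 1L) {
  stopifnot(inherits(report, "model_report"))
  f <- function(m) predict_prob(report$model, report$family, m, report$levels)
  shapley_attribution_fun(f, fm, subjects = subjects, n_samples = n_samples,
                          seed = seed, features = report$selected_features)
}

#' @rdname shapley_attribution
#' @param f Prediction function mapping a feature matrix to a numeric vector
#'   (one value per row); used in place of a fitted model.
#' @param features Feature columns to explain (default: all columns of `fm`).
#' @export
shapley_attribution_fun <- function(f, fm, subjects = NULL, n_samples = 100L,
                                    seed = 1L, features = colnames(fm$values)) {
  x <- fm$values[, features, drop = FALSE]
  if (is.null(subjects)) subjects <- which(fm$split == "test")
  p <- ncol(x)
  if (n_samples < 2L * p)
    warn_("n_samples (%d) below twice the feature count (%d); estimates will be noisy",
          n_samples, p)
  bg <- apply(x[fm$split == "train", , drop = FALSE], 2L, median)
  baseline <- f(matrix(bg, 1L, p, dimnames = list(NULL, colnames(x))))
  phi <- matrix(0, length(subjects), p, dimnames = list(fm$subject_ids[subjects],
                                                        colnames(x)))
  with_seed(derive_seed(seed, "shapley"), {
    for (si in seq_along(subjects)) {
      xs <- x[subjects[si], ]
      for (it in seq_len(n_samples)) {
        perm <- sample.int(p)
        # rows: background progressively replaced by subject values
        steps <- matrix(rep(bg, p + 1L), p + 1L, p, byrow = TRUE,
                        dimnames = list(NULL, colnames(x)))
        for (k in seq_len(p)) steps[(k + 1L):(p + 1L), perm[k]] <- xs[perm[k]]
        preds <- f(steps)
        phi[si, perm] <- phi[si, perm] + diff(preds)
      }
      phi[si, ] <- phi[si, ] / n_samples
    }
  })
  ranking <- colnames(phi)[order(-colMeans(abs(phi)))]
  structure(list(values = phi, baseline = baseline, ranking = ranking,
                 subjects = fm$subject_ids[subjects]),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("Shapley attributions for %d subjects; top features: %s\n",
              nrow(x$values), paste(head(x$ranking, 5L), collapse = ", ")))
  invisible(x)
}

#' Run the four staged binary tasks end to end
#'
#' For each task the pipeline is: stratified 70/30 split, train-only
#' standardization, univariate filtering, LASSO selection, training of the
#' requested classifier families with CV tuning, and selection of the
#' family with the best cross-validated AUC (the held-out split plays no
#' part in the choice).
#'
#' @param cohort A `cohort_tables` object (or list with `suvr` and
#'   `demographics`).
#' @param net_features Result of [cohort_network_features()]; computed here
#'   (with `small_world = FALSE` for speed) when NULL.
#' @param tasks List of 2-vectors of group labels.
#' @param families Classifier families to try.
#' @param filter_alpha Univariate filter level.
#' @param train_fraction,n_folds,n_boot,seed Passed through.
#' @return List of `model_report` objects (one per feasible task), with
#'   attribute `skipped` naming tasks whose groups were missing.
#' @export
run_task_suite <- function(cohort, net_features = NULL,
                           tasks = list(c("CN", "AD"), c("CN", "EMCI"),
                                        c("EMCI", "LMCI"), c("LMCI", "AD")),
                           families = c("lr", "rf", "xgb"),
                           filter_alpha = 0.05, train_fraction = 0.7,
                           n_folds = 5L, n_boot = 500L, seed = 1L) {
  groups <- cohort$demographics$group
  if (is.null(net_features))
    net_features <- cohort_network_features(cohort$suvr, groups,
                                            small_world = FALSE, seed = seed)
  reports <- list()
  skipped <- character()
  for (task in tasks) {
    nm <- paste(task, collapse = "_vs_")
    if (!all(task %in% groups)) {
      skipped <- c(skipped, nm)
      message("task ", nm, " skipped: group absent")
      next
    }
    fm <- assemble_features(cohort$suvr, net_features, groups, task)
    fm <- stratified_split(fm, train_fraction, seed)
    fm <- standardize_features(fm)
    fm <- tryCatch(univariate_filter(fm, filter_alpha), error = function(e) fm)
    sel <- lasso_select(fm, n_folds, seed)
    fm$values <- fm$values[, sel$selected, drop = FALSE]
    fits <- lapply(families, function(fam)
      train_evaluate(fm, fam, n_folds = n_folds, n_boot = n_boot, seed = seed))
    best <- which.max(vapply(fits, function(r) r$cv_auc, numeric(1L)))
    rep_ <- fits[[best]]
    rep_$lambda <- sel$lambda
    reports[[nm]] <- rep_
  }
  attr(reports, "skipped") <- skipped
  reports
}

#' Write a model report (metrics + ROC) to CSV/JSON
#' @param report A `model_report`.
#' @param dir Output directory.
#' @export
write_model_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- paste(report$task, collapse = "_vs_")
  write.csv(report$metrics, file.path(dir, paste0(base, "_metrics.csv")),
            row.names = FALSE)
  write.csv(report$roc, file.path(dir, paste0(base, "_roc.csv")),
            row.names = FALSE)
  jsonlite::write_json(
    list(task = report$task, family = report$family,
         hyperparameters = report$hyperparameters, cv_auc = report$cv_auc,
         selected_features = report$selected_features, seed = report$seed),
    file.path(dir, paste0(base, "_report.json")), auto_unbox = TRUE)
  invisible(dir)
}
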