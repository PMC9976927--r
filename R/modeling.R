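# Gradient-boosted (and reference) regression models of the pausing
# index: holdout splitting, grid-searched cross-validated training,
# evaluation, cross-cell-line feature synchronization and the
# differential-pausing evaluation.

#' Model specification
#'
#' @param learner `"xgb"` (extreme gradient boosting, default), `"gbdt"`
#'   (plain gradient-boosted trees: no row/column subsampling), `"rf"`
#'   (random forest) or `"ridge"` (L2-penalized linear regression).
#' @param eta,max_depth candidate learning rates and tree depths; the
#'   full grid is searched by mean cross-validated R-squared. The
#'   defaults favor shallow trees with a small learning rate, which
#'   generalize markedly better than deep trees on sparse binary
#'   binding designs (low-order interactions, many weak main effects).
#' @param subsample,colsample row/column subsampling for `"xgb"`.
#' @param nrounds_max boosting-round cap; each CV fold early-stops on its
#'   validation fold.
#' @param early_stopping early-stopping patience (rounds).
#' @param n_folds number of CV folds (default 5).
#' @param holdout_fraction fraction of transcripts held out before
#'   training (default 0.5).
#' @param num_trees trees for `"rf"`.
#' @param seed integer; every source of randomness (split, folds,
#'   learner) derives from it.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(learner = c("xgb", "gbdt", "rf", "ridge"),
                       eta = c(0.03, 0.05), max_depth = c(2L, 3L, 4L),
                       subsample = 0.8, colsample = 0.8,
                       nrounds_max = 2000L, early_stopping = 100L,
                       n_folds = 5L, holdout_fraction = 0.5,
                       num_trees = 500L, seed = 1L) {
  learner <- match.arg(learner)
  stopifnot(holdout_fraction > 0, holdout_fraction < 1, n_folds >= 2L)
  structure(list(learner = learner,
                 grid = CJ(eta = eta, max_depth = as.integer(max_depth)),
                 subsample = subsample, colsample = colsample,
                 nrounds_max = as.integer(nrounds_max),
                 early_stopping = as.integer(early_stopping),
                 n_folds = as.integer(n_folds),
                 holdout_fraction = holdout_fraction,
                 num_trees = as.integer(num_trees),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Random holdout split
#'
#' @param ids transcript ids (>= 10 required).
#' @param fraction holdout fraction in (0, 1).
#' @param seed integer seed; the split is seed-reproducible.
#' @return List with disjoint, exhaustive `train` and `test` id vectors;
#'   test size is `round(fraction * n)`.
#' @export
split_holdout <- function(ids, fraction = 0.5, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  if (length(ids) < 10L) stop("need at least 10 ids to split")
  set.seed(seed)
  n_test <- round(fraction * length(ids))
  test <- sample(ids, n_test)
  list(train = setdiff(ids, test), test = test)
}

r_squared <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - yhat)^2)
  if (ss_tot == 0) return(if (ss_res == 0) 0 else -Inf) # constant target
  1 - ss_res / ss_tot
}

xgb_params <- function(spec, cfg) {
  list(objective = "reg:squarederror", eta = cfg$eta,
       max_depth = cfg$max_depth,
       subsample = if (spec$learner == "gbdt") 1 else spec$subsample,
       colsample_bytree = if (spec$learner == "gbdt") 1 else spec$colsample,
       nthread = 1L, seed = spec$seed)
}

#' Train a pausing-index regressor
#'
#' For tree-boosting learners, every grid configuration is scored by
#' mean R-squared over `n_folds` cross-validation folds (each fold early
#' stops on its validation fold), the best configuration is chosen (ties:
#' fewer boosting rounds, then smaller depth) and refit on all training
#' rows at the fold-mean best iteration. `"rf"` and `"ridge"` fit their
#' standard estimators (ridge selects its penalty by internal CV).
#'
#' @param X numeric feature matrix (training rows only).
#' @param y numeric targets; non-finite values are an error.
#' @param spec a [model_spec()].
#' @return A list of class `pause_fit`: `learner`, `model`,
#'   `feature_names`, `cv_table` (per-config mean CV R-squared),
#'   `best_config`, `nrounds`, `train_ids`, `train_col_means`, `seed`.
#' @export
train_model <- function(X, y, spec = model_spec()) {
  if (any(!is.finite(y))) stop("non-finite targets")
  stopifnot(nrow(X) == length(y))
  set.seed(spec$seed)
  folds <- sample(rep_len(seq_len(spec$n_folds), nrow(X)))
  cv_table <- NULL; best <- NULL; nrounds <- NA_integer_

  if (spec$learner %in% c("xgb", "gbdt")) {
    grid <- spec$grid
    res <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
      cfg <- grid[g]
      r2s <- numeric(spec$n_folds); iters <- integer(spec$n_folds)
      for (f in seq_len(spec$n_folds)) {
        tr <- folds != f
        dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
        dva <- xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], label = y[!tr])
        m <- xgboost::xgb.train(params = xgb_params(spec, cfg), data = dtr,
                                nrounds = spec$nrounds_max,
                                evals = list(val = dva), verbose = 0,
                                early_stopping_rounds = spec$early_stopping)
        it <- xgboost::xgb.attributes(m)$best_iteration
        iters[f] <- if (is.null(it)) spec$nrounds_max else as.integer(it)
        p <- predict(m, X[!tr, , drop = FALSE])
        r2s[f] <- r_squared(y[!tr], p)
      }
      res[[g]] <- data.table(eta = cfg$eta, max_depth = cfg$max_depth,
                             cv_r2 = mean(r2s),
                             mean_iter = max(1L, as.integer(round(mean(iters)))))
    }
    cv_table <- rbindlist(res)
    # best mean CV R2; ties -> fewer rounds, then smaller depth
    ord <- order(-cv_table$cv_r2, cv_table$mean_iter, cv_table$max_depth)
    best <- cv_table[ord[1L]]
    nrounds <- best$mean_iter
    dall <- xgboost::xgb.DMatrix(X, label = y)
    model <- xgboost::xgb.train(params = xgb_params(spec, best), data = dall,
                                nrounds = nrounds, verbose = 0)
  } else if (spec$learner == "rf") {
    r2s <- numeric(spec$n_folds)
    for (f in seq_len(spec$n_folds)) {
      tr <- folds != f
      m <- ranger::ranger(x = X[tr, , drop = FALSE], y = y[tr],
                          num.trees = spec$num_trees, seed = spec$seed,
                          mtry = max(1L, floor(ncol(X) / 3)),
                          num.threads = 1L)
      p <- predict(m, X[!tr, , drop = FALSE], num.threads = 1L)$predictions
      r2s[f] <- r_squared(y[!tr], p)
    }
    cv_table <- data.table(cv_r2 = mean(r2s))
    model <- ranger::ranger(x = X, y = y, num.trees = spec$num_trees,
                            seed = spec$seed,
                            mtry = max(1L, floor(ncol(X) / 3)),
                            num.threads = 1L)
  } else { # ridge
    set.seed(spec$seed)
    cvm <- glmnet::cv.glmnet(X, y, alpha = 0, nfolds = spec$n_folds)
    model <- cvm
    p_cv <- predict(cvm, X, s = "lambda.min")[, 1L]
    cv_table <- data.table(cv_r2 = r_squared(y, p_cv),
                           lambda = cvm$lambda.min)
  }
  structure(list(learner = spec$learner, model = model,
                 feature_names = colnames(X), cv_table = cv_table,
                 best_config = best, nrounds = nrounds,
                 train_col_means = colMeans(X), seed = spec$seed),
            class = "pause_fit")
}

check_columns <- function(fit, X) {
  missing <- setdiff(fit$feature_names, colnames(X))
  extra <- setdiff(colnames(X), fit$feature_names)
  if (length(missing) || length(extra))
    stop(sprintf("feature columns mismatch; missing: [%s]; extra: [%s]",
                 paste(head(missing, 5L), collapse = ", "),
                 paste(head(extra, 5L), collapse = ", ")))
  X[, fit$feature_names, drop = FALSE]
}

#' Predict from a fitted pausing model
#' @param object a `pause_fit`.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.pause_fit <- function(object, newdata, ...) {
  X <- check_columns(object, newdata)
  switch(object$learner,
         xgb = , gbdt = predict(object$model, X),
         rf = predict(object$model, X, num.threads = 1L)$predictions,
         ridge = predict(object$model, X, s = "lambda.min")[, 1L])
}

#' Evaluate a fitted model
#'
#' @param fit a `pause_fit`.
#' @param X feature matrix; columns must match the training feature list
#'   (mismatches error listing missing/extra names).
#' @param y observed targets.
#' @return List with `r2` (coefficient of determination), `rho` (Pearson
#'   correlation of observed and predicted) and `predictions`.
#' @export
evaluate_model <- function(fit, X, y) {
  p <- predict(fit, X)
  list(r2 = r_squared(y, p),
       rho = suppressWarnings(cor(y, p)),
       predictions = setNames(p, rownames(X)))
}

#' Synchronize two feature matrices to their common columns
#'
#' Cross-cell-line models are trained only on features present in both
#' cell lines; this restricts both matrices to the name intersection in
#' identical column order.
#'
#' @param fmA,fmB `feature_matrix` objects.
#' @return List of the two restricted matrices (`a`, `b`); an empty
#'   intersection is an error.
#' @export
synchronize_features <- function(fmA, fmB) {
  common <- intersect(fmA$meta$name, fmB$meta$name)
  if (length(common) == 0L) stop("no common feature columns")
  list(a = structure(list(X = fmA$X[, common, drop = FALSE],
                          meta = fmA$meta[match(common, name)],
                          polii = fmA$polii), class = "feature_matrix"),
       b = structure(list(X = fmB$X[, common, drop = FALSE],
                          meta = fmB$meta[match(common, name)],
                          polii = fmB$polii), class = "feature_matrix"))
}

#' Differential pausing evaluation between two cell lines
#'
#' Transcripts shared by both cell lines are grouped by observed
#' pausing-index difference: A-specific (`yA - yB >= threshold`),
#' B-specific (`<= -threshold`) and stable (absolute difference below
#' threshold). Within each group the Pearson correlation of observed
#' differences with differences of cross-cell predictions is reported.
#'
#' @param yA,yB named observed pausing indices per cell line.
#' @param predA_by_Bmodel named predictions of cell A's indices by the
#'   model trained on cell B.
#' @param predB_by_Amodel named predictions of cell B's indices by the
#'   model trained on cell A.
#' @param log2_fc_threshold group threshold on the log2 difference
#'   (default 1, i.e. 2-fold).
#' @return `data.table(group, n, rho)`; groups with fewer than 3 members
#'   get `NA` with a warning.
#' @export
differential_pausing_eval <- function(yA, yB, predA_by_Bmodel,
                                      predB_by_Amodel,
                                      log2_fc_threshold = 1) {
  shared <- Reduce(intersect, list(names(yA), names(yB),
                                   names(predA_by_Bmodel),
                                   names(predB_by_Amodel)))
  if (length(shared) == 0L) stop("no shared transcript ids")
  d_obs <- yA[shared] - yB[shared]
  d_pred <- predA_by_Bmodel[shared] - predB_by_Amodel[shared]
  grp <- fifelse(d_obs >= log2_fc_threshold, "A_specific",
                 fifelse(d_obs <= -log2_fc_threshold, "B_specific",
                         "stable"))
  out <- vector("list", 3L)
  for (k in seq_along(c("A_specific", "B_specific", "stable"))) {
    g <- c("A_specific", "B_specific", "stable")[k]
    idx <- grp == g
    rho <- if (sum(idx) >= 3L) cor(d_obs[idx], d_pred[idx]) else {
      warning(sprintf("group '%s' has fewer than 3 members", g))
      NA_real_
    }
    out[[k]] <- data.table(group = g, n = sum(idx), rho = rho)
  }
  rbindlist(out)
}

#' Pol II-only reference model
#'
#' Trains and evaluates a model restricted to the POLR2* binding columns
#' held in the feature matrix's side table (no annotation block).
#'
#' @param fm a `feature_matrix` with a non-empty `polii` side table.
#' @param y named pausing indices aligned with `rownames(fm$X)`.
#' @param spec a [model_spec()].
#' @return List with `fit`, `r2`, `rho`, `split`.
#' @export
polii_only_model <- function(fm, y, spec = model_spec()) {
  if (is.null(fm$polii) || ncol(fm$polii) == 0L)
    stop("no POLR2* columns available")
  X <- fm$polii
  ids <- rownames(X)
  sp <- split_holdout(ids, spec$holdout_fraction, spec$seed)
  fit <- train_model(X[sp$train, , drop = FALSE], y[sp$train], spec)
  ev <- evaluate_model(fit, X[sp$test, , drop = FALSE], y[sp$test])
  list(fit = fit, r2 = ev$r2, rho = ev$rho, split = sp)
}
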