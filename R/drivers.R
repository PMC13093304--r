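DRIVER_FEATURES <- c("duration", "elevation", "mat", "map", "igbp")

#' Build the driver feature table
#'
#' Joins valid resistance records to event durations and site metadata,
#' yielding one row per event with the five drivers of resistance:
#' freeze-thaw duration (days), elevation (m), MAT (degC), MAP (mm) and
#' IGBP ecosystem type, plus the chosen target ratio.
#'
#' @param records Row-bound [event_resistance()] records.
#' @param events The matching [detect_events()] table.
#' @param sites Site table from [read_site_table()].
#' @param target `"rt_nee"` or `"rt_re"`.
#' @return Data frame `event_id`, `site_id`, the five features (`igbp` as
#'   a factor over the five classes) and `target`; attribute
#'   `target_name` records which ratio it is.
#' @export
build_feature_table <- function(records, events, sites,
                                target = c("rt_nee", "rt_re")) {
  target <- match.arg(target)
  if (anyDuplicated(events$event_id)) {
    stop("duplicate event_id in events: ",
         events$event_id[anyDuplicated(events$event_id)])
  }
  keep <- records[records$valid, , drop = FALSE]
  ev_idx <- match(keep$event_id, events$event_id)
  site_idx <- match(keep$site_id, sites$site_id)
  if (anyNA(ev_idx)) {
    stop("event_id not joinable: ",
         paste(keep$event_id[is.na(ev_idx)], collapse = ", "))
  }
  if (anyNA(site_idx)) {
    stop("site_id not in site table: ",
         paste(unique(keep$site_id[is.na(site_idx)]), collapse = ", "))
  }
  out <- data.frame(event_id = keep$event_id,
                    site_id = keep$site_id,
                    duration = events$duration[ev_idx],
                    elevation = sites$elevation[site_idx],
                    mat = sites$mat[site_idx],
                    map = sites$map[site_idx],
                    igbp = factor(sites$igbp[site_idx],
                                  levels = IGBP_CLASSES),
                    target = keep[[target]],
                    stringsAsFactors = FALSE)
  attr(out, "target_name") <- target
  out
}

encode_features <- function(df) {
  m <- cbind(duration = as.numeric(df$duration),
             elevation = as.numeric(df$elevation),
             mat = as.numeric(df$mat),
             map = as.numeric(df$map))
  igbp <- factor(df$igbp, levels = IGBP_CLASSES)
  onehot <- outer(igbp, IGBP_CLASSES, "==") * 1
  colnames(onehot) <- paste0("igbp_", IGBP_CLASSES)
  cbind(m, onehot)
}

#' Fit a gradient-boosted tree model of resistance
#'
#' Boosted regression trees (XGBoost backend) predicting a resistance
#' ratio from the five site/event drivers. Defaults are the tuned
#' hyperparameters `max_depth = 4`, `eta = 0.5`, `nrounds = 20`; the
#' non-tuned parameters are pinned (`subsample = 1`,
#' `min_child_weight = 1`, `colsample_bytree = 1`) and recorded in the
#' fit. Performance (out-of-fold R2, MAE, RMSE, and the slope of observed
#' regressed on predicted) comes from seeded k-fold cross-validation; the
#' returned predictor is refit on all rows. Training-set metrics are kept
#' alongside under `metrics_train`.
#'
#' @param table A [build_feature_table()] result.
#' @param hyperparams List with `max_depth`, `eta`, `nrounds`.
#' @param cv_k Number of folds (default 5).
#' @param seed Integer seed fixing fold assignment.
#' @return Object of class `ftc_gbt` with elements `booster`,
#'   `hyperparams`, `fixed_params`, `cv_k`, `seed`, `metrics` (out-of-fold
#'   `r2`, `slope`, `mae`, `rmse`), `metrics_train`, `oof_predictions`.
#' @export
fit_gbt <- function(table,
                    hyperparams = list(max_depth = 4, eta = 0.5, nrounds = 20),
                    cv_k = 5L, seed = 1L) {
  n <- nrow(table)
  if (n < 2L * cv_k) stop("need at least 2*cv_k rows, have ", n)
  # canonical row order (by event id when available) so that fold
  # assignment, hence every metric, is invariant to input row order
  ord <- if (!is.null(table$event_id)) order(table$event_id) else seq_len(n)
  table <- table[ord, , drop = FALSE]
  y <- table$target
  X <- encode_features(table)
  fixed <- list(subsample = 1, min_child_weight = 1, colsample_bytree = 1)
  params <- list(max_depth = hyperparams$max_depth, eta = hyperparams$eta,
                 objective = "reg:squarederror", nthread = 1,
                 subsample = fixed$subsample,
                 min_child_weight = fixed$min_child_weight,
                 colsample_bytree = fixed$colsample_bytree)
  train <- function(idx) {
    dm <- xgboost::xgb.DMatrix(X[idx, , drop = FALSE], label = y[idx],
                               nthread = 1)
    xgboost::xgb.train(params = params, data = dm,
                       nrounds = hyperparams$nrounds, verbose = 0)
  }
  folds <- with_seed(seed, sample(rep(seq_len(cv_k), length.out = n)))
  oof <- rep(NA_real_, n)
  for (k in seq_len(cv_k)) {
    hold <- folds == k
    bst <- train(which(!hold))
    oof[hold] <- predict(bst, xgboost::xgb.DMatrix(X[hold, , drop = FALSE],
                                                   nthread = 1))
  }
  booster <- train(seq_len(n))
  fitted <- predict(booster, xgboost::xgb.DMatrix(X, nthread = 1))

  score <- function(obs, pred, warn = TRUE) {
    mae <- mean(abs(obs - pred))
    rmse <- sqrt(mean((obs - pred)^2))
    if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
      if (warn) {
        warning("[ftcflux] degenerate target or predictions; r2 set to 0",
                call. = FALSE)
      }
      return(list(r2 = 0, slope = NA_real_, mae = mae, rmse = rmse))
    }
    fit <- stats::lm(obs ~ pred)
    list(r2 = stats::cor(obs, pred)^2,
         slope = unname(stats::coef(fit)[2L]),
         mae = mae, rmse = rmse)
  }
  structure(list(booster = booster, hyperparams = hyperparams,
                 fixed_params = fixed, cv_k = cv_k, seed = seed,
                 feature_names = colnames(X),
                 target_name = attr(table, "target_name"),
                 metrics = score(y, oof),
                 metrics_train = score(y, fitted, warn = FALSE),
                 oof_predictions = oof, n = n),
            class = "ftc_gbt")
}

#' Predict from a fitted resistance model
#' @param object An `ftc_gbt` fit.
#' @param newdata Data frame with the five driver columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.ftc_gbt <- function(object, newdata, ...) {
  X <- encode_features(newdata)
  predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1))
}

#' @export
print.ftc_gbt <- function(x, ...) {
  cat(sprintf("<ftc_gbt> boosted-tree model of %s on %d events\n",
              x$target_name %||% "resistance", x$n))
  cat(sprintf("  max_depth = %d, eta = %.2f, nrounds = %d (cv_k = %d, seed = %d)\n",
              x$hyperparams$max_depth, x$hyperparams$eta,
              x$hyperparams$nrounds, x$cv_k, x$seed))
  m <- x$metrics
  cat(sprintf("  out-of-fold: R2 = %.3f, slope = %.3f, MAE = %.4g, RMSE = %.4g\n",
              m$r2, m$slope, m$mae, m$rmse))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact Shapley attribution of one prediction
#'
#' Attributes a model prediction to the features by full subset
#' enumeration: the contribution of feature i is the average of its
#' marginal contribution `v(S u {i}) - v(S)` over all subsets S of the
#' remaining features, weighted by `|S|! (n - |S| - 1)! / n!`. The value
#' `v(S)` of a coalition is the interventional expectation: the mean model
#' output over the background rows with the coalition's columns replaced
#' by the instance's values. Because features enter as whole columns of
#' the raw table, a categorical feature (ecosystem type) is a single
#' player regardless of how the model encodes it, keeping n = 5.
#'
#' The allocation is exact, so it satisfies efficiency
#' (`baseline + sum(phi) = f(instance)`), symmetry and the dummy axiom up
#' to floating-point error.
#'
#' @param predictor Function mapping a feature data frame to numeric
#'   predictions (e.g. `function(d) predict(fit, d)`).
#' @param background Data frame of feature rows defining the reference
#'   distribution.
#' @param instance Single feature row to explain.
#' @param features Columns to treat as players; defaults to all columns of
#'   `background`. At most 15 (2^n enumeration); beyond that a sampling
#'   approximation would be needed, which this package does not provide.
#' @return Object of class `shap_explanation`: `baseline` (v of the empty
#'   coalition), named `phi`, `fx` (prediction for the instance), and the
#'   `instance` row.
#' @export
exact_shapley <- function(predictor, background, instance,
                          features = names(background)) {
  stopifnot(nrow(background) >= 1L, nrow(instance) == 1L)
  n <- length(features)
  if (n > 15L) {
    stop(n, " players would need 2^", n, " coalitions; ",
         "use a sampling approximation (not provided) or group features")
  }
  n_masks <- bitwShiftL(1L, n)
  v <- numeric(n_masks)
  for (mask in 0:(n_masks - 1L)) {
    rows <- background
    for (j in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) {
        rows[[features[j]]] <- rep(instance[[features[j]]], nrow(rows))
      }
    }
    v[mask + 1L] <- mean(predictor(rows))
  }
  w <- factorial(0:(n - 1L)) * factorial(n - (0:(n - 1L)) - 1L) / factorial(n)
  sizes <- vapply(0:(n_masks - 1L), function(m) sum(bitwAnd(
    m, bitwShiftL(1L, 0:(n - 1L))) != 0L), numeric(1))
  phi <- numeric(n)
  names(phi) <- features
  for (j in seq_len(n)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(n_masks - 1L), bit) == 0L) - 1L
    phi[j] <- sum(w[sizes[without + 1L] + 1L] *
                    (v[bitwOr(without, bit) + 1L] - v[without + 1L]))
  }
  structure(list(baseline = v[1L], phi = phi, fx = v[n_masks],
                 instance = instance, features = features),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation> f(x) = %.6g, baseline = %.6g\n",
              x$fx, x$baseline))
  print(round(x$phi, 6))
  invisible(x)
}

#' Shapley attributions for every row of a feature table
#'
#' @param fit An `ftc_gbt` fit (or any object with a `predict` method on
#'   feature data frames).
#' @param table A [build_feature_table()] result; also used as the
#'   background unless overridden.
#' @param background Optional reference rows.
#' @return List with `explanations` (one `shap_explanation` per row) and
#'   `table`: tidy rows of `event_id`, `feature`, `value`, `phi`,
#'   `baseline`, `fx`.
#' @export
model_shapley <- function(fit, table, background = table) {
  predictor <- function(d) predict(fit, d)
  bg <- background[, DRIVER_FEATURES, drop = FALSE]
  expl <- lapply(seq_len(nrow(table)), function(i) {
    exact_shapley(predictor, bg,
                  table[i, DRIVER_FEATURES, drop = FALSE])
  })
  rows <- do.call(rbind, lapply(seq_along(expl), function(i) {
    e <- expl[[i]]
    data.frame(event_id = table$event_id[i],
               feature = e$features,
               value = vapply(e$features, function(f)
                 as.numeric(e$instance[[f]]), numeric(1)),
               phi = unname(e$phi),
               baseline = e$baseline, fx = e$fx,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(explanations = expl, table = rows)
}

#' Mean-|phi| feature importance
#' @param shap_table Tidy table from [model_shapley()].
#' @return Data frame `feature`, `mean_abs_phi`, sorted descending.
#' @export
shap_importance <- function(shap_table) {
  agg <- aggregate(abs(shap_table$phi),
                   list(feature = shap_table$feature), mean)
  names(agg)[2L] <- "mean_abs_phi"
  agg[order(-agg$mean_abs_phi), ]
}

#' Shapley dependence table
#'
#' Raw (unbinned, unsmoothed) rows for a dependence plot: one feature's
#' value against its Shapley contribution, coloured by a second feature.
#'
#' @param explanations List of `shap_explanation`s sharing one model.
#' @param feature Feature whose dependence is examined.
#' @param color_feature Feature supplying the colour gradient.
#' @return Data frame `value`, `phi`, `color_value`.
#' @export
shapley_dependence_table <- function(explanations, feature, color_feature) {
  feats <- explanations[[1L]]$features
  if (!feature %in% feats) stop("unknown feature: ", feature)
  if (!color_feature %in% feats) stop("unknown feature: ", color_feature)
  do.call(rbind, lapply(explanations, function(e) {
    data.frame(value = as.numeric(e$instance[[feature]]),
               phi = unname(e$phi[[feature]]),
               color_value = as.numeric(e$instance[[color_feature]]))
  }))
}
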