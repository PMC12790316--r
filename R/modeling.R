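#' Multivariate linear regression modeling of CO2 affinity
#'
#' Ordinary least squares on z-scored descriptors, with leave-one-out and
#' k-fold cross-validation, exhaustive best-subset selection, the
#' HOMO-energy screening threshold, and the Mayr-nucleophilicity benchmark
#' correlation. Features are standardized with training-split statistics
#' only; coefficients are reported in both standardized and raw space.
#'
#' @name co2screen-modeling
#' @keywords internal
NULL

## design matrix (no intercept column) for the requested features
.design <- function(table, features) {
  missing <- setdiff(features, names(table))
  if (length(missing)) {
    abort_co2(sprintf("feature(s) not in table: %s",
                      paste(missing, collapse = ", ")), "feature_error")
  }
  as.matrix(table[, features, drop = FALSE])
}

## rank check; returns names of columns implicated in a deficiency
.collinear_features <- function(X) {
  q <- qr(cbind(1, X))
  if (q$rank == ncol(X) + 1) return(character(0))
  colnames(X)[q$pivot[seq(q$rank + 1, ncol(X) + 1)] - 1]
}

#' Fit a multivariate linear regression model
#'
#' OLS of the response on z-scored features. With a noiseless linear
#' response the fit reproduces the inputs exactly.
#'
#' @param table descriptor table (data.frame).
#' @param features character vector of feature column names.
#' @param response response column name (default `"co2a"`), kcal/mol.
#' @return an `mlr_model`: feature names, standardized and raw-space
#'   coefficients, intercepts, per-feature scaler (mean, sd).
#' @export
fit_mlr <- function(table, features, response = "co2a") {
  X <- .design(table, features)
  y <- table[[response]]
  if (is.null(y)) {
    abort_co2(sprintf("response column '%s' not in table", response),
              "feature_error")
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) {
    abort_co2(sprintf("need more than %d rows to fit %d features", p + 1, p),
              "input_error")
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv <= 0)) {
    abort_co2(sprintf("constant feature(s): %s",
                      paste(features[sdv <= 0], collapse = ", ")),
              "collinearity_error")
  }
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  bad <- .collinear_features(Z)
  if (length(bad)) {
    abort_co2(sprintf("collinear feature set (offending: %s)",
                      paste(bad, collapse = ", ")), "collinearity_error")
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Z), y)
  coef_std <- fit$coefficients[-1]
  b0_std <- fit$coefficients[1]
  coef_raw <- coef_std / sdv
  b0_raw <- b0_std - sum(coef_std * mu / sdv)
  structure(
    list(feature_names = features,
         coefficients = stats::setNames(coef_std, features),
         intercept = unname(b0_std),
         coefficients_raw = stats::setNames(coef_raw, features),
         intercept_raw = unname(b0_raw),
         scaler = data.frame(feature = features, mean = unname(mu),
                             sd = unname(sdv)),
         response = response, response_units = "kcal/mol", n_train = n),
    class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("<mlr_model: %s ~ %s (n = %d)>\n", x$response,
              paste(x$feature_names, collapse = " + "), x$n_train))
  cat("standardized coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict CO2 affinity for descriptor rows
#'
#' @param object an `mlr_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return numeric vector of predictions, kcal/mol.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  X <- .design(newdata, object$feature_names)
  drop(X %*% object$coefficients_raw) + object$intercept_raw
}

r_squared <- function(obs, pred) 1 - sum((obs - pred)^2) /
  sum((obs - mean(obs))^2)

#' Evaluate a model on a train/test split
#'
#' R-squared is computed on each split against that split's own
#' observations; MAE in kcal/mol.
#'
#' @param model an `mlr_model`.
#' @param table descriptor table with the response column.
#' @param split logical/integer vector: TRUE (or 1) marks training rows.
#' @return list r2_train, mae_train, r2_test, mae_test.
#' @export
evaluate_model <- function(model, table, split = rep(TRUE, nrow(table))) {
  split <- as.logical(split)
  if (length(split) != nrow(table)) {
    abort_co2("split does not cover all rows", "split_error")
  }
  y <- table[[model$response]]
  pred <- predict(model, table)
  out <- list(r2_train = r_squared(y[split], pred[split]),
              mae_train = mean(abs(y[split] - pred[split])))
  if (any(!split)) {
    out$r2_test <- r_squared(y[!split], pred[!split])
    out$mae_test <- mean(abs(y[!split] - pred[!split]))
  } else {
    out$r2_test <- NA_real_; out$mae_test <- NA_real_
  }
  out
}

#' Seeded random train/test assignment
#'
#' @param n number of rows.
#' @param train_fraction fraction assigned to training (default 0.75).
#' @param seed RNG seed.
#' @return logical vector, TRUE = training row.
#' @export
train_test_split <- function(n, train_fraction = 0.75, seed = 42) {
  n_train <- max(1L, round(n * train_fraction))
  idx <- with_local_seed(derive_seed(seed, 301L), sample.int(n, n_train))
  seq_len(n) %in% idx
}

#' Leave-one-out cross-validation
#'
#' Performs n full refits, each excluding one row (features re-standardized
#' on each training subset), and computes Q2 from the held-out predictions
#' against the total sum of squares.
#'
#' @inheritParams fit_mlr
#' @return list q2_loo, press, predictions (held-out).
#' @export
loo_cv <- function(table, features, response = "co2a") {
  n <- nrow(table)
  if (n < 3) abort_co2("need at least 3 rows for LOO", "input_error")
  X <- .design(table, features)
  y <- table[[response]]
  preds <- vapply(seq_len(n), function(i) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    fit <- stats::lm.fit(cbind(1, Xi), yi)
    if (any(is.na(fit$coefficients))) {
      abort_co2("collinear feature set in LOO refit", "collinearity_error")
    }
    sum(c(1, X[i, ]) * fit$coefficients)
  }, numeric(1))
  press <- sum((y - preds)^2)
  list(q2_loo = 1 - press / sum((y - mean(y))^2), press = press,
       predictions = preds)
}

#' k-fold cross-validation
#'
#' Seeded shuffle into k folds whose sizes differ by at most one; reports
#' per-fold R2/MAE and the pooled-prediction R2 over all held-out rows.
#'
#' @inheritParams fit_mlr
#' @param k number of folds (default 5).
#' @param seed RNG seed for the shuffle.
#' @return list folds (data.frame fold, r2, mae, n), r2_pooled, mae_pooled,
#'   k, seed, assignment.
#' @export
kfold_cv <- function(table, features, response = "co2a", k = 5, seed = 42) {
  n <- nrow(table)
  if (k > n) abort_co2(sprintf("k = %d exceeds n = %d", k, n), "split_error")
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  perm <- with_local_seed(derive_seed(seed, 302L), sample.int(n))
  assignment <- integer(n)
  assignment[perm] <- rep(seq_len(k), times = sizes)
  y <- table[[response]]
  pooled <- numeric(n)
  folds <- lapply(seq_len(k), function(f) {
    test <- assignment == f
    model <- fit_mlr(table[!test, , drop = FALSE], features, response)
    pred <- predict(model, table[test, , drop = FALSE])
    pooled[test] <<- pred
    data.frame(fold = f, r2 = r_squared(y[test], pred),
               mae = mean(abs(y[test] - pred)), n = sum(test))
  })
  list(folds = do.call(rbind, folds),
       r2_pooled = r_squared(y, pooled),
       mae_pooled = mean(abs(y - pooled)),
       k = k, seed = seed, assignment = assignment)
}

#' Exhaustive best-subset model search
#'
#' Enumerates every feature subset of the given size (below `cap`
#' candidates), skips collinear subsets with a recorded reason, ranks by
#' leave-one-out Q2 (primary) and test-set MAE (tiebreak; LOO MAE when no
#' split is supplied), and returns the full leaderboard plus the best
#' refitted model.
#'
#' @param table descriptor table.
#' @param pool candidate feature names.
#' @param subset_size subset size (default 3).
#' @param response response column.
#' @param split optional logical train/test assignment; the search runs on
#'   training rows and tiebreaks on test MAE.
#' @param cap maximum number of candidate subsets (default 100000); beyond
#'   it the search aborts and instructs a staged run over smaller pools.
#' @return list leaderboard (data.frame), best (an `mlr_model`),
#'   best_features.
#' @export
best_subset_search <- function(table, pool, subset_size = 3,
                               response = "co2a", split = NULL,
                               cap = 100000) {
  stopifnot(length(pool) >= subset_size)
  n_cand <- choose(length(pool), subset_size)
  if (n_cand > cap) {
    abort_co2(sprintf(
      "%d candidate subsets exceed the cap (%d); stage the search over smaller pools",
      n_cand, cap), "cap_exceeded")
  }
  train_tab <- if (is.null(split)) table else table[split, , drop = FALSE]
  combos <- utils::combn(pool, subset_size, simplify = FALSE)
  rows <- lapply(combos, function(fs) {
    res <- tryCatch({
      model <- fit_mlr(train_tab, fs, response)
      cv <- loo_cv(train_tab, fs, response)
      mae_loo <- mean(abs(train_tab[[response]] - cv$predictions))
      tie <- if (is.null(split)) mae_loo else {
        pred <- predict(model, table[!split, , drop = FALSE])
        mean(abs(table[[response]][!split] - pred))
      }
      data.frame(features = paste(fs, collapse = "+"), q2_loo = cv$q2_loo,
                 mae_tiebreak = tie, skipped = NA_character_)
    }, co2screen_collinearity_error = function(e)
      data.frame(features = paste(fs, collapse = "+"), q2_loo = NA_real_,
                 mae_tiebreak = NA_real_, skipped = "collinear"))
    res
  })
  lb <- do.call(rbind, rows)
  ok <- is.na(lb$skipped)
  lb <- lb[order(!ok, -lb$q2_loo, lb$mae_tiebreak), ]
  rownames(lb) <- NULL
  if (!any(ok)) {
    abort_co2("every candidate subset was collinear", "collinearity_error")
  }
  best_features <- strsplit(lb$features[1], "+", fixed = TRUE)[[1]]
  list(leaderboard = lb,
       best = fit_mlr(train_tab, best_features, response),
       best_features = best_features)
}

#' HOMO-energy screening filter
#'
#' Candidates with HOMO energies at or above the threshold proceed to the
#' second (affinity) round; the boundary value passes (inclusive
#' comparison).
#'
#' @param epsilon_homo HOMO energy (Hartree), finite.
#' @param threshold screening threshold in Hartree (default -0.140).
#' @return logical vector.
#' @export
homo_filter <- function(epsilon_homo, threshold = -0.140) {
  if (any(!is.finite(epsilon_homo))) {
    abort_co2("non-finite HOMO energy", "input_error")
  }
  epsilon_homo >= threshold
}

#' Assemble a screening prediction row
#'
#' @param id nucleophile id.
#' @param epsilon_homo HOMO energy used for screening, Hartree.
#' @param co2a_pred predicted affinity (kcal/mol) or NA when screened out.
#' @param threshold filter threshold, Hartree.
#' @return one-row data.frame: id, epsilon_homo, passed_homo_filter,
#'   co2a_pred, stability_call (stable / unstable / screened-out).
#' @export
prediction_row <- function(id, epsilon_homo, co2a_pred = NA_real_,
                           threshold = -0.140) {
  passed <- homo_filter(epsilon_homo, threshold)
  if (passed && is.na(co2a_pred)) {
    abort_co2("filter survivor lacks an affinity prediction",
              "consistency_error")
  }
  data.frame(
    id = id, epsilon_homo = epsilon_homo, passed_homo_filter = passed,
    co2a_pred = if (passed) co2a_pred else NA_real_,
    stability_call = if (!passed) "screened-out"
                     else if (co2a_pred > 0) "stable" else "unstable")
}

#' Correlation of CO2 affinity with Mayr nucleophilicity
#'
#' Simple linear regression of the affinity on the empirical
#' nucleophilicity parameter N; serves as a kinetic benchmark of the
#' thermodynamic predictions.
#'
#' @param affinities data.frame with columns `id`, `co2a`.
#' @param n_values data.frame with columns `id`, `N`.
#' @return list r2, slope, intercept, n.
#' @export
nucleophilicity_correlation <- function(affinities, n_values) {
  unpaired <- c(setdiff(affinities$id, n_values$id),
                setdiff(n_values$id, affinities$id))
  if (length(unpaired)) {
    abort_co2(sprintf("unpaired id(s): %s", paste(unpaired, collapse = ", ")),
              "join_error")
  }
  merged <- merge(affinities, n_values, by = "id")
  if (nrow(merged) < 3) {
    abort_co2("need at least 3 paired records", "input_error")
  }
  if (stats::sd(merged$N) == 0) {
    abort_co2("nucleophilicity N is constant; slope undefined",
              "degenerate_input")
  }
  fit <- stats::lm(co2a ~ N, data = merged)
  list(r2 = r_squared(merged$co2a, stats::fitted(fit)),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = nrow(merged))
}

#' Serialize / load an MLR model as structured text
#'
#' @param model an `mlr_model`.
#' @param path JSON path.
#' @export
write_mlr_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlr_model
#' @export
read_mlr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$feature_names <- as.character(obj$feature_names)
  obj$coefficients <- stats::setNames(as.numeric(obj$coefficients),
                                      obj$feature_names)
  obj$coefficients_raw <- stats::setNames(as.numeric(obj$coefficients_raw),
                                          obj$feature_names)
  structure(obj, class = "mlr_model")
}
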