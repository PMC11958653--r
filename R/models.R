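#' Likelihood-ratio degrees of freedom
#'
#' Degrees of freedom of the likelihood-ratio test of a logistic model
#' against the intercept-only null: `(nClasses - 1) * nSelected`.
#'
#' @param nSelected number of retained predictors (>= 1).
#' @param nClasses number of outcome classes (>= 2).
#' @return Integer degrees of freedom.
#' @examples
#' lrDf(15, 3)  # 30
#' lrDf(12, 2)  # 12
#' @export
lrDf <- function(nSelected, nClasses) {
  stopifnot(nSelected >= 1, nClasses >= 2)
  as.integer((nClasses - 1) * nSelected)
}

zscore <- function(m) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(x = sweep(sweep(m, 2, mu), 2, sdv, "/"), mean = mu, sd = sdv)
}

#' Fit a (multinomial) logistic condition classifier
#'
#' Maximum-likelihood logistic regression of the session label on a set of
#' segment-level features, with the stated reference class (binary models
#' via `glm`, three or more classes via `nnet::multinom`). Predictors are
#' z-scored by default, so coefficients are on the standardized scale. The
#' fit is assessed against the intercept-only null by the likelihood-ratio
#' chi-square with `lrDf(nSelected, nClasses)` degrees of freedom. A
#' negative coefficient means the predictor decreases the odds of the
#' condition relative to the reference class. Apparent separation (divergent
#' standardized coefficients) is flagged and the model refit with a small
#' ridge penalty via repeated observations is *not* attempted; instead the
#' flag accompanies the Wald statistics so callers can fall back.
#'
#' @param data `data.frame` holding the features and the label column.
#' @param features character vector of predictor column names (may be empty:
#'   the null model, `chiSquare = 0`, `df = 0`).
#' @param target name of the label column (factor or character).
#' @param referenceClass reference level (default: first sorted level).
#' @param standardize z-score the predictors (default TRUE).
#' @return A `ModelFit` list: `kind`, `referenceClass`, `selectedFeatures`,
#'   `B` (coefficient matrix, one row per non-reference class), `pValues`
#'   (per-feature Wald p; for multinomial the joint Wald test across
#'   classes), `chiSquare`, `df`, `modelP`, `separation`, plus the internal
#'   fitted object and scaling for prediction.
#' @export
fitLogistic <- function(data, features, target, referenceClass = NULL,
                        standardize = TRUE) {
  y <- factor(data[[target]])
  if (nlevels(y) < 2L) stop("at least 2 classes must be present")
  if (!is.null(referenceClass)) y <- stats::relevel(y, ref = referenceClass)
  k <- nlevels(y)
  features <- as.character(features)
  if (length(features) && anyNA(data[features]))
    stop("missing values in features")
  scl <- NULL
  X <- if (length(features)) {
    m <- as.matrix(data[features])
    if (standardize) { scl <- zscore(m); scl$x } else m
  } else matrix(numeric(0), nrow(data), 0)
  df0 <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~",
    if (length(features)) paste(sprintf("`%s`", features), collapse = " + ")
    else "1"))
  sepWarn <- FALSE
  quietFit <- function(expr) withCallingHandlers(expr, warning = function(w) {
    if (grepl("fitted probabilities|algorithm did not converge",
              conditionMessage(w))) {
      sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    }
  })
  if (k == 2L) {
    fit <- quietFit(stats::glm(fml, data = df0, family = stats::binomial()))
    ll <- as.numeric(stats::logLik(fit))
    null <- stats::glm(.y ~ 1, data = df0, family = stats::binomial())
    chi <- max(0, 2 * (ll - as.numeric(stats::logLik(null))))
    sm <- stats::summary.glm(fit)$coefficients
    B <- matrix(stats::coef(fit)[-1], nrow = 1,
                dimnames = list(levels(y)[2], features))
    ## aliased (rank-deficient) predictors drop out of the summary table;
    ## they keep an NA p-value here and are eliminated first upstream
    pv <- stats::setNames(rep(NA_real_, length(features)), features)
    hit <- intersect(features, rownames(sm))
    pv[hit] <- sm[hit, "Pr(>|z|)"]
    sep <- sepWarn || (length(features) > 0 &&
      any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE))
  } else {
    fit <- nnet::multinom(fml, data = df0, trace = FALSE, maxit = 500,
                          reltol = 1e-10)
    null <- nnet::multinom(.y ~ 1, data = df0, trace = FALSE)
    chi <- max(0, null$deviance - fit$deviance)
    cf <- stats::coef(fit)
    B <- if (length(features)) cf[, features, drop = FALSE]
    else matrix(numeric(0), k - 1, 0)
    V <- stats::vcov(fit)
    vn <- rownames(V)
    pv <- vapply(features, function(f) {
      ## joint Wald test of the feature's k-1 class coefficients
      idx <- which(endsWith(vn, paste0(":", f)) | endsWith(vn, paste0(":`", f, "`")))
      if (length(idx) != k - 1) return(NA_real_)
      b <- B[, f]
      w <- tryCatch(as.numeric(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b),
                    error = function(e) NA_real_)
      stats::pchisq(w, df = k - 1, lower.tail = FALSE)
    }, numeric(1))
    sep <- sepWarn || (length(features) > 0 && any(abs(B) > 15))
  }
  df <- if (length(features)) lrDf(length(features), k) else 0L
  list(kind = if (k == 2L) "binary" else "multinomial",
       referenceClass = levels(y)[1],
       selectedFeatures = features,
       B = B, pValues = pv,
       chiSquare = chi, df = df,
       modelP = if (df > 0) stats::pchisq(chi, df, lower.tail = FALSE)
                else NA_real_,
       separation = sep,
       fit = fit, scaling = scl, levels = levels(y), target = target)
}

#' Backward-elimination feature selection
#'
#' Starts from the full candidate set and, per iteration, removes the single
#' least-contributing feature as long as its removal p-value exceeds
#' `removalAlpha`. The default criterion is the drop-one likelihood-ratio
#' test (refit without the feature, chi-square on `nClasses - 1` df), which
#' stays informative when quasi-separation drives Wald standard errors to
#' infinity; `criterion = "wald"` uses the per-feature Wald p-values
#' instead. Constant features are dropped before fitting with a warning.
#' Removed features never re-enter; the trace records every step.
#'
#' @inheritParams fitLogistic
#' @param removalAlpha removal threshold on the p-value (default 0.10).
#' @param criterion `"lr"` (drop-one likelihood ratio, default) or `"wald"`.
#' @return List with `fit` (the final [fitLogistic()] model), `selected`,
#'   and `trace` (data frame: step, removed feature, its p-value, model
#'   chi-square after removal).
#' @export
backwardEliminate <- function(data, features, target, referenceClass = NULL,
                              removalAlpha = 0.10, standardize = TRUE,
                              criterion = c("lr", "wald")) {
  criterion <- match.arg(criterion)
  features <- as.character(features)
  if (!length(features)) stop("at least one candidate feature is required")
  const <- features[vapply(features,
                           function(f) stats::sd(data[[f]]) == 0, logical(1))]
  if (length(const)) {
    warning("dropping constant feature(s): ", paste(const, collapse = ", "))
    features <- setdiff(features, const)
  }
  cur <- features
  fit <- fitLogistic(data, cur, target, referenceClass, standardize)
  trace <- data.frame(step = 0L, removed = NA_character_, pValue = NA_real_,
                      chiSquare = fit$chiSquare)
  step <- 0L
  while (length(cur) > 0L) {
    pv <- if (criterion == "wald") fit$pValues else
      vapply(stats::setNames(nm = cur), function(f) {
        sub <- fitLogistic(data, setdiff(cur, f), target, referenceClass,
                           standardize)
        chi <- max(0, fit$chiSquare - sub$chiSquare)
        stats::pchisq(chi, df = max(1L, fit$df - sub$df),
                      lower.tail = FALSE)
      }, numeric(1))
    pv[is.na(pv)] <- 1          # aliased predictors leave first
    worst <- names(pv)[which.max(pv)]
    if (!length(worst) || max(pv) <= removalAlpha) break
    step <- step + 1L
    cur <- setdiff(cur, worst)
    fit <- fitLogistic(data, cur, target, referenceClass, standardize)
    trace <- rbind(trace, data.frame(step = step, removed = worst,
                                     pValue = max(pv),
                                     chiSquare = fit$chiSquare))
  }
  list(fit = fit, selected = cur, trace = trace)
}

predictClasses <- function(model, newdata) {
  features <- model$selectedFeatures
  X <- if (length(features)) {
    m <- as.matrix(newdata[features])
    if (!is.null(model$scaling))
      m <- sweep(sweep(m, 2, model$scaling$mean), 2, model$scaling$sd, "/")
    m
  } else matrix(numeric(0), nrow(newdata), 0)
  df0 <- data.frame(X, check.names = FALSE)
  if (model$kind == "binary") {
    p <- stats::predict(model$fit, newdata = df0, type = "response")
    factor(ifelse(p >= 0.5, model$levels[2], model$levels[1]),
           levels = model$levels)
  } else {
    factor(as.character(stats::predict(model$fit, newdata = df0)),
           levels = model$levels)
  }
}

confusionMetrics <- function(truth, pred) {
  lev <- levels(truth)
  cm <- table(truth = truth, pred = factor(pred, levels = lev))
  acc <- 100 * sum(diag(cm)) / sum(cm)
  prec <- vapply(lev, function(l) {
    s <- sum(cm[, l]); if (s == 0) NA_real_ else 100 * cm[l, l] / s
  }, numeric(1))
  rec <- vapply(lev, function(l) {
    s <- sum(cm[l, ]); if (s == 0) NA_real_ else 100 * cm[l, l] / s
  }, numeric(1))
  list(accuracy = acc, precision = mean(prec, na.rm = TRUE),
       recall = mean(rec, na.rm = TRUE),
       perClass = data.frame(class = lev, precision = prec, recall = rec),
       confusion = cm)
}

#' Classification metrics of a fitted condition model
#'
#' Accuracy and macro-averaged precision/recall (percentages). `in-sample`
#' evaluates the supplied fit on its own training rows; `k-fold` runs
#' stratified cross-validation, repeating the backward elimination inside
#' every training fold so selection bias is not leaked into the estimate.
#'
#' @param model a fit from [fitLogistic()] or the `fit` element of
#'   [backwardEliminate()].
#' @param data the feature data frame with the label column.
#' @param scheme `"in-sample"` or `"k-fold"`.
#' @param k number of folds for `"k-fold"`.
#' @param candidates candidate features for the in-fold selection (defaults
#'   to the model's selected features).
#' @param removalAlpha passed to the in-fold elimination.
#' @return List with `accuracy`, `precision`, `recall` (percent), `perClass`,
#'   `confusion`, `scheme`.
#' @export
evaluateModel <- function(model, data, scheme = c("in-sample", "k-fold"),
                          k = 5, candidates = NULL, removalAlpha = 0.10) {
  scheme <- match.arg(scheme)
  truth <- factor(data[[model$target]], levels = model$levels)
  if (any(!model$levels %in% as.character(truth)))
    stop("every model class must be present in the labels")
  if (scheme == "in-sample") {
    pred <- predictClasses(model, data)
    out <- confusionMetrics(truth, pred)
  } else {
    if (is.null(candidates)) candidates <- model$selectedFeatures
    fold <- stats::ave(seq_along(truth), truth,
                       FUN = function(i) (seq_along(i) - 1L) %% k + 1L)
    pred <- factor(rep(NA_character_, length(truth)), levels = model$levels)
    for (f in seq_len(k)) {
      tr <- data[fold != f, , drop = FALSE]
      te <- data[fold == f, , drop = FALSE]
      sel <- backwardEliminate(tr, candidates, model$target,
                               referenceClass = model$referenceClass,
                               removalAlpha = removalAlpha)
      pred[fold == f] <- predictClasses(sel$fit, te)
    }
    out <- confusionMetrics(truth, pred)
  }
  c(out, list(scheme = scheme))
}
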