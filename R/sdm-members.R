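## Member-model engines: GLM (linear + quadratic, AIC-bidirectional
## stepwise), GAM (five-basis-dimension penalised regression splines) and
## random forest (4000 trees, node size 1, per-tree balanced background
## subsampling).  GLM and GAM weight each background row by the species'
## presence/background ratio so the two classes carry equal total weight.

## Weighted logistic fit on a model matrix; C++ IRLS with a stats::glm.fit
## fallback for degenerate designs.  AIC convention matches stats::glm.
fit_logistic <- function(X, y, w, beta0 = NULL, maxit = 30) {
  fit <- tryCatch(irls_logit(X, y, w, maxit = maxit, beta0 = beta0),
                  error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$ok) || !is.finite(fit$deviance)) {
    fit <- suppressWarnings(stats::glm.fit(X, y, weights = w,
                                           family = stats::binomial()))
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    return(list(coefficients = coefs, deviance = fit$deviance,
                aic = fit$deviance + 2 * fit$rank))
  }
  list(coefficients = drop(fit$coefficients), deviance = fit$deviance,
       aic = fit$deviance + 2 * ncol(X))
}

## Quadratic-term model matrix (no intercept column) for a predictor set.
quad_matrix <- function(data, predictors) {
  cols <- lapply(predictors, function(v) {
    x <- data[[v]]
    cbind(x, x^2)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(vapply(predictors, function(v)
    c(v, paste0(v, "^2")), character(2)))
  out
}

## Bidirectional stepwise AIC selection over linear and quadratic terms,
## starting from the full model; the intercept is always kept.  The search
## runs in compiled code; the pure-R path below is the fallback for
## degenerate designs and doubles as the test oracle for the C++ search.
stepwise_logit <- function(Xterms, y, w, max_steps = NULL, aic_tol = 1e-4,
                           maxit = 12, use_cpp = TRUE) {
  if (is.null(max_steps)) max_steps <- 2L * ncol(Xterms)
  if (use_cpp) {
    fit <- tryCatch(stepwise_logit_cpp(Xterms, y, w, maxit = maxit,
                                       aic_tol = aic_tol,
                                       max_steps = max_steps),
                    error = function(e) list(ok = FALSE))
    if (isTRUE(fit$ok) && all(is.finite(fit$coefficients))) {
      beta <- drop(fit$coefficients)
      names(beta) <- c("(Intercept)", colnames(Xterms))
      return(list(coefficients = beta, active = as.logical(fit$active),
                  deviance = fit$deviance, aic = fit$aic))
    }
  }
  n_terms <- ncol(Xterms)
  ones <- matrix(1, nrow(Xterms), 1)
  active <- rep(TRUE, n_terms)
  fit_active <- function(act, warm = NULL) {
    b0 <- if (!is.null(warm)) c(warm[1], warm[-1][act]) else NULL
    fit_logistic(cbind(ones, Xterms[, act, drop = FALSE]), y, w,
                 beta0 = b0, maxit = maxit)
  }
  cur <- fit_active(active)
  ## full coefficient vector aligned to all terms (0 for inactive); used to
  ## warm-start the candidate refits of the stepwise search
  full_beta <- function(act, fit) {
    b <- numeric(n_terms + 1)
    b[c(TRUE, act)] <- fit$coefficients
    b
  }
  for (step in seq_len(max_steps)) {
    best_aic <- cur$aic
    best_act <- NULL
    warm <- full_beta(active, cur)
    for (j in seq_len(n_terms)) {
      cand <- active
      cand[j] <- !cand[j]            # drop if active, add if not
      f <- fit_active(cand, warm = warm)
      if (f$aic < best_aic - aic_tol) {
        best_aic <- f$aic
        best_act <- cand
        best_fit <- f
      }
    }
    if (is.null(best_act)) break
    active <- best_act
    cur <- best_fit
  }
  beta <- numeric(n_terms + 1)
  beta[c(TRUE, active)] <- cur$coefficients
  names(beta) <- c("(Intercept)", colnames(Xterms))
  list(coefficients = beta, active = active, deviance = cur$deviance,
       aic = cur$aic)
}

#' Fit one SDM member model
#'
#' Fits a presence (1) versus background (0) model with one of three
#' algorithms: `"glm"` (linear + quadratic terms with bidirectional
#' stepwise AIC selection), `"gam"` (one smooth per predictor, five basis
#' dimensions, penalised regression splines) or `"rf"` (random forest with
#' `rf_trees` trees, terminal node size 1, and per-tree balanced
#' subsampling of background down to the presence count).  For GLM and GAM
#' each background row is weighted by `n_presence / n_background`.  Rows
#' with a missing value in any predictor are dropped.
#'
#' @param train Data frame with a 0/1 `label` column and the predictor
#'   columns.
#' @param algorithm `"glm"`, `"gam"` or `"rf"`.
#' @param predictors Character vector of predictor column names.
#' @param rf_trees Number of forest trees (default 4000).
#' @param seed Integer seed (forest and any stochastic fitting).
#' @return An object of class `sdm_member` (no evaluation fields yet; see
#'   [evaluate_member()]), or `NULL` with a warning when the fit fails.
#' @export
fit_member <- function(train, algorithm = c("glm", "gam", "rf"),
                       predictors, rf_trees = 4000, seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(all(predictors %in% names(train)), "label" %in% names(train))
  keep <- stats::complete.cases(train[, predictors, drop = FALSE])
  d <- train[keep, , drop = FALSE]
  np <- sum(d$label == 1); nb <- sum(d$label == 0)
  if (np < 2 || nb < 2) {
    warning("fit_member: fewer than two rows in a class after NA removal")
    return(NULL)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  w <- ifelse(d$label == 1, 1, np / nb)

  model <- tryCatch(switch(
    algorithm,
    glm = {
      Xt <- quad_matrix(d, predictors)
      stepwise_logit(Xt, d$label, w)
    },
    gam = {
      fml <- stats::as.formula(paste(
        "label ~", paste(sprintf("s(%s, k = 5)", predictors),
                         collapse = " + ")))
      suppressWarnings(mgcv::gam(fml, family = stats::binomial, data = d,
                                 weights = w))
    },
    rf = {
      k <- min(np, nb)
      suppressWarnings(randomForest::randomForest(
        x = d[, predictors, drop = FALSE],
        y = factor(d$label, levels = c(0, 1)),
        ntree = rf_trees, nodesize = 1,
        sampsize = c(`0` = k, `1` = k),
        strata = factor(d$label, levels = c(0, 1))))
    }), error = function(e) {
      warning(sprintf("fit_member (%s): fit failed: %s", algorithm,
                      conditionMessage(e)))
      NULL
    })
  if (is.null(model)) return(NULL)
  structure(list(algorithm = algorithm, predictors = predictors,
                 model = model, n_presence = np, n_background = nb,
                 rf_trees = if (algorithm == "rf") rf_trees else NA_integer_,
                 rf_sampsize = if (algorithm == "rf") min(np, nb) else
                   NA_integer_,
                 cv_tss = NA_real_, threshold = NA_real_, retained = NA),
            class = "sdm_member")
}

#' Predict member presence probabilities
#'
#' @param member An [fit_member()] result.
#' @param newdata Data frame with the member's predictor columns; rows with
#'   missing predictor values yield `NA` (missing, never zero).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_member <- function(member, newdata) {
  stopifnot(inherits(member, "sdm_member"))
  ok <- stats::complete.cases(newdata[, member$predictors, drop = FALSE])
  out <- rep(NA_real_, nrow(newdata))
  if (!any(ok)) return(out)
  nd <- newdata[ok, , drop = FALSE]
  out[ok] <- switch(
    member$algorithm,
    glm = {
      X <- cbind(1, quad_matrix(nd, member$predictors))
      as.vector(stats::plogis(X %*% member$model$coefficients))
    },
    gam = as.vector(suppressWarnings(
      stats::predict(member$model, nd, type = "response"))),
    rf = suppressWarnings(
      stats::predict(member$model, nd, type = "prob")[, "1"])
  )
  out
}

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1 = tp/(tp+fn) + tn/(tn+fp) - 1`,
#' ranging from -1 to 1 (0 = no better than random).  Undefined when either
#' class is empty.
#'
#' @param tp,fp,fn,tn Confusion-matrix counts.
#' @return The TSS value.
#' @export
tss <- function(tp, fp, fn, tn) {
  if (tp + fn <= 0 || tn + fp <= 0)
    stop("tss: undefined when a class is empty")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Threshold maximising the true skill statistic
#'
#' Candidate thresholds are the unique predicted values; presence is
#' predicted when `prob >= threshold`.  Returns the TSS-maximising
#' candidate, taking the lowest value on ties.  Constant predictions return
#' that constant (TSS 0) with a warning.
#'
#' @param probs Predicted probabilities.
#' @param labels 0/1 observed labels (both classes present).
#' @return The threshold, with the achieved TSS in `attr(, "tss")`.
#' @export
max_tss_threshold <- function(probs, labels) {
  ok <- !is.na(probs) & !is.na(labels)
  probs <- probs[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("max_tss_threshold: both classes must be present")
  cand <- sort(unique(probs))
  if (length(cand) == 1) {
    warning("max_tss_threshold: constant predictions")
    return(structure(cand, tss = 0))
  }
  ## at threshold t: predicted presence = probs >= t
  ord <- order(probs)
  p_sorted <- probs[ord]
  y_sorted <- labels[ord]
  ## for each candidate, index of first prob >= cand
  n_below <- findInterval(cand, p_sorted, left.open = TRUE)
  cum1 <- c(0, cumsum(y_sorted == 1))
  cum0 <- c(0, cumsum(y_sorted == 0))
  below1 <- cum1[n_below + 1]   # fn: presences predicted absent
  below0 <- cum0[n_below + 1]   # tn: absences predicted absent
  tp <- n1 - below1
  tn <- below0
  tss_v <- tp / n1 + tn / n0 - 1
  best <- which.max(tss_v)          # ties -> lowest threshold
  structure(cand[best], tss = tss_v[best])
}

## TSS of probabilities at a fixed threshold (>= convention).  The tiny
## tolerance keeps scoring stable when fits saturate (perfect separation
## pushes probabilities within 1e-12 of one another).
tss_at <- function(probs, labels, threshold) {
  ok <- !is.na(probs)
  pred <- probs[ok] >= threshold - 1e-9
  y <- labels[ok] == 1
  tss(sum(pred & y), sum(pred & !y), sum(!pred & y), sum(!pred & !y))
}

#' Repeated split-sample cross-validation of a member specification
#'
#' The data are split at random into `folds` near-equal parts; the member
#' is trained on the other parts (75 percent with the default 4 folds) and
#' predicts the held-out part, once per part.  Each fold's TSS is evaluated
#' on the held-out part at the threshold maximising TSS on that fold's
#' training predictions (choosing the cut on the held-out part itself
#' would inflate skill), and the mean over folds is returned.  If a split
#' leaves a fold with a single class the split is redrawn with a fresh
#' seed, up to `max_retries` times.
#'
#' @param data Training data (0/1 `label` plus predictors).
#' @param algorithm,predictors,rf_trees As in [fit_member()].
#' @param folds Number of parts (default 4).
#' @param seed Integer seed; identical inputs and seed give identical folds
#'   and TSS.
#' @param max_retries Resplit attempts on degenerate folds.
#' @return Mean cross-validated TSS, with per-fold values in
#'   `attr(, "fold_tss")`.
#' @export
cross_validate <- function(data, algorithm, predictors, folds = 4,
                           rf_trees = 4000, seed = 1, max_retries = 10) {
  stopifnot(folds >= 2, nrow(data) >= folds)
  n <- nrow(data)
  for (attempt in 0:max_retries) {
    old <- local_seed(derive_seed(seed, attempt))
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    restore_seed(old)
    ok <- all(vapply(seq_len(folds), function(k) {
      yk <- data$label[fold_id == k]
      yt <- data$label[fold_id != k]
      length(unique(yk)) == 2 && length(unique(yt)) == 2
    }, logical(1)))
    if (ok) break
    if (attempt == max_retries)
      stop("cross_validate: could not form folds with both classes")
  }
  fold_tss <- vapply(seq_len(folds), function(k) {
    tr <- data[fold_id != k, , drop = FALSE]
    te <- data[fold_id == k, , drop = FALSE]
    m <- fit_member(tr, algorithm, predictors, rf_trees = rf_trees,
                    seed = derive_seed(seed, 100 + k))
    if (is.null(m)) return(NA_real_)
    ## fold threshold from the fold's own calibration predictions; the
    ## held-out part is only scored, never used to pick the cut
    p_tr <- predict_member(m, tr)
    thr <- suppressWarnings(max_tss_threshold(p_tr, tr$label))
    p_te <- predict_member(m, te)
    if (all(is.na(p_te))) return(NA_real_)
    tss_at(p_te, te$label, as.numeric(thr))
  }, numeric(1))
  structure(mean(fold_tss, na.rm = TRUE), fold_tss = fold_tss)
}

#' Evaluate a member: cross-validated TSS, retention, deployment threshold
#'
#' Runs [cross_validate()] for the member's specification, fits the member
#' on all data, and refits the deployment binarisation threshold on the
#' full-data calibration predictions.  The member is retained when its
#' cross-validated TSS is at least `tss_min` (default 0.35).
#'
#' @param train Training data (0/1 `label` plus predictors).
#' @param algorithm,predictors,rf_trees As in [fit_member()].
#' @param tss_min Retention threshold on cross-validated TSS.
#' @param folds Cross-validation parts.
#' @param seed Integer seed.
#' @return An `sdm_member` with `cv_tss`, `threshold` and `retained`
#'   filled in, or `NULL` when fitting fails.
#' @export
evaluate_member <- function(train, algorithm, predictors, tss_min = 0.35,
                            folds = 4, rf_trees = 4000, seed = 1) {
  member <- fit_member(train, algorithm, predictors, rf_trees = rf_trees,
                       seed = seed)
  if (is.null(member)) return(NULL)
  cv <- tryCatch(
    cross_validate(train, algorithm, predictors, folds = folds,
                   rf_trees = rf_trees, seed = seed),
    error = function(e) {
      warning("evaluate_member: cross-validation failed: ",
              conditionMessage(e))
      NA_real_
    })
  member$cv_tss <- as.numeric(cv)
  p_full <- predict_member(member, train)
  thr <- suppressWarnings(max_tss_threshold(p_full, train$label))
  member$threshold <- as.numeric(thr)
  member$retained <- is.finite(member$cv_tss) && member$cv_tss >= tss_min
  member
}

#' Project a member onto the climatology
#'
#' Predicts the member's presence probability for every monthly cell where
#' all of its predictors are defined and binarises at the member's
#' deployment threshold (`prob >= threshold` is presence).  Cells with any
#' missing predictor are `NA` -- no data, never absence.
#'
#' @param member An evaluated `sdm_member`.
#' @param env An [env_clim()] holding the member's predictors.
#' @param month A month 1-12, or `NULL` (default) for all twelve.
#' @return With `month`, an `(n_lat, n_lon)` 0/1 matrix; otherwise a
#'   `(12, n_lat, n_lon)` array.
#' @export
project_member <- function(member, env, month = NULL) {
  stopifnot(inherits(member, "sdm_member"), inherits(env, "env_clim"))
  if (is.na(member$threshold))
    stop("project_member: member has no deployment threshold; ",
         "run evaluate_member first")
  frame <- as.data.frame(lapply(member$predictors, function(v)
    as.vector(env_field(env, v))))
  names(frame) <- member$predictors
  p <- predict_member(member, frame)
  bin <- array(as.numeric(p >= member$threshold),
               dim = c(12L, env$grid$n_lat, env$grid$n_lon))
  if (is.null(month)) bin else bin[month, , ]
}

#' @export
print.sdm_member <- function(x, ...) {
  cat(sprintf("<sdm_member> %s on %s\n", toupper(x$algorithm),
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  %d presences, %d background; cv TSS %.3f; threshold %.3f; %s\n",
              x$n_presence, x$n_background, x$cv_tss, x$threshold,
              if (isTRUE(x$retained)) "retained" else "not retained"))
  invisible(x)
}
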