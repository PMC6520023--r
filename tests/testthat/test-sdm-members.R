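test_that("the logistic engine reproduces stats::glm", {
  set.seed(14)
  n <- 250
  d <- data.frame(y = rbinom(n, 1, 0.35), a = rnorm(n), b = runif(n))
  X <- cbind(1, d$a, d$a^2, d$b)
  for (w in list(rep(1, n), ifelse(d$y == 1, 1, 0.25))) {
    ours <- phytosdm:::fit_logistic(X, d$y, w)
    ref <- suppressWarnings(stats::glm(y ~ a + I(a^2) + b,
                                       family = stats::binomial, data = d,
                                       weights = w))
    expect_equal(unname(ours$coefficients), unname(stats::coef(ref)),
                 tolerance = 1e-7)
    expect_equal(ours$deviance, stats::deviance(ref), tolerance = 1e-9)
  }
  ## AIC convention agrees with stats::glm for unit weights
  ours <- phytosdm:::fit_logistic(X, d$y, rep(1, n))
  ref <- stats::glm(y ~ a + I(a^2) + b, family = stats::binomial, data = d)
  expect_equal(ours$aic, stats::AIC(ref), tolerance = 1e-9)
})

test_that("the compiled stepwise search matches the reference search", {
  set.seed(33)
  for (i in 1:10) {
    n <- 150 + 20 * i
    X <- matrix(rnorm(n * 6), n, 6)
    colnames(X) <- paste0("t", 1:6)
    y <- rbinom(n, 1, stats::plogis(X[, 1] - 0.7 * X[, 2]))
    w <- ifelse(y == 1, 1, 0.5)
    a <- phytosdm:::stepwise_logit(X, y, w, use_cpp = TRUE, maxit = 30)
    b <- phytosdm:::stepwise_logit(X, y, w, use_cpp = FALSE, maxit = 30)
    expect_identical(a$active, b$active)
    expect_equal(a$aic, b$aic, tolerance = 1e-6)
    expect_equal(a$coefficients, b$coefficients, tolerance = 1e-5)
  }
})

test_that("the true skill statistic follows its definition", {
  expect_equal(tss(10, 0, 0, 10), 1)                 # perfect
  expect_equal(tss(5, 5, 5, 5), 0)                   # random
  expect_equal(tss(50, 50, 0, 450), 0.9)             # sens 1, spec 0.9
  expect_error(tss(0, 5, 0, 5), "empty")
  ## random-instance equivalence with the sensitivity/specificity oracle
  set.seed(3)
  for (i in 1:1000) {
    cm <- rmultinom(1, 50, c(0.3, 0.2, 0.2, 0.3)) + c(1, 0, 1, 0)
    oracle <- cm[1] / (cm[1] + cm[3]) + cm[4] / (cm[4] + cm[2]) - 1
    expect_identical(tss(cm[1], cm[2], cm[3], cm[4]), oracle)
  }
})

test_that("the max-TSS threshold picks the best cut, lowest on ties", {
  thr <- max_tss_threshold(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))
  expect_equal(as.numeric(thr), 0.8)
  expect_equal(attr(thr, "tss"), 1)
  ## inverted predictions cannot score above zero
  thr2 <- max_tss_threshold(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_lte(attr(thr2, "tss"), 0)
  ## constant predictions degrade gracefully
  expect_warning(thr3 <- max_tss_threshold(rep(0.4, 6),
                                           c(1, 1, 1, 0, 0, 0)),
                 "constant")
  expect_equal(as.numeric(thr3), 0.4)
  expect_equal(attr(thr3, "tss"), 0)
})

test_that("the max-TSS threshold matches exhaustive enumeration", {
  set.seed(8)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    probs <- round(runif(n), 2)    # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2 || length(unique(probs)) < 2) next
    got <- max_tss_threshold(probs, labels)
    cand <- sort(unique(probs))
    tv <- vapply(cand, function(t) {
      pred <- probs >= t
      tss(sum(pred & labels == 1), sum(pred & labels == 0),
          sum(!pred & labels == 1), sum(!pred & labels == 0))
    }, numeric(1))
    expect_equal(attr(got, "tss"), max(tv), tolerance = 1e-12)
    expect_equal(as.numeric(got), cand[which.max(tv)])  # lowest on ties
  }
})

test_that("member models separate a clean thermal niche perfectly", {
  set.seed(61)
  d <- data.frame(label = rep(c(1, 0), c(50, 300)),
                  T = c(runif(50, 18, 22),
                        sample(c(runif(150, -2, 12), runif(150, 28, 32)))),
                  junk1 = rnorm(350))
  for (alg in c("glm", "gam", "rf")) {
    m <- fit_member(d, alg, c("T", "junk1"), rf_trees = 300, seed = 1)
    p <- predict_member(m, d)
    thr <- max_tss_threshold(p, d$label)
    expect_equal(attr(thr, "tss"), 1, tolerance = 1e-9)
  }
})

test_that("cross-validation is deterministic and perfect on separable
           data", {
  set.seed(62)
  d <- data.frame(label = rep(c(1, 0), c(40, 200)),
                  T = c(runif(40, 18, 22),
                        sample(c(runif(100, -2, 10), runif(100, 30, 32)))),
                  junk1 = rnorm(240))
  cv1 <- cross_validate(d, "glm", c("T", "junk1"), seed = 4)
  cv2 <- cross_validate(d, "glm", c("T", "junk1"), seed = 4)
  expect_identical(cv1, cv2)
  expect_equal(as.numeric(cv1), 1, tolerance = 1e-9)
  expect_length(attr(cv1, "fold_tss"), 4)
})

test_that("cross-validated skill of label-independent data is near zero", {
  set.seed(55)
  base <- data.frame(label = rep(c(1, 0), c(30, 120)),
                     a = rnorm(150), b = rnorm(150))
  shuffles <- vapply(1:50, function(i) {
    d <- base
    d$label <- sample(d$label)
    as.numeric(cross_validate(d, "glm", c("a", "b"), seed = i))
  }, numeric(1))
  expect_lt(abs(mean(shuffles)), 0.05)
})

test_that("member evaluation fills retention, threshold and skill", {
  d <- thermal_training_data(n_pres = 40, n_bg = 240)
  m <- evaluate_member(d, "glm", c("T", "junk1"), seed = 7)
  expect_s3_class(m, "sdm_member")
  expect_true(is.finite(m$cv_tss))
  expect_true(m$threshold >= 0 && m$threshold <= 1)
  expect_identical(m$retained, m$cv_tss >= 0.35)
  ## retention monotonicity in the TSS floor
  retained_at <- function(t) is.finite(m$cv_tss) && m$cv_tss >= t
  counts <- vapply(c(0, 0.35, 0.8, 0.99), retained_at, logical(1))
  expect_true(all(diff(as.integer(counts)) <= 0))
})

test_that("random forests follow the balanced-subsample configuration", {
  d <- thermal_training_data(n_pres = 30, n_bg = 150)
  m <- fit_member(d, "rf", c("T", "junk1"), seed = 2)  # default trees
  expect_equal(m$model$ntree, 4000)
  ## per-tree subsample balanced to the presence count
  expect_equal(m$rf_sampsize, 30L)
  expect_equal(m$rf_trees, 4000L)
})

test_that("projection binarises at the threshold and keeps missing cells
           missing", {
  env <- small_env()
  ## fabricated GLM member with a known linear response in T
  member <- structure(list(
    algorithm = "glm", predictors = "T",
    model = list(coefficients = c(`(Intercept)` = -2, T = 0.2,
                                  `T^2` = 0)),
    n_presence = 10, n_background = 100, rf_trees = NA_integer_,
    cv_tss = 0.9, threshold = 0.5, retained = TRUE),
    class = "sdm_member")
  map <- project_member(member, env)
  tv <- env_field(env, "T")
  expect_identical(is.na(map), is.na(tv))        # missing, never zero
  ## prob >= threshold convention: plogis(-2 + 0.2 T) >= 0.5 <=> T >= 10
  inside <- !is.na(tv)
  expect_equal(map[inside], as.numeric(tv[inside] >= 10))
})

test_that("ensembles average retained members only", {
  env <- small_env()
  mk <- function(thr, cv) structure(list(
    algorithm = "glm", predictors = "T",
    model = list(coefficients = c(`(Intercept)` = -2, T = 0.2,
                                  `T^2` = 0)),
    n_presence = 10, n_background = 100, rf_trees = NA_integer_,
    cv_tss = cv, threshold = thr, retained = cv >= 0.35),
    class = "sdm_member")
  members <- list(mk(0.5, 0.9), mk(0.7, 0.6), mk(0.9, 0.1))  # last fails
  ens <- build_ensemble(members, env, species_id = "v1")
  expect_equal(ens$n_retained, 2L)
  expect_true(all(ens$values[!is.na(ens$values)] %in% c(0, 0.5, 1)))
  ## a cell with plogis(-2 + .2T) in [0.5, 0.7): member 1 votes, member 2
  ## does not
  tv <- env_field(env, "T")
  sel <- !is.na(tv) & tv >= 10 & tv < (log(0.7 / 0.3) + 2) / 0.2
  if (any(sel)) expect_true(all(ens$values[sel] == 0.5))
  expect_message(
    expect_null(build_ensemble(list(mk(0.5, 0.1)), env)), "excluded")
})
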