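test_that("preprocessing drops zero-variance columns and scales on train only", {
  train <- cbind(a = c(2, 4, 3), b = c(5, 5, 5), c = c(0, 1, 0.5))
  apply_m <- cbind(a = c(5), b = c(7), c = c(2))
  pp <- preprocess_features(train, apply_m)
  expect_equal(pp$dropped, "b")
  expect_equal(colnames(pp$train), c("a", "c"))
  expect_equal(pp$train[, "a"], c(0, 1, 0.5))
  # apply rows may exceed [0, 1] and are not clipped
  expect_equal(unname(pp$apply[1, "a"]), 1.5)
  expect_equal(unname(pp$apply[1, "c"]), 2)
  # already-[0,1] train data is unchanged
  pp2 <- preprocess_features(cbind(x = c(0, 1, 0.25)))
  expect_equal(pp2$train[, "x"], c(0, 1, 0.25), tolerance = 1e-12)
  # a single training row cannot define a scale
  expect_error(preprocess_features(cbind(a = 1)), "single")
})

test_that("cross-validation splits are subject-level with no leakage", {
  ids <- sprintf("s%02d", 1:20)
  labels <- rep(c(0, 1), 10)
  # leave-one-out
  loo <- make_cv_splits(ids, labels, cv_plan("loo"))
  expect_length(loo, 20L)
  for (sp in loo) {
    expect_length(sp$validation, 1L)
    expect_length(intersect(sp$train, sp$validation), 0L)
    expect_setequal(c(sp$train, sp$validation), ids)
  }
  # repeated stratified k-fold: 100 splits, each subject validated 10 times
  rskf <- make_cv_splits(ids, labels, cv_plan("rskf", 10, 10), seed = 4)
  expect_length(rskf, 100L)
  val_counts <- table(unlist(lapply(rskf, function(s) s$validation)))
  expect_true(all(val_counts == 10))
  for (sp in rskf) {
    expect_length(intersect(sp$train, sp$validation), 0L)
    # stratification: each fold's validation set has both classes represented
    # proportionally (1 of each here)
    expect_equal(sum(labels[match(sp$validation, ids)]), 1)
  }
  # determinism
  rskf2 <- make_cv_splits(ids, labels, cv_plan("rskf", 10, 10), seed = 4)
  expect_identical(rskf, rskf2)
  # class smaller than the fold count
  expect_error(make_cv_splits(ids[1:15], c(rep(0, 10), rep(1, 5)),
                              cv_plan("rskf", 10, 10)), "folds")
})

test_that("hard voting takes the majority with ties positive", {
  expect_equal(hard_vote(c(1, 1, 0)), 1L)
  expect_equal(hard_vote(c(0, 0, 0, 0)), 0L)
  expect_equal(hard_vote(c(1, 0)), 1L)
  expect_equal(hard_vote(1), 1L)
})

test_that("separable data is classified perfectly; conflicting rows are not", {
  set.seed(31)
  x <- cbind(a = c(rnorm(15, 0, 0.3), rnorm(15, 5, 0.3)), b = rnorm(30))
  rownames(x) <- sprintf("s%02d", 1:30)
  y <- rep(c(0, 1), each = 15)
  m <- ci_train(x, y, config = toy_model_config(), plan = cv_plan("loo"),
                seed = 2)
  expect_equal(unname(m$voted), y)

  # identical rows with conflicting labels: no better than the base rate
  x2 <- cbind(a = rep(1:5, 6), b = rep(2, 30))
  rownames(x2) <- sprintf("t%02d", 1:30)
  y2 <- rep(c(0, 1, 1), 10)[order(rep(1:5, 6))]
  m2 <- ci_train(x2, y2, config = toy_model_config(), plan = cv_plan("loo"),
                 seed = 2)
  expect_lte(mean(m2$voted == y2), max(mean(y2), 1 - mean(y2)) + 1e-9)
})

test_that("shuffled labels give chance-level voted accuracy", {
  set.seed(77)
  n <- 40
  x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  rownames(x) <- sprintf("s%02d", 1:n)
  y <- sample(rep(c(0, 1), n / 2))
  m <- ci_train(x, y, config = toy_model_config(),
                plan = cv_plan("rskf", 5, 3), seed = 9)
  acc <- mean(m$voted == y)
  # binomial noise around 0.5: 0.5 +- 3*sqrt(.25/40) ~ [0.26, 0.74]
  expect_gt(acc, 0.25)
  expect_lt(acc, 0.75)
})

test_that("single-class data and single-class labels are rejected", {
  x <- cbind(a = rnorm(10)); rownames(x) <- letters[1:10]
  expect_error(ci_train(x, rep(1, 10)), "single-class")
  expect_error(evaluate(runif(10), rep(0, 10)), "single class")
})

test_that("evaluation metrics match closed forms", {
  y <- c(0, 0, 1, 1)
  ev <- evaluate(c(0, 0, 1, 1), y, n_bootstrap = 0)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$f1, 1.0)
  expect_equal(ev$accuracy, 1.0)
  # all-positive predictions on balanced data
  ev2 <- evaluate(rep(1, 4), y, n_bootstrap = 0)
  expect_equal(ev2$recall, 1.0)
  expect_equal(ev2$precision, 0.5)
  # uninformative scores on large balanced data sit near 0.5
  set.seed(6)
  yy <- rep(c(0, 1), 500)
  ev3 <- evaluate(runif(1000), yy, n_bootstrap = 0)
  expect_gt(ev3$auc, 0.44)
  expect_lt(ev3$auc, 0.56)
  # bootstrap CIs bracket the point estimate
  ev4 <- evaluate(runif(100), rep(c(0, 1), 50), n_bootstrap = 200, seed = 2)
  expect_true(ev4$ci["auc", 1] <= ev4$auc && ev4$auc <= ev4$ci["auc", 2])
})

test_that("stump attributions are additive and local", {
  set.seed(12)
  n <- 40
  x <- cbind(filler_rate = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
             noise1 = rnorm(n), noise2 = rnorm(n))
  rownames(x) <- sprintf("s%02d", 1:n)
  y <- rep(c(0, 1), each = n / 2)
  m <- ci_train(x, y, config = toy_model_config(), plan = cv_plan("loo"),
                seed = 5)
  for (i in c(1, 10, 25, 40)) {
    p <- build_profile(x[i, ], m, subject_id = rownames(x)[i])
    # contributions + base reproduce the raw score
    expect_lt(abs(p$base_value + sum(unlist(p$feature_contributions)) -
                    p$raw_score), 1e-6)
    expect_gte(p$predicted_probability, 0)
    expect_lte(p$predicted_probability, 1)
  }
  # two subjects differing only in one feature differ only in its contribution
  a <- x[1, ]; b <- a; b["filler_rate"] <- a["filler_rate"] + 2
  pa <- build_profile(a, m); pb <- build_profile(b, m)
  expect_equal(pa$feature_contributions$noise1, pb$feature_contributions$noise1)
  expect_equal(pa$feature_contributions$noise2, pb$feature_contributions$noise2)

  # schema mismatch errors name the offending feature
  bad <- c(a, extra_feature = 1)
  expect_error(build_profile(bad, m), "extra_feature")
})

test_that("the stump booster agrees with an independent gradient-boosting
           implementation on separable data", {
  set.seed(3)
  n <- 60
  x <- cbind(a = c(rnorm(n / 2, 0), rnorm(n / 2, 4)), b = rnorm(n))
  rownames(x) <- sprintf("s%02d", 1:n)
  y <- rep(c(0, 1), each = n / 2)
  m <- ci_train(x, y, config = toy_model_config(), plan = cv_plan("loo"),
                seed = 7)
  acc_ours <- mean(m$voted == y)

  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xg <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         max_depth = 1, nthread = 1),
                           data = dtrain, nrounds = 50, verbose = 0)
  acc_xgb <- mean(as.integer(predict(xg, dtrain) >= 0.5) == y)
  expect_gte(acc_ours, 0.95)
  expect_gte(acc_xgb, 0.95)
})

test_that("training is reproducible given the seed", {
  set.seed(100)
  x <- matrix(rnorm(40 * 4), 40, dimnames = list(sprintf("s%02d", 1:40),
                                                 paste0("f", 1:4)))
  y <- rep(c(0, 1), 20)
  m1 <- ci_train(x, y, config = toy_model_config(),
                 plan = cv_plan("rskf", 5, 2), seed = 11)
  m2 <- ci_train(x, y, config = toy_model_config(),
                 plan = cv_plan("rskf", 5, 2), seed = 11)
  expect_identical(m1$voted, m2$voted)
  expect_identical(m1$prob, m2$prob)
})

test_that("profiles serialize to JSON with contributions and provenance", {
  set.seed(13)
  x <- cbind(a = c(rnorm(10, 0), rnorm(10, 4)), b = rnorm(20))
  rownames(x) <- sprintf("s%02d", 1:20)
  y <- rep(c(0, 1), each = 10)
  m <- ci_train(x, y, config = toy_model_config(), plan = cv_plan("loo"),
                seed = 1)
  p <- build_profile(x[1, ], m, subject_id = "s01")
  path <- tempfile(fileext = ".json")
  write_profile_json(p, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$subject_id, "s01")
  expect_equal(sort(names(back$feature_contributions)), c("a", "b"))
  expect_equal(back$provenance$seed, 1)
})
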