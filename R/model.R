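# Stage 3: predictive modelling. The classifier is a gradient-boosted ensemble
# of depth-1 trees (stumps) with logistic loss, L1-soft-thresholded leaf
# weights, a per-tree feature subsample, and early stopping on an inner
# validation split. Depth-1 trees make the model additive across features, so
# the diagnostic profile's per-feature contributions plus the base value
# reproduce the raw score exactly.

#' Classifier configuration
#'
#' Defaults are the tuned screening configuration: binary objective, 10,000
#' stumps with early-stopping patience of 50 rounds, maximum depth 1, at least
#' 12 samples per leaf, L1 leaf regularization, and each tree restricted to
#' 20% of the features.
#'
#' @param n_estimators maximum number of trees.
#' @param early_stopping_rounds patience (rounds without validation
#'   improvement) before stopping.
#' @param max_depth tree depth; only depth 1 (stumps) is supported, which is
#'   what makes per-feature attribution exact.
#' @param min_samples_per_leaf minimum data count per leaf.
#' @param lambda_l1 L1 regularization on leaf weights (strength 1 by default).
#' @param lambda_l2 L2 regularization on leaf weights (0 by default).
#' @param feature_fraction fraction of features sampled per tree, in `(0, 1]`.
#' @param learning_rate shrinkage applied to each leaf weight.
#' @export
model_config <- function(n_estimators = 10000, early_stopping_rounds = 50,
                         max_depth = 1, min_samples_per_leaf = 12,
                         lambda_l1 = 1.0, lambda_l2 = 0,
                         feature_fraction = 0.20, learning_rate = 0.1) {
  stopifnot(n_estimators >= 1, early_stopping_rounds >= 1,
            identical(as.integer(max_depth), 1L),
            min_samples_per_leaf >= 1, lambda_l1 >= 0, lambda_l2 >= 0,
            feature_fraction > 0, feature_fraction <= 1, learning_rate > 0)
  structure(list(objective = "binary", n_estimators = as.integer(n_estimators),
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 max_depth = 1L,
                 min_samples_per_leaf = as.integer(min_samples_per_leaf),
                 lambda_l1 = lambda_l1, lambda_l2 = lambda_l2,
                 feature_fraction = feature_fraction,
                 learning_rate = learning_rate),
            class = "model_config")
}

#' Cross-validation plan
#'
#' Folds are always formed at the subject level so no subject contributes to
#' both the training and validation side of a split.
#'
#' @param strategy `"loo"` (leave-one-out) or `"rskf"` (repeated stratified
#'   k-fold).
#' @param folds folds per repeat for RSKF (default 10).
#' @param repeats repeats for RSKF (default 10).
#' @export
cv_plan <- function(strategy = c("rskf", "loo"), folds = 10, repeats = 10) {
  strategy <- match.arg(strategy)
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(strategy = strategy, folds = as.integer(folds),
                 repeats = as.integer(repeats),
                 stratified = strategy == "rskf", unit = "subject"),
            class = "cv_plan")
}

#' Zero-variance drop and train-fitted min-max scaling
#'
#' Columns with zero variance in the training matrix are dropped from both
#' matrices; the remaining columns are affinely mapped so the training minimum
#' becomes 0 and the training maximum 1. Apply rows may land outside `[0, 1]`
#' and are not clipped.
#'
#' @param train training feature matrix (>= 2 rows).
#' @param apply matrix to transform with the train-fitted scaler (same
#'   columns); may be `NULL`.
#' @return list with `train`, `apply`, `dropped` (column names), and `scaler`
#'   (`kept`, `min`, `range`).
#' @export
preprocess_features <- function(train, apply = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("scaling undefined for a single training row",
                            call. = FALSE)
  if (!is.null(apply)) {
    apply <- as.matrix(apply)
    stopifnot(identical(colnames(train), colnames(apply)))
  }
  col_min <- vapply(seq_len(ncol(train)), function(j) min(train[, j]),
                    numeric(1))
  col_max <- vapply(seq_len(ncol(train)), function(j) max(train[, j]),
                    numeric(1))
  rng <- col_max - col_min
  keep <- rng > 0
  dropped <- colnames(train)[!keep]
  mins <- stats::setNames(col_min[keep], colnames(train)[keep])
  ranges <- stats::setNames(rng[keep], colnames(train)[keep])
  scale_mat <- function(m) {
    m <- m[, keep, drop = FALSE]
    sweep(sweep(m, 2, mins, "-"), 2, ranges, "/")
  }
  list(train = scale_mat(train),
       apply = if (is.null(apply)) NULL else scale_mat(apply),
       dropped = dropped,
       scaler = list(kept = colnames(train)[keep], min = mins, range = ranges))
}

apply_scaler <- function(scaler, m) {
  m <- as.matrix(m)
  missing_cols <- setdiff(scaler$kept, colnames(m))
  if (length(missing_cols)) {
    stop("feature schema mismatch; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- m[, scaler$kept, drop = FALSE]
  sweep(sweep(m, 2, scaler$min, "-"), 2, scaler$range, "/")
}

#' Subject-level cross-validation splits
#'
#' @param ids subject identifiers.
#' @param labels binary labels (0/1), aligned with `ids`.
#' @param plan a [cv_plan()].
#' @param seed integer seed; split generation is deterministic given the seed.
#' @return list of `list(train =, validation =)` id vectors. LOO yields one
#'   split per subject; RSKF yields `folds * repeats` splits in which every
#'   subject is validated exactly once per repeat.
#' @export
make_cv_splits <- function(ids, labels, plan = cv_plan(), seed = 1L) {
  stopifnot(inherits(plan, "cv_plan"), length(ids) == length(labels),
            !anyDuplicated(ids))
  labels <- as.integer(labels)
  if (plan$strategy == "loo") {
    return(lapply(seq_along(ids), function(i)
      list(train = ids[-i], validation = ids[i])))
  }
  counts <- table(labels)
  if (length(counts) < 2) stop("need two classes to stratify", call. = FALSE)
  if (any(counts < plan$folds)) {
    stop(sprintf("class with %d subjects cannot be split into %d folds",
                 min(counts), plan$folds), call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  splits <- list()
  for (r in seq_len(plan$repeats)) {
    fold_of <- integer(length(ids))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(plan$folds), length(idx))
    }
    for (f in seq_len(plan$folds)) {
      splits[[length(splits) + 1L]] <- list(train = ids[fold_of != f],
                                            validation = ids[fold_of == f])
    }
  }
  splits
}

#' Majority vote over binary predictions
#'
#' Ties break toward the positive class (screening favours sensitivity).
#'
#' @param votes vector of 0/1 votes (at least one).
#' @return 0 or 1.
#' @export
hard_vote <- function(votes) {
  stopifnot(length(votes) >= 1)
  as.integer(mean(votes) >= 0.5)
}

# ---- boosted stumps --------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

logloss <- function(y, p) {
  p <- pmin(1 - 1e-15, pmax(1e-15, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

soft_threshold <- function(g, alpha) sign(g) * pmax(abs(g) - alpha, 0)

# Fit the gradient-boosted stump classifier.
# x: numeric matrix (n x d), y: 0/1, xval/yval: early-stopping set (optional).
fit_stump_booster <- function(x, y, cfg, xval = NULL, yval = NULL) {
  n <- nrow(x); d <- ncol(x)
  stopifnot(n >= 1, d >= 1, all(y %in% c(0, 1)))
  pbar <- min(1 - 1e-6, max(1e-6, mean(y)))
  f0 <- log(pbar / (1 - pbar))
  ord <- lapply(seq_len(d), function(j) order(x[, j]))
  n_feat <- max(1L, floor(cfg$feature_fraction * d))
  min_leaf <- cfg$min_samples_per_leaf

  trees <- matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("feature", "threshold", "w_left",
                                          "w_right")))
  margin <- rep(f0, n)
  margin_val <- if (!is.null(xval)) rep(f0, nrow(xval)) else NULL
  best_loss <- if (!is.null(xval)) logloss(yval, sigmoid(margin_val)) else Inf
  best_iter <- 0L
  trees_list <- vector("list", cfg$n_estimators)
  n_trees <- 0L

  for (m in seq_len(cfg$n_estimators)) {
    p <- sigmoid(margin)
    g <- p - y
    h <- p * (1 - p)
    feats <- if (n_feat >= d) seq_len(d) else sample.int(d, n_feat)
    best <- NULL
    for (j in feats) {
      o <- ord[[j]]
      xs <- x[o, j]; gs <- cumsum(g[o]); hs <- cumsum(h[o])
      G <- gs[n]; H <- hs[n]
      if (n < 2 * min_leaf) next
      pos <- min_leaf:(n - min_leaf)         # left sizes
      valid <- pos[xs[pos] < xs[pos + 1L]]   # split between distinct values
      if (!length(valid)) next
      GL <- gs[valid]; HL <- hs[valid]
      GR <- G - GL; HR <- H - HL
      sc <- function(gg, hh) soft_threshold(gg, cfg$lambda_l1)^2 /
        (hh + cfg$lambda_l2 + 1e-12)
      gain <- sc(GL, HL) + sc(GR, HR) - sc(G, H)
      k <- which.max(gain)
      if (is.null(best) || gain[k] > best$gain) {
        thr <- (xs[valid[k]] + xs[valid[k] + 1L]) / 2
        best <- list(gain = gain[k], feature = j, threshold = thr,
                     GL = GL[k], HL = HL[k], GR = GR[k], HR = HR[k])
      }
    }
    if (is.null(best) || best$gain <= 1e-12) break  # nothing left to learn
    wl <- -soft_threshold(best$GL, cfg$lambda_l1) /
      (best$HL + cfg$lambda_l2 + 1e-12) * cfg$learning_rate
    wr <- -soft_threshold(best$GR, cfg$lambda_l1) /
      (best$HR + cfg$lambda_l2 + 1e-12) * cfg$learning_rate
    n_trees <- n_trees + 1L
    trees_list[[n_trees]] <- c(best$feature, best$threshold, wl, wr)
    left <- x[, best$feature] <= best$threshold
    margin <- margin + ifelse(left, wl, wr)

    if (!is.null(xval)) {
      left_v <- xval[, best$feature] <= best$threshold
      margin_val <- margin_val + ifelse(left_v, wl, wr)
      loss <- logloss(yval, sigmoid(margin_val))
      if (loss < best_loss - 1e-12) {
        best_loss <- loss; best_iter <- n_trees
      } else if (n_trees - best_iter >= cfg$early_stopping_rounds) {
        break
      }
    } else {
      best_iter <- n_trees
    }
  }
  if (best_iter > 0L) {
    trees <- matrix(unlist(trees_list[seq_len(best_iter)]), ncol = 4,
                    byrow = TRUE,
                    dimnames = list(NULL, c("feature", "threshold", "w_left",
                                            "w_right")))
  }
  structure(list(trees = trees, base = f0, best_iter = best_iter,
                 feature_names = colnames(x), config = cfg),
            class = "stump_booster")
}

# raw additive score (log-odds margin)
predict_margin <- function(booster, x) {
  x <- as.matrix(x)
  out <- rep(booster$base, nrow(x))
  tr <- booster$trees
  if (!is.null(tr) && nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      left <- x[, tr[i, "feature"]] <= tr[i, "threshold"]
      out <- out + ifelse(left, tr[i, "w_left"], tr[i, "w_right"])
    }
  }
  out
}

# per-feature contributions for one row: each stump credits its split feature;
# contributions + base == raw margin exactly
stump_contributions <- function(booster, xrow) {
  contrib <- stats::setNames(numeric(length(booster$feature_names)),
                             booster$feature_names)
  tr <- booster$trees
  if (!is.null(tr) && nrow(tr)) {
    for (i in seq_len(nrow(tr))) {
      f <- tr[i, "feature"]
      w <- if (xrow[[f]] <= tr[i, "threshold"]) tr[i, "w_left"] else tr[i, "w_right"]
      contrib[f] <- contrib[f] + w
    }
  }
  contrib
}

# stratified inner split for early stopping: ~20% of each class to validation
inner_split <- function(y, fraction = 0.2) {
  val <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < 2) next
    n_val <- max(1L, round(fraction * length(idx)))
    n_val <- min(n_val, length(idx) - 1L)
    val <- c(val, sample(idx, n_val))
  }
  val
}

#' Fit the cross-validated voting classifier
#'
#' For every subject-level split: zero-variance features are dropped and a
#' min-max scaler fitted on the fold's training subjects only; an inner
#' stratified 80/20 split of the training fold provides the early-stopping
#' set; a boosted-stump classifier is fitted and the held-out subjects are
#' scored. Per-subject votes across folds are ensembled by [hard_vote()];
#' the per-subject probability is the mean predicted probability across the
#' folds that validated the subject. A final model (same recipe, all
#' subjects) is fitted for the diagnostic profile.
#'
#' @param features numeric feature matrix, one row per subject, with subject
#'   ids as row names (see [feature_matrix()]).
#' @param labels binary labels (0 = cognitively normal, 1 = impaired), aligned
#'   with the rows.
#' @param config a [model_config()].
#' @param plan a [cv_plan()].
#' @param seed integer seed controlling split generation, feature subsampling
#'   and the inner splits; the whole procedure is reproducible given the seed.
#' @return object of class `ci_model` with voted labels, mean probabilities,
#'   per-subject vote lists, per-fold models, and the final model + scaler.
#' @export
ci_train <- function(features, labels, config = model_config(),
                     plan = cv_plan(), seed = 1L) {
  features <- as.matrix(features)
  stopifnot(!is.null(rownames(features)), !is.null(colnames(features)))
  ids <- rownames(features)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(features), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2) {
    stop("single-class data: need both classes to train", call. = FALSE)
  }
  names(labels) <- ids

  splits <- make_cv_splits(ids, labels, plan, seed)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + 1L)

  votes <- stats::setNames(vector("list", length(ids)), ids)
  probs <- stats::setNames(vector("list", length(ids)), ids)
  fold_models <- vector("list", length(splits))
  log <- character()

  fit_one <- function(xtr, ytr) {
    if (length(unique(ytr)) < 2) return(NULL)
    val_idx <- inner_split(ytr)
    if (length(val_idx) && length(unique(ytr[-val_idx])) == 2) {
      fit_stump_booster(xtr[-val_idx, , drop = FALSE], ytr[-val_idx], config,
                        xtr[val_idx, , drop = FALSE], ytr[val_idx])
    } else {
      fit_stump_booster(xtr, ytr, config)
    }
  }

  for (s in seq_along(splits)) {
    tr_ids <- splits[[s]]$train; va_ids <- splits[[s]]$validation
    pp <- preprocess_features(features[tr_ids, , drop = FALSE],
                              features[va_ids, , drop = FALSE])
    ytr <- labels[tr_ids]
    booster <- fit_one(pp$train, ytr)
    if (is.null(booster)) {
      log <- c(log, sprintf("split %d: single-class training fold, majority prediction", s))
      p <- rep(mean(ytr), length(va_ids))
    } else {
      p <- sigmoid(predict_margin(booster, pp$apply))
      fold_models[[s]] <- booster
    }
    for (k in seq_along(va_ids)) {
      id <- va_ids[k]
      votes[[id]] <- c(votes[[id]], as.integer(p[k] >= 0.5))
      probs[[id]] <- c(probs[[id]], p[k])
    }
  }

  voted <- vapply(votes, hard_vote, integer(1))
  prob <- vapply(probs, mean, numeric(1))

  pp_all <- preprocess_features(features)
  final <- fit_one(pp_all$train, labels)

  structure(list(
    subjects = ids, labels = labels, voted = voted, prob = prob,
    votes = votes, fold_models = fold_models,
    final_model = final, scaler = pp_all$scaler,
    dropped_features = pp_all$dropped,
    config = config, plan = plan, seed = seed, log = log
  ), class = "ci_model")
}

#' @export
print.ci_model <- function(x, ...) {
  acc <- mean(x$voted == x$labels)
  cat(sprintf("<ci_model> %s CV over %d subjects (%d impaired / %d normal)\n",
              toupper(x$plan$strategy), length(x$subjects), sum(x$labels),
              sum(1 - x$labels)))
  cat(sprintf("  voted accuracy %.3f; %d trees in final model; %d feature(s) dropped\n",
              acc, if (is.null(x$final_model)) 0L else nrow(x$final_model$trees),
              length(x$dropped_features)))
  invisible(x)
}

#' @export
summary.ci_model <- function(object, ...) {
  ev <- evaluate(object$prob, object$labels, n_bootstrap = 0)
  cat(sprintf("Cross-validated (%s) voting classifier, %d subjects\n",
              toupper(object$plan$strategy), length(object$subjects)))
  cat(sprintf("  AUC %.3f  F1 %.3f  precision %.3f  recall %.3f  accuracy %.3f\n",
              ev$auc, ev$f1, ev$precision, ev$recall, ev$accuracy))
  if (length(object$dropped_features)) {
    cat("  dropped (zero variance):",
        paste(object$dropped_features, collapse = ", "), "\n")
  }
  if (length(object$log)) cat("  notes:", length(object$log), "degenerate fold(s)\n")
  invisible(ev)
}

#' Predict with a fitted `ci_model`
#'
#' @param object a `ci_model`.
#' @param newdata feature matrix with the training schema (extra columns are
#'   ignored; missing ones are an error).
#' @param type `"prob"` (default) or `"label"`.
#' @param ... unused.
#' @export
predict.ci_model <- function(object, newdata, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  if (is.null(object$final_model)) stop("model has no final fit", call. = FALSE)
  x <- apply_scaler(object$scaler, newdata)
  p <- sigmoid(predict_margin(object$final_model, x))
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Evaluate predictions against labels
#'
#' AUC is computed from the continuous scores (Mann-Whitney, via pROC); F1,
#' precision, recall and accuracy from the binarized predictions (threshold
#' 0.5 when scores are continuous). Confidence intervals are percentile
#' bootstrap over subjects.
#'
#' @param scores continuous scores or 0/1 predictions.
#' @param labels binary labels (both classes must be present).
#' @param n_bootstrap bootstrap replicates (default 1000; 0 disables CIs).
#' @param seed bootstrap seed.
#' @return list with `auc`, `f1`, `precision`, `recall`, `accuracy`, and (when
#'   bootstrapped) a `ci` matrix of 95% percentile intervals.
#' @export
evaluate <- function(scores, labels, n_bootstrap = 1000, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("labels contain a single class; metrics undefined", call. = FALSE)
  }
  metrics <- function(sc, y) {
    pred <- as.integer(sc >= 0.5)
    tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
    fn <- sum(pred == 0 & y == 1)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    auc <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                          levels = c(0, 1), direction = "<")))
    c(auc = auc, f1 = f1, precision = prec, recall = rec,
      accuracy = mean(pred == y))
  }
  point <- metrics(scores, labels)
  out <- as.list(point)
  if (n_bootstrap > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    boot <- matrix(NA_real_, n_bootstrap, length(point),
                   dimnames = list(NULL, names(point)))
    n <- length(labels)
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) < 2) next
      boot[b, ] <- metrics(scores[idx], labels[idx])
    }
    out$ci <- t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
                      na.rm = TRUE))
  }
  out
}

#' Build an explainable diagnostic profile for one subject
#'
#' Decomposes the model's raw score into per-feature contributions using the
#' additive stump structure: each tree credits exactly one feature, and the
#' contributions plus the base value reproduce the raw log-odds score exactly.
#'
#' @param features named numeric vector (or 1-row matrix) on the training
#'   feature schema.
#' @param model a fitted `ci_model`.
#' @param detections optional per-indicator detection lists to embed.
#' @param subject_id identifier stamped on the profile.
#' @return object of class `diagnostic_profile` (serializable with
#'   [write_profile_json()]).
#' @export
build_profile <- function(features, model, detections = NULL,
                          subject_id = "subject") {
  stopifnot(inherits(model, "ci_model"))
  if (is.null(model$final_model)) stop("model has no final fit", call. = FALSE)
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list(subject_id, names(features)))
  }
  extra <- setdiff(colnames(features), c(model$scaler$kept,
                                         model$dropped_features))
  if (length(extra)) {
    stop("feature schema mismatch; extra: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  x <- apply_scaler(model$scaler, features)
  contrib <- stump_contributions(model$final_model, x[1, ])
  raw <- model$final_model$base + sum(contrib)
  prob <- sigmoid(raw)
  structure(list(
    subject_id = subject_id,
    feature_values = as.list(features[1, model$scaler$kept]),
    feature_contributions = as.list(contrib),
    base_value = model$final_model$base,
    raw_score = raw,
    predicted_label = as.integer(prob >= 0.5),
    predicted_probability = prob,
    detections = detections,
    provenance = list(config = unclass(model$config),
                      plan = unclass(model$plan), seed = model$seed,
                      dropped_features = model$dropped_features,
                      package_version = as.character(utils::packageVersion("cogspeech")))
  ), class = "diagnostic_profile")
}

#' @export
print.diagnostic_profile <- function(x, ...) {
  cat(sprintf("<diagnostic_profile> subject %s: predicted %s (p = %.3f)\n",
              x$subject_id,
              if (x$predicted_label == 1) "IMPAIRED" else "normal",
              x$predicted_probability))
  contrib <- unlist(x$feature_contributions)
  contrib <- contrib[order(-abs(contrib))]
  for (n in names(head(contrib, 6))) {
    cat(sprintf("  %-26s %+.4f\n", n, contrib[[n]]))
  }
  invisible(x)
}

#' Write a diagnostic profile as JSON
#' @param profile a `diagnostic_profile`.
#' @param path output file.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
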