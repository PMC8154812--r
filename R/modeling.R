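# Feature selection (filter + wrapper, LOOCV) and the multi-classifier
# benchmark for detecting significant aortic regurgitation.
#
# Conventions: positive class = AR present (label 1). Tie-breaking everywhere
# follows feature catalogue order (stable sorts over the catalogue-ordered
# columns), so results are reproducible rather than arbitrary.

#' A labeled feature table
#'
#' Validates a data.frame of extracted features: one row per recording, the
#' 19 catalogue feature columns, a binary `ar_label` and (optionally) a
#' `recording_id`. Missing values are permitted but must be handled by an
#' explicit imputation step (fitted on training folds only); modeling
#' functions never impute silently across the train/test boundary.
#'
#' @param df a data.frame containing the feature columns and `ar_label`.
#' @return the validated table, class `feature_table`.
#' @export
feature_table <- function(df) {
  need <- c(feature_names(), "ar_label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("feature table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$ar_label %in% c(0, 1)))
    stop("ar_label must be binary 0/1")
  if (!"recording_id" %in% names(df))
    df$recording_id <- sprintf("rec%04d", seq_len(nrow(df)))
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Write / read a feature table as CSV
#'
#' One row per recording: `recording_id`, the 19 feature columns in catalogue
#' order, and `ar_label`. Missing features are empty cells.
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @return `path` invisibly (write); a `feature_table` (read).
#' @export
write_feature_csv <- function(table, path) {
  cols <- c("recording_id", feature_names(), "ar_label")
  utils::write.csv(as.data.frame(table)[, cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  # all-missing columns come back logical; features are always numeric
  present <- intersect(feature_names(), names(df))
  df[present] <- lapply(df[present], as.numeric)
  feature_table(df)
}

.table_xy <- function(table, features = feature_names()) {
  X <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = as.integer(table$ar_label))
}

# median imputation: medians estimated on `fit_rows` only, applied everywhere
.impute_median <- function(X, fit_rows = seq_len(nrow(X))) {
  for (j in seq_len(ncol(X))) {
    if (anyNA(X[, j])) {
      m <- stats::median(X[fit_rows, j], na.rm = TRUE)
      if (is.na(m)) m <- stats::median(X[, j], na.rm = TRUE)
      X[is.na(X[, j]), j] <- m
    }
  }
  X
}

.scale_fit <- function(X, rows) {
  mu <- colMeans(X[rows, , drop = FALSE])
  sd <- apply(X[rows, , drop = FALSE], 2, stats::sd)
  sd[!is.finite(sd) | sd <= 0] <- 1
  list(mu = mu, sd = sd)
}
.scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

#' Rank features by unpaired t-test p-value
#'
#' Two-sample pooled-variance t-test per feature (complete observations),
#' features ordered by ascending p-value, ties broken by catalogue order.
#'
#' @param table a [feature_table()].
#' @return data.frame with columns `feature`, `p_value`, ordered by rank.
#' @export
rank_by_ttest <- function(table) {
  xy <- .table_xy(table)
  if (length(unique(xy$y)) < 2)
    stop("single-class table: both AR classes are required")
  p <- vapply(seq_len(ncol(xy$X)), function(j) {
    x0 <- xy$X[xy$y == 0, j]; x1 <- xy$X[xy$y == 1, j]
    x0 <- x0[!is.na(x0)]; x1 <- x1[!is.na(x1)]
    if (length(x0) < 2 || length(x1) < 2) return(NA_real_)
    tryCatch(stats::t.test(x0, x1, var.equal = TRUE)$p.value,
             # zero pooled variance: infinitely significant unless the class
             # means coincide
             error = function(e) if (mean(x0) == mean(x1)) 1 else 0)
  }, numeric(1))
  ord <- order(p, seq_along(p), na.last = TRUE)  # stable: catalogue order ties
  data.frame(feature = colnames(xy$X)[ord], p_value = p[ord],
             stringsAsFactors = FALSE)
}

#' Rank features by random-forest Gini importance
#'
#' Mean decrease in Gini impurity from a random forest grown on the (median
#' imputed) table, features in descending importance, deterministic for a
#' given seed.
#'
#' @param table a [feature_table()].
#' @param seed integer seed for the forest.
#' @param ntree number of trees.
#' @return data.frame with columns `feature`, `importance`, ordered by rank.
#' @export
rank_by_gini <- function(table, seed = 1, ntree = 500) {
  xy <- .table_xy(table)
  X <- .impute_median(xy$X)
  imp <- .with_seed(seed, {
    rf <- randomForest::randomForest(X, factor(xy$y, levels = c(0, 1)),
                                     ntree = ntree)
    rf$importance[, "MeanDecreaseGini"]
  })
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = colnames(X)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

# ---- internal regularized linear discriminant (selection work-horse) -------
#
# Pooled-covariance LDA with automatic diagonal shrinkage when the covariance
# is singular. Leave-one-out predictions use exact rank-one downdates of the
# class means and pooled scatter, so LOOCV costs one p x p solve per sample.

.lda_loo_error <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  n1 <- sum(y == 1); n0 <- n - n1
  if (n0 < 2 || n1 < 2) stop("need at least 2 samples per class")
  s0 <- colSums(X[y == 0, , drop = FALSE])
  s1 <- colSums(X[y == 1, , drop = FALSE])
  xx <- crossprod(X)
  wrong <- 0L
  for (i in seq_len(n)) {
    xi <- X[i, ]
    if (y[i] == 1) { s1i <- s1 - xi; s0i <- s0; n1i <- n1 - 1L; n0i <- n0 }
    else { s0i <- s0 - xi; s1i <- s1; n0i <- n0 - 1L; n1i <- n1 }
    m0 <- s0i / n0i; m1 <- s1i / n1i
    W <- xx - tcrossprod(xi) - n0i * tcrossprod(m0) - n1i * tcrossprod(m1)
    S <- W / (n - 1L - 2L)
    lam <- 1e-8 * mean(diag(S))
    if (!is.finite(lam) || lam <= 0) lam <- 1e-8
    fit <- NULL
    for (boost in c(1, 1e4, 1e8)) {
      fit <- tryCatch(solve(S + diag(lam * boost, p), cbind(m0, m1)),
                      error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) { wrong <- wrong + (y[i] != as.integer(n1i >= n0i)); next }
    d0 <- sum(xi * fit[, 1]) - 0.5 * sum(m0 * fit[, 1]) + log(n0i / (n - 1L))
    d1 <- sum(xi * fit[, 2]) - 0.5 * sum(m1 * fit[, 2]) + log(n1i / (n - 1L))
    pred <- as.integer(d1 > d0)
    wrong <- wrong + as.integer(pred != y[i])
  }
  wrong / n
}

#' Filter feature selection by discriminant-analysis misclassification
#'
#' Features are added one at a time in ranking order; after each addition the
#' leave-one-out misclassification error of a (regularized) linear
#' discriminant classifier is recorded. The selected subset is the earliest
#' prefix achieving the minimum error.
#'
#' @param table a [feature_table()].
#' @param ranking a ranking data.frame (from [rank_by_ttest()],
#'   [rank_by_gini()] or [rank_by_nca()]) or a character vector of feature
#'   names in rank order.
#' @return list with `subset` (character), `trace` (data.frame of `feature`,
#'   `n_features`, `loo_error`).
#' @export
filter_select <- function(table, ranking) {
  feats <- if (is.data.frame(ranking)) ranking$feature else as.character(ranking)
  xy <- .table_xy(table, feats)
  X <- .impute_median(xy$X)
  errs <- numeric(length(feats))
  for (k in seq_along(feats))
    errs[k] <- .lda_loo_error(X[, seq_len(k), drop = FALSE], xy$y)
  best <- which.min(errs)  # earliest prefix on ties
  list(subset = feats[seq_len(best)],
       trace = data.frame(feature = feats, n_features = seq_along(feats),
                          loo_error = errs, stringsAsFactors = FALSE))
}

#' Wrapper feature selection by forward sequential search
#'
#' Greedy forward selection over the filter-selected features, scored by
#' leave-one-out misclassification of the discriminant classifier. The first
#' (best single) feature is always taken; thereafter a feature is added only
#' if it strictly lowers the LOOCV error, so the final error never exceeds
#' that of any prefix. Ties prefer the candidate earliest in catalogue order.
#'
#' @param table a [feature_table()].
#' @param filter_subset non-empty character vector of candidate features.
#' @return list with `subset` (character) and `trace` (error after each
#'   accepted addition).
#' @export
wrapper_select <- function(table, filter_subset) {
  if (length(filter_subset) == 0) stop("filter_subset must be non-empty")
  cand <- feature_names()[feature_names() %in% filter_subset]  # catalogue order
  xy <- .table_xy(table, cand)
  X <- .impute_median(xy$X)
  selected <- integer(0)
  best_err <- Inf
  trace <- data.frame(feature = character(0), loo_error = numeric(0),
                      stringsAsFactors = FALSE)
  repeat {
    remaining <- setdiff(seq_along(cand), selected)
    if (length(remaining) == 0) break
    errs <- vapply(remaining, function(j)
      .lda_loo_error(X[, c(selected, j), drop = FALSE], xy$y), numeric(1))
    j_best <- remaining[which.min(errs)]
    e_best <- min(errs)
    improves <- if (length(selected) == 0) TRUE else e_best < best_err
    if (!improves) break
    selected <- c(selected, j_best)
    best_err <- e_best
    trace <- rbind(trace, data.frame(feature = cand[j_best],
                                     loo_error = e_best))
  }
  list(subset = cand[selected], trace = trace)
}

#' Rank features by neighborhood component analysis
#'
#' Diagonal NCA: feature weights maximize the expected leave-one-out
#' classification accuracy under a softmax neighbor model on standardized
#' features, with an L2 penalty. Off by default in the selection pipeline.
#'
#' @param table a [feature_table()].
#' @param seed integer seed (the optimization itself is deterministic from a
#'   unit initialization; the seed is kept for interface stability).
#' @param lambda L2 regularization weight.
#' @return data.frame with columns `feature`, `weight`, ordered by descending
#'   weight.
#' @export
rank_by_nca <- function(table, seed = 1, lambda = 0.01) {
  xy <- .table_xy(table)
  X <- .impute_median(xy$X)
  sc <- .scale_fit(X, seq_len(nrow(X)))
  X <- .scale_apply(X, sc)
  y <- xy$y
  n <- nrow(X); p <- ncol(X)
  same <- outer(y, y, "==")
  diag(same) <- FALSE
  D <- lapply(seq_len(p), function(k) outer(X[, k], X[, k], "-")^2)
  objective <- function(w) {
    d <- Reduce(`+`, Map(function(Dk, wk) wk^2 * Dk, D, as.list(w)))
    K <- exp(-(d - apply(d + diag(Inf, n), 1, min)))  # row-stabilized
    diag(K) <- 0
    P <- K / pmax(rowSums(K), 1e-300)
    -(mean(rowSums(P * same)) - lambda * sum(w^2))
  }
  opt <- stats::optim(rep(1, p), objective, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = 200))
  if (opt$convergence != 0)
    warning("NCA optimization did not converge; ranking may be unstable")
  w <- opt$par
  ord <- order(-w, seq_along(w))
  data.frame(feature = colnames(X)[ord], weight = w[ord],
             stringsAsFactors = FALSE)
}

#' Run the full selection pipeline
#'
#' t-test and Gini rankings, the filter stage (iterative addition in rank
#' order, minimum discriminant-analysis LOOCV error), and the wrapper stage
#' (forward sequential selection within the filter subset).
#'
#' @param table a [feature_table()].
#' @param seed seed for the Gini forest.
#' @param ranking which ranking drives the filter stage: `"ttest"` (default),
#'   `"gini"`, or `"nca"`.
#' @return an object of class `selection_result`.
#' @export
select_features <- function(table, seed = 1, ranking = c("ttest", "gini", "nca")) {
  ranking <- match.arg(ranking)
  tt <- rank_by_ttest(table)
  gg <- rank_by_gini(table, seed = seed)
  driver <- switch(ranking, ttest = tt, gini = gg,
                   nca = rank_by_nca(table, seed = seed))
  filt <- filter_select(table, driver)
  wrap <- wrapper_select(table, filt$subset)
  structure(list(ttest_ranking = tt, gini_ranking = gg,
                 driver = ranking, filter_trace = filt$trace,
                 filter_subset = filt$subset, wrapper_subset = wrap$subset,
                 wrapper_trace = wrap$trace,
                 cv_scheme = "leave-one-out within selection", seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>\n")
  cat("  ranking driver:", x$driver, "\n")
  cat("  filter subset: ", paste(x$filter_subset, collapse = ", "), "\n")
  cat("  wrapper subset:", paste(x$wrapper_subset, collapse = ", "), "\n")
  invisible(x)
}

#' Classification metrics
#'
#' Accuracy, AUC (rank statistic over scores, midranks for ties — identical
#' scores for every sample give 0.5), true positive rate (detected AR among
#' AR) and true negative rate.
#'
#' @param predictions 0/1 predicted labels.
#' @param scores numeric scores, higher = more AR-like (AUC is invariant to
#'   monotone transformations of these).
#' @param labels 0/1 true labels.
#' @return named numeric `c(accuracy, auc, tpr, tnr)`.
#' @export
evaluate_metrics <- function(predictions, scores, labels) {
  predictions <- as.integer(as.character(predictions))
  labels <- as.integer(labels)
  stopifnot(length(predictions) == length(labels),
            length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  acc <- mean(predictions == labels)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(scores)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  tpr <- if (n1 == 0) NA_real_ else mean(predictions[labels == 1] == 1)
  tnr <- if (n0 == 0) NA_real_ else mean(predictions[labels == 0] == 0)
  c(accuracy = acc, auc = auc, tpr = tpr, tnr = tnr)
}

#' Stratified train/test split
#'
#' @param labels 0/1 labels.
#' @param train_frac fraction assigned to training.
#' @param seed integer seed.
#' @return integer vector of training-row indices.
#' @export
stratified_split <- function(labels, train_frac = 0.75, seed = 1) {
  .with_seed(seed, {
    idx <- unlist(lapply(unique(labels), function(cl) {
      rows <- which(labels == cl)
      sample(rows, max(1, round(train_frac * length(rows))))
    }))
    sort(idx)
  })
}

# ---- individual classifiers -------------------------------------------------
# each .clf_* returns list(pred = 0/1 integer, score = numeric AR score)

.clf_lda <- function(Xtr, ytr, Xte, tune, seed) {
  yf <- factor(ytr, levels = c(0, 1))
  fit <- tryCatch(MASS::lda(Xtr, grouping = yf, tol = 1e-8),
                  error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate within-class covariance: regularize with a small seeded jitter
    Xj <- .with_seed(seed, Xtr + matrix(stats::rnorm(length(Xtr), 0,
                                                     1e-3 * max(abs(Xtr), 1)),
                                        nrow(Xtr)))
    fit <- MASS::lda(Xj, grouping = yf, tol = 1e-10)
  }
  pr <- stats::predict(fit, Xte)
  list(pred = as.integer(as.character(pr$class)), score = pr$posterior[, "1"])
}

.clf_knn <- function(Xtr, ytr, Xte, tune, seed, k = 5) {
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  d2[d2 < 0] <- 0
  score <- numeric(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    nn <- order(d2[i, ])[seq_len(min(k, ncol(d2)))]
    w <- 1 / (sqrt(d2[i, nn]) + 1e-9)
    score[i] <- sum(w[ytr[nn] == 1]) / sum(w)
  }
  list(pred = as.integer(score > 0.5), score = score)
}

.clf_nb <- function(Xtr, ytr, Xte, tune, seed) {
  fit <- e1071::naiveBayes(Xtr, factor(ytr, levels = c(0, 1)))
  raw <- stats::predict(fit, Xte, type = "raw")
  list(pred = as.integer(raw[, "1"] > 0.5), score = raw[, "1"])
}

# kernel naive Bayes: kernel-density class-conditional per feature
.clf_knb <- function(Xtr, ytr, Xte, tune, seed) {
  classes <- c(0, 1)
  loglik <- matrix(0, nrow(Xte), 2)
  for (ci in 1:2) {
    rows <- ytr == classes[ci]
    loglik[, ci] <- log(mean(rows))
    for (j in seq_len(ncol(Xtr))) {
      xj <- Xtr[rows, j]
      if (stats::sd(xj) < 1e-12) {
        dens <- stats::dnorm(Xte[, j], mean(xj), max(1e-6, 1e-3 * abs(mean(xj))))
      } else {
        d <- stats::density(xj, bw = "nrd0", n = 512,
                            from = min(xj) - 3 * stats::bw.nrd0(xj),
                            to = max(xj) + 3 * stats::bw.nrd0(xj))
        dens <- stats::approx(d$x, d$y, xout = Xte[, j], rule = 2)$y
      }
      loglik[, ci] <- loglik[, ci] + log(pmax(dens, 1e-12))
    }
  }
  post <- 1 / (1 + exp(loglik[, 1] - loglik[, 2]))
  list(pred = as.integer(post > 0.5), score = post)
}

.clf_rf <- function(Xtr, ytr, Xte, tune, seed) {
  yf <- factor(ytr, levels = c(0, 1))
  p <- ncol(Xtr)
  mtry <- max(1, floor(sqrt(p)))
  if (tune && p > 2) {
    # tenfold stratified CV over a small mtry grid
    grid <- unique(pmax(1, c(floor(sqrt(p)), floor(p / 3), floor(2 * p / 3))))
    folds <- .with_seed(seed + 1, .stratified_folds(ytr, 10))
    cv_acc <- vapply(grid, function(m) {
      acc <- 0
      for (f in seq_along(folds)) {
        te <- folds[[f]]; tr <- setdiff(seq_along(ytr), te)
        fit <- .with_seed(seed + 2 + f,
                          randomForest::randomForest(Xtr[tr, , drop = FALSE],
                                                     yf[tr], ntree = 200,
                                                     mtry = m))
        acc <- acc + sum(stats::predict(fit, Xtr[te, , drop = FALSE]) == yf[te])
      }
      acc / length(ytr)
    }, numeric(1))
    mtry <- grid[which.max(cv_acc)]
  }
  fit <- .with_seed(seed, randomForest::randomForest(Xtr, yf, ntree = 500,
                                                     mtry = mtry))
  prob <- stats::predict(fit, Xte, type = "prob")[, "1"]
  list(pred = as.integer(prob > 0.5), score = prob)
}

.svm_loo_acc <- function(Xtr, ytr, kernel, cost, gamma) {
  n <- length(ytr)
  yf <- factor(ytr, levels = c(0, 1))
  ok <- 0L
  for (i in seq_len(n)) {
    fit <- tryCatch(
      e1071::svm(Xtr[-i, , drop = FALSE], yf[-i], kernel = kernel,
                 cost = cost, gamma = gamma, scale = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- ok + (stats::predict(fit, Xtr[i, , drop = FALSE]) == yf[i])
  }
  ok / n
}

.clf_svm <- function(Xtr, ytr, Xte, tune, seed, kernel = "linear") {
  yf <- factor(ytr, levels = c(0, 1))
  p <- ncol(Xtr)
  cost <- 1; gamma <- 1 / p
  if (tune) {
    grid <- if (kernel == "linear")
      expand.grid(cost = c(0.1, 1, 10), gamma = 1 / p)
    else expand.grid(cost = c(1, 10), gamma = c(0.5, 1, 2) / p)
    acc <- mapply(function(c_, g_) .svm_loo_acc(Xtr, ytr, kernel, c_, g_),
                  grid$cost, grid$gamma)
    best <- which.max(acc)
    cost <- grid$cost[best]; gamma <- grid$gamma[best]
  }
  fit <- .with_seed(seed,
                    e1071::svm(Xtr, yf, kernel = kernel, cost = cost,
                               gamma = gamma, scale = FALSE, probability = TRUE))
  pr <- stats::predict(fit, Xte, probability = TRUE)
  prob <- attr(pr, "probabilities")[, "1"]
  list(pred = as.integer(as.character(pr)), score = prob)
}

.clf_tree <- function(Xtr, ytr, Xte, tune, seed) {
  df <- data.frame(Xtr, y = factor(ytr, levels = c(0, 1)))
  fit <- .with_seed(seed,
                    rpart::rpart(y ~ ., df, method = "class",
                                 control = rpart::rpart.control(
                                   xval = if (tune) 10 else 0, cp = 0.01,
                                   minsplit = 5)))
  if (tune && nrow(fit$cptable) > 1) {
    best_cp <- fit$cptable[which.min(fit$cptable[, "xerror"]), "CP"]
    fit <- rpart::prune(fit, cp = best_cp)
  }
  prob <- stats::predict(fit, data.frame(Xte), type = "prob")[, "1"]
  list(pred = as.integer(prob > 0.5), score = prob)
}

# bootstrap-aggregated decision trees (default ensemble), or AdaBoost.M1
.clf_ensemble <- function(Xtr, ytr, Xte, tune, seed, type = "bagging",
                          n_trees = 100) {
  dtr <- data.frame(Xtr, y = factor(ytr, levels = c(0, 1)))
  dte <- data.frame(Xte)
  if (type == "bagging") {
    score <- .with_seed(seed, {
      probs <- matrix(0, nrow(Xte), n_trees)
      for (b in seq_len(n_trees)) {
        rows <- sample.int(nrow(dtr), replace = TRUE)
        fit <- rpart::rpart(y ~ ., dtr[rows, ], method = "class",
                            control = rpart::rpart.control(xval = 0, cp = 0.01,
                                                           minsplit = 5))
        probs[, b] <- stats::predict(fit, dte, type = "prob")[, "1"]
      }
      rowMeans(probs)
    })
  } else {  # adaboost with shallow trees
    score <- .with_seed(seed, {
      n <- nrow(dtr)
      w <- rep(1 / n, n)
      fmargin <- numeric(nrow(Xte))
      ypm <- ifelse(ytr == 1, 1, -1)
      for (b in seq_len(n_trees)) {
        fit <- rpart::rpart(y ~ ., dtr, weights = w, method = "class",
                            control = rpart::rpart.control(xval = 0, cp = 0,
                                                           maxdepth = 2,
                                                           minsplit = 5))
        pred_tr <- ifelse(stats::predict(fit, dtr, type = "class") == "1", 1, -1)
        err <- sum(w * (pred_tr != ypm))
        if (err <= 0 || err >= 0.5) break
        alpha <- 0.5 * log((1 - err) / err)
        w <- w * exp(-alpha * ypm * pred_tr)
        w <- w / sum(w)
        fmargin <- fmargin +
          alpha * ifelse(stats::predict(fit, dte, type = "class") == "1", 1, -1)
      }
      1 / (1 + exp(-2 * fmargin))
    })
  }
  list(pred = as.integer(score > 0.5), score = score)
}

.stratified_folds <- function(y, k) {
  folds <- vector("list", k)
  for (cl in unique(y)) {
    rows <- sample(which(y == cl))
    assign_to <- rep(seq_len(k), length.out = length(rows))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], rows[assign_to == f])
  }
  folds
}

#' Classifier names reported by the benchmark
#' @return character vector of the 9 classifier identifiers (8 algorithms
#'   plus the ensemble).
#' @export
classifier_names <- function() {
  c("discriminant_analysis", "knn", "naive_bayes", "kernel_naive_bayes",
    "random_forest", "svm", "kernel_svm", "decision_tree", "ensemble")
}

#' Benchmark the classifier suite on a held-out split
#'
#' Stratified 75/25 train/test split; median imputation and z-scaling fitted
#' on the training rows only; hyper-parameters tuned on training data
#' (leave-one-out for the support vector machines, tenfold stratified CV for
#' the random forest, internal tenfold CV pruning for the decision tree);
#' metrics computed on the untouched test rows. Reports all 8 algorithms plus
#' the ensemble (bootstrap-aggregated decision trees by default).
#'
#' @param table a [feature_table()].
#' @param feature_subset non-empty character vector of features to use.
#' @param split_seed seed controlling the split and every stochastic fit.
#' @param split optional pre-computed training-row indices (e.g. the split
#'   already used for feature selection); drawn from `split_seed` when `NULL`.
#' @param tune logical; `FALSE` skips hyper-parameter search (defaults used).
#' @param ensemble_type `"bagging"` (default) or `"boosting"`.
#' @param n_trees ensemble size.
#' @param classifiers subset of [classifier_names()] to run.
#' @return an object of class `model_report`: a data.frame with one row per
#'   classifier and columns `classifier`, `accuracy`, `auc`, `tpr`, `tnr`,
#'   with the split, subset and seed attached as attributes.
#' @export
benchmark_classifiers <- function(table, feature_subset, split_seed = 1,
                                  split = NULL, tune = TRUE,
                                  ensemble_type = c("bagging", "boosting"),
                                  n_trees = 100,
                                  classifiers = classifier_names()) {
  ensemble_type <- match.arg(ensemble_type)
  if (length(feature_subset) == 0) stop("feature_subset must be non-empty")
  xy <- .table_xy(table, feature_subset)
  y <- xy$y
  if (is.null(split)) {
    for (attempt in 0:20) {
      split <- stratified_split(y, 0.75, split_seed + attempt)
      if (length(unique(y[-split])) == 2 && length(unique(y[split])) == 2) break
      message("redrawing split: a class was absent from one side")
    }
  }
  tr <- split; te <- setdiff(seq_along(y), split)
  if (length(unique(y[te])) < 2)
    stop("test split lacks a class; provide a usable split")
  X <- .impute_median(xy$X, fit_rows = tr)
  sc <- .scale_fit(X, tr)
  Xs <- .scale_apply(X, sc)
  Xtr <- Xs[tr, , drop = FALSE]; Xte <- Xs[te, , drop = FALSE]
  ytr <- y[tr]; yte <- y[te]

  runners <- list(
    discriminant_analysis = .clf_lda,
    knn = .clf_knn,
    naive_bayes = .clf_nb,
    kernel_naive_bayes = .clf_knb,
    random_forest = .clf_rf,
    svm = function(...) .clf_svm(..., kernel = "linear"),
    kernel_svm = function(...) .clf_svm(..., kernel = "radial"),
    decision_tree = .clf_tree,
    ensemble = function(Xtr, ytr, Xte, tune, seed)
      .clf_ensemble(Xtr, ytr, Xte, tune, seed, type = ensemble_type,
                    n_trees = n_trees))
  runners <- runners[classifiers]

  rows <- lapply(names(runners), function(nm) {
    out <- runners[[nm]](Xtr, ytr, Xte, tune, split_seed)
    m <- evaluate_metrics(out$pred, out$score, yte)
    data.frame(classifier = nm, accuracy = m[["accuracy"]], auc = m[["auc"]],
               tpr = m[["tpr"]], tnr = m[["tnr"]], stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "split_seed") <- split_seed
  attr(rep, "train_idx") <- tr
  attr(rep, "feature_subset") <- feature_subset
  attr(rep, "split_description") <-
    sprintf("stratified 75/25 (train %d, test %d)", length(tr), length(te))
  class(rep) <- c("model_report", "data.frame")
  rep
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report>", attr(x, "split_description"), "\n")
  cat("features:", paste(attr(x, "feature_subset"), collapse = ", "), "\n")
  df <- as.data.frame(x)
  df[, -1] <- round(df[, -1], 3)
  print(df, row.names = FALSE)
  invisible(x)
}
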