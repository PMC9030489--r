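#' The classifier roster
#'
#' Eleven binary classifiers mirroring a standard point-and-click roster:
#' k-nearest neighbours with city-block and Euclidean metrics, Gaussian and
#' kernel-density naive Bayes, logistic regression, linear discriminant
#' analysis, linear and cubic-kernel support vector machines, a single
#' decision tree, bagged trees (100 trees) and an "optimized ensemble" that
#' picks its bagging/random-subspace configuration by inner cross-validation.
#'
#' @return Character vector of roster identifiers.
#' @export
classifier_roster <- function() {
  c("knn_cityblock", "knn_euclidean", "gaussian_nb", "kernel_nb",
    "logistic", "lda", "svm_linear", "svm_cubic", "tree",
    "bagged_trees", "optimized_ensemble")
}

drop_constant <- function(x) {
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) keep[1] <- TRUE
  keep
}

knn_predict <- function(train, cl, test, k, metric) {
  k <- min(k, nrow(train))
  apply(test, 1, function(row) {
    d <- if (metric == "cityblock")
      colSums(abs(t(train) - row))
    else
      sqrt(colSums((t(train) - row)^2))
    nn <- order(d)[seq_len(k)]
    votes <- table(cl[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else as.character(cl[nn[1]])
  })
}

kernel_nb_fit <- function(x, y) {
  classes <- levels(y)
  dens <- lapply(classes, function(cls) {
    apply(x[y == cls, , drop = FALSE], 2, function(col) {
      if (stats::sd(col) == 0)
        list(x = c(col[1] - 1e-6, col[1], col[1] + 1e-6),
             y = c(0, 1e6, 0))
      else {
        d <- stats::density(col, n = 512)
        list(x = d$x, y = d$y)
      }
    })
  })
  names(dens) <- classes
  priors <- table(y) / length(y)
  list(dens = dens, priors = priors, classes = classes)
}

kernel_nb_predict <- function(model, x) {
  eps <- 1e-12
  ll <- sapply(model$classes, function(cls) {
    d <- model$dens[[cls]]
    lp <- log(as.numeric(model$priors[cls]))
    for (j in seq_len(ncol(x))) {
      f <- stats::approx(d[[j]]$x, d[[j]]$y, xout = x[, j],
                         yleft = 0, yright = 0)$y
      lp <- lp + log(f + eps)
    }
    lp
  })
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  model$classes[max.col(ll)]
}

rf_inner_cv <- function(x, y, grid, k = 5, seed = 1) {
  folds <- stratified_folds(y, k, seed)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(k), function(i) {
      tr <- folds != i
      fit <- randomForest::randomForest(
        x[tr, , drop = FALSE], y[tr], ntree = grid$ntree[g],
        mtry = min(grid$mtry[g], ncol(x)), nodesize = grid$nodesize[g])
      mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(acc), ]
}

#' Fit one roster classifier
#'
#' @param id Roster identifier (see [classifier_roster()]).
#' @param x Numeric feature matrix (rows = trials), typically standardized.
#' @param y Factor of class labels (two levels).
#' @param seed Seed for the stochastic learners (forests, inner CV).
#' @return A fitted model object (list with class `swaylab_classifier`).
#' @export
fit_classifier <- function(id, x, y, seed = 1) {
  id <- match.arg(id, classifier_roster())
  keep <- drop_constant(x)
  xk <- x[, keep, drop = FALSE]
  with_local_seed(seed, fit_classifier_impl(id, xk, y, seed, keep))
}

fit_classifier_impl <- function(id, xk, y, seed, keep) {
  fit <- switch(id,
    knn_cityblock = ,
    knn_euclidean = list(train = xk, cl = y, k = 5,
                         metric = sub("knn_", "", id)),
    gaussian_nb = e1071::naiveBayes(xk, y),
    kernel_nb = kernel_nb_fit(xk, y),
    logistic = {
      df <- data.frame(xk, .y = y)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    # collinear standardized features are routine here; lda handles them
    lda = suppressWarnings(MASS::lda(xk, grouping = y)),
    svm_linear = e1071::svm(xk, y, kernel = "linear", scale = FALSE),
    svm_cubic = e1071::svm(xk, y, kernel = "polynomial", degree = 3,
                           scale = FALSE),
    tree = {
      df <- data.frame(xk, .y = y)
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    bagged_trees = randomForest::randomForest(xk, y, ntree = 100,
                                              mtry = ncol(xk)),
    optimized_ensemble = {
      grid <- expand.grid(
        mtry = unique(c(max(1, floor(sqrt(ncol(xk)))), ncol(xk))),
        nodesize = c(1, 5), ntree = 100)
      best <- rf_inner_cv(xk, y, grid, seed = seed)
      randomForest::randomForest(xk, y, ntree = best$ntree,
                                 mtry = best$mtry, nodesize = best$nodesize)
    })
  structure(list(id = id, fit = fit, keep = keep, levels = levels(y)),
            class = "swaylab_classifier")
}

#' Predict with a fitted roster classifier
#'
#' @param object A `swaylab_classifier` from [fit_classifier()].
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.swaylab_classifier <- function(object, newdata, ...) {
  xk <- newdata[, object$keep, drop = FALSE]
  id <- object$id
  out <- switch(id,
    knn_cityblock = ,
    knn_euclidean = knn_predict(object$fit$train, object$fit$cl, xk,
                                object$fit$k, object$fit$metric),
    gaussian_nb = as.character(predict(object$fit, xk)),
    kernel_nb = kernel_nb_predict(object$fit, xk),
    logistic = {
      pr <- suppressWarnings(
        stats::predict(object$fit, newdata = data.frame(xk),
                       type = "response"))
      object$levels[1 + (pr > 0.5)]
    },
    lda = as.character(predict(object$fit, xk)$class),
    svm_linear = ,
    svm_cubic = as.character(predict(object$fit, xk)),
    tree = as.character(predict(object$fit, newdata = data.frame(xk),
                                type = "class")),
    bagged_trees = ,
    optimized_ensemble = as.character(predict(object$fit, xk)))
  factor(out, levels = object$levels)
}

#' Classification accuracy
#'
#' `(TP + TN) / (P + N) * 100`, in percent.
#'
#' @param tp,tn True positive and true negative counts.
#' @param p,n Positive and negative totals.
#' @return Accuracy in percent.
#' @examples
#' accuracy_eq1(40, 45, 50, 50) # 85
#' @export
accuracy_eq1 <- function(tp, tn, p, n) (tp + tn) / (p + n) * 100

# Grouped fold assignment: whole groups (e.g. subjects) are dealt to
# folds, so no group straddles a train/test split.
grouped_folds <- function(groups, k, seed) {
  with_local_seed(seed, {
    g <- unique(groups)
    if (length(g) < k) stop("fewer groups than folds")
    assign_ <- rep_len(seq_len(k), length(g))[sample(length(g))]
    assign_[match(groups, g)]
  })
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin, so fold class proportions match the dataset's.
stratified_folds <- function(y, k, seed) {
  with_local_seed(seed, {
    folds <- integer(length(y))
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Splits trials into `k` class-stratified folds (seeded), trains on k-1
#' folds, evaluates accuracy on the held-out fold, and averages.
#'
#' @param features Numeric matrix (rows = trials), typically standardized.
#' @param labels Factor with both classes present.
#' @param classifier Roster identifier.
#' @param k Number of folds (default 5).
#' @param seed Seed controlling the fold assignment and learners.
#' @param groups Optional grouping vector (e.g. subject ids); when given,
#'   whole groups are assigned to folds instead of class-stratified
#'   trials, so no group appears in both a training and a test fold.
#' @return List with `fold_accuracy` (length `k`, percent) and
#'   `mean_accuracy`.
#' @export
cross_validate <- function(features, labels, classifier, k = 5, seed = 1,
                           groups = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("labels contain a single class; cannot cross-validate")
  if (nrow(features) < k) stop("fewer trials than folds")
  folds <- if (is.null(groups)) stratified_folds(labels, k, seed)
           else grouped_folds(groups, k, seed)
  accs <- vapply(seq_len(k), function(i) {
    tr <- folds != i
    model <- fit_classifier(classifier, features[tr, , drop = FALSE],
                            labels[tr], seed = seed + i)
    pred <- predict(model, features[!tr, , drop = FALSE])
    truth <- labels[!tr]
    pos <- levels(labels)[2]
    tp <- sum(pred == pos & truth == pos)
    tn <- sum(pred != pos & truth != pos)
    accuracy_eq1(tp, tn, sum(truth == pos), sum(truth != pos))
  }, numeric(1))
  list(fold_accuracy = accs, mean_accuracy = mean(accs))
}

#' Run the sensor-configuration x feature-set x classifier grid
#'
#' Extracts features, standardizes, labels trials by the chosen criterion
#' and cross-validates every roster classifier for every requested
#' combination.
#'
#' @param dataset A `study_dataset` with signals.
#' @param scs Sensor-configuration names (default `c("SC1","SC2","SC3")`).
#' @param fss Feature-set names (default `c("FS1","FS2","FS3")`).
#' @param classifiers Roster identifiers (default: the full roster).
#' @param criterion Labeling criterion, `"pps"` or `"copv_ap"`.
#' @param k Folds (default 5).
#' @param seed Seed for fold assignment and learners.
#' @param fold_safe Standardize within training folds instead of globally
#'   (default `FALSE`, matching the extract-then-standardize order; the
#'   default leaks fold statistics and is kept for fidelity).
#' @param group_by_subject Assign whole subjects to folds instead of
#'   stratifying trials by class (default `FALSE`: trials are treated
#'   i.i.d.).
#' @return A `classification_report`: data frame (`sc`, `fs`, `classifier`,
#'   `accuracy`, fold accuracies as a list column) with attribute
#'   `criterion`.
#' @export
run_grid <- function(dataset, scs = c("SC1", "SC2", "SC3"),
                     fss = c("FS1", "FS2", "FS3"),
                     classifiers = classifier_roster(),
                     criterion = c("pps", "copv_ap"), k = 5, seed = 1,
                     fold_safe = FALSE, group_by_subject = FALSE) {
  criterion <- match.arg(criterion)
  labels <- label_trials(dataset, criterion)
  groups <- if (group_by_subject)
    vapply(dataset$trials, function(tr) tr$subject_id, numeric(1))
  else NULL
  rows <- list()
  for (sc in scs) {
    for (fs in fss) {
      feats <- extract_features(dataset, sensors = sc, feature_set = fs)
      if (!fold_safe) feats <- zscore_features(feats)
      for (cl in classifiers) {
        cv <- if (fold_safe)
          cross_validate_foldsafe(feats, labels, cl, k, seed)
        else
          cross_validate(feats, labels, cl, k, seed, groups = groups)
        rows[[length(rows) + 1L]] <- data.frame(
          sc = sc, fs = fs, classifier = cl,
          accuracy = cv$mean_accuracy)
        attr(rows[[length(rows)]], "folds") <- cv$fold_accuracy
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, criterion = criterion, class = c("classification_report",
                                                  "data.frame"))
}

cross_validate_foldsafe <- function(features, labels, classifier, k, seed) {
  labels <- factor(labels)
  folds <- stratified_folds(labels, k, seed)
  accs <- vapply(seq_len(k), function(i) {
    tr <- folds != i
    mu <- colMeans(features[tr, , drop = FALSE])
    sdp <- sqrt(colMeans(sweep(features[tr, , drop = FALSE], 2, mu)^2))
    sdp[sdp == 0] <- 1
    std <- function(m) sweep(sweep(m, 2, mu), 2, sdp, "/")
    model <- fit_classifier(classifier, std(features[tr, , drop = FALSE]),
                            labels[tr], seed = seed + i)
    pred <- predict(model, std(features[!tr, , drop = FALSE]))
    mean(pred == labels[!tr]) * 100
  }, numeric(1))
  list(fold_accuracy = accs, mean_accuracy = mean(accs))
}

#' Format a classification report as an accuracy grid
#'
#' @param report Output of [run_grid()].
#' @param digits Decimals for the printed accuracies (default 1).
#' @return Data frame, rows = classifiers plus `Maximum` and `Average`
#'   rows, columns = `SC.FS` blocks, accuracies in percent.
#' @export
report_grid <- function(report, digits = 1) {
  blocks <- unique(paste(report$sc, report$fs, sep = "."))
  cls <- unique(report$classifier)
  grid <- sapply(blocks, function(b) {
    sel <- paste(report$sc, report$fs, sep = ".") == b
    report$accuracy[sel][match(cls, report$classifier[sel])]
  })
  if (is.null(dim(grid))) grid <- matrix(grid, nrow = 1)
  out <- rbind(round(grid, digits),
               Maximum = round(apply(grid, 2, max), digits),
               Average = round(colMeans(grid), digits))
  data.frame(classifier = c(cls, "Maximum", "Average"), out,
             check.names = FALSE, row.names = NULL)
}
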