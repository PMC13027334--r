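#' Gradient-boosted classifier configuration
#'
#' Hyperparameters of the boosted-tree disease classifier: shallow-ish
#' trees (depth 6), a conservative learning rate (0.01), row subsampling
#' of 0.5 per round, and 10 boosting rounds.
#'
#' @param max_depth maximum tree depth.
#' @param learning_rate shrinkage per round (eta).
#' @param subsample training sample ratio per round, in (0, 1].
#' @param n_rounds boosting iterations.
#' @param seed integer seed.
#' @return object of class `boost_config`.
#' @export
boost_config <- function(max_depth = 6, learning_rate = 0.01,
                         subsample = 0.5, n_rounds = 10, seed = 1) {
  stopifnot(max_depth >= 1, learning_rate > 0,
            subsample > 0, subsample <= 1, n_rounds >= 1)
  structure(list(max_depth = max_depth, learning_rate = learning_rate,
                 subsample = subsample, n_rounds = n_rounds, seed = seed),
            class = "boost_config")
}

#' Donor-level train/test split
#'
#' Assigns each donor's entire set of cells to either the training or
#' the test side (donors are indivisible units), targeting a given
#' train-cell fraction.  This prevents a classifier from exploiting
#' donor identity (batch or genetic background) instead of disease
#' signal.  When `require_both_classes` is set, splits leaving a side
#' without both diagnosis classes among its donors are resampled up to
#' `max_retry` times before erroring.
#'
#' @param cells data frame with `cell_id` and `donor` columns (and
#'   `diagnosis` when class coverage is required).
#' @param ratio target train-cell fraction (default 0.7).
#' @param seed integer seed.
#' @param require_both_classes require both classes on both sides.
#' @param max_retry resampling cap (default 100).
#' @return list with `train` and `test` cell-id vectors (disjoint) and
#'   `train_donors` / `test_donors`.
#' @export
donor_split <- function(cells, ratio = 0.7, seed = 1,
                        require_both_classes = TRUE, max_retry = 100) {
  stopifnot(all(c("cell_id", "donor") %in% names(cells)))
  donors <- unique(cells$donor)
  if (length(donors) < 2) stop("donor_split: need >= 2 donors")
  n_cells <- table(cells$donor)[donors]
  total <- sum(n_cells)
  one_split <- function(s) {
    set.seed(s)
    ord <- sample(donors)
    csum <- cumsum(as.numeric(n_cells[ord]))
    # donors join train while it stays below the target; at least one
    # donor on each side
    n_train <- max(1, min(length(donors) - 1, sum(csum <= ratio * total)))
    if (n_train == 0) n_train <- 1
    list(train = ord[seq_len(n_train)], test = ord[-seq_len(n_train)])
  }
  covered <- function(sp) {
    if (!require_both_classes) return(TRUE)
    dx <- cells$diagnosis[match(sp$train, cells$donor)]
    dx2 <- cells$diagnosis[match(sp$test, cells$donor)]
    length(unique(dx)) == 2 && length(unique(dx2)) == 2
  }
  sp <- NULL
  for (try in 0:max_retry) {
    cand <- one_split((seed + 104729L * try) %% .Machine$integer.max)
    if (covered(cand)) { sp <- cand; break }
  }
  if (is.null(sp))
    stop("donor_split: could not cover both classes on both sides after ",
         max_retry, " retries")
  list(train = cells$cell_id[cells$donor %in% sp$train],
       test = cells$cell_id[cells$donor %in% sp$test],
       train_donors = sp$train, test_donors = sp$test)
}

#' Train a gradient-boosted disease classifier on module features
#'
#' Fits an XGBoost binary classifier on training cells (features =
#' module core genes from the RUD or expression matrix) and evaluates
#' accuracy on held-out cells.  Train and test should come from a
#' donor-level split; nothing from the test cells enters training.
#'
#' @param features cells x genes numeric matrix (training cells).
#' @param labels two-level diagnosis per training cell.
#' @param cfg a [boost_config()].
#' @param test_features,test_labels held-out cells (optional; accuracy
#'   is NA without them).
#' @param positive level encoded as class 1.
#' @return list of class `boost_model`: model, accuracy,
#'   balanced_accuracy, predictions, positive level.
#' @export
train_boosted <- function(features, labels, cfg = boost_config(),
                          test_features = NULL, test_labels = NULL,
                          positive = NULL) {
  stopifnot(nrow(features) == length(labels))
  enc <- encode_labels(labels, positive)
  y <- as.numeric(enc$y > 0)
  if (length(unique(y)) < 2)
    stop("train_boosted: training labels are single-class")
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  dtrain <- xgboost::xgb.DMatrix(features, label = y)
  params <- list(max_depth = cfg$max_depth, eta = cfg$learning_rate,
                 subsample = cfg$subsample, objective = "binary:logistic",
                 nthread = 1, seed = cfg$seed)
  model <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = cfg$n_rounds, verbose = 0)
  acc <- bal <- NA_real_
  pred <- NULL
  if (!is.null(test_features)) {
    test_features <- as.matrix(test_features)
    storage.mode(test_features) <- "double"
    # test labels may be single-class (e.g. a small donor-held-out set)
    yt <- as.numeric(test_labels == enc$positive)
    pr <- predict(model, xgboost::xgb.DMatrix(test_features))
    # with a conservative learning rate and few rounds the ensemble's
    # probabilities stay near the training base rate, so classify
    # against the training prevalence rather than an absolute 0.5
    pred <- as.numeric(pr > mean(y))
    acc <- mean(pred == yt)
    bal <- mean(c(mean(pred[yt == 1] == 1), mean(pred[yt == 0] == 0)))
  }
  structure(list(model = model, accuracy = acc, balanced_accuracy = bal,
                 predictions = pred, positive = enc$positive, cfg = cfg),
            class = "boost_model")
}

## standardize columns with train statistics only (leakage guard)
scale_train <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(apply = function(M) sweep(sweep(M, 2, mu), 2, sdv, "/"),
       mu = mu, sd = sdv)
}

## coupled two-view least-squares large-margin fit: squared-error loss to
## the +/-1 labels per view, ridge penalty, and an agreement penalty
## gamma * ||f_a - f_b||^2 on the decision values; solved by alternating
## closed-form ridge updates (convex, monotone).
fit_two_view <- function(Xa, Xb, y, lambda = 1, gamma = 1, iters = 10) {
  add1 <- function(X) cbind(`(intercept)` = 1, X)
  Xa <- add1(Xa); Xb <- add1(Xb)
  ridge_solve <- function(X, target, w_mult) {
    p <- ncol(X)
    pen <- diag(lambda, p); pen[1, 1] <- 1e-8   # free intercept
    solve(crossprod(X) * w_mult + pen, crossprod(X, target))
  }
  wa <- ridge_solve(Xa, y, 1)
  wb <- ridge_solve(Xb, y, 1)
  for (i in seq_len(iters)) {
    fb <- drop(Xb %*% wb)
    wa <- ridge_solve(Xa, (y + gamma * fb) / (1 + gamma), 1 + gamma)
    fa <- drop(Xa %*% wa)
    wb <- ridge_solve(Xb, (y + gamma * fa) / (1 + gamma), 1 + gamma)
  }
  list(wa = wa, wb = wb,
       decision = function(Ma, Mb)
         list(fa = drop(add1(Ma) %*% wa), fb = drop(add1(Mb) %*% wb)))
}

#' Two-view fusion classifier with per-view contribution weights
#'
#' Couples two feature views of the same cells (APA usage and gene
#' expression) into one decision rule: per view, a large-margin linear
#' classifier (least-squares loss to the +/-1 labels with a ridge
#' penalty) is trained jointly with an agreement penalty that pulls the
#' two views' decision values together, in the style of two-view SVM
#' coupling.  The fused score is `sum_v beta_v f_v(x)` where the
#' contribution weight `beta_v` of each view is obtained by
#' softmax-normalizing the views' accuracies on an inner validation
#' split of the training cells; `beta_v` lies in [0, 1] and sums to 1
#' over views, quantifying each modality's contribution.  This is a
#' documented surrogate for the published two-view formulation, not a
#' reimplementation of it.
#'
#' @param view_a,view_b cells x features matrices over the same cells
#'   (rows aligned; rownames checked when present).
#' @param labels two-level diagnosis per training cell.
#' @param test_a,test_b held-out cells for the two views (optional).
#' @param test_labels held-out labels.
#' @param gamma agreement-penalty weight (default 1).
#' @param lambda ridge penalty (default 1).
#' @param beta_scale softmax temperature on validation accuracy
#'   (default 10).
#' @param val_fraction inner validation fraction for estimating beta
#'   (default 0.2).
#' @param seed integer seed (inner split).
#' @param positive level encoded +1.
#' @return list of class `fusion_model`: beta (named weights), accuracy,
#'   balanced_accuracy, view_accuracy (per-view test accuracy),
#'   val_accuracy (per-view inner-validation accuracy), predictions.
#' @export
train_fusion <- function(view_a, view_b, labels, test_a = NULL,
                         test_b = NULL, test_labels = NULL, gamma = 1,
                         lambda = 1, beta_scale = 10, val_fraction = 0.2,
                         seed = 1, positive = NULL) {
  stopifnot(nrow(view_a) == nrow(view_b),
            nrow(view_a) == length(labels))
  if (!is.null(rownames(view_a)) && !is.null(rownames(view_b)) &&
      !identical(rownames(view_a), rownames(view_b)))
    stop("train_fusion: view cell sets are not aligned")
  enc <- encode_labels(labels, positive)
  y <- enc$y
  if (length(unique(y)) < 2)
    stop("train_fusion: training labels are single-class")

  ## inner split for beta estimation
  set.seed(seed)
  n <- length(y)
  val <- sample(n, max(2, floor(val_fraction * n)))
  tr <- setdiff(seq_len(n), val)
  sa <- scale_train(as.matrix(view_a)[tr, , drop = FALSE])
  sb <- scale_train(as.matrix(view_b)[tr, , drop = FALSE])
  inner <- fit_two_view(sa$apply(as.matrix(view_a)[tr, , drop = FALSE]),
                        sb$apply(as.matrix(view_b)[tr, , drop = FALSE]),
                        y[tr], lambda, gamma)
  dv <- inner$decision(sa$apply(as.matrix(view_a)[val, , drop = FALSE]),
                       sb$apply(as.matrix(view_b)[val, , drop = FALSE]))
  val_acc <- c(a = mean(sign(dv$fa) == y[val]),
               b = mean(sign(dv$fb) == y[val]))
  e <- exp(beta_scale * (val_acc - max(val_acc)))
  beta <- e / sum(e)

  ## final fit on all training cells
  sa <- scale_train(as.matrix(view_a))
  sb <- scale_train(as.matrix(view_b))
  fit <- fit_two_view(sa$apply(as.matrix(view_a)),
                      sb$apply(as.matrix(view_b)), y, lambda, gamma)

  acc <- bal <- NA_real_
  view_acc <- c(a = NA_real_, b = NA_real_)
  pred <- NULL
  if (!is.null(test_a)) {
    yt <- ifelse(test_labels == enc$positive, 1, -1)
    dv <- fit$decision(sa$apply(as.matrix(test_a)),
                       sb$apply(as.matrix(test_b)))
    fused <- beta["a"] * dv$fa + beta["b"] * dv$fb
    pred <- ifelse(fused >= 0, 1, -1)
    acc <- mean(pred == yt)
    bal <- mean(c(mean(pred[yt == 1] == 1), mean(pred[yt == -1] == -1)))
    view_acc <- c(a = mean(sign(dv$fa) == yt), b = mean(sign(dv$fb) == yt))
  }
  structure(list(beta = beta, accuracy = acc, balanced_accuracy = bal,
                 view_accuracy = view_acc, val_accuracy = val_acc,
                 predictions = pred, positive = enc$positive,
                 gamma = gamma, lambda = lambda),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("two-view fusion model: beta = (%.3f, %.3f), accuracy = %s\n",
              x$beta["a"], x$beta["b"],
              ifelse(is.na(x$accuracy), "NA",
                     sprintf("%.3f", x$accuracy))))
  invisible(x)
}
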