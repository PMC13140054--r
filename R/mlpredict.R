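#' Named feature sets of the prediction protocol
#'
#' The five trait subsets evaluated against bending strength: (i) all 32
#' traits; (ii) the five stem-size/shape traits; (iii) the 21 vascular-bundle
#' traits (five whole-section basic traits, four periphery-zone and four
#' inner-zone traits, eight mechanical descriptors); (iv) the six zone traits;
#' (v) the top-five key traits `VB_A, PZ_VB_A, PZ_T, PZ_A, MOA`.
#'
#' @return Named list of character vectors (`all`, `stem`, `vb`, `zone`,
#'   `top5`), each a subset of [trait_names()].
#' @export
feature_sets <- function() {
  all32 <- trait_names()
  list(
    all = all32,
    stem = c("SZ_A", "SZ_P", "SZ_LA", "SZ_SA", "SZ_LWR"),
    vb = c("VB_N", "VB_A", "VB_Aave", "VB_D", "VB_AreaRatio",
           "PZ_VB_N", "PZ_VB_A", "PZ_VB_D", "PZ_VB_AreaRatio",
           "IZ_VB_N", "IZ_VB_A", "IZ_VB_D", "IZ_VB_AreaRatio",
           "MOA", "PMOI", "MOIAL", "MOIAS",
           "aveMOA", "avePMOI", "aveMOIAL", "aveMOIAS"),
    zone = c("EZ_A", "EZ_T", "PZ_A", "PZ_T", "IZ_A", "IZ_T"),
    top5 = c("VB_A", "PZ_VB_A", "PZ_T", "PZ_A", "MOA"))
}

#' Adjusted coefficient of determination
#'
#' Ezekiel's correction: `1 - (1 - R2) * (n - 1) / (n - p - 1)`.
#'
#' @param r2 coefficient of determination.
#' @param n number of samples.
#' @param p number of predictors.
#' @return Adjusted R-squared.
#' @export
#' @examples
#' adjusted_r2(0.5, 101, 5)  # 0.4736842...
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted R2 requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# ---- model registry ---------------------------------------------------------

# Each family is a list(fit = function(X, y, seed) model,
#                       predict = function(model, X) numeric).
# X is a numeric matrix. Stochastic learners are seeded per fit.
model_registry <- function() {
  std_fit <- function(X) {
    mu <- colMeans(X); sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
    list(mu = mu, sd = sdv)
  }
  std_apply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")
  list(
    lr = list(
      fit = function(X, y, seed) {
        d <- data.frame(y = y, X)
        lm(y ~ ., data = d)
      },
      predict = function(m, X) unname(predict(m, data.frame(X)))),
    ridge = list(
      fit = function(X, y, seed) {
        glmnet::glmnet(X, y, alpha = 0, lambda = 0.01, standardize = TRUE)
      },
      predict = function(m, X) as.numeric(predict(m, X))),
    rf = list(
      fit = function(X, y, seed) {
        ranger::ranger(x = X, y = y, num.trees = 100, max.depth = 10,
                       seed = seed, num.threads = 1)
      },
      predict = function(m, X) predict(m, data.frame(X), num.threads = 1)$predictions),
    adaboost = list(
      fit = function(X, y, seed) adaboost_r2_fit(X, y, seed = seed),
      predict = function(m, X) adaboost_r2_predict(m, X)),
    svr = list(
      fit = function(X, y, seed) {
        e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                   cost = 1, scale = TRUE)
      },
      predict = function(m, X) as.numeric(predict(m, X))),
    nnet = list(
      fit = function(X, y, seed) {
        st <- std_fit(X)
        ys <- (y - mean(y)) / sd(y)
        m <- with_seed(seed,
          nnet::nnet(std_apply(X, st), ys, size = 5, decay = 0.1,
                     maxit = 1000, linout = TRUE, trace = FALSE))
        list(net = m, st = st, y_mu = mean(y), y_sd = sd(y))
      },
      predict = function(m, X) {
        as.numeric(predict(m$net, std_apply(X, m$st))) * m$y_sd + m$y_mu
      }))
}

#' @rdname evaluate_models
#' @export
model_families <- function() names(model_registry())

# AdaBoost.R2 (Drucker-style boosting for regression) over rpart trees.
adaboost_r2_fit <- function(X, y, n_estimators = 50, max_depth = 4, seed = 1) {
  n <- length(y)
  w <- rep(1 / n, n)
  learners <- list()
  betas <- numeric()
  d <- data.frame(y = y, X)
  with_seed(seed, {
    for (t in seq_len(n_estimators)) {
      fit <- rpart::rpart(y ~ ., data = d, weights = w * n,
                          control = rpart::rpart.control(
                            maxdepth = max_depth, cp = 0.001, xval = 0))
      pred <- predict(fit, d)
      err <- abs(pred - y)
      D <- max(err)
      if (D <= 0) { learners[[t]] <- fit; betas[t] <- 1e-10; break }
      loss <- err / D
      ebar <- sum(w * loss)
      if (ebar >= 0.5) break
      beta <- ebar / (1 - ebar)
      learners[[t]] <- fit
      betas[t] <- beta
      w <- w * beta^(1 - loss)
      w <- w / sum(w)
    }
  })
  if (!length(learners)) {
    learners <- list(rpart::rpart(y ~ ., data = d,
                                  control = rpart::rpart.control(
                                    maxdepth = max_depth, xval = 0)))
    betas <- 0.5
  }
  list(learners = learners, betas = betas)
}

adaboost_r2_predict <- function(model, X) {
  d <- data.frame(X)
  P <- vapply(model$learners, function(f) predict(f, d), numeric(nrow(d)))
  P <- matrix(P, nrow = nrow(d))
  wts <- log(1 / pmax(model$betas, 1e-10))
  # weighted median across learners
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(wts[o])
    p[o][which(cw >= sum(wts) / 2)[1]]
  })
}

# ---- cross-validated evaluation --------------------------------------------

#' Cross-validated evaluation of regression models on trait features
#'
#' Splits the samples into `cv` folds (deterministic under `seed`), trains
#' each requested model family on the out-of-fold data and scores only
#' out-of-fold predictions. Reported metrics: RMSE and adjusted R-squared per
#' fold and pooled over all out-of-fold predictions, plus the out-of-fold
#' Pearson correlation.
#'
#' @param features data frame or matrix of predictors (numeric columns).
#' @param target numeric response (e.g. `BMMax` in N m).
#' @param models character vector of model families; see [model_families()].
#'   Default: the five classic families (AdaBoost, linear regression, random
#'   forest with 100 trees of depth 10, ridge, SVR); `"nnet"` adds a small
#'   feed-forward network.
#' @param cv number of folds.
#' @param seed integer seed controlling fold assignment and stochastic
#'   learners.
#' @param folds optional pre-computed fold assignment (overrides `seed`'s
#'   fold draw; still seeds the learners).
#' @return Object of class `prediction_report`: list with `per_fold`
#'   (`model, fold, rmse, adj_r2`), `pooled` (`model, rmse, r2, adj_r2,
#'   pearson`), `predictions` (out-of-fold), `folds`, `seed`, `n`, `p`.
#' @export
evaluate_models <- function(features, target,
                            models = c("adaboost", "lr", "rf", "ridge", "svr"),
                            cv = 5, seed = 2021, folds = NULL) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.numeric(target)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y))
  if (n < 10) stop("need at least 10 samples")
  if (sd(y) == 0) stop("constant target")
  registry <- model_registry()
  stopifnot(all(models %in% names(registry)))
  if (is.null(folds)) folds <- with_seed(seed, sample(rep(seq_len(cv), length.out = n)))
  if (min(table(folds)) < 2) stop("fold with fewer than 2 samples")
  per_fold <- list()
  pooled <- list()
  preds <- matrix(NA_real_, n, length(models),
                  dimnames = list(NULL, models))
  for (m in models) {
    fam <- registry[[m]]
    for (f in sort(unique(folds))) {
      te <- folds == f
      fit <- fam$fit(X[!te, , drop = FALSE], y[!te],
                     seed = seed * 100 + f)
      ph <- fam$predict(fit, X[te, , drop = FALSE])
      preds[te, m] <- ph
      rmse_f <- sqrt(mean((ph - y[te])^2))
      r2_f <- 1 - sum((ph - y[te])^2) / sum((y[te] - mean(y[te]))^2)
      adj_f <- if (sum(te) > p + 1) adjusted_r2(r2_f, sum(te), p) else NA_real_
      per_fold[[length(per_fold) + 1]] <-
        data.frame(model = m, fold = f, rmse = rmse_f, adj_r2 = adj_f)
    }
    oof <- preds[, m]
    r2 <- 1 - sum((oof - y)^2) / sum((y - mean(y))^2)
    pooled[[length(pooled) + 1]] <-
      data.frame(model = m, rmse = sqrt(mean((oof - y)^2)), r2 = r2,
                 adj_r2 = adjusted_r2(r2, n, p),
                 pearson = suppressWarnings(cor(oof, y)))
  }
  structure(list(per_fold = do.call(rbind, per_fold),
                 pooled = do.call(rbind, pooled),
                 predictions = preds, folds = folds,
                 seed = seed, n = n, p = p),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("prediction_report: n = %d, p = %d, %d folds (seed %d)\n",
              x$n, x$p, length(unique(x$folds)), x$seed))
  print(x$pooled, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Recursive feature elimination under a base estimator
#'
#' Iteratively removes the feature with the lowest importance under the base
#' estimator (ridge: standardized coefficient magnitude; rf: permutation
#' importance from a 100-tree depth-10 random forest) until `k` features
#' remain. The full elimination order and the cross-validated RMSE of each
#' intermediate subset are reported.
#'
#' @inheritParams evaluate_models
#' @param k number of features to retain.
#' @param base `"ridge"` or `"rf"` importance.
#' @return List with `selected` (the `k` retained names), `ranking` (all
#'   features, best first: the retained set followed by the eliminated ones in
#'   reverse elimination order), `elimination_order`, and `cv_rmse`
#'   (`n_features, rmse`).
#' @export
rfe_rank <- function(features, target, k = 5, base = c("ridge", "rf"),
                     cv = 5, seed = 2021) {
  base <- match.arg(base)
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.numeric(target)
  if (sd(y) == 0) stop("constant target")
  if (k > ncol(X)) stop("k exceeds the number of features")
  folds <- with_seed(seed, sample(rep(seq_len(cv), length.out = nrow(X))))
  importance <- function(Xs) {
    if (base == "ridge") {
      st <- apply(Xs, 2, sd); st[st == 0] <- 1e-12
      Z <- sweep(sweep(Xs, 2, colMeans(Xs)), 2, st, "/")
      fit <- glmnet::glmnet(Z, y, alpha = 0, lambda = 0.01)
      abs(as.numeric(coef(fit))[-1])
    } else {
      fit <- ranger::ranger(x = Xs, y = y, num.trees = 100, max.depth = 10,
                            importance = "permutation", seed = seed,
                            num.threads = 1)
      fit$variable.importance
    }
  }
  cv_rmse_of <- function(Xs) {
    errs <- vapply(sort(unique(folds)), function(f) {
      te <- folds == f
      fit <- glmnet::glmnet(Xs[!te, , drop = FALSE], y[!te],
                            alpha = 0, lambda = 0.01)
      mean((as.numeric(predict(fit, Xs[te, , drop = FALSE])) - y[te])^2)
    }, 0)
    sqrt(mean(errs))
  }
  current <- colnames(X)
  eliminated <- character()
  scores <- data.frame(n_features = integer(), rmse = numeric())
  repeat {
    Xs <- X[, current, drop = FALSE]
    scores <- rbind(scores, data.frame(n_features = length(current),
                                       rmse = cv_rmse_of(Xs)))
    if (length(current) <= k) break
    imp <- importance(Xs)
    drop_ix <- which.min(imp)  # ties: first (deterministic column order)
    eliminated <- c(eliminated, current[drop_ix])
    current <- current[-drop_ix]
  }
  list(selected = current,
       ranking = c(current, rev(eliminated)),
       elimination_order = eliminated,
       cv_rmse = scores)
}

#' Rank feature sets by pooled out-of-fold performance
#'
#' Orders feature sets by pooled adjusted R-squared per model, with paired
#' fold-wise RMSE differences against the best set and a paired t-test
#' summary. All reports must share the same fold assignment.
#'
#' @param reports named list of `prediction_report`s (one per feature set)
#'   evaluated on identical folds.
#' @return Data frame `model, feature_set, rank, adj_r2, rmse,
#'   delta_rmse_vs_best, p_value`.
#' @export
compare_feature_sets <- function(reports) {
  stopifnot(length(reports) >= 2, !is.null(names(reports)))
  f0 <- reports[[1]]$folds
  for (r in reports) if (!identical(r$folds, f0)) stop("mismatched folds")
  models <- Reduce(intersect, lapply(reports, function(r) r$pooled$model))
  out <- list()
  for (m in models) {
    adj <- vapply(reports, function(r) r$pooled$adj_r2[r$pooled$model == m], 0)
    rmse <- vapply(reports, function(r) r$pooled$rmse[r$pooled$model == m], 0)
    ord <- order(-adj)
    best <- names(reports)[ord[1]]
    bf <- fold_rmse(reports[[best]], m)
    for (i in seq_along(ord)) {
      nm <- names(reports)[ord[i]]
      ff <- fold_rmse(reports[[nm]], m)
      pv <- if (nm == best || all(ff == bf)) NA_real_ else
        t.test(ff, bf, paired = TRUE)$p.value
      out[[length(out) + 1]] <- data.frame(
        model = m, feature_set = nm, rank = i,
        adj_r2 = adj[[nm]], rmse = rmse[[nm]],
        delta_rmse_vs_best = mean(ff - bf), p_value = pv)
    }
  }
  do.call(rbind, out)
}

fold_rmse <- function(report, model) {
  pf <- report$per_fold
  pf$rmse[pf$model == model][order(pf$fold[pf$model == model])]
}
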