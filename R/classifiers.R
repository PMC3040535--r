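#' Train a base binary classifier
#'
#' Both learners satisfy the same contract: deterministic training given
#' `(X, y, seed)`, a real-valued decision function where higher means more
#' positive-like, and serializable state. Columns are standardized to mean
#' 0 / sd 1 using training statistics that are stored in the model and
#' re-applied at prediction time.
#'
#' `"svm"` is an L2-regularized squared-hinge linear SVM
#' (objective `||w||^2 / 2 + C * sum(max(0, 1 - y f(x))^2)`) fitted by
#' BFGS from a zero start — convex, so the fit is deterministic.
#' `"boosting"` is adaptive boosting over depth-1 threshold learners
#' (decision stumps), 50 rounds by default, returning the real-valued
#' weighted vote.
#'
#' @param X Numeric feature matrix (rows = examples).
#' @param y Labels: logical, 0/1, or -1/+1 (positive class = larger value).
#' @param learner `"svm"` or `"boosting"`.
#' @param seed Integer seed (kept for contract symmetry; both built-in
#'   learners are deterministic and do not consume randomness).
#' @param cost Soft-margin cost C for the SVM.
#' @param n_rounds Boosting rounds.
#' @return Object of class `base_classifier`.
#' @export
train_base <- function(X, y, learner = c("svm", "boosting"), seed = 1L,
                       cost = 1.0, n_rounds = 50L) {
  learner <- match.arg(learner)
  X <- as.matrix(X)
  y <- as_pm1(y)
  if (length(unique(y)) < 2L) stop("single-class input: need both classes")
  stopifnot(nrow(X) == length(y))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl < 1e-12] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  fit <- switch(learner,
                svm = fit_linear_svm(Xs, y, cost),
                boosting = fit_adaboost(Xs, y, n_rounds))
  structure(list(learner = learner, fit = fit, center = ctr, scale = scl,
                 seed = as.integer(seed), n_features = ncol(X)),
            class = "base_classifier")
}

as_pm1 <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1, -1))
  y <- as.numeric(y)
  u <- sort(unique(y))
  if (identical(u, c(-1, 1)) || identical(u, 1) || identical(u, -1)) return(y)
  if (all(u %in% c(0, 1))) return(ifelse(y > 0, 1, -1))
  stop("labels must be logical, 0/1 or -1/+1")
}

fit_linear_svm <- function(X, y, cost) {
  n <- nrow(X); p <- ncol(X)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    m <- pmax(0, 1 - y * (drop(X %*% w) + b))
    0.5 * sum(w^2) + cost * sum(m^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    m <- pmax(0, 1 - y * (drop(X %*% w) + b))
    gw <- w - 2 * cost * drop(crossprod(X, y * m))
    gb <- -2 * cost * sum(y * m)
    c(gw, gb)
  }
  res <- optim(numeric(p + 1L), obj, grad, method = "BFGS",
               control = list(maxit = 500L, reltol = 1e-12))
  list(w = res$par[seq_len(p)], b = res$par[p + 1L], cost = cost)
}

# AdaBoost over decision stumps. Each stump is (feature j, threshold t,
# polarity s): predicts s * sign(x_j - t) with sign(0) treated as -1.
# Thresholds are midpoints between consecutive distinct sorted values;
# ties in weighted error are broken by (feature, threshold) order.
fit_adaboost <- function(X, y, n_rounds) {
  n <- nrow(X); p <- ncol(X)
  ord <- lapply(seq_len(p), function(j) order(X[, j], method = "radix"))
  w <- rep(1 / n, n)
  stumps <- vector("list", n_rounds)
  used <- 0L
  for (r in seq_len(n_rounds)) {
    best <- list(err = Inf)
    for (j in seq_len(p)) {
      o <- ord[[j]]
      xv <- X[o, j]; yv <- y[o]; wv <- w[o]
      # error of stump "predict +1 when x > t" with t before position i:
      # err(i) = w(pos among first i-1) + w(neg among i..n)
      wpos <- cumsum(wv * (yv > 0))
      wneg_total <- sum(wv * (yv < 0))
      wneg <- cumsum(wv * (yv < 0))
      # candidate cut after position i (i = 0..n): first i predicted -1
      err_up <- c(wneg_total,
                  wpos[seq_len(n)] + (wneg_total - wneg[seq_len(n)]))
      # only cuts between distinct values are realizable
      realizable <- c(TRUE, xv[seq_len(n - 1L)] != xv[-1L], TRUE)
      err_dn <- 1 - err_up  # opposite polarity
      for (pol in c(1, -1)) {
        e <- if (pol > 0) err_up else err_dn
        e[!realizable] <- Inf
        i <- which.min(e)
        if (e[i] < best$err - 1e-15) {
          t <- if (i == 1L) xv[1L] - 1 else if (i == n + 1L) xv[n] + 1
               else (xv[i - 1L] + xv[i]) / 2
          best <- list(err = e[i], feature = j, threshold = t,
                       polarity = pol)
        }
      }
    }
    err <- min(max(best$err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    h <- stump_predict(best, X)
    stumps[[r]] <- c(best[c("feature", "threshold", "polarity")],
                     list(alpha = alpha))
    used <- r
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
    if (best$err < 1e-10) break  # perfect stump: voting is decided
  }
  list(stumps = stumps[seq_len(used)])
}

stump_predict <- function(s, X) {
  v <- ifelse(X[, s$feature] > s$threshold, 1, -1)
  s$polarity * v
}

#' Decision values of a trained base classifier
#'
#' @param model A [train_base()] model.
#' @param X Feature matrix with the same columns as at training.
#' @return Numeric vector; higher means more positive-like.
#' @export
decision_values <- function(model, X) {
  UseMethod("decision_values")
}

#' @export
decision_values.base_classifier <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop("feature count mismatch: model expects ", model$n_features,
         ", got ", ncol(X))
  }
  Xs <- scale(X, center = model$center, scale = model$scale)
  if (model$learner == "svm") {
    drop(Xs %*% model$fit$w) + model$fit$b
  } else {
    out <- numeric(nrow(Xs))
    for (s in model$fit$stumps) {
      out <- out + s$alpha * stump_predict(s, Xs)
    }
    out
  }
}

#' Bagging configuration
#'
#' Bootstrap aggregating for highly unbalanced site data: each round draws
#' a small class-balanced subsample (all positives up to a cap, plus
#' `negative_ratio` times as many negatives), trains a base learner on it,
#' and the ensemble averages the rounds' decision values.
#'
#' @param n_rounds Number of bagging rounds (default 20).
#' @param positives_per_round Cap on positives sampled per round
#'   (default 2000; all positives are used when fewer exist).
#' @param negative_ratio Negatives sampled per positive (default 1.0).
#' @param base_learner `"svm"` or `"boosting"`.
#' @param replace Sample within rounds with replacement (classical
#'   bootstrap) instead of without (default `FALSE`; rounds still differ
#'   through their seeds).
#' @param seed Integer master seed; round r uses a seed derived from
#'   `(seed, r)`.
#' @param cost,boost_rounds Passed to [train_base()].
#' @return Object of class `bagging_config`.
#' @export
bagging_config <- function(n_rounds = 20L, positives_per_round = 2000L,
                           negative_ratio = 1.0,
                           base_learner = c("svm", "boosting"),
                           replace = FALSE, seed = 1L, cost = 1.0,
                           boost_rounds = 50L) {
  base_learner <- match.arg(base_learner)
  stopifnot(n_rounds >= 1L, negative_ratio > 0, positives_per_round >= 1L)
  structure(list(n_rounds = as.integer(n_rounds),
                 positives_per_round = as.integer(positives_per_round),
                 negative_ratio = negative_ratio,
                 base_learner = base_learner, replace = isTRUE(replace),
                 seed = as.integer(seed), cost = cost,
                 boost_rounds = as.integer(boost_rounds)),
            class = "bagging_config")
}

round_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 1009 + r * 7919) %% 2147483647)
}

#' Train a bagging ensemble
#'
#' @param X Feature matrix.
#' @param y Labels (see [train_base()]).
#' @param config A [bagging_config()].
#' @return Object of class `bagging_ensemble` holding one trained base
#'   model per round plus the config and feature layout.
#' @export
train_bagging <- function(X, y, config = bagging_config()) {
  X <- as.matrix(X)
  y <- as_pm1(y)
  pos <- which(y > 0); neg <- which(y < 0)
  if (length(pos) < 1L) stop("no positive examples")
  n_pos <- min(config$positives_per_round, length(pos))
  n_neg <- as.integer(round(config$negative_ratio * n_pos))
  if (!config$replace && length(neg) < n_neg) {
    stop("insufficient negatives: need ", n_neg, ", have ", length(neg))
  }
  models <- vector("list", config$n_rounds)
  for (r in seq_len(config$n_rounds)) {
    idx <- with_seed(round_seed(config$seed, r), {
      c(sample(pos, n_pos, replace = config$replace),
        sample(neg, n_neg, replace = config$replace))
    })
    models[[r]] <- train_base(X[idx, , drop = FALSE], y[idx],
                              learner = config$base_learner,
                              seed = round_seed(config$seed, r),
                              cost = config$cost,
                              n_rounds = config$boost_rounds)
  }
  structure(list(base_models = models, config = config,
                 feature_layout = attr(X, "layout")),
            class = "bagging_ensemble")
}

#' Aggregated decision values of a bagging ensemble
#'
#' Per-example arithmetic mean of the rounds' base decision values.
#'
#' @param ensemble A [train_bagging()] ensemble.
#' @param X Feature matrix; when both carry a layout attribute they must
#'   match.
#' @return Numeric vector of aggregated decision values.
#' @export
predict_bagging <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "bagging_ensemble"))
  lay <- attr(X, "layout")
  if (!is.null(lay) && !is.null(ensemble$feature_layout) &&
      !layout_compatible(lay, ensemble$feature_layout)) {
    stop("feature layout mismatch between ensemble and query matrix")
  }
  Xm <- as.matrix(X)
  vals <- vapply(ensemble$base_models,
                 function(m) decision_values(m, Xm), numeric(nrow(Xm)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  rowMeans(vals)
}
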