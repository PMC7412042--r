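# Binary base classifiers behind the hierarchy: CART, SVM, KNN, NN, BET.
# No tree/SVM/NN package is available in the target environment, so these are
# self-contained implementations with a common fit/predict contract:
# fit(x, y, ...) -> model; model_predict(model, x) -> factor with y's levels.

## ---- CART: binary recursive partitioning with Gini impurity ----

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Best split of one numeric feature: returns cut, gain (n * impurity decrease).
best_split_feature <- function(v, yi, K, min_bucket) {
  n <- length(v)
  ord <- order(v)
  vs <- v[ord]; ys <- yi[ord]
  cum <- matrix(0, n, K)
  for (k in seq_len(K)) cum[, k] <- cumsum(ys == k)
  tot <- cum[n, ]
  g_parent <- gini_impurity(tot)
  cand <- which(vs[-n] < vs[-1])
  cand <- cand[cand >= min_bucket & (n - cand) >= min_bucket]
  if (length(cand) == 0) return(NULL)
  nl <- cand
  gl <- 1 - rowSums((cum[cand, , drop = FALSE] / nl)^2)
  cr <- matrix(tot, length(cand), K, byrow = TRUE) - cum[cand, , drop = FALSE]
  gr <- 1 - rowSums((cr / (n - nl))^2)
  gain <- n * g_parent - (nl * gl + (n - nl) * gr)
  j <- which.max(gain)
  if (gain[j] <= 1e-12) return(NULL)
  list(cut = (vs[cand[j]] + vs[cand[j] + 1]) / 2, gain = gain[j])
}

#' Fit a classification tree (CART, Gini splitting)
#'
#' @param x numeric feature matrix.
#' @param y factor response.
#' @param max_depth maximum tree depth.
#' @param min_split minimum node size to attempt a split.
#' @param min_bucket minimum child size.
#' @param mtry number of features sampled per split (all by default; used by
#'   the bagged ensemble).
#' @return Object of class `cart_model` with a per-feature Gini-importance
#'   vector in `$importance`.
#' @export
cart_fit <- function(x, y, max_depth = 6, min_split = 10, min_bucket = 5,
                     mtry = NULL) {
  x <- as.matrix(x); y <- as.factor(y)
  lev <- levels(y); K <- length(lev)
  yi <- as.integer(y)
  p <- ncol(x)
  importance <- stats::setNames(numeric(p), colnames(x) %||% paste0("x", seq_len(p)))
  nodes <- list()
  grow <- function(idx, depth) {
    counts <- tabulate(yi[idx], nbins = K)
    pred <- which.max(counts)
    node <- list(pred = pred, n = length(idx), leaf = TRUE)
    if (depth < max_depth && length(idx) >= min_split &&
        gini_impurity(counts) > 0) {
      feats <- seq_len(p)
      if (!is.null(mtry) && mtry < p) feats <- sample(feats, mtry)
      best <- NULL
      for (f in feats) {
        s <- best_split_feature(x[idx, f], yi[idx], K, min_bucket)
        if (!is.null(s) && (is.null(best) || s$gain > best$gain)) {
          best <- s; best$feature <- f
        }
      }
      if (!is.null(best)) {
        importance[best$feature] <<- importance[best$feature] + best$gain
        go_left <- x[idx, best$feature] <= best$cut
        node$leaf <- FALSE
        node$feature <- best$feature
        node$cut <- best$cut
        node$left <- grow(idx[go_left], depth + 1)
        node$right <- grow(idx[!go_left], depth + 1)
      }
    }
    node
  }
  root <- grow(seq_along(yi), 0)
  structure(list(root = root, levels = lev, importance = importance),
            class = "cart_model")
}

#' @export
predict.cart_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  pred <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    node <- object$root
    while (!node$leaf)
      node <- if (x[i, node$feature] <= node$cut) node$left else node$right
    pred[i] <- node$pred
  }
  factor(object$levels[pred], levels = object$levels)
}

## ---- SVM: soft-margin kernel SVM via the dual QP (quadprog) ----

kernel_matrix <- function(a, b, kernel, gamma, degree = 3) {
  if (kernel == "linear") return(tcrossprod(a, b))
  if (kernel == "poly") return((tcrossprod(a, b) * gamma + 1)^degree)
  # rbf
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a soft-margin support vector machine
#'
#' The dual problem is solved exactly with `quadprog::solve.QP` (a small ridge
#' keeps the kernel matrix positive definite).  Features are z-scaled
#' internally.
#'
#' @param x numeric feature matrix.
#' @param y two-level factor.
#' @param C box constraint (default 10, chosen by cross-validation on the
#'   synthetic cohort; C = 1 underfits the high-dimensional octant features).
#' @param kernel `"rbf"` (default), `"linear"` or `"poly"`.
#' @param gamma kernel width (default `1/ncol(x)`).
#' @return Object of class `svm_model`.
#' @export
svm_fit <- function(x, y, C = 10, kernel = "rbf", gamma = NULL) {
  x <- as.matrix(x); y <- as.factor(y)
  lev <- levels(y)
  if (length(lev) != 2) stop("svm_fit is a binary classifier")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  yy <- ifelse(as.integer(y) == 1, -1, 1)
  n <- nrow(xs)
  if (is.null(gamma)) gamma <- 1 / ncol(xs)
  Km <- kernel_matrix(xs, xs, kernel, gamma)
  Dmat <- (yy %o% yy) * Km + diag(1e-8, n)
  Amat <- cbind(yy, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat, rep(1, n), Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- alpha > 1e-6
  f0 <- drop(Km %*% (alpha * yy))
  margin <- alpha > 1e-6 & alpha < C - 1e-6
  b <- if (any(margin)) mean(yy[margin] - f0[margin]) else mean(yy[sv] - f0[sv])
  structure(list(x = xs[sv, , drop = FALSE], coef = (alpha * yy)[sv], b = b,
                 kernel = kernel, gamma = gamma, center = ctr, scale = scl,
                 levels = lev),
            class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), object$center, object$scale)
  f <- drop(kernel_matrix(xs, object$x, object$kernel, object$gamma) %*%
              object$coef) + object$b
  factor(object$levels[ifelse(f >= 0, 2, 1)], levels = object$levels)
}

## ---- KNN ----

#' Fit a k-nearest-neighbour classifier (stores the training set)
#' @param x,y training data (y a factor).
#' @param k number of neighbours.
#' @return Object of class `knn_model`.
#' @export
knn_fit <- function(x, y, k = 5) {
  x <- as.matrix(x); y <- as.factor(y)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  structure(list(x = scale(x, ctr, scl), y = y, k = min(k, nrow(x)),
                 center = ctr, scale = scl, levels = levels(y)),
            class = "knn_model")
}

#' @export
predict.knn_model <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), object$center, object$scale)
  d2 <- outer(rowSums(xs^2), rowSums(object$x^2), `+`) -
    2 * tcrossprod(xs, object$x)
  pred <- apply(d2, 1, function(di) {
    nn <- order(di)[seq_len(object$k)]
    votes <- table(object$y[nn])
    names(votes)[which.max(votes)]     # ties: first (factor-level) order
  })
  factor(pred, levels = object$levels)
}

## ---- NN: one hidden layer, tanh units, logistic output, BFGS ----

#' Fit a single-hidden-layer neural network
#'
#' Cross-entropy loss with L2 weight decay, minimised by `optim(method =
#' "BFGS")` with analytic gradients; seeded random initialisation.
#'
#' @param x,y training data (y a two-level factor).
#' @param hidden hidden-layer width.
#' @param decay L2 penalty.
#' @param maxit BFGS iteration cap.
#' @param seed RNG seed for the initial weights.
#' @return Object of class `nn_model`.
#' @export
nn_fit <- function(x, y, hidden = 8, decay = 1e-3, maxit = 200, seed = 1) {
  x <- as.matrix(x); y <- as.factor(y)
  lev <- levels(y)
  if (length(lev) != 2) stop("nn_fit is a binary classifier")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  t01 <- as.integer(y) - 1L
  p <- ncol(xs); H <- hidden; n <- nrow(xs)
  n_w1 <- (p + 1) * H
  unpack <- function(w) list(W1 = matrix(w[seq_len(n_w1)], p + 1, H),
                             W2 = w[-seq_len(n_w1)])
  X1 <- cbind(1, xs)
  obj <- function(w) {
    par <- unpack(w)
    Hd <- tanh(X1 %*% par$W1)
    f <- drop(cbind(1, Hd) %*% par$W2)
    pr <- 1 / (1 + exp(-f))
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -sum(t01 * log(pr) + (1 - t01) * log(1 - pr)) / n + decay * sum(w^2)
  }
  grad <- function(w) {
    par <- unpack(w)
    Hd <- tanh(X1 %*% par$W1)
    H1 <- cbind(1, Hd)
    f <- drop(H1 %*% par$W2)
    pr <- 1 / (1 + exp(-f))
    e <- (pr - t01) / n
    gW2 <- drop(crossprod(H1, e))
    back <- (e %o% par$W2[-1]) * (1 - Hd^2)
    gW1 <- crossprod(X1, back)
    c(as.vector(gW1), gW2) + 2 * decay * w
  }
  w0 <- with_seed(seed, stats::rnorm(n_w1 + H + 1, 0, 0.5))
  fit <- stats::optim(w0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit))
  structure(list(w = fit$par, hidden = H, center = ctr, scale = scl,
                 levels = lev, n_w1 = n_w1, p = p),
            class = "nn_model")
}

#' @export
predict.nn_model <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), object$center, object$scale)
  W1 <- matrix(object$w[seq_len(object$n_w1)], object$p + 1, object$hidden)
  W2 <- object$w[-seq_len(object$n_w1)]
  Hd <- tanh(cbind(1, xs) %*% W1)
  f <- drop(cbind(1, Hd) %*% W2)
  factor(object$levels[ifelse(f >= 0, 2, 1)], levels = object$levels)
}

## ---- BET: bagged ensemble of CART trees ----

#' Fit a bagged ensemble of classification trees
#'
#' @param x,y training data.
#' @param n_trees ensemble size.
#' @param max_depth per-tree depth cap.
#' @param mtry features sampled per split (default `sqrt(p)`).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `bag_model`.
#' @export
bag_fit <- function(x, y, n_trees = 50, max_depth = 6, mtry = NULL, seed = 1) {
  x <- as.matrix(x); y <- as.factor(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(i) {
    idx <- sample.int(nrow(x), replace = TRUE)
    cart_fit(x[idx, , drop = FALSE], y[idx], max_depth = max_depth,
             mtry = mtry)
  }))
  structure(list(trees = trees, levels = levels(y)), class = "bag_model")
}

#' @export
predict.bag_model <- function(object, newdata, ...) {
  votes <- vapply(object$trees,
                  function(tr) as.integer(predict(tr, newdata)),
                  integer(nrow(as.matrix(newdata))))
  votes <- matrix(votes, nrow = nrow(as.matrix(newdata)))
  pred <- apply(votes, 1, function(v) which.max(tabulate(v, nbins = length(object$levels))))
  factor(object$levels[pred], levels = object$levels)
}

## ---- registry ----

#' Registry of the five supported base models
#'
#' Returns a factory with `fit(x, y, seed, ...)` and standard `predict`;
#' hyperparameters are passed through `...` with documented defaults
#' (CART depth 6; SVM: RBF, C = 10, gamma = 1/p; KNN k = 5; NN: 8 hidden
#' units, decay 1e-3; BET: 50 trees).
#'
#' @param name one of `"CART"`, `"SVM"`, `"KNN"`, `"NN"`, `"BET"`.
#' @return List with a `fit` function; `fit` returns a model whose `predict`
#'   method yields a factor with the training levels.
#' @export
base_model_registry <- function(name) {
  supported <- c("CART", "SVM", "KNN", "NN", "BET")
  if (!name %in% supported)
    stop("unknown base model '", name, "'; supported: ",
         paste(supported, collapse = ", "))
  # hyperparameters not applicable to a given model are dropped, so one `...`
  # can carry settings for several levels with different base models
  filtered <- function(f, seeded = FALSE) {
    function(x, y, seed = 1, ...) {
      args <- list(...)
      args <- args[names(args) %in% names(formals(f))]
      if (seeded) args$seed <- seed
      do.call(f, c(list(x, y), args))
    }
  }
  fit <- switch(name,
    CART = {
      g <- filtered(cart_fit)
      function(x, y, seed = 1, ...) with_seed(seed, g(x, y, seed, ...))
    },
    SVM  = filtered(svm_fit),
    KNN  = filtered(knn_fit),
    NN   = filtered(nn_fit, seeded = TRUE),
    BET  = filtered(bag_fit, seeded = TRUE))
  list(name = name, fit = fit)
}
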