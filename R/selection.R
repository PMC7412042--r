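# Feature weighting, selection and class balancing.

#' PCA contribution weights
#'
#' Features are z-standardised (their scales differ by orders of magnitude
#' across groups) and the correlation-matrix eigendecomposition retained up to
#' the smallest number of components explaining `variance_fraction` of the
#' total variance.  The contribution of feature k is
#' `w_k = sum_i beta_i * c_ki^2` over the retained components, with `beta_i`
#' the eigenvalue and `c_ki` the loading.  Constant columns get weight 0.
#'
#' @param features numeric matrix (rows = samples).
#' @param variance_fraction fraction of variance the retained components must
#'   reach (default 0.80).
#' @return Object of class `pca_weights`: `w` (named, >= 0), `beta`
#'   (eigenvalues), `loadings`, `n_components`, `variance_fraction`.
#' @export
pca_weights <- function(features, variance_fraction = 0.80) {
  x <- as.matrix(features)
  if (nrow(x) < 2) stop("need at least 2 samples")
  nm <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  w <- stats::setNames(numeric(ncol(x)), nm)
  xs <- scale(x[, keep, drop = FALSE])
  R <- stats::cor(xs)
  eg <- eigen(R, symmetric = TRUE)
  beta <- pmax(eg$values, 0)
  n <- which(cumsum(beta) / sum(beta) >= variance_fraction)[1]
  C <- eg$vectors[, seq_len(n), drop = FALSE]
  w[keep] <- drop(C^2 %*% beta[seq_len(n)])
  structure(list(w = w, beta = beta, loadings = eg$vectors,
                 n_components = n, variance_fraction = variance_fraction,
                 kept = keep),
            class = "pca_weights")
}

#' @export
print.pca_weights <- function(x, ...) {
  cat(sprintf("<pca_weights> %d features, %d components (>= %.0f%% variance)\n",
              length(x$w), x$n_components, 100 * x$variance_fraction))
  invisible(x)
}

#' Select features by cumulative contribution weight
#'
#' Features are sorted by `w_k` descending (ties broken by name for
#' determinism) and the smallest prefix whose weight sum reaches
#' `mass_fraction` of the total is returned.
#'
#' @param weights a [pca_weights()] result.
#' @param mass_fraction cumulative-weight cutoff (default 0.80).
#' @return Character vector of selected feature names, in decreasing-weight
#'   order.
#' @export
select_by_weight <- function(weights, mass_fraction = 0.80) {
  w <- weights$w
  ord <- order(-w, names(w))
  cum <- cumsum(w[ord])
  k <- which(cum >= mass_fraction * sum(w))[1]
  names(w)[ord][seq_len(k)]
}

#' Rank features by Gini importance
#'
#' Mean decrease in Gini impurity across a seeded bagged tree ensemble, with
#' the cutoff placed at the largest consecutive drop in ranked importance.
#'
#' @param features numeric matrix.
#' @param labels factor (>= 2 classes).
#' @param n_trees ensemble size.
#' @param seed RNG seed.
#' @return List: `ranking` (names, decreasing importance), `importance`
#'   (named, same order), `cutoff` (index: features 1..cutoff are retained),
#'   `selected`.
#' @export
gini_rank <- function(features, labels, n_trees = 100, seed = 1) {
  x <- as.matrix(features); y <- as.factor(labels)
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes")
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  mtry <- max(1L, floor(sqrt(ncol(x))))
  imp <- with_seed(seed, {
    acc <- stats::setNames(numeric(ncol(x)), colnames(x))
    for (i in seq_len(n_trees)) {
      idx <- sample.int(nrow(x), replace = TRUE)
      tr <- cart_fit(x[idx, , drop = FALSE], y[idx], mtry = mtry)
      acc <- acc + tr$importance
    }
    acc / n_trees
  })
  ord <- order(-imp, names(imp))
  ranked <- imp[ord]
  drops <- ranked[-length(ranked)] - ranked[-1]
  cutoff <- if (length(drops)) which.max(drops) else 1L
  list(ranking = names(ranked), importance = ranked, cutoff = cutoff,
       selected = names(ranked)[seq_len(cutoff)])
}

#' Borderline-SMOTE class balancing (Borderline-1)
#'
#' Minority samples whose k-neighbourhood (over all classes) is at least half
#' majority — but not entirely majority — form the "danger" set; synthetic
#' samples are convex combinations `x + u (x' - x)`, `u ~ U(0, 1)`, of danger
#' samples and their nearest minority neighbours.  Classes are equalised to
#' the majority count; original samples are preserved verbatim.  When no
#' danger samples exist the seeds fall back to all minority samples
#' (plain SMOTE).
#'
#' @param features numeric matrix.
#' @param labels factor or character vector.
#' @param k neighbourhood size (default 5).
#' @param seed RNG seed.
#' @return Object of class `balanced_set`: `x`, `labels`, `synthetic`
#'   (logical flag per row), `k`.
#' @export
borderline_smote <- function(features, labels, k = 5, seed = 1) {
  x <- as.matrix(features)
  y <- as.character(labels)
  if (k < 1) stop("k must be >= 1")
  counts <- table(y)
  n_max <- max(counts)
  out_x <- x; out_y <- y; synth <- rep(FALSE, nrow(x))
  with_seed(seed, {
    for (cls in names(counts)) {
      need <- n_max - counts[[cls]]
      if (need == 0) next
      min_idx <- which(y == cls)
      if (length(min_idx) < 2)
        stop("minority class '", cls, "' has fewer than 2 samples")
      # danger set from the k-NN over ALL samples
      kk <- min(k, nrow(x) - 1)
      danger <- min_idx[vapply(min_idx, function(i) {
        d2 <- rowSums(sweep(x, 2, x[i, ])^2)
        d2[i] <- Inf
        nn <- order(d2)[seq_len(kk)]
        m <- sum(y[nn] != cls)
        m >= kk / 2 && m < kk
      }, logical(1))]
      seeds <- if (length(danger)) danger else min_idx
      # minority-only neighbour table for interpolation
      km <- min(k, length(min_idx) - 1)
      xm <- x[min_idx, , drop = FALSE]
      new_rows <- matrix(0, need, ncol(x))
      for (j in seq_len(need)) {
        i <- seeds[sample.int(length(seeds), 1)]
        d2 <- rowSums(sweep(xm, 2, x[i, ])^2)
        d2[min_idx == i] <- Inf
        nb <- min_idx[order(d2)[sample.int(km, 1)]]
        u <- stats::runif(1)
        new_rows[j, ] <- x[i, ] + u * (x[nb, ] - x[i, ])
      }
      out_x <- rbind(out_x, new_rows)
      out_y <- c(out_y, rep(cls, need))
      synth <- c(synth, rep(TRUE, need))
    }
  })
  colnames(out_x) <- colnames(x)
  structure(list(x = out_x, labels = out_y, synthetic = synth, k = k),
            class = "balanced_set")
}
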