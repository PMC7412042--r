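test_that("pca_weights implements the contribution formula", {
  set.seed(51)
  # single feature: one component, loading 1, weight = standardised variance
  x1 <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "a"))
  w1 <- pca_weights(x1)
  expect_equal(unname(w1$w), 1)
  expect_equal(w1$n_components, 1L)
  expect_equal(formals(pca_weights)$variance_fraction, 0.80)
  # dense eigen-oracle on a random matrix
  x <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, letters[1:5]))
  pw <- pca_weights(x, 0.9)
  eg <- eigen(cor(scale(x)), symmetric = TRUE)
  n <- which(cumsum(eg$values) / sum(eg$values) >= 0.9)[1]
  w_oracle <- drop(eg$vectors[, 1:n]^2 %*% eg$values[1:n])
  expect_equal(unname(pw$w), w_oracle, tolerance = 1e-10)
  # invariant: sum of weights = total retained variance
  expect_equal(sum(pw$w), sum(eg$values[1:n]), tolerance = 1e-8)
  # constant columns are guarded with zero weight
  xc <- cbind(x, const = 1)
  expect_equal(unname(pca_weights(xc)$w["const"]), 0)
})

test_that("select_by_weight takes the smallest sufficient prefix", {
  w <- structure(list(w = c(a = 10, b = 0, c = 0)), class = "pca_weights")
  expect_equal(select_by_weight(w, 0.8), "a")
  wu <- structure(list(w = stats::setNames(rep(1, 10), letters[1:10])),
                  class = "pca_weights")
  expect_length(select_by_weight(wu, 0.8), 8)
  # deterministic tie-break by name
  expect_identical(select_by_weight(wu, 0.8), select_by_weight(wu, 0.8))
  expect_identical(select_by_weight(wu, 0.8), letters[1:8])
})

test_that("gini_rank finds a planted discriminative feature", {
  set.seed(52)
  n <- 80
  y <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  x[, 3] <- ifelse(y == "A", 0, 4) + rnorm(n, 0, 0.1)  # planted separator
  g <- gini_rank(x, y, n_trees = 40, seed = 3)
  expect_equal(g$ranking[1], "f3")
  expect_true("f3" %in% g$selected)
  # seeded determinism
  g2 <- gini_rank(x, y, n_trees = 40, seed = 3)
  expect_identical(g$importance, g2$importance)
  # identical columns share importance within Monte-Carlo tolerance
  xx <- cbind(x[, 3, drop = FALSE], x[, 3, drop = FALSE])
  colnames(xx) <- c("p", "q")
  gg <- gini_rank(cbind(xx, x[, 1:2]), y, n_trees = 200, seed = 4)
  expect_lt(abs(gg$importance["p"] - gg$importance["q"]) /
              max(gg$importance), 0.25)
  expect_error(gini_rank(x, rep("A", n)), "2 classes")
})

test_that("borderline-SMOTE balances classes on convex segments", {
  set.seed(53)
  # already balanced: unchanged
  xb <- matrix(rnorm(40), 20, 2)
  yb <- rep(c("A", "B"), 10)
  bal <- borderline_smote(xb, yb, seed = 1)
  expect_identical(bal$x, xb)
  expect_false(any(bal$synthetic))
  # minority of exactly 2 points: synthetics on their segment
  x <- rbind(matrix(rnorm(40, 5), 20, 2), c(0, 0), c(1, 2))
  y <- c(rep("maj", 20), "min", "min")
  b <- borderline_smote(x, y, k = 3, seed = 2)
  expect_equal(as.vector(table(b$labels)), c(20L, 20L))
  expect_equal(sum(b$labels == "min"), 20)
  syn <- b$x[b$synthetic, , drop = FALSE]
  # each synthetic point is collinear with and between the two minority points
  d <- c(1, 2) - c(0, 0)
  for (i in seq_len(nrow(syn))) {
    u <- syn[i, 1] / d[1]
    expect_equal(syn[i, 2], u * d[2], tolerance = 1e-10)
    expect_gte(u, 0); expect_lte(u, 1)
  }
  # originals preserved verbatim
  expect_identical(b$x[1:22, ], x)
  expect_error(borderline_smote(rbind(x, c(9, 9)),
                                c(y, "solo"), seed = 1), "fewer than 2")
})

test_that("SMOTE properties hold over random imbalanced sets", {
  set.seed(54)
  for (trial in 1:20) {
    n_min <- sample(2:6, 1)
    x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(n_min * 2, 3), n_min, 2))
    y <- c(rep("big", 30), rep("small", n_min))
    b <- borderline_smote(x, y, seed = trial)
    tab <- table(b$labels)
    expect_equal(unname(tab["big"]), unname(tab["small"]))  # uniform histogram
    # convexity: coordinate-wise betweenness w.r.t. the minority hull
    syn <- b$x[b$synthetic, , drop = FALSE]
    mins <- x[y == "small", , drop = FALSE]
    for (j in 1:2) {
      expect_true(all(syn[, j] >= min(mins[, j]) - 1e-12))
      expect_true(all(syn[, j] <= max(mins[, j]) + 1e-12))
    }
    # seeded reproducibility
    expect_identical(b$x, borderline_smote(x, y, seed = trial)$x)
  }
})
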