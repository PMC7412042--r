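# Four-level angiography-mimicking hierarchy:
#   L1: HC vs MI        (all samples)
#   L2: E vs LR         (MI samples; LR = {LAD, LCX, RCA})
#   L3: LCA vs RCA      (LR samples; LCA = {LAD, LCX})
#   L4: LAD vs LCX      (LCA samples)

HIERARCHY_LEVELS <- data.frame(
  level = c("L1", "L2", "L3", "L4"),
  pos = c("MI", "LR", "LCA", "LAD"),
  neg = c("HC", "E", "RCA", "LCX"),
  stringsAsFactors = FALSE)

# Binary level label of each sample at a given level (NA = not relevant).
level_label <- function(labels, level) {
  y <- as.character(labels)
  switch(level,
    L1 = ifelse(y == "HC", "HC", "MI"),
    L2 = ifelse(y %in% c("LAD", "LCX", "RCA"), "LR",
                ifelse(y == "E", "E", NA_character_)),
    L3 = ifelse(y %in% c("LAD", "LCX"), "LCA",
                ifelse(y == "RCA", "RCA", NA_character_)),
    L4 = ifelse(y == "LAD", "LAD", ifelse(y == "LCX", "LCX", NA_character_)))
}

#' Fit the hierarchical infarct-related-artery classifier
#'
#' Trains four binary classifiers along the coronary anatomy: healthy vs
#' infarct, discernible vs not, left main vs right coronary, LAD vs LCX.
#' The per-level base model defaults to the configuration found optimal in
#' validation — CART for detection (L1), SVM for localization (L2-L4).
#' Borderline-SMOTE balancing is applied per level to the training samples
#' only.
#'
#' @param x numeric feature matrix (named columns).
#' @param y labels among `r paste(IRA_CLASSES, collapse = ", ")`.
#' @param level_models character vector of length 4 with base-model names for
#'   L1..L4 (see [base_model_registry()]).
#' @param features optional named list (`L1`..`L4`) of feature-name subsets
#'   per level; default: all columns at every level.
#' @param balance apply [borderline_smote()] to each level's training set.
#' @param seed RNG seed.
#' @param ... hyperparameters passed to every base-model fit.
#' @return Object of class `ira_hierarchy`.
#' @export
ira_hierarchy <- function(x, y, level_models = c("CART", "SVM", "SVM", "SVM"),
                          features = NULL, balance = TRUE, seed = 1,
                          strict = TRUE, ...) {
  x <- as.matrix(x)
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  y <- as.character(y)
  if (!all(y %in% IRA_CLASSES)) stop("unknown labels present")
  stopifnot(length(level_models) == 4)
  fits <- list()
  for (li in 1:4) {
    lev <- HIERARCHY_LEVELS$level[li]
    yl <- level_label(y, lev)
    rel <- !is.na(yl)
    cls <- c(HIERARCHY_LEVELS$neg[li], HIERARCHY_LEVELS$pos[li])
    if (length(unique(yl[rel])) < 2) {
      if (strict) stop("untrainable level ", lev, ": only one class present")
      fits[lev] <- list(NULL)
      next
    }
    feats <- if (!is.null(features)) features[[lev]] else colnames(x)
    xl <- x[rel, feats, drop = FALSE]
    yf <- factor(yl[rel], levels = cls)
    if (balance) {
      bal <- borderline_smote(xl, yf, seed = seed + li)
      xl <- bal$x
      yf <- factor(bal$labels, levels = cls)
    }
    reg <- base_model_registry(level_models[li])
    fits[[lev]] <- list(model = reg$fit(xl, yf, seed = seed + li, ...),
                        features = feats, name = reg$name)
  }
  structure(list(fits = fits, level_models = level_models, seed = seed),
            class = "ira_hierarchy")
}

#' @export
print.ira_hierarchy <- function(x, ...) {
  cat("<ira_hierarchy> four-level infarct-related-artery classifier\n")
  for (li in 1:4) {
    lev <- HIERARCHY_LEVELS$level[li]
    cat(sprintf("  %s: %s vs %s [%s, %d features]\n", lev,
                HIERARCHY_LEVELS$neg[li], HIERARCHY_LEVELS$pos[li],
                x$level_models[li], length(x$fits[[lev]]$features)))
  }
  invisible(x)
}

#' @export
summary.ira_hierarchy <- function(object, ...) print(object)

#' Predict labels with audit path
#'
#' Prediction descends the hierarchy: a sample called HC at L1 short-circuits;
#' otherwise L2 decides E vs LR, L3 left vs right, L4 LAD vs LCX.  The
#' returned per-level decisions make the path auditable — the final label is
#' always the leaf of its own path.
#'
#' @param object a fitted [ira_hierarchy()].
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return data.frame with `label` and per-level decision columns `L1`..`L4`
#'   (NA where a level was not invoked).
#' @export
predict.ira_hierarchy <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  n <- nrow(x)
  dec <- data.frame(L1 = rep(NA_character_, n), L2 = NA_character_,
                    L3 = NA_character_, L4 = NA_character_,
                    stringsAsFactors = FALSE)
  label <- rep(NA_character_, n)
  lvl_pred <- function(lev, rows) {
    f <- object$fits[[lev]]
    if (is.null(f))
      stop("level ", lev, " was not trainable; cannot descend the hierarchy")
    if (!all(f$features %in% colnames(x)))
      stop("feature mismatch: prediction data lacks training features")
    as.character(predict(f$model, x[rows, f$features, drop = FALSE]))
  }
  rows <- seq_len(n)
  dec$L1 <- lvl_pred("L1", rows)
  label[dec$L1 == "HC"] <- "HC"
  mi <- which(dec$L1 == "MI")
  if (length(mi) && is.null(object$fits$L2)) mi <- integer(0)
  if (length(mi)) {
    dec$L2[mi] <- lvl_pred("L2", mi)
    label[mi][dec$L2[mi] == "E"] <- "E"
    lr <- mi[dec$L2[mi] == "LR"]
    if (length(lr)) {
      dec$L3[lr] <- lvl_pred("L3", lr)
      label[lr][dec$L3[lr] == "RCA"] <- "RCA"
      lca <- lr[dec$L3[lr] == "LCA"]
      if (length(lca)) {
        dec$L4[lca] <- lvl_pred("L4", lca)
        label[lca] <- dec$L4[lca]
      }
    }
  }
  cbind(data.frame(label = label, stringsAsFactors = FALSE), dec)
}

#' Cross-validated evaluation of the hierarchy
#'
#' Repeated stratified k-fold cross-validation; borderline-SMOTE balancing is
#' applied inside training folds only, so synthetic samples never cross the
#' train/test boundary.  Each level's accuracy is measured on the test samples
#' relevant to that level (its own two classes), matching the per-level
#' reporting of the hierarchy.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param level_models per-level base models, as in [ira_hierarchy()].
#' @param folds number of folds (downgraded with a warning when a class is
#'   smaller than the fold count).
#' @param repeats number of repetitions with reshuffled folds.
#' @param seed RNG seed; the report is bit-reproducible given a seed.
#' @param balance balance training folds.
#' @param features per-level feature subsets, as in [ira_hierarchy()].
#' @param ... hyperparameters for the base models.
#' @return Object of class `ira_cv`: `accuracy` (data.frame with per-level
#'   mean and SD over folds x repeats, in percent), `per_fold` (matrix),
#'   `confusion` (summed per-level confusion matrices), `folds`, `repeats`,
#'   `seed`.
#' @export
cross_validate <- function(x, y, level_models = c("CART", "SVM", "SVM", "SVM"),
                           folds = 10, repeats = 1, seed = 1, balance = TRUE,
                           features = NULL, ...) {
  x <- as.matrix(x)
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  y <- as.character(y)
  min_class <- min(table(y))
  if (min_class < folds) {
    warning("smallest class (", min_class, ") below fold count; using ",
            min_class, " folds")
    folds <- max(2, min_class)
  }
  acc <- array(NA_real_, c(repeats, folds, 4),
               dimnames = list(NULL, NULL, HIERARCHY_LEVELS$level))
  conf <- lapply(1:4, function(li) {
    cls <- c(HIERARCHY_LEVELS$neg[li], HIERARCHY_LEVELS$pos[li])
    matrix(0, 2, 2, dimnames = list(truth = cls, pred = cls))
  })
  names(conf) <- HIERARCHY_LEVELS$level
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_of <- integer(length(y))
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold_of[idx] <- rep_len(seq_len(folds), length(idx))
      }
      for (f in seq_len(folds)) {
        test <- which(fold_of == f)
        train <- which(fold_of != f)
        model <- ira_hierarchy(x[train, , drop = FALSE], y[train],
                               level_models = level_models,
                               features = features, balance = balance,
                               seed = seed + 97 * r + f, strict = FALSE, ...)
        for (li in 1:4) {
          lev <- HIERARCHY_LEVELS$level[li]
          yl <- level_label(y[test], lev)
          rel <- which(!is.na(yl))
          if (!length(rel)) next
          fit <- model$fits[[lev]]
          if (is.null(fit)) next
          pr <- as.character(predict(fit$model,
                                     x[test[rel], fit$features, drop = FALSE]))
          acc[r, f, li] <- 100 * mean(pr == yl[rel])
          for (k in seq_along(rel))
            conf[[lev]][yl[rel][k], pr[k]] <- conf[[lev]][yl[rel][k], pr[k]] + 1
        }
      }
    }
  })
  flat <- apply(acc, 3, as.vector)
  accuracy <- data.frame(
    level = HIERARCHY_LEVELS$level,
    contrast = paste(HIERARCHY_LEVELS$neg, "vs", HIERARCHY_LEVELS$pos),
    mean = colMeans(flat, na.rm = TRUE),
    sd = apply(flat, 2, stats::sd, na.rm = TRUE))
  structure(list(accuracy = accuracy, per_fold = flat, confusion = conf,
                 folds = folds, repeats = repeats, seed = seed),
            class = "ira_cv")
}

#' @export
print.ira_cv <- function(x, ...) {
  cat(sprintf("<ira_cv> %d-fold x %d repeats (seed %d)\n",
              x$folds, x$repeats, x$seed))
  df <- x$accuracy
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %s %-11s %5.1f +/- %.1f %%\n", df$level[i],
                paste0("(", df$contrast[i], ")"), df$mean[i], df$sd[i]))
  invisible(x)
}
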