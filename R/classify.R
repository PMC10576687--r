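#' SVM-RFE in stratified five-fold cross-validation
#'
#' Stratified (class-ratio preserving) seeded folds. Within each training
#' fold: features are z-scored on training statistics only, a linear SVM
#' is fitted, and the single feature with the smallest squared weight is
#' eliminated and the model refitted until one feature remains, yielding
#' a full ranking. Every nested subset of the ranking is then evaluated
#' on the held-out fold; the fold's best subset is the one maximizing
#' held-out accuracy (ties to the smaller subset). Sensitivity is the
#' recall of the positive (patient) class, specificity the recall of the
#' other. The reported accuracy/sensitivity/specificity are fold means at
#' each fold's best subset; `selection_counts` counts, per feature, the
#' folds whose best subset retained it.
#'
#' @param features subjects x F numeric matrix or data.frame (a
#'   `subject_id` column is carried along but not used as a feature).
#' @param labels binary class labels over subjects.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param cost linear-SVM cost parameter C (default 1).
#' @param positive label of the positive (patient) class; default the
#'   second factor level.
#' @return a `microdyn_clf` report: `folds` (per-fold detail),
#'   `accuracy`, `sensitivity`, `specificity`, `selection_counts`,
#'   `fold_assignments`, `seed`.
#' @export
svm_rfe_cv <- function(features, labels, n_folds = 5, seed = 1, cost = 1,
                       positive = NULL) {
  ft <- as.data.frame(features)
  ids <- ft$subject_id
  ft$subject_id <- NULL
  X <- as.matrix(ft)
  if (ncol(X) < 2) stop("need at least 2 features")
  y <- as.factor(labels)
  if (nlevels(y) != 2) stop("labels must be binary")
  if (is.null(positive)) positive <- levels(y)[2]
  if (!positive %in% levels(y)) stop("unknown positive class: ", positive)
  if (nrow(X) != length(y)) stop("features/labels length mismatch")
  feat_names <- colnames(X) %||% sprintf("f%d", seq_len(ncol(X)))
  colnames(X) <- feat_names

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(nrow(X))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  if (any(table(fold, y) < 2)) stop("a fold has fewer than 2 subjects of one class")

  folds <- vector("list", n_folds)
  counts <- stats::setNames(integer(ncol(X)), feat_names)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    ytr <- y[tr]; yte <- y[!tr]
    ranking <- .rfe_rank(Xtr, ytr, cost)
    best <- list(acc = -1, size = NA_integer_, sens = NA_real_, spec = NA_real_)
    for (s in seq_along(ranking)) {
      feats <- ranking[seq_len(s)]
      m <- e1071::svm(Xtr[, feats, drop = FALSE], ytr, kernel = "linear",
                      cost = cost, scale = FALSE)
      pred <- stats::predict(m, Xte[, feats, drop = FALSE])
      acc <- mean(pred == yte)
      if (acc > best$acc) {
        pos <- yte == positive
        best <- list(acc = acc, size = s,
                     sens = if (any(pos)) mean(pred[pos] == yte[pos]) else NA_real_,
                     spec = if (any(!pos)) mean(pred[!pos] == yte[!pos]) else NA_real_,
                     features = feat_names[feats])
      }
    }
    counts[best$features] <- counts[best$features] + 1L
    folds[[f]] <- list(fold = f, accuracy = best$acc, sensitivity = best$sens,
                       specificity = best$spec, best_size = best$size,
                       best_features = best$features,
                       ranking = feat_names[ranking])
  }
  structure(list(
    folds = folds,
    accuracy = mean(vapply(folds, `[[`, numeric(1), "accuracy")),
    sensitivity = mean(vapply(folds, `[[`, numeric(1), "sensitivity"), na.rm = TRUE),
    specificity = mean(vapply(folds, `[[`, numeric(1), "specificity"), na.rm = TRUE),
    selection_counts = sort(counts, decreasing = TRUE),
    fold_assignments = stats::setNames(fold, ids %||% rownames(X)),
    positive = positive, cost = cost, seed = seed
  ), class = "microdyn_clf")
}

# Full RFE ranking on a training fold: returns column indices, best first.
.rfe_rank <- function(Xtr, ytr, cost) {
  active <- seq_len(ncol(Xtr))
  ranking <- integer(0)
  while (length(active) > 1) {
    m <- e1071::svm(Xtr[, active, drop = FALSE], ytr, kernel = "linear",
                    cost = cost, scale = FALSE)
    w <- crossprod(m$coefs, m$SV)          # 1 x p weight vector
    worst <- which.min(w^2)
    ranking <- c(active[worst], ranking)
    active <- active[-worst]
  }
  c(active, ranking)
}

#' @export
print.microdyn_clf <- function(x, ...) {
  cat(sprintf("<microdyn_clf> %d-fold SVM-RFE: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              length(x$folds), 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity))
  top <- utils::head(x$selection_counts[x$selection_counts > 0], 5)
  if (length(top)) {
    cat("top selected:", paste(sprintf("%s (%d/%d)", names(top), top,
                                       length(x$folds)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Merge microstate features with significant component loadings
#'
#' Joins the per-subject microstate feature table with the loadings of
#' the selected ICA components on `subject_id`; subjects must match
#' exactly between tables.
#'
#' @param microstate_features data.frame with `subject_id` plus feature
#'   columns.
#' @param loadings subjects x components matrix (rownames = subject ids)
#'   or data.frame with `subject_id`; may have zero columns.
#' @return merged data.frame, microstate features first.
#' @export
assemble_inputs <- function(microstate_features, loadings) {
  mf <- as.data.frame(microstate_features)
  if (is.null(mf$subject_id)) stop("`microstate_features` needs a subject_id column")
  if (is.matrix(loadings)) {
    loadings <- data.frame(subject_id = rownames(loadings),
                           as.data.frame(loadings), check.names = FALSE)
  }
  ld <- as.data.frame(loadings)
  if (is.null(ld$subject_id)) stop("`loadings` needs subject ids")
  only_mf <- setdiff(mf$subject_id, ld$subject_id)
  only_ld <- setdiff(ld$subject_id, mf$subject_id)
  if (length(only_mf) || length(only_ld)) {
    stop("subject mismatch between tables: ",
         paste(c(only_mf, only_ld), collapse = ", "))
  }
  merged <- merge(mf, ld, by = "subject_id", sort = FALSE)
  merged[match(mf$subject_id, merged$subject_id), , drop = FALSE]
}
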