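# Cell-of-origin k-NN classification and the stepwise PCA-LDA subtype
# classifier with leave-one-out cross-validation and external projection.

as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) {
    if (names(x)[1] == "region_id") return(signal_matrix(x))
    return(as.matrix(x))
  }
  abort("expected a samples-by-features matrix or a stabilized wide tibble")
}

new_confusion_matrix <- function(truth, pred, labels = NULL) {
  labels <- labels %||% sort(unique(c(truth, pred)))
  tab <- table(factor(truth, levels = labels),
               factor(pred, levels = labels))
  structure(list(table = unclass(tab), labels = labels,
                 accuracy = sum(diag(tab)) / sum(tab)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (%d classes, accuracy %.3f)\n",
              length(x$labels), x$accuracy))
  print(x$table)
  invisible(x)
}

#' Tidy a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Long tibble with `truth`, `prediction`, `n`.
#' @exportS3Method generics::tidy
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(x$table), stringsAsFactors = FALSE)
  names(df) <- c("truth", "prediction", "n")
  as_tibble(df)
}

#' @rdname tidy.confusion_matrix
#' @exportS3Method generics::glance
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = sum(x$table),
         n_classes = length(x$labels))
}

#' Fit a k-nearest-neighbour classifier
#'
#' Stores the training signal (samples x features) and labels.
#' Prediction is by majority vote among the `k` nearest training points
#' (Euclidean distance); vote ties are broken by the label of the single
#' nearest neighbour.
#'
#' @param x Samples-by-features matrix, or a stabilized wide tibble
#'   (regions x samples; transposed internally).  For cell-of-origin
#'   classification this is the stabilized, locus-Z-scored signal at
#'   progenitor identity loci.
#' @param labels Character vector of training labels, one per sample.
#' @param k Neighbour count (default 5).
#' @return An object of class `knn_model`.
#' @export
knn_fit <- function(x, labels, k = 5) {
  m <- as_feature_matrix(x)
  if (nrow(m) != length(labels)) abort("labels must match training samples")
  if (k < 1 || k > nrow(m)) abort("k must be in [1, n_train]")
  structure(list(x = m, labels = as.character(labels), k = as.integer(k),
                 features = colnames(m), metric = "euclidean"),
            class = "knn_model")
}

#' Predict with a k-NN model
#'
#' @param object A `knn_model`.
#' @param newdata Query samples (matrix or stabilized tibble) over the
#'   model's feature set, in the same order.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.knn_model <- function(object, newdata, ...) {
  q <- as_feature_matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(q))) {
    if (!identical(colnames(q), object$features)) {
      abort("query features do not match the training feature set/order")
    }
  } else if (ncol(q) != ncol(object$x)) {
    abort("query feature count differs from training")
  }
  tr <- object$x; labs <- object$labels; k <- object$k
  # squared Euclidean distances query x train
  d2 <- outer(rowSums(q^2), rowSums(tr^2), "+") - 2 * q %*% t(tr)
  apply_vote <- function(drow) {
    ord <- order(drow)             # stable: earliest index wins exact ties
    nn <- ord[seq_len(k)]
    votes <- table(labs[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else labs[ord[1]]
  }
  vapply(seq_len(nrow(q)), function(i) apply_vote(d2[i, ]), character(1))
}

#' @rdname predict.knn_model
#' @param model A `knn_model`.
#' @export
knn_predict <- function(model, newdata) predict(model, newdata)

#' Leave-one-out cross-validation of the k-NN classifier
#'
#' Each sample is predicted by a model trained on all other samples.
#'
#' @inheritParams knn_fit
#' @return A `confusion_matrix` over the truth labels.
#' @export
knn_loocv <- function(x, labels, k = 5) {
  m <- as_feature_matrix(x)
  labels <- as.character(labels)
  n <- nrow(m)
  if (n < 2) abort("LOOCV needs at least 2 samples")
  if (any(table(labels) < 2)) {
    warn("some classes have < 2 samples; their LOOCV folds cannot be correct")
  }
  pred <- vapply(seq_len(n), function(i) {
    fit <- knn_fit(m[-i, , drop = FALSE], labels[-i], k = min(k, n - 1))
    predict(fit, m[i, , drop = FALSE])
  }, character(1))
  new_confusion_matrix(labels, pred, labels = sort(unique(labels)))
}

# --- regularized LDA in a reduced (PC) space ------------------------------

# scores: n x q; returns discriminant axes (q x d), class means in
# discriminant space, labels.  Within-class covariance regularized as
# (1-gamma)*S + gamma*diag(S).
lda_core <- function(scores, labels, gamma = 0.1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  C <- length(classes); q <- ncol(scores); n <- nrow(scores)
  mu <- t(vapply(classes, function(cl) colMeans(scores[labels == cl, , drop = FALSE]),
                 double(q)))
  Sw <- matrix(0, q, q)
  for (ci in seq_along(classes)) {
    xc <- scores[labels == classes[ci], , drop = FALSE]
    xc <- sweep(xc, 2, mu[ci, ])
    Sw <- Sw + crossprod(xc)
  }
  Sw <- Sw / max(n - C, 1)
  Sg <- (1 - gamma) * Sw + gamma * diag(diag(Sw), q)
  ev <- eigen(Sg, symmetric = TRUE)
  vals <- pmax(ev$values, max(ev$values, 1e-12) * 1e-10)
  Wi <- ev$vectors %*% (t(ev$vectors) / sqrt(vals))   # Sg^{-1/2}
  nc <- as.numeric(table(factor(labels, levels = classes)))
  Mw <- mu %*% Wi
  gmean <- colSums(Mw * nc) / n
  Mc <- sweep(Mw, 2, gmean)
  Sb <- crossprod(Mc * sqrt(nc)) / n
  eb <- eigen(Sb, symmetric = TRUE)
  d <- min(C - 1, q)
  V <- eb$vectors[, seq_len(d), drop = FALSE]
  axes <- Wi %*% V                                    # q x d
  list(axes = axes, class_means = mu %*% axes, classes = classes)
}

lda_predict_core <- function(fit, scores) {
  z <- scores %*% fit$axes
  cm <- fit$class_means
  d2 <- outer(rowSums(z^2), rowSums(cm^2), "+") - 2 * z %*% t(cm)
  # nearest class mean; exact ties go to the lexicographically first label
  idx <- apply(d2, 1, function(r) which(r <= min(r) + 1e-12)[1])
  list(labels = fit$classes[idx], coords = z)
}

# One LOOCV sweep: per fold refit centering/scaling + PCA + LDA on the
# fixed feature set; a single SVD per fold serves every n_pc in the grid.
pca_lda_loocv <- function(m, labels, grid, gamma) {
  n <- nrow(m)
  max_pc <- max(grid)
  correct <- matrix(FALSE, n, length(grid),
                    dimnames = list(NULL, as.character(grid)))
  pred_at <- matrix(NA_character_, n, length(grid))
  for (i in seq_len(n)) {
    tr <- m[-i, , drop = FALSE]
    ctr <- colMeans(tr)
    scl <- apply(tr, 2, sd); scl[scl == 0] <- 1
    trs <- sweep(sweep(tr, 2, ctr), 2, scl, "/")
    sv <- svd(trs, nu = 0, nv = max_pc)
    sc_tr <- trs %*% sv$v
    qy <- sweep(sweep(m[i, , drop = FALSE], 2, ctr), 2, scl, "/") %*% sv$v
    for (gi in seq_along(grid)) {
      k <- grid[gi]
      fit <- lda_core(sc_tr[, seq_len(k), drop = FALSE], labels[-i], gamma)
      pr <- lda_predict_core(fit, qy[, seq_len(k), drop = FALSE])$labels
      pred_at[i, gi] <- pr
      correct[i, gi] <- pr == labels[i]
    }
  }
  list(accuracy = colMeans(correct), predictions = pred_at)
}

#' Fit the stepwise PCA-LDA subtype classifier
#'
#' Features (stabilized signal at subtype-enriched DASs) are centred and
#' scaled, projected by PCA (SVD), and classified by regularized LDA on
#' the leading principal components.  The number of components is chosen
#' by internal leave-one-out cross-validation over `n_pc_grid`
#' (PCA and LDA are refit in every fold on the fixed feature set);
#' accuracy ties go to the smallest `n_pc`.  The final model is refit on
#' all samples.
#'
#' @param x Samples-by-features matrix or stabilized wide tibble
#'   (regions x samples).
#' @param labels Subtype label per sample.
#' @param n_pc_grid Candidate component counts; default
#'   `2:min(50, n_samples - 2)`.
#' @param gamma Shrinkage weight of the diagonal regularization of the
#'   pooled within-class covariance (default 0.1).
#' @return Object of class `pca_lda` with the selected `n_pc`, the LOOCV
#'   accuracy curve (`cv` tibble), the LOOCV confusion matrix at the
#'   selected size (`loocv_confusion`), and everything needed to project
#'   new cohorts.
#' @export
pca_lda_fit <- function(x, labels, n_pc_grid = NULL, gamma = 0.1) {
  m <- as_feature_matrix(x)
  labels <- as.character(labels)
  n <- nrow(m)
  if (n != length(labels)) abort("labels must match samples")
  classes <- sort(unique(labels))
  if (n <= length(classes)) abort("need more samples than classes")
  cap <- min(n - 2, ncol(m))
  grid <- n_pc_grid %||% seq(2, min(50, cap))
  grid <- sort(unique(as.integer(grid[grid >= 1 & grid <= cap])))
  if (length(grid) == 0) abort("empty n_pc grid after capping at n_samples - 2")
  cvres <- pca_lda_loocv(m, labels, grid, gamma)
  best <- grid[which.max(cvres$accuracy)]   # ties -> smallest (first index)
  sel <- which(grid == best)
  # final refit on all samples
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd); scl[scl == 0] <- 1
  ms <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  sv <- svd(ms, nu = 0, nv = best)
  scores <- ms %*% sv$v
  lda <- lda_core(scores, labels, gamma)
  structure(list(
    features = colnames(m),
    center = ctr, scale = scl,
    rotation = sv$v, n_pc = best, gamma = gamma,
    lda = lda,
    labels = labels,
    fitted = lda_predict_core(lda, scores),
    cv = tibble(n_pc = grid, accuracy = unname(cvres$accuracy)),
    loocv_accuracy = unname(cvres$accuracy[sel]),
    loocv_confusion = new_confusion_matrix(labels, cvres$predictions[, sel],
                                           labels = classes)
  ), class = "pca_lda")
}

#' @export
print.pca_lda <- function(x, ...) {
  cat(sprintf("PCA-LDA classifier: %d features, %d classes, n_pc = %d (LOOCV accuracy %.3f)\n",
              length(x$features), length(x$lda$classes), x$n_pc,
              x$loocv_accuracy))
  invisible(x)
}

#' Project new samples through a fitted PCA-LDA model
#'
#' New cohorts are stabilized and scaled with the training constants,
#' projected through the stored principal axes and discriminant axes,
#' and classified by the nearest class mean in discriminant space (exact
#' ties break to the lexicographically first label).
#'
#' @param object A `pca_lda` model.
#' @param newdata Matrix or stabilized wide tibble carrying the model's
#'   feature regions (missing features raise an error listing them).
#' @param ... Unused.
#' @return Tibble `sample_id`, `prediction`, plus discriminant
#'   coordinates `LD1`, `LD2`, ...
#' @export
predict.pca_lda <- function(object, newdata, ...) {
  q <- as_feature_matrix(newdata)
  if (!is.null(colnames(q))) {
    miss <- setdiff(object$features, colnames(q))
    if (length(miss) > 0) {
      abort(paste0("query lacks model feature(s): ",
                   paste(utils::head(miss, 5), collapse = ", "),
                   if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5) else ""))
    }
    q <- q[, object$features, drop = FALSE]
  } else if (ncol(q) != nrow(object$rotation)) {
    abort("query feature count differs from the model")
  }
  qs <- sweep(sweep(q, 2, object$center), 2, object$scale, "/")
  scores <- qs %*% object$rotation
  pr <- lda_predict_core(object$lda, scores)
  coords <- pr$coords
  colnames(coords) <- paste0("LD", seq_len(ncol(coords)))
  bind_cols(
    tibble(sample_id = rownames(q) %||% paste0("sample", seq_len(nrow(q))),
           prediction = pr$labels),
    as_tibble(coords)
  )
}

#' @rdname predict.pca_lda
#' @param model A `pca_lda` model.
#' @export
pca_lda_predict <- function(model, newdata) predict(model, newdata)

#' Tidy and glance methods for PCA-LDA models
#'
#' `tidy()` returns the internal LOOCV accuracy over the component grid;
#' `glance()` the selected model's summary.
#'
#' @param x A `pca_lda` model.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.pca_lda <- function(x, ...) x$cv

#' @rdname tidy.pca_lda
#' @exportS3Method generics::glance
#' @export
glance.pca_lda <- function(x, ...) {
  tibble(n_pc = x$n_pc, loocv_accuracy = x$loocv_accuracy,
         n = length(x$labels), n_classes = length(x$lda$classes),
         n_features = length(x$features))
}

#' Accuracy after merging classes of a confusion matrix
#'
#' Collapses rows and columns of a confusion matrix according to a
#' partition of the labels (e.g. merging two molecularly related
#' subtypes into one class) and recomputes accuracy as the collapsed
#' trace over the total.
#'
#' @param confusion A `confusion_matrix`.
#' @param groups Named list of character vectors partitioning the label
#'   set; labels omitted from `groups` keep their own class.
#' @return The collapsed accuracy (scalar).
#' @export
merge_classes_accuracy <- function(confusion, groups) {
  labs <- confusion$labels
  mapping <- setNames(labs, labs)
  seen <- character(0)
  for (gname in names(groups)) {
    g <- groups[[gname]]
    if (any(!g %in% labs)) abort("groups contain unknown labels")
    if (any(g %in% seen)) abort("groups do not partition the label set")
    seen <- c(seen, g)
    mapping[g] <- gname
  }
  f <- factor(mapping[labs], levels = unique(mapping[labs]))
  tab <- confusion$table
  collapsed <- rowsum(t(rowsum(tab, f)), f)
  sum(diag(as.matrix(collapsed))) / sum(collapsed)
}
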