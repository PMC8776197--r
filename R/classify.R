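# Per-subject 7-class decoding for every (feature family x band) cell with
# the four study classifiers: BP neural network (single hidden layer),
# KNN (k = 5), random forest (500 trees) and linear-kernel SVM (libsvm,
# one-vs-one). Canonical protocol: stratified 10-fold cross-validation with
# per-fold column standardization fitted on the training folds; an 80/20
# stratified holdout is available as protocol = "holdout".

#' Classifier specification
#'
#' @param kind one of "bp", "knn", "rf", "svm".
#' @param ... hyperparameter overrides. Defaults follow the study: knn
#'   `k = 5`; rf `num_trees = 500`; svm `kernel = "linear"`, `cost = 1`;
#'   bp (architecture not published) `size = 64` hidden units, softmax
#'   output, early stopping on a 10% inner validation split, at most
#'   `maxit = 500` iterations.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("bp", "knn", "rf", "svm"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    knn = list(k = 5L),
    rf = list(num_trees = 500L),
    svm = list(kernel = "linear", cost = 1),
    bp = list(size = 64L, maxit = 500L, check = 10L, patience = 3L,
              val_frac = 0.1, lr = 0.1, momentum = 0.9))
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown))
    stop("unknown ", kind, " hyperparameter(s): ",
         paste(unknown, collapse = ", "))
  defaults[names(ov)] <- ov
  structure(list(kind = kind, params = defaults), class = "classifier_spec")
}

#' The four default classifier specifications
#' @return named list of `classifier_spec` (bp, knn, rf, svm).
#' @export
default_classifier_specs <- function() {
  specs <- lapply(c("bp", "knn", "rf", "svm"), classifier_spec)
  names(specs) <- c("bp", "knn", "rf", "svm")
  specs
}

#' Design matrix for one (family, band) slice
#'
#' Rows containing non-finite sentinel values (zero-variance DE, undefined
#' RASM ratios) are dropped and counted.
#'
#' @param tensor a `feature_tensor`.
#' @param family,band slice selectors.
#' @return list with `X` (epochs x dim), `y` (factor of class ids),
#'   `n_dropped`.
#' @export
make_design <- function(tensor, family, band) {
  X <- feature_matrix(tensor, family, band)
  y <- tensor$info$class_id
  ok <- apply(is.finite(X), 1, all)
  if (!any(ok))
    stop("all epochs in ", family, "/", band, " carry sentinel values")
  list(X = X[ok, , drop = FALSE],
       y = factor(y[ok], levels = sort(unique(tensor$info$class_id))),
       n_dropped = sum(!ok))
}

# stratified fold assignment; every class is spread round-robin over folds
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop("class ", cl, " has ", length(idx),
           " examples, fewer than the ", k, " folds")
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

.fit_bp <- function(Xtr, ytr, Xte, p, seed) {
  set.seed(seed)
  lev <- levels(ytr)
  # inner stratified validation split for early stopping
  vi <- unlist(lapply(lev, function(cl) {
    idx <- which(ytr == cl)
    sample(idx, max(1L, round(p$val_frac * length(idx))))
  }))
  ti <- setdiff(seq_along(ytr), vi)
  yz <- as.integer(ytr) - 1L # 0-based class codes
  pred <- .bp_fit_predict(Xtr[ti, , drop = FALSE], yz[ti],
                          Xtr[vi, , drop = FALSE], yz[vi], Xte,
                          n_classes = length(lev), size = p$size,
                          lr = p$lr, momentum = p$momentum,
                          max_epochs = p$maxit, check = p$check,
                          patience = p$patience)
  factor(lev[pred + 1L], levels = lev)
}

.fit_predict <- function(spec, Xtr, ytr, Xte, seed) {
  p <- spec$params
  lev <- levels(ytr)
  switch(spec$kind,
    knn = {
      set.seed(seed)
      class::knn(Xtr, Xte, ytr, k = p$k)
    },
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = p$kernel, cost = p$cost,
                        scale = FALSE)
      predict(fit, Xte)
    },
    rf = {
      fit <- ranger::ranger(x = Xtr, y = ytr, num.trees = p$num_trees,
                            num.threads = 1L, seed = seed)
      predict(fit, data = Xte, num.threads = 1L)$predictions
    },
    bp = .fit_bp(Xtr, ytr, Xte, p, seed))
}

.standardize <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(tr = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       te = sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
}

#' Evaluate one classifier on one design
#'
#' @param X epochs x dim design matrix.
#' @param y class factor, one label per row of `X`.
#' @param spec a `classifier_spec`.
#' @param protocol "cv10" (stratified k-fold) or "holdout" (stratified
#'   80/20 split).
#' @param n_folds folds for "cv10".
#' @param seed seed for fold assignment and stochastic fitters.
#' @return list (an evaluation cell): `classifier`, `fold_accuracy`,
#'   `mean_accuracy`, `sd_accuracy` (over folds), `confusion` (true x
#'   predicted counts over all held-out epochs), `sensitivity` (per-class
#'   recall), `n_test`.
#' @export
evaluate_subject <- function(X, y, spec, protocol = c("cv10", "holdout"),
                             n_folds = 10L, seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- droplevels(as.factor(y))
  if (any(table(y) < 2L)) stop("every class needs at least 2 examples")
  folds <- if (protocol == "cv10") {
    .stratified_folds(y, n_folds, seed)
  } else {
    f <- .stratified_folds(y, 5L, seed) # 1 of 5 folds held out = 20%
    ifelse(f == 1L, 1L, 2L)
  }
  test_sets <- if (protocol == "cv10") seq_len(n_folds) else 1L
  lev <- levels(y)
  conf <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  accs <- numeric(0)
  for (f in test_sets) {
    te <- folds == f
    st <- .standardize(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    pred <- .fit_predict(spec, st$tr, y[!te], st$te, seed = seed + f)
    pred <- factor(as.character(pred), levels = lev)
    accs <- c(accs, mean(pred == y[te]))
    conf <- conf + unclass(table(y[te], pred))
  }
  sens <- diag(conf) / rowSums(conf)
  list(classifier = spec$kind, fold_accuracy = accs,
       mean_accuracy = mean(accs),
       sd_accuracy = if (length(accs) > 1) sd(accs) else NA_real_,
       confusion = conf, sensitivity = sens, n_test = sum(conf))
}

#' Evaluate the full (subject x family x band x classifier) grid
#'
#' For every subject and (family, band) slice, all classifiers are run on
#' the same stratified folds with standardization fitted per training fold.
#' Cross-subject aggregates (mean and n-1 SD of the per-subject accuracies)
#' give the Table-2-shaped summary.
#'
#' @param tensors list of `feature_tensor`, one per subject.
#' @param specs named list of `classifier_spec`.
#' @param families,bands axes to evaluate (defaults: all six families, five
#'   bands plus "total").
#' @param protocol,n_folds evaluation protocol (see [evaluate_subject()]).
#' @param seed global seed; subject i uses `seed + 1000 * (i - 1)` so
#'   subjects are independent but reproducible.
#' @return object of class `evaluation_grid`: `cells` (one row per subject
#'   x family x band x classifier, with list-columns for fold accuracies,
#'   sensitivity and confusion), `aggregate` (mean/sd across subjects),
#'   plus protocol metadata (`sd_axis = "subjects"`).
#' @export
evaluate_grid <- function(tensors, specs = default_classifier_specs(),
                          families = .feature_families,
                          bands = c(band_scheme()$band, "total"),
                          protocol = "cv10", n_folds = 10L, seed = 1L) {
  stopifnot(length(tensors) >= 1)
  rows <- list()
  for (i in seq_along(tensors)) {
    tensor <- tensors[[i]]
    sid <- tensor$subject_id %||% sprintf("S%02d", i)
    subj_seed <- seed + 1000L * (i - 1L)
    for (fm in families) for (bn in bands) {
      des <- make_design(tensor, fm, bn)
      for (sp in names(specs)) {
        cell <- evaluate_subject(des$X, des$y, specs[[sp]],
                                 protocol = protocol, n_folds = n_folds,
                                 seed = subj_seed)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, family = fm, band = bn, classifier = sp,
          mean_accuracy = cell$mean_accuracy,
          sd_accuracy = cell$sd_accuracy, n_test = cell$n_test,
          n_dropped = des$n_dropped, stringsAsFactors = FALSE)
        rows[[length(rows)]]$fold_accuracy <- I(list(cell$fold_accuracy))
        rows[[length(rows)]]$sensitivity <- I(list(cell$sensitivity))
        rows[[length(rows)]]$confusion <- I(list(cell$confusion))
      }
    }
  }
  cells <- do.call(rbind, rows)
  agg <- .aggregate_cells(cells)
  structure(list(cells = cells, aggregate = agg, protocol = protocol,
                 n_folds = n_folds, seed = seed, sd_axis = "subjects"),
            class = "evaluation_grid")
}

.aggregate_cells <- function(cells) {
  key <- interaction(cells$family, cells$band, cells$classifier, drop = TRUE)
  parts <- split(cells, key)
  agg <- do.call(rbind, lapply(parts, function(p) data.frame(
    family = p$family[1], band = p$band[1], classifier = p$classifier[1],
    mean_accuracy = mean(p$mean_accuracy),
    sd_accuracy = if (nrow(p) > 1) sd(p$mean_accuracy) else NA_real_,
    n_subjects = nrow(p), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg[order(agg$family, agg$band, agg$classifier), ]
}

#' Best cell per subject along one axis
#'
#' For each subject and each level of `by` ("classifier": the best
#' family/band per classifier; "family": the best band/classifier per
#' family), returns the maximal-accuracy cell(s). Ties are all reported,
#' ordered by (band, family, classifier).
#'
#' @param grid an `evaluation_grid`.
#' @param by "classifier" or "family".
#' @return data.frame of argmax cells.
#' @export
best_per_subject <- function(grid, by = c("classifier", "family")) {
  by <- match.arg(by)
  cells <- grid$cells[, c("subject_id", "family", "band", "classifier",
                          "mean_accuracy")]
  key <- interaction(cells$subject_id, cells[[by]], drop = TRUE)
  out <- do.call(rbind, lapply(split(cells, key), function(p) {
    mx <- max(p$mean_accuracy)
    hit <- p[p$mean_accuracy >= mx - 1e-12, , drop = FALSE]
    hit[order(hit$band, hit$family, hit$classifier), , drop = FALSE]
  }))
  rownames(out) <- NULL
  out[order(out$subject_id, out[[by]]), ]
}
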