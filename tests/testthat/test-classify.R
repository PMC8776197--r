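mont <- default_montage()

# small feature tensor with n epochs per class
toy_tensor <- function(n_per_class = 12, seed = 20) {
  set.seed(seed)
  n <- n_per_class * 7
  data <- array(rnorm(29 * 500 * n), c(29, 500, n),
                dimnames = list(mont$feature_channels, NULL, NULL))
  as_epoch_set(data, class_id = rep(1:7, each = n_per_class))
}

test_that("make_design shapes the matrix and drops sentinel rows", {
  fx <- extract_features(toy_tensor(), mont)
  d <- make_design(fx, "DE", "gamma")
  expect_equal(dim(d$X), c(84, 29))
  expect_equal(as.vector(table(d$y)), rep(12L, 7))
  d2 <- make_design(fx, "DE", "total")
  expect_equal(ncol(d2$X), 145)

  fx$features$DE$gamma[3, 5] <- -Inf
  fx$features$DE$gamma[9, 1] <- NA
  d3 <- make_design(fx, "DE", "gamma")
  expect_equal(d3$n_dropped, 2)
  expect_equal(nrow(d3$X), 82)

  fx$features$DE$gamma[] <- -Inf
  expect_error(make_design(fx, "DE", "gamma"), "sentinel")
  expect_error(make_design(fx, "DE", "nope"), "no feature slice")
})

test_that("a class with fewer examples than folds is reported by name", {
  set.seed(21)
  X <- matrix(rnorm(60 * 4), 60)
  y <- factor(c(rep(1, 5), rep(2, 25), rep(3, 30)))
  expect_error(
    evaluate_subject(X, y, classifier_spec("knn"), n_folds = 10),
    "class 1")
})

test_that("permuted labels decode at chance; separable data decode perfectly", {
  set.seed(22)
  n <- 280
  y <- factor(rep(1:7, each = 40))
  Xnull <- matrix(rnorm(n * 10), n)
  for (kind in c("knn", "svm")) {
    cell <- evaluate_subject(Xnull, y, classifier_spec(kind), seed = 3)
    p <- 1 / 7
    band <- 2.576 * sqrt(p * (1 - p) / n)
    expect_gt(cell$mean_accuracy, p - band - 0.02)
    expect_lt(cell$mean_accuracy, p + band + 0.02)
  }
  mu <- matrix(rnorm(7 * 10, sd = 20), 7)
  Xsep <- mu[as.integer(y), ] + matrix(rnorm(n * 10, sd = 0.01), n)
  for (kind in c("svm", "knn")) {
    cell <- evaluate_subject(Xsep, y, classifier_spec(kind), seed = 3)
    expect_equal(cell$mean_accuracy, 1.0)
  }
})

test_that("stochastic classifiers are reproducible under a fixed seed", {
  set.seed(23)
  y <- factor(rep(1:7, each = 20))
  X <- matrix(rnorm(140 * 8), 140) + as.integer(y)
  for (kind in c("rf", "bp")) {
    a <- evaluate_subject(X, y, classifier_spec(kind), seed = 7)
    b <- evaluate_subject(X, y, classifier_spec(kind), seed = 7)
    expect_identical(a$fold_accuracy, b$fold_accuracy)
    expect_identical(a$confusion, b$confusion)
    c_ <- evaluate_subject(X, y, classifier_spec(kind), seed = 8)
    expect_false(identical(a$fold_accuracy, c_$fold_accuracy))
  }
})

test_that("confusion counts are conserved and sensitivities are recalls", {
  set.seed(24)
  y <- factor(rep(1:7, each = 20))
  X <- matrix(rnorm(140 * 6), 140) + 0.5 * as.integer(y)
  cell <- evaluate_subject(X, y, classifier_spec("svm"), seed = 1)
  expect_equal(sum(cell$confusion), 140)
  expect_equal(unname(rowSums(cell$confusion)), rep(20, 7))
  expect_equal(unname(cell$sensitivity),
               unname(diag(cell$confusion) / 20))
  expect_true(all(cell$fold_accuracy >= 0 & cell$fold_accuracy <= 1))
})

test_that("holdout protocol tests a stratified fifth of the data", {
  set.seed(25)
  y <- factor(rep(1:7, each = 20))
  X <- matrix(rnorm(140 * 6), 140) + 2 * as.integer(y)
  cell <- evaluate_subject(X, y, classifier_spec("knn"),
                           protocol = "holdout", seed = 1)
  expect_equal(cell$n_test, 28)
  expect_length(cell$fold_accuracy, 1)
  expect_equal(unname(rowSums(cell$confusion)), rep(4, 7))
})

test_that("evaluate_grid aggregates across subjects with n-1 SD", {
  fx1 <- extract_features(toy_tensor(12, seed = 30), mont)
  fx1$subject_id <- "S01"; fx1$info$subject_id <- "S01"
  fx2 <- extract_features(toy_tensor(12, seed = 31), mont)
  fx2$subject_id <- "S02"; fx2$info$subject_id <- "S02"
  grid <- evaluate_grid(list(fx1, fx2),
                        specs = list(knn = classifier_spec("knn")),
                        families = c("DE", "DASM"),
                        bands = c("alpha", "gamma"), seed = 5)
  expect_equal(nrow(grid$cells), 2 * 2 * 2)
  expect_equal(nrow(grid$aggregate), 4)
  expect_equal(grid$aggregate$n_subjects, rep(2, 4))
  i <- 1
  manual <- grid$cells$mean_accuracy[grid$cells$family == "DE" &
                                       grid$cells$band == "alpha"]
  row <- grid$aggregate[grid$aggregate$family == "DE" &
                          grid$aggregate$band == "alpha", ]
  expect_equal(row$mean_accuracy, mean(manual))
  expect_equal(row$sd_accuracy, sd(manual))

  g1 <- evaluate_grid(list(fx1), specs = list(knn = classifier_spec("knn")),
                      families = "DE", bands = "gamma")
  expect_true(is.na(g1$aggregate$sd_accuracy))
})

test_that("best_per_subject finds the argmax and reports ties", {
  cells <- expand.grid(subject_id = c("S01", "S02"),
                       family = c("DE", "PSD"),
                       band = c("alpha", "gamma"),
                       classifier = c("knn", "svm"),
                       stringsAsFactors = FALSE)
  set.seed(26)
  cells$mean_accuracy <- runif(nrow(cells))
  grid <- structure(list(cells = cells), class = "evaluation_grid")
  best <- best_per_subject(grid, by = "classifier")
  # exhaustive scan oracle
  for (s in c("S01", "S02")) for (cl in c("knn", "svm")) {
    sub <- cells[cells$subject_id == s & cells$classifier == cl, ]
    got <- best[best$subject_id == s & best$classifier == cl, ]
    expect_equal(got$mean_accuracy, max(sub$mean_accuracy))
  }
  # a tie reports every tied cell
  cells$mean_accuracy[cells$subject_id == "S01" &
                        cells$classifier == "knn"] <- 0.5
  grid2 <- structure(list(cells = cells), class = "evaluation_grid")
  best2 <- best_per_subject(grid2, by = "classifier")
  expect_equal(sum(best2$subject_id == "S01" & best2$classifier == "knn"), 4)
})
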