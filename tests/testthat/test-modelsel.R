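# independent brute-force Kennard-Stone oracle
ks_oracle <- function(X, n_sel) {
  D <- as.matrix(dist(X))^2
  pair <- which(D == max(D), arr.ind = TRUE)
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
  sel <- sort(unname(pair[1, ]))
  while (length(sel) < n_sel) {
    cand <- setdiff(seq_len(nrow(X)), sel)
    mind <- vapply(cand, function(j) min(D[j, sel]), numeric(1))
    sel <- c(sel, cand[which.max(mind)])
  }
  sel
}

test_that("kennard-stone reproduces the brute-force max-min trace", {
  # 1-D worked example: calibration {0, 10, 2}, prediction {1}
  X <- matrix(c(0, 1, 2, 10))
  sp <- kennard_stone_split(X, labels = rep("a", 4), ratio = 0.75)
  expect_equal(sort(X[sp$calibration, 1]), c(0, 2, 10))
  expect_equal(X[sp$prediction, 1], 1)

  set.seed(7)
  Xr <- matrix(rnorm(24), 12, 2)
  sp2 <- kennard_stone_split(Xr, labels = rep("a", 12), ratio = 0.75)
  expect_setequal(sp2$calibration, ks_oracle(Xr, ceiling(0.75 * 12)))
})

test_that("kennard-stone is deterministic under duplicated points", {
  X <- matrix(c(0, 0, 1, 1, 5, 5, 0.5, 0.5), 4, 2, byrow = TRUE)
  sp1 <- kennard_stone_split(X, labels = rep("a", 4), ratio = 0.75)
  sp2 <- kennard_stone_split(X, labels = rep("a", 4), ratio = 0.75)
  expect_identical(sp1, sp2)
  expect_length(sp1$calibration, 3)
})

test_that("the default split is 3:1 within every class", {
  tbl <- generate_spectra(synth_config(seed = 21))
  sp <- kennard_stone_split(tbl)
  expect_length(sp$calibration, 2025)
  expect_length(sp$prediction, 675)
  expect_length(intersect(sp$calibration, sp$prediction), 0)
  per_class <- table(tbl$label[sp$calibration])
  expect_true(all(per_class == 135))  # ceiling(0.75 * 180)
  expect_error(kennard_stone_split(matrix(rnorm(6), 3),
                                   labels = rep("a", 3)),
               "fewer than 4")
})

test_that("the rbf kernel matches its closed form and is positive definite", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), g = 3), 1)
  expect_equal(rbf_kernel(c(0, 0), c(0, 1), g = 1), exp(-1))
  expect_error(rbf_kernel(1, 1, g = 0), "g")
  expect_error(rbf_kernel(c(1, 2), 1, g = 1), "lengths")

  set.seed(8)
  X <- matrix(rnorm(20), 10, 2)
  G <- outer(seq_len(10), seq_len(10),
             Vectorize(function(i, j) rbf_kernel(X[i, ], X[j, ], g = 0.7)))
  expect_equal(G, t(G))
  expect_gte(min(eigen(G, symmetric = TRUE)$values), -1e-10)
})

blobs <- function(n_per = 30, sep = 6, seed = 9) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
               matrix(rnorm(n_per * 2, mean = sep), n_per, 2))
    list(X = X, y = rep(c("a", "b"), each = n_per))
  })
}

test_that("svm fitness separates blobs and is seeded", {
  d <- blobs()
  f <- svm_fitness(1, 1, d$X, d$y, folds = 5, seed = 1)
  expect_lte(f, 0.02)
  expect_identical(f, svm_fitness(1, 1, d$X, d$y, folds = 5, seed = 1))

  # permutation null: balanced two-class error near 0.5
  d2 <- blobs(n_per = 60)
  y_perm <- withr::with_seed(2, sample(d2$y))
  f_null <- svm_fitness(1, 0.5, d2$X, y_perm, folds = 5, seed = 1)
  expect_gt(f_null, 0.4)
  expect_lt(f_null, 0.6)
})

test_that("our rbf-svm agrees with an independent solver on easy data", {
  skip_if_not_installed("kernlab")
  d <- blobs(n_per = 25, sep = 5)
  grid <- matrix(runif(40, -2, 7), 20, 2)
  ours <- predict(fit_rbf_svm(d$X, d$y, C = 10, g = 0.5), grid)
  ref <- kernlab::ksvm(d$X, factor(d$y), type = "C-svc", C = 10,
                       kernel = "rbfdot", kpar = list(sigma = 0.5),
                       scaled = FALSE)
  theirs <- kernlab::predict(ref, grid)
  expect_gte(mean(as.character(ours) == as.character(theirs)), 0.95)
})

test_that("tuning never loses to the default on its own fitness surface", {
  withr::with_seed(10, {
    X <- rbind(matrix(rnorm(60, sd = 0.6), 30, 2),
               matrix(rnorm(60, mean = 2.5, sd = 0.6), 30, 2),
               matrix(rnorm(60, mean = c(5, 0), sd = 0.6), 30, 2))
  })
  y <- rep(c("a", "b", "c"), each = 30)
  tn <- tune_svm(X, y, algorithm = "pso", pop_size = 6, max_iter = 5,
                 folds = 5, seed = 11)
  default_f <- svm_fitness(1, 1, X, y, folds = 5,
                           fold_id = jujuspec:::stratified_folds(y, 5, 11))
  expect_lte(tn$best_fitness, default_f + 1e-9)
  expect_length(tn$optimizer$trace, 5)
  expect_true(all(diff(tn$optimizer$trace) <= 0))
  expect_true(all(c(tn$best_C, tn$best_g) >= 0.001 &
                  c(tn$best_C, tn$best_g) <= 100))
})

test_that("classification reports have exact confusion semantics", {
  d <- blobs(n_per = 20, sep = 8)
  m <- fit_rbf_svm(d$X, d$y, C = 10, g = 0.5)

  rep_perfect <- evaluate_classifier(m, d$X, d$y)
  expect_equal(rep_perfect$accuracy, 100)
  expect_equal(sum(rep_perfect$confusion), 40)
  expect_equal(rep_perfect$confusion["a", "b"] +
               rep_perfect$confusion["b", "a"], 0)

  # all-wrong truth labels give 0% and an antidiagonal matrix
  swapped <- ifelse(d$y == "a", "b", "a")
  rep_wrong <- evaluate_classifier(m, d$X, swapped)
  expect_equal(rep_wrong$accuracy, 0)
  expect_equal(unname(diag(rep_wrong$confusion)), c(0, 0))

  # row sums preserve per-class counts
  expect_equal(unname(rowSums(rep_wrong$confusion)), c(20, 20))

  expect_error(evaluate_classifier(m, d$X, rep("zz", 40)), "outside")
  rep_unknown <- evaluate_classifier(m, d$X, rep("zz", 40),
                                     allow_unknown = TRUE)
  expect_true("unknown" %in% rownames(rep_unknown$confusion))
  expect_equal(rep_unknown$accuracy, 0)
})

test_that("pca embedding recovers known directions and conserves variance", {
  x <- seq(-2, 2, length.out = 50)
  emb <- pca_embed(cbind(x, 2 * x + rnorm(50, sd = 1e-8)), 2)
  expect_equal(abs(emb$loadings[, 1]), c(1, 2) / sqrt(5), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_lt(emb$explained_variance[2], 1e-10)

  set.seed(12)
  X <- matrix(rnorm(30 * 6), 30, 6)
  emb2 <- pca_embed(X, 6)
  expect_equal(sum(emb2$explained_variance), sum(apply(X, 2, var)))
  expect_equal(crossprod(emb2$loadings), diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(pca_embed(X, 10), "n_components")
})
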