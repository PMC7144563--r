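test_that("noiseless rank-1 data give near-perfect Q2", {
  set.seed(1)
  n <- 14
  l <- rnorm(n)
  X <- sapply(1:5, function(j) l + rnorm(n, sd = 0.05))
  colnames(X) <- paste0("d", 1:5)
  cv <- cross_validate(X, l, ncomp_max = 1, n_folds = 7)
  expect_gt(cv$Q2[1], 0.99)
  expect_true(cv$significant[1])
  expect_equal(cv$recommended_ncomp, 1L)
})

test_that("PRESS at one component matches a brute-force fold loop", {
  d <- rand_xy(17, n = 21, p = 6)
  cv <- cross_validate(d$X, d$y, ncomp_max = 1, n_folds = 7)
  # independent loop: explicit scaling, closed-form 1-component PLS, raw
  # residuals re-scaled by the full-data response sd
  folds <- ((seq_len(21) - 1) %% 7) + 1
  press_raw <- 0
  for (k in 1:7) {
    tr <- folds != k
    mu <- colMeans(d$X[tr, ]); sdv <- apply(d$X[tr, ], 2, sd)
    ymu <- mean(d$y[tr]); ysd <- sd(d$y[tr])
    Xs <- sweep(sweep(d$X[tr, ], 2, mu, "-"), 2, sdv, "/")
    ys <- (d$y[tr] - ymu) / ysd
    w <- drop(crossprod(Xs, ys)); w <- w / sqrt(sum(w^2))
    t1 <- drop(Xs %*% w)
    c1 <- sum(t1 * ys) / sum(t1^2)
    Xh <- sweep(sweep(d$X[!tr, , drop = FALSE], 2, mu, "-"), 2, sdv, "/")
    pred <- ymu + ysd * c1 * drop(Xh %*% w)
    press_raw <- press_raw + sum((pred - d$y[!tr])^2)
  }
  expect_equal(cv$PRESS[1], press_raw / sd(d$y)^2, tolerance = 1e-10)
})

test_that("every observation is predicted exactly once per fold scheme", {
  d <- rand_xy(4, n = 20, p = 5)
  cv <- cross_validate(d$X, d$y, ncomp_max = 2, n_folds = 7)
  expect_length(cv$fold_assignment, 20L)
  expect_true(all(table(cv$fold_assignment) >= 2))
  expect_false(anyNA(cv$cv_prediction_matrix))
})

test_that("PRESS is invariant to row order under a fixed fold map", {
  d <- rand_xy(9, n = 18, p = 5)
  folds <- cv_folds(18, 6)
  cv1 <- cross_validate(d$X, d$y, ncomp_max = 2, n_folds = 6,
                        assignment = folds)
  perm <- sample(18)
  cv2 <- cross_validate(d$X[perm, ], d$y[perm], ncomp_max = 2, n_folds = 6,
                        assignment = folds[perm])
  expect_equal(cv1$PRESS, cv2$PRESS, tolerance = 1e-10)
})

test_that("cross-validation rejects impossible fold counts", {
  d <- rand_xy(2, n = 5, p = 3)
  expect_error(cross_validate(d$X, d$y, 1, n_folds = 6), "n_folds")
})

test_that("Q2 never exceeds R2Y on the same data", {
  for (seed in 1:10) {
    g <- generate_qspr(synthetic_spec(seed = seed))
    m <- pls_qspr(g$table, g$response, 3)
    cv <- cross_validate(g$table, g$response, ncomp_max = 3)
    expect_lte(cv$Q2_cum[3], m$R2Y_cum)
    expect_lte(cv$Q2_pooled[3], m$R2Y_cum)
  }
})

test_that("the unpermuted point reproduces the model's own statistics", {
  g <- generate_qspr(synthetic_spec(seed = 3))
  pv <- permutation_validation(g$table, g$response, ncomp = 3,
                               n_permutations = 5, seed = 11)
  expect_equal(nrow(pv$points), 6L)
  orig <- pv$points[!pv$points$permuted, ]
  expect_equal(orig$correlation, 1)
  m <- pls_qspr(g$table, g$response, 3)
  cv <- cross_validate(g$table, g$response, ncomp_max = 3)
  expect_equal(orig$R2Y, m$R2Y_cum, tolerance = 1e-12)
  expect_equal(orig$Q2, cv$Q2_pooled[3], tolerance = 1e-12)
  expect_true(all(pv$points$correlation >= 0 & pv$points$correlation <= 1))
})

test_that("permutation validation is reproducible from its seed", {
  g <- generate_qspr(synthetic_spec(seed = 6))
  p1 <- permutation_validation(g$table, g$response, 3, n_permutations = 5,
                               seed = 42)
  p2 <- permutation_validation(g$table, g$response, 3, n_permutations = 5,
                               seed = 42)
  expect_equal(p1$points, p2$points)
  expect_equal(p1$intercept_R2, p2$intercept_R2)
})

test_that("constant responses cannot be permuted", {
  d <- rand_xy(5, n = 8, p = 3)
  expect_error(permutation_validation(d$X, rep(1, 8), 1), "constant")
})

test_that("external swap validation is symmetric and exact when noiseless", {
  set.seed(12)
  n <- 16
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("c", 1:n),
                                                  paste0("d", 1:4)))
  y <- as.numeric(X %*% c(1, 2, -1, 0.5))
  ev <- external_swap_validation(X, y, ncomp = 4, seed = 7)
  expect_lt(ev$RMSEP_train, 1e-8)
  expect_lt(ev$RMSEP_test, 1e-8)
  expect_gt(ev$Q2_train, 1 - 1e-10)

  # swapping the halves exchanges the two (Q2, RMSEP) pairs
  split <- ev$split_assignment
  swapped <- ifelse(split == "train", "test", "train")
  d <- rand_xy(33, n = n, p = 4)
  e1 <- external_swap_validation(d$X, d$y, ncomp = 2, split = split)
  e2 <- external_swap_validation(d$X, d$y, ncomp = 2, split = swapped)
  expect_equal(e1$Q2_train, e2$Q2_test, tolerance = 1e-12)
  expect_equal(e1$RMSEP_train, e2$RMSEP_test, tolerance = 1e-12)
})

test_that("RMSEP equals its direct re-summation", {
  d <- rand_xy(21, n = 15, p = 5)
  ev <- external_swap_validation(d$X, d$y, ncomp = 2, seed = 3)
  pr <- ev$predictions[ev$predictions$predicting_model == "train", ]
  expect_equal(ev$RMSEP_train,
               sqrt(sum((pr$observed - pr$predicted)^2) / nrow(pr)),
               tolerance = 1e-12)
  # odd n: first half takes the extra observation
  expect_equal(sum(ev$split_assignment == "train"), 8L)
})

test_that("external validation guards its split", {
  d <- rand_xy(3, n = 6, p = 3)
  expect_error(external_swap_validation(d$X[1:3, ], d$y[1:3], 1),
               "at least 4")
  bad <- c(rep("train", 5), "test")
  expect_error(external_swap_validation(d$X, d$y, 1, split = bad),
               "at most one")
})

test_that("validation report serializes to JSON", {
  g <- generate_qspr(synthetic_spec(seed = 2))
  cv <- cross_validate(g$table, g$response, ncomp_max = 3)
  pv <- permutation_validation(g$table, g$response, 3, n_permutations = 3,
                               seed = 1)
  ev <- external_swap_validation(g$table, g$response, 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  validation_report_json(cv, pv, ev, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$cross_validation$recommended_ncomp,
               cv$recommended_ncomp)
  expect_equal(back$permutation$intercept_R2, pv$intercept_R2)
  expect_equal(back$external$RMSEP_train, ev$RMSEP_train)
})
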