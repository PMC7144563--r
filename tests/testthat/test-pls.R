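test_that("perfect univariate fit is exact", {
  x <- c(1, 2, 3, 4, 5)
  tab <- descriptor_table(cbind(d1 = x), ids = paste0("c", 1:5))
  resp <- response_block(2 * x + 1, ids = paste0("c", 1:5), name = "y")
  m <- pls_qspr(tab, resp, ncomp = 1)
  expect_equal(m$R2Y_cum, 1, tolerance = 1e-12)
  expect_equal(m$RMSEE, 0, tolerance = 1e-10)
  expect_equal(unname(m$coef_raw["d1"]), 2, tolerance = 1e-10)
  expect_equal(unname(m$coef_raw["(Intercept)"]), 1, tolerance = 1e-9)
})

test_that("NIPALS matches the independent PLS oracle on scaled data", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(8:16, 1); p <- sample(3:8, 1)
    A <- min(3, n - 1, p)
    sp <- scaled_problem(seed, n = n, p = p)
    m <- fit_pls(sp$X, sp$y, A)
    mo <- mixOmics::pls(sp$X, sp$y, ncomp = A, scale = FALSE,
                        mode = "regression")
    po <- predict(mo, sp$X)
    expect_lt(max(abs(m$fitted_scaled - po$predict[, 1, A])), 1e-8)
    expect_lt(max(abs(m$coef_scaled - po$B.hat[, 1, A])), 1e-8)
    expect_lt(max(abs(abs(m$scores) - abs(mo$variates$X[, 1:A]))), 1e-8)
  }
})

test_that("a response orthogonal to X stops early with zero components", {
  # X columns sum to zero patterns orthogonal to y by construction
  Xs <- cbind(d1 = c(1, -1, 1, -1), d2 = c(1, 1, -1, -1))
  ys <- c(1, 1, 1, 1) - 1  # constant zero after centering
  expect_warning(m <- fit_pls(Xs, ys, 1), "stopping at 0")
  expect_equal(m$ncomp, 0L)
  expect_equal(m$fitted_scaled, rep(0, 4))
})

test_that("ncomp beyond the rank bound is rejected", {
  sp <- scaled_problem(2, n = 5, p = 3)
  expect_error(fit_pls(sp$X, sp$y, 5), "ncomp")
})

test_that("predictions are consistent, centered, and name-aligned", {
  sp <- scaled_problem(7, n = 12, p = 6)
  m <- fit_pls(sp$X, sp$y, 3, scaling_x = sp$scaling_x,
               scaling_y = sp$scaling_y)
  X_raw <- sp$table$values
  expect_lt(max(abs(predict(m, X_raw) - m$fitted)), 1e-10)

  mean_row <- matrix(colMeans(X_raw), 1,
                     dimnames = list("m", colnames(X_raw)))
  expect_equal(unname(predict(m, mean_row)),
               mean(sp$response$values), tolerance = 1e-10)

  shuffled <- X_raw[, sample(ncol(X_raw))]
  expect_equal(predict(m, shuffled), predict(m, X_raw))

  expect_error(predict(m, X_raw[, -1]), "lacks descriptor")
})

test_that("RMSEE and R2Y match their defining sums", {
  sp <- scaled_problem(13, n = 15, p = 6)
  m <- fit_pls(sp$X, sp$y, 2, scaling_x = sp$scaling_x,
               scaling_y = sp$scaling_y)
  res <- m$fitted - m$observed
  expect_equal(rmsee(m), sqrt(sum(res^2) / 15), tolerance = 1e-12)
  expect_equal(rmsee(m, df_correct = TRUE), sqrt(sum(res^2) / (15 - 1 - 2)),
               tolerance = 1e-12)
  expect_equal(r2y(m),
               1 - sum(res^2) / sum((m$observed - mean(m$observed))^2),
               tolerance = 1e-12)
  # scaled-space bookkeeping agrees with the raw-space ratio definition
  expect_equal(m$R2Y_cum, r2y(m), tolerance = 1e-10)
})

test_that("R2Y is monotone in the number of components", {
  for (seed in c(3, 17, 29)) {
    sp <- scaled_problem(seed, n = 12, p = 7)
    r2 <- vapply(1:4, function(a) fit_pls(sp$X, sp$y, a)$R2Y_cum, 0)
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("scores are orthogonal and weights unit-norm on every fit", {
  for (seed in 1:10) {
    sp <- scaled_problem(seed, n = sample(8:20, 1), p = sample(4:10, 1))
    A <- min(3, ncol(sp$X))
    m <- fit_pls(sp$X, sp$y, A)
    G <- crossprod(m$scores)
    expect_lt(max(abs(G[lower.tri(G)])), 1e-8)
    expect_equal(unname(colSums(m$weights^2)), rep(1, m$ncomp),
                 tolerance = 1e-10)
    expect_true(all(m$ssy_explained >= -1e-12))
    expect_equal(sum(m$ssy_explained), m$R2Y_cum, tolerance = 1e-10)
  }
})

test_that("full-rank noiseless linear responses are fit exactly", {
  set.seed(41)
  X <- matrix(rnorm(9 * 3), 9, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(X %*% c(1, -2, 0.5))
  Xs <- scale(X); ys <- as.numeric(scale(y))
  m <- fit_pls(Xs, ys, 3)
  expect_equal(m$R2Y_cum, 1, tolerance = 1e-10)
  expect_lt(max(abs(m$fitted_scaled - ys)), 1e-9)
})

test_that("w x c coordinates expose descriptor-response geometry", {
  set.seed(5)
  n <- 200
  x1 <- rnorm(n)
  X <- cbind(driver = x1, noise1 = rnorm(n), noise2 = rnorm(n))
  y <- x1 + rnorm(n, sd = 0.05)
  tab <- descriptor_table(X, ids = paste0("c", 1:n))
  resp <- response_block(y, ids = paste0("c", 1:n), name = "y",
                         check_nonneg = FALSE)
  m <- pls_qspr(tab, resp, ncomp = 2)
  wc <- wc_coordinates(m)
  expect_equal(nrow(wc), 4L)  # 3 descriptors + response
  expect_setequal(wc$role, c("descriptor", "response"))
  expect_equal(which.max(abs(wc$wc1[wc$role == "descriptor"])),
               which(colnames(X) == "driver"))
  # null descriptors stay near the origin
  expect_lt(max(abs(wc[wc$name %in% c("noise1", "noise2"), c("wc1")])), 0.1)

  m1 <- pls_qspr(tab, resp, ncomp = 1)
  expect_error(wc_coordinates(m1), "2 components")
})

test_that("models survive JSON serialization with exact predictions", {
  sp <- scaled_problem(23, n = 14, p = 5)
  m <- fit_pls(sp$X, sp$y, 2, scaling_x = sp$scaling_x,
               scaling_y = sp$scaling_y)
  path <- withr::local_tempfile(fileext = ".json")
  pls_to_json(m, path)
  m2 <- pls_from_json(path)
  X_raw <- sp$table$values
  expect_equal(predict(m2, X_raw), predict(m, X_raw), tolerance = 1e-12)
  expect_equal(m2$R2Y_cum, m$R2Y_cum)
  expect_equal(m2$weights, m$weights)
})

test_that("y-deflated PLS1 equals the no-y-deflation variant", {
  # for a single response, deflating y changes nothing: X'y_deflated
  # differs from X'y only within the span already removed from X
  sp <- scaled_problem(31, n = 12, p = 6)
  m <- fit_pls(sp$X, sp$y, 3)
  Xa <- sp$X; ya <- sp$y
  W2 <- NULL
  for (a in 1:3) {
    w <- crossprod(Xa, ya)  # no y-deflation: ya stays the original
    w <- w / sqrt(sum(w^2))
    imax <- which.max(abs(w)); if (w[imax] < 0) w <- -w
    t_a <- as.numeric(Xa %*% w)
    p_a <- crossprod(Xa, t_a) / sum(t_a^2)
    Xa <- Xa - tcrossprod(t_a, p_a)
    W2 <- cbind(W2, w)
  }
  expect_equal(unname(m$weights), unname(W2), tolerance = 1e-9)
})
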