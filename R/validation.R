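# -- internal helpers ---------------------------------------------------------

as_xy <- function(X, y) {
  if (inherits(X, "descriptor_table")) X <- X$values
  if (inherits(y, "response_block")) y <- y$values
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(rownames(X))) rownames(X) <- paste0("obs", seq_len(nrow(X)))
  list(X = X, y = stats::setNames(y, rownames(X)))
}

# scaling refit + PLS fit on a raw subset; zero-variance columns dropped
# silently, component count capped by the subset's rank bound
fit_subset <- function(X, y, ncomp) {
  sc <- suppressWarnings(autoscale_xy(X, y))
  a <- min(ncomp, nrow(X) - 1L, ncol(sc$X))
  suppressWarnings(fit_pls(sc$X, sc$y, a, scaling_x = sc$scaling_x,
                           scaling_y = sc$scaling_y))
}

# raw-unit predictions of a fitted model truncated to 1..a components,
# for every a up to model$ncomp; returns n_new x ncomp matrix
predict_per_component <- function(model, X_new) {
  xs <- apply_scaling(model$scaling_x, X_new)
  A <- model$ncomp
  out <- matrix(invert_scaling(model$scaling_y, 0), nrow(X_new), max(A, 1L))
  if (A >= 1L) {
    for (a in seq_len(A)) {
      b_a <- model$rotated_weights[, seq_len(a), drop = FALSE] %*%
        model$y_loadings[seq_len(a)]
      out[, a] <- invert_scaling(model$scaling_y, as.numeric(xs %*% b_a))
    }
  }
  out
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# -- cross-validation ---------------------------------------------------------

#' Cross-validated PRESS, Q-squared and component significance
#'
#' Seven-fold (by default) cross-validation in the SIMCA style: the data are
#' divided into `n_folds` groups, each group is left out in turn, scaling
#' and the PLS model are refit on the remainder, and the left-out responses
#' are predicted, until every observation has been predicted exactly once.
#' Per component a, \eqn{PRESS_a} is the sum of squared out-of-fold
#' prediction errors and \eqn{Q^2_a = 1 - PRESS_a / SS_{a-1}} with
#' \eqn{SS_{a-1}} the residual sum of squares of the full-data model after
#' a-1 components (\eqn{SS_0} = total corrected sum of squares). A component
#' is significant when \eqn{PRESS_a / SS_{a-1} < 1}; the recommended model
#' size is the largest a whose every component up to a is significant.
#'
#' Error sums are accumulated in scaled-response units of the full-data
#' scaling so the PRESS/SS ratios are coherent; each fold's model still
#' refits its own scaling (no leakage).
#'
#' @param X descriptor matrix or [descriptor_table].
#' @param y response vector or [response_block].
#' @param ncomp_max largest component count to evaluate.
#' @param n_folds number of cross-validation groups (default 7).
#' @param assignment optional integer vector of fold labels in `1:n_folds`;
#'   default is the deterministic interleaved ("venetian blind") assignment
#'   observation i -> ((i - 1) mod n_folds) + 1. Use [cv_folds()] with a
#'   seed for a randomized assignment.
#' @return An object of class `cv_result`: `n_folds`, `fold_assignment`,
#'   `PRESS` (per component), `Q2` (per component), `Q2_cum` (product-rule
#'   cumulative), `Q2_pooled` (1 - PRESS_a/SS0), `significant`,
#'   `recommended_ncomp`, `cv_predictions` (out-of-fold raw-unit predictions
#'   at the recommended size, or 1 component if none is significant), and
#'   `cv_prediction_matrix` (all component counts).
#' @export
cross_validate <- function(X, y, ncomp_max, n_folds = 7L, assignment = NULL) {
  xy <- as_xy(X, y)
  X <- xy$X; y <- xy$y
  n <- nrow(X)
  if (n_folds < 2L || n_folds > n)
    stop("need 2 <= n_folds <= n_obs", call. = FALSE)
  if (is.null(assignment)) assignment <- cv_folds(n, n_folds)
  assignment <- as.integer(assignment)
  if (length(assignment) != n || !all(assignment %in% seq_len(n_folds)))
    stop("fold assignment must map every observation to 1..n_folds",
         call. = FALSE)
  # full-data model supplies the residual sums of squares SS_{a-1}
  sc <- suppressWarnings(autoscale_xy(X, y))
  a_cap <- min(ncomp_max, n - 1L, ncol(sc$X))
  full <- suppressWarnings(fit_pls(sc$X, sc$y, a_cap))
  A <- full$ncomp
  if (A < 1L) stop("no PLS component can be extracted from these data",
                   call. = FALSE)
  ss <- numeric(A + 1L)
  ss[1L] <- sum(sc$y^2)
  for (a in seq_len(A)) {
    res <- sc$y - as.numeric(full$scores[, seq_len(a), drop = FALSE] %*%
                               full$y_loadings[seq_len(a)])
    ss[a + 1L] <- sum(res^2)
  }
  y_sd_full <- sc$scaling_y$sd
  pred <- matrix(NA_real_, n, A, dimnames = list(rownames(X), NULL))
  for (k in seq_len(n_folds)) {
    hold <- which(assignment == k)
    train <- which(assignment != k)
    if (length(train) < 2L)
      stop("a fold leaves fewer than 2 training observations", call. = FALSE)
    m_k <- fit_subset(X[train, , drop = FALSE], y[train], A)
    pk <- predict_per_component(m_k, X[hold, , drop = FALSE])
    if (ncol(pk) < A)  # fold model stopped early: carry its last component
      pk <- cbind(pk, pk[, rep(ncol(pk), A - ncol(pk)), drop = FALSE])
    pred[hold, ] <- pk[, seq_len(A), drop = FALSE]
  }
  press <- colSums(((pred - y) / y_sd_full)^2)
  ratio <- press / ss[seq_len(A)]
  q2 <- 1 - ratio
  q2_cum <- 1 - cumprod(ratio)
  q2_pooled <- 1 - press / ss[1L]
  significant <- ratio < 1
  rec <- if (significant[1L]) max(which(cumsum(!significant) == 0L)) else 0L
  at <- max(rec, 1L)
  structure(list(n_folds = n_folds, fold_assignment = assignment,
                 ncomp_max = A, PRESS = press, Q2 = q2, Q2_cum = q2_cum,
                 Q2_pooled = q2_pooled, significant = significant,
                 recommended_ncomp = rec,
                 cv_predictions = pred[, at],
                 cv_prediction_matrix = pred,
                 SS = ss[seq_len(A)]), class = "cv_result")
}

#' Fold assignments for cross-validation
#'
#' Deterministic interleaved assignment by default (observation i goes to
#' fold ((i-1) mod n_folds) + 1); with a seed, a random balanced shuffle.
#'
#' @param n number of observations.
#' @param n_folds number of folds.
#' @param seed optional seed for a randomized assignment.
#' @return Integer vector of length `n` with values in `1:n_folds`.
#' @export
cv_folds <- function(n, n_folds = 7L, seed = NULL) {
  base <- ((seq_len(n) - 1L) %% n_folds) + 1L
  if (is.null(seed)) return(base)
  with_seed(seed, sample(base))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over %d component(s)\n",
              x$n_folds, x$ncomp_max))
  tab <- data.frame(component = seq_len(x$ncomp_max),
                    PRESS = x$PRESS, Q2 = x$Q2, Q2_cum = x$Q2_cum,
                    significant = x$significant)
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("Recommended number of components: %d\n", x$recommended_ncomp))
  invisible(x)
}

# -- response permutation (Y-scrambling) --------------------------------------

#' Response-permutation (Y-scrambling) internal validation
#'
#' The response is randomly rearranged `n_permutations` times; after each
#' shuffle the PLS model is refit and its R2Y and cross-validated Q2
#' recomputed. Each refit is plotted at x = |Pearson correlation between the
#' permuted and original response|; the unpermuted model sits at x = 1.
#' Least-squares lines through all `n_permutations + 1` points give the
#' R2 and Q2 intercepts at x = 0; the model passes when the R2 intercept is
#' below `intercept_limits[1]` (default 0.4) and the Q2 intercept below
#' `intercept_limits[2]` (default 0.05).
#'
#' @inheritParams cross_validate
#' @param ncomp number of components of the model under test.
#' @param n_permutations number of response shuffles (default 20).
#' @param n_folds folds used for each Q2 recomputation (default 7).
#' @param intercept_limits numeric length-2: R2 and Q2 intercept limits.
#' @param seed seed for the permutation stream (recorded in the result).
#' @return An object of class `permutation_result`: `points` (data.frame
#'   with `correlation`, `R2Y`, `Q2`, `permuted`; the original model is the
#'   last, unpermuted row), `intercept_R2`, `intercept_Q2`, `valid`,
#'   `n_permutations`, `seed`, `intercept_limits`.
#' @export
permutation_validation <- function(X, y, ncomp, n_permutations = 20L,
                                   n_folds = 7L,
                                   intercept_limits = c(0.4, 0.05),
                                   seed = NULL) {
  xy <- as_xy(X, y)
  X <- xy$X; y <- xy$y
  if (stats::sd(y) == 0) stop("constant response cannot be permuted",
                              call. = FALSE)
  if (n_permutations < 2L) stop("need at least 2 permutations", call. = FALSE)
  # the scatter carries the pooled Q2 (1 - PRESS_A/SS0): the flavor whose
  # magnitude permutation plots conventionally show; the product-rule
  # cumulative Q2 explodes downward when forced components all degrade
  eval_once <- function(y_cur) {
    m <- fit_subset(X, y_cur, ncomp)
    cv <- cross_validate(X, y_cur, ncomp_max = m$ncomp, n_folds = n_folds)
    c(R2Y = m$R2Y_cum, Q2 = cv$Q2_pooled[min(ncomp, cv$ncomp_max)])
  }
  perms <- with_seed(seed,
                     replicate(n_permutations, sample.int(length(y)),
                               simplify = FALSE))
  rows <- lapply(perms, function(idx) {
    yp <- y[idx]
    c(correlation = abs(stats::cor(yp, y)), eval_once(yp))
  })
  orig <- c(correlation = 1, eval_once(y))
  pts <- as.data.frame(do.call(rbind, c(rows, list(orig))))
  pts$permuted <- c(rep(TRUE, n_permutations), FALSE)
  fit_r2 <- stats::lm(R2Y ~ correlation, data = pts)
  fit_q2 <- stats::lm(Q2 ~ correlation, data = pts)
  i_r2 <- unname(stats::coef(fit_r2)[1L])
  i_q2 <- unname(stats::coef(fit_q2)[1L])
  structure(list(points = pts, intercept_R2 = i_r2, intercept_Q2 = i_q2,
                 valid = i_r2 < intercept_limits[1L] &&
                   i_q2 < intercept_limits[2L],
                 n_permutations = n_permutations, seed = seed,
                 intercept_limits = intercept_limits),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Response permutation validation (%d permutations)\n",
              x$n_permutations))
  cat(sprintf("  R2 intercept = %.3f (limit %.2f), Q2 intercept = %.3f (limit %.2f)\n",
              x$intercept_R2, x$intercept_limits[1L],
              x$intercept_Q2, x$intercept_limits[2L]))
  cat(sprintf("  valid: %s\n", x$valid))
  invisible(x)
}

# -- external two-half swap validation ----------------------------------------

#' External validation by swapping two halves
#'
#' The dataset is split into two (near-)equal halves. A model is fitted on
#' the first half (scaling refit on that half only) and predicts the second;
#' then the roles are swapped. Each direction reports the root-mean-square
#' error of prediction \eqn{RMSEP = \sqrt{\sum (obs - pred)^2 / N}} in
#' original response units and the external
#' \eqn{Q^2 = 1 - \sum (obs - pred)^2 / \sum (obs - \bar y_{train})^2},
#' attributed to the predicting model ("train" = the model fitted on the
#' train half, "test" = the model fitted on the test half).
#'
#' @inheritParams cross_validate
#' @param ncomp number of components for both half-models.
#' @param split optional assignment: character vector of "train"/"test" per
#'   observation (sizes differing by at most 1). Default: seeded shuffle,
#'   the first half taking the extra observation when n is odd.
#' @param seed seed for the default split.
#' @return An object of class `external_validation_result` with
#'   `split_assignment`, `Q2_train`, `Q2_test`, `RMSEP_train`, `RMSEP_test`,
#'   and a `predictions` data.frame (id, role, observed, predicted).
#' @export
external_swap_validation <- function(X, y, ncomp, split = NULL, seed = NULL) {
  xy <- as_xy(X, y)
  X <- xy$X; y <- xy$y
  n <- nrow(X)
  if (n < 4L) stop("external swap validation needs at least 4 observations",
                   call. = FALSE)
  if (is.null(split)) {
    ord <- with_seed(seed, sample.int(n))
    n_train <- ceiling(n / 2)
    split <- rep("test", n)
    split[ord[seq_len(n_train)]] <- "train"
  }
  split <- as.character(split)
  if (length(split) != n || !all(split %in% c("train", "test")))
    stop("split must label every observation 'train' or 'test'",
         call. = FALSE)
  idx_tr <- which(split == "train")
  idx_te <- which(split == "test")
  if (abs(length(idx_tr) - length(idx_te)) > 1L)
    stop("the two halves may differ by at most one observation",
         call. = FALSE)
  if (length(idx_tr) < 2L || length(idx_te) < 2L)
    stop("each half needs at least 2 observations", call. = FALSE)
  direction <- function(fit_idx, pred_idx) {
    m <- fit_subset(X[fit_idx, , drop = FALSE], y[fit_idx], ncomp)
    pred <- predict(m, X[pred_idx, , drop = FALSE])
    obs <- y[pred_idx]
    list(rmsep = sqrt(sum((obs - pred)^2) / length(obs)),
         q2 = 1 - sum((obs - pred)^2) / sum((obs - mean(y[fit_idx]))^2),
         pred = pred)
  }
  d_train <- direction(idx_tr, idx_te)  # train-half model predicts test half
  d_test <- direction(idx_te, idx_tr)   # test-half model predicts train half
  preds <- data.frame(
    id = c(rownames(X)[idx_te], rownames(X)[idx_tr]),
    predicting_model = c(rep("train", length(idx_te)),
                         rep("test", length(idx_tr))),
    observed = c(y[idx_te], y[idx_tr]),
    predicted = c(d_train$pred, d_test$pred),
    stringsAsFactors = FALSE)
  structure(list(split_assignment = stats::setNames(split, rownames(X)),
                 Q2_train = d_train$q2, Q2_test = d_test$q2,
                 RMSEP_train = d_train$rmsep, RMSEP_test = d_test$rmsep,
                 predictions = preds, ncomp = ncomp),
            class = "external_validation_result")
}

#' @export
print.external_validation_result <- function(x, ...) {
  cat("External two-half swap validation\n")
  cat(sprintf("  train-half model: Q2 = %.3f, RMSEP = %.6g\n",
              x$Q2_train, x$RMSEP_train))
  cat(sprintf("  test-half model:  Q2 = %.3f, RMSEP = %.6g\n",
              x$Q2_test, x$RMSEP_test))
  invisible(x)
}

#' Bundle and serialize a validation report
#'
#' @param cv a [cross_validate()] result (or `NULL`).
#' @param permutation a [permutation_validation()] result (or `NULL`).
#' @param external an [external_swap_validation()] result (or `NULL`).
#' @param path optional path; if `NULL` the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
validation_report_json <- function(cv = NULL, permutation = NULL,
                                   external = NULL, path = NULL) {
  obj <- list(
    cross_validation = if (!is.null(cv)) list(
      n_folds = cv$n_folds, fold_assignment = cv$fold_assignment,
      PRESS = cv$PRESS, Q2 = cv$Q2, Q2_cum = cv$Q2_cum,
      Q2_pooled = cv$Q2_pooled, significant = cv$significant,
      recommended_ncomp = cv$recommended_ncomp),
    permutation = if (!is.null(permutation)) list(
      n_permutations = permutation$n_permutations,
      points = permutation$points,
      intercept_R2 = permutation$intercept_R2,
      intercept_Q2 = permutation$intercept_Q2,
      intercept_limits = permutation$intercept_limits,
      valid = permutation$valid, seed = permutation$seed),
    external = if (!is.null(external)) list(
      split_assignment = as.list(external$split_assignment),
      Q2_train = external$Q2_train, Q2_test = external$Q2_test,
      RMSEP_train = external$RMSEP_train, RMSEP_test = external$RMSEP_test))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                            null = "null", dataframe = "columns"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}
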