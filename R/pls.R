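#' Single-response PLS regression by NIPALS
#'
#' Classical PLS1 on autoscaled data. For each component a, on the current
#' (deflated) blocks X_a, y_a:
#' \enumerate{
#'   \item weight \eqn{w_a \propto X_a' y_a}, normalized to unit length;
#'   \item score \eqn{t_a = X_a w_a};
#'   \item response loading \eqn{c_a = t_a' y_a / t_a' t_a};
#'   \item X loading \eqn{p_a = X_a' t_a / t_a' t_a};
#'   \item deflation \eqn{X_{a+1} = X_a - t_a p_a'},
#'     \eqn{y_{a+1} = y_a - c_a t_a}.
#' }
#' With one response the weight solve is closed-form; no inner iteration is
#' needed. Each weight vector is flipped so its largest-magnitude element is
#' positive (fixes the reflection ambiguity so that loading plots are
#' reproducible). Rotated weights \eqn{W^* = W (P'W)^{-1}} give regression
#' coefficients \eqn{b = W^* c} acting directly on the scaled X.
#'
#' If a component's weight norm falls below `tol` (response exhausted), the
#' fit stops early with a warning and fewer components.
#'
#' @param Xs scaled descriptor matrix (columns named), from [autoscale()].
#' @param ys scaled response vector.
#' @param ncomp number of components A; must not exceed
#'   `min(nrow(Xs) - 1, ncol(Xs))`.
#' @param scaling_x,scaling_y optional [scaling_model]s; when supplied, the
#'   model also carries coefficients and errors in original response units.
#' @param tol weight-norm cutoff for early stopping.
#' @return An object of class `pls_model` with elements `ncomp`, `weights`
#'   (W), `loadings` (P), `y_loadings` (c), `scores` (T),
#'   `rotated_weights` (W*), `coef_scaled`, `coef_raw` (intercept + slopes,
#'   original units; `NULL` without scaling models), `fitted_scaled`,
#'   `fitted` (raw units), `observed`, `ssy_explained` (fraction of scaled-y
#'   sum of squares per component), `R2Y_cum`, `RMSEE`, and the scaling
#'   models.
#' @references Wold, S., Sjostrom, M., Eriksson, L. (2001) PLS-regression: a
#'   basic tool of chemometrics. Chemom. Intell. Lab. Syst. 58, 109-130.
#' @export
fit_pls <- function(Xs, ys, ncomp, scaling_x = NULL, scaling_y = NULL,
                    tol = 1e-12) {
  Xs <- as.matrix(Xs)
  ys <- as.numeric(ys)
  n <- nrow(Xs); p <- ncol(Xs)
  if (length(ys) != n) stop("X and y sizes differ", call. = FALSE)
  if (is.null(colnames(Xs))) colnames(Xs) <- paste0("x", seq_len(p))
  max_a <- min(n - 1L, p)
  if (ncomp < 1L || ncomp > max_a)
    stop(sprintf("ncomp must be in 1..%d (min(n_obs - 1, n_desc))", max_a),
         call. = FALSE)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  cvec <- numeric(0)
  Xa <- Xs; ya <- ys
  ssy_tot <- sum(ys^2)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < tol) {
      warning(sprintf("response exhausted: stopping at %d component(s)",
                      a - 1L), call. = FALSE)
      break
    }
    w <- w / nw
    imax <- which.max(abs(w))
    if (w[imax] < 0) w <- -w
    t_a <- as.numeric(Xa %*% w)
    tt <- sum(t_a^2)
    c_a <- sum(t_a * ya) / tt
    p_a <- crossprod(Xa, t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - c_a * t_a
    W <- cbind(W, w); P <- cbind(P, p_a); Tm <- cbind(Tm, t_a)
    cvec <- c(cvec, c_a)
  }
  A <- ncol(W)
  if (A == 0L) {
    W <- P <- matrix(0, p, 0, dimnames = list(colnames(Xs), NULL))
    fitted_s <- rep(0, n)
    Wstar <- W
    b <- stats::setNames(rep(0, p), colnames(Xs))
    ssy_a <- numeric(0)
  } else {
    comp_names <- paste0("comp", seq_len(A))
    dimnames(W) <- dimnames(P) <- list(colnames(Xs), comp_names)
    dimnames(Tm) <- list(rownames(Xs), comp_names)
    names(cvec) <- comp_names
    Wstar <- W %*% solve(crossprod(P, W))
    dimnames(Wstar) <- dimnames(W)
    b <- stats::setNames(as.numeric(Wstar %*% cvec), colnames(Xs))
    fitted_s <- as.numeric(Tm %*% cvec)
    # variance bookkeeping: component a explains c_a^2 * t_a't_a of sum(ys^2)
    ssy_a <- cvec^2 * colSums(Tm^2) / ssy_tot
  }
  r2y <- sum(ssy_a)
  coef_raw <- NULL
  fitted_raw <- fitted_s
  observed_raw <- ys
  if (!is.null(scaling_y)) {
    fitted_raw <- invert_scaling(scaling_y, fitted_s)
    observed_raw <- invert_scaling(scaling_y, ys)
    if (!is.null(scaling_x)) {
      slopes <- b * scaling_y$sd / scaling_x$sd
      intercept <- scaling_y$mean - sum(slopes * scaling_x$mean)
      coef_raw <- c(`(Intercept)` = unname(intercept), slopes)
    }
  }
  rmsee <- sqrt(sum((fitted_raw - observed_raw)^2) / n)
  structure(list(ncomp = A, descriptor_names = colnames(Xs),
                 X_scaled = Xs,
                 weights = W, loadings = P, y_loadings = cvec,
                 scores = Tm, rotated_weights = Wstar,
                 coef_scaled = b, coef_raw = coef_raw,
                 fitted_scaled = fitted_s, fitted = fitted_raw,
                 observed = observed_raw,
                 ssy_explained = ssy_a, R2Y_cum = r2y, RMSEE = rmsee,
                 scaling_x = scaling_x, scaling_y = scaling_y,
                 n_obs = n), class = "pls_model")
}

#' Fit a PLS model straight from a raw dataset
#'
#' Convenience wrapper: autoscales the descriptor table and response
#' (mean centering + unit variance on both blocks), then runs [fit_pls()].
#'
#' @param table a [descriptor_table].
#' @param response a [response_block].
#' @param ncomp number of PLS components.
#' @param exclude optional compound ids to drop before fitting.
#' @return A [fit_pls()] model carrying both scaling models.
#' @export
pls_qspr <- function(table, response, ncomp, exclude = character()) {
  ds <- exclude_observations(table, response, exclude)
  sc <- autoscale(ds$table, ds$response)
  fit_pls(sc$X, sc$y, ncomp, scaling_x = sc$scaling_x,
          scaling_y = sc$scaling_y)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d component(s), %d observations, %d descriptors\n",
              x$ncomp, x$n_obs, length(x$descriptor_names)))
  cat(sprintf("  R2Y(cum) = %.4f, RMSEE = %.6g\n", x$R2Y_cum, x$RMSEE))
  if (x$ncomp > 0) {
    cat("  per-component SSY fraction:",
        paste(sprintf("%.4f", x$ssy_explained), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict the response for new compounds
#'
#' New descriptor rows are matched to the training descriptors by column
#' name (order-independent); the model's X scaling is applied, the scaled
#' coefficient vector multiplied through, and the result back-transformed
#' to original response units.
#'
#' @param object a [fit_pls()] model fitted with scaling models.
#' @param newdata numeric matrix (or [descriptor_table]) whose columns cover
#'   the model's descriptors; extra columns are ignored with an error only
#'   when required ones are missing.
#' @param ... unused.
#' @return Numeric vector of predictions in original response units.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "descriptor_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)))
    stop("newdata must have named descriptor columns", call. = FALSE)
  extra <- setdiff(colnames(newdata), object$descriptor_names)
  missing <- setdiff(object$descriptor_names, colnames(newdata))
  if (length(missing))
    stop("newdata lacks descriptor(s): ", paste(missing, collapse = ", "),
         if (length(extra)) paste0("; unknown: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  if (is.null(object$scaling_x)) {
    xs <- newdata[, object$descriptor_names, drop = FALSE]
    return(as.numeric(xs %*% object$coef_scaled))
  }
  xs <- apply_scaling(object$scaling_x, newdata)
  yhat_s <- as.numeric(xs %*% object$coef_scaled)
  invert_scaling(object$scaling_y, yhat_s)
}

#' Root-mean-square error of estimation
#'
#' Training-set error in original response units,
#' \eqn{\sqrt{\sum_i (\hat y_i - y_i)^2 / N}} with N the training size.
#' `df_correct = TRUE` switches the denominator to N - 1 - A (the
#' degrees-of-freedom convention of some chemometrics software).
#'
#' @param model a fitted [fit_pls()] model.
#' @param df_correct use N - 1 - A instead of N (default `FALSE`).
#' @return RMSEE, a non-negative scalar.
#' @export
rmsee <- function(model, df_correct = FALSE) {
  res <- model$fitted - model$observed
  denom <- if (df_correct) model$n_obs - 1L - model$ncomp else model$n_obs
  if (denom <= 0) stop("no residual degrees of freedom", call. = FALSE)
  sqrt(sum(res^2) / denom)
}

#' Fraction of response variance explained
#'
#' \eqn{R^2Y = 1 - \sum_i (\hat y_i - y_i)^2 / \sum_i (y_i - \bar y)^2},
#' computed on the training set. Non-decreasing in the number of components
#' on the same data.
#'
#' @param model a fitted [fit_pls()] model.
#' @return R2Y in (-Inf, 1]; 1 for a perfect fit, 0 for the mean model.
#' @export
r2y <- function(model) {
  y <- model$observed
  1 - sum((model$fitted - y)^2) / sum((y - mean(y))^2)
}

#' Combined weight-loading coordinates for the first two components
#'
#' The w x c plot places every descriptor at its rotated-weight coordinates
#' for components 1-2 and the response at its y-loading coordinates
#' (c1, c2); descriptors plotting near the response (and far from the
#' origin) associate positively with it, descriptors opposite associate
#' negatively.
#'
#' @param model a [fit_pls()] model with at least 2 components.
#' @return A data.frame with columns `name`, `role` ("descriptor" or
#'   "response"), `wc1`, `wc2`; `n_desc + 1` rows.
#' @export
wc_coordinates <- function(model) {
  if (model$ncomp < 2L)
    stop("w x c coordinates need at least 2 components", call. = FALSE)
  Ws <- model$rotated_weights
  y_name <- names(model$scaling_y$mean) %||% "y"
  out <- data.frame(name = c(rownames(Ws), y_name),
                    role = c(rep("descriptor", nrow(Ws)), "response"),
                    wc1 = c(Ws[, 1L], model$y_loadings[1L]),
                    wc2 = c(Ws[, 2L], model$y_loadings[2L]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Serialize a fitted PLS model to JSON
#'
#' All matrices, scalings and metadata; [pls_from_json()] restores a model
#' whose predictions match the original exactly.
#'
#' @param model a [fit_pls()] model.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly.
#' @export
pls_to_json <- function(model, path = NULL) {
  mat <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  sm <- function(s) if (is.null(s)) NULL else
    list(mean = as.list(s$mean), sd = as.list(s$sd),
         excluded_zero_variance = s$excluded_zero_variance)
  obj <- list(ncomp = model$ncomp, descriptor_names = model$descriptor_names,
              weights = mat(model$weights), loadings = mat(model$loadings),
              y_loadings = model$y_loadings,
              scores = mat(model$scores),
              rotated_weights = mat(model$rotated_weights),
              coef_scaled = as.list(model$coef_scaled),
              coef_raw = as.list(model$coef_raw),
              fitted = model$fitted, observed = model$observed,
              ssy_explained = model$ssy_explained,
              R2Y_cum = model$R2Y_cum, RMSEE = model$RMSEE,
              n_obs = model$n_obs,
              scaling_x = sm(model$scaling_x), scaling_y = sm(model$scaling_y))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pls_to_json
#' @param json JSON string or path from [pls_to_json()].
#' @export
pls_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  p <- length(o$descriptor_names)
  remat <- function(m, ncol_names) {
    # fromJSON simplifies rectangular row-lists to a matrix already
    if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
    m <- as.matrix(m)
    colnames(m) <- ncol_names
    m
  }
  comp_names <- if (o$ncomp > 0) paste0("comp", seq_len(o$ncomp)) else NULL
  sm <- function(s) if (is.null(s)) NULL else
    scaling_model(unlist(s$mean), unlist(s$sd),
                  unlist(s$excluded_zero_variance) %||% character())
  W <- remat(o$weights, comp_names); rownames(W) <- o$descriptor_names
  P <- remat(o$loadings, comp_names); rownames(P) <- o$descriptor_names
  Ws <- remat(o$rotated_weights, comp_names); rownames(Ws) <- o$descriptor_names
  Tm <- remat(o$scores, comp_names)
  structure(list(ncomp = o$ncomp, descriptor_names = o$descriptor_names,
                 weights = W, loadings = P,
                 y_loadings = stats::setNames(o$y_loadings, comp_names),
                 scores = Tm, rotated_weights = Ws,
                 coef_scaled = stats::setNames(unlist(o$coef_scaled),
                                               o$descriptor_names),
                 coef_raw = if (length(o$coef_raw))
                   unlist(o$coef_raw) else NULL,
                 fitted_scaled = NULL,
                 fitted = o$fitted, observed = o$observed,
                 ssy_explained = stats::setNames(o$ssy_explained, comp_names),
                 R2Y_cum = o$R2Y_cum, RMSEE = o$RMSEE,
                 scaling_x = sm(o$scaling_x), scaling_y = sm(o$scaling_y),
                 n_obs = o$n_obs), class = "pls_model")
}
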