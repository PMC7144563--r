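#' Variable importance in the projection (VIP)
#'
#' For a model with components a = 1..A, unit-norm weight vectors w_a and
#' per-component explained response sums of squares SSY_a,
#' \deqn{VIP_j = \sqrt{p \sum_a w_{ja}^2 SSY_a / \sum_a SSY_a}}
#' with p the number of descriptors. The squared VIPs always average to 1,
#' so descriptors with VIP > 1 carry more than an equal share of the
#' model's explanatory weight and are conventionally called influential.
#'
#' @param model a fitted [fit_pls()] model with at least 1 component.
#' @return An object of class `vip_profile`: data.frame with columns
#'   `descriptor`, `VIP`, `influential` (VIP > 1), sorted by decreasing VIP.
#' @export
vip <- function(model) {
  if (model$ncomp < 1L) stop("model has no components", call. = FALSE)
  ssy <- model$ssy_explained
  if (sum(ssy) <= 0)
    stop("model explains no response variance; VIP undefined", call. = FALSE)
  p <- nrow(model$weights)
  v <- sqrt(p * as.numeric(model$weights^2 %*% ssy) / sum(ssy))
  out <- data.frame(descriptor = rownames(model$weights), VIP = v,
                    influential = v > 1, stringsAsFactors = FALSE)
  out <- out[order(-out$VIP), ]
  rownames(out) <- NULL
  class(out) <- c("vip_profile", "data.frame")
  out
}

#' Contribution of each descriptor to one observation's deviation
#'
#' Explains, in model terms, why one compound differs from a reference
#' group: per descriptor j,
#' \deqn{contribution_j = d_j \sum_a |w^*_{ja}| \, SSY_a / \sum_a SSY_a}
#' where d_j is the observation's autoscaled value minus the mean autoscaled
#' value of the reference group, and the weights are the model's rotated
#' weights averaged across components by explained response variance. The
#' sign follows the deviation: positive means the compound sits above the
#' reference on that descriptor.
#'
#' @param model a fitted [fit_pls()] model (with its X scaling).
#' @param table the [descriptor_table] holding the observation (typically
#'   the training table).
#' @param obs_id compound label to explain.
#' @param reference `"remaining"` (default): all other observations in
#'   `table`; `"mean"`: the whole table including the observation.
#' @return An object of class `contribution_profile`: data.frame with
#'   columns `descriptor`, `deviation` (d_j), `weight`, `contribution`.
#' @export
contribution <- function(model, table, obs_id,
                         reference = c("remaining", "mean")) {
  reference <- match.arg(reference)
  if (model$ncomp < 1L) stop("model has no components", call. = FALSE)
  if (inherits(table, "descriptor_table")) table <- table$values
  if (!obs_id %in% rownames(table))
    stop("unknown observation id: ", obs_id, call. = FALSE)
  xs <- apply_scaling(model$scaling_x, table)
  ref_rows <- if (reference == "remaining")
    setdiff(rownames(xs), obs_id) else rownames(xs)
  if (length(ref_rows) < 1L)
    stop("empty reference group", call. = FALSE)
  d <- xs[obs_id, ] - colMeans(xs[ref_rows, , drop = FALSE])
  ssy <- model$ssy_explained
  wgt <- as.numeric(abs(model$rotated_weights) %*% ssy) / sum(ssy)
  out <- data.frame(descriptor = colnames(xs), deviation = unname(d),
                    weight = wgt, contribution = unname(d) * wgt,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "obs_id") <- obs_id
  attr(out, "reference") <- reference
  class(out) <- c("contribution_profile", "data.frame")
  out
}

#' Observed versus predicted table
#'
#' Pairs each training observation's measured response with the model's
#' fitted value (or, given new blocks, predictions), with residuals and the
#' model's RMSEE attached as an attribute — the tabular form of the
#' observed-vs-estimated scatter.
#'
#' @param model a fitted [fit_pls()] model.
#' @param X,y optional raw blocks to predict instead of the training set.
#' @return data.frame (`id`, `observed`, `predicted`, `residual`) with
#'   attribute `RMSEE`.
#' @export
observed_vs_predicted <- function(model, X = NULL, y = NULL) {
  if (is.null(X) != is.null(y))
    stop("supply both X and y, or neither", call. = FALSE)
  if (is.null(X)) {
    ids <- rownames(model$scores) %||% paste0("obs", seq_len(model$n_obs))
    obs <- model$observed
    pred <- model$fitted
  } else {
    xy <- as_xy(X, y)
    ids <- rownames(xy$X)
    obs <- xy$y
    pred <- predict(model, xy$X)
  }
  out <- data.frame(id = ids, observed = unname(obs),
                    predicted = unname(pred),
                    residual = unname(pred - obs), stringsAsFactors = FALSE)
  attr(out, "RMSEE") <- sqrt(sum(out$residual^2) / nrow(out))
  out
}

#' Score-space and residual-space outlier flags
#'
#' Two complementary distances per observation: Hotelling's T-squared in the
#' model's score space, \eqn{T^2_i = \sum_a t_{ia}^2 / var(t_a)}, against
#' the exact in-sample Beta-based critical value
#' \eqn{((n-1)^2/n)\,Beta_{\alpha}(A/2, (n-A-1)/2)}; and the X-residual
#' distance (row norm of \eqn{X_{scaled} - T P'}) against a moment-matched
#' scaled chi-square critical value. An observation is flagged when either
#' distance exceeds its critical value. The stated confidence is
#' family-wise: each sub-test runs at 1 - (1 - confidence)/2, so the
#' combined false-flag rate on homogeneous data stays at about
#' 1 - confidence. Flagging never removes rows: exclusion is an explicit
#' call to [exclude_observations()].
#'
#' @param model a fitted [fit_pls()] model.
#' @param X optional raw descriptor matrix of new observations to score; by
#'   default the training data are assessed.
#' @param confidence family-wise confidence level in (0, 1); default 0.95.
#' @return An object of class `outlier_flags`: data.frame (`id`, `T2`,
#'   `x_residual`, `flag_T2`, `flag_residual`, `flagged`) with attributes
#'   `T2_crit`, `residual_crit`, `confidence`.
#' @export
outlier_flags <- function(model, X = NULL, confidence = 0.95) {
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)", call. = FALSE)
  if (model$ncomp < 1L) stop("model has no components", call. = FALSE)
  A <- model$ncomp
  n <- model$n_obs
  score_var <- apply(model$scores, 2L, stats::var)
  # residual distances of the training set calibrate the residual criterion
  E_train <- model$X_scaled -
    tcrossprod(model$scores, model$loadings)
  d2_train <- rowSums(E_train^2)
  if (is.null(X)) {
    Tm <- model$scores
    d2 <- d2_train
    ids <- rownames(model$scores) %||% paste0("obs", seq_len(n))
  } else {
    if (inherits(X, "descriptor_table")) X <- X$values
    xs <- apply_scaling(model$scaling_x, X)
    Tm <- xs %*% model$rotated_weights
    E <- xs - tcrossprod(Tm, model$loadings)
    d2 <- rowSums(E^2)
    ids <- rownames(X) %||% paste0("new", seq_len(nrow(X)))
  }
  t2 <- rowSums(sweep(Tm^2, 2L, score_var, "/"))
  conf_each <- 1 - (1 - confidence) / 2
  t2_crit <- if (n - A - 1L > 0L)
    ((n - 1)^2 / n) * stats::qbeta(conf_each, A / 2, (n - A - 1) / 2)
  else Inf
  m <- mean(d2_train)
  v <- stats::var(d2_train)
  residual_crit <- if (is.finite(v) && v > 0 && m > 0) {
    g <- v / (2 * m)
    h <- 2 * m^2 / v
    sqrt(g * stats::qchisq(conf_each, h))
  } else sqrt(m) + sqrt(.Machine$double.eps)
  out <- data.frame(id = ids, T2 = unname(t2),
                    x_residual = sqrt(unname(d2)),
                    flag_T2 = unname(t2 > t2_crit),
                    flag_residual = sqrt(unname(d2)) > residual_crit,
                    stringsAsFactors = FALSE)
  out$flagged <- out$flag_T2 | out$flag_residual
  attr(out, "T2_crit") <- t2_crit
  attr(out, "residual_crit") <- residual_crit
  attr(out, "confidence") <- confidence
  class(out) <- c("outlier_flags", "data.frame")
  out
}
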