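#' Column scaling model (mean centering + unit variance)
#'
#' Stores per-variable means and sample (n-1) standard deviations so that
#' autoscaling can be applied to new data and inverted exactly. Zero-variance
#' columns are recorded by name in `excluded_zero_variance`.
#'
#' @param mean named numeric vector of column means (retained columns).
#' @param sd named numeric vector of column sds; all strictly positive.
#' @param excluded_zero_variance names of dropped zero-variance columns.
#' @return An object of class `scaling_model`.
#' @export
scaling_model <- function(mean, sd, excluded_zero_variance = character()) {
  stopifnot(length(mean) == length(sd))
  if (any(sd <= 0)) stop("stored sd must be > 0", call. = FALSE)
  structure(list(mean = mean, sd = sd,
                 excluded_zero_variance = as.character(excluded_zero_variance)),
            class = "scaling_model")
}

#' Autoscale a dataset (mean centering and unit variance)
#'
#' Centers every retained descriptor column and the response to mean 0 and
#' scales to sample standard deviation 1, the standard pretreatment before
#' PLS so that descriptors measured in incommensurate units (logP, Angstrom^2,
#' degrees C, counts) weigh equally. Zero-variance descriptors are dropped
#' with a warning and recorded; a zero-variance response is an error.
#'
#' @param table a [descriptor_table].
#' @param response a [response_block] aligned with `table`.
#' @return A list: `X` scaled matrix, `y` scaled vector, `scaling_x` and
#'   `scaling_y` ([scaling_model]s).
#' @export
autoscale <- function(table, response) {
  check_alignment(table, response)
  autoscale_xy(table$values, response$values, y_name = response$name)
}

# raw-matrix workhorse; also used for per-fold scaling refits inside CV,
# where warnings about zero-variance columns are suppressed by the caller
autoscale_xy <- function(X, y, y_name = "y") {
  if (nrow(X) < 2L) stop("need at least 2 observations to scale", call. = FALSE)
  if (anyNA(X) || anyNA(y))
    stop("missing values are not supported in modelling calls", call. = FALSE)
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  zero <- sdev <= 0 | !is.finite(sdev)
  if (any(zero))
    warning("dropping zero-variance descriptor(s): ",
            paste(colnames(X)[zero], collapse = ", "), call. = FALSE)
  keep <- !zero
  sm_x <- scaling_model(mu[keep], sdev[keep],
                        excluded_zero_variance = colnames(X)[zero])
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep], "-"),
              2L, sdev[keep], "/")
  y_mu <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd <= 0)
    stop("zero-variance response cannot be scaled", call. = FALSE)
  sm_y <- scaling_model(stats::setNames(y_mu, y_name),
                        stats::setNames(y_sd, y_name))
  list(X = Xs, y = stats::setNames(as.numeric((y - y_mu) / y_sd), names(y)),
       scaling_x = sm_x, scaling_y = sm_y)
}

#' Apply a fitted scaling model to new data
#'
#' Columns are matched by name; columns the model excluded as zero-variance
#' are ignored, and any retained column missing from `x` is an error.
#'
#' @param scaling a [scaling_model].
#' @param x numeric matrix with named columns, or a vector for a
#'   single-variable (response) scaling.
#' @return Scaled matrix (or vector), columns ordered as in the model.
#' @export
apply_scaling <- function(scaling, x) {
  if (is.null(dim(x))) {
    stopifnot(length(scaling$mean) == 1L)
    return((x - scaling$mean) / scaling$sd)
  }
  x <- as.matrix(x)
  need <- names(scaling$mean)
  missing <- setdiff(need, colnames(x))
  if (length(missing))
    stop("missing descriptor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  xs <- x[, need, drop = FALSE]
  sweep(sweep(xs, 2L, scaling$mean, "-"), 2L, scaling$sd, "/")
}

#' Invert a scaling model
#'
#' @param scaling a [scaling_model].
#' @param xs scaled matrix (columns named as in the model) or vector.
#' @return Data in original units.
#' @export
invert_scaling <- function(scaling, xs) {
  if (is.null(dim(xs))) {
    stopifnot(length(scaling$mean) == 1L)
    return(xs * scaling$sd + scaling$mean)
  }
  xs <- as.matrix(xs)[, names(scaling$mean), drop = FALSE]
  sweep(sweep(xs, 2L, scaling$sd, "*"), 2L, scaling$mean, "+")
}

#' Serialize / deserialize a scaling model as JSON
#'
#' @param scaling a [scaling_model].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly.
#' @export
scaling_to_json <- function(scaling, path = NULL) {
  obj <- list(mean = as.list(scaling$mean), sd = as.list(scaling$sd),
              excluded_zero_variance = scaling$excluded_zero_variance)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scaling_to_json
#' @param json JSON string or path produced by [scaling_to_json()].
#' @export
scaling_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  scaling_model(unlist(obj$mean), unlist(obj$sd),
                excluded_zero_variance = unlist(obj$excluded_zero_variance) %||%
                  character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
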