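#' Descriptor table (compounds x physicochemical descriptors)
#'
#' The X block of a QSPR analysis: a numeric matrix of observations
#' (compounds) by named descriptors, with an optional per-descriptor
#' provenance tag recording which software or database supplied the value.
#'
#' @param values numeric matrix, rows = compounds, columns = descriptors.
#'   Row and column names are taken from the matrix unless given explicitly.
#' @param ids character vector of unique compound labels.
#' @param descriptors character vector of unique descriptor labels.
#' @param provenance optional character vector (length = number of
#'   descriptors) of free-text source tags.
#'
#' @return An object of class `descriptor_table`: a list with elements
#'   `values` (the dimnamed matrix) and `provenance`.
#' @seealso [response_block()], [read_dataset()], [autoscale()]
#' @export
descriptor_table <- function(values, ids = rownames(values),
                             descriptors = colnames(values),
                             provenance = NULL) {
  force(ids); force(descriptors)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(ids)) stop("observation ids are required", call. = FALSE)
  if (is.null(descriptors)) stop("descriptor names are required", call. = FALSE)
  ids <- as.character(ids)
  descriptors <- as.character(descriptors)
  if (nrow(values) != length(ids) || ncol(values) != length(descriptors))
    stop("matrix dimensions do not match id/descriptor counts", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate observation id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(descriptors))
    stop("duplicate descriptor name(s): ",
         paste(unique(descriptors[duplicated(descriptors)]), collapse = ", "),
         call. = FALSE)
  if (nrow(values) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (ncol(values) < 1L) stop("need at least 1 descriptor", call. = FALSE)
  if (any(is.infinite(values)))
    stop("non-finite descriptor value(s); only NA marks missing", call. = FALSE)
  if (!is.null(provenance)) {
    provenance <- as.character(provenance)
    if (length(provenance) != length(descriptors))
      stop("provenance length must equal descriptor count", call. = FALSE)
    names(provenance) <- descriptors
  }
  dimnames(values) <- list(ids, descriptors)
  structure(list(values = values, provenance = provenance),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("Descriptor table: %d compounds x %d descriptors\n",
              nrow(x$values), ncol(x$values)))
  cat("Descriptors:", paste(utils::head(colnames(x$values), 6L),
                            collapse = ", "),
      if (ncol(x$values) > 6L) "...", "\n")
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

#' Response block (one permeability response per compound)
#'
#' The Y column of a QSPR model: the measured response (apparent
#' permeability or cumulative permeation at a fixed sampling time), aligned
#' to the compound labels of a [descriptor_table()].
#'
#' @param values numeric vector of responses.
#' @param ids compound labels, same label space as the descriptor table.
#' @param name response label, e.g. `"P_app"`, `"P_2h"`.
#' @param check_nonneg permeability responses must be non-negative; set
#'   `FALSE` for already-transformed responses.
#'
#' @return An object of class `response_block`.
#' @export
response_block <- function(values, ids = names(values), name = "P_app",
                           check_nonneg = TRUE) {
  force(ids)  # capture before coercion strips names
  values <- as.numeric(values)
  if (is.null(ids)) stop("observation ids are required", call. = FALSE)
  ids <- as.character(ids)
  if (length(values) != length(ids))
    stop("response length does not match id count", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate observation id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(is.infinite(values)))
    stop("non-finite response value(s)", call. = FALSE)
  if (check_nonneg && any(values < 0, na.rm = TRUE))
    stop("permeability responses must be non-negative", call. = FALSE)
  names(values) <- ids
  structure(list(values = values, name = name), class = "response_block")
}

#' @export
print.response_block <- function(x, ...) {
  cat(sprintf("Response block '%s': %d observations, range [%g, %g]\n",
              x$name, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

check_alignment <- function(table, response) {
  if (!identical(rownames(table$values), names(response$values)))
    stop("descriptor table and response block ids do not align", call. = FALSE)
  invisible(TRUE)
}

#' Read a compounds x descriptors table with its response column
#'
#' Reads a delimited text file (comma by default, tab accepted) with a header
#' row, compound ids in the first column, a numeric descriptor body, and one
#' response column named `response_name`. Row order is preserved.
#'
#' @param path path to the delimited file, UTF-8.
#' @param response_name name of the response column to split off.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#'
#' @return A list with components `table` ([descriptor_table]) and
#'   `response` ([response_block]).
#' @export
read_dataset <- function(path, response_name, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8",
                          comment.char = "")
  if (ncol(df) < 3L)
    stop("expected an id column, at least one descriptor and a response",
         call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate observation id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  body <- df[, -1L, drop = FALSE]
  if (!response_name %in% colnames(body))
    stop("response column '", response_name, "' not found", call. = FALSE)
  num <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    cell <- body[[j]]
    conv <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(conv) & !is.na(cell) &
                   !cell %in% c("", "NA", "na", "NaN"))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   cell[bad[1L]], ids[bad[1L]], colnames(body)[j]),
           call. = FALSE)
    num[, j] <- conv
  }
  y <- num[, response_name]
  X <- num[, setdiff(colnames(num), response_name), drop = FALSE]
  list(table = descriptor_table(X),
       response = response_block(y, ids = ids, name = response_name))
}

#' Write a descriptor table and response to delimited text
#'
#' Inverse of [read_dataset()]: id column first, descriptors, then the
#' response column (named after the response block). Full numeric precision.
#'
#' @param table a [descriptor_table].
#' @param response a [response_block] aligned with `table`.
#' @param path output path.
#' @param sep field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(table, response, path, sep = ",") {
  check_alignment(table, response)
  df <- data.frame(compound = rownames(table$values),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[[response$name]] <- unname(response$values)
  # quote everything: descriptor labels may contain the field separator
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = sep, quote = TRUE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove observations from a dataset
#'
#' Drops the named compounds from both the descriptor table and the response
#' block consistently; the inputs are untouched (copy semantics). Exclusion
#' is always an explicit user action — outlier flags never remove rows.
#'
#' @param table a [descriptor_table].
#' @param response a [response_block] aligned with `table`.
#' @param ids compound labels to drop; every id must be present. An empty
#'   vector returns the dataset unchanged.
#' @return A list with the reduced `table` and `response`.
#' @export
exclude_observations <- function(table, response, ids) {
  check_alignment(table, response)
  ids <- as.character(ids)
  if (length(ids) == 0L) return(list(table = table, response = response))
  missing <- setdiff(ids, rownames(table$values))
  if (length(missing))
    stop("unknown observation id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- setdiff(rownames(table$values), ids)
  list(table = descriptor_table(table$values[keep, , drop = FALSE],
                                provenance = table$provenance),
       response = response_block(response$values[keep],
                                 name = response$name, check_nonneg = FALSE))
}
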