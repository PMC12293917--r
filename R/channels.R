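#' Shannon channel: conditional table P(y|x)
#'
#' A row-stochastic matrix; row `i`, column `j` holds `P(y_j | x_i)`.
#'
#' @param table numeric matrix with entries in `[0, 1]` and rows summing to
#'   one within `1e-9`.
#' @param x_labels,y_labels input/output alphabet labels; default to
#'   dimnames or `x1.../y1...`.
#' @return an object of class `shannon_channel`.
#' @export
shannon_channel <- function(table, x_labels = NULL, y_labels = NULL) {
  table <- as.matrix(table)
  if (is.null(x_labels)) x_labels <- rownames(table) %||% paste0("x", seq_len(nrow(table)))
  if (is.null(y_labels)) y_labels <- colnames(table) %||% paste0("y", seq_len(ncol(table)))
  x_labels <- as.character(x_labels); y_labels <- as.character(y_labels)
  if (length(x_labels) != nrow(table) || length(y_labels) != ncol(table)) {
    .stop_class("label lengths do not match table dimensions", "infoeff_alphabet_error")
  }
  if (any(table < 0) || any(table > 1 + 1e-12)) {
    .stop_class("channel entries must lie in [0, 1]", "infoeff_invalid_channel")
  }
  rs <- rowSums(table)
  if (any(abs(rs - 1) > 1e-9)) {
    .stop_class("channel rows must each sum to 1", "infoeff_invalid_channel")
  }
  dimnames(table) <- list(x_labels, y_labels)
  structure(list(x_labels = x_labels, y_labels = y_labels, table = table),
            class = "shannon_channel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.shannon_channel <- function(x, ...) {
  cat("Shannon channel P(y|x):", length(x$x_labels), "x", length(x$y_labels), "\n")
  print(x$table)
  invisible(x)
}

#' Joint, output-marginal and posterior tables of a channel
#'
#' @param channel a `shannon_channel`.
#' @param source a `discrete_distribution` on the channel's input alphabet.
#' @return `joint_distribution()`: matrix `P(x_i, y_j)`; `marginal_y()`: the
#'   output distribution as a `discrete_distribution`; `posterior_x()`:
#'   matrix with column `j` equal to `P(x | y_j)` (columns with zero output
#'   probability are left as zero).
#' @export
joint_distribution <- function(channel, source) {
  .check_labels(channel$x_labels, source$labels)
  source$probs * channel$table
}

#' @rdname joint_distribution
#' @export
marginal_y <- function(channel, source) {
  discrete_distribution(colSums(joint_distribution(channel, source)),
                        channel$y_labels)
}

#' @rdname joint_distribution
#' @export
posterior_x <- function(channel, source) {
  jnt <- joint_distribution(channel, source)
  py <- colSums(jnt)
  post <- jnt
  pos <- py > 0
  post[, pos] <- sweep(jnt[, pos, drop = FALSE], 2, py[pos], "/")
  post[, !pos] <- 0
  post
}

#' Semantic channel: truth-function table T(theta_j|x)
#'
#' Membership grades of each `x` in the fuzzy set theta_j associated with
#' label `y_j`. Entries lie in `[0, 1]`; rows and columns are not normalized
#' (a column may be a tautology of all ones).
#'
#' @param table numeric matrix of truth values in `[0, 1]`.
#' @param x_labels,theta_labels alphabet / label identifiers.
#' @param params optional per-label parameter records (e.g. center/width of
#'   Gaussian truth functions), kept as metadata.
#' @return an object of class `semantic_channel`.
#' @export
semantic_channel <- function(table, x_labels = NULL, theta_labels = NULL,
                             params = NULL) {
  table <- as.matrix(table)
  if (is.null(x_labels)) x_labels <- rownames(table) %||% paste0("x", seq_len(nrow(table)))
  if (is.null(theta_labels)) theta_labels <- colnames(table) %||% paste0("theta", seq_len(ncol(table)))
  x_labels <- as.character(x_labels); theta_labels <- as.character(theta_labels)
  if (length(x_labels) != nrow(table) || length(theta_labels) != ncol(table)) {
    .stop_class("label lengths do not match table dimensions", "infoeff_alphabet_error")
  }
  if (any(table < 0) || any(table > 1 + 1e-12)) {
    .stop_class("truth values must lie in [0, 1]", "infoeff_invalid_channel")
  }
  dimnames(table) <- list(x_labels, theta_labels)
  structure(list(x_labels = x_labels, theta_labels = theta_labels,
                 table = table, params = params),
            class = "semantic_channel")
}

#' @export
print.semantic_channel <- function(x, ...) {
  cat("Semantic channel T(theta|x):", length(x$x_labels), "x",
      length(x$theta_labels), "\n")
  print(x$table)
  invisible(x)
}

#' Likelihood family: columns P(x|theta_j)
#'
#' One model likelihood column per label; each column is a distribution over
#' the input alphabet.
#'
#' @param columns numeric matrix; column `j` is `P(x | theta_j)` and sums to
#'   one within `1e-9`.
#' @param x_labels,theta_labels alphabet / label identifiers.
#' @return an object of class `likelihood_family`.
#' @export
likelihood_family <- function(columns, x_labels = NULL, theta_labels = NULL) {
  columns <- as.matrix(columns)
  if (is.null(x_labels)) x_labels <- rownames(columns) %||% paste0("x", seq_len(nrow(columns)))
  if (is.null(theta_labels)) theta_labels <- colnames(columns) %||% paste0("theta", seq_len(ncol(columns)))
  x_labels <- as.character(x_labels); theta_labels <- as.character(theta_labels)
  if (any(columns < 0)) {
    .stop_class("likelihood entries must be nonnegative", "infoeff_invalid_channel")
  }
  cs <- colSums(columns)
  if (any(abs(cs - 1) > 1e-9)) {
    .stop_class("likelihood columns must each sum to 1", "infoeff_invalid_channel")
  }
  dimnames(columns) <- list(x_labels, theta_labels)
  structure(list(x_labels = x_labels, theta_labels = theta_labels,
                 columns = columns),
            class = "likelihood_family")
}

#' @export
print.likelihood_family <- function(x, ...) {
  cat("Likelihood family P(x|theta):", length(x$x_labels), "x",
      length(x$theta_labels), "\n")
  print(x$columns)
  invisible(x)
}

## ---- TSV I/O for tables ---------------------------------------------------

.read_table_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  x_labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  list(x_labels = x_labels, col_labels = colnames(df)[-1], table = m)
}

.write_table_tsv <- function(table, x_labels, col_labels, path, first = "x") {
  df <- data.frame(x_labels, table, check.names = FALSE)
  colnames(df) <- c(first, col_labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write conditional tables as TSV
#'
#' Header row carries the y/theta labels; the first column the x labels.
#'
#' @param path file path.
#' @return the corresponding channel object; writers return `path` invisibly.
#' @export
read_channel_tsv <- function(path) {
  t <- .read_table_tsv(path)
  shannon_channel(t$table, t$x_labels, t$col_labels)
}

#' @rdname read_channel_tsv
#' @export
read_truth_tsv <- function(path) {
  t <- .read_table_tsv(path)
  semantic_channel(t$table, t$x_labels, t$col_labels)
}

#' @rdname read_channel_tsv
#' @export
read_likelihood_tsv <- function(path) {
  t <- .read_table_tsv(path)
  likelihood_family(t$table, t$x_labels, t$col_labels)
}

#' @rdname read_channel_tsv
#' @param x a `shannon_channel`, `semantic_channel` or `likelihood_family`.
#' @export
write_table_tsv <- function(x, path) {
  if (inherits(x, "shannon_channel")) {
    .write_table_tsv(x$table, x$x_labels, x$y_labels, path)
  } else if (inherits(x, "semantic_channel")) {
    .write_table_tsv(x$table, x$x_labels, x$theta_labels, path)
  } else if (inherits(x, "likelihood_family")) {
    .write_table_tsv(x$columns, x$x_labels, x$theta_labels, path)
  } else {
    .stop_class("unsupported object for TSV serialization", "infoeff_io_error")
  }
}
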