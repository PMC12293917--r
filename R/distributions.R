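#' Discrete probability distribution over a labeled alphabet
#'
#' A finite probability vector with unique labels. Probabilities must be
#' nonnegative and sum to one within `1e-9`; no silent renormalization is
#' performed (use [renormalize()] explicitly).
#'
#' @param probs numeric vector of probabilities.
#' @param labels character vector of unique alphabet labels; defaults to
#'   `names(probs)` or `x1, x2, ...`.
#' @return an object of class `discrete_distribution` with fields `labels`
#'   and `probs`.
#' @examples
#' discrete_distribution(c(0.3, 0.7), c("a", "b"))
#' @export
discrete_distribution <- function(probs, labels = NULL) {
  if (is.null(labels)) {
    labels <- if (!is.null(names(probs))) names(probs) else paste0("x", seq_along(probs))
  }
  probs <- as.numeric(probs)
  labels <- as.character(labels)
  if (length(labels) != length(probs)) {
    .stop_class("labels and probs must have equal length", "infoeff_alphabet_error")
  }
  if (anyDuplicated(labels)) {
    .stop_class("alphabet labels must be unique", "infoeff_alphabet_error")
  }
  if (any(probs < 0)) {
    .stop_class("probabilities must be nonnegative", "infoeff_invalid_distribution")
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    .stop_class(sprintf("probabilities sum to %.12g, not 1", sum(probs)),
                "infoeff_invalid_distribution")
  }
  structure(list(labels = labels, probs = probs), class = "discrete_distribution")
}

#' @export
print.discrete_distribution <- function(x, ...) {
  cat("Discrete distribution over", length(x$labels), "labels\n")
  print(stats::setNames(x$probs, x$labels))
  invisible(x)
}

#' @export
length.discrete_distribution <- function(x) length(x$probs)

#' Renormalize a nonnegative weight vector into a distribution
#'
#' @param x numeric vector of nonnegative weights, or a
#'   `discrete_distribution` whose probabilities should be rescaled.
#' @param labels optional labels when `x` is a bare vector.
#' @return a `discrete_distribution`.
#' @export
renormalize <- function(x, labels = NULL) {
  if (inherits(x, "discrete_distribution")) {
    labels <- x$labels
    x <- x$probs
  }
  s <- sum(x)
  if (s <= 0) .stop_class("cannot renormalize: total mass is zero", "infoeff_invalid_distribution")
  discrete_distribution(x / s, labels)
}

#' Shannon entropy of a discrete distribution
#'
#' @param source a `discrete_distribution`.
#' @param unit `"bits"` (default) or `"nats"`.
#' @return entropy H(X).
#' @export
shannon_entropy <- function(source, unit = c("bits", "nats")) {
  unit <- .match_unit(unit)
  .entropy(source$probs, unit)
}

#' KL divergence between two distributions on the same alphabet
#'
#' `KL(p || q)` with the conventions `0 log 0 := 0` and positive mass on a
#' zero of `q` giving `+Inf`.
#'
#' @param p,q `discrete_distribution` objects with identical labels, or bare
#'   probability vectors of equal length.
#' @param unit `"bits"` (default) or `"nats"`.
#' @return the divergence, a nonnegative number (possibly `Inf`).
#' @export
kl_divergence <- function(p, q, unit = c("bits", "nats")) {
  unit <- .match_unit(unit)
  if (inherits(p, "discrete_distribution")) {
    if (inherits(q, "discrete_distribution") && !identical(p$labels, q$labels)) {
      .stop_class("distributions are on different alphabets", "infoeff_alphabet_error")
    }
    p <- p$probs
  }
  if (inherits(q, "discrete_distribution")) q <- q$probs
  .kl(p, q, unit)
}

#' Cross-entropy of a model distribution under a data distribution
#'
#' `H(p, q) = -sum_i p_i log q_i`: the mean code length when data distributed
#' as `p` are coded with a model `q`. Rises as `p` disperses relative to `q`.
#'
#' @inheritParams kl_divergence
#' @return cross-entropy in the requested unit; `+Inf` if `p` has mass where
#'   `q` is zero.
#' @export
cross_entropy <- function(p, q, unit = c("bits", "nats")) {
  unit <- .match_unit(unit)
  if (inherits(p, "discrete_distribution")) p <- p$probs
  if (inherits(q, "discrete_distribution")) q <- q$probs
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  -sum(p[pos] * .ilog(q[pos], unit))
}

.check_labels <- function(a, b, what = "alphabet") {
  if (!identical(as.character(a), as.character(b))) {
    .stop_class(paste0(what, " labels do not match"), "infoeff_alphabet_error")
  }
}

## ---- file I/O -------------------------------------------------------------

#' Read / write a distribution as TSV
#'
#' Two tab-separated columns: `label`, `prob`. A header row is required.
#'
#' @param path file path.
#' @return `read_distribution_tsv()` returns a `discrete_distribution`;
#'   `write_distribution_tsv()` returns `path` invisibly.
#' @export
read_distribution_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  discrete_distribution(df[[2]], df[[1]])
}

#' @rdname read_distribution_tsv
#' @param d a `discrete_distribution`.
#' @export
write_distribution_tsv <- function(d, path) {
  utils::write.table(data.frame(label = d$labels, prob = d$probs),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' JSON round-trip of probability objects
#'
#' Serializes distributions, channels, truth tables and likelihood families
#' to a small JSON object with a `type` tag, and reads them back.
#'
#' @param x an infoeff probability object.
#' @param path file path.
#' @return `write_prob_json()` returns `path` invisibly; `read_prob_json()`
#'   the reconstructed object.
#' @export
write_prob_json <- function(x, path) {
  obj <- if (inherits(x, "discrete_distribution")) {
    list(type = "discrete_distribution", labels = x$labels, probs = x$probs)
  } else if (inherits(x, "shannon_channel")) {
    list(type = "shannon_channel", x_labels = x$x_labels, y_labels = x$y_labels,
         table = x$table)
  } else if (inherits(x, "semantic_channel")) {
    list(type = "semantic_channel", x_labels = x$x_labels,
         theta_labels = x$theta_labels, table = x$table)
  } else if (inherits(x, "likelihood_family")) {
    list(type = "likelihood_family", x_labels = x$x_labels,
         theta_labels = x$theta_labels, columns = x$columns)
  } else {
    .stop_class("unsupported object for JSON serialization", "infoeff_io_error")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_prob_json
#' @export
read_prob_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- function(m) matrix(as.numeric(t(m)), nrow = nrow(m), byrow = TRUE)
  switch(obj$type,
    discrete_distribution = discrete_distribution(obj$probs, obj$labels),
    shannon_channel = shannon_channel(tab(obj$table), obj$x_labels, obj$y_labels),
    semantic_channel = semantic_channel(tab(obj$table), obj$x_labels, obj$theta_labels),
    likelihood_family = likelihood_family(tab(obj$columns), obj$x_labels, obj$theta_labels),
    .stop_class(paste("unknown type:", obj$type), "infoeff_io_error"))
}
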