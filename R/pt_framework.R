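#' Logical probability of each label
#'
#' The logical probability `T(theta_j)` is the expectation of the truth
#' function under the source: `T(theta_j) = sum_i P(x_i) T(theta_j|x_i)`.
#' It plays the role of a partition function and of a regularization term;
#' unlike statistical label probabilities, the logical probabilities of a
#' label set may sum to more than one (a tautology has logical probability 1).
#'
#' @param sc a `semantic_channel`.
#' @param source a `discrete_distribution` on the same x alphabet.
#' @return named numeric vector `T(theta_j)`, each in `[0, 1]`.
#' @export
logical_probability <- function(sc, source) {
  .check_labels(sc$x_labels, source$labels)
  stats::setNames(as.numeric(crossprod(sc$table, source$probs)), sc$theta_labels)
}

#' Semantic Bayes prediction
#'
#' Combines a truth function with the source prior to predict
#' `P(x|theta_j) = T(theta_j|x) P(x) / T(theta_j)`.
#'
#' @inheritParams logical_probability
#' @param j label index or label name.
#' @return a `discrete_distribution` over x.
#' @export
semantic_bayes_predict <- function(sc, source, j) {
  .check_labels(sc$x_labels, source$labels)
  if (is.character(j)) j <- match(j, sc$theta_labels)
  tj <- sum(sc$table[, j] * source$probs)
  if (tj <= 0) {
    .stop_class("label has empty extension under this source (T(theta_j) = 0)",
                "infoeff_empty_extension")
  }
  discrete_distribution(sc$table[, j] * source$probs / tj, source$labels)
}

#' Model posterior columns P(x|theta_j) of a constraint
#'
#' For a `likelihood_family` these are its columns; for a `semantic_channel`
#' they are the semantic Bayes predictions under `source`.
#'
#' @param constraint a `semantic_channel` or `likelihood_family`.
#' @param source the source distribution.
#' @return matrix with column `j` equal to `P(x|theta_j)`.
#' @export
model_posteriors <- function(constraint, source) {
  if (inherits(constraint, "likelihood_family")) {
    .check_labels(constraint$x_labels, source$labels)
    return(constraint$columns)
  }
  if (!inherits(constraint, "semantic_channel")) {
    .stop_class("constraint must be a semantic_channel or likelihood_family",
                "infoeff_invalid_channel")
  }
  .check_labels(constraint$x_labels, source$labels)
  tt <- logical_probability(constraint, source)
  if (any(tt <= 0)) {
    .stop_class("some label has empty extension under this source",
                "infoeff_empty_extension")
  }
  sweep(constraint$table * source$probs, 2, tt, "/")
}

#' Prediction ratio matrix m_ij
#'
#' `m_ij = T(theta_j|x_i) / T(theta_j) = P(x_i|theta_j) / P(x_i)`: how much
#' label `y_j` amplifies or attenuates the prior probability of `x_i`.
#' Where `P(x_i) = 0` (likelihood form) the ratio is undefined and set to 1;
#' such rows never contribute to information sums.
#'
#' @inheritParams model_posteriors
#' @return matrix of prediction ratios, rows = x, columns = labels.
#' @export
prediction_ratio <- function(constraint, source) {
  if (inherits(constraint, "semantic_channel")) {
    tt <- logical_probability(constraint, source)
    if (any(tt <= 0)) {
      .stop_class("some label has empty extension under this source",
                  "infoeff_empty_extension")
    }
    return(sweep(constraint$table, 2, tt, "/"))
  }
  .check_labels(constraint$x_labels, source$labels)
  m <- constraint$columns / source$probs
  m[source$probs == 0, ] <- 1
  m
}

#' Convert between truth values and distortions
#'
#' Truth values and distortion (loss) values are linked by
#' `T = exp(-d)`, `d = -ln T`. `T = 0` maps to `+Inf` distortion.
#'
#' @param truth truth values in `[0, 1]`.
#' @param distortion nonnegative distortions.
#' @return the converted vector (same shape as the input).
#' @export
truth_to_distortion <- function(truth) {
  if (any(truth < 0 | truth > 1)) {
    .stop_class("truth values must lie in [0, 1]", "infoeff_invalid_channel")
  }
  -log(truth)
}

#' @rdname truth_to_distortion
#' @export
distortion_to_truth <- function(distortion) {
  if (any(distortion < 0)) {
    .stop_class("distortions must be nonnegative", "infoeff_invalid_channel")
  }
  exp(-distortion)
}

#' Truth functions from a Shannon channel by Logical Bayesian Inference
#'
#' The optimal truth function is proportional to the transition probability
#' column: `T*(theta_j|x) = P(y_j|x) / max_x P(y_j|x)`, scaled so its maximum
#' is exactly 1 (the fuzzy-membership convention).
#'
#' @param ch a `shannon_channel`.
#' @param j column index or label; if missing, all columns are converted and
#'   a `semantic_channel` is returned.
#' @return numeric truth column, or a `semantic_channel` when `j` is missing.
#' @export
lbi_truth_from_channel <- function(ch, j) {
  if (missing(j)) {
    cols <- vapply(seq_along(ch$y_labels),
                   function(k) lbi_truth_from_channel(ch, k),
                   numeric(length(ch$x_labels)))
    return(semantic_channel(cols, ch$x_labels, ch$y_labels))
  }
  if (is.character(j)) j <- match(j, ch$y_labels)
  col <- ch$table[, j]
  m <- max(col)
  if (m <= 0) {
    .stop_class("channel column is identically zero; label never occurs",
                "infoeff_undefined_label")
  }
  col / m
}

#' Amount of semantic information of a single (x, label) pair
#'
#' `I(x_i; theta_j) = log[T(theta_j|x_i) / T(theta_j)]`: positive when the
#' truth value exceeds the logical probability (an informative, correct
#' prediction), negative when below it.
#'
#' @inheritParams logical_probability
#' @param i x index or label.
#' @param j label index or name.
#' @param unit `"bits"` (default) or `"nats"`.
#' @return information amount; `-Inf` when the truth value is 0.
#' @export
info_amount <- function(sc, source, i, j, unit = c("bits", "nats")) {
  unit <- .match_unit(unit)
  .check_labels(sc$x_labels, source$labels)
  if (is.character(i)) i <- match(i, sc$x_labels)
  if (is.character(j)) j <- match(j, sc$theta_labels)
  tj <- sum(sc$table[, j] * source$probs)
  if (tj <= 0) {
    .stop_class("label has empty extension under this source", "infoeff_empty_extension")
  }
  .ilog(sc$table[i, j] / tj, unit)
}

#' Gaussian truth function bank
#'
#' Builds a `semantic_channel` of Gaussian-shaped truth functions
#' `T(theta_j|x) = exp(-(x - c_j)^2 / (2 w_j^2))` over a numeric grid: the
#' standard fuzzy representation of "x is near c_j".
#'
#' @param x numeric grid of instance values.
#' @param centers,widths numeric vectors (recycled to the same length).
#' @param labels optional label names.
#' @return a `semantic_channel` with `params` holding centers and widths.
#' @export
gaussian_truth_bank <- function(x, centers, widths, labels = NULL) {
  k <- max(length(centers), length(widths))
  centers <- rep_len(centers, k); widths <- rep_len(widths, k)
  if (any(widths <= 0)) .stop_class("widths must be positive", "infoeff_invalid_channel")
  tab <- vapply(seq_len(k),
                function(j) exp(-(x - centers[j])^2 / (2 * widths[j]^2)),
                numeric(length(x)))
  if (is.null(labels)) labels <- paste0("y", seq_len(k))
  semantic_channel(tab, as.character(x), labels,
                   params = data.frame(label = labels, center = centers,
                                       width = widths))
}
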