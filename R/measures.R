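#' Shannon mutual information of a source and channel
#'
#' `I(X;Y) = sum_ij P(x_i, y_j) log[P(x_i|y_j) / P(x_i)]` with the output
#' marginal computed from the joint and the `0 log 0 := 0` convention.
#'
#' @param source a `discrete_distribution`.
#' @param channel a `shannon_channel` on the same x alphabet.
#' @param unit `"bits"` (default) or `"nats"`.
#' @return nonnegative mutual information.
#' @export
shannon_mi <- function(source, channel, unit = c("bits", "nats")) {
  unit <- .match_unit(unit)
  jnt <- joint_distribution(channel, source)
  py <- colSums(jnt)
  tot <- 0
  for (j in seq_along(py)) {
    if (py[j] == 0) next
    pos <- jnt[, j] > 0
    tot <- tot + sum(jnt[pos, j] *
                       .ilog(channel$table[pos, j] / py[j], unit))
  }
  max(tot, 0)
}

# -Inf-aware weighted sum of log(m) terms over the joint.
.semantic_sum <- function(jnt, m, unit) {
  pos <- jnt > 0
  if (any(pos & m == 0)) {
    .warn_class("positive joint mass on zero prediction ratio: semantic information is -Inf",
                "infoeff_infinite_information")
    return(-Inf)
  }
  sum(jnt[pos] * .ilog(m[pos], unit))
}

#' Semantic mutual information
#'
#' `G = I(X;Y_theta) = sum_ij P(x_i, y_j) log m_ij` with the prediction
#' ratio `m_ij = T(theta_j|x_i)/T(theta_j) = P(x_i|theta_j)/P(x_i)`. G is the
#' average code length saved by the semantic prediction; it can be negative
#' for bad predictions and never exceeds the Shannon mutual information.
#'
#' @inheritParams shannon_mi
#' @param constraint a `semantic_channel` or `likelihood_family` whose labels
#'   align with the channel's output alphabet.
#' @return semantic mutual information (possibly `-Inf`, with a warning).
#' @export
semantic_mi <- function(source, channel, constraint, unit = c("bits", "nats")) {
  unit <- .match_unit(unit)
  jnt <- joint_distribution(channel, source)
  m <- prediction_ratio(constraint, source)
  .semantic_sum(jnt, m, unit)
}

#' Semantic conditional entropy H(X|Y_theta)
#'
#' The mean code length of x under the model posteriors:
#' `H(X|Y_theta) = -sum_ij P(x_i, y_j) log P(x_i|theta_j)`. This is the
#' quantity usually reported as variational free energy once the latent prior
#' matches the channel marginal.
#'
#' @inheritParams semantic_mi
#' @return entropy in the requested unit (`+Inf` if the model gives zero
#'   probability to observed mass).
#' @export
semantic_cond_entropy <- function(source, channel, constraint,
                                  unit = c("bits", "nats")) {
  unit <- .match_unit(unit)
  jnt <- joint_distribution(channel, source)
  px_theta <- model_posteriors(constraint, source)
  pos <- jnt > 0
  if (any(pos & px_theta == 0)) return(Inf)
  -sum(jnt[pos] * .ilog(px_theta[pos], unit))
}

#' Per-label cross-entropy H(X|theta_j)
#'
#' `H(X|theta_j) = -sum_i P(x_i|y_j) log P(x_i|theta_j)`: the coding cost of
#' the actual posterior under the model posterior for one label. Equals the
#' Shannon conditional entropy of the posterior when the two coincide, and
#' grows as the actual posterior disperses relative to the model.
#'
#' @param posterior `P(x|y_j)` as a `discrete_distribution` or vector.
#' @param model `P(x|theta_j)` as a `discrete_distribution` or vector.
#' @param unit `"bits"` (default) or `"nats"`.
#' @return cross-entropy in the requested unit.
#' @export
label_cross_entropy <- function(posterior, model, unit = c("bits", "nats")) {
  cross_entropy(posterior, model, unit)
}

#' Full information and free-energy diagnostics
#'
#' Computes every standing diagnostic for a (source, channel, constraint)
#' triple: Shannon and semantic mutual information `R` and `G`, the entropy
#' decompositions, the variational free energy
#' `F = H(X|Y_theta) + KL(P_Y^+1 || P_Y)` (with `P_Y^+1` the channel output
#' marginal and `P_Y` the supplied latent prior), its negative `F'`, the
#' mean-field variational objective `F#`, the complete-data log-likelihood
#' `Q = -H(X, Y_theta)`, and the divergences `KL(P || P_theta)` and
#' `KL(P_Y^+1 || P_Y)`. The identity `R - G = H(X|Y_theta) - H(X|Y)` holds
#' for every input.
#'
#' @inheritParams semantic_mi
#' @param prior_y the latent prior `P(y)` used inside `F`, `F#` and `Q`;
#'   defaults to the channel output marginal (in which case
#'   `F = H(X|Y_theta)` exactly).
#' @return an object of class `info_report`: a named list of numeric fields.
#' @export
entropy_report <- function(source, channel, constraint, prior_y = NULL,
                           unit = c("bits", "nats")) {
  unit <- .match_unit(unit)
  jnt <- joint_distribution(channel, source)
  py_plus <- colSums(jnt)
  if (is.null(prior_y)) {
    prior_y <- discrete_distribution(py_plus, channel$y_labels)
  }
  .check_labels(channel$y_labels, prior_y$labels, "output alphabet")
  px_theta <- model_posteriors(constraint, source)
  m <- prediction_ratio(constraint, source)

  H_X <- .entropy(source$probs, unit)
  R <- shannon_mi(source, channel, unit)
  H_XgY <- H_X - R
  G <- .semantic_sum(jnt, m, unit)
  H_XgYtheta <- {
    pos <- jnt > 0
    if (any(pos & px_theta == 0)) Inf else -sum(jnt[pos] * .ilog(px_theta[pos], unit))
  }

  # semantic entropy / fuzzy entropy only identified for truth constraints
  if (inherits(constraint, "semantic_channel")) {
    tt <- logical_probability(constraint, source)
    H_Ytheta <- -sum(py_plus[py_plus > 0] * .ilog(tt[py_plus > 0], unit))
    pos <- jnt > 0
    H_YthetagX <- if (any(pos & constraint$table == 0)) Inf else
      -sum(jnt[pos] * .ilog(constraint$table[pos], unit))
  } else {
    H_Ytheta <- NA_real_
    H_YthetagX <- NA_real_
  }

  KL_Yplus_Y <- .kl(py_plus, prior_y$probs, unit)
  p_theta_x <- as.numeric(px_theta %*% prior_y$probs)
  KL_P_Ptheta <- .kl(source$probs, p_theta_x, unit)

  F_vfe <- H_XgYtheta + KL_Yplus_Y
  # Q: complete-data log-likelihood, joint model P(x, y | theta) = P(x|theta_j) P(y_j)
  model_joint <- sweep(px_theta, 2, prior_y$probs, "*")
  pos <- jnt > 0
  Q <- if (any(pos & model_joint == 0)) -Inf else
    sum(jnt[pos] * .ilog(model_joint[pos], unit))
  # F#: mean-field objective, sum_ij P(x_i,y_j) log[P(y_j|x_i) / P(x_i,y_j|theta)]
  F_sharp <- if (any(pos & model_joint == 0)) Inf else
    sum(jnt[pos] * .ilog(channel$table[pos] / model_joint[pos], unit))

  structure(list(
    unit = unit,
    R = R, G = G, RG_diff = R - G, efficiency = if (R > 0) G / R else NA_real_,
    H_X = H_X, H_XgY = H_XgY, H_XgYtheta = H_XgYtheta,
    H_Ytheta = H_Ytheta, H_YthetagX = H_YthetagX,
    F = F_vfe, F_prime = -F_vfe, F_sharp = F_sharp, Q = Q,
    KL_P_Ptheta = KL_P_Ptheta, KL_Yplus_Y = KL_Yplus_Y
  ), class = "info_report")
}

#' @export
print.info_report <- function(x, ...) {
  cat("Information report (", x$unit, ")\n", sep = "")
  flds <- setdiff(names(x), "unit")
  v <- unlist(x[flds])
  print(round(v, 6))
  invisible(x)
}

#' @export
as.data.frame.info_report <- function(x, ...) {
  flds <- setdiff(names(x), "unit")
  as.data.frame(as.list(unlist(x[flds])), check.names = FALSE)
}

#' Serialize an info report
#'
#' @param x an `info_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x[setdiff(names(x), "unit")], path,
                       auto_unbox = TRUE, digits = NA, na = "string")
  invisible(path)
}
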