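#' One Minimum Information Difference (MID) update
#'
#' The alternating-minimization step for the information rate-fidelity
#' problem: with prediction ratios `m_ij` and constraint strength `s`,
#' `P*(y_j|x_i) = P(y_j) m_ij^s / lambda_i`, `lambda_i = sum_j P(y_j) m_ij^s`,
#' followed by the marginal update `P*(y_j) = sum_i P(x_i) P*(y_j|x_i)`.
#' Powers are taken in the log domain so large `s` (up to 40 and beyond)
#' does not overflow; `0^s := 0` for `s > 0` and `0^0 := 1`.
#'
#' @param source a `discrete_distribution`.
#' @param constraint a `semantic_channel` or `likelihood_family` (or a
#'   precomputed prediction-ratio matrix).
#' @param prior_y current latent prior `P(y)`.
#' @param s constraint strength (Lagrange multiplier), `s >= 0` normally;
#'   negative values are accepted experimentally.
#' @return list with `channel` (a `shannon_channel`) and `prior_y` (the
#'   updated `discrete_distribution`).
#' @export
mid_step <- function(source, constraint, prior_y, s) {
  m <- if (is.matrix(constraint)) constraint else prediction_ratio(constraint, source)
  logm <- suppressWarnings(log(m))          # m = 0 -> -Inf, fine in log domain
  if (s == 0) {
    slogm <- matrix(0, nrow(m), ncol(m))    # 0^0 := 1
  } else {
    slogm <- s * logm
    slogm[m == 0] <- -Inf
  }
  logprior <- suppressWarnings(log(prior_y$probs))
  lw <- sweep(slogm, 2, logprior, "+")
  rmax <- apply(lw, 1, max)
  dead <- rmax == -Inf
  if (any(dead & source$probs > 0)) {
    .stop_class("degenerate constraint: some x with positive probability has zero weight on every label",
                "infoeff_degenerate_constraint")
  }
  tab <- exp(lw - ifelse(dead, 0, rmax))
  tab[dead, ] <- rep(prior_y$probs, each = sum(dead))   # unreachable x: neutral row
  ch <- shannon_channel(tab / rowSums(tab), source$labels, prior_y$labels)
  list(channel = ch,
       prior_y = marginal_y(ch, source))
}

.constraint_labels <- function(constraint) {
  if (inherits(constraint, "shannon_channel")) constraint$y_labels else constraint$theta_labels
}

#' Iterate MID updates to a fixed point
#'
#' Repeats [mid_step()] until the latent prior stops changing
#' (`max_j |P^+1(y_j) - P(y_j)| < tol`) or `max_iter` is reached. The
#' objective `R - s G` is non-increasing across iterations.
#'
#' @inheritParams mid_step
#' @param prior_y0 initial prior; default uniform over the constraint labels.
#' @param tol convergence tolerance on the max prior change (default `1e-8`).
#' @param max_iter iteration cap (default 1000).
#' @param trace if `TRUE`, attach a per-iteration data frame of
#'   `(iter, R, G, objective, prior_change)`.
#' @return an `rg_point`: list with `s`, `R`, `G`, `efficiency`, `channel`,
#'   `prior_y`, `iterations`, `converged` (and `trace` if requested).
#' @export
mid_iterate <- function(source, constraint, s, prior_y0 = NULL,
                        tol = 1e-8, max_iter = 1000, trace = FALSE) {
  stopifnot(tol > 0)
  labels <- .constraint_labels(constraint)
  if (is.null(prior_y0)) {
    prior_y0 <- discrete_distribution(rep(1 / length(labels), length(labels)), labels)
  }
  m <- prediction_ratio(constraint, source)
  prior <- prior_y0
  rows <- if (trace) vector("list", max_iter) else NULL
  converged <- FALSE
  it <- 0
  channel <- NULL
  repeat {
    it <- it + 1
    stp <- mid_step(source, m, prior, s)
    channel <- stp$channel
    delta <- max(abs(stp$prior_y$probs - prior$probs))
    if (trace) {
      jnt <- joint_distribution(channel, source)
      R <- shannon_mi(source, channel)
      G <- .semantic_sum(jnt, m, "bits")
      rows[[it]] <- data.frame(iter = it, R = R, G = G,
                               objective = R - s * G, prior_change = delta)
    }
    prior <- stp$prior_y
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  jnt <- joint_distribution(channel, source)
  R <- shannon_mi(source, channel)
  G <- .semantic_sum(jnt, m, "bits")
  out <- structure(list(
    s = s, R = R, G = G,
    efficiency = if (R > 0) G / R else NA_real_,
    channel = channel, prior_y = prior,
    iterations = it, converged = converged
  ), class = "rg_point")
  if (trace) out$trace <- do.call(rbind, rows[seq_len(it)])
  out
}

#' @export
print.rg_point <- function(x, ...) {
  cat(sprintf("R(G) point  s = %g:  R = %.6f bits, G = %.6f bits, G/R = %s (%d iterations%s)\n",
              x$s, x$R, x$G,
              ifelse(is.na(x$efficiency), "NA", sprintf("%.4f", x$efficiency)),
              x$iterations, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' One point of the information rate-fidelity function
#'
#' Runs the MID iteration at strength `s` and evaluates the parametric
#' solution at the converged prior:
#' `G(s) = sum_ij I_ij P(x_i) P(y_j) m_ij^s / Z_i` and
#' `R(s) = s G(s) - sum_i P(x_i) log2 Z_i` with
#' `Z_i = sum_k P(y_k) m_ik^s`. These parametric values agree with the
#' direct mutual-information measures of the returned channel.
#'
#' @inheritParams mid_iterate
#' @return an `rg_point` with additional fields `R_param` and `G_param`.
#' @export
rg_point <- function(source, constraint, s, prior_y0 = NULL,
                     tol = 1e-8, max_iter = 1000) {
  pt <- mid_iterate(source, constraint, s, prior_y0, tol, max_iter)
  m <- prediction_ratio(constraint, source)
  logm <- suppressWarnings(log(m))
  slogm <- if (s == 0) matrix(0, nrow(m), ncol(m)) else {
    tmp <- s * logm; tmp[m == 0] <- -Inf; tmp
  }
  logprior <- suppressWarnings(log(pt$prior_y$probs))
  G_param <- 0; R_sum <- 0
  for (i in seq_len(nrow(m))) {
    if (source$probs[i] == 0) next
    lw <- logprior + slogm[i, ]
    lz <- .logsumexp(lw)
    w <- exp(lw - lz)                       # row of the parametric channel
    pos <- w > 0 & is.finite(logm[i, ])
    G_param <- G_param + source$probs[i] * sum(w[pos] * logm[i, pos] / log(2))
    R_sum <- R_sum + source$probs[i] * lz / log(2)
  }
  pt$G_param <- G_param
  pt$R_param <- s * G_param - R_sum
  pt
}

#' The R(G) rate-fidelity curve over a grid of strengths
#'
#' One [rg_point()] per `s`. The curve is bowl-shaped: `G(s)` is
#' non-decreasing in `s` and `R` is convex in `G`, with slope `dR/dG = s`.
#'
#' @inheritParams mid_iterate
#' @param s_grid sorted numeric vector of strengths (negative values probe
#'   the lying branch, without convergence guarantees).
#' @return an `rg_curve`: list of points with an `as.data.frame` method.
#' @export
rg_curve <- function(source, constraint, s_grid, prior_y0 = NULL,
                     tol = 1e-8, max_iter = 1000) {
  pts <- lapply(s_grid, function(s) {
    tryCatch(rg_point(source, constraint, s, prior_y0, tol, max_iter),
             error = function(e) structure(list(s = s, error = conditionMessage(e)),
                                           class = "rg_point_failure"))
  })
  structure(list(points = pts), class = "rg_curve")
}

#' @export
as.data.frame.rg_curve <- function(x, ...) {
  ok <- !vapply(x$points, inherits, logical(1), "rg_point_failure")
  do.call(rbind, lapply(x$points[ok], function(p) {
    data.frame(s = p$s, R_bits = p$R, G_bits = p$G,
               efficiency = p$efficiency, iterations = p$iterations,
               converged = p$converged)
  }))
}

#' @export
print.rg_curve <- function(x, ...) {
  df <- as.data.frame(x)
  cat("R(G) curve with", nrow(df), "points\n")
  print(df, row.names = FALSE)
  invisible(x)
}
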