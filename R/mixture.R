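#' Gaussian mixture specification
#'
#' Component means, standard deviations and mixing weights for a
#' one-dimensional Gaussian mixture.
#'
#' @param mu,sigma numeric vectors of component means and standard
#'   deviations (`sigma > 0`).
#' @param weights mixing weights (summing to one) or a
#'   `discrete_distribution` over components.
#' @param labels optional component labels (default `y1, y2, ...`).
#' @return an object of class `gaussian_mixture_spec`.
#' @export
gaussian_mixture_spec <- function(mu, sigma, weights, labels = NULL) {
  if (any(sigma <= 0)) .stop_class("sigma must be positive", "infoeff_invalid_spec")
  k <- length(mu)
  if (length(sigma) != k) .stop_class("mu and sigma lengths differ", "infoeff_invalid_spec")
  if (is.null(labels)) labels <- paste0("y", seq_len(k))
  if (!inherits(weights, "discrete_distribution")) {
    weights <- discrete_distribution(weights, labels)
  }
  if (length(weights) != k) .stop_class("weights length differs", "infoeff_invalid_spec")
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 weights = weights, labels = as.character(labels)),
            class = "gaussian_mixture_spec")
}

#' @export
print.gaussian_mixture_spec <- function(x, ...) {
  cat("Gaussian mixture with", length(x$mu), "components\n")
  print(data.frame(label = x$labels, mu = x$mu, sigma = x$sigma,
                   weight = x$weights$probs), row.names = FALSE)
  invisible(x)
}

#' Regular discretization grid
#'
#' @param x_min,x_max grid range.
#' @param step positive grid step.
#' @return object of class `sim_grid` with a `points` field.
#' @export
sim_grid <- function(x_min, x_max, step = 1) {
  if (step <= 0) .stop_class("step must be positive", "infoeff_invalid_spec")
  structure(list(x_min = x_min, x_max = x_max, step = step,
                 points = seq(x_min, x_max, by = step)),
            class = "sim_grid")
}

.check_coverage <- function(spec, grid) {
  # total mixture mass clipped outside the grid must stay below 0.1%
  lo <- grid$x_min - grid$step / 2
  hi <- grid$x_max + grid$step / 2
  clipped <- sum(spec$weights$probs *
                   (stats::pnorm(lo, spec$mu, spec$sigma) +
                    stats::pnorm(hi, spec$mu, spec$sigma, lower.tail = FALSE)))
  if (clipped > 1e-3) {
    .stop_class(sprintf("grid clips %.3g of the mixture mass; widen it", clipped),
                "infoeff_coverage_error")
  }
  invisible(clipped)
}

#' Discretize a Gaussian mixture onto a grid (population mode)
#'
#' The deterministic large-sample limit: the source is the renormalized
#' mixture density on the grid, and likelihood column `j` the renormalized
#' component density. Grid labels are the x values as strings.
#'
#' @param spec a `gaussian_mixture_spec`.
#' @param grid a `sim_grid` covering all components (less than 0.1% of the
#'   mass may fall outside, otherwise an error is raised).
#' @return list with `source` (`discrete_distribution`), `likelihoods`
#'   (`likelihood_family`) and `grid`.
#' @export
discretize_mixture <- function(spec, grid) {
  .check_coverage(spec, grid)
  x <- grid$points
  dens <- vapply(seq_along(spec$mu),
                 function(j) stats::dnorm(x, spec$mu[j], spec$sigma[j]),
                 numeric(length(x)))
  lik <- sweep(dens, 2, colSums(dens), "/")
  src <- as.numeric(dens %*% spec$weights$probs)
  list(source = discrete_distribution(src / sum(src), as.character(x)),
       likelihoods = likelihood_family(lik, as.character(x), spec$labels),
       grid = grid)
}

#' Sample a Gaussian mixture onto a grid (finite-sample mode)
#'
#' Draws `n` points from the mixture, snaps them to the nearest grid point
#' (clamping to the range) and returns the empirical distribution.
#'
#' @inheritParams discretize_mixture
#' @param n sample size.
#' @param seed integer seed; sampling is reproducible for a fixed seed.
#' @return an empirical `discrete_distribution` on the grid labels.
#' @export
sample_mixture <- function(spec, grid, n, seed) {
  stopifnot(n > 0)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  comp <- sample.int(length(spec$mu), n, replace = TRUE, prob = spec$weights$probs)
  xs <- stats::rnorm(n, spec$mu[comp], spec$sigma[comp])
  idx <- round((xs - grid$x_min) / grid$step) + 1
  idx <- pmin(pmax(idx, 1L), length(grid$points))
  counts <- tabulate(idx, nbins = length(grid$points))
  discrete_distribution(counts / n, as.character(grid$points))
}

## ---- E and M steps --------------------------------------------------------

#' E-step: posterior channel of a mixture model
#'
#' `P(y_j|x) = P(y_j) P(x|theta_j) / P_theta(x)` with
#' `P_theta(x) = sum_k P(y_k) P(x|theta_k)`.
#'
#' @param source the data distribution `P(x)`.
#' @param likelihoods a `likelihood_family`.
#' @param prior_y the current latent prior.
#' @return a `shannon_channel` P(y|x).
#' @export
e_step <- function(source, likelihoods, prior_y) {
  .check_labels(likelihoods$x_labels, source$labels)
  .check_labels(likelihoods$theta_labels, prior_y$labels, "component")
  p_theta <- as.numeric(likelihoods$columns %*% prior_y$probs)
  bad <- source$probs > 0 & p_theta == 0
  if (any(bad)) {
    .stop_class("mixture model gives zero probability to observed mass",
                "infoeff_support_error")
  }
  tab <- sweep(likelihoods$columns, 2, prior_y$probs, "*")
  ok <- p_theta > 0
  tab[ok, ] <- tab[ok, , drop = FALSE] / p_theta[ok]
  tab[!ok, ] <- rep(prior_y$probs, each = sum(!ok))   # unobserved x: neutral row
  shannon_channel(tab, source$labels, prior_y$labels)
}

#' M-step variants
#'
#' `m1_step()` updates the latent prior to the channel marginal
#' `P^+1(y_j) = sum_i P(x_i) P(y_j|x_i)`. `m2_step()` refits the likelihood
#' columns nonparametrically to the actual posteriors
#' `P(x|theta_j^+1) = P(x) P(y_j|x) / P^+1(y_j)`. `m2_refit_gaussian()`
#' refits each component's `(mu, sigma)` as the weighted mean/sd of x under
#' the same weights (the Gaussian-family M-step). `eq24_step()` is the
#' post-n-step parameter update `P(x|theta_j^+1) = P(x) P(x|theta_j) /
#' P_theta(x)` (columns renormalized).
#'
#' @param source the data distribution.
#' @param channel the posterior channel from [e_step()].
#' @return `m1_step()`: a `discrete_distribution`; `m2_step()` and
#'   `eq24_step()`: a `likelihood_family`; `m2_refit_gaussian()`: a
#'   `gaussian_mixture_spec` with weights set to the channel marginal.
#' @export
m1_step <- function(source, channel) {
  marginal_y(channel, source)
}

#' @rdname m1_step
#' @export
m2_step <- function(source, channel) {
  py <- marginal_y(channel, source)
  if (any(py$probs == 0)) {
    .warn_class("component with zero posterior weight dropped from refit",
                "infoeff_component_death")
  }
  jnt <- joint_distribution(channel, source)
  cols <- jnt
  ok <- py$probs > 0
  cols[, ok] <- sweep(jnt[, ok, drop = FALSE], 2, py$probs[ok], "/")
  cols[, !ok] <- 1 / nrow(jnt)              # frozen placeholder column
  likelihood_family(cols, source$labels, channel$y_labels)
}

#' @rdname m1_step
#' @param grid the `sim_grid` carrying numeric x values.
#' @param sigma_min lower bound for refitted standard deviations (default
#'   half a grid step, keeping the discretization meaningful).
#' @export
m2_refit_gaussian <- function(source, channel, grid, sigma_min = grid$step / 2) {
  x <- grid$points
  py <- marginal_y(channel, source)
  jnt <- joint_distribution(channel, source)
  k <- ncol(jnt)
  mu <- numeric(k); sg <- numeric(k)
  for (j in seq_len(k)) {
    if (py$probs[j] <= 0) { mu[j] <- NA; sg[j] <- NA; next }
    w <- jnt[, j] / py$probs[j]
    mu[j] <- sum(w * x)
    sg[j] <- sqrt(max(sum(w * (x - mu[j])^2), 0))
  }
  if (anyNA(mu)) {
    .warn_class("component with zero posterior weight frozen at previous value",
                "infoeff_component_death")
    mu[is.na(mu)] <- x[1]; sg[is.na(sg)] <- sigma_min
  }
  sg <- pmax(sg, sigma_min)
  gaussian_mixture_spec(mu, sg, py, channel$y_labels)
}

#' @rdname m1_step
#' @param likelihoods current `likelihood_family`.
#' @param prior_y current latent prior.
#' @export
eq24_step <- function(source, likelihoods, prior_y) {
  p_theta <- as.numeric(likelihoods$columns %*% prior_y$probs)
  ok <- p_theta > 0
  cols <- likelihoods$columns
  cols[ok, ] <- source$probs[ok] * likelihoods$columns[ok, , drop = FALSE] / p_theta[ok]
  cols[!ok, ] <- 0
  cols <- sweep(cols, 2, colSums(cols), "/")
  likelihood_family(cols, likelihoods$x_labels, likelihoods$theta_labels)
}

## ---- algorithm driver -----------------------------------------------------

.trace_row <- function(iter, stage, rep, spec) {
  row <- data.frame(iter = iter, stage = stage,
                    R = rep$R, G = rep$G, RG_diff = rep$RG_diff,
                    F = rep$F, F_prime = rep$F_prime, Q = rep$Q,
                    H_XgY = rep$H_XgY, H_XgYtheta = rep$H_XgYtheta,
                    KL_P_Ptheta = rep$KL_P_Ptheta,
                    KL_Yplus_Y = rep$KL_Yplus_Y)
  if (!is.null(spec)) {
    k <- length(spec$mu)
    row[paste0("mu", seq_len(k))] <- as.list(spec$mu)
    row[paste0("sigma", seq_len(k))] <- as.list(spec$sigma)
    row[paste0("py", seq_len(k))] <- as.list(spec$weights$probs)
  }
  row
}

#' Run EM, EnM or En on a discrete mixture problem
#'
#' One outer iteration of EnM(n) repeats the (E-step, M1-step) pair `n`
#' times — so the latent prior approximately matches the channel marginal —
#' then refits the Gaussian parameters (M2). `EM` is `EnM` with `n = 1`.
#' `En` keeps the likelihoods fixed and only iterates (E, M1), solving the
#' latent prior for fixed constraints.
#'
#' Diagnostics are recorded twice per (E, M1) block: after the E-step (where
#' the prior may differ from the channel marginal, so
#' `KL(P||P_theta) = (R - G) + KL(P_Y^+1||P_Y)` can be checked) and after
#' the M1-step (where the prior equals the marginal, so the variational free
#' energy reduces to `F = H(X|Y_theta)`).
#'
#' @param source the data distribution (population or sampled).
#' @param init_spec initial `gaussian_mixture_spec` (EM/EnM), or `NULL` for
#'   `En` with explicit `likelihoods` and `prior_y0`.
#' @param grid the `sim_grid` (required for Gaussian refits).
#' @param algorithm `"EM"`, `"EnM"` or `"En"`.
#' @param n number of (E, M1) repetitions per outer iteration for `EnM`.
#' @param likelihoods,prior_y0 explicit constraint and initial prior for
#'   `En` (ignored otherwise; for EM/EnM they derive from `init_spec`).
#' @param stop_rule `"delta_kl"` (stop when `|Delta KL(P||P_theta)| <
#'   threshold` across outer iterations, the default) or `"kl"` (stop when
#'   `KL(P||P_theta) < threshold`).
#' @param threshold stopping threshold in bits (default `1e-9`).
#' @param max_iter outer-iteration cap.
#' @return a `mixture_trace`: the per-stage diagnostics `data.frame` plus
#'   attributes `algorithm`, `n`, `iterations`, `converged`, `final_spec`,
#'   `final_prior`, `final_likelihoods`.
#' @export
run_mixture <- function(source, init_spec = NULL, grid = NULL,
                        algorithm = c("EM", "EnM", "En"), n = 1,
                        likelihoods = NULL, prior_y0 = NULL,
                        stop_rule = c("delta_kl", "kl"), threshold = 1e-9,
                        max_iter = 2000) {
  algorithm <- match.arg(algorithm)
  stop_rule <- match.arg(stop_rule)
  if (algorithm == "EM") n <- 1
  if (algorithm == "En") {
    if (is.null(likelihoods)) .stop_class("En requires fixed likelihoods", "infoeff_invalid_spec")
    spec <- NULL
    if (is.null(prior_y0)) {
      k <- length(likelihoods$theta_labels)
      prior_y0 <- discrete_distribution(rep(1 / k, k), likelihoods$theta_labels)
    }
  } else {
    if (is.null(init_spec) || is.null(grid)) {
      .stop_class("EM/EnM require init_spec and grid", "infoeff_invalid_spec")
    }
    spec <- init_spec
    likelihoods <- discretize_mixture(spec, grid)$likelihoods
    prior_y0 <- spec$weights
  }
  prior <- prior_y0
  rows <- list()
  kl_prev <- Inf
  converged <- FALSE
  outer <- 0
  channel <- NULL
  repeat {
    outer <- outer + 1
    for (r in seq_len(max(n, 1))) {
      channel <- e_step(source, likelihoods, prior)
      rows[[length(rows) + 1]] <-
        .trace_row(outer, "post_E",
                   entropy_report(source, channel, likelihoods, prior_y = prior),
                   spec)
      prior <- m1_step(source, channel)
      rows[[length(rows) + 1]] <-
        .trace_row(outer, "post_M1",
                   entropy_report(source, channel, likelihoods, prior_y = prior),
                   spec)
    }
    if (algorithm != "En") {
      spec <- m2_refit_gaussian(source, channel, grid)
      spec$weights <- prior
      likelihoods <- discretize_mixture(spec, grid)$likelihoods
    }
    p_theta <- as.numeric(likelihoods$columns %*% prior$probs)
    kl_now <- .kl(source$probs, p_theta, "bits")
    done <- switch(stop_rule,
                   delta_kl = is.finite(kl_prev) && abs(kl_prev - kl_now) < threshold,
                   kl = kl_now < threshold)
    kl_prev <- kl_now
    if (done) { converged <- TRUE; break }
    if (outer >= max_iter) break
  }
  df <- do.call(rbind, rows)
  structure(df, class = c("mixture_trace", "data.frame"),
            algorithm = algorithm, n = n, iterations = outer,
            converged = converged, final_spec = spec, final_prior = prior,
            final_likelihoods = likelihoods, final_kl = kl_prev)
}

#' @export
print.mixture_trace <- function(x, ...) {
  cat(sprintf("%s trace: %d outer iterations (%sconverged), final KL(P||Ptheta) = %.3g bits\n",
              attr(x, "algorithm"),
              attr(x, "iterations"),
              if (attr(x, "converged")) "" else "NOT ",
              attr(x, "final_kl")))
  invisible(x)
}

#' Write a mixture trace as CSV
#'
#' @param trace a `mixture_trace`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Check the E-step information identity on a trace
#'
#' At every recorded post-E-step state,
#' `KL(P||P_theta) = (R - G) + KL(P_Y^+1||P_Y)` must hold; at convergence
#' the prior divergence vanishes so `KL(P||P_theta)` equals `R - G`.
#'
#' @param trace a `mixture_trace`.
#' @param tol tolerance in bits (default `1e-9`).
#' @return list with `ok`, `max_dev`, and `violations` (a data frame naming
#'   any offending iteration).
#' @export
convergence_identity_check <- function(trace, tol = 1e-9) {
  e <- trace[trace$stage == "post_E", , drop = FALSE]
  dev <- abs(e$KL_P_Ptheta - (e$RG_diff + e$KL_Yplus_Y))
  bad <- which(dev > tol)
  list(ok = length(bad) == 0,
       max_dev = if (nrow(e)) max(dev) else 0,
       violations = data.frame(iter = e$iter[bad], deviation = dev[bad]))
}

#' Packaged mixture-model study configurations
#'
#' Three standing configurations used throughout the package's convergence
#' experiments, each a true/initial model pair on a unit-step grid:
#' `"neal_hinton"` (well/narrow component pair 46/50 with sd 2/20; optional
#' swapped mixing ratio 0.3:0.7 which makes the negative free energy
#' non-monotone), `"counterexample"` (equal components 40/75 with sd 15
#' initialized at sd 5, the configuration where free energy rises while the
#' information difference falls), and `"poor_convergence"` (components
#' 100/125 with sd 10 initialized far off at 80/95 with sd 5).
#'
#' @param name one of `"neal_hinton"`, `"counterexample"`,
#'   `"poor_convergence"`.
#' @param swap_ratio for `"neal_hinton"`: use mixing ratio 0.3:0.7 instead
#'   of 0.7:0.3.
#' @return list with `true_spec`, `init_spec` and `grid`.
#' @export
mixture_fixture <- function(name = c("neal_hinton", "counterexample",
                                     "poor_convergence"),
                            swap_ratio = FALSE) {
  name <- match.arg(name)
  switch(name,
    neal_hinton = list(
      true_spec = gaussian_mixture_spec(c(46, 50), c(2, 20),
                                        if (swap_ratio) c(0.3, 0.7) else c(0.7, 0.3)),
      init_spec = gaussian_mixture_spec(c(30, 70), c(20, 20), c(0.5, 0.5)),
      grid = sim_grid(-100, 150, 1)),
    counterexample = list(
      true_spec = gaussian_mixture_spec(c(40, 75), c(15, 15), c(0.5, 0.5)),
      init_spec = gaussian_mixture_spec(c(40, 80), c(5, 5), c(0.5, 0.5)),
      grid = sim_grid(-60, 175, 1)),
    poor_convergence = list(
      true_spec = gaussian_mixture_spec(c(100, 125), c(10, 10), c(0.7, 0.3)),
      init_spec = gaussian_mixture_spec(c(80, 95), c(5, 5), c(0.5, 0.5)),
      grid = sim_grid(20, 205, 1)))
}
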