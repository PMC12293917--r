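#' Energy spectrum with degeneracies
#'
#' Energy levels `e_i` with microstate counts (degeneracies) `g_i`. The
#' total microstate count per molecule is `Gm = sum(g)`; the prior level
#' distribution is `P(e_i) = g_i / Gm` (microstates equiprobable a priori).
#'
#' @param levels numeric energy levels.
#' @param degeneracies positive integer microstate counts (default all 1).
#' @return an object of class `energy_spectrum` with fields `levels`,
#'   `degeneracies`, `Gm` and `prior` (a `discrete_distribution`).
#' @export
energy_spectrum <- function(levels, degeneracies = rep(1L, length(levels))) {
  if (length(levels) != length(degeneracies)) {
    .stop_class("levels and degeneracies lengths differ", "infoeff_invalid_spec")
  }
  if (any(degeneracies < 1)) .stop_class("degeneracies must be >= 1", "infoeff_invalid_spec")
  Gm <- sum(degeneracies)
  structure(list(levels = as.numeric(levels),
                 degeneracies = as.numeric(degeneracies), Gm = Gm,
                 prior = discrete_distribution(degeneracies / Gm,
                                               paste0("e", seq_along(levels)))),
            class = "energy_spectrum")
}

#' Boltzmann distribution over energy levels
#'
#' `P(e_i|T) = P(e_i) exp(-e_i / kT) / Z` with `Z = sum_i P(e_i)
#' exp(-e_i/kT)`; computed in the log domain so very small temperatures do
#' not underflow.
#'
#' @param spectrum an `energy_spectrum`.
#' @param T absolute temperature, `> 0`.
#' @param k Boltzmann constant (default 1, natural units).
#' @return a `discrete_distribution` over the levels.
#' @export
boltzmann_distribution <- function(spectrum, T, k = 1) {
  if (T <= 0) .stop_class("temperature must be positive", "infoeff_invalid_spec")
  lw <- log(spectrum$prior$probs) - spectrum$levels / (k * T)
  lz <- .logsumexp(lw)
  discrete_distribution(exp(lw - lz), spectrum$prior$labels)
}

#' Helmholtz-type free-energy functional of a level distribution
#'
#' `F[q] = U[q] - kT S[q]/(kN)` per molecule in natural units:
#' `sum_i q_i e_i + kT sum_i q_i ln(q_i / g_i)` (entropy counted over
#' microstates, uniform within each degeneracy). The Boltzmann distribution
#' is its unique minimizer.
#'
#' @param spectrum an `energy_spectrum`.
#' @param q a level distribution (vector or `discrete_distribution`).
#' @inheritParams boltzmann_distribution
#' @return the functional value (energy units).
#' @export
helmholtz_functional <- function(spectrum, q, T, k = 1) {
  if (inherits(q, "discrete_distribution")) q <- q$probs
  pos <- q > 0
  sum(q * spectrum$levels) +
    k * T * sum(q[pos] * log(q[pos] / spectrum$degeneracies[pos]))
}

#' Local (non-)equilibrium thermodynamic system
#'
#' A spectrum shared by regions `y_j` holding fractions `P(y_j)` of the `N`
#' molecules at temperatures `T_j`. In equilibrium mode each region's level
#' distribution is Boltzmann at its temperature; in non-equilibrium mode
#' arbitrary region conditionals may be supplied.
#'
#' @param spectrum an `energy_spectrum`.
#' @param temperatures positive region temperatures `T_j`.
#' @param fractions region fractions `P(y_j)` (summing to one).
#' @param conditionals optional matrix with column `j` = `P(e|y_j)`
#'   (non-equilibrium mode); default Boltzmann at each `T_j`.
#' @param k Boltzmann constant (default 1).
#' @param N molecule count (a pure scale factor; default 1).
#' @return an object of class `local_thermo_system`.
#' @export
local_thermo_system <- function(spectrum, temperatures, fractions,
                                conditionals = NULL, k = 1, N = 1) {
  if (any(temperatures <= 0)) .stop_class("temperatures must be positive", "infoeff_invalid_spec")
  fr <- discrete_distribution(fractions, paste0("T", seq_along(temperatures)))
  if (is.null(conditionals)) {
    conditionals <- vapply(temperatures,
                           function(Tj) boltzmann_distribution(spectrum, Tj, k)$probs,
                           numeric(length(spectrum$levels)))
    equilibrium <- TRUE
  } else {
    conditionals <- as.matrix(conditionals)
    if (any(abs(colSums(conditionals) - 1) > 1e-9)) {
      .stop_class("region conditionals must be distributions", "infoeff_invalid_spec")
    }
    equilibrium <- FALSE
  }
  structure(list(spectrum = spectrum, temperatures = temperatures,
                 fractions = fr, conditionals = conditionals,
                 equilibrium = equilibrium, k = k, N = N),
            class = "local_thermo_system")
}

# microstate-level conditional entropy of one region, nats:
# H(X|y_j) = H(E|y_j) + sum_i P(e_i|y_j) ln g_i
.microstate_cond_entropy <- function(spectrum, pe) {
  .entropy(pe, "nats") + sum(pe * log(spectrum$degeneracies))
}

#' Information-entropy identity report for a local system
#'
#' Computes, in nats: the energy information `I(E;Y) = sum_j P(y_j)
#' KL(P(e|y_j) || P(e))`, the microstate information `I(X;Y)` (microstates
#' uniform within each degeneracy), the entropy ratio `S/(kN) = H(X|Y)`, and
#' verifies `I(E;Y) = ln Gm - S/(kN) = I(X;Y)`. In equilibrium mode it also
#' evaluates the semantic form with truth functions
#' `T(theta_j|x) = exp(-e_i/(k T_j))`: `I(X;Y_theta) = H(Y_theta) -
#' H(Y_theta|X)`, which equals the Shannon value, and checks that
#' `H(X|Y_theta)` equals `S/(kN)` (so variational free energy is
#' proportional to thermodynamic entropy).
#'
#' @param system a `local_thermo_system`.
#' @return list of the computed quantities and deviations `dev_energy_vs_lnGm`,
#'   `dev_energy_vs_microstate`, and (equilibrium mode)
#'   `dev_semantic_vs_shannon`, `dev_entropy_vs_semantic_cond`.
#' @export
energy_info_identity <- function(system) {
  sp <- system$spectrum
  py <- system$fractions$probs
  pe_prior <- sp$prior$probs
  k <- system$k; N <- system$N
  kj <- ncol(system$conditionals)

  I_EY <- sum(vapply(seq_len(kj), function(j) {
    py[j] * .kl(system$conditionals[, j], pe_prior, "nats")
  }, numeric(1)))

  H_XgY <- sum(vapply(seq_len(kj), function(j) {
    py[j] * .microstate_cond_entropy(sp, system$conditionals[, j])
  }, numeric(1)))
  lnGm <- log(sp$Gm)
  I_XY <- lnGm - H_XgY          # H(X) = ln Gm (uniform microstate prior)
  S_over_kN <- H_XgY
  S <- k * N * H_XgY

  out <- list(I_EY_nats = I_EY, I_XY_nats = I_XY, ln_Gm = lnGm,
              S_over_kN = S_over_kN, S = S,
              dev_energy_vs_lnGm = abs(I_EY - (lnGm - S_over_kN)),
              dev_energy_vs_microstate = abs(I_EY - I_XY))

  if (system$equilibrium) {
    # semantic form: T(theta_j|x) = exp(-e_i/(k T_j)); logical probability of
    # theta_j under the uniform microstate prior is the partition function Z_j
    logZ <- vapply(system$temperatures, function(Tj) {
      .logsumexp(log(pe_prior) - sp$levels / (k * Tj))
    }, numeric(1))
    H_Ytheta <- -sum(py * logZ)
    mean_e_over_T <- sum(vapply(seq_len(kj), function(j) {
      py[j] * sum(system$conditionals[, j] * sp$levels) / (k * system$temperatures[j])
    }, numeric(1)))
    I_sem <- H_Ytheta - mean_e_over_T
    H_XgYtheta <- lnGm - I_sem
    out$I_semantic_nats <- I_sem
    out$H_XgYtheta <- H_XgYtheta
    out$dev_semantic_vs_shannon <- abs(I_sem - I_XY)
    out$dev_entropy_vs_semantic_cond <- abs(H_XgYtheta - S_over_kN)
  }
  out
}

#' Free-energy increment of a local system against a reference temperature
#'
#' At constant internal energy the free-energy change between the global
#' equilibrium state at `T0` and the local regional states is
#' `dF = k N [T0 H(X|T0) - sum_j T_j P(y_j) H(X|y_j)]` (natural-log
#' entropies at microstate level). As all temperatures grow with `T0`, the
#' increment per `k N T0` approaches the Shannon mutual information
#' `I(X;Y)`.
#'
#' @param system a `local_thermo_system`.
#' @param T0 reference (global) temperature.
#' @return the increment, energy units.
#' @export
free_energy_increment <- function(system, T0) {
  if (T0 <= 0) .stop_class("T0 must be positive", "infoeff_invalid_spec")
  sp <- system$spectrum
  k <- system$k; N <- system$N
  global <- boltzmann_distribution(sp, T0, k)$probs
  H0 <- .microstate_cond_entropy(sp, global)
  py <- system$fractions$probs
  Hj <- vapply(seq_len(ncol(system$conditionals)), function(j) {
    .microstate_cond_entropy(sp, system$conditionals[, j])
  }, numeric(1))
  k * N * (T0 * H0 - sum(system$temperatures * py * Hj))
}

#' Read / write a thermodynamic system as JSON
#'
#' @param path file path.
#' @return `read_thermo_json()` returns a `local_thermo_system`;
#'   `write_thermo_json()` returns `path` invisibly.
#' @export
read_thermo_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- energy_spectrum(obj$levels, obj$degeneracies)
  cond <- if (!is.null(obj$conditionals)) {
    m <- as.matrix(obj$conditionals); storage.mode(m) <- "double"; m
  } else NULL
  local_thermo_system(sp, obj$temperatures, obj$fractions, cond,
                      k = obj$k %||% 1, N = obj$N %||% 1)
}

#' @rdname read_thermo_json
#' @param system a `local_thermo_system`.
#' @export
write_thermo_json <- function(system, path) {
  obj <- list(levels = system$spectrum$levels,
              degeneracies = system$spectrum$degeneracies,
              temperatures = system$temperatures,
              fractions = system$fractions$probs,
              k = system$k, N = system$N)
  if (!system$equilibrium) obj$conditionals <- system$conditionals
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
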