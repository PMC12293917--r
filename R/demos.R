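#' Grayscale truth-function bank for semantic compression
#'
#' Eight (by default) Gaussian-shaped truth functions over 256 gray levels,
#' with centers denser and narrower at low brightness — the eye
#' discriminates dark grays more finely than bright ones. Centers follow a
#' power law `c_j = (L-1) ((j - 1/2) / K)^gamma` and widths scale with the
#' local center spacing.
#'
#' @param n_levels number of gray levels (default 256).
#' @param n_labels number of compressed labels (default 8).
#' @param gamma power-law exponent for center placement (default 1.5;
#'   `gamma > 1` packs centers toward black).
#' @param width_factor width as a fraction of the local center spacing
#'   (default 0.45).
#' @return a `semantic_channel` over gray levels `0 ... n_levels - 1`.
#' @export
grayscale_truth_bank <- function(n_levels = 256, n_labels = 8,
                                 gamma = 1.5, width_factor = 0.45) {
  x <- seq(0, n_levels - 1)
  centers <- (n_levels - 1) * (((seq_len(n_labels)) - 0.5) / n_labels)^gamma
  gaps <- diff(centers)
  local <- c(gaps[1], (gaps[-length(gaps)] + gaps[-1]) / 2, gaps[length(gaps)])
  widths <- width_factor * local
  gaussian_truth_bank(x, centers, widths)
}

#' Semantic compression demo: many gray levels into few labels
#'
#' Runs the En algorithm (MID iteration at `s = 1` with fixed truth-function
#' constraints) from a uniform latent prior, compressing `n_levels` gray
#' levels into `n_labels` labels. With 8 labels the initial prior entropy
#' `H(Y)` is 3 bits; at convergence the Shannon rate `R` drops below
#' `H(Y)` while the information efficiency `G/R` stays close to one.
#'
#' @param source source distribution over gray levels (default uniform).
#' @param bank truth-function bank (default [grayscale_truth_bank()]).
#' @param tol,max_iter MID convergence controls.
#' @return list with `R`, `G`, `efficiency`, `H_Y_init`, `H_Y_final`,
#'   `iterations`, `converged`, `prior_y`, `channel`.
#' @export
run_compression_demo <- function(source = NULL, bank = grayscale_truth_bank(),
                                 tol = 1e-8, max_iter = 100) {
  nx <- length(bank$x_labels)
  if (is.null(source)) {
    source <- discrete_distribution(rep(1 / nx, nx), bank$x_labels)
  }
  k <- length(bank$theta_labels)
  pt <- mid_iterate(source, bank, s = 1, tol = tol, max_iter = max_iter)
  list(R = pt$R, G = pt$G, efficiency = pt$efficiency,
       H_Y_init = log2(k),
       H_Y_final = shannon_entropy(pt$prior_y),
       iterations = pt$iterations, converged = pt$converged,
       prior_y = pt$prior_y, channel = pt$channel)
}

#' Two-pasture constraint-control demo
#'
#' A one-dimensional world (positions 0 ... 100) with an initial herd
#' density and two fuzzy goal regions (Gaussian truth functions around
#' positions 25 and 75). Solves the control problem over a grid of
#' strengths: outcomes concentrate on the pastures as `s` grows, with
#' rapidly diminishing gains in purposeful information beyond `s` around 5.
#'
#' @param s_grid strengths to solve at.
#' @param centers,widths goal truth-function parameters.
#' @param source_mu,source_sigma initial herd density parameters (a
#'   discretized normal).
#' @return list with `solutions` (one `control_solution` per `s`) and
#'   `curve` (data frame of s, R, G, efficiency).
#' @export
two_pastures_demo <- function(s_grid = c(0.5, 1, 2, 5, 10, 20, 40),
                              centers = c(25, 75), widths = c(15, 15),
                              source_mu = 50, source_sigma = 22) {
  x <- 0:100
  d <- stats::dnorm(x, source_mu, source_sigma)
  src <- discrete_distribution(d / sum(d), as.character(x))
  goals <- gaussian_truth_bank(x, centers, widths, labels = c("a0", "a1"))
  sols <- lapply(s_grid, function(s) {
    optimize_control(control_problem(src, goals, s))
  })
  curve <- do.call(rbind, lapply(sols, function(sl) {
    data.frame(s = sl$s, R_bits = sl$R, G_bits = sl$G,
               efficiency = sl$efficiency)
  }))
  list(solutions = sols, curve = curve, source = src, goals = goals)
}

#' Binary-communication R(G) demo
#'
#' An equiprobable binary source with a symmetric two-label truth constraint
#' produces the canonical bowl-shaped rate-fidelity curve.
#'
#' @param truth off-diagonal truth value (default 0.25).
#' @param s_grid strengths to trace the curve at.
#' @return an `rg_curve`.
#' @export
rg_binary_demo <- function(truth = 0.25,
                           s_grid = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6)) {
  src <- discrete_distribution(c(0.5, 0.5), c("x1", "x2"))
  sc <- semantic_channel(matrix(c(1, truth, truth, 1), 2, 2),
                         c("x1", "x2"), c("y1", "y2"))
  rg_curve(src, sc, s_grid)
}

#' Run a packaged demo and write its artifacts
#'
#' Dispatches on a demo name: the three mixture-model convergence studies
#' (`"neal_hinton"` — swapped mixing ratio, non-monotone negative free
#' energy; `"counterexample"` — free energy rising while the information
#' difference falls; `"poor_convergence"` — EM vs E3M iteration counts),
#' the semantic compression demo (`"compression_8to3"`), the control demo
#' (`"two_pastures"`), and the binary rate-fidelity curve (`"rg_binary"`).
#' Population (discretized) sources make every artifact deterministic.
#'
#' @param name demo name.
#' @param out_dir output directory for CSV/JSON artifacts, or `NULL` to
#'   return results without writing.
#' @param seed integer seed (only used by demos with sampling; population
#'   demos are deterministic).
#' @return the demo's result object, invisibly when files are written.
#' @export
run_demo <- function(name = c("neal_hinton", "counterexample",
                              "poor_convergence", "compression_8to3",
                              "two_pastures", "rg_binary"),
                     out_dir = NULL, seed = 1) {
  name <- match.arg(name)
  emit_json <- function(obj, file) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(obj, file.path(out_dir, file),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  emit_csv <- function(df, file) {
    if (!is.null(out_dir)) {
      utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- switch(name,
    neal_hinton = {
      fx <- mixture_fixture("neal_hinton", swap_ratio = TRUE)
      pop <- discretize_mixture(fx$true_spec, fx$grid)
      tr <- run_mixture(pop$source, fx$init_spec, fx$grid, "EM")
      emit_csv(as.data.frame(tr), "neal_hinton_trace.csv")
      tr
    },
    counterexample = {
      fx <- mixture_fixture("counterexample")
      pop <- discretize_mixture(fx$true_spec, fx$grid)
      tr <- run_mixture(pop$source, fx$init_spec, fx$grid, "EM")
      emit_csv(as.data.frame(tr), "counterexample_trace.csv")
      tr
    },
    poor_convergence = {
      fx <- mixture_fixture("poor_convergence")
      pop <- discretize_mixture(fx$true_spec, fx$grid)
      em <- run_mixture(pop$source, fx$init_spec, fx$grid, "EM")
      e3m <- run_mixture(pop$source, fx$init_spec, fx$grid, "EnM", n = 3)
      emit_csv(as.data.frame(em), "poor_convergence_em_trace.csv")
      emit_csv(as.data.frame(e3m), "poor_convergence_e3m_trace.csv")
      list(EM = em, E3M = e3m)
    },
    compression_8to3 = {
      rep <- run_compression_demo()
      emit_json(rep[c("R", "G", "efficiency", "H_Y_init", "H_Y_final",
                      "iterations", "converged")],
                "compression_report.json")
      rep
    },
    two_pastures = {
      demo <- two_pastures_demo()
      emit_csv(demo$curve, "two_pastures_curve.csv")
      demo
    },
    rg_binary = {
      curve <- rg_binary_demo()
      emit_csv(as.data.frame(curve), "rg_binary_curve.csv")
      curve
    })
  if (is.null(out_dir)) res else invisible(res)
}
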