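test_that("discretization reproduces mixture shape and moments", {
  g <- sim_grid(-10, 10, 0.5)
  one <- gaussian_mixture_spec(0, 2, 1)
  d <- discretize_mixture(one, g)
  expect_equal(d$source$probs, rev(d$source$probs), tolerance = 1e-12)
  expect_equal(sum(d$source$probs), 1, tolerance = 1e-12)

  two <- gaussian_mixture_spec(c(-40, 40), c(2, 2), c(0.5, 0.5))
  g2 <- sim_grid(-60, 60, 0.5)
  d2 <- discretize_mixture(two, g2)
  left <- sum(d2$source$probs[g2$points < 0])
  expect_equal(left, 0.5, tolerance = 1e-6)

  # first moment of the discretized two-component model
  fx <- mixture_fixture("neal_hinton")
  d3 <- discretize_mixture(fx$true_spec, fx$grid)
  mean_x <- sum(fx$grid$points * d3$source$probs)
  expect_equal(mean_x, 0.7 * 46 + 0.3 * 50, tolerance = 1e-3)

  # a grid clipping real mass is refused
  expect_error(discretize_mixture(one, sim_grid(-2, 2, 0.5)),
               class = "infoeff_coverage_error")
})

test_that("sampling is reproducible and converges to the population law", {
  fx <- mixture_fixture("counterexample")
  a <- sample_mixture(fx$true_spec, fx$grid, 5000, seed = 42)
  b <- sample_mixture(fx$true_spec, fx$grid, 5000, seed = 42)
  expect_identical(a, b)

  single <- sample_mixture(fx$true_spec, fx$grid, 1, seed = 7)
  expect_equal(sum(single$probs > 0), 1)

  pop <- discretize_mixture(fx$true_spec, fx$grid)$source
  for (seed in 1:3) {
    emp <- sample_mixture(fx$true_spec, fx$grid, 1e6, seed = seed)
    # smoothed KL (empirical zeros get no mass in the divergence direction)
    expect_lt(kl_divergence(emp, pop), 1e-3)
  }
})

test_that("E-step and M-step formulas match direct evaluation", {
  src <- discrete_distribution(c(0.2, 0.5, 0.3), c("a", "b", "c"))
  prior <- discrete_distribution(c(0.4, 0.6), c("y1", "y2"))

  # equal likelihood columns: posterior rows equal the prior
  eq <- likelihood_family(cbind(c(.2, .5, .3), c(.2, .5, .3)),
                          src$labels, prior$labels)
  che <- e_step(src, eq, prior)
  expect_true(all(abs(sweep(che$table, 2, prior$probs)) < 1e-12))

  # crisp disjoint likelihoods: hard assignment
  crisp <- likelihood_family(cbind(c(1, 0, 0), c(0, 5 / 8, 3 / 8)),
                             src$labels, prior$labels)
  chh <- e_step(src, crisp, prior)
  expect_equal(unname(chh$table[, 1]), c(1, 0, 0))

  # direct formula on a generic instance
  lik <- likelihood_family(cbind(c(.6, .3, .1), c(.1, .3, .6)),
                           src$labels, prior$labels)
  ch <- e_step(src, lik, prior)
  ptheta <- 0.4 * lik$columns[, 1] + 0.6 * lik$columns[, 2]
  expect_equal(unname(ch$table[, 1]),
               unname(0.4 * lik$columns[, 1] / ptheta), tolerance = 1e-12)
  expect_equal(unname(ch$table[, 2]),
               unname(0.6 * lik$columns[, 2] / ptheta), tolerance = 1e-12)

  # M1 conserves mass; M2 on a hard channel returns per-cluster conditionals
  expect_equal(sum(m1_step(src, ch)$probs), 1, tolerance = 1e-12)
  hard <- shannon_channel(rbind(c(1, 0), c(0, 1), c(0, 1)), src$labels, prior$labels)
  m2 <- m2_step(src, hard)
  expect_equal(unname(m2$columns[, 2]), c(0, 0.5 / 0.8, 0.3 / 0.8))

  # Gaussian refit recovers moments of a single discretized component
  g <- sim_grid(-10, 10, 0.1)
  one <- discretize_mixture(gaussian_mixture_spec(1.5, 2, 1), g)
  ident <- shannon_channel(matrix(1, length(g$points), 1),
                           one$source$labels, "y1")
  refit <- m2_refit_gaussian(one$source, ident, g)
  expect_equal(refit$mu, 1.5, tolerance = 0.01)
  expect_equal(refit$sigma, 2, tolerance = 0.01)
})

test_that("EnM(1) is the EM algorithm", {
  fx <- mixture_fixture("counterexample")
  pop <- discretize_mixture(fx$true_spec, fx$grid)
  a <- run_mixture(pop$source, fx$init_spec, fx$grid, "EM", threshold = 1e-6)
  b <- run_mixture(pop$source, fx$init_spec, fx$grid, "EnM", n = 1,
                   threshold = 1e-6)
  da <- as.data.frame(a); db <- as.data.frame(b)
  attributes(da) <- attributes(da)[c("names", "row.names", "class")]
  attributes(db) <- attributes(db)[c("names", "row.names", "class")]
  expect_equal(da, db, tolerance = 1e-14)
})

test_that("the E-step information identity holds on random instances", {
  set.seed(31)
  for (r in 1:100) {
    nx <- sample(3:6, 1); k <- sample(2:3, 1)
    src <- rand_distribution(nx)
    lik <- rand_likelihoods(nx, k, src$labels)
    prior <- rand_distribution(k)
    prior <- discrete_distribution(prior$probs, lik$theta_labels)
    ch <- e_step(src, lik, prior)
    rep <- entropy_report(src, ch, lik, prior_y = prior)
    # both sides computed independently of entropy_report internals
    ptheta <- as.numeric(lik$columns %*% prior$probs)
    lhs <- oracle_kl(src$probs, ptheta)
    py_plus <- colSums(src$probs * ch$table)
    rhs <- (oracle_shannon_mi(src$probs, ch$table) -
              sum((src$probs * ch$table) * log2(lik$columns / src$probs))) +
      oracle_kl(py_plus, prior$probs)
    expect_lt(abs(lhs - rhs), 1e-9)
    expect_lt(abs(rep$KL_P_Ptheta - (rep$RG_diff + rep$KL_Yplus_Y)), 1e-9)
  }
})

test_that("trace diagnostics satisfy the identity and fixed-point checks", {
  fx <- mixture_fixture("counterexample")
  pop <- discretize_mixture(fx$true_spec, fx$grid)
  tr <- run_mixture(pop$source, fx$init_spec, fx$grid, "EM", threshold = 1e-7)
  chk <- convergence_identity_check(tr)
  expect_true(chk$ok)
  expect_lt(chk$max_dev, 1e-9)
  # after M1 the prior equals the marginal: F collapses onto H(X|Y_theta)
  m1 <- tr[tr$stage == "post_M1", ]
  expect_lt(max(m1$KL_Yplus_Y), 1e-10)
  expect_equal(m1$F, m1$H_XgYtheta, tolerance = 1e-12)
  # matched initialization: both sides of the identity start at zero
  tr0 <- run_mixture(pop$source, fx$true_spec, fx$grid, "EM", max_iter = 3)
  e0 <- tr0[tr0$stage == "post_E", ][1, ]
  expect_lt(e0$KL_P_Ptheta, 1e-6)
  expect_lt(e0$RG_diff, 1e-6)
})

test_that("information difference decreases within each (E, M1) block", {
  fx <- mixture_fixture("neal_hinton", swap_ratio = TRUE)
  pop <- discretize_mixture(fx$true_spec, fx$grid)
  tr <- run_mixture(pop$source, fx$init_spec, fx$grid, "EnM", n = 3,
                    threshold = 1e-7)
  for (it in unique(tr$iter)) {
    blk <- tr[tr$iter == it & tr$stage == "post_E", ]
    if (nrow(blk) > 1) expect_lt(max(diff(blk$RG_diff)), 1e-10)
  }
})

test_that("population EM recovers the generating parameters", {
  fx <- mixture_fixture("neal_hinton")
  pop <- discretize_mixture(fx$true_spec, fx$grid)
  tr <- run_mixture(pop$source, fx$init_spec, fx$grid, "EnM", n = 3)
  expect_true(attr(tr, "converged"))
  fit <- attr(tr, "final_spec")
  expect_lt(max(abs(fit$mu - fx$true_spec$mu)), fx$grid$step)
  expect_lt(max(abs(fit$sigma / fx$true_spec$sigma - 1)), 0.05)
  expect_lt(max(abs(fit$weights$probs - fx$true_spec$weights$probs)), 0.02)
})

test_that("config round trip drives the same run", {
  cfg <- list(true = list(mu = c(40, 75), sigma = c(15, 15), weights = c(0.5, 0.5)),
              init = list(mu = c(40, 80), sigma = c(5, 5), weights = c(0.5, 0.5)),
              grid = list(x_min = -60, x_max = 175, step = 1),
              algorithm = "EM", threshold = 1e-4)
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  tr1 <- run_mixture_config(read_mixture_config(fy))
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE, digits = NA)
  tr2 <- run_mixture_config(read_mixture_config(fj))
  expect_equal(as.data.frame(tr1)$KL_P_Ptheta, as.data.frame(tr2)$KL_P_Ptheta,
               tolerance = 1e-12)
  # trace CSV round trip
  fc <- tempfile(fileext = ".csv")
  write_trace_csv(tr1, fc)
  back <- utils::read.csv(fc)
  expect_equal(back$F, as.data.frame(tr1)$F, tolerance = 1e-9)
})
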