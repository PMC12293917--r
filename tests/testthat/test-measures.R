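test_that("Shannon mutual information matches direct double sums", {
  u <- discrete_distribution(c(0.5, 0.5))
  ident <- shannon_channel(diag(2))
  expect_equal(shannon_mi(u, ident), 1)
  flat <- shannon_channel(matrix(0.5, 2, 2))
  expect_equal(shannon_mi(discrete_distribution(c(0.2, 0.8)), flat), 0)
  bsc <- shannon_channel(matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  h2 <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(shannon_mi(u, bsc), 1 - h2(0.9), tolerance = 1e-12)
  set.seed(2)
  for (r in 1:25) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    src <- rand_distribution(nx); ch <- rand_channel(nx, ny)
    expect_equal(shannon_mi(src, ch),
                 oracle_shannon_mi(src$probs, ch$table), tolerance = 1e-12)
  }
})

test_that("semantic mutual information: tautologies, matched channels, oracle", {
  u <- discrete_distribution(c(0.5, 0.5))
  taut <- semantic_channel(matrix(1, 2, 3))
  ch <- rand_channel(2, 3, u$labels)
  expect_equal(semantic_mi(u, ch, taut), 0)

  # matched channels: constraint from the channel by LBI gives G = R
  set.seed(3)
  for (r in 1:20) {
    nx <- sample(2:5, 1); ny <- sample(2:4, 1)
    src <- rand_distribution(nx)
    chan <- rand_channel(nx, ny, src$labels)
    sc <- lbi_truth_from_channel(chan)
    expect_equal(semantic_mi(src, chan, sc), shannon_mi(src, chan),
                 tolerance = 1e-9)
  }

  sc <- semantic_channel(matrix(c(1, 0.25, 0.25, 1), 2, 2))
  expect_equal(semantic_mi(u, shannon_channel(diag(2)), sc),
               oracle_semantic_mi(c(0.5, 0.5), diag(2), sc$table),
               tolerance = 1e-12)

  # likelihood form and truth form agree when they encode the same ratios
  set.seed(5)
  for (r in 1:15) {
    nx <- sample(2:5, 1); k <- sample(2:4, 1)
    src <- rand_distribution(nx)
    lik <- rand_likelihoods(nx, k, src$labels)
    m <- lik$columns / src$probs
    truth <- sweep(m, 2, apply(m, 2, max), "/")
    sct <- semantic_channel(truth, src$labels, lik$theta_labels)
    chan <- rand_channel(nx, k, src$labels)
    expect_equal(semantic_mi(src, chan, lik), semantic_mi(src, chan, sct),
                 tolerance = 1e-9)
  }
})

test_that("semantic information is -Inf with a warning on zero-ratio mass", {
  u <- discrete_distribution(c(0.5, 0.5))
  sc <- semantic_channel(matrix(c(0, 1, 1, 1), 2, 2))
  ch <- shannon_channel(diag(2))
  expect_warning(g <- semantic_mi(u, ch, sc),
                 class = "infoeff_infinite_information")
  expect_identical(g, -Inf)
})

test_that("per-label cross-entropy worked example: dispersion raises the cost", {
  model <- c(0.1, 0.4, 0.4, 0.1)
  concentrated <- c(0, 0.5, 0.5, 0)
  expect_equal(label_cross_entropy(concentrated, model), log2(10 / 4),
               tolerance = 1e-12)
  expect_equal(label_cross_entropy(model, model),
               0.2 * log2(10) + 0.8 * log2(10 / 4), tolerance = 1e-12)
  # equals the Shannon conditional entropy when posterior matches the model
  expect_equal(label_cross_entropy(model, model),
               shannon_entropy(discrete_distribution(model)), tolerance = 1e-12)
})

test_that("semantic conditional entropy matches its defining sum", {
  set.seed(6)
  for (r in 1:15) {
    nx <- sample(2:5, 1); k <- sample(2:4, 1)
    src <- rand_distribution(nx)
    chan <- rand_channel(nx, k, src$labels)
    lik <- rand_likelihoods(nx, k, src$labels)
    expect_equal(semantic_cond_entropy(src, chan, lik),
                 oracle_semantic_cond_entropy(src$probs, chan$table, lik$columns),
                 tolerance = 1e-12)
  }
})

test_that("entropy report fields match independent brute-force sums", {
  set.seed(8)
  src <- rand_distribution(3)
  chan <- rand_channel(3, 2, src$labels)
  lik <- rand_likelihoods(3, 2, src$labels)
  prior <- rand_distribution(2)
  prior <- discrete_distribution(prior$probs, chan$y_labels)
  rep <- entropy_report(src, chan, lik, prior_y = prior)

  jnt <- src$probs * chan$table
  py_plus <- colSums(jnt)
  expect_equal(rep$R, oracle_shannon_mi(src$probs, chan$table), tolerance = 1e-12)
  m <- lik$columns / src$probs
  expect_equal(rep$G, sum(jnt * log2(m)), tolerance = 1e-12)
  expect_equal(rep$H_X, -sum(src$probs * log2(src$probs)), tolerance = 1e-12)
  expect_equal(rep$H_XgYtheta, -sum(jnt * log2(lik$columns)), tolerance = 1e-12)
  expect_equal(rep$KL_Yplus_Y, oracle_kl(py_plus, prior$probs), tolerance = 1e-12)
  expect_equal(rep$F, rep$H_XgYtheta + rep$KL_Yplus_Y, tolerance = 1e-12)
  expect_equal(rep$F_prime, -rep$F, tolerance = 1e-12)
  model_joint <- sweep(lik$columns, 2, prior$probs, "*")
  expect_equal(rep$Q, sum(jnt * log2(model_joint)), tolerance = 1e-12)
  expect_equal(rep$F_sharp, sum(jnt * log2(chan$table / model_joint)),
               tolerance = 1e-12)
  ptheta <- as.numeric(lik$columns %*% prior$probs)
  expect_equal(rep$KL_P_Ptheta, oracle_kl(src$probs, ptheta), tolerance = 1e-12)

  # matched prior: F collapses to the semantic conditional entropy
  rep2 <- entropy_report(src, chan, lik)
  expect_equal(rep2$F, rep2$H_XgYtheta, tolerance = 1e-12)

  # perfect model: model posteriors equal actual posteriors, prior matched
  post <- posterior_x(chan, src)
  likp <- likelihood_family(post, src$labels, chan$y_labels)
  rep3 <- entropy_report(src, chan, likp)
  expect_equal(rep3$F, rep3$H_XgY, tolerance = 1e-12)
  H_XY <- -sum(jnt * log2(jnt))
  expect_equal(rep3$Q, -H_XY, tolerance = 1e-12)
})

test_that("information difference identity holds on random triples", {
  set.seed(9)
  for (r in 1:200) {
    nx <- sample(2:6, 1); k <- sample(2:5, 1)
    src <- rand_distribution(nx)
    chan <- rand_channel(nx, k, src$labels)
    sc <- rand_truth(nx, k, src$labels)
    rep <- entropy_report(src, chan, sc)
    expect_lt(abs((rep$R - rep$G) - (rep$H_XgYtheta - rep$H_XgY)), 1e-9)
    expect_gte(rep$R - rep$G, -1e-10)
    # R - G is the posterior-weighted KL between actual and model posteriors
    post <- posterior_x(chan, src)
    mp <- model_posteriors(sc, src)
    py <- colSums(src$probs * chan$table)
    rg <- sum(vapply(seq_len(k), function(j) {
      py[j] * oracle_kl(post[, j], mp[, j])
    }, numeric(1)))
    expect_equal(rep$R - rep$G, rg, tolerance = 1e-9)
  }
})

test_that("bits and nats differ exactly by ln 2", {
  set.seed(10)
  src <- rand_distribution(4)
  chan <- rand_channel(4, 3, src$labels)
  sc <- rand_truth(4, 3, src$labels)
  expect_equal(shannon_mi(src, chan, unit = "nats"),
               shannon_mi(src, chan) * log(2), tolerance = 1e-12)
  expect_equal(semantic_mi(src, chan, sc, unit = "nats"),
               semantic_mi(src, chan, sc) * log(2), tolerance = 1e-12)
})

test_that("info reports serialize to a flat row and JSON", {
  set.seed(12)
  src <- rand_distribution(3)
  chan <- rand_channel(3, 2, src$labels)
  lik <- rand_likelihoods(3, 2, src$labels)
  rep <- entropy_report(src, chan, lik)
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 1)
  expect_true(all(c("R", "G", "F", "Q") %in% names(df)))
  f <- tempfile(fileext = ".json")
  write_report_json(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$R, rep$R, tolerance = 1e-12)
  expect_equal(back$F, rep$F, tolerance = 1e-12)
})
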