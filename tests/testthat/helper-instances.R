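# Random problem generators and independent brute-force oracles used across
# the suite. The oracles evaluate the defining double sums directly and never
# share code with the implementation paths they check.

rand_distribution <- function(nx, full_support = TRUE) {
  w <- stats::runif(nx) + if (full_support) 1e-3 else 0
  renormalize(w)
}

rand_channel <- function(nx, ny, x_labels = paste0("x", seq_len(nx))) {
  tab <- matrix(stats::runif(nx * ny) + 1e-3, nx, ny)
  shannon_channel(tab / rowSums(tab), x_labels, paste0("y", seq_len(ny)))
}

rand_truth <- function(nx, k, x_labels = paste0("x", seq_len(nx))) {
  semantic_channel(matrix(stats::runif(nx * k, 0.05, 1), nx, k),
                   x_labels, paste0("y", seq_len(k)))
}

rand_likelihoods <- function(nx, k, x_labels = paste0("x", seq_len(nx))) {
  cols <- matrix(stats::runif(nx * k) + 1e-3, nx, k)
  likelihood_family(sweep(cols, 2, colSums(cols), "/"),
                    x_labels, paste0("y", seq_len(k)))
}

# direct double-sum Shannon MI, bits
oracle_shannon_mi <- function(px, pygx) {
  jnt <- px * pygx
  py <- colSums(jnt)
  tot <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (jnt[i, j] > 0) tot <- tot + jnt[i, j] * log2(jnt[i, j] / (px[i] * py[j]))
  }
  unname(tot)
}

# direct double-sum semantic MI given truth table, bits
oracle_semantic_mi <- function(px, pygx, truth) {
  tt <- as.numeric(crossprod(truth, px))
  jnt <- px * pygx
  tot <- 0
  for (i in seq_along(px)) for (j in seq_along(tt)) {
    if (jnt[i, j] > 0) tot <- tot + jnt[i, j] * log2(truth[i, j] / tt[j])
  }
  unname(tot)
}

# direct H(X|Y_theta) given model posterior columns, bits
oracle_semantic_cond_entropy <- function(px, pygx, px_theta) {
  jnt <- px * pygx
  tot <- 0
  for (i in seq_along(px)) for (j in seq_len(ncol(pygx))) {
    if (jnt[i, j] > 0) tot <- tot - jnt[i, j] * log2(px_theta[i, j])
  }
  unname(tot)
}

oracle_kl <- function(p, q) {
  tot <- 0
  for (i in seq_along(p)) if (p[i] > 0) tot <- tot + p[i] * log2(p[i] / q[i])
  unname(tot)
}

# exhaustive grid search over 2-output row-stochastic channels, returns the
# minimum of R - s G at the given resolution
oracle_rg_grid_search <- function(source, constraint, s, resolution = 0.01) {
  labels <- if (inherits(constraint, "semantic_channel")) {
    constraint$theta_labels
  } else constraint$theta_labels
  stopifnot(length(labels) == 2, length(source) == 2)
  m <- prediction_ratio(constraint, source)
  best <- Inf
  for (p in seq(0, 1, resolution)) for (q in seq(0, 1, resolution)) {
    tab <- matrix(c(p, 1 - p, q, 1 - q), 2, byrow = TRUE)
    jnt <- source$probs * tab
    R <- oracle_shannon_mi(source$probs, tab)
    pos <- jnt > 0
    if (any(pos & m == 0)) next
    G <- sum(jnt[pos] * log2(m[pos]))
    best <- min(best, R - s * G)
  }
  best
}
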