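# Internal numeric helpers shared across modules.

# log with the unit convention used throughout: "bits" (log2) or "nats" (ln).
.ilog <- function(x, unit = "bits") {
  if (unit == "bits") log2(x) else log(x)
}

# x * log(y) with the 0 * log(0) := 0 convention. Positive mass on a zero
# model probability yields a signed infinity, never NaN.
.xlogy <- function(x, y, unit = "bits") {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * .ilog(y[pos], unit)
  out
}

.entropy <- function(p, unit = "bits") {
  -sum(.xlogy(p, p, unit))
}

# KL(p || q); p_i > 0 with q_i = 0 contributes +Inf.
.kl <- function(p, q, unit = "bits") {
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  sum(p[pos] * .ilog(p[pos] / q[pos], unit))
}

.logsumexp <- function(lw) {
  m <- max(lw)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(lw - m)))
}

.match_unit <- function(unit) {
  match.arg(unit, c("bits", "nats"))
}

.stop_class <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "infoeff_error")))
}

.warn_class <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "infoeff_warning")))
}
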