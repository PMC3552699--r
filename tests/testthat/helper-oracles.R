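# Independent oracles, re-derived with stats:: primitives only.

# brute-force enumeration oracle for the variance-adaptive permutation test:
# recomputes every permutation's adaptive p with stats::var.test/t.test
perm_oracle <- function(x, y, f_alpha = 0.05) {
  z <- c(x, y); n1 <- length(x); n <- length(z)
  obs_p <- function(g1) {
    a <- z[g1]; b <- z[-g1]
    fp <- tryCatch(stats::var.test(a, b)$p.value, error = function(e) 0)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
    tryCatch(
      stats::t.test(a, b, var.equal = fp >= f_alpha)$p.value,
      error = function(e) 1)
  }
  p0 <- obs_p(seq_len(n1))
  sets <- utils::combn(n, n1)
  mean(apply(sets, 2, obs_p) <= p0 + 1e-12)
}
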