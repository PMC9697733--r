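# Independent brute-force oracles used to freeze expected values.

# Exact two-sided rank-sum p-value by full enumeration of all assignments
# of the pooled ranks to group A. Independent of stats::pwilcox.
enum_wilcox_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  rk <- rank(c(a, b))
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(na + nb, na)
  u_all <- apply(idx, 2, function(s) sum(rk[s]) - na * (na + 1) / 2)
  p <- if (u_obs > na * nb / 2) mean(u_all >= u_obs) else mean(u_all <= u_obs)
  min(2 * p, 1)
}

# Sort-based median oracle (explicit order statistics).
sort_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
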