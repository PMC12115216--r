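# Independent brute-force oracle: exact two-sided Mann-Whitney p by
# enumerating every assignment of pooled ranks to the first sample.
enumerate_mw_p <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  2 * min(mean(us <= u_obs), mean(us >= u_obs), 0.5)
}
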