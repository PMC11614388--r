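# Independent oracles used to check the implementation. These deliberately
# use brute force (naive loops, full enumeration) and never call the code
# paths they verify.

# O(n^2) convolution by double loop
naive_convolve <- function(a, b, K) {
  out <- numeric(K + 1)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    s <- i + j - 2
    if (s <= K) out[s + 1] <- out[s + 1] + a[i] * b[j]
  }
  out
}

# isotope pattern by convolving one atom at a time
naive_natural_pattern <- function(f, K, table = default_isotope_table()) {
  out <- c(1, numeric(K))
  for (el in names(f)) {
    e <- table[[el]]
    atom <- numeric(K + 1)
    keep <- e$shift <= K
    atom[e$shift[keep] + 1] <- e$abundance[keep]
    for (i in seq_len(f[[el]])) out <- naive_convolve(out, atom, K)
  }
  out
}

# exact two-sided rank-sum p by full enumeration of all C(n1+n2, n1)
# group-A rank assignments
enum_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(length(pooled), n1), 2,
              function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# BH step-up by hand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# forward substitution on the square upper block of a purity-1 (lower
# triangular) correction matrix; valid for noise-free data only
back_substitution_mid <- function(raw, A) {
  n <- ncol(A)
  x <- numeric(n)
  for (i in seq_len(n)) {
    x[i] <- (raw[i] - sum(A[i, seq_len(i - 1)] * x[seq_len(i - 1)])) / A[i, i]
  }
  x / sum(x)
}

# random fragment-like formula (always carbon-bearing, TBDMS-ish elements)
random_formula <- function() {
  counts <- c(C = sample(1:8, 1), H = sample(0:20, 1), N = sample(0:2, 1),
              O = sample(0:6, 1), Si = sample(0:2, 1))
  elemental_formula(counts[counts > 0])
}

random_mid <- function(n) {
  x <- stats::rgamma(n + 1, shape = 1)
  x / sum(x)
}
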