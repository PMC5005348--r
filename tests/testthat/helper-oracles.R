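# independent oracles, kept deliberately naive and differently parametrised
# from the implementation they check

# conditional NB exact test by explicit enumeration, size/prob parametrisation
oracle_nb_exact <- function(kA, kB, sfA, sfB, alpha) {
  total <- kA + kB
  if (total == 0) return(1)
  sA <- sum(sfA); sB <- sum(sfB)
  sizeA <- sA^2 / (alpha * sum(sfA^2))
  sizeB <- sB^2 / (alpha * sum(sfB^2))
  q0 <- total / (sA + sB)
  pA <- sizeA / (sizeA + q0 * sA)
  pB <- sizeB / (sizeB + q0 * sB)
  joint <- vapply(0:total, function(a) {
    dnbinom(a, size = sizeA, prob = pA) *
      dnbinom(total - a, size = sizeB, prob = pB)
  }, numeric(1))
  sum(joint[joint <= joint[kA + 1] * (1 + 1e-7)]) / sum(joint)
}

# hypergeometric upper tail P(X >= b) from binomial coefficients
oracle_hyper_upper <- function(b, N, B, n) {
  ks <- b:min(B, n)
  if (b > min(B, n)) return(0)
  sum(exp(lchoose(B, ks) + lchoose(N - B, n - ks) - lchoose(N, n)))
}

# hypergeometric lower tail P(X <= x)
oracle_hyper_lower <- function(x, N, B, n) {
  ks <- max(0, n - (N - B)):x
  sum(exp(lchoose(B, ks) + lchoose(N - B, n - ks) - lchoose(N, n)))
}

# median-of-ratios size factors via explicit per-gene loops
oracle_size_factors <- function(counts) {
  geo <- apply(counts, 1, function(r) prod(r)^(1 / length(r)))
  keep <- geo > 0
  sapply(seq_len(ncol(counts)), function(j) {
    median(counts[keep, j] / geo[keep])
  })
}

# Pearson r from the raw covariance formula
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
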