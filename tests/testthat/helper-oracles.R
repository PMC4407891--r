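# Brute-force oracles, independent of the implementation paths they check.

# two-sided Fisher exact P for the 2x2 table [[a, b], [c, d]] by summing
# hypergeometric point probabilities no larger than the observed one
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  pk <- stats::dhyper(k, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  sum(pk[pk <= pobs * (1 + 1e-7)])
}

# one-sided (enrichment) Fisher exact P: upper hypergeometric tail
oracle_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  pk <- stats::dhyper(k, r1, r2, c1)
  sum(pk[k >= a])
}

# exact two-sided Wilcoxon rank-sum P by enumerating all assignments of the
# pooled observations to the two groups (tie-free data only)
oracle_wilcox_two_sided <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  sets <- utils::combn(length(pooled), n)
  u_null <- apply(sets, 2, function(i) u_of(pooled[i], pooled[-i]))
  p_lo <- mean(u_null <= u_obs)
  p_hi <- mean(u_null >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Kolmogorov-Smirnov D by brute-force maximum ECDF gap
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# exact mean/SD of the bootstrap-null RED of one event: both samples redrawn
# as binomials of their observed totals under the pooled set2 proportion,
# with the +0.5-on-zero pseudocount
oracle_saap_null <- function(a1, a2, b1, b2) {
  na <- a1 + a2; nb <- b1 + b2
  p2 <- (a2 + b2) / (na + nb)
  ka <- 0:na; kb <- 0:nb
  pa <- stats::dbinom(ka, na, p2)
  pb <- stats::dbinom(kb, nb, p2)
  red1 <- function(x1, x2, y1, y2) {
    z <- x1 == 0 | x2 == 0 | y1 == 0 | y2 == 0
    x1 <- x1 + 0.5 * z; x2 <- x2 + 0.5 * z; y1 <- y1 + 0.5 * z; y2 <- y2 + 0.5 * z
    log2(x2 / x1) - log2(y2 / y1)
  }
  grid <- expand.grid(ka = ka, kb = kb)
  r <- red1(na - grid$ka, grid$ka, nb - grid$kb, grid$kb)
  w <- pa[grid$ka + 1] * pb[grid$kb + 1]
  mu <- sum(w * r)
  list(mean = mu, sd = sqrt(sum(w * (r - mu)^2)))
}
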