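# Independent dense oracles for the combined statistics: literal
# evaluation of the printed formulas with explicit matrix inverses, no
# code shared with the package implementation.

oracle_w <- function(n, scheme = "sqrt_n") {
  switch(scheme, sqrt_n = sqrt(n), n = n, unit = rep(1, length(n)))
}

# S_Hom = [e'(RW)^-1 T]^2 / [e'(WRW)^-1 e]
s_hom_oracle <- function(T, n, R, scheme = "sqrt_n") {
  obs <- which(is.finite(T))
  T <- T[obs]; R <- R[obs, obs, drop = FALSE]
  W <- diag(oracle_w(n[obs], scheme), length(obs))
  e <- rep(1, length(obs))
  num <- drop(t(e) %*% solve(R %*% W) %*% T)^2
  den <- drop(t(e) %*% solve(W %*% R %*% W) %*% e)
  num / den
}

# S(tau) on the active set with sign-aligned weights
s_tau_oracle <- function(T, n, R, tau, scheme = "sqrt_n") {
  act <- which(is.finite(T) & abs(T) > tau)
  if (!length(act)) return(NA_real_)
  Ta <- T[act]
  W <- diag(oracle_w(n[act], scheme) * sign(Ta), length(act))
  Ra <- R[act, act, drop = FALSE]
  e <- rep(1, length(act))
  num <- drop(t(e) %*% solve(Ra %*% W) %*% Ta)^2
  den <- drop(t(e) %*% solve(W) %*% solve(Ra) %*% solve(W) %*% e)
  num / den
}

# Exhaustive S_Het: evaluate S on every threshold-reachable subset (a
# subset is reachable iff its smallest |T| strictly exceeds every
# excluded |T|), take the max.
s_het_oracle <- function(T, n, R, scheme = "sqrt_n") {
  obs <- which(is.finite(T))
  Tn <- T[obs]
  if (all(Tn == 0)) return(0)
  m <- length(Tn)
  best <- -Inf
  for (mask in 1:(2^m - 1)) {
    sub <- which(bitwAnd(mask, 2^(0:(m - 1))) > 0)
    inn <- abs(Tn[sub]); out <- abs(Tn[-sub])
    if (length(out) && min(inn) <= max(out)) next
    if (any(inn == 0)) next
    W <- diag(oracle_w(n[obs][sub], scheme) * sign(Tn[sub]), length(sub))
    Ra <- R[obs[sub], obs[sub], drop = FALSE]
    e <- rep(1, length(sub))
    s <- tryCatch({
      num <- drop(t(e) %*% solve(Ra %*% W) %*% Tn[sub])^2
      den <- drop(t(e) %*% solve(W) %*% solve(Ra) %*% solve(W) %*% e)
      num / den
    }, error = function(e) NA_real_)
    if (!is.na(s) && s > best) best <- s
  }
  best
}

# random correlation matrix with eigenvalues bounded away from zero
random_corr <- function(p, jitter = 0.3) {
  A <- matrix(stats::rnorm(p * p), p)
  stats::cov2cor(crossprod(A) + diag(p) * jitter * p)
}

random_case <- function(p_max = 6) {
  p <- sample(2:p_max, 1)
  list(T = stats::rnorm(p, sd = 2),
       n = sample(1000:100000, p, replace = TRUE),
       R = random_corr(p))
}
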