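test_that("s_hom trivial cases", {
  R <- matrix(c(1, 0.2, 0.2, 1), 2)
  z0 <- s_hom(c(0, 0), c(100, 100), R)
  expect_equal(z0$stat, 0)
  expect_equal(z0$p, 1)

  one <- s_hom(2.0, n = 1, R = matrix(1), w = weight_spec("unit"))
  expect_equal(one$stat, 4.0)
  expect_equal(one$p, pchisq(4, 1, lower.tail = FALSE))

  # missing panels subset T, R, W
  m <- s_hom(c(NA, 3.0), c(100, 200), R)
  expect_equal(m$stat, 9.0)
  expect_equal(m$n_panels_used, 1L)
  allm <- s_hom(c(NA_real_, NA_real_), c(1, 1), R)
  expect_true(is.na(allm$stat))
})

test_that("the Table-2-style worked example is genome-wide significant", {
  # sex-specific evidence reconstructed from two-sided p-values and beta
  # signs; neither panel alone reaches 5e-8, the combination does
  z_m <- z_from_record(-1, p = 3.88e-5, mode = "p_sign")
  z_f <- z_from_record(-1, p = 2.11e-5, mode = "p_sign")
  res <- s_hom(c(z_m, z_f), n = c(60586, 73137),
               R = matrix(c(1, 0.0126, 0.0126, 1), 2))
  expect_lt(res$p, 5e-8)
  expect_gt(min(3.88e-5, 2.11e-5), 1e-7)
})

test_that("s_tau: single component, signed-weight algebra, empty set", {
  expect_equal(s_tau(3.0, n = 1, R = matrix(1), w = weight_spec("unit"),
                     tau = 1.0), 9.0)
  # hand algebra: a = (1/w, -1/w), a'T = 5/w, a'a = 2/w^2 -> 12.5
  expect_equal(s_tau(c(2.5, -2.5), n = c(100, 100), R = diag(2), tau = 2.0),
               12.5)
  expect_true(is.na(s_tau(c(2.5, -2.5), n = c(100, 100), R = diag(2),
                          tau = 3.0)))
})

test_that("s_het: single panel, weak-component dropping, zero vector", {
  one <- s_het(-3.2, n = 1, R = matrix(1), w = weight_spec("unit"))
  expect_equal(one$stat, 10.24)
  expect_equal(one$active_set, 1L)

  two <- s_het(c(5.0, 0.1), n = c(1000, 1000), R = diag(2))
  expect_equal(two$stat, 25.0)           # dropping 0.1 beats keeping it
  expect_equal(two$active_set, 1L)
  expect_lt(two$tau_star, 5.0)
  expect_gt(two$tau_star, 5.0 - 1e-6)

  zero <- s_het(c(0, 0), n = c(10, 10), R = diag(2))
  expect_equal(zero$stat, 0)
})

test_that("oracle equivalence on random instances (dense formulas, subsets)", {
  set.seed(20)
  for (i in 1:40) {
    cs <- random_case()
    ref_hom <- s_hom_oracle(cs$T, cs$n, cs$R)
    got <- s_hom(cs$T, cs$n, cs$R)
    expect_equal(got$stat, ref_hom, tolerance = 1e-10)

    ref_het <- s_het_oracle(cs$T, cs$n, cs$R)
    goth <- s_het(cs$T, cs$n, cs$R)
    expect_equal(goth$stat, ref_het, tolerance = 1e-10)

    tau <- runif(1, 0, max(abs(cs$T)))
    expect_equal(s_tau(cs$T, cs$n, cs$R, tau = tau),
                 s_tau_oracle(cs$T, cs$n, cs$R, tau), tolerance = 1e-10)
  }
})

test_that("batch kernel agrees with the single-SNP reference", {
  set.seed(21)
  P <- 4; M <- 60
  R <- random_corr(P)
  n <- sample(5000:50000, P)
  z <- matrix(rnorm(M * P, sd = 1.5), M, P)
  z[sample(M * P, 25)] <- NA       # missingness handled by subsetting
  zp <- zpanel(data.frame(snp_id = sprintf("s%03d", 1:M), chromosome = "1",
                          position = 1:M * 100, effect_allele = "A",
                          other_allele = "G"),
               data.frame(cohort_id = paste0("c", 1:P), trait_id = "t",
                          n_max = n),
               z, matrix(rep(n, each = M), M, P))
  got <- cpassoc_batch(zp, R)
  for (i in seq_len(M)) {
    Ti <- z[i, ]
    if (all(is.na(Ti))) {
      expect_true(is.na(got$s_hom[i]))
      next
    }
    expect_equal(got$s_hom[i], s_hom(Ti, n, R)$stat, tolerance = 1e-10)
    expect_equal(got$s_het[i], s_het(Ti, n, R)$stat, tolerance = 1e-10)
  }
})

test_that("invariances: weight scaling, sign symmetry, reduction", {
  set.seed(22)
  cs <- random_case()
  # scaling all weights is a no-op (weights enter as a ratio)
  base <- s_hom(cs$T, cs$n, cs$R)$stat
  scaled <- s_hom(cs$T, cs$n * 7, cs$R, w = weight_spec("n"))$stat
  comp <- s_hom(cs$T, cs$n, cs$R, w = weight_spec("n"))$stat
  expect_equal(scaled, comp, tolerance = 1e-12)

  # sign symmetry
  expect_equal(s_hom(-cs$T, cs$n, cs$R)$stat, base, tolerance = 1e-12)
  expect_equal(s_het(-cs$T, cs$n, cs$R)$stat,
               s_het(cs$T, cs$n, cs$R)$stat, tolerance = 1e-12)

  # equal-n reduction: S_Hom == (weighted-Z)^2 with R = I
  T2 <- c(1.2, -0.4, 0.9)
  n2 <- c(8000, 8000, 8000)
  wz <- weighted_z_meta(T2, n2)
  expect_equal(s_hom(T2, n2, diag(3))$stat, wz$z^2, tolerance = 1e-10)
  # unequal n: the implemented form weights by 1/w, documented relation
  # checked against the dense oracle instead
  n3 <- c(2000, 60000, 8000)
  expect_equal(s_hom(T2, n3, diag(3))$stat, s_hom_oracle(T2, n3, diag(3)),
               tolerance = 1e-12)
})

test_that("s_het max over the tau grid dominates every evaluated S(tau)", {
  set.seed(23)
  for (i in 1:10) {
    cs <- random_case()
    sh <- s_het(cs$T, cs$n, cs$R)
    taus <- sort(unique(abs(cs$T))) - 1e-8
    vals <- vapply(taus, function(tau) {
      v <- s_tau(cs$T, cs$n, cs$R, tau = tau)
      if (is.na(v)) -Inf else v
    }, 0)
    expect_gte(sh$stat + 1e-12, max(vals))
  }
})

test_that("build_shet_null is deterministic and calibrated at moderate depth", {
  R <- diag(2)
  n <- c(1000, 1000)
  a <- build_shet_null(R, n = n, B = 20000, seed = 99)
  b <- build_shet_null(R, n = n, B = 20000, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_true(all(a$draws >= 0))

  # P(S_Het > chi2 95% quantile) for two independent equal-weight panels:
  # S_Het = max(T1^2, T2^2, (|T1|+|T2|)^2/2); exceedance probability
  # 0.132471 computed by numerical integration of the bivariate normal
  # (frozen oracle value; tolerance ~3 Monte Carlo SEs at B = 20000)
  q95 <- qchisq(0.95, 1)
  frac <- mean(a$draws > q95)
  expect_lt(abs(frac - 0.132471), 0.008)

  # B = 1000 vs larger B: medians within 5% relative
  small <- build_shet_null(R, n = n, B = 1000, seed = 5)
  expect_equal(median(small$draws), median(a$draws), tolerance = 0.05)

  # tail fit reproduces the empirical 99th percentile within 10%
  expect_lt(a$tail_fit$q99_rel_err, 0.10)
})

test_that("p_het: boundary, median, monotone fitted tail", {
  null <- build_shet_null(diag(2), n = c(100, 100), B = 20000, seed = 17)
  expect_equal(p_het(0, null), 1, tolerance = 2 / null$B)
  med <- median(null$draws)
  expect_equal(p_het(med, null), 0.5, tolerance = 0.02)
  # far-tail values come from the fitted beta and decrease monotonically
  grid <- seq(max(null$draws) + 1, max(null$draws) + 40, by = 2)
  pv <- p_het(grid, null)
  expect_true(all(diff(pv) < 0))
  expect_true(all(pv > 0 & pv < 1))
  expect_error(p_het(-1, null), ">= 0")
})

test_that("shet null round-trips through the portable text format", {
  null <- build_shet_null(matrix(c(1, .3, .3, 1), 2), n = c(500, 800),
                          B = 2000, seed = 3)
  base <- tempfile()
  write_shet_null(null, base)
  back <- read_shet_null(base)
  expect_equal(back$draws, null$draws)
  expect_equal(back$B, null$B)
  expect_equal(back$tail_fit$alpha, null$tail_fit$alpha)
  expect_equal(back$r_used$r, null$r_used$r, ignore_attr = TRUE)
  unlink(paste0(base, c(".tsv.gz", ".json")))
})

test_that("power ordering: S_Het wins under opposite effects, S_Hom under equal", {
  set.seed(31)
  R <- matrix(c(1, 0.096, 0.096, 1), 2)
  n <- c(60586, 73137)
  null <- build_shet_null(R, n = n, B = 50000, seed = 32)
  alpha <- 5e-4
  thr_het <- quantile(null$draws, 1 - alpha, names = FALSE)
  thr_hom <- qchisq(1 - alpha, 1)
  L <- chol(R)
  nrep <- 300
  power <- function(delta_vec) {
    Z <- matrix(rnorm(nrep * 2), nrep, 2) %*% L +
      matrix(delta_vec, nrep, 2, byrow = TRUE)
    W <- matrix(rep(sqrt(n), each = nrep), nrep, 2)
    res <- cpmeta:::.cpassoc_batch(Z, W, R, TRUE, TRUE, 1e-8)
    c(hom = mean(res$s_hom > thr_hom), het = mean(res$s_het > thr_het))
  }
  opp <- power(c(4, -4))
  expect_gt(opp["het"], opp["hom"])
  same <- power(c(4, 4))
  expect_gte(same["hom"], same["het"])
})
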