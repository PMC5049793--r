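test_that("ld_prune keeps low-r2 pairs and drops high-r2 ones", {
  # construct dosages with known pairwise r2: snp2 nearly copies snp1,
  # snp3 is independent
  set.seed(1)
  n <- 400
  g1 <- rbinom(n, 2, 0.3)
  g2 <- ifelse(runif(n) < 0.85, g1, rbinom(n, 2, 0.3))
  g3 <- rbinom(n, 2, 0.3)
  G <- cbind(s1 = g1, s2 = g2, s3 = g3)
  r2 <- cor(G)^2
  expect_gt(r2["s1", "s2"], 0.2)
  expect_lt(r2["s1", "s3"], 0.2)
  expect_lt(r2["s2", "s3"], 0.2)
  kept <- ld_prune(G, positions = c(100, 200, 300))
  expect_equal(as.character(kept), c("s1", "s3"))
  # brute-force post-condition: all retained pairs below threshold
  expect_true(all(cor(G[, kept])[upper.tri(diag(2))]^2 < 0.2))
})

test_that("independent SNPs are all retained; duplicates and monomorphic removed", {
  set.seed(7)
  G <- matrix(rbinom(500 * 30, 2, 0.4), 500, 30)
  colnames(G) <- paste0("s", 1:30)
  kept <- ld_prune(G, positions = 1:30 * 1000)
  expect_equal(length(kept), 30L)

  # duplicate column (r2 = 1) -> second removed; monomorphic excluded
  G2 <- cbind(G[, 1:3], dup = G[, 3], mono = rep(2L, 500))
  colnames(G2)[1:3] <- c("s1", "s2", "s3")
  kept2 <- ld_prune(G2, positions = 1:5 * 1000)
  expect_false("dup" %in% kept2)
  expect_true(all(c("s1", "s2", "s3") %in% kept2))
  expect_equal(attr(kept2, "monomorphic"), "mono")
})

test_that("select_null_snps applies the joint |Z| filter with inclusive boundary", {
  snps <- data.frame(snp_id = paste0("rs", 1:3), chromosome = "1",
                     position = 1:3 * 1000, effect_allele = "A",
                     other_allele = "G")
  panels <- data.frame(cohort_id = c("m", "f"), trait_id = "t",
                       n_max = c(100, 100))
  z <- rbind(c(1.0, -2.5), c(1.96, -1.96), c(0.5, 0.2))
  zp <- zpanel(snps, panels, z, matrix(100, 3, 2))
  kept <- select_null_snps(zp)
  expect_equal(kept$snps$snp_id, c("rs2", "rs3"))  # boundary kept
  expect_equal(attr(kept, "z_cut"), 1.96)
  expect_error(select_null_snps(zpanel_subset(zp, 1), z_cut = 0.5), "null SNPs")
})

test_that("null retention rate matches the binomial expectation", {
  set.seed(11)
  M <- 4000; P <- 3
  snps <- data.frame(snp_id = sprintf("s%04d", 1:M), chromosome = "1",
                     position = 1:M, effect_allele = "A", other_allele = "G")
  panels <- data.frame(cohort_id = paste0("c", 1:P), trait_id = "t",
                       n_max = 100)
  zp <- zpanel(snps, panels, matrix(rnorm(M * P), M, P), matrix(100, M, P))
  kept <- select_null_snps(zp)
  expect_equal(nrow(kept$z) / M, 0.95^P, tolerance = 0.03)
})

test_that("estimate_R: exact and sampling-error cases", {
  mk <- function(z) {
    M <- nrow(z)
    zpanel(data.frame(snp_id = sprintf("s%05d", 1:M), chromosome = "1",
                      position = 1:M, effect_allele = "A", other_allele = "G"),
           data.frame(cohort_id = paste0("c", 1:ncol(z)), trait_id = "t",
                      n_max = 100),
           z, matrix(100, M, ncol(z)))
  }
  # identical columns -> off-diagonal 1 (no truncation attribute, no correction)
  set.seed(2)
  z1 <- rnorm(200)
  cm <- estimate_R(mk(cbind(z1, z1)))
  expect_equal(cm$r[1, 2], 1)
  expect_equal(diag(cm$r), c(1, 1), ignore_attr = TRUE)

  # independent columns, 50k rows: off-diagonal within ±0.01 of 0
  z <- matrix(rnorm(50000 * 2), ncol = 2)
  cm2 <- estimate_R(mk(z))
  expect_lt(abs(cm2$r[1, 2]), 0.01)

  # too few shared rows errors naming the pair
  expect_error(estimate_R(mk(matrix(rnorm(20 * 2), ncol = 2))), "fewer than 30")
})

test_that("negating one Z column negates exactly that row/column of R", {
  set.seed(3)
  z <- matrix(rnorm(2000 * 3), ncol = 3)
  z[, 2] <- 0.5 * z[, 1] + z[, 2]
  mk <- function(z) {
    M <- nrow(z)
    zpanel(data.frame(snp_id = sprintf("s%05d", 1:M), chromosome = "1",
                      position = 1:M, effect_allele = "A", other_allele = "G"),
           data.frame(cohort_id = paste0("c", 1:3), trait_id = "t", n_max = 100),
           z, matrix(100, M, 3))
  }
  r0 <- estimate_R(mk(z))$r
  zneg <- z; zneg[, 2] <- -zneg[, 2]
  r1 <- estimate_R(mk(zneg))$r
  flip <- diag(c(1, -1, 1))
  expect_equal(r1, flip %*% r0 %*% flip, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("block-diagonal truth: cross-block entries shrink to 0 at 50k rows", {
  set.seed(4)
  R_true <- diag(4)
  R_true[1, 2] <- R_true[2, 1] <- 0.2
  R_true[3, 4] <- R_true[4, 3] <- 0.3
  L <- chol(R_true)
  z <- matrix(rnorm(50000 * 4), ncol = 4) %*% L
  M <- nrow(z)
  zp <- zpanel(data.frame(snp_id = sprintf("s%05d", 1:M), chromosome = "1",
                          position = 1:M, effect_allele = "A",
                          other_allele = "G"),
               data.frame(cohort_id = paste0("c", 1:4), trait_id = "t",
                          n_max = 100),
               z, matrix(100, M, 4))
  cm <- estimate_R(zp)
  expect_lt(max(abs(cm$r[1:2, 3:4])), 0.02)
  expect_equal(cm$r[1, 2], 0.2, tolerance = 0.02)
})

test_that("PSD repair is gentle on nearly-PSD matrices and restores PSD", {
  set.seed(5)
  for (i in 1:10) {
    R <- random_corr(5)
    P <- R + matrix(rnorm(25, sd = 0.004), 5)
    P <- (P + t(P)) / 2; diag(P) <- 1
    ev_min <- min(eigen(P, symmetric = TRUE)$values)
    fix <- near_psd(P)
    expect_gte(min(eigen(fix$r, symmetric = TRUE)$values), -1e-10)
    if (ev_min >= -0.01) expect_lt(max(abs(fix$r - P)), 0.05)
  }
})

test_that("truncation de-attenuation restores the untruncated correlation", {
  set.seed(6)
  r_true <- 0.25
  L <- chol(matrix(c(1, r_true, r_true, 1), 2))
  z <- matrix(rnorm(200000 * 2), ncol = 2) %*% L
  M <- nrow(z)
  zp <- zpanel(data.frame(snp_id = sprintf("s%06d", 1:M), chromosome = "1",
                          position = 1:M, effect_allele = "A",
                          other_allele = "G"),
               data.frame(cohort_id = c("m", "f"), trait_id = "t", n_max = 100),
               z, matrix(100, M, 2))
  nullp <- select_null_snps(zp, z_cut = 1.96)
  raw <- estimate_R(nullp, z_cut = NULL)$r[1, 2]
  corr <- estimate_R(nullp)$r[1, 2]
  expect_lt(raw, r_true - 0.03)        # attenuation is real
  expect_equal(corr, r_true, tolerance = 0.02)
})

test_that("corr matrix TSV round-trips with sidecar", {
  R <- matrix(c(1, .1, .1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  cm <- corr_matrix(R)
  f <- tempfile(fileext = ".tsv")
  write_corr(cm, f)
  back <- read_corr(f)
  expect_equal(back$r, cm$r)
  expect_equal(back$labels, cm$labels)
  unlink(c(f, paste0(f, ".json")))
})
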