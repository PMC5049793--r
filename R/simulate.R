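#' Simulation configuration for synthetic summary-statistic panels
#'
#' Describes a J-cohort x K-trait study in the style of the GIANT
#' sex-stratified anthropometric GWAS: panel columns are ordered cohort
#' fastest within trait (T_11, ..., T_J1, ..., T_1K, ..., T_JK).  Null
#' rows are multivariate normal with the stated between-panel correlation
#' R_true; causal SNPs receive a mean shift `sqrt(n_j) * b_jk * delta` so
#' that effect sizes are interpretable on the per-sqrt(n) scale.
#'
#' The default layout is two sex cohorts (sample sizes 60,586 males and
#' 73,137 females) and three traits (height, BMI, WHRadjBMI) with
#' male-female null correlations 0.0126, 0.096 and 0.03 respectively and
#' a small (0.01) residual correlation between traits.
#'
#' @param J,K cohort and trait counts.
#' @param M number of SNPs.
#' @param n per-cohort sample sizes (length J).
#' @param R_true (J*K) x (J*K) null correlation; default as described.
#' @param causal list of causal specifications, each
#'   `list(index =, pattern =, delta =)` where `pattern` is a length-J*K
#'   vector `b` and `delta >= 0` scales the mean shift.
#' @param maf_range range of simulated effect-allele frequencies.
#' @param cohorts,traits label vectors.
#' @param seed RNG seed (mandatory).
#' @return `sim_config` list, validated.
#' @export
sim_config <- function(J = 2L, K = 3L, M = 10000L,
                       n = c(60586, 73137),
                       R_true = NULL,
                       causal = list(),
                       maf_range = c(0.05, 0.5),
                       cohorts = NULL, traits = NULL,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(n) != J) stop("n must have one entry per cohort")
  if (is.null(cohorts))
    cohorts <- if (J == 2L) c("males", "females") else paste0("cohort", 1:J)
  if (is.null(traits))
    traits <- if (K <= 3L) c("height", "bmi", "whradjbmi")[1:K]
              else paste0("trait", 1:K)
  if (is.null(R_true)) R_true <- default_R_true(J, K)
  P <- J * K
  if (!all(dim(as.matrix(R_true)) == c(P, P)))
    stop("R_true must be (J*K) x (J*K)")
  ev <- eigen(as.matrix(R_true), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("R_true is not positive semidefinite")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) stop("maf must be in (0, 0.5]")
  for (cs in causal) {
    if (!all(c("index", "pattern", "delta") %in% names(cs)))
      stop("each causal entry needs index, pattern, delta")
    if (length(cs$pattern) != P) stop("causal pattern must have length J*K")
    if (cs$delta < 0) stop("delta must be >= 0")
    if (cs$index < 1 || cs$index > M) stop("causal index out of range")
  }
  structure(list(J = J, K = K, M = M, n = n, R_true = as.matrix(R_true),
                 causal = causal, maf_range = maf_range, cohorts = cohorts,
                 traits = traits, seed = seed),
            class = "sim_config")
}

# Default null correlation: male-female correlation within trait from the
# observed sex-stratified values (height 0.0126, BMI 0.096, WHRadjBMI
# 0.03); between-trait correlation much smaller (0.01).
default_R_true <- function(J, K) {
  P <- J * K
  R <- matrix(0.01, P, P)
  within <- c(0.0126, 0.096, 0.03)
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * J + 1L):(k * J)
    r_k <- within[((k - 1L) %% 3L) + 1L]
    R[idx, idx] <- r_k
  }
  diag(R) <- 1
  R
}

#' Simulate a summary-statistics panel with known truth
#'
#' Null rows are drawn from MVN(0, R_true); causal rows receive their
#' configured mean shift.  Effect estimates are back-filled so that the
#' Wald Z inverts exactly: `se = 1 / sqrt(2 maf (1 - maf) n)`,
#' `beta = z * se`.  SNPs are laid out on chromosomes 1..22 at 10 kb
#' spacing (no LD between scan rows by design).
#'
#' @param cfg a [sim_config()].
#' @return List with `zpanel` (a [zpanel]) and `truth` (data.frame:
#'   `snp_id`, `causal`, `pattern` label, `ncp` per-panel noncentrality as
#'   comma-separated string).
#' @export
simulate_zpanel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  P <- cfg$J * cfg$K
  M <- cfg$M
  L <- chol(cfg$R_true + diag(1e-12, P))
  Z <- matrix(stats::rnorm(M * P), M, P) %*% L
  n_panel <- rep(cfg$n, times = cfg$K)

  # mean shift sqrt(n_j) * b * delta, with delta on the per-sqrt(max n)
  # scale so the largest cohort's noncentral mean is b * delta
  shift <- matrix(0, M, P)
  for (cs in cfg$causal)
    shift[cs$index, ] <- shift[cs$index, ] +
      sqrt(n_panel / max(n_panel)) * cs$pattern * cs$delta
  Z <- Z + shift

  maf <- stats::runif(M, cfg$maf_range[1], cfg$maf_range[2])
  nmat <- matrix(rep(n_panel, each = M), M, P)
  se <- 1 / sqrt(2 * maf * (1 - maf) * nmat)
  beta <- Z * se

  per_chr <- ceiling(M / 22L)
  chr <- as.character(rep(1:22, each = per_chr, length.out = M))
  pos <- (sequence(rle(chr)$lengths)) * 10000L
  ids <- sprintf("snp%06d", seq_len(M))
  alleles <- matrix(c("A", "G"), M, 2, byrow = TRUE)

  panels <- data.frame(
    cohort_id = rep(cfg$cohorts, times = cfg$K),
    trait_id = rep(cfg$traits, each = cfg$J),
    n_max = n_panel, stringsAsFactors = FALSE
  )
  zp <- zpanel(
    data.frame(snp_id = ids, chromosome = chr, position = pos,
               effect_allele = alleles[, 1], other_allele = alleles[, 2],
               stringsAsFactors = FALSE),
    panels, Z, nmat, beta = beta, se = se
  )

  causal_idx <- vapply(cfg$causal, `[[`, 0, "index")
  truth <- data.frame(snp_id = ids, causal = FALSE,
                      pattern = "null",
                      ncp = "", stringsAsFactors = FALSE)
  for (cs in cfg$causal) {
    lab <- classify_pattern(cs$pattern, cfg$J, cfg$K)
    truth$causal[cs$index] <- TRUE
    truth$pattern[cs$index] <- lab
    truth$ncp[cs$index] <- paste(
      signif(sqrt(n_panel / max(n_panel)) * cs$pattern * cs$delta, 6),
      collapse = ",")
  }
  # rows were possibly re-sorted by zpanel(); align truth to the panel
  truth <- truth[match(zp$snps$snp_id, truth$snp_id), , drop = FALSE]
  rownames(truth) <- NULL
  list(zpanel = zp, truth = truth)
}

classify_pattern <- function(b, J, K) {
  nz <- b != 0
  if (!any(nz)) return("null")
  cohort_of <- rep(seq_len(J), times = K)
  if (length(unique(cohort_of[nz])) == 1L && J > 1L) return("sex_specific")
  if (length(unique(b[nz])) == 1L && all(nz)) return("homogeneous")
  "heterogeneous"
}

#' Simulate a block-correlated genotype dosage matrix
#'
#' Fixture generator for LD pruning: within each block, every SNP copies a
#' shared ancestral allele with probability `sqrt(r)` per chromosome copy
#' (so the dosage correlation of any within-block pair is `r`); blocks are
#' mutually independent.
#'
#' @param n_samples number of individuals.
#' @param blocks list of `c(n_snps, r)` pairs (within-block dosage
#'   correlation `0 <= r < 1`).
#' @param maf minor-allele frequency of every SNP.
#' @param seed RNG seed.
#' @param spacing_bp base-pair spacing of consecutive SNPs.
#' @return List `genotypes` (samples x SNPs matrix, columns named) and
#'   `positions`.
#' @export
simulate_genotypes <- function(n_samples, blocks, maf = 0.3, seed,
                               spacing_bp = 1000L) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  mats <- lapply(seq_along(blocks), function(bi) {
    m <- blocks[[bi]][1]; r <- blocks[[bi]][2]
    if (r < 0 || r >= 1) stop("within-block r must be in [0, 1)")
    phi <- sqrt(r)
    hap <- function() {
      anc <- stats::rbinom(n_samples, 1L, maf)
      copy <- matrix(stats::rbinom(n_samples * m, 1L, phi), n_samples, m)
      fresh <- matrix(stats::rbinom(n_samples * m, 1L, maf), n_samples, m)
      copy * anc + (1L - copy) * fresh
    }
    hap() + hap()
  })
  g <- do.call(cbind, mats)
  colnames(g) <- sprintf("gsnp%05d", seq_len(ncol(g)))
  list(genotypes = g,
       positions = seq_len(ncol(g)) * spacing_bp)
}

#' Write a simulated study as per-panel GIANT-style files
#'
#' One whitespace-delimited summary file per (cohort, trait) panel, a
#' truth TSV, the true correlation matrix and a manifest JSON recording
#' paths and seed.
#'
#' @param sim output of [simulate_zpanel()].
#' @param dir output directory (created).
#' @param cfg the [sim_config()] used (for the manifest and R_true).
#' @return Manifest list (invisibly); files written under `dir`.
#' @export
write_simulated_study <- function(sim, dir, cfg) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  zp <- sim$zpanel
  lab <- panel_labels(zp$panels)
  recs <- zpanel_records(zp)
  files <- character(0)
  for (j in seq_along(lab)) {
    df <- recs[[j]]
    out <- data.frame(SNP = df$snp_id, CHR = df$chromosome, POS = df$position,
                      EA = df$effect_allele, OA = df$other_allele,
                      EAF = df$eaf, BETA = df$beta, SE = df$se,
                      P = df$p_value, N = df$n)
    f <- file.path(dir, paste0("sumstats_", gsub(":", "_", lab[j]), ".tsv"))
    data.table::fwrite(out, f, sep = "\t", na = "NA", quote = FALSE)
    files <- c(files, f)
  }
  truth_f <- file.path(dir, "truth.tsv")
  data.table::fwrite(sim$truth, truth_f, sep = "\t", quote = FALSE)
  r_f <- file.path(dir, "R_true.tsv")
  write_corr(corr_matrix(cfg$R_true, labels = lab), r_f)
  manifest <- list(panels = lab, files = files, truth = truth_f,
                   r_true = r_f, seed = cfg$seed, M = cfg$M,
                   J = cfg$J, K = cfg$K, n = cfg$n)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
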