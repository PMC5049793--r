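#' Weight specification for the combined statistics
#'
#' The diagonal weight matrix W enters the combined statistic through
#' `a = W^-1 e`.  The default scheme `"sqrt_n"` sets `w_jk = sqrt(n_j)`;
#' `"n"` uses the sample size itself and `"unit"` ignores sample size.
#' With `per_snp = TRUE` the per-SNP sample size is used when the panel
#' carries one, otherwise the panel maximum.
#'
#' @param scheme one of `"sqrt_n"`, `"n"`, `"unit"`.
#' @param per_snp logical; use per-SNP sample sizes.
#' @return An object of class `weight_spec`.
#' @export
weight_spec <- function(scheme = c("sqrt_n", "n", "unit"), per_snp = TRUE) {
  structure(list(scheme = match.arg(scheme), per_snp = isTRUE(per_snp)),
            class = "weight_spec")
}

panel_w <- function(n, spec) {
  switch(spec$scheme,
         sqrt_n = sqrt(n),
         n = n,
         unit = rep(1, length(n)))
}

#' Homogeneous-effect combined statistic S_Hom
#'
#' Combines the panel Z statistics of one SNP under the assumption of a
#' shared effect across cohorts and traits, accounting for the null
#' correlation R of the statistics:
#' `S_Hom = (e'(RW)^-1 T)^2 / (e'(WRW)^-1 e)`, which follows a chi-squared
#' distribution with one degree of freedom under the null.  Missing
#' entries of `T` are handled by restricting T, R and W to the observed
#' panels.
#'
#' @param T numeric vector of panel Z statistics (may contain `NA`).
#' @param n per-panel sample sizes (same length).
#' @param R correlation matrix of the statistics under the null (matrix or
#'   [corr_matrix()]).
#' @param w a [weight_spec()].
#' @return List with `stat`, `p` (upper-tail chi-squared, 1 df) and
#'   `n_panels_used`; `stat` is `NA` when every panel is missing.
#' @export
#' @examples
#' s_hom(c(2, 2), n = c(1000, 1000), R = diag(2))
s_hom <- function(T, n, R, w = weight_spec()) {
  R <- as_corr(R, length(T))
  obs <- which(is.finite(T))
  if (!length(obs))
    return(list(stat = NA_real_, p = NA_real_, n_panels_used = 0L))
  t_o <- T[obs]
  a <- 1 / panel_w(n[obs], w)
  Rs <- R[obs, obs, drop = FALSE]
  x <- tryCatch(solve(Rs, cbind(a, t_o)), error = function(e) NULL)
  if (is.null(x))
    stop("singular correlation matrix after missing-panel subsetting")
  den <- sum(a * x[, 1]); num <- sum(a * x[, 2])
  stat <- num^2 / den
  list(stat = stat, p = stats::pchisq(stat, 1L, lower.tail = FALSE),
       n_panels_used = length(obs))
}

#' Truncated combined statistic S(tau)
#'
#' The S_Hom-form quadratic restricted to the active set of panels with
#' `|T| > tau`, with sign-aligned weights `w_jk * sign(T_jk)`.  Undefined
#' (`NA`) when the active set is empty or the restricted correlation
#' matrix is singular.
#'
#' @inheritParams s_hom
#' @param tau positive truncation threshold.
#' @return The statistic value, or `NA` when undefined.
#' @export
s_tau <- function(T, n, R, w = weight_spec(), tau) {
  stopifnot(tau > 0)
  R <- as_corr(R, length(T))
  act <- which(is.finite(T) & abs(T) > tau)
  if (!length(act)) return(NA_real_)
  t_a <- T[act]
  a <- sign(t_a) / panel_w(n[act], w)
  Rs <- R[act, act, drop = FALSE]
  x <- tryCatch(solve(Rs, cbind(a, t_a)), error = function(e) NULL)
  if (is.null(x)) return(NA_real_)
  den <- sum(a * x[, 1])
  if (den <= 0) return(NA_real_)
  sum(a * x[, 2])^2 / den
}

#' Heterogeneous-effect combined statistic S_Het
#'
#' `S_Het = max over tau > 0 of S(tau)`.  Because S(tau) is piecewise
#' constant between the order statistics of `|T|`, the maximum over the
#' finite grid of thresholds just below each distinct non-zero `|T|` is
#' exact.  Ties are broken toward the smaller threshold (larger active
#' set).
#'
#' @inheritParams s_hom
#' @param tau_eps offset below each distinct `|T|` used for the candidate
#'   grid.
#' @return List with `stat`, `tau_star` (threshold attaining the max),
#'   `active_set` (indices with `|T| > tau_star`) and `n_panels_used`.
#' @export
s_het <- function(T, n, R, w = weight_spec(), tau_eps = 1e-8) {
  R <- as_corr(R, length(T))
  obs <- which(is.finite(T))
  if (!length(obs))
    return(list(stat = NA_real_, tau_star = NA_real_,
                active_set = integer(), n_panels_used = 0L))
  if (all(T[obs] == 0))
    return(list(stat = 0, tau_star = NA_real_, active_set = integer(),
                n_panels_used = length(obs)))
  grid <- sort(unique(abs(T[obs][T[obs] != 0])), decreasing = TRUE) - tau_eps
  best <- -Inf; best_tau <- NA_real_
  for (tau in grid) {
    s <- s_tau(T, n, R, w, tau)
    if (!is.na(s) && s >= best) { best <- s; best_tau <- tau }
  }
  if (!is.finite(best))
    return(list(stat = NA_real_, tau_star = NA_real_,
                active_set = integer(), n_panels_used = length(obs)))
  list(stat = best, tau_star = best_tau,
       active_set = which(is.finite(T) & abs(T) > best_tau),
       n_panels_used = length(obs))
}

as_corr <- function(R, p) {
  if (inherits(R, "corr_matrix")) R <- R$r
  R <- as.matrix(R)
  if (!all(dim(R) == c(p, p)))
    stop("correlation matrix dimension does not match T")
  R
}

weight_matrix <- function(zp, w) {
  if (w$per_snp) W <- zp$n
  else W <- matrix(rep(zp$panels$n_max, each = nrow(zp$z)), nrow(zp$z))
  W <- switch(w$scheme, sqrt_n = sqrt(W), n = W,
              unit = matrix(1, nrow(zp$z), ncol(zp$z)))
  W[is.na(zp$z)] <- NA_real_
  W
}

#' Batch S_Hom / S_Het over all SNPs of a panel
#'
#' Compiled batch version of [s_hom()] and [s_het()] used by genome-wide
#' scans; agrees with the single-SNP reference implementations to
#' numerical precision.
#'
#' @param zp a [zpanel].
#' @param R a [corr_matrix()] (or plain matrix) over the panel columns.
#' @param w a [weight_spec()].
#' @param what statistics to compute (`"s_hom"`, `"s_het"` or both).
#' @return data.frame with one row per SNP: `snp_id`, `chromosome`,
#'   `position`, `s_hom`, `p_hom`, `s_het`, `tau_star`, `n_panels_used`.
#'   `p_het` is appended by [cpassoc_scan()] once a null is available.
#' @export
cpassoc_batch <- function(zp, R, w = weight_spec(),
                          what = c("s_hom", "s_het")) {
  what <- match.arg(what, several.ok = TRUE)
  Rm <- as_corr(R, ncol(zp$z))
  W <- weight_matrix(zp, w)
  res <- .cpassoc_batch(zp$z, W, Rm, "s_hom" %in% what, "s_het" %in% what,
                        1e-8)
  if (any(res$hom_fail == 1))
    stop("singular correlation matrix after subsetting at SNP(s): ",
         paste(utils::head(zp$snps$snp_id[res$hom_fail == 1], 5),
               collapse = ", "))
  out <- data.frame(
    snp_id = zp$snps$snp_id,
    chromosome = zp$snps$chromosome,
    position = zp$snps$position,
    n_panels_used = res$n_used,
    stringsAsFactors = FALSE
  )
  if ("s_hom" %in% what) {
    out$s_hom <- res$s_hom
    out$p_hom <- stats::pchisq(res$s_hom, 1L, lower.tail = FALSE)
  }
  if ("s_het" %in% what) {
    out$s_het <- res$s_het
    out$tau_star <- res$tau_star
    out$n_active <- res$n_active
  }
  out
}

#' Monte Carlo null distribution of S_Het
#'
#' Draws `B` vectors from MVN(0, R) (via the Cholesky factor of the
#' PSD-repaired R), evaluates S_Het for each, and fits a beta tail model:
#' `V = exp(-S_Het / 2)` in (0, 1] is fitted with a Beta(alpha, beta)
#' distribution by maximum likelihood, so extreme p-values are computed as
#' `P(V <= v)`.  The fit diagnostic compares the fitted and empirical 99th
#' percentiles of S_Het.
#'
#' @param R a [corr_matrix()] or plain correlation matrix.
#' @param w a [weight_spec()].
#' @param n per-panel sample sizes used for the weights.
#' @param B number of Monte Carlo draws (>= 1000).
#' @param seed mandatory RNG seed; the null is fully reproducible from it.
#' @return Object of class `shet_null`: sorted `draws`, `B`, `seed`,
#'   `tail_fit` (list `alpha`, `beta`, `q99_rel_err`), plus the inputs.
#' @export
build_shet_null <- function(R, w = weight_spec(), n, B = 100000L, seed) {
  if (missing(seed)) stop("seed is mandatory for the S_Het null")
  if (B < 1000L) stop("B must be >= 1000")
  cm <- if (inherits(R, "corr_matrix")) R else corr_matrix(as.matrix(R))
  p <- length(cm$labels)
  if (length(n) != p) stop("n must have one entry per panel")
  L <- tryCatch(chol(cm$r), error = function(e) NULL)
  if (is.null(L)) {
    cm$r <- near_psd(cm$r)$r
    # tiny ridge: Cholesky needs strict positive definiteness
    L <- tryCatch(chol(cm$r + diag(1e-10, p)), error = function(e) NULL)
    if (is.null(L)) stop("correlation matrix not factorizable even after PSD repair")
  }
  set.seed(seed)
  Z <- matrix(stats::rnorm(B * p), B, p) %*% L
  W <- matrix(rep(panel_w(n, w), each = B), B, p)
  res <- .cpassoc_batch(Z, W, cm$r, FALSE, TRUE, 1e-8)
  draws <- sort(res$s_het)
  fit <- fit_beta_tail(draws)
  structure(
    list(draws = draws, B = B, seed = seed, tail_fit = fit,
         r_used = cm, w_used = w, n_used = n),
    class = "shet_null"
  )
}

# Beta tail model on V = exp(-S/2).  A beta fitted to the whole V sample
# tracks the bulk, not the extreme tail, and was measured several-fold
# conservative at p ~ 1e-6; instead the MLE uses only the top `tail_frac`
# of draws (smallest V), right-censoring the rest at the window edge, so
# the fitted shape reflects the tail exponent.  Still mildly conservative
# (factor ~2-4 at p ~ 5e-7 against a 2e6-draw reference), never
# anti-conservative in those checks.
fit_beta_tail <- function(draws, tail_frac = 0.01) {
  v <- exp(-draws / 2)
  v <- pmin(pmax(v, 1e-300), 1 - 1e-16)
  frac <- max(tail_frac, min(200 / length(v), 1))
  v_u <- stats::quantile(v, frac, names = FALSE)
  tail_v <- v[v < v_u]
  n_cens <- length(v) - length(tail_v)
  nll <- function(lp) {
    a <- exp(lp[1]); b <- exp(lp[2])
    -(sum(stats::dbeta(tail_v, a, b, log = TRUE)) +
        n_cens * stats::pbeta(v_u, a, b, lower.tail = FALSE, log.p = TRUE))
  }
  opt <- stats::optim(log(c(1, 3)), nll, method = "Nelder-Mead",
                      control = list(maxit = 500))
  a <- exp(opt$par[1]); b <- exp(opt$par[2])
  q99_emp <- stats::quantile(draws, 0.99, names = FALSE)
  q99_fit <- -2 * log(stats::qbeta(0.01, a, b))
  list(alpha = a, beta = b, tail_frac = frac,
       q99_rel_err = abs(q99_fit - q99_emp) / q99_emp,
       converged = opt$convergence == 0)
}

#' @export
print.shet_null <- function(x, ...) {
  cat(sprintf("shet_null: B = %d draws, %d panels, seed = %s\n",
              x$B, length(x$r_used$labels), format(x$seed)))
  cat(sprintf("tail fit: Beta(%.3f, %.1f), q99 rel. err. %.3f\n",
              x$tail_fit$alpha, x$tail_fit$beta, x$tail_fit$q99_rel_err))
  invisible(x)
}

#' p-value of S_Het against a Monte Carlo null
#'
#' Empirical tail probability `(1 + #\{draws >= s\}) / (B + 1)` while at
#' least 10 draws exceed the statistic; beyond that the fitted beta tail
#' takes over (`P(V <= exp(-s/2))`).
#'
#' @param stat S_Het statistic(s), non-negative (vectorised).
#' @param null a [build_shet_null()] object.
#' @param min_tail_count empirical/fitted crossover (default 10).
#' @return p-value(s) in (0, 1].
#' @export
p_het <- function(stat, null, min_tail_count = 10L) {
  if (!inherits(null, "shet_null")) stop("null must be a shet_null")
  if (any(stat < 0, na.rm = TRUE)) stop("S_Het statistic must be >= 0")
  B <- null$B
  # draws >= s  <=>  draws > s - eps  (draws are continuous)
  cnt <- B - findInterval(stat - 1e-12, null$draws)
  p <- (1 + cnt) / (B + 1)
  use_fit <- !is.na(stat) & cnt < min_tail_count
  if (any(use_fit)) {
    pf <- stats::pbeta(exp(-stat[use_fit] / 2), null$tail_fit$alpha,
                       null$tail_fit$beta)
    p[use_fit] <- pmin(pmax(pf, .Machine$double.xmin), 1)
  }
  p[is.na(stat)] <- NA_real_
  p
}

#' Persist / restore an S_Het null distribution
#'
#' Portable text representation: gzipped single-column TSV of the sorted
#' draws plus a JSON header with B, seed, tail fit and the correlation
#' matrix used.
#'
#' @param null a `shet_null`.
#' @param path base path; `<path>.tsv.gz` and `<path>.json` are written.
#' @return `write_shet_null` returns `path` invisibly; `read_shet_null`
#'   the restored object.
#' @export
write_shet_null <- function(null, path) {
  data.table::fwrite(data.frame(s_het = null$draws),
                     paste0(path, ".tsv.gz"), sep = "\t")
  jsonlite::write_json(
    list(B = null$B, seed = null$seed, tail_fit = null$tail_fit,
         labels = null$r_used$labels, r = null$r_used$r,
         w_scheme = null$w_used$scheme, w_per_snp = null$w_used$per_snp,
         n_used = null$n_used),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_shet_null
#' @export
read_shet_null <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  draws <- fread_auto(paste0(path, ".tsv.gz"))$s_het
  r <- matrix(unlist(meta$r), length(meta$labels))
  dimnames(r) <- list(meta$labels, meta$labels)
  structure(
    list(draws = sort(draws), B = meta$B, seed = meta$seed,
         tail_fit = as.list(meta$tail_fit),
         r_used = corr_matrix(r),
         w_used = weight_spec(meta$w_scheme, meta$w_per_snp),
         n_used = meta$n_used),
    class = "shet_null"
  )
}

#' Genome-wide CPASSOC scan
#'
#' Runs [cpassoc_batch()] over a panel and attaches S_Het p-values from a
#' Monte Carlo null (built here when not supplied).
#'
#' @param zp a [zpanel].
#' @param R a [corr_matrix()].
#' @param w a [weight_spec()].
#' @param null optional prebuilt [build_shet_null()]; when `NULL` and
#'   `s_het` is requested, a null of `B` draws is built from `seed`.
#' @param B,seed null-distribution parameters when `null` is not given.
#' @param what statistics to compute.
#' @return Per-SNP results data.frame (`snp_id`, `chromosome`, `position`,
#'   `s_hom`, `p_hom`, `s_het`, `p_het`, `tau_star`, `n_panels_used`);
#'   attribute `shet_null` holds the null used.
#' @export
cpassoc_scan <- function(zp, R, w = weight_spec(), null = NULL,
                         B = 100000L, seed = NULL,
                         what = c("s_hom", "s_het")) {
  what <- match.arg(what, several.ok = TRUE)
  out <- cpassoc_batch(zp, R, w, what = what)
  if ("s_het" %in% what) {
    if (is.null(null)) {
      if (is.null(seed))
        stop("seed is mandatory when S_Het p-values are requested")
      n_ref <- if (w$per_snp)
        apply(zp$n, 2L, function(x) stats::median(x, na.rm = TRUE))
      else zp$panels$n_max
      null <- build_shet_null(R, w, n_ref, B = B, seed = seed)
    }
    out$p_het <- p_het(out$s_het, null)
    attr(out, "shet_null") <- null
  }
  out
}
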