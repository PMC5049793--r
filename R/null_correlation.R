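#' Greedy LD pruning of a dosage matrix
#'
#' Walks the SNPs left to right in position order with a sliding window and
#' drops any SNP whose squared Pearson correlation with an earlier retained
#' SNP inside the window reaches the threshold, so every retained pair
#' within a window has r^2 below the threshold.  Monomorphic SNPs are
#' excluded before pruning.
#'
#' @param genotypes numeric matrix, samples x SNPs, 0/1/2 dosages with
#'   optional `NA`; columns named by SNP id.
#' @param positions numeric vector of base-pair positions (one per SNP),
#'   non-decreasing.
#' @param r2_threshold prune when r^2 >= this value (default 0.2).
#' @param window_snps sliding-window width in SNP count (default 50).
#' @param step_snps step between window starts in SNP count (default 5).
#' @return Character vector of retained SNP ids; attribute `monomorphic`
#'   lists SNPs excluded for zero variance.
#' @export
ld_prune <- function(genotypes, positions, r2_threshold = 0.2,
                     window_snps = 50L, step_snps = 5L) {
  if (r2_threshold <= 0 || r2_threshold >= 1)
    stop("r2_threshold must be in (0, 1)")
  genotypes <- as.matrix(genotypes)
  M <- ncol(genotypes)
  if (M < 2L) stop("need at least 2 SNPs")
  if (length(positions) != M) stop("positions must match the SNP count")
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(M))
  ord <- order(positions)
  genotypes <- genotypes[, ord, drop = FALSE]
  ids <- ids[ord]

  v <- apply(genotypes, 2L, stats::var, na.rm = TRUE)
  mono <- which(is.na(v) | v == 0)
  keep_cols <- setdiff(seq_len(M), mono)
  g <- genotypes[, keep_cols, drop = FALSE]
  m <- ncol(g)
  alive <- rep(TRUE, m)
  start <- 1L
  while (start <= m) {
    end <- min(start + window_snps - 1L, m)
    win <- start:end
    act <- win[alive[win]]
    if (length(act) > 1L) {
      r2 <- suppressWarnings(stats::cor(g[, act, drop = FALSE],
                                        use = "pairwise.complete.obs"))^2
      for (a in seq_along(act)[-1L]) {
        if (!alive[act[a]]) next
        earlier <- act[seq_len(a - 1L)]
        earlier <- earlier[alive[earlier]]
        if (length(earlier) &&
            any(r2[a, match(earlier, act)] >= r2_threshold, na.rm = TRUE))
          alive[act[a]] <- FALSE
      }
    }
    if (end == m) break
    start <- start + step_snps
  }
  out <- ids[keep_cols[alive]]
  attr(out, "monomorphic") <- ids[mono]
  out
}

#' Keep null SNPs: pruned and with all |Z| at or below a cutoff
#'
#' SNPs with large statistics may carry true associations and would inflate
#' the between-panel correlation estimate, so rows where any panel's
#' |Z| exceeds `z_cut` are removed (boundary kept).  The row must pass in
#' every panel jointly; missing entries do not disqualify a row.
#'
#' @param zp a [zpanel].
#' @param retained optional SNP-id vector from LD pruning (e.g.
#'   [ld_prune()] output or an externally pruned list); `NULL` keeps all.
#' @param z_cut absolute-Z threshold (default 1.96).
#' @return The filtered [zpanel]; attribute `n_kept_per_panel` reports the
#'   non-missing row count per panel.
#' @export
select_null_snps <- function(zp, retained = NULL, z_cut = 1.96) {
  if (!inherits(zp, "zpanel")) stop("zp must be a zpanel")
  if (z_cut <= 0) stop("z_cut must be > 0")
  keep <- rep(TRUE, nrow(zp$z))
  if (!is.null(retained)) {
    bad <- setdiff(retained, zp$snps$snp_id)
    if (length(bad)) stop("retained ids not in panel: ",
                          paste(utils::head(bad, 5), collapse = ", "))
    keep <- zp$snps$snp_id %in% retained
  }
  keep <- keep & apply(abs(zp$z) <= z_cut, 1L, all, na.rm = TRUE)
  if (!any(keep))
    stop("no null SNPs left after |Z| <= ", z_cut,
         " filtering; supply a larger input panel")
  out <- zpanel_subset(zp, which(keep))
  attr(out, "n_kept_per_panel") <- colSums(!is.na(out$z))
  attr(out, "z_cut") <- z_cut
  out
}

#' Nearest positive-semidefinite repair of a correlation matrix
#'
#' Clips negative eigenvalues at zero and rescales back to unit diagonal.
#' @param r symmetric matrix with unit diagonal.
#' @param tol eigenvalues below `-tol` trigger repair.
#' @return List `r` (repaired matrix) and `adjusted` (logical).
#' @export
near_psd <- function(r, tol = 1e-10) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= -tol) return(list(r = r, adjusted = FALSE))
  v <- pmax(e$values, 0)
  m <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  diag(m) <- 1
  dimnames(m) <- dimnames(r)
  list(r = (m + t(m)) / 2, adjusted = TRUE)
}

#' Estimate the between-panel correlation of null test statistics
#'
#' Pairwise-complete Pearson correlation of the Z columns of a null
#' (pruned, |Z|-filtered) panel.  The result carries the pairwise row
#' counts and is projected to the nearest positive-semidefinite
#' correlation matrix if sampling noise made it indefinite.
#'
#' When the panel comes from [select_null_snps()], the |Z| <= z_cut filter
#' biases every pairwise correlation toward zero: for a bivariate normal
#' pair doubly truncated to \[-a, a\] the correlation shrinks by
#' approximately the variance of the truncated standard normal,
#' `kappa(a) = 1 - 2 a phi(a) / (2 Phi(a) - 1)` (0.759 at a = 1.96).
#' Because the estimand is the correlation of the untruncated statistics
#' (the matrix that parameterises the null of every SNP, filtered or not),
#' off-diagonals are de-attenuated by `1/kappa` by default.  The linear
#' correction is accurate for the small correlations overlap induces
#' (|r| below ~0.3).
#'
#' @param zp_null a [zpanel] of null SNPs, e.g. from [select_null_snps()].
#' @param min_pairs minimum shared non-missing rows required per panel
#'   pair (default 30).
#' @param complete_cases use only rows complete across all panels instead
#'   of pairwise-complete rows.
#' @param z_cut truncation bound used when selecting the null SNPs; taken
#'   from the [select_null_snps()] attribute when present.  `NULL`
#'   disables the de-attenuation.
#' @return An object of class `corr_matrix`: list with `labels`, `r`,
#'   `n_snps_used` (pairwise counts), `psd_adjusted` and
#'   `truncation_kappa` (1 when no correction applied).
#' @export
estimate_R <- function(zp_null, min_pairs = 30L, complete_cases = FALSE,
                       z_cut = attr(zp_null, "z_cut")) {
  z <- zp_null$z
  if (ncol(z) < 2L) stop("need at least 2 panels to estimate R")
  if (complete_cases) z <- z[stats::complete.cases(z), , drop = FALSE]
  pres <- !is.na(z)
  counts <- crossprod(pres)
  low <- which(counts < min_pairs & upper.tri(counts), arr.ind = TRUE)
  if (nrow(low)) {
    lab <- colnames(z)
    stop("panel pair(s) share fewer than ", min_pairs, " null SNPs: ",
         paste(sprintf("%s~%s (%d)", lab[low[, 1]], lab[low[, 2]],
                       counts[low]), collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(z, use = "pairwise.complete.obs"))
  kappa <- 1
  if (!is.null(z_cut)) {
    a <- z_cut
    kappa <- 1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1)
    r <- r / kappa
  }
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  r <- (r + t(r)) / 2
  fix <- near_psd(r)
  structure(
    list(labels = colnames(z), r = fix$r, n_snps_used = counts,
         psd_adjusted = fix$adjusted, truncation_kappa = kappa),
    class = "corr_matrix"
  )
}

#' Construct a corr_matrix from a plain matrix
#'
#' Convenience wrapper used by simulations and when importing an external
#' correlation estimate.
#' @param r symmetric unit-diagonal matrix.
#' @param labels panel labels (default from `colnames(r)`).
#' @return A `corr_matrix`.
#' @export
corr_matrix <- function(r, labels = colnames(r)) {
  r <- as.matrix(r)
  if (is.null(labels)) labels <- paste0("panel", seq_len(ncol(r)))
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8)))
    stop("r must be symmetric")
  if (any(abs(diag(r) - 1) > 1e-8)) stop("r must have unit diagonal")
  if (any(abs(r) > 1 + 1e-8)) stop("|off-diagonals| must be <= 1")
  r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(labels, labels)
  fix <- near_psd(r)
  structure(
    list(labels = labels, r = fix$r,
         n_snps_used = matrix(NA_integer_, ncol(r), ncol(r),
                              dimnames = list(labels, labels)),
         psd_adjusted = fix$adjusted),
    class = "corr_matrix"
  )
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("corr_matrix: %d panels%s\n", length(x$labels),
              if (x$psd_adjusted) " (PSD-repaired)" else ""))
  print(round(x$r, 4))
  invisible(x)
}

#' Write / read a correlation matrix as labelled TSV plus JSON sidecar
#'
#' @param cm a `corr_matrix`.
#' @param path TSV path; the sidecar is written next to it as
#'   `<path>.json` with the pairwise counts and the PSD flag.
#' @return `write_corr` returns `path` invisibly; `read_corr` a
#'   `corr_matrix`.
#' @export
write_corr <- function(cm, path) {
  df <- data.frame(panel = cm$labels, cm$r, check.names = FALSE)
  names(df) <- c("panel", cm$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(labels = cm$labels, psd_adjusted = cm$psd_adjusted,
         n_snps_used = cm$n_snps_used),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_corr
#' @export
read_corr <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  r <- as.matrix(df[, -1, drop = FALSE])
  rownames(r) <- df$panel
  side <- paste0(path, ".json")
  cm <- corr_matrix(r, labels = df$panel)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$n_snps_used))
      cm$n_snps_used <- matrix(as.integer(meta$n_snps_used),
                               length(cm$labels),
                               dimnames = list(cm$labels, cm$labels))
    cm$psd_adjusted <- isTRUE(meta$psd_adjusted) || cm$psd_adjusted
  }
  cm
}
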