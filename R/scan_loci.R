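#' Conventional sample-size-weighted Z meta-analysis
#'
#' The single-trait baseline: `z = sum(sqrt(n_j) T_j) / sqrt(sum(n_j))`
#' over non-missing panels, assuming independent cohorts; two-sided normal
#' p-value.
#'
#' @param T numeric vector of panel Z statistics (may contain `NA`).
#' @param n per-panel sample sizes.
#' @return List with `z` and `p` (`NA` when all panels are missing).
#' @export
#' @examples
#' weighted_z_meta(c(2, 2), c(5000, 5000)) # z = 2.83
weighted_z_meta <- function(T, n) {
  obs <- which(is.finite(T))
  if (!length(obs)) return(list(z = NA_real_, p = NA_real_))
  z <- sum(sqrt(n[obs]) * T[obs]) / sqrt(sum(n[obs]))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Batch weighted-Z scan over a panel
#'
#' @param zp a [zpanel].
#' @param panels optional column subset (indices or labels) to combine;
#'   default all.
#' @return data.frame `snp_id`, `chromosome`, `position`, `z`, `p`.
#' @export
weighted_z_scan <- function(zp, panels = NULL) {
  z <- zp$z; n <- zp$n
  if (!is.null(panels)) {
    z <- z[, panels, drop = FALSE]; n <- n[, panels, drop = FALSE]
  }
  sw <- sqrt(n); sw[is.na(z)] <- NA
  num <- rowSums(sw * z, na.rm = TRUE)
  den <- sqrt(rowSums(n * !is.na(z), na.rm = TRUE))
  zz <- ifelse(den > 0, num / den, NA_real_)
  data.frame(snp_id = zp$snps$snp_id, chromosome = zp$snps$chromosome,
             position = zp$snps$position, z = zz,
             p = 2 * stats::pnorm(-abs(zz)), stringsAsFactors = FALSE)
}

#' Genomic-control inflation factor lambda
#'
#' `lambda = median(observed chi-squared) / 0.4549364`, the chi-squared
#' (1 df) median.  Accepts 1-df chi-squared statistics directly or
#' two-sided p-values, which are converted through the inverse CDF.
#'
#' @param statistics chi-squared (1 df) statistics.
#' @param p two-sided p-values (alternative input).
#' @return lambda (positive scalar).
#' @export
genomic_control_lambda <- function(statistics = NULL, p = NULL) {
  if (is.null(statistics) == is.null(p))
    stop("supply exactly one of statistics or p")
  if (!is.null(p)) {
    p <- p[!is.na(p)]
    if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]")
    statistics <- stats::qchisq(p, 1L, lower.tail = FALSE)
  }
  statistics <- statistics[!is.na(statistics)]
  if (length(statistics) < 100L)
    stop("need >= 100 values for a stable lambda")
  stats::median(statistics) / stats::qchisq(0.5, 1L)
}

#' Identify significant loci by greedy clumping
#'
#' Repeatedly takes the most significant remaining SNP below the threshold
#' as a lead, assigns every significant SNP within `flank` base pairs on
#' the same chromosome to its locus, and removes them.  Ties on p are
#' broken by (chromosome, position).
#'
#' @param results data.frame with `snp_id`, `chromosome`, `position` and a
#'   p-value column.
#' @param threshold significance threshold (default 5e-8).
#' @param flank half-window in base pairs around the lead (default
#'   500 kb, i.e. a 1.0 Mb locus).
#' @param p_col name of the p-value column (default `"p"`).
#' @return data.frame of loci: `lead_snp`, `chromosome`, `lead_pos`,
#'   `lead_p`, `window_start`, `window_end`, `n_members`, `member_snps`
#'   (comma-separated ids).
#' @export
identify_loci <- function(results, threshold = 5e-8, flank = 5e5,
                          p_col = "p") {
  p <- results[[p_col]]
  sig <- results[!is.na(p) & p < threshold, , drop = FALSE]
  sig$.p <- sig[[p_col]]
  loci <- list()
  while (nrow(sig)) {
    lead <- sig[order(sig$.p, sig$chromosome, sig$position)[1L], ]
    inwin <- sig$chromosome == lead$chromosome &
      abs(sig$position - lead$position) <= flank
    members <- sig[inwin, , drop = FALSE]
    loci[[length(loci) + 1L]] <- data.frame(
      lead_snp = lead$snp_id, chromosome = lead$chromosome,
      lead_pos = lead$position, lead_p = lead$.p,
      window_start = lead$position - flank,
      window_end = lead$position + flank,
      n_members = nrow(members),
      member_snps = paste(members$snp_id, collapse = ","),
      stringsAsFactors = FALSE
    )
    sig <- sig[!inwin, , drop = FALSE]
  }
  if (!length(loci))
    return(data.frame(lead_snp = character(), chromosome = character(),
                      lead_pos = numeric(), lead_p = numeric(),
                      window_start = numeric(), window_end = numeric(),
                      n_members = integer(), member_snps = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, loci)
}

#' Flag loci missed by the baseline method
#'
#' A locus is novel if and only if no baseline SNP below the threshold
#' lies within the 1.0 Mb region centred on the lead (lead +/- `flank`)
#' and, when an LD pair list is supplied, the lead is not listed as
#' correlated with any significant baseline SNP.
#'
#' @param loci output of [identify_loci()].
#' @param baseline_results per-SNP baseline results (`snp_id`,
#'   `chromosome`, `position`, p-value column).
#' @param threshold baseline significance threshold (default 5e-8).
#' @param flank half-window (default 500 kb).
#' @param ld_pairs optional data.frame of correlated id pairs (columns
#'   `a`, `b`), e.g. from an external LD reference.
#' @param p_col baseline p-value column.
#' @return `loci` with a logical `novel_vs_baseline` column appended.
#' @export
novel_vs_baseline <- function(loci, baseline_results, threshold = 5e-8,
                              flank = 5e5, ld_pairs = NULL, p_col = "p") {
  bp <- baseline_results[[p_col]]
  bsig <- baseline_results[!is.na(bp) & bp < threshold, , drop = FALSE]
  ld_hit <- function(id) {
    if (is.null(ld_pairs) || !nrow(bsig)) return(FALSE)
    mates <- c(ld_pairs$b[ld_pairs$a == id], ld_pairs$a[ld_pairs$b == id])
    any(mates %in% bsig$snp_id)
  }
  loci$novel_vs_baseline <- vapply(seq_len(nrow(loci)), function(i) {
    near <- bsig$chromosome == loci$chromosome[i] &
      abs(bsig$position - loci$lead_pos[i]) <= flank
    !any(near) && !ld_hit(loci$lead_snp[i])
  }, logical(1))
  loci
}

#' Cross-tabulate loci found by two methods
#'
#' Clumps each method's per-SNP results into loci and classifies every
#' locus by whether the other method has a significant SNP within the
#' 1.0 Mb region around its lead.
#'
#' @param res_a,res_b per-SNP results of the two methods over the same
#'   SNP set (`snp_id`, `chromosome`, `position`, p-value column).
#' @param threshold significance threshold.
#' @param flank half-window for both clumping and counterpart lookup.
#' @param p_col_a,p_col_b p-value column names.
#' @param labels method names for the output.
#' @return List with `table` (data.frame: per-method total, shared,
#'   method-only locus counts) and the annotated `loci_a`, `loci_b`.
#' @export
cross_tabulate <- function(res_a, res_b, threshold = 5e-8, flank = 5e5,
                           p_col_a = "p", p_col_b = "p",
                           labels = c("method_a", "method_b")) {
  if (nrow(res_a) != nrow(res_b) ||
      !identical(sort(res_a$snp_id), sort(res_b$snp_id)))
    stop("the two scans must cover the same SNP set")
  loci_a <- identify_loci(res_a, threshold, flank, p_col_a)
  loci_b <- identify_loci(res_b, threshold, flank, p_col_b)
  loci_a <- novel_vs_baseline(loci_a, res_b, threshold, flank, p_col = p_col_b)
  loci_b <- novel_vs_baseline(loci_b, res_a, threshold, flank, p_col = p_col_a)
  tab <- data.frame(
    method = labels,
    n_loci = c(nrow(loci_a), nrow(loci_b)),
    shared = c(sum(!loci_a$novel_vs_baseline), sum(!loci_b$novel_vs_baseline)),
    only = c(sum(loci_a$novel_vs_baseline), sum(loci_b$novel_vs_baseline)),
    stringsAsFactors = FALSE
  )
  list(table = tab, loci_a = loci_a, loci_b = loci_b)
}

#' Per-panel effect sizes for forest plots
#'
#' Extracts the harmonized per-panel beta and SE of the requested SNPs in
#' long format; panels built from p + sign only (no usable SE) are
#' flagged.
#'
#' @param zp a [zpanel] carrying beta/se matrices.
#' @param snp_ids SNP ids to extract.
#' @return Long data.frame: `snp_id`, `cohort_id`, `trait_id`, `beta`,
#'   `se`, `z`, `n`; attribute `missing_se` flags panels without SEs.
#' @export
forest_data <- function(zp, snp_ids) {
  miss <- setdiff(snp_ids, zp$snps$snp_id)
  if (length(miss))
    stop("SNP id(s) not in panel: ", paste(miss, collapse = ", "))
  if (is.null(zp$beta) || is.null(zp$se))
    stop("panel carries no effect estimates (p + sign ingestion?)")
  i <- match(snp_ids, zp$snps$snp_id)
  out <- do.call(rbind, lapply(seq_len(ncol(zp$z)), function(j) {
    data.frame(
      snp_id = snp_ids,
      cohort_id = zp$panels$cohort_id[j],
      trait_id = zp$panels$trait_id[j],
      beta = zp$beta[i, j], se = zp$se[i, j],
      z = zp$z[i, j], n = zp$n[i, j],
      stringsAsFactors = FALSE
    )
  }))
  out <- out[!is.na(out$z), , drop = FALSE]
  attr(out, "missing_se") <- any(is.na(out$se) & !is.na(out$beta))
  rownames(out) <- NULL
  out
}

#' Q-Q and Manhattan plotting data
#'
#' Data-only outputs: expected vs observed -log10 p for a Q-Q plot, and
#' cumulative genome coordinates for a Manhattan plot.  Rendering is left
#' to the caller.
#'
#' @param p p-values (Q-Q).
#' @return `qq_data`: data.frame `expected`, `observed` (sorted);
#' @export
qq_data <- function(p) {
  p <- sort(p[!is.na(p)], decreasing = TRUE)
  m <- length(p)
  data.frame(expected = rev(-log10(stats::ppoints(m))), observed = -log10(p))
}

#' @rdname qq_data
#' @param results per-SNP results with `chromosome`, `position` and a
#'   p-value column.
#' @param p_col p-value column name.
#' @return `manhattan_data`: results with `x` (cumulative bp coordinate)
#'   and `neglog10p` columns.
#' @export
manhattan_data <- function(results, p_col = "p") {
  chr <- results$chromosome
  chr_num <- suppressWarnings(as.numeric(chr))
  ord <- order(chr_num, chr, results$position)
  res <- results[ord, , drop = FALSE]
  offs <- 0; x <- numeric(nrow(res))
  for (c_ in unique(res$chromosome)) {
    i <- res$chromosome == c_
    x[i] <- offs + res$position[i]
    offs <- max(x[i]) + 1e6
  }
  res$x <- x
  res$neglog10p <- -log10(res[[p_col]])
  res
}

#' Scan summary (method, lambda, significant count)
#'
#' @param method name of the scan statistic.
#' @param results per-SNP results.
#' @param p_col p-value column.
#' @param threshold significance threshold.
#' @return `scan_summary` list: `method`, `lambda_gc`, `n_snps`,
#'   `n_significant`.
#' @export
scan_summary <- function(method, results, p_col = "p", threshold = 5e-8) {
  p <- results[[p_col]]
  structure(
    list(method = method,
         lambda_gc = genomic_control_lambda(p = p),
         n_snps = sum(!is.na(p)),
         n_significant = sum(p < threshold, na.rm = TRUE)),
    class = "scan_summary"
  )
}

#' @export
print.scan_summary <- function(x, ...) {
  cat(sprintf("%s: lambda = %.3f, %d SNPs, %d significant\n",
              x$method, x$lambda_gc, x$n_snps, x$n_significant))
  invisible(x)
}
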