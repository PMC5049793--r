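#' ZPanel: an aligned SNP-by-panel matrix of association Z statistics
#'
#' A `zpanel` holds, for a common set of SNPs, the Wald Z statistics
#' `T_jk = beta_jk / se_jk` of every (cohort, trait) panel, together with
#' per-SNP per-panel sample sizes and (when available) the underlying
#' effect estimates.  All panels are expressed on one reference effect
#' allele per SNP, so signs are comparable across columns.
#'
#' @param snps data.frame with columns `snp_id`, `chromosome` (character),
#'   `position` (1-based integer), `effect_allele`, `other_allele`.
#'   Rows must be sorted by (chromosome, position).
#' @param panels data.frame with columns `cohort_id`, `trait_id`, `n_max`;
#'   one row per panel (column of `z`).  (cohort_id, trait_id) pairs must
#'   be unique.
#' @param z numeric matrix, SNPs x panels; `NA` marks a missing entry,
#'   all non-missing entries must be finite.
#' @param n numeric matrix of per-SNP per-panel sample sizes, same shape
#'   as `z`; may simply recycle each panel's `n_max`.
#' @param beta,se optional matrices of effect estimates and standard
#'   errors on the reference-allele orientation (used for forest plots).
#'
#' @return An object of class `zpanel`.
#' @export
zpanel <- function(snps, panels, z, n, beta = NULL, se = NULL) {
  snps <- as.data.frame(snps)
  panels <- as.data.frame(panels)
  need <- c("snp_id", "chromosome", "position", "effect_allele", "other_allele")
  if (!all(need %in% names(snps)))
    stop("snps must have columns: ", paste(need, collapse = ", "))
  if (!all(c("cohort_id", "trait_id", "n_max") %in% names(panels)))
    stop("panels must have columns cohort_id, trait_id, n_max")
  if (anyDuplicated(panels[, c("cohort_id", "trait_id")]))
    stop("duplicated (cohort_id, trait_id) panel keys")
  z <- as.matrix(z)
  n <- as.matrix(n)
  if (nrow(z) != nrow(snps) || ncol(z) != nrow(panels))
    stop("z must be length(snps) x length(panels)")
  if (!all(dim(n) == dim(z))) stop("n must have the same shape as z")
  if (any(!is.finite(z[!is.na(z)])))
    stop("non-missing z entries must be finite")
  ord <- order(snps$chromosome, snps$position)
  if (is.unsorted(ord)) {
    snps <- snps[ord, , drop = FALSE]
    z <- z[ord, , drop = FALSE]
    n <- n[ord, , drop = FALSE]
    if (!is.null(beta)) beta <- as.matrix(beta)[ord, , drop = FALSE]
    if (!is.null(se)) se <- as.matrix(se)[ord, , drop = FALSE]
  }
  rownames(snps) <- NULL
  lab <- panel_labels(panels)
  colnames(z) <- lab
  colnames(n) <- lab
  rownames(z) <- snps$snp_id
  rownames(n) <- snps$snp_id
  if (!is.null(beta)) {
    beta <- as.matrix(beta); dimnames(beta) <- dimnames(z)
  }
  if (!is.null(se)) {
    se <- as.matrix(se); dimnames(se) <- dimnames(z)
  }
  structure(
    list(snps = snps, panels = panels, z = z, n = n, beta = beta, se = se),
    class = "zpanel"
  )
}

panel_labels <- function(panels) paste(panels$cohort_id, panels$trait_id, sep = ":")

#' @export
print.zpanel <- function(x, ...) {
  cat(sprintf("zpanel: %d SNPs x %d panels\n", nrow(x$z), ncol(x$z)))
  cat("panels:", paste(panel_labels(x$panels), collapse = ", "), "\n")
  miss <- sum(is.na(x$z))
  if (miss > 0) cat(sprintf("missing entries: %d (%.2f%%)\n", miss,
                            100 * miss / length(x$z)))
  invisible(x)
}

#' @export
dim.zpanel <- function(x) dim(x$z)

#' Subset a zpanel by SNP ids or row indices
#'
#' @param zp a [zpanel].
#' @param i SNP ids (character) or row indices (numeric/logical).
#' @return The subset `zpanel` (row order re-sorted by position).
#' @export
zpanel_subset <- function(zp, i) {
  if (is.character(i)) {
    i <- match(i, zp$snps$snp_id)
    if (anyNA(i)) stop("unknown SNP id(s) in subset")
  }
  zpanel(zp$snps[i, , drop = FALSE], zp$panels,
         zp$z[i, , drop = FALSE], zp$n[i, , drop = FALSE],
         beta = if (!is.null(zp$beta)) zp$beta[i, , drop = FALSE],
         se = if (!is.null(zp$se)) zp$se[i, , drop = FALSE])
}

#' Write / read the ZPanel interchange file
#'
#' The interchange format is a tab-delimited table with one row per SNP:
#' the five SNP-index columns followed by one `Z.<cohort:trait>` and
#' `N.<cohort:trait>` column pair per panel (and `BETA.`/`SE.` pairs when
#' effect estimates are carried).  Files ending in `.gz` are compressed
#' transparently.
#'
#' @param zp a [zpanel].
#' @param path output (input) file path.
#' @return `write_zpanel` returns `path` invisibly; `read_zpanel` returns
#'   a [zpanel].
#' @export
write_zpanel <- function(zp, path) {
  lab <- panel_labels(zp$panels)
  df <- zp$snps
  for (j in seq_along(lab)) {
    df[[paste0("Z.", lab[j])]] <- zp$z[, j]
    df[[paste0("N.", lab[j])]] <- zp$n[, j]
    if (!is.null(zp$beta)) df[[paste0("BETA.", lab[j])]] <- zp$beta[, j]
    if (!is.null(zp$se)) df[[paste0("SE.", lab[j])]] <- zp$se[, j]
  }
  # full precision so that a round trip is exact
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

# gzip-transparent fread without the R.utils dependency
fread_auto <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    data.table::fread(text = readLines(con), ...)
  } else {
    data.table::fread(path, ...)
  }
}

#' @rdname write_zpanel
#' @export
read_zpanel <- function(path) {
  df <- as.data.frame(fread_auto(path, sep = "\t", na.strings = "NA"))
  df$chromosome <- as.character(df$chromosome)
  zcols <- grep("^Z\\.", names(df), value = TRUE)
  lab <- sub("^Z\\.", "", zcols)
  key <- strsplit(lab, ":", fixed = TRUE)
  n_mat <- as.matrix(df[paste0("N.", lab)])
  panels <- data.frame(
    cohort_id = vapply(key, `[`, "", 1L),
    trait_id = vapply(key, `[`, "", 2L),
    n_max = apply(n_mat, 2L, max, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  has_beta <- all(paste0("BETA.", lab) %in% names(df))
  zpanel(
    df[c("snp_id", "chromosome", "position", "effect_allele", "other_allele")],
    panels,
    as.matrix(df[zcols]),
    n_mat,
    beta = if (has_beta) as.matrix(df[paste0("BETA.", lab)]),
    se = if (has_beta) as.matrix(df[paste0("SE.", lab)])
  )
}
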