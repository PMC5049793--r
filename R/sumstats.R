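#' Column-name dialects for summary-statistics files
#'
#' GWAS consortia name their columns differently; a dialect maps the file's
#' header names onto the canonical fields `snp_id`, `chromosome`,
#' `position`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `p_value`, `n`.  `chromosome`/`position` and `eaf`/`n` may be absent
#' from a file (positions can then be supplied by a map file; `n` falls
#' back to the panel maximum).
#'
#' @param ... canonical field = file column name pairs overriding the
#'   default (which maps identically-named upper-case columns
#'   SNP/CHR/POS/EA/OA/EAF/BETA/SE/P/N).
#' @return Named character vector usable as the `dialect` argument of
#'   [read_sumstats()].
#' @export
#' @examples
#' giant_dialect() # historical GIANT column names
sumstats_dialect <- function(...) {
  d <- c(snp_id = "SNP", chromosome = "CHR", position = "POS",
         effect_allele = "EA", other_allele = "OA", eaf = "EAF",
         beta = "BETA", se = "SE", p_value = "P", n = "N")
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad)) stop("unknown canonical field(s): ",
                          paste(bad, collapse = ", "))
    d[names(ov)] <- ov
  }
  d
}

#' @rdname sumstats_dialect
#' @export
giant_dialect <- function() {
  sumstats_dialect(
    snp_id = "MarkerName", effect_allele = "Allele1", other_allele = "Allele2",
    eaf = "Freq.Allele1.HapMapCEU", beta = "b", se = "SE", p_value = "p",
    n = "N", chromosome = "CHR", position = "POS"
  )
}

#' Read one panel's summary statistics
#'
#' Reads a whitespace- or tab-delimited file with header, applies a
#' column dialect, validates each record and returns the clean records
#' sorted by genomic coordinate.  Malformed records (non-numeric beta/se/p,
#' `se <= 0`, p outside (0, 1], eaf outside \[0, 1\], effect allele equal to
#' other allele) are dropped and counted.
#'
#' @param path file path (gzip-transparent).
#' @param dialect column mapping from [sumstats_dialect()].
#' @param autosomes_only drop records whose chromosome is not "1".."22"
#'   (default `TRUE`; sex chromosomes are not analysed).
#' @return A data.frame of validated records with canonical column names,
#'   sorted by (chromosome, position); attributes `n_rejected` (count) and
#'   `reject_lines` (1-based data-line numbers of rejected records, capped
#'   at 1000).
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          autosomes_only = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- as.data.frame(fread_auto(
    path, header = TRUE, na.strings = c("NA", "."), colClasses = "character"
  ))
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se",
                 "p_value")
  missing_cols <- setdiff(dialect[mandatory], names(raw))
  if (length(missing_cols))
    stop("mandatory column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  have <- names(dialect)[dialect %in% names(raw)]
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in have) df[[f]] <- raw[[dialect[[f]]]]
  for (f in intersect(c("position", "eaf", "beta", "se", "p_value", "n"), have))
    df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  if (!"chromosome" %in% have) df$chromosome <- NA_character_
  if (!"position" %in% have) df$position <- NA_real_
  if (!"eaf" %in% have) df$eaf <- NA_real_
  if (!"n" %in% have) df$n <- NA_real_
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)

  ok <- !is.na(df$beta) & !is.na(df$se) & !is.na(df$p_value) &
    df$se > 0 & df$p_value > 0 & df$p_value <= 1 &
    df$effect_allele != df$other_allele &
    df$effect_allele %in% c("A", "C", "G", "T") &
    df$other_allele %in% c("A", "C", "G", "T") &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)) &
    (is.na(df$n) | df$n >= 1)
  if (autosomes_only)
    ok <- ok & (is.na(df$chromosome) | df$chromosome %in% as.character(1:22))
  rejected <- which(!ok)
  out <- df[ok, , drop = FALSE]
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- length(rejected)
  attr(out, "reject_lines") <- utils::head(rejected, 1000L)
  out
}

#' Wald Z statistic for one association record
#'
#' @param beta effect estimate(s).
#' @param se standard error(s) (> 0), used by mode `"beta_se"`.
#' @param p two-sided p-value(s), used by mode `"p_sign"`.
#' @param mode `"beta_se"` returns `beta / se`; `"p_sign"` reconstructs
#'   `sign(beta) * qnorm(1 - p/2)` from the printed two-sided p-value.
#' @return Numeric Z (vectorised).
#' @export
#' @examples
#' z_from_record(0.10, se = 0.05)                 # 2
#' z_from_record(1, p = 0.05, mode = "p_sign")    # 1.959964
z_from_record <- function(beta, se = NULL, p = NULL,
                          mode = c("beta_se", "p_sign")) {
  mode <- match.arg(mode)
  if (mode == "beta_se") {
    if (is.null(se)) stop("mode 'beta_se' needs se")
    if (any(se <= 0, na.rm = TRUE)) stop("se must be > 0")
    beta / se
  } else {
    if (is.null(p)) stop("mode 'p_sign' needs p")
    if (any(p <= 0, na.rm = TRUE)) stop("p must be > 0")
    if (any(p > 1, na.rm = TRUE)) stop("p must be <= 1")
    # p = 1 gives qnorm(.5) = 0 as required
    sign(beta) * stats::qnorm(p / 2, lower.tail = FALSE)
  }
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_ambiguous_pair <- function(ea, oa) COMPLEMENT[ea] == oa

#' Align panels onto shared SNPs and one effect-allele orientation
#'
#' Takes one record table per (cohort, trait) panel, restricts to the SNP
#' intersection (or union), fixes each SNP's reference effect allele from
#' the first panel carrying it, and flips the sign of Z (and beta) for
#' panels reporting the swapped orientation.  A panel whose allele pair
#' matches neither orientation directly nor after strand complement is set
#' missing for that SNP.  Strand-ambiguous A/T and C/G SNPs are dropped by
#' default because their orientation cannot be resolved from alleles alone.
#'
#' @param records named list: `"<cohort>:<trait>"` -> record data.frame as
#'   returned by [read_sumstats()].
#' @param policy `"intersection"` (default) keeps SNPs present in every
#'   panel; `"union"` keeps all SNPs, leaving absent panels `NA`.
#' @param drop_ambiguous drop A/T and C/G SNPs (default `TRUE`).
#' @param z_mode passed to [z_from_record()]; `"auto"` (default) uses
#'   beta/se and falls back to p + sign when se is unusable.
#' @return A [zpanel]; attribute `n_dropped_ambiguous` counts removed
#'   strand-ambiguous SNPs.
#' @export
harmonize <- function(records, policy = c("intersection", "union"),
                      drop_ambiguous = TRUE,
                      z_mode = c("auto", "beta_se", "p_sign")) {
  policy <- match.arg(policy)
  z_mode <- match.arg(z_mode)
  if (!length(records)) stop("no panels supplied")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("records must be a named list (\"cohort:trait\" keys)")

  ids <- lapply(records, function(r) r$snp_id)
  keep <- if (policy == "intersection") Reduce(intersect, ids)
          else Reduce(union, ids)
  if (!length(keep))
    stop("empty SNP intersection across panels: ",
         paste(names(records), collapse = ", "))

  first <- records[[1L]]
  ref <- first[match(keep, first$snp_id), , drop = FALSE]
  # under union policy a SNP may be absent from panel 1: take metadata from
  # the first panel that carries it
  if (anyNA(ref$snp_id)) {
    for (j in seq_along(records)[-1L]) {
      miss <- which(is.na(ref$snp_id))
      if (!length(miss)) break
      hit <- match(keep[miss], records[[j]]$snp_id)
      ref[miss[!is.na(hit)], ] <- records[[j]][hit[!is.na(hit)], , drop = FALSE]
    }
  }
  n_amb <- 0L
  if (drop_ambiguous) {
    amb <- is_ambiguous_pair(ref$effect_allele, ref$other_allele)
    n_amb <- sum(amb)
    keep <- keep[!amb]
    ref <- ref[!amb, , drop = FALSE]
  }
  if (!length(keep)) stop("no SNPs left after ambiguous-allele filtering")

  M <- length(keep); J <- length(records)
  z <- n <- b <- s <- matrix(NA_real_, M, J)
  for (j in seq_len(J)) {
    rec <- records[[j]]
    idx <- match(keep, rec$snp_id)
    pres <- !is.na(idx)
    ea <- rec$effect_allele[idx[pres]]; oa <- rec$other_allele[idx[pres]]
    flip_ea <- unname(COMPLEMENT[ea]); flip_oa <- unname(COMPLEMENT[oa])
    ref_ea <- ref$effect_allele[pres]; ref_oa <- ref$other_allele[pres]
    same <- (ea == ref_ea & oa == ref_oa) |
            (flip_ea == ref_ea & flip_oa == ref_oa)
    swap <- (ea == ref_oa & oa == ref_ea) |
            (flip_ea == ref_oa & flip_oa == ref_ea)
    sgn <- ifelse(same, 1, ifelse(swap, -1, NA_real_))
    beta_j <- rec$beta[idx[pres]] * sgn
    se_j <- rec$se[idx[pres]]
    zj <- switch(z_mode,
      beta_se = beta_j / se_j,
      p_sign = z_from_record(beta_j, p = rec$p_value[idx[pres]],
                             mode = "p_sign"),
      auto = {
        zz <- beta_j / se_j
        bad <- !is.finite(zz) & !is.na(sgn)
        if (any(bad))
          zz[bad] <- z_from_record(beta_j[bad], p = rec$p_value[idx[pres]][bad],
                                   mode = "p_sign")
        zz
      })
    z[pres, j] <- zj
    b[pres, j] <- beta_j
    s[pres, j] <- se_j
    n[pres, j] <- rec$n[idx[pres]]
  }
  key <- strsplit(names(records), ":", fixed = TRUE)
  panels <- data.frame(
    cohort_id = vapply(key, `[`, "", 1L),
    trait_id = vapply(key, function(k) if (length(k) > 1L) k[2L] else "trait", ""),
    n_max = vapply(seq_len(J), function(j) {
      nm <- suppressWarnings(max(records[[j]]$n, na.rm = TRUE))
      if (!is.finite(nm)) NA_real_ else nm
    }, 0),
    stringsAsFactors = FALSE
  )
  # per-SNP n column when present, else panel maximum
  for (j in seq_len(J)) n[is.na(n[, j]) & !is.na(z[, j]), j] <- panels$n_max[j]
  zp <- zpanel(
    data.frame(snp_id = keep, chromosome = ref$chromosome,
               position = ref$position, effect_allele = ref$effect_allele,
               other_allele = ref$other_allele, stringsAsFactors = FALSE),
    panels, z, n, beta = b, se = s
  )
  attr(zp, "n_dropped_ambiguous") <- n_amb
  zp
}

#' Convert a zpanel back to per-panel record tables
#'
#' Inverse view of [harmonize()]; used to show harmonization idempotence
#' and for the forest-plot extraction.
#' @param zp a [zpanel].
#' @return Named list of record data.frames (one per panel).
#' @export
zpanel_records <- function(zp) {
  lab <- panel_labels(zp$panels)
  out <- vector("list", length(lab))
  names(out) <- lab
  for (j in seq_along(lab)) {
    pres <- !is.na(zp$z[, j])
    beta <- if (!is.null(zp$beta)) zp$beta[pres, j] else zp$z[pres, j]
    se <- if (!is.null(zp$se)) zp$se[pres, j] else rep(1, sum(pres))
    out[[j]] <- data.frame(
      snp_id = zp$snps$snp_id[pres],
      chromosome = zp$snps$chromosome[pres],
      position = zp$snps$position[pres],
      effect_allele = zp$snps$effect_allele[pres],
      other_allele = zp$snps$other_allele[pres],
      eaf = NA_real_,
      beta = beta, se = se,
      p_value = 2 * stats::pnorm(-abs(zp$z[pres, j])),
      n = zp$n[pres, j],
      stringsAsFactors = FALSE
    )
  }
  out
}
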