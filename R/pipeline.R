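#' Run configuration
#'
#' Validates and normalises the configuration driving [run_pipeline()].
#' Configurations are plain lists, read from / written to JSON so that a
#' manifest round-trips exactly.
#'
#' Fields: either `simulate` (a list of [sim_config()] arguments) or
#' `inputs` (named list panel label -> list(path, dialect overrides));
#' `weight_scheme` ("sqrt_n"/"n"/"unit"), `z_cut` (1.96), `prune`
#' (optional list: `r2_threshold`, `window_snps`, `step_snps`,
#' `genotypes`/`positions` paths or `snp_list` path), `B` and `seed` for
#' the S_Het null, `threshold` (5e-8), `threshold_secondary` (1e-7),
#' `flank` (500000), `out_dir`.
#'
#' @param ... configuration fields, or a single list.
#' @return Validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1L && is.list(cfg[[1]]) && is.null(names(cfg)))
    cfg <- cfg[[1]]
  defaults <- list(weight_scheme = "sqrt_n", z_cut = 1.96,
                   B = 100000L, threshold = 5e-8,
                   threshold_secondary = 1e-7, flank = 5e5,
                   out_dir = "cpmeta_out", prune = NULL)
  for (f in names(defaults)) if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs either 'simulate' or 'inputs'")
  if (!is.null(cfg$inputs)) {
    for (inp in cfg$inputs)
      if (!file.exists(inp$path)) stop("input path does not exist: ", inp$path)
  }
  if (is.null(cfg$seed)) stop("seed is mandatory (S_Het null simulation)")
  stopifnot(cfg$threshold > 0, cfg$threshold < 1,
            cfg$threshold_secondary > 0, cfg$threshold_secondary < 1,
            cfg$z_cut > 0, cfg$flank > 0, cfg$B >= 1000)
  if (!cfg$weight_scheme %in% c("sqrt_n", "n", "unit"))
    stop("unknown weight scheme: ", cfg$weight_scheme)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON file.
#' @export
read_run_config <- function(path) {
  run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full cross-phenotype meta-analysis pipeline
#'
#' Stages, in dependency order: obtain a panel (simulate, or ingest +
#' harmonize), select null SNPs and estimate the between-panel correlation
#' matrix, scan (S_Hom, S_Het, weighted-Z baseline), clump loci at the
#' primary and secondary thresholds, flag loci missed by the baseline,
#' cross-tabulate, and write all artifacts plus a manifest.  Re-running an
#' identical configuration reproduces identical result files.
#'
#' @param cfg a [run_config()].
#' @return The manifest list (also written as `manifest.json`), recording
#'   every artifact, the config hash and the seed; on stage failure the
#'   manifest records the completed stages and the failing stage.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   stages = character(0), artifacts = list())
  art <- function(name, path) manifest$artifacts[[name]] <<- path
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(res)
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages <<- c(manifest$stages, name)
    res
  }

  zp <- stage("panel", {
    if (!is.null(cfg$simulate)) {
      sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
      sim <- simulate_zpanel(sc)
      write_simulated_study(sim, file.path(cfg$out_dir, "simulated"), sc)
      art("truth", file.path(cfg$out_dir, "simulated", "truth.tsv"))
      sim$zpanel
    } else {
      recs <- lapply(cfg$inputs, function(inp) {
        d <- do.call(sumstats_dialect, as.list(inp$dialect %||% list()))
        read_sumstats(inp$path, d)
      })
      harmonize(recs)
    }
  })
  stage("write_panel", {
    f <- file.path(cfg$out_dir, "zpanel.tsv.gz")
    write_zpanel(zp, f); art("zpanel", f)
  })

  cm <- stage("estimate_R", {
    retained <- NULL
    if (!is.null(cfg$prune)) {
      if (!is.null(cfg$prune$snp_list)) {
        retained <- readLines(cfg$prune$snp_list)
      } else if (!is.null(cfg$prune$genotypes)) {
        g <- as.matrix(data.table::fread(cfg$prune$genotypes), rownames = 1)
        pos <- as.numeric(readLines(cfg$prune$positions))
        retained <- ld_prune(g, pos,
                             r2_threshold = cfg$prune$r2_threshold %||% 0.2,
                             window_snps = cfg$prune$window_snps %||% 50L,
                             step_snps = cfg$prune$step_snps %||% 5L)
        retained <- intersect(retained, zp$snps$snp_id)
      }
    }
    nullp <- select_null_snps(zp, retained, z_cut = cfg$z_cut)
    cm <- estimate_R(nullp)
    f <- file.path(cfg$out_dir, "correlation.tsv")
    write_corr(cm, f); art("correlation", f)
    cm
  })

  w <- weight_spec(cfg$weight_scheme)
  scan <- stage("scan", {
    res <- cpassoc_scan(zp, cm, w, B = cfg$B, seed = cfg$seed)
    base <- weighted_z_scan(zp)
    res$z_meta <- base$z
    res$p_meta <- base$p
    f <- file.path(cfg$out_dir, "scan.tsv.gz")
    data.table::fwrite(res, f, sep = "\t"); art("scan", f)
    null <- attr(res, "shet_null")
    write_shet_null(null, file.path(cfg$out_dir, "shet_null"))
    art("shet_null", file.path(cfg$out_dir, "shet_null.tsv.gz"))
    res
  })

  stage("lambda", {
    lam <- list(
      s_hom = genomic_control_lambda(scan$s_hom),
      s_het_pbased = genomic_control_lambda(p = scan$p_het),
      weighted_z = genomic_control_lambda(p = scan$p_meta)
    )
    f <- file.path(cfg$out_dir, "lambda.json")
    jsonlite::write_json(lam, f, auto_unbox = TRUE, digits = NA)
    art("lambda", f)
  })

  loci <- stage("loci", {
    out <- list()
    for (m in c("p_hom", "p_het", "p_meta")) {
      for (thr in c(primary = cfg$threshold,
                    secondary = cfg$threshold_secondary)) {
        tier <- if (thr == cfg$threshold) "primary" else "secondary"
        lc <- identify_loci(scan, thr, cfg$flank, p_col = m)
        if (m != "p_meta")
          lc <- novel_vs_baseline(lc, scan, cfg$threshold, cfg$flank,
                                  ld_pairs = NULL, p_col = "p_meta")
        f <- file.path(cfg$out_dir, sprintf("loci_%s_%s.tsv", m, tier))
        data.table::fwrite(lc, f, sep = "\t")
        art(sprintf("loci_%s_%s", m, tier), f)
        out[[paste(m, tier, sep = ".")]] <- lc
      }
    }
    out
  })

  stage("compare", {
    ct_hom <- cross_tabulate(scan, scan, cfg$threshold, cfg$flank,
                             p_col_a = "p_hom", p_col_b = "p_meta",
                             labels = c("s_hom", "weighted_z"))
    ct_het <- cross_tabulate(scan, scan, cfg$threshold, cfg$flank,
                             p_col_a = "p_het", p_col_b = "p_meta",
                             labels = c("s_het", "weighted_z"))
    f <- file.path(cfg$out_dir, "cross_tab.tsv")
    data.table::fwrite(rbind(ct_hom$table, ct_het$table), f, sep = "\t")
    art("cross_tab", f)
  })

  stage("report", {
    qq <- qq_data(scan$p_hom)
    f <- file.path(cfg$out_dir, "qq_s_hom.tsv")
    data.table::fwrite(qq, f, sep = "\t"); art("qq_s_hom", f)
    mh <- manhattan_data(scan, "p_hom")
    f2 <- file.path(cfg$out_dir, "manhattan_s_hom.tsv.gz")
    data.table::fwrite(
      mh[c("snp_id", "chromosome", "position", "x", "neglog10p")],
      f2, sep = "\t")
    art("manhattan_s_hom", f2)
  })

  manifest$n_novel_primary <- sum(
    loci[["p_hom.primary"]]$novel_vs_baseline,
    loci[["p_het.primary"]]$novel_vs_baseline)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
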