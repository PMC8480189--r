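#' Pipeline configuration
#'
#' Exactly one of `vcf`/`popmap`/`ecotype` input paths or a `simulate`
#' block must be given.
#'
#' @param vcf,popmap,ecotype input file paths (all three or none).
#' @param simulate a [sim_config()] or NULL.
#' @param filter a [filter_config()].
#' @param scan a [scan_config()].
#' @param ldna an [ldna_params()].
#' @param delta karyotype-frequency shift threshold for SOC cause
#'   classification.
#' @param prune_window LD-pruning window for the neutral set (bp).
#' @param min_gap_bp,min_cross_gap_r2 SOC span gap-exclusion rule.
#' @param out_dir output directory.
#' @param seed seed recorded in the manifest and used for simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf = NULL, popmap = NULL, ecotype = NULL,
                            simulate = NULL,
                            filter = filter_config(),
                            scan = scan_config(),
                            ldna = ldna_params(),
                            delta = 0.5,
                            prune_window = 10000,
                            min_gap_bp = 5e6,
                            min_cross_gap_r2 = 0.5,
                            out_dir = tempfile("parinv_run_"),
                            seed = 1L) {
  has_files <- !is.null(vcf) || !is.null(popmap) || !is.null(ecotype)
  if (has_files && is.null(simulate)) {
    if (is.null(vcf) || is.null(popmap) || is.null(ecotype)) {
      stop("vcf, popmap and ecotype paths must all be given")
    }
  } else if (!has_files && !is.null(simulate)) {
    stopifnot(inherits(simulate, "sim_config"))
  } else {
    stop("give either input paths (vcf/popmap/ecotype) or a simulate block")
  }
  structure(list(vcf = vcf, popmap = popmap, ecotype = ecotype,
                 simulate = simulate, filter = filter, scan = scan,
                 ldna = ldna, delta = delta, prune_window = prune_window,
                 min_gap_bp = min_gap_bp,
                 min_cross_gap_r2 = min_cross_gap_r2,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `simulate`,
#' `filter`, `scan` and `ldna` blocks are passed to their constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("vcf", "popmap", "ecotype", "delta", "prune_window",
              "min_gap_bp", "min_cross_gap_r2", "out_dir", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$simulate)) args$simulate <- do.call(sim_config, y$simulate)
  if (!is.null(y$filter))   args$filter <- do.call(filter_config, y$filter)
  if (!is.null(y$scan))     args$scan <- do.call(scan_config, y$scan)
  if (!is.null(y$ldna))     args$ldna <- do.call(ldna_params, y$ldna)
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

stage <- function(name, expr) {
  message("[parinv] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orders the stages: load or simulate genotypes; SNP filtering; dual
#' outlier scans with all-pairs intersection; FWA assignment; LD-network
#' SOC detection; per-SOC karyotyping and cause classification; neutral
#' set construction; inversion-region FST elevation; summary statistics
#' and FWA summary. All stage tables
#' are written as TSV/BED under `config$out_dir` together with a
#' machine-readable run manifest.
#'
#' @param config a [pipeline_config()].
#' @return list of class `parinv_report`: `dataset` (filtered),
#'   `filter_report`, `scan`, `fwa`, `fwa_summary`, `socs`, `karyotypes`
#'   (per SOC), `classifications`, `inversion_fst`, `neutral`, `het`
#'   (per population), `pairwise_fst`, `summary` (flat named list of
#'   headline numbers), `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(...) file.path(config$out_dir, ...)

  raw <- stage("load", {
    if (!is.null(config$simulate)) {
      cfg <- config$simulate
      cfg$seed <- config$seed
      sim <- simulate_genotypes(cfg)
      sim$dataset
    } else {
      read_vcf(config$vcf, config$popmap, config$ecotype)
    }
  })

  filt <- stage("filter", apply_filters(raw, config$filter))
  ds <- filt$dataset
  write_filter_report(filt$report, od("filter_report.tsv"))

  scan <- stage("scan", outlier_scan(ds, config$scan))
  anc <- ancestral_pop(ds); der <- derived_pops(ds)
  scan_tab <- data.frame(snp_id = ds$variants$snp_id,
                         chrom = ds$variants$chrom,
                         pos = ds$variants$pos,
                         scan$fet_p,
                         d2 = scan$pca$d2, p_pca = scan$pca$p,
                         q_pca = scan$pca$q, check.names = FALSE)
  utils::write.table(scan_tab, od("scan.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(scan$candidates, od("candidates.txt"))
  manhattan <- data.frame(chrom = ds$variants$chrom,
                          pos = ds$variants$pos,
                          neglog10_p_fet = -log10(apply(
                            scan$fet_p, 1L, min, na.rm = TRUE)),
                          neglog10_p_pca = -log10(scan$pca$p))
  utils::write.table(manhattan, od("manhattan.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  fwa <- NULL; fwa_sum <- NULL
  if (length(scan$candidates)) {
    fwa <- stage("fwa", assign_fwa(ds, scan$candidates))
    utils::write.table(fwa, od("fwa.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  ldn <- stage("ldna", ld_network_scan(ds, config$ldna,
                                       min_gap_bp = config$min_gap_bp,
                                       min_cross_gap_r2 =
                                         config$min_cross_gap_r2))
  socs <- ldn$socs
  lambda_trace <- do.call(rbind, lapply(names(ldn$trees), function(chr) {
    cl <- ldn$trees[[chr]]$clusters
    if (is.null(cl) || !nrow(cl)) return(NULL)
    cbind(chrom = chr,
          cl[, c("cluster", "threshold", "n_loci", "n_edges",
                 "median_r2", "merged_median_r2", "lambda")])
  }))
  if (!is.null(lambda_trace)) {
    utils::write.table(lambda_trace, od("lambda_trace.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(socs)) {
    soc_tab <- socs[, c("chrom", "cluster", "type", "n_loci", "n_edges",
                        "lambda", "median_r2", "span_start", "span_end",
                        "raw_span", "adjusted_span", "n_excluded_gaps")]
    soc_tab$size_mb <- socs$adjusted_span / 1e6
    utils::write.table(soc_tab, od("soc_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    bed <- do.call(rbind, lapply(seq_len(nrow(socs)), function(i) {
      m <- socs$members[[i]]
      v <- ds$variants[match(m, ds$variants$snp_id), ]
      data.frame(chrom = v$chrom, start = v$pos - 1L, end = v$pos,
                 name = socs$cluster[i])
    }))
    write_bed(bed, od("soc_members.bed"))
  }

  karyos <- list(); classifications <- NULL
  if (!is.null(socs) && nrow(socs)) {
    karyos <- stage("karyotype", {
      lapply(seq_len(nrow(socs)), function(i) {
        karyotype_soc(ds, socs[i, , drop = FALSE], delta = config$delta)
      })
    })
    names(karyos) <- socs$cluster
    karyo_tab <- do.call(rbind, lapply(names(karyos), function(cl) {
      t <- karyos[[cl]]$assignment$table
      t$soc <- cl
      t
    }))
    utils::write.table(karyo_tab, od("karyotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    freq_tab <- do.call(rbind, lapply(names(karyos), function(cl) {
      f <- karyos[[cl]]$frequencies
      f$soc <- cl
      f
    }))
    utils::write.table(freq_tab, od("arrangement_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    classifications <- data.frame(
      soc = names(karyos),
      chrom = socs$chrom,
      cause = vapply(karyos, `[[`, character(1), "cause"),
      failed_het_gate = vapply(karyos, function(k)
        k$assignment$failed, logical(1)),
      stringsAsFactors = FALSE)
    utils::write.table(classifications, od("soc_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  neutral <- stage("neutral_set", {
    regions <- if (!is.null(socs) && nrow(socs)) {
      data.frame(chrom = socs$chrom, start = socs$span_start - 1L,
                 end = socs$span_end)
    }
    build_neutral_set(ds, outlier_ids = union(
      scan$candidates,
      unlist(lapply(names(scan$flags), function(nm)
        names(which(scan$flags[[nm]]))))),
      inversion_regions = regions,
      prune_window = config$prune_window)
  })

  stats_out <- stage("stats", {
    pops <- dataset_pops(neutral)
    het <- lapply(pops, function(p) het_stats(neutral, p))
    names(het) <- pops
    fst <- pairwise_fst(neutral)
    list(het = het, fst = fst)
  })
  het_tab <- data.frame(
    population = names(stats_out$het),
    mean_ho = vapply(stats_out$het, `[[`, numeric(1), "mean_ho"),
    mean_he = vapply(stats_out$het, `[[`, numeric(1), "mean_he"))
  utils::write.table(het_tab, od("heterozygosity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(stats_out$fst, od("pairwise_fst.tsv"), sep = "\t",
                     quote = FALSE)

  inv_fst <- NULL
  if (!is.null(socs) && nrow(socs)) {
    inv_fst <- stage("inversion_fst", {
      rows <- lapply(seq_len(nrow(socs)), function(i) {
        f <- inversion_fst(ds, socs$members[[i]],
                           neutral$variants$snp_id)
        data.frame(soc = socs$cluster[i],
                   mean_inversion_theta = f$mean_inversion_theta,
                   mean_neutral_theta = f$mean_neutral_theta,
                   elevation_ratio = f$elevation_ratio,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    utils::write.table(inv_fst, od("inversion_fst.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (!is.null(fwa)) {
    neutral_maf_anc <- {
      af <- allele_freq(neutral, anc)
      pmin(af, 1 - af, na.rm = FALSE)
    }
    fwa_sum <- fwa_summary(fwa, neutral_maf_anc[!is.na(neutral_maf_anc)])
  }

  summary <- list(
    n_snps_input = filt$report$n_input,
    n_snps_retained = filt$report$n_retained,
    n_candidates = length(scan$candidates),
    n_socs = if (is.null(socs)) 0L else nrow(socs),
    soc_causes = if (is.null(classifications)) character(0) else
      stats::setNames(classifications$cause, classifications$soc),
    mean_neutral_fst_anc_der = if (length(der))
      mean(stats_out$fst[anc, der]) else NA_real_,
    mean_fwa_increment = if (!is.null(fwa_sum))
      mean(fwa_sum$mean_increment) else NA_real_,
    inversion_fst_ratio = if (!is.null(inv_fst))
      stats::setNames(inv_fst$elevation_ratio, inv_fst$soc) else NULL
  )
  manifest <- list(
    package = "parinv",
    version = as.character(utils::packageVersion("parinv")),
    seed = config$seed,
    config_hash = config_hash(config),
    n_samples = length(ds$samples),
    summary = summary[c("n_snps_input", "n_snps_retained",
                        "n_candidates", "n_socs")]
  )
  jsonlite::write_json(manifest, od("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(list(dataset = ds, filter_report = filt$report, scan = scan,
                 fwa = fwa, fwa_summary = fwa_sum, socs = socs,
                 karyotypes = karyos, classifications = classifications,
                 inversion_fst = inv_fst,
                 neutral = neutral, het = stats_out$het,
                 pairwise_fst = stats_out$fst, summary = summary,
                 out_dir = config$out_dir),
            class = "parinv_report")
}

#' @export
print.parinv_report <- function(x, ...) {
  s <- x$summary
  cat("parinv pipeline report\n")
  cat("  SNPs: ", s$n_snps_input, " in, ", s$n_snps_retained,
      " retained\n", sep = "")
  cat("  candidate outlier SNPs:", s$n_candidates, "\n")
  cat("  retained SOCs:", s$n_socs, "\n")
  if (length(s$soc_causes)) {
    for (cl in names(s$soc_causes)) {
      cat("    ", cl, ": ", s$soc_causes[[cl]], "\n", sep = "")
    }
  }
  cat(sprintf("  mean neutral FST (ancestral vs derived): %.4f\n",
              s$mean_neutral_fst_anc_der))
  if (!is.na(s$mean_fwa_increment)) {
    cat(sprintf("  mean FWA frequency increment: %.3f\n",
                s$mean_fwa_increment))
  }
  cat("  outputs:", x$out_dir, "\n")
  invisible(x)
}
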