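#' Simulation configuration
#'
#' Defaults emulate the study design the analysis assumes: one ancestral
#' (anadromous) population and four derived freshwater populations of ~22
#' samples each; neutral drift differentiation at multi-locus FST ~ 0.03
#' (Balding-Nichols); a set of selected SNPs whose favored (alt) allele
#' rises from ~0.12 ancestrally to ~0.85 in every derived population; and
#' one recombination-suppressed inversion of many mutually linked SNPs with
#' arrangement frequencies shifted between ecotypes.
#'
#' @param n_derived_pops number of derived populations.
#' @param samples_per_pop samples per population.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param n_neutral_snps neutral SNP count (genome-wide).
#' @param n_selected_snps selected SNP count.
#' @param neutral_fst Balding-Nichols F for neutral drift (0 = panmixia).
#' @param anc_freq_range ancestral allele-frequency law Uniform(lo, hi).
#' @param selected_p0 ancestral alt frequency of selected SNPs.
#' @param selected_p1 derived alt frequency of selected SNPs.
#' @param frac_selected_in_inversion fraction of selected SNPs placed
#'   inside the inversion span (default 0: all outside).
#' @param inversion_chrom chromosome carrying the inversion (0 = none).
#' @param inversion_start,inversion_end inversion span in bp (1-based).
#' @param n_inversion_snps SNPs inside the inversion.
#' @param arr_divergence fraction of inversion SNPs diagnostic between
#'   arrangements (fixed ref in pool A, fixed alt in pool B).
#' @param arr_freq_B_anc,arr_freq_B_der B-arrangement frequency in the
#'   ancestral / each derived population.
#' @param missing_rate uniform genotype missingness rate.
#' @param mean_depth mean simulated per-genotype read depth.
#' @param seed integer seed (mandatory for reproducibility).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_derived_pops = 4L,
                       samples_per_pop = 22L,
                       n_chromosomes = 3L,
                       chrom_length_bp = 4e7,
                       n_neutral_snps = 5000L,
                       n_selected_snps = 60L,
                       neutral_fst = 0.03,
                       anc_freq_range = c(0.05, 0.95),
                       selected_p0 = 0.12,
                       selected_p1 = 0.85,
                       frac_selected_in_inversion = 0,
                       inversion_chrom = 3L,
                       inversion_start = 1e7,
                       inversion_end = 3e7,
                       n_inversion_snps = 300L,
                       arr_divergence = 0.8,
                       arr_freq_B_anc = 0.1,
                       arr_freq_B_der = 0.8,
                       missing_rate = 0.02,
                       mean_depth = 20,
                       seed = 1L) {
  cfg <- list(n_derived_pops = as.integer(n_derived_pops),
              samples_per_pop = as.integer(samples_per_pop),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp,
              n_neutral_snps = as.integer(n_neutral_snps),
              n_selected_snps = as.integer(n_selected_snps),
              neutral_fst = neutral_fst,
              anc_freq_range = anc_freq_range,
              selected_p0 = selected_p0,
              selected_p1 = selected_p1,
              frac_selected_in_inversion = frac_selected_in_inversion,
              inversion_chrom = as.integer(inversion_chrom),
              inversion_start = inversion_start,
              inversion_end = inversion_end,
              n_inversion_snps = as.integer(n_inversion_snps),
              arr_divergence = arr_divergence,
              arr_freq_B_anc = arr_freq_B_anc,
              arr_freq_B_der = arr_freq_B_der,
              missing_rate = missing_rate,
              mean_depth = mean_depth,
              seed = as.integer(seed))
  probs <- c(cfg$neutral_fst, cfg$selected_p0, cfg$selected_p1,
             cfg$arr_divergence, cfg$arr_freq_B_anc, cfg$arr_freq_B_der,
             cfg$missing_rate, cfg$frac_selected_in_inversion)
  stopifnot(all(probs >= 0), all(probs <= 1),
            cfg$anc_freq_range[1] > 0, cfg$anc_freq_range[2] < 1,
            cfg$anc_freq_range[1] < cfg$anc_freq_range[2])
  if (cfg$inversion_chrom > 0) {
    if (cfg$inversion_chrom > cfg$n_chromosomes) {
      stop("inversion_chrom exceeds n_chromosomes")
    }
    if (cfg$inversion_start < 1 || cfg$inversion_end > cfg$chrom_length_bp ||
        cfg$inversion_start >= cfg$inversion_end) {
      stop("inversion span must lie within the chromosome")
    }
  }
  structure(cfg, class = "sim_config")
}

# Balding-Nichols draw: population frequency around ancestral p at F
bn_freq <- function(p, f, n) {
  if (f <= 0) return(rep(p, n))
  stats::rbeta(n, p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

# run expr with a locally seeded RNG, restoring global state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv())
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' Simulate a genotype dataset with ground truth
#'
#' Neutral SNPs: ancestral frequency from Uniform(`anc_freq_range`), each
#' population's frequency from the Balding-Nichols beta law at
#' F = `neutral_fst`, genotypes binomial(2, p_pop). Selected SNPs: alt
#' frequency exactly `selected_p0` ancestrally and `selected_p1` in every
#' derived population (the favored allele is alt by construction).
#' Inversion SNPs: two arrangement haplotype pools; at the diagnostic
#' fraction of sites pool A is fixed ref and pool B fixed alt; remaining
#' inversion sites share a common frequency in both pools. Each individual
#' draws two arrangement labels from its population's B frequency, then one
#' haplotype per label; genotype = haplotype sum. Missingness is applied
#' uniformly at random; positions are uniform per chromosome, sorted and
#' deduplicated. Per-genotype depths (rounded gamma, mean `mean_depth`) and
#' genotype qualities around 40 are attached.
#'
#' @param cfg a [sim_config()].
#' @return list with `dataset` (a [geno_dataset()]) and `truth` (class
#'   `sim_truth`): `selected_ids`, `inversion` (chrom/start/end of the
#'   generated span), `karyotype` (named per-sample AA/AB/BB),
#'   `arr_freq_B` (named per-population generating frequency), `config`.
#' @export
simulate_genotypes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    pops <- c("ANA", if (cfg$n_derived_pops > 0)
      paste0("FW", seq_len(cfg$n_derived_pops)))
    eco <- stats::setNames(c("ancestral",
                             rep("derived", cfg$n_derived_pops)), pops)
    n_per <- cfg$samples_per_pop
    samples <- unlist(lapply(pops, function(p) paste0(p, "_", seq_len(n_per))))
    popmap <- stats::setNames(rep(pops, each = n_per), samples)
    n_ind <- length(samples)

    has_inv <- cfg$inversion_chrom > 0 && cfg$n_inversion_snps > 0
    n_sel <- cfg$n_selected_snps
    n_inv <- if (has_inv) cfg$n_inversion_snps else 0L

    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    inv_chrom <- if (has_inv) chroms[cfg$inversion_chrom] else NA_character_

    # --- positions ---------------------------------------------------------
    draw_pos <- function(n, lo, hi) sort(unique(floor(stats::runif(n, lo, hi))))
    neutral_chrom <- sample(chroms, cfg$n_neutral_snps, replace = TRUE)
    place <- function(n_target, chrom_vec, lo = 1, hi = cfg$chrom_length_bp,
                      avoid = NULL) {
      # rejection-sample positions per chromosome, unique within chromosome
      out_pos <- integer(0); out_chr <- character(0)
      for (ch in unique(chrom_vec)) {
        need <- sum(chrom_vec == ch)
        pos <- integer(0)
        while (length(pos) < need) {
          cand <- floor(stats::runif(2 * need, lo, hi + 1))
          if (!is.null(avoid) && ch == avoid$chrom) {
            cand <- cand[cand < avoid$start | cand > avoid$end]
          }
          pos <- unique(c(pos, cand))
        }
        pos <- pos[seq_len(need)]
        out_pos <- c(out_pos, pos); out_chr <- c(out_chr, rep(ch, need))
      }
      list(chrom = out_chr, pos = out_pos)
    }
    avoid <- NULL
    neutral_loc <- place(cfg$n_neutral_snps, neutral_chrom)
    sel_inside <- if (has_inv) round(n_sel * cfg$frac_selected_in_inversion)
      else 0L
    sel_outside <- n_sel - sel_inside
    sel_loc <- if (sel_outside > 0) {
      sc <- sample(chroms, sel_outside, replace = TRUE)
      place(sel_outside, sc,
            avoid = if (has_inv) list(chrom = inv_chrom,
                                      start = cfg$inversion_start,
                                      end = cfg$inversion_end))
    } else list(chrom = character(0), pos = integer(0))
    sel_in_loc <- if (sel_inside > 0) {
      place(sel_inside, rep(inv_chrom, sel_inside),
            lo = cfg$inversion_start, hi = cfg$inversion_end)
    } else list(chrom = character(0), pos = integer(0))
    inv_loc <- if (has_inv) {
      place(n_inv, rep(inv_chrom, n_inv),
            lo = cfg$inversion_start, hi = cfg$inversion_end)
    } else list(chrom = character(0), pos = integer(0))

    # --- genotypes ---------------------------------------------------------
    pop_of <- match(popmap, pops)

    # neutral
    n_neu <- cfg$n_neutral_snps
    p_anc <- stats::runif(n_neu, cfg$anc_freq_range[1], cfg$anc_freq_range[2])
    g_neu <- matrix(NA_integer_, n_ind, n_neu)
    p_pop <- matrix(NA_real_, length(pops), n_neu)
    for (k in seq_along(pops)) {
      p_pop[k, ] <- bn_freq_vec(p_anc, cfg$neutral_fst)
    }
    for (i in seq_len(n_ind)) {
      g_neu[i, ] <- stats::rbinom(n_neu, 2L, p_pop[pop_of[i], ])
    }

    # selected
    g_sel <- NULL
    if (n_sel > 0) {
      p_sel <- matrix(cfg$selected_p1, length(pops), n_sel)
      p_sel[1L, ] <- cfg$selected_p0
      g_sel <- matrix(NA_integer_, n_ind, n_sel)
      for (i in seq_len(n_ind)) {
        g_sel[i, ] <- stats::rbinom(n_sel, 2L, p_sel[pop_of[i], ])
      }
    }

    # inversion
    g_inv <- NULL; karyo <- NULL; arr_freq <- NULL
    if (has_inv) {
      n_diag <- round(n_inv * cfg$arr_divergence)
      diag_sites <- seq_len(n_diag)        # first n_diag sites diagnostic
      p_shared <- stats::runif(n_inv, cfg$anc_freq_range[1],
                               cfg$anc_freq_range[2])
      hapA_p <- p_shared; hapB_p <- p_shared
      hapA_p[diag_sites] <- 0; hapB_p[diag_sites] <- 1
      arr_freq <- stats::setNames(
        c(cfg$arr_freq_B_anc, rep(cfg$arr_freq_B_der, cfg$n_derived_pops)),
        pops)
      n_B <- stats::rbinom(n_ind, 2L, arr_freq[pop_of])
      karyo <- stats::setNames(c("AA", "AB", "BB")[n_B + 1L], samples)
      g_inv <- matrix(NA_integer_, n_ind, n_inv)
      for (i in seq_len(n_ind)) {
        h1 <- stats::rbinom(n_inv, 1L,
                            if (n_B[i] >= 1) hapB_p else hapA_p)
        h2 <- stats::rbinom(n_inv, 1L,
                            if (n_B[i] == 2) hapB_p else hapA_p)
        g_inv[i, ] <- h1 + h2
      }
    }

    chrom_all <- c(neutral_loc$chrom, sel_loc$chrom, sel_in_loc$chrom,
                   inv_loc$chrom)
    pos_all <- c(neutral_loc$pos, sel_loc$pos, sel_in_loc$pos, inv_loc$pos)
    geno <- cbind(g_neu, g_sel, g_inv)
    classes <- c(rep("neutral", n_neu), rep("selected", n_sel),
                 rep("inversion", n_inv))

    # resolve cross-class position collisions within a chromosome by nudging
    key <- paste(chrom_all, pos_all)
    while (any(duplicated(key))) {
      dup <- duplicated(key)
      pos_all[dup] <- pos_all[dup] + 1L
      key <- paste(chrom_all, pos_all)
    }
    snp_id <- paste0(chrom_all, ":", pos_all)
    variants <- data.frame(snp_id = snp_id, chrom = chrom_all, pos = pos_all,
                           ref = "A", alt = "G",
                           qual = round(stats::runif(length(snp_id), 60, 999)),
                           stringsAsFactors = FALSE)

    # missingness, depth, quality
    miss <- matrix(stats::runif(length(geno)) < cfg$missing_rate,
                   nrow(geno), ncol(geno))
    geno[miss] <- NA_integer_
    depth <- matrix(pmax(1, round(stats::rgamma(length(geno),
                                                shape = 8,
                                                scale = cfg$mean_depth / 8))),
                    nrow(geno), ncol(geno))
    gq <- matrix(pmin(99, pmax(20, round(stats::rnorm(length(geno), 40, 8)))),
                 nrow(geno), ncol(geno))
    depth[miss] <- NA; gq[miss] <- NA
    rownames(geno) <- samples

    ds <- geno_dataset(geno, variants, popmap, eco, depth = depth, gq = gq)
    sel_ids <- snp_id[classes == "selected"]
    inv_ids <- snp_id[classes == "inversion"]
    neutral_ids <- snp_id[classes == "neutral"]
    truth <- structure(list(
      selected_ids = sel_ids,
      neutral_ids = neutral_ids,
      inversion_ids = inv_ids,
      inversion = if (has_inv) list(chrom = inv_chrom,
                                    start = cfg$inversion_start,
                                    end = cfg$inversion_end),
      karyotype = karyo,
      arr_freq_B = arr_freq,
      config = cfg), class = "sim_truth")
    list(dataset = ds, truth = truth)
  })
}

# vectorized Balding-Nichols over loci (one population draw per locus)
bn_freq_vec <- function(p, f) {
  if (f <= 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a null dataset (no selection, no inversion)
#'
#' As [simulate_genotypes()] with `n_selected_snps = 0` and no inversion;
#' `neutral_fst` as configured (0 gives panmixia).
#'
#' @param cfg a [sim_config()]; selection/inversion fields are overridden.
#' @return list with `dataset` and `truth` (empty selections).
#' @export
simulate_null <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$n_selected_snps <- 0L
  cfg$inversion_chrom <- 0L
  cfg$n_inversion_snps <- 0L
  simulate_genotypes(cfg)
}

#' Write a simulation to disk (VCF, maps, truth JSON, inversion BED)
#'
#' @param sim a [simulate_genotypes()] result.
#' @param dir output directory (created if needed).
#' @return named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             ecotype = file.path(dir, "ecotype.tsv"),
             truth = file.path(dir, "truth.json"),
             inversion_bed = file.path(dir, "inversion.bed"))
  write_vcf(sim$dataset, paths["vcf"], paths["popmap"], paths["ecotype"])
  tr <- sim$truth
  jsonlite::write_json(list(
    selected_ids = tr$selected_ids,
    inversion = tr$inversion,
    karyotype = as.list(tr$karyotype),
    arr_freq_B = as.list(tr$arr_freq_B),
    config = unclass(tr$config)), paths["truth"], auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  if (!is.null(tr$inversion)) {
    write_bed(data.frame(chrom = tr$inversion$chrom,
                         start = tr$inversion$start - 1L,
                         end = tr$inversion$end,
                         name = "inversion"), paths["inversion_bed"])
  }
  paths
}
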