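#' Read genotypes, population map and ecotype map
#'
#' Parses a VCF 4.x file of diploid genotypes into a [geno_dataset()].
#' Multi-allelic records and non-SNP records (indels, symbolic alleles) are
#' skipped; the number skipped is reported via a message and recorded in the
#' `skipped` attribute of the result. Per-genotype `DP` and `GQ` FORMAT
#' fields are captured when present.
#'
#' @param path path to a VCF file (plain text or bgzip, anything vcfR reads).
#' @param popmap_path TSV with two columns (no header):
#'   sample id, population label. Every VCF sample must appear.
#' @param ecotype_path TSV with two columns (no header): population label,
#'   `ancestral` or `derived`.
#' @return A [geno_dataset()] with attribute `skipped` (count of skipped
#'   non-biallelic/non-SNP records).
#' @export
read_vcf <- function(path, popmap_path, ecotype_path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  popmap <- read_popmap(popmap_path)
  ecotype <- read_ecotype(ecotype_path)

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  unk <- setdiff(samples, names(popmap))
  if (length(unk)) {
    stop("VCF sample(s) not in popmap: ", paste(unk, collapse = ", "))
  }

  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0) {
    message("read_vcf: skipped ", n_skip, " non-biallelic/non-SNP record(s)")
  }
  keep <- which(is_snp)
  if (!length(keep)) stop("no biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dose <- gt_to_dosage(gt)
  fmt <- strsplit(v@gt[keep, 1L], ":", fixed = TRUE)
  has_dp <- any(vapply(fmt, function(f) "DP" %in% f, logical(1)))
  has_gq <- any(vapply(fmt, function(f) "GQ" %in% f, logical(1)))
  depth <- if (has_dp) {
    m <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    t(m[keep, , drop = FALSE])
  }
  gq <- if (has_gq) {
    m <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
    t(m[keep, , drop = FALSE])
  }

  variants <- data.frame(
    snp_id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                    paste0(fix$CHROM[keep], ":", fix$POS[keep]),
                    fix$ID[keep]),
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    qual = suppressWarnings(as.numeric(fix$QUAL[keep])),
    stringsAsFactors = FALSE
  )
  ds <- geno_dataset(t(dose), variants, popmap, ecotype,
                     depth = depth, gq = gq)
  attr(ds, "skipped") <- n_skip
  ds
}

# GT strings ("0/0", "0|1", "./.", NA) -> integer dosage matrix (snp x sample)
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  d[clean == "0/0"] <- 0L
  d[clean == "0/1" | clean == "1/0"] <- 1L
  d[clean == "1/1"] <- 2L
  d
}

#' Read a sample-to-population map
#' @param path TSV: sample_id <TAB> population (no header).
#' @return named character vector, sample id -> population.
#' @export
read_popmap <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("sample", "population"))
  stats::setNames(x$population, x$sample)
}

#' Read a population-to-ecotype map
#' @param path TSV: population <TAB> ancestral|derived (no header).
#' @return named character vector, population -> ecotype.
#' @export
read_ecotype <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("population", "ecotype"))
  stats::setNames(x$ecotype, x$population)
}

#' Write a genotype dataset as plain-text VCF (+ popmap/ecotype TSVs)
#'
#' Emits a minimal VCF 4.2 file that [read_vcf()] reads back to an identical
#' dataset. Missing genotypes are written as `./.`; per-genotype DP/GQ are
#' written when the dataset carries them.
#'
#' @param dataset a [geno_dataset()].
#' @param path output VCF path.
#' @param popmap_path,ecotype_path optional output paths for the companion
#'   TSV maps.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dataset, path, popmap_path = NULL, ecotype_path = NULL) {
  stopifnot(inherits(dataset, "geno_dataset"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))

  v <- dataset$variants
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$samples), collapse = "\t")
  ), con)
  if (nrow(v) == 0L) return(invisible(path))

  gt_str <- matrix("./.", nrow(v), length(dataset$samples))
  g <- t(dataset$geno)  # snp x sample
  gt_str[!is.na(g) & g == 0L] <- "0/0"
  gt_str[!is.na(g) & g == 1L] <- "0/1"
  gt_str[!is.na(g) & g == 2L] <- "1/1"
  has_dp <- !is.null(dataset$depth)
  has_gq <- !is.null(dataset$gq)
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_gq) "GQ"), collapse = ":")
  if (has_dp) {
    dp <- t(dataset$depth)
    gt_str <- matrix(paste(gt_str, ifelse(is.na(dp), ".", dp), sep = ":"),
                     nrow(v))
  }
  if (has_gq) {
    gq <- t(dataset$gq)
    gt_str <- matrix(paste(gt_str, ifelse(is.na(gq), ".", gq), sep = ":"),
                     nrow(v))
  }
  qual <- ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE,
                                            scientific = FALSE))
  lines <- paste(v$chrom, v$pos, v$snp_id, v$ref, v$alt, qual, "PASS", ".",
                 fmt, sep = "\t")
  lines <- paste(lines, apply(gt_str, 1L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)

  if (!is.null(popmap_path)) {
    utils::write.table(
      data.frame(names(dataset$popmap), unname(dataset$popmap)),
      popmap_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(ecotype_path)) {
    utils::write.table(
      data.frame(names(dataset$ecotype), unname(dataset$ecotype)),
      ecotype_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' SNP filter configuration
#'
#' Thresholds for the six-step SNP retention rule: (1) at least
#' `min_individuals_per_pop` called individuals in every population (after
#' per-genotype depth/quality masking), (2) per-genotype depth at least
#' `min_depth`, (3) site quality at least `min_site_quality` and genotype
#' quality at least `min_genotype_quality`, (4) observed heterozygosity at
#' most `max_pop_Ho` in every population, (5) global minor allele frequency
#' at least `min_global_maf`, or (6) rescue when the local (per-population)
#' MAF reaches `rescue_local_maf` in any population.
#'
#' @param min_individuals_per_pop minimum called individuals per population.
#' @param min_depth minimum per-genotype read depth.
#' @param min_site_quality minimum site Phred quality.
#' @param min_genotype_quality minimum per-genotype Phred quality.
#' @param max_pop_Ho maximum per-population observed heterozygosity.
#' @param min_global_maf global MAF threshold.
#' @param rescue_local_maf local MAF rescuing a SNP that fails the global
#'   MAF threshold.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_individuals_per_pop = 12L,
                          min_depth = 6,
                          min_site_quality = 30,
                          min_genotype_quality = 15,
                          max_pop_Ho = 0.5,
                          min_global_maf = 0.05,
                          rescue_local_maf = 0.2) {
  stopifnot(min_individuals_per_pop >= 1, min_depth >= 0,
            max_pop_Ho >= 0, max_pop_Ho <= 1,
            min_global_maf >= 0, min_global_maf <= 1,
            rescue_local_maf >= 0, rescue_local_maf <= 1)
  structure(list(min_individuals_per_pop = as.integer(min_individuals_per_pop),
                 min_depth = min_depth,
                 min_site_quality = min_site_quality,
                 min_genotype_quality = min_genotype_quality,
                 max_pop_Ho = max_pop_Ho,
                 min_global_maf = min_global_maf,
                 rescue_local_maf = rescue_local_maf),
            class = "filter_config")
}

#' Apply SNP retention filters
#'
#' Genotypes failing the depth or genotype-quality thresholds are first set
#' to missing; SNPs are then removed in order by the first criterion they
#' fail: per-population call rate, site quality, per-population observed
#' heterozygosity, and the global-MAF-or-local-MAF-rescue rule.
#'
#' @param dataset a [geno_dataset()].
#' @param cfg a [filter_config()].
#' @return list with elements `dataset` (filtered) and `report` (class
#'   `filter_report`): genotype masking counts, per-criterion SNP removal
#'   counts, and retained SNP ids. Removal counts plus retained count equal
#'   the input SNP count.
#' @export
apply_filters <- function(dataset, cfg = filter_config()) {
  stopifnot(inherits(dataset, "geno_dataset"))
  pops <- dataset_pops(dataset)
  if (!length(pops)) stop("dataset has no populations")
  geno <- dataset$geno

  masked_depth <- 0L; masked_gq <- 0L
  if (!is.null(dataset$depth)) {
    bad <- !is.na(geno) & !is.na(dataset$depth) & dataset$depth < cfg$min_depth
    masked_depth <- sum(bad)
    geno[bad] <- NA_integer_
  }
  if (!is.null(dataset$gq)) {
    bad <- !is.na(geno) & !is.na(dataset$gq) &
      dataset$gq < cfg$min_genotype_quality
    masked_gq <- sum(bad)
    geno[bad] <- NA_integer_
  }

  small <- pops[table(dataset$popmap)[pops] < cfg$min_individuals_per_pop]
  if (length(small)) {
    warning("population(s) smaller than min_individuals_per_pop (",
            paste(small, collapse = ", "),
            "): the call-rate criterion removes every SNP for them")
  }

  n_snp <- ncol(geno)
  reason <- rep(NA_character_, n_snp)

  pop_idx <- lapply(pops, function(p) which(dataset$popmap == p))
  names(pop_idx) <- pops

  # criterion 1: called individuals per population
  called <- vapply(pop_idx, function(ix)
    colSums(!is.na(geno[ix, , drop = FALSE])), numeric(n_snp))
  called <- matrix(called, nrow = n_snp)
  fail1 <- rowSums(called < cfg$min_individuals_per_pop) > 0
  reason[fail1 & is.na(reason)] <- "call_rate"

  # criterion 3 (site part): site quality
  qual <- dataset$variants$qual
  fail3 <- !is.na(qual) & qual < cfg$min_site_quality
  reason[fail3 & is.na(reason)] <- "site_quality"

  # criterion 4: per-population observed heterozygosity
  ho_max <- rep(0, n_snp)
  for (p in pops) {
    g <- geno[pop_idx[[p]], , drop = FALSE]
    ho <- colSums(g == 1L, na.rm = TRUE) / pmax(colSums(!is.na(g)), 1L)
    ho_max <- pmax(ho_max, ho)
  }
  reason[ho_max > cfg$max_pop_Ho & is.na(reason)] <- "pop_het"

  # criteria 5/6: global MAF with local-MAF rescue
  af_global <- colMeans(geno, na.rm = TRUE) / 2
  maf_global <- pmin(af_global, 1 - af_global)
  local_rescue <- rep(FALSE, n_snp)
  for (p in pops) {
    g <- geno[pop_idx[[p]], , drop = FALSE]
    af <- colMeans(g, na.rm = TRUE) / 2
    maf <- pmin(af, 1 - af)
    local_rescue <- local_rescue | (!is.na(maf) & maf >= cfg$rescue_local_maf)
  }
  fail_maf <- (is.na(maf_global) | maf_global < cfg$min_global_maf) &
    !local_rescue
  reason[fail_maf & is.na(reason)] <- "maf"

  keep <- is.na(reason)
  removed <- table(factor(reason[!keep],
                          levels = c("call_rate", "site_quality",
                                     "pop_het", "maf")))
  ds_out <- geno_dataset(
    geno[, keep, drop = FALSE],
    dataset$variants[keep, , drop = FALSE],
    dataset$popmap, dataset$ecotype,
    depth = if (!is.null(dataset$depth)) dataset$depth[, keep, drop = FALSE],
    gq = if (!is.null(dataset$gq)) dataset$gq[, keep, drop = FALSE]
  )
  report <- structure(list(
    n_input = n_snp,
    n_retained = sum(keep),
    masked_genotypes = c(depth = masked_depth, genotype_quality = masked_gq),
    removed = c(removed),
    retained_ids = dataset$variants$snp_id[keep],
    removal_reason = stats::setNames(reason, dataset$variants$snp_id)
  ), class = "filter_report")
  list(dataset = ds_out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filter report:", x$n_input, "in,", x$n_retained, "retained\n")
  cat("genotypes masked: depth =", x$masked_genotypes[["depth"]],
      ", genotype quality =", x$masked_genotypes[["genotype_quality"]], "\n")
  cat("SNPs removed by first failed criterion:\n")
  for (r in names(x$removed)) cat("  ", r, ":", x$removed[[r]], "\n")
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report`.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(snp_id = names(report$removal_reason),
                   removed_by = ifelse(is.na(report$removal_reason),
                                       "retained", report$removal_reason))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the neutral, LD-pruned SNP set
#'
#' Removes outlier SNPs (any method, any population pair), SNPs inside
#' candidate inversion regions, and then thins the remainder to one SNP per
#' `prune_window` bp window on each chromosome (the first SNP encountered
#' scanning left to right is kept; window id is `floor(pos0 / window)` on
#' 0-based positions).
#'
#' @param dataset a [geno_dataset()].
#' @param outlier_ids character vector of SNP ids to exclude.
#' @param inversion_regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), or NULL.
#' @param prune_window window size in bp (default 10 kb).
#' @return A pruned `geno_dataset`.
#' @export
build_neutral_set <- function(dataset, outlier_ids = character(),
                              inversion_regions = NULL,
                              prune_window = 10000) {
  stopifnot(inherits(dataset, "geno_dataset"))
  v <- dataset$variants
  keep <- !(v$snp_id %in% outlier_ids)
  if (!is.null(inversion_regions) && nrow(inversion_regions)) {
    pos0 <- v$pos - 1L
    for (i in seq_len(nrow(inversion_regions))) {
      r <- inversion_regions[i, ]
      keep <- keep & !(v$chrom == r$chrom & pos0 >= r$start & pos0 < r$end)
    }
  }
  if (!any(keep)) {
    stop("no SNPs left after outlier/inversion exclusion; ",
         "consider a smaller prune window or fewer exclusions")
  }
  win <- floor((v$pos - 1L) / prune_window)
  idx <- which(keep)
  key <- paste(v$chrom[idx], win[idx], sep = "\r")
  idx <- idx[!duplicated(key)]  # first retained SNP of each window wins
  if (!length(idx)) stop("pruning removed all SNPs; use a smaller window")
  subset_dataset(dataset, snp_ids = v$snp_id[idx])
}

#' Write BED intervals (0-based half-open)
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(regions))
  utils::write.table(regions[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
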