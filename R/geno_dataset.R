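#' Genotype dataset container
#'
#' Bundles a samples x SNPs allele-dosage matrix with variant records,
#' a sample-to-population map and a population-to-ecotype map. This is the
#' substrate every analysis stage operates on.
#'
#' @param geno integer matrix of alt-allele dosages in \{0, 1, 2\}, `NA` for
#'   missing genotypes; rows are samples, columns are SNPs.
#' @param variants data.frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based, as in VCF), `ref`, `alt` and optionally `qual` (site Phred
#'   quality, `NA` when absent).
#' @param popmap named character vector mapping sample id to population
#'   label; must cover every row of `geno`.
#' @param ecotype named character vector mapping population label to
#'   `"ancestral"` or `"derived"`.
#' @param depth optional integer matrix of per-genotype read depths (same
#'   shape as `geno`).
#' @param gq optional numeric matrix of per-genotype Phred qualities.
#'
#' @return An object of class `geno_dataset`: a list with elements `geno`,
#'   `variants`, `samples`, `popmap`, `ecotype`, `depth`, `gq`. Variants are
#'   sorted by chromosome then position; positions are strictly increasing
#'   within each chromosome.
#' @export
geno_dataset <- function(geno, variants, popmap, ecotype,
                         depth = NULL, gq = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(variants))
  req <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants))) {
    stop("variants must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(variants$qual)) variants$qual <- NA_real_
  if (ncol(geno) != nrow(variants)) {
    stop("geno has ", ncol(geno), " columns but variants has ",
         nrow(variants), " rows")
  }
  if (is.null(rownames(geno))) stop("geno must have sample ids as rownames")
  samples <- rownames(geno)
  missing_pop <- setdiff(samples, names(popmap))
  if (length(missing_pop)) {
    stop("sample(s) missing from popmap: ",
         paste(missing_pop, collapse = ", "))
  }
  popmap <- popmap[samples]
  pops <- unique(unname(popmap))
  missing_eco <- setdiff(pops, names(ecotype))
  if (length(missing_eco)) {
    stop("population(s) missing from ecotype map: ",
         paste(missing_eco, collapse = ", "))
  }
  if (!all(ecotype %in% c("ancestral", "derived"))) {
    stop("ecotype values must be 'ancestral' or 'derived'")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }

  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  if (!is.null(depth)) depth <- as.matrix(depth)[, ord, drop = FALSE]
  if (!is.null(gq))    gq    <- as.matrix(gq)[, ord, drop = FALSE]
  dup <- unlist(lapply(split(variants$pos, variants$chrom),
                       function(p) any(duplicated(p))))
  if (any(dup)) stop("duplicate positions within a chromosome")
  rownames(variants) <- NULL
  colnames(geno) <- variants$snp_id
  if (!is.null(depth)) dimnames(depth) <- dimnames(geno)
  if (!is.null(gq))    dimnames(gq)    <- dimnames(geno)

  structure(list(geno = geno, variants = variants, samples = samples,
                 popmap = popmap, ecotype = ecotype,
                 depth = depth, gq = gq),
            class = "geno_dataset")
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat("geno_dataset:", length(x$samples), "samples x",
      nrow(x$variants), "SNPs\n")
  tab <- table(x$popmap)
  eco <- x$ecotype[names(tab)]
  cat("populations:\n")
  for (p in names(tab)) {
    cat("  ", p, " (", eco[[p]], "): ", tab[[p]], " samples\n", sep = "")
  }
  cat("chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_dataset <- function(x) c(length(x$samples), nrow(x$variants))

#' Subset a genotype dataset by SNPs and/or samples
#'
#' @param dataset a [geno_dataset()].
#' @param snp_ids SNP ids to keep (default all, original order preserved).
#' @param samples sample ids to keep (default all).
#' @return A `geno_dataset` restricted to the requested SNPs and samples.
#' @export
subset_dataset <- function(dataset, snp_ids = NULL, samples = NULL) {
  stopifnot(inherits(dataset, "geno_dataset"))
  keep_v <- if (is.null(snp_ids)) seq_len(nrow(dataset$variants)) else {
    idx <- match(snp_ids, dataset$variants$snp_id)
    if (anyNA(idx)) stop("unknown snp_id(s): ",
                         paste(snp_ids[is.na(idx)], collapse = ", "))
    sort(idx)
  }
  keep_s <- if (is.null(samples)) dataset$samples else {
    unk <- setdiff(samples, dataset$samples)
    if (length(unk)) stop("unknown sample(s): ", paste(unk, collapse = ", "))
    dataset$samples[dataset$samples %in% samples]
  }
  geno_dataset(
    dataset$geno[keep_s, keep_v, drop = FALSE],
    dataset$variants[keep_v, , drop = FALSE],
    dataset$popmap, dataset$ecotype,
    depth = if (!is.null(dataset$depth))
      dataset$depth[keep_s, keep_v, drop = FALSE],
    gq = if (!is.null(dataset$gq))
      dataset$gq[keep_s, keep_v, drop = FALSE]
  )
}

# samples belonging to one population
pop_samples <- function(dataset, population) {
  if (!population %in% dataset$popmap) {
    stop("unknown population: ", population)
  }
  dataset$samples[dataset$popmap == population]
}

# population labels in dataset order of first appearance
dataset_pops <- function(dataset) unique(unname(dataset$popmap))

# ancestral population label (exactly one expected for ecotype contrasts)
ancestral_pop <- function(dataset) {
  pops <- dataset_pops(dataset)
  anc <- pops[dataset$ecotype[pops] == "ancestral"]
  if (length(anc) != 1L) {
    stop("expected exactly one ancestral population, found ", length(anc))
  }
  anc
}

derived_pops <- function(dataset) {
  pops <- dataset_pops(dataset)
  pops[dataset$ecotype[pops] == "derived"]
}
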