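#' Per-SNP alt-allele frequency within one population
#'
#' Frequencies are computed over called genotypes only; a SNP with no called
#' genotype in the population gets `NA`.
#'
#' @param dataset a [geno_dataset()].
#' @param population population label.
#' @return named numeric vector (snp_id -> alt frequency in `[0, 1]`).
#' @export
allele_freq <- function(dataset, population) {
  g <- dataset$geno[pop_samples(dataset, population), , drop = FALSE]
  n_called <- colSums(!is.na(g))
  af <- colSums(g, na.rm = TRUE) / (2 * n_called)
  af[n_called == 0L] <- NA_real_
  stats::setNames(af, dataset$variants$snp_id)
}

#' Observed and expected heterozygosity within one population
#'
#' Per SNP, observed heterozygosity is the fraction of heterozygous calls
#' among called genotypes; expected heterozygosity uses the small-sample
#' corrected form `2p(1-p) * n/(n-1)` with `n` the number of called
#' individuals.
#'
#' @param dataset a [geno_dataset()].
#' @param population population label.
#' @return list with `ho`, `he` (per-SNP vectors) and `mean_ho`, `mean_he`.
#' @export
het_stats <- function(dataset, population) {
  samp <- pop_samples(dataset, population)
  if (!length(samp)) stop("empty population: ", population)
  g <- dataset$geno[samp, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  ho <- colSums(g == 1L, na.rm = TRUE) / n_called
  ho[n_called == 0L] <- NA_real_
  p <- colSums(g, na.rm = TRUE) / (2 * n_called)
  he <- 2 * p * (1 - p) * ifelse(n_called > 1L,
                                 n_called / (n_called - 1L), NA_real_)
  he[n_called == 0L] <- NA_real_
  ids <- dataset$variants$snp_id
  list(ho = stats::setNames(ho, ids), he = stats::setNames(he, ids),
       mean_ho = mean(ho, na.rm = TRUE), mean_he = mean(he, na.rm = TRUE))
}

#' Per-individual heterozygosity over a SNP set
#'
#' For each sample, the fraction of heterozygous calls among called
#' genotypes restricted to `snp_ids`. Samples with no called genotype in
#' the region get `NA`.
#'
#' @param dataset a [geno_dataset()].
#' @param snp_ids SNP ids defining the region.
#' @return named numeric vector (sample -> heterozygosity proportion).
#' @export
individual_het <- function(dataset, snp_ids) {
  if (!length(snp_ids)) stop("snp_ids must be non-empty")
  idx <- match(snp_ids, dataset$variants$snp_id)
  if (anyNA(idx)) stop("unknown snp_id(s)")
  g <- dataset$geno[, idx, drop = FALSE]
  n_called <- rowSums(!is.na(g))
  het <- rowSums(g == 1L, na.rm = TRUE) / n_called
  het[n_called == 0L] <- NA_real_
  stats::setNames(het, dataset$samples)
}

# Weir & Cockerham (1984) per-locus variance components for two populations.
# p1, p2 alt freqs; h1, h2 observed het proportions; n1, n2 called counts.
wc_components <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham FST between two populations
#'
#' Per-locus variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) are computed
#' for each usable SNP; the multi-locus estimate is the ratio of sums
#' `sum(a) / sum(a + b + c)`. Loci with a zero denominator (monomorphic in
#' the pooled pair) are skipped.
#'
#' @param dataset a [geno_dataset()].
#' @param popA,popB population labels.
#' @param snp_ids SNPs to use (default all).
#' @return list of class `fst_result`: `theta` (multi-locus), `per_locus`
#'   (per-SNP theta, NA where undefined), `n_loci_used`, `pair`.
#' @export
wc_fst <- function(dataset, popA, popB, snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- dataset$variants$snp_id
  idx <- match(snp_ids, dataset$variants$snp_id)
  if (anyNA(idx)) stop("unknown snp_id(s)")
  gA <- dataset$geno[pop_samples(dataset, popA), idx, drop = FALSE]
  gB <- dataset$geno[pop_samples(dataset, popB), idx, drop = FALSE]
  n1 <- colSums(!is.na(gA)); n2 <- colSums(!is.na(gB))
  ok <- n1 >= 2 & n2 >= 2
  p1 <- colSums(gA, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(gB, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(gA == 1L, na.rm = TRUE) / n1
  h2 <- colSums(gB == 1L, na.rm = TRUE) / n2
  comp <- wc_components(p1, p2, h1, h2, n1, n2)
  denom <- comp$a + comp$b + comp$c
  usable <- ok & !is.na(denom) & denom > 0
  if (!any(usable)) stop("no usable loci for FST between ", popA,
                         " and ", popB)
  theta <- sum(comp$a[usable]) / sum(denom[usable])
  per_locus <- ifelse(usable, comp$a / denom, NA_real_)
  structure(list(theta = theta,
                 per_locus = stats::setNames(per_locus, snp_ids),
                 n_loci_used = sum(usable),
                 pair = c(popA, popB)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham FST %s vs %s: theta = %.4f (%d loci)\n",
              x$pair[1], x$pair[2], x$theta, x$n_loci_used))
  invisible(x)
}

# Multi-locus theta from two genotype submatrices (rows = individuals).
theta_from_matrices <- function(gA, gB) {
  n1 <- colSums(!is.na(gA)); n2 <- colSums(!is.na(gB))
  p1 <- colSums(gA, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(gB, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(gA == 1L, na.rm = TRUE) / n1
  h2 <- colSums(gB == 1L, na.rm = TRUE) / n2
  comp <- wc_components(p1, p2, h1, h2, n1, n2)
  denom <- comp$a + comp$b + comp$c
  usable <- n1 >= 2 & n2 >= 2 & !is.na(denom) & denom > 0
  if (!any(usable)) return(NA_real_)
  sum(comp$a[usable]) / sum(denom[usable])
}

#' Permutation significance for a pairwise FST estimate
#'
#' Individuals are permuted between the two populations (sample sizes
#' preserved) and the multi-locus theta recomputed for each permutation;
#' the p-value is `(1 + # permuted theta >= observed) / (n_perm + 1)`.
#'
#' @param dataset a [geno_dataset()].
#' @param popA,popB population labels.
#' @param snp_ids SNPs to use (default all).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutation stream (restored on exit).
#' @return list: `theta` (observed), `p` (permutation p-value), `n_perm`.
#' @export
fst_permutation_test <- function(dataset, popA, popB, snp_ids = NULL,
                                 n_perm = 10000L, seed = 1L) {
  if (is.null(snp_ids)) snp_ids <- dataset$variants$snp_id
  idx <- match(snp_ids, dataset$variants$snp_id)
  if (anyNA(idx)) stop("unknown snp_id(s)")
  rowsA <- pop_samples(dataset, popA)
  rowsB <- pop_samples(dataset, popB)
  g <- dataset$geno[c(rowsA, rowsB), idx, drop = FALSE]
  nA <- length(rowsA); n <- nrow(g)
  obs <- theta_from_matrices(g[seq_len(nA), , drop = FALSE],
                             g[seq(nA + 1L, n), , drop = FALSE])
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ord <- sample.int(n)
    theta_from_matrices(g[ord[seq_len(nA)], , drop = FALSE],
                        g[ord[seq(nA + 1L, n)], , drop = FALSE])
  }, numeric(1)))
  list(theta = obs,
       p = (1 + sum(perm >= obs, na.rm = TRUE)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Pairwise multi-locus FST matrix over all populations
#'
#' With `n_perm > 0`, permutation p-values ([fst_permutation_test()]) are
#' computed for every pair and adjusted across pairs by the
#' Benjamini-Yekutieli step-up rule; they are attached as attribute
#' `p_adj` (a symmetric matrix, NA diagonal).
#'
#' @param dataset a [geno_dataset()].
#' @param snp_ids SNPs to use (default all).
#' @param n_perm permutations per pair (0 = no significance testing).
#' @param seed RNG seed for the permutation streams.
#' @return symmetric numeric matrix of multi-locus theta, zero diagonal.
#' @export
pairwise_fst <- function(dataset, snp_ids = NULL, n_perm = 0L, seed = 1L) {
  pops <- dataset_pops(dataset)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  if (length(pops) < 2) return(m)
  pmat <- matrix(NA_real_, length(pops), length(pops),
                 dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in seq((i + 1), length(pops))) {
      if (n_perm > 0) {
        pt <- fst_permutation_test(dataset, pops[i], pops[j], snp_ids,
                                   n_perm = n_perm, seed = seed)
        th <- pt$theta
        pmat[i, j] <- pt$p; pmat[j, i] <- pt$p
      } else {
        th <- wc_fst(dataset, pops[i], pops[j], snp_ids)$theta
      }
      m[i, j] <- th; m[j, i] <- th
    }
  }
  if (n_perm > 0) {
    up <- upper.tri(pmat)
    pmat[up] <- stats::p.adjust(pmat[up], method = "BY")
    pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
    attr(m, "p_adj") <- pmat
  }
  m
}

#' Welch two-sample t-test
#'
#' Two-sided Welch t-test (unequal variances, Welch-Satterthwaite degrees
#' of freedom).
#'
#' @param x,y numeric samples, each of length at least 2, with nonzero
#'   variance in at least one.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("both samples have zero variance")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Nearest-neighbor spacing and LD-extent coverage of a SNP map
#'
#' Reports the fraction of SNPs whose nearest same-chromosome neighbor is
#' within `d` bp (chromosomes carrying a single SNP are excluded from the
#' fraction), and the total number of bases lying within `d` bp of any SNP
#' (union of the inclusive intervals `[pos - d, pos + d]`, clipped at
#' position 0; with `d = 0` each SNP covers exactly its own base).
#'
#' @param positions list of sorted integer position vectors, one per
#'   chromosome (names are chromosome ids).
#' @param d distance in bp.
#' @param genome_size optional total assembly size in bp; when given, the
#'   covered fraction `covered_bases / genome_size` is reported (the
#'   assembly size cannot be inferred from a SNP map).
#' @return list with `fraction_within_d`, `covered_bases`, `n_snps`,
#'   `n_with_neighbor`, and `coverage_fraction` (NA without
#'   `genome_size`).
#' @export
neighbor_coverage <- function(positions, d, genome_size = NULL) {
  stopifnot(is.list(positions), d >= 0,
            is.null(genome_size) || genome_size > 0)
  n_within <- 0L; n_eligible <- 0L; covered <- 0
  for (pos in positions) {
    pos <- sort(as.numeric(pos))
    n <- length(pos)
    if (n >= 2) {
      gaps <- diff(pos)
      nn <- pmin(c(gaps, Inf), c(Inf, gaps))
      n_within <- n_within + sum(nn <= d)
      n_eligible <- n_eligible + n
    }
    # union of inclusive intervals [pos-d, pos+d], clipped at 0
    lo <- pmax(pos - d, 0); hi <- pos + d
    if (n > 0) {
      cur_lo <- lo[1]; cur_hi <- hi[1]
      if (n > 1) for (i in 2:n) {
        if (lo[i] <= cur_hi + 1) cur_hi <- max(cur_hi, hi[i])
        else { covered <- covered + (cur_hi - cur_lo + 1); cur_lo <- lo[i]; cur_hi <- hi[i] }
      }
      covered <- covered + (cur_hi - cur_lo + 1)
    }
  }
  list(fraction_within_d = if (n_eligible) n_within / n_eligible else NA_real_,
       covered_bases = covered,
       n_snps = sum(lengths(positions)),
       n_with_neighbor = n_eligible,
       coverage_fraction = if (is.null(genome_size)) NA_real_ else
         covered / genome_size)
}
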