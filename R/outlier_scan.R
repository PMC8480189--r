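#' Outlier-scan configuration
#'
#' @param fet_neglogp_threshold Fisher-exact-test significance cutoff on the
#'   -log10(p) scale (default 4, i.e. p < 1e-4).
#' @param pca_K number of principal components retained in the PCA scan.
#' @param q_threshold FDR level on Benjamini-Hochberg q-values for the PCA
#'   scan.
#' @return A `scan_config` list.
#' @export
scan_config <- function(fet_neglogp_threshold = 4,
                        pca_K = 2L,
                        q_threshold = 0.1) {
  stopifnot(fet_neglogp_threshold > 0, pca_K >= 1, q_threshold > 0)
  structure(list(fet_neglogp_threshold = fet_neglogp_threshold,
                 pca_K = as.integer(pca_K),
                 q_threshold = q_threshold),
            class = "scan_config")
}

#' Two-sided Fisher exact p-value for one 2x2 allele-count table
#'
#' For the table `[[a1, b1], [a2, b2]]` (rows = alleles, columns =
#' populations), the two-sided p-value is the sum of hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the probability of the observed table (with a relative
#' tolerance of 1e-12 for ties).
#'
#' @param a1,b1 allele counts of the first allele in each population.
#' @param a2,b2 allele counts of the second allele in each population.
#' @return p-value in (0, 1]; degenerate margins give 1.
#' @export
fet_exact_p <- function(a1, b1, a2, b2) {
  m <- a1 + b1          # total allele-1 count
  n <- a2 + b2          # total allele-2 count
  k <- a1 + a2          # column-1 margin
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a1, m, n, k)
  sum(dens[dens <= obs * (1 + 1e-12)])
}

#' Fisher's exact test scan of allele-frequency differences
#'
#' For each SNP, allele counts over called genotypes in the two populations
#' form a 2x2 table (ref/alt x population); the two-sided exact p-value sums
#' the hypergeometric probabilities of all tables with the observed margins
#' that are no more probable than the observed one. A SNP monomorphic in
#' both populations gets p = 1.
#'
#' @param dataset a [geno_dataset()].
#' @param popA,popB population labels.
#' @return named numeric vector of p-values in (0, 1].
#' @export
fet_scan <- function(dataset, popA, popB) {
  gA <- dataset$geno[pop_samples(dataset, popA), , drop = FALSE]
  gB <- dataset$geno[pop_samples(dataset, popB), , drop = FALSE]
  nA <- colSums(!is.na(gA)); nB <- colSums(!is.na(gB))
  altA <- colSums(gA, na.rm = TRUE); altB <- colSums(gB, na.rm = TRUE)
  refA <- 2 * nA - altA; refB <- 2 * nB - altB
  p <- vapply(seq_along(altA), function(i) {
    fet_exact_p(refA[i], refB[i], altA[i], altB[i])
  }, numeric(1))
  stats::setNames(pmin(p, 1), dataset$variants$snp_id)
}

#' Benjamini-Hochberg q-values
#'
#' Monotone step-up BH adjustment.
#'
#' @param pvals numeric p-values in (0, 1].
#' @return q-values in the input order.
#' @export
bh_q <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

#' PCA-based outlier scan
#'
#' A pcadapt-style scan: genotypes are mean-imputed and scaled by
#' `sqrt(p(1-p))` of the mean allele frequency; the top `K` principal
#' components over samples are computed; for each SNP the vector of
#' multiple-regression z-scores of its (scaled) genotypes on the K PCs is
#' formed; the squared Mahalanobis distance `D2` of the z-vectors, with
#' robustly estimated location and scatter (minimum covariance determinant;
#' classical covariance when fewer than `classical_below` SNPs), is divided
#' by the genomic inflation factor (median `D2` over the chi-squared_K
#' median) and referred to a chi-squared distribution with K degrees of
#' freedom; q-values are Benjamini-Hochberg.
#'
#' @param dataset a [geno_dataset()].
#' @param K number of retained components (default 2).
#' @param classical_below SNP count below which classical covariance is used
#'   instead of MCD.
#' @param mcd_seed seed for the MCD subsampling (RNG state is restored).
#' @return data.frame with `snp_id`, `d2`, `p`, `q` (`NA` rows for SNPs
#'   excluded as zero-variance or all-missing), plus attribute `gif`.
#' @export
pca_outlier_scan <- function(dataset, K = 2L, classical_below = 500L,
                             mcd_seed = 42L) {
  g <- dataset$geno
  n <- nrow(g)
  if (n < K + 2) stop("need at least K + 2 samples")
  af <- colMeans(g, na.rm = TRUE) / 2
  usable <- !is.na(af) & af > 0 & af < 1
  res <- data.frame(snp_id = dataset$variants$snp_id,
                    d2 = NA_real_, p = NA_real_, q = NA_real_,
                    stringsAsFactors = FALSE)
  if (sum(usable) < 2) stop("fewer than 2 polymorphic SNPs")
  x <- g[, usable, drop = FALSE]
  mu <- 2 * af[usable]
  x <- sweep(x, 2L, mu)
  x[is.na(x)] <- 0                       # mean imputation after centering
  x <- sweep(x, 2L, sqrt(af[usable] * (1 - af[usable])), "/")

  sv <- svd(x, nu = K, nv = 0)
  u <- sv$u                              # n x K orthonormal sample scores
  bt <- crossprod(u, x)                  # K x p regression coefficients
  fitted <- u %*% bt
  rss <- colSums((x - fitted)^2)
  sigma <- sqrt(rss / (n - K))
  z <- t(bt) / sigma                     # p x K z-scores
  ok <- is.finite(rowSums(z)) & sigma > 0
  z_ok <- z[ok, , drop = FALSE]
  if (nrow(z_ok) < K + 1) stop("too few SNPs with defined z-scores")

  if (nrow(z_ok) >= classical_below) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv())
    set.seed(mcd_seed)
    rob <- MASS::cov.rob(z_ok, method = "mcd")
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
    center <- rob$center; scatter <- rob$cov
  } else {
    center <- colMeans(z_ok); scatter <- stats::cov(z_ok)
  }
  d2 <- stats::mahalanobis(z_ok, center, scatter)
  gif <- stats::median(d2) / stats::qchisq(0.5, df = K)
  p <- stats::pchisq(d2 / gif, df = K, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  q <- bh_q(p)

  idx <- which(usable)[ok]
  res$d2[idx] <- d2; res$p[idx] <- p; res$q[idx] <- q
  n_excl <- nrow(res) - length(idx)
  if (n_excl > 0) {
    message("pca_outlier_scan: excluded ", n_excl,
            " monomorphic/undefined SNP(s)")
  }
  attr(res, "gif") <- gif
  res
}

#' Intersect outlier flags across methods and population pairs
#'
#' @param flags named list of logical vectors, one per (method x pair)
#'   combination, all over the same SNP universe (same names, any order).
#' @return character vector of SNP ids flagged in every input.
#' @export
intersect_candidates <- function(flags) {
  stopifnot(length(flags) >= 1)
  ids <- names(flags[[1]])
  out <- rep(TRUE, length(ids))
  for (f in flags) {
    if (!setequal(names(f), ids)) stop("flag vectors cover different SNPs")
    out <- out & f[ids] %in% TRUE
  }
  ids[out]
}

#' Assign the freshwater-favored allele (FWA) at candidate SNPs
#'
#' The FWA is the allele whose frequency increased in every derived
#' population relative to the ancestral one; a SNP where no allele does so
#' is left unassigned. FWA present at nonzero frequency in the ancestral
#' population is recorded as standing variation.
#'
#' @param dataset a [geno_dataset()].
#' @param candidates candidate SNP ids (non-empty).
#' @param ancestral ancestral population label (default from the
#'   ecotype map).
#' @param derived list of derived population labels (default from map).
#' @return data.frame of class `fwa_table`: one row per candidate SNP with
#'   `fwa` (ref/alt/unassigned), per-population FWA frequency columns
#'   (`freq_<pop>`), per-derived-population increments (`inc_<pop>`), and
#'   `standing_variation`.
#' @export
assign_fwa <- function(dataset, candidates,
                       ancestral = NULL, derived = NULL) {
  if (!length(candidates)) stop("candidates must be non-empty")
  if (is.null(ancestral)) ancestral <- ancestral_pop(dataset)
  if (is.null(derived)) derived <- derived_pops(dataset)
  pops <- c(ancestral, derived)
  af <- vapply(pops, function(p) allele_freq(dataset, p)[candidates],
               numeric(length(candidates)))
  af <- matrix(af, nrow = length(candidates), dimnames = list(candidates, pops))
  d_alt <- af[, derived, drop = FALSE] - af[, ancestral]
  alt_up <- rowSums(d_alt > 0, na.rm = FALSE) == length(derived)
  ref_up <- rowSums(-d_alt > 0, na.rm = FALSE) == length(derived)
  fwa <- ifelse(!is.na(alt_up) & alt_up, "alt",
                ifelse(!is.na(ref_up) & ref_up, "ref", "unassigned"))

  fwa_freq <- af
  flip <- fwa == "ref"
  fwa_freq[flip, ] <- 1 - af[flip, , drop = FALSE]
  fwa_freq[fwa == "unassigned", ] <- NA_real_
  inc <- fwa_freq[, derived, drop = FALSE] - fwa_freq[, ancestral]

  out <- data.frame(snp_id = candidates, fwa = fwa,
                    stringsAsFactors = FALSE)
  for (p in pops) out[[paste0("freq_", p)]] <- unname(fwa_freq[, p])
  for (p in derived) out[[paste0("inc_", p)]] <- unname(inc[, p])
  out$standing_variation <- !is.na(fwa_freq[, ancestral]) &
    fwa_freq[, ancestral] > 0
  out$standing_variation[fwa == "unassigned"] <- NA
  attr(out, "ancestral_pop") <- ancestral
  attr(out, "derived_pops") <- derived
  class(out) <- c("fwa_table", "data.frame")
  out
}

#' Summarize FWA frequencies and shifts
#'
#' @param fwa a `fwa_table` from [assign_fwa()].
#' @param neutral_maf per-SNP minor allele frequencies of neutral SNPs in
#'   the ancestral population, for the Welch t-test contrast.
#' @return list: per-population mean FWA frequency, per-population mean
#'   increment, fraction of assigned SNPs with increment >= 0.5 in every
#'   derived population, fraction occurring as standing variation, and the
#'   Welch t-test of ancestral FWA frequency against neutral MAF.
#' @export
fwa_summary <- function(fwa, neutral_maf = NULL) {
  stopifnot(inherits(fwa, "fwa_table"), nrow(fwa) > 0)
  anc <- attr(fwa, "ancestral_pop")
  der <- attr(fwa, "derived_pops")
  assigned <- fwa[fwa$fwa != "unassigned", , drop = FALSE]
  freq_cols <- paste0("freq_", c(anc, der))
  inc_cols <- paste0("inc_", der)
  mean_freq <- vapply(freq_cols, function(cn)
    mean(assigned[[cn]], na.rm = TRUE), numeric(1))
  names(mean_freq) <- c(anc, der)
  mean_inc <- vapply(inc_cols, function(cn)
    mean(assigned[[cn]], na.rm = TRUE), numeric(1))
  names(mean_inc) <- der
  inc_mat <- as.matrix(assigned[, inc_cols, drop = FALSE])
  frac_ge_0.5 <- mean(apply(inc_mat >= 0.5, 1L, all, na.rm = TRUE))
  frac_standing <- mean(assigned$standing_variation, na.rm = TRUE)
  welch <- NULL
  if (!is.null(neutral_maf) && length(neutral_maf) >= 2 &&
      nrow(assigned) >= 2) {
    welch <- welch_t(assigned[[paste0("freq_", anc)]], neutral_maf)
  }
  list(n_candidates = nrow(fwa), n_assigned = nrow(assigned),
       mean_fwa_freq = mean_freq, mean_increment = mean_inc,
       frac_increment_ge_0.5 = frac_ge_0.5,
       frac_standing_variation = frac_standing,
       welch_vs_neutral_maf = welch)
}

#' Run both outlier scans over all ancestral-derived pairs and intersect
#'
#' Convenience wrapper: FET per ancestral-derived pair, a single PCA scan,
#' per-pair/method flags, and the all-pairs dual-method candidate set.
#'
#' @param dataset a [geno_dataset()].
#' @param cfg a [scan_config()].
#' @return list: `fet_p` (matrix snp x pair), `pca` (PCA scan data.frame),
#'   `flags` (named list of logical vectors), `candidates` (SNP ids).
#' @export
outlier_scan <- function(dataset, cfg = scan_config()) {
  anc <- ancestral_pop(dataset)
  der <- derived_pops(dataset)
  if (!length(der)) stop("no derived populations")
  ids <- dataset$variants$snp_id
  fet <- vapply(der, function(p) fet_scan(dataset, anc, p),
                numeric(length(ids)))
  fet <- matrix(fet, nrow = length(ids),
                dimnames = list(ids, paste0(der, "_vs_", anc)))
  pca <- pca_outlier_scan(dataset, K = cfg$pca_K)
  pca_flag <- stats::setNames(!is.na(pca$q) & pca$q <= cfg$q_threshold, ids)
  flags <- list()
  for (j in seq_along(der)) {
    pair <- colnames(fet)[j]
    flags[[paste0("fet_", pair)]] <-
      stats::setNames(-log10(fet[, j]) > cfg$fet_neglogp_threshold, ids)
    # the PCA statistic is pair-free; it enters every pair's intersection
    flags[[paste0("pca_", pair)]] <- pca_flag
  }
  list(fet_p = fet, pca = pca, flags = flags,
       candidates = intersect_candidates(flags))
}
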