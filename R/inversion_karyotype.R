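#' PCA of the genotype submatrix of one SOC region
#'
#' Genotypes at the cluster's member SNPs are mean-imputed and centered
#' (unscaled by default) and decomposed; for an inversion, individuals fall
#' into three groups along PC1 (the two homokaryotypes and the
#' heterokaryotypes between them). The PC1 sign is fixed so the
#' ancestral-population mean is negative, making the AA/BB orientation
#' reproducible.
#'
#' @param dataset a [geno_dataset()].
#' @param snp_ids member SNP ids of the region (at least 2).
#' @param scale scale SNPs to unit variance as well (default FALSE).
#' @return matrix of per-individual PC coordinates (samples x 2), sign
#'   convention applied to PC1; samples with no called genotype in the
#'   region are dropped with a message.
#' @export
region_pca <- function(dataset, snp_ids, scale = FALSE) {
  if (length(snp_ids) < 2) stop("region needs at least 2 SNPs")
  idx <- match(snp_ids, dataset$variants$snp_id)
  if (anyNA(idx)) stop("unknown snp_id(s)")
  g <- dataset$geno[, idx, drop = FALSE]
  if (nrow(g) < 3) stop("need at least 3 individuals")
  all_missing <- rowSums(!is.na(g)) == 0L
  if (any(all_missing)) {
    message("region_pca: excluded ", sum(all_missing),
            " individual(s) with no called genotype in region")
    g <- g[!all_missing, , drop = FALSE]
  }
  mu <- colMeans(g, na.rm = TRUE)
  x <- sweep(g, 2L, mu)
  x[is.na(x)] <- 0
  if (scale) {
    s <- apply(x, 2L, stats::sd)
    s[s == 0] <- 1
    x <- sweep(x, 2L, s, "/")
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  anc <- ancestral_pop(dataset)
  anc_rows <- rownames(scores) %in% pop_samples(dataset, anc)
  if (any(anc_rows) && mean(scores[anc_rows, 1L]) > 0) {
    scores[, 1L] <- -scores[, 1L]
  }
  scores
}

#' Globally optimal one-dimensional k-means
#'
#' Exact dynamic program over sorted values (contiguity of optimal 1-D
#' clusters); deterministic, no seed. Returns labels 1..k ordered by
#' cluster center.
#'
#' @param values numeric vector.
#' @param k number of clusters (default 3).
#' @return integer labels in input order, with attributes `centers` and
#'   `withinss` (total within-cluster sum of squares). If fewer than `k`
#'   distinct values exist, fewer groups are returned and attribute
#'   `degenerate` is TRUE.
#' @export
kmeans_1d <- function(values, k = 3L) {
  n <- length(values)
  stopifnot(n >= 1, k >= 1)
  n_distinct <- length(unique(values))
  k_eff <- min(k, n_distinct)
  degenerate <- k_eff < k
  if (degenerate) {
    warning("only ", n_distinct, " distinct value(s); returning ",
            k_eff, " group(s)")
  }
  ord <- order(values)
  x <- values[ord]
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  seg_cost <- function(i, j) { # sum of squared deviations of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k_eff, n)
  back <- matrix(0L, k_eff, n)
  for (j in seq_len(n)) cost[1L, j] <- seg_cost(1L, j)
  if (k_eff > 1) for (m in 2:k_eff) {
    for (j in m:n) {
      best <- Inf; arg <- m
      for (i in m:j) {
        cand <- cost[m - 1L, i - 1L] + seg_cost(i, j)
        if (cand < best) { best <- cand; arg <- i }
      }
      cost[m, j] <- best; back[m, j] <- arg
    }
  }
  labels_sorted <- integer(n)
  j <- n
  for (m in k_eff:1) {
    i <- if (m > 1) back[m, j] else 1L
    labels_sorted[i:j] <- m
    j <- i - 1L
  }
  labels <- integer(n)
  labels[ord] <- labels_sorted
  centers <- vapply(seq_len(k_eff), function(m) mean(values[labels == m]),
                    numeric(1))
  structure(labels, centers = centers, withinss = cost[k_eff, n],
            degenerate = degenerate)
}

#' Assign inversion karyotypes from PC1 groups
#'
#' The three PC1 groups are ordered by center; the extreme group holding
#' the majority of ancestral-population individuals becomes AA (reference
#' homokaryotypes), the middle group AB (heterokaryotypes), the other
#' extreme BB. Validity gates (reported, never silently relabeled): the
#' ancestral majority must sit in an extreme group, and the AB group must
#' have the strictly highest mean region heterozygosity.
#'
#' @param pc1 named numeric vector of PC1 coordinates (names = samples).
#' @param dataset a [geno_dataset()] (for popmap/ecotype).
#' @param region_het named per-sample heterozygosity over the region, as
#'   from [individual_het()].
#' @param k number of karyotype groups (default 3).
#' @return list of class `karyotype_assignment`: `table` (data.frame
#'   sample, population, pc1, karyotype, region_het, dist_to_center),
#'   `group_mean_het` (named AA/AB/BB), `failed` (logical), `failure_reason`.
#' @export
assign_karyotypes <- function(pc1, dataset, region_het, k = 3L) {
  labels <- suppressWarnings(kmeans_1d(pc1, k = k))
  centers <- attr(labels, "centers")
  k_eff <- length(centers)
  ord <- order(centers)                 # group ids from low to high PC1
  rank_of <- match(seq_len(k_eff), ord) # group id -> position 1..k_eff

  anc <- ancestral_pop(dataset)
  anc_samples <- pop_samples(dataset, anc)
  failed <- FALSE; reason <- NA_character_

  if (k_eff < 3) {
    # degenerate: all individuals one arrangement class
    karyo <- rep("AA", length(pc1))
    if (k_eff == 2) karyo[rank_of[labels] == 2] <- "BB"
  } else {
    anc_groups <- rank_of[labels[names(pc1) %in% anc_samples]]
    if (!length(anc_groups)) {
      stop("no ancestral-population individuals among PC1 values")
    }
    maj <- as.integer(names(which.max(table(anc_groups))))
    if (maj == 2L) {
      failed <- TRUE
      reason <- "ancestral majority falls in the middle PC1 group"
      aa_rank <- 1L
    } else {
      aa_rank <- maj
    }
    bb_rank <- if (aa_rank == 1L) 3L else 1L
    karyo <- character(length(pc1))
    karyo[rank_of[labels] == aa_rank] <- "AA"
    karyo[rank_of[labels] == 2L] <- "AB"
    karyo[rank_of[labels] == bb_rank] <- "BB"
  }

  het <- region_het[names(pc1)]
  gm <- tapply(het, factor(karyo, levels = c("AA", "AB", "BB")), mean,
               na.rm = TRUE)
  if (!failed && k_eff == 3) {
    if (!(isTRUE(gm[["AB"]] > gm[["AA"]]) && isTRUE(gm[["AB"]] > gm[["BB"]]))) {
      failed <- TRUE
      reason <- "heterokaryotype group does not have the highest mean heterozygosity"
    }
  }
  tab <- data.frame(
    sample = names(pc1),
    population = unname(dataset$popmap[names(pc1)]),
    pc1 = unname(pc1),
    karyotype = karyo,
    region_het = unname(het),
    dist_to_center = abs(unname(pc1) - centers[labels]),
    stringsAsFactors = FALSE)
  structure(list(table = tab, group_mean_het = gm,
                 failed = failed, failure_reason = reason),
            class = "karyotype_assignment")
}

#' @export
print.karyotype_assignment <- function(x, ...) {
  cat("karyotype assignment:",
      paste(names(table(x$table$karyotype)),
            table(x$table$karyotype), sep = "=", collapse = " "), "\n")
  cat("group mean heterozygosity:",
      paste(names(x$group_mean_het),
            sprintf("%.3f", x$group_mean_het), collapse = " "), "\n")
  if (x$failed) cat("FAILED validity gate:", x$failure_reason, "\n")
  invisible(x)
}

#' Karyotype and arrangement frequencies per population
#'
#' @param assignment a [assign_karyotypes()] result.
#' @return data.frame with one row per population: karyotype counts and
#'   frequencies (summing to 1) and arrangement allele frequencies
#'   `freq_A`, `freq_B` with `freq_B = (nAB + 2 nBB) / (2N)`.
#' @export
karyotype_frequencies <- function(assignment) {
  tab <- assignment$table
  pops <- unique(tab$population)
  rows <- lapply(pops, function(p) {
    sub <- tab[tab$population == p, ]
    n <- nrow(sub)
    if (n == 0L) return(NULL)
    nAA <- sum(sub$karyotype == "AA")
    nAB <- sum(sub$karyotype == "AB")
    nBB <- sum(sub$karyotype == "BB")
    data.frame(population = p, n = n, nAA = nAA, nAB = nAB, nBB = nBB,
               freq_AA = nAA / n, freq_AB = nAB / n, freq_BB = nBB / n,
               freq_A = (2 * nAA + nAB) / (2 * n),
               freq_B = (nAB + 2 * nBB) / (2 * n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' FST elevation inside an inversion region
#'
#' Multi-locus Weir-Cockerham theta over the SOC member SNPs for each
#' ancestral-derived pair, compared with theta over a neutral SNP set.
#'
#' @param dataset a [geno_dataset()].
#' @param soc_snp_ids member SNP ids of the SOC.
#' @param neutral_snp_ids neutral SNP ids for the baseline.
#' @return list: `inversion_theta` (named per pair), `neutral_theta`
#'   (named per pair), `mean_inversion_theta`, `mean_neutral_theta`,
#'   `elevation_ratio`.
#' @export
inversion_fst <- function(dataset, soc_snp_ids, neutral_snp_ids) {
  anc <- ancestral_pop(dataset)
  der <- derived_pops(dataset)
  inv <- vapply(der, function(p)
    wc_fst(dataset, anc, p, soc_snp_ids)$theta, numeric(1))
  neu <- vapply(der, function(p)
    wc_fst(dataset, anc, p, neutral_snp_ids)$theta, numeric(1))
  list(inversion_theta = inv, neutral_theta = neu,
       mean_inversion_theta = mean(inv), mean_neutral_theta = mean(neu),
       elevation_ratio = mean(inv) / mean(neu))
}

#' Classify the inferred cause of a SOC
#'
#' "parallel adaptation" when the B-arrangement frequency shifts by at
#' least `delta`, with the same sign, in every derived population relative
#' to the ancestral one; "geographic structure" when the derived
#' populations split among themselves into groups differing by at least
#' `delta` while not all shifting against the ancestral population;
#' otherwise "unresolved".
#'
#' @param freqs a [karyotype_frequencies()] data.frame.
#' @param ecotype named population -> ecotype map.
#' @param delta frequency-shift threshold (default 0.5).
#' @return one of "parallel adaptation", "geographic structure",
#'   "unresolved".
#' @export
classify_soc_cause <- function(freqs, ecotype, delta = 0.5) {
  eco <- ecotype[freqs$population]
  anc <- freqs$freq_B[eco == "ancestral"]
  der <- freqs$freq_B[eco == "derived"]
  if (length(anc) < 1 || length(der) < 2) {
    stop("need at least 1 ancestral and 2 derived populations")
  }
  anc <- mean(anc)
  shift <- der - anc
  if (all(abs(shift) >= delta) && length(unique(sign(shift))) == 1L) {
    return("parallel adaptation")
  }
  if (max(der) - min(der) >= delta) return("geographic structure")
  "unresolved"
}

#' Karyotype one SOC end to end
#'
#' Region PCA, 1-D k-means on PC1, karyotype assignment with validity
#' gates, per-population frequencies and cause classification.
#'
#' @param dataset a [geno_dataset()].
#' @param soc one row of the SOC table from [ld_network_scan()].
#' @param delta classification threshold for [classify_soc_cause()].
#' @return list: `assignment`, `frequencies`, `cause`, `pc`.
#' @export
karyotype_soc <- function(dataset, soc, delta = 0.5) {
  members <- soc$members[[1]]
  pc <- region_pca(dataset, members)
  het <- individual_het(dataset, members)
  pc1 <- stats::setNames(pc[, 1L], rownames(pc))
  assignment <- assign_karyotypes(pc1, dataset, het)
  freqs <- karyotype_frequencies(assignment)
  cause <- if (assignment$failed) "unresolved (failed validity gate)"
  else classify_soc_cause(freqs, dataset$ecotype, delta = delta)
  list(assignment = assignment, frequencies = freqs, cause = cause, pc = pc)
}
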