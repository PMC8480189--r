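#' Pairwise LD (r-squared) matrix for one chromosome
#'
#' Populations are pooled before computing LD, so ecotype-frequency
#' differences deliberately contribute admixture LD. r2 is the squared
#' Pearson correlation of allele dosages across samples (pairwise-complete
#' over called genotypes), among SNPs whose pooled MAF reaches `maf_floor`.
#'
#' @param dataset a [geno_dataset()].
#' @param chromosome chromosome id.
#' @param maf_floor minimum pooled minor allele frequency (default 0.1).
#' @return list of class `ld_matrix`: `chrom`, `snp_id`, `pos`, `r2`
#'   (symmetric matrix, `NA` diagonal and undefined pairs).
#' @export
ld_r2 <- function(dataset, chromosome, maf_floor = 0.1) {
  v <- dataset$variants
  on_chr <- which(v$chrom == chromosome)
  if (!length(on_chr)) stop("no SNPs on chromosome ", chromosome)
  g <- dataset$geno[, on_chr, drop = FALSE]
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- !is.na(maf) & maf >= maf_floor
  if (sum(keep) < 2) stop("fewer than 2 SNPs pass MAF floor on ", chromosome)
  g <- g[, keep, drop = FALSE]
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- NA_real_
  structure(list(chrom = chromosome,
                 snp_id = v$snp_id[on_chr][keep],
                 pos = v$pos[on_chr][keep],
                 r2 = r2),
            class = "ld_matrix")
}

# minimal union-find with path compression
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Build the LD threshold-descent merger tree
#'
#' Starting from every SNP as a singleton, the r2 threshold descends along
#' `grid`; at each level the connected components of the graph with edges
#' `r2 >= threshold` are formed. Whenever components merge, each focal
#' (pre-merge) component of two or more loci is recorded as a cluster with:
#' its members, the median pairwise r2 among them (`median_r2`, with
#' unstored pairs counted as 0), the post-merger median pairwise r2 of the
#' merged component, `lambda = nLoci * (median_before - median_after)`, and
#' `nE`, the number of edges at the merge threshold among its members. Any
#' components remaining after the grid are merged into a chromosome-level
#' root at threshold 0 so their lambdas are defined.
#'
#' @param ld an [ld_r2()] result (or a compatible list with `chrom`,
#'   `snp_id`, `pos`, `r2`).
#' @param grid descending vector of r2 thresholds; default steps of 0.01
#'   from the maximum observed r2 down to 0.
#' @param edge_floor pairs with r2 below this are dropped before graph
#'   construction (they still count as 0 in median computations).
#' @return list of class `ld_merger_tree`: `chrom`, `snp_id`, `pos`,
#'   `clusters` (data.frame with `cluster`, `threshold`, `n_loci`, `n_edges`,
#'   `median_r2`, `merged_median_r2`, `lambda`), `members` (list of member
#'   SNP ids per cluster row).
#' @export
build_merger_tree <- function(ld, grid = NULL, edge_floor = 0.05) {
  r2 <- ld$r2
  n <- nrow(r2)
  ids <- ld$snp_id
  ut <- upper.tri(r2)
  vals <- r2[ut]
  if (is.null(grid)) {
    top <- max(vals, na.rm = TRUE)
    if (!is.finite(top)) top <- 0
    grid <- rev(seq(0, ceiling(top * 100) / 100, by = 0.01))
  }
  if (any(diff(grid) >= 0)) stop("grid must be strictly descending")

  pair_idx <- which(ut & !is.na(r2) & r2 >= edge_floor, arr.ind = TRUE)
  ord <- order(r2[pair_idx], decreasing = TRUE)
  pair_idx <- pair_idx[ord, , drop = FALSE]
  pair_r2 <- r2[pair_idx]

  parent <- seq_len(n)
  members <- as.list(seq_len(n))      # component id -> member indices
  rec <- list()
  r2_zero <- r2
  r2_zero[is.na(r2_zero)] <- 0

  median_within <- function(m) {
    if (length(m) < 2) return(NA_real_)
    sub <- r2_zero[m, m]
    stats::median(sub[upper.tri(sub)])
  }
  count_edges <- function(m, thr) {
    if (length(m) < 2) return(0L)
    sub <- r2[m, m]
    sum(sub[upper.tri(sub)] >= thr, na.rm = TRUE)
  }

  record_merge <- function(parts, merged, thr) {
    x2 <- median_within(merged)
    for (m in parts) {
      if (length(m) < 2) next
      x1 <- median_within(m)
      rec[[length(rec) + 1L]] <<- list(
        threshold = thr, n_loci = length(m),
        n_edges = count_edges(m, thr),
        median_r2 = x1, merged_median_r2 = x2,
        lambda = length(m) * (x1 - x2),
        member_idx = m)
    }
  }

  # Process one grid level at a time: all edges whose r2 falls in the level
  # are applied together, so a multi-way merge is recorded against the
  # pre-level components (a cluster is never grown one chance edge at a
  # time within a level).
  ei <- 1L
  n_edges_total <- nrow(pair_idx)
  for (thr in grid) {
    lvl_from <- ei
    while (ei <= n_edges_total && pair_r2[ei] >= thr) ei <- ei + 1L
    if (ei == lvl_from) next
    lvl_edges <- pair_idx[lvl_from:(ei - 1L), , drop = FALSE]
    pre_root <- integer(0)    # pre-level component ids touched
    merged_into <- list()     # new root -> list of pre-level parts
    for (r in seq_len(nrow(lvl_edges))) {
      a0 <- uf_find(parent, lvl_edges[r, 1L])
      b0 <- uf_find(parent, lvl_edges[r, 2L])
      if (a0 == b0) next
      parts_a <- if (is.null(merged_into[[as.character(a0)]]))
        list(members[[a0]]) else merged_into[[as.character(a0)]]
      parts_b <- if (is.null(merged_into[[as.character(b0)]]))
        list(members[[b0]]) else merged_into[[as.character(b0)]]
      parent[b0] <- a0
      members[[a0]] <- c(members[[a0]], members[[b0]])
      members[b0] <- list(NULL)
      merged_into[[as.character(b0)]] <- NULL
      merged_into[[as.character(a0)]] <- c(parts_a, parts_b)
    }
    for (root_id in names(merged_into)) {
      parts <- merged_into[[root_id]]
      record_merge(parts, members[[as.integer(root_id)]], thr)
    }
  }
  roots <- unique(vapply(seq_len(n), function(i) uf_find(parent, i),
                         integer(1)))
  if (length(roots) > 1L) {
    parts <- members[roots]
    record_merge(parts, unlist(parts), 0)
  }

  if (length(rec)) {
    clusters <- data.frame(
      cluster = paste0(ld$chrom, "_C", seq_along(rec)),
      threshold = vapply(rec, `[[`, numeric(1), "threshold"),
      n_loci = vapply(rec, `[[`, integer(1), "n_loci"),
      n_edges = vapply(rec, `[[`, numeric(1), "n_edges"),
      median_r2 = vapply(rec, `[[`, numeric(1), "median_r2"),
      merged_median_r2 = vapply(rec, `[[`, numeric(1), "merged_median_r2"),
      lambda = vapply(rec, `[[`, numeric(1), "lambda"),
      stringsAsFactors = FALSE)
    member_ids <- lapply(rec, function(r) ids[r$member_idx])
  } else {
    clusters <- data.frame(cluster = character(), threshold = numeric(),
                           n_loci = integer(), n_edges = numeric(),
                           median_r2 = numeric(),
                           merged_median_r2 = numeric(),
                           lambda = numeric(), stringsAsFactors = FALSE)
    member_ids <- list()
  }
  structure(list(chrom = ld$chrom, snp_id = ids, pos = ld$pos,
                 clusters = clusters, members = member_ids),
            class = "ld_merger_tree")
}

#' LD-network clustering parameters
#'
#' @param E_min minimum number of edges for a cluster to enter the lambda
#'   outlier comparison (default 30).
#' @param phi outlier stringency; `NULL` selects it with [select_phi()].
#' @param min_cluster_loci minimum loci for a retained cluster (default 30).
#' @param min_median_r2 minimum median within-cluster r2 (default 0.3).
#' @param maf_floor pooled MAF floor for [ld_r2()].
#' @param edge_floor r2 below which pairs are dropped before graph
#'   construction (they can never form edges at meaningful thresholds).
#' @return An `ldna_params` list.
#' @export
ldna_params <- function(E_min = 30L, phi = NULL,
                        min_cluster_loci = 30L, min_median_r2 = 0.3,
                        maf_floor = 0.1, edge_floor = 0.05) {
  stopifnot(E_min >= 1, is.null(phi) || phi >= 0,
            min_cluster_loci >= 1,
            min_median_r2 >= 0, min_median_r2 <= 1,
            edge_floor >= 0, edge_floor < 1)
  structure(list(E_min = as.integer(E_min), phi = phi,
                 min_cluster_loci = as.integer(min_cluster_loci),
                 min_median_r2 = min_median_r2, maf_floor = maf_floor,
                 edge_floor = edge_floor),
            class = "ldna_params")
}

# lambda outlier limit: median + phi * MAD; MAD==0 falls back to sd;
# both 0 -> no limit (nothing extracted)
lambda_limit <- function(lambda, phi) {
  spread <- stats::mad(lambda)
  if (spread == 0) spread <- stats::sd(lambda)
  if (is.na(spread) || spread == 0) return(Inf)
  stats::median(lambda) + phi * spread
}

#' Extract outlier clusters (OCs) from a merger tree
#'
#' Among clusters with at least `E_min` edges, a cluster is an outlier
#' cluster when its lambda exceeds `median(lambda) + phi * MAD(lambda)`.
#' An OC containing no other extracted OC nested inside it is a
#' single-outlier cluster (SOC); otherwise it is a compound outlier
#' cluster (COC).
#'
#' @param tree an [build_merger_tree()] result.
#' @param params an [ldna_params()]; `params$phi` must be set (use
#'   [select_phi()] first or pass `phi`).
#' @param phi overrides `params$phi`.
#' @return data.frame of class `ld_clusters` with Table-style columns
#'   (`chrom`, `cluster`, `type`, `threshold` (merge threshold at which
#'   the cluster version was recorded), `n_loci`, `n_edges`, `lambda`,
#'   `median_r2`, `span_start`, `span_end`) plus a `members` list column.
#' @export
extract_ocs <- function(tree, params = ldna_params(), phi = NULL) {
  if (is.null(phi)) phi <- params$phi
  if (is.null(phi)) stop("phi not set; run select_phi() or pass phi")
  cl <- tree$clusters
  eligible <- which(cl$n_edges >= params$E_min)
  empty <- data.frame(chrom = character(), cluster = character(),
                      type = character(), threshold = numeric(),
                      n_loci = integer(),
                      n_edges = numeric(), lambda = numeric(),
                      median_r2 = numeric(), span_start = numeric(),
                      span_end = numeric(), stringsAsFactors = FALSE)
  empty$members <- list()
  class(empty) <- c("ld_clusters", "data.frame")
  if (length(eligible) < 5) {
    if (length(eligible) > 0) {
      warning("fewer than 5 eligible lambda values on ", tree$chrom,
              "; no outlier clusters extracted")
    }
    return(empty)
  }
  lam <- cl$lambda[eligible]
  lim <- lambda_limit(lam, phi)
  oc_idx <- eligible[lam > lim]
  if (!length(oc_idx)) return(empty)

  mem <- tree$members[oc_idx]
  # SOC = extracted OC containing no other extracted OC strictly inside it
  is_soc <- vapply(seq_along(oc_idx), function(i) {
    for (j in seq_along(oc_idx)) {
      if (i == j) next
      if (length(mem[[j]]) < length(mem[[i]]) &&
          all(mem[[j]] %in% mem[[i]])) return(FALSE)
    }
    TRUE
  }, logical(1))

  pos_of <- stats::setNames(tree$pos, tree$snp_id)
  out <- data.frame(
    chrom = tree$chrom,
    cluster = cl$cluster[oc_idx],
    type = ifelse(is_soc, "SOC", "COC"),
    threshold = cl$threshold[oc_idx],
    n_loci = cl$n_loci[oc_idx],
    n_edges = cl$n_edges[oc_idx],
    lambda = cl$lambda[oc_idx],
    median_r2 = cl$median_r2[oc_idx],
    span_start = vapply(mem, function(m) min(pos_of[m]), numeric(1)),
    span_end = vapply(mem, function(m) max(pos_of[m]), numeric(1)),
    stringsAsFactors = FALSE)
  out$members <- mem
  class(out) <- c("ld_clusters", "data.frame")
  out
}

#' Select the outlier-stringency parameter phi
#'
#' Starting from `phi_start`, phi is increased by one until the extracted
#' cluster set stays unchanged for three consecutive unit increments; the
#' smallest such phi is returned. If no stabilisation occurs by `phi_max`
#' a warning is raised and `phi_max` returned.
#'
#' @param tree an [build_merger_tree()] result.
#' @param params an [ldna_params()].
#' @param phi_start starting value (default 2).
#' @param phi_max upper bound (default 20).
#' @return selected phi (numeric scalar).
#' @export
select_phi <- function(tree, params = ldna_params(), phi_start = 2,
                       phi_max = 20) {
  sets <- lapply(phi_start:(phi_max + 2), function(phi) {
    suppressWarnings(extract_ocs(tree, params, phi = phi)$cluster)
  })
  for (i in seq_len(phi_max - phi_start + 1)) {
    if (identical(sets[[i]], sets[[i + 1]]) &&
        identical(sets[[i]], sets[[i + 2]])) {
      return(phi_start + i - 1)
    }
  }
  warning("phi did not stabilise by ", phi_max, "; returning phi_max")
  phi_max
}

#' Structure-corrected (within-population) r2 for a set of SNPs
#'
#' Pooling populations before computing LD deliberately creates sample
#' admixture LD, which is what makes a diverged rearrangement visible as
#' an LD cluster. The same admixture LD, however, links any two loci
#' that are differentiated along the same population axis, whether or
#' not they are physically associated. Centering each SNP's dosages on
#' its population mean before correlating removes the between-population
#' component: loci inside a recombination-suppressed rearrangement stay
#' in high LD within every population (the two arrangement haplotype
#' pools segregate within populations), while loci linked to the
#' rearrangement only through shared population structure drop to
#' near-zero.
#'
#' @param dataset a [geno_dataset()].
#' @param snp_ids SNP ids to correlate.
#' @return symmetric matrix of squared population-centered Pearson
#'   correlations (pairwise-complete), `NA` diagonal.
#' @export
within_pop_r2 <- function(dataset, snp_ids) {
  g <- dataset$geno[, snp_ids, drop = FALSE]
  for (p in dataset_pops(dataset)) {
    rows <- pop_samples(dataset, p)
    mu <- colMeans(g[rows, , drop = FALSE], na.rm = TRUE)
    g[rows, ] <- sweep(g[rows, , drop = FALSE], 2L, mu)
  }
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- NA_real_
  r2
}

#' Trim admixture-linked loci from an extracted cluster
#'
#' A single-linkage component admits a locus on the strength of one edge,
#' so a cluster extracted at a low merge threshold can carry loci whose
#' only tie to it is a chance pairing, or loci whose LD with the cluster
#' is admixture LD between ecotype-differentiated loci and the
#' rearrangement rather than position inside it. A genuine member of a
#' rearrangement cluster remains in LD with the other members within
#' populations: members whose median structure-corrected r2
#' ([within_pop_r2()]) to the other members falls below `floor` are
#' removed, iterating to a fixed point. With `floor` set to the cluster
#' retention gate `min_median_r2`, this is the member-wise, structure-
#' corrected form of that gate.
#'
#' @param members character vector of member SNP ids.
#' @param dataset a [geno_dataset()] (for population-centered dosages).
#' @param floor member-wise median-LD trimming floor.
#' @return character vector of retained member SNP ids.
#' @export
trim_bridge_loci <- function(members, dataset, floor = 0.3) {
  if (length(members) < 2) return(members)
  r2w <- within_pop_r2(dataset, members)
  repeat {
    if (length(members) < 2) return(members)
    sub <- r2w[members, members, drop = FALSE]
    sub[is.na(sub) & row(sub) != col(sub)] <- 0
    diag(sub) <- NA
    med <- apply(sub, 1L, stats::median, na.rm = TRUE)
    drop <- med < floor
    if (!any(drop)) return(members)
    members <- members[!drop]
  }
}

#' Retain SOCs passing the size and LD gates
#'
#' Keeps single-outlier clusters with at least `min_cluster_loci` member
#' SNPs and median within-cluster r2 of at least `min_median_r2`. When
#' the dataset and the chromosome's r2 matrix are supplied, bridge and
#' admixture-LD satellite loci are first trimmed from each SOC with
#' [trim_bridge_loci()] (floor `min_median_r2`) and the cluster statistics
#' (`n_loci`, `n_edges`, `median_r2`, `span_start`, `span_end`) are
#' recomputed on the trimmed member set before the gates are applied;
#' `lambda` is left as extracted since it scores the merger event, not
#' the trimmed set.
#'
#' @param ocs an [extract_ocs()] result.
#' @param params an [ldna_params()].
#' @param ld optional [ld_r2()] result for the same chromosome; with
#'   `dataset`, enables trimming and statistic recomputation.
#' @param dataset optional [geno_dataset()]; with `ld`, enables trimming.
#' @return filtered `ld_clusters` data.frame (SOCs only).
#' @export
soc_postfilter <- function(ocs, params = ldna_params(), ld = NULL,
                           dataset = NULL) {
  out <- ocs[ocs$type == "SOC", , drop = FALSE]
  if (!is.null(ld) && !is.null(dataset) && nrow(out)) {
    pos_of <- stats::setNames(ld$pos, ld$snp_id)
    for (i in seq_len(nrow(out))) {
      m <- trim_bridge_loci(out$members[[i]], dataset,
                            params$min_median_r2)
      out$members[[i]] <- m
      out$n_loci[i] <- length(m)
      if (length(m) >= 2) {
        sub <- ld$r2[m, m, drop = FALSE]
        vals <- sub[upper.tri(sub)]
        vals[is.na(vals)] <- 0
        out$n_edges[i] <- sum(vals >= out$threshold[i])
        out$median_r2[i] <- stats::median(vals)
        out$span_start[i] <- min(pos_of[m])
        out$span_end[i] <- max(pos_of[m])
      } else {
        out$n_edges[i] <- 0
        out$median_r2[i] <- NA_real_
      }
    }
  }
  keep <- out$n_loci >= params$min_cluster_loci &
    !is.na(out$median_r2) & out$median_r2 >= params$min_median_r2
  out <- out[keep, , drop = FALSE]
  class(out) <- c("ld_clusters", "data.frame")
  out
}

#' SOC span with assembly-gap exclusion
#'
#' The raw span is the distance between the most extreme member positions.
#' Any internal interval of at least `min_gap_bp` containing no member SNP,
#' whose flanking member groups show median cross-gap r2 of at least
#' `min_cross_gap_r2`, is treated as an assembly artifact and subtracted
#' from the adjusted span; gaps with low cross-gap LD are kept as genuine
#' extent.
#'
#' @param soc one row of an `ld_clusters` data.frame (with `members`).
#' @param ld the chromosome's [ld_r2()] result (for cross-gap r2).
#' @param min_gap_bp minimum gap width considered (default 5 Mb).
#' @param min_cross_gap_r2 median cross-gap r2 required to exclude a gap.
#' @return list: `raw_span`, `adjusted_span`, `excluded_gaps` (data.frame
#'   `start`, `end`, `median_cross_r2`), `span_start`, `span_end`.
#' @export
soc_span <- function(soc, ld, min_gap_bp = 5e6, min_cross_gap_r2 = 0.5) {
  members <- soc$members[[1]]
  pos <- unname(stats::setNames(ld$pos, ld$snp_id)[members])
  ord <- order(pos)
  members <- members[ord]; pos <- pos[ord]
  raw <- max(pos) - min(pos)
  gaps <- data.frame(start = numeric(), end = numeric(),
                     median_cross_r2 = numeric())
  adjusted <- raw
  if (length(pos) >= 2) {
    d <- diff(pos)
    for (i in which(d >= min_gap_bp)) {
      left <- members[seq_len(i)]
      right <- members[seq(i + 1, length(members))]
      cross <- ld$r2[left, right, drop = FALSE]
      med <- stats::median(cross, na.rm = TRUE)
      if (!is.na(med) && med >= min_cross_gap_r2) {
        gaps <- rbind(gaps, data.frame(start = pos[i], end = pos[i + 1],
                                       median_cross_r2 = med))
        adjusted <- adjusted - (pos[i + 1] - pos[i])
      }
    }
  }
  list(raw_span = raw, adjusted_span = adjusted, excluded_gaps = gaps,
       span_start = min(pos), span_end = max(pos))
}

#' Run the full LD-network stage over all chromosomes
#'
#' For each chromosome: r2 matrix, merger tree, phi selection (unless
#' fixed), OC extraction, SOC gates and span computation.
#'
#' @param dataset a [geno_dataset()].
#' @param params an [ldna_params()].
#' @param min_gap_bp,min_cross_gap_r2 gap-exclusion rule for [soc_span()].
#' @return list with `socs` (data.frame, one row per retained SOC, with
#'   members list column and raw/adjusted span columns), `ocs` (all
#'   extracted OCs), `phi` (named per-chromosome), `trees` (per-chromosome
#'   merger trees), `ld` (per-chromosome `ld_matrix`).
#' @export
ld_network_scan <- function(dataset, params = ldna_params(),
                            min_gap_bp = 5e6, min_cross_gap_r2 = 0.5) {
  chroms <- unique(dataset$variants$chrom)
  all_ocs <- list(); socs <- list(); phis <- numeric(0)
  trees <- list(); lds <- list()
  for (chr in chroms) {
    ld <- try(ld_r2(dataset, chr, maf_floor = params$maf_floor),
              silent = TRUE)
    if (inherits(ld, "try-error")) next
    tree <- build_merger_tree(ld, edge_floor = params$edge_floor)
    phi <- if (is.null(params$phi)) select_phi(tree, params) else params$phi
    phis[chr] <- phi
    ocs <- extract_ocs(tree, params, phi = phi)
    trees[[chr]] <- tree; lds[[chr]] <- ld
    if (!nrow(ocs)) next
    all_ocs[[chr]] <- ocs
    retained <- soc_postfilter(ocs, params, ld = ld, dataset = dataset)
    if (!nrow(retained)) next
    for (i in seq_len(nrow(retained))) {
      sp <- soc_span(retained[i, , drop = FALSE], ld,
                     min_gap_bp = min_gap_bp,
                     min_cross_gap_r2 = min_cross_gap_r2)
      row <- retained[i, , drop = FALSE]
      row$span_start <- sp$span_start
      row$span_end <- sp$span_end
      row$raw_span <- sp$raw_span
      row$adjusted_span <- sp$adjusted_span
      row$n_excluded_gaps <- nrow(sp$excluded_gaps)
      socs[[length(socs) + 1L]] <- row
    }
  }
  socs_df <- if (length(socs)) do.call(rbind, socs) else NULL
  ocs_df <- if (length(all_ocs)) do.call(rbind, all_ocs) else NULL
  list(socs = socs_df, ocs = ocs_df, phi = phis, trees = trees, ld = lds)
}
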