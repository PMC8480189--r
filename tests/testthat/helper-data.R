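# Shared fixtures and independent oracles for the test suite.
# Expensive objects (the default simulation and its derived stages) are
# computed once per session and cached.

.parinv_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .parinv_cache)) {
    assign(key, expr, envir = .parinv_cache)
  }
  get(key, envir = .parinv_cache)
}

default_sim <- function() {
  cached("sim", simulate_genotypes(sim_config(seed = 7)))
}

default_filtered <- function() {
  cached("filtered",
         apply_filters(default_sim()$dataset, filter_config())$dataset)
}

default_scan <- function() {
  cached("scan", outlier_scan(default_filtered(), scan_config()))
}

default_ldscan <- function() {
  cached("ldscan", ld_network_scan(default_filtered()))
}

# Small hand-built dataset: two populations (ANC ancestral, DER derived),
# genotypes supplied as a samples x SNPs matrix.
make_dataset <- function(geno, pops, chrom = NULL, pos = NULL,
                         qual = NULL, depth = NULL, gq = NULL) {
  geno <- as.matrix(geno)
  n_snp <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("chr1", n_snp)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = n_snp)
  if (is.null(rownames(geno))) {
    rownames(geno) <- paste0("s", seq_len(nrow(geno)))
  }
  variants <- data.frame(snp_id = paste0(chrom, ":", pos), chrom = chrom,
                         pos = pos, ref = "A", alt = "G",
                         qual = if (is.null(qual)) NA_real_ else qual,
                         stringsAsFactors = FALSE)
  colnames(geno) <- variants$snp_id
  popmap <- stats::setNames(pops, rownames(geno))
  eco <- unique(unname(pops))
  ecotype <- stats::setNames(
    ifelse(eco == eco[1], "ancestral", "derived"), eco)
  geno_dataset(geno, variants, popmap, ecotype, depth = depth, gq = gq)
}

# Hand-built LD matrix object for merger-tree tests.
make_ld <- function(r2, pos, chrom = "chr1") {
  ids <- paste0(chrom, ":", pos)
  dimnames(r2) <- list(ids, ids)
  diag(r2) <- NA_real_
  structure(list(chrom = chrom, snp_id = ids, pos = pos, r2 = r2),
            class = "ld_matrix")
}

# Independent Fisher-exact oracle: full enumeration over all tables with
# the observed margins using log-binomial coefficients (no dhyper).
fet_enum_oracle <- function(a1, b1, a2, b2) {
  m <- a1 + b1; n <- a2 + b2; k <- a1 + a2
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) -
    lchoose(m + n, k)
  obs <- lchoose(m, a1) + lchoose(n, k - a1) - lchoose(m + n, k)
  sum(exp(logp[logp <= obs + log1p(1e-12)]))
}

# Independent Welch t oracle from the textbook formulas.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Brute-force base-counting oracle for neighbor_coverage on small maps.
coverage_oracle <- function(pos, d) {
  length(unique(unlist(lapply(pos, function(p) max(0, p - d):(p + d)))))
}

# Interval-set Jaccard; a and b are 2-column matrices of [start, end].
interval_set_jaccard <- function(a, b) {
  merge_intervals <- function(m) {
    m <- m[order(m[, 1]), , drop = FALSE]
    out <- m[1, , drop = FALSE]
    for (i in seq_len(nrow(m))[-1]) {
      if (m[i, 1] <= out[nrow(out), 2]) {
        out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
      } else out <- rbind(out, m[i, ])
    }
    out
  }
  total <- function(m) sum(m[, 2] - m[, 1])
  inter <- function(ma, mb) {
    s <- 0
    for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(mb))) {
      s <- s + max(0, min(ma[i, 2], mb[j, 2]) - max(ma[i, 1], mb[j, 1]))
    }
    s
  }
  ma <- merge_intervals(a); mb <- merge_intervals(b)
  ix <- inter(ma, mb)
  ix / (total(ma) + total(mb) - ix)
}

# SOC row -> interval set of its adjusted span (raw span minus gaps
# excluded by the gap rule).
soc_adjusted_intervals <- function(soc_row, ld, min_gap_bp = 5e6,
                                   min_cross_gap_r2 = 0.5) {
  sp <- soc_span(soc_row, ld, min_gap_bp = min_gap_bp,
                 min_cross_gap_r2 = min_cross_gap_r2)
  iv <- matrix(c(sp$span_start, sp$span_end), ncol = 2)
  if (nrow(sp$excluded_gaps)) {
    pieces <- list()
    cur <- sp$span_start
    g <- sp$excluded_gaps[order(sp$excluded_gaps$start), ]
    for (i in seq_len(nrow(g))) {
      pieces[[length(pieces) + 1L]] <- c(cur, g$start[i])
      cur <- g$end[i]
    }
    pieces[[length(pieces) + 1L]] <- c(cur, sp$span_end)
    iv <- do.call(rbind, pieces)
  }
  iv
}

# Diagnostic inversion sites: genotype equals the true karyotype's B
# dosage for every called individual.
diagnostic_ids <- function(sim) {
  ds <- sim$dataset
  tr <- sim$truth
  dos <- c(AA = 0L, AB = 1L, BB = 2L)[tr$karyotype[ds$samples]]
  inv <- intersect(tr$inversion_ids, ds$variants$snp_id)
  keep <- vapply(inv, function(id) {
    g <- ds$geno[, id]
    all(g[!is.na(g)] == dos[!is.na(g)])
  }, logical(1))
  inv[keep]
}
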