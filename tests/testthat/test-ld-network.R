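test_that("r2 is 1 for co-varying dosages and invariant to relabeling", {
  g1 <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L)
  g <- cbind(g1, g1, 2L - g1)
  d <- make_dataset(g, pops = rep(c("P1", "P2"), each = 6))
  ld <- ld_r2(d, "chr1")
  expect_equal(ld$r2[1, 2], 1)
  expect_equal(ld$r2[1, 3], 1)  # flipping ref/alt preserves r2
  expect_true(all(is.na(diag(ld$r2))))
})

test_that("independent loci show near-zero background LD", {
  set.seed(111)
  g <- sapply(runif(40, 0.3, 0.7), function(p) rbinom(100, 2, p))
  d <- make_dataset(g, pops = rep(c("P1", "P2"), each = 50))
  ld <- ld_r2(d, "chr1")
  expect_lt(mean(ld$r2[upper.tri(ld$r2)], na.rm = TRUE), 0.05)
})

test_that("the MAF floor excludes rare loci from the LD graph", {
  g1 <- c(rep(0L, 19), 1L)
  g2 <- rep(c(0L, 1L, 2L, 1L), 5)
  d <- make_dataset(cbind(g1, g2, g2), pops = rep(c("P1", "P2"), each = 10))
  ld <- ld_r2(d, "chr1", maf_floor = 0.1)
  expect_equal(length(ld$snp_id), 2L)
  expect_false(d$variants$snp_id[1] %in% ld$snp_id)
})

test_that("the toy two-component matrix yields lambda 3 at the root merge", {
  r2 <- matrix(0, 6, 6)
  r2[1:3, 1:3] <- 1
  ld <- make_ld(r2, pos = c(1e5, 2e5, 3e5, 5e6, 6e6, 7e6))
  tree <- build_merger_tree(ld)
  expect_equal(nrow(tree$clusters), 1L)
  expect_equal(tree$clusters$lambda, 3)
  expect_equal(tree$clusters$median_r2, 1)
  expect_equal(tree$clusters$merged_median_r2, 0)
  expect_equal(tree$clusters$threshold, 0)
  expect_setequal(tree$members[[1]], ld$snp_id[1:3])
})

test_that("a fully connected graph produces no internal mergers", {
  r2 <- matrix(0.9, 4, 4)
  ld <- make_ld(r2, pos = c(1e5, 2e5, 3e5, 4e5))
  tree <- build_merger_tree(ld)
  expect_equal(nrow(tree$clusters), 0L)
})

test_that("merger records respect component monotonicity", {
  set.seed(121)
  n <- 12
  r2 <- matrix(runif(n * n, 0, 0.9), n, n)
  r2 <- (r2 + t(r2)) / 2
  ld <- make_ld(r2, pos = seq(1e5, by = 1e5, length.out = n))
  tree <- build_merger_tree(ld)
  cl <- tree$clusters
  # recorded merge thresholds lie in [0, max r2] and each recorded
  # cluster is contained in every cluster recorded at a lower threshold
  # whose members intersect it
  expect_true(all(cl$threshold >= 0 & cl$threshold <= max(r2)))
  if (nrow(cl) >= 2) {
    for (i in seq_len(nrow(cl))) for (j in seq_len(nrow(cl))) {
      if (cl$threshold[j] < cl$threshold[i] &&
          length(intersect(tree$members[[i]], tree$members[[j]]))) {
        expect_true(all(tree$members[[i]] %in% tree$members[[j]]) ||
                    cl$threshold[j] == cl$threshold[i])
      }
    }
  }
})

test_that("phi selection stabilizes where extraction stops changing", {
  # one dominant cluster far above the rest: stable from the start
  mk_tree <- function(lambdas, n_edges = 50) {
    k <- length(lambdas)
    members <- lapply(seq_len(k), function(i)
      paste0("s", i, "_", seq_len(4)))
    list(chrom = "chr1",
         snp_id = unlist(members),
         pos = seq_along(unlist(members)) * 1e5,
         clusters = data.frame(
           cluster = paste0("C", seq_len(k)),
           threshold = rep(0.5, k), n_loci = rep(4L, k),
           n_edges = rep(n_edges, k), median_r2 = rep(0.9, k),
           merged_median_r2 = rep(0.1, k), lambda = lambdas,
           stringsAsFactors = FALSE),
         members = members)
  }
  tree <- mk_tree(c(seq(0.4, 0.6, length.out = 9), 60))
  expect_equal(select_phi(tree, ldna_params()), 2)
  # all lambdas equal: empty extraction is immediately stable
  tree0 <- mk_tree(rep(1, 8))
  expect_equal(select_phi(tree0, ldna_params()), 2)
  expect_equal(nrow(suppressWarnings(
    extract_ocs(tree0, ldna_params(), phi = 2))), 0L)
})

test_that("outlier clusters exceed the lambda limit and nest as COC/SOC", {
  members <- list(paste0("a", 1:6), paste0("a", 1:4),
                  paste0("b", 1:5), paste0("c", 1:5), paste0("d", 1:5),
                  paste0("e", 1:5))
  tree <- list(chrom = "chr1",
               snp_id = unique(unlist(members)),
               pos = NULL,
               clusters = data.frame(
                 cluster = paste0("C", 1:6),
                 threshold = c(0.2, 0.6, 0.3, 0.3, 0.3, 0.3),
                 n_loci = vapply(members, length, integer(1)),
                 n_edges = rep(40, 6), median_r2 = rep(0.8, 6),
                 merged_median_r2 = rep(0.2, 6),
                 lambda = c(50, 45, 0.9, 1, 1.1, 1.2),
                 stringsAsFactors = FALSE),
               members = members)
  tree$pos <- stats::setNames(seq_along(tree$snp_id) * 1e5, tree$snp_id)
  ocs <- extract_ocs(tree, ldna_params(), phi = 2)
  expect_setequal(ocs$cluster, c("C1", "C2"))
  expect_equal(ocs$type[ocs$cluster == "C1"], "COC")  # contains C2
  expect_equal(ocs$type[ocs$cluster == "C2"], "SOC")
})

test_that("fewer than five eligible lambda values yields no clusters", {
  members <- list(paste0("a", 1:4), paste0("b", 1:4))
  tree <- list(chrom = "chr1", snp_id = unlist(members),
               pos = stats::setNames(seq_len(8) * 1e5, unlist(members)),
               clusters = data.frame(
                 cluster = c("C1", "C2"), threshold = c(0.5, 0.4),
                 n_loci = c(4L, 4L), n_edges = c(40, 40),
                 median_r2 = c(0.9, 0.9), merged_median_r2 = c(0.1, 0.1),
                 lambda = c(10, 1), stringsAsFactors = FALSE),
               members = members)
  expect_warning(ocs <- extract_ocs(tree, ldna_params(), phi = 2),
                 "fewer than 5")
  expect_equal(nrow(ocs), 0L)
})

test_that("retention gates drop small and low-LD clusters", {
  mk <- function(n_loci, median_r2) {
    df <- data.frame(chrom = "chr1", cluster = "C1", type = "SOC",
                     threshold = 0.3, n_loci = n_loci, n_edges = 100,
                     lambda = 5, median_r2 = median_r2,
                     span_start = 1e6, span_end = 2e6,
                     stringsAsFactors = FALSE)
    df$members <- list(paste0("s", seq_len(n_loci)))
    class(df) <- c("ld_clusters", "data.frame")
    df
  }
  expect_equal(nrow(soc_postfilter(mk(29, 1.0), ldna_params())), 0L)
  expect_equal(nrow(soc_postfilter(mk(53, 0.29), ldna_params())), 0L)
  expect_equal(nrow(soc_postfilter(mk(53, 1.0), ldna_params())), 1L)
})

test_that("population-centered LD separates rearrangement from admixture", {
  # two populations with shifted frequencies at every SNP; SNPs 1-3
  # share one haplotype (identical dosages), SNPs 4-5 are independent
  # draws that correlate with 1-3 only through structure
  set.seed(131)
  n <- 60
  pop <- rep(c("P1", "P2"), each = n / 2)
  p <- ifelse(pop == "P1", 0.1, 0.8)
  hap <- rbinom(n, 2, p)
  ind1 <- rbinom(n, 2, p)
  ind2 <- rbinom(n, 2, p)
  d <- make_dataset(cbind(hap, hap, hap, ind1, ind2), pops = pop)
  ids <- d$variants$snp_id
  w <- within_pop_r2(d, ids)
  expect_gt(w[1, 2], 0.99)
  expect_lt(w[1, 4], 0.2)
  pooled <- ld_r2(d, "chr1")
  expect_gt(pooled$r2[ids[1], ids[4]], 0.2)  # admixture LD is present
  kept <- trim_bridge_loci(ids, d, floor = 0.3)
  expect_setequal(kept, ids[1:3])
})

test_that("span gap exclusion follows the cross-gap LD rule", {
  pos <- c(seq(1e6, 5e6, length.out = 5), seq(15e6, 20e6, length.out = 5))
  r2 <- matrix(0.8, 10, 10)
  ld <- make_ld(r2, pos = pos)
  soc <- data.frame(chrom = "chr1", cluster = "C1", stringsAsFactors = FALSE)
  soc$members <- list(ld$snp_id)
  sp <- soc_span(soc, ld, min_gap_bp = 5e6, min_cross_gap_r2 = 0.5)
  expect_equal(sp$raw_span, 19e6)
  expect_equal(sp$adjusted_span, 9e6)
  expect_equal(nrow(sp$excluded_gaps), 1L)

  # low cross-gap LD: the gap is genuine extent and is kept
  r2_low <- r2; r2_low[1:5, 6:10] <- 0.1; r2_low[6:10, 1:5] <- 0.1
  ld_low <- make_ld(r2_low, pos = pos)
  sp_low <- soc_span(soc, ld_low, min_gap_bp = 5e6, min_cross_gap_r2 = 0.5)
  expect_equal(sp_low$adjusted_span, sp_low$raw_span)
  expect_equal(nrow(sp_low$excluded_gaps), 0L)

  # no gap of the minimum width
  sp_no <- soc_span(soc, ld, min_gap_bp = 15e6, min_cross_gap_r2 = 0.5)
  expect_equal(sp_no$adjusted_span, sp_no$raw_span)
})

test_that("panmictic linkage-free data yields no clusters", {
  for (seed in c(141, 142, 143)) {
    sim <- simulate_null(sim_config(seed = seed, n_neutral_snps = 900,
                                    neutral_fst = 0, n_chromosomes = 1,
                                    inversion_chrom = 1))
    res <- suppressWarnings(ld_network_scan(sim$dataset))
    expect_null(res$socs)
  }
})
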