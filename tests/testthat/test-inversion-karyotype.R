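test_that("region PCA separates the three karyotype groups", {
  sim <- default_sim()
  d <- default_filtered()
  ids <- intersect(diagnostic_ids(sim), d$variants$snp_id)
  pc <- region_pca(d, ids)
  anc <- pop_samples(d, "ANA")
  expect_lt(mean(pc[rownames(pc) %in% anc, 1]), 0)

  karyo <- sim$truth$karyotype[rownames(pc)]
  pc1 <- split(pc[, 1], karyo)
  # group PC1 ranges are disjoint and ordered AA < AB < BB
  expect_lt(max(pc1$AA), min(pc1$AB))
  expect_lt(max(pc1$AB), min(pc1$BB))
})

test_that("individuals with no called genotype in the region are dropped", {
  g <- rbind(c(0L, 0L), c(1L, 1L), c(2L, 2L), c(NA_integer_, NA_integer_),
             c(0L, 0L), c(2L, 2L))
  d <- make_dataset(g, pops = rep(c("ANC", "DER"), each = 3))
  expect_message(pc <- region_pca(d, d$variants$snp_id), "excluded 1")
  expect_equal(nrow(pc), 5L)
  expect_false("s4" %in% rownames(pc))
})

test_that("one-dimensional k-means recovers obvious groupings", {
  x <- c(-10, -9, 0, 1, 9, 10)
  lab <- kmeans_1d(x, 3)
  expect_equal(as.integer(lab), c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(attr(lab, "centers"), c(-9.5, 0.5, 9.5))
  expect_equal(attr(lab, "withinss"), 0.5 * 3)
  expect_false(attr(lab, "degenerate"))

  expect_warning(lab2 <- kmeans_1d(c(0, 0, 0, 5, 5, 5), 3), "distinct")
  expect_true(attr(lab2, "degenerate"))
  expect_equal(as.integer(lab2), rep(c(1L, 2L), each = 3))
})

test_that("the dynamic program never does worse than restarted Lloyd", {
  set.seed(201)
  for (i in 1:25) {
    x <- rnorm(30, mean = sample(c(-4, 0, 4), 30, replace = TRUE))
    lab <- kmeans_1d(x, 3)
    km <- suppressWarnings(
      stats::kmeans(x, centers = 3, nstart = 50, algorithm = "Lloyd",
                    iter.max = 100))
    expect_lte(attr(lab, "withinss"), km$tot.withinss + 1e-8)
  }
})

test_that("karyotypes match simulated truth and the het gate passes", {
  sim <- default_sim()
  d <- default_filtered()
  socs <- default_ldscan()$socs
  expect_equal(nrow(socs), 1L)
  res <- karyotype_soc(d, socs[1, , drop = FALSE])
  a <- res$assignment
  expect_false(a$failed)
  got <- stats::setNames(a$table$karyotype, a$table$sample)
  truth <- sim$truth$karyotype[names(got)]
  expect_equal(mean(got == truth), 1)
  gm <- a$group_mean_het
  expect_gt(gm[["AB"]], gm[["AA"]])
  expect_gt(gm[["AB"]], gm[["BB"]])
  expect_equal(res$cause, "parallel adaptation")
})

test_that("an ancestral majority in the middle group is flagged, not hidden", {
  g <- matrix(rep(c(0L, 1L, 2L), 4), nrow = 6, ncol = 2)
  d <- make_dataset(g, pops = rep(c("ANC", "DER"), each = 3))
  pc1 <- stats::setNames(c(-0.1, 0, 0.1, -5, -5.2, 5), rownames(d$geno))
  het <- stats::setNames(c(1, 1, 1, 0, 0, 0), rownames(d$geno))
  a <- assign_karyotypes(pc1, d, het)
  expect_true(a$failed)
  expect_match(a$failure_reason, "middle")
  # fallback orientation is still reported for inspection
  expect_setequal(unique(a$table$karyotype), c("AA", "AB", "BB"))
})

test_that("a non-peaking heterozygosity profile is flagged", {
  g <- matrix(rep(c(0L, 1L, 2L), 4), nrow = 6, ncol = 2)
  d <- make_dataset(g, pops = rep(c("ANC", "DER"), each = 3))
  pc1 <- stats::setNames(c(-5, -5.2, -4.8, 0.1, 0, 5), rownames(d$geno))
  het <- stats::setNames(c(0.2, 0.2, 0.2, 0.1, 0.1, 0.9), rownames(d$geno))
  a <- assign_karyotypes(pc1, d, het)
  expect_true(a$failed)
  expect_match(a$failure_reason, "heterozygosity")
})

test_that("a region with a single PC1 group yields all reference karyotypes", {
  g <- matrix(rep(c(0L, 1L, 2L), 4), nrow = 6, ncol = 2)
  d <- make_dataset(g, pops = rep(c("ANC", "DER"), each = 3))
  pc1 <- stats::setNames(rep(0, 6), rownames(d$geno))
  het <- stats::setNames(rep(0.1, 6), rownames(d$geno))
  a <- assign_karyotypes(pc1, d, het)
  expect_false(a$failed)
  expect_true(all(a$table$karyotype == "AA"))
})

test_that("karyotype frequencies follow the allele-counting rule", {
  tab <- data.frame(
    sample = paste0("s", 1:28),
    population = rep(c("P1", "P2"), c(21, 7)),
    karyotype = c(rep("AA", 17), rep("AB", 3), "BB",
                  rep("BB", 7)),
    stringsAsFactors = FALSE)
  a <- structure(list(table = tab), class = "karyotype_assignment")
  f <- karyotype_frequencies(a)
  p1 <- f[f$population == "P1", ]
  expect_equal(p1$freq_AA, 17 / 21)
  expect_equal(p1$freq_B, (3 + 2 * 1) / 42)
  expect_equal(p1$freq_AA + p1$freq_AB + p1$freq_BB, 1)
  p2 <- f[f$population == "P2", ]
  expect_equal(p2$freq_B, 1)
  expect_equal(p2$freq_A, 0)
})

test_that("differentiation is elevated inside the rearrangement", {
  sim <- default_sim()
  d <- default_filtered()
  socs <- default_ldscan()$socs
  members <- socs$members[[1]]
  neutral <- intersect(sim$truth$neutral_ids, d$variants$snp_id)
  f <- inversion_fst(d, members, neutral)
  expect_gt(f$elevation_ratio, 5)
  expect_named(f$inversion_theta, derived_pops(d))

  # a "region" drawn from neutral SNPs shows no elevation
  set.seed(211)
  fake <- sample(neutral, length(members))
  f0 <- inversion_fst(d, fake, setdiff(neutral, fake))
  expect_lt(f0$elevation_ratio, 2)
  expect_gt(f0$elevation_ratio, 0.5)

  # invariant to the order in which member SNPs are listed
  f_rev <- inversion_fst(d, rev(members), neutral)
  expect_equal(f_rev$elevation_ratio, f$elevation_ratio)
})

test_that("cause classification distinguishes parallel shifts from splits", {
  eco <- c(ANA = "ancestral", FW1 = "derived", FW2 = "derived",
           FW3 = "derived", FW4 = "derived")
  mk <- function(freq_B) data.frame(population = names(eco), freq_B = freq_B,
                                    stringsAsFactors = FALSE)
  expect_equal(classify_soc_cause(mk(c(0.10, 0.80, 0.75, 0.95, 0.62)), eco),
               "parallel adaptation")
  expect_equal(classify_soc_cause(mk(c(0.50, 0.95, 0.92, 0.05, 0.08)), eco),
               "geographic structure")
  expect_equal(classify_soc_cause(mk(c(0.50, 0.55, 0.60, 0.45, 0.52)), eco),
               "unresolved")
  expect_error(classify_soc_cause(mk(c(0.1, 0.8, 0.8, 0.8, 0.8)),
                                  c(ANA = "ancestral", FW1 = "derived",
                                    FW2 = "derived", FW3 = "derived",
                                    FW4 = "ancestral")),
               NA)
  expect_error(
    classify_soc_cause(
      data.frame(population = c("ANA", "FW1"), freq_B = c(0.1, 0.9)),
      c(ANA = "ancestral", FW1 = "derived")),
    "derived")
})
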