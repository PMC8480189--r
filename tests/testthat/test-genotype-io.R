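test_that("read_vcf transcribes a hand-written VCF exactly", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sA", "sB", "sC", sep = "\t"),
    paste("chr1", "100", "chr1:100", "A", "G", "50", "PASS", ".", "GT:DP",
          "0/0:10", "0/1:12", "1/1:9", sep = "\t"),
    paste("chr1", "200", "chr1:200", "C", "T", "60", "PASS", ".", "GT:DP",
          "./.:.", "0/0:15", "0/1:20", sep = "\t")), vcf)
  popmap <- file.path(dir, "popmap.tsv")
  writeLines(c("sA\tP1", "sB\tP1", "sC\tP2"), popmap)
  eco <- file.path(dir, "eco.tsv")
  writeLines(c("P1\tancestral", "P2\tderived"), eco)

  ds <- read_vcf(vcf, popmap, eco)
  expect_equal(dim(ds$geno), c(3L, 2L))
  expect_equal(unname(ds$geno[, "chr1:100"]), c(0L, 1L, 2L))
  expect_equal(unname(ds$geno[, "chr1:200"]), c(NA_integer_, 0L, 1L))
  expect_equal(unname(ds$depth[, "chr1:100"]), c(10L, 12L, 9L))
  expect_equal(ds$variants$qual, c(50, 60))
})

test_that("multi-allelic and non-SNP records are skipped with a count", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sA", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", "50", "PASS", ".", "GT", "0/1",
          sep = "\t"),
    paste("chr1", "200", ".", "C", "A,T", "50", "PASS", ".", "GT", "0/1",
          sep = "\t"),
    paste("chr1", "300", ".", "CT", "C", "50", "PASS", ".", "GT", "0/1",
          sep = "\t")), vcf)
  writeLines("sA\tP1", file.path(dir, "popmap.tsv"))
  writeLines("P1\tancestral", file.path(dir, "eco.tsv"))
  expect_message(
    ds <- read_vcf(vcf, file.path(dir, "popmap.tsv"),
                   file.path(dir, "eco.tsv")),
    "skip")
  expect_equal(nrow(ds$variants), 1L)
  expect_equal(attr(ds, "skipped"), 2L)
})

test_that("a VCF sample absent from the popmap is named in the error", {
  dir <- withr::local_tempdir()
  sim <- simulate_genotypes(sim_config(seed = 4, n_neutral_snps = 20,
                                       n_selected_snps = 0,
                                       n_inversion_snps = 0,
                                       n_chromosomes = 1,
                                       inversion_chrom = 1,
                                       inversion_start = 1e6,
                                       inversion_end = 2e6))
  write_simulation(sim, dir)
  pm <- read.table(file.path(dir, "popmap.tsv"), sep = "\t")
  pm <- pm[pm$V1 != "ANA_1", ]
  write.table(pm, file.path(dir, "popmap.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_error(
    read_vcf(file.path(dir, "genotypes.vcf"), file.path(dir, "popmap.tsv"),
             file.path(dir, "ecotype.tsv")),
    "ANA_1")
})

test_that("write_vcf then read_vcf is the identity", {
  dir <- withr::local_tempdir()
  sim <- simulate_genotypes(sim_config(seed = 11, n_neutral_snps = 60,
                                       n_selected_snps = 5,
                                       n_inversion_snps = 20,
                                       n_chromosomes = 2,
                                       inversion_chrom = 2,
                                       inversion_start = 5e6,
                                       inversion_end = 1.5e7))
  d <- sim$dataset
  vcf <- file.path(dir, "rt.vcf")
  write_vcf(d, vcf, popmap_path = file.path(dir, "pm.tsv"),
            ecotype_path = file.path(dir, "eco.tsv"))
  d2 <- read_vcf(vcf, file.path(dir, "pm.tsv"), file.path(dir, "eco.tsv"))
  expect_identical(d2$geno, d$geno)
  expect_identical(d2$depth, d$depth)
  expect_identical(d2$gq, d$gq)
  expect_equal(d2$variants[, c("snp_id", "chrom", "pos", "ref", "alt")],
               d$variants[, c("snp_id", "chrom", "pos", "ref", "alt")])
  expect_identical(d2$popmap, d$popmap)
  expect_identical(d2$ecotype[sort(names(d2$ecotype))],
                   d$ecotype[sort(names(d$ecotype))])
})

test_that("write_vcf handles empty variant sets and missing genotypes", {
  dir <- withr::local_tempdir()
  d <- make_dataset(matrix(NA_integer_, 1, 1,
                           dimnames = list("s1", NULL)), pops = "P1")
  vcf <- file.path(dir, "miss.vcf")
  write_vcf(d, vcf)
  body <- grep("^[^#]", readLines(vcf), value = TRUE)
  expect_match(body, "\\./\\.")

  empty <- subset_dataset(d, snp_ids = character(0))
  vcf0 <- file.path(dir, "empty.vcf")
  write_vcf(empty, vcf0)
  lines <- readLines(vcf0)
  expect_true(any(grepl("^#CHROM", lines)))
  expect_length(grep("^[^#]", lines), 0L)
})

test_that("filters remove SNPs for the stated reasons, in order", {
  # 36 P1 samples + 6 P2 samples so a SNP can have global MAF < 0.05
  # while one population's local MAF clears the 0.2 rescue.
  cfg <- filter_config(min_individuals_per_pop = 4)
  n1 <- 36L; n2 <- 6L; n <- n1 + n2
  g <- matrix(0L, n, 5)
  g[, 1] <- rep(c(0L, 1L, 1L, 0L, 2L, 0L), length.out = n)  # common SNP
  g[seq_len(n1), 2] <- 1L                      # P1 fully heterozygous
  g[n1 + 1:3, 3] <- 1L                         # P2 local MAF 0.25, global 0.036
  g[1, 4] <- 1L                                # global MAF 0.012, no rescue
  # SNP5 polymorphic but P2 will be masked by depth
  g[, 5] <- rep(c(0L, 1L), length.out = n)
  dp <- matrix(30L, n, 5)
  dp[n1 + 1:n2, 5] <- 3L
  gq <- matrix(60L, n, 5)
  d <- make_dataset(g, pops = rep(c("P1", "P2"), c(n1, n2)),
                    qual = rep(90, 5), depth = dp, gq = gq)
  res <- apply_filters(d, cfg)
  reason <- res$report$removal_reason
  ids <- d$variants$snp_id
  expect_true(is.na(reason[ids[1]]))          # retained
  expect_equal(unname(reason[ids[2]]), "pop_het")
  expect_true(is.na(reason[ids[3]]))          # rescued by local MAF
  expect_equal(unname(reason[ids[4]]), "maf")
  expect_equal(unname(reason[ids[5]]), "call_rate")
  expect_equal(res$report$n_input,
               res$report$n_retained + sum(res$report$removed))
})

test_that("low site quality removes a SNP under the quality criterion", {
  g <- matrix(rep(c(0L, 1L, 0L, 1L), 5), 4, 5)
  d <- make_dataset(g, pops = rep(c("P1", "P2"), each = 2),
                    qual = c(90, 10, 90, 90, 90))
  res <- apply_filters(d, filter_config(min_individuals_per_pop = 2))
  expect_equal(unname(res$report$removal_reason[d$variants$snp_id[2]]),
               "site_quality")
})

test_that("filtering is idempotent", {
  ds <- default_filtered()
  res2 <- apply_filters(ds, filter_config())
  expect_equal(res2$report$n_retained, nrow(ds$variants))
  expect_equal(sum(res2$report$removed), 0L)
})

test_that("a population too small for the call-rate criterion warns", {
  g <- matrix(rep(c(0L, 1L), 10), 4, 5)
  d <- make_dataset(g, pops = c("P1", "P1", "P1", "P2"))
  expect_warning(apply_filters(d, filter_config()), "P2")
})

test_that("neutral-set pruning keeps the first SNP per window", {
  g <- matrix(rep(c(0L, 1L, 2L, 1L), 3), 4, 3)
  d <- make_dataset(g, pops = rep(c("P1", "P2"), each = 2),
                    pos = c(100L, 5100L, 20100L))
  kept <- build_neutral_set(d, outlier_ids = character(0),
                            inversion_regions = NULL,
                            prune_window = 10000)
  expect_equal(kept$variants$pos, c(100L, 20100L))
})

test_that("neutral-set construction errors when nothing survives", {
  g <- matrix(rep(c(0L, 1L, 2L, 1L), 2), 4, 2)
  d <- make_dataset(g, pops = rep(c("P1", "P2"), each = 2),
                    pos = c(100L, 200L))
  region <- data.frame(chrom = "chr1", start = 0, end = 1000)
  expect_error(build_neutral_set(d, character(0), region), "window")
  expect_error(build_neutral_set(d, d$variants$snp_id, NULL), "window")
})

test_that("neutral sets satisfy the pairwise spacing and exclusion rules", {
  ds <- default_filtered()
  scan <- default_scan()
  socs <- default_ldscan()$socs
  regions <- data.frame(chrom = socs$chrom, start = socs$span_start - 1,
                        end = socs$span_end)
  neutral <- build_neutral_set(ds, scan$candidates, regions,
                               prune_window = 10000)
  v <- neutral$variants
  expect_false(any(v$snp_id %in% scan$candidates))
  for (i in seq_len(nrow(regions))) {
    inside <- v$chrom == regions$chrom[i] & v$pos > regions$start[i] &
      v$pos <= regions$end[i]
    expect_false(any(inside))
  }
  for (chr in unique(v$chrom)) {
    pos <- sort(v$pos[v$chrom == chr])
    win <- pos %/% 10000
    # each retained SNP is the unique representative of its 10-kb window,
    # so any pair is either > 10 kb apart or in different windows
    expect_true(all(!duplicated(win)))
    expect_true(all(diff(pos) > 10000 | diff(win) >= 1))
  }
})
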