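test_that("TSV genotypes round-trip bit-identically", {
  g <- make_panel(rbind(c(0, 1), c(2, 1)),
                  sample_ids = c("a", "b"), snp_ids = c("s1", "s2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, f, format = "tsv")
  g2 <- read_genotypes(f, format = "tsv")
  expect_identical(g2$dosages, g$dosages)
  expect_identical(g2$sample_ids, g$sample_ids)
  expect_identical(g2$snp_ids, g$snp_ids)
})

test_that("missing TSV entries are NA and excluded from MAF denominators", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ts1", "a\tNA", "b\t1", "c\t1"), f)
  g <- read_genotypes(f, format = "tsv")
  expect_true(is.na(g$dosages["a", "s1"]))
  # allele frequency over the 2 observed samples: 2/4 = 0.5
  st <- attr(qc_filter(g, maf_min = 0, miss_max = 1, hwe_p_min = 0)$report,
             "per_snp")
  expect_equal(st$maf, 0.5)
  expect_equal(st$miss_rate, 1 / 3)
})

test_that("hand-built PLINK .bed bytes decode to the expected dosages", {
  # 3 samples, 2 SNPs, SNP-major: 1 byte per SNP (ceil(3/4)).
  # SNP1 codes (low bits first): sample1=00 (dos 2), sample2=10 (dos 1),
  # sample3=11 (dos 0), pad 00 -> byte 00 11 10 00 = 0x38
  # SNP2: sample1=01 (missing), sample2=00 (dos 2), sample3=10 (dos 1)
  #   -> byte 00 10 00 01 = 0x21
  prefix <- withr::local_tempfile()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x38, 0x21)), paste0(prefix, ".bed"))
  writeLines(c("1\tsA\t0\t100\tA\tB", "1\tsB\t0\t200\tA\tB"),
             paste0(prefix, ".bim"))
  writeLines(c("f1\ti1\t0\t0\t0\t-9", "f2\ti2\t0\t0\t0\t-9",
               "f3\ti3\t0\t0\t0\t-9"), paste0(prefix, ".fam"))
  g <- read_genotypes(prefix, format = "plink")
  expect_equal(unname(g$dosages[, "sA"]), c(2, 1, 0))
  expect_equal(unname(g$dosages[, "sB"]), c(NA, 2, 1))
  expect_equal(g$pos, c(100L, 200L))
})

test_that("PLINK writer round-trips random panels, and rejects bad magic", {
  g <- random_panel(m = 11, p = 7, miss = 0.1, seed = 3)
  prefix <- withr::local_tempfile()
  write_genotypes(g, prefix, format = "plink")
  g2 <- read_genotypes(prefix, format = "plink")
  expect_identical(g2$dosages, g$dosages)
  # corrupt the magic bytes
  bad <- readBin(paste0(prefix, ".bed"), "raw", 100)
  bad[1] <- as.raw(0x00)
  writeBin(bad, paste0(prefix, ".bed"))
  expect_error(read_genotypes(prefix, format = "plink"), "magic")
})

test_that("PLINK reader catches bed/bim/fam dimension mismatch", {
  g <- random_panel(m = 8, p = 5, seed = 4)
  prefix <- withr::local_tempfile()
  write_genotypes(g, prefix, format = "plink")
  bim <- readLines(paste0(prefix, ".bim"))
  writeLines(bim[-1], paste0(prefix, ".bim"))
  expect_error(read_genotypes(prefix, format = "plink"), "inconsistent")
})

test_that("QC removes monomorphic, HWE-violating and high-missing SNPs", {
  # col1 monomorphic; col2 perfect HWE (25/50/25); col3 all hets (extreme
  # HWE violation); col4 fine
  n <- 100
  dos <- cbind(rep(0, n),
               rep(c(0, 1, 1, 2), times = 25),
               rep(c(0, 2), times = 50),
               rep(c(0, 1, 2, 1), times = 25))
  g <- make_panel(dos)
  res <- qc_filter(g)
  st <- attr(res$report, "per_snp")
  expect_equal(res$report$n_removed_maf, 1)
  # independent 1-df chi-square oracle for col3 (50/0/50): expected counts
  # 25/50/25 -> chisq = 25 + 50 + 25 = 100
  chisq <- 100
  p_oracle <- pchisq(chisq, df = 1, lower.tail = FALSE)
  expect_lt(p_oracle, 1e-4)
  expect_equal(st$hwe_p[3], p_oracle, tolerance = 1e-12)
  expect_equal(res$report$n_removed_hwe, 1)
  # perfect HWE: chi-square 0, p = 1
  expect_equal(st$hwe_p[2], 1)
  expect_equal(res$genotypes$snp_ids, g$snp_ids[c(2, 4)])
  expect_equal(res$report$n_input,
               with(res$report, n_removed_maf + n_removed_missing +
                      n_removed_hwe + n_kept))
})

test_that("QC attributes multi-rule failures to the first rule and is idempotent", {
  set.seed(5)
  dos <- matrix(rbinom(300, 2, 0.4), 30, 10)
  dos[1:10, 1] <- NA            # high missingness
  dos[, 2] <- 0; dos[1, 2] <- NA  # monomorphic AND missing -> counted as MAF
  g <- make_panel(dos)
  res <- qc_filter(g)
  st <- attr(res$report, "per_snp")
  expect_false(st$kept[1]); expect_false(st$kept[2])
  expect_gte(res$report$n_removed_maf, 1)  # col2 under MAF, not missingness
  res2 <- qc_filter(res$genotypes)
  expect_equal(res2$report$n_kept, res$report$n_kept)
  expect_equal(res2$report$n_removed_maf + res2$report$n_removed_missing +
                 res2$report$n_removed_hwe, 0)
  expect_error(qc_filter(make_panel(matrix(0, 5, 2))), "every SNP")
})

test_that("gene mapping honors the inclusive buffer and nearest-gene ties", {
  ann <- data.frame(chrom = "1", start = 20000, end = 30000, gene_id = "gB")
  g <- make_panel(matrix(1, 2, 4), chrom = "1",
                  pos = c(25000, 10000, 9999, 40000))
  gs <- map_snps_to_genes(g, ann, buffer_bp = 10000)
  # interior; exactly on the buffer edge (inclusive); one bp outside
  expect_equal(unname(gs$membership), c("gB", "gB", "snp3", "gB"))
  expect_equal(sum(gs$sizes), 4)
  # overlapping buffers resolve to the nearest gene body
  ann_ov <- data.frame(chrom = "1", start = c(1000, 20000),
                       end = c(2000, 30000), gene_id = c("gA", "gB"))
  g_ov <- make_panel(matrix(1, 1, 1), chrom = "1", pos = 10000)
  # distances: 8000 to gA's body, 10000 to gB's -> gA
  expect_equal(unname(map_snps_to_genes(g_ov, ann_ov)$membership), "gA")
  # SNP equidistant from two gene bodies -> lexicographically smallest id
  ann2 <- data.frame(chrom = "1", start = c(100, 300), end = c(150, 350),
                     gene_id = c("gZ", "gA"))
  g2 <- make_panel(matrix(1, 1, 1), chrom = "1", pos = 225)
  expect_equal(unname(map_snps_to_genes(g2, ann2)$membership), "gA")
  expect_error(map_snps_to_genes(g, ann[0, ]), "empty")
  expect_warning(map_snps_to_genes(make_panel(matrix(1, 1, 1), chrom = "7"),
                                   ann), "chromosome")
})

test_that("group files validate ids, forbid overlap, and conserve sizes", {
  g <- make_panel(matrix(1, 2, 3), snp_ids = c("s1", "s2", "s3"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tgroup_id", "s1\tg1", "s2\tg1", "s3\tg2"), f)
  gs <- read_groups(f, g)
  expect_equal(unname(gs$sizes), c(2L, 1L))
  expect_equal(sum(gs$sizes), 3)
  writeLines(c("snp_id\tgroup_id", "s1\tg1", "s1\tg2"), f)
  expect_error(read_groups(f, g), "overlap")
  writeLines(c("snp_id\tgroup_id", "s9\tg1"), f)
  expect_error(read_groups(f, g), "absent")
})

test_that("phenotype alignment drops extra samples with a warning", {
  g <- make_panel(matrix(1, 2, 2), sample_ids = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tvalue", "a\t1.5", "b\t2.5", "zzz\t9"), f)
  expect_warning(ph <- read_phenotype(f, g), "absent")
  expect_equal(ph$sample_id, c("a", "b"))
  expect_equal(ph$value, c(1.5, 2.5))
})
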