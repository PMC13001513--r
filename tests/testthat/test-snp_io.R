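test_that("read_sync applies the global minor-allele rule and tie-break", {
  metas <- founder_samples(2)
  f <- withr::local_tempfile()
  writeLines(c("2L\t5\tA\t10:0:0:0:0:0\t8:2:0:0:0:0"), f)
  tab <- read_sync(f, metas)
  expect_equal(nrow(tab$loci), 1)
  expect_equal(tab$loci$minor_base, "T")   # A = 18 total, T = 2
  expect_equal(tab$loci$major_base, "A")
  expect_equal(as.vector(tab$minor), c(0L, 2L))
  expect_equal(as.vector(tab$coverage), c(10L, 10L))

  # equal totals: lexicographic tie-break toward the minor (A < C)
  writeLines(c("3R\t77\tC\t3:0:2:0:0:0\t2:0:3:0:0:0"), f)
  tab2 <- read_sync(f, metas)
  expect_equal(tab2$loci$minor_base, "A")
  expect_equal(tab2$loci$major_base, "C")

  # four-field count strings (A:T:C:G) are accepted
  writeLines(c("2L\t5\tA\t10:0:0:0\t8:2:0:0"), f)
  expect_equal(read_sync(f, metas)$minor, tab$minor)
})

test_that("read_sync drops multi-allelic sites and rejects malformed input", {
  metas <- founder_samples(2)
  f <- withr::local_tempfile()
  writeLines(c("2L\t5\tA\t5:0:3:1:0:0\t5:0:3:1:0:0",   # triallelic
               "2L\t9\tA\t5:5:0:0:0:0\t5:5:0:0:0:0"), f)
  expect_message(tab <- read_sync(f, metas), "dropped 1 site")
  expect_equal(nrow(tab$loci), 1)
  expect_equal(tab$loci$pos, 9)

  writeLines(c("2L\t5\tA\t5:0:0:0:0:0\tbad-string"), f)
  expect_error(read_sync(f, metas), "malformed count string on sync line 1")
})

test_that("sync round-trip reproduces minor/coverage matrices exactly", {
  set.seed(42)
  metas <- founder_samples(4)
  f <- withr::local_tempfile()
  for (rep in 1:5) {
    cov <- matrix(rpois(3 * 4, 60), 3, 4)
    minor <- matrix(rbinom(12, as.vector(cov), 0.2), 3, 4)
    tab <- toy_table(minor, cov, chrom = c("2L", "X", "4"), samples = metas)
    write_sync(tab, f)
    back <- read_sync(f, metas)
    expect_identical(back$minor, tab$minor)
    expect_identical(back$coverage, tab$coverage)
    expect_equal(back$loci$minor_base, tab$loci$minor_base)
  }
  # empty table round-trips to an empty table through a header-free file
  empty <- toy_table(matrix(integer(), 0, 4), matrix(integer(), 0, 4),
                     chrom = character(0), samples = metas)
  write_sync(empty, f)
  expect_equal(length(readLines(f)), 0)
  expect_equal(nrow(read_sync(f, metas)$loci), 0)
  # a zero-coverage cell becomes an all-zero count string and survives
  tab0 <- toy_table(matrix(c(2L, 0L), 1, 2),
                    matrix(c(10L, 0L), 1, 2), samples = founder_samples(2))
  write_sync(tab0, f)
  back0 <- read_sync(f, founder_samples(2))
  expect_identical(back0$minor, tab0$minor)
  expect_identical(back0$coverage, tab0$coverage)
})

test_that("after read_sync the minor allele is globally the rarer one", {
  set.seed(7)
  metas <- founder_samples(3)
  f <- withr::local_tempfile()
  lines <- vapply(1:40, function(i) {
    cnt <- vapply(1:3, function(j)
      paste(c(rpois(1, 40), rpois(1, 40), 0, 0, 0, 0), collapse = ":"),
      character(1))
    paste(c("2R", i, "A", cnt), collapse = "\t")
  }, character(1))
  writeLines(lines, f)
  tab <- read_sync(f, metas)
  expect_true(all(rowSums(tab$minor) <= rowSums(tab$coverage - tab$minor)))
})

test_that("filter_snps enforces inclusive coverage and pooled-MAF bounds", {
  # one sample at coverage 19 removes the locus; 20 keeps it
  tab <- toy_table(matrix(c(5L, 30L), 1, 2), matrix(c(19L, 100L), 1, 2))
  expect_equal(nrow(filter_snps(tab, min_cov = 20)$loci), 0)
  tab <- toy_table(matrix(c(5L, 30L), 1, 2), matrix(c(20L, 100L), 1, 2))
  expect_equal(nrow(filter_snps(tab, min_cov = 20)$loci), 1)

  # pooled frequency exactly 0.02 is retained (inclusive)
  tab <- toy_table(matrix(c(2L, 2L), 1, 2), matrix(c(100L, 100L), 1, 2))
  expect_equal(nrow(filter_snps(tab, min_maf = 0.02)$loci), 1)

  # hand-computed pooled frequencies {0.01, 0.02, 0.3, 0.5, 0} -> 3 survive
  minor <- rbind(c(1L, 1L), c(2L, 2L), c(30L, 30L), c(50L, 50L), c(0L, 0L))
  cov <- matrix(100L, 5, 2)
  tab <- toy_table(minor, cov)
  kept <- filter_snps(tab, min_cov = 20, min_maf = 0.02)
  expect_equal(nrow(kept$loci), 3)
  expect_equal(kept$loci$pos, c(20L, 30L, 40L))  # order preserved

  # idempotence
  expect_identical(filter_snps(kept, min_cov = 20, min_maf = 0.02)$minor,
                   kept$minor)
  # chromosome-4 exclusion and argument validation
  tab4 <- toy_table(minor, cov, chrom = c("2L", "4", "4", "3R", "X"))
  expect_true(all(filter_snps(tab4, exclude_chrom4 = TRUE)$loci$chrom != "4"))
  expect_error(filter_snps(tab, min_maf = 0.6), "min_maf")
})

test_that("frequencies applies the pseudocount formula and range bounds", {
  tab <- toy_table(matrix(c(10L, 0L, 50L), 3, 1),
                   matrix(c(100L, 90L, 50L), 3, 1))
  expect_equal(as.vector(frequencies(tab)), c(0.1, 0, 1))
  expect_equal(as.vector(frequencies(tab, pseudocount = 1)),
               c(11 / 102, 1 / 92, 51 / 52))
  f0 <- frequencies(tab); f1 <- frequencies(tab, pseudocount = 1)
  expect_true(all(f0 >= 0 & f0 <= 1))
  expect_true(all(f1 > 0 & f1 < 1))
  tabz <- toy_table(matrix(0L, 1, 1), matrix(0L, 1, 1))
  expect_error(frequencies(tabz), "coverage 0")
  expect_equal(as.vector(frequencies(tabz, pseudocount = 1)), 0.5)
})

test_that("the tabular SNP-table dialect round-trips with its sidecar", {
  set.seed(11)
  cov <- matrix(rpois(8, 80), 4, 2)
  tab <- toy_table(matrix(rbinom(8, as.vector(cov), 0.3), 4, 2), cov,
                   chrom = c("2L", "2R", "3L", "X"))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_snp_table(tab, f1, f2)
  back <- read_snp_table(f1, f2)
  expect_identical(back$minor, tab$minor)
  expect_identical(back$coverage, tab$coverage)
  expect_equal(back$samples$sample_id, tab$samples$sample_id)
})

test_that("snp_table validation catches inconsistent objects", {
  expect_error(toy_table(matrix(5L, 1, 1), matrix(4L, 1, 1)),
               "exceeds coverage")
  expect_error(toy_table(matrix(1L, 1, 1), matrix(4L, 1, 1), chrom = "7"),
               "chrom labels")
  s <- founder_samples(2); s$replicate <- c(1L, 1L)
  expect_error(toy_table(matrix(1L, 1, 2), matrix(4L, 1, 2), samples = s),
               "unique")
})

test_that("the packaged synthetic sync slice loads cleanly", {
  f <- system.file("extdata", "example_synthetic.sync", package = "evoltraj")
  s <- system.file("extdata", "example_synthetic_samples.tsv",
                   package = "evoltraj")
  metas <- utils::read.table(s, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  tab <- read_sync(f, metas)
  expect_equal(dim(tab), c(30L, 4L))
  expect_true(all(rowSums(tab$minor) <= rowSums(tab$coverage - tab$minor)))
})
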