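# Window-based IBD / polymorphic classification against brute-force
# oracles, dialect boundary semantics, and SNP catalog I/O.

mk_catalog <- function(pos, c3h, nzo, chrom = "chrT") {
  out <- data.frame(chrom = chrom, pos = pos, ref = "A",
                    C3H = c3h, NZO = nzo, stringsAsFactors = FALSE)
  class(out) <- c("snp_catalog", "data.frame")
  out
}

test_that("discordant positions are sorted, unique, and skip missing calls", {
  cat0 <- mk_catalog(c(10, 20, 30), c("A", "C", "G"), c("A", "C", "G"))
  expect_identical(discordant_positions(cat0), integer(0))

  cat1 <- mk_catalog(c(10, 20, 30), c("A", "C", "G"), c("T", "C", "A"))
  expect_identical(discordant_positions(cat1), c(10L, 30L))

  # a missing call excludes the record
  cat2 <- mk_catalog(c(10, 20, 30), c("A", ".", "G"), c("T", "C", NA))
  expect_identical(discordant_positions(cat2), c(10L))

  expect_error(discordant_positions(cat1, strain_a = "B6"), "unknown strain")
})

test_that("window counts tile the region and match a brute-force recount", {
  region <- list(chrom = "chrT", start_bp = 1000, end_bp = 10000)

  ws0 <- window_counts(integer(0), region, 2000)
  expect_identical(ws0$snp_count, rep(0L, 5))
  expect_identical(ws0$end_bp[5], 10000)  # truncated final window

  # boundary position belongs to the right-hand window
  wsb <- window_counts(c(3000), region, 2000)
  expect_identical(wsb$snp_count, c(0L, 1L, 0L, 0L, 0L))

  set.seed(91)
  for (i in 1:20) {
    w <- sample(c(500, 1000, 1500, 2000), 1)
    pos <- sort(sample(1000:9999, sample(50:400, 1)))
    ws <- window_counts(pos, region, w)
    oracle <- brute_window_counts(pos, region, w)
    expect_identical(ws$snp_count, oracle$snp_count)
    expect_identical(ws$start_bp, oracle$start_bp)
    expect_identical(sum(ws$snp_count),
                     interval_snp_count(pos, region$start_bp, region$end_bp))
  }
  expect_error(window_counts(1:3, list(chrom = "c", start_bp = 5, end_bp = 5),
                             100), "empty region")
})

test_that("dialect thresholds sit exactly on the published boundaries", {
  region <- list(chrom = "chrT", start_bp = 1, end_bp = 150001)
  mk_ws <- function(k, w, reg) window_counts(seq_len(k) + 10, reg, w)

  # 150 kb dialect: strictly more than 50
  expect_identical(classify_windows(mk_ws(50, 150000, region))$class, "IBD")
  expect_identical(classify_windows(mk_ws(51, 150000, region))$class,
                   "POLYMORPHIC")
  expect_identical(classify_windows(mk_ws(0, 150000, region))$class, "IBD")

  # 250 kb dialect: at least 100
  region250 <- list(chrom = "chrT", start_bp = 1, end_bp = 250001)
  expect_identical(classify_windows(mk_ws(99, 250000, region250),
                                    dialect = "250kb")$class, "IBD")
  expect_identical(classify_windows(mk_ws(100, 250000, region250),
                                    dialect = "250kb")$class, "POLYMORPHIC")

  # dialect / window width mismatch rejected
  expect_error(classify_windows(mk_ws(10, 100000, region)), "150,000")
  expect_error(classify_windows(mk_ws(10, 100000, region), dialect = "250kb"),
               "250,000")

  # custom rule
  # custom rule; two windows: [1,100001) holds all 10 SNPs, truncated rest 0
  cw <- classify_windows(mk_ws(10, 100000, region), dialect = "custom",
                         min_count = 10, strict = FALSE)
  expect_identical(cw$class, c("POLYMORPHIC", "IBD"))
})

test_that("classification is monotone in SNP count", {
  region <- list(chrom = "chrT", start_bp = 1, end_bp = 150001)
  for (k in c(49, 50, 51, 52)) {
    ws <- window_counts(seq_len(k), region, 150000)
    cls <- classify_windows(ws)$class
    ws2 <- window_counts(seq_len(k + 1), region, 150000)
    cls2 <- classify_windows(ws2)$class
    if (cls == "POLYMORPHIC") expect_identical(cls2, "POLYMORPHIC")
  }
})

test_that("block merging joins maximal polymorphic runs and conserves SNPs", {
  region <- list(chrom = "chrT", start_bp = 1, end_bp = 600001)
  ws <- window_counts(c(seq_len(60), 150001 + seq_len(70),
                        450001 + seq_len(55)), region, 150000)
  cls <- classify_windows(ws)   # classes P, P, I, P
  expect_identical(cls$class, c("POLYMORPHIC", "POLYMORPHIC", "IBD",
                                "POLYMORPHIC"))
  blocks <- merge_blocks(cls)
  expect_identical(nrow(blocks), 2L)
  expect_identical(blocks$n_windows, c(2L, 1L))
  expect_identical(blocks$total_snps, c(130L, 55L))
  expect_identical(blocks$start_bp, c(1, 450001))
  expect_identical(blocks$end_bp, c(300001, 600001))

  # all IBD -> empty block list
  ws_ibd <- classify_windows(window_counts(1:10, region, 150000))
  expect_identical(nrow(merge_blocks(ws_ibd)), 0L)

  # conservation on random fixtures
  set.seed(93)
  for (i in 1:10) {
    pos <- sort(sample(1:600000, 2500))
    cls_r <- classify_windows(window_counts(pos, region, 150000))
    blocks_r <- merge_blocks(cls_r)
    expect_identical(sum(blocks_r$total_snps),
                     sum(cls_r$snp_count[cls_r$class == "POLYMORPHIC"]))
    oracle <- brute_merge(cls_r$start_bp, cls_r$end_bp, cls_r$snp_count,
                          cls_r$class == "POLYMORPHIC")
    expect_identical(nrow(blocks_r), length(oracle))
  }
})

test_that("interval SNP count is half-open and matches a linear scan", {
  expect_identical(interval_snp_count(c(10, 20, 30), 10, 30), 2L)
  expect_identical(interval_snp_count(c(10, 20, 30), 15, 15), 0L)
  set.seed(95)
  pos <- sort(sample(1:10000, 500))
  for (i in 1:20) {
    ab <- sort(sample(1:10000, 2))
    linear <- sum(vapply(pos, function(p) p >= ab[1] && p < ab[2], logical(1)))
    expect_identical(interval_snp_count(pos, ab[1], ab[2]), as.integer(linear))
  }
})

test_that("one-step block calling chains the pieces consistently", {
  region <- list(chrom = "chrT", start_bp = 1L, end_bp = 1200001L)
  spec <- data.frame(start_bp = c(150002, 750002),
                     end_bp = c(450001, 900001),
                     density_per_kb = c(1, 1.2))
  catalog <- simulate_snp_catalog(region, spec, seed = 44,
                                  background_per_kb = 0.05)
  called <- call_polymorphic_blocks(catalog, dialect = "150kb")
  expect_identical(called$positions, discordant_positions(catalog))
  expect_gte(nrow(called$blocks), 2L)
  # planted block spans recovered (window-resolution)
  expect_true(any(called$blocks$start_bp <= 150002 + 150000 &
                    called$blocks$end_bp >= 450001 - 150000))
})

test_that("SNP catalogs round-trip through TSV and minimal VCF", {
  skip_if_not_installed("vcfR")
  region <- list(chrom = "chr15", start_bp = 1L, end_bp = 100001L)
  spec <- data.frame(start_bp = 10001, end_bp = 60001, density_per_kb = 0.8)
  catalog <- simulate_snp_catalog(region, spec, seed = 17)
  catalog$NZO[3] <- NA  # exercise the missing-call path

  tsv <- tempfile(fileext = ".tsv")
  vcf <- tempfile(fileext = ".vcf")
  on.exit(unlink(c(tsv, vcf)), add = TRUE)
  write_snp_catalog_tsv(catalog, tsv)
  write_snp_catalog_vcf(catalog, vcf)

  back_tsv <- read_snp_catalog(tsv)
  expect_identical(back_tsv$pos, catalog$pos)
  expect_identical(back_tsv$C3H, catalog$C3H)

  back_vcf <- read_snp_catalog(vcf)
  expect_identical(back_vcf$pos, catalog$pos)
  expect_identical(is.na(back_vcf$NZO), is.na(catalog$NZO))
  expect_identical(discordant_positions(back_vcf),
                   discordant_positions(catalog))
})
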