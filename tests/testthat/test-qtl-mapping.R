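# Marker-regression LOD scan, permutation threshold, support interval and
# allelic segregation.

test_that("marker LOD matches the closed form and a least-squares oracle", {
  expect_identical(marker_lod(c(0, 0, 1, 1), c(1, 2, 1, 2)), 0)

  lod <- marker_lod(c(0, 0, 1, 1), c(1, 2, 3, 4))
  expect_equal(lod, (4 / 2) * log10(5), tolerance = 1e-12)  # RSS0=5, RSS1=1
  expect_equal(lod, 1.39794, tolerance = 1e-5)
  expect_equal(lod, lm_lod_oracle(c(0, 0, 1, 1), c(1, 2, 3, 4)),
               tolerance = 1e-12)

  set.seed(81)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    g <- c(0, 0, 1, 1, rbinom(n - 4, 1, 0.5))
    y <- rnorm(n) + 0.8 * g
    expect_equal(marker_lod(g, y), lm_lod_oracle(g, y), tolerance = 1e-9)
  }
})

test_that("LOD identity: RSS form equals correlation form", {
  set.seed(82)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    g <- c(0, 0, 1, 1, rbinom(n - 4, 1, 0.5))
    y <- rnorm(n, sd = runif(1, 0.5, 3)) + runif(1, -2, 2) * g
    r <- cor(g, y)
    expect_equal(marker_lod(g, y), -(n / 2) * log10(1 - r^2),
                 tolerance = 1e-9)
  }
})

test_that("degenerate markers are skipped or flagged", {
  expect_warning(out <- marker_lod(c(0, 1), c(0, 1)), "fewer than 2")
  expect_true(is.na(out))
  expect_warning(out2 <- marker_lod(c(0, 0, 1, 1), c(5, 5, 5, 5)),
                 "zero variance")
  expect_true(is.na(out2))
  expect_warning(out3 <- marker_lod(c(0, 0, 1, 1), c(1, 1, 2, 2)),
                 "perfect")
  expect_identical(out3, Inf)
})

test_that("lod_scan orders by position, handles missing data, rejects all-degenerate input", {
  map <- toy_map(10)
  geno <- simulate_backcross(map, 60, seed = 21)
  y <- rnorm(60) + geno[, "m005"]
  curve <- lod_scan(geno, y, map)
  expect_s3_class(curve, "lod_curve")
  expect_identical(curve$marker_id, map$marker_id)
  expect_true(all(diff(curve$position_bp) > 0))
  expect_true(all(curve$lod >= 0))
  expect_identical(curve$n_used, rep(60L, 10))

  geno_na <- geno
  geno_na[1:5, "m003"] <- NA
  curve_na <- lod_scan(geno_na, y, map)
  expect_identical(curve_na$n_used[curve_na$marker_id == "m003"], 55L)

  expect_error(suppressWarnings(lod_scan(geno, rep(1, 60), map)),
               "no usable marker")
})

test_that("permutation threshold is the ceil-rank order statistic", {
  # degenerate fixture: all maxima equal c -> threshold = c
  expect_identical(permutation_quantile(rep(3.2, 50), alpha = 0.05), 3.2)
  # supplied null list of 20 values -> 19th smallest
  set.seed(31)
  vals <- rnorm(20)
  expect_identical(permutation_quantile(vals, alpha = 0.05),
                   sort(vals)[19])
  expect_error(permutation_quantile(vals, alpha = 0), "alpha")
  expect_error(permutation_quantile(vals, alpha = 1), "alpha")
})

test_that("permutation threshold is reproducible and id-label invariant", {
  map <- toy_map(12)
  geno <- simulate_backcross(map, 80, seed = 41)
  y <- rnorm(80)
  t1 <- permutation_threshold(geno, y, map, n_perm = 50, seed = 99)
  t2 <- permutation_threshold(geno, y, map, n_perm = 50, seed = 99)
  expect_identical(as.numeric(t1), as.numeric(t2))
  expect_length(attr(t1, "max_lods"), 50)

  relabeled <- geno
  rownames(relabeled) <- sprintf("mouse_%04d", seq_len(nrow(geno)))
  t3 <- permutation_threshold(relabeled, y, map, n_perm = 50, seed = 99)
  expect_identical(as.numeric(t1), as.numeric(t3))
})

test_that("support interval follows the drop rule and snaps to flanking markers", {
  mk_curve <- function(bp, lod) {
    structure(data.frame(marker_id = sprintf("m%02d", seq_along(bp)),
                         chromosome = "chr1", position_bp = bp,
                         position_cM = bp / 1e6, lod = lod,
                         n_used = 100L, stringsAsFactors = FALSE),
              class = c("lod_curve", "data.frame"))
  }

  # hand-trace: run >= 6.6 - 1.5 = 5.1 is [30,40] Mbp, extended to [20,50]
  cv <- mk_curve(c(10, 20, 30, 40, 50) * 1e6, c(2.0, 5.0, 6.6, 5.2, 4.0))
  si <- support_interval(cv, drop = 1.5)
  expect_identical(si$left_bp, 20e6)
  expect_identical(si$right_bp, 50e6)
  expect_identical(si$peak_marker, "m03")

  # single marker: interval collapses onto it
  s1 <- support_interval(mk_curve(5e6, 3), drop = 1.5)
  expect_identical(s1$left_bp, 5e6)
  expect_identical(s1$right_bp, 5e6)

  # flat curve: everything within drop of peak
  sf <- support_interval(mk_curve(c(1, 2, 3, 4) * 1e6, rep(2.5, 4)))
  expect_identical(sf$left_bp, 1e6)
  expect_identical(sf$right_bp, 4e6)

  # peak ties broken towards the smaller bp coordinate
  st <- support_interval(mk_curve(c(1, 2, 3) * 1e6, c(1, 4, 4)), drop = 0)
  expect_identical(st$peak_marker, "m02")

  # interval contains the peak and never narrows as drop grows
  set.seed(55)
  for (i in 1:20) {
    cvr <- mk_curve(seq(1e6, 20e6, by = 1e6), runif(20, 0, 8))
    a <- support_interval(cvr, drop = 1.0)
    b <- support_interval(cvr, drop = 2.5)
    expect_true(a$left_bp <= cvr$position_bp[which.max(cvr$lod)])
    expect_true(a$right_bp >= cvr$position_bp[which.max(cvr$lod)])
    expect_true(b$left_bp <= a$left_bp)
    expect_true(b$right_bp >= a$right_bp)
  }
})

test_that("peak LOD is monotone in the planted effect size", {
  map <- toy_map(15)
  geno <- simulate_backcross(map, 120, seed = 61)
  set.seed(61)
  noise <- rnorm(120)
  peaks <- vapply(c(0.25, 0.5, 1, 2, 4), function(eff) {
    max(lod_scan(geno, noise + eff * geno[, "m008"], map)$lod)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("allelic segregation computes per-week Welch statistics", {
  geno <- matrix(c(0L, 0L, 1L, 1L), 4, 1,
                 dimnames = list(c("a1", "a2", "a3", "a4"), "mk"))
  class(geno) <- c("backcross_genotypes", class(geno))

  ph <- toy_cohort(list(
    a1 = list(week = 1:2, glucose = c(300, 300)),
    a2 = list(week = 1:2, glucose = c(320, 320)),
    a3 = list(week = 1:2, glucose = c(200, 300)),
    a4 = list(week = 1:2, glucose = c(220, 320))))

  seg <- allelic_segregation(geno, "mk", ph)
  # week 1: [300,320] vs [200,220] -> diff 100, t = 7.071, df = 2
  w1 <- seg[seg$week == 1, ]
  expect_equal(w1$mean_0 - w1$mean_1, 100)
  expect_equal(w1$t, 100 / sqrt(200), tolerance = 1e-6)
  expect_equal(w1$df, 2, tolerance = 1e-9)
  oracle <- t.test(c(300, 320), c(200, 220))
  expect_equal(w1$p, oracle$p.value, tolerance = 1e-9)
  expect_equal(w1$t, unname(oracle$statistic), tolerance = 1e-9)

  # week 2: identical groups -> t = 0, p = 1
  w2 <- seg[seg$week == 2, ]
  expect_equal(w2$t, 0)
  expect_equal(w2$p, 1)

  # group of size 1 rejected
  geno1 <- matrix(c(0L, 1L, 1L, 1L), 4, 1,
                  dimnames = list(c("a1", "a2", "a3", "a4"), "mk"))
  class(geno1) <- c("backcross_genotypes", class(geno1))
  expect_error(allelic_segregation(geno1, "mk", ph), "at least 2")
})

test_that("full qtl analysis recovers a strongly planted locus", {
  map <- toy_map(20)
  geno <- simulate_backcross(map, 150, seed = 71)
  y <- rnorm(150) + 1.5 * geno[, "m012"]
  res <- qtl_analysis(geno, y, map, n_perm = 100, seed = 71)
  expect_s3_class(res, "qtl_result")
  expect_true(res$significant)
  expect_true(abs(map$position_cM[match(res$peak_marker, map$marker_id)] -
                    map$position_cM[12]) <= 11)
  si <- res$support_interval
  expect_true(si$left_bp <= map$position_bp[12] &&
                si$right_bp >= map$position_bp[12])
})
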