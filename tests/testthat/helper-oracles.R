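# Independent oracles and small fixture builders used across tests.

# brute-force per-position window assignment: loops positions x windows
brute_window_counts <- function(positions, region, window_bp) {
  len <- region$end_bp - region$start_bp
  n_win <- ceiling(len / window_bp)
  starts <- region$start_bp + (seq_len(n_win) - 1) * window_bp
  ends <- pmin(starts + window_bp, region$end_bp)
  counts <- integer(n_win)
  for (p in positions) {
    for (k in seq_len(n_win)) {
      if (p >= starts[k] && p < ends[k]) {
        counts[k] <- counts[k] + 1L
        break
      }
    }
  }
  data.frame(start_bp = starts, end_bp = ends, snp_count = counts)
}

# brute-force block merging from classified window classes
brute_merge <- function(starts, ends, counts, poly) {
  blocks <- list()
  i <- 1L
  while (i <= length(poly)) {
    if (poly[i]) {
      j <- i
      while (j < length(poly) && poly[j + 1L]) j <- j + 1L
      blocks[[length(blocks) + 1L]] <-
        c(start = starts[i], end = ends[j], total = sum(counts[i:j]),
          nw = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  blocks
}

# independent least-squares LOD oracle via lm(): anova residual sums
lm_lod_oracle <- function(g, y) {
  fit1 <- stats::lm(y ~ factor(g))
  fit0 <- stats::lm(y ~ 1)
  rss1 <- sum(stats::residuals(fit1)^2)
  rss0 <- sum(stats::residuals(fit0)^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

# evenly spaced single-chromosome map: m markers over span_cM
toy_map <- function(m, span_cM = 100, chrom = "chr1") {
  cm <- seq(0, span_cM, length.out = m)
  genetic_map(sprintf("m%03d", seq_len(m)), chrom,
              as.integer(1e6 + cm * 5e5), cm)
}

# long-format cohort table from a named list of (weeks, glucose) series
toy_cohort <- function(series, death_week = NULL) {
  rows <- lapply(names(series), function(a) {
    s <- series[[a]]
    data.frame(animal = a, group = "N/N", week = s$week,
               glucose = s$glucose,
               dead = if (!is.null(death_week) && !is.na(death_week[a]))
                 s$week == death_week[a] else FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(death_week)) attr(out, "death_week") <- death_week
  class(out) <- c("phenotype_table", "data.frame")
  out
}
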