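# Single-QTL marker-regression LOD scan for an N2 backcross, permutation
# genome-wide thresholds, 1.5-LOD support intervals and per-week allelic
# segregation.

#' LOD score of a single marker by marker regression
#'
#' In an N2 backcross each marker has two genotype classes (0 =
#' homozygous, 1 = heterozygous), so the single-QTL model is a two-group
#' mean comparison.  The LOD score is
#' `(n/2) * log10(RSS0 / RSS1)` with `RSS0` the residual sum of squares
#' about the grand mean and `RSS1` about the genotype-group means; for
#' binary genotypes this equals `-(n/2) * log10(1 - r^2)` for the
#' genotype-phenotype correlation `r`.
#'
#' @param genotypes_at_marker vector of 0/1 codes (NA allowed).
#' @param phenotype numeric phenotype aligned to the genotypes.
#' @return the LOD score; `NA` with a warning when a genotype class has
#'   fewer than 2 informative individuals or the phenotype is constant;
#'   `Inf` with a warning when the genotype fit is perfect (`RSS1 = 0`).
#' @examples
#' marker_lod(c(0, 0, 1, 1), c(1, 2, 3, 4))  # 1.39794
#' @export
marker_lod <- function(genotypes_at_marker, phenotype) {
  .assert(length(genotypes_at_marker) == length(phenotype),
          "genotype and phenotype lengths differ")
  keep <- !is.na(genotypes_at_marker) & !is.na(phenotype)
  g <- genotypes_at_marker[keep]
  y <- phenotype[keep]
  .assert(all(g %in% c(0, 1)), "genotype codes must be 0/1")
  n0 <- sum(g == 0); n1 <- sum(g == 1)
  if (n0 < 2L || n1 < 2L) {
    warning("marker skipped: a genotype class has fewer than 2 individuals")
    return(NA_real_)
  }
  rss0 <- sum((y - mean(y))^2)
  if (rss0 == 0) {
    warning("marker skipped: phenotype has zero variance")
    return(NA_real_)
  }
  fitted <- ifelse(g == 1, mean(y[g == 1]), mean(y[g == 0]))
  rss1 <- sum((y - fitted)^2)
  if (rss1 == 0) {
    warning("perfect genotype fit: LOD reported as +Inf")
    return(Inf)
  }
  (length(y) / 2) * log10(rss0 / rss1)
}

# Vectorised LOD over markers for complete data: G is an n x m 0/1 matrix,
# Y an n x p matrix of phenotype columns; returns a p x m LOD matrix via
# the correlation identity.  Used by the scan fast path and permutations.
.lod_matrix <- function(G, Y) {
  n <- nrow(G)
  Gs <- scale(G)
  Ys <- scale(Y)
  r <- crossprod(Ys, Gs) / (n - 1)
  r2 <- pmin(r * r, 1)
  -(n / 2) * log10(1 - r2)
}

# markers usable for scanning/permutation: both classes have >= 2 members
.usable_markers <- function(geno) {
  n1 <- colSums(geno == 1L, na.rm = TRUE)
  n0 <- colSums(geno == 0L, na.rm = TRUE)
  n1 >= 2L & n0 >= 2L
}

#' Genome scan: LOD at every genotyped marker
#'
#' Applies [marker_lod()] at each marker with per-marker casewise deletion
#' of missing data; the returned curve is ordered by map position.
#'
#' @param genotypes individuals x markers 0/1 matrix (NA = missing), e.g.
#'   from [simulate_backcross()].
#' @param phenotype numeric vector aligned to the rows of `genotypes`.
#' @param map a [genetic_map()] covering the genotyped markers.
#' @return A `data.frame` of class `lod_curve` with columns `marker_id`,
#'   `chromosome`, `position_bp`, `position_cM`, `lod`, `n_used`, ordered
#'   by map position.  Markers skipped for degeneracy are dropped with a
#'   warning; an error is raised if no marker is usable.
#' @export
lod_scan <- function(genotypes, phenotype, map) {
  .assert(inherits(map, "genetic_map"), "map must be a genetic_map")
  .assert(nrow(genotypes) == length(phenotype),
          "phenotype must align to genotype rows")
  common <- intersect(map$marker_id, colnames(genotypes))
  .assert(length(common) >= 1, "no genotyped marker found in the map")
  map <- map[map$marker_id %in% common, , drop = FALSE]

  lod <- n_used <- numeric(nrow(map))
  for (j in seq_len(nrow(map))) {
    g <- genotypes[, map$marker_id[j]]
    keep <- !is.na(g) & !is.na(phenotype)
    n_used[j] <- sum(keep)
    lod[j] <- suppressWarnings(marker_lod(g, phenotype))
  }
  ok <- !is.na(lod)
  if (!all(ok)) {
    warning(sprintf("%d marker(s) skipped (degenerate genotype class or phenotype)",
                    sum(!ok)))
  }
  .assert(any(ok), "no usable marker: scan rejected")
  out <- data.frame(marker_id = map$marker_id[ok],
                    chromosome = map$chromosome[ok],
                    position_bp = map$position_bp[ok],
                    position_cM = map$position_cM[ok],
                    lod = lod[ok],
                    n_used = as.integer(n_used[ok]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("lod_curve", "data.frame")
  out
}

#' Genome-wide LOD threshold by phenotype permutation
#'
#' Permutes phenotype labels against the intact genotype rows `n_perm`
#' times, records the genome-wide maximum LOD of each permutation, and
#' returns the ceil-rank `(1 - alpha)` order statistic of those maxima —
#' the standard permutation estimate of the genome-wide significance
#' threshold.
#'
#' @inheritParams lod_scan
#' @param n_perm number of permutations (>= 1; 100 is the conventional
#'   small-scan default).
#' @param alpha genome-wide type-I error rate, in (0, 1).
#' @param seed integer seed for the permutation stream.
#' @return the threshold (numeric scalar) with the sorted per-permutation
#'   maxima attached as attribute `max_lods`.
#' @export
permutation_threshold <- function(genotypes, phenotype, map = NULL,
                                  n_perm = 100L, alpha = 0.05, seed = 1L) {
  .assert(.is_count(n_perm, 1L), "n_perm must be an integer >= 1")
  .assert(.is_number(alpha) && alpha > 0 && alpha < 1,
          "alpha must be strictly between 0 and 1")
  .assert(nrow(genotypes) == length(phenotype),
          "phenotype must align to genotype rows")
  .assert(stats::sd(phenotype, na.rm = TRUE) > 0,
          "phenotype has zero variance")
  set.seed(.substream(seed, 101L))

  complete <- !anyNA(genotypes) && !anyNA(phenotype)
  if (complete) {
    usable <- .usable_markers(genotypes)
    .assert(any(usable), "no usable marker for permutation")
    G <- genotypes[, usable, drop = FALSE]
    n <- length(phenotype)
    P <- vapply(seq_len(n_perm), function(i) phenotype[sample.int(n)],
                numeric(n))
    lods <- .lod_matrix(G, P)
    max_lods <- apply(lods, 1L, max)
  } else {
    .assert(inherits(map, "genetic_map"),
            "map is required when genotypes contain missing values")
    max_lods <- vapply(seq_len(n_perm), function(i) {
      perm <- phenotype[sample.int(length(phenotype))]
      max(suppressWarnings(lod_scan(genotypes, perm, map))$lod)
    }, numeric(1))
  }
  thr <- permutation_quantile(max_lods, alpha)
  attr(thr, "max_lods") <- sort(max_lods)
  thr
}

#' Ceil-rank order statistic of permutation maxima
#'
#' Given a vector of per-permutation genome-wide maximum LODs, the
#' threshold is the `ceiling((1 - alpha) * n)`-th smallest value — a
#' conservative quantile for small permutation counts.
#'
#' @param max_lods numeric vector of permutation maxima.
#' @param alpha genome-wide type-I error rate.
#' @return the threshold.
#' @export
permutation_quantile <- function(max_lods, alpha = 0.05) {
  .assert(length(max_lods) >= 1, "need at least one permutation maximum")
  .assert(.is_number(alpha) && alpha > 0 && alpha < 1,
          "alpha must be strictly between 0 and 1")
  sort(max_lods)[ceiling((1 - alpha) * length(max_lods))]
}

#' 1.5-LOD support interval snapped to genotyped markers
#'
#' Finds the maximal contiguous run of markers around the peak whose LOD
#' stays within `drop` of the peak LOD, then extends each end outward by
#' one genotyped marker where one exists — the "LOD drop interval plus the
#' nearest genotyping marker" convention for reporting QTL confidence
#' intervals.  Peak ties are broken towards the smaller bp coordinate.
#'
#' @param curve a `lod_curve` from [lod_scan()] (single chromosome).
#' @param drop LOD units defining the support interval (default 1.5).
#' @return list with `left_marker`, `right_marker`, `left_bp`, `right_bp`,
#'   `peak_marker`, `peak_lod`.
#' @export
support_interval <- function(curve, drop = 1.5) {
  .assert(inherits(curve, "lod_curve") && nrow(curve) >= 1,
          "curve must be a non-empty lod_curve")
  .assert(.is_number(drop) && drop >= 0, "drop must be >= 0")
  .assert(length(unique(curve$chromosome)) == 1L,
          "support interval is defined per chromosome")
  curve <- curve[order(curve$position_bp), , drop = FALSE]
  peak <- which(curve$lod == max(curve$lod))[1L]  # tie -> lowest bp
  keep <- curve$lod >= curve$lod[peak] - drop
  left <- peak
  while (left > 1L && keep[left - 1L]) left <- left - 1L
  right <- peak
  while (right < nrow(curve) && keep[right + 1L]) right <- right + 1L
  # snap outward to the nearest flanking genotyped marker
  left <- max(1L, left - 1L)
  right <- min(nrow(curve), right + 1L)
  list(left_marker = curve$marker_id[left],
       right_marker = curve$marker_id[right],
       left_bp = curve$position_bp[left],
       right_bp = curve$position_bp[right],
       peak_marker = curve$marker_id[peak],
       peak_lod = curve$lod[peak])
}

#' Full single-QTL analysis: scan, threshold, support interval
#'
#' @inheritParams permutation_threshold
#' @param drop LOD drop for the support interval.
#' @return list of class `qtl_result` with `curve`, `peak_marker`,
#'   `peak_lod`, `threshold`, `significant` and `support_interval`.
#' @export
qtl_analysis <- function(genotypes, phenotype, map, n_perm = 100L,
                         alpha = 0.05, drop = 1.5, seed = 1L) {
  curve <- lod_scan(genotypes, phenotype, map)
  thr <- permutation_threshold(genotypes, phenotype, map,
                               n_perm = n_perm, alpha = alpha, seed = seed)
  si <- support_interval(curve, drop = drop)
  structure(list(curve = curve,
                 peak_marker = si$peak_marker,
                 peak_lod = si$peak_lod,
                 threshold = as.numeric(thr),
                 significant = si$peak_lod >= as.numeric(thr),
                 support_interval = si[c("left_marker", "right_marker",
                                         "left_bp", "right_bp")]),
            class = "qtl_result")
}

#' Per-week allelic segregation at a marker
#'
#' Splits the cohort by genotype at one marker and compares the weekly
#' phenotype between the two allele groups: per-week group means, SEMs,
#' and a Welch two-sample t statistic with Satterthwaite degrees of
#' freedom.
#'
#' @param genotypes `backcross_genotypes` matrix.
#' @param marker_id marker used to split the cohort.
#' @param pheno a `phenotype_table` (long format).
#' @param value phenotype column to compare (default `"glucose"`).
#' @return data.frame with one row per week: `week`, `n_0`, `mean_0`,
#'   `sem_0`, `n_1`, `mean_1`, `sem_1`, `t`, `df`, `p` (groups labelled by
#'   genotype code 0/1).  Weeks with fewer than 2 observations in a group
#'   carry NA statistics.
#' @export
allelic_segregation <- function(genotypes, marker_id, pheno,
                                value = "glucose") {
  .assert(marker_id %in% colnames(genotypes), "unknown marker")
  .assert(inherits(pheno, "phenotype_table"), "pheno must be a phenotype_table")
  .assert(value %in% names(pheno), sprintf("no column '%s'", value))
  g <- genotypes[, marker_id]
  grp <- g[pheno$animal]
  .assert(sum(g == 0, na.rm = TRUE) >= 2 && sum(g == 1, na.rm = TRUE) >= 2,
          "each allele group needs at least 2 animals")
  weeks <- sort(unique(pheno$week))
  rows <- lapply(weeks, function(w) {
    sel <- pheno$week == w & !is.na(pheno[[value]]) & !is.na(grp)
    y0 <- pheno[[value]][sel & grp == 0]
    y1 <- pheno[[value]][sel & grp == 1]
    st <- welch_t(y0, y1)
    data.frame(week = w,
               n_0 = length(y0), mean_0 = mean(y0), sem_0 = stats::sd(y0) / sqrt(length(y0)),
               n_1 = length(y1), mean_1 = mean(y1), sem_1 = stats::sd(y1) / sqrt(length(y1)),
               t = st$t, df = st$df, p = st$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch two-sample comparison
#'
#' Plain Welch t statistic with Satterthwaite degrees of freedom and
#' two-sided p value.  Groups of fewer than 2 observations yield NA; two
#' zero-variance groups yield `t = 0, p = 1` when means agree and
#' `|t| = Inf, p = 0` otherwise.
#'
#' @param x,y numeric vectors (the two groups).
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_diff = if (length(x) && length(y)) mean(x) - mean(y) else NA_real_))
  }
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  d <- mean(x) - mean(y)
  if (v1 + v2 == 0) {
    if (d == 0) return(list(t = 0, df = NA_real_, p = 1, mean_diff = 0))
    return(list(t = sign(d) * Inf, df = NA_real_, p = 0, mean_diff = d))
  }
  tt <- d / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), mean_diff = d)
}

#' Write a LOD curve as TSV / a QTL result as JSON
#'
#' @param curve a `lod_curve`; `result` a `qtl_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lod_curve <- function(curve, path) {
  .assert(inherits(curve, "lod_curve"), "curve must be a lod_curve")
  out <- curve
  out$lod <- .fmt_num(out$lod)
  .write_tsv(out, path)
}

#' @rdname write_lod_curve
#' @param result a `qtl_result`.
#' @export
write_qtl_result <- function(result, path) {
  .assert(inherits(result, "qtl_result"), "result must be a qtl_result")
  jsonlite::write_json(result[c("peak_marker", "peak_lod", "threshold",
                                "significant", "support_interval")],
                       path, auto_unbox = TRUE, digits = 8, pretty = TRUE)
  invisible(path)
}
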