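# Tissue-specificity scoring of a gene x (strain, tissue) expression
# matrix and qPCR delta-Ct relative expression.

#' Construct / read an expression matrix
#'
#' Columns are named `strain.tissue` (e.g. `NZO.islet`).  All values must
#' be positive linear-scale intensities; zeros and negatives are floored at
#' a pseudo-value (default: half the smallest positive value in the matrix)
#' with a warning, so that log-ratios stay defined.
#'
#' @param values numeric matrix, genes x conditions, with `strain.tissue`
#'   column names and gene ids as rownames.
#' @param pseudo_value optional explicit floor for non-positive entries.
#' @return a matrix of class `expression_matrix`.
#' @export
expression_matrix <- function(values, pseudo_value = NULL) {
  .assert(is.matrix(values) && is.numeric(values), "numeric matrix required")
  .assert(!is.null(rownames(values)) && !is.null(colnames(values)),
          "gene rownames and strain.tissue colnames required")
  .assert(all(grepl("^[^.]+\\.[^.]+$", colnames(values))),
          "column names must follow strain.tissue")
  if (any(values <= 0)) {
    floor_ <- pseudo_value %||% (min(values[values > 0]) / 2)
    .assert(.is_number(floor_) && floor_ > 0,
            "no positive values to derive a pseudo-value from")
    warning(sprintf("%d non-positive value(s) floored at %g",
                    sum(values <= 0), floor_))
    values[values <= 0] <- floor_
  }
  if (!inherits(values, "expression_matrix")) {
    class(values) <- c("expression_matrix", class(values))
  }
  values
}

#' @rdname expression_matrix
#' @param path CSV with first column `gene`, remaining columns
#'   `strain.tissue`.
#' @export
read_expression_matrix <- function(path, pseudo_value = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  expression_matrix(m, pseudo_value)
}

#' @rdname expression_matrix
#' @param x an `expression_matrix`.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.parse_conditions <- function(m) {
  parts <- strsplit(colnames(m), ".", fixed = TRUE)
  data.frame(column = colnames(m),
             strain = vapply(parts, `[`, character(1), 1L),
             tissue = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Tissue-specificity Z-scores of an expression matrix
#'
#' For every strain `s` and every non-target tissue `t`, the per-gene
#' log2 ratio `L(g) = log2(x[g, s, target] / x[g, s, t])` is standardized
#' across genes into a Z-score using the population (n-denominator) SD.
#' The per-gene scores are combined over all (strain, comparison) cells by
#' the minimum (default) — a gene scores high only when it is enriched in
#' the target tissue in *all* strains versus *all* tissues — or by the
#' mean.  `ratio_scale = "linear"` skips the log transform.
#'
#' @param m an [expression_matrix()].
#' @param target_tissue tissue whose specificity is scored (default
#'   `"islet"`).
#' @param combine `"min"` (default) or `"mean"` across cells.
#' @param ratio_scale `"log2"` (default) or `"linear"`.
#' @return A `data.frame` of class `specificity_scores`: `gene`, one
#'   Z-score column per `strain.tissue` comparison cell, `combined`, and
#'   `rank` (1 = most specific), sorted by descending combined score.
#' @export
specificity_zscores <- function(m, target_tissue = "islet",
                                combine = c("min", "mean"),
                                ratio_scale = c("log2", "linear")) {
  combine <- match.arg(combine)
  ratio_scale <- match.arg(ratio_scale)
  .assert(inherits(m, "expression_matrix"),
          "m must be an expression_matrix (see expression_matrix())")
  .assert(nrow(m) >= 3, "at least 3 genes required to standardize scores")
  cond <- .parse_conditions(m)
  strains <- unique(cond$strain)
  for (s in strains) {
    .assert(target_tissue %in% cond$tissue[cond$strain == s],
            sprintf("strain %s lacks the target tissue", s))
    .assert(length(setdiff(cond$tissue[cond$strain == s], target_tissue)) >= 1,
            sprintf("strain %s lacks a comparison tissue", s))
  }
  z <- list()
  for (s in strains) {
    tcol <- cond$column[cond$strain == s & cond$tissue == target_tissue]
    for (t in setdiff(cond$tissue[cond$strain == s], target_tissue)) {
      ocol <- cond$column[cond$strain == s & cond$tissue == t]
      ratio <- m[, tcol] / m[, ocol]
      L <- if (ratio_scale == "log2") log2(ratio) else ratio
      sd_ <- .pop_sd(L)
      if (sd_ == 0) {
        warning(sprintf("degenerate cell %s.%s: all ratios equal, scores set to 0",
                        s, t))
        z[[paste(s, t, sep = ".")]] <- rep(0, nrow(m))
      } else {
        z[[paste(s, t, sep = ".")]] <- (L - mean(L)) / sd_
      }
    }
  }
  zm <- do.call(cbind, z)
  combined <- if (combine == "min") apply(zm, 1L, min) else rowMeans(zm)
  out <- data.frame(gene = rownames(m), zm, combined = combined,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(-out$combined, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("specificity_scores", "data.frame")
  out
}

#' Select target-tissue-specific candidate genes
#'
#' @param scores a [specificity_zscores()] result.
#' @param min_combined_z minimum combined Z-score.
#' @return character vector of gene ids with `combined >= min_combined_z`,
#'   sorted by descending combined score.
#' @export
select_candidates <- function(scores, min_combined_z) {
  .assert(inherits(scores, "specificity_scores"), "specificity_scores required")
  .assert(is.numeric(min_combined_z) && length(min_combined_z) == 1L,
          "min_combined_z must be a single number")
  scores$gene[scores$combined >= min_combined_z]
}

#' Relative expression by the delta-Ct method
#'
#' Relative expression of a target gene against a housekeeping reference:
#' `2^-(Ct_target - Ct_reference)`.  Strictly decreasing in the target Ct.
#'
#' @param target_ct,reference_ct finite cycle-threshold values (vectors
#'   recycle).
#' @return positive relative expression values.
#' @examples
#' delta_ct_relative_expression(25, 20)  # 0.03125
#' @export
delta_ct_relative_expression <- function(target_ct, reference_ct) {
  .assert(is.numeric(target_ct) && is.numeric(reference_ct),
          "Ct values must be numeric")
  .assert(all(is.finite(target_ct)) && all(is.finite(reference_ct)),
          "non-finite Ct rejected")
  2 ^ (-(target_ct - reference_ct))
}

#' Two-group qPCR comparison on the relative-expression scale
#'
#' Converts per-sample Ct pairs to relative expression, then compares two
#' groups: fold change of group means (`group_a / group_b`) and a
#' two-sided Welch test on the relative expressions.
#'
#' @param qpcr data.frame with columns `sample`, `group`, `target_ct`,
#'   `reference_ct` (as produced by [simulate_qpcr()]).
#' @param group_a,group_b group labels; defaults: first two label values in
#'   order of appearance.
#' @return list with `fold_change`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   and the per-sample `relative_expression` vector.
#' @export
qpcr_group_comparison <- function(qpcr, group_a = NULL, group_b = NULL) {
  .assert(all(c("group", "target_ct", "reference_ct") %in% names(qpcr)),
          "qpcr table needs group, target_ct, reference_ct")
  labels <- unique(qpcr$group)
  group_a <- group_a %||% labels[1L]
  group_b <- group_b %||% labels[2L]
  .assert(all(c(group_a, group_b) %in% labels), "unknown group label")
  rel <- delta_ct_relative_expression(qpcr$target_ct, qpcr$reference_ct)
  a <- rel[qpcr$group == group_a]
  b <- rel[qpcr$group == group_b]
  st <- welch_t(a, b)
  list(fold_change = mean(a) / mean(b), mean_a = mean(a), mean_b = mean(b),
       t = st$t, df = st$df, p = st$p, relative_expression = rel)
}
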