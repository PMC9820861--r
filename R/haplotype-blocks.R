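# IBD vs polymorphic haplotype structure between inbred strains: discordant
# SNP extraction, fixed-window density counting, dialect-based window
# classification and block merging.

#' Positions where two strains carry discordant alleles
#'
#' @param catalog a `snp_catalog` (columns `chrom`, `pos`, plus one allele
#'   column per strain; missing calls as NA or `"."`).
#' @param strain_a,strain_b column names of the two strains (default
#'   `"C3H"`, `"NZO"`).
#' @return sorted unique integer positions where both strains are called
#'   and the calls differ.
#' @export
discordant_positions <- function(catalog, strain_a = "C3H", strain_b = "NZO") {
  .assert(inherits(catalog, "data.frame"), "catalog must be a data.frame")
  .assert(strain_a %in% names(catalog),
          sprintf("unknown strain label '%s'", strain_a))
  .assert(strain_b %in% names(catalog),
          sprintf("unknown strain label '%s'", strain_b))
  .assert(length(unique(catalog$chrom)) <= 1L,
          "discordant_positions operates on a single chromosome")
  a <- as.character(catalog[[strain_a]])
  b <- as.character(catalog[[strain_b]])
  called <- !is.na(a) & !is.na(b) & a != "." & b != "."
  sort(unique(as.integer(catalog$pos[called & a != b])))
}

#' Count SNPs in non-overlapping tiling windows
#'
#' Tiles the region `[start, end)` with half-open windows
#' `[start + k*w, start + (k+1)*w)` (the last window truncated at the
#' region end) and counts the positions falling in each; a position exactly
#' on a boundary belongs to the right-hand window.
#'
#' @param positions sorted SNP positions (1-based bp).
#' @param region list with `chrom`, `start_bp`, `end_bp` (half-open).
#' @param window_bp window width in bp (> 0).
#' @return A `data.frame` of class `window_set` with columns `chrom`,
#'   `start_bp`, `end_bp`, `snp_count`; attributes `window_bp` and
#'   `region`.  Window counts sum to the number of in-region positions.
#' @export
window_counts <- function(positions, region, window_bp) {
  .assert(is.list(region) && all(c("chrom", "start_bp", "end_bp") %in% names(region)),
          "region must be list(chrom, start_bp, end_bp)")
  .assert(region$end_bp > region$start_bp, "empty region rejected")
  .assert(.is_number(window_bp) && window_bp > 0, "window_bp must be > 0")
  len <- region$end_bp - region$start_bp
  n_win <- ceiling(len / window_bp)
  starts <- region$start_bp + (seq_len(n_win) - 1L) * window_bp
  ends <- pmin(starts + window_bp, region$end_bp)
  pos <- positions[positions >= region$start_bp & positions < region$end_bp]
  idx <- floor((pos - region$start_bp) / window_bp) + 1L
  counts <- tabulate(idx, nbins = n_win)
  out <- data.frame(chrom = region$chrom,
                    start_bp = as.numeric(starts),
                    end_bp = as.numeric(ends),
                    snp_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "window_bp") <- window_bp
  attr(out, "region") <- region
  class(out) <- c("window_set", "data.frame")
  out
}

#' Classify windows as IBD or polymorphic
#'
#' Two published dialects of the density rule are supported:
#' `"150kb"` — 150,000 bp windows, polymorphic iff strictly more than 50
#' discordant SNPs; `"250kb"` — 250,000 bp windows, polymorphic iff at
#' least 100 SNPs.  The window width of the input must match the dialect.
#' `min_count`/`strict` allow custom rules under `dialect = "custom"`.
#'
#' @param window_set a counted [window_counts()] result.
#' @param dialect `"150kb"` (default), `"250kb"`, or `"custom"`.
#' @param min_count,strict for `dialect = "custom"`: polymorphic iff
#'   `count > min_count` (strict) or `count >= min_count`.
#' @return the `window_set` with an added `class` column
#'   (`"POLYMORPHIC"`/`"IBD"`).
#' @export
classify_windows <- function(window_set, dialect = c("150kb", "250kb", "custom"),
                             min_count = NULL, strict = NULL) {
  .assert(inherits(window_set, "window_set"), "window_set required")
  dialect <- match.arg(dialect)
  w <- attr(window_set, "window_bp")
  if (dialect == "150kb") {
    .assert(w == 150000, "150kb dialect requires 150,000 bp windows")
    min_count <- 50L; strict <- TRUE     # "more than 50" -> strict >
  } else if (dialect == "250kb") {
    .assert(w == 250000, "250kb dialect requires 250,000 bp windows")
    min_count <- 100L; strict <- FALSE   # "threshold of 100" -> >=
  } else {
    .assert(.is_count(min_count, 0L), "min_count required for custom dialect")
    .assert(is.logical(strict) && length(strict) == 1L,
            "strict (TRUE/FALSE) required for custom dialect")
  }
  poly <- if (strict) window_set$snp_count > min_count
          else window_set$snp_count >= min_count
  window_set$class <- ifelse(poly, "POLYMORPHIC", "IBD")
  attr(window_set, "dialect") <- dialect
  attr(window_set, "min_count") <- min_count
  attr(window_set, "strict") <- strict
  window_set
}

#' Merge adjacent polymorphic windows into blocks
#'
#' Maximal runs of consecutive POLYMORPHIC windows become one block whose
#' `total_snps` is the sum of the member window counts.
#'
#' @param classified a [classify_windows()] result.
#' @return A `data.frame` of class `polymorphic_blocks` with columns
#'   `chrom`, `start_bp`, `end_bp`, `total_snps`, `n_windows` (possibly
#'   zero rows).
#' @export
merge_blocks <- function(classified) {
  .assert(inherits(classified, "window_set") && "class" %in% names(classified),
          "windows must be classified first")
  poly <- classified$class == "POLYMORPHIC"
  empty <- data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), total_snps = integer(0),
                      n_windows = integer(0), stringsAsFactors = FALSE)
  if (!any(poly)) {
    class(empty) <- c("polymorphic_blocks", "data.frame")
    return(empty)
  }
  r <- rle(poly)
  stop_idx <- cumsum(r$lengths)
  start_idx <- stop_idx - r$lengths + 1L
  keep <- which(r$values)
  rows <- lapply(keep, function(k) {
    i <- start_idx[k]:stop_idx[k]
    data.frame(chrom = classified$chrom[i[1L]],
               start_bp = classified$start_bp[i[1L]],
               end_bp = classified$end_bp[i[length(i)]],
               total_snps = sum(classified$snp_count[i]),
               n_windows = length(i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("polymorphic_blocks", "data.frame")
  out
}

#' Count SNP positions in a half-open interval
#'
#' @param positions SNP positions.
#' @param start_bp,end_bp interval `[start, end)`.
#' @return integer count.
#' @export
interval_snp_count <- function(positions, start_bp, end_bp) {
  .assert(.is_number(start_bp) && .is_number(end_bp) && end_bp >= start_bp,
          "interval must be well-formed")
  sum(positions >= start_bp & positions < end_bp)
}

#' Call polymorphic blocks from a SNP catalog in one step
#'
#' Convenience chain: [discordant_positions()] -> [window_counts()] ->
#' [classify_windows()] -> [merge_blocks()].
#'
#' @inheritParams discordant_positions
#' @param region analysed interval (defaults to the catalog's recorded
#'   region).
#' @inheritParams classify_windows
#' @return list with `positions`, `windows` (classified) and `blocks`.
#' @export
call_polymorphic_blocks <- function(catalog, region = NULL,
                                    dialect = c("150kb", "250kb", "custom"),
                                    strain_a = "C3H", strain_b = "NZO",
                                    min_count = NULL, strict = NULL) {
  dialect <- match.arg(dialect)
  region <- region %||% attr(catalog, "region")
  .assert(!is.null(region), "region required (none recorded in catalog)")
  window_bp <- switch(dialect, "150kb" = 150000, "250kb" = 250000,
                      custom = {
                        .assert(!is.null(attr(catalog, "window_bp")),
                                "custom dialect needs window_bp via window_counts")
                        attr(catalog, "window_bp")
                      })
  pos <- discordant_positions(catalog, strain_a, strain_b)
  ws <- window_counts(pos, region, window_bp)
  cls <- classify_windows(ws, dialect, min_count = min_count, strict = strict)
  list(positions = pos, windows = cls, blocks = merge_blocks(cls))
}

#' Write window sets and polymorphic blocks
#'
#' Windows are written as TSV (1-based half-open bp); blocks as BED
#' (0-based half-open) plus a JSON summary.
#'
#' @param windows a classified `window_set`.
#' @param blocks a `polymorphic_blocks` table.
#' @param path,prefix output file / file prefix.
#' @return written path(s), invisibly.
#' @export
write_window_set <- function(windows, path) {
  .assert(inherits(windows, "window_set"), "window_set required")
  .write_tsv(windows, path)
}

#' @rdname write_window_set
#' @export
write_blocks <- function(blocks, prefix) {
  .assert(inherits(blocks, "polymorphic_blocks"), "polymorphic_blocks required")
  bed_path <- paste0(prefix, ".bed")
  json_path <- paste0(prefix, ".json")
  bed <- data.frame(chrom = blocks$chrom,
                    start = format(blocks$start_bp - 1, scientific = FALSE, trim = TRUE),
                    end = format(blocks$end_bp - 1, scientific = FALSE, trim = TRUE),
                    name = sprintf("block%02d", seq_len(nrow(blocks))),
                    score = blocks$total_snps,
                    strand = rep(".", nrow(blocks)))
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(n_blocks = nrow(blocks),
                            total_snps = sum(blocks$total_snps),
                            blocks = blocks),
                       json_path, auto_unbox = TRUE, digits = 8, pretty = TRUE)
  invisible(c(bed_path, json_path))
}
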