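# Candidate-gene prioritization: consequence impact + SIFT filtering,
# restriction to polymorphic blocks, and conservation of mutated residues.

.IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Filter annotated variants by impact class and SIFT deleteriousness
#'
#' A gene is retained when it carries at least one variant that is either
#' HIGH impact (unconditionally) or MODERATE impact with a SIFT score
#' strictly below `sift_cutoff` (default 0.5; lower SIFT = more likely
#' deleterious).  LOW and MODIFIER variants never qualify.  MODERATE
#' variants without a SIFT score are excluded by default
#' (`include_missing_sift = TRUE` relaxes this).  Per retained gene the
#' best evidence is reported: HIGH beats any SIFT score, otherwise the
#' minimum SIFT among qualifying variants.
#'
#' @param annotations a `variant_annotation` data.frame (columns `gene_id`,
#'   `symbol`, `impact`, `sift`, ...).  Records with a malformed impact
#'   label are rejected with a warning (not silently dropped).
#' @param sift_cutoff strict SIFT cutoff (default 0.5).
#' @param include_missing_sift treat MODERATE variants lacking a SIFT score
#'   as qualifying (default FALSE).
#' @return data.frame with one row per retained gene: `gene_id`, `symbol`,
#'   `impact` (best qualifying class), `min_sift` (NA when the evidence is
#'   a HIGH variant without score), `n_qualifying`.
#' @export
filter_by_impact <- function(annotations, sift_cutoff = 0.5,
                             include_missing_sift = FALSE) {
  .assert(inherits(annotations, "data.frame") && nrow(annotations) >= 1,
          "annotations must be a non-empty data.frame")
  .assert(all(c("gene_id", "impact") %in% names(annotations)),
          "annotations need gene_id and impact columns")
  .assert(.is_number(sift_cutoff) && sift_cutoff >= 0 && sift_cutoff <= 1,
          "sift_cutoff must be in [0, 1]")
  bad <- !(annotations$impact %in% .IMPACT_LEVELS)
  if (any(bad)) {
    warning(sprintf("%d record(s) with malformed impact label rejected: %s",
                    sum(bad),
                    paste(unique(annotations$impact[bad]), collapse = ", ")))
    annotations <- annotations[!bad, , drop = FALSE]
    .assert(nrow(annotations) >= 1, "no well-formed annotation records left")
  }
  sift <- annotations$sift %||% rep(NA_real_, nrow(annotations))
  .assert(all(is.na(sift) | (sift >= 0 & sift <= 1)),
          "sift scores must lie in [0, 1]")
  qualifies <- annotations$impact == "HIGH" |
    (annotations$impact == "MODERATE" &
       (ifelse(is.na(sift), include_missing_sift, sift < sift_cutoff)))
  hits <- annotations[qualifies, , drop = FALSE]
  if (!nrow(hits)) {
    out <- data.frame(gene_id = character(0), symbol = character(0),
                      impact = character(0), min_sift = numeric(0),
                      n_qualifying = integer(0), stringsAsFactors = FALSE)
    return(out)
  }
  rows <- lapply(split(hits, hits$gene_id), function(h) {
    has_high <- any(h$impact == "HIGH")
    ms <- suppressWarnings(min(h$sift, na.rm = TRUE))
    data.frame(gene_id = h$gene_id[1L],
               symbol = (h$symbol %||% h$gene_id)[1L],
               impact = if (has_high) "HIGH" else "MODERATE",
               min_sift = if (is.finite(ms)) ms else NA_real_,
               n_qualifying = nrow(h),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes overlapping polymorphic blocks within a locus
#'
#' A gene is retained iff its span overlaps at least one polymorphic block
#' (non-empty intersection of half-open intervals) and lies within the
#' locus interval.  A gene abutting a block end-to-start does not overlap
#' under the half-open convention.
#'
#' @param genes a [gene_table()] (half-open `[start_bp, end_bp)`).
#' @param blocks a `polymorphic_blocks` table (same convention).
#' @param locus optional list `(start_bp, end_bp)`; genes must lie within
#'   it (default: no locus restriction).
#' @return the retained subset of `genes` with added columns `n_blocks`
#'   (overlapping block count) and `block_snps` (total SNPs of overlapped
#'   blocks).
#' @export
genes_in_blocks <- function(genes, blocks, locus = NULL) {
  .assert(inherits(genes, "data.frame") &&
            all(c("gene_id", "start_bp", "end_bp") %in% names(genes)),
          "genes must have gene_id, start_bp, end_bp")
  .assert(inherits(blocks, "data.frame") &&
            all(c("start_bp", "end_bp") %in% names(blocks)),
          "blocks must have start_bp, end_bp")
  .assert(all(genes$end_bp > genes$start_bp), "malformed gene interval")
  if (nrow(blocks)) {
    .assert(all(blocks$end_bp > blocks$start_bp), "malformed block interval")
  }
  in_locus <- if (is.null(locus)) rep(TRUE, nrow(genes)) else {
    .assert(locus$end_bp > locus$start_bp, "malformed locus interval")
    genes$start_bp >= locus$start_bp & genes$end_bp <= locus$end_bp
  }
  n_blocks <- integer(nrow(genes))
  block_snps <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    hit <- genes$start_bp[i] < blocks$end_bp &
      blocks$start_bp < genes$end_bp[i]
    n_blocks[i] <- sum(hit)
    block_snps[i] <- if (any(hit)) sum(blocks$total_snps[hit] %||% 0L) else 0L
  }
  out <- genes[in_locus & n_blocks > 0L, , drop = FALSE]
  out$n_blocks <- n_blocks[in_locus & n_blocks > 0L]
  out$block_snps <- block_snps[in_locus & n_blocks > 0L]
  rownames(out) <- NULL
  out
}

#' Construct / read a protein multiple sequence alignment
#'
#' @param sequences named character vector of equal-length aligned protein
#'   sequences (gap character `-`).
#' @param reference name of the reference sequence, used for ungapped
#'   coordinate mapping.
#' @return object of class `msa`.
#' @export
msa <- function(sequences, reference) {
  .assert(is.character(sequences) && length(sequences) >= 2,
          "need at least two aligned sequences")
  .assert(!is.null(names(sequences)) && !anyDuplicated(names(sequences)),
          "sequences must have unique names")
  .assert(length(unique(nchar(sequences))) == 1L,
          "aligned sequences must have equal length")
  .assert(reference %in% names(sequences), "reference sequence not present")
  structure(list(sequences = sequences, reference = reference),
            class = "msa")
}

#' @rdname msa
#' @param path aligned FASTA file.
#' @param reference reference sequence name (default: first record).
#' @export
read_msa <- function(path, reference = NULL) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- stats::setNames(as.character(aas), names(aas))
  msa(seqs, reference %||% names(seqs)[1L])
}

#' @rdname msa
#' @param x an `msa` object.
#' @export
write_msa <- function(x, path) {
  .assert(inherits(x, "msa"), "msa object required")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(x$sequences), path,
                              width = 80L)
  invisible(path)
}

# ungapped reference position -> alignment column (and back)
#' Map reference coordinates to alignment columns
#'
#' `ref_to_alignment_column` converts a 1-based ungapped position of the
#' reference sequence into the corresponding alignment column;
#' `alignment_column_to_ref` inverts it (NA when the reference is gapped at
#' that column).  The two round-trip exactly.
#'
#' @param x an [msa()].
#' @param i ungapped reference position / `col` alignment column.
#' @return integer index.
#' @export
ref_to_alignment_column <- function(x, i) {
  .assert(inherits(x, "msa"), "msa object required")
  chars <- strsplit(x$sequences[[x$reference]], "")[[1]]
  nongap <- which(chars != "-")
  .assert(.is_count(i, 1L) && i <= length(nongap),
          "position beyond the ungapped reference length")
  nongap[i]
}

#' @rdname ref_to_alignment_column
#' @param col alignment column index.
#' @export
alignment_column_to_ref <- function(x, col) {
  .assert(inherits(x, "msa"), "msa object required")
  chars <- strsplit(x$sequences[[x$reference]], "")[[1]]
  .assert(.is_count(col, 1L) && col <= length(chars), "column out of range")
  if (chars[col] == "-") return(NA_integer_)
  sum(chars[seq_len(col)] != "-")
}

#' Conservation of an alignment column at a mutated residue
#'
#' Measures how conserved a reference-coordinate residue is across species
#' and whether the query strain deviates from it — the signature used to
#' flag a missense variant as falling in a highly conserved region.  The
#' modal residue is computed over the non-query sequences; the conservation
#' fraction is the share of non-gap non-query sequences carrying it.
#'
#' @param x an [msa()].
#' @param column_index 1-based position in ungapped reference coordinates.
#' @param query name of the query (mutated-strain) sequence; default: the
#'   reference itself.
#' @param threshold conservation fraction at or above which the column is
#'   called conserved (default 0.9).
#' @return list with `fraction`, `conserved`, `modal_residue`,
#'   `query_residue`, `query_deviates`, `residues` (named per-species) and
#'   `alignment_column`.
#' @export
column_conservation <- function(x, column_index, query = NULL,
                                threshold = 0.9) {
  .assert(inherits(x, "msa"), "msa object required")
  query <- query %||% x$reference
  .assert(query %in% names(x$sequences), "unknown query sequence")
  col <- ref_to_alignment_column(x, column_index)
  residues <- vapply(x$sequences, function(s) substr(s, col, col), character(1))
  others <- residues[setdiff(names(residues), query)]
  others <- others[others != "-"]
  .assert(length(others) >= 1, "column is all gaps in the non-query sequences")
  tab <- sort(table(others), decreasing = TRUE)
  modal <- names(tab)[1L]
  fraction <- as.numeric(tab[1L]) / length(others)
  qres <- residues[[query]]
  list(fraction = fraction,
       conserved = fraction >= threshold,
       modal_residue = modal,
       query_residue = qres,
       query_deviates = qres != "-" && qres != modal,
       residues = residues,
       alignment_column = col)
}
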