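# Orchestration of the full positional-cloning chain: QTL confirmation ->
# polymorphic blocks -> impact/SIFT filter -> expression filter -> ranked
# candidate report.

#' Pipeline configuration
#'
#' Collects every tunable of the positional-cloning chain.  Defaults mirror
#' a 50-80 Mbp chromosome-15 locus with proximal (63 Mbp) and distal
#' (79 Mbp) sublocus peaks; the sublocus boundary defaults to the midpoint
#' between the peaks since only the peaks, not a boundary coordinate, are
#' ever reported for such loci.
#'
#' @param locus list `(chrom, start_bp, end_bp)`, half-open.
#' @param proximal_peak_bp,distal_peak_bp sublocus peak positions (bp).
#' @param sublocus_boundary_bp boundary assigning genes to subloci by their
#'   midpoint; default midpoint of the two peaks.
#' @param dialect window dialect for block calling (see
#'   [classify_windows()]).
#' @param sift_cutoff strict SIFT cutoff (default 0.5).
#' @param min_combined_z minimum combined specificity Z-score (default 1).
#' @param n_perm,alpha,drop LOD-scan permutation count, genome-wide error
#'   rate and support-interval drop.
#' @param use_qtl,use_blocks,use_impact,use_expression stage toggles for
#'   ablation; all on by default.
#' @param seed integer seed for the permutation stream.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(locus = list(chrom = "chr15",
                                         start_bp = 50000000,
                                         end_bp = 80000000),
                            proximal_peak_bp = 63000000,
                            distal_peak_bp = 79000000,
                            sublocus_boundary_bp = NULL,
                            dialect = "150kb",
                            sift_cutoff = 0.5,
                            min_combined_z = 1.0,
                            n_perm = 100L,
                            alpha = 0.05,
                            drop = 1.5,
                            use_qtl = TRUE,
                            use_blocks = TRUE,
                            use_impact = TRUE,
                            use_expression = TRUE,
                            seed = 1L) {
  .assert(is.list(locus) &&
            all(c("chrom", "start_bp", "end_bp") %in% names(locus)),
          "locus must be list(chrom, start_bp, end_bp)")
  .assert(locus$end_bp > locus$start_bp, "malformed locus interval")
  .assert(.is_number(sift_cutoff) && sift_cutoff >= 0 && sift_cutoff <= 1,
          "sift_cutoff must be in [0, 1]")
  .assert(.is_number(min_combined_z), "min_combined_z must be a number")
  .assert(.is_count(n_perm, 1L), "n_perm must be >= 1")
  .assert(.is_number(alpha) && alpha > 0 && alpha < 1, "alpha in (0, 1)")
  .assert(.is_number(drop) && drop >= 0, "drop must be >= 0")
  structure(list(locus = locus,
                 proximal_peak_bp = proximal_peak_bp,
                 distal_peak_bp = distal_peak_bp,
                 sublocus_boundary_bp = sublocus_boundary_bp %||%
                   ((proximal_peak_bp + distal_peak_bp) / 2),
                 dialect = dialect,
                 sift_cutoff = sift_cutoff,
                 min_combined_z = min_combined_z,
                 n_perm = as.integer(n_perm),
                 alpha = alpha,
                 drop = drop,
                 use_qtl = isTRUE(use_qtl),
                 use_blocks = isTRUE(use_blocks),
                 use_impact = isTRUE(use_impact),
                 use_expression = isTRUE(use_expression),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# consistency of the gene universes across annotation/expression/coordinates
.check_gene_universe <- function(genes, annotations, expression) {
  gid <- genes$gene_id
  diffs <- list(
    annotation_not_in_genes = setdiff(unique(annotations$gene_id), gid),
    expression_not_in_genes = setdiff(rownames(expression), gid))
  bad <- lengths(diffs) > 0
  if (any(bad)) {
    msg <- paste(vapply(names(diffs)[bad], function(k)
      sprintf("%s: %s", k, paste(diffs[[k]], collapse = ", ")),
      character(1)), collapse = "; ")
    stop("inconsistent gene universes - ", msg, call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the positional-cloning pipeline
#'
#' Executes the full chain on one set of inputs: (1) LOD scan with
#' permutation threshold to confirm the locus (when genotypes and
#' phenotypes are supplied); (2) polymorphic-block calling over the locus;
#' (3) variant impact/SIFT filtering; (4) restriction of impact-passing
#' genes to polymorphic blocks; (5) tissue-specificity expression
#' filtering; (6) ranking into a candidate report.  Candidates are ranked
#' by impact class (HIGH before MODERATE), then ascending minimum SIFT,
#' then descending combined specificity Z, ties broken by coordinate.  Any
#' stage can be toggled off in the config, in which case it does not
#' restrict the candidate set.
#'
#' @param inputs a [simulate_study()] result, a [read_study()] result, or a
#'   plain list with the same element names (`genes`, `annotations` and
#'   `expression` are required; `map`, `genotypes`, `phenotypes`,
#'   `snp_catalog`, `msa`, `qpcr` optional).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every intermediate and
#'   the final report are written to it.
#' @return A list of class `candidate_report` with elements `candidates`
#'   (ranked data.frame), `stage_counts` (filter funnel), `qtl`
#'   (`qtl_result` or NULL), `blocks`, `windows`, `scores`, `config`.
#'   An empty candidate set is a valid report, not an error.
#' @export
run_positional_cloning <- function(inputs, config = pipeline_config(),
                                   out_dir = NULL) {
  .assert(inherits(config, "pipeline_config"), "pipeline_config required")
  .assert(is.list(inputs), "inputs must be a list of pipeline inputs")
  .assert(!is.null(inputs$genes) && !is.null(inputs$annotations) &&
            !is.null(inputs$expression),
          "genes, annotations and expression inputs are required")
  .check_gene_universe(inputs$genes, inputs$annotations, inputs$expression)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  emit <- function(writer, obj, file) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
  }

  # stage 1: locus confirmation by LOD scan
  qtl <- NULL
  if (config$use_qtl && !is.null(inputs$genotypes) &&
      !is.null(inputs$phenotypes) && !is.null(inputs$map)) {
    pheno_vec <- scan_phenotype(inputs$phenotypes, rownames(inputs$genotypes))
    qtl <- qtl_analysis(inputs$genotypes, pheno_vec, inputs$map,
                        n_perm = config$n_perm, alpha = config$alpha,
                        drop = config$drop, seed = config$seed)
    emit(write_lod_curve, qtl$curve, "lod_curve.tsv")
    emit(write_qtl_result, qtl, "qtl_result.json")
  }

  # stage 2: polymorphic blocks over the locus
  windows <- NULL
  blocks <- NULL
  if (!is.null(inputs$snp_catalog)) {
    called <- call_polymorphic_blocks(inputs$snp_catalog,
                                      region = config$locus,
                                      dialect = config$dialect)
    windows <- called$windows
    blocks <- called$blocks
    emit(write_window_set, windows, "windows.tsv")
    if (!is.null(out_dir)) write_blocks(blocks, file.path(out_dir, "blocks"))
  }

  genes <- inputs$genes
  total <- nrow(genes)

  # stage 3: impact / SIFT filter
  impact_tab <- filter_by_impact(inputs$annotations,
                                 sift_cutoff = config$sift_cutoff)
  impact_pass <- if (config$use_impact) impact_tab$gene_id else genes$gene_id
  n_impact <- length(intersect(genes$gene_id, impact_pass))
  if (!is.null(out_dir) && nrow(impact_tab)) {
    .write_tsv(impact_tab, file.path(out_dir, "impact_pass.tsv"))
  }

  # stage 4: restriction to polymorphic blocks within the locus
  block_pass <- if (config$use_blocks && !is.null(blocks)) {
    hit <- genes_in_blocks(genes, blocks,
                           locus = list(start_bp = config$locus$start_bp,
                                        end_bp = config$locus$end_bp))
    hit$gene_id
  } else genes$gene_id
  n_block <- length(intersect(intersect(genes$gene_id, impact_pass),
                              block_pass))

  # stage 5: tissue-specificity expression filter
  scores <- specificity_zscores(expression_matrix(unclass(inputs$expression)))
  expr_pass <- if (config$use_expression) {
    select_candidates(scores, config$min_combined_z)
  } else genes$gene_id
  emit(function(obj, f) .write_tsv(obj, f), scores, "specificity_scores.tsv")

  surviving <- Reduce(intersect, list(genes$gene_id, impact_pass,
                                      block_pass, expr_pass))
  n_expr <- length(surviving)

  # stage 6: assemble and rank the report
  cand <- genes[genes$gene_id %in% surviving, , drop = FALSE]
  report_rows <- if (nrow(cand)) {
    ev <- impact_tab[match(cand$gene_id, impact_tab$gene_id), , drop = FALSE]
    zc <- scores$combined[match(cand$gene_id, scores$gene)]
    midpoint <- (cand$start_bp + cand$end_bp) / 2
    in_block <- if (!is.null(blocks)) {
      vapply(seq_len(nrow(cand)), function(i)
        any(cand$start_bp[i] < blocks$end_bp &
              blocks$start_bp < cand$end_bp), logical(1))
    } else rep(NA, nrow(cand))
    conserved <- rep(NA, nrow(cand))
    if (!is.null(inputs$msa)) {
      msa_gene <- attr(inputs$msa, "gene_id") %||%
        (if (!is.null(inputs$truth)) inputs$truth$msa_gene else NULL)
      msa_site <- attr(inputs$msa, "site") %||%
        (if (!is.null(inputs$truth)) inputs$truth$msa_site else NULL)
      msa_query <- attr(inputs$msa, "query") %||%
        (if (!is.null(inputs$truth)) inputs$truth$msa_query else NULL)
      if (!is.null(msa_gene) && msa_gene %in% cand$gene_id &&
          !is.null(msa_site)) {
        cc <- column_conservation(inputs$msa, msa_site, query = msa_query)
        conserved[match(msa_gene, cand$gene_id)] <-
          cc$conserved && cc$query_deviates
      }
    }
    fold <- rep(NA_real_, nrow(cand))
    if (!is.null(inputs$qpcr) && !is.null(inputs$truth) &&
        !is.na(inputs$truth$causal_gene) &&
        inputs$truth$causal_gene %in% cand$gene_id) {
      qc <- qpcr_group_comparison(inputs$qpcr)
      fold[match(inputs$truth$causal_gene, cand$gene_id)] <- qc$fold_change
    }
    data.frame(gene_id = cand$gene_id,
               symbol = cand$symbol,
               chrom = cand$chrom,
               start_bp = cand$start_bp,
               end_bp = cand$end_bp,
               sublocus = ifelse(midpoint < config$sublocus_boundary_bp,
                                 "proximal", "distal"),
               in_polymorphic_block = in_block,
               impact = ev$impact,
               min_sift = ev$min_sift,
               combined_z = zc,
               qpcr_fold_change = fold,
               conserved_site = conserved,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), symbol = character(0),
               chrom = character(0), start_bp = integer(0),
               end_bp = integer(0), sublocus = character(0),
               in_polymorphic_block = logical(0), impact = character(0),
               min_sift = numeric(0), combined_z = numeric(0),
               qpcr_fold_change = numeric(0), conserved_site = logical(0),
               stringsAsFactors = FALSE)
  }
  if (nrow(report_rows)) {
    impact_rank <- match(report_rows$impact, .IMPACT_LEVELS)
    impact_rank[is.na(impact_rank)] <- length(.IMPACT_LEVELS) + 1L
    sift_key <- ifelse(is.na(report_rows$min_sift), -1, report_rows$min_sift)
    ord <- order(impact_rank, sift_key, -report_rows$combined_z,
                 report_rows$start_bp)
    report_rows <- report_rows[ord, , drop = FALSE]
    report_rows$final_rank <- seq_len(nrow(report_rows))
    rownames(report_rows) <- NULL
  } else {
    report_rows$final_rank <- integer(0)
  }

  report <- structure(
    list(candidates = report_rows,
         stage_counts = c(total_genes = total,
                          impact_pass = n_impact,
                          block_pass = n_block,
                          expression_pass = n_expr),
         qtl = qtl, blocks = blocks, windows = windows, scores = scores,
         config = config),
    class = "candidate_report")
  if (!is.null(out_dir)) write_report(report, file.path(out_dir, "report"))
  report
}

#' Write a candidate report as TSV + JSON
#'
#' The TSV carries one row per surviving gene (header-only when the report
#' is empty); the JSON echoes the configuration and the filter-funnel
#' counts (total genes -> impact-pass -> block-pass -> expression-pass).
#'
#' @param report a `candidate_report`.
#' @param out_prefix path prefix; `<prefix>.tsv` and `<prefix>.json` are
#'   written.
#' @return the two paths, invisibly.
#' @export
write_report <- function(report, out_prefix) {
  .assert(inherits(report, "candidate_report"), "candidate_report required")
  tsv <- paste0(out_prefix, ".tsv")
  json <- paste0(out_prefix, ".json")
  out <- report$candidates
  for (col in c("min_sift", "combined_z", "qpcr_fold_change")) {
    if (nrow(out)) out[[col]] <- .fmt_num(out[[col]])
  }
  .write_tsv(out, tsv)
  cfg <- unclass(report$config)
  jsonlite::write_json(
    list(config = cfg[setdiff(names(cfg), "locus")],
         locus = cfg$locus,
         stage_counts = as.list(report$stage_counts),
         n_candidates = nrow(report$candidates),
         qtl = if (!is.null(report$qtl))
           report$qtl[c("peak_marker", "peak_lod", "threshold",
                        "significant")] else NULL),
    json, auto_unbox = TRUE, digits = 8, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Read back a written candidate report TSV
#'
#' @param path the `<prefix>.tsv` written by [write_report()].
#' @return data.frame with the candidate rows (numeric columns restored).
#' @export
read_report_tsv <- function(path) {
  df <- .read_tsv(path)
  for (col in c("min_sift", "combined_z", "qpcr_fold_change")) {
    if (col %in% names(df)) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df
}
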