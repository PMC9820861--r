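# One-call synthetic study: every input of the positional-cloning chain
# with a planted causal gene, plus disk round-trip of all inputs in the
# plain-text formats the pipeline consumes.

#' Simulate a complete positional-cloning study
#'
#' Builds all inputs of the pipeline from one seed with mutually consistent
#' coordinates: a chromosome-15-style 30 Mbp locus (50-80 Mbp) genotyped at
#' 1 Mbp marker spacing, an N2 backcross cohort with a planted protective
#' QTL at the distal peak, a strain SNP catalog with polymorphic blocks
#' under both subloci, a gene table with one planted causal gene inside the
#' distal block, variant annotations and a multi-tissue expression matrix
#' in which only the planted gene is deleterious-and-islet-specific, a
#' protein alignment carrying its missense change in a conserved column,
#' and qPCR Ct measurements.
#'
#' With `planted = FALSE` a null study is produced: no QTL effect, no
#' deleterious variant, no islet-enriched gene (the haplotype structure is
#' retained — absence of candidates must come from the filters, not from an
#' empty genome).
#'
#' @param seed integer master seed; all substreams derive from it.
#' @param n_individuals backcross cohort size (default 150).
#' @param planted plant the causal signals (default TRUE).
#' @param cfg_overrides named list overriding [sim_config()] fields.
#' @return list of class `cloning_study` with elements `map`, `genotypes`,
#'   `phenotypes`, `snp_catalog`, `genes`, `annotations`, `expression`,
#'   `msa`, `qpcr`, `truth` (planted-signal bookkeeping) and `region`.
#' @export
simulate_study <- function(seed = 1L, n_individuals = 150L, planted = TRUE,
                           cfg_overrides = list()) {
  region <- list(chrom = "chr15", start_bp = 50000000L, end_bp = 80000000L)
  bp <- seq(region$start_bp, region$end_bp, by = 1000000L)
  map <- genetic_map(sprintf("mk%02d", seq_along(bp)), region$chrom,
                     bp, (bp - region$start_bp) / 2e6)  # ~0.5 cM / Mbp
  causal_marker <- map$marker_id[match(79000000L, map$position_bp)]

  cfg_args <- utils::modifyList(
    list(n_individuals = n_individuals,
         causal_marker_id = causal_marker,
         additive_effect = if (planted) 40 else 0,
         protection = if (planted) 1 else 0,
         seed = seed),
    cfg_overrides)
  cfg <- do.call(sim_config, cfg_args)

  genotypes <- simulate_backcross(map, cfg$n_individuals, seed = seed)
  phenotypes <- simulate_phenotypes(genotypes, cfg)

  # polymorphic blocks under the proximal (63 Mbp) and distal (79 Mbp)
  # sublocus peaks; densities well above the 50/150kb calling threshold
  blocks <- data.frame(start_bp = c(62300000, 78200000),
                       end_bp = c(63500000, 79800000),
                       density_per_kb = c(0.8, 1.0))
  snp_catalog <- simulate_snp_catalog(region, blocks, seed = seed)

  genes <- gene_table(
    gene_id = sprintf("g%02d", 1:12),
    symbol = c("Kdelr3", "Cbx6", "Fam135b", "Gramd4", "Celsr1", "Atxn10",
               "Ppara", "Pmm1", "Sco2", "Tymp", "Shank3", "Arsa"),
    chrom = region$chrom,
    start_bp = c(79000000, 78500000, 79300000, 62500000, 62900000, 55000000,
                 57500000, 60000000, 65200000, 68000000, 71500000, 74800000),
    end_bp   = c(79050000, 78560000, 79420000, 62580000, 63010000, 55120000,
                 57620000, 60080000, 65300000, 68060000, 71650000, 74900000))

  # decoys exercising every arm of the funnel: deleterious-but-outside-blocks
  # (g10), in-block-but-tolerated (g02, g03, g04), islet-specific-but-benign
  # (g05)
  overrides <- data.frame(gene_id = c("g02", "g03", "g04", "g05", "g10"),
                          impact = c("MODERATE", "MODERATE", "MODERATE",
                                     "LOW", "MODERATE"),
                          sift = c(0.72, 0.9, 0.61, NA, 0.12),
                          islet_fold = c(NA, NA, NA, 9, NA),
                          stringsAsFactors = FALSE)
  ae <- simulate_annotations_and_expression(
    genes, planted_causal = if (planted) "g01" else NULL,
    seed = seed, overrides = overrides)

  alignment <- simulate_msa(site = 96L, seed = seed)
  qpcr <- simulate_qpcr(fold_change = if (planted) 0.3 else 1.0, seed = seed)

  structure(list(map = map, config = cfg, genotypes = genotypes,
                 phenotypes = phenotypes, snp_catalog = snp_catalog,
                 genes = genes, annotations = ae$annotations,
                 expression = ae$expression, msa = alignment, qpcr = qpcr,
                 region = region,
                 truth = list(planted = planted,
                              causal_gene = if (planted) "g01" else NA_character_,
                              causal_symbol = if (planted) "Kdelr3" else NA_character_,
                              causal_marker = causal_marker,
                              msa_gene = "g01", msa_site = 96L,
                              msa_query = "Mouse_NZO",
                              blocks = blocks)),
            class = "cloning_study")
}

#' Write / read all study inputs as plain-text files
#'
#' Serializes every pipeline input in its standard exchange format:
#' genotypes CSV (rows = individuals, columns = markers, 0/1/NA), map TSV,
#' phenotypes CSV (long format `animal, group, week, glucose, weight,
#' insulin, dead`), SNP catalog as TSV and minimal VCF, gene table as BED
#' (0-based half-open), annotations TSV, expression CSV, protein alignment
#' FASTA and qPCR CSV.  Files written under the same seed are
#' byte-identical across runs.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  .assert(inherits(study, "cloning_study"), "cloning_study required")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  geno <- data.frame(individual = rownames(study$genotypes),
                     unclass(study$genotypes), check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.csv(geno, p("genotypes.csv"), row.names = FALSE, quote = FALSE)
  write_genetic_map(study$map, p("map.tsv"))
  utils::write.csv(study$phenotypes, p("phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  write_snp_catalog_tsv(study$snp_catalog, p("snp_catalog.tsv"))
  write_snp_catalog_vcf(study$snp_catalog, p("snp_catalog.vcf"))
  bed <- data.frame(chrom = study$genes$chrom,
                    start = study$genes$start_bp - 1L,
                    end = study$genes$end_bp - 1L,
                    name = study$genes$gene_id,
                    score = 0L,
                    strand = ".",
                    symbol = study$genes$symbol)
  utils::write.table(bed, p("genes.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  .write_tsv(study$annotations, p("annotations.tsv"))
  write_expression_matrix(study$expression, p("expression.csv"))
  write_msa(study$msa, p("msa.fasta"))
  utils::write.csv(study$qpcr, p("qpcr.csv"), row.names = FALSE, quote = FALSE)

  invisible(c(genotypes = p("genotypes.csv"), map = p("map.tsv"),
              phenotypes = p("phenotypes.csv"),
              snp_catalog_tsv = p("snp_catalog.tsv"),
              snp_catalog_vcf = p("snp_catalog.vcf"),
              genes = p("genes.bed"), annotations = p("annotations.tsv"),
              expression = p("expression.csv"), msa = p("msa.fasta"),
              qpcr = p("qpcr.csv")))
}

#' @rdname write_study
#' @return `read_study()` returns a list with the re-loaded `map`,
#'   `genotypes`, `phenotypes`, `snp_catalog`, `genes`, `annotations`,
#'   `expression`, `msa` and `qpcr` objects.
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  geno_df <- utils::read.csv(p("genotypes.csv"), check.names = FALSE,
                             stringsAsFactors = FALSE)
  genotypes <- as.matrix(geno_df[, -1L, drop = FALSE])
  rownames(genotypes) <- geno_df[[1L]]
  storage.mode(genotypes) <- "integer"
  class(genotypes) <- c("backcross_genotypes", class(genotypes))

  pheno <- utils::read.csv(p("phenotypes.csv"), stringsAsFactors = FALSE)
  class(pheno) <- c("phenotype_table", "data.frame")

  bed <- utils::read.table(p("genes.bed"), sep = "\t",
                           stringsAsFactors = FALSE)
  genes <- gene_table(bed$V4, bed$V7, bed$V1, bed$V2 + 1L, bed$V3 + 1L)

  ann <- .read_tsv(p("annotations.tsv"))
  class(ann) <- c("variant_annotation", "data.frame")

  list(map = read_genetic_map(p("map.tsv")),
       genotypes = genotypes,
       phenotypes = pheno,
       snp_catalog = read_snp_catalog(p("snp_catalog.tsv")),
       genes = genes,
       annotations = ann,
       expression = read_expression_matrix(p("expression.csv")),
       msa = read_msa(p("msa.fasta")),
       qpcr = utils::read.csv(p("qpcr.csv"), stringsAsFactors = FALSE))
}
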