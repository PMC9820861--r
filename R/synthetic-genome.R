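# Synthetic strain genomics: SNP catalogs with planted polymorphic blocks,
# variant annotation tables, multi-tissue expression matrices, protein
# alignments and qPCR measurements with a planted causal gene.

#' Simulate a two-strain SNP catalog with planted polymorphic blocks
#'
#' Emulates a strain-comparison SNP catalog (reference genome vs two inbred
#' strains).  Inside each planted block the two strains disagree at
#' Poisson-placed positions with the requested density (non-IBD structure);
#' outside blocks the strains carry identical calls, optionally with a
#' background of shared (concordant) deviations from the reference, so the
#' region looks identical-by-descent.
#'
#' @param region list with `chrom`, `start_bp`, `end_bp` (1-based, half-open
#'   `[start, end)`).
#' @param block_spec data.frame with columns `start_bp`, `end_bp`,
#'   `density_per_kb` (discordant SNPs per kb); blocks must lie inside the
#'   region and must not overlap.
#' @param seed integer seed.
#' @param background_per_kb density of concordant (IBD) SNPs across the whole
#'   region; default 0.2/kb.
#' @return A `data.frame` of class `snp_catalog` with columns `chrom`, `pos`
#'   (sorted, unique), `ref`, `C3H`, `NZO`; attribute `region` records the
#'   simulated interval.
#' @export
simulate_snp_catalog <- function(region, block_spec, seed = 1L,
                                 background_per_kb = 0.2) {
  .assert(is.list(region) && all(c("chrom", "start_bp", "end_bp") %in% names(region)),
          "region must be list(chrom, start_bp, end_bp)")
  .assert(region$end_bp > region$start_bp, "region end must exceed start")
  .assert(is.data.frame(block_spec) &&
            all(c("start_bp", "end_bp", "density_per_kb") %in% names(block_spec)),
          "block_spec must have start_bp, end_bp, density_per_kb")
  if (nrow(block_spec)) {
    .assert(all(block_spec$start_bp >= region$start_bp) &&
              all(block_spec$end_bp <= region$end_bp),
            "blocks must lie inside the region")
    .assert(all(block_spec$end_bp > block_spec$start_bp), "empty block")
    .assert(all(block_spec$density_per_kb >= 0), "densities must be >= 0")
    bs <- block_spec[order(block_spec$start_bp), , drop = FALSE]
    if (nrow(bs) > 1L) {
      .assert(all(bs$start_bp[-1L] >= bs$end_bp[-nrow(bs)]),
              "blocks must not overlap")
    }
  }
  set.seed(.substream(seed, 37L))
  bases <- c("A", "C", "G", "T")
  draw_positions <- function(start, end, per_kb) {
    len <- end - start
    k <- stats::rpois(1L, len / 1000 * per_kb)
    if (k == 0L) return(integer(0))
    sort(unique(as.integer(start + floor(stats::runif(k) * len))))
  }

  disc_pos <- integer(0)
  for (b in seq_len(nrow(block_spec))) {
    disc_pos <- c(disc_pos,
                  draw_positions(block_spec$start_bp[b], block_spec$end_bp[b],
                                 block_spec$density_per_kb[b]))
  }
  bg_pos <- draw_positions(region$start_bp, region$end_bp, background_per_kb)
  bg_pos <- setdiff(bg_pos, disc_pos)

  pos <- c(disc_pos, bg_pos)
  discordant <- c(rep(TRUE, length(disc_pos)), rep(FALSE, length(bg_pos)))
  ord <- order(pos)
  pos <- pos[ord]; discordant <- discordant[ord]

  n <- length(pos)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  c3h <- ifelse(discordant, ref, alt)   # shared deviation when concordant
  nzo <- alt                            # NZO always differs from C3H in blocks
  out <- data.frame(chrom = region$chrom, pos = pos, ref = ref,
                    C3H = unname(c3h), NZO = unname(nzo),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "region") <- region
  class(out) <- c("snp_catalog", "data.frame")
  out
}

#' Build a gene coordinate table
#'
#' @param gene_id,symbol,chrom,start_bp,end_bp vectors of equal length;
#'   coordinates are 1-based half-open `[start, end)`.
#' @return data.frame of class `gene_table`.
#' @export
gene_table <- function(gene_id, symbol, chrom, start_bp, end_bp) {
  n <- length(gene_id)
  .assert(n >= 1, "at least one gene required")
  .assert(!anyDuplicated(gene_id), "gene ids must be unique")
  .assert(all(end_bp > start_bp), "gene end must exceed start")
  out <- data.frame(gene_id = as.character(gene_id),
                    symbol = as.character(symbol),
                    chrom = as.character(chrom),
                    start_bp = as.integer(start_bp),
                    end_bp = as.integer(end_bp),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Simulate variant annotations and a multi-tissue expression matrix
#'
#' Emulates the downstream outputs of a variant-effect/SIFT annotation run
#' and a multi-tissue microarray on three strains (NZO, C3H, B6) and five
#' tissues (islet, liver, quadriceps, gWAT, BAT).  The planted causal gene
#' receives a MODERATE-impact missense variant with a deleterious SIFT score
#' (< 0.5) and islet expression at least `islet_fold`-fold above every other
#' tissue in all three strains.  Decoy genes receive tolerated or
#' non-coding variants and tissue-flat expression; both can be overridden
#' per gene to build richer filter funnels.
#'
#' @param genes a [gene_table()].
#' @param planted_causal gene_id of the planted causal gene, or `NULL` for a
#'   null fixture with no planted signal.
#' @param seed integer seed.
#' @param islet_fold guaranteed islet enrichment of the planted gene
#'   (>= 8; default 10).
#' @param overrides optional data.frame with columns `gene_id` and any of
#'   `impact`, `sift`, `islet_fold` forcing those values for specific decoys.
#' @return list with elements `annotations` (data.frame of class
#'   `variant_annotation`: gene_id, symbol, chrom, pos, consequence, impact,
#'   sift, aa_change) and `expression` (numeric matrix of class
#'   `expression_matrix`, genes x `strain.tissue` columns).
#' @export
simulate_annotations_and_expression <- function(genes, planted_causal,
                                                seed = 1L, islet_fold = 10,
                                                overrides = NULL) {
  .assert(inherits(genes, "gene_table"), "genes must be a gene_table")
  if (!is.null(planted_causal)) {
    .assert(planted_causal %in% genes$gene_id,
            sprintf("unknown gene id '%s'", planted_causal))
    .assert(islet_fold >= 8, "planted islet enrichment must be >= 8-fold")
  }
  set.seed(.substream(seed, 51L))
  strains <- c("NZO", "C3H", "B6")
  tissues <- c("islet", "liver", "quadriceps", "gWAT", "BAT")
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K")

  ov <- function(gid, field, default) {
    if (!is.null(overrides) && gid %in% overrides$gene_id &&
        field %in% names(overrides)) {
      v <- overrides[[field]][match(gid, overrides$gene_id)]
      if (!is.na(v)) return(v)
    }
    default
  }

  ann <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    pos <- as.integer(genes$start_bp[i] +
                        floor(stats::runif(1) * (genes$end_bp[i] - genes$start_bp[i])))
    if (!is.null(planted_causal) && gid == planted_causal) {
      impact <- "MODERATE"
      sift <- round(stats::runif(1, 0.01, 0.2), 2)
      consequence <- "missense_variant"
      site <- 96L
      change <- sprintf("%s%d%s", "E", site, "V")
    } else {
      impact <- ov(gid, "impact",
                   sample(c("MODIFIER", "LOW", "MODERATE"), 1L,
                          prob = c(0.4, 0.25, 0.35)))
      sift <- if (impact == "MODERATE") {
        ov(gid, "sift", round(stats::runif(1, 0.5, 0.99), 2))
      } else NA_real_
      consequence <- switch(impact,
                            MODIFIER = "intron_variant",
                            LOW = "synonymous_variant",
                            MODERATE = "missense_variant",
                            HIGH = "stop_gained")
      change <- if (impact == "MODERATE") {
        from <- sample(aa, 1L)
        sprintf("%s%d%s", from, sample(50:400, 1L),
                sample(setdiff(aa, from), 1L))
      } else NA_character_
    }
    ann[[i]] <- data.frame(gene_id = gid, symbol = genes$symbol[i],
                           chrom = genes$chrom[i], pos = pos,
                           consequence = consequence, impact = impact,
                           sift = sift, aa_change = change,
                           stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, ann)
  class(annotations) <- c("variant_annotation", "data.frame")

  cond <- as.vector(outer(strains, tissues, paste, sep = "."))
  expr <- matrix(NA_real_, nrow(genes), length(cond),
                 dimnames = list(genes$gene_id, cond))
  base <- 2 ^ stats::runif(nrow(genes), 6, 10)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    vals <- base[i] * 2 ^ stats::rnorm(length(cond), 0, 0.25)
    names(vals) <- cond
    fold <- if (!is.null(planted_causal) && gid == planted_causal) {
      islet_fold
    } else {
      ov(gid, "islet_fold", NA_real_)
    }
    if (!is.na(fold)) {
      # exact enrichment guarantee: islet = fold * max(other tissues), per strain
      for (s in strains) {
        others <- paste(s, setdiff(tissues, "islet"), sep = ".")
        vals[paste0(s, ".islet")] <- fold * max(vals[others])
      }
    }
    expr[i, ] <- vals
  }
  expr <- round(expr, 3)
  class(expr) <- c("expression_matrix", class(expr))
  list(annotations = annotations, expression = expr)
}

#' Simulate a multi-species protein alignment around a mutated residue
#'
#' Builds an aligned FASTA-style MSA in which a chosen reference-coordinate
#' residue is perfectly conserved across species but substituted in one
#' query strain — the classic signature of a missense hit in a conserved
#' domain.  A few columns carry gaps so that reference-coordinate mapping is
#' exercised.
#'
#' @param site 1-based ungapped position of the mutated residue in the
#'   reference sequence.
#' @param width ungapped reference length (>= site).
#' @param ref_residue,mut_residue conserved residue and the query's variant.
#' @param species species labels; first is the reference, `query` (default
#'   last) carries the mutation.
#' @param query label of the mutated sequence.
#' @param seed integer seed.
#' @return an [msa()] object.
#' @export
simulate_msa <- function(site = 96L, width = 120L,
                         ref_residue = "E", mut_residue = "V",
                         species = c("Mouse_B6", "Human", "Rat", "Dog",
                                     "Chicken", "Xenopus", "Zebrafish",
                                     "Mouse_NZO"),
                         query = "Mouse_NZO", seed = 1L) {
  .assert(site >= 1 && site <= width, "site must lie within the reference")
  .assert(query %in% species, "query must be one of the species")
  set.seed(.substream(seed, 67L))
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  consensus <- sample(aa, width, replace = TRUE)
  consensus[site] <- ref_residue
  mat <- matrix(rep(consensus, each = length(species)),
                nrow = length(species), dimnames = list(species, NULL))
  # sprinkle substitutions in non-site columns of non-reference species
  for (i in seq_along(species)[-1L]) {
    k <- sample(setdiff(seq_len(width), site), size = max(2L, width %/% 12L))
    mat[i, k] <- sample(aa, length(k), replace = TRUE)
  }
  mat[query, site] <- mut_residue
  # insert a gapped column block before the site in two distant species
  gap_cols <- sort(sample(setdiff(seq_len(width), c(site, 1L, width)), 3L))
  aln <- mat
  for (sp in utils::tail(species, 2L)) aln[sp, gap_cols] <- "-"
  seqs <- apply(aln, 1L, paste, collapse = "")
  msa(seqs, reference = species[1L])
}

#' Simulate qPCR cycle-threshold measurements for two groups
#'
#' Generates target/housekeeping Ct pairs with a configured fold change in
#' relative expression between groups (group A vs group B), for exercising
#' the delta-Ct arithmetic.  A fold change of 0.3 emulates a 70% knockdown.
#'
#' @param n_per_group replicates per group.
#' @param fold_change mean relative expression of group A divided by group B.
#' @param base_ct mean target Ct of group B.
#' @param ref_ct mean housekeeping Ct.
#' @param ct_sd replicate noise on each Ct.
#' @param groups two group labels.
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `group`, `target_ct`,
#'   `reference_ct`.
#' @export
simulate_qpcr <- function(n_per_group = 6L, fold_change = 0.3,
                          base_ct = 25, ref_ct = 18, ct_sd = 0.15,
                          groups = c("KD", "NTC"), seed = 1L) {
  .assert(fold_change > 0, "fold_change must be > 0")
  .assert(length(groups) == 2L, "exactly two groups")
  set.seed(.substream(seed, 83L))
  # lower relative expression  <=>  higher target Ct
  delta <- -log2(fold_change)
  df <- data.frame(
    sample = sprintf("s%02d", seq_len(2L * n_per_group)),
    group = rep(groups, each = n_per_group),
    target_ct = round(c(stats::rnorm(n_per_group, base_ct + delta, ct_sd),
                        stats::rnorm(n_per_group, base_ct, ct_sd)), 3),
    reference_ct = round(stats::rnorm(2L * n_per_group, ref_ct, ct_sd), 3),
    stringsAsFactors = FALSE)
  df
}
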