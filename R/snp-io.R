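# SNP catalog I/O: TSV and a minimal two-sample VCF.

#' Read a strain SNP catalog from TSV or VCF
#'
#' TSV input needs columns `chrom`, `pos`, `ref` and one allele column per
#' strain.  VCF input is read with the vcfR package: per-strain GT fields
#' are resolved against REF/ALT (`0` -> REF allele, `1` -> ALT allele,
#' `.` -> missing); only biallelic records with homozygous calls are
#' expected, as appropriate for inbred strains.
#'
#' @param path input file; format chosen by extension (`.vcf` vs anything
#'   else) unless `format` is given.
#' @param format `"auto"`, `"tsv"` or `"vcf"`.
#' @return a `snp_catalog` data.frame.
#' @export
read_snp_catalog <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "vcf") "vcf" else "tsv"
  }
  if (format == "tsv") {
    df <- .read_tsv(path)
    .assert(all(c("chrom", "pos", "ref") %in% names(df)),
            "catalog TSV needs chrom, pos, ref columns")
    out <- df[order(df$pos), , drop = FALSE]
  } else {
    .assert(requireNamespace("vcfR", quietly = TRUE),
            "reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    resolve <- function(code, ref, alt) {
      first <- substr(code, 1L, 1L)
      ifelse(is.na(first) | first == ".", NA_character_,
             ifelse(first == "0", ref, alt))
    }
    out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, stringsAsFactors = FALSE)
    for (s in colnames(gt)) {
      out[[s]] <- resolve(gt[, s], fix$REF, fix$ALT)
    }
    out <- out[order(out$pos), , drop = FALSE]
  }
  rownames(out) <- NULL
  .assert(!anyDuplicated(out[c("chrom", "pos")]), "duplicate positions in catalog")
  class(out) <- c("snp_catalog", "data.frame")
  out
}

#' Write a SNP catalog as TSV or minimal VCF
#'
#' The VCF writer emits a minimal VCFv4.2 file with CHROM/POS/ID/REF/ALT
#' and one GT sample column per strain (homozygous calls, `./.` for
#' missing), sufficient for round-tripping strain catalogs through
#' standard VCF tooling.
#'
#' @param catalog a `snp_catalog`.
#' @param path output file.
#' @param strains strain columns to emit as samples (VCF only).
#' @return `path`, invisibly.
#' @export
write_snp_catalog_tsv <- function(catalog, path) {
  .assert(inherits(catalog, "snp_catalog"), "snp_catalog required")
  .write_tsv(catalog, path)
}

#' @rdname write_snp_catalog_tsv
#' @export
write_snp_catalog_vcf <- function(catalog, path, strains = c("C3H", "NZO")) {
  .assert(inherits(catalog, "snp_catalog"), "snp_catalog required")
  .assert(all(strains %in% names(catalog)), "strain column missing")
  ref <- catalog$ref
  # ALT = the set of non-reference alleles observed across strains
  alt <- rep(NA_character_, nrow(catalog))
  gt <- matrix("./.", nrow(catalog), length(strains),
               dimnames = list(NULL, strains))
  for (i in seq_len(nrow(catalog))) {
    calls <- vapply(strains, function(s) as.character(catalog[[s]][i]),
                    character(1))
    nonref <- unique(calls[!is.na(calls) & calls != "." & calls != ref[i]])
    alt[i] <- if (length(nonref)) paste(nonref, collapse = ",") else "."
    alleles <- c(ref[i], nonref)
    for (k in seq_along(strains)) {
      cl <- calls[k]
      gt[i, k] <- if (is.na(cl) || cl == ".") "./." else {
        j <- match(cl, alleles) - 1L
        sprintf("%d/%d", j, j)
      }
    }
  }
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(catalog$chrom)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", strains), collapse = "\t"))
  body <- paste(catalog$chrom,
                format(catalog$pos, scientific = FALSE, trim = TRUE),
                sprintf("snp%06d", seq_len(nrow(catalog))),
                ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
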