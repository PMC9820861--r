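#' Construct a genetic map
#'
#' A genetic map lists genotyping markers with both physical (bp) and
#' genetic (cM) coordinates, ordered along each chromosome.  It is the
#' coordinate backbone for backcross simulation and LOD scans.
#'
#' @param marker_id character vector of unique marker names (e.g. SNP ids).
#' @param chromosome character vector of chromosome labels.
#' @param position_bp integer physical positions (1-based, >= 1).
#' @param position_cM numeric genetic positions in centimorgan (>= 0).
#'
#' @return A `data.frame` of class `genetic_map` with one row per marker,
#'   sorted by chromosome and physical position.
#'
#' @details Positions must be strictly increasing within a chromosome in
#'   both bp and cM: co-located or out-of-order markers are rejected rather
#'   than silently reordered, because inconsistent bp/cM orderings usually
#'   indicate an assembly/map mismatch.
#'
#' @examples
#' gmap <- genetic_map(paste0("mk", 1:3), "chr15",
#'                     c(50e6, 60e6, 70e6), c(0, 5, 10))
#' @export
genetic_map <- function(marker_id, chromosome, position_bp, position_cM) {
  n <- length(marker_id)
  .assert(n >= 1, "genetic map must contain at least one marker")
  .assert(length(chromosome) %in% c(1L, n), "chromosome length mismatch")
  .assert(length(position_bp) == n && length(position_cM) == n,
          "position vectors must match marker_id length")
  .assert(!anyDuplicated(marker_id), "marker ids must be unique")
  .assert(all(is.finite(position_bp)) && all(position_bp >= 1) &&
            all(position_bp == round(position_bp)),
          "position_bp must be positive integers")
  .assert(all(is.finite(position_cM)) && all(position_cM >= 0),
          "position_cM must be finite and >= 0")

  map <- data.frame(marker_id = as.character(marker_id),
                    chromosome = as.character(chromosome),
                    position_bp = as.integer(position_bp),
                    position_cM = as.numeric(position_cM),
                    stringsAsFactors = FALSE)
  map <- map[order(map$chromosome, map$position_bp), , drop = FALSE]
  rownames(map) <- NULL
  for (chr in unique(map$chromosome)) {
    sub <- map[map$chromosome == chr, ]
    .assert(all(diff(sub$position_bp) > 0),
            sprintf("bp positions must be strictly increasing on %s", chr))
    .assert(all(diff(sub$position_cM) > 0),
            sprintf("cM positions must be strictly increasing on %s", chr))
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Write / read a genetic map as TSV
#'
#' @param map a [genetic_map()].
#' @param path file path.
#' @return `path` (writer) or a `genetic_map` (reader).
#' @export
write_genetic_map <- function(map, path) {
  .assert(inherits(map, "genetic_map"), "map must be a genetic_map")
  .write_tsv(map, path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  df <- .read_tsv(path)
  genetic_map(df$marker_id, df$chromosome, df$position_bp, df$position_cM)
}
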