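# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

.is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

.is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Population (n-denominator) standard deviation.
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Deterministic substream seed derived from one top-level seed.  Each
# generator operation mixes in its own fixed offset so that, e.g., adding
# phenotype noise never perturbs the genotype stream.  Kept well below
# 2^31 so it is always a valid R integer seed.
.substream <- function(seed, offset) {
  .assert(.is_count(seed) || (is.numeric(seed) && length(seed) == 1L && is.finite(seed)),
          "seed must be a single finite number")
  (abs(as.integer(seed)) %% 1000003L) * 1009L + as.integer(offset)
}

# Fixed-format numeric rendering so that files written under the same seed
# are byte-identical across runs and platforms.
.fmt_num <- function(x, digits = 6) {
  out <- formatC(x, digits = digits, format = "g")
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
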