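# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stop with a message naming the offending argument/field.
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}

# Canonical SNP key: chrom:pos:alleleA:alleleB with alleles in alphabetical
# order, so matching across panels is allele-aware but order-insensitive.
make_snp_keys <- function(chrom, pos, a1, a2) {
  lo <- ifelse(as.character(a1) <= as.character(a2), as.character(a1),
               as.character(a2))
  hi <- ifelse(as.character(a1) <= as.character(a2), as.character(a2),
               as.character(a1))
  paste(chrom, pos, lo, hi, sep = ":")
}
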