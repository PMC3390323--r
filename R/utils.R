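# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
NLAIII_ANCHOR <- "CATG"
TAG_WIDTH <- 21L      # CATG anchor + 17 variable bases
READ_WIDTH <- 35L     # 21-bp tag + 14-bp adaptor suffix
ADAPTOR_14 <- "TCGTATGCCGTCTT"  # fixed synthetic 3' adaptor prefix

# Run `expr` under a fixed seed when one is supplied, otherwise use the
# current RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(lengths) {
  vapply(
    lengths,
    function(L) paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""),
    character(1)
  )
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %s, got %s.", name, format(min), format(x)))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %s, got %s.", name, format(min), format(x)))
  }
  invisible(x)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

assert_counts <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative counts.", name))
  }
  invisible(x)
}

# Largest-remainder allocation of `n` items to fractions summing to 1.
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
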