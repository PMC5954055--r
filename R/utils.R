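# Internal helpers shared across modules.

# Order chromosome labels naturally: chr1..chr22, chrX, chrY, then others.
chrom_levels <- function(chrom) {
  u <- unique(as.character(chrom))
  stripped <- sub("^chr", "", u)
  num <- suppressWarnings(as.integer(stripped))
  key <- ifelse(!is.na(num), num,
                ifelse(stripped == "X", 23L,
                       ifelse(stripped == "Y", 24L, 25L)))
  u[order(key, stripped)]
}

chrom_factor <- function(chrom) {
  factor(as.character(chrom), levels = chrom_levels(chrom))
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pull a single sample's profile (named numeric vector) out of a matrix,
# an expression_panel, or pass a named vector through.
as_profile <- function(x, sample = NULL) {
  if (inherits(x, "expression_panel")) x <- x$values
  if (is.matrix(x)) {
    if (is.null(sample)) {
      if (ncol(x) != 1L) stopf("sample must be named when the input has %d columns", ncol(x))
      sample <- colnames(x)[1L]
    }
    if (!sample %in% colnames(x)) stopf("sample '%s' not found", sample)
    return(setNames(x[, sample], rownames(x)))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stopf("cannot interpret input as an expression profile")
}
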