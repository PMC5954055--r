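# Fixture builders and brute-force oracles shared across test files.

# A hand-specified probe matrix (no generator involved).
make_probe_fixture <- function(values, chromosome, position = NULL) {
  n <- nrow(values)
  if (is.null(position)) position <- seq_len(n)
  if (is.null(rownames(values))) rownames(values) <- sprintf("P%03d", seq_len(n))
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  structure(list(
    values = values,
    annotation = data.frame(probe_id = rownames(values),
                            chromosome = chromosome, position = position,
                            stringsAsFactors = FALSE),
    samples = colnames(values)), class = "probe_matrix")
}

# Naive O(n * w) sliding mean.
naive_rollmean <- function(x, w) {
  n <- length(x) - w + 1
  if (n < 1) return(numeric(0))
  vapply(seq_len(n), function(i) mean(x[i:(i + w - 1)]), 0)
}

# Naive sliding median.
naive_rollmedian <- function(x, w) {
  n <- length(x) - w + 1
  if (n < 1) return(numeric(0))
  vapply(seq_len(n), function(i) median(x[i:(i + w - 1)]), 0)
}

# Brute-force quantile normalization: sort each column, average across
# columns, remap through each column's ranks (ties share the mean of the
# target values they span).
naive_quantile_normalize <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    out[, j] <- (target[lo] + target[hi]) / 2
  }
  out
}

# A minimal long-format Ct frame from a genes x samples matrix plus metadata.
make_ct_fixture <- function(mat, line = "L1", condition = "neutral",
                            day = 0L, replicate = 1L) {
  meta <- data.frame(sample = colnames(mat), line = line,
                     condition = condition, day = day, replicate = replicate,
                     stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(ncol(mat)), function(j) {
    data.frame(gene = rownames(mat), sample = colnames(mat)[j],
               line = meta$line[j], condition = meta$condition[j],
               day = meta$day[j], replicate = meta$replicate[j],
               ct = mat[, j], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("ct_matrix", "data.frame")
  out
}

# Small tissue panel config reused in teratoscore tests.
four_tissue_map <- function() {
  c(skin = "ectoderm", heart = "mesoderm", liver = "endoderm",
    placenta = "extraembryonic")
}
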