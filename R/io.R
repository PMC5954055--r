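# TSV readers and writers for every container the modules exchange.
# All formats are plain text so that simulated datasets round-trip exactly
# at full double precision (values are serialised with format "%.17g").

write_tsv <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(file, ...) {
  read.delim(file, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_num_matrix <- function(m, file, id_col) {
  df <- data.frame(rownames(m), apply(m, 2L, fmt_num), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  write_tsv(df, file)
}

read_num_matrix <- function(file, id_col) {
  df <- read_tsv(file, colClasses = "character")
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[id_col]]
  m
}

#' Write / read a probe expression matrix with its annotation
#'
#' @param x A `probe_matrix`.
#' @param matrix_file TSV path for the probe x sample log2 intensities.
#' @param annotation_file TSV path for the probe annotation
#'   (`probe_id`, `chromosome`, `position`).
#' @return `read_probe_matrix` returns a `probe_matrix`.
#' @export
write_probe_matrix <- function(x, matrix_file, annotation_file) {
  write_num_matrix(x$values, matrix_file, "probe_id")
  write_tsv(x$annotation, annotation_file)
  invisible(c(matrix_file, annotation_file))
}

#' @rdname write_probe_matrix
#' @export
read_probe_matrix <- function(matrix_file, annotation_file) {
  values <- read_num_matrix(matrix_file, "probe_id")
  ann <- read_tsv(annotation_file)
  ann$chromosome <- as.character(ann$chromosome)
  ann <- ann[match(rownames(values), ann$probe_id), , drop = FALSE]
  rownames(ann) <- NULL
  structure(list(values = values, annotation = ann,
                 samples = colnames(values)),
            class = "probe_matrix")
}

#' Write / read per-SNP allele-count tables
#'
#' A minimal VCF-like long TSV with columns CHROM, POS, REF_COUNT,
#' ALT_COUNT, SAMPLE.
#'
#' @param tables A `snp_table` or list of them (one per sample).
#' @param file TSV path.
#' @return `read_snp_tables` returns a named list of `snp_table`s.
#' @export
write_snp_tables <- function(tables, file) {
  if (is.data.frame(tables)) tables <- list(tables)
  long <- do.call(rbind, tables)
  out <- data.frame(CHROM = long$chromosome, POS = long$position,
                    REF_COUNT = long$ref_count, ALT_COUNT = long$alt_count,
                    SAMPLE = long$sample)
  write_tsv(out, file)
  invisible(file)
}

#' @rdname write_snp_tables
#' @export
read_snp_tables <- function(file) {
  df <- read_tsv(file)
  tab <- data.frame(chromosome = as.character(df$CHROM), position = df$POS,
                    ref_count = df$REF_COUNT, alt_count = df$ALT_COUNT,
                    sample = as.character(df$SAMPLE),
                    stringsAsFactors = FALSE)
  lapply(split(tab, tab$sample), function(d) {
    rownames(d) <- NULL
    class(d) <- c("snp_table", "data.frame")
    d
  })
}

#' Read SNP allele counts from a VCF with AD-style allele depths
#'
#' Maps the AD (allelic depth) FORMAT field of a VCF onto `snp_table`s.
#' Multi-allelic sites are dropped with a logged count.
#'
#' @param file VCF path (plain text or gzipped).
#' @return Named list of `snp_table`s, one per VCF sample column.
#' @export
read_snp_vcf <- function(file) {
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    message(sprintf("read_snp_vcf: dropped %d multi-allelic site(s)",
                    sum(multi)))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  ad <- ad[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  out <- lapply(colnames(ad), function(s) {
    parts <- strsplit(ad[, s], ",", fixed = TRUE)
    ref <- vapply(parts, function(p) suppressWarnings(as.integer(p[1])), 0L)
    alt <- vapply(parts, function(p) suppressWarnings(as.integer(p[2])), 0L)
    d <- data.frame(chromosome = as.character(fix[, "CHROM"]),
                    position = as.integer(fix[, "POS"]),
                    ref_count = ref, alt_count = alt, sample = s,
                    stringsAsFactors = FALSE)
    d <- d[!is.na(d$ref_count) & !is.na(d$alt_count), , drop = FALSE]
    rownames(d) <- NULL
    class(d) <- c("snp_table", "data.frame")
    d
  })
  setNames(out, colnames(ad))
}

#' Write / read a long-format Ct matrix with sample metadata
#'
#' @param ct A `ct_matrix` data frame.
#' @param file TSV path.
#' @return `read_ct_matrix` returns a `ct_matrix`.
#' @export
write_ct_matrix <- function(ct, file) {
  out <- ct
  out$ct <- fmt_num(out$ct)
  write_tsv(out, file)
  invisible(file)
}

#' @rdname write_ct_matrix
#' @export
read_ct_matrix <- function(file) {
  df <- read_tsv(file, colClasses = "character")
  df$day <- as.integer(df$day)
  df$replicate <- as.integer(df$replicate)
  df$ct <- suppressWarnings(as.numeric(df$ct))
  class(df) <- c("ct_matrix", "data.frame")
  df
}

#' Write / read an expression panel (FPKM matrix plus metadata sidecar)
#'
#' @param panel An [expression_panel()].
#' @param values_file TSV path for the genes x samples FPKM matrix.
#' @param meta_file TSV path for the sample metadata sidecar.
#' @return `read_expression_panel` returns an [expression_panel()].
#' @export
write_expression_panel <- function(panel, values_file, meta_file) {
  write_num_matrix(panel$values, values_file, "gene")
  write_tsv(panel$meta, meta_file)
  invisible(c(values_file, meta_file))
}

#' @rdname write_expression_panel
#' @export
read_expression_panel <- function(values_file, meta_file) {
  values <- read_num_matrix(values_file, "gene")
  meta <- read_tsv(meta_file, colClasses = "character")
  meta[meta == "NA"] <- NA
  expression_panel(values, meta[match(colnames(values), meta$sample), ,
                                drop = FALSE])
}

#' Write / read a projection model as a TSV bundle
#'
#' The model directory holds `basis.tsv`, `weights.tsv`,
#' `h9_reference.tsv` and `manifest.tsv` (thresholds and novelty
#' calibration).
#'
#' @param model A `projection_model`.
#' @param dir Directory path (created if needed).
#' @return `read_projection_model` returns a `projection_model`.
#' @export
write_projection_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_num_matrix(model$basis, file.path(dir, "basis.tsv"), "gene")
  write_tsv(data.frame(component = colnames(model$basis),
                       score_weight = fmt_num(model$score_weights)),
            file.path(dir, "weights.tsv"))
  write_tsv(data.frame(gene = rownames(model$basis),
                       h9_reference = fmt_num(model$h9_reference)),
            file.path(dir, "h9_reference.tsv"))
  cal <- model$novelty_calibration %||% c(intercept = 0, slope = 1)
  write_tsv(data.frame(
    key = c("threshold_pluripotency", "threshold_novelty",
            "novelty_intercept", "novelty_slope"),
    value = fmt_num(c(model$thresholds[["pluripotency"]],
                      model$thresholds[["novelty"]],
                      cal[["intercept"]], cal[["slope"]]))),
    file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname write_projection_model
#' @export
read_projection_model <- function(dir) {
  basis <- read_num_matrix(file.path(dir, "basis.tsv"), "gene")
  w <- read_tsv(file.path(dir, "weights.tsv"), colClasses = "character")
  h9 <- read_tsv(file.path(dir, "h9_reference.tsv"), colClasses = "character")
  man <- read_tsv(file.path(dir, "manifest.tsv"), colClasses = "character")
  val <- setNames(as.numeric(man$value), man$key)
  structure(list(
    basis = basis,
    score_weights = as.numeric(w$score_weight),
    h9_reference = setNames(as.numeric(h9$h9_reference), h9$gene),
    thresholds = c(pluripotency = unname(val["threshold_pluripotency"]),
                   novelty = unname(val["threshold_novelty"])),
    novelty_calibration = c(intercept = unname(val["novelty_intercept"]),
                            slope = unname(val["novelty_slope"]))),
    class = "projection_model")
}

#' Write a moving-average track as a BED-like TSV
#'
#' Columns: chromosome, window start and end probe ordinals, sample, window
#' mean.
#'
#' @param track A `ma_track` from [moving_average()].
#' @param file TSV path.
#' @export
write_ma_track <- function(track, file) {
  write_tsv(track[c("chromosome", "start", "end", "sample", "mean")], file)
  invisible(file)
}

#' Write an allelic-ratio track as a TSV
#'
#' @param track A `ratio_track` from [moving_median_track()].
#' @param file TSV path.
#' @export
write_ratio_track <- function(track, file) {
  write_tsv(track[c("chromosome", "median_position", "median_ratio",
                    "sample")], file)
  invisible(file)
}

#' Write a tissue signature as a TSV
#'
#' @param signature A `terato_signature`.
#' @param file TSV path.
#' @return `read_signature` returns a `terato_signature`.
#' @export
write_signature <- function(signature, file) {
  out <- as.data.frame(signature)
  out$reference_level <- fmt_num(out$reference_level)
  out$fold <- fmt_num(out$fold)
  write_tsv(out, file)
  invisible(file)
}

#' @rdname write_signature
#' @export
read_signature <- function(file) {
  df <- read_tsv(file, colClasses = "character")
  df$reference_level <- as.numeric(df$reference_level)
  df$fold <- as.numeric(df$fold)
  class(df) <- c("terato_signature", "data.frame")
  df
}
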