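# Plain-text interchange: whitespace-delimited dosage matrices, minimal
# genotype-only VCF, and dense/sparse relationship-matrix formats.

#' Write / read a dosage matrix
#'
#' Whitespace-delimited text: header row of SNP ids, then one row per
#' animal starting with its id. Missing genotypes are written as `NA`.
#'
#' @param dosages Animals x SNP matrix with dimnames.
#' @param path File path.
#' @return `write_dosage` returns `path` invisibly; `read_dosage` the
#'   numeric matrix.
#' @export
write_dosage <- function(dosages, path) {
  dt <- data.table::data.table(id = rownames(dosages))
  dt <- cbind(dt, data.table::as.data.table(dosages))
  data.table::fwrite(dt, path, sep = " ", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage
#' @export
read_dosage <- function(path) {
  dt <- data.table::fread(path, sep = " ", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1L]]
  m
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT fields only (`0/0`, `0/1`, `1/1`, missing
#' `./.`), REF/ALT set to placeholder alleles A/B, positions from the map.
#'
#' @param dosages Animals x SNP matrix (`NA` = missing call).
#' @param map Data frame with `snp`, `chr`, `pos_bp` matching the columns.
#' @param path Output path (plain text, uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dosages, map, path) {
  stopifnot(identical(map$snp, colnames(dosages)))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ovipred",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dosages)), collapse = "\t")),
             con)
  for (j in seq_len(ncol(dosages))) {
    g <- dosages[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(map$chr[j], map$pos_bp[j], map$snp[j], "A", "B", ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages back from a GT-only VCF
#'
#' Uses `VariantAnnotation` (suggested dependency) to parse the file, then
#' converts GT strings to alternate-allele dosages.
#'
#' @param path VCF file path.
#' @return Animals x SNP numeric matrix with `NA` for missing calls.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf requires the VariantAnnotation package", call. = FALSE)
  }
  v <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(v)$GT
  dose <- matrix(NA_real_, ncol(gt), nrow(gt),
                 dimnames = list(colnames(gt), rownames(gt)))
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
           "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2)
  dose[] <- t(matrix(lut[gt], nrow(gt), ncol(gt)))
  dose
}

#' Write / read a relationship matrix
#'
#' `"dense"` writes a CSV with an `id` header column; `"sparse"` writes
#' three columns (`id1`, `id2`, `value`) for the upper triangle including
#' the diagonal.
#'
#' @param M Symmetric relationship matrix with dimnames.
#' @param path File path.
#' @param format `"dense"` or `"sparse"`.
#' @return `write_relationship` returns `path` invisibly;
#'   `read_relationship` the matrix.
#' @export
write_relationship <- function(M, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  if (format == "dense") {
    dt <- data.table::data.table(id = rownames(M))
    dt <- cbind(dt, data.table::as.data.table(M))
    data.table::fwrite(dt, path, quote = FALSE)
  } else {
    ut <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
    dt <- data.table::data.table(id1 = rownames(M)[ut[, 1L]],
                                 id2 = colnames(M)[ut[, 2L]],
                                 value = M[ut])
    data.table::fwrite(dt, path, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_relationship
#' @export
read_relationship <- function(path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  dt <- data.table::fread(path)
  if (format == "dense") {
    M <- as.matrix(dt[, -1])
    rownames(M) <- dt[[1L]]
    return(M)
  }
  ids <- unique(c(dt$id1, dt$id2))
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  M[cbind(dt$id1, dt$id2)] <- dt$value
  M[cbind(dt$id2, dt$id1)] <- dt$value
  M
}
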