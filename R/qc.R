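# Genotype quality control: SNP filters (call rate, MAF, Hardy-Weinberg,
# LD pruning), animal filters (call rate, heterozygosity excess) and
# mean-dosage imputation, with an auditable report.

#' QC thresholds
#'
#' Defaults match routine 50K-chip QC for multi-breed sheep data: SNP call
#' rate >= 0.95, minor allele frequency >= 0.01, Hardy-Weinberg chi-square
#' p >= 1e-15, LD pruning at r^2 > 0.99, animal call rate >= 0.90 and mean
#' heterozygosity <= 0.5 (higher indicates sample contamination).
#'
#' @param snp_call_rate_min,maf_min,hwe_p_min,ld_r2_max,animal_call_rate_min,het_max
#'   Fractions/probabilities in `[0, 1]`.
#' @param ld_window Sliding-window width (in SNPs, map order) for pruning.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.95, maf_min = 0.01,
                          hwe_p_min = 1e-15, ld_r2_max = 0.99,
                          animal_call_rate_min = 0.90, het_max = 0.5,
                          ld_window = 100L) {
  vals <- c(snp_call_rate_min, maf_min, hwe_p_min, ld_r2_max,
            animal_call_rate_min, het_max)
  if (any(vals < 0 | vals > 1)) stop("thresholds must be in [0, 1]", call. = FALSE)
  structure(list(snp_call_rate_min = snp_call_rate_min, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, ld_r2_max = ld_r2_max,
                 animal_call_rate_min = animal_call_rate_min,
                 het_max = het_max, ld_window = as.integer(ld_window)),
            class = "qc_thresholds")
}

#' Per-SNP call rate
#'
#' @param genotypes Dosage matrix with `NA` for missing calls.
#' @return Named vector: fraction of non-missing entries per SNP.
#' @export
snp_call_rate <- function(genotypes) {
  if (nrow(genotypes) < 1L) stop("need at least one animal", call. = FALSE)
  colMeans(!is.na(genotypes))
}

#' Hardy-Weinberg chi-square test
#'
#' One-degree-of-freedom goodness-of-fit chi-square of observed genotype
#' counts against Hardy-Weinberg proportions at the sample allele frequency.
#' Monomorphic SNPs return p = 1 (no test possible). At the extreme
#' cut-offs used in chip QC (1e-15) only gross failures matter, so the
#' chi-square approximation is adequate.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (vectorised).
#' @return Vector of p-values.
#' @export
hwe_chisq <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0) || any(n < 1)) {
    stop("counts must be non-negative and sum to >= 1", call. = FALSE)
  }
  p <- (2 * n_hom_alt + n_het) / (2 * n)
  mono <- p == 0 | p == 1
  e_rr <- n * (1 - p)^2
  e_ra <- n * 2 * p * (1 - p)
  e_aa <- n * p^2
  chi2 <- ifelse(mono, 0,
                 (n_hom_ref - e_rr)^2 / pmax(e_rr, 1e-300) +
                   (n_het - e_ra)^2 / pmax(e_ra, 1e-300) +
                   (n_hom_alt - e_aa)^2 / pmax(e_aa, 1e-300))
  ifelse(mono, 1, pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Per-SNP HWE p-values from a dosage matrix
hwe_pvalues <- function(genotypes) {
  n0 <- colSums(genotypes == 0, na.rm = TRUE)
  n1 <- colSums(genotypes == 1, na.rm = TRUE)
  n2 <- colSums(genotypes == 2, na.rm = TRUE)
  ok <- (n0 + n1 + n2) >= 1
  out <- rep(1, ncol(genotypes))
  out[ok] <- hwe_chisq(n0[ok], n1[ok], n2[ok])
  setNames(out, colnames(genotypes))
}

#' Prune SNPs in complete linkage disequilibrium
#'
#' Greedy scan in map order with a sliding window: each SNP is compared with
#' the retained SNPs among the previous `window` positions, and dropped when
#' any pairwise `r^2` (squared Pearson correlation of dosages,
#' pairwise-complete) exceeds `r2_max`. The later SNP of an offending pair
#' is always the one dropped, so the result is deterministic.
#'
#' @param genotypes Dosage matrix (columns in map order).
#' @param r2_max Squared-correlation threshold (default 0.99).
#' @param window Window width in SNPs (default 100).
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(genotypes, r2_max = 0.99, window = 100L) {
  m <- ncol(genotypes)
  if (m <= 1L) return(colnames(genotypes))
  keep <- logical(m)
  keep[1L] <- TRUE
  for (j in 2:m) {
    lo <- max(1L, j - window)
    prev <- which(keep[lo:(j - 1L)]) + lo - 1L
    if (!length(prev)) { keep[j] <- TRUE; next }
    r <- suppressWarnings(
      cor(genotypes[, j], genotypes[, prev, drop = FALSE],
          use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0
    keep[j] <- all(r^2 <= r2_max)
  }
  colnames(genotypes)[keep]
}

#' Animal-level filters
#'
#' Flags animals whose genotype call rate is below `call_rate_min` or whose
#' mean heterozygosity (fraction of non-missing genotypes equal to 1)
#' exceeds `het_max`, the signature of a contaminated DNA sample.
#'
#' @param genotypes Dosage matrix.
#' @param call_rate_min,het_max Thresholds.
#' @return Data frame of removed animals: `id`, `call_rate`, `heterozygosity`,
#'   `reason`.
#' @export
animal_filters <- function(genotypes, call_rate_min = 0.90, het_max = 0.5) {
  if (ncol(genotypes) < 1L) stop("need at least one SNP", call. = FALSE)
  cr <- rowMeans(!is.na(genotypes))
  het <- rowMeans(genotypes == 1, na.rm = TRUE)
  bad_cr <- cr < call_rate_min
  bad_het <- !is.na(het) & het > het_max
  idx <- which(bad_cr | bad_het)
  data.frame(id = rownames(genotypes)[idx], call_rate = cr[idx],
             heterozygosity = het[idx],
             reason = ifelse(bad_cr[idx], "call_rate", "heterozygosity"),
             row.names = NULL)
}

#' Mean-dosage imputation of missing genotypes
#'
#' Replaces each missing entry with twice the observed allele frequency of
#' its SNP (the mean observed dosage), which preserves per-SNP mean dosage
#' exactly. This is a deliberate, simple substitute for haplotype-based
#' imputation and is adequate for relationship-matrix construction.
#'
#' @param genotypes Dosage matrix with `NA` for missing calls.
#' @return Numeric matrix with no missing entries.
#' @export
impute_missing <- function(genotypes) {
  g <- genotypes
  storage.mode(g) <- "double"
  mns <- colMeans(g, na.rm = TRUE)
  if (anyNA(mns)) {
    stop("SNP with all genotypes missing: ",
         paste(head(colnames(g)[is.na(mns)]), collapse = ", "), call. = FALSE)
  }
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mns[idx[, 2L]]
  g
}

#' Run the full genotype QC pipeline
#'
#' Applies, in this fixed order: SNP call rate, minor allele frequency
#' (computed on genotyped entries only), Hardy-Weinberg, LD pruning, animal
#' call rate, animal heterozygosity, then mean-dosage imputation. Every
#' removal is recorded with the offending statistic. The pipeline is
#' idempotent: re-running it on its own output removes nothing.
#'
#' @param genotypes Dosage matrix (animals x SNP, `NA` missing).
#' @param thresholds A [qc_thresholds()].
#' @return A list of class `qc_result`: `genotypes` (filtered, imputed),
#'   `report` (class `qc_report`: per-stage removals and reconciled counts).
#' @export
run_qc <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  g <- genotypes
  storage.mode(g) <- "double"
  stages <- list()
  note <- function(stage, ids, stat) {
    stages[[stage]] <<- data.frame(id = ids, stat = stat, row.names = NULL)
  }

  cr <- snp_call_rate(g)
  drop <- cr < thresholds$snp_call_rate_min
  note("snp_call_rate", colnames(g)[drop], cr[drop])
  g <- g[, !drop, drop = FALSE]

  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop <- is.na(maf) | maf < thresholds$maf_min
  note("maf", colnames(g)[drop], maf[drop])
  g <- g[, !drop, drop = FALSE]

  pv <- hwe_pvalues(g)
  drop <- pv < thresholds$hwe_p_min
  note("hwe", colnames(g)[drop], pv[drop])
  g <- g[, !drop, drop = FALSE]

  kept <- ld_prune(g, thresholds$ld_r2_max, thresholds$ld_window)
  drop <- setdiff(colnames(g), kept)
  note("ld_prune", drop, rep(NA_real_, length(drop)))
  g <- g[, kept, drop = FALSE]

  af <- animal_filters(g, thresholds$animal_call_rate_min, thresholds$het_max)
  acr <- af[af$reason == "call_rate", ]
  ahet <- af[af$reason == "heterozygosity", ]
  note("animal_call_rate", acr$id, acr$call_rate)
  note("animal_heterozygosity", ahet$id, ahet$heterozygosity)
  g <- g[setdiff(rownames(g), af$id), , drop = FALSE]

  if (nrow(g) == 0L || ncol(g) == 0L) {
    stop("QC removed every animal or every SNP", call. = FALSE)
  }
  g <- impute_missing(g)

  report <- structure(
    list(stages = stages,
         n_snp_before = ncol(genotypes), n_snp_after = ncol(g),
         n_animal_before = nrow(genotypes), n_animal_after = nrow(g),
         thresholds = thresholds,
         order = c("snp_call_rate", "maf", "hwe", "ld_prune",
                   "animal_call_rate", "animal_heterozygosity", "impute")),
    class = "qc_report")
  structure(list(genotypes = g, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> SNP %d -> %d; animals %d -> %d\n",
              x$n_snp_before, x$n_snp_after,
              x$n_animal_before, x$n_animal_after))
  for (s in names(x$stages)) {
    cat(sprintf("  %-22s removed %d\n", s, nrow(x$stages[[s]])))
  }
  invisible(x)
}

#' Turn a QC report into a tidy removal table
#'
#' @param report A `qc_report`.
#' @return Data frame: `stage`, `id`, `stat`.
#' @export
qc_report_table <- function(report) {
  rows <- lapply(names(report$stages), function(s) {
    d <- report$stages[[s]]
    if (!nrow(d)) return(NULL)
    cbind(stage = s, d)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(stage = character(), id = character(), stat = numeric())
  }
  out
}
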