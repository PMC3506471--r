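# QC fixture: a clean founder genotype matrix plus a copy with planted
# failures of each filter type, recorded so exactness can be asserted.

qc_fixture <- function(seed = 77) {
  cached(paste0("qc_fixture_", seed), {
    n <- 80L
    m <- 300L
    set.seed(seed)
    # chip-like minor-allele spectrum: mean heterozygosity ~0.36, well
    # below the 0.5 contamination threshold
    p <- runif(m, 0.1, 0.4)
    clean <- founder_genotypes(n, p, seed = seed + 1L)
    # the clean part must be genuinely clean: polymorphic, complete calls
    stopifnot(all(colMeans(clean) / 2 >= 0.05), all(colMeans(clean) / 2 <= 0.95))

    planted <- list(
      low_call_snp = c("snp3", "snp150"),
      low_maf_snp = c("snp20", "snp210"),
      hwe_snp = c("snp40", "snp260"),
      dup_snp_src = c("snp60", "snp100"),   # duplicated; the COPY is removed
      low_call_animal = c("F0007", "F0031"),
      contaminated_animal = "F0050"
    )

    g <- inject_missingness_and_contamination(
      clean, missing_rate = 0, bad_snp_ids = planted$low_call_snp,
      bad_animal_ids = planted$low_call_animal,
      contaminate_animal = planted$contaminated_animal,
      bad_call_rate = 0.1, seed = seed + 2L)

    # low-MAF SNPs: a single heterozygote among 80 animals (maf 1/160)
    for (s in planted$low_maf_snp) {
      g[, s] <- 0
      g["F0001", s] <- 1
    }
    # gross HWE failure: every animal heterozygous
    for (s in planted$hwe_snp) g[, s] <- 1
    # duplicate columns inserted right after their source (map order)
    for (s in planted$dup_snp_src) {
      pos <- which(colnames(g) == s)
      dup <- g[, s, drop = FALSE]
      colnames(dup) <- paste0(s, "_dup")
      g <- cbind(g[, 1:pos, drop = FALSE], dup,
                 g[, (pos + 1L):ncol(g), drop = FALSE])
    }
    planted$dup_snp <- paste0(planted$dup_snp_src, "_dup")
    planted$snp_removed <- c(planted$low_call_snp, planted$low_maf_snp,
                             planted$hwe_snp, planted$dup_snp)
    planted$animal_removed <- c(planted$low_call_animal,
                                planted$contaminated_animal)
    list(clean = clean, genotypes = g, planted = planted)
  })
}
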