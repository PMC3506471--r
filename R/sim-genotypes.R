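# Gene-drop genotype simulation: founder haplotypes from breed allele
# frequencies, descendant haplotypes by meiosis with Haldane recombination
# (Poisson crossover counts, no interference).

#' Drop genes through a pedigree
#'
#' Assigns each founder two haplotypes drawn from its breed's allele
#' frequencies, then simulates meiosis down the pedigree: per chromosome the
#' number of crossovers is Poisson with mean `morgans_per_chr` and crossover
#' positions are uniform (Haldane map), so offspring chromosomes are mosaics
#' of the two parental haplotypes. With `morgans_per_chr = 0` each gamete
#' chromosome is an exact copy of one parental haplotype.
#'
#' @param pedigree Pedigree data frame in parent-first order; every founder
#'   must carry a `founder_breed` present in `breed_model`, and every
#'   non-founder must have both parents recorded.
#' @param breed_model A [simulate_breed_frequencies()] result supplying the
#'   per-breed allele frequencies; its SNP count fixes the marker panel.
#' @param n_chromosomes Number of chromosomes the panel is spread over.
#' @param morgans_per_chr Genetic length per chromosome (Morgans).
#' @param seed Integer RNG seed.
#' @param keep_haplotypes Keep the two phased haplotype matrices (needed for
#'   Mendelian-consistency checks; doubles memory).
#'
#' @return A list of class `gene_drop` with `dosages` (animals x SNP integer
#'   matrix in 0/1/2, dimnames set), `map` (data frame: `snp`, `chr`,
#'   `pos_morgan`, `pos_bp`), and optionally `haplotypes = list(h1, h2)`.
#' @export
gene_drop <- function(pedigree, breed_model, n_chromosomes = 10,
                      morgans_per_chr = 1, seed = 1,
                      keep_haplotypes = FALSE) {
  stopifnot(inherits(breed_model, "breed_model"))
  validate_pedigree(pedigree)
  check_scalar(morgans_per_chr, "morgans_per_chr", lo = 0)
  half_known <- xor(is.na(pedigree$sire), is.na(pedigree$dam))
  if (any(half_known)) {
    stop(sprintf("non-founder with a single known parent: %s",
                 pedigree$id[which(half_known)[1L]]), call. = FALSE)
  }
  n_snp <- ncol(breed_model$breed_freqs)
  if (n_snp %% n_chromosomes != 0) {
    stop("SNP count must divide evenly across chromosomes", call. = FALSE)
  }
  set.seed(seed)

  snp_per_chr <- n_snp %/% n_chromosomes
  chr <- rep(seq_len(n_chromosomes), each = snp_per_chr)
  pos <- unlist(lapply(seq_len(n_chromosomes),
                       function(i) sort(runif(snp_per_chr, 0, max(morgans_per_chr, 1e-9)))))
  if (morgans_per_chr == 0) pos <- rep(0, n_snp)
  snp_ids <- colnames(breed_model$breed_freqs)
  map <- data.frame(snp = snp_ids, chr = chr, pos_morgan = pos,
                    pos_bp = as.integer(round(pos * 1e8)) + 1L,
                    stringsAsFactors = FALSE)
  chr_idx <- split(seq_len(n_snp), chr)

  n <- nrow(pedigree)
  h1 <- matrix(0L, n, n_snp, dimnames = list(pedigree$id, snp_ids))
  h2 <- h1
  row_of <- setNames(seq_len(n), pedigree$id)
  is_founder <- is.na(pedigree$sire)

  # one gamete: recombinant mosaic of a parent's two haplotypes
  gamete <- function(pa, pb) {
    out <- integer(n_snp)
    for (ci in seq_along(chr_idx)) {
      idx <- chr_idx[[ci]]
      k <- if (morgans_per_chr > 0) rpois(1L, morgans_per_chr) else 0L
      phase <- sample.int(2L, 1L) - 1L
      if (k == 0L) {
        out[idx] <- if (phase == 0L) pa[idx] else pb[idx]
      } else {
        xo <- sort(runif(k, 0, morgans_per_chr))
        seg <- (phase + findInterval(pos[idx], xo)) %% 2L
        out[idx] <- ifelse(seg == 0L, pa[idx], pb[idx])
      }
    }
    out
  }

  for (i in seq_len(n)) {
    if (is_founder[i]) {
      p <- breed_model$breed_freqs[pedigree$founder_breed[i], ]
      h1[i, ] <- rbinom(n_snp, 1L, p)
      h2[i, ] <- rbinom(n_snp, 1L, p)
    } else {
      s <- row_of[[pedigree$sire[i]]]
      d <- row_of[[pedigree$dam[i]]]
      h1[i, ] <- gamete(h1[s, ], h2[s, ])
      h2[i, ] <- gamete(h1[d, ], h2[d, ])
    }
  }

  out <- list(dosages = h1 + h2, map = map)
  if (keep_haplotypes) out$haplotypes <- list(h1 = h1, h2 = h2)
  class(out) <- "gene_drop"
  out
}

#' @export
print.gene_drop <- function(x, ...) {
  cat(sprintf("<gene_drop> %d animals x %d SNP on %d chromosomes\n",
              nrow(x$dosages), ncol(x$dosages), max(x$map$chr)))
  invisible(x)
}

#' Inject genotype missingness and planted QC failures
#'
#' Fixture builder for quality-control tests: adds background random
#' missingness, forces named SNPs and animals down to a low call rate, and
#' turns one animal into a heterozygosity-excess "contaminated sample"
#' (mean heterozygosity above 0.5, as seen when two DNA samples are mixed).
#'
#' @param genotypes Dosage matrix (animals x SNP), no missing values.
#' @param missing_rate Background probability an entry is set missing.
#' @param bad_snp_ids,bad_animal_ids Column/row names to degrade to
#'   `bad_call_rate`.
#' @param contaminate_animal Row name to fill with heterozygous calls at 80%
#'   of SNPs.
#' @param bad_call_rate Call rate forced on planted SNPs/animals.
#' @param seed Integer RNG seed.
#' @return The matrix with `NA` for missing genotypes.
#' @export
inject_missingness_and_contamination <- function(genotypes, missing_rate = 0,
                                                 bad_snp_ids = NULL,
                                                 bad_animal_ids = NULL,
                                                 contaminate_animal = NULL,
                                                 bad_call_rate = 0.1,
                                                 seed = 1) {
  check_scalar(missing_rate, "missing_rate", lo = 0, hi = 1)
  check_scalar(bad_call_rate, "bad_call_rate", lo = 0, hi = 1)
  unknown <- c(setdiff(bad_snp_ids, colnames(genotypes)),
               setdiff(bad_animal_ids, rownames(genotypes)),
               setdiff(contaminate_animal, rownames(genotypes)))
  if (length(unknown)) {
    stop("unknown ids: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  g <- genotypes
  storage.mode(g) <- "double"
  if (missing_rate > 0) {
    g[runif(length(g)) < missing_rate] <- NA
  }
  for (s in bad_snp_ids) {
    g[runif(nrow(g)) >= bad_call_rate, s] <- NA
  }
  for (a in bad_animal_ids) {
    g[a, runif(ncol(g)) >= bad_call_rate] <- NA
  }
  if (!is.null(contaminate_animal)) {
    het <- runif(ncol(g)) < 0.8
    g[contaminate_animal, het] <- 1
  }
  g
}
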