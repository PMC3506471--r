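# Relationship matrices: pedigree numerator matrix A (tabular method),
# genomic relationship matrix G, and pedigree breed composition Q.

# Topologically sort a pedigree; error (naming the offending ids) on a cycle.
topological_order <- function(ped) {
  n <- nrow(ped)
  pos <- setNames(seq_len(n), ped$id)
  placed <- logical(n)
  order <- integer(n)
  k <- 0L
  remaining <- seq_len(n)
  repeat {
    ready <- remaining[vapply(remaining, function(i) {
      s <- ped$sire[i]; d <- ped$dam[i]
      (is.na(s) || placed[pos[[s]]]) && (is.na(d) || placed[pos[[d]]])
    }, logical(1))]
    if (!length(ready)) {
      if (!length(remaining)) break
      stop("pedigree contains a cycle involving: ",
           paste(head(ped$id[remaining], 5L), collapse = ", "), call. = FALSE)
    }
    order[k + seq_along(ready)] <- ready
    k <- k + length(ready)
    placed[ready] <- TRUE
    remaining <- setdiff(remaining, ready)
    if (!length(remaining)) break
  }
  order
}

#' Build the pedigree numerator relationship matrix A
#'
#' Computes expected additive relationships (twice the kinship) by the
#' tabular method: `a(i,i) = 1 + 0.5 a(sire, dam)` and
#' `a(i,j) = 0.5 (a(j, sire) + a(j, dam))`, with unknown parents
#' contributing zero. The pedigree is topologically sorted first; a cyclic
#' pedigree is an error naming the animals involved.
#'
#' @param pedigree Pedigree data frame (`id`, `sire`, `dam`).
#' @return Symmetric matrix with `dimnames` equal to `pedigree$id` (input
#'   order) and attribute `kind = "A"`.
#' @export
build_nrm <- function(pedigree) {
  ord <- topological_order(pedigree)
  ped <- pedigree[ord, ]
  pos <- setNames(seq_len(nrow(ped)), ped$id)
  s <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  d <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  A <- nrm_tabular(as.integer(s), as.integer(d))
  dimnames(A) <- list(ped$id, ped$id)
  A <- A[pedigree$id, pedigree$id]
  attr(A, "kind") <- "A"
  A
}

#' Build the genomic relationship matrix G
#'
#' Computes G from a complete (imputed) dosage matrix using allele
#' frequencies observed over all genotyped animals pooled across breeds (no
#' breed base-frequency adjustment). SNPs with pooled allele frequency below
#' `freq_min` (or above `1 - freq_min`) are excluded for numerical
#' stability.
#'
#' Two estimators are available. `"yang"` (default) uses, per SNP k with
#' frequency p:
#' off-diagonal `(x_i - 2p)(x_j - 2p) / (2p(1-p))` and diagonal
#' `1 + (x^2 - (1 + 2p) x + 2 p^2) / (2p(1-p))`, each averaged over SNPs.
#' `"vanraden"` is the average-scaled variant `G = Z Z' / m` with `Z` the
#' per-SNP standardised dosages, which makes GBLUP exactly equivalent to
#' equal-variance SNP-BLUP (ridge regression).
#'
#' @param genotypes Complete dosage matrix (animals x SNP, dimnames set).
#' @param freq_min Allele-frequency exclusion threshold (default 0.005).
#' @param method `"yang"` or `"vanraden"`.
#' @return Symmetric matrix with animal dimnames, attributes `kind = "G"`,
#'   `method`, `n_snp_used`, and `freqs` (the pooled frequencies used).
#' @export
build_grm <- function(genotypes, freq_min = 0.005,
                      method = c("yang", "vanraden")) {
  method <- match.arg(method)
  if (anyNA(genotypes)) {
    stop("genotypes must be complete (impute first)", call. = FALSE)
  }
  p <- colMeans(genotypes) / 2
  keep <- p >= freq_min & p <= 1 - freq_min
  if (!any(keep)) stop("no SNPs left after frequency exclusion", call. = FALSE)
  X <- genotypes[, keep, drop = FALSE]
  p <- p[keep]
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNP in G calculation; increase freq_min", call. = FALSE)
  }
  m <- ncol(X)
  w <- 1 / sqrt(2 * p * (1 - p))
  Z <- sweep(sweep(X, 2L, 2 * p), 2L, w, `*`)
  G <- tcrossprod(Z) / m
  if (method == "yang") {
    # Yang-style diagonal: distinct estimator of 1 + F_i
    d <- X^2 - sweep(X, 2L, 1 + 2 * p, `*`)
    d <- sweep(d, 2L, 2 * p^2, `+`)
    d <- sweep(d, 2L, 2 * p * (1 - p), `/`)
    diag(G) <- 1 + rowMeans(d)
  }
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  attr(G, "kind") <- "G"
  attr(G, "method") <- method
  attr(G, "n_snp_used") <- m
  attr(G, "freqs") <- p
  G
}

#' Breed composition from pedigree
#'
#' Derives per-animal breed fractions recursively: founders are unit vectors
#' on their labelled breed and every non-founder is the average of its
#' parents' fractions. Rows sum to 1.
#'
#' @param pedigree Pedigree data frame with `founder_breed` labels on all
#'   founders.
#' @return Matrix (animals x breeds) with rownames `pedigree$id`.
#' @export
breed_composition <- function(pedigree) {
  ord <- topological_order(pedigree)
  ped <- pedigree[ord, ]
  founder <- is.na(ped$sire) & is.na(ped$dam)
  if (any(founder & is.na(ped$founder_breed))) {
    stop("founder without breed label: ",
         ped$id[which(founder & is.na(ped$founder_breed))[1L]], call. = FALSE)
  }
  breeds <- sort(unique(ped$founder_breed[founder]))
  Q <- matrix(0, nrow(ped), length(breeds),
              dimnames = list(ped$id, breeds))
  pos <- setNames(seq_len(nrow(ped)), ped$id)
  for (i in seq_len(nrow(ped))) {
    if (founder[i]) {
      Q[i, ped$founder_breed[i]] <- 1
    } else {
      Q[i, ] <- 0.5 * (Q[pos[[ped$sire[i]]], ] + Q[pos[[ped$dam[i]]], ])
    }
  }
  Q[pedigree$id, , drop = FALSE]
}

#' Relatedness of validation animals to a reference set
#'
#' For each validation animal, summarises its genomic relationships to the
#' reference population as (i) the mean of the squared relationships and
#' (ii) the mean of its 10 largest relationships. These are the relatedness
#' measures most predictive of realised prediction accuracy.
#'
#' @param G Genomic relationship matrix.
#' @param validation_ids,reference_ids Disjoint id sets (rownames of `G`).
#' @return Data frame: `id`, `mean_sq`, `top10_mean`.
#' @export
relatedness_to_reference <- function(G, validation_ids, reference_ids) {
  stopifnot(all(validation_ids %in% rownames(G)),
            all(reference_ids %in% rownames(G)))
  if (length(intersect(validation_ids, reference_ids))) {
    stop("validation and reference ids must be disjoint", call. = FALSE)
  }
  k <- min(10L, length(reference_ids))
  if (k < 10L) {
    warning("fewer than 10 reference animals; top-k uses all available")
  }
  B <- G[validation_ids, reference_ids, drop = FALSE]
  data.frame(
    id = validation_ids,
    mean_sq = rowMeans(B^2),
    top10_mean = apply(B, 1L, function(r) mean(sort(r, decreasing = TRUE)[seq_len(k)])),
    row.names = NULL
  )
}
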