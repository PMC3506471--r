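# Breed allele-frequency model: Balding-Nichols divergence around a shared
# ancestral frequency spectrum.

DEFAULT_BREEDS <- c("Merino", "BorderLeicester", "PolledDorset",
                    "WhiteSuffolk", "Texel", "Suffolk")

#' Simulate breed allele frequencies under a Balding-Nichols model
#'
#' Draws an ancestral allele-frequency spectrum and, for each breed, per-SNP
#' frequencies from a Beta distribution centred on the ancestral frequency
#' `p` with between-breed variance `fst * p * (1 - p)`. With `fst = 0` all
#' breeds share the ancestral frequencies exactly.
#'
#' @param n_snp Number of SNPs (>= 1).
#' @param n_breeds Number of breeds (>= 2, so a breed-regression term is
#'   always estimable downstream).
#' @param fst Wright's fixation index controlling breed divergence, in
#'   `[0, 0.5]`. Sheep meat breeds diverge at roughly 0.05-0.15.
#' @param seed Integer RNG seed; the result is deterministic given the seed.
#' @param breed_names Optional character vector of breed labels; defaults to
#'   the first `n_breeds` of Merino, BorderLeicester, PolledDorset,
#'   WhiteSuffolk, Texel, Suffolk (recycled with suffixes beyond six).
#' @param ancestral_freqs Optional numeric vector of length `n_snp` in (0,1);
#'   by default drawn uniformly on (0.05, 0.95).
#'
#' @return An object of class `breed_model`: a list with `n_breeds`,
#'   `breed_names`, `fst`, `ancestral_freqs` (length `n_snp`) and
#'   `breed_freqs` (`n_breeds` x `n_snp` matrix, rownames = breeds).
#' @export
#' @examples
#' bm <- simulate_breed_frequencies(200, n_breeds = 3, fst = 0.1, seed = 1)
#' range(bm$breed_freqs)
simulate_breed_frequencies <- function(n_snp, n_breeds = 2, fst = 0.1,
                                       seed = 1, breed_names = NULL,
                                       ancestral_freqs = NULL) {
  check_scalar(n_snp, "n_snp", lo = 1)
  check_scalar(n_breeds, "n_breeds", lo = 2)
  check_scalar(fst, "fst", lo = 0, hi = 0.5)
  n_snp <- as.integer(n_snp)
  n_breeds <- as.integer(n_breeds)
  if (is.null(breed_names)) {
    breed_names <- if (n_breeds <= length(DEFAULT_BREEDS)) {
      DEFAULT_BREEDS[seq_len(n_breeds)]
    } else {
      c(DEFAULT_BREEDS, paste0("Breed", seq_len(n_breeds - length(DEFAULT_BREEDS))))
    }
  }
  stopifnot(length(breed_names) == n_breeds, !anyDuplicated(breed_names))

  set.seed(seed)
  if (is.null(ancestral_freqs)) {
    ancestral_freqs <- runif(n_snp, 0.05, 0.95)
  }
  stopifnot(length(ancestral_freqs) == n_snp,
            all(ancestral_freqs > 0), all(ancestral_freqs < 1))

  if (fst == 0) {
    breed_freqs <- matrix(rep(ancestral_freqs, each = n_breeds),
                          nrow = n_breeds)
  } else {
    # Beta(p(1-F)/F, (1-p)(1-F)/F): mean p, variance F p (1-p)
    scale <- (1 - fst) / fst
    a <- ancestral_freqs * scale
    b <- (1 - ancestral_freqs) * scale
    breed_freqs <- matrix(
      rbeta(n_breeds * n_snp, rep(a, each = n_breeds), rep(b, each = n_breeds)),
      nrow = n_breeds
    )
  }
  dimnames(breed_freqs) <- list(breed_names, paste0("snp", seq_len(n_snp)))

  structure(
    list(n_breeds = n_breeds, breed_names = breed_names, fst = fst,
         ancestral_freqs = ancestral_freqs, breed_freqs = breed_freqs),
    class = "breed_model"
  )
}

#' @export
print.breed_model <- function(x, ...) {
  cat(sprintf("<breed_model> %d breeds x %d SNP, fst = %g\n",
              x$n_breeds, length(x$ancestral_freqs), x$fst))
  cat("  breeds:", paste(x$breed_names, collapse = ", "), "\n")
  invisible(x)
}
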