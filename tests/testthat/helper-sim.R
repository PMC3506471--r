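# Shared fixtures, generated in code and cached for the duration of a test
# run. Everything is seeded, so fixtures are identical across runs.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small complete dataset reused by several module tests
small_sim <- function() {
  cached("small_sim", {
    cfg <- sim_config(n_snp = 300, n_chromosomes = 10, n_sires_A = 8,
                      family_size_A = 18, n_sires_B = 4, family_size_B = 20,
                      n_founders_per_breed = c(Merino = 50, BorderLeicester = 6),
                      h2 = 0.4, seed = 42)
    simulate_dataset(cfg)
  })
}

# founder-only pedigree: n unrelated animals of one breed
founder_pedigree <- function(n, breed = "Merino", prefix = "F") {
  data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
             sire = NA_character_, dam = NA_character_,
             generation = 0L, founder_breed = breed,
             sex = rep(c("M", "F"), length.out = n),
             stringsAsFactors = FALSE)
}

# founder-population dosage matrix with allele frequencies p
founder_genotypes <- function(n, p, seed = 1, prefix = "F") {
  set.seed(seed)
  X <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
  dimnames(X) <- list(sprintf("%s%04d", prefix, seq_len(n)),
                      sprintf("snp%d", seq_along(p)))
  X
}

# random symmetric positive-definite matrix with unit-scale diagonal
random_spd <- function(q, seed) {
  set.seed(seed)
  B <- matrix(rnorm(q * (q + 2L)), q + 2L, q)
  K <- crossprod(B) / (q + 2L)
  K + diag(0.5, q)
}

# direct GLS/BLUP oracle: independent of the MME code path
gls_blup_oracle <- function(y, X, Z, K, sigma2, sigma_e2) {
  n <- length(y)
  V <- diag(sigma_e2, n)
  for (nm in names(Z)) {
    V <- V + sigma2[[nm]] * Z[[nm]] %*% K[[nm]] %*% t(Z[[nm]])
  }
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- Vi %*% (y - X %*% b)
  u <- lapply(names(Z), function(nm) {
    drop(sigma2[[nm]] * K[[nm]] %*% t(Z[[nm]]) %*% r)
  })
  names(u) <- names(Z)
  list(b = drop(b), u = u)
}

# independent REML log-likelihood (same constant convention as the package
# documents): -0.5 (log|V| + log|X'V^-1 X| + y'Py), all by direct inversion
reml_ll_oracle <- function(y, X, V) {
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus[1] + determinant(XtViX)$modulus[1] +
            drop(t(y) %*% P %*% y))
}
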