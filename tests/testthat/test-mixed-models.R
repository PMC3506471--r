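# Design construction, REML, Henderson MME, GBLUP prediction, adjustment

test_that("reference-level coding yields the expected design columns", {
  ph <- data.frame(id = paste0("a", 1:8),
                   y = rnorm(8),
                   sex = rep(c("M", "F"), 4),
                   cg = rep(c("g1", "g2"), each = 4))
  spec <- model_spec(fixed_factors = c("sex", "cg"), covariates = NULL)
  des <- build_design(ph, spec)
  expect_equal(ncol(des$X), 3L)   # intercept + one per factor
  # genotyped-animal restriction
  des2 <- build_design(ph, spec, restrict_to = paste0("a", 1:6))
  expect_equal(length(des2$y), 6L)
  # covariates pass through unchanged
  ph$hcwt <- c(10, 20, 30, 40, 50, 60, 70, 80)
  des3 <- build_design(ph, model_spec(fixed_factors = "sex", covariates = "hcwt"))
  expect_equal(unname(des3$X[, "hcwt"]), ph$hcwt)
})

test_that("MME solutions equal direct GLS on random tiny instances", {
  for (case in 1:10) {
    set.seed(300 + case)
    n <- sample(10:20, 1)
    p <- sample(1:3, 1)
    q <- sample(3:6, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    lv <- paste0("u", 1:q)
    Z <- list(t1 = incidence_matrix(sample(lv, n, TRUE), lv))
    K <- list(t1 = random_spd(q, 400 + case))
    s2 <- c(t1 = runif(1, 0.2, 2))
    se2 <- runif(1, 0.3, 1.5)
    y <- rnorm(n)
    mme <- solve_mme(y, X, Z, K, s2, se2)
    oracle <- gls_blup_oracle(y, X, Z, K, s2, se2)
    expect_lt(max(abs(mme$b - oracle$b)), 1e-8)
    expect_lt(max(abs(mme$u$t1 - oracle$u$t1)), 1e-8)
    expect_lt(mme$rel_residual, 1e-8)
  }
})

test_that("vanishing variance shrinks random effects to zero", {
  set.seed(5)
  n <- 15
  X <- matrix(1, n, 1)
  lv <- paste0("u", 1:5)
  Z <- list(a = incidence_matrix(sample(lv, n, TRUE), lv))
  K <- list(a = diag(5))
  sol <- solve_mme(rnorm(n), X, Z, K, c(a = 1e-20), 1)
  expect_true(all(sol$u$a == 0))
})

test_that("identical-information records get identical predictions", {
  set.seed(6)
  lv <- c("t1", "t2")
  ids <- rep(lv, each = 4)
  Z <- list(a = incidence_matrix(ids, lv))
  y <- rep(c(1.5, -0.5), each = 4)   # twins: same records per level
  # swap the two levels: predictions must swap accordingly, equal information
  sol <- solve_mme(y, matrix(1, 8, 1), Z, list(a = diag(2)), c(a = 1), 1)
  expect_equal(abs(sol$u$a[["t1"]]), abs(sol$u$a[["t2"]]), tolerance = 1e-10)
})

test_that("REML matches a likelihood-grid oracle on a tiny instance", {
  set.seed(7)
  ped <- rbind(founder_pedigree(10),
               data.frame(id = paste0("k", 1:20),
                          sire = sample(paste0("F", sprintf("%04d", 1:5)), 20, TRUE),
                          dam = sample(paste0("F", sprintf("%04d", 6:10)), 20, TRUE),
                          generation = 1L, founder_breed = NA, sex = "M"))
  A <- build_nrm(ped)
  n <- nrow(ped)
  X <- cbind(1, rnorm(n))
  L <- chol(A + diag(1e-8, n))
  y <- drop(crossprod(L, rnorm(n)) * sqrt(0.8)) + rnorm(n, 0, sqrt(0.5))
  fit <- reml_fit(y, X, random = list(animal = A))
  # independent 2-D grid search over (sigma_a2, sigma_e2)
  grid_opt <- function(centre, width, steps) {
    sa <- seq(max(0.01, centre[1] - width), centre[1] + width, length.out = steps)
    se <- seq(max(0.01, centre[2] - width), centre[2] + width, length.out = steps)
    best <- c(NA, NA); best_ll <- -Inf
    for (i in sa) for (j in se) {
      ll <- reml_ll_oracle(y, X, i * A + diag(j, n))
      if (ll > best_ll) { best_ll <- ll; best <- c(i, j) }
    }
    list(par = best, ll = best_ll)
  }
  g1 <- grid_opt(c(1, 1), 0.95, 21)
  g2 <- grid_opt(g1$par, 0.1, 21)
  g3 <- grid_opt(g2$par, 0.011, 23)
  expect_lt(abs(fit$sigma2[["animal"]] - g3$par[1]), 2e-3)
  expect_lt(abs(fit$sigma2[["residual"]] - g3$par[2]), 2e-3)
  expect_lt(abs(fit$loglik - g3$ll), 1e-2)
})

test_that("REML is invariant to adding a constant to the response", {
  sim <- small_sim()
  A <- build_nrm(sim$pedigree)
  spec <- model_spec(covariates = NULL)
  des <- build_design(sim$phenotypes, spec, restrict_to = rownames(A))
  M <- list(animal = A[des$ids, des$ids])
  f1 <- reml_fit(des$y, des$X, M)
  f2 <- reml_fit(des$y + 100, des$X, M)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-8)
})

test_that("pure-noise phenotypes on a family pedigree give near-zero h2", {
  set.seed(8)
  ped <- rbind(founder_pedigree(30),
               data.frame(id = paste0("k", 1:500),
                          sire = sample(sprintf("F%04d", 1:15), 500, TRUE),
                          dam = sample(sprintf("F%04d", 16:30), 500, TRUE),
                          generation = 1L, founder_breed = NA, sex = "M"))
  A <- build_nrm(ped)
  idx <- paste0("k", 1:500)
  y <- rnorm(500)
  fit <- reml_fit(y, matrix(1, 500, 1), random = list(animal = A[idx, idx]))
  expect_lt(fit$sigma2[["animal"]] / sum(fit$sigma2), 0.05)
})

test_that("h2 recovery at a moderate scale", {
  cfg <- sim_config(n_snp = 300, n_chromosomes = 10, n_sires_A = 25,
                    family_size_A = 30, n_sires_B = 10, family_size_B = 30,
                    n_founders_per_breed = c(Merino = 100, BorderLeicester = 8),
                    h2 = 0.3, hcwt_beta = 0, seed = 31)
  sim <- simulate_dataset(cfg)
  A <- build_nrm(sim$pedigree)
  spec <- model_spec(covariates = "age",
                     fixed_factors = c("sex", "birth_type", "rearing_type",
                                       "cg", "age_of_dam"))
  # the age-of-dam dummies sum to a cohort indicator already spanned by the
  # contemporary groups; the QR drop of the aliased column is expected
  des <- suppressWarnings(build_design(sim$phenotypes, spec,
                                       restrict_to = rownames(A)))
  Q <- breed_composition(sim$pedigree)
  fit <- reml_fit(des$y, des$X,
                  random = list(animal = A[des$ids, des$ids],
                                breed = tcrossprod(Q[des$ids, , drop = FALSE])))
  expect_lt(abs(fit$h2 - 0.3), 0.1)
})

test_that("GBLUP prediction flows through relationship links", {
  set.seed(9)
  ids <- c(paste0("r", 1:40), "clone", "lone")
  K <- diag(length(ids)); dimnames(K) <- list(ids, ids)
  K["clone", "r1"] <- K["r1", "clone"] <- 1   # genomic duplicate of r1
  u <- drop(crossprod(chol(K + diag(1e-8, length(ids))), rnorm(length(ids))))
  ph <- data.frame(id = ids, y = u + rnorm(length(ids), 0, 0.5))
  spec <- model_spec(fixed_factors = NULL, covariates = NULL)
  fit <- gblup_predict(ph, spec, K = list(genomic = K),
                       validation_ids = c("clone", "lone"),
                       components = c(genomic = 1, residual = 0.25))
  # the clone inherits r1's prediction exactly (identical K rows off ref)
  expect_equal(fit$u$genomic[["clone"]], fit$u$genomic[["r1"]],
               tolerance = 1e-10)
  # an unrelated animal gets no information
  expect_equal(fit$u$genomic[["lone"]], 0, tolerance = 1e-10)
  # no validation phenotype in the reference design
  expect_false(any(c("clone", "lone") %in% fit$reference_ids))
})

test_that("GBLUP with the VanRaden-variant G equals ridge-regression SNP-BLUP", {
  # desk-scale version of the equivalence (full scale in the acceptance suite)
  set.seed(10)
  n <- 60; m <- 120
  g <- founder_genotypes(n, runif(m, 0.15, 0.85), seed = 15)
  G <- build_grm(g, method = "vanraden")
  sg2 <- 0.6; se2 <- 0.4
  y <- rnorm(n)
  val <- rownames(g)[1:10]
  ph <- data.frame(id = rownames(g), y = y)
  spec <- model_spec(fixed_factors = NULL, covariates = NULL)
  fit <- gblup_predict(ph, spec, K = list(genomic = G), validation_ids = val,
                       components = c(genomic = sg2, residual = se2))
  # independent oracle: ridge regression on standardised dosages with an
  # unpenalised intercept, lambda = m * se2 / sg2
  p <- colMeans(g) / 2
  Z <- sweep(sweep(g, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), `/`)
  ref <- setdiff(rownames(g), val)
  Zr <- Z[ref, ]
  lam <- m * se2 / sg2
  C <- rbind(cbind(length(ref), t(rep(1, length(ref))) %*% Zr),
             cbind(t(Zr) %*% rep(1, length(ref)), crossprod(Zr) + diag(lam, m)))
  sol <- solve(C, c(sum(y[match(ref, rownames(g))]),
                    crossprod(Zr, y[match(ref, rownames(g))])))
  ghat_oracle <- drop(Z %*% sol[-1])
  expect_lt(max(abs(fit$u$genomic[val] - ghat_oracle[match(val, rownames(g))])),
            1e-6)
})

test_that("phenotype adjustment removes fixed and breed effects", {
  sim <- small_sim()
  Q <- breed_composition(sim$pedigree)
  spec <- model_spec(covariates = NULL)
  ys <- adjust_phenotypes(sim$phenotypes, spec, Q = Q,
                          restrict_to = rownames(sim$dosages))
  expect_lt(abs(mean(ys)), 1e-8)
  # idempotence: adjusting the adjusted phenotypes changes nothing
  ph2 <- sim$phenotypes[sim$phenotypes$id %in% names(ys), ]
  ph2$y <- as.numeric(ys[ph2$id])
  # the fixed part is a projection, so re-adjustment is near-identity; the
  # random breed term shrinks, making it a contraction rather than exactly
  # idempotent -- hence the looser tolerance here
  ys2 <- adjust_phenotypes(ph2, spec, Q = Q, restrict_to = rownames(sim$dosages))
  expect_lt(max(abs(ys2[names(ys)] - ys)), 1e-6)
  # without the random term, adjustment is an exact projection
  ph3 <- ph2
  ys3 <- adjust_phenotypes(ph3, spec)
  ph3$y <- as.numeric(ys3[ph3$id])
  ys4 <- adjust_phenotypes(ph3, spec)
  expect_lt(max(abs(ys4 - ys3)), 1e-10)
})

test_that("with no fixed effects or breed term adjustment is mean-centring", {
  ph <- data.frame(id = paste0("a", 1:20), y = rnorm(20, 5))
  spec <- model_spec(fixed_factors = NULL, covariates = NULL)
  ys <- adjust_phenotypes(ph, spec)
  expect_equal(as.numeric(ys), ph$y - mean(ph$y), tolerance = 1e-12)
})

test_that("fixed-effects-only data leaves residual variance after adjustment", {
  set.seed(11)
  n <- 400
  sex <- sample(c("M", "F"), n, TRUE)
  cgl <- sample(paste0("g", 1:5), n, TRUE)
  eff_sex <- c(M = 1.2, F = -0.4)
  eff_cg <- setNames(rnorm(5, 0, 2), paste0("g", 1:5))
  se <- 0.7
  ph <- data.frame(id = paste0("a", 1:n), sex = sex, cg = cgl,
                   y = 10 + eff_sex[sex] + eff_cg[cgl] + rnorm(n, 0, se))
  ys <- adjust_phenotypes(ph, model_spec(fixed_factors = c("sex", "cg"),
                                         covariates = NULL))
  expect_equal(var(ys), se^2, tolerance = 0.2)
})
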