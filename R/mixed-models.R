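# Linear mixed models for genetic evaluation: design construction, REML
# variance components, Henderson mixed-model equations, GBLUP prediction and
# fixed-effect adjustment of phenotypes.
#
# Two model shapes are used throughout:
#   model 1 (pedigree):  y = 1mu + Xb + Z a        + Z Q q + e
#   model 2 (genomic):   y = 1mu + Xb + Z a + Z g  + Z Q q + e
# with a ~ N(0, sa2 A), g ~ N(0, sg2 G), q ~ N(0, sq2 I) fitted as random
# partial regressions on the breed-composition columns of Q.

#' Model specification
#'
#' @param response Name of the trait column.
#' @param fixed_factors Factor columns entering the fixed part with
#'   reference-level coding. The contemporary group must be supplied as a
#'   single column (`cg`), constructed as birth year x site x slaughter
#'   group.
#' @param covariates Numeric covariate columns (e.g. the carcass-weight
#'   stand-in `hcwt`, `age`). Excluded for dressing-percentage/lean-yield
#'   style traits by simply omitting them here.
#' @param random_terms Named character vector mapping term names to
#'   relationship kinds: `"A"`, `"G"`, or `"Q"` (breed partial regressions
#'   with i.i.d. coefficient variance).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response = "y",
                       fixed_factors = c("sex", "birth_type", "rearing_type", "cg"),
                       covariates = "hcwt",
                       random_terms = c(animal = "A", breed = "Q")) {
  structure(list(response = response, fixed_factors = fixed_factors,
                 covariates = covariates, random_terms = random_terms),
            class = "model_spec")
}

#' Build fixed-effect design matrices
#'
#' Constructs the response vector and a full-rank fixed-effect matrix
#' (intercept plus reference-level coded factors and covariates). Records
#' with missing response, or with ids outside `restrict_to` (the genotyped
#' set) are dropped. Aliased columns are removed by QR with a warning.
#'
#' @param phenotypes Phenotype data frame including an `id` column.
#' @param spec A [model_spec()].
#' @param restrict_to Optional id vector; records outside it are excluded
#'   (e.g. the restriction of phenotypes to genotyped animals).
#' @return List: `y`, `X`, `ids` (animal id per record), `keep` (row index
#'   into `phenotypes`).
#' @export
build_design <- function(phenotypes, spec, restrict_to = NULL) {
  stopifnot(inherits(spec, "model_spec"), "id" %in% names(phenotypes))
  keep <- !is.na(phenotypes[[spec$response]])
  if (!is.null(restrict_to)) keep <- keep & phenotypes$id %in% restrict_to
  used <- intersect(c(spec$fixed_factors, spec$covariates), names(phenotypes))
  if (length(used)) {
    cc <- stats::complete.cases(phenotypes[, used, drop = FALSE])
    if (any(keep & !cc)) {
      warning(sum(keep & !cc), " record(s) dropped for missing factor/covariate values")
    }
    keep <- keep & cc
  }
  dat <- phenotypes[keep, , drop = FALSE]
  if (!nrow(dat)) stop("no usable records", call. = FALSE)

  terms <- character(0)
  for (f in spec$fixed_factors) {
    dat[[f]] <- factor(dat[[f]])
    # cohort-specific factors code "does not apply" as "none": make it the
    # reference so the intercept absorbs it instead of aliasing a column
    if ("none" %in% levels(dat[[f]])) dat[[f]] <- stats::relevel(dat[[f]], "none")
    if (nlevels(dat[[f]]) > 1L) terms <- c(terms, f)
  }
  terms <- c(terms, spec$covariates)
  fml <- if (length(terms)) {
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  } else ~1
  X <- stats::model.matrix(fml, data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    warning("dropping aliased fixed-effect columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  list(y = dat[[spec$response]], X = X, ids = dat$id, keep = which(keep))
}

# REML log-likelihood (constant terms dropped):
#   -0.5 * (log|V| + log|X' V^-1 X| + y' P y)
reml_loglik_direct <- function(y, X, V) {
  cV <- chol(V)
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  XtViX <- crossprod(X, Vi_X)
  b <- solve(XtViX, crossprod(Vi_X, y))
  yPy <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * b)
  -0.5 * (2 * sum(log(diag(cV))) + determinant(XtViX)$modulus[1] + yPy)
}

# Polish a smooth 1-D minimum beyond optimize()'s sqrt(eps) precision:
# a few central-difference Newton steps with shrinking step size.
refine_minimum <- function(f, x0, h = 1e-4, iters = 4L) {
  x <- x0
  fx <- f(x)
  for (i in seq_len(iters)) {
    fp <- f(x + h); fm <- f(x - h)
    curv <- fp - 2 * fx + fm
    if (!is.finite(curv) || curv <= 0) break
    step <- -0.5 * h * (fp - fm) / curv
    step <- max(min(step, 10 * h), -10 * h)
    xn <- x + step
    fn <- f(xn)
    if (is.finite(fn) && fn <= fx) { x <- xn; fx <- fn }
    h <- h / 10
  }
  x
}

# Profiled single-component REML for a low-rank term M = Z Z' (Z: n x r,
# r << n). All criterion pieces reduce to r x r algebra via Woodbury:
#   Vbar = lambda Z Z' + I,  Vbar^-1 = I - lambda Z A^-1 Z',  A = I + lambda Z'Z
reml_lowrank <- function(y, X, Z) {
  n <- length(y); p <- ncol(X); r <- ncol(Z)
  ZtZ <- crossprod(Z); Zty <- crossprod(Z, y); ZtX <- crossprod(Z, X)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)

  pieces <- function(loglambda) {
    lam <- exp(loglambda)
    A <- diag(r) + lam * ZtZ
    cA <- chol(A)
    sv <- function(B) backsolve(cA, forwardsolve(t(cA), B))
    XtViX <- XtX - lam * crossprod(ZtX, sv(ZtX))
    XtViy <- Xty - lam * crossprod(ZtX, sv(Zty))
    ytViy <- yty - lam * crossprod(Zty, sv(Zty))
    b <- solve(XtViX, XtViy)
    rss <- drop(ytViy - crossprod(XtViy, b))
    list(logdetV = 2 * sum(log(diag(cA))),
         logdetXVX = determinant(XtViX)$modulus[1], rss = rss)
  }
  crit <- function(loglambda) {
    pc <- pieces(loglambda)
    se2 <- pc$rss / (n - p)
    (n - p) * log(se2) + pc$logdetV + pc$logdetXVX + (n - p)
  }
  grid <- seq(-18, 12, length.out = 40)
  vals <- vapply(grid, crit, numeric(1))
  i <- which.min(vals)
  opt <- optimize(crit, c(grid[max(1L, i - 1L)], grid[min(length(grid), i + 1L)]),
                  tol = 1e-10)
  xopt <- refine_minimum(crit, opt$minimum)
  lam <- exp(xopt)
  pc <- pieces(xopt)
  se2 <- pc$rss / (n - p)
  ll <- -0.5 * (n * log(se2) + pc$logdetV + pc$logdetXVX - p * log(se2) + (n - p))
  list(sigma2 = lam * se2, sigma_e2 = se2, loglik = ll,
       converged = TRUE, n_iter = 1L)
}

# Profiled single-component REML via spectral decomposition of M:
# V = s2 M + se2 I = se2 (lambda M + I); everything is diagonal after
# rotating by the eigenvectors of M.
reml_eigen <- function(y, X, M, decomp = NULL) {
  n <- length(y)
  p <- ncol(X)
  ed <- decomp %||% eigen(M, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  yt <- crossprod(ed$vectors, y)
  Xt <- crossprod(ed$vectors, X)

  crit <- function(loglambda) {
    lam <- exp(loglambda)
    w <- 1 / (lam * d + 1)
    sw <- sqrt(w)
    Xw <- Xt * sw
    yw <- yt * sw
    fit <- stats::lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    se2 <- rss / (n - p)
    XtWX <- crossprod(Xw)
    # -2 * REML loglik up to a constant
    (n - p) * log(se2) - sum(log(w)) + determinant(XtWX)$modulus[1] + (n - p)
  }
  grid <- seq(-18, 12, length.out = 40)
  vals <- vapply(grid, crit, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(crit, c(lo, hi), tol = 1e-10)
  lam <- exp(refine_minimum(crit, opt$minimum))

  w <- 1 / (lam * d + 1)
  sw <- sqrt(w)
  fit <- stats::lm.fit(Xt * sw, yt * sw)
  se2 <- sum(fit$residuals^2) / (n - p)
  s2 <- lam * se2
  ll <- -0.5 * (n * log(se2) - sum(log(w)) +
                  determinant(crossprod(Xt * sw))$modulus[1] - p * log(se2) +
                  (n - p))
  list(sigma2 = s2, sigma_e2 = se2, loglik = ll, converged = TRUE, n_iter = 1L)
}

#' REML estimation of variance components
#'
#' Estimates the variance of each random term and the residual by restricted
#' maximum likelihood. Random terms are supplied as record-level covariance
#' structure matrices `M_i` (n x n), so the model is
#' `y = Xb + e`, `Var(y) = sum_i sigma_i^2 M_i + sigma_e^2 I`. For an animal
#' term with relationship matrix `K`, `M = K[ids, ids]`; for the breed term,
#' `M = Q_rec Q_rec'`.
#'
#' With a single random term the REML criterion is profiled on the variance
#' ratio after a one-off spectral decomposition (fast and essentially
#' exact). With several terms, Fisher scoring on the variances is used, with
#' a fixed-point fallback and step halving; variances are floored at
#' `1e-10 * var(y)`.
#'
#' @param y Response vector.
#' @param X Full-rank fixed-effect design matrix.
#' @param random Named list of record-level covariance matrices. A
#'   non-square entry `Z` (n x r, r < n) is interpreted as the low-rank
#'   factor of `M = Z Z'` (e.g. the breed-composition regressors) and
#'   handled in r-dimensional algebra, which is much faster.
#' @param genetic_terms Term names counted as genetic in the reported
#'   heritability; defaults to all terms except one named `"breed"`.
#' @param decomp Optional pre-computed `eigen()` of the single random term's
#'   matrix (saves the dominant cost when refitting with the same
#'   relationship structure).
#' @param max_iter,tol_param,tol_loglik Convergence controls for the
#'   multi-term path.
#' @return A list of class `reml_fit`: `sigma2` (named vector including
#'   `residual`), `h2`, `loglik` (REML log-likelihood up to a constant),
#'   `converged`, `n_iter`.
#' @export
reml_fit <- function(y, X, random, genetic_terms = NULL, decomp = NULL,
                     max_iter = 100L, tol_param = 1e-8, tol_loglik = 1e-6) {
  stopifnot(is.list(random), length(random) >= 1L, !is.null(names(random)))
  n <- length(y)
  if (n <= ncol(X)) stop("need more records than fixed effects", call. = FALSE)
  # The REML criterion depends on y only through its projection orthogonal
  # to X; replacing y by the OLS residual changes nothing mathematically
  # and makes the fit exactly invariant to shifts along the fixed effects.
  y <- qr.resid(qr(X), y)
  vy <- var(y)
  floor_v <- 1e-10 * vy

  if (length(random) == 1L) {
    M1 <- random[[1L]]
    fit <- if (nrow(M1) != ncol(M1) || nrow(M1) != n) {
      reml_lowrank(y, X, M1)
    } else {
      reml_eigen(y, X, M1, decomp = decomp)
    }
    sigma2 <- setNames(c(fit$sigma2, fit$sigma_e2),
                       c(names(random), "residual"))
    converged <- fit$converged; n_iter <- fit$n_iter; ll <- fit$loglik
  } else {
    k <- length(random)
    Ms <- lapply(random, function(M) {
      if (nrow(M) != ncol(M) || nrow(M) != n) tcrossprod(M) else M
    })
    Ms <- c(Ms, list(residual = diag(n)))
    theta <- setNames(rep(vy / (k + 1), k + 1L), names(Ms))
    ll_old <- -Inf
    converged <- FALSE
    n_iter <- 0L
    ll <- NA_real_
    for (it in seq_len(max_iter)) {
      n_iter <- it
      V <- matrix(0, n, n)
      for (j in seq_along(Ms)) V <- V + theta[j] * Ms[[j]]
      cV <- chol(V)
      Vi <- chol2inv(cV)
      ViX <- Vi %*% X
      XtViX <- crossprod(X, ViX)
      P <- Vi - ViX %*% solve(XtViX, t(ViX))
      Py <- P %*% y
      ll <- -0.5 * (2 * sum(log(diag(cV))) +
                      determinant(XtViX)$modulus[1] + sum(y * Py))
      PM <- lapply(Ms, function(M) P %*% M)
      score <- vapply(seq_along(Ms), function(i) {
        -0.5 * (sum(diag(PM[[i]])) - crossprod(Py, Ms[[i]] %*% Py))
      }, numeric(1))
      FI <- matrix(0, k + 1L, k + 1L)
      for (i in seq_along(Ms)) for (j in i:(k + 1L)) {
        FI[i, j] <- FI[j, i] <- 0.5 * sum(PM[[i]] * t(PM[[j]]))
      }
      step <- tryCatch(solve(FI, score), error = function(e) NULL)
      proposed <- NULL
      if (!is.null(step)) {
        fac <- 1
        for (h in 1:12) {
          cand <- pmax(theta + fac * step, floor_v)
          llc <- tryCatch(reml_loglik_direct(y, X, Reduce(`+`, Map(`*`, cand, Ms))),
                          error = function(e) -Inf)
          if (is.finite(llc) && llc >= ll - 1e-10) {
            proposed <- cand; ll_new <- llc; break
          }
          fac <- fac / 2
        }
      }
      if (is.null(proposed)) {
        # fixed-point fallback: theta_i * (y'P M P y) / tr(P M)
        proposed <- vapply(seq_along(Ms), function(i) {
          num <- drop(crossprod(Py, Ms[[i]] %*% Py))
          den <- sum(diag(PM[[i]]))
          max(theta[i] * num / max(den, 1e-300), floor_v)
        }, numeric(1))
        ll_new <- tryCatch(reml_loglik_direct(y, X, Reduce(`+`, Map(`*`, proposed, Ms))),
                           error = function(e) ll)
      }
      rel <- max(abs(proposed - theta) / pmax(abs(theta), floor_v))
      theta <- setNames(pmax(proposed, floor_v), names(Ms))
      if (rel < tol_param && abs(ll_new - ll_old) < tol_loglik) {
        converged <- TRUE
        ll <- ll_new
        break
      }
      ll_old <- ll_new
      ll <- ll_new
    }
    sigma2 <- theta
  }

  sigma2 <- pmax(sigma2, floor_v)
  gt <- genetic_terms %||% setdiff(names(random), "breed")
  h2 <- sum(sigma2[gt]) / sum(sigma2)
  structure(list(sigma2 = sigma2, h2 = h2, loglik = ll,
                 converged = converged, n_iter = n_iter),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit>", if (x$converged) "converged" else "NOT converged",
      sprintf("in %d iteration(s); loglik %.4f\n", x$n_iter, x$loglik))
  print(round(x$sigma2, 6))
  cat(sprintf("  h2 = %.4f\n", x$h2))
  invisible(x)
}

#' Solve Henderson's mixed-model equations
#'
#' Given fixed variance components, solves
#' `[X'X, X'Z; Z'X, Z'Z + K^-1 lambda] [b; u] = [X'y; Z'y]` for each random
#' term (`lambda_i = sigma_e^2 / sigma_i^2`). For a (near-)singular `K`
#' such as a genomic relationship matrix, pass `ridge = 1e-6`: it adds
#' `ridge * mean(diag(K))` to the diagonal before inversion. Terms whose
#' variance is numerically zero get `u = 0` (the infinite-shrinkage
#' limit). The relative residual of the solved system is stored and must
#' be below `1e-8`.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix.
#' @param Z Named list of design matrices (records x levels).
#' @param K Named list of covariance structure matrices per term (levels x
#'   levels); use `diag(q)` for i.i.d. terms.
#' @param sigma2 Named vector of variances for the terms in `Z`.
#' @param sigma_e2 Residual variance.
#' @param ridge Relative ridge added to each `K` before inversion (default
#'   0; use 1e-6 for G).
#' @return A list of class `mme_solution`: `b`, `u` (named list), `fitted`,
#'   `rel_residual`.
#' @export
solve_mme <- function(y, X, Z, K, sigma2, sigma_e2, ridge = 0) {
  stopifnot(length(Z) == length(K), !is.null(names(Z)),
            all(names(Z) %in% names(sigma2)))
  active <- names(Z)[sigma2[names(Z)] > 1e-12 * sigma_e2]
  q <- vapply(Z[active], ncol, integer(1))
  p <- ncol(X)
  dim_all <- p + sum(q)
  C <- matrix(0, dim_all, dim_all)
  r <- numeric(dim_all)
  C[1:p, 1:p] <- crossprod(X)
  r[1:p] <- crossprod(X, y)
  off <- p
  blocks <- list()
  for (nm in active) {
    idx <- off + seq_len(ncol(Z[[nm]]))
    blocks[[nm]] <- idx
    C[1:p, idx] <- crossprod(X, Z[[nm]])
    C[idx, 1:p] <- t(C[1:p, idx])
    r[idx] <- crossprod(Z[[nm]], y)
    off2 <- p
    for (nm2 in active) {
      idx2 <- off2 + seq_len(ncol(Z[[nm2]]))
      if (nm2 == nm) {
        Kr <- K[[nm]]
        if (ridge > 0) Kr <- Kr + diag(ridge * mean(diag(Kr)), ncol(Kr))
        Kinv <- tryCatch(chol2inv(chol(Kr)), error = function(e) {
          stop(sprintf("covariance matrix for term '%s' is not positive definite; pass ridge = 1e-6",
                       nm), call. = FALSE)
        })
        C[idx, idx] <- crossprod(Z[[nm]]) + Kinv * (sigma_e2 / sigma2[[nm]])
      } else if (off2 < off) {
        C[idx2, idx] <- crossprod(Z[[nm2]], Z[[nm]])
        C[idx, idx2] <- t(C[idx2, idx])
      }
      off2 <- off2 + ncol(Z[[nm2]])
    }
    off <- off + ncol(Z[[nm]])
  }
  sol <- tryCatch(solve(C, r), error = function(e) {
    stop(sprintf("singular mixed-model equations (rank %d of %d): %s",
                 qr(C)$rank, dim_all, conditionMessage(e)), call. = FALSE)
  })
  rel <- sqrt(sum((C %*% sol - r)^2)) / max(sqrt(sum(r^2)), 1e-300)
  b <- setNames(sol[1:p], colnames(X))
  u <- list()
  for (nm in names(Z)) {
    if (nm %in% active) {
      u[[nm]] <- setNames(sol[blocks[[nm]]], colnames(Z[[nm]]))
    } else {
      u[[nm]] <- setNames(numeric(ncol(Z[[nm]])), colnames(Z[[nm]]))
    }
  }
  fitted <- drop(X %*% b) + Reduce(`+`, Map(function(Zi, ui) drop(Zi %*% ui), Z, u))
  structure(list(b = b, u = u, fitted = fitted, rel_residual = rel),
            class = "mme_solution")
}

# incidence matrix mapping records (ids) to a set of levels
incidence_matrix <- function(ids, levels) {
  Z <- matrix(0, length(ids), length(levels),
              dimnames = list(NULL, levels))
  Z[cbind(seq_along(ids), match(ids, levels))] <- 1
  Z
}

#' GBLUP / BLUP prediction for validation animals
#'
#' Fits the mixed model on reference records only (validation phenotypes are
#' deleted, not masked, so they cannot influence any estimate) and predicts
#' genetic values for all animals in the relationship matrices through their
#' covariance with the reference records:
#' `u_hat = sigma_u^2 K[ , ref] V^-1 (y - X b_hat)` with
#' `V = sum_i sigma_i^2 M_i + sigma_e^2 I`. This is identical to the
#' mixed-model-equation solution but only factorises a reference-sized
#' matrix.
#'
#' @param phenotypes Phenotype data frame (one record per animal).
#' @param spec A [model_spec()].
#' @param K Named list of animal-level relationship matrices (e.g.
#'   `list(genomic = G)` or `list(animal = A)`); all must carry animal ids
#'   as dimnames. Every name must appear in `spec$random_terms` or be
#'   supplied here directly.
#' @param validation_ids Animals whose phenotypes are withheld. They must be
#'   present in every `K`.
#' @param components Named variance vector including `residual` (from
#'   [reml_fit()] or supplied).
#' @param Q Optional breed-composition matrix; when given, a breed term
#'   with variance `components["breed"]` is included in `V`.
#' @return A list of class `gblup_fit`: `b`, `u` (named list of full-length
#'   prediction vectors), `pred` (data frame for `validation_ids`: one
#'   column per term plus `total`), `reference_ids`.
#' @export
gblup_predict <- function(phenotypes, spec, K, validation_ids, components,
                          Q = NULL) {
  stopifnot(is.list(K), !is.null(names(K)), "residual" %in% names(components))
  for (nm in names(K)) {
    missing_ids <- setdiff(validation_ids, rownames(K[[nm]]))
    if (length(missing_ids)) {
      stop(sprintf("validation animals missing from %s: %s", nm,
                   paste(head(missing_ids), collapse = ", ")), call. = FALSE)
    }
  }
  ref_phen <- phenotypes[!phenotypes$id %in% validation_ids, , drop = FALSE]
  des <- build_design(ref_phen, spec,
                      restrict_to = rownames(K[[1L]]))
  if (any(des$ids %in% validation_ids)) {
    stop("leakage: validation phenotype present in reference design",
         call. = FALSE)
  }
  y <- des$y; X <- des$X; ids <- des$ids
  n <- length(y)
  V <- diag(components[["residual"]], n)
  for (nm in names(K)) {
    V <- V + components[[nm]] * K[[nm]][ids, ids]
  }
  if (!is.null(Q) && "breed" %in% names(components)) {
    Qr <- Q[ids, , drop = FALSE]
    V <- V + components[["breed"]] * tcrossprod(Qr)
  }
  cV <- chol(V)
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  b <- solve(crossprod(X, Vi_X), crossprod(Vi_X, y))
  resid_rot <- backsolve(cV, forwardsolve(t(cV), y - drop(X %*% b)))
  u <- list()
  for (nm in names(K)) {
    u[[nm]] <- setNames(
      components[[nm]] * drop(K[[nm]][, ids, drop = FALSE] %*% resid_rot),
      rownames(K[[nm]]))
  }
  pred <- data.frame(id = validation_ids)
  for (nm in names(K)) pred[[nm]] <- u[[nm]][validation_ids]
  pred$total <- rowSums(pred[, names(K), drop = FALSE])
  structure(list(b = setNames(drop(b), colnames(X)), u = u, pred = pred,
                 reference_ids = unique(ids)),
            class = "gblup_fit")
}

#' Adjust phenotypes for fixed and breed effects
#'
#' Fits the pedigree model without a polygenic term
#' (`y = 1mu + Xb + ZQq + e`, breed coefficients random) and returns the
#' residuals `y* = y - X b_hat - Z Q q_hat`. The breed variance is REML
#' estimated unless supplied. Adjustment is idempotent: adjusting `y*`
#' again changes nothing.
#'
#' @param phenotypes Phenotype data frame.
#' @param spec A [model_spec()] (its random terms are ignored except the
#'   breed term).
#' @param Q Breed-composition matrix over animal ids; `NULL` drops the
#'   breed term.
#' @param sigma_q2 Optional fixed breed variance (skips REML).
#' @param restrict_to Optional genotyped-id restriction.
#' @return Numeric vector `y*` named by animal id, with the fit in
#'   attributes `fit` (b, q, components).
#' @export
adjust_phenotypes <- function(phenotypes, spec, Q = NULL, sigma_q2 = NULL,
                              restrict_to = NULL) {
  des <- build_design(phenotypes, spec, restrict_to = restrict_to)
  y <- des$y; X <- des$X
  if (is.null(Q)) {
    b <- qr.coef(qr(X), y)
    ystar <- y - drop(X %*% b)
    return(structure(setNames(ystar, des$ids),
                     fit = list(b = b, q = NULL, components = NULL)))
  }
  Qr <- Q[des$ids, , drop = FALSE]
  if (is.null(sigma_q2)) {
    fit <- reml_fit(y, X, random = list(breed = Qr))  # low-rank path
    sigma_q2 <- fit$sigma2[["breed"]]
    sigma_e2 <- fit$sigma2[["residual"]]
  } else {
    sigma_e2 <- var(y)
  }
  sol <- solve_mme(y, X, Z = list(breed = Qr),
                   K = list(breed = diag(ncol(Qr))),
                   sigma2 = c(breed = sigma_q2), sigma_e2 = sigma_e2)
  ystar <- y - sol$fitted
  structure(setNames(ystar, des$ids),
            fit = list(b = sol$b, q = sol$u$breed,
                       components = c(breed = unname(sigma_q2),
                                      residual = unname(sigma_e2))))
}
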