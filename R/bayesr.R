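# BayesR: Bayesian marker-effect model with a four-component normal mixture
# (one zero-variance class), run as multiple Gibbs chains on adjusted
# phenotypes and summarised into per-SNP posterior means and class
# probabilities.

#' BayesR run configuration
#'
#' Production defaults are 10 chains of 50,000 iterations with a 20,000
#' burn-in; tests use desk-scale values (3 chains x 5,000 / 2,000). Marker
#' effects come from normal distributions with variances `0`, `1e-4`,
#' `1e-3` and `1e-2` times `sigma_g2`; the anchor `sigma_g2` starts from a
#' GBLUP estimate and is, by default, resampled each sweep from the current
#' marker effects (set `update_sigma_g2 = FALSE` to pin it at the start
#' value).
#'
#' @param n_iter,burn_in,n_chains Chain length, burn-in, number of chains.
#' @param class_variance_multipliers Strictly increasing, first element 0.
#' @param dirichlet_prior Four pseudo-counts for the mixture proportions.
#' @param sigma_g2_init Starting genetic-variance anchor (typically the
#'   GBLUP REML estimate); `NULL` defaults to half the variance of `y*`.
#' @param update_sigma_g2,update_sigma_e2,update_pi Sampler toggles (all
#'   `TRUE` in normal use; pinning them gives conjugate special cases used
#'   by the unit tests).
#' @param include_polygenic Add a pedigree polygenic term (single-site
#'   Gibbs, needs `A`).
#' @param residual_check Verify the running-residual identity every 1,000
#'   sweeps (debug mode).
#' @param seed Base seed; chain `c` uses `seed + c`.
#' @return A list of class `bayesr_config`.
#' @export
bayesr_config <- function(n_iter = 50000L, burn_in = 20000L, n_chains = 10L,
                          class_variance_multipliers = c(0, 1e-4, 1e-3, 1e-2),
                          dirichlet_prior = c(1, 1, 1, 1),
                          sigma_g2_init = NULL,
                          update_sigma_g2 = TRUE, update_sigma_e2 = TRUE,
                          update_pi = TRUE, include_polygenic = FALSE,
                          residual_check = FALSE, seed = 1L) {
  if (burn_in >= n_iter) stop("burn_in must be < n_iter", call. = FALSE)
  m <- class_variance_multipliers
  if (length(m) != 4L || m[1L] != 0 || any(diff(m) <= 0)) {
    stop("class_variance_multipliers must be 4 strictly increasing values starting at 0",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "bayesr_config")
}

#' Run BayesR chains
#'
#' Centres the training dosages by twice the training allele frequency,
#' runs `n_chains` independent Gibbs chains and averages post-burn-in
#' posterior summaries across chains. Reports per-SNP posterior mean
#' effects (also standardised by the SD of the adjusted phenotypes),
#' class-membership probabilities including the probability of the largest
#' class, and a split Gelman-Rubin R-hat for the genetic variance.
#'
#' @param ystar Adjusted phenotypes, named by animal id.
#' @param dosages Dosage matrix; rows covering `names(ystar)` are used for
#'   training.
#' @param config A [bayesr_config()].
#' @param A Pedigree relationship matrix over the training ids (required
#'   when `config$include_polygenic`).
#' @return A list of class `marker_posterior`: `snp`, `mean_effect`,
#'   `sd_effect`, `standardised_effect`, `class_probs` (m x 4, rows sum to
#'   1), `p_class4`, `pi_mean`, `sd_ystar`, `freqs` (training allele
#'   frequencies used for centring), `a_mean` (polygenic posterior means,
#'   if fitted), `rhat_genvar`, `chains` (per-chain scalars), `config`.
#' @export
run_bayesr <- function(ystar, dosages, config = bayesr_config(), A = NULL) {
  stopifnot(inherits(config, "bayesr_config"))
  if (config$n_chains < 1L) stop("n_chains must be >= 1", call. = FALSE)
  ids <- names(ystar)
  if (is.null(ids) || !all(ids %in% rownames(dosages))) {
    stop("ystar must be named by animal ids present in dosages", call. = FALSE)
  }
  X <- dosages[ids, , drop = FALSE]
  if (anyNA(X)) stop("dosages must be imputed before BayesR", call. = FALSE)
  p <- colMeans(X) / 2
  W <- sweep(X, 2L, 2 * p)
  vy <- var(ystar)
  sg2_init <- config$sigma_g2_init %||% (0.5 * vy)
  se2_init <- max(vy - sg2_init, 0.1 * vy, 1e-8)
  Ainv <- NULL
  if (config$include_polygenic) {
    if (is.null(A)) stop("A required when include_polygenic = TRUE", call. = FALSE)
    Am <- A[ids, ids] + diag(1e-6, length(ids))
    Ainv <- chol2inv(chol(Am))
  }

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    chains[[ch]] <- bayesr_chain(
      W, unname(ystar), config$class_variance_multipliers,
      config$dirichlet_prior, as.integer(config$n_iter),
      as.integer(config$burn_in), sg2_init, se2_init,
      config$update_sigma_g2, config$update_sigma_e2, config$update_pi,
      Ainv, config$residual_check, NULL)
  }

  mean_effect <- rowMeans(do.call(cbind, lapply(chains, `[[`, "mean_effect")))
  sd_effect <- rowMeans(do.call(cbind, lapply(chains, `[[`, "sd_effect")))
  class_probs <- Reduce(`+`, lapply(chains, `[[`, "class_probs")) / length(chains)
  dimnames(class_probs) <- list(colnames(W), paste0("class", 1:4))
  pi_mean <- rowMeans(vapply(chains, `[[`, numeric(4L), "pi_mean"))
  sd_ystar <- sd(ystar)
  a_mean <- if (config$include_polygenic) {
    setNames(rowMeans(vapply(chains, `[[`, numeric(length(ids)), "a_mean")), ids)
  } else NULL
  rhat <- split_rhat(lapply(chains, `[[`, "genvar_trace"))
  chain_stats <- data.frame(
    chain = seq_along(chains),
    sigma_g2 = vapply(chains, `[[`, numeric(1), "sigma_g2_mean"),
    sigma_e2 = vapply(chains, `[[`, numeric(1), "sigma_e2_mean"),
    mu = vapply(chains, `[[`, numeric(1), "mu_mean"),
    seed = config$seed + seq_along(chains))

  structure(
    list(snp = colnames(W), mean_effect = setNames(mean_effect, colnames(W)),
         sd_effect = setNames(sd_effect, colnames(W)),
         standardised_effect = setNames(mean_effect / sd_ystar, colnames(W)),
         class_probs = class_probs,
         p_class4 = setNames(class_probs[, 4L], colnames(W)),
         pi_mean = setNames(pi_mean, paste0("class", 1:4)),
         sd_ystar = sd_ystar, freqs = p, a_mean = a_mean,
         rhat_genvar = rhat, chains = chain_stats, config = config),
    class = "marker_posterior")
}

#' @export
print.marker_posterior <- function(x, ...) {
  cat(sprintf("<marker_posterior> %d SNP, %d chain(s); R-hat(genetic var) = %.3f\n",
              length(x$snp), nrow(x$chains), x$rhat_genvar))
  cat("  mixture proportions:", paste(sprintf("%.4f", x$pi_mean), collapse = " "), "\n")
  invisible(x)
}

# split Gelman-Rubin R-hat over a list of numeric chains
split_rhat <- function(traces) {
  halves <- unlist(lapply(traces, function(tr) {
    h <- length(tr) %/% 2L
    list(tr[seq_len(h)], tr[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1L]])
  if (n < 2L || m < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  B <- n * var(means)
  Wv <- mean(vars)
  if (Wv <= 0) return(1)
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

#' Table of SNPs with large standardised effects
#'
#' Lists SNPs whose absolute posterior mean effect, in units of the SD of
#' the adjusted phenotypes, exceeds `threshold_sd` (default 0.005), sorted
#' by decreasing absolute effect, with the probability of membership in the
#' largest-variance class.
#'
#' @param posterior A [run_bayesr()] result.
#' @param threshold_sd Effect threshold in adjusted-phenotype SD units.
#' @param map Optional SNP map (`snp`, `chr`, `pos_bp`) to annotate rows.
#' @return Data frame: `snp`, (`chr`, `pos_bp`,) `effect_sd`, `p_class4`.
#' @export
report_large_effects <- function(posterior, threshold_sd = 0.005, map = NULL) {
  stopifnot(inherits(posterior, "marker_posterior"))
  eff <- posterior$standardised_effect
  sel <- which(abs(eff) > threshold_sd)
  out <- data.frame(snp = posterior$snp[sel], effect_sd = eff[sel],
                    p_class4 = posterior$p_class4[sel], row.names = NULL)
  if (!is.null(map)) {
    out <- merge(out, map[, intersect(c("snp", "chr", "pos_bp"), names(map))],
                 by = "snp", sort = FALSE)
  }
  out[order(-abs(out$effect_sd)), , drop = FALSE]
}

#' Genomic values from posterior marker effects
#'
#' Computes `g_hat = (X - 2p) %*% mean_effect` using the training allele
#' frequencies stored in the posterior; optionally adds polygenic estimates
#' for a `g_hat + a_hat` prediction.
#'
#' @param dosages Dosage matrix whose columns must match the training SNP
#'   set exactly.
#' @param posterior A [run_bayesr()] result.
#' @param a_hat Optional named polygenic predictions to add.
#' @return Named vector of genomic (plus polygenic) values.
#' @export
genomic_value_from_markers <- function(dosages, posterior, a_hat = NULL) {
  stopifnot(inherits(posterior, "marker_posterior"))
  missing_snp <- setdiff(posterior$snp, colnames(dosages))
  if (length(missing_snp)) {
    stop("dosages are missing training SNPs: ",
         paste(head(missing_snp), collapse = ", "), call. = FALSE)
  }
  X <- dosages[, posterior$snp, drop = FALSE]
  g <- drop(sweep(X, 2L, 2 * posterior$freqs) %*% posterior$mean_effect)
  g <- setNames(g, rownames(dosages))
  if (!is.null(a_hat)) {
    g <- g + a_hat[names(g)]
  }
  g
}
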