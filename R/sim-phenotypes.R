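# True marker effects (four-class normal mixture) and phenotype simulation.

BAYESR_MULTIPLIERS <- c(0, 1e-4, 1e-3, 1e-2)

#' Draw true marker effects from a four-class normal mixture
#'
#' Each SNP is assigned to one of four classes with probabilities
#' `prop_classes`; effects are Normal with variance 0, `1e-4`, `1e-3` or
#' `1e-2` times `sigma_g2` by class (class 1 effects are exactly zero).
#'
#' @param n_snp Number of SNPs.
#' @param prop_classes Four non-negative mixture proportions summing to 1.
#' @param sigma_g2 Total genetic variance anchoring the class variances.
#' @param seed Integer RNG seed.
#' @return A list of class `marker_effects`: `effects` (length `n_snp`),
#'   `class` (integers 1-4), `multipliers`, `sigma_g2`.
#' @export
draw_marker_effects <- function(n_snp, prop_classes = c(0.95, 0.03, 0.015, 0.005),
                                sigma_g2 = 1, seed = 1) {
  check_scalar(n_snp, "n_snp", lo = 1)
  if (length(prop_classes) != 4L || any(prop_classes < 0)) {
    stop("`prop_classes` must be 4 non-negative proportions", call. = FALSE)
  }
  if (abs(sum(prop_classes) - 1) > 1e-8) {
    stop("`prop_classes` must sum to 1", call. = FALSE)
  }
  check_scalar(sigma_g2, "sigma_g2", lo = 0)
  set.seed(seed)
  cls <- sample.int(4L, n_snp, replace = TRUE, prob = prop_classes)
  sds <- sqrt(BAYESR_MULTIPLIERS * sigma_g2)
  eff <- rnorm(n_snp, 0, sds[cls])
  eff[cls == 1L] <- 0
  structure(list(effects = eff, class = cls,
                 multipliers = BAYESR_MULTIPLIERS, sigma_g2 = sigma_g2),
            class = "marker_effects")
}

# Polygenic values with covariance sigma2 * A, by recursion down the
# pedigree: offspring = parent average + Mendelian-sampling deviation.
drop_polygenic <- function(pedigree, sigma2) {
  n <- nrow(pedigree)
  a <- numeric(n)
  if (sigma2 <= 0) return(setNames(a, pedigree$id))
  row_of <- setNames(seq_len(n), pedigree$id)
  founder <- is.na(pedigree$sire)
  a[founder] <- rnorm(sum(founder), 0, sqrt(sigma2))
  for (i in which(!founder)) {
    ms <- rnorm(1L, 0, sqrt(sigma2 / 2))
    a[i] <- 0.5 * (a[row_of[[pedigree$sire[i]]]] + a[row_of[[pedigree$dam[i]]]]) + ms
  }
  setNames(a, pedigree$id)
}

#' Simulate phenotypes for the slaughter generation
#'
#' Builds `y = mu + fixed effects + breed effects + breeding value +
#' residual` for every cohort-A/B animal. The breeding value is the centred
#' dosage of `true_values$effects` (rescaled so the marker share of variance
#' is `(1 - polygenic_prop) * sigma_g2`) plus a pedigree-distributed
#' polygenic remainder. The residual variance is set from the realised
#' genetic variance so that the realised narrow-sense heritability matches
#' `config$h2`. A correlated carcass-weight covariate (`hcwt`, heritability
#' `config$hcwt_h2`) is also generated and enters `y` with coefficient
#' `config$hcwt_beta`.
#'
#' @param pedigree Pedigree from [simulate_pedigree()].
#' @param genotypes A [gene_drop()] result (or a dosage matrix covering all
#'   pedigree animals).
#' @param true_values A [draw_marker_effects()] result.
#' @param config A [sim_config()]; uses `h2`, `sigma_g2`, `polygenic_prop`,
#'   `breed_effect_sd`, `fixed_effect_sds`, `hcwt_h2`, `hcwt_beta`, `seed`.
#'
#' @return A list of class `sim_phenotypes`: `phenotypes` (one row per
#'   phenotyped animal: `id`, `cohort`, `y`, `hcwt`, `age`, factor columns
#'   and `cg` the contemporary group) and `truth` (scaled marker effects and
#'   classes, per-animal breeding values, breed and fixed effects, `mu`,
#'   `sigma_e2`).
#' @export
simulate_phenotypes <- function(pedigree, genotypes, true_values, config) {
  stopifnot(inherits(config, "sim_config"), inherits(true_values, "marker_effects"))
  if (config$h2 <= 0 || config$h2 >= 1) stop("h2 outside (0,1)", call. = FALSE)
  dos <- if (inherits(genotypes, "gene_drop")) genotypes$dosages else genotypes
  if (!all(pedigree$id %in% rownames(dos))) {
    stop("all pedigree animals must be genotyped (or flagged out beforehand)",
         call. = FALSE)
  }
  set.seed(config$seed + 303L)

  dos <- dos[pedigree$id, , drop = FALSE]
  phen_rows <- which(!is.na(pedigree$cohort))
  if (!length(phen_rows)) stop("no phenotyped (cohort) animals", call. = FALSE)

  # genetic values: scaled marker term + polygenic remainder
  eff <- true_values$effects
  centred <- sweep(dos, 2L, colMeans(dos))
  g_marker <- drop(centred %*% eff)
  v_mark <- var(g_marker[phen_rows])
  target_mark <- (1 - config$polygenic_prop) * config$sigma_g2
  scale_m <- if (v_mark > 0) sqrt(target_mark / v_mark) else 1
  g_marker <- g_marker * scale_m
  eff_scaled <- eff * scale_m
  g_poly <- drop_polygenic(pedigree, config$polygenic_prop * config$sigma_g2)
  tbv <- setNames(g_marker + g_poly, pedigree$id)

  # breed effects through pedigree breed composition
  Q <- breed_composition(pedigree)
  q_true <- setNames(rnorm(ncol(Q), 0, config$breed_effect_sd), colnames(Q))
  g_breed <- drop(Q %*% q_true)

  ph <- pedigree[phen_rows, c("id", "cohort", "sire_family", "sex",
                              "birth_type", "rearing_type", "site",
                              "birth_year", "slaughter_group", "age_of_dam")]
  ph$age_of_dam[is.na(ph$age_of_dam)] <- "none"  # cohort-B records
  ph$cg <- interaction(ph$site, ph$birth_year, ph$slaughter_group, drop = TRUE)
  ph$age <- round(rnorm(nrow(ph), 300, 25))

  sds <- config$fixed_effect_sds
  fx <- list(
    sex = setNames(rnorm(2, 0, sds[["sex"]]), c("M", "F")),
    birth_type = setNames(rnorm(3, 0, sds[["birth_type"]]), as.character(1:3)),
    rearing_type = setNames(rnorm(3, 0, sds[["rearing_type"]]), as.character(1:3)),
    cg = setNames(rnorm(nlevels(ph$cg), 0, sds[["cg"]]), levels(ph$cg)),
    age_of_dam = c(setNames(rnorm(3, 0, sds[["age_of_dam"]]),
                            c("2yo", "3yo", "4plus")), none = 0)
  )
  beta_age <- sds[["age"]]
  fixed_part <- fx$sex[ph$sex] + fx$birth_type[as.character(ph$birth_type)] +
    fx$rearing_type[as.character(ph$rearing_type)] +
    fx$cg[as.character(ph$cg)] +
    beta_age * (ph$age - 300) / 25
  fixed_part <- as.numeric(fixed_part + fx$age_of_dam[ph$age_of_dam])

  # hot-carcass-weight stand-in: own h2, genetic correlation 0.4 with y
  rg <- 0.4
  g_y <- tbv[phen_rows]
  sd_gy <- sd(g_y)
  g_std <- if (sd_gy > 0) (g_y - mean(g_y)) / sd_gy else g_y * 0
  z_ind <- drop_polygenic(pedigree, 1)[phen_rows]
  u_h <- rg * g_std + sqrt(1 - rg^2) * z_ind
  sd_h <- 3.0
  hcwt <- 22 + sd_h * (sqrt(config$hcwt_h2) * u_h +
                         sqrt(1 - config$hcwt_h2) * rnorm(length(u_h)))

  v_g <- var(g_y)
  sigma_e2 <- v_g * (1 - config$h2) / config$h2
  mu <- 30
  e <- if (sigma_e2 > 0) rnorm(length(phen_rows), 0, sqrt(sigma_e2)) else 0
  ph$hcwt <- as.numeric(hcwt)
  ph$y <- mu + fixed_part + g_breed[phen_rows] + g_y +
    config$hcwt_beta * (ph$hcwt - mean(ph$hcwt)) + e
  rownames(ph) <- NULL

  truth <- list(true_marker_effects = eff_scaled, true_class = true_values$class,
                true_breeding_values = tbv, true_polygenic = g_poly,
                true_breed_effects = q_true, true_fixed_effects = fx,
                beta_age = beta_age, mu = mu, sigma_e2 = sigma_e2,
                marker_scale = scale_m)
  structure(list(phenotypes = ph, truth = truth), class = "sim_phenotypes")
}

#' Standardise a trait within datasets
#'
#' Centres and scales a trait to mean 0, sample SD 1 (denominator `n - 1`)
#' within each level of a grouping column, leaving all other columns
#' untouched. Used to put a trait measured with different protocols in two
#' datasets on a common scale before merging.
#'
#' @param phenotypes Data frame of phenotype records.
#' @param trait Name of the numeric trait column.
#' @param group_field Name of the grouping column (default `"cohort"`).
#' @return The data frame with the trait standardised within groups.
#' @export
standardise_within_dataset <- function(phenotypes, trait, group_field = "cohort") {
  stopifnot(trait %in% names(phenotypes), group_field %in% names(phenotypes))
  out <- phenotypes
  for (g in unique(out[[group_field]])) {
    idx <- which(out[[group_field]] == g & !is.na(out[[trait]]))
    if (length(idx) < 2L) {
      stop(sprintf("group '%s' has fewer than 2 non-missing records", g),
           call. = FALSE)
    }
    s <- sd(out[[trait]][idx])
    if (s == 0) {
      stop(sprintf("group '%s' has zero variance in '%s'", g, trait),
           call. = FALSE)
    }
    out[[trait]][idx] <- (out[[trait]][idx] - mean(out[[trait]][idx])) / s
  }
  out
}

#' Simulate a complete multi-breed dataset
#'
#' Convenience wrapper chaining [simulate_breed_frequencies()],
#' [simulate_pedigree()], [gene_drop()], [draw_marker_effects()] and
#' [simulate_phenotypes()] with seeds derived from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param keep_haplotypes Passed to [gene_drop()].
#' @return A list of class `sim_dataset` with `config`, `breed_model`,
#'   `pedigree`, `dosages`, `map`, `phenotypes`, `truth` (and `haplotypes`
#'   when requested).
#' @export
simulate_dataset <- function(config = sim_config(), keep_haplotypes = FALSE) {
  bm <- simulate_breed_frequencies(config$n_snp, config$n_breeds, config$fst,
                                   seed = config$seed)
  ped <- simulate_pedigree(config, bm)
  gd <- gene_drop(ped, bm, config$n_chromosomes, config$morgans_per_chr,
                  seed = config$seed + 202L, keep_haplotypes = keep_haplotypes)
  me <- draw_marker_effects(config$n_snp, config$prop_classes,
                            config$sigma_g2, seed = config$seed + 404L)
  sp <- simulate_phenotypes(ped, gd, me, config)
  structure(list(config = config, breed_model = bm, pedigree = ped,
                 dosages = gd$dosages, map = gd$map,
                 haplotypes = gd$haplotypes,
                 phenotypes = sp$phenotypes, truth = sp$truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d animals (%d phenotyped) x %d SNP\n",
              nrow(x$pedigree), nrow(x$phenotypes), ncol(x$dosages)))
  invisible(x)
}
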