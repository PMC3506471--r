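# Multi-breed pedigree simulation. The stated world mirrors the two sheep
# resource populations the package is patterned on: cohort A (research-flock
# style, many sires sampled widely with ~40 progeny each, 8 sites) and cohort
# B (linkage-study style, ~20 sires with large progeny groups, one site).
# Dams are Merino or Border Leicester x Merino F1 ewes, sires are meat-breed
# or Merino rams, so the slaughter generation is Merino-dominated crossbreds.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator with defaults at
#' desk scale (a few thousand animals, 1000 SNP standing in for a ~50K chip).
#'
#' @param n_snp Number of SNPs; must divide evenly over `n_chromosomes`.
#' @param n_chromosomes Number of chromosomes.
#' @param morgans_per_chr Genetic length of each chromosome in Morgans.
#' @param n_breeds,fst Passed to [simulate_breed_frequencies()].
#' @param sire_breed_props Named proportions of cohort sires per breed;
#'   renormalised over breeds present in the breed model.
#' @param n_founders_per_breed Named counts for the maternal founder base
#'   (Merino ewes and Border Leicester rams used to breed the dam flock).
#' @param dam_f1_prop Proportion of dams that are Border Leicester x Merino
#'   F1 ewes; the remainder are purebred Merino.
#' @param n_sires_A,family_size_A Cohort-A sire count and mean progeny per
#'   sire (family sizes are Poisson around the mean, minimum 1).
#' @param n_sires_B,family_size_B Cohort-B sire count and exact progeny per
#'   sire (large half-sib groups).
#' @param n_dams Number of gen-1 dams; default scales with total progeny.
#' @param h2 Target narrow-sense heritability of the simulated trait.
#' @param prop_classes Four mixture proportions for marker-effect classes
#'   (variances 0, 1e-4, 1e-3, 1e-2 times `sigma_g2`); must sum to 1.
#' @param sigma_g2 Total additive-genetic variance of the trait.
#' @param polygenic_prop Share of `sigma_g2` carried by a residual polygenic
#'   term (pedigree-distributed) rather than by the simulated markers.
#' @param breed_effect_sd SD of true additive breed effects.
#' @param fixed_effect_sds Named SDs of the fixed-effect contributions
#'   (sex, birth_type, rearing_type, cg = contemporary group, age,
#'   age_of_dam).
#' @param hcwt_h2,hcwt_beta Heritability of the hot-carcass-weight stand-in
#'   covariate trait and its regression on the focal trait.
#' @param missing_rate Genotype missingness rate used by
#'   [inject_missingness_and_contamination()] defaults.
#' @param seed Master RNG seed; all stages derive their streams from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snp = 1000, n_chromosomes = 10, morgans_per_chr = 1,
                       n_breeds = 6, fst = 0.1,
                       sire_breed_props = c(Merino = 0.35,
                                            BorderLeicester = 0.15,
                                            PolledDorset = 0.20,
                                            WhiteSuffolk = 0.15,
                                            Texel = 0.10, Suffolk = 0.05),
                       n_founders_per_breed = c(Merino = 150,
                                                BorderLeicester = 12),
                       dam_f1_prop = 0.3,
                       n_sires_A = 25, family_size_A = 40,
                       n_sires_B = 20, family_size_B = 50,
                       n_dams = NULL,
                       h2 = 0.3,
                       prop_classes = c(0.95, 0.03, 0.015, 0.005),
                       sigma_g2 = 1, polygenic_prop = 0.3,
                       breed_effect_sd = 0.3,
                       fixed_effect_sds = c(sex = 0.25, birth_type = 0.2,
                                            rearing_type = 0.15, cg = 0.5,
                                            age = 0.1, age_of_dam = 0.1),
                       hcwt_h2 = 0.59, hcwt_beta = 0.3,
                       missing_rate = 0.01, seed = 1) {
  check_scalar(n_snp, "n_snp", lo = 1)
  check_scalar(h2, "h2")
  if (h2 <= 0 || h2 >= 1) stop("`h2` must lie strictly in (0, 1)", call. = FALSE)
  if (length(prop_classes) != 4L || any(prop_classes < 0)) {
    stop("`prop_classes` must be 4 non-negative proportions", call. = FALSE)
  }
  if (abs(sum(prop_classes) - 1) > 1e-8) {
    stop("`prop_classes` must sum to 1", call. = FALSE)
  }
  if (n_snp %% n_chromosomes != 0) {
    stop("`n_snp` must divide evenly across `n_chromosomes`", call. = FALSE)
  }
  if (family_size_A < 1 || family_size_B < 1) {
    stop("family sizes must be >= 1: an empty sire family is not allowed",
         call. = FALSE)
  }
  check_scalar(polygenic_prop, "polygenic_prop", lo = 0, hi = 1)
  check_scalar(dam_f1_prop, "dam_f1_prop", lo = 0, hi = 1)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d SNP on %d chromosomes; h2 = %g; seed = %d\n",
              x$n_snp, x$n_chromosomes, x$h2, x$seed))
  cat(sprintf("  cohort A: %d sires x ~%g progeny; cohort B: %d sires x %d\n",
              x$n_sires_A, x$family_size_A, x$n_sires_B,
              as.integer(x$family_size_B)))
  invisible(x)
}

#' Simulate a two-cohort multi-breed sheep pedigree
#'
#' Builds a three-layer pedigree: founder rams and ewes (generation 0), a dam
#' flock of Merino and Border Leicester x Merino F1 ewes (generation 1), and
#' the phenotyped slaughter generation (generation 2) split into cohort A
#' (many ~40-progeny sire families across 8 sites) and cohort B (few large
#' sire families at one site). Fixed-effect factors (sex, birth type, rearing
#' type, contemporary group = birth year x site x slaughter group, and an
#' age-of-dam factor for cohort A only) are assigned to slaughter progeny.
#'
#' @param config A [sim_config()].
#' @param breed_model A [simulate_breed_frequencies()] result; its breed set
#'   must include Merino and BorderLeicester.
#'
#' @return A `data.frame` with columns `id`, `sire`, `dam` (NA when
#'   unknown), `generation`, `founder_breed`, `sex`, `cohort` (`"A"`/`"B"`
#'   for slaughter progeny, NA otherwise), `sire_family`, and the
#'   fixed-effect factors. Rows are in generation order (parents precede
#'   offspring).
#' @export
simulate_pedigree <- function(config, breed_model) {
  stopifnot(inherits(config, "sim_config"), inherits(breed_model, "breed_model"))
  breeds <- breed_model$breed_names
  if (!all(c("Merino", "BorderLeicester") %in% breeds)) {
    stop("breed model must include Merino and BorderLeicester for the mating design",
         call. = FALSE)
  }
  set.seed(config$seed + 101L)

  props <- config$sire_breed_props[names(config$sire_breed_props) %in% breeds]
  if (length(props) == 0L) stop("no sire breeds available", call. = FALSE)
  props <- props / sum(props)

  n_mer_ewes <- as.integer(config$n_founders_per_breed[["Merino"]])
  n_bl_rams  <- as.integer(config$n_founders_per_breed[["BorderLeicester"]])
  n_mer_rams <- max(5L, n_mer_ewes %/% 15L)

  fam_A <- pmax(1L, rpois(config$n_sires_A, config$family_size_A))
  fam_B <- rep(as.integer(config$family_size_B), config$n_sires_B)
  n_prog <- sum(fam_A) + sum(fam_B)
  n_dams <- config$n_dams %||% max(20L, ceiling(n_prog / 4))

  founder <- function(id, breed, sex) {
    data.frame(id = id, sire = NA_character_, dam = NA_character_,
               generation = 0L, founder_breed = breed, sex = sex,
               stringsAsFactors = FALSE)
  }
  mer_ewes <- founder(sprintf("ME%03d", seq_len(n_mer_ewes)), "Merino", "F")
  mer_rams <- founder(sprintf("MR%03d", seq_len(n_mer_rams)), "Merino", "M")
  bl_rams  <- founder(sprintf("BR%03d", seq_len(n_bl_rams)), "BorderLeicester", "M")
  sire_breeds_A <- sample(names(props), config$n_sires_A, TRUE, props)
  sire_breeds_B <- sample(names(props), config$n_sires_B, TRUE, props)
  sires_A <- founder(sprintf("SA%03d", seq_len(config$n_sires_A)), sire_breeds_A, "M")
  sires_B <- founder(sprintf("SB%03d", seq_len(config$n_sires_B)), sire_breeds_B, "M")

  # generation 1: the dam flock
  is_f1 <- runif(n_dams) < config$dam_f1_prop
  dam_sire <- ifelse(is_f1,
                     sample(bl_rams$id, n_dams, TRUE),
                     sample(mer_rams$id, n_dams, TRUE))
  dams <- data.frame(id = sprintf("D%04d", seq_len(n_dams)),
                     sire = dam_sire,
                     dam = sample(mer_ewes$id, n_dams, TRUE),
                     generation = 1L, founder_breed = NA_character_,
                     sex = "F", stringsAsFactors = FALSE)

  # generation 2: slaughter progeny in two cohorts
  make_progeny <- function(sires, fam_sizes, cohort, prefix, n_sites) {
    n <- sum(fam_sizes)
    sire <- rep(sires$id, fam_sizes)
    bt <- sample(1:3, n, TRUE, prob = c(0.45, 0.45, 0.10))
    site <- if (n_sites > 1L) {
      sprintf("%s_site%d", cohort, sample.int(n_sites, n, TRUE))
    } else {
      rep(sprintf("%s_site1", cohort), n)
    }
    data.frame(
      id = sprintf("%s%05d", prefix, seq_len(n)),
      sire = sire,
      dam = sample(dams$id, n, TRUE),
      generation = 2L, founder_breed = NA_character_,
      sex = sample(c("M", "F"), n, TRUE),
      cohort = cohort, sire_family = sire,
      birth_type = bt,
      rearing_type = vapply(bt, function(b) sample.int(b, 1L), integer(1)),
      site = site,
      birth_year = sprintf("Y%d", sample.int(3L, n, TRUE)),
      slaughter_group = sprintf("SG%d", sample.int(4L, n, TRUE)),
      age_of_dam = if (cohort == "A") {
        sample(c("2yo", "3yo", "4plus"), n, TRUE)
      } else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  prog_A <- make_progeny(sires_A, fam_A, "A", "PA", 8L)
  prog_B <- make_progeny(sires_B, fam_B, "B", "PB", 1L)

  parents <- rbind(mer_ewes, mer_rams, bl_rams, sires_A, sires_B)
  parents$cohort <- NA_character_
  parents$sire_family <- NA_character_
  dams$cohort <- NA_character_
  dams$sire_family <- dams$sire
  for (col in c("birth_type", "rearing_type")) {
    parents[[col]] <- NA_integer_; dams[[col]] <- NA_integer_
  }
  for (col in c("site", "birth_year", "slaughter_group", "age_of_dam")) {
    parents[[col]] <- NA_character_; dams[[col]] <- NA_character_
  }
  ped <- rbind(parents, dams, prog_A, prog_B)
  rownames(ped) <- NULL
  validate_pedigree(ped)
  ped
}

#' Validate pedigree structure
#'
#' Checks that parents precede offspring (hence the pedigree is acyclic),
#' that founders carry a breed label and non-founders a sire family equal to
#' their sire's id.
#'
#' @param ped A pedigree data frame as from [simulate_pedigree()].
#' @return The pedigree, invisibly; errors describe the first violation.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("id", "sire", "dam", "generation") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicated animal ids", call. = FALSE)
  pos <- setNames(seq_len(nrow(ped)), ped$id)
  for (pcol in c("sire", "dam")) {
    p <- ped[[pcol]]
    known <- !is.na(p)
    if (!all(p[known] %in% ped$id)) {
      stop(sprintf("unknown %s id(s): %s", pcol,
                   paste(head(setdiff(p[known], ped$id)), collapse = ", ")),
           call. = FALSE)
    }
    bad <- known & pos[p] >= seq_len(nrow(ped))
    if (any(bad)) {
      stop(sprintf("pedigree not in parent-first order (cycle or misordering) at id %s",
                   ped$id[which(bad)[1L]]), call. = FALSE)
    }
  }
  is_founder <- is.na(ped$sire) & is.na(ped$dam)
  if ("founder_breed" %in% names(ped) &&
      any(is_founder & is.na(ped$founder_breed))) {
    stop("founder without a breed label", call. = FALSE)
  }
  if ("sire_family" %in% names(ped)) {
    nf <- !is.na(ped$sire) & !is.na(ped$sire_family)
    if (any(ped$sire_family[nf] != ped$sire[nf])) {
      stop("sire_family must equal the sire id", call. = FALSE)
    }
  }
  invisible(ped)
}
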