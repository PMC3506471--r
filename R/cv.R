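# Across-sire-family cross-validation: whole sire families are packed into
# validation subsets so that no half-sib of a validation animal is ever in
# the reference set; a second cohort is always reference, never validated.

#' Build an across-sire-family cross-validation design
#'
#' Shuffles cohort-A sire families (seeded) and packs them greedily into
#' subsets: a subset is closed at the first family that takes its size to
#' `target_size` or beyond, so subsets hold ~`target_size` animals and no
#' family is ever split. The last subset may be smaller. Cohort-B animals
#' are always reference and never validated.
#'
#' @param pedigree Pedigree with `cohort` and `sire_family` columns.
#' @param target_size Target animals per subset (default 500).
#' @param seed Integer RNG seed.
#' @return A list of class `cv_design`: `subsets` (list of id vectors),
#'   `always_reference` (cohort-B ids), `target_subset_size`, `seed`.
#' @export
make_subsets <- function(pedigree, target_size = 500, seed = 1) {
  a_ids <- pedigree$id[!is.na(pedigree$cohort) & pedigree$cohort == "A"]
  fams <- split(a_ids, pedigree$sire_family[match(a_ids, pedigree$id)])
  if (length(fams) < 2L) stop("cohort A needs >= 2 sire families", call. = FALSE)
  sizes <- lengths(fams)
  if (any(sizes > 2 * target_size)) {
    stop(sprintf("sire family '%s' (%d animals) exceeds twice the target size; increase target_size",
                 names(fams)[which.max(sizes)], max(sizes)), call. = FALSE)
  }
  set.seed(seed)
  ord <- sample.int(length(fams))
  subsets <- list()
  cur <- character(0)
  for (f in ord) {
    cur <- c(cur, fams[[f]])
    if (length(cur) >= target_size) {
      subsets[[length(subsets) + 1L]] <- cur
      cur <- character(0)
    }
  }
  if (length(cur)) subsets[[length(subsets) + 1L]] <- cur
  structure(
    list(subsets = subsets,
         always_reference = pedigree$id[!is.na(pedigree$cohort) &
                                          pedigree$cohort == "B"],
         target_subset_size = target_size, seed = seed),
    class = "cv_design")
}

#' @export
print.cv_design <- function(x, ...) {
  cat(sprintf("<cv_design> %d subsets (sizes %s); %d always-reference animals\n",
              length(x$subsets),
              paste(lengths(x$subsets), collapse = ", "),
              length(x$always_reference)))
  invisible(x)
}

#' Prepare the shared inputs for cross-validation
#'
#' Builds the relationship matrices and breed composition once from a
#' simulated (or assembled) dataset so folds can reuse them.
#'
#' @param sim A [simulate_dataset()] result, or a list with `pedigree`,
#'   `dosages`, `phenotypes`.
#' @param freq_min Allele-frequency exclusion for [build_grm()].
#' @param grm_method G estimator (see [build_grm()]).
#' @return A list: `phenotypes`, `pedigree`, `dosages`, `A`, `G`, `Q`.
#' @export
prepare_cv_data <- function(sim, freq_min = 0.005, grm_method = "yang") {
  list(phenotypes = sim$phenotypes, pedigree = sim$pedigree,
       dosages = sim$dosages,
       A = build_nrm(sim$pedigree),
       G = build_grm(sim$dosages, freq_min = freq_min, method = grm_method),
       Q = breed_composition(sim$pedigree))
}

#' Run one cross-validation fold
#'
#' Predicts the animals of one validation subset using all other subsets
#' plus the always-reference cohort. Validation phenotypes are deleted from
#' every model-fitting step (including the step-1 adjustment for BayesR); a
#' leakage assertion fails hard if any validation phenotype reaches a
#' fitted design.
#'
#' @param design A [make_subsets()] design.
#' @param fold Index of the validation subset.
#' @param method `"BLUP"` (pedigree), `"GBLUP"` or `"BayesR"`.
#' @param data A [prepare_cv_data()] list.
#' @param spec A [model_spec()]; its `random_terms` are overridden by the
#'   method's relationship structure.
#' @param components Named variance vector (with `residual`) to fix the
#'   variance components; `NULL` re-estimates them by REML on the fold's
#'   reference data (stricter, slower).
#' @param include_polygenic For GBLUP/BayesR, add a pedigree polygenic term
#'   and report `ghat + ahat`.
#' @param bayesr A [bayesr_config()] for the BayesR method.
#' @return Data frame for the fold animals: `id`, `fold`, `method`, `pred`
#'   (the method's canonical prediction), `ghat`, `ahat`.
#' @export
run_fold <- function(design, fold, method = c("BLUP", "GBLUP", "BayesR"),
                     data, spec = model_spec(), components = NULL,
                     include_polygenic = FALSE,
                     bayesr = bayesr_config(n_iter = 5000L, burn_in = 2000L,
                                            n_chains = 3L)) {
  method <- match.arg(method)
  stopifnot(inherits(design, "cv_design"), fold >= 1,
            fold <= length(design$subsets))
  val_ids <- design$subsets[[fold]]
  ref_ids <- c(unlist(design$subsets[-fold], use.names = FALSE),
               design$always_reference)
  if (length(intersect(val_ids, ref_ids))) {
    stop("leakage: validation ids appear in the reference set", call. = FALSE)
  }
  phen <- data$phenotypes[data$phenotypes$id %in% c(ref_ids, val_ids), ]

  if (method %in% c("BLUP", "GBLUP")) {
    K <- switch(method,
                BLUP = list(animal = data$A),
                GBLUP = if (include_polygenic) {
                  list(genomic = data$G, animal = data$A)
                } else list(genomic = data$G))
    if (is.null(components)) {
      ref_phen <- phen[phen$id %in% ref_ids, ]
      des <- build_design(ref_phen, spec, restrict_to = rownames(K[[1L]]))
      M <- lapply(K, function(k) k[des$ids, des$ids])
      fit <- reml_fit(des$y, des$X, M)
      components <- fit$sigma2
    }
    g <- gblup_predict(phen, spec, K, validation_ids = val_ids,
                       components = components,
                       Q = if ("breed" %in% names(components)) data$Q else NULL)
    ghat <- if (method == "GBLUP") g$u$genomic[val_ids] else NULL
    ahat <- if (!is.null(g$u$animal)) g$u$animal[val_ids] else NULL
    pred <- switch(method,
                   BLUP = ahat,
                   GBLUP = if (include_polygenic) ghat + ahat else ghat)
  } else { # BayesR on reference-adjusted phenotypes
    ref_phen <- phen[phen$id %in% ref_ids, ]
    adj_spec <- spec
    ystar <- adjust_phenotypes(ref_phen, adj_spec, Q = data$Q,
                               restrict_to = rownames(data$dosages))
    if (any(names(ystar) %in% val_ids)) {
      stop("leakage: validation phenotype in BayesR training set", call. = FALSE)
    }
    if (is.null(bayesr$sigma_g2_init) && !is.null(components)) {
      bayesr$sigma_g2_init <- unname(components[setdiff(names(components),
                                                        c("residual", "breed"))][1L])
    }
    post <- run_bayesr(ystar, data$dosages, config = bayesr,
                       A = if (include_polygenic) data$A else NULL)
    gall <- genomic_value_from_markers(data$dosages, post)
    ghat <- gall[val_ids]
    ahat <- NULL
    pred <- ghat
  }

  out <- data.frame(id = val_ids, fold = fold, method = method,
                    pred = as.numeric(pred), row.names = NULL)
  out$ghat <- if (is.null(ghat)) NA_real_ else as.numeric(ghat)
  out$ahat <- if (is.null(ahat)) NA_real_ else as.numeric(ahat)
  out
}

#' Prediction accuracy
#'
#' Pearson correlation of predictions with observed values (phenotypes or
#' adjusted phenotypes), divided by `h` -- the square root of the trait
#' heritability -- to adjust for the upper limit on the correlation
#' achievable against a single phenotype. Values above 1 are reported as
#' computed, never truncated.
#'
#' @param predictions,observed Numeric vectors (pairwise-complete pairs are
#'   used).
#' @param h Accuracy denominator, `sqrt(h2)` from the pedigree model.
#' @return Accuracy, or `NA` (with attribute `reason`) when fewer than 3
#'   pairs or zero-variance predictions make it undefined.
#' @export
accuracy <- function(predictions, observed, h = 1) {
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  ok <- !is.na(predictions) & !is.na(observed)
  if (sum(ok) < 3L) {
    return(structure(NA_real_, reason = "fewer than 3 complete pairs"))
  }
  if (var(predictions[ok]) == 0 || var(observed[ok]) == 0) {
    return(structure(NA_real_, reason = "zero-variance predictions or observations"))
  }
  cor(predictions[ok], observed[ok]) / h
}

#' Bias regression
#'
#' Ordinary least squares of observed on predicted values; a slope of 1
#' indicates calibrated (unbiased) predictions, and the intercept should be
#' near 0.
#'
#' @param observed,predictions Numeric vectors.
#' @return Named vector `c(slope, intercept)`, `NA` when undefined.
#' @export
bias_regression <- function(observed, predictions) {
  ok <- !is.na(predictions) & !is.na(observed)
  if (sum(ok) < 3L || var(predictions[ok]) == 0) {
    return(structure(c(slope = NA_real_, intercept = NA_real_),
                     reason = "undefined regression"))
  }
  cf <- coef(lm(observed[ok] ~ predictions[ok]))
  c(slope = unname(cf[2L]), intercept = unname(cf[1L]))
}

#' Split a validation subset by sire breed
#'
#' Assigns each validation animal to its sire's breed group (MER, BL, PD,
#' WS); animals with other or unknown sire breeds contribute to the overall
#' group only.
#'
#' @param fold_ids Validation animal ids.
#' @param pedigree Pedigree with `founder_breed` on sires.
#' @return Named list of id vectors: `ALL` plus any of `MER`, `BL`, `PD`,
#'   `WS` that are non-empty.
#' @export
split_by_sire_breed <- function(fold_ids, pedigree) {
  code <- c(Merino = "MER", BorderLeicester = "BL",
            PolledDorset = "PD", WhiteSuffolk = "WS")
  sires <- pedigree$sire[match(fold_ids, pedigree$id)]
  sire_breed <- pedigree$founder_breed[match(sires, pedigree$id)]
  grp <- unname(code[sire_breed])
  out <- list(ALL = fold_ids)
  for (g in c("MER", "BL", "PD", "WS")) {
    ids <- fold_ids[!is.na(grp) & grp == g]
    if (length(ids)) out[[g]] <- ids
  }
  out
}

#' Run the full cross-validation pipeline
#'
#' For every subset and method, predicts the validation animals from all
#' other subsets plus the always-reference cohort, then scores accuracy
#' (correlation divided by `h = sqrt(h2)`), bias (regression of observed on
#' predicted) and relatedness summaries, for the whole subset and for each
#' sire-breed subdivision, against phenotypes and against adjusted
#' phenotypes.
#'
#' @param data A [prepare_cv_data()] list.
#' @param design A [make_subsets()] design.
#' @param methods Subset of `c("BLUP", "GBLUP", "BayesR")`.
#' @param spec A [model_spec()].
#' @param h2_model1 Heritability used for the accuracy denominator,
#'   normally the pedigree-model REML estimate on the full data; `NULL`
#'   estimates it here (one single-term REML fit).
#' @param components Fixed variance components per method (named list, e.g.
#'   `list(GBLUP = c(genomic = ..., residual = ...))`); `NULL` re-estimates
#'   per fold.
#' @param min_cell_n Breed-group cells smaller than this are flagged
#'   `reliable = FALSE` (never dropped).
#' @param ... Passed to [run_fold()].
#' @return A list of class `cv_result`: `cells` (tidy data frame: one row
#'   per fold x method x response x breed group) and `predictions`.
#' @export
cv_run <- function(data, design, methods = c("BLUP", "GBLUP"),
                   spec = model_spec(), h2_model1 = NULL, components = NULL,
                   min_cell_n = 10L, ...) {
  phen <- data$phenotypes
  if (is.null(h2_model1)) {
    des <- build_design(phen, spec, restrict_to = rownames(data$A))
    fit <- reml_fit(des$y, des$X,
                    random = list(animal = data$A[des$ids, des$ids]))
    h2_model1 <- fit$h2
  }
  h <- sqrt(h2_model1)
  ystar <- adjust_phenotypes(phen, spec, Q = data$Q,
                             restrict_to = rownames(data$dosages))

  cells <- list()
  preds <- list()
  for (method in methods) {
    comp <- if (is.list(components)) components[[method]] else components
    for (fold in seq_along(design$subsets)) {
      pf <- run_fold(design, fold, method, data, spec = spec,
                     components = comp, ...)
      preds[[paste(method, fold)]] <- pf
      val_ids <- pf$id
      ref_ids <- c(unlist(design$subsets[-fold], use.names = FALSE),
                   design$always_reference)
      rel <- relatedness_to_reference(data$G, val_ids,
                                      intersect(ref_ids, rownames(data$G)))
      groups <- split_by_sire_breed(val_ids, data$pedigree)
      obs_y <- setNames(phen$y[match(val_ids, phen$id)], val_ids)
      obs_adj <- ystar[val_ids]
      for (gname in names(groups)) {
        ids <- groups[[gname]]
        p <- setNames(pf$pred, pf$id)[ids]
        for (resp in c("phenotype", "adjusted")) {
          o <- if (resp == "phenotype") obs_y[ids] else obs_adj[ids]
          acc <- accuracy(p, o, h = h)
          br <- bias_regression(o, p)
          cells[[length(cells) + 1L]] <- data.frame(
            fold = fold, method = method, response = resp,
            breed_group = gname, n = length(ids),
            accuracy = as.numeric(acc), slope = br[["slope"]],
            intercept = br[["intercept"]],
            mean_sq = mean(rel$mean_sq[match(ids, rel$id)]),
            top10_mean = mean(rel$top10_mean[match(ids, rel$id)]),
            reliable = length(ids) >= min_cell_n)
        }
      }
    }
  }
  structure(list(cells = do.call(rbind, cells),
                 predictions = do.call(rbind, preds),
                 h = h, h2_model1 = h2_model1),
            class = "cv_result")
}

#' Summarise cross-validation results
#'
#' Means and standard errors (SD across subsets / sqrt(number of subsets))
#' of accuracy and bias slope per method, response type and breed group.
#'
#' @param results A [cv_run()] result (or its `cells` data frame).
#' @return Data frame of class `accuracy_summary`.
#' @export
summarise_cv <- function(results) {
  cells <- if (inherits(results, "cv_result")) results$cells else results
  if (length(unique(cells$fold)) < 2L) {
    stop("need at least 2 subsets to summarise", call. = FALSE)
  }
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    sd(x) / sqrt(length(x))
  }
  agg <- aggregate(cbind(accuracy, slope) ~ method + response + breed_group,
                   data = cells, FUN = mean, na.rm = TRUE, na.action = NULL)
  agg_se <- aggregate(cbind(accuracy, slope) ~ method + response + breed_group,
                      data = cells, FUN = se, na.action = NULL)
  names(agg)[names(agg) == "accuracy"] <- "mean_accuracy"
  names(agg)[names(agg) == "slope"] <- "mean_slope"
  agg$se_accuracy <- agg_se$accuracy
  agg$se_slope <- agg_se$slope
  class(agg) <- c("accuracy_summary", "data.frame")
  agg
}
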