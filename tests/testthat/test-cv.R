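# Across-sire-family cross-validation: design, fold orchestration, scoring

fam_pedigree <- function(sizes, cohort = "A") {
  n_s <- length(sizes)
  sires <- data.frame(id = sprintf("S%02d", seq_len(n_s)),
                      sire = NA_character_, dam = NA_character_,
                      generation = 0L, founder_breed = "Merino", sex = "M",
                      cohort = NA_character_, sire_family = NA_character_,
                      stringsAsFactors = FALSE)
  dams <- data.frame(id = "D01", sire = NA_character_, dam = NA_character_,
                     generation = 0L, founder_breed = "Merino", sex = "F",
                     cohort = NA_character_, sire_family = NA_character_,
                     stringsAsFactors = FALSE)
  kids <- data.frame(id = sprintf("K%04d", seq_len(sum(sizes))),
                     sire = rep(sires$id, sizes), dam = "D01",
                     generation = 1L, founder_breed = NA_character_,
                     sex = "F", cohort = cohort,
                     sire_family = rep(sires$id, sizes),
                     stringsAsFactors = FALSE)
  rbind(sires, dams, kids)
}

test_that("exact packing: ten families of 100 at target 500 give two subsets", {
  ped <- fam_pedigree(rep(100L, 10))
  d <- make_subsets(ped, target_size = 500, seed = 1)
  expect_length(d$subsets, 2L)
  expect_equal(lengths(d$subsets), c(500L, 500L))
})

test_that("the greedy closure rule produces 600 + 300 for (300,300,300)", {
  ped <- fam_pedigree(rep(300L, 3))
  d <- make_subsets(ped, target_size = 500, seed = 2)
  expect_equal(sort(lengths(d$subsets)), c(300L, 600L))
})

test_that("designs are deterministic, partition cohort A and keep families whole", {
  sim <- small_sim()
  d1 <- make_subsets(sim$pedigree, target_size = 60, seed = 5)
  d2 <- make_subsets(sim$pedigree, target_size = 60, seed = 5)
  expect_identical(d1, d2)
  a_ids <- sim$pedigree$id[!is.na(sim$pedigree$cohort) & sim$pedigree$cohort == "A"]
  for (seed in 1:10) {
    d <- make_subsets(sim$pedigree, target_size = 60, seed = seed)
    flat <- unlist(d$subsets)
    expect_setequal(flat, a_ids)            # union = cohort A
    expect_equal(anyDuplicated(flat), 0L)   # disjoint
    fam <- sim$pedigree$sire_family[match(flat, sim$pedigree$id)]
    assign_of <- rep(seq_along(d$subsets), lengths(d$subsets))
    expect_true(all(tapply(assign_of, fam, function(x) length(unique(x))) == 1L))
    expect_false(any(d$always_reference %in% flat))
  }
})

test_that("an oversized family is rejected with advice", {
  ped <- fam_pedigree(c(50L, 500L))
  expect_error(make_subsets(ped, target_size = 100), "twice the target size")
})

test_that("run_fold refuses leaking designs and unlinked animals predict zero", {
  set.seed(6)
  ped <- fam_pedigree(rep(20L, 4))
  ids <- ped$id[!is.na(ped$cohort)]
  A <- diag(length(ids)); dimnames(A) <- list(ids, ids)
  ph <- data.frame(id = ids, y = rnorm(length(ids)))
  data <- list(phenotypes = ph, pedigree = ped, A = A, G = A,
               dosages = matrix(0, length(ids), 1, dimnames = list(ids, "s1")),
               Q = matrix(1, length(ids), 1, dimnames = list(ids, "Merino")))
  design <- make_subsets(ped, target_size = 40, seed = 3)
  spec <- model_spec(fixed_factors = NULL, covariates = NULL)
  # identity A: validation animals share nothing with the reference
  pf <- run_fold(design, 1, "BLUP", data, spec = spec,
                 components = c(animal = 1, residual = 1))
  expect_true(all(abs(pf$pred) < 1e-12))
  # tampered design with overlap must fail hard
  bad <- design
  bad$always_reference <- c(bad$always_reference, bad$subsets[[1L]][1L])
  expect_error(run_fold(bad, 1, "BLUP", data, spec = spec,
                        components = c(animal = 1, residual = 1)),
               "leakage")
})

test_that("accuracy and bias match their definitions and an independent path", {
  expect_equal(accuracy(1:10, 1:10, h = 1), 1)
  expect_equal(accuracy(c(1, 2, 3), c(2, 4, 6), h = 0.5), 2)  # can exceed 1
  expect_true(is.na(accuracy(rep(1, 5), rnorm(5))))
  expect_match(attr(accuracy(rep(1, 5), rnorm(5)), "reason"), "zero-variance")
  expect_true(is.na(accuracy(1:2, 1:2)))
  br <- bias_regression(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(br), c(1, 0))
  br2 <- bias_regression(2 * c(1, 3, 2, 5) + 3, c(1, 3, 2, 5))
  expect_equal(br2[["slope"]], 2)
  expect_equal(br2[["intercept"]], 3)
  # independent straightforward reimplementation on random vectors
  set.seed(7)
  for (i in 1:5) {
    p <- rnorm(50); o <- rnorm(50); h <- runif(1, 0.3, 0.9)
    acc_direct <- (sum((p - mean(p)) * (o - mean(o))) /
                     ((50 - 1) * sd(p) * sd(o))) / h
    expect_equal(accuracy(p, o, h), acc_direct, tolerance = 1e-12)
    sl <- sum((p - mean(p)) * (o - mean(o))) / sum((p - mean(p))^2)
    ic <- mean(o) - sl * mean(p)
    expect_equal(unname(bias_regression(o, p)), c(sl, ic), tolerance = 1e-12)
  }
})

test_that("sire-breed splits partition by the sire's founder breed", {
  sim <- small_sim()
  design <- make_subsets(sim$pedigree, target_size = 60, seed = 8)
  fold_ids <- design$subsets[[1L]]
  groups <- split_by_sire_breed(fold_ids, sim$pedigree)
  expect_identical(groups$ALL, fold_ids)
  sub <- setdiff(names(groups), "ALL")
  expect_lte(sum(lengths(groups[sub])), length(fold_ids))
  for (g in sub) {
    sires <- sim$pedigree$sire[match(groups[[g]], sim$pedigree$id)]
    breeds <- sim$pedigree$founder_breed[match(sires, sim$pedigree$id)]
    code <- c(Merino = "MER", BorderLeicester = "BL",
              PolledDorset = "PD", WhiteSuffolk = "WS")
    expect_true(all(code[breeds] == g))
  }
})

test_that("summaries aggregate across subsets with the stated SE", {
  cells <- data.frame(fold = c(1, 2, 1, 2), method = "GBLUP",
                      response = "adjusted", breed_group = "ALL",
                      accuracy = c(0.1, 0.3, 0.2, 0.2),
                      slope = c(1, 1, 1, 1))
  s <- summarise_cv(cells[1:2, ])
  expect_equal(s$mean_accuracy, 0.2)
  expect_equal(s$se_accuracy, 0.1)
  expect_equal(s$se_slope, 0)
  expect_error(summarise_cv(cells[1, ]), "at least 2 subsets")
})

test_that("the full pipeline scores all three methods end to end", {
  sim <- small_sim()
  data <- prepare_cv_data(sim)
  design <- make_subsets(sim$pedigree, target_size = 70, seed = 9)
  spec <- model_spec(covariates = NULL)
  res <- cv_run(data, design, methods = c("BLUP", "GBLUP", "BayesR"),
                spec = spec, h2_model1 = 0.4,
                components = list(
                  BLUP = c(animal = 1, residual = 1.5),
                  GBLUP = c(genomic = 1, residual = 1.5)),
                bayesr = bayesr_config(n_iter = 400, burn_in = 100,
                                       n_chains = 1, seed = 11,
                                       sigma_g2_init = 1))
  cells <- res$cells
  expect_true(all(c("BLUP", "GBLUP", "BayesR") %in% cells$method))
  all_cells <- cells[cells$breed_group == "ALL", ]
  expect_true(all(is.finite(all_cells$accuracy)))
  expect_true(all(is.finite(all_cells$mean_sq)))
  # determinism of the whole orchestration
  res2 <- cv_run(data, design, methods = "GBLUP", spec = spec,
                 h2_model1 = 0.4,
                 components = list(GBLUP = c(genomic = 1, residual = 1.5)))
  res3 <- cv_run(data, design, methods = "GBLUP", spec = spec,
                 h2_model1 = 0.4,
                 components = list(GBLUP = c(genomic = 1, residual = 1.5)))
  expect_identical(res2$cells, res3$cells)
})
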