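# Cross-validation machinery, grid search, summaries.

make_sired_panel <- function(n_sires, per_sire, seed = 40) {
  withr::with_seed(seed, {
    map <- make_test_map(8)
    n <- n_sires * per_sire
    make_test_panel(matrix(rbinom(n * 8, 1L, 0.5), n, 8),
                    matrix(rbinom(n * 8, 1L, 0.5), n, 8), map,
                    sire = rep(sprintf("S%02d", seq_len(n_sires)),
                               each = per_sire))
  })
}

test_that("sire families are never split across folds", {
  panel <- make_sired_panel(50, 15)
  plan <- make_cv_plan(panel, n_folds = 5, seed = 41)
  expect_identical(as.vector(table(plan$sire_fold)), rep(10L, 5))
  expect_identical(as.vector(table(plan$fold_of)), rep(150L, 5))
  expect_identical(sort(names(plan$fold_of)), sort(panel$ind$id))
  by_sire <- tapply(plan$fold_of, panel$ind$sire, unique)
  expect_true(all(lengths(by_sire) == 1L))
  expect_error(make_cv_plan(panel, n_folds = 1), "folds")
  panel$ind$sire[1] <- NA
  expect_error(make_cv_plan(panel), "sire")
})

test_that("scenario arithmetic is produced by the CV machinery", {
  sz <- cv_scenario_sizes(100, n_hf = 400, n_folds = 5, n_sires = 20,
                          seed = 42)
  expect_identical(sz$validation, 20L)
  expect_identical(sz$within_ref, 80L)
  expect_identical(sz$multi_ref, 480L)
  expect_equal(sz$pct_an_multi, round(100 * 80 / 480, 2))
  expect_identical(sz$sires_per_fold, 4L)
})

test_that("validation phenotypes never influence their own fold", {
  sc <- simulate_scenario(n_an = 90, n_hf = 180, n_sires_an = 6,
                          n_markers = 900, n_chromosomes = 3,
                          chromosome_length_bp = 1.5e7, n_qtl = 90,
                          seed = 43)
  plan <- make_cv_plan(sc$an, seed = 44)
  res <- run_cv(sc, plan)
  mutated <- sc
  val_ids <- names(plan$fold_of)[plan$fold_of == 1]
  i <- mutated$phen_an$individual_id %in% val_ids
  mutated$phen_an$y[i] <- mutated$phen_an$y[i] + 100
  res_mut <- run_cv(mutated, plan)
  expect_equal(res[res$fold == 1, ], res_mut[res_mut$fold == 1, ],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(res[res$fold == 2, "accuracy"],
                                res_mut[res_mut$fold == 2, "accuracy"])))
})

test_that("fold fitting on Gram blocks equals the explicit solver route", {
  sc <- simulate_scenario(n_an = 90, n_hf = 180, n_sires_an = 6,
                          n_markers = 900, n_chromosomes = 3,
                          chromosome_length_bp = 1.5e7, n_qtl = 90,
                          seed = 45)
  plan <- make_cv_plan(sc$an, seed = 46)
  r <- 0.75
  res <- run_cv(sc, plan, models = "boa", r = r)

  mask <- filter_markers(list(AN = sc$an, HF = sc$hf), sc$arch$qtl_idx)
  comb <- combine_panels(sc$an, sc$hf)
  oc <- combine_origin_maps(sc$origins_assigned, sc$origins_hf)
  phen <- rbind(sc$phen_an, sc$phen_hf)
  freqs <- cbind(AN = allele_freq(sc$an)[mask],
                 HF = allele_freq(sc$hf)[mask])
  vs <- make_variance_spec(0.3, freqs, r, 1)
  val_ids <- names(plan$fold_of)[plan$fold_of == 1]
  ref_ids <- c(setdiff(sc$an$ind$id, val_ids), sc$hf$ind$id)
  ds_ref <- build_design(subset_individuals(comb, ref_ids),
                         subset_origin_map(oc, match(ref_ids, comb$ind$id)),
                         y = phen, marker_mask = mask)
  fit <- solve_boa_mme(ds_ref, vs)
  ds_val <- build_design(subset_individuals(comb, val_ids),
                         subset_origin_map(oc, match(val_ids, comb$ind$id)),
                         marker_mask = mask)
  gebv <- predict_gebv(fit, ds_val)
  tbv <- sc$phen_an$tbv[match(val_ids, sc$phen_an$individual_id)]
  expect_equal(res$accuracy[res$fold == 1], cor(gebv, tbv),
               tolerance = 1e-6)
})

test_that("grid search degenerates correctly and summaries are exact", {
  sc <- simulate_scenario(n_an = 90, n_hf = 180, n_sires_an = 6,
                          n_markers = 900, n_chromosomes = 3,
                          chromosome_length_bp = 1.5e7, n_qtl = 90,
                          seed = 47)
  g <- grid_search_correlation(sc, grid = 0.75, seed = 48)
  expect_identical(g$r, 0.75)
  expect_error(grid_search_correlation(sc, grid = numeric(0)), "empty")

  same <- data.frame(model = "boa", replicate = rep(1:3, each = 5),
                     accuracy = 0.4)
  s1 <- summarize_accuracies(same)
  expect_equal(s1$sd, 0)
  expect_equal(s1$se, 0)
  two <- data.frame(model = "boa", replicate = c(1, 2),
                    accuracy = c(0.4, 0.6))
  s2 <- summarize_accuracies(two)
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$sd, sd(c(0.4, 0.6)), tolerance = 1e-12)
  expect_equal(s2$se, sd(c(0.4, 0.6)) / sqrt(2), tolerance = 1e-12)
})

test_that("constant predictions yield a missing accuracy with a warning", {
  expect_warning(out <- boapred:::.fold_accuracy(rep(1, 5), rnorm(5)),
                 "constant")
  expect_true(is.na(out))
})
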