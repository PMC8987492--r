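# QTL selection, correlated effects, variance scaling, TBVs, phenotypes.

test_that("QTL selection samples only eligible markers, deterministically", {
  map <- make_test_map(100)
  eligible <- rep(c(TRUE, FALSE), 50)
  a1 <- select_qtls(map, eligible, 20, seed = 1)
  a2 <- select_qtls(map, eligible, 20, seed = 1)
  expect_identical(a1$qtl_idx, a2$qtl_idx)
  expect_true(all(eligible[a1$qtl_idx]))
  expect_identical(length(unique(a1$qtl_idx)), 20L)
  # exhaustive case: n_qtl equal to the number of eligible markers
  all_of_them <- select_qtls(map, eligible, 50, seed = 2)
  expect_identical(all_of_them$qtl_idx, which(eligible))
  expect_error(select_qtls(map, eligible, 51, seed = 3), "eligible")
})

test_that("effect pairs have the requested correlation structure", {
  map <- make_test_map(100000, spacing_bp = 1e3)
  arch <- structure(list(qtl_idx = seq_len(1e5),
                         qtl_id = map$marker_id), class = "trait_architecture")
  a_dup <- sample_qtl_effects(arch, 1, rho = 1, seed = 4)
  expect_equal(a_dup$effects[, 1], a_dup$effects[, 2],
               tolerance = 1e-12, ignore_attr = TRUE)
  a95 <- sample_qtl_effects(arch, 1, rho = 0.95, seed = 5)
  expect_lt(abs(cor(a95$effects)[1, 2] - 0.95), 0.01)
  a0 <- sample_qtl_effects(arch, 1, rho = 0, seed = 6)
  expect_lt(abs(cor(a0$effects)[1, 2]), 0.01)
  expect_error(sample_qtl_effects(arch, 1, rho = 1.2), "rho")
})

test_that("per-breed scaling hits the target additive variance exactly", {
  map <- make_test_map(10)
  arch <- select_qtls(map, rep(TRUE, 10), 10, seed = 7)
  arch$effects <- matrix(0.3, 10, 2, dimnames = list(arch$qtl_id,
                                                     c("AN", "HF")))
  arch$group_labels <- c("AN", "HF")
  freqs <- matrix(0.5, 10, 2, dimnames = list(NULL, c("AN", "HF")))
  sc <- scale_effects_to_va(arch, freqs, target_va = 0.3)
  # closed form: L QTLs at p = 0.5 with equal effects -> a' = sqrt(va/(0.5 L))
  expect_equal(unname(sc$effects[1, 1]), sqrt(0.3 / (0.5 * 10)),
               tolerance = 1e-10)
  expect_equal(unname(sc$va_by_group), c(0.3, 0.3), tolerance = 1e-10)
})

test_that("positive rescaling leaves the effect correlation unchanged", {
  map <- make_test_map(400)
  arch <- select_qtls(map, rep(TRUE, 400), 400, seed = 8)
  arch <- sample_qtl_effects(arch, 1, rho = 0.8, seed = 9)
  before <- cor(arch$effects)[1, 2]
  freqs <- withr::with_seed(10, matrix(runif(800, 0.05, 0.95), 400, 2))
  sc <- scale_effects_to_va(arch, freqs, 0.3)
  expect_equal(cor(sc$effects)[1, 2], before, tolerance = 1e-12)
  # degenerate: all effects zero in a group
  arch$effects[, 1] <- 0
  expect_error(scale_effects_to_va(arch, freqs, 0.3), "zero")
})

test_that("origin-split TBVs follow the allele-count formula", {
  map <- make_test_map(3)
  # ind 1: hom ref everywhere; ind 2: QTL2 hom alt, one copy per origin
  pat <- rbind(c(0L, 0L, 0L), c(0L, 1L, 0L))
  mat <- rbind(c(0L, 0L, 0L), c(0L, 1L, 0L))
  panel <- make_test_panel(pat, mat, map)
  om <- origin_map(matrix(1L, 2, 3), matrix(2L, 2, 3), c("AN", "HF"))
  arch <- list(qtl_idx = 2L, qtl_id = map$marker_id[2],
               effects = matrix(c(0.4, -0.1), 1, 2,
                                dimnames = list(NULL, c("AN", "HF"))),
               group_labels = c("AN", "HF"))
  class(arch) <- "trait_architecture"
  tbv <- compute_tbv(panel, om, arch)
  expect_equal(unname(tbv[1]), 0)
  expect_equal(unname(tbv[2]), 0.4 + (-0.1))
  # purebred reduction: all-HF origins use only the HF effect column
  om_hf <- constant_origin_map(panel, "HF", c("AN", "HF"))
  tbv_hf <- compute_tbv(panel, om_hf, arch)
  expect_equal(unname(tbv_hf[2]), 2 * (-0.1))
})

test_that("origin-split dosages partition the plain allele count", {
  map <- make_test_map(50)
  set.seed(11)
  panel <- random_test_panel(30, runif(50, 0.2, 0.8), map)
  om <- origin_map(matrix(sample.int(2, 1500, TRUE), 30, 50),
                   matrix(sample.int(2, 1500, TRUE), 30, 50), c("AN", "HF"))
  ds <- build_design(panel, om)
  expect_identical(ds$Z[[1]] + ds$Z[[2]], dosage(panel))
})

test_that("phenotypes realize the phenotypic-variance target", {
  expect_error(simulate_phenotypes(c(a = 1), va = 0.3, target_vp = 0.3),
               "exceed")
  tbv <- withr::with_seed(12, rnorm(20000, 0, sqrt(0.3)))
  names(tbv) <- sprintf("i%05d", seq_along(tbv))
  ph <- simulate_phenotypes(tbv, va = 0.3, target_vp = 1, seed = 13)
  expect_lt(abs(var(ph$y) - 1), 0.05)
  expect_lt(abs(var(ph$y - ph$tbv) - 0.7), 0.05)
  expect_lt(abs(unname(coef(lm(ph$y ~ ph$tbv))[2]) - 1), 0.05)
})
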