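# Mixed-model solvers and GEBV prediction.

test_that("MME and GLS routes agree with each other and the dense oracle", {
  for (seed in 1:6) {
    inst <- random_boa_instance(N = sample(4:10, 1), M = sample(2:5, 1),
                                K = 2, seed = seed)
    fit_mme <- solve_boa_mme(inst$design, inst$vspec, method = "mme")
    fit_gls <- solve_boa_mme(inst$design, inst$vspec, method = "gls")
    ora <- oracle_mixed_model(inst$design$y, inst$design$X, inst$design$Z,
                              inst$vspec$sigma, inst$vspec$sigma_e2)
    expect_equal(unname(fit_mme$a_hat), ora$a_hat, tolerance = 1e-8)
    expect_equal(unname(fit_gls$a_hat), ora$a_hat, tolerance = 1e-8)
    expect_equal(unname(fit_mme$beta_hat), ora$beta, tolerance = 1e-8)
    expect_equal(unname(fit_gls$beta_hat), ora$beta, tolerance = 1e-8)
  }
})

test_that("single-group model collapses to standard SNP-BLUP", {
  withr::with_seed(30, {
    map <- make_test_map(6)
    panel <- random_test_panel(12, runif(6, 0.3, 0.7), map)
    y <- rnorm(12)
  })
  om <- constant_origin_map(panel, "AN", "AN")
  ds <- build_design(panel, om, y = y)
  fit1 <- solve_boa_mme(ds, variance_spec(matrix(0.1, 1, 1), 0.5))
  fit2 <- solve_snp_blup(y, dosage(panel), 0.1, 0.5)
  expect_equal(unname(fit1$a_hat), unname(fit2$a_hat), tolerance = 1e-10)
  expect_equal(unname(fit1$beta_hat), unname(fit2$beta_hat),
               tolerance = 1e-10)
})

test_that("infinite shrinkage drives effects to zero and the intercept to the mean", {
  withr::with_seed(31, {
    map <- make_test_map(5)
    panel <- random_test_panel(15, runif(5, 0.3, 0.7), map)
    y <- rnorm(15, 2)
  })
  fit <- solve_snp_blup(y, dosage(panel), sigma_a2 = 1e-12, sigma_e2 = 0.5)
  expect_lt(max(abs(fit$a_hat)), 1e-6)
  expect_equal(unname(fit$beta_hat), mean(y), tolerance = 1e-4)
})

test_that("an unobserved origin group shrinks toward the observed one", {
  # Z_2 = 0: the BLUP of a_2 is the prior regression (sigma_21/sigma_1^2) a_1
  withr::with_seed(32, {
    map <- make_test_map(4)
    panel <- random_test_panel(10, runif(4, 0.3, 0.7), map)
    y <- rnorm(10)
  })
  om <- constant_origin_map(panel, "AN", c("AN", "HF"))
  ds <- build_design(panel, om, y = y)
  sigma <- matrix(c(0.2, 0.09, 0.09, 0.15), 2)
  fit <- solve_boa_mme(ds, variance_spec(sigma, 0.6))
  expect_equal(fit$a_hat[, "HF"], (0.09 / 0.2) * fit$a_hat[, "AN"],
               tolerance = 1e-8)
})

test_that("GEBVs follow the origin-split prediction formula", {
  fit <- structure(list(
    beta_hat = c(AN = 0, HF = 0),
    a_hat = cbind(AN = c(0.1, -0.2), HF = c(0.05, 0.3)),
    model_kind = "boa", marker_ids = c("m1", "m2"),
    group_labels = c("AN", "HF")), class = "model_fit")
  z <- list(AN = matrix(c(1, 0), 1), HF = matrix(c(1, 2), 1))
  expect_equal(unname(predict_gebv(fit, z)), 1 * 0.1 + 1 * 0.05 + 2 * 0.3)
  # identical effect columns make origins irrelevant
  fit$a_hat[, "HF"] <- fit$a_hat[, "AN"]
  base <- structure(list(beta_hat = c(intercept = 0),
                         a_hat = cbind(a = c(0.1, -0.2)),
                         model_kind = "snp_blup", marker_ids = c("m1", "m2"),
                         group_labels = "a"), class = "model_fit")
  expect_equal(unname(predict_gebv(fit, z)),
               unname(predict_gebv(base, z[[1]] + z[[2]])))
})

test_that("solutions are equivariant under individual and marker permutations", {
  inst <- random_boa_instance(N = 9, M = 4, K = 2, seed = 33)
  fit <- solve_boa_mme(inst$design, inst$vspec, method = "mme")
  perm_i <- sample(9)
  perm_m <- sample(4)
  ds2 <- inst$design
  ds2$y <- ds2$y[perm_i]
  ds2$X <- ds2$X[perm_i, , drop = FALSE]
  ds2$Z <- lapply(ds2$Z, function(z) z[perm_i, perm_m, drop = FALSE])
  ds2$marker_ids <- ds2$marker_ids[perm_m]
  fit2 <- solve_boa_mme(ds2, inst$vspec, method = "mme")
  expect_equal(unname(fit2$a_hat), unname(fit$a_hat[perm_m, ]),
               tolerance = 1e-8)
  expect_equal(fit2$beta_hat, fit$beta_hat, tolerance = 1e-8)
})

test_that("GEBVs are shrunken relative to the phenotypes", {
  inst <- random_boa_instance(N = 10, M = 5, K = 2, seed = 34)
  ds <- inst$design
  ds$y <- ds$y - mean(ds$y)
  fit <- solve_boa_mme(ds, inst$vspec)
  gebv <- predict_gebv(fit, ds)
  expect_lte(var(gebv), var(ds$y) + 1e-12)
})

test_that("SNP-BLUP GEBVs match the GBLUP oracle", {
  withr::with_seed(35, {
    map <- make_test_map(5)
    panel <- random_test_panel(14, runif(5, 0.3, 0.7), map)
    y <- rnorm(14)
  })
  Z <- dosage(panel)
  ref <- 1:10
  val <- 11:14
  fit <- solve_snp_blup(y[ref], Z[ref, ], 0.12, 0.6)
  gebv <- predict_gebv(fit, Z[val, ])
  expect_equal(unname(gebv),
               oracle_gblup_gebv(y[ref], Z[ref, ], Z[val, ], 0.12, 0.6),
               tolerance = 1e-8)
})

test_that("the origin-split model converges to multi-breed SNP-BLUP as r -> 1", {
  # F1-style panel: paternal haplotypes native, maternal foreign, so the
  # contribution matrix is constant (rank-deficient X, minimum-norm path)
  withr::with_seed(36, {
    map <- make_test_map(30)
    pat <- matrix(rbinom(12 * 30, 1L, 0.4), 12, 30)
    mat <- matrix(rbinom(12 * 30, 1L, 0.6), 12, 30)
    y <- rnorm(12)
  })
  panel <- make_test_panel(pat, mat, map)
  om <- origin_map(matrix(1L, 12, 30), matrix(2L, 12, 30), c("AN", "HF"))
  ds <- build_design(panel, om, y = y)
  s2 <- 0.01
  base <- solve_snp_blup(y, dosage(panel), s2, 0.7)
  g_base <- predict_gebv(base, dosage(panel))
  dev <- vapply(c(0.9, 0.99, 0.999), function(r) {
    vs <- variance_spec(s2 * matrix(c(1, r, r, 1), 2), 0.7)
    max(abs(predict_gebv(solve_boa_mme(ds, vs), ds) - g_base))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], dev[1] / 10)
})
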