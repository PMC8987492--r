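# Founder simulator and gene-dropping machinery.

test_that("no migration leaves the admixed panel fully native", {
  cfg <- founder_sim_config(n_markers = 60, n_chromosomes = 2,
                            breed_sizes = c(AN = 20, HF = 5),
                            admixture_fraction = 0, seed = 4)
  f <- simulate_founder_breeds(cfg)
  expect_true(all(f$true_origins$pat == 1L))
  expect_true(all(f$true_origins$mat == 1L))
})

test_that("migrant pulse calibrates the genome-wide foreign-origin fraction", {
  cfg <- founder_sim_config(n_markers = 2000, n_chromosomes = 6,
                            chromosome_length_bp = 2.5e7,
                            breed_sizes = c(AN = 500, HF = 10), seed = 1)
  f <- simulate_founder_breeds(cfg)
  fr <- (mean(f$true_origins$pat == 2L) + mean(f$true_origins$mat == 2L)) / 2
  expect_lt(abs(fr - 0.157), 0.03)
})

test_that("small Fst yields nearly identical breed allele frequencies", {
  mean_absdiff <- function(fst) {
    cfg <- founder_sim_config(n_markers = 1500, fst = fst,
                              breed_sizes = c(AN = 5, HF = 5), seed = 9)
    f <- simulate_founder_breeds(cfg)
    mean(abs(f$frequencies$AN - f$frequencies$HF))
  }
  d_small <- mean_absdiff(0.001)
  d_large <- mean_absdiff(0.3)
  # E|p_AN - p_HF| ~ sqrt(2 fst p0 q0) * sqrt(2/pi) <= 0.018 at fst = 0.001
  expect_lt(d_small, 0.03)
  expect_gt(d_large, 3 * d_small)
})

test_that("zero genetic map length transmits whole parental haplotypes", {
  map <- make_test_map(40, cm_per_mb = 0)
  set.seed(2)
  panel <- random_test_panel(10, runif(40, 0.2, 0.8), map)
  gen <- simulate_generation(panel, 8, n_sires = 4, n_dams = 6, seed = 3)
  off <- gen$panel
  for (i in seq_len(n_ind(off))) {
    s <- match(off$ind$sire[i], panel$ind$id)
    expect_true(identical(off$pat[i, ], panel$pat[s, ]) ||
                  identical(off$pat[i, ], panel$mat[s, ]))
    d <- match(off$ind$dam[i], panel$ind$id)
    expect_true(identical(off$mat[i, ], panel$pat[d, ]) ||
                  identical(off$mat[i, ], panel$mat[d, ]))
  }
})

test_that("equal family sizes give every sire the same offspring count", {
  map <- make_test_map(10)
  set.seed(5)
  panel <- random_test_panel(120, runif(10, 0.3, 0.7), map)
  gen <- simulate_generation(panel, 750, n_sires = 50, n_dams = 70, seed = 6)
  expect_identical(unname(sort(unique(table(gen$panel$ind$sire)))), 15L)
  expect_identical(length(unique(gen$panel$ind$sire)), 50L)
  expect_error(
    simulate_generation(panel, 751, n_sires = 50, n_dams = 70, seed = 6),
    "divisible"
  )
})

test_that("every offspring allele is a copy of a transmitting-parent allele", {
  map <- make_test_map(200, spacing_bp = 5e5, n_chrom = 2)
  set.seed(7)
  panel <- random_test_panel(20, runif(200, 0.1, 0.9), map)
  gen <- simulate_generation(panel, 30, n_sires = 5, n_dams = 15, seed = 8)
  off <- gen$panel
  for (i in seq_len(n_ind(off))) {
    s <- match(off$ind$sire[i], panel$ind$id)
    d <- match(off$ind$dam[i], panel$ind$id)
    expect_true(all(off$pat[i, ] == panel$pat[s, ] |
                      off$pat[i, ] == panel$mat[s, ]))
    expect_true(all(off$mat[i, ] == panel$pat[d, ] |
                      off$mat[i, ] == panel$mat[d, ]))
  }
})

test_that("origin bookkeeping is closed under meiosis", {
  # give the parents haplotype-identifying origins: paternal = group 1,
  # maternal = group 2; the offspring origin then reveals which parental
  # haplotype each allele was copied from, checked exhaustively
  map <- make_test_map(150, spacing_bp = 1e6)
  set.seed(10)
  panel <- random_test_panel(12, runif(150, 0.2, 0.8), map)
  om <- origin_map(matrix(1L, 12, 150), matrix(2L, 12, 150), c("P", "M"))
  gen <- simulate_generation(panel, 16, n_sires = 4, n_dams = 8,
                             origins = om, seed = 11)
  off <- gen$panel
  for (i in seq_len(n_ind(off))) {
    s <- match(off$ind$sire[i], panel$ind$id)
    src <- gen$origins$pat[i, ]  # 1 = sire's paternal, 2 = sire's maternal
    expect_identical(off$pat[i, ],
                     ifelse(src == 1L, panel$pat[s, ], panel$mat[s, ]))
    d <- match(off$ind$dam[i], panel$ind$id)
    src <- gen$origins$mat[i, ]
    expect_identical(off$mat[i, ],
                     ifelse(src == 1L, panel$pat[d, ], panel$mat[d, ]))
  }
})

test_that("random mating preserves expected heterozygosity", {
  map <- make_test_map(1200, spacing_bp = 2e5, n_chrom = 3)
  set.seed(12)
  panel <- random_test_panel(200, runif(1200, 0.1, 0.9), map)
  gen <- simulate_generation(panel, 200, n_sires = 100, n_dams = 100,
                             seed = 13)
  het <- function(p) colMeans(p$pat != p$mat)
  d <- het(gen$panel) - het(panel)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se + 1e-12)
})

test_that("configuration errors are rejected", {
  expect_error(founder_sim_config(admixture_fraction = 1.2), "admixture")
  expect_error(founder_sim_config(n_markers = 2, n_chromosomes = 3),
               "n_markers")
  expect_error(founder_sim_config(fst = 0), "fst")
})
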