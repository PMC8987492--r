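#' Simulate a complete two-breed prediction scenario
#'
#' Runs the full generating pipeline behind the model-comparison
#' experiments: founder breeds with historic admixture, one further
#' generation of breeding per breed with equal sire families, QTL
#' selection among markers segregating in both breeds, correlated
#' per-origin QTL effects scaled to the target additive variance in each
#' pure breed, true breeding values, phenotypes, and (optionally)
#' segment-based origin assignment of the admixed panel against purebred
#' references.
#'
#' @param n_an,n_hf Sizes of the simulated target-breed (AN) and
#'   introgressed-breed (HF) offspring generations.
#' @param n_sires_an Number of AN sires; default `n_an / 15` (each sire
#'   then has 15 offspring, as in the 750-individual design with 50
#'   sires). `n_an` must be divisible by `n_sires_an`.
#' @param n_markers,n_chromosomes,chromosome_length_bp Genome settings,
#'   passed to [founder_sim_config()].
#' @param n_qtl Number of QTLs drawn from the markers segregating in both
#'   breeds.
#' @param rho Across-origin QTL-effect correlation (default 0.95).
#' @param target_va,target_vp Additive and phenotypic variance targets
#'   (defaults 0.3 and 1).
#' @param qtl_in_marker_set If `FALSE` (default) the QTLs are excluded
#'   from the prediction markers, as in the chip-based design; `TRUE`
#'   keeps them in, which makes the marker effects coincide with the QTL
#'   effects (useful for parameter-recovery experiments).
#' @param assign If `TRUE` (default) run [assign_origins()] on the AN
#'   offspring against the HF panel and the native AN reference panel.
#' @param rule [segment_rule()] used for assignment.
#' @param seed Integer seed; all stages derive their randomness from it.
#' @param ... Further arguments to [founder_sim_config()].
#' @return A list of class `boa_scenario`: panels (`an`, `hf`,
#'   `an_ref`), origin maps (`origins_true`, `origins_assigned`), trait
#'   architecture (`arch`), phenotypes (`phen_an`, `phen_hf`), and the
#'   configuration pieces.
#' @export
simulate_scenario <- function(n_an = 300L, n_hf = 1200L, n_sires_an = NULL,
                              n_markers = 3000L, n_chromosomes = 3L,
                              chromosome_length_bp = 5e7, n_qtl = 150L,
                              rho = 0.95, target_va = 0.3, target_vp = 1,
                              qtl_in_marker_set = FALSE,
                              assign = TRUE, rule = segment_rule(),
                              seed = 1L, ...) {
  if (is.null(n_sires_an)) {
    if (n_an %% 15L != 0L) {
      stop("n_an must be divisible by 15 for the default sire design; ",
           "set n_sires_an explicitly otherwise")
    }
    n_sires_an <- n_an %/% 15L
  }
  cfg <- founder_sim_config(n_markers = n_markers,
                            n_chromosomes = n_chromosomes,
                            chromosome_length_bp = chromosome_length_bp,
                            breed_sizes = c(AN = n_an, HF = n_hf),
                            seed = seed, ...)
  founders <- simulate_founder_breeds(cfg)

  gen_an <- simulate_generation(founders$AN, n_an, n_sires_an,
                                n_dams = n_ind(founders$AN) - n_sires_an,
                                origins = founders$true_origins,
                                seed = seed + 101L)
  hf_origins <- constant_origin_map(founders$HF, "HF", c("AN", "HF"))
  # HF family structure is irrelevant to the CV design; pick the largest
  # sire count <= n_hf/60 that divides n_hf evenly
  n_sires_hf <- max(Filter(function(s) n_hf %% s == 0L,
                           seq_len(max(2L, n_hf %/% 60L))))
  gen_hf <- simulate_generation(founders$HF, n_hf, n_sires_hf,
                                n_dams = n_ind(founders$HF) - n_sires_hf,
                                origins = hf_origins,
                                seed = seed + 102L)

  an <- gen_an$panel; hf <- gen_hf$panel
  assigned <- NULL
  if (assign) {
    assigned <- assign_origins(an, list(AN = founders$AN_ref, HF = hf),
                               rule = rule)
  }
  eligible <- segregating_markers(list(AN = an, HF = hf))
  arch <- select_qtls(an$map, eligible, n_qtl, seed = seed + 103L)
  arch <- sample_qtl_effects(arch, sigma_a2 = 1, rho = rho,
                             group_labels = c("AN", "HF"),
                             seed = seed + 104L)
  qtl_freq <- cbind(AN = allele_freq(an)[arch$qtl_idx],
                    HF = allele_freq(hf)[arch$qtl_idx])
  arch <- scale_effects_to_va(arch, qtl_freq, target_va)

  # TBVs of the admixed breed use the segment-assigned origins when
  # available (the chip-based design defines origin-specific QTL dosages
  # through the same segment assignment as the markers); the generating
  # truth stays available for validating the assignment itself
  tbv_an <- compute_tbv(an, if (assign) assigned else gen_an$origins, arch)
  tbv_hf <- compute_tbv(hf, gen_hf$origins, arch)
  phen_an <- simulate_phenotypes(tbv_an, target_va, target_vp,
                                 seed = seed + 105L)
  phen_hf <- simulate_phenotypes(tbv_hf, target_va, target_vp,
                                 seed = seed + 106L)

  structure(
    list(an = an, hf = hf, an_ref = founders$AN_ref,
         origins_true = gen_an$origins, origins_assigned = assigned,
         origins_hf = gen_hf$origins, arch = arch,
         phen_an = phen_an, phen_hf = phen_hf,
         config = cfg, rule = rule, target_va = target_va,
         target_vp = target_vp, qtl_in_marker_set = qtl_in_marker_set,
         seed = seed),
    class = "boa_scenario"
  )
}

#' Take a nested target-breed subset of a scenario
#'
#' Mimics the breed-size design in which the smaller target-breed panels
#' are nested subsets of the largest one: the first `n_an` AN individuals
#' (whole sire families, since families are contiguous and equal-sized)
#' are kept, along with their origin maps and phenotypes; the HF side and
#' the trait architecture are unchanged.
#'
#' @param scenario A `boa_scenario`.
#' @param n_an Subset size; must keep whole sire families.
#' @return A `boa_scenario`.
#' @export
subset_scenario <- function(scenario, n_an) {
  stopifnot(inherits(scenario, "boa_scenario"))
  fam <- table(scenario$an$ind$sire)
  if (length(unique(fam)) != 1L || n_an %% fam[1L] != 0L) {
    stop("subset must consist of whole, equal-sized sire families")
  }
  if (n_an > n_ind(scenario$an)) stop("subset larger than the panel")
  i <- seq_len(n_an)
  scenario$an <- subset_individuals(scenario$an, i)
  scenario$origins_true <- subset_origin_map(scenario$origins_true, i)
  if (!is.null(scenario$origins_assigned)) {
    scenario$origins_assigned <- subset_origin_map(scenario$origins_assigned, i)
  }
  scenario$phen_an <- scenario$phen_an[i, , drop = FALSE]
  scenario
}

#' Sire-family cross-validation plan
#'
#' Sires are shuffled and dealt round-robin into `n_folds` folds; every
#' individual inherits its sire's fold, so individuals from different
#' folds never have sires in common. With 50 equal-size sire families and
#' 5 folds, each fold holds the offspring of exactly 10 sires.
#'
#' @param panel Target-breed [haplotype_panel] with sires recorded.
#' @param n_folds Number of folds (default 5, must be >= 2).
#' @param seed Optional seed for the sire shuffle.
#' @return A list of class `cv_plan`: `n_folds`, `fold_of` (named integer
#'   per individual), `sire_fold` (named integer per sire).
#' @export
make_cv_plan <- function(panel, n_folds = 5L, seed = NULL) {
  if (n_folds < 2L) stop("need at least 2 folds for a held-out set")
  sires <- panel$ind$sire
  if (anyNA(sires)) stop("every individual needs a known sire")
  us <- unique(sires)
  if (length(us) < n_folds) stop("fewer sires than folds")
  shuffle <- function() sample(us)
  us <- if (is.null(seed)) shuffle() else withr::with_seed(seed, shuffle())
  sire_fold <- stats::setNames(rep_len(seq_len(n_folds), length(us)), us)
  fold_of <- stats::setNames(sire_fold[sires], panel$ind$id)
  structure(list(n_folds = as.integer(n_folds), fold_of = fold_of,
                 sire_fold = sire_fold),
            class = "cv_plan")
}

# shared precomputation for CV and grid search: marker mask, combined
# design, Gram blocks T_kl = Z_k Z_l', variance building blocks
.prepare_cv <- function(scenario, maf_min = 0.03,
                        use_true_origins = FALSE,
                        target_va = scenario$target_va,
                        target_vp = scenario$target_vp) {
  an <- scenario$an; hf <- scenario$hf
  origins_an <- if (use_true_origins) scenario$origins_true else
    scenario$origins_assigned
  if (is.null(origins_an)) {
    stop("scenario has no assigned origins; rerun with assign = TRUE ",
         "or use_true_origins = TRUE")
  }
  drop_qtl <- if (isTRUE(scenario$qtl_in_marker_set)) integer(0) else
    scenario$arch$qtl_idx
  mask <- filter_markers(list(AN = an, HF = hf), drop_qtl, maf_min)
  comb <- combine_panels(an, hf)
  oc <- combine_origin_maps(origins_an, scenario$origins_hf)
  phen <- rbind(scenario$phen_an, scenario$phen_hf)
  ds <- build_design(comb, oc, y = phen, marker_mask = mask)
  K <- length(ds$Z)
  Tkl <- vector("list", K * K)
  dim(Tkl) <- c(K, K)
  for (k in seq_len(K)) {
    for (l in k:K) {
      Tkl[[k, l]] <- tcrossprod(ds$Z[[k]], ds$Z[[l]])
      if (l != k) Tkl[[l, k]] <- t(Tkl[[k, l]])
    }
  }
  Ttot <- Reduce(`+`, Tkl)
  freqs <- cbind(AN = allele_freq(an)[mask], HF = allele_freq(hf)[mask])
  j <- match(comb$ind$id, phen$individual_id)
  list(design = ds, mask = mask, Tkl = Tkl, Ttot = Ttot, K = K,
       y = ds$y, tbv = phen$tbv[j],
       an_idx = seq_len(n_ind(an)),
       hf_idx = n_ind(an) + seq_len(n_ind(hf)),
       freqs = freqs, target_va = target_va, target_vp = target_vp,
       ids = comb$ind$id)
}

# fit one fold on precomputed Gram blocks and return validation GEBVs;
# V_rr = sigma_e2 I + sum_kl sigma_kl T_kl[ref, ref],
# GEBV_val = sum_kl sigma_kl T_kl[val, ref] V_rr^-1 (y_ref - X_ref beta)
.gram_gebv <- function(prep, ref, val, sigma, sigma_e2, X) {
  K <- nrow(sigma)
  n_r <- length(ref)
  V <- diag(sigma_e2, n_r)
  G_vr <- matrix(0, length(val), n_r)
  for (k in seq_len(K)) {
    for (l in seq_len(K)) {
      if (sigma[k, l] != 0) {
        V <- V + sigma[k, l] * prep$Tkl[[k, l]][ref, ref]
        G_vr <- G_vr + sigma[k, l] * prep$Tkl[[k, l]][val, ref, drop = FALSE]
      }
    }
  }
  ch <- chol(V)
  yr <- prep$y[ref]
  Xr <- X[ref, , drop = FALSE]
  ViX <- backsolve(ch, backsolve(ch, Xr, transpose = TRUE))
  A <- crossprod(Xr, ViX)
  beta <- if (qr(A)$rank < ncol(Xr)) {
    MASS::ginv(A) %*% crossprod(Xr, backsolve(ch, backsolve(ch, yr, transpose = TRUE)))
  } else {
    solve(A, crossprod(Xr, backsolve(ch, backsolve(ch, yr, transpose = TRUE))))
  }
  w <- backsolve(ch, backsolve(ch, yr - Xr %*% beta, transpose = TRUE))
  as.numeric(G_vr %*% w)
}

.gram_gebv_blup <- function(prep, ref, val, sigma_a2, sigma_e2) {
  n_r <- length(ref)
  V <- sigma_a2 * prep$Ttot[ref, ref] + diag(sigma_e2, n_r)
  ch <- chol(V)
  yr <- prep$y[ref]
  one <- matrix(1, n_r, 1)
  Vi1 <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
  Viy <- backsolve(ch, backsolve(ch, yr, transpose = TRUE))
  beta <- sum(Vi1 * yr) / sum(Vi1 * one)
  w <- backsolve(ch, backsolve(ch, yr - beta, transpose = TRUE))
  as.numeric(sigma_a2 * prep$Ttot[val, ref, drop = FALSE] %*% w)
}

.fold_accuracy <- function(gebv, tbv) {
  if (stats::sd(gebv) == 0 || stats::sd(tbv) == 0) {
    warning("constant GEBV or TBV in a validation fold; accuracy undefined")
    return(NA_real_)
  }
  stats::cor(gebv, tbv)
}

.cv_engine <- function(prep, plan, models, r) {
  vs <- make_variance_spec(prep$target_va, prep$freqs, r, prep$target_vp)
  sig_multi <- snp_blup_variance(prep$target_va, .pooled_freq(prep))
  sig_within <- snp_blup_variance(prep$target_va, prep$freqs[, "AN"])
  an_fold <- plan$fold_of[prep$ids[prep$an_idx]]
  out <- list()
  for (f in seq_len(plan$n_folds)) {
    val <- prep$an_idx[an_fold == f]
    an_ref <- prep$an_idx[an_fold != f]
    multi_ref <- c(an_ref, prep$hf_idx)
    tbv_val <- prep$tbv[val]
    for (mdl in models) {
      gebv <- switch(
        mdl,
        boa = .gram_gebv(prep, multi_ref, val, vs$sigma, vs$sigma_e2,
                         prep$design$X),
        multi = .gram_gebv_blup(prep, multi_ref, val, sig_multi,
                                vs$sigma_e2),
        within = .gram_gebv_blup(prep, an_ref, val, sig_within,
                                 vs$sigma_e2),
        stop("unknown model: ", mdl)
      )
      out[[length(out) + 1L]] <- data.frame(
        fold = f, model = mdl, r = if (mdl == "boa") r else NA_real_,
        n_val = length(val),
        n_ref = if (mdl == "within") length(an_ref) else length(multi_ref),
        accuracy = .fold_accuracy(gebv, tbv_val),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

.pooled_freq <- function(prep) {
  Reduce(`+`, lapply(prep$design$Z, colSums)) / (2 * length(prep$y))
}

#' Run sire-family cross-validation for the model comparison
#'
#' For each fold, the within-breed baseline is fitted on the target-breed
#' (AN) reference classes only, while the multi-breed baseline and the
#' origin-split (BOA) model are fitted on the AN reference joined with
#' all HF individuals; GEBVs are computed for the held-out AN fold and
#' the accuracy is their Pearson correlation with the true breeding
#' values. Validation phenotypes never enter any fit.
#'
#' @param scenario A `boa_scenario` from [simulate_scenario()].
#' @param plan A [make_cv_plan()] plan for `scenario$an`; built with
#'   `seed` when `NULL`.
#' @param models Subset of `c("boa", "multi", "within")`.
#' @param r Across-origin marker-effect correlation of the BOA model
#'   (default 0.75).
#' @param maf_min Within-breed MAF threshold for prediction markers.
#' @param use_true_origins Use the simulator's generating origins instead
#'   of the assigned ones (default `FALSE`).
#' @param seed Seed for the CV plan when `plan` is `NULL`.
#' @return `data.frame` with one row per fold and model: `fold`, `model`,
#'   `r`, `n_val`, `n_ref`, `accuracy`.
#' @export
run_cv <- function(scenario, plan = NULL,
                   models = c("boa", "multi", "within"), r = 0.75,
                   maf_min = 0.03, use_true_origins = FALSE, seed = NULL) {
  stopifnot(inherits(scenario, "boa_scenario"))
  if (is.null(plan)) plan <- make_cv_plan(scenario$an, seed = seed)
  prep <- .prepare_cv(scenario, maf_min, use_true_origins)
  .cv_engine(prep, plan, models, r)
}

#' Grid search for the across-origin marker-effect correlation
#'
#' Runs the 5-fold (or `plan`-fold) cross-validation of the BOA model for
#' every candidate correlation and returns the value maximizing the mean
#' accuracy across folds. Ties are resolved toward the larger correlation
#' (pooling information is the safer default when accuracies tie).
#'
#' @param scenario A `boa_scenario`.
#' @param plan A [make_cv_plan()] plan (built from `seed` when `NULL`).
#' @param grid Candidate correlations in (-1, 1]; default
#'   `c(seq(0.05, 0.95, by = 0.1), 1 - 1e-6)`.
#' @param maf_min,use_true_origins,seed As in [run_cv()].
#' @return List with `r` (selected value) and `profile` (`data.frame`
#'   of candidate `r` and mean CV accuracy).
#' @export
grid_search_correlation <- function(scenario, plan = NULL,
                                    grid = c(seq(0.05, 0.95, by = 0.1),
                                             1 - 1e-6),
                                    maf_min = 0.03,
                                    use_true_origins = FALSE,
                                    seed = NULL) {
  if (length(grid) == 0L) stop("empty correlation grid")
  if (any(grid <= -1 | grid > 1)) stop("grid values must be in (-1, 1]")
  if (is.null(plan)) plan <- make_cv_plan(scenario$an, seed = seed)
  prep <- .prepare_cv(scenario, maf_min, use_true_origins)
  prof <- vapply(grid, function(r) {
    res <- .cv_engine(prep, plan, "boa", r)
    mean(res$accuracy)
  }, numeric(1))
  best <- max(prof)
  sel <- max(grid[prof >= best - 1e-12])  # ties -> larger r
  list(r = sel, profile = data.frame(r = grid, mean_accuracy = prof))
}

#' Summarize cross-validation accuracies
#'
#' Accuracies are first averaged over folds within a replicate; the
#' headline mean, sd and standard error (`sd / sqrt(n_replicates)`) are
#' taken across those replicate means. The sd across all fold-level
#' values is reported alongside (`sd_folds`).
#'
#' @param results `data.frame` with columns `model`, `accuracy` and
#'   optionally `replicate` (assumed 1 when absent) and `scenario`.
#' @return `data.frame` with one row per (scenario,) model: `mean`, `sd`,
#'   `se`, `sd_folds`, `n_replicates`.
#' @export
summarize_accuracies <- function(results) {
  if (nrow(results) == 0L) stop("no accuracies to summarize")
  if (is.null(results$replicate)) results$replicate <- 1L
  if (is.null(results$scenario)) results$scenario <- "scenario"
  groups <- unique(results[, c("scenario", "model")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- results[results$scenario == groups$scenario[i] &
                     results$model == groups$model[i], ]
    rep_means <- tapply(sub$accuracy, sub$replicate, mean, na.rm = TRUE)
    n_rep <- length(rep_means)
    s <- if (n_rep > 1L) stats::sd(rep_means) else 0
    data.frame(scenario = groups$scenario[i], model = groups$model[i],
               mean = mean(rep_means), sd = s, se = s / sqrt(n_rep),
               sd_folds = stats::sd(sub$accuracy), n_replicates = n_rep,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Reference and validation sizes of the breed-size scenarios
#'
#' Exercises the cross-validation machinery on an equal-family sire
#' design and reports, per scenario, the validation-set size, the
#' within-breed reference size, the multi-breed reference size (AN
#' reference joined with all HF individuals), and the percentage of AN
#' individuals in the multi-breed reference.
#'
#' @param n_an Vector of target-breed panel sizes.
#' @param n_hf Introgressed-breed panel size (default 6000).
#' @param n_folds Number of CV folds (default 5).
#' @param n_sires Number of sires (default 50).
#' @param seed Seed for panel simulation and fold assignment.
#' @return `data.frame` with one row per scenario: `n_an`,
#'   `validation`, `within_ref`, `multi_ref`, `pct_an_multi`,
#'   `sires_per_fold`.
#' @export
cv_scenario_sizes <- function(n_an, n_hf = 6000L, n_folds = 5L,
                              n_sires = 50L, seed = 1L) {
  out <- lapply(n_an, function(n) {
    cfg <- founder_sim_config(n_markers = 12L, n_chromosomes = 1L,
                              breed_sizes = c(AN = max(2L * n_sires, 120L),
                                              HF = 2L),
                              admixture_fraction = 0, seed = seed)
    founders <- simulate_founder_breeds(cfg)
    gen <- simulate_generation(founders$AN, n, n_sires,
                               n_dams = n_ind(founders$AN) - n_sires,
                               seed = seed + 1L)
    plan <- make_cv_plan(gen$panel, n_folds, seed = seed + 2L)
    sizes <- table(plan$fold_of)
    spf <- table(plan$sire_fold)
    if (length(unique(sizes)) != 1L || length(unique(spf)) != 1L) {
      stop("folds are not balanced under the equal-family design")
    }
    val <- as.integer(sizes[1L])
    within_ref <- as.integer(n - val)
    multi_ref <- as.integer(within_ref + n_hf)
    data.frame(n_an = as.integer(n), validation = val,
               within_ref = within_ref, multi_ref = multi_ref,
               pct_an_multi = round(100 * within_ref / multi_ref, 2),
               sires_per_fold = as.integer(spf[1L]))
  })
  do.call(rbind, out)
}
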