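#' Markers segregating in every panel
#'
#' @param panels List of [haplotype_panel]s (one per breed).
#' @return Logical mask over markers: allele frequency strictly in (0,1)
#'   in every panel.
#' @export
segregating_markers <- function(panels) {
  masks <- lapply(panels, function(p) {
    f <- allele_freq(p)
    f > 0 & f < 1
  })
  Reduce(`&`, masks)
}

#' Select QTL markers
#'
#' Samples `n_qtl` distinct markers uniformly without replacement from the
#' markers segregating in both breeds. Selected markers are flagged for
#' exclusion from the prediction marker set.
#'
#' @param map A [marker_map].
#' @param eligible Logical mask of eligible markers (typically
#'   [segregating_markers()] of the pure breeds).
#' @param n_qtl Number of QTLs to draw.
#' @param seed Optional seed.
#' @return A `trait_architecture` skeleton: list with `qtl_idx` (sorted
#'   marker indices), `qtl_id`, and empty effect slots.
#' @export
select_qtls <- function(map, eligible, n_qtl, seed = NULL) {
  cand <- which(eligible)
  if (n_qtl > length(cand)) {
    stop(sprintf("requested %d QTLs but only %d eligible markers",
                 n_qtl, length(cand)))
  }
  draw <- function() sort(cand[sample.int(length(cand), n_qtl)])
  qtl <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(
    list(qtl_idx = qtl, qtl_id = map$marker_id[qtl], effects = NULL,
         effect_correlation = NA_real_, sigma_a2 = NA_real_,
         group_labels = NULL),
    class = "trait_architecture"
  )
}

#' Sample correlated per-origin QTL effects
#'
#' Per-QTL additive effects for the `K` origin groups are drawn i.i.d.
#' from a multivariate normal with zero mean, common variance `sigma_a2`
#' and common pairwise correlation `rho` (for two breeds this is the
#' bivariate normal with correlation `rho`).
#'
#' @param arch A `trait_architecture` from [select_qtls()].
#' @param sigma_a2 Per-origin effect variance (> 0) before scaling.
#' @param rho Across-origin effect correlation in `[-1, 1]`.
#' @param group_labels Origin group names (default `c("AN","HF")`,
#'   target breed first).
#' @param seed Optional seed.
#' @return The architecture with `effects` filled in (`n_qtl x K` matrix).
#' @export
sample_qtl_effects <- function(arch, sigma_a2 = 1, rho = 0.95,
                               group_labels = c("AN", "HF"), seed = NULL) {
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  if (sigma_a2 <= 0) stop("sigma_a2 must be > 0")
  K <- length(group_labels)
  sig <- sigma_a2 * ((1 - rho) * diag(K) + rho)
  q <- length(arch$qtl_idx)
  draw <- function() MASS::mvrnorm(q, mu = rep(0, K), Sigma = sig)
  eff <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  eff <- matrix(eff, nrow = q, ncol = K,
                dimnames = list(arch$qtl_id, group_labels))
  arch$effects <- eff
  arch$effect_correlation <- rho
  arch$sigma_a2 <- sigma_a2
  arch$group_labels <- group_labels
  arch
}

#' Scale QTL effects to a target additive variance per breed
#'
#' For each breed `k` the effect column is multiplied by one positive
#' scalar so that the additive variance by the standard
#' linkage-equilibrium formula, `V_A = sum_q 2 p_qk (1 - p_qk) a_qk^2`,
#' equals `target_va` exactly in that breed. Per-breed positive rescaling
#' leaves the effect correlation unchanged.
#'
#' @param arch A `trait_architecture` with sampled effects.
#' @param qtl_freq `n_qtl x K` matrix of QTL allele frequencies per breed
#'   (columns ordered as `arch$group_labels`).
#' @param target_va Target additive variance (default 0.3).
#' @return The architecture with scaled `effects`; the realized `V_A` per
#'   breed is stored in `va_by_group`.
#' @export
scale_effects_to_va <- function(arch, qtl_freq, target_va = 0.3) {
  if (is.null(arch$effects)) stop("sample effects before scaling")
  qtl_freq <- as.matrix(qtl_freq)
  if (!identical(dim(qtl_freq), dim(arch$effects))) {
    stop("qtl_freq must match the effects matrix")
  }
  for (k in seq_len(ncol(arch$effects))) {
    p <- qtl_freq[, k]
    va <- sum(2 * p * (1 - p) * arch$effects[, k]^2)
    if (va <= 0) {
      stop("additive variance is zero in group ", arch$group_labels[k],
           " (all QTLs monomorphic or all effects zero)")
    }
    arch$effects[, k] <- arch$effects[, k] * sqrt(target_va / va)
  }
  arch$va_by_group <- vapply(seq_len(ncol(arch$effects)), function(k) {
    p <- qtl_freq[, k]
    sum(2 * p * (1 - p) * arch$effects[, k]^2)
  }, numeric(1))
  names(arch$va_by_group) <- arch$group_labels
  arch$target_va <- target_va
  arch
}

#' Additive variance by the standard formula
#'
#' `V_A = sum_q 2 p_q (1 - p_q) a_q^2`, assuming linkage equilibrium among
#' QTLs.
#'
#' @param p Allele frequencies at the QTLs.
#' @param a Additive effects at the QTLs.
#' @return Scalar additive variance.
#' @export
additive_variance <- function(p, a) sum(2 * p * (1 - p) * a^2)

#' True breeding values under origin-specific QTL effects
#'
#' `TBV_i = sum_q sum_k Z_Aiqk a_qk`, where `Z_Aiqk` in 0/1/2 counts the
#' alternative-allele copies at QTL `q` whose haplotype origin is group
#' `k`. For a purebred individual this collapses to the plain dosage sum
#' with that breed's effect column.
#'
#' @param panel A [haplotype_panel].
#' @param origins An [origin_map] for the panel whose `group_labels` match
#'   `arch$group_labels`.
#' @param arch A scaled `trait_architecture`.
#' @return Named numeric vector of TBVs.
#' @export
compute_tbv <- function(panel, origins, arch) {
  if (!identical(origins$group_labels, arch$group_labels)) {
    stop("origin groups do not match the trait architecture")
  }
  if (!identical(dim(origins$pat), dim(panel$pat))) {
    stop("origin map does not cover the panel")
  }
  q <- arch$qtl_idx
  tbv <- numeric(n_ind(panel))
  for (k in seq_along(arch$group_labels)) {
    zk <- panel$pat[, q, drop = FALSE] *
      (origins$pat[, q, drop = FALSE] == k) +
      panel$mat[, q, drop = FALSE] * (origins$mat[, q, drop = FALSE] == k)
    tbv <- tbv + as.vector(zk %*% arch$effects[, k])
  }
  names(tbv) <- panel$ind$id
  tbv
}

#' Simulate phenotypes from true breeding values
#'
#' `y_i = TBV_i + e_i` with `e_i` i.i.d. normal and error variance
#' `target_vp - va`, so the trait has the configured phenotypic variance
#' (defaults: `V_A = 0.3`, `V_P = 1`, hence `sigma_e^2 = 0.7`).
#'
#' @param tbv Named vector of true breeding values.
#' @param va Additive variance used in effect scaling.
#' @param target_vp Target phenotypic variance (> `va`).
#' @param seed Optional seed.
#' @return `data.frame` with `individual_id`, `y`, `tbv`.
#' @export
simulate_phenotypes <- function(tbv, va = 0.3, target_vp = 1, seed = NULL) {
  if (target_vp <= va) {
    stop("target_vp must exceed the additive variance (error variance > 0)")
  }
  draw <- function() tbv + stats::rnorm(length(tbv), 0, sqrt(target_vp - va))
  y <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  data.frame(individual_id = names(tbv), y = as.numeric(y),
             tbv = as.numeric(tbv), stringsAsFactors = FALSE)
}
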