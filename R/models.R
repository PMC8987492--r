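#' Filter prediction markers
#'
#' Retains the markers used for genomic prediction: non-QTL markers that
#' segregate in every breed and have a minor allele frequency of at least
#' `maf_min` in every breed.
#'
#' @param panels Named list of per-breed [haplotype_panel]s.
#' @param qtl_idx Marker indices excluded as QTLs (may be empty).
#' @param maf_min Minimum within-breed MAF (default 0.03).
#' @return Logical mask over markers.
#' @export
filter_markers <- function(panels, qtl_idx = integer(0), maf_min = 0.03) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  keep <- rep(TRUE, n_markers(panels[[1L]]))
  for (p in panels) {
    f <- allele_freq(p)
    keep <- keep & f > 0 & f < 1 & pmin(f, 1 - f) >= maf_min
  }
  keep[qtl_idx] <- FALSE
  if (!any(keep)) stop("no markers left after filtering")
  keep
}

#' Build the design matrices of the origin-split model
#'
#' Constructs, for the retained markers, the origin-split allele-count
#' matrices `Z_Ak` (entry `Z_Aimk = h_im_pat * d_kim_pat + h_im_mat *
#' d_kim_mat`, the number of alternative-allele copies of individual `i`
#' at marker `m` that originate from group `k`) and the fixed-effect
#' design `X` of genetic contributions `c_ik` (origin fractions over the
#' retained markers; rows sum to 1).
#'
#' @param panel A [haplotype_panel].
#' @param origins An [origin_map] for the panel.
#' @param y Optional phenotype vector aligned with the panel (or a
#'   `data.frame` from [simulate_phenotypes()], matched by id).
#' @param marker_mask Logical/integer marker subset (default: all).
#' @return A list of class `design_set` with `y`, `X` (`N x K`), `Z`
#'   (list of `K` `N x M'` matrices), `ids`, `marker_ids`,
#'   `group_labels`.
#' @export
build_design <- function(panel, origins, y = NULL, marker_mask = NULL) {
  if (!identical(dim(origins$pat), dim(panel$pat))) {
    stop("origin map does not match the panel")
  }
  if (is.null(marker_mask)) marker_mask <- rep(TRUE, n_markers(panel))
  cols <- which(if (is.logical(marker_mask)) marker_mask else
    seq_len(n_markers(panel)) %in% marker_mask)
  K <- length(origins$group_labels)
  Z <- lapply(seq_len(K), function(k) {
    panel$pat[, cols, drop = FALSE] *
      (origins$pat[, cols, drop = FALSE] == k) +
      panel$mat[, cols, drop = FALSE] *
      (origins$mat[, cols, drop = FALSE] == k)
  })
  names(Z) <- origins$group_labels
  X <- origin_fractions(origins, cols)
  if (!is.null(y)) {
    if (is.data.frame(y)) {
      j <- match(panel$ind$id, y$individual_id)
      if (anyNA(j)) stop("phenotypes missing for some panel individuals")
      y <- y$y[j]
    }
    if (length(y) != n_ind(panel)) stop("phenotype/individual mismatch")
  }
  structure(list(y = y, X = X, Z = Z, ids = panel$ind$id,
                 marker_ids = panel$map$marker_id[cols],
                 group_labels = origins$group_labels),
            class = "design_set")
}

#' Marker-effect covariance specification
#'
#' Per-origin marker-effect variances follow the allele-substitution
#' heuristic `sigma_Ak^2 = target_va / sum_m 2 p_mk (1 - p_mk)` over the
#' retained markers, with `p_mk` the allele frequency in breed `k`;
#' off-diagonals are `r * sqrt(sigma_Ak^2 sigma_Al^2)`. The residual
#' variance is `target_vp - target_va` (defaults 1 - 0.3 = 0.7).
#'
#' @param target_va Additive variance captured by the markers.
#' @param freqs `M' x K` matrix of retained-marker allele frequencies per
#'   breed (columns ordered and named by group).
#' @param r Across-origin marker-effect correlation in (-1, 1].
#' @param target_vp Phenotypic variance.
#' @return A list of class `variance_spec` with `sigma` (`K x K`) and
#'   `sigma_e2`.
#' @export
make_variance_spec <- function(target_va = 0.3, freqs, r = 0.75,
                               target_vp = 1) {
  if (target_va <= 0) stop("target_va must be > 0")
  if (r <= -1 || r > 1) stop("r must be in (-1, 1]")
  if (target_vp <= target_va) stop("target_vp must exceed target_va")
  freqs <- as.matrix(freqs)
  het <- colSums(2 * freqs * (1 - freqs))
  if (any(het <= 0)) stop("zero heterozygosity sum in some group")
  s2 <- target_va / het
  sigma <- (r + (1 - r) * diag(length(s2))) * tcrossprod(sqrt(s2))
  dimnames(sigma) <- list(colnames(freqs), colnames(freqs))
  variance_spec(sigma, target_vp - target_va)
}

#' Construct a variance specification directly
#'
#' @param sigma Symmetric positive (semi)definite `K x K` marker-effect
#'   covariance matrix.
#' @param sigma_e2 Residual variance (> 0).
#' @return A list of class `variance_spec`.
#' @export
variance_spec <- function(sigma, sigma_e2) {
  sigma <- as.matrix(sigma)
  if (!isSymmetric(unname(sigma), tol = 1e-10)) stop("sigma must be symmetric")
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-10 * max(abs(sigma))) {
    stop("sigma must be positive semidefinite")
  }
  if (sigma_e2 <= 0) stop("sigma_e2 must be > 0")
  structure(list(sigma = sigma, sigma_e2 = sigma_e2),
            class = "variance_spec")
}

#' SNP-BLUP marker-effect variance from pooled frequencies
#'
#' `sigma_a^2 = target_va / sum_m 2 p_m (1 - p_m)` with `p_m` computed on
#' the pooled reference population.
#'
#' @param target_va Additive variance captured by the markers.
#' @param freqs Vector of retained-marker allele frequencies in the pooled
#'   reference.
#' @return Scalar marker-effect variance.
#' @export
snp_blup_variance <- function(target_va = 0.3, freqs) {
  het <- sum(2 * freqs * (1 - freqs))
  if (het <= 0) stop("zero heterozygosity sum")
  target_va / het
}
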