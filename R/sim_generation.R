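#' Simulate one generation of breeding with recombination
#'
#' Offspring are produced by meiosis from designated sires and dams:
#' crossover counts are Poisson per chromosome from the genetic map
#' (Haldane model, no interference), crossover placement is uniform in
#' genetic distance, and there is no mutation. With
#' `equal_family_sizes = TRUE` every sire has exactly
#' `n_offspring / n_sires` offspring, which the sire-family
#' cross-validation design relies on. Dams are drawn at random (with
#' replacement) for every offspring. The pedigree is recorded in the
#' returned panel.
#'
#' @param panel Parent [haplotype_panel].
#' @param n_offspring Number of offspring to produce.
#' @param n_sires,n_dams Numbers of sires and dams drawn (disjointly) from
#'   the panel.
#' @param equal_family_sizes If `TRUE` (default) each sire has the same
#'   number of offspring; requires `n_offspring %% n_sires == 0`.
#' @param origins Optional [origin_map] of the parents; when supplied, the
#'   breed origin of every transmitted allele is propagated through
#'   meiosis and the offspring origin map is returned.
#' @param seed Optional integer seed.
#' @return A list with `panel` (the offspring [haplotype_panel], pedigree
#'   filled in) and `origins` (offspring [origin_map], or `NULL` when no
#'   parental origins were given).
#' @export
simulate_generation <- function(panel, n_offspring, n_sires, n_dams,
                                equal_family_sizes = TRUE, origins = NULL,
                                seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (n_sires + n_dams > n_ind(panel)) {
    stop("panel too small for disjoint sire and dam sets")
  }
  if (equal_family_sizes && n_offspring %% n_sires != 0L) {
    stop("n_offspring must be divisible by n_sires under equal family sizes")
  }
  if (!is.null(origins) &&
      !identical(dim(origins$pat), dim(panel$pat))) {
    stop("origin map does not match the panel")
  }
  run <- function() {
    cs <- .map_chrom_split(panel$map)
    m <- n_markers(panel)
    parents <- sample.int(n_ind(panel), n_sires + n_dams)
    sires <- parents[seq_len(n_sires)]
    dams <- parents[n_sires + seq_len(n_dams)]
    if (equal_family_sizes) {
      sire_of <- rep(sires, each = n_offspring %/% n_sires)
    } else {
      sire_of <- sample(sires, n_offspring, replace = TRUE)
    }
    dam_of <- sample(dams, n_offspring, replace = TRUE)
    pat <- matrix(0L, n_offspring, m)
    mat <- matrix(0L, n_offspring, m)
    track <- !is.null(origins)
    if (track) {
      opat <- matrix(0L, n_offspring, m)
      omat <- matrix(0L, n_offspring, m)
    }
    for (i in seq_len(n_offspring)) {
      s <- sire_of[i]; d <- dam_of[i]
      g <- .meiose(panel$pat[s, ], panel$mat[s, ], cs)
      pat[i, ] <- g$h
      if (track) {
        opat[i, ] <- ifelse(g$src == 1L, origins$pat[s, ], origins$mat[s, ])
      }
      g <- .meiose(panel$pat[d, ], panel$mat[d, ], cs)
      mat[i, ] <- g$h
      if (track) {
        omat[i, ] <- ifelse(g$src == 1L, origins$pat[d, ], origins$mat[d, ])
      }
    }
    breed <- panel$ind$breed[sires[1L]]
    off <- haplotype_panel(
      data.frame(id = sprintf("%s_G1_%05d", breed, seq_len(n_offspring)),
                 sire = panel$ind$id[sire_of], dam = panel$ind$id[dam_of],
                 breed = breed, stringsAsFactors = FALSE),
      pat, mat, panel$map
    )
    list(panel = off,
         origins = if (track) {
           origin_map(opat, omat, origins$group_labels)
         } else NULL)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
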