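#' Configuration of the two-breed founder simulator
#'
#' Describes the synthetic stand-in for real chip data: two breeds (target
#' `AN`, introgressed `HF`) diverged from a common ancestral population
#' under a Balding-Nichols model, with a one-way historic migrant pulse
#' from HF into AN followed by several generations of random mating so the
#' introgressed material fragments into mosaic segments.
#'
#' @param n_markers Total number of SNPs.
#' @param n_chromosomes Number of autosomes.
#' @param chromosome_length_bp Chromosome length in bp (all equal).
#' @param fst Wright's fixation index of the breed divergence, in (0,1).
#' @param ancestral_maf_range Range of the uniform ancestral allele
#'   frequencies.
#' @param admixture_fraction Fraction of AN founder haplotypes replaced by
#'   HF migrants at the pulse. Default 0.157, the genome-wide
#'   Holstein-origin proportion the model is designed for.
#' @param admixture_generations_ago Generations of random mating between
#'   the pulse and the sampled founder generation (default 10).
#' @param breed_sizes Named vector `c(AN = ..., HF = ...)` of diploid
#'   panel sizes.
#' @param n_founder_haplotypes Size of the per-breed ancestral haplotype
#'   pool from which panel haplotypes descend. A finite pool creates the
#'   within-breed haplotype sharing and LD that both segment-based origin
#'   assignment and marker-based prediction rely on.
#' @param founder_pool_age Mosaic scale of descent from the pool, in
#'   generations: crossover breakpoints on a panel haplotype are Poisson
#'   with rate `founder_pool_age` per Morgan.
#' @param n_native_reference Number of purebred AN individuals returned as
#'   the native reference panel for origin assignment.
#' @param cm_per_mb Recombination rate (default 1 cM/Mb, Haldane map).
#' @param seed Integer seed driving all randomness of the simulator.
#' @return A validated list of class `founder_sim_config`.
#' @export
founder_sim_config <- function(n_markers = 3000L, n_chromosomes = 3L,
                               chromosome_length_bp = 5e7, fst = 0.10,
                               ancestral_maf_range = c(0.05, 0.95),
                               admixture_fraction = 0.157,
                               admixture_generations_ago = 10L,
                               breed_sizes = c(AN = 300L, HF = 1200L),
                               n_founder_haplotypes = 40L,
                               founder_pool_age = 20,
                               n_native_reference = 100L,
                               cm_per_mb = 1, seed = 1L) {
  if (admixture_fraction < 0 || admixture_fraction > 1) {
    stop("admixture_fraction must be in [0, 1]")
  }
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)")
  if (n_markers < n_chromosomes) stop("n_markers < n_chromosomes")
  if (!all(c("AN", "HF") %in% names(breed_sizes)) ||
      any(breed_sizes < 1)) {
    stop("breed_sizes must name AN and HF with sizes >= 1")
  }
  if (admixture_generations_ago < 1) {
    stop("admixture_generations_ago must be >= 1")
  }
  structure(
    list(n_markers = as.integer(n_markers),
         n_chromosomes = as.integer(n_chromosomes),
         chromosome_length_bp = chromosome_length_bp, fst = fst,
         ancestral_maf_range = ancestral_maf_range,
         admixture_fraction = admixture_fraction,
         admixture_generations_ago = as.integer(admixture_generations_ago),
         breed_sizes = breed_sizes,
         n_founder_haplotypes = as.integer(n_founder_haplotypes),
         founder_pool_age = founder_pool_age,
         n_native_reference = as.integer(n_native_reference),
         cm_per_mb = cm_per_mb, seed = as.integer(seed)),
    class = "founder_sim_config"
  )
}

# one meiosis on one chromosome: Haldane model, Poisson crossover count,
# uniform placement in genetic distance, no interference, no mutation.
# Returns the transmitted source haplotype (1 = pat, 2 = mat) per marker.
.meiosis_sources <- function(gpos, length_morgan) {
  n_cross <- stats::rpois(1L, length_morgan)
  phase0 <- sample.int(2L, 1L)
  if (n_cross == 0L) return(rep.int(phase0, length(gpos)))
  cuts <- sort(stats::runif(n_cross, min(gpos), min(gpos) + length_morgan))
  seg <- findInterval(gpos, cuts)
  1L + (phase0 - 1L + seg) %% 2L
}

# gamete + per-marker source for a whole genome
.meiose <- function(pat_row, mat_row, chrom_split) {
  m <- length(pat_row)
  src <- integer(m)
  for (cs in chrom_split) {
    src[cs$idx] <- .meiosis_sources(cs$gpos, cs$length_morgan)
  }
  h <- ifelse(src == 1L, pat_row, mat_row)
  list(h = h, src = src)
}

# draw n_hap mosaic haplotypes descending from a pool of founder
# haplotypes; breakpoints are Poisson(age * Morgan), pool source iid per
# segment
.pool_mosaics <- function(n_hap, pool, chrom_split, age) {
  m <- ncol(pool)
  out <- matrix(0L, n_hap, m)
  n_pool <- nrow(pool)
  for (i in seq_len(n_hap)) {
    for (cs in chrom_split) {
      n_cross <- stats::rpois(1L, age * cs$length_morgan)
      if (n_cross == 0L) {
        out[i, cs$idx] <- pool[sample.int(n_pool, 1L), cs$idx]
      } else {
        cuts <- sort(stats::runif(n_cross, min(cs$gpos),
                                  min(cs$gpos) + cs$length_morgan))
        seg <- findInterval(cs$gpos, cuts) + 1L
        srcs <- sample.int(n_pool, n_cross + 1L, replace = TRUE)
        out[i, cs$idx] <- pool[cbind(srcs[seg], cs$idx)]
      }
    }
  }
  out
}

# one generation of balanced random mating with origin tracking: every
# parent contributes exactly two gametes, which pins the genome-wide
# migrant fraction to the pulse fraction instead of letting it drift
.drop_generation <- function(pat, mat, opat, omat, chrom_split) {
  n <- nrow(pat)
  if (n < 2L) stop("need at least two individuals to mate")
  p1 <- sample.int(n)
  repeat {
    p2 <- sample.int(n)
    if (!any(p1 == p2)) break
  }
  new_pat <- pat; new_mat <- mat
  new_opat <- opat; new_omat <- omat
  for (i in seq_len(n)) {
    g <- .meiose(pat[p1[i], ], mat[p1[i], ], chrom_split)
    new_pat[i, ] <- g$h
    new_opat[i, ] <- ifelse(g$src == 1L, opat[p1[i], ], omat[p1[i], ])
    g <- .meiose(pat[p2[i], ], mat[p2[i], ], chrom_split)
    new_mat[i, ] <- g$h
    new_omat[i, ] <- ifelse(g$src == 1L, opat[p2[i], ], omat[p2[i], ])
  }
  list(pat = new_pat, mat = new_mat, opat = new_opat, omat = new_omat)
}

#' Simulate two diverged breeds with one-way historic admixture
#'
#' Ancestral allele frequencies are uniform on `ancestral_maf_range`;
#' breed frequencies follow the Balding-Nichols Beta divergence model at
#' the configured F_ST. Each breed owns a finite pool of founder
#' haplotypes; panel haplotypes are recombinant mosaics of that pool,
#' which gives realistic within-breed haplotype sharing and LD. The AN
#' panel receives a single pulse of HF migrant haplotypes
#' (`admixture_fraction` of founder haplotypes, rounded to an exact
#' count) `admixture_generations_ago` generations back, followed by
#' balanced random mating with Haldane recombination; the generating
#' origin of every allele is tracked through every meiosis, so segment
#' lengths emerge from recombination.
#'
#' @param config A [founder_sim_config].
#' @return A list with elements `AN` and `HF` ([haplotype_panel]s on a
#'   shared map), `AN_ref` (a purebred AN reference panel for origin
#'   assignment), `true_origins` (the generating [origin_map] of the AN
#'   panel, groups `c("AN","HF")`), `frequencies` (per-breed generating
#'   allele frequencies) and `map`.
#' @export
simulate_founder_breeds <- function(config) {
  stopifnot(inherits(config, "founder_sim_config"))
  withr::with_seed(config$seed, {
    map <- random_marker_map(config$n_markers, config$n_chromosomes,
                             config$chromosome_length_bp, config$cm_per_mb)
    cs <- .map_chrom_split(map)
    m <- nrow(map)
    p0 <- stats::runif(m, config$ancestral_maf_range[1],
                       config$ancestral_maf_range[2])
    theta <- (1 - config$fst) / config$fst
    p_an <- stats::rbeta(m, p0 * theta, (1 - p0) * theta)
    p_hf <- stats::rbeta(m, p0 * theta, (1 - p0) * theta)
    n_pool <- config$n_founder_haplotypes
    pool_an <- matrix(stats::rbinom(n_pool * m, 1L, rep(p_an, each = n_pool)),
                      n_pool, m)
    pool_hf <- matrix(stats::rbinom(n_pool * m, 1L, rep(p_hf, each = n_pool)),
                      n_pool, m)
    age <- config$founder_pool_age

    make_panel <- function(n, pool, breed, prefix) {
      h <- .pool_mosaics(2L * n, pool, cs, age)
      odd <- seq(1L, 2L * n, by = 2L)
      haplotype_panel(
        data.frame(id = sprintf("%s%04d", prefix, seq_len(n)),
                   sire = NA_character_, dam = NA_character_, breed = breed,
                   stringsAsFactors = FALSE),
        h[odd, , drop = FALSE], h[odd + 1L, , drop = FALSE], map
      )
    }

    hf <- make_panel(config$breed_sizes[["HF"]], pool_hf, "HF", "HF")
    an_ref <- make_panel(config$n_native_reference, pool_an, "AN", "ANR")

    # admixed AN: migrant pulse, then gene dropping
    n_an <- config$breed_sizes[["AN"]]
    n_hap <- 2L * n_an
    n_mig <- round(config$admixture_fraction * n_hap)
    hap <- .pool_mosaics(n_hap, pool_an, cs, age)
    ori <- matrix(1L, n_hap, m)
    if (n_mig > 0L) {
      mig <- sample.int(n_hap, n_mig)
      hap[mig, ] <- .pool_mosaics(n_mig, pool_hf, cs, age)
      ori[mig, ] <- 2L
    }
    odd <- seq(1L, n_hap, by = 2L)
    pat <- hap[odd, , drop = FALSE]; mat <- hap[odd + 1L, , drop = FALSE]
    opat <- ori[odd, , drop = FALSE]; omat <- ori[odd + 1L, , drop = FALSE]
    if (n_an >= 2L) {
      for (g in seq_len(config$admixture_generations_ago)) {
        gen <- .drop_generation(pat, mat, opat, omat, cs)
        pat <- gen$pat; mat <- gen$mat; opat <- gen$opat; omat <- gen$omat
      }
    }
    an <- haplotype_panel(
      data.frame(id = sprintf("AN%04d", seq_len(n_an)),
                 sire = NA_character_, dam = NA_character_, breed = "AN",
                 stringsAsFactors = FALSE),
      pat, mat, map
    )
    list(AN = an, HF = hf, AN_ref = an_ref,
         true_origins = origin_map(opat, omat, c("AN", "HF")),
         frequencies = list(AN = p_an, HF = p_hf), map = map)
  })
}
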