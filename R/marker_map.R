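#' Construct a marker map
#'
#' A marker map holds the physical and genetic positions of the SNPs of a
#' genotyping panel. Genetic positions are derived from physical positions
#' with a constant recombination rate (`cm_per_mb`), the usual working
#' assumption for medium-density cattle chips.
#'
#' @param chromosome Integer vector of chromosome numbers (>= 1).
#' @param position_bp Integer vector of physical positions in base pairs
#'   (1-based, >= 1).
#' @param marker_id Optional character vector of marker names; generated as
#'   `"chr<c>_<pos>"` when missing.
#' @param cm_per_mb Recombination rate in centimorgan per megabase used to
#'   derive `genetic_pos_morgan`. Default 1 cM/Mb.
#'
#' @return A `data.frame` of class `marker_map` with columns `marker_id`,
#'   `chromosome`, `position_bp` and `genetic_pos_morgan`, strictly sorted by
#'   `(chromosome, position_bp)`.
#' @export
marker_map <- function(chromosome, position_bp, marker_id = NULL, cm_per_mb = 1) {
  chromosome <- as.integer(chromosome)
  position_bp <- as.numeric(position_bp)
  if (length(chromosome) != length(position_bp)) {
    stop("'chromosome' and 'position_bp' must have equal length")
  }
  if (any(chromosome < 1L) || any(position_bp < 1)) {
    stop("chromosomes and positions must be >= 1")
  }
  ord <- order(chromosome, position_bp)
  chromosome <- chromosome[ord]
  position_bp <- position_bp[ord]
  if (anyDuplicated(cbind(chromosome, position_bp))) {
    stop("duplicate physical position within a chromosome")
  }
  if (is.null(marker_id)) {
    marker_id <- sprintf("chr%d_%d", chromosome, as.integer(position_bp))
  } else {
    marker_id <- as.character(marker_id)[ord]
    if (anyDuplicated(marker_id)) stop("duplicate marker ids")
  }
  map <- data.frame(
    marker_id = marker_id,
    chromosome = chromosome,
    position_bp = position_bp,
    genetic_pos_morgan = position_bp * cm_per_mb * 1e-8,
    stringsAsFactors = FALSE
  )
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Draw a random marker map
#'
#' Markers are spread across chromosomes as evenly as possible; positions
#' within a chromosome are sampled uniformly without replacement and sorted.
#'
#' @param n_markers Total number of markers.
#' @param n_chromosomes Number of autosomes.
#' @param chromosome_length_bp Length of every chromosome in base pairs.
#' @param cm_per_mb Recombination rate (cM/Mb).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A [marker_map].
#' @export
random_marker_map <- function(n_markers, n_chromosomes = 3L,
                              chromosome_length_bp = 1e8, cm_per_mb = 1,
                              seed = NULL) {
  if (n_markers < n_chromosomes) {
    stop("n_markers must be >= n_chromosomes")
  }
  draw <- function() {
    per_chrom <- diff(round(seq(0, n_markers, length.out = n_chromosomes + 1)))
    chrom <- rep(seq_len(n_chromosomes), per_chrom)
    pos <- unlist(lapply(per_chrom, function(m) {
      sort(sample.int(chromosome_length_bp, m, replace = FALSE))
    }))
    marker_map(chrom, pos, cm_per_mb = cm_per_mb)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# split a map into per-chromosome pieces used by the meiosis machinery:
# marker indices, genetic positions, and total genetic length (Morgan)
.map_chrom_split <- function(map) {
  lapply(split(seq_len(nrow(map)), map$chromosome), function(idx) {
    g <- map$genetic_pos_morgan[idx]
    list(idx = idx, gpos = g, length_morgan = max(g) - min(g))
  })
}

.same_map <- function(a, b) {
  isTRUE(all.equal(a$chromosome, b$chromosome)) &&
    isTRUE(all.equal(a$position_bp, b$position_bp))
}
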