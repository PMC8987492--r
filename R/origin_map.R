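#' Construct a per-allele breed-origin map
#'
#' For every individual, haplotype (paternal/maternal) and marker, the
#' origin map records which genetic group (breed of origin) the allele
#' descends from. Group 1 is always the target breed; foreign groups carry
#' the introgressed material. Origins partition the genome: every allele
#' has exactly one origin.
#'
#' @param pat,mat Integer `N x M` matrices with entries in `1..K`.
#' @param group_labels Character vector of the `K` group (breed) names;
#'   element 1 is the target breed.
#' @return An object of class `origin_map`.
#' @export
origin_map <- function(pat, mat, group_labels) {
  stopifnot(is.matrix(pat), is.matrix(mat))
  K <- length(group_labels)
  if (K < 1L || anyDuplicated(group_labels)) stop("invalid group labels")
  if (!identical(dim(pat), dim(mat))) stop("pat/mat dimensions differ")
  if (!all(pat %in% seq_len(K)) || !all(mat %in% seq_len(K))) {
    stop("origins must be integers in 1..K")
  }
  storage.mode(pat) <- "integer"
  storage.mode(mat) <- "integer"
  structure(list(pat = pat, mat = mat, group_labels = group_labels),
            class = "origin_map")
}

#' @export
print.origin_map <- function(x, ...) {
  fr <- vapply(seq_along(x$group_labels), function(k) {
    (sum(x$pat == k) + sum(x$mat == k)) / (2 * length(x$pat))
  }, numeric(1))
  cat(sprintf("origin_map: %d individuals x %d markers; groups: %s\n",
              nrow(x$pat), ncol(x$pat),
              paste(sprintf("%s(%.3f)", x$group_labels, fr), collapse = ", ")))
  invisible(x)
}

#' Constant origin map for a purebred panel
#'
#' @param panel A [haplotype_panel].
#' @param group Label (present in `group_labels`) assigned everywhere.
#' @param group_labels Full ordered label set of the analysis.
#' @return An [origin_map].
#' @export
constant_origin_map <- function(panel, group, group_labels) {
  k <- match(group, group_labels)
  if (is.na(k)) stop("'group' not among group_labels")
  m <- matrix(k, n_ind(panel), n_markers(panel))
  origin_map(m, m, group_labels)
}

#' Subset an origin map by individuals
#' @param om An [origin_map].
#' @param i Row index.
#' @return An [origin_map].
#' @export
subset_origin_map <- function(om, i) {
  origin_map(om$pat[i, , drop = FALSE], om$mat[i, , drop = FALSE],
             om$group_labels)
}

#' Stack two origin maps with identical group labels
#' @param a,b [origin_map]s.
#' @return An [origin_map].
#' @export
combine_origin_maps <- function(a, b) {
  if (!identical(a$group_labels, b$group_labels)) {
    stop("group labels differ")
  }
  origin_map(rbind(a$pat, b$pat), rbind(a$mat, b$mat), a$group_labels)
}

#' Genetic contributions per origin group
#'
#' The genetic contribution `c_ik` of group `k` to individual `i` is the
#' fraction of the individual's `2M` origin-labelled marker alleles that
#' are assigned to group `k`. Rows sum to one.
#'
#' @param om An [origin_map].
#' @param marker_mask Optional logical/integer column subset over which the
#'   fractions are computed (e.g. the retained prediction markers).
#' @return Numeric `N x K` matrix with `group_labels` as column names.
#' @export
origin_fractions <- function(om, marker_mask = NULL) {
  pat <- om$pat
  mat <- om$mat
  if (!is.null(marker_mask)) {
    pat <- pat[, marker_mask, drop = FALSE]
    mat <- mat[, marker_mask, drop = FALSE]
  }
  K <- length(om$group_labels)
  out <- vapply(seq_len(K), function(k) {
    (rowSums(pat == k) + rowSums(mat == k)) / (2 * ncol(pat))
  }, numeric(nrow(pat)))
  out <- matrix(out, nrow = nrow(pat), ncol = K,
                dimnames = list(rownames(pat), om$group_labels))
  out
}

#' Agreement between two origin maps
#'
#' Fraction of (individual, haplotype, marker) positions on which two
#' origin maps agree -- typically an estimated map against the simulator's
#' generating truth.
#'
#' @param estimated,truth [origin_map]s of identical dimension and labels.
#' @return List with `overall` (scalar) and `by_group` (named vector: the
#'   recall of each true origin group).
#' @export
origin_accuracy <- function(estimated, truth) {
  if (!identical(dim(estimated$pat), dim(truth$pat)) ||
      !identical(estimated$group_labels, truth$group_labels)) {
    stop("origin maps are not comparable")
  }
  hits <- (estimated$pat == truth$pat) + (estimated$mat == truth$mat)
  total <- 2 * length(truth$pat)
  by_group <- vapply(seq_along(truth$group_labels), function(k) {
    denom <- sum(truth$pat == k) + sum(truth$mat == k)
    if (denom == 0) return(NA_real_)
    (sum(estimated$pat == k & truth$pat == k) +
       sum(estimated$mat == k & truth$mat == k)) / denom
  }, numeric(1))
  names(by_group) <- truth$group_labels
  list(overall = sum(hits) / total, by_group = by_group)
}

#' Write an origin map as a BED-like segment track
#'
#' One row per constant-origin run: `individual`, `haplotype`
#' (`pat`/`mat`), `chrom`, `start_bp`, `end_bp`, `origin_label`. Intervals
#' are 1-based and closed on both ends ("bed1" dialect, matching VCF
#' coordinates rather than BED's 0-based half-open convention); the header
#' names the dialect to avoid silent misuse.
#'
#' @param om An [origin_map].
#' @param panel The [haplotype_panel] the map annotates (supplies ids and
#'   physical positions).
#' @param path Output file path.
#' @param seed Optional seed recorded in the header for provenance.
#' @return `path`, invisibly.
#' @export
write_origin_track <- function(om, panel, path, seed = NULL) {
  map <- panel$map
  rows <- list()
  for (side in c("pat", "mat")) {
    o <- om[[side]]
    for (i in seq_len(nrow(o))) {
      for (chr in unique(map$chromosome)) {
        idx <- which(map$chromosome == chr)
        r <- rle(o[i, idx])
        ends <- cumsum(r$lengths)
        starts <- c(1L, head(ends, -1L) + 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          individual = panel$ind$id[i], haplotype = side, chrom = chr,
          start_bp = map$position_bp[idx[starts]],
          end_bp = map$position_bp[idx[ends]],
          origin_label = om$group_labels[r$values],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  .write_tsv_with_header(out, path, extra = c(
    "## coordinates=bed1 (1-based, closed intervals)",
    sprintf("## groups=%s", paste(om$group_labels, collapse = ","))
  ), seed = seed)
  invisible(path)
}

#' Read a BED-like origin track back into an origin map
#'
#' Inverse of [write_origin_track()]; the round trip is lossless because
#' segment boundaries always fall on marker positions.
#'
#' @param path File written by [write_origin_track()].
#' @param panel The [haplotype_panel] the track annotates.
#' @param group_labels Ordered group labels of the analysis.
#' @return An [origin_map].
#' @export
read_origin_track <- function(path, panel, group_labels) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  map <- panel$map
  n <- n_ind(panel)
  m <- n_markers(panel)
  out <- list(pat = matrix(NA_integer_, n, m), mat = matrix(NA_integer_, n, m))
  row_of <- match(tr$individual, panel$ind$id)
  if (anyNA(row_of)) stop("track names individuals absent from the panel")
  k_of <- match(tr$origin_label, group_labels)
  if (anyNA(k_of)) stop("track contains unknown origin labels")
  for (j in seq_len(nrow(tr))) {
    sel <- map$chromosome == tr$chrom[j] &
      map$position_bp >= tr$start_bp[j] & map$position_bp <= tr$end_bp[j]
    out[[tr$haplotype[j]]][row_of[j], sel] <- k_of[j]
  }
  if (anyNA(out$pat) || anyNA(out$mat)) {
    stop("track does not cover every marker of every haplotype")
  }
  origin_map(out$pat, out$mat, group_labels)
}
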