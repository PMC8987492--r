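#' Segment rule for breed-origin assignment
#'
#' Foreign haplotype segments are only accepted when they consist of at
#' least `min_markers` consecutive markers and span at least
#' `min_length_bp` (first to last marker, 1-based inclusive). The window
#' classifier behind the rule calls a window of `min_markers` consecutive
#' alleles "foreign-supported" for group `k` when the window haplotype
#' occurs at least `min_foreign_count` times among the group-`k` reference
#' haplotypes and occurs in the target-breed references with frequency not
#' above `max_native_freq`.
#'
#' @param min_markers Minimum consecutive markers per segment (default 20).
#' @param min_length_bp Minimum physical span in bp (default 1,500,000).
#' @param min_foreign_count Minimum occurrences of the window haplotype
#'   among the foreign references (default 1).
#' @param max_native_freq Maximum tolerated frequency of the window
#'   haplotype among target-breed references (default 0: must be absent).
#' @return A list of class `segment_rule`.
#' @export
segment_rule <- function(min_markers = 20L, min_length_bp = 1500000,
                         min_foreign_count = 1L, max_native_freq = 0) {
  if (min_markers < 1L || min_length_bp < 1) {
    stop("min_markers and min_length_bp must be >= 1")
  }
  if (min_markers > 50L) {
    stop("min_markers > 50 is not supported by the window encoder")
  }
  structure(list(min_markers = as.integer(min_markers),
                 min_length_bp = min_length_bp,
                 min_foreign_count = as.integer(min_foreign_count),
                 max_native_freq = max_native_freq),
            class = "segment_rule")
}

# encode every window of `mm` consecutive alleles of each haplotype row as
# one number (exact for mm <= 50 in double precision)
.window_codes <- function(h, mm) {
  w <- ncol(h) - mm + 1L
  codes <- matrix(0, nrow(h), w)
  pow <- 2^(seq_len(mm) - 1)
  for (j in seq_len(mm)) {
    codes <- codes + h[, j:(j + w - 1L), drop = FALSE] * pow[j]
  }
  codes
}

# occurrence count of each query code among the reference codes, column
# (window) wise
.window_support <- function(q_codes, r_codes) {
  out <- matrix(0L, nrow(q_codes), ncol(q_codes))
  for (s in seq_len(ncol(q_codes))) {
    u <- unique(r_codes[, s])
    cnt <- tabulate(match(r_codes[, s], u), nbins = length(u))
    hit <- match(q_codes[, s], u)
    out[, s] <- ifelse(is.na(hit), 0L, cnt[hit])
  }
  out
}

#' Assign a breed origin to every marker allele
#'
#' Slides windows of exactly `min_markers` consecutive markers (step 1)
#' along each haplotype of the admixed panel, within chromosomes. Windows
#' whose haplotype is carried by the foreign references but effectively
#' absent from the target-breed references support a foreign origin;
#' maximal runs of overlapping supported windows are merged into candidate
#' segments, which are accepted when they satisfy the [segment_rule].
#' Every position outside an accepted foreign segment is assigned to the
#' target breed (group 1). Segments never span chromosome boundaries.
#' With more than one foreign group, overlaps are resolved
#' deterministically: higher window-support count first, then the longer
#' candidate, then the lower group index.
#'
#' @param admixed [haplotype_panel] to annotate.
#' @param references Named list of [haplotype_panel]s, one per genetic
#'   group, all on the same map as `admixed`; the first element is the
#'   target breed. Names become the origin `group_labels`.
#' @param rule A [segment_rule].
#' @return An [origin_map] for `admixed`.
#' @export
assign_origins <- function(admixed, references, rule = segment_rule()) {
  stopifnot(inherits(admixed, "haplotype_panel"), is.list(references))
  K <- length(references)
  if (K < 2L) stop("need the target breed plus at least one foreign group")
  if (is.null(names(references)) || anyDuplicated(names(references))) {
    stop("references must be uniquely named by breed")
  }
  for (p in references) {
    if (n_ind(p) == 0L) stop("empty reference panel")
    if (!.same_map(p$map, admixed$map)) {
      stop("reference panels must share the admixed panel's marker map")
    }
  }
  group_labels <- names(references)
  mm <- rule$min_markers
  map <- admixed$map
  n <- n_ind(admixed)
  m <- n_markers(admixed)
  adm <- rbind(admixed$pat, admixed$mat)  # 2N x M, pat block first
  refs <- lapply(references, function(p) rbind(p$pat, p$mat))
  orig <- matrix(1L, 2L * n, m)

  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    len <- length(idx)
    if (len < mm) next
    pos <- map$position_bp[idx]
    qc <- .window_codes(adm[, idx, drop = FALSE], mm)
    native_cnt <- .window_support(qc, .window_codes(refs[[1L]][, idx, drop = FALSE], mm))
    native_ok <- native_cnt <= rule$max_native_freq * nrow(refs[[1L]])
    support <- lapply(2:K, function(k) {
      cnt <- .window_support(qc, .window_codes(refs[[k]][, idx, drop = FALSE], mm))
      (cnt >= rule$min_foreign_count) & native_ok
    })
    for (h in seq_len(2L * n)) {
      cands <- list()
      for (j in seq_along(support)) {
        sup <- support[[j]][h, ]
        r <- rle(sup)
        ends <- cumsum(r$lengths)
        starts <- c(1L, utils::head(ends, -1L) + 1L)
        for (seg in which(r$values)) {
          s1 <- starts[seg]; s2 <- ends[seg]
          first <- s1; last <- s2 + mm - 1L
          span <- pos[last] - pos[first]
          n_mark <- last - first + 1L
          if (span >= rule$min_length_bp && n_mark >= mm) {
            cands[[length(cands) + 1L]] <- c(group = j + 1L, first = first,
                                             last = last,
                                             support = s2 - s1 + 1L,
                                             span = span)
          }
        }
      }
      if (length(cands) == 0L) next
      cd <- do.call(rbind, cands)
      ord <- order(-cd[, "support"], -cd[, "span"], cd[, "group"])
      claimed <- logical(len)
      for (r_i in ord) {
        rng <- cd[r_i, "first"]:cd[r_i, "last"]
        free <- rng[!claimed[rng]]
        if (length(free)) {
          orig[h, idx[free]] <- as.integer(cd[r_i, "group"])
          claimed[free] <- TRUE
        }
      }
    }
  }
  origin_map(orig[seq_len(n), , drop = FALSE],
             orig[n + seq_len(n), , drop = FALSE],
             group_labels)
}
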