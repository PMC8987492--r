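#' Construct a phased haplotype panel
#'
#' The central genotype container: `N` individuals typed at `M` biallelic
#' markers, phased into a paternal and a maternal haplotype. Alleles are
#' coded 0 (reference) / 1 (alternative); dosages used by the prediction
#' models are counts of the alternative allele.
#'
#' @param individuals `data.frame` with columns `id`, `sire`, `dam`,
#'   `breed`. `sire`/`dam` may be `NA` for founders.
#' @param pat,mat Integer `N x M` matrices of 0/1 alleles, paternal and
#'   maternal haplotype respectively. Column order follows `map`.
#' @param map A [marker_map] with `M` rows.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(individuals, pat, mat, map) {
  stopifnot(is.data.frame(individuals), is.matrix(pat), is.matrix(mat))
  req <- c("id", "sire", "dam", "breed")
  if (!all(req %in% names(individuals))) {
    stop("individuals needs columns: ", paste(req, collapse = ", "))
  }
  n <- nrow(individuals)
  if (nrow(pat) != n || nrow(mat) != n) stop("haplotype rows != individuals")
  if (ncol(pat) != nrow(map) || ncol(mat) != nrow(map)) {
    stop("haplotype columns != markers in map")
  }
  if (anyDuplicated(individuals$id)) stop("duplicate individual ids")
  if (!all(pat %in% c(0L, 1L)) || !all(mat %in% c(0L, 1L))) {
    stop("alleles must be 0/1")
  }
  storage.mode(pat) <- "integer"
  storage.mode(mat) <- "integer"
  rownames(pat) <- rownames(mat) <- individuals$id
  structure(
    list(ind = individuals, pat = pat, mat = mat, map = map),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %d individuals x %d markers (%d chromosomes); breeds: %s\n",
    n_ind(x), n_markers(x), length(unique(x$map$chromosome)),
    paste(sprintf("%s(%d)", names(table(x$ind$breed)), table(x$ind$breed)),
          collapse = ", ")
  ))
  invisible(x)
}

#' Number of individuals in a panel
#' @param panel A [haplotype_panel].
#' @return Integer.
#' @export
n_ind <- function(panel) nrow(panel$ind)

#' Number of markers in a panel
#' @param panel A [haplotype_panel].
#' @return Integer.
#' @export
n_markers <- function(panel) ncol(panel$pat)

#' Genotype dosage matrix
#'
#' @param panel A [haplotype_panel].
#' @return Integer `N x M` matrix of alternative-allele counts (0/1/2).
#' @export
dosage <- function(panel) panel$pat + panel$mat

#' Alternative-allele frequencies of a panel
#'
#' @param panel A [haplotype_panel].
#' @return Numeric vector of length `M`.
#' @export
allele_freq <- function(panel) colMeans(panel$pat + panel$mat) / 2

#' Subset a panel by individuals
#'
#' @param panel A [haplotype_panel].
#' @param i Integer/logical row index or character vector of ids.
#' @return A [haplotype_panel].
#' @export
subset_individuals <- function(panel, i) {
  if (is.character(i)) i <- match(i, panel$ind$id)
  haplotype_panel(panel$ind[i, , drop = FALSE],
                  panel$pat[i, , drop = FALSE],
                  panel$mat[i, , drop = FALSE],
                  panel$map)
}

#' Stack two panels typed on the same map
#'
#' @param a,b [haplotype_panel]s sharing an identical marker map.
#' @return A [haplotype_panel] with the individuals of `a` followed by `b`.
#' @export
combine_panels <- function(a, b) {
  if (!.same_map(a$map, b$map)) stop("panels are not on the same marker map")
  haplotype_panel(rbind(a$ind, b$ind), rbind(a$pat, b$pat),
                  rbind(a$mat, b$mat), a$map)
}
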