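# File formats. All outputs are plain text with "##"-prefixed header
# comment lines carrying the tool version and, when given, the seed, so
# reruns are traceable. Physical coordinates are 1-based (VCF
# convention) throughout.

.header_lines <- function(seed = NULL, extra = character(0)) {
  c(sprintf("## boapred %s",
            as.character(utils::packageVersion("boapred"))),
    if (!is.null(seed)) sprintf("## seed=%d", as.integer(seed)),
    extra)
}

.write_tsv_with_header <- function(df, path, extra = character(0),
                                   seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_lines(seed, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a phased panel as VCF
#'
#' Phased genotypes are written as `GT` fields `a|b`; by the package's
#' fixed convention the first allele of `a|b` is the paternal one. REF is
#' `A`, ALT is `C` (the simulator's markers are abstract biallelic SNPs;
#' the alternative allele of the model formulas is ALT).
#'
#' @param panel A [haplotype_panel].
#' @param path Output path (plain-text `.vcf`).
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, seed = NULL) {
  map <- panel$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=boapred%s%s",
            as.character(utils::packageVersion("boapred")),
            if (is.null(seed)) "" else sprintf(";seed=%d", as.integer(seed))),
    "##haplotypeOrder=paternal|maternal",
    sprintf("##contig=<ID=%d>", unique(map$chromosome)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$ind$id), collapse = "\t")
  ), con)
  gt <- matrix(paste(t(panel$pat), t(panel$mat), sep = "|"),
               nrow = n_markers(panel))
  body <- cbind(map$chromosome, map$position_bp, map$marker_id, "A", "C",
                ".", "PASS", ".", "GT", gt)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read phased genotypes into a haplotype panel
#'
#' For VCF input every `GT` must be phased (`a|b`); an unphased or
#' multiallelic record is a hard error naming the record. The first
#' allele of `a|b` is taken as paternal (the package convention).
#'
#' @param path Input file.
#' @param format `"vcf"` or `"haplotype_tsv"`.
#' @param map Required for `haplotype_tsv` input (the TSV stores alleles
#'   only); ignored for VCF.
#' @param breed Breed label given to the individuals (default
#'   `"unknown"`).
#' @param cm_per_mb Recombination rate used to rebuild genetic positions
#'   from VCF physical positions.
#' @return A [haplotype_panel].
#' @export
read_phased_genotypes <- function(path, format = c("vcf", "haplotype_tsv"),
                                  map = NULL, breed = "unknown",
                                  cm_per_mb = 1) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
    if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
      bad <- which(grepl(",", fix[, "ALT"], fixed = TRUE))[1L]
      stop(sprintf("multiallelic site at %s:%s", fix[bad, "CHROM"],
                   fix[bad, "POS"]))
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) {
      ids_tmp <- names(gt)
      gt <- matrix(gt, nrow = nrow(fix),
                   dimnames = list(fix[, "ID"], ids_tmp))
    }
    unph <- !grepl("|", gt, fixed = TRUE)
    dim(unph) <- dim(gt)  # grepl drops the dim attribute
    if (any(unph)) {
      bad <- which(unph, arr.ind = TRUE)
      stop(sprintf(
        "unphased genotype '%s' at marker %s, individual %s",
        gt[bad[1L, 1L], bad[1L, 2L]],
        rownames(gt)[bad[1L, 1L]], colnames(gt)[bad[1L, 2L]]))
    }
    pat <- t(matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt)))
    mat <- t(matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt)))
    m <- marker_map(as.integer(fix[, "CHROM"]),
                    as.integer(fix[, "POS"]),
                    marker_id = fix[, "ID"], cm_per_mb = cm_per_mb)
    ids <- colnames(gt)
    haplotype_panel(
      data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                 breed = breed, stringsAsFactors = FALSE),
      pat, mat, m
    )
  } else {
    if (is.null(map)) stop("haplotype_tsv input needs a marker map")
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE,
                             colClasses = "character")
    ids <- unique(tab$individual_id)
    alle <- function(side) {
      rows <- tab[tab$parent_of_origin == side, ]
      rows <- rows[match(ids, rows$individual_id), ]
      do.call(rbind, lapply(strsplit(rows$alleles, ""), as.integer))
    }
    haplotype_panel(
      data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                 breed = breed, stringsAsFactors = FALSE),
      alle("pat"), alle("mat"), map
    )
  }
}

#' Write a panel as a haplotype table
#'
#' One row per haplotype: `individual_id`, `parent_of_origin`
#' (`pat`/`mat`) and the alleles as a compact 0/1 string in map order.
#'
#' @param panel A [haplotype_panel].
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_haplotype_tsv <- function(panel, path, seed = NULL) {
  pack <- function(h) apply(h, 1L, paste, collapse = "")
  df <- data.frame(
    individual_id = rep(panel$ind$id, 2L),
    parent_of_origin = rep(c("pat", "mat"), each = n_ind(panel)),
    alleles = c(pack(panel$pat), pack(panel$mat)),
    stringsAsFactors = FALSE
  )
  .write_tsv_with_header(df, path, seed = seed)
}

#' Write a marker map as PLINK-style .bim table
#'
#' Columns: chromosome, marker id, genetic position (cM), physical
#' position (bp), allele 1, allele 2.
#'
#' @param map A [marker_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_map_bim <- function(map, path) {
  df <- data.frame(map$chromosome, map$marker_id,
                   map$genetic_pos_morgan * 100, map$position_bp, "A", "C")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a three-column pedigree table
#'
#' @param panel A [haplotype_panel].
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_pedigree_tsv <- function(panel, path, seed = NULL) {
  df <- data.frame(id = panel$ind$id, sire = panel$ind$sire,
                   dam = panel$ind$dam, stringsAsFactors = FALSE)
  .write_tsv_with_header(df, path, seed = seed)
}

#' Write phenotypes (and true breeding values)
#'
#' @param phen `data.frame` from [simulate_phenotypes()].
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_phenotypes_tsv <- function(phen, path, seed = NULL) {
  .write_tsv_with_header(phen, path, seed = seed)
}

#' Write estimated marker effects
#'
#' One row per marker and origin group: `marker_id`, `group_label`,
#' `a_hat`.
#'
#' @param fit A `model_fit`.
#' @param path Output path.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_marker_effects_tsv <- function(fit, path, seed = NULL) {
  df <- data.frame(
    marker_id = rep(fit$marker_ids, ncol(fit$a_hat)),
    group_label = rep(fit$group_labels, each = nrow(fit$a_hat)),
    a_hat = as.numeric(fit$a_hat),
    stringsAsFactors = FALSE
  )
  .write_tsv_with_header(df, path,
                         extra = sprintf("## model=%s", fit$model_kind),
                         seed = seed)
}
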