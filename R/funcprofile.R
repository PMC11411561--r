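#' Genome equivalents from universal single-copy marker genes
#'
#' The number of genome copies sequenced in a sample is estimated as the
#' arithmetic mean per-base sequencing depth of 16 universal, single-copy
#' ribosomal genes. Dividing a functional gene's depth by this value gives
#' the fraction of genomes carrying that gene.
#'
#' @param marker_depths Numeric vector of exactly 16 non-negative per-marker
#'   mean coverages; at least one must be positive.
#' @return Genome equivalents (dimensionless mean coverage).
#' @examples
#' genome_equivalents(rep(10, 16))
#' @export
genome_equivalents <- function(marker_depths) {
  if (length(marker_depths) != 16L) {
    stop("expected exactly 16 marker depths, got ", length(marker_depths),
         call. = FALSE)
  }
  if (any(is.na(marker_depths)) || any(marker_depths < 0)) {
    stop("marker depths must be non-negative and non-missing", call. = FALSE)
  }
  if (all(marker_depths == 0)) {
    stop("degenerate sample: all 16 marker depths are zero", call. = FALSE)
  }
  mean(marker_depths)
}

#' Fraction of genomes carrying a gene
#'
#' `100 * gene_depth_sum / genome_equivalents`. Values above 100% are
#' reported, not clipped (multi-copy gene families are real); they carry a
#' `multi_copy` attribute flag.
#'
#' @param gene_depth_sum Summed per-base depth of the gene family (numeric,
#'   vectorized).
#' @param ge Genome equivalents from [genome_equivalents()]; must be > 0.
#' @return Percent of genomes, with logical attribute `multi_copy` marking
#'   values above 100.
#' @examples
#' fraction_of_genomes(5.1, 10)
#' @export
fraction_of_genomes <- function(gene_depth_sum, ge) {
  if (!is.numeric(ge) || length(ge) != 1L || is.na(ge) || ge <= 0) {
    stop("degenerate sample: genome equivalents must be positive",
         call. = FALSE)
  }
  frac <- 100 * gene_depth_sum / ge
  attr(frac, "multi_copy") <- frac > 100
  frac
}

#' Taxonomic breakdown of a functional gene family
#'
#' Shares of a gene family's total depth by taxon, in percent, sorted
#' descending. Proportions sum to 100 (within rounding).
#'
#' @param table A data.frame with columns `gene_family`, `taxon`, `depth`.
#' @param gene_family Gene family to break down.
#' @return Named numeric vector of percentages (taxa, descending); an absent
#'   gene family yields an empty vector with a warning.
#' @examples
#' taxon_breakdown(
#'   data.frame(gene_family = "hyd", taxon = c("SUP05", "Sulfurimonas"),
#'              depth = c(3, 1)),
#'   "hyd")
#' @export
taxon_breakdown <- function(table, gene_family) {
  stopifnot(is.data.frame(table),
            all(c("gene_family", "taxon", "depth") %in% names(table)))
  sub <- table[table$gene_family == gene_family, , drop = FALSE]
  if (!nrow(sub) || sum(sub$depth) <= 0) {
    warning("gene family '", gene_family, "' absent (or zero depth)")
    return(stats::setNames(numeric(0), character(0)))
  }
  by_taxon <- tapply(sub$depth, sub$taxon, sum)
  pct <- 100 * by_taxon / sum(by_taxon)
  sort(c(pct), decreasing = TRUE)
}

#' Convert read counts to mean per-base depth
#'
#' When the input supplies raw counts instead of depths, depth is
#' reconstructed as `count * read_length / gene_length`. The default read
#' length of 250 nt matches 2x250 bp paired-end sequencing.
#'
#' @param counts Read counts (numeric).
#' @param gene_lengths Gene lengths in bp (recycled against `counts`).
#' @param read_length Read length in nt, default 250.
#' @return Mean per-base depth.
#' @examples
#' counts_to_depth(100, 1000)
#' @export
counts_to_depth <- function(counts, gene_lengths, read_length = 250) {
  stopifnot(all(gene_lengths > 0), read_length > 0)
  counts * read_length / gene_lengths
}

#' Per-sample functional gene profile
#'
#' Combines a per-sample, per-taxon gene depth table with per-sample marker
#' depths: for every sample and gene family, the fraction of genomes
#' carrying the family (summing depth over taxa, then dividing by genome
#' equivalents).
#'
#' @param genes Data.frame with columns `sample`, `gene_family`, `taxon`,
#'   `depth`.
#' @param markers Data.frame with columns `sample`, `depth` (16 rows per
#'   sample; a `marker` column is allowed and ignored for the mean).
#' @return Data.frame with columns `sample`, `gene_family`,
#'   `fraction_of_genomes`, `multi_copy`.
#' @examples
#' genes <- data.frame(sample = "s1", gene_family = "coxS",
#'                     taxon = c("SAR202", "SAR324"), depth = c(3, 2))
#' markers <- data.frame(sample = "s1", depth = rep(10, 16))
#' gene_profile(genes, markers)
#' @export
gene_profile <- function(genes, markers) {
  stopifnot(is.data.frame(genes),
            all(c("sample", "gene_family", "taxon", "depth") %in% names(genes)),
            is.data.frame(markers),
            all(c("sample", "depth") %in% names(markers)))
  out <- lapply(unique(genes$sample), function(s) {
    ge <- genome_equivalents(markers$depth[markers$sample == s])
    sub <- genes[genes$sample == s, , drop = FALSE]
    fam_depth <- tapply(sub$depth, sub$gene_family, sum)
    frac <- fraction_of_genomes(c(fam_depth), ge)
    data.frame(sample = s,
               gene_family = names(fam_depth),
               fraction_of_genomes = as.numeric(frac),
               multi_copy = as.logical(attr(frac, "multi_copy")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
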