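#' Reads per kilobase per million mapped reads
#'
#' `RPKM_i = reads_i * 1e9 / (length_i * total_mapped_reads)`. The library
#' total is library-wide and may exceed the sum over the features supplied.
#'
#' @param counts Named numeric vector of mapped read (fragment) counts.
#' @param lengths Feature lengths in bp, same order as `counts`.
#' @param total_mapped_reads Library size; defaults to `sum(counts)`.
#' @return Named numeric vector of RPKM values.
#' @examples
#' rpkm(c(geneA = 1000), 1000, total_mapped_reads = 1e6)
#' @export
rpkm <- function(counts, lengths, total_mapped_reads = sum(counts)) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0),
            all(counts >= 0))
  if (total_mapped_reads <= 0) {
    stop("degenerate library: total mapped reads must be positive",
         call. = FALSE)
  }
  counts * 1e9 / (lengths * total_mapped_reads)
}

#' Transcripts per million
#'
#' Length-normalized read rates rescaled so each sample sums to one million:
#' `rate_i = reads_i / length_i`, `TPM_i = 1e6 * rate_i / sum(rate)`.
#'
#' @param counts Named numeric vector of mapped read (fragment) counts.
#' @param lengths Feature lengths in bp, same order as `counts`.
#' @return Named numeric vector of TPM values summing to 1e6.
#' @examples
#' tpm(c(a = 100, b = 100), c(1000, 2000))
#' @export
tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0),
            all(counts >= 0))
  if (all(counts == 0)) {
    stop("degenerate library: all feature counts are zero", call. = FALSE)
  }
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Housekeeping-gene transcription baseline
#'
#' Mean TPM over a reference set of constitutively expressed genes, used to
#' judge whether a pathway is highly transcribed: a target gene is called
#' above-baseline iff its TPM exceeds the housekeeping mean.
#'
#' @param tpms Named numeric vector of TPM values for a sample.
#' @param housekeeping Character vector of reference gene identifiers; the
#'   intersection with `names(tpms)` must be non-empty.
#' @return The baseline (mean TPM over the housekeeping genes present).
#' @examples
#' housekeeping_baseline(c(rpoB = 1000, gyrA = 2000, sqr = 900),
#'                       c("rpoB", "gyrA"))
#' @export
housekeeping_baseline <- function(tpms, housekeeping) {
  stopifnot(length(housekeeping) > 0)
  present <- intersect(housekeeping, names(tpms))
  if (!length(present)) {
    stop("missing housekeeping genes: none of the reference set is present",
         call. = FALSE)
  }
  mean(tpms[present])
}

#' Is a gene transcribed above the housekeeping baseline?
#'
#' @param gene_tpm TPM of the target gene.
#' @param baseline Housekeeping baseline from [housekeeping_baseline()].
#' @return Logical.
#' @examples
#' above_baseline(4619, 1349)
#' @export
above_baseline <- function(gene_tpm, baseline) {
  gene_tpm > baseline
}

#' Per-sample transcription contrast between two genes
#'
#' Ratio of gene A to gene B TPM per sample, preserving sample order — used
#' e.g. to follow the hydrogenase:sqr transcription ratio from rising to
#' non-buoyant plume, where sulfide oxidation takes over from hydrogen
#' oxidation as the plume dilutes. Ratios with a zero (or absent)
#' denominator are reported as `NA`.
#'
#' @param tpm_table Data.frame with columns `sample`, `feature_id`, `tpm`.
#' @param gene_a,gene_b Feature identifiers to contrast.
#' @return Data.frame with columns `sample`, `tpm_a`, `tpm_b`, `ratio`, in
#'   the sample order of first appearance. If neither gene occurs anywhere,
#'   an empty data.frame with a warning.
#' @examples
#' niche_contrast(
#'   data.frame(sample = c("rp", "rp", "p", "p"),
#'              feature_id = c("hyd", "sqr", "hyd", "sqr"),
#'              tpm = c(282591, 20000, 61619, 135169)),
#'   "hyd", "sqr")
#' @export
niche_contrast <- function(tpm_table, gene_a, gene_b) {
  stopifnot(is.data.frame(tpm_table),
            all(c("sample", "feature_id", "tpm") %in% names(tpm_table)))
  if (!any(tpm_table$feature_id %in% c(gene_a, gene_b))) {
    warning("neither '", gene_a, "' nor '", gene_b,
            "' is present in the table")
    return(data.frame(sample = character(), tpm_a = numeric(),
                      tpm_b = numeric(), ratio = numeric(),
                      stringsAsFactors = FALSE))
  }
  samples <- unique(tpm_table$sample)
  grab <- function(s, g) {
    v <- tpm_table$tpm[tpm_table$sample == s & tpm_table$feature_id == g]
    if (length(v)) v[[1]] else NA_real_
  }
  tpm_a <- vapply(samples, grab, numeric(1), g = gene_a)
  tpm_b <- vapply(samples, grab, numeric(1), g = gene_b)
  ratio <- ifelse(!is.na(tpm_b) & tpm_b > 0, tpm_a / tpm_b, NA_real_)
  data.frame(sample = samples, tpm_a = tpm_a, tpm_b = tpm_b, ratio = ratio,
             row.names = NULL, stringsAsFactors = FALSE)
}
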