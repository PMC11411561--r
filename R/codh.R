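# Amino-acid alphabet accepted by the motif scanner (20 standard + X).
.AA_CHARS <- "ACDEFGHIKLMNPQRSTVWYX"

# Active-site loop motifs of the CODH large subunit (coxL). The exact
# AYRGAGR heptamer marks form II; the form I convention has a single
# wildcard position (AY-x-CSFR). Both configurable in classify_codh().
.MOTIF_FORM_II <- "AYRGAGR"
.MOTIF_FORM_I <- "AY[ACDEFGHIKLMNPQRSTVWYX]CSFR"

#' Scan a coxL protein for form-discriminating active-site motifs
#'
#' Searches an amino-acid sequence for the form II CODH active-site motif
#' (exact `AYRGAGR`) and the form I motif (`AY-x-CSFR`, one wildcard
#' position). The leftmost match wins; its 1-based position is reported.
#'
#' @param protein_sequence A single amino-acid string over the 20-letter
#'   alphabet (X permitted).
#' @param form_ii_motif,form_i_pattern Override the built-in motif (fixed
#'   string) and pattern (regular expression).
#' @return A list with `form` (`"form_II"`, `"form_I"` or `"none"`), `motif`
#'   (matched substring or `NA`) and `position` (1-based or `NA`).
#' @examples
#' scan_motif("MKAYRGAGRLV")
#' scan_motif("GGAYXCSFRGG")
#' @export
scan_motif <- function(protein_sequence,
                       form_ii_motif = .MOTIF_FORM_II,
                       form_i_pattern = .MOTIF_FORM_I) {
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1L)
  seq <- toupper(protein_sequence)
  if (!grepl(sprintf("^[%s]*$", .AA_CHARS), seq)) {
    stop("illegal characters in protein sequence (expected amino acids, ",
         "X permitted)", call. = FALSE)
  }
  hit2 <- regexpr(form_ii_motif, seq, fixed = TRUE)
  hit1 <- regexpr(form_i_pattern, seq)
  pos2 <- if (hit2 > 0) as.integer(hit2) else NA_integer_
  pos1 <- if (hit1 > 0) as.integer(hit1) else NA_integer_
  if (is.na(pos2) && is.na(pos1)) {
    return(list(form = "none", motif = NA_character_, position = NA_integer_))
  }
  # leftmost match wins; form II takes priority on (impossible) ties
  if (!is.na(pos2) && (is.na(pos1) || pos2 <= pos1)) {
    list(form = "form_II",
         motif = substr(seq, pos2, pos2 + attr(hit2, "match.length") - 1L),
         position = pos2)
  } else {
    list(form = "form_I",
         motif = substr(seq, pos1, pos1 + attr(hit1, "match.length") - 1L),
         position = pos1)
  }
}

# Single-letter subunit code for a cox structural role, NA for accessory.
.structural_letter <- function(role) {
  c(coxS = "S", coxM = "M", coxL = "L")[role]
}

#' Detect cox gene clusters (candidate operons)
#'
#' Groups cox genes that lie on the same contig and strand with intergenic
#' gaps of at most `gap` bp (standard prokaryotic operon heuristic). Groups
#' containing at least two structural subunits (coxS/M/L) become operons;
#' remaining cox genes are reported as singletons, not operons. Gene order
#' follows the direction of transcription (reversed for the minus strand).
#'
#' @param genes Data.frame of annotated genes with columns `contig`, `start`,
#'   `end` (1-based inclusive), `strand` (`"+"`/`"-"`), `role` (one of
#'   `coxS`, `coxM`, `coxL`, `coxD`, `coxE`, `coxF`, `coxG`, `other`) and
#'   `protein_id`.
#' @param gap Maximum intergenic distance in bp (default 500).
#' @return A list with `operons` (list of `cox_operon` objects, each holding
#'   `contig`, `strand`, `genes` in transcription order, `structural_order`
#'   such as `"S-L-M"`, and `accessory_present`) and `singletons` (data.frame
#'   of ungrouped cox genes).
#' @examples
#' g <- data.frame(contig = "c1", start = c(1, 1600, 4200),
#'                 end = c(1500, 4100, 5000), strand = "+",
#'                 role = c("coxS", "coxL", "coxM"),
#'                 protein_id = c("p1", "p2", "p3"))
#' detect_operons(g)
#' @export
detect_operons <- function(genes, gap = 500) {
  stopifnot(is.data.frame(genes),
            all(c("contig", "start", "end", "strand", "role", "protein_id")
                %in% names(genes)))
  if (any(genes$start > genes$end)) {
    stop("gene start must not exceed end", call. = FALSE)
  }
  cox_roles <- c("coxS", "coxM", "coxL", "coxD", "coxE", "coxF", "coxG")
  cox <- genes[genes$role %in% cox_roles, , drop = FALSE]
  operons <- list()
  singletons <- cox[0, , drop = FALSE]
  if (!nrow(cox)) return(list(operons = operons, singletons = singletons))

  for (key in unique(paste(cox$contig, cox$strand))) {
    sub <- cox[paste(cox$contig, cox$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    # new cluster when the intergenic gap exceeds the threshold
    gaps <- if (nrow(sub) > 1L) {
      sub$start[-1L] - sub$end[-nrow(sub)] - 1L
    } else integer(0)
    grp <- cumsum(c(1L, as.integer(gaps > gap)))
    for (g in unique(grp)) {
      cluster <- sub[grp == g, , drop = FALSE]
      structural <- cluster$role %in% c("coxS", "coxM", "coxL")
      if (sum(structural) >= 2L) {
        if (cluster$strand[1L] == "-") {
          cluster <- cluster[rev(seq_len(nrow(cluster))), , drop = FALSE]
        }
        letters <- .structural_letter(cluster$role[cluster$role %in%
                                                     c("coxS", "coxM", "coxL")])
        operons[[length(operons) + 1L]] <- structure(
          list(contig = cluster$contig[1L],
               strand = cluster$strand[1L],
               genes = cluster,
               structural_order = paste(letters, collapse = "-"),
               accessory_present =
                 sort(unique(sub("cox", "",
                                 cluster$role[cluster$role %in%
                                                c("coxD", "coxE", "coxF",
                                                  "coxG")])))),
          class = "cox_operon")
      } else {
        singletons <- rbind(singletons, cluster)
      }
    }
  }
  rownames(singletons) <- NULL
  list(operons = operons, singletons = singletons)
}

#' @export
print.cox_operon <- function(x, ...) {
  cat(sprintf("<cox_operon> %s (%s strand): %s%s\n", x$contig, x$strand,
              x$structural_order,
              if (length(x$accessory_present))
                paste0(" + accessory ", paste(x$accessory_present,
                                              collapse = "/")) else ""))
  invisible(x)
}

#' Classify a cox operon as form II, putative form I, partial, or unknown
#'
#' Decision order: (1) an operon missing any of the S/M/L structural
#' subunits is `partial`; (2) otherwise, a coxL carrying the form II motif
#' gives `form_II` (the S-L-M order is recorded as supporting evidence);
#' (3) a coxL with the form I motif gives `putative_form_I`; (4) otherwise
#' `unknown`. Accessory coxD/E/F/G genes — which may lie anywhere on the
#' genome, not only inside the operon — are reported as evidence only and
#' never change the form call.
#'
#' @param operon A `cox_operon` from [detect_operons()].
#' @param proteins Named character vector (or `Biostrings::AAStringSet`)
#'   mapping `protein_id` to amino-acid sequence; must cover coxL when an L
#'   subunit is present.
#' @param genome_roles Optional character vector of all cox roles found
#'   genome-wide, used to widen the accessory evidence.
#' @return A list of class `codh_classification` with `form`,
#'   `motif_evidence`, `motif_position`, `order_evidence`,
#'   `accessory_evidence`.
#' @export
classify_operon <- function(operon, proteins, genome_roles = NULL) {
  stopifnot(inherits(operon, "cox_operon"))
  if (methods::is(proteins, "AAStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  letters_present <- strsplit(operon$structural_order, "-", fixed = TRUE)[[1L]]
  hit <- list(form = "none", motif = NA_character_, position = NA_integer_)
  if ("L" %in% letters_present) {
    lid <- operon$genes$protein_id[operon$genes$role == "coxL"][1L]
    if (!lid %in% names(proteins)) {
      stop("missing protein: no translation for coxL '", lid, "'",
           call. = FALSE)
    }
    hit <- scan_motif(proteins[[lid]])
  }
  accessory <- operon$accessory_present
  if (!is.null(genome_roles)) {
    accessory <- sort(union(
      accessory,
      sub("cox", "", intersect(genome_roles,
                               c("coxD", "coxE", "coxF", "coxG")))))
  }
  form <- if (!all(c("S", "M", "L") %in% letters_present)) {
    "partial"
  } else if (hit$form == "form_II") {
    "form_II"
  } else if (hit$form == "form_I") {
    "putative_form_I"
  } else {
    "unknown"
  }
  structure(
    list(form = form,
         motif_evidence = hit$motif,
         motif_position = hit$position,
         order_evidence = operon$structural_order,
         accessory_evidence = accessory),
    class = "codh_classification")
}

#' @export
print.codh_classification <- function(x, ...) {
  cat(sprintf("<codh_classification> %s (order %s, motif %s%s)\n",
              x$form, x$order_evidence,
              ifelse(is.na(x$motif_evidence), "none", x$motif_evidence),
              if (length(x$accessory_evidence))
                paste0(", accessory ",
                       paste(x$accessory_evidence, collapse = "/")) else ""))
  invisible(x)
}

#' Detect and classify all cox operons in an annotation set
#'
#' @param genes Annotated genes as for [detect_operons()].
#' @param proteins Named character vector or `AAStringSet` of protein
#'   translations.
#' @param gap Operon gap threshold in bp (default 500).
#' @param genome_wide_accessory Search accessory coxD/E/F/G genes across the
#'   whole annotation set (default TRUE) rather than only inside each operon.
#' @return Data.frame with one row per operon: `contig`, `strand`, `start`,
#'   `end`, `n_genes`, `structural_order`, `form`, `motif`, `motif_position`,
#'   `accessory`.
#' @examples
#' fx <- gen_operon_fixtures(seed = 1, n_per_class = 1)
#' classify_codh(fx$genes, fx$proteins)
#' @export
classify_codh <- function(genes, proteins, gap = 500,
                          genome_wide_accessory = TRUE) {
  det <- detect_operons(genes, gap = gap)
  genome_roles <- if (genome_wide_accessory) unique(genes$role) else NULL
  rows <- lapply(det$operons, function(op) {
    cls <- classify_operon(op, proteins, genome_roles = genome_roles)
    data.frame(contig = op$contig,
               strand = op$strand,
               start = min(op$genes$start),
               end = max(op$genes$end),
               n_genes = nrow(op$genes),
               structural_order = op$structural_order,
               form = cls$form,
               motif = cls$motif_evidence,
               motif_position = cls$motif_position,
               accessory = paste(cls$accessory_evidence, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), strand = character(), start = integer(),
               end = integer(), n_genes = integer(),
               structural_order = character(), form = character(),
               motif = character(), motif_position = integer(),
               accessory = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read cox gene annotations from GFF3
#'
#' Imports a GFF3 file and extracts the columns the operon detector needs.
#' The cox subunit role is taken from the `gene` attribute (falling back to
#' `Name`, then `product`) when it matches `coxS/M/L/D/E/F/G`; anything else
#' becomes `other`. Protein identifiers come from the `ID` attribute.
#'
#' @param path Path to a GFF3 file.
#' @return Data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `role`, `protein_id`.
#' @export
read_cox_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  mc <- as.data.frame(gr)
  pick <- function(col) {
    if (col %in% names(mc)) as.character(mc[[col]]) else
      rep(NA_character_, nrow(mc))
  }
  role_raw <- pick("gene")
  role_raw <- ifelse(is.na(role_raw), pick("Name"), role_raw)
  role_raw <- ifelse(is.na(role_raw), pick("product"), role_raw)
  role <- ifelse(!is.na(role_raw) &
                   grepl("^cox[SMLDEFG]$", role_raw), role_raw, "other")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             role = role,
             protein_id = pick("ID"),
             stringsAsFactors = FALSE)
}

#' Classify cox operons from GFF3 and protein FASTA files
#'
#' @param gff Path to GFF3 annotations.
#' @param faa Path to a protein FASTA whose names match the GFF3 `ID`
#'   attributes.
#' @param ... Passed to [classify_codh()].
#' @return See [classify_codh()].
#' @export
codh_from_files <- function(gff, faa, ...) {
  genes <- read_cox_annotations(gff)
  proteins <- Biostrings::readAAStringSet(faa)
  names(proteins) <- sub("\\s.*$", "", names(proteins))
  classify_codh(genes, proteins, ...)
}
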