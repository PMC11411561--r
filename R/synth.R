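# Run code under a generator-specific RNG stream derived from the master
# seed, restoring the caller's RNG state afterwards. Each generator has its
# own offset so adding one never perturbs the others.
with_stream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  force(code)
}

#' Generate a synthetic CTD cast with a turbidity anomaly
#'
#' Emulates a vertical cast through a hydrothermal plume: a depth grid with
#' background turbidity `|Normal(background_ntu, noise_sd)|` plus a Gaussian
#' anomaly of the given peak intensity and width centred at the plume depth.
#' The true plume category of every bottle is derived from the noise-free
#' signal via the package's turbidity thresholds and emitted as ground
#' truth. Potential temperature and salinity get plausible deep-water
#' values.
#'
#' @param seed Master seed; the generator is a pure function of its
#'   arguments including the seed.
#' @param depths Depth grid in metres.
#' @param plume_depth Centre of the turbidity anomaly (m).
#' @param plume_intensity Peak delta-NTU of the anomaly; 0 gives a pure
#'   background cast.
#' @param plume_width Gaussian standard deviation of the anomaly (m).
#' @param background_ntu Mean background delta-NTU.
#' @param noise_sd Per-bottle measurement noise standard deviation.
#' @return A list with `samples` (data.frame: `name`, `cast`, `depth`,
#'   `delta_ntu`, `potential_temp`, `salinity`) and `truth` (data.frame:
#'   `name`, `depth`, `true_delta_ntu`, `true_category`).
#' @examples
#' cast <- gen_ctd_cast(seed = 1)
#' table(cast$truth$true_category)
#' @export
gen_ctd_cast <- function(seed,
                         depths = seq(2000, 3400, by = 50),
                         plume_depth = 2650,
                         plume_intensity = 0.5,
                         plume_width = 100,
                         background_ntu = 0.005,
                         noise_sd = 0.002) {
  stopifnot(plume_intensity >= 0, noise_sd >= 0)
  with_stream(seed, 101L, {
    n <- length(depths)
    anomaly <- plume_intensity *
      exp(-(depths - plume_depth)^2 / (2 * plume_width^2))
    background <- abs(stats::rnorm(n, background_ntu, noise_sd))
    observed <- background + anomaly
    true_signal <- background_ntu + anomaly
    samples <- data.frame(
      name = sprintf("synthCTD_b%02d", seq_len(n)),
      cast = "synthCTD",
      depth = depths,
      delta_ntu = observed,
      potential_temp = round(2.9 - 3e-4 * (depths - min(depths)) +
                               stats::rnorm(n, 0, 0.02), 3),
      salinity = round(34.93 + stats::rnorm(n, 0, 0.01), 3),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      name = samples$name,
      depth = depths,
      true_delta_ntu = true_signal,
      true_category = classify_turbidity(true_signal),
      stringsAsFactors = FALSE)
    list(samples = samples, truth = truth)
  })
}

#' Generate a mock community with known gene carriage
#'
#' Builds `n_genomes` genomes, each with 16 single-copy ribosomal markers
#' and a taxon label; every genome carries each functional gene family
#' independently with its carriage probability, and genome coverages are
#' drawn log-normally. Observed depths are sums over carrying genomes of
#' their coverage; optional multiplicative noise can be added per observed
#' depth. Default carriage fractions follow gene carriage observed in
#' non-buoyant plume communities (coxS 0.51, NiFe-hydrogenase 0.38,
#' soxY 0.25).
#'
#' @param seed Master seed.
#' @param n_genomes Number of genomes.
#' @param carriage_fractions Named vector of per-family carriage
#'   probabilities in \[0, 1\].
#' @param coverage_meanlog,coverage_sdlog Log-normal coverage parameters.
#' @param noise_sd Multiplicative log-normal noise sd on observed depths
#'   (0 = noise-free, the default: depth tables are aggregated means).
#' @param taxa Taxon labels to assign to genomes.
#' @param taxa_probs Sampling probabilities for `taxa`.
#' @return A list with `genes` (data.frame: `sample`, `gene_family`,
#'   `taxon`, `depth`), `markers` (data.frame: `sample`, `marker`, `depth`;
#'   16 rows), and `truth` (list: `genomes` data.frame with per-genome
#'   coverage/taxon/carriage flags, `carriage_realized`,
#'   `carriage_weighted`, `total_coverage`).
#' @examples
#' mock <- gen_mock_community(seed = 1, n_genomes = 100)
#' mock$truth$carriage_realized
#' @export
gen_mock_community <- function(seed,
                               n_genomes = 500,
                               carriage_fractions = c(coxS = 0.51,
                                                      nife_hydrogenase = 0.38,
                                                      soxY = 0.25),
                               coverage_meanlog = 1,
                               coverage_sdlog = 0.5,
                               noise_sd = 0,
                               taxa = c("SUP05", "Sulfurimonas", "SAR324",
                                        "SAR202", "other"),
                               taxa_probs = c(0.30, 0.25, 0.20, 0.10, 0.15)) {
  stopifnot(n_genomes >= 1,
            all(carriage_fractions >= 0), all(carriage_fractions <= 1),
            coverage_sdlog >= 0, noise_sd >= 0)
  with_stream(seed, 202L, {
    coverage <- stats::rlnorm(n_genomes, coverage_meanlog, coverage_sdlog)
    taxon <- sample(taxa, n_genomes, replace = TRUE, prob = taxa_probs)
    carrier <- vapply(carriage_fractions, function(p)
      stats::runif(n_genomes) < p, logical(n_genomes))
    carrier <- matrix(carrier, nrow = n_genomes,
                      dimnames = list(NULL, names(carriage_fractions)))
    noisy <- function(x) {
      if (noise_sd > 0) x * stats::rlnorm(length(x), 0, noise_sd) else x
    }
    genes <- do.call(rbind, lapply(names(carriage_fractions), function(fam) {
      depth_by_taxon <- tapply(coverage * carrier[, fam], taxon, sum)
      depth_by_taxon[is.na(depth_by_taxon)] <- 0
      data.frame(sample = "mock", gene_family = fam,
                 taxon = names(depth_by_taxon),
                 depth = noisy(as.numeric(depth_by_taxon)),
                 stringsAsFactors = FALSE)
    }))
    rownames(genes) <- NULL
    marker_names <- c("rpL2", "rpL3", "rpL4", "rpL5", "rpL6", "rpL14",
                      "rpL15", "rpL16", "rpL18", "rpL22", "rpL24", "rpS3",
                      "rpS8", "rpS10", "rpS17", "rpS19")
    markers <- data.frame(sample = "mock", marker = marker_names,
                          depth = noisy(rep(sum(coverage), 16L)),
                          stringsAsFactors = FALSE)
    genomes <- data.frame(genome = sprintf("g%04d", seq_len(n_genomes)),
                          taxon = taxon, coverage = coverage,
                          stringsAsFactors = FALSE)
    genomes <- cbind(genomes, as.data.frame(carrier))
    truth <- list(
      genomes = genomes,
      carriage_realized = colMeans(carrier),
      carriage_weighted = colSums(coverage * carrier) / sum(coverage),
      total_coverage = sum(coverage))
    list(genes = genes, markers = markers, truth = truth)
  })
}

# Random amino-acid sequence guaranteed to contain neither coxL motif.
random_protein <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  repeat {
    s <- paste(sample(aa, n, replace = TRUE), collapse = "")
    if (scan_motif(s)$form == "none") return(s)
  }
}

# Plant a motif at a random interior position; rejection-sample until the
# scanner reports exactly the intended form.
plant_motif <- function(n, motif) {
  want <- scan_motif(paste0("GG", motif, "GG"))$form
  repeat {
    s <- random_protein(n)
    pos <- sample.int(n - nchar(motif) - 1L, 1L) + 1L
    planted <- paste0(substr(s, 1L, pos - 1L), motif,
                      substr(s, pos + nchar(motif), n))
    if (scan_motif(planted)$form == want) return(planted)
  }
}

# Flip gene coordinates onto the reverse strand of a contig of given length.
flip_genes <- function(genes, contig_length) {
  flipped <- genes
  flipped$start <- contig_length - genes$end + 1L
  flipped$end <- contig_length - genes$start + 1L
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  flipped
}

#' Generate cox operon fixtures with planted motifs and subunit orders
#'
#' Plants, per seed, `n_per_class` operons of each of the four
#' classification outcomes — `form_II` (S-L-M order, coxL with the AYRGAGR
#' motif), `putative_form_I` (S-L-M, coxL with the AY-x-CSFR motif),
#' `partial` (L-S only), and `unknown` (S-L-M, motif-free coxL) — plus
#' contigs holding two cox genes far beyond the gap threshold (singletons:
#' zero operons expected). Background sequence is rejection-sampled to
#' contain neither motif. Some form II fixtures carry accessory coxD/E/F/G
#' genes elsewhere on the contig, outside the operon. When
#' `include_flipped` is TRUE every fixture contig is duplicated with
#' coordinates and strands reverse-complement-flipped, exercising classifier
#' strand invariance.
#'
#' @param seed Master seed.
#' @param n_per_class Operon fixtures per class (default 5: 20 labelled
#'   operons per seed before flipping).
#' @param protein_length Amino acids per synthetic protein.
#' @param intergenic_gap Gap between operon genes in bp (must be below the
#'   detector's threshold).
#' @param include_flipped Add the strand-flipped duplicate of every contig.
#' @return A list with `genes` (annotation data.frame as for
#'   [detect_operons()]), `proteins` (named character vector), and `truth`
#'   (data.frame: `contig`, `true_class`, `flipped`; singleton contigs have
#'   class `"singleton"`).
#' @examples
#' fx <- gen_operon_fixtures(seed = 1, n_per_class = 2)
#' table(fx$truth$true_class)
#' @export
gen_operon_fixtures <- function(seed,
                                n_per_class = 5,
                                protein_length = 150,
                                intergenic_gap = 50,
                                include_flipped = TRUE) {
  with_stream(seed, 303L, {
    classes <- c("form_II", "putative_form_I", "partial", "unknown")
    gene_rows <- list()
    proteins <- character(0)
    truth_rows <- list()
    pid <- 0L
    next_pid <- function() {
      pid <<- pid + 1L
      sprintf("prot_%04d", pid)
    }
    glen <- 3L * protein_length + 3L

    add_contig <- function(contig, roles, seqs, true_class,
                           accessory = character(0)) {
      strand <- sample(c("+", "-"), 1L)
      starts <- 101L + (seq_along(roles) - 1L) * (glen + intergenic_gap)
      ids <- vapply(roles, function(.) next_pid(), character(1))
      rows <- data.frame(contig = contig, start = starts,
                         end = starts + glen - 1L, strand = "+",
                         role = roles, protein_id = ids,
                         stringsAsFactors = FALSE)
      # accessory genes live far from the operon (beyond the gap threshold)
      if (length(accessory)) {
        acc_start <- max(rows$end) + 2000L +
          (seq_along(accessory) - 1L) * (glen + 600L)
        acc_ids <- vapply(accessory, function(.) next_pid(), character(1))
        rows <- rbind(rows, data.frame(
          contig = contig, start = acc_start, end = acc_start + glen - 1L,
          strand = "+", role = accessory, protein_id = acc_ids,
          stringsAsFactors = FALSE))
        seqs <- c(seqs, vapply(accessory, function(.)
          random_protein(protein_length), character(1)))
      }
      # genes were laid out in transcription order; realise the strand
      if (strand == "-") {
        contig_length <- max(rows$end) + 100L
        rows <- flip_genes(rows, contig_length)
      }
      gene_rows[[length(gene_rows) + 1L]] <<- rows
      proteins[rows$protein_id] <<- seqs
      truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
        contig = contig, true_class = true_class, flipped = FALSE,
        stringsAsFactors = FALSE)
    }

    for (cls in classes) {
      for (i in seq_len(n_per_class)) {
        contig <- sprintf("ctg_%s_%02d", cls, i)
        if (cls == "form_II") {
          roles <- c("coxS", "coxL", "coxM")
          seqs <- c(random_protein(protein_length),
                    plant_motif(protein_length, "AYRGAGR"),
                    random_protein(protein_length))
          accessory <- if (i %% 2L == 1L) c("coxD", "coxE", "coxF") else
            character(0)
          add_contig(contig, roles, seqs, cls, accessory)
        } else if (cls == "putative_form_I") {
          wildcard <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], 1L)
          roles <- c("coxS", "coxL", "coxM")
          seqs <- c(random_protein(protein_length),
                    plant_motif(protein_length,
                                paste0("AY", wildcard, "CSFR")),
                    random_protein(protein_length))
          add_contig(contig, roles, seqs, cls)
        } else if (cls == "partial") {
          roles <- c("coxL", "coxS")
          seqs <- c(plant_motif(protein_length, "AYRGAGR"),
                    random_protein(protein_length))
          add_contig(contig, roles, seqs, cls)
        } else {
          roles <- c("coxS", "coxL", "coxM")
          seqs <- c(random_protein(protein_length),
                    random_protein(protein_length),
                    random_protein(protein_length))
          add_contig(contig, roles, seqs, cls)
        }
      }
    }
    # distant cox gene pairs: beyond the gap threshold, so never an operon
    for (i in seq_len(max(1L, n_per_class %/% 2L))) {
      contig <- sprintf("ctg_singleton_%02d", i)
      ids <- c(next_pid(), next_pid())
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        contig = contig, start = c(101L, 101L + glen + 5000L),
        end = c(100L + glen, 100L + 2L * glen + 5000L), strand = "+",
        role = c("coxL", "coxS"), protein_id = ids,
        stringsAsFactors = FALSE)
      proteins[ids] <- c(plant_motif(protein_length, "AYRGAGR"),
                         random_protein(protein_length))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        contig = contig, true_class = "singleton", flipped = FALSE,
        stringsAsFactors = FALSE)
    }

    genes <- do.call(rbind, gene_rows)
    truth <- do.call(rbind, truth_rows)

    if (include_flipped) {
      flipped <- lapply(unique(genes$contig), function(ctg) {
        sub <- genes[genes$contig == ctg, , drop = FALSE]
        contig_length <- max(sub$end) + 100L
        out <- flip_genes(sub, contig_length)
        out$contig <- paste0(ctg, "_rc")
        out
      })
      genes <- rbind(genes, do.call(rbind, flipped))
      truth_rc <- truth
      truth_rc$contig <- paste0(truth_rc$contig, "_rc")
      truth_rc$flipped <- TRUE
      truth <- rbind(truth, truth_rc)
    }
    rownames(genes) <- NULL
    rownames(truth) <- NULL
    list(genes = genes, proteins = proteins, truth = truth)
  })
}

#' Generate a synthetic transcriptome count table
#'
#' Draws feature lengths and true per-copy transcription rates, then counts:
#' multinomial over length-weighted rates at the given library size (or the
#' exact expected counts when `exact = TRUE`, for noise-free fixtures). A
#' random subset of features is labelled as the housekeeping reference set.
#'
#' @param seed Master seed.
#' @param n_features Number of features (>= 2).
#' @param library_size Total mapped fragments.
#' @param n_housekeeping Size of the housekeeping label set.
#' @param length_range Integer range to draw feature lengths from (bp).
#' @param rate_meanlog,rate_sdlog Log-normal parameters of the true rates.
#' @param exact If TRUE, counts are the exact expected values (possibly
#'   non-integer) instead of a multinomial draw.
#' @return A list with `counts` (data.frame: `feature_id`, `length`,
#'   `count`), `housekeeping` (character vector of feature ids), and `truth`
#'   (data.frame: `feature_id`, `length`, `true_rate`, `housekeeping`).
#' @examples
#' tx <- gen_transcriptome_counts(seed = 1, n_features = 10)
#' head(tx$counts)
#' @export
gen_transcriptome_counts <- function(seed,
                                     n_features = 50,
                                     library_size = 1e6,
                                     n_housekeeping = 5,
                                     length_range = c(500L, 3000L),
                                     rate_meanlog = 0,
                                     rate_sdlog = 1,
                                     exact = FALSE) {
  stopifnot(n_features >= 2, library_size > 0,
            n_housekeeping >= 1, n_housekeeping <= n_features)
  with_stream(seed, 404L, {
    lengths <- sample(seq(length_range[1L], length_range[2L]), n_features,
                      replace = TRUE)
    rates <- stats::rlnorm(n_features, rate_meanlog, rate_sdlog)
    probs <- rates * lengths / sum(rates * lengths)
    counts <- if (exact) probs * library_size else
      as.numeric(stats::rmultinom(1L, size = library_size, prob = probs))
    ids <- sprintf("feat_%03d", seq_len(n_features))
    hk <- sort(sample(ids, n_housekeeping))
    list(
      counts = data.frame(feature_id = ids, length = lengths, count = counts,
                          stringsAsFactors = FALSE),
      housekeeping = hk,
      truth = data.frame(feature_id = ids, length = lengths,
                         true_rate = rates, housekeeping = ids %in% hk,
                         stringsAsFactors = FALSE))
  })
}

#' Write synthetic fixtures to plain-text files
#'
#' Each writer emits the generated tables as tab-separated text (and, for
#' operon fixtures, GFF3 + protein FASTA), with the ground truth as a
#' separate machine-readable file, so generated data round-trip through the
#' parsers the pipeline uses on real inputs.
#'
#' @param x A generator result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @name synth-writers
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' @rdname synth-writers
#' @export
write_ctd_cast <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  invisible(c(
    samples = write_tsv(x$samples, file.path(dir, "ctd_samples.tsv")),
    truth = write_tsv(x$truth, file.path(dir, "ctd_truth.tsv"))))
}

#' @rdname synth-writers
#' @export
write_mock_community <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  invisible(c(
    genes = write_tsv(x$genes, file.path(dir, "gene_depths.tsv")),
    markers = write_tsv(x$markers, file.path(dir, "marker_depths.tsv")),
    truth = write_tsv(x$truth$genomes, file.path(dir, "genomes_truth.tsv"))))
}

#' @rdname synth-writers
#' @export
write_operon_fixtures <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, "cox_annotations.gff3")
  gr <- GenomicRanges::GRanges(
    seqnames = x$genes$contig,
    ranges = IRanges::IRanges(start = x$genes$start, end = x$genes$end),
    strand = x$genes$strand)
  gr$source <- "hydroplume"
  gr$type <- "CDS"
  gr$ID <- x$genes$protein_id
  gr$gene <- x$genes$role
  gr$phase <- 0L
  rtracklayer::export(gr, gff, format = "GFF3")
  faa <- file.path(dir, "cox_proteins.faa")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(x$proteins), faa)
  invisible(c(
    gff = gff, faa = faa,
    truth = write_tsv(x$truth, file.path(dir, "operon_truth.tsv"))))
}

#' @rdname synth-writers
#' @export
write_transcriptome_counts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hk <- file.path(dir, "housekeeping.txt")
  writeLines(x$housekeeping, hk)
  invisible(c(
    counts = write_tsv(x$counts, file.path(dir, "transcript_counts.tsv")),
    housekeeping = hk,
    truth = write_tsv(x$truth, file.path(dir, "transcriptome_truth.tsv"))))
}
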