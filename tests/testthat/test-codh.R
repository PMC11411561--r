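# brute-force sliding-window oracle for the two coxL motifs
oracle_scan <- function(seq) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_len(max(0, n - 6))) {
    win <- chars[i:(i + 6)]
    if (identical(win, strsplit("AYRGAGR", "")[[1]])) {
      return(list(form = "form_II", position = i))
    }
    if (win[1] == "A" && win[2] == "Y" && all(win[4:7] ==
                                              c("C", "S", "F", "R"))) {
      return(list(form = "form_I", position = i))
    }
  }
  list(form = "none", position = NA_integer_)
}

test_that("motif scanning finds the form II heptamer with 1-based position", {
  hit <- scan_motif("MKAYRGAGRLV")
  expect_equal(hit$form, "form_II")
  expect_equal(hit$motif, "AYRGAGR")
  expect_equal(hit$position, 3L)
  expect_equal(scan_motif("MKLV")$form, "none")
})

test_that("the form I pattern accepts any residue at its wildcard position", {
  expect_equal(scan_motif("GGAYXCSFRGG")$form, "form_I")
  for (w in c("A", "G", "R", "W")) {
    hit <- scan_motif(paste0("MM", "AY", w, "CSFR", "MM"))
    expect_equal(hit$form, "form_I")
    expect_equal(hit$position, 3L)
  }
})

test_that("scanner agrees with a brute-force oracle on planted sequences", {
  set.seed(99)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:30) {
    s <- paste(sample(aa, 60, replace = TRUE), collapse = "")
    motif <- sample(c("AYRGAGR", "AYPCSFR", ""), 1)
    if (nzchar(motif)) {
      pos <- sample(10:40, 1)
      s <- paste0(substr(s, 1, pos - 1), motif,
                  substr(s, pos + nchar(motif), 60))
    }
    expect_equal(scan_motif(s)[c("form", "position")],
                 oracle_scan(s)[c("form", "position")])
  }
})

test_that("motif scanning validates its alphabet", {
  expect_error(scan_motif("MKAY1GAGR"), "illegal characters")
  expect_error(scan_motif("MKAY GAGR"), "illegal characters")
  expect_equal(scan_motif("mkayrgagrlv")$form, "form_II")  # case-folded
})

test_that("operon detection groups same-strand cox genes within the gap", {
  g <- data.frame(contig = "c1",
                  start = c(101, 600, 1100),
                  end = c(550, 1050, 1550),
                  strand = "+",
                  role = c("coxS", "coxL", "coxM"),
                  protein_id = c("p1", "p2", "p3"))
  det <- detect_operons(g)
  expect_length(det$operons, 1L)
  expect_equal(det$operons[[1]]$structural_order, "S-L-M")
  expect_equal(nrow(det$singletons), 0L)

  pair <- data.frame(contig = "c2", start = c(101, 600), end = c(550, 1050),
                     strand = "+", role = c("coxL", "coxS"),
                     protein_id = c("q1", "q2"))
  expect_equal(detect_operons(pair)$operons[[1]]$structural_order, "L-S")
})

test_that("genes beyond the gap threshold stay singletons, never operons", {
  far <- data.frame(contig = "c1", start = c(101, 5601),
                    end = c(550, 6050), strand = "+",
                    role = c("coxL", "coxS"), protein_id = c("p1", "p2"))
  det <- detect_operons(far)
  expect_length(det$operons, 0L)
  expect_equal(nrow(det$singletons), 2L)
  # a 500 bp gap is still within the default threshold
  near <- far
  near$start[2] <- 550 + 500 + 1
  near$end[2] <- near$start[2] + 449
  expect_length(detect_operons(near)$operons, 1L)
})

test_that("minus-strand operons are read in transcription order", {
  g <- data.frame(contig = "c1",
                  start = c(101, 600, 1100),
                  end = c(550, 1050, 1550),
                  strand = "-",
                  role = c("coxM", "coxL", "coxS"),  # genomic order
                  protein_id = c("p1", "p2", "p3"))
  op <- detect_operons(g)$operons[[1]]
  expect_equal(op$structural_order, "S-L-M")
  expect_equal(op$genes$protein_id, c("p3", "p2", "p1"))
})

test_that("classification follows structure-then-motif decision order", {
  proteins <- c(pS = "MKLMNP", pM = "MKLMNP",
                pL2 = "MKAYRGAGRLV", pL1 = "MKAYPCSFRLV", pL0 = "MKLMNPQ")
  mk <- function(roles, ids) {
    g <- data.frame(contig = "c", start = 101 + 500 * (seq_along(roles) - 1),
                    end = 550 + 500 * (seq_along(roles) - 1), strand = "+",
                    role = roles, protein_id = ids)
    detect_operons(g)$operons[[1]]
  }
  full2 <- classify_operon(mk(c("coxS", "coxL", "coxM"),
                              c("pS", "pL2", "pM")), proteins)
  expect_equal(full2$form, "form_II")
  expect_equal(full2$order_evidence, "S-L-M")
  expect_equal(full2$motif_evidence, "AYRGAGR")

  full1 <- classify_operon(mk(c("coxS", "coxL", "coxM"),
                              c("pS", "pL1", "pM")), proteins)
  expect_equal(full1$form, "putative_form_I")

  # an L-S pair is partial even when coxL carries the form II motif
  part <- classify_operon(mk(c("coxL", "coxS"), c("pL2", "pS")), proteins)
  expect_equal(part$form, "partial")
  expect_equal(part$motif_evidence, "AYRGAGR")

  unk <- classify_operon(mk(c("coxS", "coxL", "coxM"),
                            c("pS", "pL0", "pM")), proteins)
  expect_equal(unk$form, "unknown")

  expect_error(
    classify_operon(mk(c("coxS", "coxL", "coxM"), c("pS", "missing", "pM")),
                    proteins),
    "missing protein")
})

test_that("accessory genes are evidence only and may sit outside the operon", {
  g <- data.frame(
    contig = "c",
    start = c(101, 700, 1300, 9000),
    end = c(600, 1200, 1800, 9500),
    strand = "+",
    role = c("coxS", "coxL", "coxM", "coxF"),
    protein_id = c("pS", "pL", "pM", "pF"))
  proteins <- c(pS = "MKL", pL = "MKAYRGAGRLV", pM = "MKL", pF = "MKL")
  out <- classify_codh(g, proteins)
  expect_equal(nrow(out), 1L)  # the distant coxF is not part of the operon
  expect_equal(out$form, "form_II")
  expect_equal(out$accessory, "F")  # but it is reported as genome evidence
  out_local <- classify_codh(g, proteins, genome_wide_accessory = FALSE)
  expect_equal(out_local$accessory, "")
})

test_that("classification is independent of gene listing order", {
  fx <- gen_operon_fixtures(seed = 21, n_per_class = 2)
  base <- classify_codh(fx$genes, fx$proteins)
  set.seed(1)
  shuffled <- fx$genes[sample(nrow(fx$genes)), ]
  out <- classify_codh(shuffled, fx$proteins)
  key <- function(d) d[order(d$contig, d$start), , drop = FALSE]
  expect_equal(key(out)$form, key(base)$form)
  expect_equal(key(out)$contig, key(base)$contig)
})

test_that("planted fixtures are recovered perfectly, including strand flips", {
  fx <- gen_operon_fixtures(seed = 7, n_per_class = 3)
  out <- classify_codh(fx$genes, fx$proteins)
  truth <- fx$truth[fx$truth$true_class != "singleton", ]
  expect_setequal(out$contig, truth$contig)
  m <- match(out$contig, truth$contig)
  expect_equal(out$form, truth$true_class[m])
  # strand-flipped duplicates classify identically to their originals
  rc <- out[grepl("_rc$", out$contig), ]
  orig <- out[match(sub("_rc$", "", rc$contig), out$contig), ]
  expect_equal(rc$form, orig$form)
  expect_equal(rc$structural_order, orig$structural_order)
})

test_that("operon fixtures round-trip through GFF3 and FASTA files", {
  fx <- gen_operon_fixtures(seed = 13, n_per_class = 1)
  dir <- tempfile("operons")
  files <- write_operon_fixtures(fx, dir)
  out_files <- codh_from_files(files[["gff"]], files[["faa"]])
  out_mem <- classify_codh(fx$genes, fx$proteins)
  key <- function(d) d[order(d$contig, d$start),
                       c("contig", "strand", "structural_order", "form")]
  expect_equal(key(out_files), key(out_mem), ignore_attr = TRUE)
})
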