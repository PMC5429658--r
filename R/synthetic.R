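#' @name synthetic
#' @title Synthetic cohort generation
#' @description
#' Seeded generators for everything the screen and assay modules consume:
#' a multi-chromosome genome whose transcripts carry spliced 5' UTRs on
#' both strands with planted quadruplex loci of known architecture, a
#' mutation cohort with known effect classes, melt curves and qPCR tables.
#' All fixtures are pure functions of their seed, so identical seeds give
#' byte-identical output files.
NULL

.planted_classes <- c("tetrad_loss", "loop_lengthening",
                      "loop_shortening_via_new_run", "tetrad_gain",
                      "neutral_flank", "non_overlapping")

# background sequence: i.i.d.-ish with G ~ 0.2, but never two consecutive
# Gs and never a G at either boundary, so planted runs stay the only runs
# and re-enumeration windows see no confounding guanine pairs
.background <- function(len) {
  if (len == 0L) return("")
  chars <- character(len)
  prev_g <- TRUE                       # forbid G at first position
  for (i in seq_len(len)) {
    pool <- if (prev_g || i == len) c("A", "C", "U") else c("A", "C", "G", "U")
    p <- if (length(pool) == 4L) c(0.3, 0.25, 0.2, 0.25) else c(0.4, 0.3, 0.3)
    chars[i] <- sample(pool, 1L, prob = p)
    prev_g <- chars[i] == "G"
  }
  paste(chars, collapse = "")
}

.loop <- function(len) paste(sample(c("A", "C", "U"), len, TRUE,
                                    prob = c(0.4, 0.3, 0.3)), collapse = "")

# Each architecture builder returns: seq (RNA), locus start/end within seq
# (the expected quadparser span), mut_offset within seq, rna_ref, rna_alt,
# expected class and mechanism.
.arch_tetrad_loss <- function() {
  l <- sample(1:5, 3L, replace = TRUE)
  seq <- paste0("GGG", .loop(l[1]), "GGGG", .loop(l[2]), "GGG",
                .loop(l[3]), "GGG")
  list(seq = seq, locus = c(1L, nchar(seq)),
       mut_offset = 3L + l[1] + 3L,          # third G of the 4-G run
       rna_ref = "G", rna_alt = "A",
       class = "destabilising", mechanism = "tetrad_loss")
}

.arch_loop_lengthening <- function() {
  l <- sample(1:2, 3L, replace = TRUE)
  d <- sample(2:3, 1L)
  seq <- paste0("GGG", .loop(l[1]), "GGG", .loop(l[2]), "GGG",
                .loop(l[3]), "GGG", .loop(d), "GGG")
  list(seq = seq, locus = c(1L, 12L + sum(l)),  # first four runs
       mut_offset = 3L + l[1] + 2L,             # middle G of run 2
       rna_ref = "G", rna_alt = "A",
       class = "destabilising", mechanism = "loop_lengthening")
}

.arch_loop_shortening <- function() {
  p <- sample(1:2, 1L); q <- sample(1:2, 1L)
  l <- sample(3:5, 2L, replace = TRUE)
  seq <- paste0("GGG", .loop(p), "GG", "A", .loop(q), "GGG",
                .loop(l[1]), "GGG", .loop(l[2]), "GGG")
  list(seq = seq, locus = c(1L, nchar(seq)),
       mut_offset = 3L + p + 3L,               # the A after the loop GG
       rna_ref = "A", rna_alt = "G",
       class = "stabilising", mechanism = "loop_shortening")
}

.arch_tetrad_gain <- function() {
  l <- sample(1:3, 3L, replace = TRUE)
  seq <- paste0("GGGG", .loop(l[1]), "GGGG", .loop(l[2]), "GGG", "U",
                .loop(l[3]), "GGGG")
  list(seq = seq, locus = c(1L, nchar(seq)),
       mut_offset = 8L + l[1] + 3L + l[2] + 1L, # the U after the 3-G run
       rna_ref = "U", rna_alt = "G",
       class = "stabilising", mechanism = "tetrad_gain")
}

.arch_neutral <- function() {
  l <- sample(2:4, 3L, replace = TRUE)
  loops <- vapply(l, .loop, "")
  seq <- paste0("GGG", loops[1], "GGG", loops[2], "GGG", loops[3], "GGG")
  k <- sample(seq_len(l[1]), 1L)
  ref <- substr(loops[1], k, k)
  alt <- sample(setdiff(c("A", "C", "U"), ref), 1L)
  list(seq = seq, locus = c(1L, nchar(seq)),
       mut_offset = 3L + k, rna_ref = ref, rna_alt = alt,
       class = "neutral", mechanism = "none")
}

.build_arch <- function(class) {
  switch(class,
         tetrad_loss = .arch_tetrad_loss(),
         loop_lengthening = .arch_loop_lengthening(),
         loop_shortening_via_new_run = .arch_loop_shortening(),
         tetrad_gain = .arch_tetrad_gain(),
         stop("unknown planted class: ", class))
}

.rna_to_dna <- function(seq) chartr("U", "T", seq)
.revcomp <- function(dna)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))

#' Generate a synthetic screening cohort
#'
#' Builds a genome (one chromosome per transcript), transcript models with
#' spliced 5' UTRs on both strands, planted quadruplex loci, and a somatic
#' SNV cohort in which every mutation has a known intended effect class.
#' Planted loci satisfy the quadparser motif; loop-lengthening plants
#' include a fifth G-run a few nucleotides downstream of the locus (so the
#' quadruplex can shift onto it once a run is disrupted), tetrad-gain
#' plants put a U next to a three-guanine run inside a four-tetrad-capable
#' locus, and loop-shortening plants carry two successive guanines plus a
#' mutable A in the first loop. Background sequence is guanine-poor (no GG
#' dinucleotides outside planted loci) so the planted loci are provably the
#' only quadparser matches; the generator audits this by scanning every UTR
#' and errors if the audit fails. VCF records are expressed on the plus
#' strand (complemented from the planted RNA-space change for minus-strand
#' transcripts).
#'
#' @param seed Integer seed; the only source of randomness.
#' @param n_transcripts Number of transcripts (one per chromosome).
#' @param strand_mix Fraction of transcripts on the minus strand.
#' @param n_mutations Total mutations across all classes.
#' @param class_mix Named numeric vector of proportions over the planted
#'   classes `r paste(.planted_classes, collapse=", ")`; default uniform.
#' @param spliced_fraction Fraction of transcripts whose 5' UTR is split
#'   across two exons.
#' @param out_dir If non-`NULL`, write `genome.fa`, `annotation.gff3`,
#'   `mutations.vcf` and `truth.tsv` there.
#' @return List with `genome` ([Biostrings::DNAStringSet]), `models`,
#'   `mutations` (data.frame), `truth` (data.frame with intended class and
#'   mechanism per mutation) and `files` (paths, if written).
#' @examples
#' cohort <- make_cohort(seed = 1, n_transcripts = 6, n_mutations = 12)
#' nrow(cohort$truth)
#' @export
make_cohort <- function(seed, n_transcripts = 100L, strand_mix = 0.5,
                        n_mutations = 200L, class_mix = NULL,
                        spliced_fraction = 0.5, out_dir = NULL) {
  set.seed(as.integer(seed))
  if (is.null(class_mix))
    class_mix <- stats::setNames(rep(1 / 6, 6), .planted_classes)
  if (!all(names(class_mix) %in% .planted_classes))
    stop("unknown class in class_mix: ",
         paste(setdiff(names(class_mix), .planted_classes), collapse = ", "))
  if (any(class_mix < 0) || sum(class_mix) <= 0)
    stop("class_mix proportions must be non-negative and sum to > 0")
  class_mix <- class_mix / sum(class_mix)

  # integer class counts: floor + largest remainders
  counts <- floor(class_mix * n_mutations)
  rem <- n_mutations - sum(counts)
  if (rem > 0) {
    extra <- order(class_mix * n_mutations - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  classes <- rep(names(counts), counts)

  locus_classes <- setdiff(.planted_classes, "non_overlapping")
  locus_muts <- which(classes %in% locus_classes)
  flank_muts <- which(classes == "non_overlapping")
  tx_of_locus <- rep_len(seq_len(n_transcripts), length(locus_muts))
  loci_per_tx <- tabulate(tx_of_locus, n_transcripts)
  if (any(loci_per_tx > 4L))
    stop("infeasible mix: more than 4 planted loci per transcript; ",
         "increase n_transcripts")
  tx_of_flank <- rep_len(seq_len(n_transcripts), length(flank_muts))

  flank_len <- 25L; gap_len <- 60L; pad_len <- 30L; intron_len <- 60L
  strands <- ifelse(stats::runif(n_transcripts) < strand_mix, "-", "+")
  spliced <- stats::runif(n_transcripts) < spliced_fraction

  genome <- character(n_transcripts)
  models <- vector("list", n_transcripts)
  truth_rows <- list()
  mut_rows <- list()

  for (t in seq_len(n_transcripts)) {
    tid <- sprintf("tx%03d", t)
    gid <- sprintf("gene%03d", t)
    chrom <- sprintf("chr%03d", t)
    mut_idx <- locus_muts[tx_of_locus == t]
    # assemble UTR in RNA space: flank [arch gap]* flank
    archs <- lapply(classes[mut_idx], function(cl) {
      if (cl == "neutral_flank") .arch_neutral() else .build_arch(cl)
    })
    pieces <- .background(flank_len)
    planted <- list()
    for (a in archs) {
      off0 <- nchar(pieces)
      pieces <- paste0(pieces, a$seq, .background(gap_len))
      planted[[length(planted) + 1L]] <-
        list(arch = a,
             locus = a$locus + off0,
             mut_offset = a$mut_offset + off0)
    }
    utr_rna <- paste0(pieces, .background(flank_len - 10L))
    # audit: the planted loci must be exactly the quadparser matches
    found <- scan_g4(utr_rna, g4_pattern("quadparser"), seq_id = tid)
    want <- if (length(planted))
      do.call(rbind, lapply(planted, function(p) p$locus)) else
      matrix(integer(), ncol = 2L)
    if (nrow(found) != nrow(want) ||
        (nrow(want) && !all(found$start == want[, 1L] & found$end == want[, 2L])))
      stop(sprintf("generation audit failed for %s: planted loci and scan disagree", tid))

    cds_rna <- paste0("AUG", .background(24L), "UAA")
    utr_dna <- .rna_to_dna(utr_rna)
    cds_dna <- .rna_to_dna(cds_rna)
    ulen <- nchar(utr_dna)
    split_at <- if (spliced[t]) sample(10:(ulen - 10L), 1L) else ulen
    e1 <- substr(utr_dna, 1L, split_at)
    e2 <- paste0(substr(utr_dna, split_at + 1L, ulen), cds_dna)
    pad5 <- .rna_to_dna(.background(pad_len))
    pad3 <- .rna_to_dna(.background(pad_len))
    intron <- if (spliced[t]) .rna_to_dna(.background(intron_len)) else ""

    if (strands[t] == "+") {
      chrom_seq <- paste0(pad5, e1, intron, e2, pad3)
      s1 <- pad_len + 1L
      ex1 <- c(s1, s1 + nchar(e1) - 1L)
      s2 <- ex1[2L] + nchar(intron) + 1L
      ex2 <- c(s2, s2 + nchar(e2) - 1L)
      exons <- if (spliced[t])
        IRanges::IRanges(c(ex1[1L], ex2[1L]), c(ex1[2L], ex2[2L])) else
        IRanges::IRanges(ex1[1L], ex2[2L])
      utr5 <- if (spliced[t])
        IRanges::IRanges(c(ex1[1L], ex2[1L]),
                         c(ex1[2L], ex2[1L] + (ulen - split_at) - 1L)) else
        IRanges::IRanges(ex1[1L], ex1[1L] + ulen - 1L)
      utr5 <- utr5[IRanges::width(utr5) > 0L]
      cds_start <- if (spliced[t]) ex2[1L] + (ulen - split_at) else ex1[1L] + ulen
    } else {
      # minus strand: plus-strand text is the reverse complement, exon
      # order reversed (transcript 5' end at the highest coordinate)
      chrom_seq <- paste0(pad5, .revcomp(e2), intron, .revcomp(e1), pad3)
      s2 <- pad_len + 1L
      ex2 <- c(s2, s2 + nchar(e2) - 1L)
      s1 <- ex2[2L] + nchar(intron) + 1L
      ex1 <- c(s1, s1 + nchar(e1) - 1L)
      exons <- if (spliced[t])
        IRanges::IRanges(c(ex2[1L], ex1[1L]), c(ex2[2L], ex1[2L])) else
        IRanges::IRanges(ex2[1L], ex1[2L])
      # UTR part of e2 occupies the high end of the revcomp(e2) interval
      utr5 <- if (spliced[t])
        IRanges::IRanges(c(ex2[2L] - (ulen - split_at) + 1L, ex1[1L]),
                         c(ex2[2L], ex1[2L])) else
        IRanges::IRanges(ex1[2L] - ulen + 1L, ex1[2L])
      utr5 <- utr5[IRanges::width(utr5) > 0L]
      cds_start <- if (spliced[t]) ex2[2L] - (ulen - split_at) else ex1[2L] - ulen
    }
    genome[t] <- chrom_seq
    model <- transcript_model(tid, gid, chrom, strands[t], exons, utr5, cds_start)
    models[[t]] <- model

    gmap <- utr_genomic_map(model)
    stopifnot(length(gmap) == ulen)
    emit <- function(offset, rna_ref, rna_alt, class, mech, planted_class,
                     locus) {
      gpos <- gmap[offset]
      if (strands[t] == "+") {
        ref <- .rna_to_dna(rna_ref); alt <- .rna_to_dna(rna_alt)
      } else {
        ref <- .rna_to_dna(.complement(rna_ref))
        alt <- .rna_to_dna(.complement(rna_alt))
      }
      list(mut = data.frame(
             chrom = chrom, pos = gpos, ref = ref, alt = alt,
             sample_id = sprintf("S%03d", sample.int(60L, 1L)),
             cancer_type = sample(c("melanoma", "lymphoma", "colon",
                                    "breast", "lung"), 1L),
             source = "synthetic", stringsAsFactors = FALSE),
           truth = data.frame(
             transcript_id = tid, chrom = chrom, pos = gpos,
             ref = ref, alt = alt, strand = strands[t],
             utr_offset = offset, planted_class = planted_class,
             expected_class = class, expected_mechanism = mech,
             locus_start = locus[1L], locus_end = locus[2L],
             stringsAsFactors = FALSE))
    }
    for (j in seq_along(planted)) {
      p <- planted[[j]]
      a <- p$arch
      r <- emit(p$mut_offset, a$rna_ref, a$rna_alt, a$class, a$mechanism,
                classes[mut_idx[j]], p$locus)
      mut_rows[[length(mut_rows) + 1L]] <- r$mut
      truth_rows[[length(truth_rows) + 1L]] <- r$truth
    }
    for (fm in flank_muts[tx_of_flank == t]) {
      offset <- sample(3:10, 1L)   # start flank, >= 15 nt from first locus
      ref <- substr(utr_rna, offset, offset)
      alt <- sample(setdiff(c("A", "C", "U"), ref), 1L)
      r <- emit(offset, ref, alt, "non_overlapping", "none",
                "non_overlapping", c(NA_integer_, NA_integer_))
      mut_rows[[length(mut_rows) + 1L]] <- r$mut
      truth_rows[[length(truth_rows) + 1L]] <- r$truth
    }
  }

  genome_ss <- Biostrings::DNAStringSet(genome)
  names(genome_ss) <- sprintf("chr%03d", seq_len(n_transcripts))
  mutations <- do.call(rbind, mut_rows)
  truth <- do.call(rbind, truth_rows)
  mutations$mutation_id <- sprintf("m%04d", seq_len(nrow(mutations)))
  truth$mutation_id <- mutations$mutation_id
  # generator self-check: planted RNA round-trips through the annotation
  for (t in seq_len(n_transcripts)) {
    u <- utr5_sequence(genome_ss, models[[t]])
    tr <- truth[truth$transcript_id == models[[t]]$transcript_id, ]
    if (!nrow(tr)) next
    ok <- substring(u$rna_seq, tr$utr_offset, tr$utr_offset) ==
      ifelse(tr$strand == "+", as_rna(tr$ref), .complement(as_rna(tr$ref)))
    if (!all(ok))
      stop("generation audit failed: UTR base does not match planted ref")
  }

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(genome = file.path(out_dir, "genome.fa"),
                  annotation = file.path(out_dir, "annotation.gff3"),
                  mutations = file.path(out_dir, "mutations.vcf"),
                  truth = file.path(out_dir, "truth.tsv"))
    Biostrings::writeXStringSet(genome_ss, files$genome)
    write_annotation(models, files$annotation)
    write_mutations_vcf(mutations, files$mutations)
    utils::write.table(truth, files$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(genome = genome_ss, models = models, mutations = mutations,
       truth = truth, files = files, seed = seed)
}

#' Write mutation records as VCF
#'
#' Emits a VCF 4.x file with `SAMPLE`, `CTYPE` and `SRC` INFO fields. The
#' `##fileDate` header line is omitted so output is a pure function of the
#' records.
#'
#' @param mutations data.frame as produced by [make_cohort()] /
#'   [read_mutations()].
#' @param path Output path.
#' @export
write_mutations_vcf <- function(mutations, path) {
  gr <- GenomicRanges::GRanges(mutations$chrom,
                               IRanges::IRanges(mutations$pos, width = 1L))
  names(gr) <- if ("mutation_id" %in% names(mutations))
    mutations$mutation_id else sprintf("m%04d", seq_len(nrow(mutations)))
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(mutations$ref),
    ALT = Biostrings::DNAStringSetList(as.list(mutations$alt)),
    QUAL = rep(NA_real_, nrow(mutations)),
    FILTER = rep("PASS", nrow(mutations)))
  info <- S4Vectors::DataFrame(SAMPLE = mutations$sample_id,
                               CTYPE = mutations$cancer_type,
                               SRC = mutations$source)
  hdr_info <- S4Vectors::DataFrame(
    Number = rep("1", 3L), Type = rep("String", 3L),
    Description = c("Sample identifier", "Cancer type", "Source dataset"),
    row.names = c("SAMPLE", "CTYPE", "SRC"))
  hdr <- VariantAnnotation::VCFHeader(samples = character())
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    META = S4Vectors::DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
  VariantAnnotation::info(hdr) <- hdr_info
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed, info = info,
                                collapsed = TRUE)
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  # drop volatile header lines so identical cohorts give identical bytes
  lines <- readLines(path)
  lines <- lines[!grepl("^##fileDate=", lines)]
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a CD melt curve
#'
#' Variable-slope logistic plus i.i.d. Gaussian noise on a 25-95 degC grid
#' at 1 degC steps (the standard melt protocol ramp).
#'
#' @param tm Midpoint temperature, inside the grid.
#' @param hill_slope Slope parameter (> 0 for a decreasing unfolding
#'   transition).
#' @param plateaus Length-2 vector `c(lower, upper)` signal plateaus.
#' @param noise_sd Gaussian noise SD in signal units.
#' @param grid Temperature grid, degC.
#' @param seed Integer seed.
#' @return A [melt_curve()].
#' @export
simulate_melt <- function(tm = 78, hill_slope = 0.4, plateaus = c(0, 1),
                          noise_sd = 0.02, grid = seq(25, 95, by = 1),
                          seed = 1L) {
  stopifnot(tm >= min(grid), tm <= max(grid))
  set.seed(as.integer(seed))
  y <- .melt_model(grid, tm, hill_slope, plateaus[1L], plateaus[2L]) +
    stats::rnorm(length(grid), 0, noise_sd)
  melt_curve(grid, y)
}

#' Simulate a qPCR crossing-point table
#'
#' Crossing-point differences solved from the Pfaffl model for a known
#' true ratio, plus Gaussian cycle noise. With `cp_noise_sd = 0`,
#' [pfaffl_ratio()] on any row recovers `true_ratio` exactly.
#'
#' @param true_ratio Target relative expression ratio (> 0).
#' @param e_target,e_reference Amplification efficiencies in (1, 2].
#' @param cp_noise_sd Gaussian SD added to each dCP, cycles.
#' @param n Number of replicates.
#' @param seed Integer seed.
#' @return data.frame with columns `replicate, e_target, e_reference,
#'   dcp_target, dcp_reference`.
#' @export
simulate_qpcr <- function(true_ratio, e_target = 2, e_reference = 2,
                          cp_noise_sd = 0.1, n = 6L, seed = 1L) {
  stopifnot(true_ratio > 0)
  set.seed(as.integer(seed))
  dcp_ref <- stats::runif(n, -1, 1)
  dcp_tgt <- (log(true_ratio) + dcp_ref * log(e_reference)) / log(e_target)
  data.frame(replicate = seq_len(n),
             e_target = e_target, e_reference = e_reference,
             dcp_target = dcp_tgt + stats::rnorm(n, 0, cp_noise_sd),
             dcp_reference = dcp_ref + stats::rnorm(n, 0, cp_noise_sd))
}
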