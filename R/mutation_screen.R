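#' Read somatic SNV records
#'
#' Reads single-nucleotide substitutions from a VCF (sample and cancer-type
#' metadata taken from INFO keys `SAMPLE`, `CTYPE`, `SRC` when present) or
#' from a tab-separated table with columns
#' `chrom, pos, ref, alt, sample_id, cancer_type, source`. Records that are
#' not single-base substitutions (indels, MNVs) are excluded with a logged
#' reason and returned in the `"excluded"` attribute, never silently
#' dropped.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return data.frame with columns `chrom, pos, ref, alt, sample_id,
#'   cancer_type, source`; attribute `excluded` holds the filtered rows.
#' @export
read_mutations <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  df <- if (format == "vcf") .read_vcf_mutations(path) else .read_tsv_mutations(path)
  is_snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    df$ref %in% c("A", "C", "G", "T") & df$alt %in% c("A", "C", "G", "T") &
    df$ref != df$alt
  excluded <- df[!is_snv, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- "not a single-base substitution"
    message(sprintf("read_mutations: excluded %d non-SNV record(s)", nrow(excluded)))
  }
  out <- df[is_snv, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

.read_vcf_mutations <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  altc <- vapply(seq_along(alt), function(i) {
    a <- alt[[i]]
    if (length(a)) as.character(a[[1L]]) else NA_character_
  }, "")
  info <- VariantAnnotation::info(vcf)
  getinfo <- function(key) {
    if (key %in% colnames(info)) as.character(info[[key]]) else
      rep(NA_character_, length(rr))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = as.character(VariantAnnotation::ref(vcf)),
             alt = altc,
             sample_id = getinfo("SAMPLE"),
             cancer_type = getinfo("CTYPE"),
             source = getinfo("SRC"),
             stringsAsFactors = FALSE)
}

.read_tsv_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "))
  for (opt in c("sample_id", "cancer_type", "source"))
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  df[c("chrom", "pos", "ref", "alt", "sample_id", "cancer_type", "source")]
}

.complement <- function(base) chartr("ACGTU", "UGCAA", base)

#' Apply a single-base substitution to a 5' UTR sequence
#'
#' @param utr A `utr_sequence` (see [utr5_sequence()]) or plain RNA string.
#' @param offset 1-based offset in the UTR (transcript orientation).
#' @param rna_ref,rna_alt Expected reference and alternate RNA bases on the
#'   transcript strand.
#' @return Mutated RNA string differing from the input at exactly `offset`.
#' @export
apply_mutation <- function(utr, offset, rna_ref, rna_alt) {
  seq <- if (inherits(utr, "utr_sequence")) utr$rna_seq else utr
  id <- if (inherits(utr, "utr_sequence")) utr$transcript_id else "seq"
  if (offset < 1L || offset > nchar(seq))
    stop(sprintf("%s: offset %d outside UTR (length %d)", id, offset, nchar(seq)))
  have <- substr(seq, offset, offset)
  if (have != rna_ref)
    stop(sprintf("%s: reference mismatch at offset %d (expected %s, UTR has %s)",
                 id, offset, rna_ref, have))
  if (rna_ref == rna_alt) stop("ref and alt are identical")
  substr(seq, offset, offset) <- rna_alt
  seq
}

.mechanisms <- c("tetrad_loss", "tetrad_gain", "loop_lengthening",
                 "loop_shortening", "g4_shift", "none")

#' Assess the stability change caused by a mutation at a G4 locus
#'
#' Re-enumerates candidate quadruplexes in a window around the wild-type
#' locus (the locus padded by `max_span` on each side, so a shift onto a
#' nearby fifth G-run is detectable), compares the top-scoring wild-type
#' and mutant decompositions, and classifies the change. Classification is
#' decomposition-first, mirroring how predicted-structure changes are read:
#' a tetrad-count change wins, then a total-loop-length change, then a
#' locus start shift; only when the decomposition is unchanged does the
#' score difference decide, with a dead-band of `theta` score units
#' preventing float-noise flips. When `fold` options are supplied, the full
#' wild-type and mutant UTRs are folded and the call is overridden to
#' destabilising if the mutant minimum-free-energy structure has lost a
#' quadruplex the wild-type had in the window.
#'
#' @param wt_utr,mut_utr Wild-type and mutant full-UTR RNA strings
#'   differing at one position.
#' @param locus One row of the wild-type quadparser candidate data.frame
#'   (UTR coordinates).
#' @param theta Neutral dead-band half-width in score units (default 5).
#' @param max_span Re-enumeration window padding / maximum candidate span.
#' @param pattern Enumeration pattern (default relaxed preset).
#' @param fold Optional [fold_options()]; `NULL` disables fold support.
#' @return A list of class `stability_verdict`: `class` (destabilising /
#'   stabilising / neutral), `mechanism`, `disrupted`, `delta_score`,
#'   `wt_best` / `mut_best` candidate rows (or `NULL`), `rule` (which rule
#'   fired: decomposition, score, or fold_override) and `fold_support`.
#' @export
assess_stability <- function(wt_utr, mut_utr, locus, theta = 5,
                             max_span = 45L, pattern = g4_pattern("relaxed"),
                             fold = NULL) {
  wt_utr <- if (inherits(wt_utr, "utr_sequence")) wt_utr$rna_seq else wt_utr
  mut_utr <- if (inherits(mut_utr, "utr_sequence")) mut_utr$rna_seq else mut_utr
  n <- nchar(wt_utr)
  wstart <- max(1L, locus$start - max_span)
  wend <- min(n, locus$end + max_span)
  wt_win <- substr(wt_utr, wstart, wend)
  mut_win <- substr(mut_utr, wstart, wend)
  wt_df <- enumerate_qgrs(wt_win, pattern, max_span)
  mut_df <- enumerate_qgrs(mut_win, pattern, max_span)
  loc_s <- locus$start - wstart + 1L
  loc_e <- locus$end - wstart + 1L
  wt_hit <- wt_df[wt_df$start <= loc_e & wt_df$end >= loc_s, , drop = FALSE]
  if (!nrow(wt_hit))
    stop("invalid locus: no wild-type candidate overlaps it")
  tmax <- max(3L, attr(wt_df, "tmax"), attr(mut_df, "tmax"), na.rm = TRUE)
  rescore <- function(row) g4_score(row$tetrads,
                                    c(row$loop1, row$loop2, row$loop3),
                                    tmax = tmax, max_loop = pattern$max_loop_len)
  wt_best <- wt_hit[1L, , drop = FALSE]
  wt_score <- rescore(wt_best)
  disrupted <- nrow(mut_df) == 0L
  mut_best <- if (disrupted) NULL else mut_df[1L, , drop = FALSE]
  mut_score <- if (disrupted) 0 else rescore(mut_best)
  delta <- if (disrupted) -wt_score else mut_score - wt_score

  rule <- "decomposition"
  if (disrupted) {
    class <- "destabilising"; mech <- "tetrad_loss"
  } else {
    dt <- mut_best$tetrads - wt_best$tetrads
    wl <- wt_best$loop1 + wt_best$loop2 + wt_best$loop3
    ml <- mut_best$loop1 + mut_best$loop2 + mut_best$loop3
    if (dt < 0L) { class <- "destabilising"; mech <- "tetrad_loss" }
    else if (dt > 0L) { class <- "stabilising"; mech <- "tetrad_gain" }
    else if (ml > wl) { class <- "destabilising"; mech <- "loop_lengthening" }
    else if (ml < wl) { class <- "stabilising"; mech <- "loop_shortening" }
    else if (mut_best$start != wt_best$start) {
      class <- "destabilising"; mech <- "g4_shift"
    } else {
      rule <- "score"
      mech <- "none"
      class <- if (delta > theta) "stabilising"
               else if (delta < -theta) "destabilising" else "neutral"
    }
  }

  fold_support <- NULL
  if (!is.null(fold)) {
    wt_fold <- fold_rna(wt_utr, fold)
    mut_fold <- fold_rna(mut_utr, fold)
    wt_g4 <- g4_present(wt_fold, c(wstart, wend))
    mut_g4 <- g4_present(mut_fold, c(wstart, wend))
    fold_support <- list(wt = wt_fold, mut = mut_fold,
                         wt_g4 = wt_g4, mut_g4 = mut_g4)
    if (wt_g4 && !mut_g4 && class != "destabilising") {
      class <- "destabilising"
      rule <- "fold_override"
    }
  }

  structure(list(class = class, mechanism = mech, disrupted = disrupted,
                 delta_score = delta, wt_best = wt_best, mut_best = mut_best,
                 wt_score = wt_score, mut_score = if (disrupted) NA_real_ else mut_score,
                 window = c(wstart, wend), rule = rule,
                 fold_support = fold_support),
            class = "stability_verdict")
}

#' @export
print.stability_verdict <- function(x, ...) {
  cat(sprintf("stability_verdict: %s (%s), delta_score %.2f%s [rule: %s]\n",
              x$class, x$mechanism, x$delta_score,
              if (x$disrupted) ", mutant G4 disrupted" else "", x$rule))
  invisible(x)
}

#' Screen somatic mutations against 5' UTR quadruplex loci
#'
#' The end-to-end in-silico screen: assembles each transcript's spliced
#' 5' UTR, finds quadparser loci, maps plus-strand SNVs into transcript
#' space (complementing ref/alt for minus-strand transcripts so all work
#' happens in mRNA space), intersects them with the loci, applies each
#' overlapping mutation in full-UTR context and assesses the stability
#' change with [assess_stability()]. Every input record is accounted for:
#' it is a reference mismatch, overlaps at least one locus (emitting one
#' hit per transcript and candidate), or is counted non-overlapping.
#'
#' @param genome [Biostrings::DNAStringSet] genome.
#' @param models List of [transcript_model()].
#' @param mutations data.frame as from [read_mutations()].
#' @param theta,max_span,fold Passed to [assess_stability()].
#' @param scan_pattern Locus discovery pattern (default quadparser preset).
#' @return An object of class `g4_screen`: `hits` (one row per mutation x
#'   transcript x candidate with verdict columns), `mutations` (inputs with
#'   a `category` column: hit / non_overlapping / ref_mismatch), per-UTR
#'   `candidates`, `utrs`, and summary `counts`.
#' @export
screen_mutations <- function(genome, models, mutations, theta = 5,
                             max_span = 45L, fold = NULL,
                             scan_pattern = g4_pattern("quadparser")) {
  models <- Filter(function(m) m$has_utr5, models)
  utrs <- lapply(models, function(m) utr5_sequence(genome, m))
  names(utrs) <- vapply(models, `[[`, "", "transcript_id")
  cands <- lapply(seq_along(models), function(i)
    scan_g4(utrs[[i]]$rna_seq, scan_pattern,
            seq_id = models[[i]]$transcript_id))
  names(cands) <- names(utrs)
  by_chrom <- split(seq_along(models),
                    vapply(models, `[[`, "", "chrom"))

  mutations$category <- "non_overlapping"
  hit_rows <- list()
  for (k in seq_len(nrow(mutations))) {
    mut <- mutations[k, ]
    gref <- tryCatch(.genome_subseq(genome, mut$chrom, mut$pos, mut$pos),
                     error = function(e) NA_character_)
    if (is.na(gref) || gref != mut$ref) {
      mutations$category[k] <- "ref_mismatch"
      next
    }
    for (i in by_chrom[[mut$chrom]]) {
      m <- models[[i]]
      off <- genome_to_transcript(m, mut$pos)
      if (is.na(off)) next
      if (m$strand == "-") {
        rna_ref <- .complement(as_rna(mut$ref))
        rna_alt <- .complement(as_rna(mut$alt))
      } else {
        rna_ref <- as_rna(mut$ref)
        rna_alt <- as_rna(mut$alt)
      }
      cd <- cands[[m$transcript_id]]
      if (!nrow(cd)) next
      over <- which(cd$start <= off & cd$end >= off)
      for (ci in over) {
        locus <- cd[ci, , drop = FALSE]
        mut_seq <- apply_mutation(utrs[[i]], off, rna_ref, rna_alt)
        v <- assess_stability(utrs[[i]]$rna_seq, mut_seq, locus,
                              theta = theta, max_span = max_span, fold = fold)
        mutations$category[k] <- "hit"
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          mutation_id = k, chrom = mut$chrom, pos = mut$pos,
          ref = mut$ref, alt = mut$alt,
          sample_id = mut$sample_id, cancer_type = mut$cancer_type,
          transcript_id = m$transcript_id, strand = m$strand,
          utr_offset = off, rna_ref = rna_ref, rna_alt = rna_alt,
          locus_start = locus$start, locus_end = locus$end,
          wt_tetrads = v$wt_best$tetrads,
          mut_tetrads = if (v$disrupted) NA_integer_ else v$mut_best$tetrads,
          wt_loops = v$wt_best$loop1 + v$wt_best$loop2 + v$wt_best$loop3,
          mut_loops = if (v$disrupted) NA_integer_ else
            v$mut_best$loop1 + v$mut_best$loop2 + v$mut_best$loop3,
          delta_score = v$delta_score, disrupted = v$disrupted,
          class = v$class, mechanism = v$mechanism, rule = v$rule,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(mutation_id = integer(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), sample_id = character(),
               cancer_type = character(), transcript_id = character(),
               strand = character(), utr_offset = integer(),
               rna_ref = character(), rna_alt = character(),
               locus_start = integer(), locus_end = integer(),
               wt_tetrads = integer(), mut_tetrads = integer(),
               wt_loops = integer(), mut_loops = integer(),
               delta_score = numeric(), disrupted = logical(),
               class = character(), mechanism = character(),
               rule = character(), stringsAsFactors = FALSE)
  hits <- hits[order(hits$chrom, hits$pos, hits$transcript_id,
                     hits$locus_start), , drop = FALSE]
  rownames(hits) <- NULL
  counts <- list(
    n_input = nrow(mutations),
    n_hit_mutations = sum(mutations$category == "hit"),
    n_non_overlapping = sum(mutations$category == "non_overlapping"),
    n_ref_mismatch = sum(mutations$category == "ref_mismatch"),
    n_hits = nrow(hits),
    n_destabilising = sum(hits$class == "destabilising"),
    n_stabilising = sum(hits$class == "stabilising"),
    n_neutral = sum(hits$class == "neutral"),
    n_disrupted = sum(hits$disrupted),
    n_distinct_mutations = length(unique(paste(hits$chrom, hits$pos,
                                               hits$ref, hits$alt))))
  # recurrence: distinct samples per mutated position, reported not used
  recurrence <- if (nrow(hits)) {
    key <- paste(hits$chrom, hits$pos, sep = ":")
    tab <- tapply(hits$sample_id, key, function(s) length(unique(s)))
    data.frame(position = names(tab), n_samples = as.integer(tab),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(position = character(), n_samples = integer())
  structure(list(hits = hits, mutations = mutations, candidates = cands,
                 utrs = utrs, counts = counts, recurrence = recurrence,
                 theta = theta, max_span = max_span),
            class = "g4_screen")
}

#' @export
print.g4_screen <- function(x, ...) {
  c <- x$counts
  cat(sprintf(paste0("g4_screen: %d mutation(s) screened against %d UTR(s)\n",
                     "  overlaps: %d hit row(s) from %d mutation(s); ",
                     "%d non-overlapping; %d ref-mismatch\n",
                     "  classes: %d destabilising (%d disrupted), ",
                     "%d stabilising, %d neutral\n"),
              c$n_input, length(x$utrs), c$n_hits, c$n_hit_mutations,
              c$n_non_overlapping, c$n_ref_mismatch, c$n_destabilising,
              c$n_disrupted, c$n_stabilising, c$n_neutral))
  invisible(x)
}

#' @export
summary.g4_screen <- function(object, ...) {
  out <- list(counts = object$counts,
              spectrum = mutation_spectrum(object),
              recurrence = object$recurrence)
  class(out) <- "summary.g4_screen"
  out
}

#' @export
print.summary.g4_screen <- function(x, ...) {
  utils::str(x$counts, give.head = FALSE)
  cat("\nMutation spectrum (RNA alphabet):\n")
  print(x$spectrum)
  invisible(x)
}

#' Mutation-type spectrum per stability class
#'
#' Frequency table of transcript-strand RNA base changes within each
#' stability class, annotated as transition or transversion. Mirrors the
#' cohort-level observation that destabilising changes are dominated by
#' G-to-A transitions and stabilising ones by U-to-G transversions.
#'
#' @param x A `g4_screen` or a hits data.frame with `rna_ref`, `rna_alt`,
#'   `class` columns.
#' @return data.frame with `class`, `change`, `count`, `fraction`, `type`.
#' @export
mutation_spectrum <- function(x) {
  hits <- if (inherits(x, "g4_screen")) x$hits else x
  if (!nrow(hits))
    return(data.frame(class = character(), change = character(),
                      count = integer(), fraction = numeric(),
                      type = character(), stringsAsFactors = FALSE))
  purine <- c("A", "G")
  rows <- list()
  for (cl in unique(hits$class)) {
    h <- hits[hits$class == cl, ]
    tab <- table(paste0(h$rna_ref, ">", h$rna_alt))
    for (ch in names(tab)) {
      b <- strsplit(ch, ">", fixed = TRUE)[[1L]]
      type <- if ((b[1L] %in% purine) == (b[2L] %in% purine))
        "transition" else "transversion"
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, change = ch, count = as.integer(tab[[ch]]),
        fraction = as.integer(tab[[ch]]) / nrow(h), type = type,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$class, -out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}
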