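#' Transcript model
#'
#' Strand-aware exon/5' UTR structure of one transcript, the unit on which
#' the screen operates. All coordinates are 1-based closed genomic
#' positions; exons and UTR intervals are [IRanges::IRanges] sorted by
#' genomic position, and the 5' UTR must lie within the exons. On the minus
#' strand the transcript 5' end corresponds to the highest genomic
#' coordinate.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,utr5 [IRanges::IRanges] of genomic intervals.
#' @param cds_start Genomic position of the first CDS base (transcript
#'   orientation), or `NA`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exons, utr5, cds_start = NA_integer_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(IRanges::start(exons))]
  utr5 <- utr5[order(IRanges::start(utr5))]
  if (length(exons) > 1L && any(IRanges::start(exons)[-1L] <=
                                utils::head(IRanges::end(exons), -1L)))
    stop(sprintf("transcript %s: overlapping exons", transcript_id))
  if (length(utr5)) {
    cov <- IRanges::setdiff(utr5, exons)
    if (length(cov))
      stop(sprintf("transcript %s: 5' UTR interval outside exons", transcript_id))
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, utr5 = utr5,
                 cds_start = cds_start, has_utr5 = length(utr5) > 0L),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%s strand %s, %d exon(s), 5'UTR %d nt\n",
              x$transcript_id, x$gene_id, x$chrom,
              paste0(min(IRanges::start(x$exons)), "-", max(IRanges::end(x$exons))),
              x$strand, length(x$exons), sum(IRanges::width(x$utr5))))
  invisible(x)
}

#' Read transcript annotation
#'
#' Reads GFF3 (using `five_prime_UTR`, `exon`, `CDS` and `mRNA` features)
#' or BED12 (deriving the 5' UTR from `thickStart`/`thickEnd`) into
#' [transcript_model()] objects. Transcripts without a 5' UTR are returned
#' with `has_utr5 = FALSE` and are skipped by the screen.
#'
#' @param path File path (plain or gzipped).
#' @param format `"auto"` (by extension), `"gff3"` or `"bed12"`.
#' @return List of `transcript_model`.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed12" else "gff3"
  if (format == "gff3") .read_gff3_models(path) else .read_bed12_models(path)
}

.read_gff3_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  tx <- gr[type %in% c("mRNA", "transcript")]
  lapply(seq_along(tx), function(i) {
    tid <- tx$ID[i]
    gid <- if (!is.null(tx$Parent) && length(tx$Parent[[i]]))
      tx$Parent[[i]][1L] else tid
    kids <- gr[vapply(gr$Parent, function(p) tid %in% p, NA)]
    ktype <- as.character(kids$type)
    exons <- IRanges::ranges(kids[ktype == "exon"])
    utr5 <- IRanges::ranges(kids[ktype == "five_prime_UTR"])
    cds <- kids[ktype == "CDS"]
    strand <- as.character(GenomicRanges::strand(tx[i]))
    cds_start <- if (length(cds)) {
      if (strand == "+") min(GenomicRanges::start(cds)) else max(GenomicRanges::end(cds))
    } else NA_integer_
    transcript_model(tid, gid, as.character(GenomicRanges::seqnames(tx[i])),
                     strand, exons, utr5, cds_start)
  })
}

.read_bed12_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  lapply(seq_along(gr), function(i) {
    x <- gr[i]
    strand <- as.character(GenomicRanges::strand(x))
    blocks <- if (!is.null(x$blocks)) {
      IRanges::shift(x$blocks[[1L]], GenomicRanges::start(x) - 1L)
    } else IRanges::ranges(x)
    thick <- x$thick
    exons <- blocks
    utr_rng <- if (strand == "+") {
      if (IRanges::start(thick) > GenomicRanges::start(x))
        IRanges::IRanges(GenomicRanges::start(x), IRanges::start(thick) - 1L)
      else IRanges::IRanges()
    } else {
      if (IRanges::end(thick) < GenomicRanges::end(x))
        IRanges::IRanges(IRanges::end(thick) + 1L, GenomicRanges::end(x))
      else IRanges::IRanges()
    }
    utr5 <- IRanges::intersect(utr_rng, exons)
    cds_start <- if (strand == "+") IRanges::start(thick) else IRanges::end(thick)
    tid <- if (!is.null(x$name)) x$name else sprintf("bed_tx_%d", i)
    transcript_model(tid, tid, as.character(GenomicRanges::seqnames(x)),
                     strand, exons, utr5, cds_start)
  })
}

#' Write transcript models to GFF3
#'
#' Emits gene, mRNA, exon, five_prime_UTR and CDS-start features so that
#' [read_annotation()] round-trips the models.
#'
#' @param models List of [transcript_model()].
#' @param path Output path.
#' @export
write_annotation <- function(models, path) {
  chrom <- character(); strand <- character(); type <- character()
  start <- integer(); end <- integer(); id <- character()
  parent <- list()
  for (m in models) {
    span <- range(c(IRanges::start(m$exons), IRanges::end(m$exons)))
    add <- function(ty, s, e, i = NA_character_, p = character()) {
      chrom <<- c(chrom, m$chrom); strand <<- c(strand, m$strand)
      type <<- c(type, ty); start <<- c(start, s); end <<- c(end, e)
      id <<- c(id, i); parent[[length(parent) + 1L]] <<- p
    }
    add("gene", span[1L], span[2L], i = m$gene_id)
    add("mRNA", span[1L], span[2L], i = m$transcript_id, p = m$gene_id)
    for (j in seq_along(m$exons))
      add("exon", IRanges::start(m$exons)[j], IRanges::end(m$exons)[j],
          p = m$transcript_id)
    for (j in seq_along(m$utr5))
      add("five_prime_UTR", IRanges::start(m$utr5)[j],
          IRanges::end(m$utr5)[j], p = m$transcript_id)
    if (!is.na(m$cds_start))
      add("CDS", m$cds_start, m$cds_start, p = m$transcript_id)
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand, type = type, ID = id,
                               Parent = IRanges::CharacterList(parent))
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

.genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop(sprintf("chromosome %s not in genome", chrom))
  if (start < 1L || end > length(genome[[chrom]]))
    stop(sprintf("interval %d-%d out of bounds on %s", start, end, chrom))
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

#' Load a genome FASTA
#'
#' @param path FASTA path (plain or gzipped).
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Map genomic positions of all 5' UTR bases in transcript order
#'
#' Returns the genomic coordinate of each UTR base, 5' to 3' in transcript
#' orientation: increasing for plus-strand transcripts, strictly decreasing
#' for minus-strand ones.
#'
#' @param model A [transcript_model()].
#' @return Integer vector of genomic positions (length = UTR length).
#' @export
utr_genomic_map <- function(model) {
  if (!model$has_utr5) return(integer())
  pos <- unlist(lapply(seq_along(model$utr5), function(j)
    seq.int(IRanges::start(model$utr5)[j], IRanges::end(model$utr5)[j])))
  if (model$strand == "-") rev(pos) else pos
}

#' Assemble the spliced 5' UTR sequence of a transcript
#'
#' Joins the UTR exonic intervals in transcript order, reverse-complements
#' for minus-strand transcripts, and converts to RNA alphabet.
#'
#' @param genome A [Biostrings::DNAStringSet] (see [read_genome()]).
#' @param model A [transcript_model()].
#' @return An object of class `utr_sequence`: list with `transcript_id`,
#'   `rna_seq` (RNA string, 5' to 3') and `genomic_map` (see
#'   [utr_genomic_map()]).
#' @export
utr5_sequence <- function(genome, model) {
  if (!model$has_utr5)
    stop(sprintf("transcript %s has no 5' UTR", model$transcript_id))
  pieces <- vapply(seq_along(model$utr5), function(j)
    .genome_subseq(genome, model$chrom,
                   IRanges::start(model$utr5)[j], IRanges::end(model$utr5)[j]),
    "")
  plus_text <- paste(pieces, collapse = "")
  dna <- if (model$strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus_text)))
  } else plus_text
  structure(list(transcript_id = model$transcript_id,
                 rna_seq = as_rna(dna),
                 genomic_map = utr_genomic_map(model)),
            class = "utr_sequence")
}

#' @export
print.utr_sequence <- function(x, ...) {
  cat(sprintf("utr_sequence %s: %d nt\n", x$transcript_id, nchar(x$rna_seq)))
  invisible(x)
}

#' Map a genomic position into 5' UTR transcript space
#'
#' Inverse of the genomic map: positions inside the spliced 5' UTR return
#' their 1-based offset from the transcript 5' end; intronic or non-UTR
#' positions return `NA` (not-in-UTR is a value, not an error).
#'
#' @param model A [transcript_model()].
#' @param gpos 1-based genomic position(s) on the model's chromosome.
#' @return Integer offset(s), `NA` where not in the UTR.
#' @export
genome_to_transcript <- function(model, gpos) {
  match(gpos, utr_genomic_map(model))
}
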