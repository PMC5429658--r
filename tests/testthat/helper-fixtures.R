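# Hand-built two-transcript genome (one per strand) with a known G4 in
# each 5' UTR, used by coordinate and strand tests. Everything is
# constructed explicitly so expectations can be written by eye.
two_strand_fixture <- function() {
  # plus transcript: UTR = 10 nt flank + 15-nt G4 + 10 nt flank
  utr_plus <- "ACUACUACUAGGGAGGGAGGGAGGGUCAUCAUCAU"
  # minus transcript: same UTR in RNA space, encoded on the minus strand
  utr_minus <- utr_plus
  cds <- "AUGAAACCCUUUUAA"
  d <- function(x) chartr("U", "T", x)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  chr1 <- paste0(strrep("ACT", 5), d(utr_plus), d(cds), strrep("TCA", 5))
  chr2 <- paste0(strrep("ACT", 5), rc(paste0(d(utr_minus), d(cds))), strrep("TCA", 5))
  genome <- Biostrings::DNAStringSet(c(chr1 = chr1, chr2 = chr2))
  ulen <- nchar(utr_plus); clen <- nchar(cds)
  m_plus <- transcript_model(
    "txP", "geneP", "chr1", "+",
    exons = IRanges::IRanges(16, 15 + ulen + clen),
    utr5 = IRanges::IRanges(16, 15 + ulen),
    cds_start = 16 + ulen)
  # minus: exon spans the revcomp(UTR+CDS) block; UTR occupies its high end
  m_minus <- transcript_model(
    "txM", "geneM", "chr2", "-",
    exons = IRanges::IRanges(16, 15 + ulen + clen),
    utr5 = IRanges::IRanges(16 + clen, 15 + clen + ulen),
    cds_start = 15 + clen)
  list(genome = genome, models = list(m_plus, m_minus),
       utr_rna = utr_plus, g4_span = c(11, 25))
}
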