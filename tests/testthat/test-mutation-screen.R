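test_that("apply_mutation changes exactly one base and checks the reference", {
  fx <- two_strand_fixture()
  u <- utr5_sequence(fx$genome, fx$models[[1]])
  mut <- apply_mutation(u, 12, "G", "A")
  expect_equal(substr(mut, 12, 12), "A")
  diffs <- which(strsplit(u$rna_seq, "")[[1]] != strsplit(mut, "")[[1]])
  expect_equal(diffs, 12L)
  expect_error(apply_mutation(u, 12, "C", "A"), "reference mismatch")
  expect_error(apply_mutation(u, 12, "G", "G"), "identical")
  # property: Hamming distance is always 1
  set.seed(61)
  for (i in 1:200) {
    s <- random_seq(80)
    off <- sample(80, 1)
    ref <- substr(s, off, off)
    alt <- sample(setdiff(c("A", "C", "G", "U"), ref), 1)
    m <- apply_mutation(s, off, ref, alt)
    expect_equal(sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]]), 1L)
  }
})

test_that("intersect emits exactly the planted in-locus mutations", {
  co <- make_cohort(seed = 19, n_transcripts = 10, n_mutations = 20,
                    class_mix = c(tetrad_loss = 0.5, non_overlapping = 0.5))
  sc <- screen_mutations(co$genome, co$models, co$mutations)
  expect_equal(sc$counts$n_hits, 10L)
  expect_equal(sc$counts$n_non_overlapping, 10L)
  expect_equal(sc$counts$n_ref_mismatch, 0L)
  # accounting: every record lands in exactly one category
  expect_equal(sc$counts$n_hit_mutations + sc$counts$n_non_overlapping +
               sc$counts$n_ref_mismatch, nrow(co$mutations))
})

test_that("a cohort of only non-overlapping mutations yields zero hits", {
  co <- make_cohort(seed = 23, n_transcripts = 6, n_mutations = 10,
                    class_mix = c(non_overlapping = 1))
  sc <- screen_mutations(co$genome, co$models, co$mutations)
  expect_equal(sc$counts$n_hits, 0L)
  expect_equal(sc$counts$n_non_overlapping, 10L)
})

test_that("ref-mismatching records are flagged and excluded, never dropped", {
  co <- make_cohort(seed = 29, n_transcripts = 4, n_mutations = 8,
                    class_mix = c(tetrad_loss = 1))
  muts <- co$mutations
  # corrupt one record's ref to a base the genome cannot have there
  genome_base <- muts$ref[1]
  muts$ref[1] <- setdiff(c("A", "C", "G", "T"), c(genome_base, muts$alt[1]))[1]
  sc <- screen_mutations(co$genome, co$models, muts)
  expect_equal(sc$counts$n_ref_mismatch, 1L)
  expect_equal(sc$counts$n_hits, 7L)
  expect_equal(sum(sc$mutations$category == "ref_mismatch"), 1L)
})

test_that("plus and minus strand mutations are complemented into mRNA space", {
  fx <- two_strand_fixture()
  # the G4 occupies UTR offsets 11-25; offset 12 is a G in RNA space
  map_p <- utr_genomic_map(fx$models[[1]])
  map_m <- utr_genomic_map(fx$models[[2]])
  muts <- data.frame(
    chrom = c("chr1", "chr2"),
    pos = c(map_p[12], map_m[12]),
    ref = c("G", "C"),      # minus strand: RNA G is genomic plus-strand C
    alt = c("A", "T"),      # RNA G>A is plus-strand C>T on the minus strand
    sample_id = c("s1", "s2"), cancer_type = "x", source = "fixture",
    stringsAsFactors = FALSE)
  sc <- screen_mutations(fx$genome, fx$models, muts)
  expect_equal(nrow(sc$hits), 2L)
  expect_equal(sc$hits$rna_ref, c("G", "G"))
  expect_equal(sc$hits$rna_alt, c("A", "A"))
  expect_equal(sc$hits$utr_offset, c(12L, 12L))
  expect_equal(sc$hits$class, rep("destabilising", 2))
})

test_that("shuffling the input order leaves the sorted hit table unchanged", {
  co <- make_cohort(seed = 31, n_transcripts = 8, n_mutations = 16)
  sc1 <- screen_mutations(co$genome, co$models, co$mutations)
  set.seed(1)
  shuf <- co$mutations[sample(nrow(co$mutations)), ]
  sc2 <- screen_mutations(co$genome, co$models, shuf)
  drop_id <- function(h) { h$mutation_id <- NULL; rownames(h) <- NULL; h }
  expect_equal(drop_id(sc1$hits), drop_id(sc2$hits))
})

test_that("mechanism examples: fifth-run recruitment and new-run loop shortening", {
  o <- example_oligos()
  # five-run region: disrupting run 2 recruits the fifth run, lengthening a loop
  v <- assess_stability(o$cxcl14_like$wt, o$cxcl14_like$mut,
                        scan_g4(o$cxcl14_like$wt)[1, ])
  expect_equal(v$class, "destabilising")
  expect_equal(v$mechanism, "loop_lengthening")
  # A>G next to two loop guanines creates a run, shortens the first loop
  v2 <- assess_stability(o$taok2_like$wt, o$taok2_like$mut,
                         scan_g4(o$taok2_like$wt)[1, ])
  expect_equal(v2$class, "stabilising")
  expect_equal(v2$mechanism, "loop_shortening")
  # tetrad loss in the four-guanine run
  v3 <- assess_stability(o$bcl2_like$wt, o$bcl2_like$mut,
                         scan_g4(o$bcl2_like$wt)[1, ])
  expect_equal(v3$class, "destabilising")
  expect_equal(v3$mechanism, "tetrad_loss")
  expect_equal(v3$mut_best$tetrads, 2L)
})

test_that("a flank mutation that leaves the decomposition unchanged is neutral", {
  wt <- "ACUACGGGAUGGGACGGGAUAGGGCAUCA"
  locus <- scan_g4(wt)[1, ]
  mut <- apply_mutation(wt, 2, "C", "A")   # outside the locus
  v <- assess_stability(wt, mut, locus)
  expect_equal(v$class, "neutral")
  expect_equal(v$mechanism, "none")
  expect_equal(v$rule, "score")
  expect_equal(v$delta_score, 0)
})

test_that("classification is antisymmetric on stabilising/destabilising pairs", {
  o <- example_oligos()
  mirror <- c(tetrad_loss = "tetrad_gain", tetrad_gain = "tetrad_loss",
              loop_lengthening = "loop_shortening",
              loop_shortening = "loop_lengthening")
  for (case in list(o$taok2_like, o$bcl2_like)) {
    fwd <- assess_stability(case$wt, case$mut, scan_g4(case$wt)[1, ])
    back_locus <- scan_g4(case$mut)[1, ]
    if (is.na(back_locus$start[1])) next  # mutant has no quadparser locus
    rev <- assess_stability(case$mut, case$wt, back_locus)
    expect_equal(sort(c(fwd$class, rev$class)),
                 c("destabilising", "stabilising"))
    expect_equal(rev$mechanism, unname(mirror[fwd$mechanism]))
  }
  # synthetic pair built so both directions have a quadparser locus
  co <- make_cohort(seed = 37, n_transcripts = 4, n_mutations = 4,
                    class_mix = c(tetrad_gain = 1))
  sc <- screen_mutations(co$genome, co$models, co$mutations)
  for (k in seq_len(nrow(sc$hits))) {
    h <- sc$hits[k, ]
    u <- sc$utrs[[h$transcript_id]]
    mut_seq <- apply_mutation(u, h$utr_offset, h$rna_ref, h$rna_alt)
    rev_locus <- scan_g4(mut_seq)
    rev_locus <- rev_locus[rev_locus$start <= h$utr_offset &
                           rev_locus$end >= h$utr_offset, ][1, ]
    rv <- assess_stability(mut_seq, u$rna_seq, rev_locus)
    expect_equal(h$class, "stabilising")
    expect_equal(rv$class, "destabilising")
    expect_equal(rv$mechanism, "tetrad_loss")
  }
})

test_that("the mutation spectrum tallies changes per class like a manual count", {
  hits <- data.frame(
    rna_ref = c("G", "G", "G", "U", "U", "A", "G", "C"),
    rna_alt = c("A", "A", "C", "G", "G", "G", "A", "U"),
    class = c("destabilising", "destabilising", "destabilising",
              "stabilising", "stabilising", "stabilising",
              "destabilising", "neutral"),
    stringsAsFactors = FALSE)
  sp <- mutation_spectrum(hits)
  expect_equal(sp$count[sp$class == "destabilising" & sp$change == "G>A"], 3L)
  expect_equal(sp$count[sp$class == "stabilising" & sp$change == "U>G"], 2L)
  expect_equal(sum(sp$count), nrow(hits))
  expect_equal(unique(sp$type[sp$change == "G>A"]), "transition")
  expect_equal(unique(sp$type[sp$change == "U>G"]), "transversion")
  # empty input is a table, not an error
  expect_equal(nrow(mutation_spectrum(hits[0, ])), 0L)
})

test_that("planted destabilisers dominated by G>A reproduce the modal spectrum", {
  co <- make_cohort(seed = 43, n_transcripts = 12, n_mutations = 24,
                    class_mix = c(tetrad_loss = 0.8, tetrad_gain = 0.2))
  sc <- screen_mutations(co$genome, co$models, co$mutations)
  sp <- mutation_spectrum(sc)
  dsp <- sp[sp$class == "destabilising", ]
  expect_equal(dsp$change[which.max(dsp$count)], "G>A")
  ssp <- sp[sp$class == "stabilising", ]
  expect_equal(ssp$change[which.max(ssp$count)], "U>G")
})
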