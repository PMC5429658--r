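#' Synthetic worked-example oligos
#'
#' Synthetic RNA oligos engineered to the three quadruplex architectures
#' most often used to illustrate 5' UTR G4 mutation effects. These are
#' constructed sequences, not the natural human sequences; each reproduces
#' the defining architecture of its namesake locus:
#'
#' * `bcl2_like`: a 22-nt three-tetrad locus (runs 3/4/3/3, loops 2/3/4).
#'   Its `mut` form carries a single G-to-A in the four-guanine run, which
#'   removes a tetrad: the best remaining candidate has two tetrads.
#' * `cxcl14_like`: a G-rich region with five G-runs in which the four
#'   runs with the shortest loops form a 23-nt locus. Its `mut` form
#'   carries two adjacent G-to-A changes in the second run; the fifth run,
#'   a few nucleotides downstream, then joins the quadruplex and one loop
#'   lengthens.
#' * `taok2_like`: a 27-nt locus whose first loop contains two successive
#'   guanines. Its `mut` form converts the adjacent A to G, creating a new
#'   G-run that shifts the last run out of the quadruplex and shortens the
#'   first loop (a stabilising change).
#'
#' @return A named list of lists, each with elements `wt` and `mut` (RNA
#'   strings) and `locus_len` (the expected quadparser locus width in nt).
#' @examples
#' olig <- example_oligos()
#' scan_g4(olig$bcl2_like$wt)$width   # 22
#' count_g_runs(olig$cxcl14_like$wt)  # 5
#' @export
example_oligos <- function() {
  list(
    bcl2_like = list(
      wt  = "GGGACGGGGUACGGGCUACGGG",
      mut = "GGGACGGAGUACGGGCUACGGG",   # G8 -> A
      locus_len = 22L),
    cxcl14_like = list(
      wt  = "GGGUACGGGAUCAGGGCUAAGGGAUGGG",
      mut = "GGGUACAAGAUCAGGGCUAAGGGAUGGG", # G7,G8 -> A,A
      locus_len = 23L),
    taok2_like = list(
      wt  = "GGGCAGGAUGGGACUAGGGCAUCAGGG",
      mut = "GGGCAGGGUGGGACUAGGGCAUCAGGG",  # A8 -> G
      locus_len = 27L)
  )
}
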