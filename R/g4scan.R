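#' Quadruplex search patterns
#'
#' A G4 search pattern describes four guanine runs (the tetrads-to-be)
#' separated by three loops. Two presets cover the common use cases:
#'
#' * `"quadparser"`: G3+ N1-7 G3+ N1-7 G3+ N1-7 G3+, the classic
#'   genome-wide motif for putative quadruplexes (runs of at least three
#'   guanines, loops of one to seven bases).
#' * `"relaxed"`: G2-7 N1-15 G2-7 N1-15 G2-7 N1-15 G2-7, the looser motif
#'   used when re-examining a locus after mutation, where two-tetrad
#'   structures and longer loops still matter.
#'
#' @param min_run_len Minimum guanines per G-run (>= 2).
#' @param max_run_len Maximum guanines used from a run (`Inf` = unbounded).
#' @param min_loop_len,max_loop_len Loop length bounds (bases between runs).
#' @return An object of class `g4_pattern`.
#' @examples
#' g4_pattern("quadparser")
#' g4_pattern("relaxed")
#' g4_pattern(min_run_len = 2, max_run_len = 5, min_loop_len = 1, max_loop_len = 10)
#' @export
g4_pattern <- function(preset = c("quadparser", "relaxed"),
                       min_run_len = NULL, max_run_len = NULL,
                       min_loop_len = NULL, max_loop_len = NULL) {
  if (is.null(min_run_len)) {
    preset <- match.arg(preset)
    p <- switch(preset,
      quadparser = list(min_run_len = 3L, max_run_len = Inf,
                        min_loop_len = 1L, max_loop_len = 7L),
      relaxed    = list(min_run_len = 2L, max_run_len = 7L,
                        min_loop_len = 1L, max_loop_len = 15L))
    p$name <- preset
  } else {
    p <- list(min_run_len = as.integer(min_run_len),
              max_run_len = if (is.finite(max_run_len)) as.integer(max_run_len) else Inf,
              min_loop_len = as.integer(min_loop_len),
              max_loop_len = as.integer(max_loop_len),
              name = "custom")
    stopifnot(p$min_run_len >= 2L, p$min_run_len <= p$max_run_len,
              p$min_loop_len >= 0L, p$min_loop_len <= p$max_loop_len)
  }
  p$n_runs <- 4L
  structure(p, class = "g4_pattern")
}

#' @export
print.g4_pattern <- function(x, ...) {
  cat(sprintf("G4 pattern '%s': G%s-%s runs x4, loops %d-%d nt\n",
              x$name, x$min_run_len,
              if (is.finite(x$max_run_len)) x$max_run_len else "+",
              x$min_loop_len, x$max_loop_len))
  invisible(x)
}

# Validate a nucleotide string; returns uppercase character vector.
# Accepts A/C/G/T/U (case-insensitive) and N; anything else errors with the
# 1-based offending position.
.check_nt <- function(seq) {
  if (length(seq) != 1L || !is.character(seq))
    stop("sequence must be a single character string")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "U", "N"))
  if (length(bad))
    stop(sprintf("non-nucleotide character '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
  chars
}

#' Convert a nucleotide string to RNA alphabet
#'
#' Uppercases and replaces T with U. The screen works in mRNA space, so DNA
#' input is canonicalised on entry.
#' @param seq Nucleotide string.
#' @return RNA string.
#' @export
as_rna <- function(seq) chartr("Tt", "UU", toupper(seq))

# Maximal G-runs >= min_len in positions [from, to] (1-based closed).
# Returns data.frame(start, len) sorted by start.
.g_runs <- function(chars, min_len, from = 1L, to = length(chars)) {
  if (from > to) return(data.frame(start = integer(), len = integer()))
  isg <- chars[from:to] == "G"
  r <- rle(isg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = from - 1L + starts[keep], len = r$lengths[keep])
}

# Assemble a candidate record from four used run spans (matrix 4x2 of
# start,end 1-based closed).
.make_candidate <- function(seq_id, spans, alphabet) {
  runlens <- spans[, 2L] - spans[, 1L] + 1L
  loops <- spans[2:4, 1L] - spans[1:3, 2L] - 1L
  list(seq_id = seq_id,
       start = spans[1L, 1L], end = spans[4L, 2L],
       runs = spans,
       tetrads = min(runlens),
       loops = loops,
       alphabet = alphabet)
}

.cands_to_df <- function(cands, gscores = NULL) {
  if (!length(cands)) {
    df <- data.frame(seq_id = character(), start = integer(), end = integer(),
                     width = integer(), tetrads = integer(),
                     loop1 = integer(), loop2 = integer(), loop3 = integer(),
                     gscore = numeric(), alphabet = character(),
                     stringsAsFactors = FALSE)
    df$runs <- list()
    return(df)
  }
  df <- data.frame(
    seq_id = vapply(cands, `[[`, "", "seq_id"),
    start = vapply(cands, `[[`, 0L, "start"),
    end = vapply(cands, `[[`, 0L, "end"),
    width = vapply(cands, function(c) c$end - c$start + 1L, 0L),
    tetrads = vapply(cands, `[[`, 0L, "tetrads"),
    loop1 = vapply(cands, function(c) c$loops[1L], 0L),
    loop2 = vapply(cands, function(c) c$loops[2L], 0L),
    loop3 = vapply(cands, function(c) c$loops[3L], 0L),
    gscore = if (is.null(gscores)) NA_real_ else gscores,
    alphabet = vapply(cands, `[[`, "", "alphabet"),
    stringsAsFactors = FALSE)
  df$runs <- lapply(cands, `[[`, "runs")
  df
}

.alphabet_of <- function(chars) if ("U" %in% chars && !"T" %in% chars) "RNA" else "DNA"

#' Scan a sequence for non-overlapping quadruplex motif matches
#'
#' Left-to-right scan for the four-run G4 motif. At each point the leftmost
#' match is taken: the first eligible G-run starts the match and each
#' subsequent run is the earliest one reachable within the loop bounds
#' (with backtracking, so a match is reported whenever one exists at that
#' start). G-runs are used maximally from their left end, truncated to the
#' pattern's `max_run_len`; surplus guanines count towards the following
#' loop. After a match is reported scanning resumes at the next base, so
#' reported candidates never overlap.
#'
#' @param seq Nucleotide string over A/C/G/T/U/N (case-insensitive). `N`
#'   never extends a G-run but may sit in loops.
#' @param pattern A [g4_pattern()]; default the quadparser preset.
#' @param seq_id Identifier recorded on candidates.
#' @return A data.frame of candidates with columns `seq_id`, `start`, `end`
#'   (1-based closed), `width`, `tetrads` (minimum run length = stackable
#'   tetrads), `loop1`..`loop3`, `gscore` (NA; see [enumerate_qgrs()] for
#'   scored enumeration), `alphabet`, and a list-column `runs` holding the
#'   4x2 matrix of run start/end positions.
#' @examples
#' scan_g4("GGGAGGGAGGGAGGG")
#' scan_g4(strrep("A", 30))          # no candidates
#' @seealso [enumerate_qgrs()], [count_g_runs()]
#' @export
scan_g4 <- function(seq, pattern = g4_pattern("quadparser"), seq_id = "seq") {
  chars <- .check_nt(seq)
  alphabet <- .alphabet_of(chars)
  n <- length(chars)
  out <- list()
  ptr <- 1L
  repeat {
    runs <- .g_runs(chars, pattern$min_run_len, from = ptr, to = n)
    if (nrow(runs) < 4L) break
    spans <- .first_chain(runs, pattern)
    if (is.null(spans)) break
    out[[length(out) + 1L]] <- .make_candidate(seq_id, spans, alphabet)
    ptr <- spans[4L, 2L] + 1L
  }
  .cands_to_df(out)
}

# Find the lexicographically earliest chain of 4 runs satisfying the loop
# bounds. runs: data.frame(start, len). Returns 4x2 span matrix or NULL.
# Used span of run i: [start_i, start_i + min(len_i, max_run) - 1].
.first_chain <- function(runs, pattern) {
  m <- nrow(runs)
  used_len <- as.integer(pmin(runs$len, pattern$max_run_len))
  used_end <- runs$start + used_len - 1L
  extend <- function(chain) {
    depth <- length(chain)
    if (depth == 4L) return(chain)
    last <- chain[depth]
    for (j in seq_len(m)) {
      if (j <= last) next
      loop <- runs$start[j] - used_end[last] - 1L
      if (loop < pattern$min_loop_len) next
      if (loop > pattern$max_loop_len) break  # runs sorted: later only worse
      res <- extend(c(chain, j))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  for (i in seq_len(m)) {
    res <- extend(i)
    if (!is.null(res))
      return(cbind(runs$start[res], used_end[res]))
  }
  NULL
}

#' Count maximal guanine runs
#'
#' Number of maximal runs of at least `min_len` consecutive guanines, e.g.
#' to verify the five-G-run architecture of a G-rich region where only four
#' runs take part in the folded quadruplex at a time.
#'
#' @inheritParams scan_g4
#' @param min_len Minimum run length.
#' @return Integer count.
#' @examples
#' count_g_runs("GGGAGGGAGGGAGGGACGGG", 3) # 5
#' count_g_runs("GGGG", 3)                 # one maximal run
#' @export
count_g_runs <- function(seq, min_len = 3L) {
  chars <- .check_nt(seq)
  nrow(.g_runs(chars, min_len))
}

#' Score a quadruplex candidate
#'
#' Deterministic, unitless stability proxy for a candidate decomposition:
#' \deqn{gscore = 100 (t - 2)/(t_{max} - 2) - \bar{l}/L - (l_{max}-l_{min})/(3L)}
#' where `t` is the candidate tetrad count, `tmax` the largest tetrad count
#' observed in the enumeration it came from (floored at 3 so two-tetrad-only
#' scans score their tetrad term as zero), `l` the three loop lengths and
#' `L` the pattern's maximum loop length. The score rises strictly with
#' tetrad count and falls as loops lengthen or become unequal, the two
#' monotonicities that track quadruplex thermodynamic stability; it does
#' not reproduce any external tool's numeric scale.
#'
#' @param tetrads Tetrad count (minimum run length).
#' @param loops Integer vector of three loop lengths.
#' @param tmax Reference maximum tetrad count (>= tetrads).
#' @param max_loop Pattern maximum loop length.
#' @return Numeric score.
#' @export
g4_score <- function(tetrads, loops, tmax = max(tetrads, 3), max_loop = 15) {
  stopifnot(length(loops) == 3L, tetrads >= 2)
  denom <- max(tmax, 3) - 2
  100 * (tetrads - 2) / denom - mean(loops) / max_loop -
    (max(loops) - min(loops)) / (3 * max_loop)
}

#' Enumerate and score all quadruplex candidate decompositions
#'
#' QGRS-style enumeration: every ordered choice of four disjoint G-run
#' segments (sub-runs of the maximal runs, lengths within the pattern's run
#' bounds) whose loops fit the pattern and whose total span does not exceed
#' `max_span`. Overlapping candidates are all reported, scored with
#' [g4_score()] (using the maximum tetrad count observed here as `tmax`),
#' and sorted by descending score with ties broken by smaller start, then
#' shorter span.
#'
#' @inheritParams scan_g4
#' @param pattern A [g4_pattern()]; default the relaxed preset.
#' @param max_span Maximum candidate span in nt (default 45, covering all
#'   loci of interest while keeping enumeration cheap).
#' @return Candidate data.frame as in [scan_g4()], with `gscore` filled and
#'   attributes `tmax` and `max_loop` recording the scoring context.
#' @examples
#' head(enumerate_qgrs("GGGAGGGAGGGAGGG"))
#' @export
enumerate_qgrs <- function(seq, pattern = g4_pattern("relaxed"),
                           max_span = 45L, seq_id = "seq") {
  chars <- .check_nt(seq)
  alphabet <- .alphabet_of(chars)
  runs <- .g_runs(chars, pattern$min_run_len)
  subs <- .sub_runs(runs, pattern)
  cands <- .enumerate_chains(subs, pattern, max_span)
  cands <- lapply(cands, .make_candidate, seq_id = seq_id, alphabet = alphabet)
  if (!length(cands)) {
    df <- .cands_to_df(cands)
  } else {
    tmax <- max(vapply(cands, `[[`, 0L, "tetrads"))
    gs <- vapply(cands, function(c)
      g4_score(c$tetrads, c$loops, tmax = tmax, max_loop = pattern$max_loop_len),
      0)
    df <- .cands_to_df(cands, gs)
    ord <- order(-df$gscore, df$start, df$width)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "tmax") <- tmax
  }
  attr(df, "max_loop") <- pattern$max_loop_len
  df
}

# All G-run segments: for each maximal run, every (start, len) with
# len in [min_run, min(run_len, max_run)]. Returns matrix (start, end).
.sub_runs <- function(runs, pattern) {
  out <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; L <- runs$len[i]
    maxl <- as.integer(min(L, pattern$max_run_len))
    for (len in pattern$min_run_len:maxl) {
      if (len > maxl) break
      for (off in 0:(L - len)) {
        out[[length(out) + 1L]] <- c(s + off, s + off + len - 1L)
      }
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 2L))
  m <- do.call(rbind, out)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

# DFS over ordered quadruples of sub-runs with loop and span bounds.
.enumerate_chains <- function(subs, pattern, max_span) {
  n <- nrow(subs)
  if (n < 4L) return(list())
  res <- list()
  starts <- subs[, 1L]; ends <- subs[, 2L]
  recurse <- function(chain) {
    depth <- length(chain)
    last <- chain[depth]
    first_start <- starts[chain[1L]]
    for (j in seq_len(n)) {
      if (starts[j] <= ends[last]) next
      if (starts[j] - first_start + 1L > max_span) break  # sorted by start
      loop <- starts[j] - ends[last] - 1L
      if (loop < pattern$min_loop_len || loop > pattern$max_loop_len) next
      if (ends[j] - first_start + 1L > max_span) next
      if (depth == 3L) {
        res[[length(res) + 1L]] <<- cbind(starts[c(chain, j)], ends[c(chain, j)])
      } else {
        recurse(c(chain, j))
      }
    }
  }
  for (i in seq_len(n)) recurse(i)
  res
}

#' Extract the sequence slice of a candidate
#'
#' @param seq The sequence the candidate was found in.
#' @param cand One row of a candidate data.frame.
#' @return The candidate's sequence slice.
#' @export
candidate_slice <- function(seq, cand) {
  substr(seq, cand$start, cand$end)
}
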