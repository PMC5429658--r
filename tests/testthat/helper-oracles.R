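# Independent oracle implementations used to check the scanner and
# enumerator. Deliberately written with a different structure from the
# package code (character walks and exhaustive nested loops, no shared
# helpers).

# maximal G-runs by explicit character walk
oracle_g_runs <- function(seq, min_len) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  runs <- list()
  i <- 1L; n <- length(chars)
  while (i <= n) {
    if (chars[i] == "G") {
      j <- i
      while (j < n && chars[j + 1L] == "G") j <- j + 1L
      if (j - i + 1L >= min_len) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# Non-overlapping leftmost-match scan: enumerate every 4-tuple of maximal
# runs satisfying the loop bounds, then repeatedly take the tuple whose
# run starts are lexicographically smallest among those beginning after
# the previous match.
oracle_scan <- function(seq, min_run = 3, max_run = Inf,
                        min_loop = 1, max_loop = 7) {
  n <- nchar(seq)
  out <- list(); ptr <- 0L
  repeat {
    # the scan restarts on the unconsumed suffix, so run discovery is
    # repeated there (a truncated run's tail can seed a later match)
    runs <- oracle_g_runs(substr(seq, ptr + 1L, n), min_run)
    used <- lapply(runs, function(r)
      c(r[1], min(r[2], r[1] + max_run - 1)) + ptr)
    m <- length(used)
    if (m < 4L) break
    tuples <- list()
    for (a in 1:(m - 3)) for (b in (a + 1):(m - 2))
      for (cc in (b + 1):(m - 1)) for (d in (cc + 1):m) {
        idx <- c(a, b, cc, d)
        ok <- TRUE
        for (k in 1:3) {
          loop <- used[[idx[k + 1]]][1] - used[[idx[k]]][2] - 1L
          if (loop < min_loop || loop > max_loop) { ok <- FALSE; break }
        }
        if (ok) tuples[[length(tuples) + 1L]] <- idx
      }
    if (!length(tuples)) break
    keys <- vapply(tuples, function(t)
      paste(sprintf("%08d", vapply(t, function(i) used[[i]][1], 0)),
            collapse = ""), "")
    best <- tuples[[order(keys)[1]]]
    spans <- do.call(rbind, used[best])
    out[[length(out) + 1L]] <- spans
    ptr <- spans[4, 2]
  }
  out
}

# Exhaustive QGRS-style enumeration: every quadruple of all-G segments
# (found by scanning every substring) with loops and span in bounds.
oracle_enumerate <- function(seq, min_run = 2, max_run = 7,
                             min_loop = 1, max_loop = 15, max_span = 45) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(chars)
  segs <- list()
  for (s in 1:n) {
    if (chars[s] != "G") next
    e <- s
    while (e <= n && chars[e] == "G" && e - s + 1L <= max_run) {
      if (e - s + 1L >= min_run) segs[[length(segs) + 1L]] <- c(s, e)
      e <- e + 1L
    }
  }
  m <- length(segs)
  out <- list()
  if (m >= 4L) {
    succ <- lapply(1:m, function(i)
      Filter(function(j) {
        loop <- segs[[j]][1] - segs[[i]][2] - 1L
        loop >= min_loop && loop <= max_loop
      }, 1:m))
    for (a in 1:m) for (b in succ[[a]]) for (cc in succ[[b]])
      for (d in succ[[cc]]) {
        if (segs[[d]][2] - segs[[a]][1] + 1L <= max_span)
          out[[length(out) + 1L]] <-
            rbind(segs[[a]], segs[[b]], segs[[cc]], segs[[d]])
      }
  }
  out
}

# independent re-statement of the candidate score
oracle_gscore <- function(tetrads, loops, tmax, max_loop) {
  tetrad_term <- 100 * (tetrads - 2) / (max(tmax, 3) - 2)
  tetrad_term - mean(loops) / max_loop -
    (max(loops) - min(loops)) / (3 * max_loop)
}

span_key <- function(spans) paste(t(spans), collapse = ",")

random_seq <- function(n, p_g = 0.25) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - p_g) / 3, (1 - p_g) / 3, p_g, (1 - p_g) / 3)),
        collapse = "")
}

revcomp_rna <- function(seq) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}
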