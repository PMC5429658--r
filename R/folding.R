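#' Folding options
#'
#' Options for obtaining a minimum-free-energy (MFE) secondary structure
#' with quadruplex support for a full 5' UTR. Two engines implement the
#' same contract:
#'
#' * `"external"`: the ViennaRNA command-line tools. `RNAfold --gquad` is
#'   used for global folding (with `--noGU` unless `allow_gu_pairs`), or
#'   `RNALfold` when `local_window` is set, scanning for locally stable
#'   structures. If the executable is missing the call degrades to the
#'   fallback engine with an explicit warning, never silently.
#' * `"fallback"`: a pattern-based stand-in requiring no external binary.
#'   It reports a quadruplex exactly when [enumerate_qgrs()] (relaxed
#'   preset) finds a candidate whose gscore exceeds `gscore_floor`, and
#'   assigns `mfe = -gscore / 10` kcal/mol, a documented monotone map so
#'   that relative stabilities order the same way as the pattern score.
#'   Base pairing outside quadruplexes is not modelled (dots).
#'
#' @param engine `"fallback"` (default) or `"external"`.
#' @param allow_gu_pairs Allow GU wobble pairs in the external engine
#'   (default `FALSE`).
#' @param local_window Optional window size for local folding (RNALfold).
#' @param g4_enabled Include quadruplexes in the structure (default `TRUE`).
#' @param gscore_floor Fallback engine: minimum gscore for a candidate to
#'   count as a quadruplex (default 0, i.e. any candidate scoring above the
#'   two-tetrad baseline).
#' @return An object of class `fold_options`.
#' @export
fold_options <- function(engine = c("fallback", "external"),
                         allow_gu_pairs = FALSE, local_window = NULL,
                         g4_enabled = TRUE, gscore_floor = 0) {
  structure(list(engine = match.arg(engine),
                 allow_gu_pairs = isTRUE(allow_gu_pairs),
                 local_window = local_window,
                 g4_enabled = isTRUE(g4_enabled),
                 gscore_floor = gscore_floor),
            class = "fold_options")
}

#' Fold an RNA sequence
#'
#' @param seq RNA string.
#' @param opts A [fold_options()].
#' @return An object of class `fold_result`: `structure` (dot-bracket
#'   string, quadruplex runs marked `+`), `mfe` (kcal/mol, more negative =
#'   more stable), `g4_loci` (matrix of 1-based closed start/end spans),
#'   `engine` used, `engine_version` (external only) and the `options`.
#' @examples
#' fold_rna("GGGAGGGAGGGAGGG", fold_options())
#' @export
fold_rna <- function(seq, opts = fold_options()) {
  seq <- as_rna(seq)
  .check_nt(seq)
  if (opts$engine == "external") {
    res <- tryCatch(.fold_external(seq, opts), error = function(e) e)
    if (!inherits(res, "error")) return(res)
    warning("external folding engine unavailable (", conditionMessage(res),
            "); degraded to fallback engine", call. = FALSE)
  }
  .fold_fallback(seq, opts)
}

# Path to the ViennaRNA executables; overridable for testing degraded mode
# via options(g4screen.rnafold = "...").
.vienna_cmd <- function(local) {
  name <- if (local) "RNALfold" else "RNAfold"
  cmd <- getOption(paste0("g4screen.", tolower(name)), name)
  path <- Sys.which(cmd)
  if (!nzchar(path)) stop(name, " not found on PATH")
  path
}

.fold_external <- function(seq, opts) {
  local <- !is.null(opts$local_window)
  cmd <- .vienna_cmd(local)
  args <- character()
  if (opts$g4_enabled) args <- c(args, "--gquad")
  if (!opts$allow_gu_pairs) args <- c(args, "--noGU")
  if (local) args <- c(args, sprintf("-L %d", as.integer(opts$local_window)))
  else args <- c(args, "--noPS")
  out <- system2(cmd, args, input = seq, stdout = TRUE, stderr = FALSE)
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
    stop("folding engine exited with status ", attr(out, "status"))
  ver <- tryCatch(sub("^.*RNA(L)?fold ", "", system2(cmd, "--version",
                                                     stdout = TRUE)[1L]),
                  error = function(e) NA_character_)
  if (local) {
    # RNALfold: one structure per line " struct ( mfe) start"; take the
    # most stable local structure and place it at its reported start.
    lines <- grep("^[.()+~]", out, value = TRUE)
    if (!length(lines)) {
      struct <- strrep(".", nchar(seq)); mfe <- 0
    } else {
      parsed <- lapply(lines, function(l) {
        m <- regmatches(l, regexec("^([.()+~]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s+(\\d+)", l))[[1L]]
        if (length(m) < 4L) return(NULL)
        list(s = m[2L], e = as.numeric(m[3L]), at = as.integer(m[4L]))
      })
      parsed <- Filter(Negate(is.null), parsed)
      best <- parsed[[which.min(vapply(parsed, `[[`, 0, "e"))]]
      struct <- strrep(".", nchar(seq))
      substr(struct, best$at, best$at + nchar(best$s) - 1L) <- best$s
      mfe <- best$e
    }
  } else {
    sline <- out[2L]
    m <- regmatches(sline, regexec("^(\\S+)\\s+\\(\\s*(-?[0-9.]+)\\)", sline))[[1L]]
    if (length(m) < 3L) stop("could not parse folding output: ", sline)
    struct <- m[2L]
    mfe <- as.numeric(m[3L])
  }
  .fold_result(struct, mfe, "external", opts, ver)
}

.fold_fallback <- function(seq, opts) {
  struct <- strrep(".", nchar(seq))
  mfe <- 0
  if (opts$g4_enabled) {
    cands <- enumerate_qgrs(seq, g4_pattern("relaxed"))
    cands <- cands[!is.na(cands$gscore) & cands$gscore > opts$gscore_floor, ,
                   drop = FALSE]
    if (nrow(cands)) {
      top <- cands[1L, ]
      for (r in seq_len(4L)) {
        rs <- top$runs[[1L]][r, ]
        substr(struct, rs[1L], rs[2L]) <- strrep("+", rs[2L] - rs[1L] + 1L)
      }
      mfe <- -top$gscore / 10
    }
  }
  .fold_result(struct, mfe, "fallback", opts)
}

.fold_result <- function(struct, mfe, engine, opts, version = NA_character_) {
  # quadruplex loci: runs of G4 marker characters, merging marked runs
  # separated by a short loop (<= 15 nt) into one locus
  is_mark <- strsplit(struct, "", fixed = TRUE)[[1L]] %in% c("+", "~")
  r <- rle(is_mark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ms <- starts[r$values]; me <- ends[r$values]
  g4 <- matrix(integer(), ncol = 2L)
  if (length(ms)) {
    cur <- c(ms[1L], me[1L])
    for (i in seq_along(ms)[-1L]) {
      if (ms[i] - cur[2L] - 1L <= 15L) cur[2L] <- me[i]
      else { g4 <- rbind(g4, cur); cur <- c(ms[i], me[i]) }
    }
    g4 <- rbind(g4, cur)
  }
  dimnames(g4) <- NULL
  structure(list(structure = struct, mfe = mfe,
                 g4_loci = g4, engine = engine,
                 engine_version = version, options = opts),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("fold_result [%s]: mfe %.2f kcal/mol, %d quadruplex locus/loci\n",
              x$engine, x$mfe, nrow(x$g4_loci)))
  invisible(x)
}

#' Is a quadruplex present in a window of a folded structure?
#'
#' @param fold A `fold_result`.
#' @param window Length-2 vector, 1-based closed span.
#' @return `TRUE` iff any quadruplex locus intersects the window.
#' @export
g4_present <- function(fold, window) {
  stopifnot(inherits(fold, "fold_result"), length(window) == 2L)
  if (!nrow(fold$g4_loci)) return(FALSE)
  any(fold$g4_loci[, 1L] <= window[2L] & fold$g4_loci[, 2L] >= window[1L])
}

#' Serialise a fold result as a Vienna-style text block
#'
#' @param fold A `fold_result`.
#' @param seq The folded sequence.
#' @return Character vector: sequence line, structure line with energy.
#' @export
format_fold <- function(fold, seq) {
  c(seq, sprintf("%s (%6.2f)", fold$structure, fold$mfe))
}
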