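#' Minimum free energy of a sequence under the built-in folding model
#'
#' A deterministic dynamic-programming folder over pseudoknot-free
#' secondary structures: Watson-Crick and wobble pairs are scored GC = -3,
#' AT = -2, GT = -1 (fixed arbitrary energy units), hairpin loops must
#' enclose at least 3 unpaired bases, and `N` pairs with nothing. The MFE is
#' 0 for sequences admitting no pair and negative otherwise. The model
#' stands in for an external thermodynamic folder (e.g. RNAfold) so the
#' package builds with no external dependency; an adapter seam
#' (`backend`) accepts any function returning an MFE for a sequence, and
#' the same backend must be used for a fragment and all its shuffles.
#'
#' @param seq a single sequence over A/C/G/T/N (RNA spelling accepted).
#' @param structure also return the dot-bracket string of one optimal
#'   structure (built-in backend only).
#' @param backend `NULL` for the built-in folder, or a function
#'   `function(seq) -> numeric MFE` wrapping an external folder.
#' @return a list with elements `mfe` (numeric) and `structure`
#'   (dot-bracket string or `NA`).
#' @export
fold_mfe <- function(seq, structure = FALSE, backend = NULL) {
  if (length(seq) != 1L || !nzchar(seq)) stopf("fold_mfe() needs one non-empty sequence")
  seq <- normalize_sequence(seq)
  if (!is.null(backend)) {
    return(list(mfe = as.numeric(backend(seq)), structure = NA_character_))
  }
  cpp_fold_mfe(seq, traceback = structure)
}

#' Shuffle a sequence preserving mononucleotide composition
#'
#' A uniform random permutation of the characters. A dinucleotide-preserving
#' shuffle (Altschul-Erickson style, via a random Eulerian walk on the
#' dinucleotide multigraph) is available behind `preserve = "dinucleotide"`
#' but is not the default.
#'
#' @param seq a single non-empty sequence string.
#' @param preserve `"mononucleotide"` (default) or `"dinucleotide"`.
#' @return a shuffled sequence string of the same length and composition.
#' @export
shuffle_sequence <- function(seq, preserve = c("mononucleotide", "dinucleotide")) {
  preserve <- match.arg(preserve)
  if (length(seq) != 1L || !nzchar(seq)) stopf("shuffle_sequence() needs one non-empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (preserve == "mononucleotide") {
    return(paste(sample(chars), collapse = ""))
  }
  dinucleotide_shuffle(chars)
}

# Altschul-Erickson dinucleotide shuffle: permute, per source letter, the
# outgoing edges of the dinucleotide walk, retrying until the walk is
# completable (connectedness); falls back after 100 attempts.
dinucleotide_shuffle <- function(chars) {
  n <- length(chars)
  if (n <= 2L) return(paste(chars, collapse = ""))
  for (attempt in 1:100) {
    edges <- split(chars[-1L], chars[-n])
    edges <- lapply(edges, sample)
    used <- lapply(edges, function(e) 0L)
    out <- character(n)
    out[1L] <- chars[1L]
    ok <- TRUE
    for (i in 2:n) {
      src <- out[i - 1L]
      k <- used[[src]] + 1L
      if (k > length(edges[[src]])) { ok <- FALSE; break }
      out[i] <- edges[[src]][k]
      used[[src]] <- k
    }
    if (ok) return(paste(out, collapse = ""))
  }
  paste(chars, collapse = "") # degenerate composition: give up, identity
}

#' Z-score of structural stability for a candidate window
#'
#' Folds the window, then `n_shuffles` composition-preserving shuffles of
#' it, and returns `(mfe - mean(shuffled mfe)) / sd(shuffled mfe)` with the
#' sample (n-1) standard deviation. Windows more stable than their shuffled
#' background score negative. If the shuffle MFEs are constant (e.g. a
#' homopolymer window) the Z-score is defined as 0.
#'
#' @param window the sequence window (nominally 101 nt, `N`-padded near
#'   transcript ends).
#' @param n_shuffles number of shuffles (default 100).
#' @param seed optional integer seed making the shuffle set reproducible.
#' @inheritParams fold_mfe
#' @inheritParams shuffle_sequence
#' @return a single numeric Z-score.
#' @export
mfe_zscore <- function(window, n_shuffles = 100L, seed = NULL,
                       backend = NULL, preserve = "mononucleotide") {
  if (n_shuffles < 2L) stopf("n_shuffles must be >= 2")
  window <- normalize_sequence(window)
  shuffles <- with_seed(seed, {
    vapply(seq_len(n_shuffles),
           function(i) shuffle_sequence(window, preserve = preserve), "")
  })
  if (is.null(backend)) {
    mfes <- cpp_fold_mfe_many(c(window, shuffles))
  } else {
    mfes <- vapply(c(window, shuffles), function(s) as.numeric(backend(s)), 0)
  }
  s <- stats::sd(mfes[-1L])
  if (is.na(s) || s == 0) return(0)
  (mfes[1L] - mean(mfes[-1L])) / s
}
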