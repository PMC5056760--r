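# Feature families, fixed block order (recorded in model metadata):
#   mature: positional one-hot (11 nt), k-mer k=3, k=4 spectrum (101 nt),
#           relative position, structure Z-score  -> 44+64+256+1+1 = 366
#   full:   positional one-hot (31 nt), k-mer k=3, k=4 spectrum (101 nt)
#           -> 124+64+256 = 444

# one-hot rows in the fixed bit order (left to right: G, C, T, A)
.onehot <- matrix(c(0, 0, 0, 1,   # A -> 0001
                    0, 0, 1, 0,   # T -> 0010
                    0, 1, 0, 0,   # C -> 0100
                    1, 0, 0, 0,   # G -> 1000
                    0, 0, 0, 0),  # N -> gap, no bit set
                  nrow = 5, byrow = TRUE,
                  dimnames = list(c("A", "T", "C", "G", "N"),
                                  c("G", "C", "T", "A")))

#' Positional one-hot encoding of a sequence window
#'
#' Each base becomes 4 bits in the order G,C,T,A (so `A` encodes as 0001,
#' `T` as 0010, `C` as 0100, `G` as 1000); the gap character `N` encodes as
#' 0000. Per-position blocks are concatenated 5' to 3'.
#'
#' @param window sequence window over A/C/G/T/N.
#' @return numeric 0/1 vector of length `4 * nchar(window)`.
#' @export
encode_positional <- function(window) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), rownames(.onehot))
  if (length(bad)) stopf("unexpected character(s) in window: %s",
                         paste(bad, collapse = ", "))
  as.numeric(t(.onehot[chars, , drop = FALSE]))
}

#' k-mer frequency spectrum of a window
#'
#' Counts every k-mer over the sliding windows of `window` for each `k`,
#' then divides by the number of k-mers counted for that `k`. k-mers
#' containing `N` are skipped and excluded from the denominator, so each
#' k-block sums to 1 whenever the window has at least one `N`-free k-mer.
#' Within each k the order is lexicographic (A < C < G < T); the k = 3
#' block precedes k = 4.
#'
#' @param window window string (nominally 101 nt; `N`-padding allowed).
#' @param ks k-mer sizes, default `c(3, 4)`.
#' @param width required window length (default 101); mismatch is an error.
#' @return named numeric vector of length `sum(4^ks)`.
#' @export
kmer_spectrum <- function(window, ks = c(3L, 4L), width = 101L) {
  if (nchar(window) != width)
    stopf("window length %d, expected %d", nchar(window), width)
  dna <- Biostrings::DNAString(window)
  blocks <- lapply(ks, function(k) {
    counts <- Biostrings::oligonucleotideFrequency(dna, width = k)
    tot <- sum(counts)
    freq <- if (tot > 0) counts / tot else counts * 0
    names(freq) <- paste0("kmer", k, "_", names(freq))
    freq
  })
  unlist(blocks)
}

#' Relative position of a site along its transcript
#'
#' The distance of the site from the transcript start, scaled so the first
#' base maps to 0 and the last base to 1: `pos / (transcript_len - 1)`.
#'
#' @param pos 0-based site position.
#' @param transcript_len transcript length (>= 2).
#' @return numeric in \[0, 1\].
#' @export
relative_position <- function(pos, transcript_len) {
  if (any(transcript_len < 2L)) stopf("transcript_len must be >= 2")
  if (any(pos < 0L | pos >= transcript_len)) stopf("pos out of range")
  pos / (transcript_len - 1)
}

#' Feature layout (ordered column names) for a prediction mode
#'
#' @param mode `"mature"` or `"full"`.
#' @param positional_flank override of the positional window half-width
#'   (defaults: 5 for mature, 15 for full); exposed for ablation
#'   experiments only.
#' @return character vector of feature names in vector order.
#' @export
feature_layout <- function(mode = c("mature", "full"), positional_flank = NULL) {
  mode <- match.arg(mode)
  flank <- positional_flank %||% if (mode == "mature") 5L else 15L
  pos_names <- as.vector(t(outer(sprintf("pos_%d", -flank:flank),
                                 c("G", "C", "T", "A"), paste, sep = "_")))
  # take the k-mer order from the same routine that produces the counts
  dummy <- Biostrings::DNAString("ACGT")
  kmer_names <- unlist(lapply(c(3L, 4L), function(k) {
    paste0("kmer", k, "_",
           names(Biostrings::oligonucleotideFrequency(dummy, width = k)))
  }))
  if (mode == "mature") c(pos_names, kmer_names, "relpos", "struct_z")
  else c(pos_names, kmer_names)
}

#' Encode one candidate site as its fixed-order feature vector
#'
#' Mature mode concatenates the 11-nt positional one-hot, the k = 3,4
#' spectrum of the 101-nt window, the relative position, and the
#' structure Z-score of the 101-nt window. Full-transcript mode uses the
#' 31-nt positional one-hot and the k-mer spectrum only.
#'
#' @param transcript_id,pos identify the candidate (0-based central A).
#' @param trans transcript `data.frame` containing `transcript_id`.
#' @param mode `"mature"` or `"full"`; must match the transcripts' mode.
#' @param n_shuffles shuffles for the structure Z-score (mature mode).
#' @param seed optional seed for the shuffle set.
#' @param backend optional external-folder adapter, see [fold_mfe()].
#' @param positional_flank see [feature_layout()].
#' @return named numeric feature vector (length 366 mature / 444 full).
#' @export
assemble_features <- function(transcript_id, pos, trans,
                              mode = c("mature", "full"),
                              n_shuffles = 100L, seed = NULL, backend = NULL,
                              positional_flank = NULL) {
  mode <- match.arg(mode)
  tr <- transcript_by_id(trans, transcript_id)
  if (!is.null(tr$mode) && tr$mode[1L] != mode)
    stopf("transcript '%s' was loaded in %s mode but %s-mode features requested",
          transcript_id, tr$mode[1L], mode)
  seq <- tr$seq[1L]
  flank <- positional_flank %||% if (mode == "mature") 5L else 15L
  posblock <- encode_positional(extract_window(seq, pos, flank))
  kmers <- kmer_spectrum(extract_window(seq, pos, 50L))
  v <- if (mode == "mature") {
    c(posblock, kmers,
      relpos = relative_position(pos, nchar(seq)),
      struct_z = mfe_zscore(extract_window(seq, pos, 50L),
                            n_shuffles = n_shuffles, seed = seed,
                            backend = backend))
  } else {
    c(posblock, kmers)
  }
  names(v) <- feature_layout(mode, positional_flank = positional_flank)
  v
}

#' Build the feature matrix for a set of labeled or candidate sites
#'
#' Rows follow the input site order; the per-site structure-shuffle seed is
#' derived from `seed` and the site identity `(transcript_id, pos)`, so the
#' matrix is reproducible and row-order independent given one master seed.
#'
#' @param sites `data.frame` with columns `transcript_id`, `pos`.
#' @inheritParams assemble_features
#' @return numeric matrix, one row per site, columns per [feature_layout()].
#' @export
build_feature_matrix <- function(sites, trans, mode = c("mature", "full"),
                                 n_shuffles = 100L, seed = NULL,
                                 backend = NULL, positional_flank = NULL) {
  mode <- match.arg(mode)
  layout <- feature_layout(mode, positional_flank = positional_flank)
  X <- matrix(NA_real_, nrow = nrow(sites), ncol = length(layout),
              dimnames = list(NULL, layout))
  for (i in seq_len(nrow(sites))) {
    site_seed <- derive_seed(seed, site_stream(sites$transcript_id[i], sites$pos[i]))
    X[i, ] <- assemble_features(sites$transcript_id[i], sites$pos[i], trans,
                                mode = mode, n_shuffles = n_shuffles,
                                seed = site_seed, backend = backend,
                                positional_flank = positional_flank)
  }
  X
}

# stable small-integer stream id from a site identity
site_stream <- function(id, pos) {
  (sum(utf8ToInt(id)) * 131L + as.integer(pos)) %% 1000003L
}

#' Write a feature matrix with its site keys as TSV
#' @param X feature matrix from [build_feature_matrix()].
#' @param sites the site table the rows correspond to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(X, sites, path) {
  df <- cbind(sites[, c("transcript_id", "pos")], as.data.frame(X))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
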