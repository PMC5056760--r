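#' Build a transcript table from id/sequence pairs
#'
#' Normalizes sequences to the DNA alphabet: `U -> T`, lower case folded to
#' upper case, and any other character (IUPAC ambiguity codes included)
#' mapped to `N`. `N` positions never seed a DRACH candidate and contribute
#' nothing to k-mer counts or base pairing downstream.
#'
#' @param ids character vector of unique transcript identifiers.
#' @param seqs character vector of nucleotide sequences (DNA or RNA spelling).
#' @param mode `"mature"` for spliced mRNA or `"full"` for full transcripts.
#'   The mode only selects which feature set / model applies; both spellings
#'   are accepted in both modes.
#' @return a `data.frame` with columns `id`, `seq`, `mode`.
#' @export
transcripts <- function(ids, seqs, mode = c("mature", "full")) {
  mode <- match.arg(mode)
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs)) stopf("ids and seqs differ in length")
  if (length(ids) == 0L) stopf("empty transcript collection")
  if (anyDuplicated(ids)) {
    stopf("duplicate transcript id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- normalize_sequence(seqs)
  if (any(!nzchar(seqs))) stopf("empty sequence for id(s): %s",
                                paste(ids[!nzchar(seqs)], collapse = ", "))
  data.frame(id = ids, seq = seqs, mode = mode, stringsAsFactors = FALSE)
}

#' Normalize a nucleotide string to the {A,C,G,T,N} alphabet
#'
#' @param x character vector of sequences.
#' @return character vector: upper-cased, U replaced by T, all other
#'   non-ACGT characters replaced by N.
#' @export
normalize_sequence <- function(x) {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  gsub("[^ACGT]", "N", x)
}

#' Read transcripts from a FASTA file
#'
#' Uses the first whitespace-delimited token of each header as the
#' transcript id. Multi-line records are supported; sequences are
#' normalized as in [transcripts()].
#'
#' @param path path to a FASTA file.
#' @inheritParams transcripts
#' @return a transcript `data.frame` in record order.
#' @export
read_fasta <- function(path, mode = c("mature", "full")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("malformed FASTA '%s': %s",
                                            path, conditionMessage(e)))
  if (length(set) == 0L) stopf("FASTA file '%s' contains no records", path)
  ids <- sub("\\s.*$", "", names(set))
  transcripts(ids, as.character(set), mode = mode)
}

#' Write transcripts to a FASTA file
#' @param trans transcript `data.frame`.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(trans, path, width = 70L) {
  set <- Biostrings::BStringSet(trans$seq)
  names(set) <- trans$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# DRACH alphabet sets; H excludes G, D excludes C
.drach_sets <- list(D = c("A", "G", "T"), R = c("A", "G"),
                    A = "A", C = "C", H = c("A", "C", "T"))

#' Test 5-mers against the DRACH consensus
#'
#' DRACH is the m6A consensus: D in {A,G,T}, R in {A,G}, the methylated A,
#' then C, then H in {A,C,T} (RNA spelling uses U for T). Strings containing
#' `N` never match.
#'
#' @param motif character vector of 5-mers (DNA or RNA spelling).
#' @return logical vector.
#' @export
is_drach <- function(motif) {
  motif <- normalize_sequence(motif)
  nchar(motif) == 5L & grepl("^[AGT][AG]AC[ACT]$", motif)
}

#' Scan a transcript for DRACH-centered candidate adenosines
#'
#' Returns every position whose 5-nt context (two bases either side of the
#' central A) matches DRACH. Candidates whose motif would run off either
#' sequence end, or whose motif contains `N`, are not emitted.
#'
#' @param trans transcript `data.frame` (one or more rows).
#' @return a `data.frame` of candidate sites with columns `transcript_id`,
#'   `pos` (0-based index of the central A) and `motif` (the 5-mer),
#'   ascending by position within each transcript.
#' @export
scan_drach <- function(trans) {
  out <- lapply(seq_len(nrow(trans)), function(i) {
    seq <- trans$seq[i]
    m <- gregexpr("(?=[AGT][AG]AC[ACT])", seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    pos <- as.integer(m) + 1L                     # 0-based central A
    data.frame(transcript_id = trans$id[i], pos = pos,
               motif = substring(seq, pos - 1L, pos + 3L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), pos = integer(),
                      motif = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Extract a fixed-width window centered on a position
#'
#' Positions outside the sequence are filled with the gap character `N`, so
#' the returned window always has length `2 * flank + 1`.
#'
#' @param seq a single sequence string.
#' @param pos 0-based center position; must index into `seq`.
#' @param flank number of bases on each side of the center.
#' @return window string of length `2 * flank + 1`.
#' @export
extract_window <- function(seq, pos, flank) {
  n <- nchar(seq)
  if (pos < 0L || pos >= n) stopf("pos %d out of range [0, %d)", pos, n)
  lo <- pos - flank + 1L   # 1-based
  hi <- pos + flank + 1L
  core <- substring(seq, max(lo, 1L), min(hi, n))
  paste0(strrep("N", max(0L, 1L - lo)), core, strrep("N", max(0L, hi - n)))
}

#' Export candidate sites as 6-column BED
#'
#' One row per site: chrom = transcript id, start = pos, end = pos + 1,
#' name = motif, score = 0 (or a supplied score), strand = "+".
#'
#' @param sites candidate-site `data.frame` from [scan_drach()]; an optional
#'   `score` column is used for the BED score field.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$transcript_id,
                    start = sites$pos,
                    end = sites$pos + 1L,
                    name = sites$motif,
                    score = if ("score" %in% names(sites)) sites$score else 0,
                    strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Look up one transcript row by id, with a clear error
transcript_by_id <- function(trans, id) {
  i <- match(id, trans$id)
  if (is.na(i)) stopf("unknown transcript id: %s", id)
  trans[i, , drop = FALSE]
}
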