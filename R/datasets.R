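# Labeled-site tables: data.frame(transcript_id, pos, label, taxon?) with
# label in {"positive", "negative"}. Site identity is (transcript_id, pos);
# duplicates collapse to one record.

site_key <- function(x) paste(x$transcript_id, x$pos, sep = "\r")

labeled_sites <- function(transcript_id, pos, label, taxon = NA_character_) {
  df <- data.frame(transcript_id = as.character(transcript_id),
                   pos = as.integer(pos), label = as.character(label),
                   taxon = rep_len(as.character(taxon),
                                   length(transcript_id)),
                   stringsAsFactors = FALSE)
  df[!duplicated(site_key(df)), , drop = FALSE]
}

# coerce any site table to the canonical labeled columns
as_labeled <- function(x, label = NULL) {
  labeled_sites(x$transcript_id, x$pos,
                if (is.null(label)) x$label else label,
                taxon = if (is.null(x$taxon)) NA_character_ else x$taxon)
}

#' Read labeled sites from a 3-column TSV
#'
#' Columns: transcript id, 0-based position, label ("positive"/"negative"
#' or 1/0). A header line is detected and skipped.
#'
#' @param path TSV path.
#' @return labeled-site `data.frame` (`transcript_id`, `pos`, `label`).
#' @export
read_sites_tsv <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  # a header line has a non-numeric second field (the position column)
  has_header <- length(first) >= 2L &&
    is.na(suppressWarnings(as.numeric(first[2L])))
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stopf("expected >= 3 columns in %s", path)
  lab <- as.character(df[[3L]])
  lab[lab %in% c("1", "TRUE")] <- "positive"
  lab[lab %in% c("0", "FALSE")] <- "negative"
  if (!all(lab %in% c("positive", "negative")))
    stopf("labels must be positive/negative (or 1/0) in %s", path)
  labeled_sites(df[[1L]], df[[2L]], lab,
                taxon = if (ncol(df) >= 4L) as.character(df[[4L]]) else NA_character_)
}

#' Write labeled sites as TSV
#' @param sites labeled-site `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  cols <- intersect(c("transcript_id", "pos", "label", "taxon"), names(sites))
  write.table(sites[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read exclusion/peak intervals from BED
#'
#' Tolerant 3+ column BED reader (chrom, start, end, then optional name,
#' score, strand, summit). A 0-based absolute `summit` coordinate may be
#' supplied as a 7th column or as a `summit` header column.
#'
#' @param path BED path.
#' @return `data.frame` with `chrom`, `start`, `end` and, when present,
#'   `name` and `summit`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#", fill = TRUE)
  if (ncol(df) < 3L) stopf("BED needs >= 3 columns: %s", path)
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stopf("BED interval with start >= end in %s", path)
  if (ncol(df) >= 4L) out$name <- as.character(df[[4L]])
  if (ncol(df) >= 7L) out$summit <- as.integer(df[[7L]])
  out
}

# TRUE for sites whose coordinate lies in any [start, end) interval of its
# transcript
site_in_intervals <- function(sites, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(rep(FALSE, nrow(sites)))
  vapply(seq_len(nrow(sites)), function(i) {
    hit <- intervals$chrom == sites$transcript_id[i] &
      intervals$start <= sites$pos[i] & sites$pos[i] < intervals$end
    any(hit)
  }, logical(1))
}

#' Sample negative (non-methylated) DRACH sites
#'
#' Draws a uniform sample without replacement from all DRACH adenosines in
#' `trans` that are not positive sites and do not fall inside any excluded
#' interval (e.g. curated methylation peaks).
#'
#' @param trans transcript `data.frame`.
#' @param positives labeled or plain site `data.frame` (`transcript_id`,
#'   `pos`) to exclude.
#' @param count number of negatives to draw.
#' @param excluded_intervals optional BED-style `data.frame` from
#'   [read_bed()]; an adenosine is excluded when its coordinate lies in
#'   `[start, end)` on the matching transcript.
#' @param seed optional integer seed.
#' @return labeled-site `data.frame` with `label == "negative"`.
#' @export
sample_negatives <- function(trans, positives, count,
                             excluded_intervals = NULL, seed = NULL) {
  cand <- scan_drach(trans)
  pos_keys <- if (!is.null(positives) && nrow(positives)) site_key(positives) else character()
  eligible <- cand[!(site_key(cand) %in% pos_keys) &
                     !site_in_intervals(cand, excluded_intervals), , drop = FALSE]
  if (count > nrow(eligible))
    stopf("requested %d negatives but only %d eligible DRACH sites (short by %d)",
          count, nrow(eligible), count - nrow(eligible))
  idx <- with_seed(seed, sample(nrow(eligible), count))
  sel <- eligible[sort(idx), , drop = FALSE]
  labeled_sites(sel$transcript_id, sel$pos, "negative")
}

#' Split positives 75/25 into training and testing sets
#'
#' @param positives site `data.frame`.
#' @param train_fraction fraction assigned to training (default 0.75); the
#'   training size is `round(train_fraction * n)`.
#' @param seed optional integer seed.
#' @return list with elements `train` and `test` (disjoint, union = input).
#' @export
split_dataset <- function(positives, train_fraction = 0.75, seed = NULL) {
  n <- nrow(positives)
  if (n < 2L) stopf("need >= 2 positives to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  n_train <- as.integer(round(train_fraction * n))
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- with_seed(seed, sample(n, n_train))
  list(train = positives[sort(idx), , drop = FALSE],
       test = positives[-sort(idx), , drop = FALSE])
}

#' Build a balanced (1:1) training set
#'
#' Combines the training positives with an equal number of negatives drawn
#' from the supplied pool.
#'
#' @param train_pos positive sites for training.
#' @param negatives_pool negative labeled sites to draw from.
#' @param seed optional integer seed.
#' @return labeled-site `data.frame`, positives then sampled negatives.
#' @export
build_training_set <- function(train_pos, negatives_pool, seed = NULL) {
  n <- nrow(train_pos)
  if (nrow(negatives_pool) < n)
    stopf("negative pool (%d) smaller than positive count (%d)",
          nrow(negatives_pool), n)
  idx <- with_seed(seed, sample(nrow(negatives_pool), n))
  neg <- negatives_pool[sort(idx), , drop = FALSE]
  rbind(as_labeled(train_pos, label = "positive"),
        as_labeled(neg, label = "negative"))
}

#' Build an unbalanced (1:ratio) independent test set
#'
#' Mirrors the transcriptome-wide class imbalance: for every test positive,
#' `ratio` negatives are drawn (default 10). Negatives already used
#' elsewhere (e.g. in training) can be excluded via `exclude`.
#'
#' @param test_pos positive sites held out for testing.
#' @param negatives_pool negative labeled sites to draw from.
#' @param ratio negatives per positive (default 10).
#' @param exclude optional site `data.frame` whose records must not be
#'   reused (training negatives).
#' @param seed optional integer seed.
#' @return labeled-site `data.frame` with `ratio * n_pos` negatives.
#' @export
build_test_set <- function(test_pos, negatives_pool, ratio = 10L,
                           exclude = NULL, seed = NULL) {
  if (ratio < 1L) stopf("ratio must be >= 1")
  pool <- negatives_pool
  if (!is.null(exclude) && nrow(exclude))
    pool <- pool[!(site_key(pool) %in% site_key(exclude)), , drop = FALSE]
  need <- as.integer(ratio) * nrow(test_pos)
  if (nrow(pool) < need)
    stopf("negative pool (%d after exclusions) smaller than required %d",
          nrow(pool), need)
  idx <- with_seed(seed, sample(nrow(pool), need))
  rbind(as_labeled(test_pos, label = "positive"),
        as_labeled(pool[sort(idx), , drop = FALSE], label = "negative"))
}

#' Pool datasets across taxa
#'
#' Concatenates labeled-site tables, tagging each record with its taxon of
#' origin (e.g. to build a joint mammalian set from human + mouse).
#'
#' @param ... named labeled-site `data.frame`s; names become taxon tags for
#'   records lacking one.
#' @return combined labeled-site `data.frame` with a `taxon` column.
#' @export
pool_taxa <- function(...) {
  parts <- list(...)
  if (length(parts) == 0L)
    return(labeled_sites(character(), integer(), character()))
  tags <- names(parts) %||% rep(NA_character_, length(parts))
  parts <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (is.null(p$taxon) || all(is.na(p$taxon))) p$taxon <- tags[i]
    p
  })
  do.call(rbind, parts)
}

#' Assert that two site sets share no (transcript_id, pos) record
#' @param a,b site `data.frame`s.
#' @return TRUE invisibly; error on overlap.
#' @export
assert_disjoint <- function(a, b) {
  ov <- intersect(site_key(a), site_key(b))
  if (length(ov))
    stopf("site sets overlap on %d record(s)", length(ov))
  invisible(TRUE)
}
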