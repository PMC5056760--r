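# Synthetic transcripts with planted methylation signal. The planted-site
# model is a per-position categorical profile (a PWM) over the 11-nt window
# around the methylated A -- the generative counterpart of the positional
# one-hot feature -- plus an optional 3' placement bias (counterpart of the
# relative-position feature) and an optional hairpin-forming context
# (counterpart of the structure Z-score).

.bases <- c("A", "C", "G", "T")

# consensus letters for the 11-nt planted window (center 5-mer is the
# DRACH consensus GGACT; flanks are an arbitrary fixed choice)
.consensus11 <- c("G", "G", "T", "G", "G", "A", "C", "T", "G", "T", "C")

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a small but realistic mammalian mRNA world: 200
#' transcripts of 300-1500 nt with uniform base composition, three planted
#' m6A sites per transcript on average (mRNAs carry 3-5 on average), a 3'
#' placement bias, and >= 50 nt spacing between planted sites.
#'
#' @param n_transcripts number of background transcripts.
#' @param length_range min/max transcript length (uniform).
#' @param background_freq named A/C/G/T sampling probabilities.
#' @param n_positive number of planted sites (default `3 * n_transcripts`).
#' @param profile_strength signal strength in \[0, 1\]: 0 plants a uniform
#'   DRACH 5-mer in an otherwise background window (no learnable profile),
#'   1 plants the concentrated consensus profile.
#' @param three_prime_bias placement-bias strength b >= 0; relative
#'   positions are drawn from Beta(1 + b, 1) (b = 0 is uniform).
#' @param structure_signal embed a complementary 8-nt stem (a hairpin
#'   former) around a fraction of planted sites.
#' @param structure_fraction fraction of positives receiving the stem when
#'   `structure_signal` is on.
#' @param min_spacing minimum distance between planted sites on one
#'   transcript (default 50 nt, so truth labels never share a window).
#' @param seed integer seed; the config plus this seed regenerates the
#'   bundle bit-identically.
#' @return config list (class `m6a_synth_config`).
#' @export
synthetic_config <- function(n_transcripts = 200L,
                             length_range = c(300L, 1500L),
                             background_freq = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                             n_positive = NULL,
                             profile_strength = 1,
                             three_prime_bias = 1,
                             structure_signal = FALSE,
                             structure_fraction = 0.5,
                             min_spacing = 50L,
                             seed = 1L) {
  background_freq <- unlist(background_freq)
  if (is.null(names(background_freq))) names(background_freq) <- .bases
  background_freq <- background_freq[.bases]
  if (anyNA(background_freq)) stopf("background_freq needs A/C/G/T entries")
  background_freq <- background_freq / sum(background_freq)
  if (any(background_freq < 0)) stopf("negative background frequency")
  if (profile_strength < 0 || profile_strength > 1)
    stopf("profile_strength must be in [0, 1]")
  if (three_prime_bias < 0) stopf("three_prime_bias must be >= 0")
  structure(list(n_transcripts = as.integer(n_transcripts),
                 length_range = as.integer(length_range),
                 background_freq = background_freq,
                 n_positive = as.integer(n_positive %||% (3L * n_transcripts)),
                 profile_strength = profile_strength,
                 three_prime_bias = three_prime_bias,
                 structure_signal = isTRUE(structure_signal),
                 structure_fraction = structure_fraction,
                 min_spacing = as.integer(min_spacing),
                 seed = as.integer(seed)),
            class = "m6a_synth_config")
}

# 11 x 4 probability matrix for the planted window at a given strength.
# Center positions stay DRACH-conformant at every strength; at strength 0
# they are uniform over the allowed letters and flanks equal background.
planted_profile <- function(config) {
  s <- config$profile_strength
  bg <- config$background_freq[.bases]
  conc <- function(allowed, peak_letter, peak = 0.8) {
    p <- stats::setNames(rep((1 - peak) / (length(allowed) - 1), 4), .bases)
    p[setdiff(.bases, allowed)] <- 0
    p[peak_letter] <- peak
    p / sum(p)
  }
  unif <- function(allowed) {
    p <- stats::setNames(rep(0, 4), .bases)
    p[allowed] <- 1 / length(allowed)
    p
  }
  prof <- matrix(0, nrow = 11L, ncol = 4L,
                 dimnames = list(sprintf("pos_%d", -5:5), .bases))
  for (i in 1:11) {
    off <- i - 6L
    prof[i, ] <- if (off %in% -5:-3 || off %in% 3:5) {
      s * conc(.bases, .consensus11[i], peak = 0.85) + (1 - s) * bg
    } else if (off == -2L) {               # D
      s * conc(c("A", "G", "T"), "G") + (1 - s) * unif(c("A", "G", "T"))
    } else if (off == -1L) {               # R
      s * conc(c("A", "G"), "G", peak = 0.85) + (1 - s) * unif(c("A", "G"))
    } else if (off == 0L) {
      unif("A")                            # the methylated A
    } else if (off == 1L) {
      unif("C")
    } else {                               # H
      s * conc(c("A", "C", "T"), "T") + (1 - s) * unif(c("A", "C", "T"))
    }
  }
  prof
}

#' Generate background transcripts
#'
#' i.i.d. sequences from the background base frequencies with lengths
#' uniform over `length_range`; deterministic given `config$seed`.
#'
#' @param config from [synthetic_config()].
#' @return transcript `data.frame` (ids `synth_0001`, ...).
#' @export
generate_background <- function(config) {
  with_seed(derive_seed(config$seed, 101L), {
    lens <- sample(config$length_range[1L]:config$length_range[2L],
                   config$n_transcripts, replace = TRUE)
    seqs <- vapply(lens, function(n)
      paste(sample(.bases, n, replace = TRUE, prob = config$background_freq),
            collapse = ""), "")
    transcripts(sprintf("synth_%04d", seq_len(config$n_transcripts)), seqs)
  })
}

#' Plant positive (methylated) sites into transcripts
#'
#' Draws an 11-nt context from the planted profile and writes it into the
#' sequence at a position sampled with the configured 3' bias, keeping
#' planted sites at least `min_spacing` apart. When the structure signal is
#' on, a complementary 8-nt stem is written at offsets -20..-13 / +13..+20
#' around a fraction of sites so their 101-nt window folds more stably
#' than shuffled background.
#'
#' @param trans background transcripts from [generate_background()].
#' @param config from [synthetic_config()].
#' @return list with `trans` (mutated sequences) and `positives` (labeled
#'   sites, `label == "positive"`, plus a `stem` flag).
#' @export
plant_positive_sites <- function(trans, config) {
  prof <- planted_profile(config)
  b <- config$three_prime_bias
  with_seed(derive_seed(config$seed, 202L), {
    placed <- vector("list", config$n_positive)
    occupied <- lapply(seq_len(nrow(trans)), function(i) integer())
    lens <- nchar(trans$seq)
    n_done <- 0L
    tries <- 0L
    max_tries <- 200L * config$n_positive
    while (n_done < config$n_positive && tries < max_tries) {
      tries <- tries + 1L
      ti <- sample.int(nrow(trans), 1L, prob = lens)
      # 0-based site position; needs room for the stem (+/-20) and motif
      lo <- 20L
      hi <- lens[ti] - 21L
      if (hi <= lo) next
      rel <- stats::rbeta(1L, 1 + b, 1)
      pos <- lo + as.integer(floor(rel * (hi - lo + 1)))
      pos <- min(pos, hi)
      if (length(occupied[[ti]]) &&
          min(abs(occupied[[ti]] - pos)) < config$min_spacing) next
      window <- vapply(1:11, function(i)
        sample(.bases, 1L, prob = prof[i, ]), "")
      seqc <- strsplit(trans$seq[ti], "", fixed = TRUE)[[1]]
      seqc[(pos - 5L):(pos + 5L) + 1L] <- window
      stem <- config$structure_signal &&
        stats::runif(1L) < config$structure_fraction
      if (stem) {
        left <- seqc[(pos - 20L):(pos - 13L) + 1L]
        seqc[(pos + 13L):(pos + 20L) + 1L] <-
          rev(chartr("ACGT", "TGCA", left))
      }
      trans$seq[ti] <- paste(seqc, collapse = "")
      occupied[[ti]] <- c(occupied[[ti]], pos)
      n_done <- n_done + 1L
      placed[[n_done]] <- data.frame(transcript_id = trans$id[ti], pos = pos,
                                     stem = stem, stringsAsFactors = FALSE)
    }
    if (n_done < config$n_positive)
      stopf("could only place %d of %d sites; transcripts too short/crowded",
            n_done, config$n_positive)
    pos_df <- do.call(rbind, placed[seq_len(n_done)])
    positives <- labeled_sites(pos_df$transcript_id, pos_df$pos, "positive")
    positives$stem <- pos_df$stem[match(site_key(positives), site_key(pos_df))]
    list(trans = trans, positives = positives)
  })
}

#' Generate a complete synthetic bundle
#'
#' Background transcripts + planted positives + the generative manifest.
#' With `dir` set, writes `transcripts.fasta`, `sites.tsv` (the positive
#' truth labels) and `manifest.json` there.
#'
#' @param config from [synthetic_config()].
#' @param dir optional output directory.
#' @return list with `trans`, `positives`, `manifest` (and `paths` when
#'   written to disk).
#' @export
generate_dataset <- function(config, dir = NULL) {
  trans <- generate_background(config)
  planted <- plant_positive_sites(trans, config)
  manifest <- unclass(config)
  manifest$background_freq <- as.list(config$background_freq)  # keep names
  manifest$generator <- "m6Ascan-synthetic"
  manifest$n_placed <- nrow(planted$positives)
  out <- list(trans = planted$trans, positives = planted$positives,
              manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "transcripts.fasta"),
                  sites = file.path(dir, "sites.tsv"),
                  manifest = file.path(dir, "manifest.json"))
    write_fasta(out$trans, paths$fasta)
    write_sites_tsv(out$positives, paths$sites)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA)
    out$paths <- paths
  }
  out
}
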