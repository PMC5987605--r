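#' Stimulus-sequence configuration
#'
#' Describes the compressed auditory sequence: repeated blocks, each holding a
#' short tone train followed by a prime-target word pair. Defaults reproduce a
#' 60-block, five-tone/two-word sequence lasting 5 minutes, with 30 congruent
#' and 30 incongruent word targets.
#'
#' @param n_blocks number of blocks.
#' @param tones_per_block tones at the start of each block.
#' @param deviant_prob probability that a tone is a deviant rather than a
#'   standard.
#' @param tone_soa tone stimulus-onset asynchrony, seconds.
#' @param prime_onset_in_block onset of the prime word within a block, seconds.
#' @param prime_target_soa prime-to-target interval, seconds.
#' @param block_duration block length, seconds.
#' @param congruent_fraction fraction of word targets labelled congruent.
#' @return A validated list of class `sequence_config`.
#' @export
sequence_config <- function(n_blocks = 60L, tones_per_block = 5L,
                            deviant_prob = 0.2, tone_soa = 0.6,
                            prime_onset_in_block = 3.3, prime_target_soa = 1.0,
                            block_duration = 5.0, congruent_fraction = 0.5) {
  cfg <- list(n_blocks = as.integer(n_blocks),
              tones_per_block = as.integer(tones_per_block),
              deviant_prob = deviant_prob, tone_soa = tone_soa,
              prime_onset_in_block = prime_onset_in_block,
              prime_target_soa = prime_target_soa,
              block_duration = block_duration,
              congruent_fraction = congruent_fraction)
  check_that(cfg$n_blocks >= 1L, "n_blocks must be >= 1")
  check_that(cfg$tones_per_block >= 1L, "tones_per_block must be >= 1")
  for (f in c("tone_soa", "prime_onset_in_block", "prime_target_soa", "block_duration")) {
    check_that(is_scalar_num(cfg[[f]]) && cfg[[f]] > 0, "%s must be > 0", f)
  }
  check_that(cfg$deviant_prob >= 0 && cfg$deviant_prob <= 1,
             "deviant_prob must be in [0, 1]")
  check_that(cfg$congruent_fraction >= 0 && cfg$congruent_fraction <= 1,
             "congruent_fraction must be in [0, 1]")
  last_tone <- (cfg$tones_per_block - 1L) * cfg$tone_soa
  check_that(last_tone < cfg$prime_onset_in_block,
             "tone train overlaps the prime: tone_soa x tones_per_block reaches %.3f s but prime_onset_in_block is %.3f s",
             last_tone, cfg$prime_onset_in_block)
  check_that(cfg$prime_onset_in_block + cfg$prime_target_soa < cfg$block_duration,
             "prime_onset_in_block + prime_target_soa must be < block_duration")
  class(cfg) <- "sequence_config"
  cfg
}

#' Generate a stimulus event sequence
#'
#' Lays out `n_blocks` blocks of tones followed by a prime-target word pair.
#' Deviant tone positions are drawn per tone with probability `deviant_prob`;
#' target conditions come from a balanced congruent/incongruent label vector
#' shuffled under the seed, so the two condition counts never differ by more
#' than one.
#'
#' @param cfg a [sequence_config].
#' @param seed integer seed; the sequence is deterministic given `(cfg, seed)`.
#' @return An `event_table`: a data.frame with columns `onset` (seconds from
#'   recording start), `kind` (`tone_std`, `tone_dev`, `word_prime`,
#'   `word_target`), `condition` (`congruent`, `incongruent`, `none`) and
#'   `block` (0-based block index).
#' @export
generate_event_sequence <- function(cfg = sequence_config(), seed = 1L) {
  if (!inherits(cfg, "sequence_config")) cfg <- do.call(sequence_config, cfg)
  n_targets <- cfg$n_blocks
  n_cong <- round(cfg$congruent_fraction * n_targets)
  labels <- c(rep("congruent", n_cong), rep("incongruent", n_targets - n_cong))
  with_seed(seed, {
    labels <- sample(labels)
    deviant <- runif(cfg$n_blocks * cfg$tones_per_block) < cfg$deviant_prob
  })
  rows <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    t0 <- (b - 1L) * cfg$block_duration
    tone_onsets <- t0 + (seq_len(cfg$tones_per_block) - 1L) * cfg$tone_soa
    dev <- deviant[(b - 1L) * cfg$tones_per_block + seq_len(cfg$tones_per_block)]
    rows[[b]] <- data.frame(
      onset = c(tone_onsets, t0 + cfg$prime_onset_in_block,
                t0 + cfg$prime_onset_in_block + cfg$prime_target_soa),
      kind = c(ifelse(dev, "tone_dev", "tone_std"), "word_prime", "word_target"),
      condition = c(rep("none", cfg$tones_per_block), "none", labels[b]),
      block = b - 1L,
      stringsAsFactors = FALSE
    )
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Write / read an event table as tab-separated text
#'
#' The on-disk format is a TSV with header `onset\tkind\tcondition\tblock`,
#' onsets printed with 6 decimals.
#'
#' @param events an `event_table` data.frame.
#' @param path file path.
#' @return `read_events` returns the `event_table`.
#' @export
write_events <- function(events, path) {
  out <- events
  out$onset <- sprintf("%.6f", out$onset)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  check_that(identical(names(ev), c("onset", "kind", "condition", "block")),
             "event file must have columns onset, kind, condition, block")
  ev$onset <- as.numeric(ev$onset)
  ev$block <- as.integer(ev$block)
  class(ev) <- c("event_table", "data.frame")
  ev
}
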