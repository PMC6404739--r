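#' Permuted-block treatment allocation
#'
#' Generates the pre-determined randomization sequence for a two-arm trial
#' using permuted blocks: every complete block of `block_size` participants
#' contains exactly `block_size / 2` of each arm in random order, keeping the
#' arms balanced over time. A final partial block is the leading portion of a
#' freshly permuted balanced block, so arm totals can differ by at most
#' `block_size / 2`.
#'
#' The sequence is a deterministic function of the R random-number state; set
#' a seed beforehand (or use the `seed` argument) to reproduce it.
#'
#' @param n Number of participants to allocate.
#' @param block_size Block length (even; default 6).
#' @param arms Character vector of the two arm labels.
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first so the allocation table is reproducible on its own.
#' @return A data.frame with columns `participant_id`, `arm`, `block_index`,
#'   `position_in_block` (0-based).
#' @export
permuted_block_sequence <- function(n, block_size = 6L,
                                    arms = c("EFMT", "CT"), seed = NULL) {
  n <- as.integer(n)
  block_size <- as.integer(block_size)
  stopifnot(n >= 1L, length(arms) == 2L, block_size %% 2L == 0L,
            block_size >= 2L)
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- ceiling(n / block_size)
  alloc <- unlist(lapply(seq_len(n_blocks), function(b) {
    sample(rep(arms, each = block_size %/% 2L))
  }))[seq_len(n)]
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    arm = alloc,
    block_index = (seq_len(n) - 1L) %/% block_size + 1L,
    position_in_block = (seq_len(n) - 1L) %% block_size,
    stringsAsFactors = FALSE
  )
}
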