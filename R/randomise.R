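#' Stratified permuted-block randomisation
#'
#' Assigns participants 1:1 to two arms within strata using randomly permuted
#' blocks. Participants are taken in entry order; within each stratum the
#' sequence of assignments is a concatenation of independent random
#' permutations of `block_size/2` zeros and ones, with the final block
#' truncated if the stratum size is not a multiple of the block length.
#' Every completed block is therefore exactly balanced and the arm imbalance
#' within a stratum never exceeds `block_size/2`.
#'
#' @param strata vector of stratum labels, one per participant, in entry
#'   order (any atomic type; typically 0/1).
#' @param block_size block length; must be a positive even integer.
#' @return Integer vector of treatment assignments in \{0,1\}, aligned with
#'   `strata`.
#' @examples
#' set.seed(1)
#' t <- randomise_stratified_blocks(rep(0:1, each = 10), block_size = 4)
#' table(t, rep(0:1, each = 10))
#' @export
randomise_stratified_blocks <- function(strata, block_size = 4L) {
  if (!is.numeric(block_size) || length(block_size) != 1L ||
      block_size <= 0 || block_size %% 2 != 0) {
    stop("`block_size` must be a positive even integer: permuted blocks ",
         "must contain each arm equally often.", call. = FALSE)
  }
  block_size <- as.integer(block_size)
  n <- length(strata)
  assign <- integer(n)
  template <- rep(c(0L, 1L), each = block_size %/% 2L)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_s <- length(idx)
    n_blocks <- ceiling(n_s / block_size)
    blocks <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      blocks[[b]] <- sample(template)
    }
    seq_s <- unlist(blocks, use.names = FALSE)
    assign[idx] <- seq_s[seq_len(n_s)]
  }
  assign
}

#' Simple (unrestricted) randomisation
#'
#' Independent fair-coin assignment, used for sensitivity analyses comparing
#' stratified with simple randomisation.
#'
#' @param n number of participants.
#' @return Integer vector of assignments in \{0,1\}.
#' @export
randomise_simple <- function(n) {
  stats::rbinom(n, 1L, 0.5)
}
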