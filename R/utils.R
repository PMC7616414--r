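#' Per-replication seed streams
#'
#' Derives one RNG seed per replication from a scenario's root seed. The
#' whole vector is generated up front from the root seed, so replication `r`
#' always receives the same seed regardless of execution order or the number
#' of workers — results are reproducible and order-insensitive.
#'
#' @param root_seed scenario root seed (integer).
#' @param n number of replications.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
replication_seeds <- function(root_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(root_seed))
  sample.int(2147483646L, n)
}
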