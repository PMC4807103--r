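#' Derive a reproducible substream seed
#'
#' Folds a master seed and a set of integer stream indices into a single
#' 31-bit seed via a multiplicative hash, so that per-subject/per-condition
#' random substreams are mutually independent yet fully determined by the
#' master seed.
#'
#' @param seed master integer seed.
#' @param ... integer stream indices (e.g. subject, condition).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  h <- 0
  for (k in idx) {
    # 31-bit LCG-style fold; constants are the classic Park-Miller modulus
    # and a large odd multiplier
    h <- (h * 69069 + as.numeric(k) * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(h %% 2147483645L + 1L)
}

#' Minimum run length (samples) for a persistence criterion
#'
#' Converts a temporal-persistence criterion in milliseconds into the number
#' of contiguous samples at a given sampling rate (e.g. 20 ms at 500 Hz =
#' 10 samples).
#'
#' @param ms criterion duration in milliseconds.
#' @param sampling_rate sampling rate in Hz.
#' @return integer number of contiguous samples.
#' @export
min_run_samples <- function(ms, sampling_rate) {
  as.integer(round(ms * sampling_rate / 1000))
}

#' Two-tailed critical t value
#'
#' The absolute t value at which a two-tailed paired t-test with `df` degrees
#' of freedom reaches significance level `alpha` (e.g. 2.14 for alpha = .05,
#' df = 14, i.e. 15 paired subjects).
#'
#' @param alpha two-tailed significance level.
#' @param df degrees of freedom (n subjects − 1).
#' @return positive numeric critical value.
#' @export
t_critical <- function(alpha = 0.05, df) {
  stats::qt(1 - alpha / 2, df)
}

# Clear runs of TRUE shorter than min_run in a logical vector.
filter_runs <- function(x, min_run) {
  if (min_run <= 1L || !any(x)) return(x)
  r <- rle(x)
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

# Contiguous TRUE runs as a two-column matrix of start/end indices.
run_intervals <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Connected components of a vertex subset under an adjacency list.
# adjacency: list of integer neighbour vectors (full graph); members: integer
# vertex ids defining the induced subgraph. Returns a list of integer vectors.
connected_components <- function(adjacency, members) {
  if (length(members) == 0L) return(list())
  in_set <- logical(length(adjacency))
  in_set[members] <- TRUE
  seen <- logical(length(adjacency))
  comps <- list()
  for (v in members) {
    if (seen[v]) next
    comp <- integer(0)
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, u)
      nb <- adjacency[[u]]
      nb <- nb[in_set[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

`%||%` <- function(a, b) if (is.null(a)) b else a
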