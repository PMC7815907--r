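# Shared small helpers: intron-chain string codecs, exact binomial point
# probabilities, percentage formatting used in result summaries.

#' Encode an intron chain as its canonical string form
#'
#' Introns are stored internally as 0-based half-open intervals
#' `(first intronic base, one-past-last intronic base)`. The canonical string
#' is `"d1-a1;d2-a2;..."` in genomic order, or `""` for an unspliced molecule.
#'
#' @param donors,acceptors integer vectors of equal length (may be empty).
#' @return a single character string.
#' @export
chain_string <- function(donors, acceptors) {
  if (length(donors) == 0L) return("")
  stopifnot(length(donors) == length(acceptors))
  o <- order(donors)
  paste(paste0(donors[o], "-", acceptors[o]), collapse = ";")
}

#' Decode an intron-chain string
#'
#' @param chain a chain string as produced by [chain_string()]; `""`, `"."`
#'   and `NA` denote an unspliced molecule.
#' @return a two-column integer matrix with columns `donor`, `acceptor`
#'   (zero rows for unspliced).
#' @export
parse_chain <- function(chain) {
  if (is.na(chain) || chain == "" || chain == ".") {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("donor", "acceptor"))))
  }
  parts <- strsplit(strsplit(chain, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE,
              dimnames = list(NULL, c("donor", "acceptor")))
  m
}

# Long-format junction table for a vector of chain strings.
# Returns data.table(read_idx, pos, donor, acceptor); spliced reads only.
chains_to_long <- function(chains) {
  spl <- strsplit(chains, ";", fixed = TRUE)
  spl[is.na(chains) | chains == "" | chains == "."] <- list(character(0))
  n <- lengths(spl)
  idx <- rep.int(seq_along(chains), n)
  flat <- unlist(spl, use.names = FALSE)
  if (length(flat) == 0L) {
    return(data.table(read_idx = integer(0), pos = integer(0),
                      donor = integer(0), acceptor = integer(0)))
  }
  da <- matrix(as.integer(unlist(strsplit(flat, "-", fixed = TRUE),
                                 use.names = FALSE)), ncol = 2L, byrow = TRUE)
  data.table(read_idx = idx,
             pos = sequence(n),
             donor = da[, 1L],
             acceptor = da[, 2L])
}

# Rebuild chain strings from a long junction table covering reads 1..n.
long_to_chains <- function(long, n) {
  out <- rep("", n)
  if (nrow(long) == 0L) return(out)
  long <- long[order(read_idx, donor)]
  agg <- long[, .(chain = paste(paste0(donor, "-", acceptor), collapse = ";")),
              by = read_idx]
  out[agg$read_idx] <- agg$chain
  out
}

#' Exact symmetric binomial point probability and tail
#'
#' `binom_point_prob()` returns `choose(n, k) * 0.5^n`, the probability of
#' exactly `k` successes among `n` fair Bernoulli trials, computed on the log
#' scale; `binom_tail_prob()` returns the one-sided upper tail `P(X >= k)`.
#'
#' @param k,n non-negative integers, `k <= n`.
#' @return a probability.
#' @export
binom_point_prob <- function(k, n) {
  stopifnot(k >= 0, n >= k)
  exp(lchoose(n, k) + n * log(0.5))
}

#' @rdname binom_point_prob
#' @export
binom_tail_prob <- function(k, n) {
  stopifnot(k >= 0, n >= k)
  pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}

#' Format a count fraction as a percentage label
#'
#' Summary tables report fractions like `31/2132` as `"1.45%"` and `151/395`
#' as `"38.2%"`, i.e. three significant digits.
#'
#' @param k numerator count.
#' @param n denominator count (> 0).
#' @param digits significant digits (default 3).
#' @return character vector of labels.
#' @export
percent_label <- function(k, n, digits = 3) {
  stopifnot(all(n > 0))
  paste0(signif(100 * k / n, digits), "%")
}

# Reverse complement of short DNA strings (vectorized, base R).
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
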