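#' Correct classification rate
#'
#' Fraction of subjects whose found cluster matches their true group under
#' the best bijective relabelling of clusters onto groups (optimal
#' assignment, found by enumerating label bijections).  Invariant under
#' label permutations of either argument; always at least `1/k` against a
#' balanced truth.
#'
#' @param p found partition (integer/factor labels).
#' @param truth reference partition of the same length.
#' @return A number in `[0, 1]`; 1 iff the partitions agree up to
#'   relabelling.
#' @examples
#' crate(c(1, 1, 1, 2), c(1, 1, 2, 2)) # 0.75
#' @export
crate <- function(p, truth) {
  if (length(p) != length(truth)) stop("partitions must have equal length")
  if (length(p) == 0L) stop("partitions must be non-empty")
  tab <- table(p, truth)
  K <- max(dim(tab))
  if (K > 8L)
    stop("label matching by enumeration supports at most 8 clusters")
  sq <- matrix(0, K, K)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  best <- 0
  for (perm in perms(K)) {
    s <- sum(sq[cbind(seq_len(K), perm)])
    if (s > best) best <- s
  }
  best / length(p)
}

# all permutations of 1..k as a list
perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in perms(k - 1L)) {
      v <- integer(k)
      v[1L] <- i
      v[-1L] <- setdiff(seq_len(k), i)[rest]
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions
#' (Hubert-Arabie adjustment): 1 for identical partitions up to
#' relabelling, expectation ~0 for independent random partitions.
#' Delegates to [e1071::classAgreement()].
#'
#' @inheritParams crate
#' @return A number in `(-1, 1]`.
#' @examples
#' arand(c(1, 2, 1, 2), c(2, 1, 2, 1)) # 1
#' @export
arand <- function(p, truth) {
  if (length(p) != length(truth)) stop("partitions must have equal length")
  e1071::classAgreement(table(p, truth))$crand
}
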