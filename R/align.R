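# Global pairwise alignment with match = 1, mismatch = 0, gap = 0.
# With this scoring the optimal score equals the maximum number of identically
# aligned residue pairs, so the dynamic program reduces to a longest-common-
# subsequence recursion whose row update is fully vectorisable (gap moves are
# free, hence each row is the running maximum of its candidate scores).

.align_score <- function(a, b) {
  n2 <- length(b)
  prev <- numeric(n2 + 1L)
  for (i in seq_along(a)) {
    m <- as.numeric(a[i] == b)
    cand <- pmax(prev[-1L], prev[-(n2 + 1L)] + m)
    prev <- c(0, cummax(cand))
  }
  prev[n2 + 1L]
}

#' Global alignment of two sequences
#'
#' Needleman-Wunsch alignment scored match = 1, mismatch = 0, gap = 0.
#' Among co-optimal alignments the traceback deterministically prefers
#' diagonal, then up (gap in the second sequence), then left moves, which
#' places gaps rightmost.
#'
#' @param s1,s2 sequences as single strings.
#' @return list with `score` (number of identical aligned pairs) and `map`,
#'   an integer vector over positions of `s1` giving the aligned position in
#'   `s2` (`NA` where `s1` is aligned to a gap).
#' @export
align_global <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n1 <- length(a)
  n2 <- length(b)
  if (!n1 || !n2) stop("sequences must be nonempty")
  H <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in seq_len(n1)) {
    m <- as.numeric(a[i] == b)
    cand <- pmax(H[i, -1L], H[i, -(n2 + 1L)] + m)
    H[i + 1L, ] <- c(0, cummax(cand))
  }
  map <- rep(NA_integer_, n1)
  i <- n1
  j <- n2
  while (i > 0L && j > 0L) {
    if (H[i + 1L, j + 1L] == H[i, j] + (a[i] == b[j])) {
      map[i] <- j
      i <- i - 1L
      j <- j - 1L
    } else if (H[i + 1L, j + 1L] == H[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = H[n1 + 1L, n2 + 1L], map = map)
}

#' Sequence identity and length ratio of a chain pair
#'
#' Identity is the number of identically aligned residues under global
#' alignment (match = 1, mismatch = 0, gap = 0) divided by the length of the
#' shorter sequence; the length ratio is min/max of the two lengths.
#'
#' @param s1,s2 sequences as single strings.
#' @return named numeric vector with `identity` and `length_ratio`.
#' @export
pairwise_identity <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  if (!length(a) || !length(b)) stop("sequences must be nonempty")
  sc <- .align_score(a, b)
  c(identity = sc / min(length(a), length(b)),
    length_ratio = min(length(a), length(b)) / max(length(a), length(b)))
}
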