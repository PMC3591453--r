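# Pairwise dissimilarity and the small analytic utilities built on it.

#' Pairwise dissimilarity between two sequences
#'
#' Global end-to-end (Needleman-Wunsch) alignment under unit costs (match 0,
#' mismatch 1, indel 1); the dissimilarity is
#' `(mismatches + indel columns) / alignment columns` taken from a
#' deterministic traceback. The pair is put into a canonical order before
#' aligning, so the measure is exactly symmetric; it is zero iff the
#' sequences are identical.
#'
#' @param a,b non-empty nucleotide sequences (character scalars).
#' @param band optional half-width of an alignment band around the diagonal.
#'   A banded alignment can only over-estimate the unbanded dissimilarity, so
#'   it is safe whenever the question is "is the distance below `d`" and the
#'   band covers `2 * d * max(nchar)`; `NULL` (default) runs the full dynamic
#'   program.
#' @return Dissimilarity as a fraction in `[0, 1]`.
#' @seealso [alignment_stats()] for the underlying counts.
#' @export
pairwise_distance <- function(a, b, band = NULL) {
  .nw_distance(a, b, if (is.null(band) || !is.finite(band)) -1L
               else as.integer(band))
}

#' Alignment statistics for a sequence pair
#'
#' @inheritParams pairwise_distance
#' @return A list with `edits`, `mismatches`, `indels`, `columns` and
#'   `distance`.
#' @export
alignment_stats <- function(a, b, band = NULL) {
  .nw_align(a, b, if (is.null(band) || !is.finite(band)) -1L
            else as.integer(band))
}

.distance_many <- function(a, bs, band = NULL) {
  .nw_distance_many(a, bs, if (is.null(band) || !is.finite(band)) -1L
                    else as.integer(band))
}

#' Number of pairwise comparisons for an all-vs-all distance matrix
#'
#' `n (n - 1) / 2`: the cost driver of distance-matrix clustering approaches
#' on high-diversity data (for 8647 dereplicated sequences this is already
#' 37,380,981 global alignments).
#'
#' @param n number of sequences (non-negative).
#' @return Number of unordered pairs, as a double to avoid integer overflow.
#' @export
pairwise_comparison_count <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop("n must be a single non-negative integer")
  n <- as.numeric(n)
  n * (n - 1) / 2
}

#' Largest error count tolerated by a dissimilarity threshold
#'
#' The maximum number of sequencing errors that still leaves a read within
#' dissimilarity `d` of its error-free original: `floor(length * d)`. At the
#' species-level 3% threshold this is 6 errors for a 200-nt read and 9 for a
#' 300-nt read, which is why isolated erroneous reads are expected to surface
#' as singleton OTUs rather than join an existing cluster.
#'
#' @param length read length in nucleotides (>= 1).
#' @param d dissimilarity threshold as a fraction.
#' @return Integer error count.
#' @export
max_tolerated_errors <- function(length, d) {
  if (length < 1) stop("length must be >= 1")
  if (d < 0 || d >= 1) stop("d must be in [0, 1)")
  # guard against 300 * 0.03 landing just below 9 in floating point
  as.integer(floor(length * d + sqrt(.Machine$double.eps)))
}

.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' K-mer candidate prefilter for centroid search
#'
#' Cheap screen used by the greedy clusterer before paying for alignments:
#' keeps the centroids sharing at least `min_shared_fraction` of the query's
#' distinct k-mers. At the defaults (`k = 8`, fraction 0.5) this is a
#' generous superset of the centroids that can lie within a 3% clustering
#' threshold of the query, while unrelated sequences share essentially no
#' 8-mers.
#'
#' @param query a nucleotide sequence.
#' @param centroid_seqs character vector of centroid sequences.
#' @param k k-mer size (>= 3).
#' @param min_shared_fraction minimum shared fraction of the query's distinct
#'   k-mers.
#' @return Integer indices into `centroid_seqs`, in input order.
#' @export
kmer_candidate_filter <- function(query, centroid_seqs, k = 8L,
                                  min_shared_fraction = 0.5) {
  if (k < 3L) stop("k must be >= 3")
  if (length(centroid_seqs) == 0L) return(integer(0))
  q <- .kmer_set(query, k)
  if (length(q) == 0L) return(seq_along(centroid_seqs))
  shared <- vapply(centroid_seqs, function(s) {
    mean(q %in% .kmer_set(s, k))
  }, numeric(1L), USE.NAMES = FALSE)
  which(shared >= min_shared_fraction)
}
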