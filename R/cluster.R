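# OTU clustering: a greedy centroid clusterer (the workhorse, the approach
# fast amplicon pipelines take) and a brute-force all-pairs single-linkage
# clusterer used as an oracle on small inputs.

new_cluster_map <- function(assignments, centroids, threshold, method) {
  structure(list(assignments = assignments,  # named integer, read id -> cluster
                 centroids = centroids,      # read id per cluster, index = id + 1
                 threshold = threshold,
                 method = method),
            class = "cluster_map")
}

#' Number of clusters in a cluster map
#' @param cm a `cluster_map`.
#' @return Integer cluster count (observed richness, S_obs).
#' @export
n_clusters <- function(cm) length(cm$centroids)

#' Cluster sizes (the abundance vector)
#'
#' @param cm a `cluster_map`.
#' @return Integer vector of cluster sizes in cluster-id order; its length is
#'   the observed richness and its sum the number of assigned reads.
#' @export
abundance_vector <- function(cm) {
  stopifnot(inherits(cm, "cluster_map"))
  if (length(cm$assignments) == 0L) return(integer(0))
  tabulate(cm$assignments + 1L, nbins = length(cm$centroids))
}

#' Reads sitting in singleton clusters
#'
#' @param cm a `cluster_map`.
#' @return Character vector of read ids whose cluster has exactly one member.
#' @export
singleton_ids <- function(cm) {
  sizes <- abundance_vector(cm)
  names(cm$assignments)[cm$assignments %in% (which(sizes == 1L) - 1L)]
}

# Dereplicate identical sequences; returns unique sequences with duplicate
# counts and the member ids of each, ordered per the requested policy.
.dereplicate <- function(reads, order = c("abundance", "length", "input")) {
  order <- match.arg(order)
  grp <- split(seq_len(nrow(reads)), factor(reads$sequence,
                                            levels = unique(reads$sequence)))
  seqs <- names(grp)
  count <- lengths(grp)
  rep_id <- unname(vapply(grp, function(ix) reads$id[ix[1L]], character(1L)))
  len <- nchar(seqs)
  ord <- switch(order,
    abundance = order(-count, -len, rep_id, method = "radix"),
    length    = order(-len, rep_id, method = "radix"),
    input     = seq_along(seqs))
  list(seqs = seqs[ord], count = count[ord], rep_id = rep_id[ord],
       members = lapply(grp[ord], function(ix) reads$id[ix]))
}

#' Greedy centroid OTU clustering at a fixed dissimilarity threshold
#'
#' Dereplicates identical sequences, processes the unique sequences in
#' decreasing duplicate-count order (ties broken by decreasing length, then
#' id), and assigns each to the first existing centroid within `d`; a
#' sequence matching no centroid founds a new cluster with itself as
#' centroid. Duplicates inherit the cluster of their representative. Cluster
#' ids are assigned in centroid-creation order starting at 0, which makes the
#' result deterministic for a given input.
#'
#' @param reads a record data frame (columns `id`, `sequence`).
#' @param d dissimilarity threshold (default 0.03, the species-level
#'   convention).
#' @param order processing order of unique sequences: `"abundance"`
#'   (default), `"length"`, or `"input"`.
#' @param best_fit if `TRUE`, assign to the closest candidate centroid within
#'   `d` instead of the first.
#' @param band alignment band half-width; the default
#'   `ceiling(2 * d * max_len) + 8` is safe for accept/reject decisions at
#'   threshold `d` (see [pairwise_distance()]). Use `Inf` for full alignments.
#' @param kmer_filter use the k-mer prefilter to restrict candidate
#'   centroids before aligning (see [kmer_candidate_filter()]).
#' @param k,min_shared_fraction prefilter parameters.
#' @return An object of class `cluster_map`.
#' @export
greedy_cluster <- function(reads, d = 0.03,
                           order = c("abundance", "length", "input"),
                           best_fit = FALSE, band = NULL,
                           kmer_filter = TRUE, k = 8L,
                           min_shared_fraction = 0.5) {
  order <- match.arg(order)
  if (nrow(reads) == 0L)
    return(new_cluster_map(setNames(integer(0), character(0)),
                           character(0), d, "greedy"))
  if (is.null(band))
    band <- as.integer(ceiling(2 * d * max(nchar(reads$sequence))) + 8L)

  dr <- .dereplicate(reads, order)
  n_unique <- length(dr$seqs)
  cent_seq <- character(0)
  cent_id <- character(0)
  uniq_cluster <- integer(n_unique)

  for (i in seq_len(n_unique)) {
    s <- dr$seqs[i]
    assigned <- NA_integer_
    if (length(cent_seq)) {
      cand <- if (kmer_filter)
        kmer_candidate_filter(s, cent_seq, k, min_shared_fraction)
      else seq_along(cent_seq)
      if (length(cand)) {
        dist <- .distance_many(s, cent_seq[cand], band)
        ok <- which(dist <= d)
        if (length(ok))
          assigned <- cand[if (best_fit) ok[which.min(dist[ok])] else ok[1L]]
      }
    }
    if (is.na(assigned)) {
      cent_seq <- c(cent_seq, s)
      cent_id <- c(cent_id, dr$rep_id[i])
      assigned <- length(cent_seq)
    }
    uniq_cluster[i] <- assigned - 1L
  }

  member_ids <- unlist(dr$members, use.names = FALSE)
  assignments <- setNames(rep.int(uniq_cluster, dr$count), member_ids)
  # report in input-read order
  assignments <- assignments[reads$id]
  new_cluster_map(assignments, cent_id, d, "greedy")
}

#' Brute-force all-pairs single-linkage clustering (oracle)
#'
#' Computes all pairwise distances among the dereplicated sequences and takes
#' the connected components of the graph with edges at distance `<= d`
#' (single linkage, via [stats::hclust()] cut at height `d`). Quadratic in
#' the number of unique sequences ([pairwise_comparison_count()] alignments),
#' so intended as a ground-truth oracle on small inputs; it warns above 2000
#' reads. Cluster ids follow first appearance in input order; each cluster's
#' centroid is its first read.
#'
#' @inheritParams greedy_cluster
#' @return An object of class `cluster_map`.
#' @export
brute_force_cluster <- function(reads, d = 0.03) {
  if (nrow(reads) == 0L)
    return(new_cluster_map(setNames(integer(0), character(0)),
                           character(0), d, "brute_force"))
  if (nrow(reads) > 2000L)
    warning("brute_force_cluster on ", nrow(reads),
            " reads: all-pairs alignment will be slow")
  dr <- .dereplicate(reads, "input")
  n <- length(dr$seqs)
  if (n == 1L) {
    comp <- 1L
  } else {
    dm <- matrix(0, n, n)
    for (i in seq_len(n - 1L))
      dm[i, (i + 1L):n] <- .distance_many(dr$seqs[i], dr$seqs[(i + 1L):n], -1L)
    dm <- dm + t(dm)
    tree <- hclust(as.dist(dm), method = "single")
    comp <- cutree(tree, h = d)
  }
  # relabel components by first appearance, 0-based
  first <- match(unique(comp), comp)
  relabel <- setNames(seq_along(first) - 1L, comp[first])
  uniq_cluster <- unname(relabel[as.character(comp)])
  cent_id <- dr$rep_id[first][order(uniq_cluster[first])]

  member_ids <- unlist(dr$members, use.names = FALSE)
  assignments <- setNames(rep.int(uniq_cluster, dr$count), member_ids)
  assignments <- assignments[reads$id]
  new_cluster_map(assignments, cent_id, d, "brute_force")
}

#' Write a cluster map as TSV files
#'
#' @param cm a `cluster_map`.
#' @param path output path for the per-read table
#'   (`read_id`, `cluster_id`, `is_centroid`).
#' @param otu_table_path optional path for the per-cluster table
#'   (`cluster_id`, `size`, `centroid_id`).
#' @return `path`, invisibly.
#' @export
write_cluster_map <- function(cm, path, otu_table_path = NULL) {
  stopifnot(inherits(cm, "cluster_map"))
  df <- data.frame(read_id = names(cm$assignments),
                   cluster_id = unname(cm$assignments),
                   is_centroid = names(cm$assignments) %in% cm$centroids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(otu_table_path)) {
    sizes <- abundance_vector(cm)
    otu <- data.frame(cluster_id = seq_along(sizes) - 1L, size = sizes,
                      centroid_id = cm$centroids)
    write.table(otu, otu_table_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a cluster map written by [write_cluster_map()]
#' @param path path to the per-read TSV.
#' @param threshold the threshold the clustering was run at (metadata only).
#' @return An object of class `cluster_map`.
#' @export
read_cluster_map <- function(path, threshold = NA_real_) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assignments <- setNames(as.integer(df$cluster_id), df$read_id)
  cent <- df$read_id[df$is_centroid]
  cent <- cent[order(assignments[cent])]
  new_cluster_map(assignments, cent, threshold, "file")
}

#' @export
print.cluster_map <- function(x, ...) {
  sizes <- abundance_vector(x)
  cat(sprintf("OTU clustering (%s) at d = %s\n", x$method, format(x$threshold)))
  cat(sprintf("  reads: %d, clusters: %d, singletons: %d, largest: %s\n",
              length(x$assignments), length(sizes), sum(sizes == 1L),
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' @export
summary.cluster_map <- function(object, ...) {
  sizes <- abundance_vector(object)
  out <- list(n_reads = length(object$assignments),
              s_obs = length(sizes),
              singletons = sum(sizes == 1L),
              doubletons = sum(sizes == 2L),
              size_summary = if (length(sizes)) summary(sizes) else NULL,
              threshold = object$threshold, method = object$method)
  class(out) <- "summary.cluster_map"
  out
}

#' @export
print.summary.cluster_map <- function(x, ...) {
  cat(sprintf("OTU clustering (%s) at d = %s\n", x$method, format(x$threshold)))
  cat(sprintf("  reads %d | OTUs %d | F1 %d | F2 %d\n",
              x$n_reads, x$s_obs, x$singletons, x$doubletons))
  if (!is.null(x$size_summary)) {
    cat("  cluster sizes:\n")
    print(x$size_summary)
  }
  invisible(x)
}
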