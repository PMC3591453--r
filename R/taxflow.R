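# Taxonomy-guided filtering workflow: quality filter, chimera exclusion,
# three-group taxonomy partition, unclassified-singleton removal, pooling,
# and the end-to-end pipeline with per-stage bookkeeping. The guiding idea is
# to keep as much high-quality data as possible: reads that cannot be
# taxonomically assigned are not discarded wholesale — only those that also
# fail to cluster with anything else (singletons among the unclassified,
# the signature of error-laden reads) are dropped, and the rest are pooled
# back with the target group before richness estimation.

#' Quality filter on read length and ambiguous bases
#'
#' Keeps a read iff `min_len <= length <= max_len` (bounds inclusive) and it
#' carries at most `max_n` ambiguous bases (`N`); the default `max_n = 0`
#' allows no undetermined bases.
#'
#' @param reads a record data frame.
#' @param min_len,max_len length bounds in nt.
#' @param max_n maximum `N` count per read.
#' @return List with `kept` (record data frame) and `dropped_ids`.
#' @export
quality_filter <- function(reads, min_len = 0L, max_len = Inf, max_n = 0L) {
  len <- nchar(reads$sequence)
  n_count <- nchar(gsub("[^N]", "", reads$sequence))
  keep <- len >= min_len & len <= max_len & n_count <= max_n
  list(kept = reads[keep, , drop = FALSE],
       dropped_ids = reads$id[!keep])
}

#' Remove reads named on an exclusion list
#'
#' Drops the reads whose id appears in `exclusion_ids` (e.g. chimeras
#' reported by an external detector), preserving input order. Exclusion ids
#' not present in the reads produce a warning, not an error.
#'
#' @param reads a record data frame.
#' @param exclusion_ids character vector of read ids to drop.
#' @return The surviving reads.
#' @export
remove_excluded <- function(reads, exclusion_ids) {
  missing <- setdiff(exclusion_ids, reads$id)
  if (length(missing))
    warning(length(missing), " exclusion id(s) not present in the reads")
  reads[!(reads$id %in% exclusion_ids), , drop = FALSE]
}

#' Partition reads into target / contaminant / unclassified groups
#'
#' Routes every read by its taxonomy-table group; reads absent from the
#' table are unclassified. Reports the U/N ratio: the unclassified fraction
#' of all partitioned reads.
#'
#' @param reads a record data frame.
#' @param taxonomy a taxonomy table (see [read_taxonomy()]), or `NULL` to
#'   treat every read as target.
#' @return An object of class `partition_result`: list with `target`,
#'   `contaminant`, `unclassified` (record data frames), `counts` and
#'   `u_n_ratio`.
#' @export
partition_by_taxonomy <- function(reads, taxonomy) {
  if (is.null(taxonomy)) {
    group <- rep("target", nrow(reads))
  } else {
    group <- taxonomy$group[match(reads$id, taxonomy$read_id)]
    group[is.na(group)] <- "unclassified"
  }
  out <- structure(list(
    target = reads[group == "target", , drop = FALSE],
    contaminant = reads[group == "contaminant", , drop = FALSE],
    unclassified = reads[group == "unclassified", , drop = FALSE]),
    class = "partition_result")
  out$counts <- c(n = nrow(reads),
                  target = nrow(out$target),
                  contaminant = nrow(out$contaminant),
                  unclassified = nrow(out$unclassified))
  out$u_n_ratio <- if (nrow(reads)) nrow(out$unclassified) / nrow(reads) else 0
  out
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Taxonomy partition:\n")
  cat(sprintf("  N = %d | target %d | contaminant %d | unclassified %d (U/N = %.2f)\n",
              x$counts["n"], x$counts["target"], x$counts["contaminant"],
              x$counts["unclassified"], x$u_n_ratio))
  invisible(x)
}

#' Naive shared-k-mer classifier (testing stand-in)
#'
#' Assigns each read the label of its best-scoring labeled reference, where
#' the score is the fraction of the read's distinct k-mers shared with the
#' reference, or `unclassified` if no score reaches `min_score`. This is a
#' deliberately simple stand-in for a BLAST + taxonomic-binning run, used to
#' exercise the pipeline in tests; it is not a production classifier.
#'
#' @param reads a record data frame.
#' @param labeled_refs a record data frame with a `group` column of
#'   `"target"` / `"contaminant"` labels.
#' @param k k-mer size.
#' @param min_score minimum shared-k-mer fraction for an assignment.
#' @return A taxonomy table (data frame `read_id`, `group`).
#' @export
naive_classifier <- function(reads, labeled_refs, k = 8L, min_score = 0.5) {
  if (nrow(labeled_refs) == 0L) stop("labeled_refs must be non-empty")
  if (!all(labeled_refs$group %in% c("target", "contaminant")))
    stop("labeled_refs groups must be target or contaminant")
  ref_kmers <- lapply(labeled_refs$sequence, .kmer_set, k = k)
  group <- vapply(reads$sequence, function(s) {
    q <- .kmer_set(s, k)
    if (length(q) == 0L) return("unclassified")
    scores <- vapply(ref_kmers, function(rk) mean(q %in% rk), numeric(1L))
    best <- which.max(scores)
    if (scores[best] >= min_score) labeled_refs$group[best] else "unclassified"
  }, character(1L), USE.NAMES = FALSE)
  data.frame(read_id = reads$id, group = group, stringsAsFactors = FALSE)
}

#' Remove singleton reads from the unclassified group
#'
#' Clusters the unclassified reads separately (the rest of the data plays no
#' part) and drops every read sitting in a size-1 cluster. The rationale:
#' misclassification at a 3% threshold requires many errors, and identical
#' error patterns in two reads are vanishingly unlikely, so error-laden
#' reads surface as singletons here; reads that do cluster with at least one
#' other unclassified read are kept as credible.
#'
#' @param unclassified_reads a record data frame.
#' @param d clustering threshold (default 0.03).
#' @param ... further arguments to [greedy_cluster()].
#' @return List with `survivors`, `dropped_ids` and the `cluster_map` used.
#' @export
filter_unclassified_singletons <- function(unclassified_reads, d = 0.03, ...) {
  if (nrow(unclassified_reads) == 0L)
    return(list(survivors = unclassified_reads, dropped_ids = character(0),
                cluster_map = NULL))
  cm <- greedy_cluster(unclassified_reads, d, ...)
  drop <- singleton_ids(cm)
  list(survivors = unclassified_reads[!(unclassified_reads$id %in% drop), ,
                                      drop = FALSE],
       dropped_ids = drop, cluster_map = cm)
}

#' Pool the target group with the unclassified survivors
#'
#' Concatenates the two read sets (id sets must be disjoint); the pooled set
#' is what the definitive clustering and richness estimation run on.
#'
#' @param target_reads,survivors record data frames.
#' @return The pooled record data frame.
#' @export
pool_reads <- function(target_reads, survivors) {
  clash <- intersect(target_reads$id, survivors$id)
  if (length(clash))
    stop("read id in both groups: ", clash[1L])
  cols <- intersect(names(target_reads), names(survivors))
  rbind(target_reads[, cols, drop = FALSE], survivors[, cols, drop = FALSE])
}

#' Run the full taxonomy-guided richness pipeline
#'
#' Stages, in order: quality filter -> exclusion-list (chimera) removal ->
#' taxonomy partition -> separate clustering of the unclassified group with
#' singleton removal -> pooling of survivors with the target group ->
#' greedy OTU clustering of the pool -> richness estimation, rarefaction
#' curve and log-normal abundance fit. Contaminants and unclassified
#' singletons are excluded from the estimates; every stage's counts and the
#' dropped ids are reported rather than silently discarded.
#'
#' @param reads a record data frame (e.g. from [read_fasta()]).
#' @param taxonomy a taxonomy table, or `NULL` to treat all reads as target.
#' @param exclusions character vector of read ids to exclude (chimeras).
#' @param config a [run_config()].
#' @param curve compute the rarefaction curve (default `TRUE`; the slowest
#'   part on large data).
#' @return An object of class `pipeline_report`: per-stage `counts`,
#'   `u_n_ratio`, dropped id lists, the pooled `cluster_map`, `abundance`,
#'   `estimate` ([richness_estimate()]), `curve` and `lognormal` fit (`NULL`
#'   when fewer than 10 clusters).
#' @export
run_pipeline <- function(reads, taxonomy = NULL, exclusions = character(0),
                         config = run_config(), curve = TRUE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$rng_seed)
  d <- config$dissimilarity_threshold

  qf <- quality_filter(reads, config$min_len, config$max_len, config$max_n)
  after_exclusion <- remove_excluded(qf$kept, exclusions)
  part <- partition_by_taxonomy(after_exclusion, taxonomy)
  uc <- filter_unclassified_singletons(part$unclassified, d)
  pooled <- pool_reads(part$target, uc$survivors)
  if (nrow(pooled) == 0L)
    stop("no reads left to analyse after filtering")

  cm <- greedy_cluster(pooled, d)
  av <- abundance_vector(cm)
  est <- richness_estimate(av, config$rare_cutoff)
  crv <- if (curve)
    rarefaction_curve(cm, config$rarefaction_step, config$rarefaction_iters,
                      config$rare_cutoff)
  else NULL
  lnf <- if (length(av) >= 10L) fit_lognormal(av) else NULL

  counts <- c(input = nrow(reads),
              after_quality = nrow(qf$kept),
              after_exclusion = nrow(after_exclusion),
              target = nrow(part$target),
              contaminant = nrow(part$contaminant),
              unclassified = nrow(part$unclassified),
              unclassified_survivors = nrow(uc$survivors),
              unclassified_dropped = length(uc$dropped_ids),
              pooled = nrow(pooled))
  structure(list(counts = counts, u_n_ratio = part$u_n_ratio,
                 dropped = list(quality = qf$dropped_ids,
                                excluded = intersect(exclusions, qf$kept$id),
                                unclassified_singletons = uc$dropped_ids),
                 cluster_map = cm, abundance = av, estimate = est,
                 curve = crv, lognormal = lnf, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat("  stage counts:\n")
  for (nm in names(x$counts))
    cat(sprintf("    %-24s %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  U/N ratio: %.3f\n", x$u_n_ratio))
  print(x$estimate)
  if (!is.null(x$lognormal)) print(x$lognormal)
  invisible(x)
}

#' Write the per-stage counts of a pipeline report as TSV
#'
#' @param report a `pipeline_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  df <- data.frame(stage = names(report$counts),
                   reads = unname(report$counts))
  df <- rbind(df, data.frame(stage = "u_n_ratio", reads = report$u_n_ratio))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
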