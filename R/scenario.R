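# End-to-end test scenarios binding the community simulator to the filtering
# pipeline: a planted community plus contaminants, unlabeled reads, planted
# unclassified singletons and a chimera exclusion list, together with a truth
# report of the expected per-stage counts. The constructions are planted so
# the expected counts are exact, not merely likely: unlabeled community reads
# are taken as whole OTUs with at least two members (so they must survive the
# unclassified-singleton filter), and planted singletons are verified to lie
# farther than the clustering threshold from every other unclassified read
# (so they must be dropped).

#' Scenario specification
#'
#' @param n_otus,mu,sigma,seed_length,member_distance,seed_min_separation,replication
#'   community design parameters (see [community_design()]). The default
#'   separation 0.06 guarantees planted OTUs cannot merge at a 0.03
#'   threshold.
#' @param contaminant_fraction fraction of the community size added as
#'   contaminant reads (sequences drawn from a disjoint random pool).
#' @param unlabeled_fraction fraction of community reads left out of the
#'   taxonomy table; realized by unlabeling whole OTUs with >= 2 members, so
#'   the realized fraction is the closest achievable one.
#' @param n_planted_singletons unlabeled reads planted farther than the
#'   clustering threshold from everything else in the unclassified group.
#' @param n_chimeras reads listed on the exclusion list.
#' @param d clustering threshold the scenario is built for.
#' @param seed master RNG seed.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_otus = 100L, mu = 1, sigma = 1,
                          seed_length = 250L, member_distance = 0.0125,
                          seed_min_separation = 0.06, replication = 1L,
                          contaminant_fraction = 0.02,
                          unlabeled_fraction = 0.15,
                          n_planted_singletons = 5L,
                          n_chimeras = 0L, d = 0.03, seed = 1L) {
  if (contaminant_fraction < 0 || unlabeled_fraction < 0 ||
      contaminant_fraction + unlabeled_fraction > 1)
    stop("fractions must be in [0,1] and jointly <= 1")
  if (n_planted_singletons < 0 || n_chimeras < 0)
    stop("counts must be >= 0")
  structure(list(design = community_design(
                   n_otus, mu, sigma, seed_length, member_distance,
                   seed_min_separation, replication),
                 contaminant_fraction = contaminant_fraction,
                 unlabeled_fraction = unlabeled_fraction,
                 n_planted_singletons = as.integer(n_planted_singletons),
                 n_chimeras = as.integer(n_chimeras),
                 d = d, seed = as.integer(seed)),
            class = "scenario_spec")
}

# random sequences strictly farther than d from every sequence in `others`
.plant_distant <- function(n, length, others, d, prefix, max_attempts = 50L * max(n, 1L)) {
  out <- character(0)
  attempts <- 0L
  while (base::length(out) < n) {
    if (attempts >= max_attempts)
      stop("could not plant ", n, " distant sequences")
    attempts <- attempts + 1L
    cand <- random_sequence(length)
    ref <- c(others, out)
    if (base::length(ref) == 0L || all(.distance_many(cand, ref, -1L) > d))
      out <- c(out, cand)
  }
  if (n == 0L) return(seq_records(character(0), character(0)))
  seq_records(paste0(prefix, seq_len(n)), out)
}

#' Build an end-to-end pipeline scenario with exact expected bookkeeping
#'
#' Builds the community, adds contaminants and chimeras, removes a set of
#' whole multi-member OTUs from the taxonomy table, plants well-separated
#' unclassified singletons, and records the per-stage counts the pipeline
#' must report. Optionally writes `reads.fasta`, `taxonomy.tsv`,
#' `chimeras.txt` and `truth.tsv` to a directory.
#'
#' @param spec a [scenario_spec()].
#' @param dir optional output directory.
#' @return An object of class `scenario`: list with `reads`, `taxonomy`,
#'   `chimera_ids`, `truth` (named expected counts, including
#'   `final_s_obs`), `community` and `spec`.
#' @export
make_scenario <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  comm <- build_community(spec$design)
  n_comm <- nrow(comm$reads)
  len <- spec$design$seed_length

  # unlabel whole OTUs with >= 2 members until the requested fraction is met
  target_unlabeled <- round(spec$unlabeled_fraction * n_comm)
  eligible <- names(comm$truth)[comm$truth >= 2L]
  unlabeled_otus <- character(0)
  acc <- 0L
  for (otu in eligible) {
    if (acc >= target_unlabeled) break
    unlabeled_otus <- c(unlabeled_otus, otu)
    acc <- acc + comm$truth[[otu]]
  }
  unlabeled_ids <- comm$reads$id[comm$reads$otu %in% unlabeled_otus]

  n_contam <- round(spec$contaminant_fraction * n_comm)
  contam <- .plant_distant(n_contam, len, comm$seeds$sequence, spec$d,
                           "contam_")
  # planted singletons must be > d away from every other unclassified read
  other_unclassified <- comm$reads$sequence[comm$reads$id %in% unlabeled_ids]
  singles <- .plant_distant(spec$n_planted_singletons, len,
                            other_unclassified, spec$d, "uc_single_")
  chim <- .plant_distant(spec$n_chimeras, len, character(0), spec$d, "chimera_")

  reads <- rbind(
    comm$reads[, c("id", "sequence")],
    contam[, c("id", "sequence"), drop = FALSE],
    singles[, c("id", "sequence"), drop = FALSE],
    chim[, c("id", "sequence"), drop = FALSE])
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  rownames(reads) <- NULL

  labeled_comm <- setdiff(comm$reads$id, unlabeled_ids)
  taxonomy <- taxonomy_table(
    read_id = c(labeled_comm, contam$id),
    taxon = c(rep("target", length(labeled_comm)),
              rep("contaminant", nrow(contam))))

  n_input <- nrow(reads)
  truth <- c(input = n_input,
             after_quality = n_input,
             after_exclusion = n_input - spec$n_chimeras,
             target = length(labeled_comm),
             contaminant = nrow(contam),
             unclassified = length(unlabeled_ids) + nrow(singles),
             unclassified_survivors = length(unlabeled_ids),
             unclassified_dropped = nrow(singles),
             pooled = n_comm,
             final_s_obs = spec$design$n_otus)

  out <- structure(list(reads = reads, taxonomy = taxonomy,
                        chimera_ids = chim$id, truth = truth,
                        community = comm, spec = spec),
                   class = "scenario")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(reads, file.path(dir, "reads.fasta"))
    write.table(taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(chim$id, file.path(dir, "chimeras.txt"))
    write.table(data.frame(stage = names(truth), reads = unname(truth)),
                file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  out
}

#' @export
print.scenario <- function(x, ...) {
  cat("Pipeline scenario:\n")
  for (nm in names(x$truth))
    cat(sprintf("  %-24s %d\n", nm, x$truth[[nm]]))
  invisible(x)
}

#' Estimator behaviour across community parameters
#'
#' For every (`mu`, `sigma`) cell, builds one base community, derives its
#' duplicated / triplicated variants, clusters each at `d` and records the
#' full-depth observed richness, Chao1 and ACE next to the true planted
#' richness. Reproduces, at reduced scale, the qualitative estimator
#' behaviour the simulator is designed to expose: gross overestimation on
#' communities full of singleton OTUs, and exact estimates once every
#' lineage has two or more individuals.
#'
#' @param mu,sigma numeric vectors; the grid is their cross product.
#' @param n_otus planted richness per community.
#' @param replications subset of `c(1, 2, 3)`.
#' @param seed master RNG seed (the whole table is deterministic given it).
#' @param d clustering threshold.
#' @param seed_length,member_distance,seed_min_separation community design
#'   parameters.
#' @return A data frame with one row per (mu, sigma, replication) cell:
#'   `n_reads`, `true_richness`, `s_obs`, `chao1`, `ace`.
#' @export
estimator_behavior_suite <- function(mu = c(0.5, 1), sigma = c(0.5, 1),
                                     n_otus = 100L, replications = c(1L, 2L),
                                     seed = 1L, d = 0.03,
                                     seed_length = 250L,
                                     member_distance = 0.0125,
                                     seed_min_separation = 0.06) {
  set.seed(seed)
  grid <- expand.grid(mu = mu, sigma = sigma, KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    base <- build_community(community_design(
      n_otus, grid$mu[g], grid$sigma[g], seed_length,
      member_distance, seed_min_separation))
    for (k in sort(replications)) {
      comm <- replicate_community(base, k)
      cm <- greedy_cluster(comm$reads, d)
      av <- abundance_vector(cm)
      rows[[length(rows) + 1L]] <- data.frame(
        mu = grid$mu[g], sigma = grid$sigma[g], replication = k,
        n_reads = nrow(comm$reads), true_richness = n_otus,
        s_obs = length(av), chao1 = chao1_corrected(av), ace = ace(av))
    }
  }
  do.call(rbind, rows)
}
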