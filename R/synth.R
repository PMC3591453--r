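# Planted-truth synthetic communities: a point-mutation engine, mutually
# separated seed sequences, log-normal per-OTU memberships and duplicated /
# triplicated (x2 / x3) variants. These communities carry their ground truth,
# so estimator behaviour can be judged against a known richness.

.BASES <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSION <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Mutation event mix
#'
#' Probabilities of each point-mutation event type. The default mix
#' (0.35 transitions, 0.35 transversions, 0.15 insertions, 0.15 deletions)
#' keeps substitutions dominant with indels present.
#'
#' @param p_transition,p_transversion,p_insertion,p_deletion non-negative
#'   event probabilities summing to 1.
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(p_transition = 0.35, p_transversion = 0.35,
                          p_insertion = 0.15, p_deletion = 0.15) {
  p <- c(transition = p_transition, transversion = p_transversion,
         insertion = p_insertion, deletion = p_deletion)
  if (any(p < 0)) stop("event probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("event probabilities must sum to 1")
  structure(list(p = p), class = "mutation_spec")
}

#' Random nucleotide sequence
#' @param length sequence length in nt.
#' @return A character scalar over `A`, `C`, `G`, `T`.
#' @export
random_sequence <- function(length) {
  paste0(sample(.BASES, length, replace = TRUE), collapse = "")
}

#' Apply random point mutations to a sequence
#'
#' Applies exactly `n_events` events, each at an independently chosen uniform
#' position, with the event type drawn from `spec`. Substitutions honor
#' transition/transversion identity (A<->G and C<->T are transitions, all
#' other substitutions transversions). Collisions and back-mutations are
#' allowed, so the final distance to the input can be below `n_events`
#' positions.
#'
#' @param seq a sequence over `A`, `C`, `G`, `T`.
#' @param n_events number of mutation events (>= 0).
#' @param spec a [mutation_spec()].
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, n_events, spec = mutation_spec()) {
  if (n_events < 0) stop("n_events must be >= 0")
  if (!nzchar(seq)) stop("seq must be non-empty")
  if (grepl("[^ACGT]", seq)) stop("seq must be over {A,C,G,T}")
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  types <- names(spec$p)
  for (ev in seq_len(n_events)) {
    type <- sample(types, 1L, prob = spec$p)
    if (type == "insertion") {
      pos <- sample.int(length(x) + 1L, 1L)  # slot before position pos
      x <- append(x, sample(.BASES, 1L), after = pos - 1L)
    } else {
      pos <- sample.int(length(x), 1L)
      if (type == "transition") {
        x[pos] <- .TRANSITION[[x[pos]]]
      } else if (type == "transversion") {
        x[pos] <- sample(.TRANSVERSION[[x[pos]]], 1L)
      } else {  # deletion
        if (length(x) == 1L) stop("cannot delete from a length-1 sequence")
        x <- x[-pos]
      }
    }
  }
  paste0(x, collapse = "")
}

#' Mutate a sequence until a target distance is reached
#'
#' Applies single mutation events iteratively, re-measuring the alignment
#' distance to the original after each event, and stops as soon as the
#' distance falls inside `[target_d - tol, target_d + tol]`. This mirrors the
#' "mutate until approximately the target distance" construction used to
#' grow community members around a seed.
#'
#' @inheritParams mutate_sequence
#' @param target_d target dissimilarity in (0, 1), or 0 for the identity.
#' @param tol half-width of the acceptance band (default 0.003).
#' @param max_events mutation budget; exceeding it raises an error (default
#'   ten times the expected event count).
#' @return A sequence whose [pairwise_distance()] to `seq` lies in the band.
#' @export
mutate_to_distance <- function(seq, target_d, spec = mutation_spec(),
                               tol = 0.003, max_events = NULL) {
  if (target_d < 0 || target_d >= 1) stop("target_d must be in [0, 1)")
  if (is.null(max_events))
    max_events <- max(20L, ceiling(10 * target_d * nchar(seq)))
  cur <- seq
  d <- 0
  events <- 0L
  repeat {
    if (d >= target_d - tol && d <= target_d + tol) return(cur)
    if (events >= max_events)
      stop(sprintf(
        "failed to reach distance %.4f +/- %.4f within %d events (at %.4f)",
        target_d, tol, max_events, d))
    cur <- mutate_sequence(cur, 1L, spec)
    events <- events + 1L
    d <- pairwise_distance(seq, cur)
  }
}

#' Generate mutually separated seed sequences
#'
#' Rejection-samples random sequences, keeping a candidate only if its
#' distance to every already-kept seed exceeds `min_separation`; the result
#' emulates a reference pool whose members found distinct OTUs.
#'
#' @param n number of seeds (>= 1).
#' @param length seed length in nt.
#' @param min_separation minimum pairwise distance between seeds
#'   (default 0.03).
#' @param max_attempts total candidate budget before giving up.
#' @return A record data frame of `n` seeds with ids `seed_1`, `seed_2`, ...
#' @export
generate_seed_set <- function(n, length, min_separation = 0.03,
                              max_attempts = 100L * n) {
  if (n < 1) stop("n must be >= 1")
  seeds <- character(0)
  attempts <- 0L
  while (base::length(seeds) < n) {
    if (attempts >= max_attempts)
      stop("could not place ", n, " seeds at separation > ", min_separation,
           " within ", max_attempts, " attempts; ",
           "try longer sequences or fewer seeds")
    attempts <- attempts + 1L
    cand <- random_sequence(length)
    if (base::length(seeds) == 0L ||
        all(.distance_many(cand, seeds, -1L) > min_separation))
      seeds <- c(seeds, cand)
  }
  seq_records(paste0("seed_", seq_len(n)), seeds)
}

#' Greedily select mutually separated representatives from a pool
#'
#' Scans the pool in input order and keeps a sequence iff its distance to
#' every already-kept sequence exceeds `min_separation` — the cleaning step
#' applied to a reference pool so that each survivor can seed a separate OTU.
#'
#' @param pool a record data frame.
#' @param min_separation minimum pairwise distance (default 0.03).
#' @return The kept subset of `pool`, in input order.
#' @export
select_seed_representatives <- function(pool, min_separation = 0.03) {
  if (nrow(pool) == 0L) stop("pool must be non-empty")
  kept <- logical(nrow(pool))
  kept_seqs <- character(0)
  for (i in seq_len(nrow(pool))) {
    s <- pool$sequence[i]
    if (length(kept_seqs) == 0L ||
        all(.distance_many(s, kept_seqs, -1L) > min_separation)) {
      kept[i] <- TRUE
      kept_seqs <- c(kept_seqs, s)
    }
  }
  pool[kept, , drop = FALSE]
}

#' Draw per-OTU member counts from a discretized log-normal
#'
#' Counts are `max(1, round(exp(z)))` with `z ~ Normal(mu, sigma)`, so every
#' OTU has at least one member. Note the discretization is not exactly
#' log-normal: the rounding grid and the floor at 1 bias the moments of
#' `log(count)` relative to (`mu`, `sigma`) — [fit_lognormal()]'s default
#' method models this explicitly.
#'
#' @param n_otus number of OTUs.
#' @param mu,sigma mean and standard deviation of the log abundances
#'   (`sigma > 0`).
#' @return Integer vector of `n_otus` counts, each >= 1.
#' @export
sample_abundances <- function(n_otus, mu, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  as.integer(pmax(1, round(exp(rnorm(n_otus, mu, sigma)))))
}

#' Community design parameters
#'
#' @param n_otus number of planted OTUs (>= 1).
#' @param mu,sigma log-normal parameters of the membership distribution.
#' @param seed_length seed length in nt (default 250, a typical amplicon
#'   read length).
#' @param member_distance distance of each mutated member from its seed
#'   (default 0.0125).
#' @param seed_min_separation minimum pairwise seed distance (default 0.03).
#'   Must exceed `member_distance`; exact recovery at threshold `d` is only
#'   guaranteed when it exceeds `d + 2 * member_distance`.
#' @param replication 1 for the base community, 2/3 for x2/x3 variants.
#' @param mutation a [mutation_spec()].
#' @param distance_tol acceptance band half-width for member mutation.
#' @return An object of class `community_design`.
#' @export
community_design <- function(n_otus, mu, sigma, seed_length = 250L,
                             member_distance = 0.0125,
                             seed_min_separation = 0.03,
                             replication = 1L,
                             mutation = mutation_spec(),
                             distance_tol = 0.003) {
  if (n_otus < 1) stop("n_otus must be >= 1")
  if (sigma <= 0) stop("sigma must be > 0")
  if (!(member_distance > 0 && member_distance < seed_min_separation))
    stop("need 0 < member_distance < seed_min_separation")
  if (replication < 1) stop("replication must be >= 1")
  structure(list(n_otus = as.integer(n_otus), mu = mu, sigma = sigma,
                 seed_length = as.integer(seed_length),
                 member_distance = member_distance,
                 seed_min_separation = seed_min_separation,
                 replication = as.integer(replication),
                 mutation = mutation, distance_tol = distance_tol),
            class = "community_design")
}

#' Build a planted-truth synthetic community
#'
#' Seeds come from [generate_seed_set()]; each OTU's member count is drawn
#' from the discretized log-normal; the first member of every OTU is the
#' unmutated seed itself and each further member is an independent
#' [mutate_to_distance()] copy of the seed at `member_distance`. Reads are
#' shuffled and annotated with their true OTU, and the per-OTU truth counts
#' are recorded. A `replication` of 2 or 3 in the design duplicates /
#' triplicates every read afterwards (see [replicate_community()]).
#'
#' @param design a [community_design()].
#' @param seed optional RNG seed for a bit-reproducible community.
#' @return An object of class `planted_community`: a list with `design`,
#'   `seeds`, `reads` (record data frame with an `otu` annotation) and
#'   `truth` (named per-OTU member counts).
#' @export
build_community <- function(design, seed = NULL) {
  stopifnot(inherits(design, "community_design"))
  if (!is.null(seed)) set.seed(seed)
  seeds <- generate_seed_set(design$n_otus, design$seed_length,
                             design$seed_min_separation)
  seeds$id <- paste0("otu_", seq_len(design$n_otus))
  counts <- sample_abundances(design$n_otus, design$mu, design$sigma)

  ids <- character(sum(counts))
  seqs <- character(sum(counts))
  otus <- character(sum(counts))
  pos <- 0L
  for (i in seq_len(design$n_otus)) {
    for (j in seq_len(counts[i])) {
      pos <- pos + 1L
      ids[pos] <- sprintf("r_%s_%d", i, j)
      seqs[pos] <- if (j == 1L) seeds$sequence[i] else
        mutate_to_distance(seeds$sequence[i], design$member_distance,
                           design$mutation, design$distance_tol)
      otus[pos] <- seeds$id[i]
    }
  }
  shuffle <- sample.int(pos)
  reads <- seq_records(ids[shuffle], seqs[shuffle], otu = otus[shuffle])
  comm <- structure(list(design = design, seeds = seeds, reads = reads,
                         truth = setNames(counts, seeds$id)),
                    class = "planted_community")
  if (design$replication > 1L)
    comm <- replicate_community(comm, design$replication, base_design = design)
  comm
}

#' Duplicate or triplicate every read of a community (x2 / x3 variants)
#'
#' Every read appears exactly `k` times in the result; copies get fresh
#' unique ids (`.dup1`, `.dup2`, ... suffixes) and keep their true OTU, and
#' truth counts are multiplied by `k`. In the replicated community every
#' genetic lineage has at least `k` individuals, which forces the singleton
#' count of a clustering at any threshold to zero.
#'
#' @param comm a `planted_community`.
#' @param k replication factor (>= 1); `k = 1` returns the community as is.
#' @param base_design internal; design to record in the result.
#' @return A `planted_community` with `k` times the reads.
#' @export
replicate_community <- function(comm, k, base_design = NULL) {
  stopifnot(inherits(comm, "planted_community"))
  if (k < 1) stop("k must be >= 1")
  k <- as.integer(k)
  if (k == 1L) return(comm)
  r <- comm$reads
  out <- vector("list", k)
  out[[1L]] <- r
  for (j in seq_len(k - 1L)) {
    cp <- r
    cp$id <- paste0(r$id, ".dup", j)
    out[[j + 1L]] <- cp
  }
  design <- if (is.null(base_design)) {
    d <- comm$design
    d$replication <- d$replication * k
    d
  } else base_design
  structure(list(design = design, seeds = comm$seeds,
                 reads = do.call(rbind, out),
                 truth = comm$truth * k),
            class = "planted_community")
}

#' @export
print.planted_community <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "Planted community: %d OTUs, %d reads (mu=%.3g, sigma=%.3g, x%d)\n",
    d$n_otus, nrow(x$reads), d$mu, d$sigma, d$replication))
  cat(sprintf(
    "  seeds: %d nt, separation > %.3g; members at %.3g +/- %.3g\n",
    d$seed_length, d$seed_min_separation, d$member_distance, d$distance_tol))
  invisible(x)
}
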