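# Independent oracles and shared fixtures. The alignment oracle below is a
# deliberately plain R dynamic program, kept separate from the package's
# compiled implementation so the two can disagree.

# Full Needleman-Wunsch under unit costs (match 0, mismatch 1, indel 1) with
# traceback preference diagonal > up > left; returns edits, alignment columns
# and the dissimilarity.
nw_oracle <- function(a, b) {
  if (b < a) { tmp <- a; a <- b; b <- tmp }  # same canonical order as the package
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in 1:n) for (j in 1:m)
    D[i + 1L, j + 1L] <- min(D[i, j] + (x[i] != y[j]),
                             D[i, j + 1L] + 1L,
                             D[i + 1L, j] + 1L)
  i <- n; j <- m
  mm <- 0L; ind <- 0L; mat <- 0L
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        D[i + 1L, j + 1L] == D[i, j] + (x[i] != y[j])) {
      if (x[i] == y[j]) mat <- mat + 1L else mm <- mm + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      ind <- ind + 1L; i <- i - 1L
    } else {
      ind <- ind + 1L; j <- j - 1L
    }
  }
  cols <- mat + mm + ind
  list(edits = mm + ind, columns = cols, distance = (mm + ind) / cols)
}

# Exact E[log(max(1, round(exp(Z))))] for Z ~ Normal(mu, sigma): the
# closed-form reference for the discretized log-normal abundance sampler.
discretized_lognormal_mean_log <- function(mu, sigma, kmax = 1e5L) {
  k <- 2:kmax
  p <- pnorm(log(k + 0.5), mu, sigma) - pnorm(log(k - 0.5), mu, sigma)
  sum(log(k) * p)  # k = 1 contributes log(1) = 0
}

# Substitute `n` positions of a sequence with a different base (deterministic
# positions), giving pairs at an exactly known distance.
substitute_at <- function(seq, positions) {
  x <- strsplit(seq, "")[[1]]
  swap <- c(A = "C", C = "G", G = "T", T = "A")
  x[positions] <- swap[x[positions]]
  paste0(x, collapse = "")
}

# Fixture cache: communities are expensive, so each is built once per run.
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Well-separated planted community: 25 OTUs, log-normal memberships.
fx_comm25 <- function() fixture("comm25", function() {
  build_community(community_design(25, 1, 0.8, seed_min_separation = 0.06),
                  seed = 7)
})

# Planted community with chosen per-OTU sizes (seeds mutually > 0.06 apart,
# members at 1.25% from their seed).
make_planted <- function(sizes, seed, seed_length = 250L) {
  set.seed(seed)
  seeds <- generate_seed_set(length(sizes), seed_length, 0.06)
  ids <- character(0); seqs <- character(0); otus <- character(0)
  for (i in seq_along(sizes)) {
    for (j in seq_len(sizes[i])) {
      ids <- c(ids, sprintf("p%d_%d", i, j))
      seqs <- c(seqs, if (j == 1L) seeds$sequence[i] else
        mutate_to_distance(seeds$sequence[i], 0.0125))
      otus <- c(otus, seeds$id[i])
    }
  }
  seq_records(ids, seqs, otu = otus)
}

relabel_by_first_occurrence <- function(assignments) {
  match(assignments, unique(assignments))
}
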