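# On-disk formats: FASTA reads, TSV taxonomy table, plain-text id lists, and
# the run configuration shared by the clustering / rarefaction / pipeline
# functions. Everything downstream works on plain data frames with columns
# `id` and `sequence` (plus optional annotation columns), so these readers are
# the only place parsing happens.

.valid_groups <- c("target", "contaminant", "unclassified")

#' Construct a set of sequence records
#'
#' Builds the `id` + `sequence` data frame used throughout the package,
#' validating the record invariants: unique non-empty ids, non-empty sequences
#' over the alphabet `A`, `C`, `G`, `T`, `N` (lowercase input is uppercased).
#' Additional vectors are kept as annotation columns.
#'
#' @param id character vector of unique read identifiers.
#' @param sequence character vector of nucleotide sequences.
#' @param ... optional annotation columns (e.g. `otu = ...`), recycled to the
#'   number of records.
#' @return A data frame with columns `id`, `sequence` and any annotations.
#' @export
seq_records <- function(id, sequence, ...) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("id and sequence must have the same length")
  if (any(!nzchar(id)))
    stop("empty read id")
  if (anyDuplicated(id))
    stop("duplicate read id: ", id[duplicated(id)][1L])
  if (any(!nzchar(sequence)))
    stop("empty sequence for read ", id[!nzchar(sequence)][1L])
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("sequence for read ", id[bad][1L],
         " contains characters outside {A,C,G,T,N}")
  df <- data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

#' Read amplicon reads from a FASTA file
#'
#' Accepts any line wrapping. Header lines are `>id key=value key=value ...`;
#' any `key=value` tokens after the id are recovered as annotation columns.
#' Sequences are uppercased on input. Malformed input (sequence data before
#' the first header, an entry with no sequence, characters outside
#' `{A,C,G,T,N}`, duplicate ids) raises an error naming the offending line.
#'
#' @param path path to a FASTA file.
#' @return A data frame of records (see [seq_records()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  hdr <- grepl("^>", lines)
  nonblank <- nzchar(trimws(lines))
  if (!any(nonblank))
    return(seq_records(character(0), character(0)))
  first <- which(nonblank)[1L]
  if (!hdr[first])
    stop("line ", first, ": sequence data before first FASTA header")

  starts <- which(hdr)
  ids <- character(length(starts))
  seqs <- character(length(starts))
  ann <- vector("list", length(starts))
  ends <- c(starts[-1L] - 1L, length(lines))
  for (k in seq_along(starts)) {
    header <- sub("^>", "", lines[starts[k]])
    toks <- strsplit(trimws(header), "[ \t]+")[[1L]]
    if (length(toks) == 0L || !nzchar(toks[1L]))
      stop("line ", starts[k], ": FASTA header with empty id")
    ids[k] <- toks[1L]
    kv <- toks[-1L][grepl("=", toks[-1L], fixed = TRUE)]
    if (length(kv)) {
      key <- sub("=.*$", "", kv)
      val <- sub("^[^=]*=", "", kv)
      ann[[k]] <- setNames(val, key)
    }
    body <- lines[seq.int(starts[k] + 1L, length.out = ends[k] - starts[k])]
    s <- paste0(trimws(body), collapse = "")
    if (!nzchar(s))
      stop("line ", starts[k], ": entry '", ids[k], "' has an empty sequence")
    seqs[k] <- toupper(s)
  }
  if (anyDuplicated(ids))
    stop("duplicate read id in ", path, ": ", ids[duplicated(ids)][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("line ", starts[bad][1L], ": entry '", ids[bad][1L],
         "' contains characters outside {A,C,G,T,N}")

  df <- seq_records(ids, seqs)
  keys <- unique(unlist(lapply(ann, names)))
  for (key in keys)
    df[[key]] <- vapply(ann, function(a) {
      if (!is.null(a) && key %in% names(a)) a[[key]] else NA_character_
    }, character(1L))
  df
}

#' Write records to a FASTA file
#'
#' Sequences are wrapped at 80 columns. Non-`NA` annotation columns are
#' serialized as `key=value` tokens after the id on the header line and
#' recovered by [read_fasta()], so `read_fasta(write_fasta(x))` round-trips.
#'
#' @param records a record data frame (see [seq_records()]).
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  ann_cols <- setdiff(names(records), c("id", "sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- paste0(">", records$id[i])
    for (col in ann_cols) {
      v <- records[[col]][i]
      if (!is.na(v)) header <- paste0(header, " ", col, "=", v)
    }
    s <- records$sequence[i]
    n <- nchar(s)
    chunks <- substring(s, seq(1L, n, by = width),
                        pmin(seq(1L, n, by = width) + width - 1L, n))
    writeLines(c(header, chunks), con)
  }
  invisible(path)
}

#' Read a per-read taxonomy assignment table
#'
#' Consumes a two-column (or wider; extra columns ignored) tab-separated table
#' of `read_id`, `taxon`, such as an export from a BLAST + taxonomic-binning
#' run. Raw taxon strings are mapped onto the three-group alphabet `target` /
#' `contaminant` / `unclassified` via `mapping`; taxa with no mapping fall
#' into `unclassified`. The table is authoritative: reads absent from it are
#' treated as unclassified downstream.
#'
#' @param path path to a TSV file without header.
#' @param mapping named character vector, taxon string -> group
#'   (e.g. `c(Bacteria = "target", Eukaryota = "contaminant")`). `NULL` keeps
#'   taxon strings that already are group names and maps everything else to
#'   `unclassified`.
#' @return A data frame with columns `read_id` and `group`.
#' @export
read_taxonomy <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("taxonomy table needs at least 2 columns")
  taxonomy_table(read_id = raw[[1L]], taxon = raw[[2L]], mapping = mapping)
}

#' Build a taxonomy table in memory
#'
#' @param read_id character vector of read ids (each at most once).
#' @param taxon character vector of raw taxon strings or group names.
#' @inheritParams read_taxonomy
#' @return A data frame with columns `read_id` and `group`.
#' @export
taxonomy_table <- function(read_id, taxon, mapping = NULL) {
  read_id <- as.character(read_id)
  taxon <- as.character(taxon)
  if (anyDuplicated(read_id))
    stop("duplicate read_id in taxonomy table: ",
         read_id[duplicated(read_id)][1L])
  group <- rep("unclassified", length(taxon))
  direct <- taxon %in% .valid_groups
  group[direct] <- taxon[direct]
  if (!is.null(mapping)) {
    if (is.null(names(mapping)) || !all(mapping %in% .valid_groups))
      stop("mapping must be a named vector with values in ",
           paste(.valid_groups, collapse = "/"))
    hit <- !direct & taxon %in% names(mapping)
    group[hit] <- unname(mapping[taxon[hit]])
  }
  data.frame(read_id = read_id, group = group, stringsAsFactors = FALSE)
}

#' Read a plain-text list of read ids
#'
#' One id per line; blank lines are ignored and duplicates collapsed. Used for
#' chimera exclusion lists produced by an external detector.
#'
#' @param path path to the id list.
#' @return Character vector of unique ids.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ids <- trimws(readLines(path))
  unique(ids[nzchar(ids)])
}

#' Run configuration
#'
#' Bundles the tunable parameters shared by the clustering, rarefaction and
#' pipeline stages.
#'
#' @param dissimilarity_threshold OTU clustering threshold as a fraction
#'   (default 0.03, the species-level convention).
#' @param rarefaction_step depth grid spacing in reads (default 100).
#' @param rarefaction_iters subsamples averaged per depth.
#' @param rng_seed integer seed controlling every randomized step.
#' @param min_len,max_len read length bounds for the quality filter (nt).
#' @param max_n maximum number of ambiguous bases (`N`) allowed per read;
#'   the default 0 discards any read with an undetermined base.
#' @param rare_cutoff abundance cutoff separating rare from abundant OTUs in
#'   the ACE estimator (default 10).
#' @return An object of class `run_config`.
#' @export
run_config <- function(dissimilarity_threshold = 0.03,
                       rarefaction_step = 100L,
                       rarefaction_iters = 10L,
                       rng_seed = 1L,
                       min_len = 0L, max_len = Inf, max_n = 0L,
                       rare_cutoff = 10L) {
  if (!(dissimilarity_threshold > 0 && dissimilarity_threshold < 1))
    stop("dissimilarity_threshold must be in (0, 1)")
  if (rarefaction_step < 1) stop("rarefaction_step must be >= 1")
  if (rarefaction_iters < 1) stop("rarefaction_iters must be >= 1")
  if (min_len < 0 || max_len < min_len)
    stop("need 0 <= min_len <= max_len")
  if (max_n < 0) stop("max_n must be >= 0")
  structure(list(dissimilarity_threshold = dissimilarity_threshold,
                 rarefaction_step = as.integer(rarefaction_step),
                 rarefaction_iters = as.integer(rarefaction_iters),
                 rng_seed = as.integer(rng_seed),
                 min_len = min_len, max_len = max_len,
                 max_n = as.integer(max_n),
                 rare_cutoff = as.integer(rare_cutoff)),
            class = "run_config")
}

#' Read a key=value run configuration file
#'
#' Lines of the form `key = value` (whitespace optional, `#` comments
#' allowed); keys are the arguments of [run_config()].
#'
#' @param path path to the configuration file.
#' @return An object of class `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  known <- names(formals(run_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key: ", unknown[1L])
  do.call(run_config, as.list(setNames(vals, keys)))
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
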