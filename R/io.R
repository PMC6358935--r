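#' Read protein sequences from a FASTA file
#'
#' Parses a standard FASTA file into a named character vector of amino-acid
#' sequences. The id of each record is the first whitespace-delimited token
#' of its header line; multi-line sequences are concatenated. Input order is
#' preserved and becomes the row/column order of every matrix built from the
#' records, so it must be stable across runs.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: names are record ids, values are
#'   upper-case amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: writes one record per sequence, single-line
#' bodies, preserving order, so that reading the file back reproduces the
#' input exactly.
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.character(records), !is.null(names(records)))
  writeLines(paste0(">", names(records), "\n", unname(records)), path)
  invisible(path)
}

#' Construct a validated kinase-substrate interaction list
#'
#' The container for known positive interactions: a set of
#' (kinase id, substrate id) pairs together with the frozen node orderings
#' that all matrices downstream inherit.
#'
#' @param pairs Two-column data frame (kinase, substrate), character ids.
#' @param kinase_ids Ordered character vector of kinase ids.
#' @param substrate_ids Ordered character vector of substrate ids.
#' @return An object of class `interaction_list`.
#' @export
interaction_list <- function(pairs, kinase_ids, substrate_ids) {
  stopifnot(is.data.frame(pairs), ncol(pairs) >= 2L)
  pairs <- data.frame(kinase = as.character(pairs[[1L]]),
                      substrate = as.character(pairs[[2L]]),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(kinase_ids)) stop("duplicate kinase ids")
  if (anyDuplicated(substrate_ids)) stop("duplicate substrate ids")
  bad_k <- setdiff(pairs$kinase, kinase_ids)
  if (length(bad_k) > 0L) {
    stop("interaction references unknown kinase id(s): ",
         paste(unique(bad_k), collapse = ", "))
  }
  bad_s <- setdiff(pairs$substrate, substrate_ids)
  if (length(bad_s) > 0L) {
    stop("interaction references unknown substrate id(s): ",
         paste(unique(bad_s), collapse = ", "))
  }
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 kinase_ids = as.character(kinase_ids),
                 substrate_ids = as.character(substrate_ids)),
            class = "interaction_list")
}

#' @export
print.interaction_list <- function(x, ...) {
  cat(sprintf("interaction_list: %d pairs over %d kinases x %d substrates\n",
              nrow(x$pairs), length(x$kinase_ids), length(x$substrate_ids)))
  invisible(x)
}

#' Read a kinase-substrate interaction list
#'
#' Reads two-column delimited text (one pair per line, kinase id then
#' substrate id). The delimiter (tab or comma) is auto-detected from the
#' first data line; lines starting with `#` are skipped. Duplicated pairs
#' are collapsed; ids absent from the sequence collections are an error.
#' Node orderings are taken from the FASTA collections, not from this file.
#'
#' @param path Path to the interaction file.
#' @param kinases Named character vector of kinase sequences (from
#'   [read_fasta()]); its names define the kinase ordering.
#' @param substrates Named character vector of substrate sequences.
#' @return An `interaction_list`.
#' @export
read_interactions <- function(path, kinases, substrates) {
  if (!file.exists(path)) stop("interaction file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(interaction_list(data.frame(kinase = character(), substrate = character()),
                            names(kinases), names(substrates)))
  }
  sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 2L)) {
    stop("interaction line(s) without exactly 2 columns: line ",
         paste(which(nfield != 2L), collapse = ", "))
  }
  pairs <- data.frame(kinase = trimws(vapply(fields, `[[`, "", 1L)),
                      substrate = trimws(vapply(fields, `[[`, "", 2L)),
                      stringsAsFactors = FALSE)
  interaction_list(pairs, names(kinases), names(substrates))
}

#' Write an interaction list as tab-separated text
#'
#' @param x An `interaction_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path) {
  stopifnot(inherits(x, "interaction_list"))
  write.table(x$pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a ranked prediction table
#'
#' Emits predictions as tab-separated text sorted by descending score with
#' deterministic tie-breaking (lexicographic kinase id, then substrate id,
#' in the C locale), so identical inputs always yield byte-identical files.
#' Optional `#`-prefixed provenance lines are written before the header.
#'
#' @param scores Data frame with columns `kinase_id`, `substrate_id`,
#'   `score`, and optionally `known` (logical).
#' @param path Output path.
#' @param provenance Character vector of provenance lines (written as
#'   `# <line>`), or `NULL`.
#' @return The sorted, ranked data frame, invisibly.
#' @export
write_scores <- function(scores, path, provenance = NULL) {
  scores <- rank_scores(scores)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste(c("kinase_id", "substrate_id", "score", "rank", "known"),
                   collapse = "\t"), con)
  if (nrow(scores) > 0L) {
    body <- sprintf("%s\t%s\t%.10g\t%d\t%d", scores$kinase_id,
                    scores$substrate_id, scores$score, scores$rank,
                    as.integer(scores$known))
    writeLines(body, con)
  }
  invisible(scores)
}

#' Sort and rank a prediction table deterministically
#'
#' @param scores Data frame with `kinase_id`, `substrate_id`, `score` and
#'   optionally `known` columns.
#' @return The same rows sorted by descending score (ties broken by
#'   kinase id then substrate id) with a `rank` column added.
#' @export
rank_scores <- function(scores) {
  stopifnot(all(c("kinase_id", "substrate_id", "score") %in% names(scores)))
  if (is.null(scores$known)) scores$known <- rep(FALSE, nrow(scores))
  ord <- order(-scores$score, scores$kinase_id, scores$substrate_id,
               method = "radix")
  scores <- scores[ord, c("kinase_id", "substrate_id", "score", "known"),
                   drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores[, c("kinase_id", "substrate_id", "score", "rank", "known")]
}

#' Write a similarity matrix as TSV (ids in header row and first column)
#'
#' @param sim Square numeric matrix with identical row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  stopifnot(is.matrix(sim), identical(rownames(sim), colnames(sim)))
  df <- data.frame(id = rownames(sim), sim, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_tsv()]
#'
#' @param path Path to the TSV file.
#' @return Square numeric matrix with ids as dimnames.
#' @export
read_similarity_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (!identical(rownames(m), colnames(m))) {
    stop("similarity TSV is not square with matching ids")
  }
  storage.mode(m) <- "double"
  m
}

#' Run configuration for the prediction pipeline
#'
#' Collects every tunable of the pipeline in one validated object. Defaults
#' follow the published method where it states a choice (similarity
#' threshold `t = 0.9`, step size `delta = (m+n)/|Omega|`) and this
#' package's documented conventions elsewhere.
#'
#' @param t Similarity threshold in \[0,1\] for network adjustment; an edge
#'   is propagated to a neighbour only when similarity is strictly greater
#'   than `t`.
#' @param tau Singular-value shrinkage threshold (> 0), or `"auto"` for
#'   `5 * (m + n)`.
#' @param delta SVT step size (> 0), or `"auto"` for `(m + n) / |Omega|`,
#'   or `"auto-literature"` for `1.2 * (m + n)^2 / |Omega|`.
#' @param max_iter Maximum SVT iterations.
#' @param tol Relative-residual convergence tolerance on observed entries.
#' @param adjust_mode One of `"substrate"`, `"kinase"`, `"both"`, `"none"`.
#' @param omega_policy One of `"positives_only"` (interaction zeros are
#'   unknowns to be predicted; default) or `"all_bipartite"` (zeros are
#'   observed).
#' @param seed Integer seed controlling all randomized steps.
#' @return An object of class `run_config`.
#' @export
run_config <- function(t = 0.9, tau = "auto", delta = "auto", max_iter = 500L,
                       tol = 1e-4, adjust_mode = "substrate",
                       omega_policy = "positives_only", seed = 1L) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0, t <= 1)
  if (!identical(tau, "auto")) stopifnot(is.numeric(tau), tau > 0)
  if (!is.character(delta)) {
    stopifnot(is.numeric(delta), delta > 0)
  } else if (!delta %in% c("auto", "auto-literature")) {
    stop("delta must be numeric, \"auto\" or \"auto-literature\"")
  }
  stopifnot(max_iter >= 1L, tol > 0)
  adjust_mode <- match.arg(adjust_mode, c("substrate", "kinase", "both", "none"))
  omega_policy <- match.arg(omega_policy, c("positives_only", "all_bipartite"))
  structure(list(t = t, tau = tau, delta = delta,
                 max_iter = as.integer(max_iter), tol = tol,
                 adjust_mode = adjust_mode, omega_policy = omega_policy,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a `key = value` configuration file
#'
#' Blank lines and `#` comments are ignored; recognized keys are the
#' arguments of [run_config()]. Unrecognized keys are an error.
#'
#' @param path Path to the config file.
#' @param ... Overrides applied after the file is read (e.g. CLI flags).
#' @return A `run_config`.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("config line without a single '=': ", path)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- names(formals(run_config))
  bad <- setdiff(keys, known)
  if (length(bad) > 0L) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- as.list(vals)
  names(args) <- keys
  numeric_keys <- c("t", "tau", "delta", "max_iter", "tol", "seed")
  for (k in intersect(keys, numeric_keys)) {
    v <- suppressWarnings(as.numeric(args[[k]]))
    if (!is.na(v)) args[[k]] <- v
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(unclass(x))) cat(sprintf("  %s = %s\n", k, format(x[[k]])))
  invisible(x)
}
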