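#' @rdname generate_clustered_sequences
#' @format NULL
#' @export
amino_acids <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Generate clustered synthetic protein sequences
#'
#' Draws one uniform-random ancestor sequence per cluster and derives each
#' member by independent per-position substitutions (to a different
#' residue) at the given rate. Within-cluster sequences are therefore far
#' more similar than between-cluster ones, giving the similarity matrices
#' the block structure the completion pipeline exploits. Sequences use the
#' uniform 20-letter alphabet; no attempt is made to mimic real amino-acid
#' composition or indels.
#'
#' @param n_clusters Number of clusters (>= 1).
#' @param per_cluster Sequences per cluster (>= 1).
#' @param length Sequence length.
#' @param mutation_rate Per-position substitution probability in \[0, 0.5);
#'   rates near 0.5 destroy cluster separation.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param prefix Id prefix (ids are `<prefix>1`, `<prefix>2`, ...).
#' @return List with `records` (named character vector of sequences) and
#'   `cluster` (integer cluster label per record, named by id).
#' @export
generate_clustered_sequences <- function(n_clusters, per_cluster, length,
                                         mutation_rate, seed, prefix = "P") {
  stopifnot(n_clusters >= 1L, per_cluster >= 1L, length >= 1L,
            mutation_rate >= 0, mutation_rate < 0.5)
  withr::with_seed(as.integer(seed), {
    records <- character(0)
    cluster <- integer(0)
    idx <- 0L
    for (cl in seq_len(n_clusters)) {
      ancestor <- sample(amino_acids, length, replace = TRUE)
      for (j in seq_len(per_cluster)) {
        idx <- idx + 1L
        seq <- ancestor
        mut <- runif(length) < mutation_rate
        if (any(mut)) {
          # substitute with a uniformly random *different* residue
          seq[mut] <- vapply(seq[mut], function(x) {
            sample(setdiff(amino_acids, x), 1L)
          }, "")
        }
        records[[paste0(prefix, idx)]] <- paste(seq, collapse = "")
        cluster[[paste0(prefix, idx)]] <- cl
      }
    }
    list(records = records, cluster = cluster)
  })
}

#' Generate a planted bipartite interaction network
#'
#' Draws kinase-substrate edges from a stochastic block model: pairs in
#' the same cluster interact with probability `link_prob_within`, pairs in
#' different clusters with probability `link_prob_between`. The expected
#' interaction matrix has rank equal to the number of clusters, the
#' low-rank structure matrix completion assumes. A fraction of true edges
#' can be withheld from the observed set to serve as recoverable ground
#' truth.
#'
#' @param kinase_clusters Named integer vector: cluster label per kinase id.
#' @param substrate_clusters Named integer vector: cluster label per
#'   substrate id.
#' @param link_prob_within Edge probability within a cluster.
#' @param link_prob_between Edge probability across clusters (must be
#'   smaller than `link_prob_within`).
#' @param hide_fraction Fraction of true edges withheld from the observed
#'   set, in \[0, 1).
#' @param seed Integer seed.
#' @return List with `true_pairs`, `observed_pairs`, `hidden_pairs` (data
#'   frames with columns kinase, substrate; hidden = true minus observed).
#' @export
generate_planted_network <- function(kinase_clusters, substrate_clusters,
                                     link_prob_within = 0.8,
                                     link_prob_between = 0.02,
                                     hide_fraction = 0, seed = 1L) {
  stopifnot(link_prob_within > link_prob_between, link_prob_between >= 0,
            hide_fraction >= 0, hide_fraction < 1,
            !is.null(names(kinase_clusters)), !is.null(names(substrate_clusters)))
  withr::with_seed(as.integer(seed), {
    p <- ifelse(outer(kinase_clusters, substrate_clusters, `==`),
                link_prob_within, link_prob_between)
    edge <- matrix(runif(length(p)) < p, nrow(p), ncol(p), dimnames = dimnames(p))
    idx <- which(edge, arr.ind = TRUE)
    true_pairs <- data.frame(kinase = names(kinase_clusters)[idx[, 1L]],
                             substrate = names(substrate_clusters)[idx[, 2L]],
                             stringsAsFactors = FALSE)
    n_hide <- floor(hide_fraction * nrow(true_pairs))
    hidden_rows <- if (n_hide > 0L) sample(nrow(true_pairs), n_hide) else integer(0)
    list(true_pairs = true_pairs,
         observed_pairs = true_pairs[setdiff(seq_len(nrow(true_pairs)), hidden_rows), ,
                                     drop = FALSE],
         hidden_pairs = true_pairs[hidden_rows, , drop = FALSE])
  })
}

#' Generate a complete planted benchmark instance
#'
#' Combines [generate_clustered_sequences()] (for kinases and substrates
#' sharing the same cluster structure) with [generate_planted_network()]
#' into a ready-to-run fixture: sequences, cluster labels, and an
#' [interaction_list()] of observed interactions. Defaults (3 clusters,
#' 8 kinases and 20 substrates per cluster, length 200, mutation rate
#' 0.05, within/between edge probabilities 0.8/0.02) give a sparse
#' bipartite network with strong low-rank structure at a size that runs
#' end-to-end in seconds.
#'
#' @param n_clusters,kinases_per_cluster,substrates_per_cluster Cluster
#'   geometry.
#' @param length Sequence length.
#' @param mutation_rate Per-position substitution rate within a cluster.
#' @param link_prob_within,link_prob_between Block-model edge
#'   probabilities.
#' @param hide_fraction Fraction of true edges withheld from the observed
#'   interaction list.
#' @param seed Integer seed (sub-generators use `seed`, `seed + 1`,
#'   `seed + 2`).
#' @return An object of class `planted_instance`: list with `kinases`,
#'   `substrates` (named sequence vectors), `kinase_clusters`,
#'   `substrate_clusters`, `interactions` (observed, as an
#'   `interaction_list`), `true_pairs`, `hidden_pairs`, `seed`.
#' @export
generate_planted_instance <- function(n_clusters = 3L, kinases_per_cluster = 8L,
                                      substrates_per_cluster = 20L, length = 200L,
                                      mutation_rate = 0.05,
                                      link_prob_within = 0.8,
                                      link_prob_between = 0.02,
                                      hide_fraction = 0, seed = 1L) {
  seed <- as.integer(seed)
  kin <- generate_clustered_sequences(n_clusters, kinases_per_cluster, length,
                                      mutation_rate, seed, prefix = "K")
  sub <- generate_clustered_sequences(n_clusters, substrates_per_cluster, length,
                                      mutation_rate, seed + 1L, prefix = "S")
  net <- generate_planted_network(kin$cluster, sub$cluster,
                                  link_prob_within, link_prob_between,
                                  hide_fraction, seed + 2L)
  structure(list(kinases = kin$records, substrates = sub$records,
                 kinase_clusters = kin$cluster, substrate_clusters = sub$cluster,
                 interactions = interaction_list(net$observed_pairs,
                                                 names(kin$records),
                                                 names(sub$records)),
                 true_pairs = net$true_pairs, hidden_pairs = net$hidden_pairs,
                 seed = seed),
            class = "planted_instance")
}

#' @export
print.planted_instance <- function(x, ...) {
  cat(sprintf("planted_instance: %d kinases, %d substrates, %d observed / %d true interactions (seed %d)\n",
              length(x$kinases), length(x$substrates),
              nrow(x$interactions$pairs), nrow(x$true_pairs), x$seed))
  invisible(x)
}

#' Destroy the structure of an interaction list by relabelling substrates
#'
#' Applies a random permutation to the substrate identities inside the
#' pair list (sequences and node orderings are untouched), breaking the
#' link between sequence similarity and interaction structure. Used as a
#' no-signal control: any evaluation on the shuffled list should give an
#' AUC near 0.5.
#'
#' @param interactions An [interaction_list()].
#' @param seed Integer seed.
#' @return A new `interaction_list` with the same number of pairs.
#' @export
shuffle_interactions <- function(interactions, seed) {
  stopifnot(inherits(interactions, "interaction_list"))
  perm <- withr::with_seed(as.integer(seed),
                           sample(interactions$substrate_ids))
  names(perm) <- interactions$substrate_ids
  pairs <- interactions$pairs
  pairs$substrate <- unname(perm[pairs$substrate])
  interaction_list(pairs, interactions$kinase_ids, interactions$substrate_ids)
}

#' Write a planted instance as FASTA + TSV files
#'
#' Emits standard files (kinases.fasta, substrates.fasta,
#' interactions.tsv) so that synthetic fixtures exercise the real I/O
#' path.
#'
#' @param instance A `planted_instance`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_instance <- function(instance, dir) {
  stopifnot(inherits(instance, "planted_instance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(kinases = file.path(dir, "kinases.fasta"),
             substrates = file.path(dir, "substrates.fasta"),
             interactions = file.path(dir, "interactions.tsv"))
  write_fasta(instance$kinases, paths[["kinases"]])
  write_fasta(instance$substrates, paths[["substrates"]])
  write_interactions(instance$interactions, paths[["interactions"]])
  invisible(paths)
}
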