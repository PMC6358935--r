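#' BLOSUM62 substitution matrix
#'
#' Returns the standard BLOSUM62 amino-acid score table (including the
#' ambiguity codes B, Z and X) as shipped with Biostrings.
#'
#' @return Symmetric integer matrix with amino-acid letters as dimnames.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  storage.mode(m) <- "double"
  m
}

#' Local-alignment scoring parameters
#'
#' Bundles the substitution matrix and affine gap penalties used for all
#' pairwise alignments. Defaults are the EMBOSS `water` defaults for
#' proteins: BLOSUM62, gap open 10, gap extend 0.5, where a gap of length
#' L costs `gap_open + (L - 1) * gap_extend`.
#'
#' @param substitution_matrix Symmetric numeric score matrix with residue
#'   letters as dimnames.
#' @param gap_open Penalty for the first residue of a gap (> 0).
#' @param gap_extend Penalty for each further gap residue (> 0, and not
#'   larger than `gap_open`).
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = blosum62(),
                             gap_open = 10, gap_extend = 0.5) {
  stopifnot(is.matrix(substitution_matrix),
            identical(rownames(substitution_matrix),
                      colnames(substitution_matrix)))
  if (!isTRUE(all.equal(substitution_matrix, t(substitution_matrix)))) {
    stop("substitution matrix must be symmetric")
  }
  stopifnot(gap_extend > 0, gap_open >= gap_extend)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

# Residues whose matrix rows exist but which are not valid sequence content.
.forbidden_residues <- c("*", "-")

# Encode a sequence as 0-based indices into the substitution matrix,
# erroring on any character without a score row.
encode_sequence <- function(seq, params, label = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) {
    stop("empty sequence", if (!is.null(label)) paste0(" for ", label))
  }
  alphabet <- rownames(params$substitution_matrix)
  idx <- match(chars, setdiff(alphabet, .forbidden_residues))
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("character(s) not in the substitution alphabet",
         if (!is.null(label)) paste0(" in ", label), ": ",
         paste(bad, collapse = ", "))
  }
  match(chars, alphabet) - 1L
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score of two amino-acid sequences under affine
#' gap penalties (EMBOSS convention: a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`). The score of the empty alignment is
#' 0, so the result is never negative; it is symmetric in its arguments.
#'
#' @param a,b Amino-acid sequences (single strings).
#' @param params An [alignment_params()] object.
#' @return Nonnegative alignment score.
#' @export
smith_waterman_score <- function(a, b, params = alignment_params()) {
  ea <- encode_sequence(a, params, "first sequence")
  eb <- encode_sequence(b, params, "second sequence")
  sw_score_cpp(ea, eb, params$substitution_matrix,
               params$gap_open, params$gap_extend)
}

#' Normalized pairwise sequence similarity
#'
#' Maps raw Smith-Waterman scores into \[0,1\] by geometric-mean self-score
#' normalization: `SW(a,b) / sqrt(SW(a,a) * SW(b,b))`. Self-similarity is
#' exactly 1 and the value is symmetric. (Under BLOSUM62 every residue has
#' a positive self-score, so self-alignment scores are strictly positive.)
#'
#' @inheritParams smith_waterman_score
#' @return Similarity in \[0,1\].
#' @export
normalized_similarity <- function(a, b, params = alignment_params()) {
  saa <- smith_waterman_score(a, a, params)
  sbb <- smith_waterman_score(b, b, params)
  if (saa <= 0 || sbb <= 0) {
    stop("sequence with non-positive self-alignment score; ",
         "cannot normalize similarity")
  }
  min(1, smith_waterman_score(a, b, params) / sqrt(saa * sbb))
}

#' All-vs-all normalized similarity matrix
#'
#' Computes every unordered pair once (in compiled code) and returns the
#' symmetric similarity matrix with unit diagonal, rows/columns in the
#' input record order.
#'
#' @param records Named character vector of sequences ([read_fasta()]).
#' @param params An [alignment_params()] object.
#' @return Square symmetric numeric matrix in \[0,1\] with record ids as
#'   dimnames and diagonal exactly 1.
#' @export
build_similarity_matrix <- function(records, params = alignment_params()) {
  stopifnot(length(records) >= 1L, !is.null(names(records)))
  enc <- lapply(seq_along(records), function(i) {
    encode_sequence(records[[i]], params, paste0("record '", names(records)[i], "'"))
  })
  raw <- sw_score_matrix_cpp(enc, params$substitution_matrix,
                             params$gap_open, params$gap_extend)
  self <- diag(raw)
  if (any(self <= 0)) {
    stop("non-positive self-alignment score for record(s): ",
         paste(names(records)[self <= 0], collapse = ", "))
  }
  sim <- raw / sqrt(outer(self, self))
  sim <- pmin(sim, 1)
  diag(sim) <- 1
  dimnames(sim) <- list(names(records), names(records))
  sim
}

# Validate a similarity matrix container: square, symmetric, unit diagonal,
# entries in [0,1]. Used by the network assembly step.
check_similarity_matrix <- function(sim, what = "similarity matrix") {
  stopifnot(is.matrix(sim))
  if (nrow(sim) != ncol(sim)) stop(what, " is not square")
  if (max(abs(sim - t(sim))) > 1e-8) stop(what, " is not symmetric")
  if (max(abs(diag(sim) - 1)) > 1e-8) stop(what, " diagonal is not 1")
  if (min(sim) < -1e-8 || max(sim) > 1 + 1e-8) stop(what, " has entries outside [0,1]")
  invisible(sim)
}
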