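# Sequence alignment and end-trimming of target/model pairs. Predicted models
# often differ from their target by a few residues at the termini; pairs are
# globally aligned (BLOSUM62, affine gaps) and the overhanging ends trimmed so
# lengths match exactly. Pairs whose optimal alignment needs interior gaps are
# rejected: only end differences are supported.

#' Globally align two structures and trim terminal overhangs
#'
#' Needleman-Wunsch global alignment of the two sequences (affine gap
#' penalties; the first position of a gap costs open + extend) followed by
#' removal of terminal overhangs on both sides so the retained lengths match
#' exactly. Any gap in the interior of the optimal alignment raises an error.
#'
#' @param target,model Structure tibbles.
#' @param substitution Substitution matrix name or matrix (default BLOSUM62).
#' @param gap_open,gap_extend Gap penalties (negative scores; defaults -10 and
#'   -0.5).
#' @return An `aligned_pair` list: `target` and `model` trimmed to equal
#'   length and re-indexed from 1, `mapping` (tibble of original
#'   `target_index`, `model_index`), and the alignment `score`.
#' @export
align_and_trim <- function(target, model, substitution = "BLOSUM62",
                           gap_open = -10, gap_extend = -0.5) {
  if (n_residues(target) < 1 || n_residues(model) < 1) {
    abort("both structures must be non-empty")
  }
  seqs <- c(structure_sequence(target), structure_sequence(model))
  if (is.character(substitution)) {
    substitution <- get(data(list = substitution, package = "Biostrings",
                             envir = environment()))
  }
  pa <- Biostrings::pairwiseAlignment(
    seqs[1], seqs[2], type = "global", substitutionMatrix = substitution,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend)
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]

  gap <- pat == "-" | sub == "-"
  matched <- which(!gap)
  if (length(matched) == 0L) abort("alignment has no aligned positions")
  if (any(gap[seq(min(matched), max(matched))])) {
    abort("interior gaps in optimal global alignment; only end differences are supported")
  }

  t_idx <- cumsum(pat != "-")
  m_idx <- cumsum(sub != "-")
  mapping <- tibble::tibble(target_index = t_idx[matched],
                            model_index = m_idx[matched])
  out <- list(
    target = subset_residues(target, mapping$target_index),
    model = subset_residues(model, mapping$model_index),
    mapping = mapping,
    score = Biostrings::score(pa)
  )
  class(out) <- "aligned_pair"
  out
}

# keep the given residues (by res_index) and renumber contiguously from 1
subset_residues <- function(structure, res_indices) {
  keep <- structure[structure$res_index %in% res_indices, ]
  keep$res_index <- as.integer(match(keep$res_index, res_indices))
  keep <- keep[order(keep$res_index), ]
  new_structure(keep, chain_id = attr(structure, "chain_id") %||% "A")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> %d aligned residues (score %.1f)\n",
              nrow(x$mapping), x$score))
  invisible(x)
}

#' @export
tidy.aligned_pair <- function(x, ...) x$mapping
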