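#' Affine gap penalties
#'
#' Cost of a length-L gap is `gap_open + (L - 1) * gap_extend`; the opening
#' charge includes the first gapped position, and terminal gaps are charged
#' like internal ones.  Defaults are the engine's baseline `(-2.5, -0.7)`.
#'
#' @param gap_open negative opening penalty.
#' @param gap_extend negative extension penalty; `gap_open <= gap_extend <= 0`.
#' @return Object of class `gap_penalties`.
#' @export
gap_penalties <- function(gap_open = -2.5, gap_extend = -0.7) {
  if (!is.numeric(gap_open) || !is.numeric(gap_extend) ||
      !(gap_open <= gap_extend && gap_extend <= 0)) {
    stop("require gap_open <= gap_extend <= 0", call. = FALSE)
  }
  structure(list(gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend)),
            class = "gap_penalties")
}

#' Exact global affine-gap alignment of a fixed score matrix
#'
#' Three-state (M / Ix / Iy) Needleman-Wunsch-Gotoh dynamic programming.  The
#' input is a fully precomputed [score_matrix()]; no scoring callback is ever
#' invoked during the recursion.  Traceback is deterministic under the frozen
#' tie preference M > Ix > Iy (Ix consumes the left / profile axis).
#'
#' @param scores a [score_matrix()] (or bare numeric matrix); may have zero
#'   rows or columns, in which case the result is a single spanning gap.
#' @param penalties a [gap_penalties()].
#' @return Object of class `pairwise_alignment` with fields `left` and
#'   `right` (gapped index traces: 1-based residue/column indices with `NA`
#'   marking gaps), `total_score`, and `cell_count`.
#' @export
gotoh_align <- function(scores, penalties = gap_penalties()) {
  stopifnot(inherits(penalties, "gap_penalties"))
  S <- if (inherits(scores, "score_matrix")) scores$scores else as.matrix(scores)
  if (length(S) && !all(is.finite(S))) {
    bad <- which(!is.finite(S), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite score at (%d, %d)", bad[1L], bad[2L]), call. = FALSE)
  }
  res <- .gotoh_core(S, penalties$gap_open, penalties$gap_extend)
  structure(list(left = res$left, right = res$right,
                 total_score = res$score, cell_count = res$cells),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment: %d columns, score %.4f>\n",
              length(x$left), x$total_score))
  invisible(x)
}

.check_traces <- function(left, right, n, m) {
  if (length(left) != length(right)) stop("traces differ in length", call. = FALSE)
  if (any(is.na(left) & is.na(right))) stop("column gapped in both traces", call. = FALSE)
  lt <- left[!is.na(left)]; rt <- right[!is.na(right)]
  if (!identical(as.integer(lt), seq_len(n)) ||
      !identical(as.integer(rt), seq_len(m))) {
    stop("traces do not enumerate their axes in order", call. = FALSE)
  }
  invisible(NULL)
}

#' Independently re-score an alignment trace
#'
#' Sums matched-cell scores and affine gap costs, charging each maximal run of
#' gaps in one trace as one gap event under the package's gap-cost convention.
#' Used as the self-consistency check on [gotoh_align()] output.
#'
#' @param left,right gapped index traces (as in `pairwise_alignment`).
#' @param scores the [score_matrix()] the alignment was computed from.
#' @param penalties a [gap_penalties()].
#' @return The total alignment score.
#' @export
score_alignment <- function(left, right, scores, penalties = gap_penalties()) {
  S <- if (inherits(scores, "score_matrix")) scores$scores else as.matrix(scores)
  .check_traces(left, right, nrow(S), ncol(S))
  matched <- !is.na(left) & !is.na(right)
  total <- if (any(matched)) sum(S[cbind(left[matched], right[matched])]) else 0
  for (gv in list(is.na(left), is.na(right))) {
    if (any(gv)) {
      runs <- rle(gv)
      lens <- runs$lengths[runs$values]
      total <- total + sum(penalties$gap_open + (lens - 1) * penalties$gap_extend)
    }
  }
  total
}
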