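# Scoring layer: turns residue / profile-column representations into the
# dense fixed ScoreMatrix consumed by the DP.  Three interchangeable backends:
# learned symmetric compatibility network, cosine control, BLOSUM62 control.
# The DP layer never calls back into this file: every score is computed here,
# in full, before any recursion starts.

#' Construct a score matrix
#'
#' @param scores numeric n x m matrix of finite backend scores.
#' @param row_source,col_source identifiers of the scored objects.
#' @param backend_id backend tag.
#' @return Object of class `score_matrix`.
#' @export
score_matrix <- function(scores, row_source = "left", col_source = "right",
                         backend_id = "unknown") {
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) {
    bad <- which(!is.finite(scores), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite score at (%d, %d)", bad[1L], bad[2L]), call. = FALSE)
  }
  structure(list(scores = unname(scores), row_source = row_source,
                 col_source = col_source, backend_id = backend_id),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix %d x %d [%s]: %s vs %s>\n", nrow(x$scores),
              ncol(x$scores), x$backend_id, x$row_source, x$col_source))
  invisible(x)
}

#' Cosine similarity score between two embedding vectors
#'
#' Inner product over the product of Euclidean norms; defined as 0 when either
#' vector has zero norm (avoids NaN on degenerate input).
#'
#' @param x,y numeric vectors of equal length.
#' @return A real in `[-1, 1]`.
#' @export
cosine_score <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("dimension mismatch: %d vs %d", length(x), length(y)), call. = FALSE)
  }
  .count_scoring_call()
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' BLOSUM62 substitution score for two amino acids
#'
#' Standard half-bit BLOSUM62 entry, embedded as a package constant.
#'
#' @param a,b single canonical amino-acid letters.
#' @return Integer score.
#' @export
blosum62_score <- function(a, b) {
  if (!a %in% AA20 || !b %in% AA20) {
    stop(sprintf("symbol outside the 20-letter alphabet: '%s'",
                 if (!a %in% AA20) a else b), call. = FALSE)
  }
  .count_scoring_call()
  BLOSUM62_20[a, b]
}

# Symmetric pair features for the learned scorer: (x+y, x*y, |x-y|).  Each
# block is symmetric in (x, y) under IEEE arithmetic, so f(x,y) == f(y,x)
# bit-for-bit — symmetry is structural, not averaged.
.pair_features <- function(X, Y) {
  cbind(X + Y, X * Y, abs(X - Y))
}

# Vectorized forward pass of the compatibility network on N pre-paired rows.
.learned_forward <- function(params, X, Y) {
  F <- .pair_features(X, Y)
  H1 <- tanh(sweep(F %*% params$W1, 2L, params$b1, `+`))
  H2 <- tanh(sweep(H1 %*% params$W2, 2L, params$b2, `+`))
  logit <- drop(H2 %*% params$w3) + params$b3
  params$calibration$scale * logit + params$calibration$offset
}

#' Evaluate the learned symmetric compatibility function on one vector pair
#'
#' @param params `scorer_params` (weights of the symmetric network; see
#'   [train_scorer()]).
#' @param x,y embedding vectors of dimension `params$d`.
#' @return A finite real score, bit-identical under argument swap.
#' @export
learned_score <- function(params, x, y) {
  stopifnot(inherits(params, "scorer_params"))
  if (length(x) != params$d || length(y) != params$d) {
    stop(sprintf("dimension mismatch: scorer expects d=%d, received %d and %d",
                 params$d, length(x), length(y)), call. = FALSE)
  }
  .count_scoring_call()
  drop(.learned_forward(params, matrix(x, 1L), matrix(y, 1L)))
}

#' Scoring backends
#'
#' Constructors for the three interchangeable scoring backends.  A backend is
#' consumed only by [compute_score_matrix()]; the alignment engine itself sees
#' nothing but the resulting fixed numbers.
#'
#' @param checkpoint a `scorer_checkpoint` from [train_scorer()] or
#'   [load_checkpoint()].
#' @return Object of class `scoring_backend`.
#' @name backends
NULL

#' @rdname backends
#' @export
backend_cosine <- function() {
  structure(list(backend_id = "cosine", needs = "embeddings"),
            class = "scoring_backend")
}

#' @rdname backends
#' @export
backend_blosum62 <- function() {
  structure(list(backend_id = "blosum62", needs = "symbols"),
            class = "scoring_backend")
}

#' @rdname backends
#' @export
backend_learned <- function(checkpoint) {
  stopifnot(inherits(checkpoint, "scorer_checkpoint"))
  structure(list(backend_id = "learned", needs = "embeddings",
                 params = checkpoint$params),
            class = "scoring_backend")
}

# Row-normalize, mapping zero-norm rows to zero vectors (cosine contract).
.unit_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  nz <- nrm > 0
  M[nz, ] <- M[nz, , drop = FALSE] / nrm[nz]
  M[!nz, ] <- 0
  M
}

# 20 x C matrix of per-column residue proportions of a profile (gaps excluded).
.column_residue_profile <- function(rows_chars) {
  C <- ncol(rows_chars)
  counts <- matrix(0, 20L, C, dimnames = list(AA20, NULL))
  for (r in seq_len(nrow(rows_chars))) {
    ch <- rows_chars[r, ]
    ok <- ch != GAP
    if (any(ok)) {
      idx <- cbind(match(ch[ok], AA20), which(ok))
      counts[idx] <- counts[idx] + 1
    }
  }
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  sweep(counts, 2L, tot, `/`)
}

#' Compute the dense score matrix a DP instance will consume
#'
#' Entry `(i, j)` is the backend score between left unit `i` (a residue of a
#' single sequence, or a profile column) and residue `j` of the right
#' sequence.  The whole matrix is produced here, before any dynamic
#' programming; the function is pure in its inputs.
#'
#' With embedding backends, `left` is an `embedding_matrix` or a profile (its
#' column embeddings are used).  The BLOSUM62 backend needs symbols instead:
#' `left_seq`/`right_seq` records for sequences, or the profile's own rows;
#' profile-column-vs-residue score is the mean BLOSUM62 score over the
#' column's non-gap members.
#'
#' @param backend a `scoring_backend`.
#' @param left `embedding_matrix` or `profile` ([new_profile()]).
#' @param right `embedding_matrix` of the incoming sequence.
#' @param left_seq,right_seq `seq_record`s, required by the BLOSUM62 backend.
#' @return A [score_matrix()].
#' @export
compute_score_matrix <- function(backend, left, right = NULL,
                                 left_seq = NULL, right_seq = NULL) {
  stopifnot(inherits(backend, "scoring_backend"))
  .count_scoring_call()
  left_is_profile <- inherits(left, "profile")

  if (backend$needs == "embeddings") {
    L <- if (left_is_profile) profile_column_embeddings(left) else {
      stopifnot(inherits(left, "embedding_matrix")); left$vectors
    }
    stopifnot(inherits(right, "embedding_matrix"))
    R <- right$vectors
    if (ncol(L) != ncol(R)) {
      stop(sprintf("embedding dimension mismatch: %d vs %d", ncol(L), ncol(R)),
           call. = FALSE)
    }
    S <- switch(backend$backend_id,
      cosine = .unit_rows(L) %*% t(.unit_rows(R)),
      learned = {
        if (ncol(L) != backend$params$d) {
          stop(sprintf("dimension mismatch: scorer expects d=%d, received %d",
                       backend$params$d, ncol(L)), call. = FALSE)
        }
        nL <- nrow(L); nR <- nrow(R)
        X <- L[rep(seq_len(nL), each = nR), , drop = FALSE]
        Y <- R[rep(seq_len(nR), times = nL), , drop = FALSE]
        matrix(.learned_forward(backend$params, X, Y), nrow = nL, byrow = TRUE)
      },
      stop("unknown embedding backend: ", backend$backend_id, call. = FALSE))
    row_src <- if (left_is_profile) "profile" else left$sequence_id
    return(score_matrix(S, row_src, right$sequence_id, backend$backend_id))
  }

  # symbol backend (BLOSUM62)
  if (is.null(right_seq)) {
    stop("BLOSUM62 backend requires right_seq symbols (configuration error)",
         call. = FALSE)
  }
  rch <- strsplit(right_seq$residues, "")[[1]]
  if (left_is_profile) {
    prof <- .column_residue_profile(profile_char_matrix(left))
    S <- t(prof) %*% BLOSUM62_20[, rch, drop = FALSE]
    return(score_matrix(S, "profile", right_seq$id, backend$backend_id))
  }
  if (is.null(left_seq)) {
    stop("BLOSUM62 backend requires left_seq symbols (configuration error)",
         call. = FALSE)
  }
  lch <- strsplit(left_seq$residues, "")[[1]]
  S <- BLOSUM62_20[lch, rch, drop = FALSE]
  score_matrix(S, left_seq$id, right_seq$id, backend$backend_id)
}
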