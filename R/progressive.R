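# Progressive assembly: order sequences under an explicit policy, then
# repeatedly align the growing profile to the next sequence with the exact
# affine-gap DP.  The ordering is an assembly heuristic only, never a
# phylogenetic estimate.

#' Start a single-sequence profile
#'
#' A profile is a partial alignment treated as one alignable object: gapped
#' rows (as index maps into the original ungapped sequences), the member
#' sequences and their embeddings, and incrementally maintained per-column
#' embedding sums/counts from which column means are derived.
#'
#' @param seq a `protein20` [seq_record()].
#' @param emb its `embedding_matrix` (may be `NULL` for symbol-only backends).
#' @return Object of class `profile`.
#' @export
new_profile <- function(seq, emb = NULL) {
  stopifnot(inherits(seq, "seq_record"))
  n <- nchar(seq$residues)
  col_sum <- if (!is.null(emb)) emb$vectors else matrix(0, n, 0L)
  structure(list(ids = seq$id,
                 maps = list(seq_len(n)),
                 seqs = list(seq),
                 embs = list(emb),
                 col_sum = col_sum,
                 col_cnt = rep(1L, n)),
            class = "profile")
}

#' Column embeddings of a profile
#'
#' Mean of member residue embeddings over the non-gap positions of each
#' column; maintained incrementally across merges and recomputable from
#' scratch with [profile_recompute_columns()].
#'
#' @param p a `profile`.
#' @return Numeric `column_count x d` matrix.
#' @export
profile_column_embeddings <- function(p) {
  stopifnot(inherits(p, "profile"))
  p$col_sum / p$col_cnt
}

#' Recompute profile column embeddings from scratch
#'
#' Oracle for the incremental maintenance: averages member embeddings per
#' column directly from the row maps.
#'
#' @param p a `profile`.
#' @return Numeric `column_count x d` matrix.
#' @export
profile_recompute_columns <- function(p) {
  stopifnot(inherits(p, "profile"))
  C <- length(p$col_cnt)
  d <- ncol(p$col_sum)
  s <- matrix(0, C, d)
  cnt <- rep(0L, C)
  for (r in seq_along(p$maps)) {
    map <- p$maps[[r]]
    ok <- !is.na(map)
    s[ok, ] <- s[ok, , drop = FALSE] + p$embs[[r]]$vectors[map[ok], , drop = FALSE]
    cnt[ok] <- cnt[ok] + 1L
  }
  s / cnt
}

#' Character matrix of a profile's gapped rows
#' @param p a `profile`.
#' @export
profile_char_matrix <- function(p) {
  stopifnot(inherits(p, "profile"))
  C <- length(p$col_cnt)
  out <- matrix(GAP, length(p$maps), C)
  for (r in seq_along(p$maps)) {
    map <- p$maps[[r]]
    ok <- !is.na(map)
    chars <- strsplit(p$seqs[[r]]$residues, "")[[1]]
    out[r, ok] <- chars[map[ok]]
  }
  rownames(out) <- p$ids
  out
}

# Merge the next sequence into the profile using a DP result whose left trace
# indexes profile columns and right trace indexes the sequence's residues.
.profile_merge <- function(p, aln, seq, emb) {
  Cn <- length(aln$left)
  d <- ncol(p$col_sum)
  col_sum <- matrix(0, Cn, d)
  col_cnt <- rep(0L, Cn)
  oldcols <- !is.na(aln$left)
  col_sum[oldcols, ] <- p$col_sum[aln$left[oldcols], , drop = FALSE]
  col_cnt[oldcols] <- p$col_cnt[aln$left[oldcols]]
  maps <- lapply(p$maps, function(map) {
    out <- rep(NA_integer_, Cn)
    out[oldcols] <- map[aln$left[oldcols]]
    out
  })
  newmap <- aln$right
  if (!is.null(emb)) {
    ok <- !is.na(newmap)
    col_sum[ok, ] <- col_sum[ok, , drop = FALSE] + emb$vectors[newmap[ok], , drop = FALSE]
  }
  col_cnt[!is.na(newmap)] <- col_cnt[!is.na(newmap)] + 1L
  structure(list(ids = c(p$ids, seq$id),
                 maps = c(maps, list(newmap)),
                 seqs = c(p$seqs, list(seq)),
                 embs = c(p$embs, list(emb)),
                 col_sum = col_sum, col_cnt = col_cnt),
            class = "profile")
}

.profile_to_msa <- function(p, order = seq_along(p$maps)) {
  chars <- profile_char_matrix(p)
  rows <- lapply(order, function(r) {
    seq_record(p$ids[r], paste(chars[r, ], collapse = ""), "gapped-protein",
               p$seqs[[r]]$description)
  })
  msa(rows)
}

#' Pairwise cosine distances between sequence-embedding centroids
#'
#' Entry `(i, j)` is `1 - cosine(centroid_i, centroid_j)`.  A zero-norm
#' centroid is assigned distance 1 to every other sequence (with a warning).
#'
#' @param embeddings list of `embedding_matrix` objects (length >= 2).
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
centroid_distance_matrix <- function(embeddings) {
  if (length(embeddings) < 2L) stop("need at least 2 sequences", call. = FALSE)
  cents <- do.call(rbind, lapply(embeddings, sequence_centroid))
  nrm <- sqrt(rowSums(cents^2))
  if (any(nrm == 0)) {
    warning("zero-norm centroid: distance to all others defined as 1", call. = FALSE)
  }
  U <- .unit_rows(cents)
  D <- 1 - U %*% t(U)
  if (any(nrm == 0)) {
    z <- which(nrm == 0)
    D[z, ] <- 1; D[, z] <- 1
  }
  diag(D) <- 0
  D[D < 0] <- 0  # clamp negative rounding residue
  (D + t(D)) / 2
}

#' Sequence insertion-order policy
#'
#' @param policy `"upgma"`, `"input"`, or `"random"`.
#' @param seed integer seed (random policy only).
#' @export
order_policy <- function(policy = c("upgma", "input", "random"), seed = 1L) {
  policy <- match.arg(policy)
  structure(list(policy = policy, seed = as.integer(seed)), class = "order_policy")
}

# UPGMA (unweighted average linkage) with frozen determinism: merge the pair
# with minimal distance, ties broken by the lexicographically smallest pair of
# smallest-original-member indices; within a merge the subtree holding the
# smaller original index goes left.  Returns leaf order; Newick topology of
# the guide tree is attached as an attribute.
.upgma_order <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), function(i) {
    list(members = i, order = i, size = 1L, newick = sprintf("s%d", i))
  })
  Dc <- D
  active <- seq_len(n)
  while (length(active) > 1L) {
    best <- NULL
    for (ai in seq_along(active)[-length(active)]) {
      for (bi in (ai + 1L):length(active)) {
        a <- active[ai]; b <- active[bi]
        key <- sort(c(min(clusters[[a]]$members), min(clusters[[b]]$members)))
        d <- Dc[a, b]
        if (is.null(best) || d < best$d - 0 ||
            (d == best$d && (key[1] < best$key[1] ||
                             (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(d = d, a = a, b = b, key = key)
        }
      }
    }
    a <- best$a; b <- best$b
    ca <- clusters[[a]]; cb <- clusters[[b]]
    first <- if (min(ca$members) < min(cb$members)) list(ca, cb) else list(cb, ca)
    merged <- list(members = c(ca$members, cb$members),
                   order = c(first[[1]]$order, first[[2]]$order),
                   size = ca$size + cb$size,
                   newick = sprintf("(%s,%s)", first[[1]]$newick, first[[2]]$newick))
    # unweighted average linkage update
    for (k in active) {
      if (k != a && k != b) {
        Dc[a, k] <- (ca$size * Dc[a, k] + cb$size * Dc[b, k]) / (ca$size + cb$size)
        Dc[k, a] <- Dc[a, k]
      }
    }
    clusters[[a]] <- merged
    active <- setdiff(active, b)
  }
  root <- clusters[[active]]
  structure(root$order, newick = paste0(root$newick, ";"))
}

#' Order sequences for progressive assembly
#'
#' @param distances symmetric nonnegative distance matrix (required for the
#'   UPGMA policy; ignored by input/random).
#' @param policy an [order_policy()].
#' @param n number of sequences (inferred from `distances` when given).
#' @return Integer permutation of `1:n`; for UPGMA the guide-tree topology is
#'   attached as attribute `"newick"` (labels `s<i>` are input indices).
#' @export
order_sequences <- function(distances = NULL, policy = order_policy("input"),
                            n = if (!is.null(distances)) nrow(distances) else NULL) {
  stopifnot(inherits(policy, "order_policy"))
  if (is.null(n)) stop("sequence count unknown", call. = FALSE)
  if (policy$policy == "input") return(seq_len(n))
  if (policy$policy == "random") {
    return(.with_seed(policy$seed, sample.int(n)))
  }
  if (is.null(distances)) stop("UPGMA policy requires a distance matrix", call. = FALSE)
  D <- as.matrix(distances)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12) || any(D < 0)) {
    stop("distance matrix must be symmetric and nonnegative", call. = FALSE)
  }
  .upgma_order(D)
}

#' Progressive multiple sequence alignment
#'
#' Orders the input under the chosen policy, initializes the profile with the
#' first sequence, then for each subsequent sequence: computes the full
#' profile-column-vs-residue score matrix with the selected backend, solves
#' the affine-gap DP exactly, and merges.  All scoring happens strictly
#' before each DP call.  Output rows are restored to the original input
#' order.
#'
#' @param sequences list of `protein20` [seq_record()]s.
#' @param provider an `embedding_provider` (required for embedding backends
#'   and for the UPGMA policy).
#' @param backend a `scoring_backend` (default cosine).
#' @param penalties a [gap_penalties()].
#' @param policy an [order_policy()] (default UPGMA).
#' @param profile record per-phase wall-clock timings (see
#'   [profile_phases()]); attached as attribute `"timings"`.
#' @return An [msa()] in input row order, with attributes `"insertion_order"`
#'   and (UPGMA) `"guide_newick"`.
#' @export
progressive_align <- function(sequences, provider = NULL,
                              backend = backend_cosine(),
                              penalties = gap_penalties(),
                              policy = order_policy("upgma"),
                              profile = FALSE) {
  stopifnot(all(vapply(sequences, inherits, logical(1), "seq_record")))
  ids <- vapply(sequences, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  timer <- if (isTRUE(profile)) .new_timer() else NULL
  if (length(sequences) == 1L) {
    warning("single sequence: returning trivial one-row alignment", call. = FALSE)
    row <- seq_record(ids[1], sequences[[1]]$residues, "gapped-protein",
                      sequences[[1]]$description)
    out <- msa(list(row))
    attr(out, "insertion_order") <- 1L
    if (!is.null(timer)) attr(out, "timings") <- .timer_close(timer)
    return(out)
  }

  needs_emb <- backend$needs == "embeddings" || policy$policy == "upgma"
  embs <- NULL
  if (needs_emb) {
    if (is.null(provider)) {
      stop("an embedding provider is required for this backend/policy", call. = FALSE)
    }
    .phase(timer, "embedding", {
      embs <- lapply(sequences, function(s) embed_sequence(provider, s))
    })
  }

  ord <- if (policy$policy == "upgma") {
    D <- NULL
    .phase(timer, "scoring", D <- centroid_distance_matrix(embs))
    order_sequences(D, policy)
  } else {
    order_sequences(policy = policy, n = length(sequences))
  }

  first <- ord[1L]
  prof <- new_profile(sequences[[first]],
                      if (!is.null(embs)) embs[[first]] else NULL)
  for (k in ord[-1L]) {
    sm <- NULL
    .phase(timer, "scoring", {
      sm <- compute_score_matrix(backend, prof,
                                 if (!is.null(embs)) embs[[k]] else NULL,
                                 right_seq = sequences[[k]])
    })
    aln <- NULL
    .phase(timer, "dp", aln <- gotoh_align(sm, penalties))
    prof <- .profile_merge(prof, aln, sequences[[k]],
                           if (!is.null(embs)) embs[[k]] else NULL)
  }
  out <- .profile_to_msa(prof, order = match(ids, prof$ids))
  attr(out, "insertion_order") <- ord
  if (policy$policy == "upgma" && !is.null(attr(ord, "newick"))) {
    attr(out, "guide_newick") <- attr(ord, "newick")
  }
  if (!is.null(timer)) attr(out, "timings") <- .timer_close(timer)
  out
}
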