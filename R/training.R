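# Training of the learned symmetric compatibility scorer from families with
# known alignments.  Supervision is aligned-vs-unaligned binary
# classification with logistic loss on the symmetric network's logit; the
# held-out surface is parameter recovery (pair AUC and downstream alignment
# accuracy), not weight-level equivalence with any external model.

.CKPT_VERSION <- "embalign-ckpt-1"

#' Initialize parameters of the symmetric compatibility network
#'
#' The network consumes the symmetric pair features `(x + y, x * y, |x - y|)`
#' (dimension `3d`), passes them through tanh hidden layers, and emits one
#' scalar logit, then an affine calibration (default identity).
#'
#' @param d embedding dimension.
#' @param hidden integer vector of the two hidden-layer widths.
#' @param seed integer seed for the Gaussian initialization.
#' @param zero start from all-zero weights (for tests).
#' @return Object of class `scorer_params`.
#' @export
init_scorer_params <- function(d, hidden = c(64L, 64L), seed = 1L, zero = FALSE) {
  d <- as.integer(d)
  h1 <- as.integer(hidden[1L]); h2 <- as.integer(hidden[2L])
  f <- 3L * d
  p <- .with_seed(seed, list(
    W1 = matrix(rnorm(f * h1, sd = sqrt(1 / f)), f, h1),
    b1 = rep(0, h1),
    W2 = matrix(rnorm(h1 * h2, sd = sqrt(1 / h1)), h1, h2),
    b2 = rep(0, h2),
    w3 = matrix(rnorm(h2, sd = sqrt(1 / h2)), h2, 1L),
    b3 = 0
  ))
  if (isTRUE(zero)) p <- lapply(p, function(x) x * 0)
  structure(c(p, list(d = d, hidden = c(h1, h2), activation = "tanh",
                      calibration = list(scale = 1, offset = 0))),
            class = "scorer_params")
}

#' Build a labeled residue-pair dataset from simulated families
#'
#' Positives are embedding pairs at residue-residue columns of the true
#' alignments (cross-row, within-column; no gap ever participates).
#' Negatives are uniformly sampled cross-sequence residue pairs of the same
#' family that are not aligned in the truth, at `negatives_per_positive` per
#' positive.  Pairs are shuffled under `seed` and regeneration is exact.
#'
#' Benchmark isolation: any family whose id appears in `exclude_families` is
#' refused with an error, mirroring strict train/evaluation separation.
#'
#' @param families list of `sim_family` objects.
#' @param provider deterministic embedding provider.
#' @param negatives_per_positive positive integer ratio.
#' @param seed integer seed.
#' @param exclude_families character vector of family ids that must never be
#'   trained on.
#' @return Object of class `pair_dataset`: matrices `X`, `Y` (N x d), `labels`
#'   (0/1), `family` (per-pair family id), `pairs` (row/position provenance
#'   of every pair), `provenance`.
#' @export
build_pair_dataset <- function(families, provider, negatives_per_positive = 1L,
                               seed = 1L, exclude_families = character(0)) {
  stopifnot(all(vapply(families, inherits, logical(1), "sim_family")))
  if (negatives_per_positive < 1L) {
    stop("negatives_per_positive must be a positive integer", call. = FALSE)
  }
  fam_ids <- vapply(families, function(f) f$params$family_id, character(1))
  banned <- intersect(fam_ids, exclude_families)
  if (length(banned)) {
    stop("benchmark isolation violation: excluded family in training set: ",
         paste(banned, collapse = ", "), call. = FALSE)
  }
  Xs <- list(); Ys <- list(); labs <- list(); fams <- list(); idxs <- list()
  .with_seed(seed, {
    for (f in families) {
      nrows <- length(f$sequences)
      if (nrows < 2L) {
        warning("skipping family ", f$params$family_id, " with < 2 rows",
                call. = FALSE)
        next
      }
      embs <- lapply(f$sequences, function(s) embed_sequence(provider, s)$vectors)
      chars <- msa_matrix(f$true_msa)
      # residue ordinal of each non-gap cell, per row
      ords <- t(apply(chars != GAP, 1L, cumsum))
      pos_a <- list(); pos_b <- list(); pr_a <- list(); pr_b <- list()
      for (a in 1:(nrows - 1L)) for (b in (a + 1L):nrows) {
        both <- which(chars[a, ] != GAP & chars[b, ] != GAP)
        if (length(both)) {
          pos_a[[length(pos_a) + 1L]] <- ords[a, both]
          pos_b[[length(pos_b) + 1L]] <- ords[b, both]
          pr_a[[length(pr_a) + 1L]] <- rep(a, length(both))
          pr_b[[length(pr_b) + 1L]] <- rep(b, length(both))
        }
      }
      pa <- unlist(pos_a); pb <- unlist(pos_b)
      ra <- unlist(pr_a); rb <- unlist(pr_b)
      npos <- length(pa)
      if (!npos) next
      # key set of true-aligned pairs for rejection sampling of negatives
      truth <- new.env(parent = emptyenv(), size = npos * 2L)
      for (k in seq_len(npos)) {
        truth[[sprintf("%d.%d.%d.%d", ra[k], pa[k], rb[k], pb[k])]] <- TRUE
      }
      lens <- vapply(f$sequences, function(s) nchar(s$residues), integer(1))
      nneg <- npos * as.integer(negatives_per_positive)
      na_r <- integer(nneg); na_p <- integer(nneg)
      nb_r <- integer(nneg); nb_p <- integer(nneg)
      k <- 0L
      while (k < nneg) {
        a <- sample.int(nrows, 1L)
        b <- sample.int(nrows, 1L)
        if (a == b) next
        if (a > b) { tmp <- a; a <- b; b <- tmp }
        i <- sample.int(lens[a], 1L); j <- sample.int(lens[b], 1L)
        if (!is.null(truth[[sprintf("%d.%d.%d.%d", a, i, b, j)]])) next
        k <- k + 1L
        na_r[k] <- a; na_p[k] <- i; nb_r[k] <- b; nb_p[k] <- j
      }
      rowsA <- rbind(
        do.call(rbind, lapply(seq_len(npos), function(k) embs[[ra[k]]][pa[k], ])),
        do.call(rbind, lapply(seq_len(nneg), function(k) embs[[na_r[k]]][na_p[k], ])))
      rowsB <- rbind(
        do.call(rbind, lapply(seq_len(npos), function(k) embs[[rb[k]]][pb[k], ])),
        do.call(rbind, lapply(seq_len(nneg), function(k) embs[[nb_r[k]]][nb_p[k], ])))
      Xs[[length(Xs) + 1L]] <- rowsA
      Ys[[length(Ys) + 1L]] <- rowsB
      labs[[length(labs) + 1L]] <- c(rep(1L, npos), rep(0L, nneg))
      fams[[length(fams) + 1L]] <- rep(f$params$family_id, npos + nneg)
      idxs[[length(idxs) + 1L]] <- data.frame(
        family_id = f$params$family_id,
        row_a = c(ra, na_r), pos_a = c(pa, na_p),
        row_b = c(rb, nb_r), pos_b = c(pb, nb_p),
        label = c(rep(1L, npos), rep(0L, nneg)))
    }
    if (!length(labs) || !sum(unlist(labs))) {
      stop("no positive pairs available for training", call. = FALSE)
    }
    X <- do.call(rbind, Xs); Y <- do.call(rbind, Ys)
    labels <- unlist(labs); family <- unlist(fams)
    pairs <- do.call(rbind, idxs)
    perm <- sample.int(length(labels))
    structure(list(X = X[perm, , drop = FALSE], Y = Y[perm, , drop = FALSE],
                   labels = labels[perm], family = family[perm],
                   pairs = pairs[perm, ], d = ncol(X),
                   provenance = list(families = fam_ids, seed = as.integer(seed),
                                     negatives_per_positive =
                                       as.integer(negatives_per_positive))),
              class = "pair_dataset")
  })
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("<pair_dataset: %d pairs (%d positive), d=%d, %d families>\n",
              length(x$labels), sum(x$labels), x$d,
              length(unique(x$family))))
  invisible(x)
}

#' Shuffle dataset labels (negative-control training)
#'
#' Permutes labels uniformly under `seed`, destroying the supervision signal
#' while keeping marginals identical; training on the result gives the
#' label-shuffled control scorer.
#'
#' @param dataset a `pair_dataset`.
#' @param seed integer seed.
#' @export
shuffle_dataset_labels <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "pair_dataset"))
  dataset$labels <- .with_seed(seed, sample(dataset$labels))
  dataset$provenance$label_shuffled <- TRUE
  dataset
}

.stable_softplus <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))

.bce_forward_backward <- function(p, F, y) {
  H1 <- tanh(sweep(F %*% p$W1, 2L, p$b1, `+`))
  H2 <- tanh(sweep(H1 %*% p$W2, 2L, p$b2, `+`))
  z <- drop(H2 %*% p$w3) + p$b3
  loss <- mean(.stable_softplus(z) - y * z)
  n <- length(y)
  dz <- (1 / (1 + exp(-z)) - y) / n
  g <- list()
  g$w3 <- t(H2) %*% dz
  g$b3 <- sum(dz)
  dH2 <- tcrossprod(dz, p$w3) * (1 - H2^2)
  g$W2 <- crossprod(H1, dH2)
  g$b2 <- colSums(dH2)
  dH1 <- (dH2 %*% t(p$W2)) * (1 - H1^2)
  g$W1 <- crossprod(F, dH1)
  g$b1 <- colSums(dH1)
  list(loss = loss, grads = g)
}

#' Train the learned scorer on a labeled pair dataset
#'
#' Binary cross-entropy on the symmetric network's logit, minimized with Adam
#' over seeded mini-batches; fully deterministic given `seed`.  The dataset
#' is split 90/10 at the family level (never the pair level) into
#' train/validation; held-out AUC and accuracy are reported in the checkpoint
#' metadata.
#'
#' @param dataset a [build_pair_dataset()] result.
#' @param hidden hidden-layer widths (default `c(64, 64)`).
#' @param learning_rate Adam step size (default 0.01).
#' @param epochs training epochs (default 40).
#' @param batch_size mini-batch size (default 512).
#' @param seed integer seed for initialization and batching.
#' @return Object of class `scorer_checkpoint`: `params` (`scorer_params`),
#'   `meta` (seed, provenance, loss curve, held-out metrics, format version).
#' @export
train_scorer <- function(dataset, hidden = c(64L, 64L), learning_rate = 0.01,
                         epochs = 40L, batch_size = 512L, seed = 1L) {
  stopifnot(inherits(dataset, "pair_dataset"))
  if (!length(dataset$labels) || length(unique(dataset$labels)) < 2L) {
    stop("dataset must contain both classes", call. = FALSE)
  }
  fams <- unique(dataset$family)
  n_val <- if (length(fams) >= 2L) max(1L, floor(length(fams) * 0.1)) else 0L
  val_f <- .with_seed(seed + 1L, sample(fams, n_val))
  is_val <- dataset$family %in% val_f
  F_tr <- .pair_features(dataset$X[!is_val, , drop = FALSE],
                         dataset$Y[!is_val, , drop = FALSE])
  y_tr <- dataset$labels[!is_val]
  p <- init_scorer_params(dataset$d, hidden, seed = seed)
  state <- lapply(p[c("W1", "b1", "W2", "b2", "w3", "b3")],
                  function(w) list(m = w * 0, v = w * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  losses <- numeric(epochs)
  .with_seed(seed + 2L, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(nrow(F_tr))
      starts <- seq(1L, nrow(F_tr), by = batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + batch_size - 1L, nrow(F_tr))]
        fb <- .bce_forward_backward(p, F_tr[idx, , drop = FALSE], y_tr[idx])
        if (!is.finite(fb$loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d", ep),
               call. = FALSE)
        }
        ep_loss <- ep_loss + fb$loss * length(idx)
        t_step <- t_step + 1L
        for (nm in names(fb$grads)) {
          st <- state[[nm]]
          st$m <- beta1 * st$m + (1 - beta1) * fb$grads[[nm]]
          st$v <- beta2 * st$v + (1 - beta2) * fb$grads[[nm]]^2
          state[[nm]] <- st
          mhat <- st$m / (1 - beta1^t_step)
          vhat <- st$v / (1 - beta2^t_step)
          p[[nm]] <- p[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      losses[ep] <- ep_loss / nrow(F_tr)
    }
  })
  val_metrics <- list(auc = NA_real_, accuracy = NA_real_, n = sum(is_val))
  if (any(is_val)) {
    zs <- .learned_forward(p, dataset$X[is_val, , drop = FALSE],
                           dataset$Y[is_val, , drop = FALSE])
    val_metrics <- c(.pair_metrics(zs, dataset$labels[is_val]),
                     list(n = sum(is_val)))
  }
  structure(list(params = p,
                 meta = list(format_version = .CKPT_VERSION, seed = as.integer(seed),
                             d = dataset$d, hidden = p$hidden,
                             provenance = dataset$provenance,
                             loss_curve = losses,
                             validation_families = val_f,
                             validation = val_metrics)),
            class = "scorer_checkpoint")
}

# AUC via the rank formula plus 0.5-threshold accuracy.
.pair_metrics <- function(scores, labels) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  auc <- if (n1 && n0) {
    r <- rank(scores)
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  list(auc = auc, accuracy = mean((scores > 0) == (labels == 1L)))
}

#' Score a checkpoint on a labeled pair dataset
#'
#' @param checkpoint a `scorer_checkpoint`.
#' @param dataset a `pair_dataset` of matching dimension.
#' @return List with `auc` and `accuracy`.
#' @export
evaluate_scorer <- function(checkpoint, dataset) {
  stopifnot(inherits(checkpoint, "scorer_checkpoint"),
            inherits(dataset, "pair_dataset"))
  if (checkpoint$params$d != dataset$d) {
    stop(sprintf("dimension error: checkpoint d=%d, dataset d=%d",
                 checkpoint$params$d, dataset$d), call. = FALSE)
  }
  z <- .learned_forward(checkpoint$params, dataset$X, dataset$Y)
  .pair_metrics(z, dataset$labels)
}

#' @export
print.scorer_checkpoint <- function(x, ...) {
  cat(sprintf("<scorer_checkpoint %s: d=%d, hidden=%s, val AUC %.3f>\n",
              x$meta$format_version, x$params$d,
              paste(x$params$hidden, collapse = "x"),
              x$meta$validation$auc))
  invisible(x)
}

#' Save / load scorer checkpoints
#'
#' Round trips are bit-exact on scorer outputs.  Loading rejects unknown
#' format versions and (when `d` is supplied) mismatched embedding
#' dimensions, naming both sides of the mismatch.
#'
#' @param checkpoint a `scorer_checkpoint`.
#' @param path file path.
#' @param d optional expected embedding dimension.
#' @name checkpoint_io
NULL

#' @rdname checkpoint_io
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "scorer_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname checkpoint_io
#' @export
load_checkpoint <- function(path, d = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot parse checkpoint file ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!inherits(obj, "scorer_checkpoint") || is.null(obj$meta$format_version)) {
    stop("not a scorer checkpoint: ", path, call. = FALSE)
  }
  if (!identical(obj$meta$format_version, .CKPT_VERSION)) {
    stop(sprintf("checkpoint format version '%s' not supported (expected '%s')",
                 obj$meta$format_version, .CKPT_VERSION), call. = FALSE)
  }
  if (!is.null(d) && obj$params$d != d) {
    stop(sprintf("dimension error: checkpoint has d=%d, expected d=%d",
                 obj$params$d, as.integer(d)), call. = FALSE)
  }
  obj
}
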