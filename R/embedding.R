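# Uniform embedding-provider interface with caching.  The synthetic provider
# is the default; external protein-language-model providers plug in through
# the same contract (deterministic, fixed, never fine-tuned).

#' Construct a per-residue embedding matrix
#'
#' @param sequence_id id of the embedded sequence.
#' @param vectors numeric matrix, one row per residue, all entries finite.
#' @param provider_id tag identifying the provider and its settings.
#' @return Object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(sequence_id, vectors, provider_id) {
  vectors <- as.matrix(vectors)
  if (!is.numeric(vectors) || !all(is.finite(vectors))) {
    stop("embedding matrix must be numeric and finite", call. = FALSE)
  }
  if (nrow(vectors) < 1L) stop("embedding matrix must have at least one row", call. = FALSE)
  structure(list(sequence_id = sequence_id, vectors = unname(vectors),
                 d = ncol(vectors), provider_id = provider_id),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix %s: %d x %d, provider %s>\n",
              x$sequence_id, nrow(x$vectors), x$d, x$provider_id))
  invisible(x)
}

#' Synthetic deterministic embedding provider
#'
#' Wraps [synth_embeddings()] behind the provider interface.  The per-sequence
#' noise seed is derived deterministically from the provider seed and the
#' sequence text, so the provider is a pure function of the sequence.
#'
#' @param d embedding dimension (>= 21).
#' @param noise_sd Gaussian noise standard deviation.
#' @param window context half-width.
#' @param seed provider-level seed.
#' @return Object of class `embedding_provider`.
#' @export
synthetic_provider <- function(d = 32L, noise_sd = 0.1, window = 2L, seed = 1L) {
  d <- as.integer(d)
  if (d < 21L) stop("embedding dimension must be at least 21", call. = FALSE)
  structure(list(
    provider_id = sprintf("synthetic-d%d-noise%g-w%d-s%d", d, noise_sd, window,
                          as.integer(seed)),
    d = d, deterministic = TRUE,
    fun = function(seq) {
      seq_seed <- (as.integer(seed) * 7919L + .fnv1a32(seq$residues)) %% 2147483647L
      synth_embeddings(seq, d = d, noise_sd = noise_sd, window = window,
                       seed = seq_seed)
    }), class = "embedding_provider")
}

#' Declare an external embedding provider hook
#'
#' The core package never requires an external protein-language-model; this
#' constructor lets a plug-in supply one under the same deterministic
#' contract.  Calling [embed_sequence()] on a hook with no function installed
#' raises an explicit capability error — never a silent fallback.
#'
#' @param provider_id tag for the external model.
#' @param d embedding dimension it produces.
#' @param fun function(seq_record) -> matrix, or `NULL` if not installed.
#' @export
external_provider <- function(provider_id, d, fun = NULL) {
  structure(list(provider_id = provider_id, d = as.integer(d),
                 deterministic = TRUE, fun = fun),
            class = "embedding_provider")
}

# Deterministic 31-bit polynomial string hash (exact in double arithmetic);
# used for cache file names and derived per-sequence seeds, avoiding an
# external digest dependency.
.fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261 %% 2147483629
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

#' Compute (or fetch from cache) per-residue embeddings for a sequence
#'
#' Results are cached in memory keyed by `(provider_id, exact sequence text)`;
#' a cache hit returns the stored matrix without re-invoking the provider
#' (observable through [embalign_counters()]).  With `cache_dir` set, matrices
#' are additionally persisted on disk, one file per key.
#'
#' @param provider an `embedding_provider`.
#' @param seq a `protein20` [seq_record()].
#' @param cache use the in-memory cache (default `TRUE`).
#' @param cache_dir optional directory for on-disk persistence.
#' @return An `embedding_matrix` with `nrow == nchar(seq$residues)`.
#' @export
embed_sequence <- function(provider, seq, cache = TRUE, cache_dir = NULL) {
  stopifnot(inherits(provider, "embedding_provider"), inherits(seq, "seq_record"))
  if (seq$alphabet != "protein20") stop("can only embed protein20 sequences", call. = FALSE)
  if (is.null(provider$fun)) {
    stop(sprintf("embedding provider '%s' is not available in this installation",
                 provider$provider_id), call. = FALSE)
  }
  .init_state()
  key <- sprintf("emb|%s|%s", provider$provider_id, seq$residues)
  if (isTRUE(cache)) {
    hit <- .embalign_state$cache[[key]]
    if (!is.null(hit)) return(.relabel_embedding(hit, seq$id))
    if (!is.null(cache_dir)) {
      f <- file.path(cache_dir, sprintf("%s_%08x.rds", provider$provider_id,
                                        .fnv1a32(seq$residues)))
      if (file.exists(f)) {
        m <- readRDS(f)
        .embalign_state$cache[[key]] <- m
        return(.relabel_embedding(m, seq$id))
      }
    }
  }
  .count_provider_call()
  emb <- provider$fun(seq)
  if (!inherits(emb, "embedding_matrix")) {
    emb <- embedding_matrix(seq$id, emb, provider$provider_id)
  }
  if (nrow(emb$vectors) != nchar(seq$residues)) {
    stop("provider returned wrong number of rows for sequence ", seq$id, call. = FALSE)
  }
  emb$provider_id <- provider$provider_id
  if (isTRUE(cache)) {
    .embalign_state$cache[[key]] <- emb
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(cache_dir, sprintf("%s_%08x.rds", provider$provider_id,
                                        .fnv1a32(seq$residues)))
      saveRDS(emb, f)
      jsonlite::write_json(list(provider_id = provider$provider_id,
                                sequence_id = seq$id, n = nrow(emb$vectors),
                                d = emb$d),
                           paste0(f, ".json"), auto_unbox = TRUE)
    }
  }
  .relabel_embedding(emb, seq$id)
}

.relabel_embedding <- function(emb, id) {
  emb$sequence_id <- id
  emb
}

#' Arithmetic-mean centroid of a residue embedding matrix
#'
#' @param emb an `embedding_matrix` with at least one row.
#' @return Numeric d-vector.
#' @export
sequence_centroid <- function(emb) {
  stopifnot(inherits(emb, "embedding_matrix"))
  if (nrow(emb$vectors) < 1L) stop("empty embedding matrix", call. = FALSE)
  colMeans(emb$vectors)
}
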