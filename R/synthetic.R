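# Synthetic homologous families with a known true alignment, matched CDS and
# synthetic residue embeddings.  Desk-scale stand-in for curated family data:
# every downstream module is testable offline against an exact truth.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so seeded helpers never perturb global randomness.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Coarse biochemical classes used to bias substitutions toward conservative
# exchanges (small/polar, acidic/amide, aromatic, basic, aliphatic, cysteine).
.aa_classes <- list(
  c("A", "G", "P", "S", "T"),
  c("C"),
  c("D", "E", "N", "Q"),
  c("F", "W", "Y"),
  c("H", "K", "R"),
  c("I", "L", "M", "V")
)

.aa_class_of <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t0 <- character(0)
      for (i in seq_along(.aa_classes)) t0[.aa_classes[[i]]] <- i
      tab <<- t0
    }
    tab
  }
})

.substitute_residue <- function(aa, background) {
  cls <- .aa_classes[[as.integer(.aa_class_of()[aa])]]
  mates <- setdiff(cls, aa)
  if (length(mates) && runif(1) < 0.7) {
    sample(mates, 1L)
  } else {
    sample(setdiff(AA20, aa), 1L, prob = background[match(setdiff(AA20, aa), AA20)])
  }
}

#' Default parameters for the family simulator
#'
#' @param ancestor_length ancestral sequence length (default 120).
#' @param n_taxa number of leaves (default 8).
#' @param sub_rate per-site substitution probability per tree edge (default 0.1).
#' @param indel_rate per-site probability that an indel event starts at a site,
#'   per edge (default 0.02).
#' @param indel_len_p geometric length parameter; indel length is
#'   `rgeom(p) + 1`, mean `1/p` (default 0.5).
#' @param background amino-acid background frequencies over the 20-letter
#'   alphabet (default uniform).
#' @param with_cds also generate matched coding sequences by reverse
#'   translation (default `FALSE`).
#' @param family_id identifier recorded in the result.
#' @return Named list of generator parameters.
#' @export
family_params <- function(ancestor_length = 120L, n_taxa = 8L, sub_rate = 0.1,
                          indel_rate = 0.02, indel_len_p = 0.5,
                          background = rep(1 / 20, 20), with_cds = FALSE,
                          family_id = "fam1") {
  list(ancestor_length = as.integer(ancestor_length), n_taxa = as.integer(n_taxa),
       sub_rate = sub_rate, indel_rate = indel_rate, indel_len_p = indel_len_p,
       background = background, with_cds = isTRUE(with_cds), family_id = family_id)
}

# One edge of evolution: substitutions then indels, threading indels through
# the shared master-column ordering kept in `world`.
.evolve_edge <- function(node, params, world) {
  len <- length(node$cols)
  if (len > 0L && params$sub_rate > 0) {
    hit <- which(runif(len) < params$sub_rate)
    for (i in hit) node$res[i] <- .substitute_residue(node$res[i], params$background)
  }
  if (len > 0L && params$indel_rate > 0) {
    sites <- which(runif(len) < params$indel_rate)
    for (site in rev(sites)) {  # descending so earlier indices stay valid
      g <- rgeom(1L, params$indel_len_p) + 1L
      if (runif(1) < 0.5) {  # deletion of g entries starting at site
        drop <- site:min(site + g - 1L, length(node$cols))
        if (length(drop) >= length(node$cols)) drop <- drop[-1L]  # never empty a lineage
        if (length(drop)) {
          node$cols <- node$cols[-drop]
          node$res <- node$res[-drop]
        }
      } else {               # insertion of g new master columns after `site`
        new_res <- sample(AA20, g, replace = TRUE, prob = params$background)
        new_ids <- world$next_id + seq_len(g) - 1L
        world$next_id <- world$next_id + g
        anchor <- match(node$cols[site], world$order)
        world$order <- append(world$order, new_ids, after = anchor)
        node$cols <- append(node$cols, new_ids, after = site)
        node$res <- append(node$res, new_res, after = site)
      }
    }
  }
  node
}

.evolve_tree <- function(node, n_leaves, params, world) {
  if (n_leaves == 1L) return(list(node))
  nl <- n_leaves %/% 2L
  left <- .evolve_edge(node, params, world)
  right <- .evolve_edge(node, params, world)
  c(.evolve_tree(left, nl, params, world),
    .evolve_tree(right, n_leaves - nl, params, world))
}

#' Simulate a homologous protein family with a known true alignment
#'
#' An ancestor is drawn from the background frequencies and evolved along a
#' balanced binary tree.  Each edge applies per-site substitutions (biased
#' toward biochemically similar residues) and geometric-length indels.  All
#' indels are threaded through one master coordinate system, so the returned
#' true alignment is exact: two residues share a column iff they descend from
#' the same ancestral (or inserted) site.
#'
#' @param params see [family_params()].
#' @param seed integer seed; same seed and params give an identical family.
#' @return An object of class `sim_family`: `true_msa` ([msa()]), `sequences`
#'   (ungapped records), `cds` (matched coding sequences or `NULL`), `params`.
#' @export
simulate_family <- function(params = family_params(), seed = 1L) {
  if (params$n_taxa < 2L) stop("family size must be at least 2", call. = FALSE)
  if (params$ancestor_length < 1L) stop("ancestor length must be >= 1", call. = FALSE)
  if (params$sub_rate < 0 || params$sub_rate >= 1 ||
      params$indel_rate < 0 || params$indel_rate >= 1) {
    stop("rates must lie in [0, 1)", call. = FALSE)
  }
  .with_seed(seed, {
    L <- params$ancestor_length
    world <- new.env(parent = emptyenv())
    world$order <- seq_len(L)
    world$next_id <- L + 1L
    root <- list(cols = seq_len(L),
                 res = sample(AA20, L, replace = TRUE, prob = params$background))
    leaves <- .evolve_tree(root, params$n_taxa, params, world)
    used <- world$order[world$order %in% unlist(lapply(leaves, `[[`, "cols"))]
    ids <- sprintf("t%d", seq_along(leaves))
    rows <- vector("list", length(leaves))
    seqs <- vector("list", length(leaves))
    for (k in seq_along(leaves)) {
      lv <- leaves[[k]]
      chars <- rep(GAP, length(used))
      chars[match(lv$cols, used)] <- lv$res
      rows[[k]] <- seq_record(ids[k], paste(chars, collapse = ""), "gapped-protein")
      seqs[[k]] <- seq_record(ids[k], paste(lv$res, collapse = ""), "protein20")
    }
    cds <- NULL
    if (params$with_cds) {
      cds <- lapply(seq_along(seqs), function(k) {
        reverse_translate(seqs[[k]], seed = sample.int(2^30, 1L))
      })
    }
    structure(list(true_msa = msa(rows), sequences = seqs, cds = cds,
                   params = params, seed = as.integer(seed)),
              class = "sim_family")
  })
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("<sim_family %s: %d sequences, true alignment %d columns%s>\n",
              x$params$family_id, length(x$sequences), x$true_msa$column_count,
              if (!is.null(x$cds)) ", with CDS" else ""))
  invisible(x)
}

# Fixed near-orthogonal identity basis: 20 exactly orthonormal unit vectors in
# R^d, built from an internal seed shared across runs so the oracle geometry
# is identical for every caller with the same d.
.residue_basis <- function(d) {
  .init_state()
  key <- sprintf("basis_%d", d)
  if (!is.null(.embalign_state$cache[[key]])) return(.embalign_state$cache[[key]])
  if (d < 21L) stop("embedding dimension must be at least 21", call. = FALSE)
  basis <- .with_seed(190721L, {
    m <- matrix(rnorm(d * 20L), nrow = d, ncol = 20L)
    t(qr.Q(qr(m)))  # 20 x d, orthonormal rows
  })
  rownames(basis) <- AA20
  .embalign_state$cache[[key]] <- basis
  basis
}

#' Synthetic per-residue embeddings
#'
#' Residue `i` is embedded as its identity basis vector plus half the mean
#' basis vector of residues within `window` positions (context), plus isotropic
#' Gaussian noise with standard deviation `noise_sd`.  The identity basis is a
#' fixed orthonormal set shared across runs, so the oracle compatibility
#' structure is known: with no noise and no window, identical residues map to
#' identical unit vectors.
#'
#' @param seq a `protein20` [seq_record()].
#' @param d embedding dimension, at least 21.
#' @param noise_sd nonnegative noise standard deviation.
#' @param window nonnegative context half-width.
#' @param seed integer seed controlling the noise draw.
#' @return An `embedding_matrix` (see [embedding_matrix()]).
#' @export
synth_embeddings <- function(seq, d = 32L, noise_sd = 0.1, window = 2L, seed = 1L) {
  stopifnot(inherits(seq, "seq_record"))
  if (seq$alphabet != "protein20") stop("embeddings require a protein20 record", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  d <- as.integer(d); window <- as.integer(window)
  basis <- .residue_basis(d)
  chars <- strsplit(seq$residues, "")[[1]]
  n <- length(chars)
  vecs <- basis[chars, , drop = FALSE]
  if (window > 0L && n > 1L) {
    ctx <- matrix(0, n, d)
    for (i in seq_len(n)) {
      nb <- setdiff(max(1L, i - window):min(n, i + window), i)
      if (length(nb)) ctx[i, ] <- colMeans(basis[chars[nb], , drop = FALSE])
    }
    vecs <- vecs + 0.5 * ctx
  }
  if (noise_sd > 0) {
    vecs <- vecs + .with_seed(seed, matrix(rnorm(n * d, sd = noise_sd), n, d))
  }
  embedding_matrix(seq$id, vecs,
                   provider_id = sprintf("synthetic-d%d-noise%g-w%d", d, noise_sd, window))
}

#' Reverse-translate a protein with uniformly chosen synonymous codons
#'
#' @param protein a `protein20` [seq_record()].
#' @param seed integer seed.
#' @return A `dna4` [seq_record()] whose translation equals `protein`.
#' @export
reverse_translate <- function(protein, seed = 1L) {
  stopifnot(inherits(protein, "seq_record"))
  if (protein$alphabet != "protein20") stop("reverse_translate expects protein20", call. = FALSE)
  gc <- .genetic_code()
  syn <- split(names(gc), unname(gc))
  chars <- strsplit(protein$residues, "")[[1]]
  codons <- .with_seed(seed, vapply(chars, function(a) {
    opts <- syn[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)))
  seq_record(protein$id, paste(codons, collapse = ""), "dna4", protein$description)
}
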