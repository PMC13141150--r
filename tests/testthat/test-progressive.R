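test_that("centroid distances match element-wise recomputation", {
  prov <- noise_free_provider()
  seqs <- lapply(1:4, function(i) random_protein(15, seed = 40 + i))
  embs <- lapply(seqs, function(s) embed_sequence(prov, s, cache = FALSE))
  D <- centroid_distance_matrix(embs)
  expect_equal(diag(D), rep(0, 4))
  expect_equal(D, t(D))
  for (i in 1:4) for (j in 1:4) {
    if (i != j) {
      expect_equal(D[i, j], 1 - cosine_score(sequence_centroid(embs[[i]]),
                                             sequence_centroid(embs[[j]])),
                   tolerance = 1e-12)
    }
  }
  # identical sequences under a noise-free provider are at distance 0
  same <- lapply(1:3, function(i) {
    e <- embed_sequence(prov, random_protein(10, seed = 7), cache = FALSE)
    e$sequence_id <- paste0("s", i); e
  })
  expect_true(all(abs(centroid_distance_matrix(same)[upper.tri(diag(3))]) < 1e-12))
  # opposite centroids are at distance 2
  v <- rnorm(24)
  opp <- list(embedding_matrix("a", rbind(v), "p"),
              embedding_matrix("b", rbind(-v), "p"))
  expect_equal(centroid_distance_matrix(opp)[1, 2], 2)
})

test_that("order_sequences honors each policy deterministically", {
  expect_equal(order_sequences(matrix(0, 2, 2), order_policy("upgma")), 1:2,
               ignore_attr = TRUE)
  D <- matrix(0.9, 3, 3); diag(D) <- 0; D[1, 3] <- D[3, 1] <- 0.1
  ord <- order_sequences(D, order_policy("upgma"))
  expect_equal(as.integer(ord), c(1L, 3L, 2L))
  expect_match(attr(ord, "newick"), "\\(\\(s1,s3\\),s2\\);")

  expect_equal(order_sequences(policy = order_policy("input"), n = 5), 1:5)
  r1 <- order_sequences(policy = order_policy("random", seed = 7), n = 8)
  r2 <- order_sequences(policy = order_policy("random", seed = 7), n = 8)
  expect_identical(r1, r2)

  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(order_sequences(bad, order_policy("upgma")), "symmetric")
})

test_that("two-sequence progressive alignment equals direct pairwise DP", {
  prov <- noise_free_provider(window = 2)
  a <- random_protein(20, seed = 61)
  b <- random_protein(24, seed = 62)
  pen <- gap_penalties()
  aln <- progressive_align(list(a, b), provider = prov,
                           backend = backend_cosine(), penalties = pen,
                           policy = order_policy("input"))
  ea <- embed_sequence(prov, a); eb <- embed_sequence(prov, b)
  direct <- gotoh_align(compute_score_matrix(backend_cosine(), ea, eb), pen)
  strs <- traces_to_strings(direct, a, b)
  expect_equal(aln$rows[[1]]$residues, strs$left)
  expect_equal(aln$rows[[2]]$residues, strs$right)
})

test_that("identical sequences align gap-free under any embedding backend", {
  prov <- noise_free_provider(window = 1)
  seqs <- lapply(1:5, function(i) {
    r <- random_protein(18, seed = 70)
    r$id <- paste0("c", i); r
  })
  for (be in list(backend_cosine(),
                  backend_learned(structure(
                    list(params = init_scorer_params(32, seed = 3),
                         meta = list(format_version = "embalign-ckpt-1")),
                    class = "scorer_checkpoint")))) {
    aln <- progressive_align(seqs, provider = prov, backend = be)
    expect_equal(aln$column_count, 18L)
    expect_false(any(grepl("-", vapply(aln$rows, `[[`, character(1), "residues"),
                           fixed = TRUE)))
  }
})

test_that("rows come back in input order under every policy", {
  fam <- quick_family(seed = 21)
  prov <- synthetic_provider(d = 32, noise_sd = 0.05)
  ids <- vapply(fam$sequences, `[[`, character(1), "id")
  for (pol in list(order_policy("upgma"), order_policy("input"),
                   order_policy("random", seed = 9))) {
    aln <- progressive_align(fam$sequences, provider = prov, policy = pol)
    expect_equal(vapply(aln$rows, `[[`, character(1), "id"), ids)
    for (k in seq_along(ids)) {
      expect_equal(gsub("-", "", aln$rows[[k]]$residues, fixed = TRUE),
                   fam$sequences[[k]]$residues)
    }
  }
})

test_that("incremental column embeddings match from-scratch recomputation", {
  fam <- quick_family(seed = 23, indel_rate = 0.06)
  prov <- synthetic_provider(d = 32, noise_sd = 0.1)
  embs <- lapply(fam$sequences, function(s) embed_sequence(prov, s))
  pen <- gap_penalties()
  prof <- new_profile(fam$sequences[[1]], embs[[1]])
  for (k in 2:length(fam$sequences)) {
    sm <- compute_score_matrix(backend_cosine(), prof, embs[[k]])
    aln <- gotoh_align(sm, pen)
    prof <- embalign:::.profile_merge(prof, aln, fam$sequences[[k]], embs[[k]])
    expect_lt(max(abs(profile_column_embeddings(prof) -
                        profile_recompute_columns(prof))), 1e-9)
    expect_true(all(prof$col_cnt > 0))  # no all-gap column at any stage
  }
})

test_that("single-sequence input warns and returns a trivial alignment", {
  expect_warning(aln <- progressive_align(list(random_protein(9, seed = 80)),
                                          provider = noise_free_provider()),
                 "single sequence")
  expect_equal(length(aln$rows), 1L)
})

test_that("upgma policy without a provider is an explicit error", {
  expect_error(progressive_align(list(random_protein(5, seed = 1),
                                      random_protein(5, seed = 2)),
                                 backend = backend_blosum62()),
               "provider is required")
})

test_that("zero-norm centroids get distance 1 with a warning", {
  z <- embedding_matrix("z", matrix(0 + 1e-300, 1, 4) * 0 + c(0, 0, 0, 0), "p")
  z$vectors <- matrix(0, 1, 4)
  v <- embedding_matrix("v", matrix(c(1, 0, 0, 0), 1), "p")
  w <- embedding_matrix("w", matrix(c(0, 1, 0, 0), 1), "p")
  expect_warning(D <- centroid_distance_matrix(list(z, v, w)), "zero-norm")
  expect_equal(D[1, 2], 1)
  expect_equal(D[1, 3], 1)
  expect_equal(diag(D), rep(0, 3))
})
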