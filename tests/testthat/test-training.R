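two_seq_family <- function(L = 15L, seed = 1L) {
  simulate_family(family_params(ancestor_length = L, n_taxa = 2,
                                sub_rate = 0, indel_rate = 0,
                                family_id = "pairfam"), seed = seed)
}

test_that("pair extraction counts and ratios are exact", {
  prov <- noise_free_provider()
  fam <- two_seq_family(L = 15)
  ds <- build_pair_dataset(list(fam), prov, negatives_per_positive = 1, seed = 1)
  expect_equal(sum(ds$labels == 1L), 15L)
  expect_equal(sum(ds$labels == 0L), 15L)
  ds3 <- build_pair_dataset(list(fam), prov, negatives_per_positive = 3, seed = 1)
  expect_equal(sum(ds3$labels == 0L), 3L * sum(ds3$labels == 1L))
})

test_that("no sampled negative coincides with a true-aligned pair", {
  prov <- noise_free_provider()
  fams <- lapply(1:3, function(i) quick_family(seed = 60 + i, n_taxa = 4,
                                               length = 20,
                                               family_id = sprintf("small%d", i)))
  ds <- build_pair_dataset(fams, prov, negatives_per_positive = 2, seed = 4)
  for (f in fams) {
    chars <- msa_matrix(f$true_msa)
    ords <- t(apply(chars != "-", 1, cumsum))
    truth <- character(0)
    for (cc in seq_len(ncol(chars))) {
      rows <- which(chars[, cc] != "-")
      if (length(rows) >= 2) {
        for (a in seq_len(length(rows) - 1)) for (b in (a + 1):length(rows)) {
          truth <- c(truth, sprintf("%d.%d.%d.%d", rows[a], ords[rows[a], cc],
                                    rows[b], ords[rows[b], cc]))
        }
      }
    }
    neg <- ds$pairs[ds$pairs$family_id == f$params$family_id & ds$pairs$label == 0L, ]
    keys <- sprintf("%d.%d.%d.%d", neg$row_a, neg$pos_a, neg$row_b, neg$pos_b)
    expect_length(intersect(keys, truth), 0L)
    pos <- ds$pairs[ds$pairs$family_id == f$params$family_id & ds$pairs$label == 1L, ]
    pkeys <- sprintf("%d.%d.%d.%d", pos$row_a, pos$pos_a, pos$row_b, pos$pos_b)
    expect_true(all(pkeys %in% truth))
  }
})

test_that("dataset building is deterministic and respects exclusion lists", {
  prov <- noise_free_provider()
  fams <- lapply(1:2, function(i) quick_family(seed = 70 + i, n_taxa = 4,
                                               length = 20,
                                               family_id = sprintf("ex%d", i)))
  d1 <- build_pair_dataset(fams, prov, seed = 9)
  d2 <- build_pair_dataset(fams, prov, seed = 9)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$labels, d2$labels)
  expect_error(build_pair_dataset(fams, prov, seed = 9,
                                  exclude_families = c("ex2", "other")),
               "isolation violation.*ex2")
})

test_that("training reduces loss, is seed-deterministic, and detects divergence", {
  prov <- synthetic_provider(d = 24, noise_sd = 0.05)
  fams <- lapply(1:4, function(i) quick_family(seed = 80 + i, n_taxa = 4,
                                               length = 30,
                                               family_id = sprintf("tr%d", i)))
  ds <- build_pair_dataset(fams, prov, seed = 2)
  ck <- train_scorer(ds, hidden = c(16, 16), epochs = 8, seed = 3)
  expect_lt(tail(ck$meta$loss_curve, 1), ck$meta$loss_curve[1])
  ck2 <- train_scorer(ds, hidden = c(16, 16), epochs = 8, seed = 3)
  expect_identical(ck$params, ck2$params)
  # non-finite loss surfaces with its epoch index: overflowing pair features
  # (x * y -> Inf) yield NaN activations on the first batch
  huge <- structure(list(X = matrix(1e200, 4, 24), Y = matrix(1e200, 4, 24),
                         labels = c(1L, 0L, 1L, 0L),
                         family = rep("f", 4), d = 24L,
                         provenance = list()), class = "pair_dataset")
  expect_error(train_scorer(huge, hidden = c(16, 16), epochs = 2, seed = 3),
               "diverged.*epoch 1")
})

test_that("checkpoints round-trip bit-exactly and validate version and d", {
  prov <- synthetic_provider(d = 24, noise_sd = 0.05)
  fams <- lapply(1:2, function(i) quick_family(seed = 85 + i, n_taxa = 3,
                                               length = 20,
                                               family_id = sprintf("ck%d", i)))
  ds <- build_pair_dataset(fams, prov, seed = 5)
  ck <- train_scorer(ds, hidden = c(8, 8), epochs = 3, seed = 1)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  back <- load_checkpoint(f)
  set.seed(31)
  probe <- lapply(1:100, function(i) list(x = rnorm(24), y = rnorm(24)))
  for (pr in probe) {
    expect_identical(learned_score(back$params, pr$x, pr$y),
                     learned_score(ck$params, pr$x, pr$y))
  }
  expect_error(load_checkpoint(f, d = 64), "d=24, expected d=64")
  bumped <- ck
  bumped$meta$format_version <- "embalign-ckpt-2"
  f2 <- tempfile(fileext = ".rds")
  saveRDS(bumped, f2)
  expect_error(load_checkpoint(f2), "'embalign-ckpt-2'.*'embalign-ckpt-1'")
  f3 <- tempfile(fileext = ".rds")
  writeLines("not an rds", f3)
  expect_error(load_checkpoint(f3), "cannot parse")
})

test_that("label shuffling keeps class balance but kills the signal", {
  prov <- synthetic_provider(d = 24, noise_sd = 0.05)
  fams <- lapply(1:2, function(i) quick_family(seed = 87 + i, n_taxa = 4,
                                               length = 25,
                                               family_id = sprintf("sh%d", i)))
  ds <- build_pair_dataset(fams, prov, seed = 6)
  sh <- shuffle_dataset_labels(ds, seed = 7)
  expect_equal(sum(sh$labels), sum(ds$labels))
  expect_false(identical(sh$labels, ds$labels))
  expect_true(sh$provenance$label_shuffled)
})

test_that("families with fewer than two rows are skipped with a warning", {
  prov <- noise_free_provider()
  fam <- quick_family(seed = 89, n_taxa = 4, length = 20, family_id = "okfam")
  broken <- fam
  broken$sequences <- broken$sequences[1]
  broken$params$family_id <- "lonely"
  expect_warning(ds <- build_pair_dataset(list(broken, fam), prov, seed = 1),
                 "lonely")
  expect_true(all(ds$family == "okfam"))
})
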