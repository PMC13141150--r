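make_ref3 <- function() {
  # 3 sequences, 2 fully populated reference columns
  msa(list(seq_record("a", "MK", "gapped-protein"),
           seq_record("b", "MK", "gapped-protein"),
           seq_record("c", "MK", "gapped-protein")))
}

test_that("sp_tc on the hand-enumerated fixtures", {
  ref <- make_ref3()
  expect_equal(unlist(sp_tc(ref, ref)[, c("sp", "tc")]), c(sp = 1, tc = 1))
  # test reproduces reference column 1 only: column 2 residues spread apart
  test <- msa(list(seq_record("a", "MK--", "gapped-protein"),
                   seq_record("b", "M-K-", "gapped-protein"),
                   seq_record("c", "M--K", "gapped-protein")))
  got <- sp_tc(test, ref)
  expect_equal(got$sp, 0.5)  # 3 of the 6 reference residue pairs survive
  expect_equal(got$tc, 0.5)
  # no shared column at all
  test0 <- msa(list(seq_record("a", "MK----", "gapped-protein"),
                    seq_record("b", "--MK--", "gapped-protein"),
                    seq_record("c", "----MK", "gapped-protein")))
  expect_equal(unlist(sp_tc(test0, ref)[, c("sp", "tc")]), c(sp = 0, tc = 0))
})

test_that("sp_tc is invariant under test-column permutation", {
  # permuting alignment columns relabels which column a residue cell sits in
  # but not which cells co-occur; scored at the cell level, SP/TC must not
  # change.  A cell-based oracle (independent of sp_tc) scores the original
  # and a column-permuted test; sp_tc is checked against the oracle on the
  # valid (unpermuted) input.
  cell_sp_tc <- function(ord_mat, ref_chars, ref_ords) {
    pairs_total <- 0; pairs_hit <- 0; cols_hit <- 0; cols_tot <- 0
    test_col_of <- list()
    for (r in seq_len(nrow(ord_mat))) {
      cols <- which(!is.na(ord_mat[r, ]))
      test_col_of[[r]] <- setNames(cols, ord_mat[r, cols])
    }
    for (cc in seq_len(ncol(ref_chars))) {
      rows <- which(ref_chars[, cc] != "-")
      if (!length(rows)) next
      tcols <- vapply(rows, function(r) {
        unname(test_col_of[[r]][as.character(ref_ords[r, cc])])
      }, numeric(1))
      if (length(rows) >= 2) {
        prs <- utils::combn(seq_along(rows), 2)
        pairs_total <- pairs_total + ncol(prs)
        pairs_hit <- pairs_hit + sum(tcols[prs[1, ]] == tcols[prs[2, ]])
      }
      cols_tot <- cols_tot + 1
      if (length(unique(tcols)) == 1) cols_hit <- cols_hit + 1
    }
    c(sp = pairs_hit / pairs_total, tc = cols_hit / cols_tot)
  }
  fam <- quick_family(seed = 41, indel_rate = 0.05)
  aln <- progressive_align(fam$sequences, provider = noise_free_provider())
  chars <- msa_matrix(aln)
  ords <- matrix(NA_integer_, nrow(chars), ncol(chars))
  for (r in seq_len(nrow(chars))) {
    ng <- chars[r, ] != "-"
    ords[r, ng] <- seq_len(sum(ng))
  }
  ref_chars <- msa_matrix(fam$true_msa)
  ref_ords <- matrix(NA_integer_, nrow(ref_chars), ncol(ref_chars))
  for (r in seq_len(nrow(ref_chars))) {
    ng <- ref_chars[r, ] != "-"
    ref_ords[r, ng] <- seq_len(sum(ng))
  }
  base_oracle <- cell_sp_tc(ords, ref_chars, ref_ords)
  base <- sp_tc(aln, fam$true_msa)
  expect_equal(unname(base_oracle["sp"]), base$sp)
  expect_equal(unname(base_oracle["tc"]), base$tc)
  set.seed(1)
  for (k in 1:3) {
    perm <- sample(ncol(ords))
    expect_equal(cell_sp_tc(ords[, perm, drop = FALSE], ref_chars, ref_ords),
                 base_oracle)
  }
})

test_that("sp_tc validates ids and sequence content", {
  ref <- make_ref3()
  other <- msa(list(seq_record("a", "MK", "gapped-protein"),
                    seq_record("b", "MK", "gapped-protein"),
                    seq_record("z", "MK", "gapped-protein")))
  expect_error(sp_tc(other, ref), "different sequence ids")
  changed <- msa(list(seq_record("a", "MA", "gapped-protein"),
                      seq_record("b", "MK", "gapped-protein"),
                      seq_record("c", "MK", "gapped-protein")))
  expect_error(sp_tc(changed, ref), "mismatch")
})

test_that("tc <= sp on fully populated references", {
  for (seed in 42:44) {
    fam <- quick_family(seed = seed, indel_rate = 0)  # gap-free truth
    aln <- progressive_align(fam$sequences,
                             provider = synthetic_provider(d = 32, noise_sd = 0.2))
    got <- sp_tc(aln, fam$true_msa)
    expect_lte(got$tc, got$sp + 1e-12)
    expect_gte(got$sp, 0); expect_lte(got$sp, 1)
  }
})

test_that("wilcoxon exact p matches full enumeration (ties included)", {
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(w$p_value, 0.0625)
  expect_equal(w$statistic, 15)
  expect_equal(w$method, "exact")
  set.seed(13)
  for (k in 1:12) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n), sample(0:1, 1))  # rounding induces ties/zeros
    if (all(d == 0)) d[1] <- 1
    expect_equal(wilcoxon_signed_rank(d)$p_value, wilcoxon_enumeration_p(d),
                 tolerance = 1e-12, label = paste("case", k))
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 wilcoxon_signed_rank(-d)$p_value)
  }
  expect_false(wilcoxon_signed_rank(c(0, 0, 0))$computable)
})

test_that("wilcoxon normal approximation agrees with stats::wilcox.test", {
  set.seed(14)
  d <- rnorm(40)
  ours <- wilcoxon_signed_rank(d)
  expect_equal(ours$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("holm correction matches the definition and stats::p.adjust", {
  expect_equal(holm_correct(0.03), 0.03)
  expect_equal(holm_correct(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(15)
  for (k in 1:10) {
    p <- runif(6)
    expect_equal(holm_correct(p), holm_definition_oracle(p))
    expect_equal(holm_correct(p), stats::p.adjust(p, "holm"))
    expect_true(all(holm_correct(p) >= p))
  }
  expect_error(holm_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("paired_comparison pairs families and recovers injected shifts", {
  fams <- sprintf("f%02d", 1:20)
  set.seed(16)
  base <- data.frame(family_id = fams, method_id = "b",
                     sp = runif(20, 0.4, 0.8), tc = runif(20, 0.2, 0.6))
  up <- transform(base, method_id = "a", sp = sp + 0.1, tc = tc + 0.1)
  cmp <- paired_comparison(rbind(base, up), "a", "b")
  expect_equal(unname(cmp$median_delta["sp"]), 0.1)
  expect_equal(unname(cmp$median_delta["tc"]), 0.1)
  expect_lt(cmp$p_holm[["sp"]], 0.01)
  same <- transform(base, method_id = "a")
  cmp2 <- paired_comparison(rbind(base, same), "a", "b")
  expect_equal(unname(cmp2$median_delta["sp"]), 0)
  expect_true(is.na(cmp2$p_raw[["sp"]]))
  expect_error(paired_comparison(rbind(base, up[-1, ]), "a", "b"),
               "missing")
})

test_that("gap_robustness recovers known shifts and validates the grid", {
  fams <- sprintf("f%d", 1:10)
  grid <- expand.grid(gap_open = c(-3.5, -2.5), gap_extend = c(-0.7, -0.3))
  set.seed(17)
  base_sp <- runif(10, 0.5, 0.9)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    shift <- if (grid$gap_open[i] == -2.5 && grid$gap_extend[i] == -0.7) 0
             else 0.01 * i
    data.frame(family_id = fams, gap_open = grid$gap_open[i],
               gap_extend = grid$gap_extend[i],
               sp = base_sp + shift, tc = base_sp / 2 + shift)
  }))
  gr <- gap_robustness(rows, gap_penalties(-2.5, -0.7))
  off <- gr$per_setting[!gr$per_setting$is_baseline & gr$per_setting$metric == "sp", ]
  for (i in seq_len(nrow(off))) {
    j <- which(grid$gap_open == off$gap_open[i] & grid$gap_extend == off$gap_extend[i])
    expect_equal(off$median_shift[i], 0.01 * j)
    expect_equal(off$median_abs_shift[i], 0.01 * j)
  }
  expect_equal(unname(gr$max_median_abs["sp"]),
               max(off$median_abs_shift))
  expect_error(gap_robustness(rows[-1, ], gap_penalties(-2.5, -0.7)),
               "missing cells")
  expect_error(gap_robustness(rows, gap_penalties(-9, -1)), "baseline")
})

test_that("phase timings satisfy their invariants and stay observational", {
  fam <- quick_family(seed = 51)
  prov <- synthetic_provider(d = 32, noise_sd = 0.05)
  embalign_reset_counters(cache = TRUE)
  a1 <- progressive_align(fam$sequences, provider = prov, profile = TRUE)
  t1 <- profile_phases(a1)
  expect_true(all(c(t1$embedding, t1$scoring, t1$dp) >= 0))
  expect_lte(t1$embedding + t1$scoring + t1$dp, t1$total)
  # warm cache: embedding phase can only get cheaper, result identical
  a2 <- progressive_align(fam$sequences, provider = prov, profile = TRUE)
  expect_lte(profile_phases(a2)$embedding, t1$embedding + 0.05)
  a3 <- progressive_align(fam$sequences, provider = prov)  # profiling off
  expect_null(profile_phases(a3))
  expect_equal(msa_matrix(a3), msa_matrix(a1))
})

test_that("nested phase timers are an instrumentation error", {
  t <- embalign:::.new_timer()
  expect_error(
    embalign:::.phase(t, "scoring", embalign:::.phase(t, "dp", Sys.time())),
    "nested phase timers")
})
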