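# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the code paths they check.

# Brute-force optimal global alignment score: enumerate every monotone path
# through the score matrix and charge each maximal gap run
# gap_open + (L - 1) * gap_extend.  Exponential; fine up to ~6x6.
brute_force_align_score <- function(S, gap_open, gap_extend) {
  n <- nrow(S); m <- ncol(S)
  best <- -Inf
  rec <- function(i, j, acc, last) {
    if (i == n && j == m) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, acc + S[i + 1L, j + 1L], "M")
    if (i < n) rec(i + 1L, j, acc + if (last == "I") gap_extend else gap_open, "I")
    if (j < m) rec(i, j + 1L, acc + if (last == "D") gap_extend else gap_open, "D")
  }
  rec(0L, 0L, 0, "S")
  best
}

# Exhaustive Wilcoxon signed-rank two-sided p: enumerate all 2^n sign
# assignments of the ranked |deltas| and count rank sums as or more extreme.
wilcoxon_enumeration_p <- function(deltas) {
  d <- deltas[deltas != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  sums <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(0:(n - 1))) > 0])
  }, numeric(1))
  p_le <- mean(sums <= v_obs + 1e-12)
  p_ge <- mean(sums >= v_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# Holm adjustment straight from the step-down definition.
holm_definition_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Small deterministic fixtures -------------------------------------------

AA20_letters <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

quick_family <- function(seed = 3L, n_taxa = 6L, length = 60L, sub_rate = 0.1,
                         indel_rate = 0.03, with_cds = FALSE,
                         family_id = sprintf("qf%d", seed)) {
  simulate_family(family_params(ancestor_length = length, n_taxa = n_taxa,
                                sub_rate = sub_rate, indel_rate = indel_rate,
                                with_cds = with_cds, family_id = family_id),
                  seed = seed)
}

noise_free_provider <- function(d = 32L, window = 0L) {
  synthetic_provider(d = d, noise_sd = 0, window = window, seed = 1L)
}

random_protein <- function(n, seed) {
  set.seed(seed)
  seq_record(sprintf("p%d", seed),
             paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N",
                            "P","Q","R","S","T","V","W","Y"), n, replace = TRUE),
                   collapse = ""), "protein20")
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# Reconstruct a pairwise alignment's two gapped strings from traces.
traces_to_strings <- function(aln, left_seq, right_seq) {
  lch <- strsplit(left_seq$residues, "")[[1]]
  rch <- strsplit(right_seq$residues, "")[[1]]
  list(left = paste(ifelse(is.na(aln$left), "-", lch[aln$left]), collapse = ""),
       right = paste(ifelse(is.na(aln$right), "-", rch[aln$right]), collapse = ""))
}
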