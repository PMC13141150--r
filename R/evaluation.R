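# Benchmarking and statistics stack: SP/TC scoring against reference
# alignments, paired Wilcoxon signed-rank with Holm correction, and
# gap-robustness summaries.  One scoring implementation serves every
# comparison.

# Per row, the test/reference column index of each residue ordinal.
.residue_columns <- function(aln) {
  chars <- msa_matrix(aln)
  lapply(seq_len(nrow(chars)), function(r) which(chars[r, ] != GAP))
}

#' Sum-of-pairs and total-column accuracy against a reference alignment
#'
#' SP is the fraction of residue pairs co-aligned in a reference column that
#' also share a column in the test alignment (reference-pair denominator;
#' reference columns containing gaps still contribute their residue pairs).
#' TC is the fraction of reference columns whose full residue content
#' reappears in a single test column.  Both alignments must contain the same
#' ids with identical ungapped sequences.
#'
#' @param test,reference [msa()] objects.
#' @param family_id,method_id labels carried into the result.
#' @return Data frame row with `family_id`, `method_id`, `sp`, `tc`.
#' @export
sp_tc <- function(test, reference, family_id = "fam", method_id = "method") {
  stopifnot(inherits(test, "msa"), inherits(reference, "msa"))
  tid <- vapply(test$rows, function(r) r$id, character(1))
  rid <- vapply(reference$rows, function(r) r$id, character(1))
  if (!setequal(tid, rid) || length(tid) != length(rid)) {
    stop("test and reference alignments contain different sequence ids", call. = FALSE)
  }
  ord <- match(rid, tid)
  for (k in seq_along(rid)) {
    a <- gsub("-", "", test$rows[[ord[k]]]$residues, fixed = TRUE)
    b <- gsub("-", "", reference$rows[[k]]$residues, fixed = TRUE)
    if (a != b) stop("ungapped sequence mismatch for id '", rid[k], "'", call. = FALSE)
  }
  rcols <- .residue_columns(reference)
  tcols <- .residue_columns(test)[ord]
  nrows <- length(rid)
  # map: per row, reference column -> test column of the same residue
  ref_chars <- msa_matrix(reference)
  r2t <- matrix(NA_integer_, nrows, reference$column_count)
  for (r in seq_len(nrows)) r2t[r, rcols[[r]]] <- tcols[[r]]

  pairs_total <- 0; pairs_hit <- 0
  cols_total <- 0; cols_hit <- 0
  for (cc in seq_len(reference$column_count)) {
    members <- which(ref_chars[, cc] != GAP)
    if (!length(members)) next
    tc_of <- r2t[members, cc]
    if (length(members) >= 2L) {
      for (ai in seq_len(length(members) - 1L)) {
        hits <- sum(tc_of[(ai + 1L):length(members)] == tc_of[ai])
        pairs_hit <- pairs_hit + hits
        pairs_total <- pairs_total + (length(members) - ai)
      }
    }
    cols_total <- cols_total + 1
    if (length(unique(tc_of)) == 1L) cols_hit <- cols_hit + 1
  }
  sp <- if (pairs_total > 0) pairs_hit / pairs_total else NA_real_
  data.frame(family_id = family_id, method_id = method_id,
             sp = sp, tc = cols_hit / cols_total)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zeros are dropped; tied absolute differences receive mid-ranks.  For
#' `n <= 25` retained pairs the two-sided p-value is exact, computed from the
#' full null distribution of the positive-rank sum (a convolution over
#' doubled ranks, so mid-ranks stay exact); above that a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param deltas numeric vector of paired differences.
#' @return List with `statistic` (positive-rank sum V), `p_value`, `n`
#'   (retained pairs), `method` (`"exact"` or `"normal"`), and `computable`
#'   (`FALSE` with `p_value = NA` when every delta is zero).
#' @export
wilcoxon_signed_rank <- function(deltas) {
  stopifnot(is.numeric(deltas))
  d <- deltas[deltas != 0]
  if (!length(d)) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                method = "none", computable = FALSE))
  }
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null: distribution of the sum of an arbitrary subset of the
    # doubled ranks (doubling makes mid-ranks integral)
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    counts <- numeric(tot + 1L)   # counts[s + 1] = #subsets with doubled-sum s
    counts[1L] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(tot + 1L - rr)])
      counts <- counts + shifted
    }
    v2 <- as.integer(round(2 * v))
    p_le <- sum(counts[seq_len(v2 + 1L)]) / 2^n
    p_ge <- sum(counts[(v2 + 1L):(tot + 1L)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = v, p_value = p, n = n, method = "exact",
                computable = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = v, p_value = p, n = n, method = "normal", computable = TRUE)
}

#' Holm step-down multiple-testing correction
#'
#' Sorts p-values ascending, multiplies the i-th by `(m - i + 1)`, enforces
#' monotone nondecrease, caps at 1, and returns the adjusted values in input
#' order.
#'
#' @param pvalues numeric vector in `[0, 1]` (NA passed through).
#' @return Adjusted p-values in input order.
#' @export
holm_correct <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(pvalues))
  p <- pvalues[ok]
  m <- length(p)
  if (m) {
    o <- order(p)
    adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
    out[ok][o] <- adj
  }
  out
}

#' Paired family-wise comparison of two methods
#'
#' Pairs SP/TC scores family-by-family, reports per-method means, median
#' paired deltas (`a - b`), the Wilcoxon signed-rank p-value per metric, and
#' Holm-adjusted p-values across the two metrics of this comparison.
#'
#' @param results data frame with columns `family_id`, `method_id`, `sp`,
#'   `tc` (e.g. rbind of [sp_tc()] rows).
#' @param method_a,method_b method ids to contrast.
#' @return List with `means`, `median_delta`, `p_raw`, `p_holm`, `n_families`.
#' @export
paired_comparison <- function(results, method_a, method_b) {
  stopifnot(is.data.frame(results),
            all(c("family_id", "method_id", "sp", "tc") %in% names(results)))
  a <- results[results$method_id == method_a, ]
  b <- results[results$method_id == method_b, ]
  miss <- c(setdiff(a$family_id, b$family_id), setdiff(b$family_id, a$family_id))
  if (length(miss)) {
    stop("families missing for one method: ", paste(unique(miss), collapse = ", "),
         call. = FALSE)
  }
  b <- b[match(a$family_id, b$family_id), ]
  deltas <- list(sp = a$sp - b$sp, tc = a$tc - b$tc)
  tests <- lapply(deltas, wilcoxon_signed_rank)
  p_raw <- vapply(tests, function(t) t$p_value, numeric(1))
  list(means = data.frame(method_id = c(method_a, method_b),
                          sp = c(mean(a$sp), mean(b$sp)),
                          tc = c(mean(a$tc), mean(b$tc))),
       median_delta = vapply(deltas, median, numeric(1)),
       p_raw = p_raw,
       p_holm = setNames(holm_correct(p_raw), names(p_raw)),
       n_families = nrow(a))
}

#' Gap-robustness summary over a penalty grid
#'
#' For each non-baseline grid setting, computes per-family SP/TC shifts
#' relative to the baseline setting and reports their median and median
#' absolute value, plus the maxima across settings.
#'
#' @param results data frame with columns `family_id`, `gap_open`,
#'   `gap_extend`, `sp`, `tc`; every family must be scored at every setting.
#' @param baseline a [gap_penalties()] identifying the baseline cell.
#' @return List with `per_setting` (data frame of median / median-absolute
#'   shifts per setting and metric) and `max_median_abs` (named: `sp`, `tc`).
#' @export
gap_robustness <- function(results, baseline = gap_penalties()) {
  stopifnot(is.data.frame(results),
            all(c("family_id", "gap_open", "gap_extend", "sp", "tc") %in%
                  names(results)))
  key <- function(go, ge) sprintf("(%g, %g)", go, ge)
  results$setting <- key(results$gap_open, results$gap_extend)
  settings <- unique(results[, c("gap_open", "gap_extend", "setting")])
  fams <- sort(unique(results$family_id))
  missing <- character(0)
  for (s in settings$setting) {
    have <- results$family_id[results$setting == s]
    gap <- setdiff(fams, have)
    if (length(gap)) missing <- c(missing, paste0(s, ":", gap))
  }
  if (length(missing)) {
    stop("incomplete penalty grid; missing cells: ",
         paste(head(missing, 10L), collapse = ", "), call. = FALSE)
  }
  base_key <- key(baseline$gap_open, baseline$gap_extend)
  if (!base_key %in% settings$setting) {
    stop("baseline setting ", base_key, " absent from results", call. = FALSE)
  }
  base <- results[results$setting == base_key, ]
  base <- base[match(fams, base$family_id), ]
  rows <- list()
  for (i in seq_len(nrow(settings))) {
    s <- settings$setting[i]
    cur <- results[results$setting == s, ]
    cur <- cur[match(fams, cur$family_id), ]
    for (metric in c("sp", "tc")) {
      shift <- cur[[metric]] - base[[metric]]
      rows[[length(rows) + 1L]] <- data.frame(
        gap_open = settings$gap_open[i], gap_extend = settings$gap_extend[i],
        metric = metric, median_shift = median(shift),
        median_abs_shift = median(abs(shift)),
        is_baseline = s == base_key)
    }
  }
  per_setting <- do.call(rbind, rows)
  off <- per_setting[!per_setting$is_baseline, ]
  max_abs <- if (nrow(off)) {
    vapply(c(sp = "sp", tc = "tc"),
           function(m) max(off$median_abs_shift[off$metric == m]), numeric(1))
  } else c(sp = 0, tc = 0)
  list(per_setting = per_setting, max_median_abs = max_abs)
}
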