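# Codon-aware alignment: validate CDS, align in protein space, back-map to a
# codon-consistent nucleotide alignment (gaps expanded to codon length,
# original codons reinserted verbatim).

# Normalize candidate CDS input (seq_records or a named character vector of
# raw text) to a list of (id, residues, description) entries with unique ids.
.as_cds_candidates <- function(records) {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids) || any(!nzchar(ids))) {
      stop("raw CDS input must be a named character vector", call. = FALSE)
    }
    records <- mapply(function(id, s) list(id = id, residues = s, description = id),
                      ids, unname(records), SIMPLIFY = FALSE, USE.NAMES = FALSE)
  } else {
    stopifnot(all(vapply(records, function(r)
      is.list(r) && !is.null(r$id) && !is.null(r$residues), logical(1))))
  }
  if (!length(records)) stop("no CDS records supplied", call. = FALSE)
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate CDS id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  records
}

#' Validate coding sequences for codon-aware alignment
#'
#' Checks, in order: (i) length divisible by three, (ii) no internal stop
#' codon, (iii) canonical A/C/G/T alphabet only.  The first failing check is
#' reported per sequence.  A trailing stop codon is accepted and noted.
#'
#' @param records list of [seq_record()]s, or a named character vector of raw
#'   candidate sequence text (validation must be able to screen input that a
#'   strict alphabet-checked parse would already reject).
#' @return A data frame of class `cds_validation` with one row per input:
#'   `id`, `accepted`, `reason` (`""`, `"frame"`, `"internal-stop"`,
#'   `"alphabet"`), `position` (offending codon/symbol index or `NA`),
#'   `trailing_stop`.
#' @export
validate_cds <- function(records) {
  records <- .as_cds_candidates(records)
  gc <- .genetic_code()
  rows <- lapply(records, function(r) {
    s <- toupper(r$residues)
    n <- nchar(s)
    if (n == 0L || n %% 3L != 0L) {
      return(data.frame(id = r$id, accepted = FALSE, reason = "frame",
                        position = NA_integer_, trailing_stop = FALSE))
    }
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    # internal-stop check runs before the alphabet check; codons containing
    # non-canonical symbols are not in the code table and cannot be stops
    aa <- unname(gc[codons])
    stops <- which(!is.na(aa) & aa == "*")
    internal <- stops[stops < length(codons)]
    if (length(internal)) {
      return(data.frame(id = r$id, accepted = FALSE, reason = "internal-stop",
                        position = internal[1L], trailing_stop = FALSE))
    }
    chars <- strsplit(s, "")[[1]]
    bad <- which(!chars %in% DNA4)
    if (length(bad)) {
      return(data.frame(id = r$id, accepted = FALSE, reason = "alphabet",
                        position = bad[1L], trailing_stop = FALSE))
    }
    data.frame(id = r$id, accepted = TRUE, reason = "",
               position = NA_integer_,
               trailing_stop = length(stops) > 0L)
  })
  report <- do.call(rbind, rows)
  class(report) <- c("cds_validation", class(report))
  if (!any(report$accepted)) {
    stop("all CDS records rejected; nothing to align", call. = FALSE)
  }
  report
}

#' Back-map an aligned protein onto its original coding sequences
#'
#' Each non-gap amino-acid position is replaced by its original codon (taken
#' verbatim from the input CDS, never re-translated); each protein gap
#' expands to `---`.  The nucleotide alignment therefore mirrors the protein
#' alignment's topology exactly: protein column `p` maps to nucleotide
#' columns `3p-2 .. 3p`.
#'
#' @param protein_msa an [msa()] over `gapped-protein`.
#' @param originals list of accepted `dna4` CDS records matching the rows by
#'   id; each row's ungapped residues must equal the translation of its CDS
#'   (after trailing-stop stripping).
#' @return An [msa()] over `gapped-dna` with
#'   `column_count == 3 * protein column_count`.
#' @export
backmap <- function(protein_msa, originals) {
  stopifnot(inherits(protein_msa, "msa"))
  ids <- vapply(originals, function(r) r$id, character(1))
  rows <- lapply(protein_msa$rows, function(row) {
    k <- match(row$id, ids)
    if (is.na(k)) stop("no CDS provided for aligned row '", row$id, "'", call. = FALSE)
    cds <- originals[[k]]
    prot <- suppressWarnings(translate_cds(cds))
    if (gsub("-", "", row$residues, fixed = TRUE) != prot$residues) {
      stop(sprintf("row '%s': aligned protein does not match translated CDS",
                   row$id), call. = FALSE)
    }
    ncod <- nchar(prot$residues)
    codons <- substring(cds$residues, seq(1L, 3L * ncod, 3L), seq(3L, 3L * ncod, 3L))
    chars <- strsplit(row$residues, "")[[1]]
    out <- character(length(chars))
    out[chars == GAP] <- "---"
    out[chars != GAP] <- codons
    seq_record(row$id, paste(out, collapse = ""), "gapped-dna", row$description)
  })
  msa(rows)
}

#' Codon-aware progressive alignment of coding sequences
#'
#' Full pipeline: validate, translate, align progressively in protein space
#' (with gap penalties scaled by `codon_gap_scale`), back-map.  Rejected
#' sequences are excluded with a report rather than aborting the run, as long
#' as at least two sequences survive.
#'
#' @param cds_records list of candidate CDS [seq_record()]s.
#' @param provider embedding provider for the protein-space alignment.
#' @param backend scoring backend.
#' @param penalties base [gap_penalties()]; codon mode multiplies both
#'   components by `codon_gap_scale`.
#' @param policy insertion-order policy.
#' @param codon_gap_scale positive multiplier on the affine penalties in
#'   codon mode (default 1; back-mapping guarantees codon-length gaps
#'   regardless of its value).
#' @param profile record phase timings.
#' @return List with `protein` ([msa()]), `nucleotide` ([msa()]), and
#'   `report` ([validate_cds()] output).
#' @export
codon_align <- function(cds_records, provider = synthetic_provider(),
                        backend = backend_cosine(),
                        penalties = gap_penalties(),
                        policy = order_policy("upgma"),
                        codon_gap_scale = 1.0,
                        profile = FALSE) {
  if (codon_gap_scale <= 0) stop("codon_gap_scale must be positive", call. = FALSE)
  cds_records <- .as_cds_candidates(cds_records)
  report <- validate_cds(cds_records)
  keep <- which(report$accepted)
  if (length(keep) < 2L) {
    stop("fewer than 2 CDS records passed validation", call. = FALSE)
  }
  accepted <- lapply(cds_records[keep], function(r) {
    seq_record(r$id, toupper(r$residues), "dna4",
               if (is.null(r$description)) r$id else r$description)
  })
  proteins <- lapply(accepted, function(r) suppressWarnings(translate_cds(r)))
  scaled <- gap_penalties(penalties$gap_open * codon_gap_scale,
                          penalties$gap_extend * codon_gap_scale)
  protein_msa <- progressive_align(proteins, provider = provider,
                                   backend = backend, penalties = scaled,
                                   policy = policy, profile = profile)
  nuc_msa <- backmap(protein_msa, accepted)
  out <- list(protein = protein_msa, nucleotide = nuc_msa, report = report)
  if (isTRUE(profile)) attr(out, "timings") <- attr(protein_msa, "timings")
  out
}
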