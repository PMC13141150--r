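#' Canonical alphabets
#'
#' `AA20` is the closed 20-letter amino-acid alphabet (alphabetical order);
#' ambiguity codes (B, J, O, U, X, Z) are rejected everywhere because both the
#' embedding providers and the BLOSUM62 backend require a closed alphabet.
#' `DNA4` is the canonical nucleotide alphabet; N and other IUPAC ambiguity
#' symbols are rejected.
#'
#' @name alphabets
NULL

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
DNA4 <- c("A", "C", "G", "T")
GAP <- "-"

ALPHABETS <- list(
  protein20        = AA20,
  dna4             = DNA4,
  `gapped-protein` = c(AA20, GAP),
  `gapped-dna`     = c(DNA4, GAP)
)

.check_alphabet_tag <- function(alphabet) {
  if (!is.character(alphabet) || length(alphabet) != 1L ||
      !alphabet %in% names(ALPHABETS)) {
    stop("unknown alphabet tag: must be one of ",
         paste(names(ALPHABETS), collapse = ", "), call. = FALSE)
  }
  alphabet
}

# Returns the 1-based position of the first invalid symbol, or 0L if valid.
.first_invalid_symbol <- function(residues, alphabet) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% ALPHABETS[[alphabet]])
  if (length(bad)) bad[1L] else 0L
}

#' Create a validated sequence record
#'
#' @param id non-empty sequence identifier.
#' @param residues sequence text; uppercased on construction.
#' @param alphabet one of `"protein20"`, `"dna4"`, `"gapped-protein"`,
#'   `"gapped-dna"`.
#' @param description optional full header text carried through FASTA output.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, alphabet, description = NULL) {
  .check_alphabet_tag(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("sequence id must be a non-empty string", call. = FALSE)
  }
  residues <- toupper(as.character(residues))
  pos <- .first_invalid_symbol(residues, alphabet)
  if (pos > 0L) {
    stop(sprintf("record '%s': invalid symbol '%s' at position %d for alphabet %s",
                 id, substr(residues, pos, pos), pos, alphabet), call. = FALSE)
  }
  structure(list(id = id, residues = residues, alphabet = alphabet,
                 description = if (is.null(description)) id else description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s [%s] length %d>\n", x$id, x$alphabet,
              nchar(x$residues)))
  invisible(x)
}

#' Sequence length of a record (gap symbols included)
#' @param x a `seq_record`.
#' @export
seq_length <- function(x) nchar(x$residues)

#' Remove gap symbols from a gapped record
#'
#' @param x a `seq_record` over a gapped alphabet.
#' @return A `seq_record` over the corresponding ungapped alphabet.
#' @export
ungap <- function(x) {
  stopifnot(inherits(x, "seq_record"))
  base <- switch(x$alphabet,
                 `gapped-protein` = "protein20",
                 `gapped-dna` = "dna4",
                 x$alphabet)
  seq_record(x$id, gsub("-", "", x$residues, fixed = TRUE), base, x$description)
}

#' Construct a validated multiple alignment
#'
#' All rows must share one gapped alphabet and one length, and no column may
#' consist entirely of gaps.
#'
#' @param rows list of `seq_record`s over a gapped alphabet.
#' @return An object of class `msa` with fields `rows` and `column_count`.
#' @export
msa <- function(rows) {
  if (!length(rows)) stop("alignment must contain at least one row", call. = FALSE)
  stopifnot(all(vapply(rows, inherits, logical(1), "seq_record")))
  alph <- unique(vapply(rows, function(r) r$alphabet, character(1)))
  if (length(alph) != 1L || !alph %in% c("gapped-protein", "gapped-dna")) {
    stop("all alignment rows must share one gapped alphabet", call. = FALSE)
  }
  lens <- vapply(rows, seq_length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("alignment rows differ in length: ", paste(lens, collapse = ", "),
         call. = FALSE)
  }
  cc <- lens[1L]
  if (cc > 0L) {
    mat <- .msa_char_matrix_rows(rows)
    all_gap <- which(colSums(mat != GAP) == 0L)
    if (length(all_gap)) {
      stop("alignment contains all-gap column(s): ",
           paste(head(all_gap, 5L), collapse = ", "), call. = FALSE)
    }
  }
  ids <- vapply(rows, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate row id in alignment: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  structure(list(rows = rows, column_count = cc), class = "msa")
}

.msa_char_matrix_rows <- function(rows) {
  do.call(rbind, lapply(rows, function(r) strsplit(r$residues, "")[[1]]))
}

#' Character matrix view of an alignment (rows x columns)
#' @param x an `msa`.
#' @export
msa_matrix <- function(x) {
  stopifnot(inherits(x, "msa"))
  m <- .msa_char_matrix_rows(x$rows)
  rownames(m) <- vapply(x$rows, function(r) r$id, character(1))
  m
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa: %d rows x %d columns>\n", length(x$rows), x$column_count))
  invisible(x)
}
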