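#' Read a FASTA file into validated sequence records
#'
#' Records are returned in file order with sequence text uppercased.  The id is
#' the header up to the first whitespace; the full header is preserved as the
#' record description.  Duplicate ids, symbols outside the declared alphabet,
#' and empty files are errors.
#'
#' @param path FASTA file.
#' @param alphabet alphabet tag; see [alphabets].
#' @return List of [seq_record()] objects in file order.
#' @export
read_fasta <- function(path, alphabet) {
  .check_alphabet_tag(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate sequence id '%s' in %s", dup[1L], path),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  mapply(function(id, s, hdr) seq_record(id, s, alphabet, description = hdr),
         ids, seqs, headers, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records to FASTA
#'
#' Round-trip stable with [read_fasta()] up to line wrapping.  Gapped records
#' produce aligned FASTA with `-` preserved.
#'
#' @param records non-empty list of [seq_record()]s.
#' @param path output file.
#' @param width positive line-wrap width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (!length(records)) stop("no records to write", call. = FALSE)
  stopifnot(all(vapply(records, inherits, logical(1), "seq_record")))
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("width must be a positive integer", call. = FALSE)
  lines <- unlist(lapply(records, function(r) {
    body <- if (nchar(r$residues) > 0L) {
      starts <- seq(1L, nchar(r$residues), by = width)
      substring(r$residues, starts, pmin(starts + width - 1L, nchar(r$residues)))
    } else character(0)
    c(paste0(">", r$description), body)
  }))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path, call. = FALSE)
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a multiple alignment as aligned FASTA
#' @param aln an [msa()].
#' @inheritParams write_fasta
#' @export
write_msa <- function(aln, path, width = 60L) {
  stopifnot(inherits(aln, "msa"))
  write_fasta(aln$rows, path, width)
}

#' Read an aligned FASTA file as a multiple alignment
#' @param path aligned FASTA file.
#' @param alphabet gapped alphabet tag (default `"gapped-protein"`).
#' @export
read_msa <- function(path, alphabet = "gapped-protein") {
  msa(read_fasta(path, alphabet))
}

# Standard genetic code (NCBI table 1), keyed by codon.
.genetic_code <- function() Biostrings::GENETIC_CODE

#' Translate a coding sequence with the standard genetic code
#'
#' The CDS must have length divisible by three and contain no internal stop
#' codon.  A trailing stop codon is stripped with a warning, so the protein
#' maps 1:1 onto the retained codons (required by codon-mode back-mapping).
#'
#' @param cds a `seq_record` over `dna4`.
#' @return A `seq_record` over `protein20`.
#' @export
translate_cds <- function(cds) {
  stopifnot(inherits(cds, "seq_record"))
  if (cds$alphabet != "dna4") stop("translate_cds expects a dna4 record", call. = FALSE)
  n <- nchar(cds$residues)
  if (n == 0L || n %% 3L != 0L) {
    stop(sprintf("record '%s': length %d not divisible by 3 (frame error)",
                 cds$id, n), call. = FALSE)
  }
  codons <- substring(cds$residues, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(.genetic_code()[codons])
  stops <- which(aa == "*")
  if (length(stops)) {
    if (any(stops < length(codons))) {
      stop(sprintf("record '%s': internal stop codon at codon %d",
                   cds$id, stops[stops < length(codons)][1L]), call. = FALSE)
    }
    warning(sprintf("record '%s': trailing stop codon stripped", cds$id),
            call. = FALSE)
    aa <- aa[-length(aa)]
  }
  if (!length(aa)) {
    stop(sprintf("record '%s': empty protein after stripping stop codon", cds$id),
         call. = FALSE)
  }
  seq_record(cds$id, paste(aa, collapse = ""), "protein20", cds$description)
}
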