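#' Sequence record
#'
#' Lightweight container for a named sequence. Most functions in the package
#' accept plain character strings; `seq_record` adds an id, an alphabet tag
#' and validation, and is what the FASTA/FASTQ readers and writers produce
#' and consume.
#'
#' @param id Single string identifier.
#' @param residues Single non-empty string of residues. DNA records may
#'   contain `A`, `C`, `G`, `T`, `N`; protein records the 20 amino acids plus
#'   `X`, `*`, `B`, `Z`, `U` and gap `-`.
#' @param alphabet `"dna"` or `"protein"`.
#' @param description Optional free-text description.
#' @return An object of class `seq_record`: a list with elements `id`,
#'   `residues`, `alphabet`, `description`.
#' @examples
#' seq_record("chr1", "ACGTACGT")
#' @export
seq_record <- function(id, residues, alphabet = c("dna", "protein"),
                       description = "") {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("residues must be non-empty")
  if (alphabet == "dna") {
    if (grepl("[^ACGTN]", residues))
      stop("non-DNA characters in a DNA record")
  } else {
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYXBZU*-]", residues))
      stop("invalid amino-acid characters in a protein record")
  }
  structure(list(id = id, residues = residues, alphabet = alphabet,
                 description = description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  head <- substr(x$residues, 1L, 60L)
  cat(sprintf("<seq_record %s> %s %d residues\n  %s%s\n",
              x$alphabet, x$id, n, head, if (n > 60L) "..." else ""))
  invisible(x)
}

as_residues <- function(x) {
  if (inherits(x, "seq_record")) x$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a seq_record or a single character string")
}

#' Reverse complement of a DNA string
#'
#' @param x DNA string or `seq_record`.
#' @return A character string (the strand-flipped sequence).
#' @examples
#' revcomp("TTAGGG")  # "CCCTAA"
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(as_residues(x))))
}

#' Random DNA sequence
#'
#' Uniform i.i.d. bases; respects the current RNG state so callers seed with
#' [set.seed()] or [withr::with_seed()]-style wrappers.
#'
#' @param n Length in bases.
#' @param freqs Optional length-4 base frequencies (A, C, G, T).
#' @return A character string of length `n`.
#' @export
random_dna <- function(n, freqs = rep(0.25, 4)) {
  stopifnot(n >= 1, length(freqs) == 4, all(freqs >= 0))
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = freqs / sum(freqs)), collapse = "")
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Read FASTA into a list of sequence records
#' @param path FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return List of [seq_record] objects.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  xs <- if (alphabet == "dna") Biostrings::readDNAStringSet(path)
        else Biostrings::readAAStringSet(path)
  mapply(function(nm, s) {
    id <- sub("\\s.*$", "", nm)
    desc <- sub("^\\S+\\s*", "", nm)
    seq_record(id, s, alphabet, desc)
  }, names(xs), as.character(xs), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records to FASTA
#' @param records List of [seq_record] (or a named character vector).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    seqs <- records
  } else {
    if (inherits(records, "seq_record")) records <- list(records)
    seqs <- vapply(records, function(r) r$residues, character(1))
    names(seqs) <- vapply(records, function(r) r$id, character(1))
  }
  alph <- if (grepl("[^ACGTN]", paste(seqs, collapse = ""))) "AA" else "DNA"
  xs <- if (alph == "DNA") Biostrings::DNAStringSet(seqs)
        else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}
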