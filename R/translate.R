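#' Six-frame translation
#'
#' Translates a DNA sequence in all six reading frames under the standard
#' genetic code: `+1`, `+2`, `+3` read the forward strand starting at offsets
#' 0, 1, 2; `-1`, `-2`, `-3` read the reverse complement the same way. Stop
#' codons are rendered `*`; codons containing `N` (or any unresolved base)
#' are rendered `X`; trailing partial codons are dropped.
#'
#' @param dna DNA string or [seq_record]; length at least 3.
#' @return Named character vector of the six peptides, names
#'   `c("+1","+2","+3","-1","-2","-3")`.
#' @examples
#' six_frame_translate("ATGGCC")
#' @export
six_frame_translate <- function(dna) {
  s <- as_residues(dna)
  if (grepl("[^ACGTN]", s)) stop("non-DNA characters (other than N)")
  if (nchar(s) < 3L) stop("sequence shorter than one codon")
  rc <- revcomp(s)
  frames <- c(`+1` = translate_frame(s, 1L),
              `+2` = translate_frame(s, 2L),
              `+3` = translate_frame(s, 3L),
              `-1` = translate_frame(rc, 1L),
              `-2` = translate_frame(rc, 2L),
              `-3` = translate_frame(rc, 3L))
  frames
}

# translate one frame (offset 1..3) of a forward string; partial codon dropped
translate_frame <- function(s, offset) {
  n <- nchar(s)
  ncod <- (n - offset + 1L) %/% 3L
  if (ncod < 1L) return("")
  starts <- offset + 3L * (seq_len(ncod) - 1L)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"   # N-containing codons
  paste(aa, collapse = "")
}

# DNA coordinates (1-based inclusive, forward strand) of a run of amino acids
# in a given frame. frame in c("+1","+2","+3","-1","-2","-3"); aa_start/aa_end
# are 1-based positions in the frame's peptide; L is the contig length.
frame_to_dna_coords <- function(frame, aa_start, aa_end, L) {
  off <- as.integer(substr(frame, 2L, 2L))
  nt_start <- off + 3L * (aa_start - 1L)
  nt_end <- off + 3L * aa_end - 1L
  if (substr(frame, 1L, 1L) == "+") {
    c(nt_start, nt_end)
  } else {
    # positions counted on the reverse complement; mirror to forward strand
    c(L - nt_end + 1L, L - nt_start + 1L)
  }
}
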