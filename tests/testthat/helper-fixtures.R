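# shared fixture builders; everything is generated in code at test time

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

# deterministic back-translation (first codon for each residue)
back_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(aa, "")[[1]],
               function(a) names(which(gc == a))[1], character(1)),
        collapse = "")
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# independent local-alignment oracle: Biostrings dynamic programming
oracle_local_score <- function(query, subject_aa,
                               gap_open = 11, gap_extend = 1) {
  if (nchar(subject_aa) == 0L) return(0)
  al <- Biostrings::pairwiseAlignment(query, subject_aa, type = "local",
                                      substitutionMatrix = blosum62(),
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  Biostrings::score(al)
}

# best oracle score over the six frames of a contig
oracle_best_sixframe <- function(query, contig) {
  max(vapply(six_frame_translate(contig), function(p)
    oracle_local_score(query, p), numeric(1)), 0)
}

# host + embedded virus convenience wrapper
make_insertion <- function(age, rate, flank_len = 2000L, tel_copies = 15L,
                           virus = NULL, ...) {
  if (is.null(virus)) virus <- viral_genome_model(n_orfs = 3L,
                                                  orf_len = 80L)
  host <- synthetic_host(flank_len = flank_len, tel_copies = tel_copies)
  list(virus = virus, host = host,
       emb = embed_viral_insertion(host, virus, age = age, rate = rate,
                                   ...))
}

# truth-based viral hit intervals (0-based half-open) for call_junction
truth_viral_hits <- function(truth, virus) {
  data.frame(s_start = truth$virus_start + virus$orfs$start - 2L,
             s_end = truth$virus_start + virus$orfs$end - 1L)
}
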