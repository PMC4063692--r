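#!/usr/bin/env Rscript
# Stage 2 — translated homology discovery.
#
# Builds consensus queries from small simulated protein clusters (each
# cluster = a viral protein plus noisy orthologue copies), runs the
# six-frame translated search against the draft contigs, applies the
# 50 aa / 1e-10 shortlist filter, and classifies each surviving region by
# reciprocal best hit against viral vs host protein sets.

suppressMessages(library(evemine))
set.seed(20140402)

contigs <- read_fasta("results/contigs.fasta")
prot <- read_fasta("results/viral_proteins.fasta", alphabet = "protein")

# cluster rows: the protein and two divergent orthologues (10% residue noise)
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
noisy <- function(p, frac = 0.1) {
  x <- strsplit(p, "")[[1]]
  i <- sample(length(x), ceiling(frac * length(x)))
  x[i] <- sample(AA20, length(i), TRUE)
  paste(x, collapse = "")
}
queries <- lapply(prot, function(p) {
  rows <- c(p$residues, noisy(p$residues), noisy(p$residues))
  build_consensus(rows, threshold = 0.5, cluster_id = paste0(p$id, "_cons"))
})

scoring <- scoring_scheme()
hits <- do.call(rbind, lapply(queries, function(q)
  translated_search(q, contigs, scoring, score_floor = 40)))
cat(sprintf("raw translated hits: %d\n", nrow(hits)))

kept <- shortlist_hits(hits, filter_policy(50L, 1e-10))
cat(sprintf("after 50 aa / 1e-10 shortlist: %d hits on %d contigs\n",
            nrow(kept), length(unique(kept$sseqid))))
export_hits_tsv(kept, "results/hits.tsv")

# reciprocal classification of each hit region: viral proteins vs a host
# decoy set (shuffled proteins emulate host homologues with no true match)
host_db <- lapply(prot, function(p)
  seq_record(paste0("host_", p$id),
             paste(sample(strsplit(p$residues, "")[[1]]), collapse = ""),
             "protein"))
cmap <- stats::setNames(lapply(contigs, function(x) x$residues),
                        vapply(contigs, function(x) x$id, character(1)))
verdicts <- vapply(seq_len(nrow(kept)), function(i) {
  region <- substr(cmap[[kept$sseqid[i]]], kept$s_start[i] + 1L,
                   kept$s_end[i])
  reciprocal_classify(region, prot, host_db, scoring)$verdict
}, character(1))
cat("reciprocal verdicts:\n")
print(table(verdicts))
utils::write.table(cbind(kept, verdict = verdicts),
                   "results/hits_classified.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/hits.tsv, results/hits_classified.tsv\n")
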