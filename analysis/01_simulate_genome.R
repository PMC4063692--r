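#!/usr/bin/env Rscript
# Stage 1 — synthetic study system.
#
# Builds a schematic roseolovirus-like genome, integrates it into the
# telomere of a synthetic host chromosome end after 75 My of neutral
# divergence at 2.2e-9 subs/site/yr (so the perfect terminal repeat has
# diverged by ~0.165 subs/site), simulates 30x error-free mate pairs, and
# fragments the genome at telomeric repeat runs the way draft assemblies
# fail. Everything downstream works from the files written here.

suppressMessages(library(evemine))
dir.create("results", showWarnings = FALSE)
set.seed(20140401)

virus <- viral_genome_model(seed = 1L)
host <- synthetic_host(flank_len = 6000L, tel_copies = 25L, seed = 2L)
emb <- embed_viral_insertion(host, virus, age = 75e6, rate = 2.2e-9,
                             seed = 3L)
genome <- emb$genome
cat(sprintf("genome: %d bp; virus at %d-%d; junction arrays end %d / start %d\n",
            nchar(genome$residues), emb$truth$virus_start,
            emb$truth$virus_end, emb$truth$junction_left,
            emb$truth$junction_right))

pairs <- simulate_reads(genome, read_len = 100L, insert_mean = 300,
                        insert_sd = 30, coverage = 30, error_rate = 0,
                        seed = 4L)
cat(sprintf("simulated %d read pairs (30x)\n", nrow(pairs)))

frag <- fragment_assembly(genome, min_copies = 8L, gap_len = 60L)
cat(sprintf("fragmented into %d contigs (%d repeat-driven gaps)\n",
            length(frag$contigs), nrow(frag$gaps)))

# a clean exogenous-like contaminant contig: the un-degraded virus itself
exo <- seq_record("exo_contig", virus$sequence, "dna",
                  "exogenous-like viral contig (no host junction)")

write_fasta(genome, "results/genome.fasta")
write_fasta(c(frag$contigs, list(exo)), "results/contigs.fasta")
write_fasta(stats::setNames(virus$proteins, names(virus$proteins)),
            "results/viral_proteins.fasta")
write_fastq(pairs, "results/reads")
utils::write.table(pairs[, c("id", "insert", "start", "end", "strand")],
                   "results/pairs_truth.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
truth <- emb$truth
truth$orf_truth <- as.list(truth$orf_truth)
jsonlite::write_json(list(truth = truth,
                          host = host[c("tel_start", "tel_end")],
                          virus_orfs = as.list(virus$orfs),
                          virus_tmr = as.list(virus$tmr),
                          gaps = as.list(frag$gaps),
                          contig_coords = vapply(frag$contigs, function(x)
                            x$description, character(1))),
                     "results/truth.json", auto_unbox = TRUE, pretty = TRUE)
cat("wrote results/{genome,contigs,viral_proteins}.fasta, reads_[12].fastq, truth.json\n")
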