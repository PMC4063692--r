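test_that("neutral evolution: identity at time zero, reproducible by seed", {
  s <- "ACGTACGTACGTACGT"
  out <- evolve_neutrally(s, rate = 2.2e-9, time = 0)
  expect_identical(out$sequence, s)
  expect_identical(out$n_events, 0L)

  a <- evolve_neutrally(strrep("TAACCC", 20), 1, 0.3, seed = 99L)
  b <- evolve_neutrally(strrep("TAACCC", 20), 1, 0.3, seed = 99L)
  expect_identical(a, b)
})

test_that("raw substitution events match L * rate * time in expectation", {
  set.seed(101)
  L <- 294L
  d <- 0.165
  reps <- 500L
  ev <- replicate(reps, evolve_neutrally(strrep("TAACCC", 49), 1, d)$n_events)
  expected <- L * d
  se <- stats::sd(ev) / sqrt(reps)
  expect_lt(abs(mean(ev) - expected), 3 * se)
})

test_that("equal-rates model saturates to ~25% identity", {
  set.seed(7)
  s <- random_dna(3000)
  out <- evolve_neutrally(s, 1, 50)   # rate*time = 50 >> 1
  ident <- mean(chars(out$sequence) == chars(s))
  expect_lt(abs(ident - 0.25), 0.03)
})

test_that("invalid GTR inputs are rejected; degenerate zero-rate flagged", {
  expect_error(gtr_model(freqs = c(0.5, 0.5, 0.2, -0.2)), "frequencies")
  expect_error(gtr_model(rates = c(-1, 1, 1, 1, 1, 1)), "non-negative")
  expect_warning(gtr_model(rates = rep(0, 6)), "degenerate")
})

test_that("viral genome model satisfies its structural invariants", {
  v <- viral_genome_model(seed = 3L)
  expect_identical(nchar(v$motif), 6L)
  expect_identical(sum(v$tmr$perfect), 2L)      # one perfect TMR per DR
  expect_identical(nrow(v$tmr), 4L)             # two TMR arrays per DR
  # ORFs non-overlapping, in bounds, translating cleanly
  o <- v$orfs[order(v$orfs$start), ]
  expect_true(all(o$start[-1] > o$end[-nrow(o)]))
  expect_true(all(o$end <= nchar(v$sequence)))
  for (i in seq_len(nrow(o))) {
    aa <- six_frame_translate(substr(v$sequence, o$start[i], o$end[i]))[["+1"]]
    expect_identical(sub("\\*$", "", aa), unname(v$proteins[o$protein_id[i]]))
    expect_false(grepl("*", sub("\\*$", "", aa), fixed = TRUE))
  }
  # perfect terminal arrays are exact motif tilings
  p1 <- v$tmr[v$tmr$perfect, ][1, ]
  expect_identical(substr(v$sequence, p1$start, p1$end),
                   strrep(v$motif, (p1$end - p1$start + 1) / 6))
})

test_that("embedding at age 0 reproduces the viral model byte-for-byte", {
  set.seed(21)
  fx <- make_insertion(age = 0, rate = 2.2e-9)
  tr <- fx$emb$truth
  g <- fx$emb$genome$residues
  expect_identical(substr(g, tr$virus_start, tr$virus_end),
                   fx$virus$sequence)
  # junction flanks: host side matches host, virus side matches virus
  site <- tr$virus_start - 1L
  expect_identical(substr(g, site - 49L, site),
                   substr(fx$host$sequence, site - 49L, site))
  expect_identical(substr(g, tr$virus_start, tr$virus_start + 49L),
                   substr(fx$virus$sequence, 1L, 50L))
  expect_true(all(tr$orf_truth$premature_stops == 0L))
  expect_error(embed_viral_insertion(fx$host, fx$virus, site = 10^9,
                                     age = 0, rate = 1e-9),
               "outside host bounds")
})

test_that("disruption truth is recomputed from the mutated sequence", {
  set.seed(22)
  fx <- make_insertion(age = 80e6, rate = 2.2e-9)
  tr <- fx$emb$truth
  # verify each recorded stop count by independent translation scan
  vseq <- substr(fx$emb$genome$residues, tr$virus_start, tr$virus_end)
  for (i in seq_len(nrow(tr$orf_truth))) {
    o <- tr$orf_truth[i, ]
    aa <- six_frame_translate(substr(vseq, o$start, o$end))[["+1"]]
    body <- substr(aa, 1, nchar(aa) - 1)
    expect_identical(o$premature_stops,
                     sum(strsplit(body, "")[[1]] == "*"))
  }
})

test_that("read simulation: pair count, exactness, insert distribution", {
  set.seed(31)
  g <- random_dna(10000)
  pairs <- simulate_reads(g, read_len = 100, insert_mean = 300,
                          insert_sd = 30, coverage = 30, error_rate = 0)
  lambda <- 30 * 10000 / 200
  expect_lt(abs(nrow(pairs) - lambda), 5 * sqrt(lambda))
  # error-free reads are exact substrings of the genome or its revcomp
  grc <- revcomp(g)
  sub50 <- pairs[sample(nrow(pairs), 50), ]
  for (i in seq_len(nrow(sub50))) {
    for (r in c(sub50$read1[i], sub50$read2[i]))
      expect_true(grepl(r, g, fixed = TRUE) || grepl(r, grc, fixed = TRUE))
  }
  # law of large numbers on the insert mean
  big <- simulate_reads(random_dna(80000), read_len = 100,
                        insert_mean = 300, insert_sd = 30, coverage = 25,
                        error_rate = 0, seed = 5)
  expect_gt(nrow(big), 9000)
  expect_lt(abs(mean(big$insert) - 300) / 300, 0.01)
  expect_true(all(big$insert >= 200))
  expect_error(simulate_reads(g, insert_sd = -1), "insert_sd")
})

test_that("fragmentation tiles the genome and breaks only in repeat runs", {
  set.seed(41)
  # no repeats -> single contig
  fam <- evemine:::motif_family("TTAGGG")
  plain <- evemine:::motif_free_dna(3000, fam)
  fr0 <- fragment_assembly(plain)
  expect_length(fr0$contigs, 1L)
  expect_identical(fr0$contigs[[1]]$residues, plain)

  # one (TTAGGG)x50 run -> exactly 2 contigs
  g <- paste0(evemine:::motif_free_dna(2000, fam), strrep("TTAGGG", 50),
              evemine:::motif_free_dna(2000, fam))
  fr <- fragment_assembly(g, min_copies = 8)
  expect_length(fr$contigs, 2L)
  # conservation: splice contigs + gaps back into the genome
  expect_equal(sum(vapply(fr$contigs, function(x) nchar(x$residues),
                          numeric(1))) +
                 sum(fr$gaps$end - fr$gaps$start + 1),
               nchar(g))
  rebuilt <- paste0(fr$contigs[[1]]$residues,
                    substr(g, fr$gaps$start[1], fr$gaps$end[1]),
                    fr$contigs[[2]]$residues)
  expect_identical(rebuilt, g)
  # the break lies inside the repeat window
  expect_gte(fr$gaps$start[1], 2001)
  expect_lte(fr$gaps$end[1], 2300)
})

test_that("FASTA and FASTQ round-trips preserve sequence", {
  set.seed(51)
  recs <- list(seq_record("a", random_dna(100)),
               seq_record("b", random_dna(80)))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(recs, fa)
  back <- read_fasta(fa)
  expect_identical(vapply(back, `[[`, character(1), "residues"),
                   vapply(recs, `[[`, character(1), "residues"))
  pairs <- simulate_reads(random_dna(5000), coverage = 2, seed = 1)
  fq <- write_fastq(pairs, tempfile())
  r1 <- Biostrings::readDNAStringSet(fq[1], format = "fastq")
  expect_identical(as.character(r1[[1]]), pairs$read1[1])
  expect_length(r1, nrow(pairs))
})
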