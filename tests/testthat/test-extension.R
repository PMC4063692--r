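test_that("read index: posting arithmetic and k-mer retrieval", {
  pairs <- data.frame(id = "p1", read1 = strrep("ACGT", 25),
                      read2 = strrep("TTGCA", 20), stringsAsFactors = FALSE)
  idx <- index_reads(pairs, k = 21)
  # 2 mates x 2 strands x (100 - 21 + 1) offsets
  expect_identical(nrow(idx$postings), 2L * 2L * 80L)
  hit <- query_index(idx, substr(pairs$read1, 11, 31))
  expect_gt(nrow(hit), 0L)
  expect_true(all(idx$postings$read[idx$lookup[[substr(pairs$read1, 1, 21)]]]
                  %in% seq_along(idx$reads)))
  expect_identical(nrow(query_index(idx, strrep("N", 21))), 0L)
  expect_error(index_reads(pairs, k = 7), "spurious")
})

test_that("edge extension is exact on error-free reads and respects
           support everywhere", {
  set.seed(111)
  for (i in 1:5) {
    template <- random_dna(1600)
    contig <- seq_record("c", substr(template, 1, 1000))
    pairs <- simulate_reads(template, read_len = 100, insert_mean = 300,
                            insert_sd = 25, coverage = 30, error_rate = 0)
    idx <- index_reads(pairs, 21)
    ext <- extend_edge(contig, "right", idx, max_append = 2000)
    expect_gt(nchar(ext$appended), 0L)
    expect_identical(ext$appended,
                     substr(template, 1001, 1000 + nchar(ext$appended)))
    expect_true(all(ext$support >= 3L))
    expect_identical(length(ext$support), nchar(ext$appended))
  }
})

test_that("left-side extension mirrors the right side", {
  set.seed(112)
  template <- random_dna(1600)
  contig <- seq_record("c", substr(template, 601, 1600))
  pairs <- simulate_reads(template, coverage = 30, error_rate = 0)
  ext <- extend_edge(contig, "left", index_reads(pairs, 21),
                     max_append = 2000)
  expect_gt(nchar(ext$appended), 0L)
  expect_identical(ext$appended,
                   substr(template, 601 - nchar(ext$appended), 600))
})

test_that("no overlapping reads means zero appended bases", {
  set.seed(113)
  pairs <- simulate_reads(random_dna(3000), coverage = 10, error_rate = 0)
  idx <- index_reads(pairs, 21)
  ext <- extend_edge(seq_record("c", random_dna(600)), "right", idx)
  expect_identical(nchar(ext$appended), 0L)
  expect_identical(ext$iterations, 0L)
  expect_identical(ext$termination, "exhausted")
})

test_that("two haplotypes diverging past the edge stop extension as
           ambiguous at the divergence point", {
  set.seed(114)
  common <- random_dna(800)
  hapA <- paste0(common, random_dna(400))
  hapB <- paste0(common, random_dna(400))
  pairs <- rbind(simulate_reads(hapA, coverage = 20, error_rate = 0),
                 simulate_reads(hapB, coverage = 20, error_rate = 0))
  pairs$id <- sprintf("pair%06d", seq_len(nrow(pairs)))
  idx <- index_reads(pairs, 21)
  ext <- extend_edge(seq_record("c", substr(common, 1, 700)), "right", idx,
                     max_append = 2000)
  expect_identical(ext$termination, "ambiguous")
  # appended sequence never passes the divergence point
  expect_lte(700 + nchar(ext$appended), 800)
  if (nchar(ext$appended) > 0)
    expect_identical(ext$appended, substr(common, 701,
                                          700 + nchar(ext$appended)))
})

test_that("determinism: identical inputs give identical extensions", {
  set.seed(115)
  template <- random_dna(1500)
  pairs <- simulate_reads(template, coverage = 25, error_rate = 0)
  contig <- seq_record("c", substr(template, 1, 900))
  idx <- index_reads(pairs, 21)
  e1 <- extend_edge(contig, "right", idx)
  e2 <- extend_edge(contig, "right", idx)
  expect_identical(e1, e2)
})

test_that("linking: spanning reads merge collinear contigs in template
           order; disjoint contigs stay apart; no reads = input", {
  set.seed(116)
  template <- random_dna(3200)
  ctg <- list(seq_record("c1", substr(template, 1, 1000)),
              seq_record("c2", substr(template, 1101, 2100)),
              seq_record("c3", substr(template, 2201, 3200)))
  pairs <- simulate_reads(template, coverage = 30, error_rate = 0)
  res <- scaffold_targeted(ctg, pairs)
  lens <- vapply(res$composites, function(cc) nchar(cc$sequence), numeric(1))
  best <- res$composites[[which.max(lens)]]
  expect_identical(best$members, c("c1", "c2", "c3"))
  expect_identical(best$sequence, template)

  # disjoint: reads from unrelated molecules cannot join the contigs
  other <- random_dna(3000)
  res2 <- scaffold_targeted(ctg[1:2], simulate_reads(other, coverage = 20,
                                                     error_rate = 0))
  expect_true(all(vapply(res2$composites, function(cc)
    length(cc$members) == 1L, logical(1))))

  # empty read set passes contigs through
  res3 <- scaffold_targeted(ctg, pairs[0, ])
  expect_identical(vapply(res3$composites, `[[`, character(1), "members"),
                   c("c1", "c2", "c3"))
})

test_that("a gene-order hint demotes contradicting joins to flagged", {
  set.seed(117)
  template <- random_dna(2100)
  ctg <- list(seq_record("c1", substr(template, 1, 1000)),
              seq_record("c2", substr(template, 1101, 2100)))
  pairs <- simulate_reads(template, coverage = 30, error_rate = 0)
  ok <- scaffold_targeted(ctg, pairs, hint = c("P1", "P2"),
                          contig_proteins = list(c1 = "P1", c2 = "P2"))
  expect_true(any(vapply(ok$composites, function(cc)
    identical(cc$members, c("c1", "c2")), logical(1))))
  bad <- scaffold_targeted(ctg, pairs, hint = c("P2", "P1"),
                           contig_proteins = list(c1 = "P1", c2 = "P2"))
  expect_false(any(vapply(bad$composites, function(cc)
    length(cc$members) > 1L, logical(1))))
  expect_gt(nrow(bad$flagged), 0L)
})

test_that("composite export records members and join evidence", {
  set.seed(118)
  template <- random_dna(2100)
  ctg <- list(seq_record("c1", substr(template, 1, 1000)),
              seq_record("c2", substr(template, 1101, 2100)))
  res <- scaffold_targeted(ctg, simulate_reads(template, coverage = 30,
                                               error_rate = 0))
  fa <- tempfile(fileext = ".fasta")
  js <- tempfile(fileext = ".json")
  ev <- export_composites(res, fa, js)
  expect_true(file.exists(fa) && file.exists(js))
  expect_identical(ev[[1]]$members, c("c1", "c2"))
  expect_gt(ev[[1]]$joins$overlap[1], 0)
})
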