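test_that("TMR arrays: exact run, interrupted run, absent motif", {
  fam <- evemine:::motif_family("TTAGGG")
  pad <- function(n) evemine:::motif_free_dna(n, fam)
  set.seed(71)
  a <- find_tmr_arrays(paste0(pad(50), strrep("TTAGGG", 10), pad(50)))
  expect_length(a, 1L)
  expect_identical(a[[1]]$copies, 10L)
  expect_identical(a[[1]]$purity, 1)
  expect_identical(a[[1]]$end - a[[1]]$start + 1L, 60L)

  mid <- paste0(strrep("TTAGGG", 5), "TTAGCG", strrep("TTAGGG", 5))
  b <- find_tmr_arrays(paste0(pad(40), mid, pad(40)), max_gap = 6)
  expect_length(b, 1L)
  expect_identical(b[[1]]$copies, 10L)
  expect_equal(b[[1]]$purity, 10 / 11)

  expect_length(find_tmr_arrays(pad(300)), 0L)
})

test_that("array detection is strand-symmetric with mirrored coordinates", {
  fam <- evemine:::motif_family("TTAGGG")
  set.seed(72)
  for (i in 1:5) {
    s <- paste0(evemine:::motif_free_dna(60, fam),
                strrep("TTAGGG", sample(4:12, 1)),
                evemine:::motif_free_dna(60, fam))
    f <- find_tmr_arrays(s)
    r <- find_tmr_arrays(revcomp(s))
    expect_length(r, length(f))
    L <- nchar(s)
    expect_identical(r[[1]]$start, L - f[[1]]$end + 1L)
    expect_identical(r[[1]]$end, L - f[[1]]$start + 1L)
    expect_false(r[[1]]$orientation == f[[1]]$orientation)
    expect_identical(r[[1]]$purity, f[[1]]$purity)
  }
})

test_that("purity is invariant under the rotation used to name the motif", {
  fam <- evemine:::motif_family("TTAGGG")
  set.seed(73)
  s <- paste0(evemine:::motif_free_dna(40, fam), strrep("TTAGGG", 5),
              "TTAGCG", strrep("TTAGGG", 5),
              evemine:::motif_free_dna(40, fam))
  p <- vapply(c("TTAGGG", "AGGGTT", "GGTTAG", "CCCTAA", "TAACCC"),
              function(m) find_tmr_arrays(s, motif = m)[[1]]$purity,
              numeric(1))
  expect_true(all(abs(p - p[1]) < 1e-12))
})

test_that("motif orientation is defined up to rotation, flipped by strand", {
  fam <- evemine:::motif_family("TTAGGG")
  set.seed(74)
  mk <- function(motif) {
    s <- paste0(evemine:::motif_free_dna(30, fam), strrep(motif, 6),
                evemine:::motif_free_dna(30, fam))
    find_tmr_arrays(s, motif = motif)[[1]]
  }
  expect_identical(motif_orientation(mk("CCCTAA"), "TTAGGG"),
                   "reverse-complement")
  expect_identical(motif_orientation(mk("AGGGTT"), "TTAGGG"), "same")
  expect_identical(motif_orientation(mk("TAACCC"), "TTAGGG"),
                   "reverse-complement")
  expect_error(motif_orientation(mk("TTAGGG"), "ACACAC"), "closure")
})

test_that("junction calling separates host from virus at the array", {
  set.seed(75)
  fx <- make_insertion(age = 0, rate = 2.2e-9)
  tr <- fx$emb$truth
  arrays <- find_tmr_arrays(fx$emb$genome)
  hits <- truth_viral_hits(tr, fx$virus)
  host_ev <- data.frame(start = 1L, end = fx$host$tel_start - 10L)
  calls <- call_junction(fx$emb$genome, arrays, hits, host_ev)
  expect_gt(length(calls), 0L)
  # the outermost call (first after host-proximity sort) is the junction
  expect_identical(calls[[1]]$virus_side, "right")
  expect_lte(abs(calls[[1]]$coordinate - tr$junction_left), 6L)

  # pure virus with internal TMRs: no host side, no calls
  vc <- seq_record("virus", fx$virus$sequence)
  va <- find_tmr_arrays(vc)
  vh <- data.frame(s_start = fx$virus$orfs$start - 1L,
                   s_end = fx$virus$orfs$end)
  expect_length(call_junction(vc, va, vh, data.frame(start = integer(),
                                                     end = integer())), 0L)

  # host-only contig with a telomeric end: no viral hits, no calls
  h <- synthetic_host(flank_len = 1500)
  expect_length(call_junction(h$sequence, find_tmr_arrays(h$sequence),
                              evemine:::empty_hits()[, c("s_start", "s_end")],
                              data.frame(start = 1L, end = 1400L)), 0L)
})

test_that("terminal overlap recovers an exact and a degraded 337 bp
           suffix/prefix construction, and rejects unrelated contigs", {
  set.seed(76)
  shared <- random_dna(337)
  A <- seq_record("A", paste0(random_dna(1200), shared))
  B0 <- seq_record("B", paste0(shared, random_dna(1200)))
  ov0 <- terminal_overlap(A, B0, min_len = 100)
  expect_identical(ov0$length, 337L)
  expect_identical(ov0$mismatches, 0L)
  expect_identical(ov0$gaps, 0L)
  expect_identical(ov0$arrangement, "A-then-B")

  # 1 substitution + 4 single-base indels, as at a degraded contig end
  sB <- shared
  substr(sB, 120, 120) <- setdiff(c("A", "C", "G", "T"),
                                  substr(sB, 120, 120))[1]
  ch <- strsplit(sB, "")[[1]]
  ch <- append(ch, "G", after = 60); ch <- ch[-160]
  ch <- append(ch, "T", after = 220); ch <- ch[-300]
  B1 <- seq_record("B", paste0(paste(ch, collapse = ""), random_dna(1200)))
  ov1 <- terminal_overlap(A, B1, min_len = 100)
  expect_identical(ov1$mismatches, 1L)
  expect_identical(ov1$gaps, 4L)
  expect_lte(abs(ov1$length - 337L), 6L)

  # revcomp arrangement is detected
  Brc <- seq_record("B", revcomp(B0$residues))
  ovr <- terminal_overlap(A, Brc, min_len = 100)
  expect_identical(ovr$orientation, "revcomp")
  expect_identical(ovr$length, 337L)

  expect_null(terminal_overlap(seq_record("X", random_dna(1500)),
                               seq_record("Y", random_dna(1500)),
                               min_len = 100))
  expect_error(terminal_overlap(A, B0, min_len = 10), "min_len")
})

test_that("array/junction export writes BED intervals 0-based half-open", {
  set.seed(77)
  fam <- evemine:::motif_family("TTAGGG")
  s <- seq_record("c1", paste0(evemine:::motif_free_dna(100, fam),
                               strrep("TTAGGG", 8),
                               evemine:::motif_free_dna(100, fam)))
  arr <- find_tmr_arrays(s)
  bed <- tempfile(fileext = ".bed")
  export_junction_report(arr, list(), bed_path = bed)
  tab <- utils::read.delim(bed, header = FALSE)
  expect_equal(tab$V2[1], arr[[1]]$start - 1)
  expect_equal(tab$V3[1], arr[[1]]$end)
})
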