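test_that("consensus construction follows plurality-with-threshold rules", {
  rows <- c("MKVA", "MKVA", "MKVA")
  expect_identical(build_consensus(rows, 0.5)$consensus, "MKVA")
  # {A,A,V} at threshold 0.5 -> A
  expect_identical(build_consensus(c("A", "A", "V"), 0.5)$consensus, "A")
  # {A,V} tie below threshold 0.6 -> X
  expect_identical(build_consensus(c("A", "V"), 0.6)$consensus, "X")
  # all-gap columns dropped
  expect_identical(build_consensus(c("M-A", "M-A"), 0.5)$consensus, "MA")
  expect_error(build_consensus(character(0)), "empty")
  expect_error(build_consensus(c("AA", "AAA")), "equal length")
})

test_that("six-frame translation matches the standard code frame by frame", {
  expect_identical(six_frame_translate("ATGGCC"),
                   c(`+1` = "MA", `+2` = "W", `+3` = "G",
                     `-1` = "GH", `-2` = "A", `-3` = "P"))
  expect_identical(six_frame_translate("TAA")[["+1"]], "*")
  expect_identical(six_frame_translate("ATGNCA")[["+1"]], "MX")
  expect_error(six_frame_translate("ATGQ"), "non-DNA")
  expect_error(six_frame_translate("AT"), "codon")
})

test_that("frames of the reverse complement are a relabelling of frames", {
  set.seed(61)
  for (i in 1:20) {
    s <- random_dna(sample(30:90, 1))
    f <- six_frame_translate(s)
    g <- six_frame_translate(revcomp(s))
    expect_setequal(unname(f), unname(g))
    expect_identical(sort(names(f)), sort(names(g)))
  }
})

test_that("translated search finds a planted peptide with the exact
           diagonal score and forward-strand coordinates", {
  set.seed(62)
  B <- blosum62()
  q <- random_protein(40)
  bt <- back_translate(q)
  contig <- paste0(random_dna(90), bt, random_dna(120))
  h <- translated_search(q, c(ctg = contig), score_floor = 20)
  expect_identical(h$frame[1], "+1")
  expect_identical(h$s_start[1], 90L)
  expect_identical(h$s_end[1], 210L)
  expect_identical(h$score[1],
                   sum(vapply(strsplit(q, "")[[1]],
                              function(a) B[a, a], numeric(1))))
  expect_identical(h$length[1], 40L)
  expect_identical(h$pident[1], 100)
})

test_that("a reverse-strand plant scores identically with mirrored
           forward coordinates", {
  set.seed(63)
  q <- random_protein(35)
  bt <- back_translate(q)
  fwd <- paste0(random_dna(60), bt, random_dna(60))
  rev <- revcomp(fwd)
  hf <- translated_search(q, c(c1 = fwd), score_floor = 20)
  hr <- translated_search(q, c(c1 = rev), score_floor = 20)
  expect_identical(hf$score[1], hr$score[1])
  expect_true(substr(hr$frame[1], 1, 1) == "-")
  # same footprint after mirroring the interval
  L <- nchar(fwd)
  expect_identical(hr$s_start[1], L - hf$s_end[1])
  expect_identical(hr$s_end[1], L - hf$s_start[1])
})

test_that("search scores equal the independent alignment oracle", {
  set.seed(64)
  for (i in 1:25) {
    q <- random_protein(sample(20:80, 1))
    contig <- random_dna(sample(120:500, 1))
    if (i %% 3 == 0) {  # plant on a strand sometimes
      pep <- back_translate(substr(q, 3, min(20, nchar(q))))
      ins <- if (i %% 2) pep else revcomp(pep)
      pos <- sample(nchar(contig) - nchar(ins), 1)
      contig <- paste0(substr(contig, 1, pos), ins,
                       substr(contig, pos + nchar(ins) + 1, nchar(contig)))
    }
    h <- translated_search(q, c(x = contig), score_floor = 1,
                           max_hits_per_frame = 1L)
    got <- if (nrow(h) > 0) max(h$score) else 0
    expect_equal(got, oracle_best_sixframe(q, contig))
  }
})

test_that("empty results: dissimilar query yields no hits; short contigs
           are skipped with a warning", {
  h <- translated_search("WWWWWWWWWW", c(ctg = strrep("CCC", 60)),
                         score_floor = 15)
  expect_identical(nrow(h), 0L)
  expect_warning(translated_search("MKV", c(tiny = "AC", ok = random_dna(60)),
                                   score_floor = 1e6), "skipped")
})

test_that("shortlist filter applies the length and significance rules", {
  hits <- empty <- evemine:::empty_hits()
  mk <- function(len, e) data.frame(qseqid = "q", sseqid = "s",
                                    frame = "+1", s_start = 0L,
                                    s_end = 3L * len, q_start = 1L,
                                    q_end = len, length = len,
                                    pident = 100, mismatch = 0L,
                                    gapopen = 0L, score = 100,
                                    bitscore = 50, evalue = e)
  hits <- do.call(rbind, list(
    mk(49L, 1e-30),    # long enough? no
    mk(200L, 1e-5),    # significant? no
    mk(60L, 1e-12),    # survives
    mk(50L, 1e-10)))   # boundary: survives (>= 50, <= 1e-10)
  out <- shortlist_hits(hits, filter_policy(50, 1e-10))
  expect_identical(out$length, c(60L, 50L))
  expect_identical(nrow(shortlist_hits(empty)), 0L)
  # literal inverted reading is available but not the default
  inv <- shortlist_hits(hits, filter_policy(
    50, 1e-10, direction = "discard_significant"))
  expect_identical(inv$length, 200L)
})

test_that("filter monotonicity: relaxing E keeps survivors, tightening
           length never adds any", {
  set.seed(65)
  hits <- do.call(rbind, lapply(1:30, function(i)
    data.frame(qseqid = "q", sseqid = "s", frame = "+1", s_start = 0L,
               s_end = 30L, q_start = 1L, q_end = 10L,
               length = sample(10:200, 1), pident = 90, mismatch = 1L,
               gapopen = 0L, score = 50, bitscore = 25,
               evalue = 10^stats::runif(1, -30, 0))))
  for (e in c(1e-20, 1e-10, 1e-4)) {
    a <- shortlist_hits(hits, filter_policy(50, e))
    b <- shortlist_hits(hits, filter_policy(50, e * 100))
    expect_true(all(rownames(a) %in% rownames(b)))
    c1 <- shortlist_hits(hits, filter_policy(80, e))
    expect_true(all(rownames(c1) %in% rownames(a)))
  }
})

test_that("E-values scale exactly with search-space size", {
  set.seed(66)
  q <- random_protein(30)
  ctg <- paste0(random_dna(40), back_translate(q), random_dna(40))
  h1 <- translated_search(q, c(a = ctg), score_floor = 20)
  h2 <- translated_search(q, c(a = ctg, b = ctg), score_floor = 20)
  # doubling the database doubles every E-value at equal score
  top2 <- h2[h2$score == h1$score[1], ]
  expect_equal(top2$evalue[1] / h1$evalue[1], 2, tolerance = 1e-9)
})

test_that("reciprocal classification separates viral plants from host
           homologues and ties break to ambiguous", {
  set.seed(67)
  vp <- random_protein(60)
  hp <- random_protein(60)
  region_v <- back_translate(vp)
  decoy <- paste(sample(strsplit(vp, "")[[1]]), collapse = "")
  call_v <- reciprocal_classify(region_v, list(seq_record("V", vp, "protein")),
                                list(seq_record("H", decoy, "protein")))
  expect_identical(call_v$verdict, "viral")
  call_h <- reciprocal_classify(back_translate(hp),
                                list(seq_record("V", vp, "protein")),
                                list(seq_record("H", hp, "protein")))
  expect_identical(call_h$verdict, "false-positive")
  tie <- reciprocal_classify(region_v, list(seq_record("V", vp, "protein")),
                             list(seq_record("H2", vp, "protein")))
  expect_identical(tie$verdict, "ambiguous")
  expect_error(reciprocal_classify(region_v, list(), list()), "non-empty")
})

test_that("hit export writes 12 BLAST-style columns plus frame", {
  set.seed(68)
  q <- random_protein(30)
  h <- translated_search(q, c(a = paste0(back_translate(q), random_dna(30))),
                         score_floor = 20)
  f <- tempfile(fileext = ".tsv")
  export_hits_tsv(h, f)
  tab <- utils::read.delim(f)
  expect_identical(colnames(tab),
                   c("qseqid", "sseqid", "pident", "length", "mismatch",
                     "gapopen", "qstart", "qend", "sstart", "send",
                     "evalue", "bitscore", "frame"))
  expect_identical(tab$sstart[1], h$s_start[1] + 1L)
})
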