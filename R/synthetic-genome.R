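#' Synthetic herpesvirus-like genome model
#'
#' Builds a schematic roseolovirus-like genome: a unique region of synthetic
#' protein-coding ORFs flanked by two direct-repeat (DR) blocks, each DR
#' carrying two telomeric-repeat (TMR) arrays — one perfect, one imperfect —
#' with the perfect array at the genome terminus. This mirrors the
#' architecture through which such viruses integrate into host telomeres and
#' gives the dating stage a known perfect-repeat ancestor. It is a schematic
#' layout, not a reconstruction of any real viral genome.
#'
#' Spacer sequence adjacent to the TMR arrays is rejection-sampled to be
#' free of telomeric-family hexamers, so array boundaries are sharp by
#' construction.
#'
#' @param motif Hexamer written in the orientation carried by the viral
#'   terminal arrays (default `"TAACCC"`, the reverse-complement family of
#'   the canonical vertebrate telomere repeat).
#' @param tmr_copies Copies in each perfect terminal array (default 49,
#'   i.e. 294 bp).
#' @param imperfect_copies Copies in each internal imperfect array.
#' @param imperfect_mut_frac Fraction of imperfect-array copies carrying a
#'   point difference.
#' @param n_orfs Number of synthetic ORFs in the unique region.
#' @param orf_len Length of each ORF in codons (including start/stop).
#' @param spacer_len Length of motif-free spacer between blocks.
#' @param seed Optional integer seed.
#' @return Object of class `viral_genome_model`: list with `sequence`,
#'   `orfs` (data frame: protein_id, start, end, strand; 1-based inclusive),
#'   `proteins` (named character vector of translations, no terminal stop),
#'   `tmr` (data frame: name, start, end, perfect), `motif`.
#' @export
viral_genome_model <- function(motif = "TAACCC", tmr_copies = 49L,
                               imperfect_copies = 25L,
                               imperfect_mut_frac = 0.2,
                               n_orfs = 6L, orf_len = 200L,
                               spacer_len = 150L, seed = NULL) {
  stopifnot(nchar(motif) == 6L, tmr_copies >= 2, n_orfs >= 1)
  if (!is.null(seed)) set.seed(seed)
  fam <- motif_family(motif)

  perfect <- strrep(motif, tmr_copies)
  imperf <- make_imperfect_array(motif, imperfect_copies, imperfect_mut_frac)
  sp <- function() motif_free_dna(spacer_len, fam)

  orf_seqs <- replicate(n_orfs, make_orf(orf_len), simplify = FALSE)
  inter <- replicate(n_orfs + 1L, motif_free_dna(100L, fam), simplify = FALSE)

  # assemble: [perfect TMR][spacer][imperfect TMR][spacer] = left DR,
  # unique region, right DR mirrored (imperfect then perfect at terminus)
  parts <- list(perfect, sp(), imperf, sp())
  unique_parts <- list()
  for (i in seq_len(n_orfs)) {
    unique_parts[[length(unique_parts) + 1L]] <- inter[[i]]
    unique_parts[[length(unique_parts) + 1L]] <- orf_seqs[[i]]
  }
  unique_parts[[length(unique_parts) + 1L]] <- inter[[n_orfs + 1L]]
  parts <- c(parts, unique_parts, list(sp(), imperf, sp(), perfect))

  lens <- vapply(parts, nchar, integer(1))
  offs <- cumsum(c(0L, lens[-length(lens)]))
  genome <- paste(unlist(parts), collapse = "")

  orf_part_idx <- 4L + 2L * seq_len(n_orfs)   # positions of ORFs in `parts`
  orfs <- data.frame(
    protein_id = sprintf("VP%02d", seq_len(n_orfs)),
    start = offs[orf_part_idx] + 1L,
    end = offs[orf_part_idx] + lens[orf_part_idx],
    strand = "+", stringsAsFactors = FALSE)
  proteins <- vapply(orf_seqs, function(s) {
    aa <- translate_frame(s, 1L)
    sub("\\*$", "", aa)
  }, character(1))
  names(proteins) <- orfs$protein_id

  np <- length(parts)
  tmr <- data.frame(
    name = c("DR-L/perfect", "DR-L/imperfect", "DR-R/imperfect",
             "DR-R/perfect"),
    start = offs[c(1L, 3L, np - 2L, np)] + 1L,
    end = offs[c(1L, 3L, np - 2L, np)] + lens[c(1L, 3L, np - 2L, np)],
    perfect = c(TRUE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE)

  structure(list(sequence = genome, orfs = orfs, proteins = proteins,
                 tmr = tmr, motif = motif),
            class = "viral_genome_model")
}

# all 12 strings denoting the same telomeric repeat family:
# 6 rotations of the motif and 6 of its reverse complement
motif_family <- function(motif) {
  rot <- vapply(0:5, function(k)
    paste0(substr(motif, k + 1L, 6L), substr(motif, 1L, k)), character(1))
  unique(c(rot, vapply(rot, revcomp, character(1))))
}

motif_rotations <- function(motif)
  vapply(0:5, function(k)
    paste0(substr(motif, k + 1L, 6L), substr(motif, 1L, k)), character(1))

# random DNA containing no hexamer of the given family
motif_free_dna <- function(n, family) {
  repeat {
    s <- random_dna(n)
    if (!any(vapply(family, function(m) grepl(m, s, fixed = TRUE),
                    logical(1))))
      return(s)
  }
}

make_imperfect_array <- function(motif, copies, mut_frac) {
  reps <- replicate(copies, motif)
  idx <- sample(copies, max(1L, round(mut_frac * copies)))
  for (i in idx) {
    pos <- sample(6L, 1L)
    base <- sample(setdiff(BASES, substr(reps[i], pos, pos)), 1L)
    substr(reps[i], pos, pos) <- base
  }
  paste(reps, collapse = "")
}

# synthetic coding sequence: ATG + random sense codons + TAA
make_orf <- function(n_codons) {
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(which(Biostrings::GENETIC_CODE == "*")))
  sense <- setdiff(sense, "ATG")
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Synthetic host chromosome end
#'
#' Random host sequence terminating in a telomeric repeat array, the
#' integration substrate for [embed_viral_insertion()]. The flank adjacent
#' to the array is motif-free so the array boundary is unambiguous.
#'
#' @param flank_len Length of host sequence before the telomere.
#' @param motif Telomere motif on the forward strand (default `"TTAGGG"`).
#' @param tel_copies Copies in the terminal telomeric array.
#' @param seed Optional integer seed.
#' @return List with `sequence`, `tel_start`, `tel_end` (1-based inclusive
#'   coordinates of the telomeric array).
#' @export
synthetic_host <- function(flank_len = 5000L, motif = "TTAGGG",
                           tel_copies = 30L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fam <- motif_family(motif)
  flank <- paste0(random_dna(max(0L, flank_len - 200L)),
                  motif_free_dna(min(200L, flank_len), fam))
  tel <- strrep(motif, tel_copies)
  list(sequence = paste0(flank, tel),
       tel_start = nchar(flank) + 1L,
       tel_end = nchar(flank) + nchar(tel))
}

#' Neutral sequence evolution under a GTR model
#'
#' Evolves each site independently by a continuous-time Markov chain with
#' the model's normalized generator, via per-site exponential waiting times
#' (every substitution event is simulated, including multiple hits and
#' reversions). `rate * time` is therefore the expected number of raw
#' substitution events per site at stationarity.
#'
#' @param seq DNA string or [seq_record].
#' @param rate Substitution rate, substitutions/site/year.
#' @param time Elapsed time, years.
#' @param model A [gtr_model()].
#' @param seed Optional integer seed.
#' @return List with `sequence` (same length as input) and `n_events`
#'   (total raw substitution events over all sites).
#' @export
evolve_neutrally <- function(seq, rate, time, model = gtr_model(),
                             seed = NULL) {
  s <- as_residues(seq)
  stopifnot(is.finite(rate), is.finite(time), rate >= 0, time >= 0)
  if (!is.null(seed)) set.seed(seed)
  d <- rate * time
  if (d == 0) return(list(sequence = s, n_events = 0L))
  Q <- model$Q
  if (all(Q == 0)) return(list(sequence = s, n_events = 0L))
  x <- chars(s)
  n_events <- 0L
  jump_prob <- lapply(BASES, function(b) {
    p <- Q[b, ]; p[b] <- 0
    if (sum(p) > 0) p / sum(p) else p
  })
  names(jump_prob) <- BASES
  exit_rate <- -diag(Q)
  for (i in seq_along(x)) {
    b <- x[i]
    if (!b %in% BASES) next   # N sites are left untouched
    t_left <- d
    repeat {
      er <- exit_rate[b]
      if (er <= 0) break
      w <- stats::rexp(1L, er)
      if (w > t_left) break
      t_left <- t_left - w
      b <- sample(BASES, 1L, prob = jump_prob[[b]])
      n_events <- n_events + 1L
    }
    x[i] <- b
  }
  list(sequence = paste(x, collapse = ""), n_events = n_events)
}

#' Embed a neutrally evolved viral insertion in a host telomere
#'
#' Inserts a viral genome at a position inside the host's telomeric repeat
#' array, evolving the viral portion neutrally for `age` years at `rate`
#' before insertion. The result is a host|TMR|virus junction: host telomere
#' repeats run into the virus's (degraded) terminal TMR array. Full ground
#' truth is recorded for parameter-recovery tests.
#'
#' @param host Output of [synthetic_host()] (or a list with `sequence`,
#'   `tel_start`, `tel_end`).
#' @param virus A [viral_genome_model()].
#' @param site Host coordinate after which the virus is inserted; must lie
#'   within the host telomeric array. Default: the array end.
#' @param age Integration age, years.
#' @param rate Neutral substitution rate, substitutions/site/year.
#' @param model A [gtr_model()].
#' @param seed Optional integer seed.
#' @return List with `genome` (a [seq_record]) and `truth`: a list holding
#'   `virus_start`/`virus_end` (1-based inclusive), `junction_left` /
#'   `junction_right` (coordinates of the viral-side edges of the two
#'   junction TMR arrays), `t_true`, `r_true`, `n_events`, `orf_truth`
#'   (per-ORF premature-stop/frameshift counts recomputed after mutation)
#'   and `seed`.
#' @export
embed_viral_insertion <- function(host, virus, site = host$tel_end,
                                  age, rate, model = gtr_model(),
                                  seed = NULL) {
  stopifnot(inherits(virus, "viral_genome_model"))
  L <- nchar(host$sequence)
  if (site < 1L || site > L) stop("site outside host bounds")
  if (site < host$tel_start || site > host$tel_end)
    warning("site does not lie within the host telomeric array")
  if (!is.null(seed)) set.seed(seed)
  ev <- evolve_neutrally(virus$sequence, rate, age, model)
  vseq <- ev$sequence
  genome <- paste0(substr(host$sequence, 1L, site), vseq,
                   substr(host$sequence, site + 1L, L))
  vs <- site + 1L
  ve <- site + nchar(vseq)

  # per-ORF disruption truth, recomputed by scanning the mutated frame
  orf_truth <- virus$orfs
  orf_truth$premature_stops <- vapply(seq_len(nrow(virus$orfs)), function(i) {
    o <- virus$orfs[i, ]
    aa <- translate_frame(substr(vseq, o$start, o$end), 1L)
    body <- substr(aa, 1L, nchar(aa) - 1L)   # terminal stop never premature
    lengths(regmatches(body, gregexpr("*", body, fixed = TRUE)))
  }, integer(1))
  orf_truth$frameshifts <- 0L   # no indel channel by default
  orf_truth$disrupted <- orf_truth$premature_stops > 0L

  tmr_vt <- virus$tmr
  truth <- list(
    virus_start = vs, virus_end = ve,
    junction_left = site + tmr_vt$end[1L],
    junction_right = site + tmr_vt$start[nrow(tmr_vt)],
    t_true = age, r_true = rate, n_events = ev$n_events,
    orf_truth = orf_truth, seed = seed)
  list(genome = seq_record("synthetic_chromosome", genome, "dna",
                           "host with embedded viral insertion"),
       truth = truth)
}

#' Simulate paired-end reads
#'
#' Draws read pairs from both strands of a genome with truncated-normal
#' insert sizes (lower bound `2 * read_len`). The pair count is Poisson
#' with mean `coverage * L / (2 * read_len)`. Sequencing errors are i.i.d.
#' substitutions at `error_rate`.
#'
#' @param genome DNA string or [seq_record].
#' @param read_len Read length, bp.
#' @param insert_mean,insert_sd Insert-size distribution, bp.
#' @param coverage Target fold coverage.
#' @param error_rate Per-base substitution error probability.
#' @param seed Optional integer seed.
#' @return Data frame, one row per pair: `id`, `read1`, `read2`, `insert`
#'   (true insert size), `start`, `end` (origin interval, 1-based inclusive
#'   on the forward strand), `strand` (strand of read1's origin).
#' @export
simulate_reads <- function(genome, read_len = 100L, insert_mean = 300,
                           insert_sd = 30, coverage = 30, error_rate = 0,
                           seed = NULL) {
  g <- as_residues(genome)
  L <- nchar(g)
  stopifnot(coverage > 0, insert_sd >= 0, read_len >= 20,
            error_rate >= 0, error_rate < 1)
  if (L < 2L * read_len) stop("genome shorter than one insert")
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1L, coverage * L / (2 * read_len))
  lo <- 2L * read_len
  inserts <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {   # truncated normal by rejection
    draw <- round(stats::rnorm(length(todo), insert_mean, insert_sd))
    ok <- draw >= lo & draw <= L
    inserts[todo[ok]] <- as.integer(draw[ok])
    todo <- todo[!ok]
    if (insert_sd == 0 && length(todo)) {
      inserts[todo] <- as.integer(max(lo, min(L, round(insert_mean))))
      break
    }
  }
  starts <- vapply(inserts, function(ins) sample.int(L - ins + 1L, 1L),
                   integer(1))
  ends <- starts + inserts - 1L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  frag_fwd <- substring(g, starts, ends)
  r_fwd <- substr(frag_fwd, 1L, read_len)
  r_rev <- vapply(substring(frag_fwd, inserts - read_len + 1L, inserts),
                  revcomp, character(1), USE.NAMES = FALSE)
  read1 <- ifelse(strands == "+", r_fwd, r_rev)
  read2 <- ifelse(strands == "+", r_rev, r_fwd)
  if (error_rate > 0) {
    read1 <- vapply(read1, add_errors, character(1), error_rate,
                    USE.NAMES = FALSE)
    read2 <- vapply(read2, add_errors, character(1), error_rate,
                    USE.NAMES = FALSE)
  }
  data.frame(id = sprintf("pair%06d", seq_len(n)), read1 = read1,
             read2 = read2, insert = inserts, start = starts, end = ends,
             strand = strands, stringsAsFactors = FALSE)
}

add_errors <- function(read, rate) {
  x <- chars(read)
  hit <- which(stats::runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(BASES, x[i]), 1L)
  paste(x, collapse = "")
}

#' Fragment a genome at repeat-driven breakpoints
#'
#' Emulates assembly failure inside low-complexity repeat runs: every
#' maximal telomeric-family run with at least `min_copies` motif copies
#' becomes a break window, and a gap of up to `gap_len` bases centred on
#' the window is removed. The concatenation of contigs and gap intervals
#' tiles the genome exactly.
#'
#' @param genome DNA string or [seq_record].
#' @param motif Hexamer defining the repeat family.
#' @param min_copies Minimum copies for a run to qualify as a break window.
#' @param gap_len Gap removed at each break (clipped to the window).
#' @param seed Unused placeholder for interface symmetry (the rule is
#'   deterministic); kept so callers can treat all generator steps alike.
#' @return List with `contigs` (list of [seq_record], ids `contig_01`...)
#'   and `gaps` (data frame: `start`, `end`, 1-based inclusive genome
#'   coordinates of the removed bases).
#' @export
fragment_assembly <- function(genome, motif = "TTAGGG", min_copies = 8L,
                              gap_len = 60L, seed = NULL) {
  g <- as_residues(genome)
  L <- nchar(g)
  arrays <- find_tmr_arrays(g, motif = motif, min_copies = min_copies)
  gaps <- list()
  for (a in arrays) {
    mid <- (a$start + a$end) %/% 2L
    gs <- max(a$start, mid - gap_len %/% 2L)
    ge <- min(a$end, gs + gap_len - 1L)
    gaps[[length(gaps) + 1L]] <- c(gs, ge)
  }
  if (length(gaps) == 0L) {
    return(list(contigs = list(seq_record("contig_01", g, "dna")),
                gaps = data.frame(start = integer(), end = integer())))
  }
  gapdf <- do.call(rbind, gaps)
  gapdf <- data.frame(start = gapdf[, 1], end = gapdf[, 2])
  gapdf <- gapdf[order(gapdf$start), , drop = FALSE]
  bounds <- c(0L, as.vector(t(as.matrix(gapdf))), L + 1L)
  contigs <- list()
  k <- 0L
  for (i in seq(1L, length(bounds) - 1L, by = 2L)) {
    cs <- bounds[i] + 1L
    ce <- bounds[i + 1L] - 1L
    if (ce >= cs) {
      k <- k + 1L
      contigs[[k]] <- seq_record(sprintf("contig_%02d", k),
                                 substr(g, cs, ce), "dna",
                                 sprintf("genome:%d-%d", cs, ce))
    }
  }
  list(contigs = contigs, gaps = gapdf)
}

#' Write read pairs to a pair of FASTQ files
#'
#' Phred+33 qualities, constant quality (Q40, `"I"`) by default.
#'
#' @param pairs Data frame from [simulate_reads()].
#' @param prefix Output prefix; writes `<prefix>_1.fastq`,
#'   `<prefix>_2.fastq`.
#' @param quality_char Single quality character applied to every base.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(pairs, prefix, quality_char = "I") {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    reads <- pairs[[paste0("read", m)]]
    xs <- Biostrings::DNAStringSet(reads)
    names(xs) <- paste0(pairs$id, "/", m)
    qual <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
    Biostrings::writeXStringSet(xs, paths[m], format = "fastq",
                                qualities = qual)
  }
  invisible(paths)
}
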