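#' Detect telomeric repeat (TMR) arrays
#'
#' Finds maximal runs of a hexamer repeat family in a contig. A family is
#' the closure of the motif under rotation and reverse complement (the
#' telomere repeat is written interchangeably as TTAGGG, ATTGGG or TAACCC
#' depending on phase and strand); occurrences of any member count toward
#' the same array. Runs are merged while the spacing between consecutive
#' occurrences is at most `max_gap` bases, so isolated point mutations do
#' not split an array.
#'
#' @param contig DNA string or [seq_record].
#' @param motif Reference hexamer (default `"TTAGGG"`).
#' @param min_copies Minimum intact copies to report an array (default 3).
#' @param max_gap Maximum spacing (bp) between consecutive motif
#'   occurrences within one array (default 6, one motif unit).
#' @return List of `tmr_array` objects: each a list with `contig_id`,
#'   `start`, `end` (1-based inclusive), `motif` (canonical family
#'   representative), `variant` (most frequent observed hexamer),
#'   `orientation` (`"same"` or `"reverse-complement"` relative to
#'   `motif`), `copies` (maximal non-overlapping intact copies), `purity`
#'   (intact copies / hexamer windows spanned) and `sequence`.
#' @export
find_tmr_arrays <- function(contig, motif = "TTAGGG", min_copies = 3L,
                            max_gap = 6L) {
  stopifnot(nchar(motif) == 6L, min_copies >= 2L)
  s <- as_residues(contig)
  cid <- if (inherits(contig, "seq_record")) contig$id else "contig"
  fwd <- motif_rotations(motif)
  rev <- motif_rotations(revcomp(motif))
  occ <- list()
  for (v in unique(c(fwd, rev))) {
    m <- gregexpr(v, s, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) next
    occ[[v]] <- data.frame(start = as.integer(m), variant = v,
                           orient = if (v %in% fwd) "same"
                                    else "reverse-complement",
                           stringsAsFactors = FALSE)
  }
  if (length(occ) == 0L) return(list())
  occ <- do.call(rbind, occ)
  occ <- occ[order(occ$start), , drop = FALSE]

  # cluster occurrences into arrays: spacing between a copy end and the
  # next copy start must not exceed max_gap
  brk <- c(TRUE, occ$start[-1L] - (occ$start[-nrow(occ)] + 6L) > max_gap)
  grp <- cumsum(brk)
  out <- list()
  for (g in unique(grp)) {
    o <- occ[grp == g, , drop = FALSE]
    a_start <- min(o$start)
    a_end <- max(o$start) + 5L
    # maximal non-overlapping intact copies (greedy left-to-right)
    copies <- 0L
    nxt <- a_start
    for (i in seq_len(nrow(o))) {
      if (o$start[i] >= nxt) {
        copies <- copies + 1L
        nxt <- o$start[i] + 6L
      }
    }
    if (copies < min_copies || a_end - a_start + 1L < 12L) next
    windows <- (a_end - a_start + 1L) %/% 6L
    tab <- sort(table(o$variant), decreasing = TRUE)
    dom <- names(tab)[1L]
    out[[length(out) + 1L]] <- structure(list(
      contig_id = cid, start = a_start, end = a_end,
      motif = canonical_motif(motif), variant = dom,
      orientation = if (dom %in% fwd) "same" else "reverse-complement",
      copies = copies, purity = copies / windows,
      sequence = substr(s, a_start, a_end)), class = "tmr_array")
  }
  out
}

# lexicographically smallest representative over rotations of both strands
canonical_motif <- function(motif) min(motif_family(motif))

#' Orientation of a TMR array relative to a reference motif
#'
#' Rotations of a motif are the same repeat in a different phase; only a
#' strand flip changes orientation. Returns the array's strand relative to
#' the reference.
#'
#' @param array A `tmr_array` from [find_tmr_arrays()].
#' @param reference_motif Hexamer to compare against.
#' @return `"same"` or `"reverse-complement"`.
#' @export
motif_orientation <- function(array, reference_motif) {
  stopifnot(inherits(array, "tmr_array"), nchar(reference_motif) == 6L)
  v <- array$variant
  if (v %in% motif_rotations(reference_motif)) return("same")
  if (v %in% motif_rotations(revcomp(reference_motif)))
    return("reverse-complement")
  stop("array motif is not in the rotation/strand closure of the reference")
}

#' Call host/virus junctions at TMR arrays
#'
#' A junction is called at every TMR array that cleanly separates a side
#' carrying viral translated hits from a side carrying host evidence and no
#' viral hits. The junction coordinate is placed at the array edge nearest
#' the viral side (the junction is the array, not a base pair; the edge is
#' where unique viral sequence begins).
#'
#' @param contig DNA string or [seq_record].
#' @param arrays List of `tmr_array` from [find_tmr_arrays()].
#' @param viral_hits Data frame from [translated_search()] (rows for this
#'   contig; `s_start`/`s_end` 0-based half-open).
#' @param host_evidence Data frame with `start`, `end` (1-based inclusive):
#'   intervals with host support (positional truth in simulation, or
#'   user-supplied annotation on real contigs).
#' @return List of `junction_call` objects, sorted by the gap between the
#'   mediating array and its host evidence (the outermost junction — the
#'   first array past the host — comes first). Each is a list: `contig_id`,
#'   `coordinate` (1-based), `virus_side` (`"left"`/`"right"`), `array`
#'   (the mediating `tmr_array`), `viral_hit_ids` (row indices of
#'   supporting hits), `host_interval`, `host_gap` (bp between array and
#'   nearest host evidence on the host side).
#' @export
call_junction <- function(contig, arrays, viral_hits, host_evidence) {
  cid <- if (inherits(contig, "seq_record")) contig$id else "contig"
  if (length(arrays) == 0L) return(list())
  if (nrow(viral_hits) == 0L || nrow(host_evidence) == 0L) return(list())
  h_start <- viral_hits$s_start + 1L
  h_end <- viral_hits$s_end
  out <- list()
  for (a in arrays) {
    viral_left <- which(h_end < a$start)
    viral_right <- which(h_start > a$end)
    if (length(viral_left) + length(viral_right) < nrow(viral_hits))
      next   # a hit straddles the array: no clean separation
    host_left <- host_evidence[host_evidence$end < a$start, , drop = FALSE]
    host_right <- host_evidence[host_evidence$start > a$end, , drop = FALSE]
    if (length(viral_right) > 0L && length(viral_left) == 0L &&
        nrow(host_left) > 0L) {
      # host | array | virus: junction at the array's right edge
      out[[length(out) + 1L]] <- structure(list(
        contig_id = cid, coordinate = a$end, virus_side = "right",
        array = a, viral_hit_ids = viral_right, host_interval = host_left,
        host_gap = a$start - max(host_left$end) - 1L),
        class = "junction_call")
    } else if (length(viral_left) > 0L && length(viral_right) == 0L &&
               nrow(host_right) > 0L) {
      # virus | array | host: junction at the array's left edge
      out[[length(out) + 1L]] <- structure(list(
        contig_id = cid, coordinate = a$start, virus_side = "left",
        array = a, viral_hit_ids = viral_left, host_interval = host_right,
        host_gap = min(host_right$start) - a$end - 1L),
        class = "junction_call")
    }
  }
  if (length(out) > 1L)
    out <- out[order(vapply(out, `[[`, numeric(1), "host_gap"))]
  out
}

#' Best terminal overlap between two contigs
#'
#' Semi-global (ends-free) alignment between the terminal windows of two
#' contigs, testing suffix(A)/prefix(B), suffix(B)/prefix(A) and both with
#' B reverse-complemented. Reports the best overlap that touches the
#' required termini, is at least `min_len` aligned columns long and meets
#' the identity floor.
#'
#' @param contigA,contigB DNA strings or [seq_record]s.
#' @param min_len Minimum overlap length in alignment columns
#'   (at least 20).
#' @param min_identity Identity floor over the overlap (default 0.8).
#' @param tail_len Terminal window searched on each contig.
#' @param match,mismatch,gap_open,gap_extend Nucleotide scoring.
#' @return An `overlap_alignment` (list: `a_id`, `b_id`, `length`,
#'   `mismatches`, `gaps`, `orientation` `"forward"`/`"revcomp"`,
#'   `arrangement` e.g. `"A-then-B"`, `score`) or `NULL` when no
#'   qualifying overlap exists.
#' @export
terminal_overlap <- function(contigA, contigB, min_len = 30L,
                             min_identity = 0.8, tail_len = 2000L,
                             match = 2, mismatch = -3, gap_open = 5,
                             gap_extend = 2) {
  stopifnot(min_len >= 20L)
  a <- as_residues(contigA)
  b <- as_residues(contigB)
  aid <- if (inherits(contigA, "seq_record")) contigA$id else "A"
  bid <- if (inherits(contigB, "seq_record")) contigB$id else "B"
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  combos <- list(
    list(x = tail_str(a, tail_len), y = head_str(b, tail_len),
         orientation = "forward", arrangement = "A-then-B"),
    list(x = tail_str(b, tail_len), y = head_str(a, tail_len),
         orientation = "forward", arrangement = "B-then-A"),
    list(x = tail_str(a, tail_len), y = head_str(revcomp(b), tail_len),
         orientation = "revcomp", arrangement = "A-then-B"),
    list(x = tail_str(revcomp(b), tail_len), y = head_str(a, tail_len),
         orientation = "revcomp", arrangement = "B-then-A"))
  best <- NULL
  for (cb in combos) {
    al <- Biostrings::pairwiseAlignment(cb$x, cb$y, type = "overlap",
                                        substitutionMatrix = mat,
                                        gapOpening = gap_open,
                                        gapExtension = gap_extend)
    pr <- Biostrings::pattern(al)
    sr <- Biostrings::subject(al)
    cols <- Biostrings::nchar(al)
    if (cols < min_len) next
    # a true suffix/prefix overlap reaches the end of x and the start of y
    if (IRanges::end(pr@range) < nchar(cb$x) - 5L) next
    if (IRanges::start(sr@range) > 6L) next
    nmis <- Biostrings::nmismatch(al)
    ngap <- sum(Biostrings::nindel(al)@insertion[, "WidthSum"],
                Biostrings::nindel(al)@deletion[, "WidthSum"])
    ident <- (cols - nmis - ngap) / cols
    if (ident < min_identity) next
    cand <- structure(list(a_id = aid, b_id = bid, length = cols,
                           mismatches = nmis, gaps = ngap,
                           orientation = cb$orientation,
                           arrangement = cb$arrangement,
                           score = Biostrings::score(al)),
                      class = "overlap_alignment")
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

tail_str <- function(s, n) substr(s, max(1L, nchar(s) - n + 1L), nchar(s))
head_str <- function(s, n) substr(s, 1L, min(n, nchar(s)))

#' Export TMR arrays and junction calls
#'
#' Arrays as BED (0-based half-open) and the full report as JSON.
#'
#' @param arrays List of `tmr_array`.
#' @param junctions List of `junction_call`.
#' @param bed_path,json_path Output files (either may be NULL to skip).
#' @return Invisibly, the list written to JSON.
#' @export
export_junction_report <- function(arrays, junctions, bed_path = NULL,
                                   json_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(
      chrom = vapply(arrays, `[[`, character(1), "contig_id"),
      start = vapply(arrays, `[[`, numeric(1), "start") - 1,
      end = vapply(arrays, `[[`, numeric(1), "end"),
      name = vapply(arrays, function(a)
        sprintf("TMR:%s:%s", a$variant, a$orientation), character(1)),
      score = round(1000 * vapply(arrays, `[[`, numeric(1), "purity")),
      strand = ifelse(vapply(arrays, `[[`, character(1), "orientation")
                      == "same", "+", "-"))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  rep <- list(
    arrays = lapply(arrays, function(a)
      a[c("contig_id", "start", "end", "motif", "variant", "orientation",
          "copies", "purity")]),
    junctions = lapply(junctions, function(j)
      list(contig_id = j$contig_id, coordinate = j$coordinate,
           virus_side = j$virus_side,
           array = j$array[c("start", "end", "variant", "orientation")])))
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(rep)
}
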