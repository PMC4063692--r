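#' k-mer index over a read library
#'
#' Indexes every k-mer of both mates of every pair, on both strands, for
#' the edge-extension search. Postings resolve to (read, offset, strand).
#'
#' @param pairs Data frame from [simulate_reads()] (columns `id`, `read1`,
#'   `read2`), or any data frame with those columns.
#' @param k k-mer size; at least 8 (shorter seeds match spuriously).
#' @return Object of class `read_index`: list with `k`, `reads` (named
#'   character vector, names `<pair>/1`, `<pair>/2`), `postings`
#'   (data frame: `read` (index into `reads`), `offset` (1-based in the
#'   oriented read), `strand`), `lookup` (kmer -> posting row ids).
#' @export
index_reads <- function(pairs, k = 21L) {
  if (k < 8L) stop("k below 8 rejected: spurious matching")
  reads <- c(pairs$read1, pairs$read2)
  names(reads) <- c(paste0(pairs$id, "/1"), paste0(pairs$id, "/2"))
  if (any(nchar(reads) < k)) stop("k exceeds a read length")
  n <- length(reads)
  all_kmers <- character(0)
  post_read <- integer(0)
  post_off <- integer(0)
  post_strand <- character(0)
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") reads else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads)))
    lens <- nchar(oriented)
    for (i in seq_len(n)) {
      m <- lens[i] - k + 1L
      all_kmers <- c(all_kmers, substring(oriented[i], 1:m, k:(k + m - 1L)))
      post_read <- c(post_read, rep.int(i, m))
      post_off <- c(post_off, 1:m)
      post_strand <- c(post_strand, rep.int(strand, m))
    }
  }
  postings <- data.frame(read = post_read, offset = post_off,
                         strand = post_strand, stringsAsFactors = FALSE)
  lookup <- split(seq_len(nrow(postings)), all_kmers)
  structure(list(k = as.integer(k), reads = reads, postings = postings,
                 lookup = lookup),
            class = "read_index")
}

oriented_read <- function(index, read_i, strand) {
  r <- index$reads[[read_i]]
  if (strand == "+") r else revcomp(r)
}

#' Retrieve reads containing a k-mer
#' @param index A [read_index()].
#' @param kmer A k-mer of the index's k.
#' @return The matching posting rows (possibly empty).
#' @export
query_index <- function(index, kmer) {
  ids <- index$lookup[[kmer]]
  if (is.null(ids))
    return(index$postings[0L, , drop = FALSE])
  index$postings[ids, , drop = FALSE]
}

#' Iteratively extend one contig edge with read-pair support
#'
#' Per iteration, reads overlapping the current edge by at least
#' `min_overlap` bases with at most `max_mismatch_frac` mismatches are
#' anchored by exact k-mers (mates of anchored reads join the candidate
#' pool, which is what makes the search mate-pair aware); the edge is then
#' extended by the column-wise majority of overhanging bases while support
#' stays at or above `min_support`. Extension stops deterministically on
#' ambiguity (two disagreeing bases each with sufficient support),
#' exhaustion, or `max_iter`.
#'
#' @param contig DNA string or [seq_record].
#' @param side `"right"` or `"left"`.
#' @param index A [read_index()].
#' @param min_overlap Minimum verified read/contig overlap, bp (at least
#'   the index k).
#' @param min_support Minimum reads supporting every appended base.
#' @param max_mismatch_frac Maximum mismatch fraction in the verified
#'   overlap.
#' @param max_iter Iteration cap.
#' @param max_append Cap on total appended bases (default 500, about one
#'   to two insert sizes: targeted extension needs to reach into a
#'   neighbouring contig, not to walk the template).
#' @return Object of class `contig_extension`: list with `contig_id`,
#'   `side`, `appended` (sequence to splice onto that side, forward
#'   orientation), `support` (per-appended-base read depth), `iterations`,
#'   `termination` (`"ambiguous"`, `"exhausted"` or `"max-iterations"`).
#' @export
extend_edge <- function(contig, side = c("right", "left"), index,
                        min_overlap = 30L, min_support = 3L,
                        max_mismatch_frac = 0.02, max_iter = 50L,
                        max_append = 500L) {
  side <- match.arg(side)
  stopifnot(min_overlap >= index$k)
  cid <- if (inherits(contig, "seq_record")) contig$id else "contig"
  s <- as_residues(contig)
  work <- if (side == "right") s else revcomp(s)
  appended <- character(0)
  support <- integer(0)
  termination <- "max-iterations"
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    step <- extend_right_once(work, index, min_overlap, min_support,
                              max_mismatch_frac)
    if (nchar(step$appended) > 0L) {
      iterations <- it
      work <- paste0(work, step$appended)
      appended <- c(appended, step$appended)
      support <- c(support, step$support)
    }
    if (step$stop != "continue") { termination <- step$stop; break }
    if (nchar(step$appended) == 0L) { termination <- "exhausted"; break }
    if (sum(nchar(appended)) >= max_append) {
      termination <- "max-iterations"
      break
    }
  }
  app <- paste(appended, collapse = "")
  if (side == "left" && nchar(app) > 0L) {
    app <- revcomp(app)
    support <- rev(support)
  }
  structure(list(contig_id = cid, side = side, appended = app,
                 support = support, iterations = iterations,
                 termination = termination),
            class = "contig_extension")
}

# one extension step at the right edge of `work`
extend_right_once <- function(work, index, min_overlap, min_support,
                              max_mismatch_frac) {
  k <- index$k
  n <- nchar(work)
  read_len <- max(nchar(index$reads))
  # anchor k-mers across the terminal read-length window
  win_lo <- max(1L, n - read_len + 1L)
  anchors <- unique(substring(work, win_lo:(n - k + 1L),
                              (win_lo + k - 1L):n))
  cand <- list()
  seen <- character(0)
  for (a_i in seq_along(anchors)) {
    a_pos <- win_lo + a_i - 1L          # anchor start in work
    p <- query_index(index, anchors[a_i])
    if (nrow(p) == 0L) next
    for (r in seq_len(nrow(p))) {
      key <- paste0(p$read[r], p$strand[r], a_pos - p$offset[r])
      if (key %in% seen) next
      seen <- c(seen, key)
      cand[[length(cand) + 1L]] <- list(read = p$read[r],
                                        strand = p$strand[r],
                                        start = a_pos - p$offset[r] + 1L)
    }
  }
  # mate rescue: mates of anchored reads, tried at every feasible offset by
  # re-anchoring through the index on their own k-mers, are already covered
  # by the anchor scan; mates with no edge k-mer cannot be verified and are
  # not used for consensus.
  if (length(cand) == 0L)
    return(list(appended = "", support = integer(0), stop = "exhausted"))

  overhang <- list()
  depths <- integer(0)
  for (cd in cand) {
    r <- oriented_read(index, cd$read, cd$strand)
    rl <- nchar(r)
    ov_start <- max(1L, cd$start)
    ov_end <- min(n, cd$start + rl - 1L)
    ov_len <- ov_end - ov_start + 1L
    if (ov_len < min_overlap) next
    r_part <- substr(r, ov_start - cd$start + 1L, ov_end - cd$start + 1L)
    w_part <- substr(work, ov_start, ov_end)
    mism <- sum(utf8ToInt(r_part) != utf8ToInt(w_part))
    if (mism > max_mismatch_frac * ov_len) next
    if (cd$start + rl - 1L > n) {
      overhang[[length(overhang) + 1L]] <-
        chars(substr(r, n - cd$start + 2L, rl))
    }
  }
  if (length(overhang) == 0L)
    return(list(appended = "", support = integer(0), stop = "exhausted"))
  max_over <- max(lengths(overhang))
  out <- character(0)
  sup <- integer(0)
  for (j in seq_len(max_over)) {
    col <- vapply(overhang, function(o)
      if (length(o) >= j) o[j] else NA_character_, character(1))
    tab <- sort(table(col[!is.na(col)]), decreasing = TRUE)
    if (length(tab) == 0L || tab[1L] < min_support)
      return(list(appended = paste(out, collapse = ""), support = sup,
                  stop = if (length(out)) "continue" else "exhausted"))
    if (length(tab) > 1L && tab[2L] >= min_support)
      return(list(appended = paste(out, collapse = ""), support = sup,
                  stop = "ambiguous"))
    out <- c(out, names(tab)[1L])
    sup <- c(sup, as.integer(tab[1L]))
  }
  list(appended = paste(out, collapse = ""), support = sup,
       stop = "continue")
}

#' Link extended contig edges into composite contigs
#'
#' Joins an extended edge to another contig when their termini overlap by
#' at least `min_overlap` at the identity floor. A contig whose extended
#' sequence is wholly contained in another's (a short contig overshot by
#' its neighbour's extension) is absorbed into the container and listed
#' among its members. Conflicting joins (one edge, two partners) are left
#' unjoined and reported; circular chains are reported, not constructed.
#'
#' @param extensions List of `contig_extension` (both sides per contig, as
#'   produced by [scaffold_targeted()]).
#' @param contigs List of [seq_record].
#' @param min_overlap Minimum overlap, bp.
#' @param min_identity Identity floor over the overlap.
#' @return List with `composites` (list of `composite_contig`: `members`,
#'   `sequence`, `joins`), `conflicts` (data frame of edges with multiple
#'   partners), `circular` (ids involved in a circular chain, if any).
#' @export
link_contigs <- function(extensions, contigs, min_overlap = 30L,
                         min_identity = 0.95) {
  ids <- vapply(contigs, function(x) x$id, character(1))
  ext_seq <- stats::setNames(vapply(contigs, function(x) x$residues,
                                    character(1)), ids)
  for (e in extensions) {
    if (nchar(e$appended) == 0L) next
    ext_seq[e$contig_id] <- if (e$side == "right")
      paste0(ext_seq[e$contig_id], e$appended)
    else paste0(e$appended, ext_seq[e$contig_id])
  }
  # containment pass: absorb contigs overshot by a neighbour's extension
  contained_in <- stats::setNames(rep(NA_character_, length(ids)), ids)
  ord <- order(nchar(ext_seq), decreasing = TRUE)
  for (j in ord) for (i in ord) {
    if (i == j || !is.na(contained_in[ids[j]])) next
    if (is.na(contained_in[ids[i]]) &&
        nchar(ext_seq[[j]]) < nchar(ext_seq[[i]]) &&
        grepl(ext_seq[[j]], ext_seq[[i]], fixed = TRUE)) {
      contained_in[ids[j]] <- ids[i]
    }
  }
  live <- ids[is.na(contained_in)]
  absorbed <- split(names(contained_in)[!is.na(contained_in)],
                    contained_in[!is.na(contained_in)])

  n <- length(live)
  joins <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ov <- suffix_prefix_overlap(ext_seq[[live[i]]], ext_seq[[live[j]]],
                                min_overlap, min_identity)
    if (!is.null(ov))
      joins[[length(joins) + 1L]] <- data.frame(
        a = live[i], b = live[j], overlap = ov$length,
        mismatches = ov$mismatches, gaps = ov$gaps,
        stringsAsFactors = FALSE)
  }
  # expand a chain member into itself + contigs absorbed into it, ordered
  # by position within the container's extended sequence
  with_absorbed <- function(id) {
    inside <- absorbed[[id]]
    if (is.null(inside)) return(id)
    pos <- vapply(c(id, inside), function(m)
      regexpr(ext_seq[[m]], ext_seq[[id]], fixed = TRUE)[1L], numeric(1))
    names(sort(pos))
  }
  if (length(joins) == 0L)
    return(list(composites = lapply(live, function(i)
      composite_contig(with_absorbed(i), ext_seq[[i]], NULL)),
      conflicts = NULL, circular = character(0)))
  joins <- do.call(rbind, joins)
  # conflicts: an edge used by more than one join
  dup_a <- joins$a[duplicated(joins$a)]
  dup_b <- joins$b[duplicated(joins$b)]
  conflicts <- joins[joins$a %in% dup_a | joins$b %in% dup_b, , drop = FALSE]
  clean <- joins[!(joins$a %in% dup_a | joins$b %in% dup_b), , drop = FALSE]

  nxt <- stats::setNames(clean$b, clean$a)
  prv <- stats::setNames(clean$a, clean$b)
  circular <- character(0)
  composites <- list()
  used <- character(0)
  for (start in live) {
    if (start %in% used) next
    # walk back to the chain head
    head_id <- start
    steps <- 0L
    while (head_id %in% names(prv)) {
      head_id <- prv[[head_id]]
      steps <- steps + 1L
      if (steps > n) { circular <- union(circular, start); break }
    }
    if (start %in% circular) next
    chain <- head_id
    cur <- head_id
    while (cur %in% names(nxt)) {
      cur <- nxt[[cur]]
      if (cur %in% chain) { circular <- union(circular, chain); break }
      chain <- c(chain, cur)
    }
    if (any(chain %in% circular)) next
    if (any(chain %in% used)) next
    used <- c(used, chain)
    seqs <- ext_seq[chain]
    merged <- seqs[[1L]]
    jrows <- list()
    if (length(chain) > 1L) for (m in 2:length(chain)) {
      jr <- clean[clean$a == chain[m - 1L] & clean$b == chain[m], ,
                  drop = FALSE][1L, ]
      merged <- paste0(merged, substr(seqs[[m]], jr$overlap + 1L,
                                      nchar(seqs[[m]])))
      jrows[[length(jrows) + 1L]] <- jr
    }
    composites[[length(composites) + 1L]] <- composite_contig(
      unlist(lapply(chain, with_absorbed)), merged,
      if (length(jrows)) do.call(rbind, jrows) else NULL)
  }
  list(composites = composites,
       conflicts = if (nrow(conflicts)) conflicts else NULL,
       circular = circular)
}

composite_contig <- function(members, sequence, joins) {
  structure(list(members = members, sequence = sequence, joins = joins),
            class = "composite_contig")
}

# exact-ish suffix(a)/prefix(b) overlap by direct comparison at every
# candidate length (longest first); mismatch tolerance from min_identity
suffix_prefix_overlap <- function(a, b, min_overlap, min_identity) {
  max_len <- min(nchar(a), nchar(b))
  if (max_len < min_overlap) return(NULL)
  for (len in seq(max_len, min_overlap)) {
    sa <- substr(a, nchar(a) - len + 1L, nchar(a))
    sb <- substr(b, 1L, len)
    mism <- sum(utf8ToInt(sa) != utf8ToInt(sb))
    if (mism <= (1 - min_identity) * len)
      return(list(length = len, mismatches = mism, gaps = 0L))
  }
  NULL
}

#' Targeted scaffolding of candidate viral contigs
#'
#' Runs [extend_edge()] on both edges of every contig, then [link_contigs()].
#' When an expected gene order is supplied (with the proteins observed per
#' contig from the homology stage), joins contradicting that order are
#' demoted to "flagged" and not applied.
#'
#' @param contigs List of [seq_record].
#' @param pairs Read pairs (data frame, as [simulate_reads()]).
#' @param hint Optional ordered character vector of expected protein ids.
#' @param contig_proteins Optional named list: contig id -> protein ids
#'   observed on it (required for the hint to act).
#' @param k,min_overlap,min_support,max_mismatch_frac,min_identity,max_append
#'   Extension/link parameters.
#' @return List with `composites`, `extensions`, `flagged` (joins demoted
#'   by the hint), `conflicts`, `circular`.
#' @export
scaffold_targeted <- function(contigs, pairs, hint = NULL,
                              contig_proteins = NULL, k = 21L,
                              min_overlap = 30L, min_support = 3L,
                              max_mismatch_frac = 0.02,
                              min_identity = 0.95, max_append = 500L) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(list(composites = lapply(contigs, function(x)
      composite_contig(x$id, x$residues, NULL)),
      extensions = list(), flagged = NULL, conflicts = NULL,
      circular = character(0)))
  }
  index <- index_reads(pairs, k = k)
  extensions <- list()
  for (ct in contigs) for (side in c("left", "right")) {
    extensions[[length(extensions) + 1L]] <-
      extend_edge(ct, side, index, min_overlap = min_overlap,
                  min_support = min_support,
                  max_mismatch_frac = max_mismatch_frac,
                  max_append = max_append)
  }
  linked <- link_contigs(extensions, contigs, min_overlap = min_overlap,
                         min_identity = min_identity)
  flagged <- NULL
  if (!is.null(hint) && !is.null(contig_proteins)) {
    keep <- list()
    for (cc in linked$composites) {
      if (length(cc$members) < 2L || is.null(cc$joins)) {
        keep[[length(keep) + 1L]] <- cc
        next
      }
      ord <- unlist(lapply(cc$members, function(m)
        match(contig_proteins[[m]], hint)))
      ord <- ord[!is.na(ord)]
      if (length(ord) > 1L && is.unsorted(ord)) {
        flagged <- rbind(flagged, cc$joins)
        for (m in cc$members)   # demote: leave members unjoined
          keep[[length(keep) + 1L]] <- composite_contig(
            m, vapply(contigs, function(x) x$residues,
                      character(1))[vapply(contigs, function(x) x$id,
                                           character(1)) == m], NULL)
      } else {
        keep[[length(keep) + 1L]] <- cc
      }
    }
    linked$composites <- keep
  }
  list(composites = linked$composites, extensions = extensions,
       flagged = flagged, conflicts = linked$conflicts,
       circular = linked$circular)
}

#' Export composite contigs as FASTA plus a join-evidence JSON
#'
#' The JSON is an AGP-like join table: member, orientation, overlap and
#' support per join (coordinates 1-based inclusive).
#'
#' @param result Output of [scaffold_targeted()] or [link_contigs()].
#' @param fasta_path,json_path Output files (either may be NULL).
#' @return Invisibly, the evidence list.
#' @export
export_composites <- function(result, fasta_path = NULL, json_path = NULL) {
  seqs <- vapply(result$composites, `[[`, character(1), "sequence")
  names(seqs) <- vapply(result$composites, function(cc)
    paste(cc$members, collapse = "+"), character(1))
  if (!is.null(fasta_path)) write_fasta(seqs, fasta_path)
  ev <- lapply(result$composites, function(cc)
    list(members = cc$members, length = nchar(cc$sequence),
         joins = if (is.null(cc$joins)) list() else cc$joins))
  if (!is.null(json_path))
    jsonlite::write_json(ev, json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(ev)
}
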