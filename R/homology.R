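#' Scoring scheme for translated homology search
#'
#' Bundles the protein substitution matrix, affine gap penalties and the
#' Karlin–Altschul parameters used to convert raw local-alignment scores into
#' bit scores and E-values. Defaults are BLOSUM62 with gap open 11 /
#' extend 1 and the published ungapped Karlin–Altschul parameters for
#' BLOSUM62 (lambda = 0.3176, K = 0.134), which reproduce BLAST-like ranking
#' at the scale this pipeline operates on.
#'
#' @param matrix Substitution matrix (numeric, symmetric, with residue
#'   dimnames) or the name `"BLOSUM62"`.
#' @param gap_open,gap_extend Gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param lambda,K Karlin–Altschul parameters, both > 0.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.3176, K = 0.134) {
  if (is.character(matrix)) {
    name <- matrix
    matrix <- get_blosum62()
  } else {
    name <- "custom"
    if (!isTRUE(all.equal(matrix, t(matrix))))
      stop("substitution matrix must be symmetric")
  }
  stopifnot(lambda > 0, K > 0, gap_open >= 0, gap_extend >= 0)
  structure(list(name = name, matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

bit_score <- function(raw, scoring)
  (scoring$lambda * raw - log(scoring$K)) / log(2)

#' Consensus sequence from a protein cluster alignment
#'
#' Per column of the alignment, emits the plurality residue provided its
#' fraction among non-gap rows reaches `threshold`; otherwise `X`. Columns
#' that are all-gap are dropped. This is the consensus-query construction
#' used to seed the translated homology search.
#'
#' @param alignment Character vector (or list of [seq_record]) of aligned
#'   protein rows, equal lengths, gaps as `-`.
#' @param threshold Minimum plurality fraction in `[0.5, 1]`.
#' @param cluster_id Identifier for the resulting query.
#' @return Object of class `consensus_query`: list with `cluster_id`,
#'   `consensus` (amino-acid string) and `support` (per-column plurality
#'   fraction).
#' @export
build_consensus <- function(alignment, threshold = 0.5, cluster_id = "cluster") {
  if (is.list(alignment))
    alignment <- vapply(alignment, as_residues, character(1))
  if (length(alignment) == 0L) stop("empty alignment")
  alignment <- toupper(alignment)
  w <- unique(nchar(alignment))
  if (length(w) != 1L) stop("alignment rows must have equal length")
  stopifnot(threshold >= 0.5, threshold <= 1)
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  cols <- lapply(seq_len(w), function(j) mat[, j])
  res <- vapply(cols, function(col) {
    col <- col[col != "-" & col != "."]
    if (length(col) == 0L) return(NA_character_)
    tab <- sort(table(col), decreasing = TRUE)
    top <- tab[1L]
    # ties at the top never reach a strict plurality unless frac passes
    frac <- as.numeric(top) / length(col)
    tied <- sum(tab == top) > 1L
    if (frac >= threshold && (!tied || frac > 0.5)) names(top) else "X"
  }, character(1))
  sup <- vapply(cols, function(col) {
    col <- col[col != "-" & col != "."]
    if (length(col) == 0L) return(NA_real_)
    max(table(col)) / length(col)
  }, numeric(1))
  keep <- !is.na(res)
  structure(list(cluster_id = cluster_id,
                 consensus = paste(res[keep], collapse = ""),
                 support = sup[keep]),
            class = "consensus_query")
}

#' Six-frame translated local-alignment search
#'
#' Searches a protein query against the six-frame translations of a set of
#' DNA contigs with exhaustive affine-gap Smith–Waterman alignment (no
#' seeding heuristics). Per frame, non-overlapping locally optimal hits are
#' enumerated by iteratively masking the best hit and re-aligning, until the
#' raw score drops below `score_floor` or `max_hits_per_frame` is reached.
#' E-values follow Karlin–Altschul statistics,
#' `E = K * m * n * exp(-lambda * S)`, with `m` the query length and `n` the
#' total translated search-space length over all contigs and frames.
#'
#' @param query Protein string, [seq_record] or `consensus_query`.
#' @param contigs List of DNA [seq_record] (or named character vector).
#' @param scoring A [scoring_scheme].
#' @param score_floor Minimum raw score to report (default 30).
#' @param max_hits_per_frame Cap on masked re-alignments per frame.
#' @return A data frame of translated hits, one row per local alignment,
#'   sorted by E-value: `qseqid`, `sseqid`, `frame` (one of +1..+3, -1..-3),
#'   `s_start`/`s_end` (0-based half-open nucleotide interval on the forward
#'   strand), `q_start`/`q_end` (1-based amino-acid positions), `length`
#'   (alignment columns, amino acids), `pident`, `mismatch`, `gapopen`,
#'   `score` (raw), `bitscore`, `evalue`.
#' @export
translated_search <- function(query, contigs, scoring = scoring_scheme(),
                              score_floor = 30, max_hits_per_frame = 10L) {
  if (inherits(query, "consensus_query")) {
    qid <- query$cluster_id; qseq <- query$consensus
  } else if (inherits(query, "seq_record")) {
    qid <- query$id; qseq <- query$residues
  } else {
    qid <- "query"; qseq <- toupper(query)
  }
  if (nchar(qseq) == 0L) stop("empty query")
  contigs <- normalize_contigs(contigs)
  m <- nchar(qseq)

  # translated search-space size: all frames of all usable contigs
  frames_by_contig <- list()
  for (cid in names(contigs)) {
    if (nchar(contigs[[cid]]) < 3L) {
      warning(sprintf("contig %s shorter than 3 nt; skipped", cid))
      next
    }
    frames_by_contig[[cid]] <- six_frame_translate(contigs[[cid]])
  }
  n_space <- sum(vapply(frames_by_contig, function(fr) sum(nchar(fr)),
                        numeric(1)))

  rows <- list()
  for (cid in names(frames_by_contig)) {
    fr <- frames_by_contig[[cid]]
    L <- nchar(contigs[[cid]])
    for (fname in names(fr)) {
      pep <- fr[[fname]]
      if (nchar(pep) < 1L) next
      masked <- pep
      for (it in seq_len(max_hits_per_frame)) {
        al <- .sw_local(qseq, masked, scoring$matrix,
                        scoring$gap_open, scoring$gap_extend)
        if (al$score < score_floor || al$length == 0L) break
        nt <- frame_to_dna_coords(fname, al$sstart, al$send, L)
        rows[[length(rows) + 1L]] <- data.frame(
          qseqid = qid, sseqid = cid, frame = fname,
          s_start = nt[1] - 1L, s_end = nt[2],
          q_start = al$qstart, q_end = al$qend,
          length = al$length,
          pident = 100 * al$matches / al$length,
          mismatch = al$mismatches, gapopen = al$gapopen,
          score = al$score,
          bitscore = bit_score(al$score, scoring),
          evalue = scoring$K * m * n_space * exp(-scoring$lambda * al$score),
          stringsAsFactors = FALSE)
        # mask the hit's footprint and look for the next local optimum
        substr(masked, al$sstart, al$send) <-
          strrep("#", al$send - al$sstart + 1L)
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  out <- do.call(rbind, rows)
  out[order(out$evalue, -out$score), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(qseqid = character(), sseqid = character(), frame = character(),
             s_start = integer(), s_end = integer(), q_start = integer(),
             q_end = integer(), length = integer(), pident = numeric(),
             mismatch = integer(), gapopen = integer(), score = numeric(),
             bitscore = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

normalize_contigs <- function(contigs) {
  if (inherits(contigs, "seq_record")) contigs <- list(contigs)
  if (is.list(contigs)) {
    out <- vapply(contigs, as_residues, character(1))
    names(out) <- vapply(contigs, function(r)
      if (inherits(r, "seq_record")) r$id else "contig", character(1))
    if (any(names(out) == "contig"))
      names(out) <- make.unique(names(out), sep = "_")
    out
  } else {
    contigs <- toupper(contigs)
    if (is.null(names(contigs)))
      names(contigs) <- paste0("contig_", seq_along(contigs))
    contigs
  }
}

#' Shortlist filter for translated hits
#'
#' Hit-level quality filter: keep hits at least `min_len` aligned amino
#' acids long and significant at `max_evalue`. The published filter phrase
#' this implements is ambiguous about direction; the default discards
#' non-significant hits (E > `max_evalue`), the reading under which strong
#' hits survive. Set `direction = "discard_significant"` for the literal
#' opposite.
#'
#' @param min_len Minimum alignment length in amino acids (default 50).
#' @param max_evalue E-value cutoff (default 1e-10).
#' @param direction `"discard_nonsignificant"` (default) or
#'   `"discard_significant"`.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_len = 50L, max_evalue = 1e-10,
                          direction = c("discard_nonsignificant",
                                        "discard_significant")) {
  direction <- match.arg(direction)
  stopifnot(min_len >= 1, max_evalue > 0)
  structure(list(min_len = as.integer(min_len), max_evalue = max_evalue,
                 direction = direction),
            class = "filter_policy")
}

#' Apply a shortlist filter to translated hits
#'
#' @param hits Data frame from [translated_search()].
#' @param policy A [filter_policy].
#' @return The surviving rows of `hits`.
#' @export
shortlist_hits <- function(hits, policy = filter_policy()) {
  if (nrow(hits) == 0L) return(hits)
  keep_len <- hits$length >= policy$min_len
  keep_e <- if (policy$direction == "discard_nonsignificant")
    hits$evalue <= policy$max_evalue else hits$evalue > policy$max_evalue
  hits[keep_len & keep_e, , drop = FALSE]
}

#' Reciprocal best-hit classification of a candidate region
#'
#' Re-searches a candidate contig region against a viral and a non-viral
#' protein set and compares the best bit scores: a best non-viral hit marks
#' the region as a false positive (a host homologue of a viral protein).
#' Exact ties are never resolved silently toward "viral".
#'
#' @param region DNA string or [seq_record]: the candidate contig region.
#' @param viral_proteins,nonviral_proteins Lists of protein [seq_record]
#'   (or named character vectors); both non-empty.
#' @param scoring A [scoring_scheme].
#' @param score_floor Raw-score floor passed to the search.
#' @return Object of class `reciprocal_call`: list with `verdict` (one of
#'   `"viral"`, `"false-positive"`, `"ambiguous"`), `best_viral` and
#'   `best_nonviral` (each `list(id, bitscore)` or NULL).
#' @export
reciprocal_classify <- function(region, viral_proteins, nonviral_proteins,
                                scoring = scoring_scheme(), score_floor = 25) {
  if (length(viral_proteins) == 0L || length(nonviral_proteins) == 0L)
    stop("both protein databases must be non-empty")
  region <- normalize_contigs(list_or_single(region))
  best_of <- function(db) {
    db <- normalize_proteins(db)
    best <- NULL
    for (pid in names(db)) {
      h <- translated_search(seq_record(pid, db[[pid]], "protein"),
                             region, scoring, score_floor = score_floor,
                             max_hits_per_frame = 1L)
      if (nrow(h) > 0L && (is.null(best) || h$bitscore[1] > best$bitscore))
        best <- list(id = pid, bitscore = h$bitscore[1])
    }
    best
  }
  bv <- best_of(viral_proteins)
  bn <- best_of(nonviral_proteins)
  verdict <- if (is.null(bv) && is.null(bn)) "ambiguous"
    else if (is.null(bn)) "viral"
    else if (is.null(bv)) "false-positive"
    else if (bv$bitscore > bn$bitscore) "viral"
    else if (bv$bitscore < bn$bitscore) "false-positive"
    else "ambiguous"
  structure(list(verdict = verdict, best_viral = bv, best_nonviral = bn),
            class = "reciprocal_call")
}

list_or_single <- function(x) if (inherits(x, "seq_record")) list(x) else x

normalize_proteins <- function(db) {
  if (inherits(db, "seq_record")) db <- list(db)
  if (is.list(db)) {
    out <- vapply(db, as_residues, character(1))
    names(out) <- vapply(db, function(r)
      if (inherits(r, "seq_record")) r$id else NA_character_, character(1))
    out
  } else {
    db <- toupper(db)
    if (is.null(names(db))) names(db) <- paste0("prot_", seq_along(db))
    db
  }
}

#' Export translated hits as BLAST-style tabular TSV
#'
#' Writes the standard 12 BLAST outfmt-6 columns plus a `frame` column.
#' Subject coordinates are converted to 1-based inclusive, as in BLAST
#' output.
#'
#' @param hits Data frame from [translated_search()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_hits_tsv <- function(hits, path) {
  tab <- data.frame(qseqid = hits$qseqid, sseqid = hits$sseqid,
                    pident = round(hits$pident, 2), length = hits$length,
                    mismatch = hits$mismatch, gapopen = hits$gapopen,
                    qstart = hits$q_start, qend = hits$q_end,
                    sstart = hits$s_start + 1L, send = hits$s_end,
                    evalue = signif(hits$evalue, 3),
                    bitscore = round(hits$bitscore, 1),
                    frame = hits$frame)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
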