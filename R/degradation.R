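#' Profile the coding integrity of a viral-like region
#'
#' Measures how far a contig region has drifted from protein-coding
#' capacity against a reference protein: translated local alignments are
#' collected in all six frames and chained along the region; every
#' transition between chained segments in different frames counts as one
#' frameshift, and stop codons inside aligned segments (or inside
#' same-frame gaps between segments) count as premature stops. A terminal
#' stop — beyond the last reference-aligned residue — is never premature.
#'
#' @param contig DNA string or [seq_record] (the candidate region).
#' @param reference Protein [seq_record] (or string) to profile against.
#' @param scoring A [scoring_scheme].
#' @param score_floor Raw-score floor for the underlying search.
#' @param covered_threshold Minimum covered fraction of the reference for
#'   the `intact` flag (default 0.9).
#' @return Object of class `orf_report`: list with `reference_id`,
#'   `premature_stops`, `frameshifts`, `covered_fraction`, `intact`,
#'   `segments` (chained hits data frame).
#' @export
profile_orf_integrity <- function(contig, reference,
                                  scoring = scoring_scheme(),
                                  score_floor = 25,
                                  covered_threshold = 0.9) {
  ref_id <- if (inherits(reference, "seq_record")) reference$id else "ref"
  ref_seq <- as_residues(reference)
  hits <- translated_search(reference, normalize_contigs(
    list_or_single(contig)), scoring, score_floor = score_floor,
    max_hits_per_frame = 10L)
  if (nrow(hits) == 0L) {
    return(structure(list(reference_id = ref_id, premature_stops = 0L,
                          frameshifts = 0L, covered_fraction = 0,
                          intact = FALSE, segments = empty_hits()),
                     class = "orf_report"))
  }
  # restrict to the majority strand, then chain greedily by score with
  # non-redundant query coverage
  strand <- substr(hits$frame, 1L, 1L)
  strand_score <- tapply(hits$score, strand, sum)
  hits <- hits[strand == names(which.max(strand_score)), , drop = FALSE]
  hits <- hits[order(-hits$score), , drop = FALSE]
  chain <- integer(0)
  for (i in seq_len(nrow(hits))) {
    qs <- hits$q_start[i]; qe <- hits$q_end[i]
    redundant <- FALSE
    for (j in chain) {
      ov <- min(qe, hits$q_end[j]) - max(qs, hits$q_start[j]) + 1L
      if (ov > 0.5 * (qe - qs + 1L)) { redundant <- TRUE; break }
    }
    if (!redundant) chain <- c(chain, i)
  }
  seg <- hits[chain, , drop = FALSE]
  seg <- seg[order(seg$q_start), , drop = FALSE]

  frameshifts <- if (nrow(seg) < 2L) 0L else
    sum(seg$frame[-1L] != seg$frame[-nrow(seg)])

  cseq <- as_residues(if (inherits(contig, "seq_record")) contig$residues
                      else contig)
  frames <- six_frame_translate(cseq)
  L <- nchar(cseq)
  stops <- 0L
  for (i in seq_len(nrow(seg))) {
    stops <- stops + count_stops_in_hit(seg[i, ], frames, L)
    if (i > 1L && seg$frame[i] == seg$frame[i - 1L]) {
      # same-frame gap between chained segments: stops there are internal
      stops <- stops + count_stops_between(seg[i - 1L, ], seg[i, ],
                                           frames, L)
    }
  }
  covered <- sum(pmin(seg$q_end, nchar(ref_seq)) - seg$q_start + 1L) /
    nchar(ref_seq)
  covered <- min(covered, 1)
  structure(list(reference_id = ref_id, premature_stops = stops,
                 frameshifts = frameshifts, covered_fraction = covered,
                 intact = stops == 0L && frameshifts == 0L &&
                   covered >= covered_threshold,
                 segments = seg),
            class = "orf_report")
}

# aa interval of a hit within its frame's peptide, from forward-strand nt
hit_aa_interval <- function(hit, L) {
  off <- as.integer(substr(hit$frame, 2L, 2L))
  if (substr(hit$frame, 1L, 1L) == "+") {
    nt1 <- hit$s_start + 1L; nt2 <- hit$s_end
  } else {
    nt1 <- L - hit$s_end + 1L; nt2 <- L - hit$s_start
  }
  c((nt1 - off) %/% 3L + 1L, (nt2 + 1L - off) %/% 3L)
}

count_stops_in_hit <- function(hit, frames, L) {
  iv <- hit_aa_interval(hit, L)
  pep <- substr(frames[[hit$frame]], iv[1L], iv[2L])
  sum(chars(pep) == "*")
}

count_stops_between <- function(h1, h2, frames, L) {
  iv1 <- hit_aa_interval(h1, L); iv2 <- hit_aa_interval(h2, L)
  lo <- min(iv1[2L], iv2[2L]) + 1L
  hi <- max(iv1[1L], iv2[1L]) - 1L
  if (hi < lo) return(0L)
  pep <- substr(frames[[h1$frame]], lo, hi)
  sum(chars(pep) == "*")
}

#' Classify contig provenance: endogenous-like vs exogenous-like
#'
#' Deterministic rule over the hallmarks of paleoviral sequence:
#' endogenous-like when a sufficient fraction of profiled ORFs is disrupted
#' (nonsense mutations / frameshifts) or a host-flank junction is present;
#' exogenous-like when there are no disruptions, no junction and no
#' transposable-element acquisition; ambiguous otherwise. TE acquisition is
#' an external annotation input, defaulting to absent.
#'
#' @param reports List of `orf_report` from [profile_orf_integrity()]
#'   (at least one).
#' @param junctions List of `junction_call` (may be empty).
#' @param te_flag TRUE if transposable-element acquisition was annotated.
#' @param disrupted_fraction Threshold D on the fraction of disrupted ORFs
#'   for the endogenous-like verdict (default 0.5).
#' @return Object of class `provenance_call`: list with `verdict`
#'   (`"endogenous-like"`, `"exogenous-like"` or `"ambiguous"`) and
#'   `evidence` (per-criterion values).
#' @export
classify_provenance <- function(reports, junctions, te_flag = FALSE,
                                disrupted_fraction = 0.5) {
  if (length(reports) == 0L) stop("at least one ORF report required")
  disrupted <- vapply(reports, function(r)
    r$premature_stops > 0L || r$frameshifts > 0L, logical(1))
  frac <- mean(disrupted)
  junction <- length(junctions) > 0L
  verdict <- if (frac >= disrupted_fraction || junction) "endogenous-like"
    else if (frac == 0 && !junction && !te_flag) "exogenous-like"
    else "ambiguous"
  structure(list(verdict = verdict,
                 evidence = list(disrupted_fraction = frac,
                                 n_orfs = length(reports),
                                 junction_present = junction,
                                 te_flag = te_flag,
                                 threshold = disrupted_fraction)),
            class = "provenance_call")
}

#' Export ORF degradation reports as TSV + JSON summary
#' @param reports List of `orf_report`.
#' @param call Optional `provenance_call` for the JSON summary.
#' @param tsv_path,json_path Output files (either may be NULL).
#' @return Invisibly, the TSV data frame.
#' @export
export_degradation_report <- function(reports, call = NULL,
                                      tsv_path = NULL, json_path = NULL) {
  tab <- data.frame(
    reference_id = vapply(reports, `[[`, character(1), "reference_id"),
    premature_stops = vapply(reports, `[[`, numeric(1), "premature_stops"),
    frameshifts = vapply(reports, `[[`, numeric(1), "frameshifts"),
    covered_fraction = round(vapply(reports, `[[`, numeric(1),
                                    "covered_fraction"), 4),
    intact = vapply(reports, `[[`, logical(1), "intact"))
  if (!is.null(tsv_path))
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path)) {
    out <- list(orfs = tab)
    if (!is.null(call)) out$provenance <- unclass(call)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(tab)
}
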