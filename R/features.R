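FEATURE_NAMES <- c(
  paste0("coverage_", c("mean", "median", "min", "max")),
  paste0("mono_", c("A", "C", "G", "T")),
  paste0("di_", as.vector(outer(c("A", "C", "G", "T"),
                                c("A", "C", "G", "T"), paste0))),
  paste0("insert_", c("mean", "median", "min", "max")))

#' Per-contig composition/coverage/insert feature vector
#'
#' The 28 variables used to ask whether candidate viral contigs are
#' compositional outliers: mean, median, minimum and maximum per-base
#' read coverage depth; the four mononucleotide and sixteen dinucleotide
#' frequencies (overlapping windows; N positions excluded); and the mean,
#' median, minimum and maximum insert size over properly placed pairs.
#'
#' @param contig DNA string or [seq_record] (length at least 2).
#' @param placements Data frame of aligned reads on this contig: columns
#'   `start`, `end` (1-based inclusive), `insert` (pair insert size, NA
#'   for improper pairs), `pair_id`. May be NULL / empty: insert fields
#'   are then NA and coverage 0.
#' @return Named numeric vector of length 28 (names stable across runs).
#' @export
contig_features <- function(contig, placements = NULL) {
  s <- as_residues(contig)
  L <- nchar(s)
  stopifnot(L >= 2L)
  x <- chars(s)
  mono <- table(factor(x, BASES))
  mono <- as.numeric(mono) / max(1, sum(mono))
  di_str <- paste0(x[-L], x[-1L])
  valid <- x[-L] %in% BASES & x[-1L] %in% BASES
  lv <- as.vector(outer(BASES, BASES, paste0))
  di <- table(factor(di_str[valid], lv))
  di <- as.numeric(di) / max(1, sum(di))
  if (is.null(placements) || nrow(placements) == 0L) {
    cov <- c(0, 0, 0, 0)
    ins <- rep(NA_real_, 4L)
  } else {
    # per-base depth via a difference array
    dd <- integer(L + 1L)
    st <- pmax(1L, placements$start)
    en <- pmin(L, placements$end)
    ok <- st <= en
    for (i in which(ok)) {
      dd[st[i]] <- dd[st[i]] + 1L
      dd[en[i] + 1L] <- dd[en[i] + 1L] - 1L
    }
    depth <- cumsum(dd[seq_len(L)])
    cov <- c(mean(depth), stats::median(depth), min(depth), max(depth))
    pp <- placements[!is.na(placements$insert), , drop = FALSE]
    pp <- pp[!duplicated(pp$pair_id), , drop = FALSE]
    ins <- if (nrow(pp) == 0L) rep(NA_real_, 4L) else
      c(mean(pp$insert), stats::median(pp$insert), min(pp$insert),
        max(pp$insert))
  }
  stats::setNames(c(cov, mono, di, ins), FEATURE_NAMES)
}

#' Place simulated read pairs on a contig interval
#'
#' Truth-based placement for synthetic data: maps pairs whose reads fall
#' inside the contig's genome interval to contig coordinates. A pair is
#' proper (insert recorded) when both mates are inside.
#'
#' @param pairs Data frame from [simulate_reads()].
#' @param contig_start,contig_end Genome interval of the contig (1-based
#'   inclusive).
#' @param read_len Read length used in the simulation.
#' @return Placements data frame for [contig_features()].
#' @export
place_reads_on_contig <- function(pairs, contig_start, contig_end,
                                  read_len = 100L) {
  r1s <- pairs$start; r1e <- pairs$start + read_len - 1L
  r2s <- pairs$end - read_len + 1L; r2e <- pairs$end
  in1 <- r1s >= contig_start & r1e <= contig_end
  in2 <- r2s >= contig_start & r2e <= contig_end
  proper <- in1 & in2
  rows <- list()
  add <- function(sel, rs, re) {
    if (!any(sel)) return(NULL)
    data.frame(pair_id = pairs$id[sel],
               start = rs[sel] - contig_start + 1L,
               end = re[sel] - contig_start + 1L,
               insert = ifelse(proper[sel], pairs$insert[sel], NA_real_),
               stringsAsFactors = FALSE)
  }
  out <- rbind(add(in1, r1s, r1e), add(in2, r2s, r2e))
  if (is.null(out))
    out <- data.frame(pair_id = character(), start = integer(),
                      end = integer(), insert = numeric())
  out
}

#' PCA over contig feature vectors
#'
#' Eigen-decomposition of the covariance (or correlation, when
#' standardized) of complete feature rows. Rows with missing values
#' (e.g. contigs with no aligned pairs) are excluded and reported.
#' Zero-variance features are centred but not rescaled.
#'
#' @param features Matrix or data frame, rows = contigs (rownames = ids),
#'   columns = the 28 features.
#' @param standardize Scale features to unit variance (default TRUE; the
#'   features mix frequency- and bp-scale units).
#' @return Object of class `contig_pca`: list with `loadings`, `scores`,
#'   `var_explained` (fractions summing to 1), `center`, `scale`,
#'   `excluded` (ids of dropped rows).
#' @export
contig_pca <- function(features, standardize = TRUE) {
  X <- as.matrix(features)
  if (nrow(X) < 2L) stop("need at least 2 contigs")
  complete <- stats::complete.cases(X)
  excluded <- rownames(X)[!complete]
  X <- X[complete, , drop = FALSE]
  if (nrow(X) < 2L) stop("fewer than 2 complete rows")
  sds <- apply(X, 2L, stats::sd)
  if (sum(sds > 0) < 2L) stop("fewer than 2 non-constant features")
  if (all(sds == 0)) stop("zero variance: all rows identical")
  ctr <- colMeans(X)
  scl <- if (standardize) ifelse(sds > 0, sds, 1) else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  pr <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(loadings = pr$rotation, scores = pr$x,
                 var_explained = ve, center = ctr, scale = scl,
                 excluded = excluded),
            class = "contig_pca")
}

#' Permutation assessment of flagged contigs in PC space
#'
#' Tests whether a flagged group (e.g. candidate viral contigs) clusters
#' away from the bulk on the first two principal components: the statistic
#' is the Euclidean distance between the flagged-group centroid and the
#' overall centroid, compared against a label-permutation null. This makes
#' the qualitative "do the viral contigs sit apart?" question testable; it
#' is a diagnostic, not a formal compositional test.
#'
#' @param pca A `contig_pca` from [contig_pca()].
#' @param flagged_ids Row ids (rownames of the score matrix) to test.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed.
#' @return List of class `outlier_report`: `statistic` (centroid
#'   distance), `p_value` (NA for a single flagged contig), `n_flagged`,
#'   `n_perm`, `per_contig` (distance of each flagged contig from the
#'   overall centroid).
#' @export
outlier_assessment <- function(pca, flagged_ids, n_perm = 999L,
                               seed = NULL) {
  sc <- pca$scores[, 1:2, drop = FALSE]
  if (!all(flagged_ids %in% rownames(sc)))
    stop("flagged ids must be scored contigs")
  if (!is.null(seed)) set.seed(seed)
  ctr <- colMeans(sc)
  flag <- rownames(sc) %in% flagged_ids
  per <- sqrt(rowSums(sweep(sc[flag, , drop = FALSE], 2L, ctr)^2))
  if (sum(flag) < 2L) {
    return(structure(list(statistic = unname(per[1L]), p_value = NA_real_,
                          n_flagged = sum(flag), n_perm = 0L,
                          per_contig = per),
                     class = "outlier_report"))
  }
  stat <- sqrt(sum((colMeans(sc[flag, , drop = FALSE]) - ctr)^2))
  nf <- sum(flag)
  perm <- replicate(n_perm, {
    idx <- sample.int(nrow(sc), nf)
    sqrt(sum((colMeans(sc[idx, , drop = FALSE]) - ctr)^2))
  })
  p <- (1 + sum(perm >= stat)) / (n_perm + 1)
  structure(list(statistic = stat, p_value = p, n_flagged = nf,
                 n_perm = n_perm, per_contig = per),
            class = "outlier_report")
}

#' Export features and PCA results as TSV
#' @param features Feature matrix (rows = contigs).
#' @param pca Optional `contig_pca`.
#' @param features_path,scores_path,loadings_path Output TSVs (any may be
#'   NULL).
#' @return Invisibly TRUE.
#' @export
export_features_tsv <- function(features, pca = NULL,
                                features_path = NULL, scores_path = NULL,
                                loadings_path = NULL) {
  wr <- function(x, path)
    utils::write.table(data.frame(id = rownames(x), x,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(features_path)) wr(as.matrix(features), features_path)
  if (!is.null(pca)) {
    if (!is.null(scores_path)) wr(pca$scores, scores_path)
    if (!is.null(loadings_path)) wr(pca$loadings, loadings_path)
  }
  invisible(TRUE)
}
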