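#' Copy number of each unclassified consensus in the genome annotation
#'
#' Copies are counted over resolved (post-trim) genome hits. Low-copy
#' unclassified consensus sequences are the segmental-duplication
#' candidates; high-copy ones are novel/partial TE candidates.
#'
#' @param annotation resolved GRanges from [annotateGenome()].
#' @param cons unclassified [ConsensusSet-class] (see
#'   [unclassifiedConsensus()]).
#' @return data.frame with consensus_id, length, copies (one row per
#'   consensus; zero-copy records included).
#' @export
copyNumberTable <- function(annotation, cons) {
  ids <- consensusInfo(cons)$family_id
  counts <- table(as.character(mcols(annotation)$query_id))
  copies <- as.integer(counts[ids])
  copies[is.na(copies)] <- 0L
  data.frame(consensus_id = ids,
             length = Biostrings::width(consensusSequences(cons)),
             copies = copies, stringsAsFactors = FALSE)
}

#' Log-log regression of copy number on consensus length
#'
#' Ordinary least squares of log10(copies) on log10(length); zero-copy
#' records are excluded (the transform is undefined for them) and reported
#' via `n_zero`.
#'
#' @param records data.frame from [copyNumberTable()].
#' @return list with slope, intercept, slope_se, intercept_se, t values,
#'   p values, n, n_zero and the fitted lm object.
#' @export
loglogRegression <- function(records) {
  usable <- records[records$copies >= 1L, , drop = FALSE]
  if (nrow(usable) < 3L)
    stop("need >= 3 records with copies >= 1 for the regression")
  fit <- stats::lm(log10(copies) ~ log10(length), data = usable)
  # a degenerate exact fit (zero residuals) is legitimate here
  s <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(s[2, 1]), intercept = unname(s[1, 1]),
       slope_se = unname(s[2, 2]), intercept_se = unname(s[1, 2]),
       t_value = unname(s[, 3]), p_value = unname(s[, 4]),
       n = nrow(usable), n_zero = sum(records$copies == 0L), fit = fit)
}

#' Positional coverage of genome hits along a consensus
#'
#' Depth of resolved genome hits per consensus position, plus coverage
#' peaks: maximal runs with depth >= `peak_frac` of the maximum and at least
#' `min_peak_bp` wide. A single peak spanning essentially the whole
#' consensus is the "uniform high coverage" pattern of a novel TE; localised
#' peaks point to a high-copy subsequence inside a lower-copy consensus.
#'
#' @param cons_id consensus id.
#' @param cons_length consensus length (bp).
#' @param annotation resolved GRanges carrying `query_id`, `q_start`, `q_end`.
#' @param peak_frac fraction of the maximum depth defining a peak.
#' @param min_peak_bp minimum peak width.
#' @return list with consensus_id, depth (integer vector) and peaks
#'   (data.frame start, end, max_depth).
#' @export
coverageProfile <- function(cons_id, cons_length, annotation,
                            peak_frac = 0.5, min_peak_bp = 30L) {
  h <- annotation[mcols(annotation)$query_id == cons_id]
  depth <- integer(cons_length)
  if (length(h)) {
    qs <- pmax(1L, mcols(h)$q_start)
    qe <- pmin(cons_length, mcols(h)$q_end)
    ok <- qs <= qe
    cov <- IRanges::coverage(IRanges(qs[ok], qe[ok]), width = cons_length)
    depth <- as.integer(cov)
  }
  peaks <- data.frame(start = integer(), end = integer(),
                      max_depth = integer())
  if (max(depth) > 0L) {
    thr <- peak_frac * max(depth)
    r <- rle(depth >= thr)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sel <- which(r$values & r$lengths >= min_peak_bp)
    if (length(sel))
      peaks <- data.frame(start = starts[sel], end = ends[sel],
                          max_depth = vapply(sel, function(k)
                            max(depth[starts[k]:ends[k]]), integer(1)))
  }
  list(consensus_id = cons_id, depth = depth, peaks = peaks)
}

#' Separate segmental-duplication candidates from high-copy TE candidates
#'
#' Unclassified consensus sequences at or below `high_copy_threshold`
#' resolved genome hits are segmental-duplication candidates (SDs are
#' intrinsically low copy); those strictly above it go to high-copy review
#' as novel or partial TE candidates, with coverage profiles attached.
#'
#' @param records data.frame from [copyNumberTable()].
#' @param annotation resolved GRanges (for the coverage profiles).
#' @param high_copy_threshold strict threshold (copies > threshold reviews).
#' @param peak_frac,min_peak_bp see [coverageProfile()].
#' @return list with data.frames `sd_candidates`, `high_copy_review` and
#'   list `profiles` (one [coverageProfile()] per reviewed consensus).
#' @export
triageUnclassified <- function(records, annotation = NULL,
                               high_copy_threshold = 2000L,
                               peak_frac = 0.5, min_peak_bp = 30L) {
  hi <- records$copies > high_copy_threshold
  profiles <- list()
  if (!is.null(annotation) && any(hi)) {
    profiles <- lapply(which(hi), function(i)
      coverageProfile(records$consensus_id[i], records$length[i],
                      annotation, peak_frac, min_peak_bp))
    names(profiles) <- records$consensus_id[hi]
  }
  list(sd_candidates = records[!hi, , drop = FALSE],
       high_copy_review = records[hi, , drop = FALSE],
       profiles = profiles)
}

#' Scatter plot of copy number against length (log-log) with the fitted line
#'
#' @param records data.frame from [copyNumberTable()].
#' @param reg optional result of [loglogRegression()].
#' @param ... passed to [plot()].
#' @return invisibly, NULL.
#' @export
plotCopyNumber <- function(records, reg = NULL, ...) {
  usable <- records[records$copies >= 1L, , drop = FALSE]
  plot(log10(usable$length), log10(usable$copies),
       xlab = "log10 consensus length (bp)", ylab = "log10 copy number",
       pch = 19, col = "#00000080", ...)
  if (!is.null(reg)) graphics::abline(reg$intercept, reg$slope, col = "red")
  invisible(NULL)
}

#' Coverage plot for one consensus
#'
#' @param profile result of [coverageProfile()].
#' @param ... passed to [plot()].
#' @return invisibly, NULL.
#' @export
plotCoverage <- function(profile, ...) {
  plot(seq_along(profile$depth), profile$depth, type = "l",
       xlab = "consensus position (bp)", ylab = "hit depth",
       main = profile$consensus_id, ...)
  if (nrow(profile$peaks))
    graphics::rect(profile$peaks$start, 0, profile$peaks$end,
                   max(profile$depth), col = "#ff000020", border = NA)
  invisible(NULL)
}
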