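#' Seed chains from genome self-comparison
#'
#' Enumerates exact shared k-mers between genome positions (both
#' orientations, excluding the self-diagonal and k-mers containing N) and
#' groups them into chains by (sequence pair, orientation, diagonal bucket),
#' splitting chains at along-diagonal gaps larger than `max_gap`.
#' This is the seeding stage of [selfAlign()]; exposed for inspection.
#'
#' @param genome DNAStringSet.
#' @param params [AlignerParams-class].
#' @return data.frame of chains with 1-based closed coordinates on the
#'   concatenated genome plus `nseeds`, `orientation` and diagonal range.
#' @export
findSeedChains <- function(genome, params = alignerParams()) {
  cat <- .catGenome(genome)
  ch <- cpp_self_seed_chains(cat$seq, params@seed_k, params@band_width,
                             params@max_gap, params@max_occ_pairs,
                             1L, 0, 0L)
  ch$orientation <- ifelse(ch$orient == 0L, "same", "opposite")
  ch
}

# chain-level gates applied before banded extension; a true alignment of
# min_length at min_identity carries ~min_identity^k seeds per column, so a
# chain must reach that seed count (times the safety factor) before it is
# worth extending - this is what keeps pairs of anciently diverged copies
# from flooding the extension stage
.chainMinSeeds <- function(params) {
  dens <- params@chain_density_frac * params@min_identity^params@seed_k
  max(params@min_chain_seeds,
      as.integer(ceiling(dens * (params@min_length - params@seed_k + 1))))
}

.filterChains <- function(ch, params) {
  if (nrow(ch) == 0L) return(ch)
  span <- pmax(ch$a_end - ch$a_start, ch$b_end - ch$b_start)
  dens <- ch$nseeds / pmax(span - params@seed_k + 1, 1)
  min_dens <- params@chain_density_frac * params@min_identity^params@seed_k
  keep <- ch$nseeds >= .chainMinSeeds(params) &
    dens >= min_dens &
    (span + 2 * params@flank) >= params@min_length
  ch[keep, , drop = FALSE]
}

# merge chains of the same locus pair that were split across diagonal
# buckets (indel drift) or along-diagonal gaps, so one extension window
# covers the whole alignment
.mergeChains <- function(ch, params) {
  if (nrow(ch) < 2L) return(ch)
  gr <- GRanges(as.character(ch$orient),
                IRanges(ch$a_start + 1, pmax(ch$a_end, ch$a_start + 1)))
  h <- findOverlaps(gr, maxgap = params@max_gap, drop.self = TRUE,
                    drop.redundant = TRUE)
  if (length(h)) {
    q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
    # same diagonal neighbourhood (within one band) on the same orientation
    dgap <- pmax(ch$d_min[q], ch$d_min[s]) - pmin(ch$d_max[q], ch$d_max[s])
    keep <- dgap <= params@band_width
    q <- q[keep]; s <- s[keep]
  } else q <- integer(0)
  if (length(q) == 0L) return(ch)
  g <- igraph::graph_from_edgelist(cbind(q, s), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(ch) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  sp <- split(seq_len(nrow(ch)), comp)
  agg <- function(f, col) vapply(sp, function(ix) f(ch[[col]][ix]), numeric(1))
  data.frame(a_start = agg(min, "a_start"), a_end = agg(max, "a_end"),
             b_start = agg(min, "b_start"), b_end = agg(max, "b_end"),
             d_min = agg(min, "d_min"), d_max = agg(max, "d_max"),
             nseeds = as.integer(agg(sum, "nseeds")),
             orient = as.integer(agg(min, "orient")))
}

# build a RepeatAlignments object from a raw extension table (0-based
# half-open coordinates on the concatenated genome)
.alignmentsFromRaw <- function(al, cat) {
  empty <- function() new("RepeatAlignments",
    first = GRanges(), second = GRanges(),
    stats = DataFrame(identity = numeric(), score = integer(),
                      matches = integer(), columns = integer(),
                      orientation = character()))
  if (nrow(al) == 0L) return(empty())
  la <- .catToLocal(cat, al$a_start, al$a_end)
  lb <- .catToLocal(cat, al$b_start, al$b_end)
  ok <- !is.na(la$seqnames) & !is.na(lb$seqnames)
  al <- al[ok, , drop = FALSE]; la <- la[ok, , drop = FALSE]; lb <- lb[ok, , drop = FALSE]
  if (nrow(al) == 0L) return(empty())
  # canonical order: first image lexicographically smaller
  swap <- la$seqnames > lb$seqnames |
    (la$seqnames == lb$seqnames & la$start > lb$start)
  tmp <- la[swap, ]; la[swap, ] <- lb[swap, ]; lb[swap, ] <- tmp
  grA <- GRanges(la$seqnames, IRanges(la$start, la$end))
  grB <- GRanges(lb$seqnames, IRanges(lb$start, lb$end))
  # discard alignments whose two images overlap each other (tandem/self)
  selfov <- as.character(seqnames(grA)) == as.character(seqnames(grB)) &
    start(grA) <= end(grB) & start(grB) <= end(grA)
  keep <- !selfov
  grA <- grA[keep]; grB <- grB[keep]; al <- al[keep, , drop = FALSE]
  new("RepeatAlignments", first = grA, second = grB,
      stats = DataFrame(identity = al$identity, score = as.integer(al$score),
                        matches = as.integer(al$matches),
                        columns = as.integer(al$columns),
                        orientation = ifelse(al$orient == 0L, "same", "opposite")))
}

# collapse duplicate/overlapping alignments of the same locus pair,
# keeping the highest-scoring one
.dedupAlignments <- function(aln, min_frac = 0.5) {
  n <- length(aln)
  if (n < 2L) return(aln)
  hA <- findOverlaps(aln@first, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hA)) {
    fr <- .overlapFrac(aln@first, hA)
    hA <- hA[fr >= min_frac]
  }
  if (length(hA) == 0L) return(aln)
  # among a-overlapping pairs, require b images to overlap too (same pair
  # of loci) and same orientation
  q <- S4Vectors::queryHits(hA); s <- S4Vectors::subjectHits(hA)
  bq <- aln@second[q]; bs <- aln@second[s]
  inter <- pmin(end(bq), end(bs)) - pmax(start(bq), start(bs)) + 1L
  okb <- as.character(seqnames(bq)) == as.character(seqnames(bs)) &
    inter >= min_frac * pmin(width(bq), width(bs)) &
    aln@stats$orientation[q] == aln@stats$orientation[s]
  q <- q[okb]; s <- s[okb]
  if (length(q) == 0L) return(aln)
  g <- igraph::graph_from_edgelist(cbind(q, s), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  sc <- aln@stats$score
  keep <- vapply(split(seq_len(n), comp[seq_len(n)]), function(ix)
    ix[which.max(sc[ix])], integer(1))
  aln[sort(unname(keep))]
}

#' All-vs-all local self-alignment of a genome
#'
#' Seed-and-extend self-comparison: exact k-mer seeds are chained by
#' diagonal, chains are extended by banded affine-gap local dynamic
#' programming, and alignments are reported when identity (matches over all
#' alignment columns, gaps included) reaches `min_identity` and both images
#' reach `min_length`. Duplicate alignments of a locus pair are collapsed to
#' the highest-scoring one; alignments whose two images overlap each other
#' (tandem self-overlap) are discarded, keeping the focus on dispersed
#' repeat families. Deterministic given input and parameters.
#'
#' @param genome DNAStringSet (e.g. from [readGenome()]).
#' @param params [AlignerParams-class]; defaults are 94% identity, 250 bp.
#' @param verbose report progress.
#' @return a [RepeatAlignments-class] object in canonical order.
#' @examples
#' set.seed(1)
#' bg <- paste(sample(c("A","C","G","T"), 6000, TRUE), collapse = "")
#' rep1 <- paste(sample(c("A","C","G","T"), 400, TRUE), collapse = "")
#' g <- Biostrings::DNAStringSet(c(chr1 = paste0(
#'   substr(bg, 1, 2000), rep1, substr(bg, 2001, 4000), rep1,
#'   substr(bg, 4001, 6000))))
#' selfAlign(g)   # one alignment, identity 1
#' @export
selfAlign <- function(genome, params = alignerParams(), verbose = FALSE) {
  stopifnot(is(genome, "DNAStringSet"))
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stop("empty genome")
  cat <- .catGenome(genome)
  ch <- cpp_self_seed_chains(cat$seq, params@seed_k, params@band_width,
                             params@max_gap, params@max_occ_pairs,
                             .chainMinSeeds(params),
                             params@chain_density_frac *
                               params@min_identity^params@seed_k,
                             0L)
  .msg(verbose, "seed chains: ", nrow(ch))
  ch <- .mergeChains(ch, params)
  ch <- .filterChains(ch, params)
  .msg(verbose, "chains after merge and density/length gates: ", nrow(ch))
  if (nrow(ch) == 0L) return(.alignmentsFromRaw(data.frame(), cat))
  al <- cpp_extend_self_chains(cat$seq, ch$a_start, ch$a_end, ch$b_start,
                               ch$b_end, ch$orient, ch$d_min, ch$d_max,
                               params@seed_k, params@band_width, params@flank,
                               params@match, params@mismatch, params@gap_open,
                               params@gap_extend, params@min_length,
                               params@min_identity)
  aln <- .alignmentsFromRaw(al, cat)
  aln <- .dedupAlignments(aln)
  .msg(verbose, "alignments reported: ", length(aln))
  ord <- order(as.character(seqnames(aln@first)), start(aln@first),
               as.character(seqnames(aln@second)), start(aln@second))
  aln[ord]
}

#' Banded local alignment of two sequences
#'
#' The extension primitive used by [selfAlign()] and [crossAlign()], exposed
#' directly: affine-gap Smith-Waterman restricted to a diagonal band.
#'
#' @param a,b character or DNAString; `a` is the query.
#' @param band diagonal band radius around the main diagonal (j - i = 0).
#' @param params [AlignerParams-class] supplying the scores.
#' @return list with score, matches, columns, identity and 1-based closed
#'   coordinates `a_start/a_end/b_start/b_end` (NULL if no positive-scoring
#'   alignment exists in the band).
#' @export
bandedAlign <- function(a, b, band = 32L, params = alignerParams()) {
  a <- as.character(a); b <- as.character(b)
  r <- cpp_banded_align(a, b, -band, band, params@match, params@mismatch,
                        params@gap_open, params@gap_extend)
  if (!r$ok) return(NULL)
  list(score = r$score, matches = r$matches, columns = r$columns,
       identity = r$matches / r$columns,
       a_start = r$a_start + 1L, a_end = r$a_end,
       b_start = r$b_start + 1L, b_end = r$b_end)
}

#' Align a set of query sequences against a genome
#'
#' Seed-and-extend alignment of each query (both orientations) against the
#' genome, used to annotate the genome with a repeat library at a relaxed
#' identity floor. The default floor of 0.80 deliberately sits below the
#' self-alignment threshold so that copies too diverged for family discovery
#' are still annotated.
#'
#' @param queries named DNAStringSet (consensus/reference library).
#' @param genome DNAStringSet.
#' @param params [AlignerParams-class]; see [annotationParams()] for the
#'   relaxed defaults.
#' @param verbose report progress.
#' @return GRanges of genome hits with metadata columns `query_id`,
#'   `q_start`, `q_end` (1-based closed span on the query's forward strand),
#'   `identity`, `score`; hit strand records orientation.
#' @export
crossAlign <- function(queries, genome, params = annotationParams(),
                       verbose = FALSE) {
  stopifnot(is(queries, "DNAStringSet"), is(genome, "DNAStringSet"))
  if (length(queries) == 0L) stop("empty query set")
  if (is.null(names(queries)) || anyDuplicated(names(queries)))
    stop("queries must have unique names")
  cat <- .catGenome(genome)
  res <- vector("list", length(queries))
  min_dens <- params@chain_density_frac * params@min_identity^params@seed_k
  for (qi in seq_along(queries)) {
    qs <- as.character(queries[[qi]])
    ch <- cpp_cross_seed_chains(qs, cat$seq, params@seed_k,
                                params@band_width, params@max_gap,
                                .chainMinSeeds(params), min_dens, 0L)
    if (nrow(ch) == 0L) next
    ch <- .mergeChains(ch, params)
    ch <- .filterChains(ch, params)
    if (nrow(ch) == 0L) next
    al <- cpp_extend_cross_chains(qs, cat$seq, ch$a_start, ch$a_end,
                                  ch$b_start, ch$b_end, ch$orient, ch$d_min,
                                  ch$d_max, params@seed_k, params@band_width,
                                  params@flank, params@match, params@mismatch,
                                  params@gap_open, params@gap_extend,
                                  params@min_length, params@min_identity)
    if (nrow(al) == 0L) next
    loc <- .catToLocal(cat, al$b_start, al$b_end)
    ok <- !is.na(loc$seqnames)
    al <- al[ok, , drop = FALSE]; loc <- loc[ok, , drop = FALSE]
    if (nrow(al) == 0L) next
    gr <- GRanges(loc$seqnames, IRanges(loc$start, loc$end),
                  strand = ifelse(al$orient == 0L, "+", "-"))
    mcols(gr) <- DataFrame(query_id = names(queries)[qi],
                           q_start = as.integer(al$a_start + 1L),
                           q_end = as.integer(al$a_end),
                           identity = al$identity,
                           score = as.integer(al$score))
    # collapse duplicate hits at the same genome locus for this query
    gr <- .dedupCrossHits(gr)
    res[[qi]] <- gr
    .msg(verbose, names(queries)[qi], ": ", length(gr), " hits")
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L)
    return(GRanges(query_id = character(), q_start = integer(),
                   q_end = integer(), identity = numeric(), score = integer()))
  out <- suppressWarnings(do.call(c, res))
  sort(out, ignore.strand = TRUE)
}

.dedupCrossHits <- function(gr, min_frac = 0.5) {
  if (length(gr) < 2L) return(gr)
  h <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE,
                    ignore.strand = TRUE)
  if (length(h)) h <- h[.overlapFrac(gr, h) >= min_frac]
  if (length(h) == 0L) return(gr)
  g <- igraph::graph_from_edgelist(
    cbind(S4Vectors::queryHits(h), S4Vectors::subjectHits(h)),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(gr) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  sc <- mcols(gr)$score
  keep <- vapply(split(seq_along(gr), comp[seq_along(gr)]), function(ix)
    ix[which.max(sc[ix])], integer(1))
  gr[sort(unname(keep))]
}

#' Relaxed aligner parameters for genome annotation
#'
#' Compared with [alignerParams()]: identity floor 0.80, shorter seeds
#' (k = 8) so diverged copies still seed, hits as short as 50 bp, and a
#' milder mismatch penalty so 80%-identity alignments score positively.
#'
#' @param min_identity,min_length,seed_k,... overrides passed to
#'   [alignerParams()].
#' @return an [AlignerParams-class].
#' @export
annotationParams <- function(min_identity = 0.80, min_length = 50L,
                             seed_k = 8L, ...) {
  alignerParams(min_identity = min_identity, min_length = min_length,
                seed_k = seed_k, mismatch = -1L, gap_open = -3L,
                gap_extend = -1L, min_chain_seeds = 3L,
                chain_density_frac = 0.2, max_gap = 100L, ...)
}

#' Write alignments as TSV
#'
#' @param aln [RepeatAlignments-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeAlignmentsTsv <- function(aln, path) {
  utils::write.table(as.data.frame(aln), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
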