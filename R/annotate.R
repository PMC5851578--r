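#' Fraction of a sequence covered by short tandem repeats
#'
#' Finds maximal tandem runs with unit length 1-6 bp, at least 4 unit copies
#' and at least 12 bp total, and returns the fraction of positions covered.
#' Used to drop simple-sequence-repeat consensus sequences.
#'
#' @param sequence character or DNAString.
#' @return covered fraction in [0, 1].
#' @examples
#' detectSsr("ACACACACACAC")  # 1.0
#' @export
detectSsr <- function(sequence) {
  s <- strsplit(as.character(sequence), "")[[1]]
  L <- length(s)
  if (L == 0L) stop("empty sequence")
  covered <- logical(L)
  for (u in 1:6) {
    if (L < max(12L, 4L * u)) next
    eq <- s[seq_len(L - u)] == s[(u + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= max(3L * u, 12L - u))
    for (h in hit) covered[starts[h]:(ends[h] + u)] <- TRUE
  }
  mean(covered)
}

# six-frame translation; returns AAStringSet (stops as '*') with frame info
.sixFrames <- function(seq) {
  dna <- Biostrings::DNAString(as.character(seq))
  rc <- Biostrings::reverseComplement(dna)
  out <- vector("list", 6L)
  info <- data.frame(strand = rep(c("+", "-"), each = 3L), frame = rep(1:3, 2L))
  for (i in 1:3) {
    for (st in 1:2) {
      src <- if (st == 1L) dna else rc
      n <- length(src)
      len <- ((n - i + 1L) %/% 3L) * 3L
      idx <- (st - 1L) * 3L + i
      out[[idx]] <- if (len >= 3L)
        suppressWarnings(Biostrings::translate(
          Biostrings::subseq(src, i, i + len - 1L), if.fuzzy.codon = "X"))
      else Biostrings::AAString("")
    }
  }
  list(prot = out, info = info)
}

#' Protein search of consensus sequences against a reference database
#'
#' Six-frame translation followed by local protein alignment (BLOSUM62,
#' affine gaps) against every database entry. Significance is an ungapped
#' Karlin-Altschul approximation (lambda = 0.318, K = 0.13) with search
#' space = query length x total database length.
#'
#' @param consensus named DNAStringSet.
#' @param protein_db AAStringSet (may be empty).
#' @param evalue_max report hits at or below this E-value.
#' @return data.frame with query_id, ref_id, frame, strand, score, evalue.
#' @export
searchProtein <- function(consensus, protein_db, evalue_max = 1e-5) {
  empty <- data.frame(query_id = character(), ref_id = character(),
                      frame = integer(), strand = character(),
                      score = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (length(protein_db) == 0L || length(consensus) == 0L) return(empty)
  db_total <- sum(Biostrings::width(protein_db))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  rows <- list()
  for (qi in seq_along(consensus)) {
    fr <- .sixFrames(consensus[[qi]])
    for (f in seq_len(6L)) {
      prot <- fr$prot[[f]]
      if (length(prot) < 10L) next
      # split at stops: local alignment cannot cross a stop codon anyway
      segs <- strsplit(as.character(prot), "*", fixed = TRUE)[[1]]
      segs <- segs[nchar(segs) >= 10L]
      if (length(segs) == 0L) next
      seg_set <- Biostrings::AAStringSet(segs)
      for (ri in seq_along(protein_db)) {
        best <- max(Biostrings::pairwiseAlignment(
          seg_set, protein_db[[ri]], type = "local",
          substitutionMatrix = B62, gapOpening = 11, gapExtension = 1,
          scoreOnly = TRUE))
        ev <- .kaEvalue(best, length(prot), db_total)
        if (ev <= evalue_max)
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = names(consensus)[qi],
            ref_id = names(protein_db)[ri], frame = fr$info$frame[f],
            strand = fr$info$strand[f], score = best, evalue = ev,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  # best frame per (query, ref)
  out <- out[order(out$query_id, out$ref_id, out$evalue), ]
  out[!duplicated(out[, c("query_id", "ref_id")]), ]
}

#' Clean a consensus set: drop SSRs and host protein-coding genes
#'
#' A consensus is removed when (a) short tandem repeats cover at least
#' `ssr_cov_max` of it, or (b) it hits the host protein database at the
#' E-value ceiling while having no hit in the retroviral/reverse-
#' transcriptase database - i.e. it looks like a bona fide host gene family,
#' not a mobile element. A consensus hitting both databases is retained.
#'
#' @param cons [ConsensusSet-class].
#' @param host_db,rt_db AAStringSet databases (either may be empty).
#' @param params [FilterParams-class].
#' @return the ConsensusSet with `removed` and `reason` filled in.
#' @export
filterConsensusSet <- function(cons, host_db = Biostrings::AAStringSet(),
                               rt_db = Biostrings::AAStringSet(),
                               params = filterParams()) {
  if (length(cons) == 0L) return(cons)
  seqs <- consensusSequences(cons)
  ssr <- vapply(seq_along(seqs), function(i) detectSsr(seqs[[i]]), numeric(1))
  host_hits <- searchProtein(seqs, host_db, params@protein_evalue_max)
  rt_hits <- searchProtein(seqs, rt_db, params@protein_evalue_max)
  has_host <- names(seqs) %in% host_hits$query_id
  has_rt <- names(seqs) %in% rt_hits$query_id
  removed <- ssr >= params@ssr_cov_max | (has_host & !has_rt)
  reason <- rep(NA_character_, length(seqs))
  reason[ssr >= params@ssr_cov_max] <- "ssr"
  reason[has_host & !has_rt & is.na(reason)] <- "host_protein"
  info <- consensusInfo(cons)
  info$removed <- removed
  info$reason <- reason
  info$ssr_fraction <- ssr
  initialize(cons, info = info)
}

#' @rdname filterConsensusSet
#' @param x a filtered ConsensusSet.
#' @return `keptConsensus()`: the subset not removed by cleaning.
#' @export
keptConsensus <- function(x) x[which(!consensusInfo(x)$removed)]

#' Classify consensus sequences against a TE reference library
#'
#' Nucleotide local-alignment hits of each consensus against the library are
#' computed at a relaxed identity floor; a consensus is `well_annotated`
#' when hits to a single reference family jointly cover at least
#' `well_annotated_cov_min` of it ("almost full length"), `partially
#' annotated` when some hit reaches `partial_hit_min_bp` but coverage stays
#' below the threshold, and `unannotated` otherwise. The partial and
#' unannotated sets together form the unclassified set handed to the
#' segmental-duplication analysis.
#'
#' @param cons [ConsensusSet-class] (typically after [filterConsensusSet()]).
#' @param te_library DNAStringSet from [readTeLibrary()] (may be empty).
#' @param params [FilterParams-class].
#' @param aln_params [AlignerParams-class] for the nucleotide search.
#' @return the ConsensusSet with `class`, `ref_family` and `ref_class`
#'   columns filled and per-consensus hit tables in the `hits` slot.
#' @export
classifyConsensus <- function(cons, te_library = Biostrings::DNAStringSet(),
                              params = filterParams(),
                              aln_params = annotationParams()) {
  if (length(cons) == 0L) return(cons)
  info <- consensusInfo(cons)
  info$class <- "unannotated"
  info$ref_family <- NA_character_
  info$ref_class <- NA_character_
  hits_list <- rep(list(NULL), length(cons))
  if (length(te_library) > 0L) {
    cls_map <- S4Vectors::metadata(te_library)$class
    if (is.null(cls_map))
      cls_map <- stats::setNames(rep("Unknown", length(te_library)),
                                 names(te_library))
    gr <- crossAlign(consensusSequences(cons), te_library, aln_params)
    if (length(gr)) {
      df <- data.frame(query_id = mcols(gr)$query_id,
                       ref_id = as.character(seqnames(gr)),
                       q_start = mcols(gr)$q_start, q_end = mcols(gr)$q_end,
                       identity = mcols(gr)$identity,
                       score = mcols(gr)$score, stringsAsFactors = FALSE)
      # NB: crossAlign treats the consensus as query; q_* is the span on
      # the consensus, seqnames the library entry
      for (i in seq_along(cons)) {
        qid <- info$family_id[i]
        h <- df[df$query_id == qid, , drop = FALSE]
        if (nrow(h) == 0L) next
        hits_list[[i]] <- h
        qlen <- Biostrings::width(consensusSequences(cons))[i]
        cov_by_ref <- vapply(split(h, h$ref_id), function(hh)
          sum(width(reduce(IRanges(hh$q_start, hh$q_end)))) / qlen,
          numeric(1))
        best_ref <- names(cov_by_ref)[which.max(cov_by_ref)]
        if (max(cov_by_ref) >= params@well_annotated_cov_min) {
          info$class[i] <- "well_annotated"
          info$ref_family[i] <- best_ref
          info$ref_class[i] <- unname(cls_map[best_ref])
        } else if (any(h$q_end - h$q_start + 1L >= params@partial_hit_min_bp)) {
          info$class[i] <- "partially_annotated"
          info$ref_family[i] <- best_ref
          info$ref_class[i] <- unname(cls_map[best_ref])
        }
      }
    }
  }
  initialize(cons, info = info, hits = hits_list)
}

#' @rdname classifyConsensus
#' @param x a classified ConsensusSet.
#' @return `unclassifiedConsensus()`: the partially annotated and
#'   unannotated consensus sequences (the segmental-duplication / novel-TE
#'   candidate pool).
#' @export
unclassifiedConsensus <- function(x) {
  x[which(!consensusInfo(x)$removed &
          consensusInfo(x)$class %in% c("partially_annotated", "unannotated"))]
}

#' Annotate a genome with a combined repeat library
#'
#' Aligns every library sequence (cleaned consensus set plus reference
#' library) against the genome at a relaxed identity floor, then resolves
#' overlapping hits best-hit-first: the higher-scoring hit wins, the loser
#' is trimmed to its largest non-overlapping piece and discarded when
#' trimmed below `min_keep_bp`.
#'
#' @param genome DNAStringSet.
#' @param library named DNAStringSet; `metadata(library)$class` may carry
#'   class labels.
#' @param params [AlignerParams-class] for the search (identity floor 0.80).
#' @param min_keep_bp discard hits trimmed below this length.
#' @param verbose report progress.
#' @return GRanges of resolved, non-overlapping hits with mcols `query_id`,
#'   `q_start`, `q_end`, `identity`, `score`, `ref_class`.
#' @export
annotateGenome <- function(genome, library, params = annotationParams(),
                           min_keep_bp = 30L, verbose = FALSE) {
  if (length(library) == 0L) stop("empty annotation library")
  gr <- crossAlign(library, genome, params, verbose = verbose)
  cls_map <- S4Vectors::metadata(library)$class
  if (is.null(cls_map))
    cls_map <- stats::setNames(rep("Unknown", length(library)), names(library))
  if (length(gr) == 0L) {
    mcols(gr)$ref_class <- character(0)
    return(gr)
  }
  mcols(gr)$ref_class <- unname(cls_map[mcols(gr)$query_id])
  .resolveOverlaps(gr, min_keep_bp)
}

# best-hit-first overlap resolution with trimming
.resolveOverlaps <- function(gr, min_keep_bp = 30L) {
  if (length(gr) < 2L) return(gr)
  conflicts <- findOverlaps(gr, drop.self = TRUE, ignore.strand = TRUE)
  in_conflict <- unique(S4Vectors::queryHits(conflicts))
  free <- setdiff(seq_along(gr), in_conflict)
  ord <- in_conflict[order(-mcols(gr)$score[in_conflict],
                           start(gr)[in_conflict])]
  kept_idx <- integer(0)
  covered <- list()  # per-seqname IRanges of already-claimed bases
  keep_rows <- list()
  for (i in ord) {
    sn <- as.character(seqnames(gr))[i]
    r <- IRanges(start(gr)[i], end(gr)[i])
    cov <- covered[[sn]]
    rem <- if (is.null(cov)) r else IRanges::setdiff(r, cov)
    if (length(rem) == 0L) next
    w <- which.max(width(rem))
    piece <- rem[w]
    if (width(piece) < min_keep_bp) next
    # trim the query interval by the same amounts (orientation-aware)
    lead <- start(piece) - start(gr)[i]
    trail <- end(gr)[i] - end(piece)
    qs <- mcols(gr)$q_start[i]; qe <- mcols(gr)$q_end[i]
    if (as.character(strand(gr))[i] == "+") {
      qs <- qs + lead; qe <- qe - trail
    } else {
      qs <- qs + trail; qe <- qe - lead
    }
    row <- gr[i]
    start(row) <- start(piece); end(row) <- end(piece)
    mcols(row)$q_start <- qs; mcols(row)$q_end <- qe
    keep_rows[[length(keep_rows) + 1L]] <- row
    covered[[sn]] <- if (is.null(cov)) piece else
      IRanges::reduce(c(cov, piece))
  }
  out <- gr[free]
  if (length(keep_rows))
    out <- c(out, do.call(c, keep_rows))
  sort(out, ignore.strand = TRUE)
}

#' Summarise repeat content per TE class
#'
#' Coverage per coarse class (SINE, LINE, LTR, DNA, Other, Unclassified)
#' over the resolved genome annotation, as base pairs and percent of the
#' genome. Hits are non-overlapping after resolution, so classes sum to the
#' total interspersed repeat coverage with no double counting.
#'
#' @param annotation resolved GRanges from [annotateGenome()].
#' @param genome_length total genome length in bp.
#' @return data.frame with class, bp, percent.
#' @export
summarizeRepeatContent <- function(annotation, genome_length) {
  classes <- c("SINE", "LINE", "LTR", "DNA", "Other", "Unclassified")
  grp <- teClassGroup(mcols(annotation)$ref_class)
  grp[is.na(mcols(annotation)$ref_class) |
      mcols(annotation)$ref_class %in% c("Unknown", "unclassified")] <- "Unclassified"
  bp <- vapply(classes, function(cl)
    sum(width(annotation[grp == cl])), numeric(1))
  data.frame(class = classes, bp = as.numeric(bp),
             percent = 100 * bp / genome_length, row.names = NULL,
             stringsAsFactors = FALSE)
}
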