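#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits SimpleList metadata metadata<-
#' @importFrom IRanges IRanges findOverlaps pintersect reduce coverage
#' @importFrom GenomicRanges GRanges granges seqnames strand strand<- start end width ranges start<- end<-
#' @importFrom Biostrings DNAStringSet AAStringSet DNAString AAString
NULL

#' Parameters of the seed-and-extend self-aligner
#'
#' Thresholds and scores used by [selfAlign()] (and, with relaxed defaults,
#' by [crossAlign()]). The two headline gates mirror the classic
#' self-alignment interface: \code{min_identity} (\code{-dpid}) and
#' \code{min_length} (\code{-dplen}).
#'
#' @slot min_identity minimum alignment identity, matches / alignment columns
#'   (gap columns count in the denominator); fraction in (0, 1].
#' @slot min_length minimum length of both alignment images, in bases.
#' @slot seed_k exact seed k-mer length.
#' @slot band_width diagonal band radius for the banded extension, in bases.
#' @slot max_gap maximum along-diagonal gap between chained seeds.
#' @slot max_occ_pairs each seed position is paired with at most this many
#'   following occurrences of its k-mer; preserves single-linkage
#'   connectivity for high-copy repeats while bounding work.
#' @slot min_chain_seeds minimum seeds in a chain before extension.
#' @slot chain_density_frac a chain is extended only if its seed density is
#'   at least \code{chain_density_frac * min_identity^seed_k}; the expected
#'   density of exact k-mers at the identity floor times a safety factor.
#' @slot flank bases of context added around a chain before extension.
#' @slot match,mismatch,gap_open,gap_extend alignment scores.
#' @exportClass AlignerParams
setClass("AlignerParams", representation(
  min_identity = "numeric", min_length = "integer", seed_k = "integer",
  band_width = "integer", max_gap = "integer", max_occ_pairs = "integer",
  min_chain_seeds = "integer", chain_density_frac = "numeric",
  flank = "integer", match = "integer", mismatch = "integer",
  gap_open = "integer", gap_extend = "integer"))

setValidity("AlignerParams", function(object) {
  msg <- character()
  if (!(object@min_identity > 0 && object@min_identity <= 1))
    msg <- c(msg, "min_identity must be in (0, 1]")
  if (object@min_length < object@seed_k)
    msg <- c(msg, "min_length must be >= seed_k")
  if (object@band_width < 1) msg <- c(msg, "band_width must be >= 1")
  if (object@seed_k < 4 || object@seed_k > 14)
    msg <- c(msg, "seed_k must be in [4, 14]")
  if (object@chain_density_frac <= 0 || object@chain_density_frac > 1)
    msg <- c(msg, "chain_density_frac must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct aligner parameters
#'
#' Defaults follow the published self-alignment settings: 94% minimum
#' identity and 250 bp minimum alignment length. \code{min_identity} may be
#' given as a fraction (0.94) or a percentage (94).
#'
#' @param min_identity minimum identity as fraction or percent.
#' @param min_length minimum image length (bp).
#' @param seed_k seed k-mer length.
#' @param band_width diagonal band radius (bp).
#' @param max_gap maximum seed gap within a chain; default `2 * band_width`.
#' @param max_occ_pairs per-seed pairing cap.
#' @param min_chain_seeds minimum seeds per extended chain.
#' @param chain_density_frac seed-density safety factor.
#' @param flank extension context (bp).
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return an [AlignerParams-class] object.
#' @examples
#' alignerParams()                   # the defaults: 0.94 / 250 bp
#' alignerParams(min_identity = 90, min_length = 200)
#' @export
alignerParams <- function(min_identity = 0.94, min_length = 250L,
                          seed_k = 12L, band_width = 32L,
                          max_gap = 2L * band_width, max_occ_pairs = 100L,
                          min_chain_seeds = 4L, chain_density_frac = 0.25,
                          flank = 150L, match = 1L, mismatch = -2L,
                          gap_open = -4L, gap_extend = -1L) {
  if (min_identity > 1) min_identity <- min_identity / 100
  new("AlignerParams", min_identity = min_identity,
      min_length = as.integer(min_length), seed_k = as.integer(seed_k),
      band_width = as.integer(band_width), max_gap = as.integer(max_gap),
      max_occ_pairs = as.integer(max_occ_pairs),
      min_chain_seeds = as.integer(min_chain_seeds),
      chain_density_frac = chain_density_frac, flank = as.integer(flank),
      match = as.integer(match), mismatch = as.integer(mismatch),
      gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

#' Consensus cleaning and classification thresholds
#'
#' @slot protein_evalue_max E-value ceiling for protein hits used in the
#'   host-gene filter (default 1e-5).
#' @slot ssr_cov_max a consensus covered by short tandem repeats at or above
#'   this fraction is removed as a simple sequence repeat.
#' @slot well_annotated_cov_min minimum fraction of the consensus jointly
#'   covered by hits to one reference family to call it well annotated.
#' @slot partial_hit_min_bp minimum single-hit length for partial annotation.
#' @exportClass FilterParams
setClass("FilterParams", representation(
  protein_evalue_max = "numeric", ssr_cov_max = "numeric",
  well_annotated_cov_min = "numeric", partial_hit_min_bp = "integer"))

setValidity("FilterParams", function(object) {
  msg <- character()
  if (object@protein_evalue_max <= 0) msg <- c(msg, "protein_evalue_max must be > 0")
  if (object@ssr_cov_max <= 0 || object@ssr_cov_max > 1)
    msg <- c(msg, "ssr_cov_max must be in (0, 1]")
  if (object@well_annotated_cov_min <= 0 || object@well_annotated_cov_min > 1)
    msg <- c(msg, "well_annotated_cov_min must be in (0, 1]")
  if (object@partial_hit_min_bp < 1) msg <- c(msg, "partial_hit_min_bp must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname FilterParams-class
#' @param protein_evalue_max,ssr_cov_max,well_annotated_cov_min,partial_hit_min_bp
#'   see the class slots.
#' @return a [FilterParams-class] object.
#' @export
filterParams <- function(protein_evalue_max = 1e-5, ssr_cov_max = 0.8,
                         well_annotated_cov_min = 0.8,
                         partial_hit_min_bp = 50L) {
  new("FilterParams", protein_evalue_max = protein_evalue_max,
      ssr_cov_max = ssr_cov_max,
      well_annotated_cov_min = well_annotated_cov_min,
      partial_hit_min_bp = as.integer(partial_hit_min_bp))
}

#' Pairwise local self-alignments of a genome
#'
#' A parallel pair of [GenomicRanges::GRanges] holding the two images of
#' each reported alignment (both on the forward strand, stored once in
#' canonical order) plus per-alignment statistics.
#'
#' @slot first GRanges of the first (lexicographically smaller) images.
#' @slot second GRanges of the second images.
#' @slot stats DataFrame with columns \code{identity}, \code{score},
#'   \code{matches}, \code{columns}, \code{orientation} ("same"/"opposite").
#' @exportClass RepeatAlignments
setClass("RepeatAlignments", representation(
  first = "GRanges", second = "GRanges", stats = "DataFrame"))

setValidity("RepeatAlignments", function(object) {
  msg <- character()
  n <- length(object@first)
  if (length(object@second) != n || nrow(object@stats) != n)
    msg <- c(msg, "first, second and stats must have equal length")
  need <- c("identity", "score", "matches", "columns", "orientation")
  if (!all(need %in% colnames(object@stats)))
    msg <- c(msg, paste("stats must have columns:", paste(need, collapse = ", ")))
  else if (n > 0) {
    id <- object@stats$identity
    if (any(id <= 0 | id > 1)) msg <- c(msg, "identity must be in (0, 1]")
    if (!all(object@stats$orientation %in% c("same", "opposite")))
      msg <- c(msg, "orientation must be 'same' or 'opposite'")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RepeatAlignments-class number of alignments
#' @param x a RepeatAlignments object.
#' @export
setMethod("length", "RepeatAlignments", function(x) length(x@first))

#' @describeIn RepeatAlignments-class first images
#' @export
setGeneric("firstImage", function(x) standardGeneric("firstImage"))
#' @rdname RepeatAlignments-class
#' @export
setMethod("firstImage", "RepeatAlignments", function(x) x@first)

#' @describeIn RepeatAlignments-class second images
#' @export
setGeneric("secondImage", function(x) standardGeneric("secondImage"))
#' @rdname RepeatAlignments-class
#' @export
setMethod("secondImage", "RepeatAlignments", function(x) x@second)

#' @describeIn RepeatAlignments-class per-alignment statistics
#' @export
setGeneric("alignmentStats", function(x) standardGeneric("alignmentStats"))
#' @rdname RepeatAlignments-class
#' @export
setMethod("alignmentStats", "RepeatAlignments", function(x) x@stats)

#' @describeIn RepeatAlignments-class subset alignments
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "RepeatAlignments", function(x, i, j, ..., drop = TRUE) {
  new("RepeatAlignments", first = x@first[i], second = x@second[i],
      stats = x@stats[i, , drop = FALSE])
})

#' @describeIn RepeatAlignments-class flat table of alignments
#' @param row.names,optional passed through.
#' @export
setMethod("as.data.frame", "RepeatAlignments",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(
      seq_a = as.character(seqnames(x@first)), start_a = start(x@first),
      end_a = end(x@first), seq_b = as.character(seqnames(x@second)),
      start_b = start(x@second), end_b = end(x@second),
      orientation = x@stats$orientation, identity = x@stats$identity,
      score = x@stats$score, matches = x@stats$matches,
      columns = x@stats$columns, stringsAsFactors = FALSE)
  })

setMethod("show", "RepeatAlignments", function(object) {
  cat("RepeatAlignments with", length(object), "pairwise local alignments\n")
  if (length(object)) {
    cat(sprintf("  identity: %.3f-%.3f, image length: %d-%d bp\n",
                min(object@stats$identity), max(object@stats$identity),
                min(width(object@first), width(object@second)),
                max(width(object@first), width(object@second))))
    cat(sprintf("  orientation: %d same / %d opposite\n",
                sum(object@stats$orientation == "same"),
                sum(object@stats$orientation == "opposite")))
  }
})

#' Element instances and their single-linkage repeat families
#'
#' Instances are merged alignment images ("piles"); families are connected
#' components of the instance graph under "linked by an alignment". The
#' edge list is retained per family as the audit trail.
#'
#' @slot instances GRanges of element instances (strand = resolved family
#'   orientation) with metadata columns \code{instance_id} and
#'   \code{family_id} (\code{NA} for singletons not in any family).
#' @slot edges DataFrame with columns \code{from}, \code{to} (instance ids),
#'   \code{alignment_id} and \code{orientation}.
#' @slot alignments the [RepeatAlignments-class] the families were built from.
#' @exportClass RepeatFamilySet
setClass("RepeatFamilySet", representation(
  instances = "GRanges", edges = "DataFrame", alignments = "RepeatAlignments"))

setValidity("RepeatFamilySet", function(object) {
  msg <- character()
  mc <- mcols(object@instances)
  if (!all(c("instance_id", "family_id") %in% colnames(mc)))
    msg <- c(msg, "instances need instance_id and family_id columns")
  else {
    if (anyDuplicated(mc$instance_id))
      msg <- c(msg, "instance ids must be unique")
    fam <- mc$family_id[!is.na(mc$family_id)]
    if (length(fam) && any(table(fam) < 2))
      msg <- c(msg, "families must have >= 2 members")
    if (nrow(object@edges)) {
      known <- c(object@edges$from, object@edges$to) %in% mc$instance_id
      if (!all(known)) msg <- c(msg, "edges reference unknown instances")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RepeatFamilySet-class instance ranges
#' @param x a RepeatFamilySet.
#' @export
setGeneric("instanceRanges", function(x) standardGeneric("instanceRanges"))
#' @rdname RepeatFamilySet-class
#' @export
setMethod("instanceRanges", "RepeatFamilySet", function(x) x@instances)

#' @describeIn RepeatFamilySet-class audit-trail edge list
#' @export
setGeneric("familyEdges", function(x) standardGeneric("familyEdges"))
#' @rdname RepeatFamilySet-class
#' @export
setMethod("familyEdges", "RepeatFamilySet", function(x) x@edges)

#' @describeIn RepeatFamilySet-class family ids
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))
#' @rdname RepeatFamilySet-class
#' @export
setMethod("familyIds", "RepeatFamilySet", function(x) {
  sort(unique(mcols(x@instances)$family_id[!is.na(mcols(x@instances)$family_id)]))
})

#' @describeIn RepeatFamilySet-class member instances of one family
#' @export
setGeneric("familyMembers", function(x, family) standardGeneric("familyMembers"))
#' @rdname RepeatFamilySet-class
#' @param family a family id.
#' @export
setMethod("familyMembers", "RepeatFamilySet", function(x, family) {
  x@instances[!is.na(mcols(x@instances)$family_id) &
              mcols(x@instances)$family_id == family]
})

setMethod("show", "RepeatFamilySet", function(object) {
  ids <- familyIds(object)
  cat("RepeatFamilySet:", length(object@instances), "element instances,",
      length(ids), "families\n")
  if (length(ids)) {
    sizes <- table(mcols(object@instances)$family_id)
    cat("  family sizes:", paste(range(sizes), collapse = "-"),
        "| edges:", nrow(object@edges), "\n")
  }
})

#' Per-family consensus sequences with classification
#'
#' @slot sequences DNAStringSet of consensus sequences, named by family id.
#' @slot info DataFrame with one row per consensus: \code{family_id},
#'   \code{n_members}, \code{n_sampled}, \code{class} (one of
#'   \code{well_annotated}, \code{partially_annotated}, \code{unannotated}
#'   or \code{NA} before classification), \code{removed}, \code{reason}.
#' @slot samples list of sampled member instance ids, parallel to sequences.
#' @slot hits list of annotation-hit data frames, filled by classification.
#' @exportClass ConsensusSet
setClass("ConsensusSet", representation(
  sequences = "DNAStringSet", info = "DataFrame", samples = "list",
  hits = "list"))

setValidity("ConsensusSet", function(object) {
  n <- length(object@sequences)
  if (nrow(object@info) != n || length(object@samples) != n)
    return("sequences, info and samples must have equal length")
  need <- c("family_id", "n_members", "n_sampled", "class", "removed", "reason")
  if (!all(need %in% colnames(object@info)))
    return(paste("info needs columns:", paste(need, collapse = ", ")))
  cls <- object@info$class
  ok <- is.na(cls) | cls %in% c("well_annotated", "partially_annotated", "unannotated")
  if (!all(ok)) return("invalid class label")
  TRUE
})

#' @describeIn ConsensusSet-class number of consensus sequences
#' @param x a ConsensusSet.
#' @export
setMethod("length", "ConsensusSet", function(x) length(x@sequences))

#' @describeIn ConsensusSet-class the consensus sequences
#' @export
setGeneric("consensusSequences", function(x) standardGeneric("consensusSequences"))
#' @rdname ConsensusSet-class
#' @export
setMethod("consensusSequences", "ConsensusSet", function(x) x@sequences)

#' @describeIn ConsensusSet-class per-consensus metadata
#' @export
setGeneric("consensusInfo", function(x) standardGeneric("consensusInfo"))
#' @rdname ConsensusSet-class
#' @export
setMethod("consensusInfo", "ConsensusSet", function(x) x@info)

#' @describeIn ConsensusSet-class sampled member ids (audit trail)
#' @export
setGeneric("sampledMembers", function(x) standardGeneric("sampledMembers"))
#' @rdname ConsensusSet-class
#' @export
setMethod("sampledMembers", "ConsensusSet", function(x) x@samples)

#' @describeIn ConsensusSet-class subset
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ConsensusSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@info$family_id)
  new("ConsensusSet", sequences = x@sequences[i],
      info = x@info[i, , drop = FALSE], samples = x@samples[i],
      hits = if (length(x@hits)) x@hits[i] else x@hits)
})

setMethod("show", "ConsensusSet", function(object) {
  cat("ConsensusSet with", length(object), "consensus sequences\n")
  if (length(object)) {
    cat("  lengths:", paste(range(Biostrings::width(object@sequences)),
        collapse = "-"), "bp\n")
    cls <- object@info$class
    if (any(!is.na(cls))) {
      tab <- table(cls, useNA = "no")
      cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    }
    if (any(object@info$removed))
      cat("  removed by cleaning:", sum(object@info$removed), "\n")
  }
})
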