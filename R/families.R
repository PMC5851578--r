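#' Alignment images as a single GRanges
#'
#' Flattens a [RepeatAlignments-class] into its 2n images, keeping the link
#' back to the alignment each image came from.
#'
#' @param aln [RepeatAlignments-class].
#' @return GRanges with metadata columns `alignment_id` (index into `aln`)
#'   and `side` ("first"/"second").
#' @export
alignmentImages <- function(aln) {
  n <- length(aln)
  gr <- c(granges(aln@first), granges(aln@second))
  mcols(gr) <- DataFrame(alignment_id = rep(seq_len(n), 2L),
                         side = rep(c("first", "second"), each = n))
  gr
}

#' Merge alignment images into element instances (piles)
#'
#' Images are merged transitively into one instance whenever they overlap by
#' at least `min_overlap` of the shorter image; an instance's interval is
#' the union span of its member images. The default of 0.5 tolerates
#' boundary jitter between alignments of the same element while not chaining
#' adjacent distinct elements that merely touch.
#'
#' @param images GRanges of alignment images (see [alignmentImages()]).
#' @param min_overlap overlap fraction (of the shorter image) required to merge.
#' @return GRanges of instances with metadata columns `instance_id` and
#'   `image_ids` (an [IRanges::IntegerList] of indices into `images`).
#' @examples
#' im <- GenomicRanges::GRanges(c("c:100-399", "c:150-449"))
#' buildPiles(im)   # one instance c:100-449
#' @export
buildPiles <- function(images, min_overlap = 0.5) {
  if (length(images) == 0L)
    return(GRanges(instance_id = character(), image_ids = IRanges::IntegerList()))
  h <- findOverlaps(images, drop.self = TRUE, drop.redundant = TRUE,
                    ignore.strand = TRUE)
  if (length(h)) h <- h[.overlapFrac(images, h) >= min_overlap]
  g <- igraph::make_empty_graph(n = length(images), directed = FALSE)
  if (length(h))
    g <- igraph::add_edges(g, rbind(S4Vectors::queryHits(h),
                                    S4Vectors::subjectHits(h)))
  comp <- igraph::components(g)$membership
  # order instances by genomic position of their span for stable ids
  sp <- split(seq_along(images), comp)
  starts <- vapply(sp, function(ix) min(start(images)[ix]), integer(1))
  seqn <- vapply(sp, function(ix) as.character(seqnames(images))[ix[1]],
                 character(1))
  ord <- order(seqn, starts)
  sp <- sp[ord]
  inst <- GRanges(
    vapply(sp, function(ix) as.character(seqnames(images))[ix[1]], character(1)),
    IRanges(vapply(sp, function(ix) min(start(images)[ix]), integer(1)),
            vapply(sp, function(ix) max(end(images)[ix]), integer(1))))
  mcols(inst) <- DataFrame(instance_id = .padIds("inst", length(sp)),
                           image_ids = IRanges::IntegerList(unname(sp)))
  inst
}

# strand assignment by BFS over the family alignment graph: the lowest-id
# instance gets '+', an edge from a same-orientation alignment copies the
# strand, an opposite-orientation edge flips it; conflicts resolved
# first-visit-wins (deterministic)
.resolveStrands <- function(n_nodes, edges_from, edges_to, edge_same) {
  strand <- rep(NA, n_nodes)
  ne <- length(edges_from)
  adj <- vector("list", n_nodes)
  if (ne) {
    sp <- split(c(seq_len(ne), seq_len(ne)), c(edges_from, edges_to))
    adj[as.integer(names(sp))] <- sp
  }
  for (root in seq_len(n_nodes)) {
    if (!is.na(strand[root])) next
    strand[root] <- TRUE  # '+'
    queue <- root; qh <- 1L
    while (qh <= length(queue)) {
      v <- queue[qh]; qh <- qh + 1L
      for (e in adj[[v]]) {
        w <- if (edges_from[e] == v) edges_to[e] else edges_from[e]
        if (is.na(strand[w])) {
          strand[w] <- if (edge_same[e]) strand[v] else !strand[v]
          queue <- c(queue, w)
        }
      }
    }
  }
  ifelse(strand, "+", "-")
}

#' Single-linkage clustering of element instances into repeat families
#'
#' Families are the connected components of the graph whose nodes are
#' element instances and whose edges are alignments linking two distinct
#' instances. Components of size one are left unassigned (`family_id = NA`).
#' The edge list is retained as the audit trail, and a consistent strand is
#' assigned to every member by propagating orientations along the alignment
#' graph.
#'
#' @param instances GRanges from [buildPiles()].
#' @param aln the [RepeatAlignments-class] used to build the piles.
#' @return a [RepeatFamilySet-class].
#' @export
linkFamilies <- function(instances, aln) {
  n_al <- length(aln)
  img2inst <- integer(2L * n_al)
  ids <- mcols(instances)$image_ids
  img2inst[unlist(ids)] <- rep(seq_along(ids), lengths(ids))
  if (n_al > 0L && any(img2inst == 0L))
    stop("internal consistency error: alignment image assigned to no instance")
  from <- img2inst[seq_len(n_al)]
  to <- img2inst[n_al + seq_len(n_al)]
  distinct <- from != to
  ef <- from[distinct]; et <- to[distinct]
  e_al <- which(distinct)
  e_same <- aln@stats$orientation[e_al] == "same"

  g <- igraph::make_empty_graph(n = length(instances), directed = FALSE)
  if (length(ef)) g <- igraph::add_edges(g, rbind(ef, et))
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  fam_comp <- which(sizes >= 2L)
  # family ids ordered by first instance position for determinism
  first_inst <- vapply(fam_comp, function(cc) min(which(comp == cc)), integer(1))
  fam_comp <- fam_comp[order(first_inst)]
  fam_id <- rep(NA_character_, length(instances))
  for (k in seq_along(fam_comp))
    fam_id[comp == fam_comp[k]] <- sprintf("family%06d", k)

  strand(instances) <- .resolveStrands(length(instances), ef, et, e_same)
  mcols(instances)$family_id <- fam_id
  iid <- mcols(instances)$instance_id
  edges <- DataFrame(from = iid[ef], to = iid[et], alignment_id = e_al,
                     orientation = ifelse(e_same, "same", "opposite"),
                     family_id = fam_id[ef])
  new("RepeatFamilySet", instances = instances, edges = edges,
      alignments = aln)
}

#' Extract member sequences of a family
#'
#' One record per member instance, reverse-complemented to the family's
#' resolved orientation; record names encode the family, instance and
#' genomic interval and can be parsed back with [parseMemberNames()].
#'
#' @param fams [RepeatFamilySet-class].
#' @param genome DNAStringSet.
#' @param family a family id (see [familyIds()]).
#' @return DNAStringSet of member sequences.
#' @export
exportFamilyMembers <- function(fams, genome, family) {
  mem <- familyMembers(fams, family)
  if (length(mem) == 0L) stop("unknown family: ", family)
  seqs <- extractInterval(genome, mem)
  names(seqs) <- sprintf("%s|%s|%s:%d-%d(%s)", family,
                         mcols(mem)$instance_id,
                         as.character(seqnames(mem)), start(mem), end(mem),
                         as.character(strand(mem)))
  seqs
}

#' @rdname exportFamilyMembers
#' @param x character vector of names produced by [exportFamilyMembers()].
#' @return `parseMemberNames()`: GRanges with mcols `family_id`, `instance_id`.
#' @export
parseMemberNames <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  fam <- vapply(parts, `[`, character(1), 1L)
  iid <- vapply(parts, `[`, character(1), 2L)
  loc <- vapply(parts, `[`, character(1), 3L)
  m <- regmatches(loc, regexec("^(.*):(\\d+)-(\\d+)\\(([+-])\\)$", loc))
  gr <- GRanges(vapply(m, `[`, character(1), 2L),
                IRanges(as.integer(vapply(m, `[`, character(1), 3L)),
                        as.integer(vapply(m, `[`, character(1), 4L))),
                strand = vapply(m, `[`, character(1), 5L))
  mcols(gr) <- DataFrame(family_id = fam, instance_id = iid)
  gr
}

#' Write family member intervals as GFF3
#'
#' @param fams [RepeatFamilySet-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFamilyGff <- function(fams, path) {
  inst <- instanceRanges(fams)
  keep <- !is.na(mcols(inst)$family_id)
  gr <- inst[keep]
  mcols(gr) <- DataFrame(type = "repeat_region",
                         ID = mcols(gr)$instance_id,
                         Family = mcols(gr)$family_id)
  writeGff3(gr, path)
}
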