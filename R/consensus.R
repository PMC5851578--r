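#' Select family members for consensus building
#'
#' Keeps members whose length is at least `length_fraction` of the longest
#' member (mixing near-full-length copies with heavily 5'-truncated ones
#' would smear the alignment), then samples at most `max_sample` of them
#' uniformly without replacement; the longest member is always included
#' since it defines the length constraint.
#'
#' @param member_ids character vector of member ids.
#' @param lengths integer vector of member lengths, parallel to `member_ids`.
#' @param length_fraction length threshold relative to the longest member.
#' @param max_sample sample-size cap.
#' @param rng_seed integer seed making the sample reproducible.
#' @return character vector of selected member ids.
#' @examples
#' selectMembers(c("a","b","c"), c(1000, 960, 949))  # threshold 950: a, b
#' @export
selectMembers <- function(member_ids, lengths, length_fraction = 0.95,
                          max_sample = 100L, rng_seed = 1L) {
  stopifnot(length(member_ids) == length(lengths), length(member_ids) >= 1L)
  thr <- length_fraction * max(lengths)
  eligible <- which(lengths >= thr)
  longest <- eligible[which.max(lengths[eligible])]
  if (length(eligible) <= max_sample) return(member_ids[eligible])
  others <- setdiff(eligible, longest)
  sel <- withr::with_seed(rng_seed,
    sample(others, max_sample - 1L, replace = FALSE))
  member_ids[sort(c(longest, sel))]
}

# parse one pairwise global alignment (member vs center) into the member
# bases per center position plus insertions after each center position
.projectOnCenter <- function(center_aln, member_aln, n_center) {
  cc <- strsplit(center_aln, "")[[1]]
  mm <- strsplit(member_aln, "")[[1]]
  isgap <- cc == "-"
  cpos <- cumsum(!isgap)              # center position of each column
  base <- rep("-", n_center)
  base[cpos[!isgap]] <- mm[!isgap]
  ins <- split(mm[isgap], cpos[isgap])  # named by center pos after which
  list(base = base, ins = ins)
}

#' Center-star multiple alignment of family members
#'
#' Progressive star alignment with the longest sequence as the center: each
#' member is globally aligned to the center ([Biostrings::pairwiseAlignment])
#' and the pairwise alignments are merged column-wise. Adequate for repeat
#' families, whose sampled members are close to the identity threshold of
#' the self-alignment stage; removing gaps from any row reproduces the
#' input sequence.
#'
#' @param seqs DNAStringSet (>= 2 sequences).
#' @return character matrix over {A,C,G,T,N,-}, rows named as `seqs`.
#' @export
alignMembers <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences to align")
  if (is.null(names(seqs))) names(seqs) <- .padIds("seq", length(seqs))
  if (length(seqs) == 1L) {
    m <- matrix(strsplit(as.character(seqs[[1]]), "")[[1]], nrow = 1)
    rownames(m) <- names(seqs)
    return(m)
  }
  ci <- which.max(Biostrings::width(seqs))
  center <- seqs[[ci]]
  n <- length(center)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = FALSE)
  others <- setdiff(seq_along(seqs), ci)
  proj <- vector("list", length(seqs))
  proj[[ci]] <- list(base = strsplit(as.character(center), "")[[1]],
                     ins = list())
  for (i in others) {
    p <- Biostrings::pairwiseAlignment(seqs[[i]], center, type = "global",
                                       substitutionMatrix = submat,
                                       gapOpening = 4, gapExtension = 1)
    proj[[i]] <- .projectOnCenter(as.character(Biostrings::alignedSubject(p)),
                                  as.character(Biostrings::alignedPattern(p)),
                                  n)
  }
  # master insertion length after each center position (0 = before first)
  ins_len <- integer(n + 1L)
  for (p in proj) {
    if (length(p$ins) == 0L) next
    at <- as.integer(names(p$ins)) + 1L
    ins_len[at] <- pmax(ins_len[at], lengths(p$ins))
  }
  ncol_out <- n + sum(ins_len)
  # column index of each center position in the output
  cstart <- cumsum(ins_len[seq_len(n)]) + seq_len(n)
  out <- matrix("-", nrow = length(seqs), ncol = ncol_out,
                dimnames = list(names(seqs), NULL))
  for (r in seq_along(proj)) {
    p <- proj[[r]]
    out[r, cstart] <- p$base
    if (length(p$ins)) {
      at <- as.integer(names(p$ins))
      for (k in seq_along(p$ins)) {
        slot0 <- if (at[k] == 0L) 0L else cstart[at[k]]
        v <- p$ins[[k]]
        out[r, slot0 + seq_along(v)] <- v
      }
    }
  }
  out
}

#' Majority-vote consensus of a multiple alignment
#'
#' Per column the most frequent base among the rows present there is
#' emitted; columns where the (internal) gap is the strict majority are
#' dropped, which is what keeps indel-rich alignments from inflating the
#' consensus length. Terminal gaps are missing data - a 5'-truncated member
#' simply does not cover the column - and therefore neither vote for a gap
#' nor count towards the majority. Base ties break in the fixed order
#' A < C < G < T; N is emitted only when all covering rows are N.
#'
#' @param msa character matrix from [alignMembers()].
#' @return a [Biostrings::DNAString] consensus.
#' @export
callConsensus <- function(msa) {
  stopifnot(is.matrix(msa), nrow(msa) >= 1L)
  nr <- nrow(msa); ncl <- ncol(msa)
  bases <- c("A", "C", "G", "T")
  nongap <- msa != "-"
  counts <- vapply(bases, function(b) colSums(msa == b), numeric(ncl))
  if (ncl == 1L) counts <- matrix(counts, nrow = 1,
                                  dimnames = list(NULL, bases))
  nc <- colSums(msa == "N")
  # rows present at a column: between their first and last non-gap columns
  first <- max.col(nongap, ties.method = "first")
  last <- max.col(nongap, ties.method = "last")
  empty_row <- rowSums(nongap) == 0L
  first[empty_row] <- ncl + 1L; last[empty_row] <- 0L
  present <- cumsum(tabulate(first, ncl)) -
    cumsum(c(0, tabulate(last, ncl)))[seq_len(ncl)]
  gapc <- present - rowSums(counts) - nc   # internal gap votes
  keep <- gapc <= present / 2
  top <- max.col(counts, ties.method = "first")  # ties: A<C<G<T order
  has_base <- rowSums(counts) > 0
  out <- character(ncl)
  out[has_base] <- bases[top[has_base]]
  out[!has_base & nc > 0 & nc == present] <- "N"
  Biostrings::DNAString(paste(out[keep & out != ""], collapse = ""))
}

#' Build consensus sequences for all families
#'
#' For each family: members are extracted in the family's resolved
#' orientation, a length-constrained sample is drawn ([selectMembers()]),
#' aligned ([alignMembers()]) and collapsed by majority vote
#' ([callConsensus()]). Deterministic given `rng_seed`.
#'
#' @param fams [RepeatFamilySet-class].
#' @param genome DNAStringSet.
#' @param length_fraction,max_sample,rng_seed see [selectMembers()].
#' @param verbose report progress.
#' @return a [ConsensusSet-class]; consensus names are the family ids.
#' @export
buildConsensusSet <- function(fams, genome, length_fraction = 0.95,
                              max_sample = 100L, rng_seed = 1L,
                              verbose = FALSE) {
  ids <- familyIds(fams)
  seqs <- vector("list", length(ids))
  info <- vector("list", length(ids))
  samples <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    mem <- exportFamilyMembers(fams, genome, ids[k])
    inst_ids <- vapply(strsplit(names(mem), "|", fixed = TRUE), `[`,
                       character(1), 2L)
    sel <- selectMembers(inst_ids, Biostrings::width(mem),
                         length_fraction, max_sample,
                         rng_seed = rng_seed + k)
    sub <- mem[match(sel, inst_ids)]
    names(sub) <- sel
    msa <- alignMembers(sub)
    cons <- callConsensus(msa)
    # guard against gap-driven expansion
    stopifnot(length(cons) <= max(Biostrings::width(sub)) * 1.05)
    seqs[[k]] <- as.character(cons)
    samples[[k]] <- sel
    info[[k]] <- data.frame(family_id = ids[k], n_members = length(mem),
                            n_sampled = length(sel), stringsAsFactors = FALSE)
    .msg(verbose, ids[k], ": ", length(mem), " members, consensus ",
         length(cons), " bp")
  }
  sequences <- if (length(ids)) Biostrings::DNAStringSet(unlist(seqs))
               else Biostrings::DNAStringSet()
  if (length(ids)) names(sequences) <- ids
  infodf <- if (length(ids)) do.call(rbind, info)
            else data.frame(family_id = character(), n_members = integer(),
                            n_sampled = integer())
  new("ConsensusSet", sequences = sequences,
      info = DataFrame(infodf,
                       class = rep(NA_character_, length(ids)),
                       removed = rep(FALSE, length(ids)),
                       reason = rep(NA_character_, length(ids))),
      samples = samples, hits = rep(list(NULL), length(ids)))
}
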