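#' Find long open reading frames
#'
#' All maximal ATG-to-stop ORFs of at least `min_orf_nt` nucleotides (stop
#' codon included), in all three frames on both strands, standard genetic
#' code. "Maximal" means the first ATG after the previous in-frame stop;
#' coordinates are reported on the input's forward strand. The default 1.5 kb
#' floor targets intact LINE ORF2; a single internal stop or frameshift
#' splits the reading frame below the floor and disqualifies the element.
#'
#' @param sequence character or DNAString.
#' @param min_orf_nt minimum ORF length in nucleotides, stop included.
#' @return data.frame with start, end (1-based closed, forward strand),
#'   strand, frame, nt_length, protein (no stop character).
#' @export
findOrfs <- function(sequence, min_orf_nt = 1500L) {
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (str in c("+", "-")) {
    seqs <- if (str == "+") s else .rcChar(s)
    for (frame in 1:3) {
      ncod <- (L - frame + 1L) %/% 3L
      if (ncod < 2L) next
      cod <- substring(seqs, frame + 3L * (seq_len(ncod) - 1L),
                       frame + 3L * seq_len(ncod) - 1L)
      is_stop <- cod %in% stops
      is_atg <- cod == "ATG"
      stop_idx <- which(is_stop)
      if (length(stop_idx) == 0L) next
      prev_stop <- c(0L, stop_idx[-length(stop_idx)])
      for (k in seq_along(stop_idx)) {
        lo <- prev_stop[k] + 1L; hi <- stop_idx[k]
        if (hi <= lo) next
        atg <- which(is_atg[lo:(hi - 1L)])
        if (length(atg) == 0L) next
        a <- lo + atg[1L] - 1L
        nt <- (stop_idx[k] - a + 1L) * 3L
        if (nt < min_orf_nt) next
        s_on <- frame + 3L * (a - 1L)          # 1-based on scanned strand
        e_on <- frame + 3L * stop_idx[k] - 1L
        if (str == "+") { fs <- s_on; fe <- e_on }
        else { fs <- L - e_on + 1L; fe <- L - s_on + 1L }
        aa <- Biostrings::GENETIC_CODE[cod[a:(stop_idx[k] - 1L)]]
        aa[is.na(aa)] <- "X"
        prot <- paste(aa, collapse = "")
        out[[length(out) + 1L]] <- data.frame(
          start = fs, end = fe, strand = str, frame = frame,
          nt_length = nt, protein = prot, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      nt_length = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Detect a reverse-transcriptase domain in an ORF protein
#'
#' Best local protein alignment (BLOSUM62, affine gaps) of the protein
#' against a set of reverse-transcriptase reference proteins. The aligned
#' span on the protein is the domain envelope; it qualifies when it covers
#' at least `min_rt_aa` residues at an E-value of `evalue_max` or better.
#'
#' @param protein character or AAString.
#' @param rt_refs AAStringSet of RT reference proteins (non-empty).
#' @param min_rt_aa minimum envelope length in amino acids.
#' @param evalue_max E-value ceiling (Karlin-Altschul, ungapped constants).
#' @return list with ref_id, start, end (envelope on the protein),
#'   aa_length, score, evalue - or NULL when nothing qualifies.
#' @export
detectRtDomain <- function(protein, rt_refs, min_rt_aa = 200L,
                           evalue_max = 1e-5) {
  if (length(rt_refs) == 0L) stop("empty reverse-transcriptase reference set")
  prot <- Biostrings::AAString(as.character(protein))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  db_total <- sum(Biostrings::width(rt_refs))
  best <- NULL
  for (ri in seq_along(rt_refs)) {
    p <- Biostrings::pairwiseAlignment(prot, rt_refs[[ri]], type = "local",
                                       substitutionMatrix = B62,
                                       gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(p)
    if (is.null(best) || sc > best$score) {
      pa <- Biostrings::pattern(p)
      best <- list(ref_id = names(rt_refs)[ri],
                   start = Biostrings::start(pa), end = Biostrings::end(pa),
                   aa_length = Biostrings::end(pa) - Biostrings::start(pa) + 1L,
                   score = sc)
    }
  }
  best$evalue <- .kaEvalue(best$score, length(prot), db_total)
  if (best$aa_length >= min_rt_aa && best$evalue <= evalue_max) best else NULL
}

#' Flag potentially active autonomous elements
#'
#' An element is flagged potentially active when it carries at least one
#' intact long ORF (>= `min_orf_nt`, start and stop codons, no internal
#' stop) whose protein contains a reverse-transcriptase domain envelope of
#' at least `min_rt_aa` residues - regardless of the state of any other ORF.
#'
#' @param elements named DNAStringSet (consensus sequences or family members
#'   exported from the audit trail).
#' @param rt_refs AAStringSet of RT reference proteins.
#' @param min_orf_nt see [findOrfs()].
#' @param min_rt_aa,evalue_max see [detectRtDomain()].
#' @return data.frame with one row per element: element, active, orf_start,
#'   orf_end, orf_strand, protein_length, rt_ref, rt_start, rt_end
#'   (NA columns when inactive).
#' @export
flagPotentiallyActive <- function(elements, rt_refs, min_orf_nt = 1500L,
                                  min_rt_aa = 200L, evalue_max = 1e-5) {
  if (is.null(names(elements))) names(elements) <- .padIds("elem", length(elements))
  rows <- lapply(seq_along(elements), function(i) {
    orfs <- findOrfs(elements[[i]], min_orf_nt)
    hit <- NULL; oi <- NA_integer_
    if (nrow(orfs)) {
      for (k in seq_len(nrow(orfs))) {
        d <- detectRtDomain(orfs$protein[k], rt_refs, min_rt_aa, evalue_max)
        if (!is.null(d)) { hit <- d; oi <- k; break }
      }
    }
    if (is.null(hit))
      data.frame(element = names(elements)[i], active = FALSE,
                 orf_start = NA_integer_, orf_end = NA_integer_,
                 orf_strand = NA_character_, protein_length = NA_integer_,
                 rt_ref = NA_character_, rt_start = NA_integer_,
                 rt_end = NA_integer_, stringsAsFactors = FALSE)
    else
      data.frame(element = names(elements)[i], active = TRUE,
                 orf_start = orfs$start[oi], orf_end = orfs$end[oi],
                 orf_strand = orfs$strand[oi],
                 protein_length = nchar(orfs$protein[oi]),
                 rt_ref = hit$ref_id, rt_start = hit$start,
                 rt_end = hit$end, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
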