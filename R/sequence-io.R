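#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased on read. Soft-masked (lowercase) stretches of the
#' input are preserved as a per-sequence mask retrievable with
#' [softMask()]; by default downstream stages ignore the mask, since the
#' method is designed to run on unmasked assemblies (it recovers segmental
#' duplications that masking would hide).
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @return a [Biostrings::DNAStringSet] with the soft-mask stored in
#'   `metadata(x)$soft_mask` as a list of [IRanges::IRanges].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTacgtACGT"), fa)
#' g <- readGenome(fa)
#' softMask(g)$chr1   # the lowercase run
#' @export
readGenome <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  chars <- as.character(raw)
  if (any(nchar(chars) == 0L)) stop("empty sequence in FASTA: ", path)
  mask <- lapply(chars, function(s) {
    lc <- grepl("[acgtn]", s)
    if (!lc) return(IRanges::IRanges())
    r <- gregexpr("[acgtn]+", s)[[1]]
    IRanges::IRanges(start = as.integer(r), width = attr(r, "match.length"))
  })
  names(mask) <- ids
  g <- Biostrings::DNAStringSet(toupper(chars))
  names(g) <- ids
  S4Vectors::metadata(g)$soft_mask <- mask
  g
}

#' @rdname readGenome
#' @param x a DNAStringSet read with [readGenome()].
#' @return `softMask()`: named list of IRanges of soft-masked positions.
#' @export
softMask <- function(x) {
  m <- S4Vectors::metadata(x)$soft_mask
  if (is.null(m)) m <- stats::setNames(rep(list(IRanges::IRanges()), length(x)), names(x))
  m
}

#' Hard-mask soft-masked positions
#'
#' Replaces soft-masked positions with N so they are excluded from seeding.
#' Opt-in: the pipeline default keeps masked sequence alignable.
#'
#' @param x DNAStringSet from [readGenome()].
#' @return DNAStringSet with masked positions set to N.
#' @export
applySoftMask <- function(x) {
  m <- softMask(x)
  out <- as.character(x)
  for (i in seq_along(out)) {
    if (length(m[[i]]) == 0L) next
    s <- strsplit(out[i], "")[[1]]
    idx <- unlist(lapply(seq_along(m[[i]]), function(j)
      seq(IRanges::start(m[[i]])[j], IRanges::end(m[[i]])[j])))
    s[idx] <- "N"
    out[i] <- paste(s, collapse = "")
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(x)
  res
}

#' Extract the sequence of a genomic interval
#'
#' @param genome DNAStringSet.
#' @param gr GRanges (1-based closed); minus-strand ranges are
#'   reverse-complemented.
#' @return DNAStringSet, one sequence per range.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
#' extractInterval(g, GenomicRanges::GRanges("chr1:3-5:+"))  # GTA
#' extractInterval(g, GenomicRanges::GRanges("chr1:3-5:-"))  # TAC
#' @export
extractInterval <- function(genome, gr) {
  sn <- as.character(seqnames(gr))
  bad <- !(sn %in% names(genome))
  if (any(bad)) stop("unknown sequence id: ", paste(unique(sn[bad]), collapse = ", "))
  lens <- Biostrings::width(genome)[match(sn, names(genome))]
  if (any(start(gr) < 1L | end(gr) > lens | start(gr) > end(gr)))
    stop("interval out of bounds")
  out <- Biostrings::DNAStringSet(substr(as.character(genome)[match(sn, names(genome))],
                                         start(gr), end(gr)))
  neg <- as.logical(strand(gr) == "-")
  if (any(neg)) out[neg] <- Biostrings::reverseComplement(out[neg])
  names(out) <- sprintf("%s:%d-%d(%s)", sn, start(gr), end(gr),
                        as.character(strand(gr)))
  out
}

#' Write interval features as GFF3
#'
#' Thin wrapper over [rtracklayer::export.gff3()]; metadata columns of the
#' GRanges become GFF attributes.
#'
#' @param gr GRanges with optional mcols `type`, `score`, `ID`, `Family`,
#'   `class`.
#' @param path output file.
#' @param source source column value.
#' @return invisibly, the path.
#' @export
writeGff3 <- function(gr, path, source = "carpr") {
  if (length(gr)) {
    mc <- mcols(gr)
    if (is.null(mc$type)) mc$type <- "repeat_region"
    mc$source <- source
    mcols(gr) <- mc
  }
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a TE reference library with class labels
#'
#' Headers in the Repbase/RepeatMasker dialect `name#class/subclass` are
#' parsed into name and class; alternatively a two-column TSV (name, class)
#' can be supplied for plain headers.
#'
#' @param path nucleotide FASTA.
#' @param class_map optional TSV path or data.frame with columns name, class.
#' @return DNAStringSet named by element name, with `metadata(x)$class`
#'   a named character vector of class labels ("Unknown" when absent).
#' @export
readTeLibrary <- function(path, class_map = NULL) {
  lib <- Biostrings::readDNAStringSet(path)
  if (length(lib) == 0L) stop("empty TE library: ", path)
  hdr <- sub("\\s.*$", "", names(lib))
  name <- sub("#.*$", "", hdr)
  cls <- ifelse(grepl("#", hdr), sub("^[^#]*#", "", hdr), "Unknown")
  if (!is.null(class_map)) {
    cm <- if (is.character(class_map))
      utils::read.delim(class_map, header = FALSE,
                        col.names = c("name", "class"),
                        stringsAsFactors = FALSE)
    else class_map
    hit <- match(name, cm$name)
    cls[!is.na(hit)] <- cm$class[hit[!is.na(hit)]]
  }
  names(lib) <- name
  S4Vectors::metadata(lib)$class <- stats::setNames(cls, name)
  lib
}

#' Top-level TE class of a class/subclass label
#'
#' Collapses Repbase-style labels to the coarse classes used in repeat
#' content summaries (SINE, LINE, LTR, DNA, Other).
#'
#' @param x character vector of class labels.
#' @return character vector of coarse classes.
#' @export
teClassGroup <- function(x) {
  top <- toupper(sub("/.*$", "", x))
  out <- rep("Other", length(x))
  out[grepl("SINE", top)] <- "SINE"
  out[grepl("LINE|^L1$|^L2$|CR1|RTE", top)] <- "LINE"
  out[grepl("LTR|ERV|GYPSY|COPIA", top)] <- "LTR"
  out[grepl("DNA|TC1|MARINER|HAT|HELITRON", top)] <- "DNA"
  out
}
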