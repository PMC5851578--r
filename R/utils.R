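# internal helpers shared across modules

# concatenate a DNAStringSet into one character string separated by N runs
# long enough that no seed k-mer or extension can bridge two sequences
.catGenome <- function(genome, spacer = 50L) {
  stopifnot(is(genome, "DNAStringSet"))
  n <- length(genome)
  lens <- Biostrings::width(genome)
  sep <- strrep("N", spacer)
  seqs <- as.character(genome)
  cat_seq <- paste(seqs, collapse = sep)
  offset <- c(0L, cumsum(lens + spacer))[seq_len(n)]  # 0-based start in cat
  list(seq = cat_seq, names = names(genome), offset = offset, len = lens)
}

# map 0-based half-open intervals on the concatenated string back to
# per-sequence coordinates (1-based closed); returns NA seq for intervals
# crossing a spacer/sequence boundary
.catToLocal <- function(cat, start0, end0) {
  idx <- findInterval(start0, cat$offset)
  seqn <- cat$names[idx]
  s_local <- start0 - cat$offset[idx] + 1L
  e_local <- end0 - cat$offset[idx]
  bad <- e_local > cat$len[idx] | s_local < 1L
  seqn[bad] <- NA_character_
  data.frame(seqnames = seqn, start = s_local, end = e_local,
             stringsAsFactors = FALSE)
}

# reverse complement of a plain character vector
.rcChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# overlap fraction (of the shorter range) for hit pairs between two GRanges
.overlapFrac <- function(gr, hits) {
  q <- gr[S4Vectors::queryHits(hits)]
  s <- gr[S4Vectors::subjectHits(hits)]
  inter <- pmin(end(q), end(s)) - pmax(start(q), start(s)) + 1L
  inter <- pmax(inter, 0L)
  inter / pmin(width(q), width(s))
}

# deterministic zero-padded ids
.padIds <- function(prefix, n) sprintf("%s%06d", prefix, seq_len(n))

# Karlin-Altschul E-value with ungapped BLOSUM62 constants
.kaEvalue <- function(score, m, n, lambda = 0.318, K = 0.13) {
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)
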