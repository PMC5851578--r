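# shared fixture builders: everything is generated in code at test time

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a single-contig genome with sequences planted at given 1-based offsets
# into a random background; returns the genome and the planted intervals
plant_genome <- function(background, inserts, positions) {
  stopifnot(length(inserts) == length(positions),
            !is.unsorted(positions))
  chunks <- character(0)
  prev <- 0L
  starts <- integer(length(inserts)); ends <- integer(length(inserts))
  offset <- 0L
  for (i in seq_along(inserts)) {
    chunks <- c(chunks, substr(background, prev + 1L, positions[i]), inserts[i])
    starts[i] <- positions[i] + offset + 1L
    ends[i] <- starts[i] + nchar(inserts[i]) - 1L
    offset <- offset + nchar(inserts[i])
    prev <- positions[i]
  }
  chunks <- c(chunks, substr(background, prev + 1L, nchar(background)))
  g <- Biostrings::DNAStringSet(paste(chunks, collapse = ""))
  names(g) <- "chr1"
  list(genome = g,
       truth = GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends)))
}

# mutate a sequence to approximately the given identity (substitutions only)
mutate_to <- function(seq, identity, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  k <- round((1 - identity) * n)
  if (k > 0) {
    pos <- sample.int(n, k)
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  }
  paste(chars, collapse = "")
}

rc <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(x)))

# independent Smith-Waterman oracle via Biostrings; identity counts all
# alignment columns (gaps included), matching the package convention
sw_oracle <- function(a, b) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = TRUE)
  p <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                     Biostrings::DNAString(b),
                                     type = "local",
                                     substitutionMatrix = submat,
                                     gapOpening = 3, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::alignedPattern(p)))
  list(score = Biostrings::score(p),
       identity = Biostrings::nmatch(p) / cols,
       length = cols)
}

# brute-force union-find over alignment pairs (oracle for single linkage)
uf_components <- function(n, edges_from, edges_to) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (e in seq_along(edges_from)) {
    a <- find(edges_from[e]); b <- find(edges_to[e])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

# reverse-translate a protein with uniform codon choice (no stop codons)
rev_translate <- function(protein, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gc_tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc_tab), gc_tab)
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) sample(by_aa[[a]], 1L), character(1)),
        collapse = "")
}

# brute-force codon-walk ORF oracle (forward strand of the given sequence)
orf_oracle_one_strand <- function(s, min_nt) {
  L <- nchar(s)
  out <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 1:3) {
    i <- frame
    current_atg <- NA
    while (i + 2 <= L) {
      cod <- substr(s, i, i + 2)
      if (is.na(current_atg) && cod == "ATG") current_atg <- i
      if (cod %in% stops) {
        if (!is.na(current_atg)) {
          nt <- i + 2 - current_atg + 1
          if (nt >= min_nt)
            out[[length(out) + 1]] <- c(start = current_atg, end = i + 2)
        }
        current_atg <- NA
      }
      i <- i + 3
    }
  }
  if (length(out)) do.call(rbind, out) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

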