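#' Specification of one planted repeat family
#'
#' @param name family name (used in the truth table and reference fixtures).
#' @param length ancestor length (bp).
#' @param copies number of recent copies planted.
#' @param sub_rate per-base substitution rate applied to each copy; the
#'   within-family pairwise identity is roughly `1 - 2 * sub_rate`.
#' @param indel_rate per-base indel rate (geometric lengths, mean 2 bp).
#' @param truncation "none" or "5prime" (exponential 5' truncation, the
#'   hallmark of LINE insertions).
#' @param trunc_mean mean truncated fraction under "5prime".
#' @param class TE class label in Repbase dialect (e.g. "LINE/L1").
#' @param has_intact_orf2 when TRUE the ancestor carries an intact >= 1.5 kb
#'   ORF embedding a reverse-transcriptase protein.
#' @param ancient_copies additional old copies planted at `ancient_sub_rate`
#'   divergence from the ancestor; they are too diverged for the
#'   self-alignment stage but are picked up by genome annotation, producing
#'   the high-copy-number signature of an old, once-active family.
#' @param ancient_sub_rate substitution rate of the old copies.
#' @return a validated list describing the family.
#' @export
teFamilySpec <- function(name, length, copies, sub_rate = 0.01,
                         indel_rate = 5e-4, truncation = c("none", "5prime"),
                         trunc_mean = 0.15, class = "Unknown",
                         has_intact_orf2 = FALSE, ancient_copies = 0L,
                         ancient_sub_rate = 0.15) {
  truncation <- match.arg(truncation)
  stopifnot(length >= 50, copies >= 2, sub_rate >= 0, sub_rate < 1,
            indel_rate >= 0, indel_rate < 1)
  list(name = name, length = as.integer(length), copies = as.integer(copies),
       sub_rate = sub_rate, indel_rate = indel_rate, truncation = truncation,
       trunc_mean = trunc_mean, class = class,
       has_intact_orf2 = isTRUE(has_intact_orf2),
       ancient_copies = as.integer(ancient_copies),
       ancient_sub_rate = ancient_sub_rate)
}

#' Specification of a synthetic genome with planted repeat structure
#'
#' The defaults encode the standard evaluation genome: 1 Mb of i.i.d.
#' background at GC 0.42 carrying five dispersed TE families spanning the
#' 95-99% within-family identity range (one 5'-truncated LINE with an intact
#' ORF2), one high-copy novel TE with a large ancient copy complement, three
#' segmental duplications of 5-15 kb at 2-3 copies, one host gene paralog
#' family and a set of dispersed simple-sequence-repeat tracts.
#'
#' @param background_length background length (bp).
#' @param gc background GC fraction.
#' @param families list of [teFamilySpec()].
#' @param sds list of segmental duplications: each `list(name, length,
#'   copies, sub_rate)`.
#' @param host_paralogs list of host gene families: each `list(name,
#'   protein_aa, copies, sub_rate)`.
#' @param ssr_tracts list of dispersed SSR tracts: each `list(name, unit,
#'   n_units, copies)`.
#' @return a validated plant specification (class `plant_spec`).
#' @export
plantSpec <- function(
    background_length = 1e6, gc = 0.42,
    families = list(
      teFamilySpec("LINE_A", 1200, 120, sub_rate = 0.010, class = "LINE/L1"),
      teFamilySpec("SINE_A", 300, 150, sub_rate = 0.005, class = "SINE/tRNA"),
      teFamilySpec("LTR_A",  800,  60, sub_rate = 0.015, class = "LTR/ERV1"),
      teFamilySpec("DNA_A",  600,  40, sub_rate = 0.020, class = "DNA/hAT"),
      teFamilySpec("LINE_B", 2400, 30, sub_rate = 0.0075, truncation = "5prime",
                   trunc_mean = 0.15, class = "LINE/L2",
                   has_intact_orf2 = TRUE),
      teFamilySpec("NOVEL_HC", 350, 40, sub_rate = 0.005, class = "Unknown",
                   ancient_copies = 2460L, ancient_sub_rate = 0.15)),
    sds = list(list(name = "SD_A", length = 8000, copies = 2, sub_rate = 0.01),
               list(name = "SD_B", length = 5000, copies = 3, sub_rate = 0.01),
               list(name = "SD_C", length = 15000, copies = 2, sub_rate = 0.01)),
    host_paralogs = list(list(name = "HOSTGENE_A", protein_aa = 400,
                              copies = 8, sub_rate = 0.01)),
    ssr_tracts = list(list(name = "SSR_AC", unit = "AC", n_units = 150,
                           copies = 12))) {
  stopifnot(background_length >= 1000, gc > 0, gc < 1)
  total_insert <- sum(vapply(families, function(f)
    (f$copies + f$ancient_copies) * f$length, numeric(1))) +
    sum(vapply(sds, function(s) s$copies * s$length, numeric(1)))
  n_inserts <- sum(vapply(families, function(f) f$copies + f$ancient_copies,
                          numeric(1)))
  if (n_inserts > background_length / 2)
    stop("spec infeasible: too many insertions for the background length")
  structure(list(background_length = as.integer(background_length), gc = gc,
                 families = families, sds = sds,
                 host_paralogs = host_paralogs, ssr_tracts = ssr_tracts),
            class = "plant_spec")
}

.randDna <- function(n, gc = 0.42) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.randProtein <- function(n) {
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# reverse-translate a protein: uniform random codon per residue (no stops)
.revTranslate <- function(protein) {
  gc_tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc_tab), gc_tab)
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- by_aa[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# substitutions then indels; returns the mutated sequence and the realized
# substitution identity to the ancestor (indels excluded from the measure)
.mutateSeq <- function(seq, sub_rate, indel_rate) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  bases <- c("A", "C", "G", "T")
  nsub <- stats::rbinom(1L, n, sub_rate)
  ident <- 1 - nsub / n
  if (nsub > 0L) {
    pos <- sample.int(n, nsub)
    cur <- chars[pos]
    repl <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), character(1))
    chars[pos] <- repl
  }
  nind <- stats::rbinom(1L, n, indel_rate)
  if (nind > 0L) {
    pos <- sort(sample.int(n, min(nind, n)), decreasing = TRUE)
    for (p in pos) {
      len <- stats::rgeom(1L, 0.5) + 1L
      if (stats::runif(1) < 0.5) {  # deletion
        del_end <- min(n, p + len - 1L)
        chars <- chars[-(p:del_end)]
      } else {                      # insertion after p
        ins <- sample(bases, len, replace = TRUE)
        chars <- append(chars, ins, after = p)
      }
      n <- length(chars)
    }
  }
  list(seq = paste(chars, collapse = ""), identity = ident)
}

# ancestor with an intact ORF2: 5' UTR + ATG + [filler aa, RT protein,
# filler aa] + stop + 3' tail, padded to the requested length
.orf2Ancestor <- function(total_len, rt_protein, gc) {
  rt_aa <- nchar(rt_protein)
  filler5 <- 150L
  filler3 <- 50L
  orf_nt <- 3L * (1L + filler5 + rt_aa + filler3 + 1L)  # ATG..stop
  utr5 <- 150L
  tail <- total_len - utr5 - orf_nt
  if (tail < 0L) stop("ancestor too short for an intact ORF2")
  prot <- paste0(.randProtein(filler5), rt_protein, .randProtein(filler3))
  orf <- paste0("ATG", .revTranslate(prot), "TAA")
  list(seq = paste0(.randDna(utr5, gc), orf, .randDna(tail, gc)),
       orf_start = utr5 + 1L, orf_end = utr5 + orf_nt)
}

#' Generate a synthetic genome with planted repeats and a truth table
#'
#' The background is i.i.d. at the requested GC; each planted copy is the
#' family ancestor mutated (substitutions then indels), optionally
#' 5'-truncated, and placed uniformly at random on a random strand without
#' overlapping any other insert. Bit-identical output for a given seed.
#'
#' @param spec a [plantSpec()].
#' @param seed integer RNG seed.
#' @return list with `genome` (DNAStringSet, one sequence "contig1"),
#'   `truth` (GRanges of planted copies with mcols family, kind, class,
#'   copy_id, strand-placed orientation, identity, trunc_frac, recent) and
#'   `library` (ancestors DNAStringSet, per-family info data.frame,
#'   rt_proteins and host_proteins AAStringSets).
#' @export
simulateGenome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "plant_spec"))
  withr::with_seed(as.integer(seed), .simulateGenomeImpl(spec))
}

.simulateGenomeImpl <- function(spec) {
  gc <- spec$gc
  inserts <- list()   # each: list(seq, family, kind, class, identity, trunc, recent)
  ancestors <- character(0)
  fam_info <- list()
  rt_prots <- character(0)
  host_prots <- character(0)

  for (f in spec$families) {
    if (f$has_intact_orf2) {
      rt <- .randProtein(300L)
      rt_prots[paste0("RT_", f$name)] <- rt
      anc <- .orf2Ancestor(f$length, rt, gc)$seq
    } else {
      anc <- .randDna(f$length, gc)
    }
    ancestors[f$name] <- anc
    fam_info[[f$name]] <- data.frame(
      name = f$name, kind = "te", class = f$class, copies = f$copies,
      ancient_copies = f$ancient_copies, length = nchar(anc),
      has_intact_orf2 = f$has_intact_orf2, stringsAsFactors = FALSE)
    ncop <- f$copies + f$ancient_copies
    for (i in seq_len(ncop)) {
      recent <- i <= f$copies
      rate <- if (recent) f$sub_rate else f$ancient_sub_rate
      m <- .mutateSeq(anc, rate, if (recent) f$indel_rate else f$indel_rate)
      sq <- m$seq
      trunc <- 0
      if (recent && f$truncation == "5prime") {
        trunc <- min(0.8, stats::rexp(1L, 1 / f$trunc_mean))
        keep_from <- floor(nchar(sq) * trunc) + 1L
        sq <- substr(sq, keep_from, nchar(sq))
      }
      inserts[[length(inserts) + 1L]] <- list(
        seq = sq, family = f$name, kind = "te", class = f$class,
        copy_id = sprintf("%s_copy%04d", f$name, i),
        identity = m$identity, trunc = trunc, recent = recent)
    }
  }
  for (s in spec$sds) {
    anc <- .randDna(s$length, gc)
    ancestors[s$name] <- anc
    fam_info[[s$name]] <- data.frame(
      name = s$name, kind = "sd", class = "SD", copies = s$copies,
      ancient_copies = 0L, length = s$length, has_intact_orf2 = FALSE,
      stringsAsFactors = FALSE)
    for (i in seq_len(s$copies)) {
      m <- .mutateSeq(anc, s$sub_rate, 2e-4)
      inserts[[length(inserts) + 1L]] <- list(
        seq = m$seq, family = s$name, kind = "sd", class = "SD",
        copy_id = sprintf("%s_copy%04d", s$name, i),
        identity = m$identity, trunc = 0, recent = TRUE)
    }
  }
  for (h in spec$host_paralogs) {
    prot <- .randProtein(h$protein_aa)
    host_prots[h$name] <- prot
    anc <- paste0("ATG", .revTranslate(prot), "TAA")
    ancestors[h$name] <- anc
    fam_info[[h$name]] <- data.frame(
      name = h$name, kind = "host", class = "Host", copies = h$copies,
      ancient_copies = 0L, length = nchar(anc), has_intact_orf2 = FALSE,
      stringsAsFactors = FALSE)
    for (i in seq_len(h$copies)) {
      m <- .mutateSeq(anc, h$sub_rate, 0)
      inserts[[length(inserts) + 1L]] <- list(
        seq = m$seq, family = h$name, kind = "host", class = "Host",
        copy_id = sprintf("%s_copy%04d", h$name, i),
        identity = m$identity, trunc = 0, recent = TRUE)
    }
  }
  for (ss in spec$ssr_tracts) {
    anc <- strrep(ss$unit, ss$n_units)
    ancestors[ss$name] <- anc
    fam_info[[ss$name]] <- data.frame(
      name = ss$name, kind = "ssr", class = "Simple_repeat",
      copies = ss$copies, ancient_copies = 0L, length = nchar(anc),
      has_intact_orf2 = FALSE, stringsAsFactors = FALSE)
    for (i in seq_len(ss$copies)) {
      m <- .mutateSeq(anc, 0.01, 0)
      inserts[[length(inserts) + 1L]] <- list(
        seq = m$seq, family = ss$name, kind = "ssr", class = "Simple_repeat",
        copy_id = sprintf("%s_copy%04d", ss$name, i),
        identity = m$identity, trunc = 0, recent = TRUE)
    }
  }

  # placement: insertion points in the background separated by at least
  # min_gap background bases, assembled with cumulative offsets so planted
  # intervals can never overlap or abut (abutting copies would read as
  # tandem doubles, which the dispersed-repeat model excludes)
  n_ins <- length(inserts)
  min_gap <- 150L
  bg <- .randDna(spec$background_length, gc)
  if (n_ins == 0L) {
    genome <- Biostrings::DNAStringSet(bg)
    names(genome) <- "contig1"
    return(list(genome = genome,
                truth = GRanges(seqnames = character(0)),
                library = list(ancestors = Biostrings::DNAStringSet(),
                               info = NULL,
                               rt_proteins = Biostrings::AAStringSet(),
                               host_proteins = Biostrings::AAStringSet())))
  }
  reduced <- spec$background_length - 1L - (n_ins - 1L) * min_gap
  if (reduced < n_ins)
    stop("spec infeasible: insufficient background space for spacing")
  points <- sort(sample.int(reduced, n_ins)) +
    (seq_len(n_ins) - 1L) * min_gap
  order_ins <- sample.int(n_ins)  # which insert goes to which point
  strands <- sample(c("+", "-"), n_ins, replace = TRUE)
  chunks <- character(2L * n_ins + 1L)
  starts <- integer(n_ins); ends <- integer(n_ins)
  prev <- 0L; offset <- 0L
  ord_rows <- integer(n_ins)
  for (j in seq_len(n_ins)) {
    idx <- order_ins[j]
    placed <- if (strands[j] == "-") .rcChar(inserts[[idx]]$seq)
              else inserts[[idx]]$seq
    chunks[2L * j - 1L] <- substr(bg, prev + 1L, points[j])
    chunks[2L * j] <- placed
    starts[j] <- points[j] + offset + 1L
    ends[j] <- starts[j] + nchar(placed) - 1L
    offset <- offset + nchar(placed)
    prev <- points[j]
    ord_rows[j] <- idx
  }
  chunks[2L * n_ins + 1L] <- substr(bg, prev + 1L, spec$background_length)
  genome <- Biostrings::DNAStringSet(paste(chunks, collapse = ""))
  names(genome) <- "contig1"

  meta <- do.call(rbind, lapply(inserts[ord_rows], function(x)
    data.frame(family = x$family, kind = x$kind, class = x$class,
               copy_id = x$copy_id, identity = x$identity,
               trunc_frac = x$trunc, recent = x$recent,
               stringsAsFactors = FALSE)))
  truth <- GRanges("contig1", IRanges(starts, ends), strand = strands)
  mcols(truth) <- DataFrame(meta)

  anc_set <- Biostrings::DNAStringSet(ancestors)
  rt_set <- if (length(rt_prots)) Biostrings::AAStringSet(rt_prots)
            else Biostrings::AAStringSet()
  host_set <- if (length(host_prots)) Biostrings::AAStringSet(host_prots)
              else Biostrings::AAStringSet()
  list(genome = genome, truth = truth,
       library = list(ancestors = anc_set,
                      info = do.call(rbind, fam_info),
                      rt_proteins = rt_set, host_proteins = host_set))
}

#' Build reference fixtures from a simulation truth table
#'
#' Emits the reference libraries the annotation and active-scan stages
#' consume: a TE library holding the chosen subset of planted ancestors
#' (with Repbase-style class labels), a host protein database (host gene
#' products, plus - as in real protein databases - reverse-transcriptase-
#' derived entries when `rt_in_host`), and an RT protein database.
#'
#' @param sim result of [simulateGenome()].
#' @param te_subset names of planted families whose ancestors go into the
#'   TE library.
#' @param rt_in_host also place the RT proteins in the host database under a
#'   host-like name (RT-derived host genes are common in curated databases;
#'   this exercises the "hits both databases" retention rule).
#' @return list with `te_library` (DNAStringSet with class metadata),
#'   `host_db`, `rt_db` (AAStringSets).
#' @export
makeReferenceFixtures <- function(sim, te_subset = character(0),
                                  rt_in_host = TRUE) {
  info <- sim$library$info
  bad <- setdiff(te_subset, info$name[info$kind == "te"])
  if (length(bad)) stop("not a planted TE family: ", paste(bad, collapse = ", "))
  te <- sim$library$ancestors[te_subset]
  if (length(te)) {
    cls <- info$class[match(te_subset, info$name)]
    S4Vectors::metadata(te)$class <- stats::setNames(cls, te_subset)
  }
  host <- sim$library$host_proteins
  rt <- sim$library$rt_proteins
  if (rt_in_host && length(rt)) {
    decoy <- rt
    names(decoy) <- paste0("HOSTLIKE_", names(rt))
    host <- c(host, decoy)
  }
  list(te_library = te, host_db = host, rt_db = rt)
}
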