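# SSR detection, protein filtering, classification, genome annotation

# brute-force tandem-run oracle: positions inside any run of a 1-6 bp unit
# repeated >= 4 times over >= 12 bp
ssr_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  covered <- logical(L)
  for (u in 1:6) for (start in seq_len(max(0, L - max(12, 4 * u) + 1))) {
    len <- 0L
    while (start + len + u - 1 <= L &&
           ch[start + len] == ch[start + len + u]) len <- len + 1L
    span <- len + u
    if (len >= 1L && span >= max(12L, 4L * u) && (span / u) >= 4)
      covered[start:(start + span - 1L)] <- TRUE
  }
  mean(covered)
}

test_that("SSR detection matches a brute-force tandem-run oracle", {
  expect_equal(detectSsr("ACACACACACAC"), 1.0)
  expect_equal(detectSsr(strrep("ACG", 20)), 1.0)
  set.seed(51)
  r1 <- rand_dna(1000)
  expect_lt(detectSsr(r1), 0.1)
  # embedded tract in unique sequence
  s <- paste0(rand_dna(500), strrep("AT", 20), rand_dna(460))
  expect_equal(detectSsr(s), ssr_oracle(s), tolerance = 1e-12)
  for (i in 1:5) {
    set.seed(510 + i)
    mix <- paste0(rand_dna(150), strrep(substr(rand_dna(3), 1, sample(1:6, 1)),
                                        sample(4:30, 1)), rand_dna(150))
    expect_equal(detectSsr(mix), ssr_oracle(mix), tolerance = 1e-12)
  }
})

test_that("protein search finds embedded coding sequence, not random DNA", {
  set.seed(52)
  prot <- random_protein(300, seed = 521)
  db <- Biostrings::AAStringSet(c(REF1 = prot,
                                  REF2 = random_protein(250, seed = 522)))
  cds <- rev_translate(prot, seed = 523)
  cons <- Biostrings::DNAStringSet(c(
    hit = paste0(rand_dna(200), cds, rand_dna(150)),
    miss = rand_dna(1200)))
  hits <- searchProtein(cons, db, evalue_max = 1e-5)
  expect_true("hit" %in% hits$query_id)
  h <- hits[hits$query_id == "hit" & hits$ref_id == "REF1", ]
  expect_lt(h$evalue, 1e-20)  # a 300-codon exact match is overwhelming
  expect_false("miss" %in% hits$query_id)
  # also detected on the reverse strand
  cons_rc <- Biostrings::DNAStringSet(c(hrc = rc(as.character(cons[["hit"]]))))
  hits_rc <- searchProtein(cons_rc, db, evalue_max = 1e-5)
  expect_true("hrc" %in% hits_rc$query_id)
  expect_equal(nrow(searchProtein(cons, Biostrings::AAStringSet())), 0L)
})

test_that("consensus cleaning removes SSRs and host genes, keeps RT hitters", {
  set.seed(53)
  host_prot <- random_protein(250, seed = 531)
  rt_prot <- random_protein(250, seed = 532)
  mk_cons <- function(seqs) {
    n <- length(seqs)
    new("ConsensusSet", sequences = Biostrings::DNAStringSet(seqs),
        info = S4Vectors::DataFrame(
          family_id = names(seqs), n_members = rep(2L, n),
          n_sampled = rep(2L, n), class = rep(NA_character_, n),
          removed = rep(FALSE, n), reason = rep(NA_character_, n)),
        samples = rep(list(character(0)), n), hits = rep(list(NULL), n))
  }
  cons <- mk_cons(c(
    clean = rand_dna(800),
    hostlike = paste0(rand_dna(100), rev_translate(host_prot, seed = 533),
                      rand_dna(100)),
    rt_and_host = paste0(rand_dna(50), rev_translate(host_prot, seed = 534),
                         rev_translate(rt_prot, seed = 535), rand_dna(50)),
    ssr = strrep("AC", 200)))
  host_db <- Biostrings::AAStringSet(c(HOST = host_prot))
  rt_db <- Biostrings::AAStringSet(c(RT = rt_prot))
  out <- filterConsensusSet(cons, host_db, rt_db)
  info <- consensusInfo(out)
  expect_equal(info$removed, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(info$reason[2], "host_protein")
  expect_equal(info$reason[4], "ssr")
  expect_equal(consensusInfo(keptConsensus(out))$family_id,
               c("clean", "rt_and_host"))
})

test_that("classification: well annotated, partial, unannotated", {
  set.seed(54)
  ref <- rand_dna(1000)
  lib <- Biostrings::DNAStringSet(c(REFA = ref))
  S4Vectors::metadata(lib)$class <- c(REFA = "LINE/L2")
  mk_cons <- function(seqs) {
    n <- length(seqs)
    new("ConsensusSet", sequences = Biostrings::DNAStringSet(seqs),
        info = S4Vectors::DataFrame(
          family_id = names(seqs), n_members = rep(2L, n),
          n_sampled = rep(2L, n), class = rep(NA_character_, n),
          removed = rep(FALSE, n), reason = rep(NA_character_, n)),
        samples = rep(list(character(0)), n), hits = rep(list(NULL), n))
  }
  cons <- mk_cons(c(
    full = mutate_to(ref, 0.95, seed = 541),             # ~full-length match
    partial = paste0(substr(ref, 1, 120), rand_dna(1000)), # 120bp hit, 11% cov
    none = rand_dna(900)))
  out <- classifyConsensus(cons, lib)
  info <- consensusInfo(out)
  expect_equal(info$class, c("well_annotated", "partially_annotated",
                             "unannotated"))
  expect_equal(info$ref_family[1], "REFA")
  expect_equal(info$ref_class[1], "LINE/L2")
  # the unclassified set is partial + unannotated
  expect_setequal(consensusInfo(unclassifiedConsensus(out))$family_id,
                  c("partial", "none"))
  # monotone: with an empty library everything is unannotated
  out0 <- classifyConsensus(cons, Biostrings::DNAStringSet())
  expect_true(all(consensusInfo(out0)$class == "unannotated"))
})

test_that("genome annotation resolves overlaps best-hit-first with trimming", {
  set.seed(55)
  anc <- rand_dna(600)
  # one planted copy at ~85% identity: invisible to the 0.94 self-alignment
  # gate but annotated at the relaxed 0.80 floor
  old_copy <- mutate_to(anc, 0.85, seed = 551)
  pg <- plant_genome(rand_dna(20000), c(anc, old_copy), c(5000, 15000))
  lib <- Biostrings::DNAStringSet(c(CONS = anc))
  ann <- annotateGenome(pg$genome, lib)
  expect_equal(length(ann), 2L)
  ov <- GenomicRanges::findOverlaps(ann, pg$truth)
  expect_equal(length(ov), 2L)
  expect_true(min(S4Vectors::mcols(ann)$identity) < 0.94)
  # best-hit resolution: no genome position annotated twice
  lib2 <- Biostrings::DNAStringSet(c(CONS = anc, SUB = substr(anc, 100, 400)))
  ann2 <- annotateGenome(pg$genome, lib2)
  cov <- IRanges::coverage(GenomicRanges::ranges(ann2))
  expect_lte(max(cov), 1L)
  # the higher-scoring full-length hit wins at each copy
  expect_equal(sum(S4Vectors::mcols(ann2)$query_id == "CONS"), 2L)
  expect_error(annotateGenome(pg$genome, Biostrings::DNAStringSet()), "empty")
})

test_that("repeat content summary counts union coverage per class", {
  gr <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 2001), c(1000, 2300)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    query_id = c("x", "y"), q_start = c(1L, 1L), q_end = c(1000L, 300L),
    identity = c(0.9, 0.9), score = c(500L, 200L),
    ref_class = c("LINE/L1", "unclassified"))
  tab <- summarizeRepeatContent(gr, 100000)
  expect_equal(tab$percent[tab$class == "LINE"], 1.0)
  expect_equal(tab$bp[tab$class == "Unclassified"], 300)
  expect_equal(sum(tab$bp), 1300)
  # empty annotation: all zeros
  tab0 <- summarizeRepeatContent(gr[0], 100000)
  expect_true(all(tab0$bp == 0))
})
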