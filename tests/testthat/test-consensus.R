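# member selection, center-star alignment, majority-vote consensus

test_that("member selection applies the 95% length rule and the sample cap", {
  ids <- c("a", "b", "c")
  expect_setequal(selectMembers(ids, c(1000, 960, 949)), c("a", "b"))
  expect_setequal(selectMembers(ids, c(1000, 950, 949)), c("a", "b"))
  expect_setequal(selectMembers(ids, c(100, 99, 98), length_fraction = 0.9),
                  ids)
  # 150 eligible members: exactly 100 sampled, longest always kept
  ids2 <- sprintf("m%03d", 1:150)
  lens <- c(2000L, rep(1950L, 149))
  sel <- selectMembers(ids2, lens, max_sample = 100L, rng_seed = 99L)
  expect_length(sel, 100L)
  expect_true("m001" %in% sel)
  # sampling is reproducible given the seed
  expect_identical(sel, selectMembers(ids2, lens, max_sample = 100L,
                                      rng_seed = 99L))
  expect_false(identical(sel, selectMembers(ids2, lens, max_sample = 100L,
                                            rng_seed = 100L)))
})

test_that("center-star alignment handles indels and round-trips rows", {
  s <- Biostrings::DNAStringSet(c(x = "ACGTACGT", y = "ACGACGT"))
  m <- alignMembers(s)
  expect_equal(ncol(m), 8L)
  expect_equal(sum(m == "-"), 1L)
  expect_equal(paste(m["y", m["y", ] != "-"], collapse = ""), "ACGACGT")
  # identical sequences align gap-free
  s2 <- Biostrings::DNAStringSet(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(sum(alignMembers(s2) == "-"), 0L)
  # degap round trip on random mutated families
  set.seed(41)
  anc <- rand_dna(300)
  fam <- Biostrings::DNAStringSet(vapply(1:6, function(i)
    mutate_to(anc, 0.95, seed = 410 + i), character(1)))
  names(fam) <- sprintf("m%d", 1:6)
  msa <- alignMembers(fam)
  expect_equal(length(unique(nchar(apply(msa, 1, paste, collapse = "")))), 1L)
  for (r in rownames(msa))
    expect_equal(paste(msa[r, msa[r, ] != "-"], collapse = ""),
                 as.character(fam[[r]]))
  expect_error(alignMembers(Biostrings::DNAStringSet()), "no sequences")
})

test_that("consensus voting: majorities, ties and gap-column dropping", {
  # all rows identical
  m <- matrix(rep(strsplit("ACGT", "")[[1]], 3), nrow = 3, byrow = TRUE)
  expect_equal(as.character(callConsensus(m)), "ACGT")
  # column {A,A,A,G} -> A ; column {A,A,G,G} -> A by the A<C<G<T tie rule
  m2 <- cbind(c("A", "A", "A", "G"), c("A", "A", "G", "G"),
              c("T", "T", "G", "G"))  # ties G vs T -> G (first in order)
  expect_equal(as.character(callConsensus(m2)), "AAG")
  # strict gap-majority columns are dropped; 50% gaps are kept
  m3 <- rbind(c("A", "-", "C"), c("A", "-", "C"), c("A", "-", "C"),
              c("A", "G", "C"))
  expect_equal(as.character(callConsensus(m3)), "AC")
  m4 <- rbind(c("A", "-"), c("A", "G"))
  expect_equal(as.character(callConsensus(m4)), "AG")
  # N only when every covering row is N
  m5 <- rbind(c("N", "N"), c("N", "A"))
  expect_equal(as.character(callConsensus(m5)), "NA")
})

test_that("consensus recovers the ancestor of a 2%-mutated family", {
  set.seed(42)
  anc <- rand_dna(800)
  fam <- Biostrings::DNAStringSet(vapply(1:20, function(i)
    mutate_to(anc, 0.98, seed = 420 + i), character(1)))
  names(fam) <- sprintf("m%02d", 1:20)
  cons <- callConsensus(alignMembers(fam))
  o <- sw_oracle(as.character(cons), anc)
  expect_gte(o$identity, 0.99)
  expect_gte(o$length / nchar(anc), 0.95)
  expect_lte(abs(length(cons) - nchar(anc)) / nchar(anc), 0.05)
})

test_that("5'-truncated members do not shorten or inflate the consensus", {
  set.seed(43)
  anc <- rand_dna(600)
  full <- vapply(1:6, function(i) mutate_to(anc, 0.99, seed = 430 + i),
                 character(1))
  truncd <- vapply(1:4, function(i)
    substr(mutate_to(anc, 0.99, seed = 440 + i), sample(10:25, 1), 600),
    character(1))
  fam <- Biostrings::DNAStringSet(c(full, truncd))
  names(fam) <- sprintf("m%02d", 1:10)
  cons <- callConsensus(alignMembers(fam))
  expect_lte(abs(length(cons) - 600) / 600, 0.02)
})

test_that("consensus building over a family set is deterministic", {
  set.seed(44)
  bg <- rand_dna(30000)
  anc <- rand_dna(400)
  copies <- vapply(1:4, function(i) mutate_to(anc, 0.98, seed = 440 + i),
                   character(1))
  pg <- plant_genome(bg, copies, c(5000, 12000, 19000, 26000))
  aln <- selfAlign(pg$genome)
  fams <- linkFamilies(buildPiles(alignmentImages(aln)), aln)
  c1 <- buildConsensusSet(fams, pg$genome, rng_seed = 7L)
  c2 <- buildConsensusSet(fams, pg$genome, rng_seed = 7L)
  expect_identical(as.character(consensusSequences(c1)),
                   as.character(consensusSequences(c2)))
  expect_identical(sampledMembers(c1), sampledMembers(c2))
  expect_equal(length(c1), 1L)
  o <- sw_oracle(as.character(consensusSequences(c1)[[1]]), anc)
  if (o$identity < 0.9) # family may be oriented as the reverse complement
    o <- sw_oracle(rc(as.character(consensusSequences(c1)[[1]])), anc)
  expect_gte(o$identity, 0.99)
})
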