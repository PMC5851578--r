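# seed-and-extend self-alignment against independent Smith-Waterman oracles

test_that("seed chains: exact duplicate pairs give the expected seed count", {
  set.seed(21)
  bg <- rand_dna(8000)
  copy <- rand_dna(300)
  pg <- plant_genome(bg, c(copy, copy), c(2000, 5000))
  ch <- findSeedChains(pg$genome)
  same <- ch[ch$orientation == "same", ]
  expect_gte(max(same$nseeds), 300 - 12 + 1)  # all 289 12-mers on one diagonal
  # reverse-complement copy appears as an opposite-orientation chain
  pg2 <- plant_genome(bg, c(copy, rc(copy)), c(2000, 5000))
  ch2 <- findSeedChains(pg2$genome)
  opp <- ch2[ch2$orientation == "opposite", ]
  expect_gte(max(opp$nseeds), 289)
  # a sequence with no shared 12-mer (either orientation) seeds nothing
  set.seed(210)
  expect_equal(nrow(findSeedChains(
    Biostrings::DNAStringSet(c(x = rand_dna(100))))), 0L)
})

test_that("two identical planted copies give one exact alignment", {
  set.seed(22)
  bg <- rand_dna(10000)
  copy <- rand_dna(300)
  pg <- plant_genome(bg, c(copy, copy), c(3000, 7000))
  aln <- selfAlign(pg$genome)
  expect_equal(length(aln), 1L)
  st <- alignmentStats(aln)
  expect_equal(st$identity, 1.0)
  # images match the planted intervals within the +-5 bp end slack
  expect_lte(abs(GenomicRanges::start(firstImage(aln)) -
                 GenomicRanges::start(pg$truth)[1]), 5)
  expect_lte(abs(GenomicRanges::end(secondImage(aln)) -
                 GenomicRanges::end(pg$truth)[2]), 5)
})

test_that("pairs below the identity gate are rejected, relaxed params accept", {
  set.seed(23)
  bg <- rand_dna(12000)
  copy <- rand_dna(300)
  div <- mutate_to(copy, 0.90, seed = 231)   # ~90% identity pair
  pg <- plant_genome(bg, c(copy, div), c(3000, 8000))
  # oracle confirms the true pair identity sits below 0.94
  expect_lt(sw_oracle(copy, div)$identity, 0.94)
  expect_equal(length(selfAlign(pg$genome)), 0L)
  # the published relaxed setting (90% / 200 bp) accepts a 91%-identity pair
  copy2 <- rand_dna(220)
  div2 <- mutate_to(copy2, 0.915, seed = 232)
  pg2 <- plant_genome(bg, c(copy2, div2), c(3000, 8000))
  expect_equal(length(selfAlign(pg2$genome)), 0L)  # defaults reject
  relaxed <- alignerParams(min_identity = 90, min_length = 200)
  aln <- selfAlign(pg2$genome, relaxed)
  expect_equal(length(aln), 1L)
  expect_gte(alignmentStats(aln)$identity, 0.90)
})

test_that("three identical copies give all unordered pairs", {
  set.seed(24)
  bg <- rand_dna(15000)
  copy <- rand_dna(500)
  pg <- plant_genome(bg, rep(copy, 3), c(3000, 8000, 12000))
  aln <- selfAlign(pg$genome)
  expect_equal(length(aln), 3L)
  expect_true(all(alignmentStats(aln)$identity == 1.0))
})

test_that("random genomes yield nothing; N-only genomes yield nothing", {
  set.seed(25)
  g <- Biostrings::DNAStringSet(c(chr1 = rand_dna(10000)))
  expect_equal(length(selfAlign(g)), 0L)
  gn <- Biostrings::DNAStringSet(c(chr1 = strrep("N", 5000)))
  expect_equal(length(selfAlign(gn)), 0L)
})

test_that("every reported alignment passes the gates under SW recomputation", {
  set.seed(26)
  bg <- rand_dna(40000)
  copies <- character(0); pos <- integer(0)
  anc1 <- rand_dna(400); anc2 <- rand_dna(600)
  for (i in 1:4) copies <- c(copies, mutate_to(anc1, 0.98, seed = 260 + i))
  for (i in 1:3) copies <- c(copies, mutate_to(anc2, 0.97, seed = 270 + i))
  copies[3] <- rc(copies[3])
  pg <- plant_genome(bg, copies, sort(c(5000, 11000, 17000, 23000, 29000,
                                        33000, 37000)))
  params <- alignerParams()
  aln <- selfAlign(pg$genome, params)
  expect_gt(length(aln), 0L)
  st <- alignmentStats(aln)
  expect_true(all(st$identity >= params@min_identity))
  expect_true(all(pmin(GenomicRanges::width(firstImage(aln)),
                       GenomicRanges::width(secondImage(aln))) >=
                  params@min_length))
  g <- pg$genome
  for (i in seq_along(aln)) {
    a <- extractInterval(g, firstImage(aln)[i])[[1]]
    b <- extractInterval(g, secondImage(aln)[i])[[1]]
    if (st$orientation[i] == "opposite")
      b <- Biostrings::reverseComplement(b)
    o <- sw_oracle(as.character(a), as.character(b))
    expect_gte(o$identity, params@min_identity)
    expect_gte(o$length, params@min_length - 10)
  }
})

test_that("planted pairs above the gates are all found with high image overlap", {
  set.seed(27)
  bg <- rand_dna(30000)
  anc <- rand_dna(320)
  copies <- vapply(1:4, function(i) mutate_to(anc, 0.975, seed = 280 + i),
                   character(1))
  pg <- plant_genome(bg, copies, c(6000, 12000, 18000, 24000))
  aln <- selfAlign(pg$genome)
  expect_equal(length(aln), choose(4, 2))
  # Jaccard overlap of each image with its planted interval >= 0.9
  imgs <- c(firstImage(aln), secondImage(aln))
  ov <- GenomicRanges::findOverlaps(imgs, pg$truth)
  expect_equal(length(ov), length(imgs))
  inter <- GenomicRanges::width(GenomicRanges::pintersect(
    imgs[S4Vectors::queryHits(ov)], pg$truth[S4Vectors::subjectHits(ov)]))
  uni <- GenomicRanges::width(imgs[S4Vectors::queryHits(ov)]) +
    GenomicRanges::width(pg$truth[S4Vectors::subjectHits(ov)]) - inter
  expect_true(all(inter / uni >= 0.9))
})

test_that("thresholds are monotone: relaxing them never removes alignments", {
  set.seed(28)
  bg <- rand_dna(20000)
  anc <- rand_dna(400)
  copies <- c(mutate_to(anc, 0.99, seed = 291), mutate_to(anc, 0.96, seed = 292),
              mutate_to(anc, 0.95, seed = 293))
  pg <- plant_genome(bg, copies, c(4000, 10000, 16000))
  strict <- selfAlign(pg$genome, alignerParams(min_identity = 0.94))
  relaxed <- selfAlign(pg$genome, alignerParams(min_identity = 0.90))
  shorter <- selfAlign(pg$genome, alignerParams(min_identity = 0.90,
                                                min_length = 150))
  expect_gt(length(strict), 0L)
  expect_gte(length(relaxed), length(strict))
  expect_gte(length(shorter), length(relaxed))
  key <- function(x) paste(GenomicRanges::start(firstImage(x)),
                           GenomicRanges::start(secondImage(x)))
  expect_true(all(key(strict) %in% key(relaxed)))
})

test_that("banded alignment primitive agrees with the SW oracle", {
  set.seed(29)
  for (i in 1:5) {
    a <- rand_dna(200)
    b <- paste0(rand_dna(30), mutate_to(a, 0.95, seed = 300 + i), rand_dna(30))
    r <- bandedAlign(a, b, band = 40)
    o <- sw_oracle(a, b)
    expect_false(is.null(r))
    # the banded score can only reach the unconstrained optimum
    expect_lte(r$score, o$score)
    expect_gte(r$score, 0.9 * o$score)
  }
})
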