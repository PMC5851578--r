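# pile construction and single-linkage clustering

test_that("piles merge by fractional overlap of the shorter image", {
  im <- GenomicRanges::GRanges(c("c:100-399", "c:150-449"))
  p <- buildPiles(im, min_overlap = 0.5)   # overlap 250 / shorter 300 = 0.83
  expect_equal(length(p), 1L)
  expect_equal(GenomicRanges::start(p), 100L)
  expect_equal(GenomicRanges::end(p), 449L)
  expect_equal(sort(unlist(S4Vectors::mcols(p)$image_ids)), 1:2)
  # below the fraction: stays separate even though the ranges touch
  im2 <- GenomicRanges::GRanges(c("c:100-399", "c:300-899"))  # 100/300 = 0.33
  expect_equal(length(buildPiles(im2, 0.5)), 2L)
  expect_equal(length(buildPiles(im2, 0.3)), 1L)
  # disjoint images and the empty case
  expect_equal(length(buildPiles(GenomicRanges::GRanges(c("c:1-100", "c:500-600")))), 2L)
  expect_equal(length(buildPiles(GenomicRanges::GRanges())), 0L)
})

test_that("pile merging is transitive", {
  im <- GenomicRanges::GRanges(c("c:100-299", "c:200-399", "c:300-499"))
  # 1-2 and 2-3 overlap 50%; 1-3 do not overlap at all
  p <- buildPiles(im, 0.5)
  expect_equal(length(p), 1L)
  expect_equal(GenomicRanges::width(p), 400L)
})

# build a RepeatAlignments object directly for clustering tests
mk_aln <- function(a, b, orientation = NULL) {
  n <- length(a)
  if (is.null(orientation)) orientation <- rep("same", n)
  new("RepeatAlignments", first = GenomicRanges::GRanges(a),
      second = GenomicRanges::GRanges(b),
      stats = S4Vectors::DataFrame(identity = rep(0.99, n),
                                   score = seq_len(n) + 100L,
                                   matches = rep(100L, n),
                                   columns = rep(101L, n),
                                   orientation = orientation))
}

test_that("single linkage links transitively and drops singletons", {
  # alignments p1-p2 and p2-p3: one family of three
  aln <- mk_aln(c("c:1000-1299", "c:2000-2299"),
                c("c:2000-2299", "c:3000-3299"))
  inst <- buildPiles(alignmentImages(aln))
  fams <- linkFamilies(inst, aln)
  expect_equal(length(familyIds(fams)), 1L)
  expect_equal(length(familyMembers(fams, familyIds(fams))), 3L)
  ed <- familyEdges(fams)
  expect_equal(nrow(ed), 2L)
  # no alignments: no families
  empty <- mk_aln(character(0), character(0))
  f0 <- linkFamilies(buildPiles(alignmentImages(empty)), empty)
  expect_equal(length(familyIds(f0)), 0L)
})

test_that("connected components agree with a brute-force union-find oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n_loci <- 20L
    loci <- GenomicRanges::GRanges("c", IRanges::IRanges(
      start = seq(1000, by = 1000, length.out = n_loci), width = 300))
    n_edges <- sample(5:25, 1)
    ef <- sample(n_loci, n_edges, replace = TRUE)
    et <- sample(n_loci, n_edges, replace = TRUE)
    keep <- ef != et
    ef <- ef[keep]; et <- et[keep]
    aln <- mk_aln(sprintf("c:%d-%d", 1000 * ef, 1000 * ef + 299),
                  sprintf("c:%d-%d", 1000 * et, 1000 * et + 299))
    inst <- buildPiles(alignmentImages(aln))
    fams <- linkFamilies(inst, aln)
    # oracle on the loci
    comp <- uf_components(n_loci, ef, et)
    sizes <- table(comp)
    oracle_fams <- sum(sizes >= 2)
    expect_equal(length(familyIds(fams)), oracle_fams)
    fam_sizes <- sort(as.integer(table(S4Vectors::mcols(
      instanceRanges(fams))$family_id)))
    expect_equal(fam_sizes, sort(as.integer(sizes[sizes >= 2])))
  }
})

test_that("two planted element types end in two separate families", {
  set.seed(32)
  bg <- rand_dna(40000)
  a <- rand_dna(400); b <- rand_dna(500)
  copies <- c(mutate_to(a, 0.99, seed = 321), mutate_to(a, 0.99, seed = 322),
              mutate_to(a, 0.99, seed = 323),
              mutate_to(b, 0.98, seed = 324), mutate_to(b, 0.98, seed = 325),
              mutate_to(b, 0.98, seed = 326))
  pg <- plant_genome(bg, copies, c(5000, 11000, 17000, 23000, 29000, 35000))
  aln <- selfAlign(pg$genome)
  fams <- linkFamilies(buildPiles(alignmentImages(aln)), aln)
  ids <- familyIds(fams)
  expect_equal(length(ids), 2L)
  sizes <- sort(vapply(ids, function(f) length(familyMembers(fams, f)),
                       integer(1)))
  expect_equal(unname(sizes), c(3L, 3L))
  # partition: family sizes sum to the non-singleton instance count
  mc <- S4Vectors::mcols(instanceRanges(fams))
  expect_equal(sum(!is.na(mc$family_id)), 6L)
  expect_false(anyDuplicated(mc$instance_id) > 0)
})

test_that("member export is oriented and round-trips through its names", {
  set.seed(33)
  bg <- rand_dna(30000)
  anc <- rand_dna(400)
  copies <- c(mutate_to(anc, 0.99, seed = 331), mutate_to(anc, 0.99, seed = 332),
              rc(mutate_to(anc, 0.99, seed = 333)))
  pg <- plant_genome(bg, copies, c(5000, 15000, 25000))
  aln <- selfAlign(pg$genome)
  fams <- linkFamilies(buildPiles(alignmentImages(aln)), aln)
  fid <- familyIds(fams)
  expect_equal(length(fid), 1L)
  mem <- exportFamilyMembers(fams, pg$genome, fid)
  expect_equal(length(mem), 3L)
  # all exported members are near-identical on the SAME strand: the
  # reverse-complemented copy was flipped to the family orientation
  for (i in 2:3) {
    o <- sw_oracle(as.character(mem[[1]]), as.character(mem[[i]]))
    expect_gte(o$identity, 0.95)
    expect_gte(o$length, 350)
  }
  # names parse back to the exact member intervals
  back <- parseMemberNames(names(mem))
  inst <- familyMembers(fams, fid)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(inst))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(inst))
  expect_equal(as.character(S4Vectors::mcols(back)$family_id),
               rep(fid, 3))
})
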