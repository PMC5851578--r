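# ORF scanning and reverse-transcriptase domain detection

test_that("a constructed 1503 nt ORF is found; an internal stop kills it", {
  set.seed(71)
  prot <- random_protein(500, seed = 711)
  orf <- paste0("ATG", rev_translate(substr(prot, 2, 500), seed = 712), "TAA")
  expect_equal(nchar(orf), 1503L)
  s <- paste0(rand_dna(211), orf, rand_dna(300))
  found <- findOrfs(s)
  expect_equal(nrow(found), 1L)
  expect_equal(found$nt_length, 1503L)
  expect_equal(nchar(found$protein), 500L)
  expect_equal(found$start, 212L)
  expect_equal(found$end, 212L + 1503L - 1L)
  # a single internal stop codon splits the frame below the floor
  broken <- paste0(substr(orf, 1, 750), "TAA", substr(orf, 754, 1503))
  expect_equal(nrow(findOrfs(paste0(rand_dna(211), broken, rand_dna(300)))), 0L)
  # a frameshift (single-base deletion) likewise disqualifies
  shifted <- paste0(substr(orf, 1, 750), substr(orf, 752, 1503))
  expect_equal(nrow(findOrfs(paste0(rand_dna(211), shifted, rand_dna(300)))), 0L)
})

test_that("ORF scan agrees with a codon-walk oracle on both strands", {
  set.seed(72)
  for (i in 1:6) {
    s <- rand_dna(8000, seed = 720 + i)
    min_nt <- 300L
    got <- findOrfs(s, min_orf_nt = min_nt)
    fwd <- orf_oracle_one_strand(s, min_nt)
    rev <- orf_oracle_one_strand(rc(s), min_nt)
    L <- nchar(s)
    exp_rows <- rbind(
      if (nrow(fwd)) cbind(fwd, strand = 1L),
      if (nrow(rev)) cbind(start = L - rev[, "end"] + 1L,
                           end = L - rev[, "start"] + 1L, strand = 2L))
    expect_equal(nrow(got), NROW(exp_rows))
    if (NROW(exp_rows)) {
      ord <- order(exp_rows[, "start"], exp_rows[, "end"])
      expect_equal(got$start, unname(exp_rows[ord, "start"]))
      expect_equal(got$end, unname(exp_rows[ord, "end"]))
    }
  }
})

test_that("ORF output is invariant under reverse complement", {
  set.seed(73)
  s <- paste0(rand_dna(100), "ATG", rev_translate(random_protein(120), ),
              "TGA", rand_dna(100))
  a <- findOrfs(s, min_orf_nt = 300L)
  b <- findOrfs(rc(s), min_orf_nt = 300L)
  L <- nchar(s)
  expect_equal(nrow(a), nrow(b))
  expect_setequal(paste(L - a$end + 1L, L - a$start + 1L),
                  paste(b$start, b$end))
  expect_setequal(a$protein, b$protein)
})

test_that("RT domain detection enforces envelope length and significance", {
  set.seed(74)
  rt <- random_protein(250, seed = 741)
  refs <- Biostrings::AAStringSet(c(RT1 = rt,
                                    RT2 = random_protein(300, seed = 742)))
  prot <- paste0(random_protein(100, seed = 743), rt,
                 random_protein(50, seed = 744))
  hit <- detectRtDomain(prot, refs)
  expect_false(is.null(hit))
  expect_equal(hit$ref_id, "RT1")
  expect_gte(hit$aa_length, 250L)
  expect_equal(c(hit$start, hit$end), c(101L, 350L))
  expect_lt(hit$evalue, 1e-20)
  # a 150-aa envelope fails the 200-aa floor even at a good E-value
  short_prot <- paste0(random_protein(100, seed = 745), substr(rt, 1, 150),
                       random_protein(100, seed = 746))
  expect_null(detectRtDomain(short_prot, refs))
  # random proteins do not qualify
  expect_null(detectRtDomain(random_protein(600, seed = 747), refs))
  expect_error(detectRtDomain(prot, Biostrings::AAStringSet()), "empty")
})

test_that("activity flag requires an intact ORF2 with an RT envelope", {
  set.seed(75)
  rt <- random_protein(300, seed = 751)
  refs <- Biostrings::AAStringSet(c(RT = rt))
  orf2_prot <- paste0(random_protein(150, seed = 752), rt,
                      random_protein(49, seed = 753))
  orf2 <- paste0("ATG", rev_translate(orf2_prot, seed = 754), "TAA")
  orf1 <- paste0("ATG", rev_translate(random_protein(340, seed = 755),
                                      seed = 756), "TGA")
  utr <- rand_dna(120)
  intact <- paste0(utr, orf1, "AC", orf2, rand_dna(150))
  # ORF1 disrupted by an internal stop: still active (ORF2 decides)
  orf1_broken <- paste0(substr(orf1, 1, 500), "TAA", substr(orf1, 504, nchar(orf1)))
  orf1_dead <- paste0(utr, orf1_broken, "AC", orf2, rand_dna(150))
  # ORF2 frameshifted: inactive
  orf2_fs <- paste0(substr(orf2, 1, 600), substr(orf2, 602, nchar(orf2)))
  dead <- paste0(utr, orf1, "AC", orf2_fs, rand_dna(150))
  els <- Biostrings::DNAStringSet(c(intact = intact, orf1_dead = orf1_dead,
                                    dead = dead))
  res <- flagPotentiallyActive(els, refs)
  expect_equal(res$active, c(TRUE, TRUE, FALSE))
  expect_equal(res$rt_ref[1], "RT")
  expect_gte(res$protein_length[1], 500L)
  # members on the minus strand are still detected
  els_rc <- Biostrings::DNAStringSet(c(intact_rc = rc(intact)))
  expect_true(flagPotentiallyActive(els_rc, refs)$active)
  # no false calls on ORF-free random sequence
  set.seed(76)
  rand_els <- Biostrings::DNAStringSet(setNames(
    vapply(1:20, function(i) rand_dna(4000), character(1)),
    sprintf("r%02d", 1:20)))
  expect_false(any(flagPotentiallyActive(rand_els, refs)$active))
})
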