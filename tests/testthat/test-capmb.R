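test_that("null candidate streams are ordered by gap-frequency products", {
  # equal-length alignment: the single empty candidate
  aln0 <- list(rows = c("ACGT", "ACGT"), weights = c(1, 1), l_align = 4L)
  nc <- null_rank(aln0, 4L)
  expect_length(nc, 1)
  expect_identical(nc[[1]]$positions, integer(0))

  # one excess column; gaps at col 2 (freq 4/5) and col 4 (freq 1/5)
  aln1 <- list(rows = c("A-GTA", "A-GTA", "A-GTA", "A-GT-", "ACGTA"),
               weights = rep(1, 5), l_align = 5L)
  nc1 <- null_rank(aln1, 4L)
  expect_identical(nc1[[1]]$positions, 2L)
  expect_identical(nc1[[2]]$positions, 5L)
  expect_equal(nc1[[1]]$score, 0.8)

  # two excess columns over three null-bearing columns: matches exhaustive
  # enumeration ordered by score
  rows2 <- c("A--GTC", "AC-G-C", "A-CG-C")
  aln2 <- list(rows = rows2, weights = c(2, 1, 1), l_align = 6L)
  nc2 <- null_rank(aln2, 4L)
  gap <- vapply(strsplit(rows2, ""), function(r) r == "-", logical(6))
  freq <- as.numeric(gap %*% c(2, 1, 1)) / 4
  oracle <- exhaustive_null_stream(freq, which(freq > 0), 2L)
  expect_identical(lapply(nc2, `[[`, "positions"),
                   lapply(oracle, `[[`, "positions"))

  # fewer null-bearing columns than the excess: unconsensusable
  aln3 <- list(rows = c("AC-GT", "AC-GT"), weights = c(1, 1), l_align = 5L)
  expect_length(null_rank(aln3, 3L), 0)
})

test_that("bit candidate streams start at the majority and follow product order", {
  # unanimous matrix: a single candidate equal to the row
  bm <- matrix(rep(c(0L, 1L, 1L, 0L), 3), nrow = 3, byrow = TRUE)
  bc <- bit_rank(bm, rep(1, 3))
  expect_length(bc, 1)
  expect_identical(bc[[1]]$bits, c(0L, 1L, 1L, 0L))

  # one position split 2 vs 1: two candidates with score ratio 2:1
  bm2 <- rbind(c(0L, 1L), c(0L, 1L), c(0L, 0L))
  bc2 <- bit_rank(bm2, rep(1, 3))
  expect_length(bc2, 2)
  expect_identical(bc2[[1]]$bits, c(0L, 1L))
  expect_identical(bc2[[2]]$bits, c(0L, 0L))
  expect_equal(bc2[[1]]$score / bc2[[2]]$score, 2)

  # three split positions: the first 8 candidates match exhaustive order
  withr::with_seed(41, {
    bm3 <- rbind(sample(0:1, 10, replace = TRUE))
    bm3 <- rbind(bm3, bm3, bm3)
    bm3[2, c(2, 5, 9)] <- 1L - bm3[2, c(2, 5, 9)]
    bm3[3, 5] <- 1L - bm3[3, 5]
    w <- c(2, 1, 1)
    got <- bit_rank(bm3, w)
    oracle <- exhaustive_bit_stream(bm3, w)
    expect_identical(lapply(got, `[[`, "bits"),
                     lapply(oracle[seq_along(got)], `[[`, "bits"))
  })

  # abstentions: a gap row does not vote; all-abstain positions are fatal
  bm4 <- rbind(c(0L, NA), c(0L, NA))
  expect_null(bit_rank(bm4, c(1, 1)))
  bm5 <- rbind(c(0L, 1L), c(0L, NA))
  bc5 <- bit_rank(bm5, c(1, 1))
  expect_identical(bc5[[1]]$bits, c(0L, 1L))
})

test_that("lazy flip-set enumeration reproduces exhaustive ordering at larger widths", {
  withr::with_seed(53, {
    for (rep in 1:5) {
      n <- 14
      w <- c(3, 2, 1)
      bm <- rbind(sample(0:1, n, replace = TRUE))
      bm <- rbind(bm, bm, bm)
      flip2 <- sample(n, 6); bm[2, flip2] <- 1L - bm[2, flip2]
      flip3 <- sample(n, 5); bm[3, flip3] <- 1L - bm[3, flip3]
      got <- bit_rank(bm, w, budget = 300L)
      oracle <- exhaustive_bit_stream(bm, w)
      got_scores <- vapply(got, `[[`, numeric(1), "score")
      want_scores <- vapply(oracle[seq_along(got)], `[[`, numeric(1), "score")
      expect_equal(got_scores, want_scores, tolerance = 1e-9)
      # scores are non-increasing along the stream
      expect_true(all(diff(got_scores) <= 1e-12))
    }
  })
})

test_that("consensus recovers planted errors and always passes detection", {
  o <- make_test_oligos(2, seed = 33)
  oligo <- o$bases[1]

  # identical clean reads: immediate success on the first candidates
  cl <- sphere_cluster(rep(oligo, 3), tau_e = 5)[[1]]
  res <- capmb(center_star_msa(cl))
  expect_identical(res$status, "error_free")
  expect_identical(res$sequence, oligo)
  expect_identical(res$null_candidates_tried, 1L)
  expect_identical(res$bit_candidates_tried, 1L)

  # one read of three carries a substitution: majority is already clean
  cl2 <- sphere_cluster(c(oligo, oligo, substitute_base(oligo, 60)),
                        tau_e = 5)[[1]]
  res2 <- capmb(center_star_msa(cl2))
  expect_identical(res2$status, "error_free")
  expect_identical(res2$sequence, oligo)

  # two-read cluster with a tie broken toward the wrong bit: a later
  # candidate passes detection and equals the truth. Substituting T -> A
  # flips two true 1-bits; the 0.5 ties resolve to 0 (the wrong value).
  tpos <- which(strsplit(oligo, "")[[1]] == "T")[1]
  wrong <- paste0(substr(oligo, 1, tpos - 1), "A",
                  substr(oligo, tpos + 1, 152))
  cl3 <- sphere_cluster(c(oligo, wrong), tau_e = 5)[[1]]
  res3 <- capmb(center_star_msa(cl3))
  expect_identical(res3$status, "error_free")
  expect_identical(res3$sequence, oligo)
  expect_gt(res3$bit_candidates_tried, 1L)

  # whatever is returned passes the inner detection (definitional)
  expect_true(parse_oligo(res3$sequence)$detect_pass)
})

test_that("adding a clean duplicate never breaks a correct consensus", {
  o <- make_test_oligos(3, seed = 44)
  withr::with_seed(15, {
    for (i in 1:10) {
      oligo <- o$bases[sample(3, 1)]
      reads <- c(oligo, oligo, substitute_base(oligo, sample(1:152, 1)))
      base_res <- capmb(center_star_msa(sphere_cluster(reads, 5)[[1]]))
      expect_identical(base_res$sequence, oligo)
      grown <- capmb(center_star_msa(sphere_cluster(c(reads, oligo), 5)[[1]]))
      expect_identical(grown$sequence, oligo)
    }
  })
})

test_that("clusters with indel members consense through null selection", {
  o <- make_test_oligos(1, seed = 55)$bases
  # EDOL center with a substitution plus two AL single-deletion reads
  edol <- substitute_base(o, 30)
  al1 <- delete_base_at(o, 90)
  al2 <- delete_base_at(o, 120)
  cl <- stage3_cluster(edol, c(al1, al2), cluster_thresholds())[[1]]
  expect_identical(cl$size, 3L)
  res <- capmb(center_star_msa(cl))
  expect_identical(res$status, "error_free")
  expect_identical(res$sequence, o)

  # an insertion-bearing member: l_align exceeds 152, nulls must be dropped
  al3 <- insert_base_at(o, 50, "G")
  cl2 <- stage3_cluster(edol, c(al1, al3), cluster_thresholds())[[1]]
  aln <- center_star_msa(cl2)
  expect_identical(aln$alignment$l_align, 153L)
  res2 <- capmb(aln)
  expect_identical(res2$status, "error_free")
  expect_identical(res2$sequence, o)
})
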