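test_that("edit distance counts match independent oracles and the length identity", {
  expect_identical(edit_distance_counts("ACGT", "ACGT"),
                   c(sub = 0L, del = 0L, ins = 0L))
  expect_identical(sum(edit_distance_counts("ACGT", "AGT")), 1L)
  expect_identical(edit_distance_counts("ACGT", "AGT")[["del"]], 1L)

  withr::with_seed(31, {
    for (i in 1:1000) {
      a <- random_bases(1, sample(0:12, 1))
      b <- random_bases(1, sample(0:12, 1))
      if (nchar(a) == 0) a <- ""
      cnt <- edit_distance_counts(a, b)
      expect_identical(sum(cnt), brute_edit(a, b))
      expect_identical(cnt[["del"]] - cnt[["ins"]],
                       nchar(a) - nchar(b))
    }
    # longer strings against base R's Levenshtein
    for (i in 1:200) {
      a <- random_bases(1, sample(50:160, 1))
      b <- random_bases(1, sample(50:160, 1))
      expect_identical(sum(edit_distance_counts(a, b)),
                       as.integer(utils::adist(a, b)))
    }
  })
})

test_that("adjusted distance discounts the forced length difference and stays non-negative", {
  o <- make_test_oligos(1, seed = 1)$bases
  expect_identical(adjusted_distance(o, o), 0L)
  q2 <- delete_base_at(delete_base_at(o, 100), 30)
  expect_identical(adjusted_distance(o, q2), 0L)
  q3 <- substitute_base(delete_base_at(o, 80), 20)
  expect_identical(adjusted_distance(o, q3), 1L)
  withr::with_seed(17, {
    for (i in 1:200) {
      a <- random_bases(1, sample(5:40, 1))
      b <- random_bases(1, sample(5:40, 1))
      expect_gte(adjusted_distance(a, b), 0L)
    }
  })
})

test_that("stage-1 clustering groups identical reads and sorts by size then sequence", {
  cl <- stage1_cluster(c("ACGT", "TTTT", "ACGT"))
  expect_length(cl, 2)
  expect_identical(cl[[1]]$center, "ACGT")
  expect_identical(cl[[1]]$size, 2L)
  expect_identical(cl[[2]]$center, "TTTT")
  # all distinct: all singletons, lexicographic on ties
  cl2 <- stage1_cluster(c("TT", "AA", "GG"))
  expect_identical(vapply(cl2, `[[`, "", "center"), c("AA", "GG", "TT"))
  expect_true(all(vapply(cl2, `[[`, integer(1), "size") == 1L))
})

test_that("sphere clustering absorbs reads within the radius greedily", {
  o <- make_test_oligos(2, seed = 9)$bases
  near <- substitute_base(o[1], 33)
  cl <- sphere_cluster(c(o[1], o[1], near), tau_e = 5)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$center, o[1])
  expect_identical(cl[[1]]$size, 3L)
  expect_identical(sort(cl[[1]]$members$distance), c(0L, 1L))

  # beyond the radius: separate clusters (distinct oligos differ by >> 5)
  cl2 <- sphere_cluster(c(o[1], o[2]), tau_e = 5)
  expect_length(cl2, 2)
  cl3 <- sphere_cluster(o[1], tau_e = 5)
  expect_length(cl3, 1)
  expect_identical(cl3[[1]]$size, 1L)
})

test_that("stage-3 clustering assigns AL reads by adjusted distance with per-type caps", {
  o <- make_test_oligos(3, seed = 12)$bases
  edol <- substitute_base(o[1], 5)
  al_del <- delete_base_at(edol, 70)              # adjusted 0 to edol
  cl <- stage3_cluster(edol, al_del, cluster_thresholds(tau_adj = 4))
  expect_length(cl, 1)
  expect_identical(cl[[1]]$size, 2L)
  expect_identical(cl[[1]]$members$adjusted[2], 0L)

  # 3 substitutions + 2 deletions: adjusted 3 joins, capped e_sub <= 2 excludes
  q <- delete_base_at(delete_base_at(
         substitute_base(substitute_base(substitute_base(edol, 10), 50), 90),
         120), 140)
  cl2 <- stage3_cluster(edol, q, cluster_thresholds(tau_adj = 4))
  expect_identical(cl2[[1]]$size, 2L)
  expect_identical(cl2[[1]]$members$e_sub[2], 3L)
  cl3 <- stage3_cluster(edol, q, cluster_thresholds(tau_adj = 4, cap_sub = 2))
  expect_identical(cl3[[1]]$size, 1L)

  # AL read from a different oligo stays unclustered
  far <- delete_base_at(o[2], 40)
  cl4 <- stage3_cluster(edol, far, cluster_thresholds(tau_adj = 4))
  expect_identical(cl4[[1]]$size, 1L)

  # an AL read matching two centers joins the smaller adjusted distance
  c1 <- o[3]
  c2 <- substitute_base(substitute_base(o[3], 20), 60)
  q2 <- delete_base_at(substitute_base(o[3], 20), 100)   # adj 1 to c1, 1 to c2
  # make it closer to c2: one sub shared with c2
  cl5 <- stage3_cluster(c(c1, c2), q2, cluster_thresholds(tau_adj = 4))
  joined <- which(vapply(cl5, `[[`, integer(1), "size") == 2L)
  expect_length(joined, 1)
  adj_both <- c(adjusted_distance(c1, q2), adjusted_distance(c2, q2))
  # the joined center must be one achieving the minimum adjusted distance
  ctr <- cl5[[joined]]$center
  expect_identical(adjusted_distance(ctr, q2), min(adj_both))
})

test_that("center-star alignment merges gaps stably and preserves members", {
  o <- make_test_oligos(1, seed = 20)$bases
  # identical members: no gaps
  cl <- sphere_cluster(c(o, o, o), tau_e = 5)[[1]]
  aln <- center_star_msa(cl)$alignment
  expect_identical(aln$l_align, 152L)
  expect_false(any(grepl("-", aln$rows, fixed = TRUE)))

  # one member with a deletion: that row gains a gap, l_align stays 152
  cl2 <- stage3_cluster(o, delete_base_at(o, 77), cluster_thresholds())[[1]]
  aln2 <- center_star_msa(cl2)$alignment
  expect_identical(aln2$l_align, 152L)
  expect_identical(unname(vapply(aln2$rows, function(r)
    sum(strsplit(r, "")[[1]] == "-"), integer(1))), c(0L, 1L))

  # one member with an insertion: the center row gains a gap, l_align 153
  cl3 <- stage3_cluster(o, insert_base_at(o, 40, "C"), cluster_thresholds())[[1]]
  aln3 <- center_star_msa(cl3)$alignment
  expect_identical(aln3$l_align, 153L)
  expect_identical(sum(strsplit(aln3$center_row, "")[[1]] == "-"), 1L)

  # degapping any row reproduces the member exactly (random indel mixes)
  withr::with_seed(27, {
    for (i in 1:25) {
      q <- o
      for (k in seq_len(sample(1:3, 1))) {
        pos <- sample(3:149, 1)
        q <- if (runif(1) < 0.5) delete_base_at(q, pos) else
          insert_base_at(q, pos, sample(c("A", "C", "G", "T"), 1))
      }
      if (sample(c(TRUE, FALSE), 1)) q <- substitute_base(q, sample(1:140, 1))
      cl <- list(center = o,
                 members = data.frame(bases = c(o, q), count = c(2L, 1L),
                                      stringsAsFactors = FALSE),
                 size = 3L, alignment = NULL)
      class(cl) <- "read_cluster"
      aln <- center_star_msa(cl)$alignment
      expect_identical(gsub("-", "", aln$rows, fixed = TRUE), c(o, q))
      expect_true(all(nchar(aln$rows) == aln$l_align))
    }
  })
})
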