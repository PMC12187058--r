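test_that("default profiles carry the measured per-class statistics", {
  pr <- default_profiles()
  expect_equal(pr$PF$sub_rate, 0.0009)
  expect_equal(pr$PF$del_rate, 0.0005)
  expect_equal(pr$PF$ins_rate, 0.0001)
  expect_equal(pr$NPF$sub_rate, 0.0384)
  expect_equal(pr$NPF$del_rate, 0.0008)
  expect_equal(pr$NPF$ins_rate, 0.0004)
  # run distributions are the printed percentages renormalized to sum to one
  expect_equal(unname(pr$PF$runs$del[1]), 0.7467, tolerance = 2e-4)
  expect_equal(unname(pr$NPF$runs$sub[1]), 0.8489, tolerance = 2e-4)
  expect_equal(unname(pr$NPF$length_dist[["152"]]), 0.5637, tolerance = 1e-6)
  expect_equal(unname(pr$PF$length_dist[["failure"]]), 0.0894, tolerance = 1e-3)
  expect_equal(sum(pr$PF$length_dist), 1)
  expect_equal(sum(pr$NPF$length_dist), 1)
})

test_that("the channel is silent at zero rates and saturates at rate one", {
  oligo <- make_test_oligos(1, seed = 2)$bases
  withr::with_seed(1, {
    cr <- corrupt_read(oligo, zero_profile())
    expect_identical(cr$bases, oligo)
    expect_identical(nrow(cr$script), 0L)

    sat <- error_profile(1, 0, 0,
                         sub_runs = c(1, 0, 0, 0), del_runs = c(1, 0, 0, 0),
                         ins_runs = c(1, 0, 0, 0),
                         length_dist = c(0, 0, 0, 1, 0, 0),
                         f_bad = 0, m_bad = 1)
    cr2 <- corrupt_read(oligo, sat)
    a <- strsplit(oligo, "")[[1]]
    b <- strsplit(cr2$bases, "")[[1]]
    expect_identical(length(b), length(a))
    expect_true(all(a != b))
  })
})

test_that("every error script replays exactly from oligo to read", {
  oligos <- make_test_oligos(5, seed = 4)
  pr <- default_profiles()
  withr::with_seed(6, {
    for (i in 1:200) {
      o <- oligos$bases[sample(5, 1)]
      cr <- corrupt_read(o, pr$NPF, multiplier = sample(c(1, 15), 1))
      expect_identical(replay_script(o, cr$script), cr$bases)
    }
  })
  # and through the full simulator (length forcing included)
  rs <- simulate_readset(oligos, 400, rng_seed = 9)
  scripts <- attr(rs, "scripts")
  for (i in seq_len(nrow(rs))) {
    expect_identical(replay_script(oligos$bases[rs$true_oligo[i]],
                                   scripts[[rs$id[i]]]),
                     rs$bases[i])
  }
})

test_that("simulated read sets honor class fractions, length forcing and determinism", {
  oligos <- make_test_oligos(4, seed = 3)
  profiles <- list(PF = zero_profile(), NPF = zero_profile())
  rs <- simulate_readset(oligos, 200, profiles = profiles, pf_fraction = 1,
                         rng_seed = 5)
  expect_true(all(rs$pf_class == "PF"))
  expect_identical(attr(rs, "n_failed"), 0L)
  # zero-error channel with forced length 152: reads equal their sources
  expect_identical(rs$bases, oligos$bases[rs$true_oligo])

  rs2 <- simulate_readset(oligos, 200, profiles = profiles, pf_fraction = 1,
                          rng_seed = 5)
  expect_identical(rs, rs2)
  rs3 <- simulate_readset(oligos, 200, profiles = profiles, pf_fraction = 0,
                          rng_seed = 5)
  expect_true(all(rs3$pf_class == "NPF"))
})

test_that("per-read error counts are overdispersed relative to the matched binomial", {
  oligo <- make_test_oligos(1, seed = 8)
  # substitution-only profile with the concentration mixture on
  pr <- error_profile(0.02, 0, 0,
                      sub_runs = c(1, 0, 0, 0), del_runs = c(1, 0, 0, 0),
                      ins_runs = c(1, 0, 0, 0),
                      length_dist = c(0, 0, 0, 1, 0, 0),
                      f_bad = 0.05, m_bad = 15)
  rs <- simulate_readset(oligo, 3000, profiles = list(PF = pr, NPF = pr),
                         pf_fraction = 1, rng_seed = 12)
  scripts <- attr(rs, "scripts")
  counts <- vapply(scripts, function(s) sum(s$len[s$type == "sub"]), numeric(1))
  p_hat <- mean(counts) / 152
  binom_var <- 152 * p_hat * (1 - p_hat)
  expect_gt(var(counts), 1.5 * binom_var)
  # and the mean rate stays at the configured marginal rate
  expect_equal(p_hat, 0.02, tolerance = 0.15)
})

test_that("optional adapter contamination appends trimmable tails", {
  oligos <- make_test_oligos(2, seed = 10)
  profiles <- list(PF = zero_profile(), NPF = zero_profile())
  rs <- simulate_readset(oligos, 100, profiles = profiles, pf_fraction = 1,
                         rng_seed = 3, adapter_tail_fraction = 1)
  expect_true(all(nchar(rs$bases) >= 152 + 7))
  trimmed <- trim_adapter_tail(rs$bases)
  expect_identical(trimmed, oligos$bases[rs$true_oligo])
})

test_that("read sets survive a FASTQ round trip with class and provenance", {
  oligos <- make_test_oligos(3, seed = 6)
  rs <- simulate_readset(oligos, 120, rng_seed = 2)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(rs, path)
  back <- read_reads_fastq(path)
  expect_identical(back$bases, rs$bases)
  expect_identical(back$id, rs$id)
  expect_identical(back$pf_class, rs$pf_class)
  expect_identical(back$true_oligo, as.integer(rs$true_oligo))
})
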