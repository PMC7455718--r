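test_that("5'-proximal mismatch shifting follows the offset rules", {
  expect_equal(effective_5p(30), 30)
  expect_equal(effective_5p(30, mm0 = 1), 31)
  expect_equal(effective_5p(30, mm0 = 1, mm1 = 1), 32)
  expect_equal(effective_5p(30, mm0 = 0, mm1 = 1), 32)
  expect_equal(effective_5p(c(5, 6, 7), mm0 = c(0, 1, 0),
                            mm1 = c(0, 0, 1)), c(5, 7, 9))
})

test_that("read filtering keeps CCA-overlapping, trailer-free pairs", {
  ann <- data.frame(ref = "t", length = 70, cca_start = 68,
                    trailer_start = 71)
  reads <- data.frame(
    ref = "t",
    start = c(30, 30, 30, 30, 30),
    end = c(70, 68, 63, 71, 70),       # at CCA end / 1 nt of CCA / short / trailer
    mm0 = 0, mm1 = 0,
    paired = c(1, 1, 1, 1, 0))
  kept <- filter_reads(reads, ann)
  expect_equal(kept$end, c(70, 68))    # trailer overlap and unpaired dropped
  # no trailer annotated: only CCA overlap matters
  ann2 <- data.frame(ref = "t", length = 70, cca_start = 68,
                     trailer_start = NA)
  expect_equal(nrow(filter_reads(reads[4, ], ann2)), 1)
})

test_that("pileups count spanning coverage from the effective 5' end", {
  reads <- data.frame(ref = "t", start = 5, end = 20, mm0 = 0, mm1 = 0,
                      paired = 1)
  cov <- build_pileup(reads, 25)
  expect_equal(cov, c(rep(0L, 4), rep(1L, 16), rep(0L, 5)))
  two <- rbind(reads, data.frame(ref = "t", start = 15, end = 22,
                                 mm0 = 0, mm1 = 0, paired = 1))
  cov2 <- build_pileup(two, 25)
  expect_equal(cov2[15:20], rep(2L, 6))
  # the mismatch shift moves the coverage edge
  shifted <- data.frame(ref = "t", start = 5, end = 20, mm0 = 1, mm1 = 0,
                        paired = 1)
  expect_equal(which(build_pileup(shifted, 25) > 0)[1], 6)
})

test_that("the drop-off score evaluates exactly and flags zero denominators", {
  expect_equal(psi_score(c(100, 100, 100), c(100, 100, 100), 1), 0)
  expect_equal(psi_score(c(100, 100, 100), c(50, 100, 100), 1), 50)
  expect_equal(psi_score(c(100, 100, 100), c(100, 50, 100), 1), -150)
  expect_true(is.na(psi_score(c(10, 0, 10), c(10, 10, 10), 1)))
  expect_error(psi_score(c(1, 1, 1), c(1, 1, 1), 2), "out of range")
})

test_that("the score matches a literal transcription on random triples", {
  set.seed(99)
  for (i in 1:1000) {
    rm_ <- sample(1:500, 3, TRUE)
    rp_ <- sample(1:500, 3, TRUE)
    expect_equal(psi_score(rm_, rp_, 1), oracle_score(rm_, rp_, 1),
                 tolerance = 1e-12)
  }
})

test_that("the score is invariant under count rescaling", {
  set.seed(17)
  rm_ <- sample(10:1000, 30, TRUE)
  rp_ <- sample(10:1000, 30, TRUE)
  base <- psi_score_track(rm_, rp_)
  for (k in c(2, 10, 0.5)) {
    expect_equal(psi_score_track(k * rm_, k * rp_), base,
                 tolerance = 1e-9)
  }
})

test_that("replicate averaging propagates undefined scores", {
  expect_equal(finalize_scores(list(c(40, NA, 10), c(60, 5, NA))),
               c(50, NA, NA))
  expect_equal(finalize_scores(list(c(1, 2, 3))), c(1, 2, 3))
})

test_that("site calling respects threshold, U restriction and the 3' edge", {
  final <- c(rep(0, 10), 50, rep(0, 9))
  expect_equal(call_psi_sites(final, threshold = 10), 11)
  expect_length(call_psi_sites(rep(0, 20), threshold = 10), 0)
  expect_length(call_psi_sites(final, threshold = Inf), 0)
  # a high score in the last 3 positions is never called
  edge <- c(rep(0, 17), 50, 50, 50)
  expect_length(call_psi_sites(edge, threshold = 10), 0)
  # restriction to reference U positions
  is_u <- rep(FALSE, 20)
  expect_length(call_psi_sites(final, threshold = 10, is_u = is_u), 0)
  is_u[11] <- TRUE
  expect_equal(call_psi_sites(final, threshold = 10, is_u = is_u), 11)
})

test_that("simulated Psi sites rank above all non-sites at standard depth", {
  L <- 69
  psi <- c(22, 27, 34, 40, 55)
  sim <- simulate_psiseq_reads(L, psi, stop_prob = 0.4,
                               baseline_dropoff = 0.005,
                               n_reads = 50000, seed = 1)
  ann <- data.frame(ref = "tRNA", length = L, cca_start = L - 2,
                    trailer_start = NA)
  res <- psi_seq_analysis(list(list(minus = sim$minus, plus = sim$plus)),
                          ann, "tRNA")
  callable <- which(!is.na(res$final))
  callable <- callable[callable <= L - 3]
  site_scores <- res$final[intersect(callable, psi)]
  non_scores <- res$final[setdiff(callable, psi)]
  expect_length(site_scores, length(psi))
  expect_gt(min(site_scores), max(non_scores))
  # and the sites pass the default calling threshold
  called <- call_psi_sites(res$final, threshold = 10,
                           pileups = res$pileups)
  expect_true(all(psi %in% called))
})

test_that("site recovery holds across seeds at moderate stop probability", {
  L <- 69
  psi <- c(22, 27, 34, 40, 55)
  ann <- data.frame(ref = "tRNA", length = L, cca_start = L - 2,
                    trailer_start = NA)
  ok <- vapply(1:20, function(seed) {
    sim <- simulate_psiseq_reads(L, psi, stop_prob = 0.3,
                                 baseline_dropoff = 0.005,
                                 n_reads = 50000, seed = seed)
    res <- psi_seq_analysis(list(list(minus = sim$minus,
                                      plus = sim$plus)), ann, "tRNA")
    callable <- which(!is.na(res$final))
    callable <- callable[callable <= L - 3]
    min(res$final[intersect(callable, psi)]) >
      max(res$final[setdiff(callable, psi)])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("a stop probability of zero leaves scores near zero", {
  sim <- simulate_psiseq_reads(69, c(30, 40), stop_prob = 0,
                               baseline_dropoff = 0.01, n_reads = 50000,
                               seed = 3)
  ann <- data.frame(ref = "tRNA", length = 69, cca_start = 67,
                    trailer_start = NA)
  res <- psi_seq_analysis(list(list(minus = sim$minus, plus = sim$plus)),
                          ann, "tRNA")
  expect_lt(max(abs(res$final[c(30, 40)])), 10)
})

test_that("complete CMC stops abolish coverage 5' of the 3'-most Psi", {
  sim <- simulate_psiseq_reads(60, 45, stop_prob = 1,
                               baseline_dropoff = 0, n_reads = 2000,
                               seed = 2)
  cov_plus <- build_pileup(sim$plus, 60)
  expect_true(all(cov_plus[1:44] == 0))
  expect_true(all(cov_plus[46:60] > 0))
})
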