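test_that("peaks assign to fragments directly and via single deltas", {
  hypo <- mt_trna_cys()
  hypo$residues[52] <- "A"   # reference without the minor methyl
  cat <- fragment_catalog(hypo, rnase_rule("A", cyclic = FALSE),
                          z_max = 2)
  # the doubly charged 661.1 species: AAAC plus one methyl
  peaks <- data.frame(mz = 661.105, z = 2, intensity = 100)
  a <- assign_peaks(peaks, cat, tol_ppm = 10)
  expect_true(all(a$matched))
  expect_true(any(a$residues == "A,A,A,C" & a$delta == "methyl"))
  # a peak far from any candidate is flagged, not an error
  far <- assign_peaks(data.frame(mz = 123.456, z = 2, intensity = 1), cat)
  expect_false(any(far$matched))
})

test_that("peak assignment round-trips a catalog at zero error", {
  set.seed(5)
  s <- mod_seq(sample(c("A", "G", "C", "U"), 40, TRUE,
                      prob = c(.3, .25, .25, .2)))
  cat <- fragment_catalog(s, rnase_rule("T1", cyclic = FALSE), z_max = 2)
  peaks <- data.frame(mz = cat$mz, z = cat$charge,
                      intensity = seq_len(nrow(cat)))
  a <- assign_peaks(peaks, cat, tol_ppm = 5, deltas = NULL)
  expect_true(all(a$matched))
  # every peak's best hit sits at zero mass error (mass-degenerate
  # fragments are legitimate co-assignments)
  best <- a[!duplicated(a$peak), ]
  expect_true(all(abs(best$ppm) < 1e-6))
  expect_equal(nrow(best), nrow(cat))
  # assignment order is stable under peak-list permutation
  perm <- sample(nrow(peaks))
  a2 <- assign_peaks(peaks[perm, ], cat, tol_ppm = 5, deltas = NULL)
  a2 <- a2[order(a2$mz, a2$start, a2$end), ]
  a_sorted <- a[order(a$mz, a$start, a$end), ]
  expect_equal(a2$start, a_sorted$start)
  expect_equal(a2$ppm, a_sorted$ppm)
})

test_that("CID series have n-1 ions each and satisfy the c/y sum rule", {
  frag <- mod_seq(c("A", "m1A", "A", "C"), five_prime = "OH",
                  three_prime = "p")
  ions <- cid_product_ions(frag)
  n <- 4
  for (ser in c("c", "y", "w", "a-B"))
    expect_equal(sum(ions$series == ser), n - 1)
  M <- oligo_neutral_mass(frag)
  h2o <- formula_mass(formula(H = 2, O = 1))
  for (k in 1:(n - 1)) {
    ck <- ions$neutral_mass[ions$series == "c" & ions$index == k]
    ynk <- ions$neutral_mass[ions$series == "y" & ions$index == n - k]
    expect_equal(ck + ynk, M + h2o, tolerance = 1e-9)
  }
  # dimer: exactly one ion per series; length-1 precursor rejected
  expect_equal(sum(cid_product_ions(mod_seq(c("A", "C")))$series == "c"), 1)
  expect_error(cid_product_ions(mod_seq("A")), "length >= 2")
})

test_that("the cyanoethylated anticodon-arm fragment localizes to its Psi", {
  # CA-i6A-A-Psi-U-C-Gp with the cyanoethyl on the Psi (fragment
  # position 5); precursor [M-2H]2- prints 1345.7
  ref <- mod_seq(c("C", "A", "i6A", "A", "Y", "U", "C", "G"),
                 five_prime = "OH", three_prime = "p")
  ce <- derivatize_cyanoethyl(ref)[[1]]
  expect_equal(round(ion_mz(oligo_neutral_mass(ce), 2), 1), 1345.7)
  # complete synthetic c/y ladders for the true product ions
  truth <- cid_product_ions(ce)
  obs <- truth[truth$series %in% c("c", "y"), c("mz", "charge")]
  names(obs) <- c("mz", "z")
  loc <- localize_modification(ref, "C3H3N", obs,
                               candidates = which(ref$residues %in%
                                                    c("Y", "U")))
  expect_equal(loc$position, 5)
  expect_equal(loc$ambiguous, 5)
})

test_that("methyl localization finds position 2 of AAACp from full ladders", {
  ref <- mod_seq(c("A", "A", "A", "C"), five_prime = "OH",
                 three_prime = "p")
  mod <- mod_seq(c("A", "m1A", "A", "C"), five_prime = "OH",
                 three_prime = "p")
  truth <- cid_product_ions(mod)
  obs <- truth[truth$series %in% c("c", "y"), c("mz", "charge")]
  names(obs) <- c("mz", "z")
  loc <- localize_modification(ref, "CH2", obs)
  expect_equal(loc$position, 2)
  # truncated ladders missing the flanking ions leave {2,3} ambiguous
  keep <- !(truth$series == "c" & truth$index == 2) &
    !(truth$series == "y" & truth$index == 2)
  obs2 <- truth[truth$series %in% c("c", "y") & keep, c("mz", "charge")]
  names(obs2) <- c("mz", "z")
  loc2 <- localize_modification(ref, "CH2", obs2)
  expect_equal(loc2$ambiguous, c(2, 3))
  expect_equal(loc2$position, 2)  # 5'-most of the tie
  # single-candidate sites need no ion evidence
  loc3 <- localize_modification(ref, "CH2", obs[0, ], candidates = 4)
  expect_equal(loc3$position, 4)
})

test_that("site frequencies are intensity ratios with Dimroth pooling", {
  x <- data.frame(trna = "Cys", position = 52,
                  isoform = c("m1A", "unmodified"), intensity = c(17, 83))
  f <- site_frequency(x)
  expect_equal(f$frequency[f$isoform == "m1A"], 0.17)
  expect_equal(sum(f$frequency), 1)
  # m6A intensity pools into m1A before normalization
  y <- data.frame(trna = "Cys", position = 52,
                  isoform = c("m1A", "m6A", "unmodified"),
                  intensity = c(10, 7, 83))
  fy <- site_frequency(y)
  expect_equal(fy$frequency[fy$isoform == "m1A"], 0.17)
  # only the modified isoform observed
  z <- data.frame(trna = "t", position = 1, isoform = "m5C",
                  intensity = 5)
  expect_equal(site_frequency(z)$frequency, 1)
  # wobble isoform normalization over four observed forms
  w <- data.frame(trna = "Lys", position = 34,
                  isoform = c("tm5s2U", "tm5U", "s2U", "U"),
                  intensity = c(67, 12, 11, 8))
  fw <- site_frequency(w, pooling = NULL)
  expect_equal(fw$frequency[match(c("tm5s2U", "tm5U", "s2U", "U"),
                                  fw$isoform)],
               c(67, 12, 11, 8) / 98, tolerance = 1e-9)
  # all-zero intensities: undefined, flagged as NA
  zz <- data.frame(trna = "t", position = 2,
                   isoform = c("m1A", "unmodified"), intensity = c(0, 0))
  expect_true(all(is.na(site_frequency(zz)$frequency)))
})

test_that("charge-series deconvolution recovers the neutral mass", {
  expect_equal(deconvolute_neutral_mass(
    data.frame(mz = 999.000, z = 1, intensity = 1))$mass,
    1000.007, tolerance = 1e-3)
  # synthetic series for the hypomodified whole molecule at z = 14..20
  M <- 22272.25
  z <- 14:20
  ions <- data.frame(mz = ion_mz(M, z), z = z, intensity = 21 - z)
  dec <- deconvolute_neutral_mass(ions)
  expect_equal(dec$mass, M, tolerance = 0.01)
  expect_lt(dec$sd, 0.01)
  # stripping charges: consecutive-charge inference gives the same mass
  ions_nz <- ions
  ions_nz$z <- NA
  dec2 <- deconvolute_neutral_mass(ions_nz)
  expect_equal(dec2$z[order(ions_nz$mz, decreasing = TRUE)], 14:20)
  expect_equal(dec2$mass, M, tolerance = 0.01)
  expect_error(deconvolute_neutral_mass(ions[0, ]), "nrow")
})
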