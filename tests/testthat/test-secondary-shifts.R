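ref <- synthetic_reference()

test_that("delta shifts are observed minus reference, missing stays missing", {
  # identity: observed == reference everywhere -> all deltas zero
  aa <- c("Q", "A", "T", "M")
  st <- shift_table(1:4, aa, list(CA = ref[aa, "CA"], HA = ref[aa, "HA"]))
  prof <- compute_delta_shifts(st, ref)
  expect_equal(prof$delta_ca, rep(0, 4))
  expect_equal(prof$delta_ha, rep(0, 4))

  # the downfield glutamine signature: CA 2.53 ppm below reference
  st2 <- shift_table(57L, "Q", list(CA = ref["Q", "CA"] - 2.53))
  prof2 <- compute_delta_shifts(st2, ref)
  expect_equal(prof2$delta_ca, -2.53)
  expect_true(is.na(prof2$delta_ha))
})

test_that("delta shifts match a row-by-row subtraction oracle", {
  st <- random_shift_table(n = 30, seed = 7)
  prof <- compute_delta_shifts(st, ref)
  for (r in seq_len(nrow(st$data))) {
    expect_equal(prof$delta_ca[r], st$data$CA[r] - ref[st$data$aa[r], "CA"])
    expect_equal(prof$delta_ha[r], st$data$HA[r] - ref[st$data$aa[r], "HA"])
  }
})

test_that("delta computation is translation-equivariant in the observed shifts", {
  st <- random_shift_table(n = 20, seed = 11)
  p0 <- compute_delta_shifts(st, ref)
  st2 <- st
  st2$data$CA <- st2$data$CA + 1.7
  p1 <- compute_delta_shifts(st2, ref)
  expect_equal(p1$delta_ca, p0$delta_ca + 1.7)
  expect_equal(p1$delta_ha, p0$delta_ha)
})

test_that("pre-proline flags follow the threshold rule", {
  aa <- c("G", "S", "Q", "Q", "P", "L", "Q", "A", "N", "T")
  st <- shift_table(1:10, aa, list(CA = ref[aa, "CA"]))
  st$data$CA[4] <- ref["Q", "CA"] - 2.0 # precedes P5, below -1.5
  prof <- flag_preproline(compute_delta_shifts(st, ref))
  expect_equal(which(prof$preproline_flag), 4L)
  s <- attr(prof, "preproline_summary")
  expect_equal(unname(s["below_threshold"]), 1L)
  expect_equal(unname(s["pre_proline_flagged"]), 1L)

  # no prolines: never flagged, regardless of how negative delta-CA is
  aa2 <- rep("Q", 6)
  st2 <- shift_table(1:6, aa2, list(CA = rep(ref["Q", "CA"] - 5, 6)))
  prof2 <- flag_preproline(compute_delta_shifts(st2, ref))
  expect_false(any(prof2$preproline_flag))
})

test_that("pre-proline flags equal an exhaustive scan and ignore delta-HA", {
  set.seed(3)
  n <- 60
  aa <- sample(c("Q", "P", "L", "S", "T"), n, replace = TRUE)
  ca <- ref[aa, "CA"] + runif(n, -3, 1)
  st <- shift_table(seq_len(n), aa, list(CA = ca, HA = ref[aa, "HA"]))
  prof <- flag_preproline(compute_delta_shifts(st, ref))
  expected <- vapply(seq_len(n), function(i) {
    i < n && aa[i + 1] == "P" && (ca[i] - ref[aa[i], "CA"]) < -1.5
  }, TRUE)
  expect_equal(prof$preproline_flag, expected)

  # flags do not depend on delta-HA at all
  st2 <- st
  st2$data$HA <- st2$data$HA + rnorm(n, 0, 2)
  prof2 <- flag_preproline(compute_delta_shifts(st2, ref))
  expect_equal(prof2$preproline_flag, prof$preproline_flag)
})

test_that("planted pre-proline offsets are recovered with perfect separation", {
  # offsets -2.0 +/- 0.2 before prolines vs +/-0.5 noise elsewhere do not
  # overlap the -1.5 threshold: sensitivity and specificity both 1
  set.seed(19)
  n <- 400
  aa <- rep(c("Q", "L", "P", "S"), n / 4)
  pre_p <- c(aa[-1] == "P", FALSE)
  ca <- ref[aa, "CA"] + ifelse(pre_p, -2.0 + runif(n, -0.2, 0.2),
                               runif(n, -0.5, 0.5))
  st <- shift_table(seq_len(n), aa, list(CA = ca))
  prof <- flag_preproline(compute_delta_shifts(st, ref))
  expect_equal(prof$preproline_flag, pre_p)
})

test_that("plateau detection finds planted runs and tolerates one dip", {
  zero <- shift_table(1:20, rep("A", 20),
                      list(CA = ref["A", "CA"] + numeric(20),
                           HA = ref["A", "HA"] + numeric(20)))
  expect_equal(nrow(detect_shift_plateaus(compute_delta_shifts(zero, ref))), 0)

  n <- 30
  aa <- rep("A", n)
  dca <- numeric(n); dha <- numeric(n)
  dca[10:20] <- 2; dha[10:20] <- -0.3
  st <- shift_table(1:n, aa, list(CA = ref["A", "CA"] + dca,
                                  HA = ref["A", "HA"] + dha))
  seg <- detect_shift_plateaus(compute_delta_shifts(st, ref))
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(10, 20))

  # single interior dip (e.g. a proline interruption) does not split it
  dca2 <- dca; dca2[15] <- -2
  st2 <- shift_table(1:n, aa, list(CA = ref["A", "CA"] + dca2,
                                   HA = ref["A", "HA"] + dha))
  seg2 <- detect_shift_plateaus(compute_delta_shifts(st2, ref))
  expect_equal(nrow(seg2), 1)
  expect_equal(c(seg2$start, seg2$end), c(10, 20))

  # two interior dips do split the run
  dca3 <- dca2; dca3[18] <- -2
  st3 <- shift_table(1:n, aa, list(CA = ref["A", "CA"] + dca3,
                                   HA = ref["A", "HA"] + dha))
  seg3 <- detect_shift_plateaus(compute_delta_shifts(st3, ref))
  expect_true(nrow(seg3) >= 1)
  expect_true(all(seg3$length < 11))
})

test_that("pre-proline-flagged residues are exempt from the plateau CA cutoff", {
  n <- 12
  aa <- rep("A", n); aa[7] <- "P"
  dca <- rep(2, n); dha <- rep(-0.3, n)
  dca[6] <- -2.5 # pre-proline dip, flagged
  st <- shift_table(1:n, aa, list(CA = ref[aa, "CA"] + dca,
                                  HA = ref[aa, "HA"] + dha))
  prof <- flag_preproline(compute_delta_shifts(st, ref))
  expect_true(prof$preproline_flag[6])
  seg <- detect_shift_plateaus(prof)
  # the flagged residue does not consume the one-dip tolerance: position 7
  # (the proline itself, CA fine) and 6 (exempt) keep the run whole
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(1, 12))
})

test_that("composite deviation follows its closed form", {
  expect_equal(composite_deviation(0, 0, 0), 0)
  expect_equal(composite_deviation(1, 2, 5), 1)
  expect_equal(composite_deviation(0.3, 0, 0), 0.3 / sqrt(3))
  expect_error(composite_deviation(NA, 0, 0), "finite")

  # symmetric under sign flips, monotone in each |input|
  set.seed(5)
  for (k in 1:20) {
    v <- rnorm(3)
    base <- composite_deviation(v[1], v[2], v[3])
    expect_gte(base, 0)
    expect_equal(composite_deviation(-v[1], v[2], -v[3]), base)
    bigger <- composite_deviation(v[1] * 2, v[2], v[3])
    expect_gte(bigger, base)
  }
})
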