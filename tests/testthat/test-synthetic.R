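ref <- synthetic_reference()

test_that("zero-noise shift tables reproduce the planted offsets exactly", {
  seqv <- c(rep("G", 5), rep("A", 8), rep("S", 5))
  spec <- segment_spec(seqv, data.frame(start = 6L, end = 13L,
                                        state = "alpha"),
                       sigma = list(ca = 0, ha = 0, n = 0, hn = 0,
                                    j = 0, hnoe = 0))
  out <- make_shift_table(spec, ref, seed = 9)
  prof <- compute_delta_shifts(out$shifts, ref)
  expect_equal(prof$delta_ca[6:13], rep(2.5, 8))
  expect_equal(prof$delta_ha[6:13], rep(-0.3, 8))
  expect_equal(prof$delta_ca[1:5], rep(0, 5))
})

test_that("generators are pure functions of (spec, seed)", {
  rs <- make_recovery_spec(3)
  a <- make_shift_table(rs$spec, ref, seed = 42)
  b <- make_shift_table(rs$spec, ref, seed = 42)
  expect_identical(a, b)
  c2 <- make_shift_table(rs$spec, ref, seed = 43)
  expect_false(identical(a$shifts$data$CA, c2$shifts$data$CA))

  e1 <- make_evidence(rs$spec, seed = 7)
  e2 <- make_evidence(rs$spec, seed = 7)
  expect_identical(e1, e2)

  # the session RNG stream is untouched
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(make_shift_table(rs$spec, ref, seed = 5))
  expect_identical(runif(3), before)
})

test_that("empirical noise of generated shifts matches the requested sigma", {
  seqv <- rep("Q", 1000)
  spec <- segment_spec(seqv, sigma = list(ca = 0.3, ha = 0.03, n = 0.3,
                                          hn = 0.03, j = 1, hnoe = 0.05))
  out <- make_shift_table(spec, ref, seed = 11)
  prof <- compute_delta_shifts(out$shifts, ref)
  expect_equal(sd(prof$delta_ca), 0.3, tolerance = 0.1)
  expect_equal(sd(prof$delta_ha), 0.03, tolerance = 0.1)
})

test_that("evidence regimes land on their configured means", {
  seqv <- rep(c("A", "L"), 5000)
  spec <- segment_spec(seqv, data.frame(start = 1L, end = 5000L,
                                        state = "alpha"))
  ev <- make_evidence(spec, seed = 13)
  helix_j <- ev$j$value[1:5000]
  other_j <- ev$j$value[5001:10000]
  expect_lt(abs(mean(helix_j) - 5.0), 3 * 1 / sqrt(5000))
  expect_lt(abs(mean(other_j) - 7.5), 3 * 0.8 / sqrt(5000))
  expect_lt(abs(mean(ev$hnoe$value[1:5000]) - 0.6), 3 * 0.05 / sqrt(5000))
  expect_lt(abs(mean(ev$hnoe$value[5001:10000]) - 0.3), 3 * 0.1 / sqrt(5000))
})

test_that("(i,i+3) NOE records appear only inside alpha segments", {
  seqv <- rep("A", 40)
  spec <- segment_spec(seqv, data.frame(start = 11L, end = 22L,
                                        state = "alpha"))
  ev <- make_evidence(spec, seed = 3)
  i3 <- ev$noe[abs(ev$noe$j - ev$noe$i) == 3, ]
  expect_true(all(i3$i >= 11 & i3$j <= 22))
  expect_gt(nrow(i3), 0)

  coil_spec <- segment_spec(seqv)
  ev0 <- make_evidence(coil_spec, seed = 3)
  expect_equal(sum(abs(ev0$noe$j - ev0$noe$i) == 3), 0)
})

test_that("generated evidence satisfies the consuming validators", {
  rs <- make_recovery_spec(8)
  ev <- make_evidence(rs$spec, seed = 21)
  expect_silent(classify_jcoupling(ev$j))
  expect_silent(classify_hnoe(ev$hnoe))
  expect_silent(suppressWarnings(tabulate_connectivities(ev$noe)))
  st <- make_shift_table(rs$spec, ref, seed = 21)
  expect_s3_class(st$shifts, "shift_table")
})

test_that("tiny backbones build and degenerate analyses stay quiet", {
  m <- make_helix_coordinates("ppii", 2)
  expect_equal(length(attr(m, "residues")), 2)
  expect_equal(nrow(fit_local_helix(m)), 0)
  expect_error(make_helix_coordinates("beta", 5), "unknown conformation")
})

test_that("peak-pair generation recovers the interface and respects seeds", {
  pp <- make_peak_pair(1:50, "Q", 10:20, loss_mode = "remove",
                       sigma = 0, seed = 17)
  inv <- classify_involvement(match_peaks(pp$fragment, pp$full))
  hit <- inv$residues$index[inv$residues$involvement == "assembly_involved"]
  expect_equal(hit, 10:20)

  none <- make_peak_pair(1:50, "Q", integer(), sigma = 0, seed = 17)
  inv0 <- classify_involvement(match_peaks(none$fragment, none$full))
  expect_true(all(inv0$residues$involvement == "monomeric"))

  expect_identical(make_peak_pair(1:20, "Q", 3:5, seed = 2),
                   make_peak_pair(1:20, "Q", 3:5, seed = 2))
  expect_error(make_peak_pair(1:10, "Q", 11L), "subset")
})

test_that("a full synthetic bundle writes and reads back coherently", {
  dir <- withr::local_tempdir()
  files <- write_synthetic_bundle(dir, reference = ref, seed = 4)
  expect_true(all(file.exists(files)))
  st <- read_shift_table(files[["shifts"]], "tsv")
  expect_equal(nrow(st$data), 180)
  j <- read_value_table(files[["j"]])
  expect_equal(nrow(j), 180)
  noe <- read_noe_records(files[["noe"]])
  expect_gt(nrow(noe), 100)
  frag <- read_peak_list(files[["fragment"]])
  full <- read_peak_list(files[["full"]])
  expect_gt(nrow(frag$peaks), nrow(full$peaks))
  ppii <- read_backbone_pdb(files[["ppii_pdb"]])
  expect_equal(nrow(detect_ppii_segments(ppii)), 1)
  auc <- read_auc_peaks(files[["auc"]])
  r <- interpret_distribution(auc, 26.1)
  expect_equal(max(r$peaks$n_mer), 40)
})
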