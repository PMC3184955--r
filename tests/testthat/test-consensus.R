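ref <- synthetic_reference()

make_fragment <- function(idx, aa, ca, construct, offset) {
  shift_table(idx, aa, list(CA = ca), construct = construct, offset = offset)
}

test_that("stitching a single fragment is the identity", {
  st <- random_shift_table(n = 10, seed = 2)
  out <- stitch_fragments(list(st))
  expect_equal(out$merged$data[c("index", "aa", "CA", "HA")],
               st$data[c("index", "aa", "CA", "HA")])
  expect_true(all(out$report$consistent))
})

test_that("identical overlap values merge without flags across the junction", {
  # two constructs covering 1-12 and 8-20 with agreeing overlap 8-12
  aa <- rep(c("Q", "L", "S", "T"), 5)
  ca <- ref[aa, "CA"] + seq(0.1, 2, length.out = 20)
  f1 <- make_fragment(1:12, aa[1:12], ca[1:12], "N-half", 0L)
  f2 <- make_fragment(1:13, aa[8:20], ca[8:20], "C-half", 7L)
  out <- stitch_fragments(list(f1, f2))
  expect_equal(out$merged$data$index, 1:20)
  expect_equal(out$merged$data$CA, unname(ca))
  expect_true(all(out$report$consistent))
  expect_equal(nrow(out$report), 5) # one comparison per overlap residue
})

test_that("a planted overlap conflict is flagged and resolved by interiority", {
  aa <- rep("Q", 20)
  ca <- rep(ref["Q", "CA"], 20)
  f1 <- make_fragment(1:12, aa[1:12], ca[1:12], "N-half", 0L)
  ca2 <- ca[8:20]
  ca2[3] <- ca2[3] + 0.5 # full-length residue 10, 0.5 ppm off
  f2 <- make_fragment(1:13, aa[8:20], ca2, "C-half", 7L)
  out <- stitch_fragments(list(f1, f2), tol_ppm = c(CA = 0.2))
  flagged <- out$report[!out$report$consistent, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$index, 10)
  # residue 10 sits 2 residues inside C-half but 9 inside N-half: keep N-half
  expect_equal(out$merged$data$CA[10], ca[10])
})

test_that("misaligned offsets are a hard error, stitching is commutative and idempotent", {
  aa1 <- c("Q", "L", "S", "T", "M", "A")
  f1 <- make_fragment(1:6, aa1, ref[aa1, "CA"], "a", 0L)
  aa2 <- c("G", "L", "S")               # G where f1 has T at full index 4
  f2 <- make_fragment(1:3, aa2, ref[aa2, "CA"], "b", 3L)
  expect_error(stitch_fragments(list(f1, f2)), "mismatch")

  aa3 <- c("T", "M", "A", "W")
  f3 <- make_fragment(1:4, aa3, ref[aa3, "CA"] + 0.1, "c", 3L)
  ab <- stitch_fragments(list(f1, f3))
  ba <- stitch_fragments(list(f3, f1))
  expect_equal(ab$merged$data, ba$merged$data)

  again <- stitch_fragments(list(ab$merged, ab$merged))
  expect_equal(again$merged$data, ab$merged$data)
})

planted_profile <- function(seq180, alpha_range, ppii_range = NULL) {
  n <- length(seq180)
  dca <- numeric(n); dha <- numeric(n)
  dca[alpha_range] <- 2.5; dha[alpha_range] <- -0.3
  pre_p <- c(seq180[-1] == "P", FALSE)
  dca[pre_p] <- -2.5
  st <- shift_table(seq_len(n), seq180,
                    list(CA = ref[seq180, "CA"] + dca,
                         HA = ref[seq180, "HA"] + dha))
  flag_preproline(compute_delta_shifts(st, ref))
}

test_that("planted helix evidence yields one alpha segment with exact bounds", {
  seqv <- rep("A", 30); seqv[1] <- "M"
  prof <- planted_profile(seqv, 9:19)
  j <- classify_jcoupling(data.frame(index = 1:30,
                                     value = ifelse(1:30 %in% 9:19, 5, 8)))
  h <- classify_hnoe(data.frame(index = 1:30,
                                value = ifelse(1:30 %in% 9:19, 0.6, 0.3)))
  noe <- tabulate_connectivities(
    noe_records(9:16, 12:19, rep("daN", 8), rep("weak", 8)))
  ev <- residue_evidence(j, h, noe, indices = 1:30)
  ann <- call_secondary_structure(prof, ev, seqv)
  alpha <- ann$segments[ann$segments$state == "alpha", ]
  expect_equal(nrow(alpha), 1)
  expect_equal(c(alpha$start, alpha$end), c(9, 19))
  expect_true(all(ann$residues$confidence[9:19] >= 3))
})

test_that("all-missing evidence yields coil everywhere with zero confidence", {
  seqv <- rep("Q", 15)
  st <- shift_table(1:15, seqv, list())
  prof <- flag_preproline(compute_delta_shifts(st, ref))
  ev <- residue_evidence(indices = 1:15)
  ann <- call_secondary_structure(prof, ev, seqv)
  expect_true(all(ann$residues$state == "coil"))
  expect_true(all(ann$residues$confidence == 0))
  expect_equal(nrow(ann$segments), 0)
})

test_that("a PXX repeat with pre-proline flags and no helix evidence calls ppii", {
  seqv <- c(rep("S", 6), "P", "L", "Q", "P", "M", "Q", "P", "F", "Q", "P",
            rep("S", 5))
  prof <- planted_profile(seqv, integer(0))
  ev <- residue_evidence(indices = seq_along(seqv))
  ann <- call_secondary_structure(prof, ev, seqv)
  ppii <- ann$segments[ann$segments$state == "ppii", ]
  expect_equal(nrow(ppii), 1)
  # the repeat spans 7..16; the called segment may extend one residue into
  # the flagged pre-proline neighbour
  expect_lte(abs(ppii$start - 7), 1)
  expect_lte(abs(ppii$end - 16), 1)
  expect_false(any(ann$residues$state == "alpha"))
})

test_that("alpha never appears on missing delta-CA without NOE support", {
  seqv <- rep("A", 20)
  prof <- planted_profile(seqv, 5:12)
  prof$delta_ca[8] <- NA # unassigned interior residue
  j <- classify_jcoupling(data.frame(index = 1:20, value = rep(5, 20)))
  ev <- residue_evidence(j, NULL, NULL, indices = 1:20)
  ann <- call_secondary_structure(prof, ev, seqv)
  expect_false(ann$residues$state[8] == "alpha")
})

test_that("domain summaries report composition and majority state", {
  seqv <- rep("Q", 40)
  st <- shift_table(1:40, seqv, list())
  prof <- flag_preproline(compute_delta_shifts(st, ref))
  ev <- residue_evidence(indices = 1:40)
  ann <- call_secondary_structure(prof, ev, seqv)
  doms <- data.frame(domain = c("d1", "d2"), start = c(1, 21), end = c(20, 40))
  s <- summarize_domains(ann, doms)
  expect_equal(s$majority, c("coil", "coil"))
  expect_equal(s$pct_coil, c(100, 100))

  # planted four-domain annotation recovers the expected majorities
  ann2 <- ann
  ann2$residues$state[1:10] <- "alpha"
  ann2$residues$state[25:34] <- "ppii"
  doms4 <- data.frame(domain = c("a", "b", "c", "d"),
                      start = c(1, 11, 25, 35), end = c(10, 24, 34, 40))
  s4 <- summarize_domains(ann2, doms4)
  expect_equal(s4$majority, c("alpha", "coil", "ppii", "coil"))

  # single-residue domain and overlap validation
  s1 <- summarize_domains(ann, data.frame(domain = "x", start = 3, end = 3))
  expect_equal(s1$n_residues, 1)
  expect_error(
    summarize_domains(ann, data.frame(domain = c("x", "y"),
                                      start = c(1, 5), end = c(6, 9))),
    "overlap")
})

test_that("planted segments are recovered on seeded synthetic constructs", {
  # smaller companion to the acceptance-scale parameter-recovery check
  n_ok <- 0; n_res <- 0; n_correct <- 0; seg_ok <- 0; seg_all <- 0
  for (seed in 1:25) {
    rs <- make_recovery_spec(seed)
    st <- make_shift_table(rs$spec, ref, seed = seed)
    ev_raw <- make_evidence(rs$spec, seed = seed + 1000)
    prof <- flag_preproline(compute_delta_shifts(st$shifts, ref))
    ev <- residue_evidence(classify_jcoupling(ev_raw$j),
                           classify_hnoe(ev_raw$hnoe),
                           tabulate_connectivities(ev_raw$noe),
                           indices = seq_along(rs$spec$sequence))
    ann <- call_secondary_structure(prof, ev, rs$spec$sequence)
    truth <- spec_truth_states(rs$spec)
    n_res <- n_res + length(truth)
    n_correct <- n_correct + sum(ann$residues$state == truth)
    for (k in seq_len(nrow(rs$truth_segments))) {
      seg_all <- seg_all + 1
      tg <- rs$truth_segments[k, ]
      cand <- ann$segments[ann$segments$state == tg$state, ]
      hit <- any(abs(cand$start - tg$start) <= 1 & abs(cand$end - tg$end) <= 1)
      seg_ok <- seg_ok + hit
    }
  }
  expect_gte(n_correct / n_res, 0.9)
  expect_gte(seg_ok / seg_all, 0.8)
})
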