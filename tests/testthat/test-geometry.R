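test_that("dihedrals of a constructed chain recover the builder angles", {
  for (st in c("ppii", "alpha", "three_ten")) {
    target <- switch(st, ppii = c(-75, 145), alpha = c(-57, -47),
                     three_ten = c(-49, -26))
    m <- make_helix_coordinates(st, 8)
    d <- backbone_dihedrals(m)
    expect_true(all(abs(d$phi[2:8] - target[1]) < 0.5))
    expect_true(all(abs(d$psi[1:7] - target[2]) < 0.5))
    expect_true(all(abs(abs(d$omega[2:8]) - 180) < 0.5))
  }
  # termini carry missing phi / psi
  d <- backbone_dihedrals(make_helix_coordinates("ppii", 5))
  expect_true(is.na(d$phi[1]) && is.na(d$psi[5]))
})

test_that("a 2-residue chain has no complete phi/psi pair", {
  d <- backbone_dihedrals(make_helix_coordinates("ppii", 2))
  expect_true(all(is.na(d$phi) | is.na(d$psi)))
})

test_that("dihedrals agree with an independent torsion oracle on random chains", {
  set.seed(21)
  for (rep in 1:3) {
    phi <- runif(8, -160, -40); psi <- runif(8, -60, 170)
    m <- build_backbone(phi, psi)
    N <- atom_xyz(m, "N"); CA <- atom_xyz(m, "CA"); C <- atom_xyz(m, "C")
    d <- backbone_dihedrals(m)
    for (i in 2:7) {
      expect_equal(d$phi[i], oracle_torsion(C[i - 1, ], N[i, ], CA[i, ], C[i, ]),
                   tolerance = 1e-6)
      expect_equal(d$psi[i], oracle_torsion(N[i, ], CA[i, ], C[i, ], N[i + 1, ]),
                   tolerance = 1e-6)
    }
  }
})

test_that("ideal PPII geometry: ~3.1 A rise, ~3 residues per turn, left-handed", {
  m <- make_helix_coordinates("ppii", 12)
  f <- fit_local_helix(m)
  expect_true(all(f$handedness == "left"))
  expect_equal(mean(f$rise_per_residue), 3.1, tolerance = 0.05)
  expect_equal(mean(f$residues_per_turn), 3.0, tolerance = 0.05)
})

test_that("ideal alpha helix is right-handed with ~3.6 residues per turn", {
  m <- make_helix_coordinates("alpha", 12)
  f <- fit_local_helix(m)
  expect_true(all(f$handedness == "right"))
  expect_equal(mean(f$residues_per_turn), 3.6, tolerance = 0.05)
})

test_that("a fully extended chain is flagged degenerate", {
  f <- fit_local_helix(make_helix_coordinates("extended", 8))
  expect_true(all(f$degenerate))
  expect_true(all(f$handedness == "undefined"))
})

test_that("helix fit matches the brute-force axis-search oracle within 2%", {
  for (st in c("ppii", "alpha", "three_ten")) {
    m <- make_helix_coordinates(st, 9)
    P <- ca_matrix(m)
    fit <- fit_local_helix(m, window = 9)
    orc <- oracle_helix_fit(P)
    expect_equal(fit$rise_per_residue[1], orc$rise, tolerance = 0.02)
    expect_equal(fit$residues_per_turn[1], 360 / abs(orc$twist),
                 tolerance = 0.02)
    expect_equal(fit$handedness[1], if (orc$twist > 0) "right" else "left")
  }
})

test_that("helix parameters are invariant under rigid motions", {
  m <- make_helix_coordinates("ppii", 10)
  f0 <- fit_local_helix(m)
  for (seed in 1:5) {
    R <- random_rotation(seed)
    m2 <- transform_model(m, R, t = c(10, -3, 7) * seed)
    f1 <- fit_local_helix(m2)
    expect_equal(f1$rise_per_residue, f0$rise_per_residue, tolerance = 1e-6)
    expect_equal(f1$residues_per_turn, f0$residues_per_turn, tolerance = 1e-6)
    expect_equal(f1$handedness, f0$handedness)
  }
})

test_that("mirror reflection flips handedness", {
  for (st in c("ppii", "alpha")) {
    m <- make_helix_coordinates(st, 10)
    mm <- as.data.frame(m)
    mm$z <- -mm$z
    f0 <- fit_local_helix(m)
    f1 <- fit_local_helix(backbone_model(mm))
    flip <- c(left = "right", right = "left")
    expect_equal(f1$handedness, unname(flip[f0$handedness]))
  }
})

test_that("PPII detection spans ideal chains of many lengths", {
  for (n in c(4, 5, 7, 12, 25, 50)) {
    seg <- detect_ppii_segments(make_helix_coordinates("ppii", n))
    expect_equal(nrow(seg), 1)
    expect_equal(c(seg$start, seg$end), c(1, n))
    expect_equal(seg$turn_length, 9.3, tolerance = 0.05 * 9.3)
  }
})

test_that("PPII detection excludes alpha stretches and finds planted segments", {
  expect_equal(nrow(detect_ppii_segments(make_helix_coordinates("alpha", 12))), 0)

  # PPII(8) + alpha(8) + PPII(8) concatenation: two segments at the ends
  phi <- c(rep(-75, 8), rep(-57, 8), rep(-75, 8))
  psi <- c(rep(145, 8), rep(-47, 8), rep(145, 8))
  m <- build_backbone(phi, psi)
  seg <- detect_ppii_segments(m)
  expect_equal(nrow(seg), 2)
  expect_lte(seg$start[1], 2)
  expect_gte(seg$end[2], 23)
  expect_true(all(seg$end[1] <= 10 & seg$start[2] >= 15))
})

test_that("turn length is three rises and rejects non-positive input", {
  expect_equal(turn_length(3.1), 9.3)
  expect_equal(turn_length(3.16), 9.48)
  expect_error(turn_length(0), "positive")
})

test_that("proline rings one turn apart in PPII are co-oriented", {
  seqv <- rep(c("P", "A", "Q"), 4)
  m <- make_helix_coordinates("ppii", 12, sequence = seqv)
  out <- proline_ring_alignment(m, 1, 4)
  expect_lte(out$angle, 30)
  expect_true(out$aligned)
  expect_equal(proline_ring_alignment(m, 4, 4)$angle, 0)
  expect_error(proline_ring_alignment(m, 1, 2), "not a proline")
})

test_that("empty models yield empty PPII output", {
  em <- backbone_model(data.frame(resno = integer(), aa = character(),
                                  atom = character(), x = numeric(),
                                  y = numeric(), z = numeric()))
  expect_equal(nrow(detect_ppii_segments(em)), 0)
})
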