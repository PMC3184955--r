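# Seeded generators producing every input the pipeline consumes, with
# planted ground truth. All are pure functions of (spec, seed): the session
# RNG stream is saved and restored around each call.

#' Segment specification for the synthetic generators
#'
#' Declares the planted secondary-structure layout of a synthetic
#' construct: non-overlapping segments over a sequence, per-observable
#' noise levels, and the state-conditional effect sizes. Default effect
#' sizes follow the magnitudes seen in secondary-shift analyses of helical
#' and proline-rich proteins: helix delta-CA about +2.5 ppm with delta-HA
#' about -0.3 ppm, pre-proline delta-CA about -2.5 ppm, helix J couplings
#' around 5 Hz versus 7.5 Hz otherwise, and heteronuclear NOEs of 0.6 in
#' rigid versus 0.3 in flexible stretches.
#'
#' @param sequence Character vector of one-letter codes.
#' @param segments data.frame with `start`, `end`, `state` (one of
#'   `alpha`, `three_ten`, `ppii`; everything uncovered is coil).
#' @param sigma Named list of noise standard deviations: `ca`, `ha`, `n`,
#'   `hn` (ppm), `j` (Hz), `hnoe`.
#' @param effects Named list of effect sizes (see Details in the code):
#'   `helix_dca`, `helix_dha`, `preproline_dca`, `j_helix`, `j_other`,
#'   `hnoe_rigid`, `hnoe_flex`.
#' @return Object of class `segment_spec`.
#' @export
segment_spec <- function(sequence,
                         segments = data.frame(start = integer(),
                                               end = integer(),
                                               state = character()),
                         sigma = list(ca = 0.3, ha = 0.03, n = 0.3,
                                      hn = 0.03, j = 1.0, hnoe = 0.05),
                         effects = list(helix_dca = 2.5, helix_dha = -0.3,
                                        preproline_dca = -2.5,
                                        j_helix = 5.0, j_other = 7.5,
                                        j_sd_helix = 1.0, j_sd_other = 0.8,
                                        hnoe_rigid = 0.6, hnoe_flex = 0.3,
                                        hnoe_sd_rigid = 0.05,
                                        hnoe_sd_flex = 0.1)) {
  sequence <- as.character(sequence)
  if (!all(is_aa1(sequence))) stopf("sequence contains invalid residue codes")
  if (nrow(segments)) {
    if (!all(segments$state %in% c("alpha", "three_ten", "ppii"))) {
      stopf("segment states must be alpha, three_ten or ppii")
    }
    o <- order(segments$start)
    segments <- segments[o, , drop = FALSE]
    if (any(segments$start < 1L) || any(segments$end > length(sequence)) ||
        any(segments$start > segments$end)) {
      stopf("segments must lie within the sequence with start <= end")
    }
    if (nrow(segments) > 1L &&
        any(segments$start[-1] <= segments$end[-nrow(segments)])) {
      stopf("segments must not overlap")
    }
  }
  if (any(unlist(sigma) < 0)) stopf("noise sigma must be >= 0")
  structure(list(sequence = sequence, segments = segments, sigma = sigma,
                 effects = effects),
            class = "segment_spec")
}

# per-residue planted state vector
spec_states <- function(spec) {
  st <- rep("coil", length(spec$sequence))
  for (k in seq_len(nrow(spec$segments))) {
    st[spec$segments$start[k]:spec$segments$end[k]] <- spec$segments$state[k]
  }
  st
}

#' Generate a synthetic shift table with planted structure
#'
#' Observed shifts are reference values plus a state-dependent offset plus
#' Gaussian noise: helix-state residues get the helix delta-CA/delta-HA
#' offsets, residues immediately preceding a proline get the pre-proline
#' delta-CA offset (overriding any state offset, as in real spectra), and
#' coil residues get none.
#'
#' @param spec A [segment_spec].
#' @param reference A [reference_shifts] table.
#' @param seed Integer seed; the generator is deterministic given
#'   (spec, seed).
#' @param construct,offset Passed to the resulting [shift_table].
#' @return List with `shifts` (a [shift_table]) and `truth` (data.frame
#'   `index`, `aa`, `state`, `pre_proline`).
#' @export
make_shift_table <- function(spec, reference, seed = 1L,
                             construct = "synthetic", offset = 0L) {
  stopifnot(inherits(spec, "segment_spec"), inherits(reference, "reference_shifts"))
  n <- length(spec$sequence)
  st <- spec_states(spec)
  pre_p <- c(spec$sequence[-1] == "P", FALSE)
  ef <- spec$effects; sg <- spec$sigma
  with_seed(seed, {
    d_ca <- ifelse(st %in% c("alpha", "three_ten"), ef$helix_dca, 0)
    d_ha <- ifelse(st %in% c("alpha", "three_ten"), ef$helix_dha, 0)
    d_ca[pre_p] <- ef$preproline_dca
    ca <- reference[spec$sequence, "CA"] + d_ca + stats::rnorm(n, 0, sg$ca)
    ha <- reference[spec$sequence, "HA"] + d_ha + stats::rnorm(n, 0, sg$ha)
    nn <- reference[spec$sequence, "N"] + stats::rnorm(n, 0, sg$n)
    hn <- reference[spec$sequence, "HN"] + stats::rnorm(n, 0, sg$hn)
    hn[spec$sequence == "P"] <- NA # prolines have no backbone amide proton
    list(
      shifts = shift_table(seq_len(n), spec$sequence,
                           list(CA = ca, HA = ha, N = nn, HN = hn),
                           construct = construct, offset = offset),
      truth = data.frame(index = seq_len(n), aa = spec$sequence, state = st,
                         pre_proline = pre_p, stringsAsFactors = FALSE)
    )
  })
}

#' Generate synthetic dynamics evidence with planted regimes
#'
#' J couplings are drawn around the helix mean inside helical segments and
#' the dispersed non-helix mean elsewhere; heteronuclear NOEs around the
#' rigid mean inside alpha segments and the flexible mean elsewhere
#' (clamped to the physical range). Sequential (i,i+1) NOE contacts are
#' emitted along the whole chain; (i,i+3) contacts only inside alpha
#' segments.
#'
#' @param spec A [segment_spec].
#' @param seed Integer seed.
#' @return List with `j` and `hnoe` (data.frames `index`, `value`),
#'   `noe` (a [noe_records] table) and `truth`.
#' @export
make_evidence <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "segment_spec"))
  n <- length(spec$sequence)
  st <- spec_states(spec)
  ef <- spec$effects
  helixish <- st %in% c("alpha", "three_ten")
  with_seed(seed, {
    j <- ifelse(helixish,
                stats::rnorm(n, ef$j_helix, ef$j_sd_helix),
                stats::rnorm(n, ef$j_other, ef$j_sd_other))
    j <- pmax(j, 0)
    hnoe <- ifelse(st == "alpha",
                   stats::rnorm(n, ef$hnoe_rigid, ef$hnoe_sd_rigid),
                   stats::rnorm(n, ef$hnoe_flex, ef$hnoe_sd_flex))
    hnoe <- pmin(pmax(hnoe, -1.5), 1.1)
    j[spec$sequence == "P"] <- NA # no amide proton, no HN-HA coupling
    hnoe[spec$sequence == "P"] <- NA
    ii <- seq_len(n - 1L)
    rec_i <- ii; rec_j <- ii + 1L
    rec_class <- rep("daN", n - 1L); rec_bin <- rep("medium", n - 1L)
    for (k in seq_len(nrow(spec$segments))) {
      if (spec$segments$state[k] != "alpha") next
      s <- spec$segments$start[k]; e <- spec$segments$end[k]
      if (e - s >= 3L) {
        i3 <- s:(e - 3L)
        rec_i <- c(rec_i, i3); rec_j <- c(rec_j, i3 + 3L)
        rec_class <- c(rec_class, rep("daN", length(i3)))
        rec_bin <- c(rec_bin, rep("weak", length(i3)))
      }
    }
    list(
      j = data.frame(index = seq_len(n), value = j),
      hnoe = data.frame(index = seq_len(n), value = hnoe),
      noe = noe_records(rec_i, rec_j, rec_class, rec_bin),
      truth = data.frame(index = seq_len(n), state = st,
                         stringsAsFactors = FALSE)
    )
  })
}

# Canonical builder dihedrals (degrees).
CANONICAL_DIHEDRALS <- list(
  alpha = c(phi = -57, psi = -47, omega = 180),
  three_ten = c(phi = -49, psi = -26, omega = 180),
  ppii = c(phi = -75, psi = 145, omega = 180),
  extended = c(phi = 180, psi = 180, omega = 180)
)

# Standard backbone internal coordinates (Angstrom, degrees).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7

# Place atom D given A, B, C with bond |CD| = r, angle BCD = theta and
# torsion ABCD = chi (degrees): the natural-extension (NeRF) step.
place_atom <- function(a, b, c_, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- unitv(c_ - b)
  nrm <- unitv(cross3(b - a, bc))
  m <- cross3(nrm, bc)
  c_ + r * (-cos(th) * bc + sin(th) * (cos(ch) * m + sin(ch) * nrm))
}

#' Build a backbone chain from dihedral angles
#'
#' Sequential natural-extension construction from canonical bond lengths
#' and angles: given per-residue phi/psi (and omega for the peptide
#' bond), returns N/CA/C coordinates. For proline residues, approximate
#' ring atoms (CB, CG, CD) are attached so that ring-plane orientation
#' can be measured.
#'
#' @param phi,psi Numeric vectors of length n (degrees); `phi[1]` and
#'   `psi[n]` are not used.
#' @param omega Peptide-bond torsions (length n, `omega[1]` unused;
#'   default all 180).
#' @param sequence One-letter codes (defaults to all-alanine).
#' @return A [backbone_model].
#' @export
build_backbone <- function(phi, psi, omega = NULL, sequence = NULL) {
  n <- length(phi)
  if (length(psi) != n) stopf("phi and psi lengths differ")
  if (n < 2L) stopf("need at least 2 residues")
  if (is.null(omega)) omega <- rep(180, n)
  if (is.null(sequence)) sequence <- rep("A", n)
  if (length(sequence) != n) stopf("sequence length mismatch")
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  ang <- ANGLE_N_CA_C * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BOND_N_CA, ANGLE_C_N_CA, omega[i])
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         BOND_CA_C, ANGLE_N_CA_C, phi[i])
  }
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      resno = i, aa = sequence[i], atom = c("N", "CA", "C"),
      x = c(N[i, 1], CA[i, 1], C[i, 1]),
      y = c(N[i, 2], CA[i, 2], C[i, 2]),
      z = c(N[i, 3], CA[i, 3], C[i, 3]), stringsAsFactors = FALSE
    )
    if (sequence[i] == "P") {
      cb <- place_atom(N[i, ], C[i, ], CA[i, ], 1.53, 111.5, 113)
      cg <- place_atom(N[i, ], CA[i, ], cb, 1.50, 104, 30)
      cd <- place_atom(CA[i, ], cb, cg, 1.51, 106, -35)
      rows[[length(rows) + 1L]] <- data.frame(
        resno = i, aa = sequence[i], atom = c("CB", "CG", "CD"),
        x = c(cb[1], cg[1], cd[1]), y = c(cb[2], cg[2], cd[2]),
        z = c(cb[3], cg[3], cd[3]), stringsAsFactors = FALSE
      )
    }
  }
  backbone_model(do.call(rbind, rows))
}

#' Ideal helix backbone coordinates
#'
#' Builds an n-residue chain with the canonical dihedrals of the requested
#' conformation: `alpha` (-57, -47), `three_ten` (-49, -26), `ppii`
#' (-75, +145) or fully `extended` (180, 180), all with trans peptide
#' bonds.
#'
#' @param state Conformation name.
#' @param n_residues Number of residues (>= 2).
#' @param sequence Optional one-letter codes (e.g. with prolines for ring
#'   geometry checks).
#' @return A [backbone_model].
#' @export
#' @examples
#' ppii <- make_helix_coordinates("ppii", 12)
#' detect_ppii_segments(ppii)
make_helix_coordinates <- function(state, n_residues, sequence = NULL) {
  if (!state %in% names(CANONICAL_DIHEDRALS)) {
    stopf("unknown conformation '%s' (expected %s)", state,
          paste(names(CANONICAL_DIHEDRALS), collapse = ", "))
  }
  if (n_residues < 2L) stopf("need at least 2 residues")
  d <- CANONICAL_DIHEDRALS[[state]]
  build_backbone(rep(d["phi"], n_residues), rep(d["psi"], n_residues),
                 rep(d["omega"], n_residues), sequence = sequence)
}

#' Generate a matched fragment / full-length HSQC peak pair
#'
#' The fragment list places one well-separated peak per residue on a
#' deterministic grid (spacing several times the matching tolerances);
#' the full-length list is the fragment list with the planted interface
#' residues either removed or attenuated below the reduced-intensity
#' threshold, plus Gaussian jitter on both dimensions of every surviving
#' peak.
#'
#' @param residues Integer residue indices of the construct.
#' @param aa One-letter codes, recycled to `length(residues)`.
#' @param interface_residues Subset of `residues` planted as
#'   assembly-involved.
#' @param loss_mode `"remove"` (peak absent from the full-length list) or
#'   `"attenuate"` (intensity scaled to `attenuation`).
#' @param sigma Gaussian jitter SD applied to the full-length peaks, as a
#'   fraction of each dimension's tolerance-scale: the same value is used
#'   as `sigma * 0.2` ppm in 15N and `sigma * 0.02` ppm in 1H.
#' @param seed Integer seed.
#' @param attenuation Intensity ratio used in attenuate mode (default
#'   0.1).
#' @return List with `fragment`, `full` (both [peak_list]) and `truth`
#'   (data.frame `index`, `involved`).
#' @export
make_peak_pair <- function(residues, aa = "Q", interface_residues = integer(),
                           loss_mode = c("remove", "attenuate"),
                           sigma = 0, seed = 1L, attenuation = 0.1) {
  loss_mode <- match.arg(loss_mode)
  residues <- as.integer(residues)
  if (!all(interface_residues %in% residues)) {
    stopf("interface residues must be a subset of the construct residues")
  }
  aa <- rep_len(as.character(aa), length(residues))
  n <- length(residues)
  # deterministic grid, spacing 0.5 ppm (15N) x 0.06 ppm (1H): several
  # tolerance widths, so matching is unambiguous under jitter
  ncol_grid <- ceiling(sqrt(n))
  row <- (seq_len(n) - 1L) %/% ncol_grid
  col <- (seq_len(n) - 1L) %% ncol_grid
  n15 <- 105 + 0.5 * row
  h1 <- 6.5 + 0.06 * col
  height <- rep(1e6, n)
  fragment <- peak_list(residues, aa, n15, h1, height, construct = "fragment")
  with_seed(seed, {
    involved <- residues %in% interface_residues
    keep <- !involved | loss_mode == "attenuate"
    h_full <- ifelse(involved, height * attenuation, height)
    jn <- stats::rnorm(n, 0, sigma * 0.2)
    jh <- stats::rnorm(n, 0, sigma * 0.02)
    full <- peak_list(residues[keep], aa[keep],
                      (n15 + jn)[keep], (h1 + jh)[keep], h_full[keep],
                      construct = "full")
    list(fragment = fragment, full = full,
         truth = data.frame(index = residues, involved = involved))
  })
}

#' Write a complete synthetic dataset bundle to a directory
#'
#' Generates every input format the pipeline consumes (shift-table TSV,
#' J-coupling and heteronuclear-NOE value tables, NOE records, a
#' fragment/full HSQC peak-list pair, an ideal PPII backbone PDB and an
#' AUC peak table) from one [segment_spec] and seed.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [segment_spec]; defaults to an amelogenin-like layout.
#' @param reference A [reference_shifts] table.
#' @param seed Integer seed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic_bundle <- function(dir, spec = NULL,
                                   reference = load_reference_shifts(),
                                   seed = 1L) {
  if (is.null(spec)) {
    seq180 <- amelogenin_like_sequence()
    spec <- segment_spec(
      seq180,
      data.frame(start = c(9L, 24L, 39L, 126L),
                 end = c(19L, 30L, 45L, 164L),
                 state = c("alpha", "alpha", "alpha", "ppii"))
    )
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- make_shift_table(spec, reference, seed = seed)
  ev <- make_evidence(spec, seed = seed + 1L)
  pp <- make_peak_pair(seq_along(spec$sequence), spec$sequence,
                       interface_residues = which(spec_states(spec) == "alpha"),
                       loss_mode = "remove", sigma = 0.25, seed = seed + 2L)
  ppii <- make_helix_coordinates("ppii", 12)
  files <- c(
    shifts = file.path(dir, "shifts.tsv"),
    j = file.path(dir, "jcoupling.tsv"),
    hnoe = file.path(dir, "hnoe.tsv"),
    noe = file.path(dir, "noe_records.tsv"),
    fragment = file.path(dir, "fragment_peaks.list"),
    full = file.path(dir, "full_peaks.list"),
    ppii_pdb = file.path(dir, "ideal_ppii.pdb"),
    auc = file.path(dir, "auc_peaks.tsv")
  )
  write_shift_table(st$shifts, files["shifts"])
  write_value_table(ev$j, files["j"], "j_hna")
  write_value_table(ev$hnoe, files["hnoe"], "hnoe")
  write_noe_records(ev$noe, files["noe"])
  write_peak_list(pp$fragment, files["fragment"])
  write_peak_list(pp$full, files["full"])
  write_backbone_pdb(ppii, files["ppii_pdb"])
  utils::write.table(
    data.frame(mass_kda = c(26.1, 1046.4), fraction = c(0.08, 0.92)),
    files["auc"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(files)
}
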