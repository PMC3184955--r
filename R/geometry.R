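# Vector helpers ------------------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stopf("cannot normalise near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Signed torsion angle (degrees, in (-180, 180]) defined by four points.
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone dihedral angles
#'
#' Computes phi (C'(i-1)-N-CA-C'), psi (N-CA-C'-N(i+1)) and omega
#' (CA(i-1)-C'(i-1)-N-CA) for every residue, using the standard four-atom torsion
#' definition. Chain termini and segment breaks carry `NA` where the
#' defining atoms are unavailable. Angles are reported in degrees in
#' (-180, 180].
#'
#' @param model A [backbone_model] with N, CA and C atoms.
#' @return data.frame with columns `resno`, `aa`, `phi`, `psi`, `omega`.
#' @export
backbone_dihedrals <- function(model) {
  stopifnot(inherits(model, "backbone_model"))
  res <- attr(model, "residues")
  nres <- length(res)
  N <- atom_coords(model, "N"); CA <- atom_coords(model, "CA")
  C <- atom_coords(model, "C")
  segs <- attr(model, "segments")
  seg_of <- integer(nres)
  for (s in seq_len(nrow(segs))) seg_of[segs$start[s]:segs$end[s]] <- s
  phi <- psi <- omega <- rep(NA_real_, nres)
  for (k in seq_len(nres)) {
    ok_here <- !anyNA(c(N[k, ], CA[k, ], C[k, ]))
    if (!ok_here) next
    if (k > 1L && seg_of[k - 1L] == seg_of[k] && !anyNA(C[k - 1L, ])) {
      phi[k] <- torsion_angle(C[k - 1L, ], N[k, ], CA[k, ], C[k, ])
      if (!anyNA(CA[k - 1L, ])) {
        omega[k] <- torsion_angle(CA[k - 1L, ], C[k - 1L, ], N[k, ], CA[k, ])
      }
    }
    if (k < nres && seg_of[k + 1L] == seg_of[k] && !anyNA(N[k + 1L, ])) {
      psi[k] <- torsion_angle(N[k, ], CA[k, ], C[k, ], N[k + 1L, ])
    }
  }
  aa <- model$aa[match(res, model$resno)]
  data.frame(resno = res, aa = aa, phi = phi, psi = psi, omega = omega,
             stringsAsFactors = FALSE)
}

# Helix parameters from a window of consecutive CA positions. The axis
# direction is taken from the bond-difference (bisector) construction:
# a_i = d_i - d_(i-1) with d_i the CA(i)->CA(i+1) bond points radially
# toward the axis, so crossing successive a_i recovers the axis direction;
# the sign is fixed to point along chain propagation. Rise is the mean
# axial bond advance, twist the mean signed rotation of successive bond
# projections about the axis.
helix_window_params <- function(P, degenerate_tol = 1e-8) {
  n <- nrow(P)
  d <- P[-1, , drop = FALSE] - P[-n, , drop = FALSE] # bonds, n-1 rows
  a <- d[-1, , drop = FALSE] - d[-(n - 1), , drop = FALSE] # n-2 rows
  prop <- P[n, ] - P[1, ]
  if (all(sqrt(rowSums(a^2)) < degenerate_tol)) {
    # straight (fully extended) chain: no curvature, axis undefined
    return(list(rise = mean(sqrt(rowSums(d^2))), residues_per_turn = 2,
                handedness = "undefined", degenerate = TRUE))
  }
  axes <- matrix(0, nrow = 0, ncol = 3)
  for (k in seq_len(nrow(a) - 1L)) {
    h <- cross3(a[k, ], a[k + 1L, ])
    if (vnorm(h) < degenerate_tol) next
    h <- unitv(h)
    if (sum(h * prop) < 0) h <- -h
    axes <- rbind(axes, h)
  }
  if (nrow(axes) == 0L) {
    # planar zig-zag (e.g. fully extended chain): curvature vectors are
    # anti-parallel, the 2-residue-repeat limit — no defined handedness
    h <- unitv(prop)
    return(list(rise = mean(d %*% h), residues_per_turn = 2,
                handedness = "undefined", degenerate = TRUE))
  }
  h <- unitv(colMeans(axes))
  rise <- mean(d %*% h)
  q <- d - outer(as.vector(d %*% h), h) # bond projections onto normal plane
  tw <- numeric()
  for (k in seq_len(nrow(q) - 1L)) {
    q1 <- q[k, ]; q2 <- q[k + 1L, ]
    if (vnorm(q1) < degenerate_tol || vnorm(q2) < degenerate_tol) next
    ang <- atan2(sum(cross3(q1, q2) * h), sum(q1 * q2)) * 180 / pi
    tw <- c(tw, ang)
  }
  if (!length(tw) || abs(mean(tw)) < 1e-6) {
    return(list(rise = rise, residues_per_turn = Inf, handedness = "undefined",
                degenerate = TRUE))
  }
  twist <- mean(tw)
  list(rise = rise,
       residues_per_turn = 360 / abs(twist),
       handedness = if (twist > 0) "right" else "left",
       # twists at the +/-180 degree branch cut are the 2-residue repeat
       # limit where the rotation sign is numerically meaningless
       degenerate = any(abs(tw) > 175))
}

#' Local helix parameters along a backbone
#'
#' Slides a window of `window` consecutive CA positions along each chain
#' segment and reports, per window, the rise per residue (Angstrom of
#' axial advance), the number of residues per turn (360 / mean twist) and
#' the handedness (sign of the twist looking along the direction of chain
#' propagation; right-handed twist is positive). Windows on straight
#' (collinear) stretches are flagged degenerate with undefined handedness.
#'
#' @param model A [backbone_model].
#' @param window Number of CA positions per window (>= 4).
#' @return data.frame with one row per window: `start`, `end` (residue
#'   numbers), `rise_per_residue`, `residues_per_turn`, `handedness`,
#'   `degenerate`.
#' @export
fit_local_helix <- function(model, window = 5L) {
  stopifnot(inherits(model, "backbone_model"))
  if (window < 4L) stopf("window must be at least 4 CA positions")
  res <- attr(model, "residues")
  CA <- atom_coords(model, "CA")
  segs <- attr(model, "segments")
  out <- list()
  for (s in seq_len(nrow(segs))) {
    pos <- segs$start[s]:segs$end[s]
    w <- min(window, length(pos))
    if (length(pos) < 4L) next
    for (st in seq_len(length(pos) - w + 1L)) {
      rows <- pos[st:(st + w - 1L)]
      if (anyNA(CA[rows, ])) next
      p <- helix_window_params(CA[rows, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        start = res[rows[1]], end = res[rows[w]],
        rise_per_residue = p$rise, residues_per_turn = p$residues_per_turn,
        handedness = p$handedness, degenerate = p$degenerate,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      rise_per_residue = numeric(),
                      residues_per_turn = numeric(),
                      handedness = character(), degenerate = logical()))
  }
  do.call(rbind, out)
}

#' Detect polyproline-II segments from backbone geometry
#'
#' A residue stretch is called PPII when every helix-parameter window
#' covering it satisfies the three criteria: (i) left handedness, (ii)
#' residues per turn within `turn_range` (nominally 3), and (iii) rise per
#' residue within `rise_range` (nominally 3.1 Angstrom). Maximal such runs
#' of at least `min_len` residues are reported with their per-segment mean
#' rise, mean residues per turn, and the per-turn length
#' `turn_length = 3 * mean rise`.
#'
#' @param model A [backbone_model].
#' @param rise_range Allowed rise per residue, Angstrom.
#' @param turn_range Allowed residues per turn.
#' @param min_len Minimum segment length in residues.
#' @param window Window size passed to [fit_local_helix].
#' @return data.frame with `start`, `end`, `length`, `mean_rise`,
#'   `mean_residues_per_turn`, `turn_length`.
#' @export
detect_ppii_segments <- function(model, rise_range = c(2.8, 3.4),
                                 turn_range = c(2.6, 3.4), min_len = 4L,
                                 window = 5L) {
  fits <- fit_local_helix(model, window = window)
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      mean_rise = numeric(), mean_residues_per_turn = numeric(),
                      turn_length = numeric())
  if (nrow(fits) == 0L) return(empty)
  ok <- !fits$degenerate & fits$handedness == "left" &
    fits$rise_per_residue >= rise_range[1] & fits$rise_per_residue <= rise_range[2] &
    fits$residues_per_turn >= turn_range[1] & fits$residues_per_turn <= turn_range[2]
  res <- attr(model, "residues")
  # a residue qualifies when covered by >= 1 window and all covering pass
  covered <- rep(FALSE, length(res)); all_ok <- rep(TRUE, length(res))
  for (k in seq_len(nrow(fits))) {
    rows <- which(res >= fits$start[k] & res <= fits$end[k])
    covered[rows] <- TRUE
    if (!ok[k]) all_ok[rows] <- FALSE
  }
  runs <- true_runs(covered & all_ok)
  if (nrow(runs) == 0L) return(empty)
  out <- list()
  for (k in seq_len(nrow(runs))) {
    s <- runs$start[k]; e <- runs$end[k]
    if (e - s + 1L < min_len) next
    inw <- ok & fits$start >= res[s] & fits$end <= res[e]
    mr <- mean(fits$rise_per_residue[inw])
    mt <- mean(fits$residues_per_turn[inw])
    out[[length(out) + 1L]] <- data.frame(
      start = res[s], end = res[e], length = e - s + 1L,
      mean_rise = mr, mean_residues_per_turn = mt,
      turn_length = turn_length(mr)
    )
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Per-turn length of a 3-residue-per-turn helix
#'
#' @param mean_rise Mean rise per residue in Angstrom (> 0).
#' @return `3 * mean_rise`, the axial length of one PPII turn.
#' @export
#' @examples
#' turn_length(3.1) # 9.3
turn_length <- function(mean_rise) {
  if (any(!is.finite(mean_rise)) || any(mean_rise <= 0)) {
    stopf("mean_rise must be positive")
  }
  3 * mean_rise
}

# best-fit unit normal of a set of >= 3 points (smallest principal axis)
plane_normal <- function(P) {
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc)
  sv$v[, 3]
}

#' Angle between proline ring planes
#'
#' Measures the angle between the mean ring-plane normals of two proline
#' residues, folded into \[0, 90\] degrees (a plane has no preferred
#' normal sign). Rings are considered aligned when the angle is at most
#' `aligned_max`. In an ideal PPII helix, prolines at i and i+3 are
#' related by a full turn and their rings point the same way.
#'
#' @param model A [backbone_model] whose prolines carry ring atoms
#'   (`N`, `CA`, `CB`, `CG`, `CD`).
#' @param i,j Residue numbers of the two prolines.
#' @param aligned_max Alignment threshold in degrees (default 30).
#' @return List with `angle` (degrees) and `aligned` (logical).
#' @export
proline_ring_alignment <- function(model, i, j, aligned_max = 30) {
  stopifnot(inherits(model, "backbone_model"))
  ring_normal <- function(r) {
    rows <- model[model$resno == r, , drop = FALSE]
    if (nrow(rows) == 0L) stopf("residue %d not in model", r)
    if (rows$aa[1] != "P") stopf("residue %d is not a proline", r)
    ring <- rows[rows$atom %in% c("N", "CA", "CB", "CG", "CD"), , drop = FALSE]
    if (nrow(ring) < 3L) stopf("residue %d lacks ring atoms", r)
    plane_normal(as.matrix(ring[, c("x", "y", "z")]))
  }
  n1 <- ring_normal(i); n2 <- ring_normal(j)
  cosang <- abs(sum(n1 * n2)) / (vnorm(n1) * vnorm(n2))
  ang <- acos(pmin(1, cosang)) * 180 / pi
  list(angle = ang, aligned = ang <= aligned_max)
}
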