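# Shared fixtures and independent oracles. Everything here is built in
# code at test time; no binary fixtures.

# Synthetic reference table with distinct, easily recognisable values so
# tests never depend on the packaged snapshot.
synthetic_reference <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- seq(50, 69, length.out = 20)
  reference_shifts(
    CA = stats::setNames(base, aa),
    HA = stats::setNames(4 + seq_along(aa) / 100, aa),
    N = stats::setNames(110 + seq_along(aa), aa),
    HN = stats::setNames(8 + seq_along(aa) / 50, aa)
  )
}

random_shift_table <- function(n = 30, seed = 1) {
  set.seed(seed)
  aa <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE)
  shift_table(
    seq_len(n), aa,
    list(CA = round(runif(n, 45, 65), 3),
         HA = round(runif(n, 3.8, 5), 3),
         N = round(runif(n, 105, 130), 3),
         HN = round(runif(n, 7.5, 9.5), 3)),
    construct = "random"
  )
}

# Independent four-point torsion (praxeolitic formulation), used as the
# vector-algebra oracle for backbone_dihedrals.
oracle_torsion <- function(p0, p1, p2, p3) {
  b0 <- p0 - p1
  b1 <- p2 - p1
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p3 - p2
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  cr <- c(b1[2] * v[3] - b1[3] * v[2],
          b1[3] * v[1] - b1[1] * v[3],
          b1[1] * v[2] - b1[2] * v[1])
  atan2(sum(cr * w), x) * 180 / pi
}

# Brute-force helix fit: grid search over axis orientations minimising the
# spread of per-bond axial advances, refined with optim. Returns rise and
# twist (deg) about the optimal axis.
oracle_helix_fit <- function(P) {
  n <- nrow(P)
  d <- P[-1, , drop = FALSE] - P[-n, , drop = FALSE]
  prop <- P[n, ] - P[1, ]
  obj <- function(ang) {
    h <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    stats::sd(d %*% h)
  }
  grid <- expand.grid(theta = seq(0, pi, length.out = 60),
                      phi = seq(0, 2 * pi, length.out = 120))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  h <- c(sin(opt$par[1]) * cos(opt$par[2]),
         sin(opt$par[1]) * sin(opt$par[2]), cos(opt$par[1]))
  if (sum(h * prop) < 0) h <- -h
  rise <- mean(d %*% h)
  q <- d - outer(as.vector(d %*% h), h)
  tw <- vapply(seq_len(nrow(q) - 1L), function(k) {
    q1 <- q[k, ]; q2 <- q[k + 1L, ]
    cr <- c(q1[2] * q2[3] - q1[3] * q2[2],
            q1[3] * q2[1] - q1[1] * q2[3],
            q1[1] * q2[2] - q1[2] * q2[1])
    atan2(sum(cr * h), sum(q1 * q2)) * 180 / pi
  }, 0)
  list(rise = rise, twist = mean(tw))
}

# Random proper rotation matrix (det +1).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

transform_model <- function(model, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  m2 <- as.data.frame(model)
  m2$x <- xyz[, 1] + t[1]; m2$y <- xyz[, 2] + t[2]; m2$z <- xyz[, 3] + t[3]
  backbone_model(m2)
}

# coordinates of one atom kind as a plain matrix, ordered by residue
atom_xyz <- function(model, atom) {
  a <- model[model$atom == atom, ]
  as.matrix(a[order(a$resno), c("x", "y", "z")])
}

ca_matrix <- function(model) atom_xyz(model, "CA")

# Exhaustive optimal one-to-one peak assignment for tiny instances:
# maximise the number of matched pairs within tolerance, then minimise the
# total normalised distance. Returns fragment-row -> full-row map.
oracle_peak_assignment <- function(fp, lp, tol_n15 = 0.2, tol_h1 = 0.02) {
  nf <- nrow(fp); nl <- nrow(lp)
  dist <- pmax(abs(outer(fp$n15, lp$n15, `-`)) / tol_n15,
               abs(outer(fp$h1, lp$h1, `-`)) / tol_h1)
  best <- list(count = -1, total = Inf, map = rep(NA_integer_, nf))
  recurse <- function(fi, used, map, count, total) {
    if (fi > nf) {
      if (count > best$count ||
          (count == best$count && total < best$total - 1e-12)) {
        best <<- list(count = count, total = total, map = map)
      }
      return(invisible())
    }
    recurse(fi + 1L, used, map, count, total) # leave fi unmatched
    if (nl > 0) {
      for (li in seq_len(nl)) {
        if (!used[li] && dist[fi, li] <= 1) {
          used[li] <- TRUE; map[fi] <- li
          recurse(fi + 1L, used, map, count + 1L, total + dist[fi, li])
          used[li] <- FALSE; map[fi] <- NA_integer_
        }
      }
    }
  }
  recurse(1L, rep(FALSE, max(nl, 1L)), rep(NA_integer_, nf), 0L, 0)
  best$map
}

# Planted per-residue state vector of a segment_spec
spec_truth_states <- function(spec) {
  st <- rep("coil", length(spec$sequence))
  for (k in seq_len(nrow(spec$segments))) {
    st[spec$segments$start[k]:spec$segments$end[k]] <- spec$segments$state[k]
  }
  st
}

# Synthetic construct with planted alpha / three_ten / ppii segments whose
# sequence composition matches each state's signature (prolines only in
# and around the PPII repeat, none in helices).
make_recovery_spec <- function(seed) {
  set.seed(seed)
  len_a <- sample(8:15, 1)
  len_p3 <- sample(2:6, 1) # ppii = P(XQP)*k, length 3k+1 in 7..19
  coil_pool <- c("G", "S", "H", "Q", "T", "V", "N")
  helix_pool <- c("A", "L", "E", "K", "M", "F")
  seq_parts <- list(
    coil1 = sample(coil_pool, 8, replace = TRUE),
    alpha = sample(helix_pool, len_a, replace = TRUE),
    coil2 = sample(coil_pool, 6, replace = TRUE),
    tten = sample(helix_pool, 3, replace = TRUE),
    coil3 = sample(coil_pool, 6, replace = TRUE),
    ppii = c("P", rep(c(sample(c("L", "M", "F"), 1), "Q", "P"), len_p3)),
    coil4 = sample(coil_pool, 6, replace = TRUE)
  )
  seqv <- unlist(seq_parts, use.names = FALSE)
  ends <- cumsum(lengths(seq_parts)) # end position of each part
  seg <- data.frame(
    start = c(ends["alpha"] - len_a + 1L,
              ends["tten"] - 3L + 1L,
              ends["ppii"] - (3L * len_p3 + 1L) + 1L),
    end = unname(c(ends["alpha"], ends["tten"], ends["ppii"])),
    state = c("alpha", "three_ten", "ppii")
  )
  seg$start <- as.integer(seg$start); seg$end <- as.integer(seg$end)
  list(spec = segment_spec(seqv, seg), truth_segments = seg)
}
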