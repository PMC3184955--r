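#' Coarse-grained monomer template rod
#'
#' The full-length monomer is represented as a straight rod of uniformly
#' spaced beads (the solution structure is elongated; the default length
#' of 11.9 nm is its end-to-end extent). Beads are labelled with the
#' functional domain whose residue span covers their fractional position
#' along the chain.
#'
#' @param length_nm Rod length in nm (> 0).
#' @param n_beads Total number of beads (>= 2).
#' @param domains data.frame of domain boundaries in residue numbering
#'   (default [amelogenin_domains]).
#' @return Object of class `monomer_template`: data.frame with `bead`,
#'   `s` (arc position from the N terminus, nm), `domain`; attribute
#'   `length_nm`.
#' @export
make_monomer_template <- function(length_nm = 11.9, n_beads = 18L,
                                  domains = amelogenin_domains()) {
  if (!is.finite(length_nm) || length_nm <= 0) stopf("length_nm must be positive")
  if (n_beads < 2L) stopf("need at least 2 beads")
  s <- seq(0, length_nm, length.out = n_beads)
  lo <- min(domains$start); hi <- max(domains$end)
  frac_res <- lo + (s / length_nm) * (hi - lo)
  dom <- vapply(frac_res, function(f) {
    domains$domain[which(f >= domains$start - 0.5 & f <= domains$end + 0.5)[1]]
  }, "")
  structure(
    data.frame(bead = seq_len(n_beads), s = s, domain = dom,
               stringsAsFactors = FALSE),
    length_nm = length_nm,
    class = c("monomer_template", "data.frame")
  )
}

# deterministic quasi-uniform directions on the unit sphere
fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build a hollow-shell nanosphere assembly
#'
#' Places `n_copies` rigid copies of the monomer rod radially on a
#' sphere: directions follow a deterministic spherical Fibonacci lattice,
#' each rod points along its radius with the C-terminal bead at the outer
#' surface and the N-terminal bead facing the hollow interior — N termini
#' meet at the assembly interface, C termini point outward. The cavity
#' radius is `outer_diameter/2 - rod length`.
#'
#' @param template A [make_monomer_template] rod.
#' @param n_copies Number of monomer copies (default 50, the copy number
#'   implied by the major assembly peak mass over the monomer mass).
#' @param outer_diameter_nm Outer diameter in nm (default 30; must be at
#'   least twice the rod length so rods cannot cross the centre).
#' @param clash_cutoff_nm Minimum allowed distance between beads of
#'   different placements; violations are reported, never repaired.
#' @return Object of class `assembly_model`: list with `beads`
#'   (data.frame `copy`, `bead`, `domain`, `x`, `y`, `z`, `r` in nm),
#'   `template`, `n_copies`, `outer_diameter_nm`, `cavity_radius_nm`,
#'   `clash_cutoff_nm`.
#' @export
#' @examples
#' m <- build_nanosphere(make_monomer_template())
#' model_metrics(m)$outer_diameter_nm
build_nanosphere <- function(template, n_copies = 50L, outer_diameter_nm = 30,
                             clash_cutoff_nm = 0.4) {
  stopifnot(inherits(template, "monomer_template"))
  if (n_copies < 1L) stopf("n_copies must be >= 1")
  L <- attr(template, "length_nm")
  R <- outer_diameter_nm / 2
  if (outer_diameter_nm < 2 * L) {
    stopf("outer diameter (%.1f nm) must be at least twice the monomer length (%.1f nm)",
          outer_diameter_nm, L)
  }
  dirs <- fibonacci_sphere(n_copies)
  rows <- vector("list", n_copies)
  for (k in seq_len(n_copies)) {
    r <- R - L + template$s # N-terminal bead innermost, C-terminal at R
    rows[[k]] <- data.frame(
      copy = k, bead = template$bead, domain = template$domain,
      x = dirs[k, 1] * r, y = dirs[k, 2] * r, z = dirs[k, 3] * r, r = r,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(beads = do.call(rbind, rows), template = template,
         n_copies = as.integer(n_copies),
         outer_diameter_nm = outer_diameter_nm,
         cavity_radius_nm = R - L,
         clash_cutoff_nm = clash_cutoff_nm),
    class = "assembly_model"
  )
}

#' @export
print.assembly_model <- function(x, ...) {
  m <- model_metrics(x)
  cat(sprintf(
    "assembly_model: %d copies, outer diameter %.1f nm, cavity radius %.2f nm, min inter-copy distance %.2f nm\n",
    x$n_copies, m$outer_diameter_nm, m$cavity_radius_nm,
    m$min_interplacement_distance_nm))
  invisible(x)
}

#' Geometric metrics of an assembly model
#'
#' @param model An [build_nanosphere] assembly.
#' @return List with `outer_diameter_nm` (2 x max bead radius),
#'   `cavity_radius_nm` (min bead radius),
#'   `min_interplacement_distance_nm` (brute-force minimum over all bead
#'   pairs of different copies; `Inf` for a single copy),
#'   `radial_orientation_ok` (all placements have monotonically
#'   increasing bead radius from N to C), and `clash_free`.
#' @export
model_metrics <- function(model) {
  stopifnot(inherits(model, "assembly_model"))
  b <- model$beads
  if (nrow(b) == 0L) stopf("empty model")
  radius <- sqrt(b$x^2 + b$y^2 + b$z^2)
  mono <- vapply(split(radius, b$copy), function(r) all(diff(r) > -1e-9), TRUE)
  min_d <- Inf
  if (model$n_copies > 1L) {
    D <- as.matrix(stats::dist(b[, c("x", "y", "z")]))
    same <- outer(b$copy, b$copy, `==`)
    min_d <- min(D[!same])
  }
  list(outer_diameter_nm = 2 * max(radius),
       cavity_radius_nm = min(radius),
       min_interplacement_distance_nm = min_d,
       radial_orientation_ok = all(mono),
       clash_free = min_d >= model$clash_cutoff_nm)
}

#' Export an assembly model as a pseudo-atom PDB file
#'
#' One CA pseudo-atom per bead, one chain per monomer copy (chain
#' identifiers cycle through A-Z then 0-9 and a-z), coordinates converted
#' from nm to Angstrom.
#'
#' @param model An assembly model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_assembly_pdb <- function(model, path) {
  stopifnot(inherits(model, "assembly_model"))
  b <- model$beads
  chain_ids <- c(LETTERS, 0:9, letters)
  chain <- chain_ids[(b$copy - 1L) %% length(chain_ids) + 1L]
  n <- nrow(b)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(b[, c("x", "y", "z")]) * 10)),
                   resno = b$bead,
                   resid = rep("GLY", n),
                   eleno = seq_len(n),
                   elety = rep("CA", n),
                   chain = chain)
  invisible(path)
}
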