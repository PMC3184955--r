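#' Construct a backbone coordinate model
#'
#' Ordered backbone heavy-atom coordinates in Angstrom, one or more atoms
#' per residue (`N`, `CA`, `C`, optionally `O`, and for prolines the ring
#' atoms `CB`, `CG`, `CD`). Chain continuity is checked through the
#' consecutive CA-CA distance, which must lie in \[2.8, 4.2\] Angstrom
#' within a segment; violations introduce segment boundaries.
#'
#' @param atoms data.frame with columns `resno` (integer), `aa` (one-letter
#'   code), `atom` (atom name), `x`, `y`, `z` (Angstrom).
#' @param warn Emit a warning when a chain break is detected?
#' @return Object of class `backbone_model`: the atom data.frame plus a
#'   `segments` attribute (data.frame `start`, `end` in residue positions).
#' @export
backbone_model <- function(atoms, warn = TRUE) {
  need <- c("resno", "aa", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stopf("atoms needs columns %s", paste(need, collapse = ", "))
  }
  atoms <- atoms[order(atoms$resno), need, drop = FALSE]
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")])))) {
    stopf("all coordinates must be finite")
  }
  rownames(atoms) <- NULL
  res <- unique(atoms$resno)
  ca <- atoms[atoms$atom == "CA", ]
  ca <- ca[match(res, ca$resno), ]
  # segment boundaries: numbering gaps or CA-CA distances outside tolerance
  seg_start <- 1L
  starts <- integer(); ends <- integer()
  if (length(res) >= 1L) {
    for (k in seq_len(length(res) - 1L)) {
      d <- sqrt(sum((unlist(ca[k + 1L, c("x", "y", "z")]) -
                       unlist(ca[k, c("x", "y", "z")]))^2))
      gap <- res[k + 1L] != res[k] + 1L
      if (gap || is.na(d) || d < 2.8 || d > 4.2) {
        if (warn && !gap) {
          warnf("chain break between residues %d and %d (CA-CA %.2f A)",
                res[k], res[k + 1L], d)
        }
        starts <- c(starts, seg_start); ends <- c(ends, k)
        seg_start <- k + 1L
      }
    }
    starts <- c(starts, seg_start); ends <- c(ends, length(res))
  }
  structure(atoms,
            segments = data.frame(start = starts, end = ends),
            residues = res,
            class = c("backbone_model", "data.frame"))
}

#' @export
print.backbone_model <- function(x, ...) {
  res <- attr(x, "residues")
  cat(sprintf("backbone_model: %d residues, %d atoms, %d segment(s)\n",
              length(res), nrow(x), nrow(attr(x, "segments"))))
  invisible(x)
}

# n x 3 matrix of coordinates for one atom kind, rows ordered by residue
atom_coords <- function(model, atom = "CA") {
  res <- attr(model, "residues")
  sel <- model[model$atom == atom, ]
  m <- as.matrix(sel[match(res, sel$resno), c("x", "y", "z")])
  rownames(m) <- res
  m
}

KEEP_ATOMS <- c("N", "CA", "C", "O", "CB", "CG", "CD")

#' Read backbone coordinates from a PDB file
#'
#' Retains `N`, `CA`, `C`, `O` and proline ring atoms (`CB`, `CG`, `CD`)
#' from ATOM records. Residues without a CA atom are skipped with a
#' warning; CA-CA distances outside \[2.8, 4.2\] Angstrom insert a segment
#' boundary with a warning. An empty file yields an empty model.
#'
#' @param path PDB file path.
#' @return A [backbone_model].
#' @export
read_backbone_pdb <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  if (!any(startsWith(lines, "ATOM"))) {
    return(backbone_model(data.frame(resno = integer(), aa = character(),
                                     atom = character(), x = numeric(),
                                     y = numeric(), z = numeric())))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom[pdb$atom$type == "ATOM", ]
  aa <- AA3_TO_1[toupper(a$resid)]
  keep <- a$elety %in% KEEP_ATOMS & !is.na(aa) &
    (a$elety %in% c("N", "CA", "C", "O") | aa == "P")
  a <- a[keep, ]; aa <- aa[keep]
  has_ca <- tapply(a$elety == "CA", a$resno, any)
  no_ca <- as.integer(names(has_ca))[!has_ca]
  if (length(no_ca)) {
    warnf("skipping residue(s) without CA: %s", paste(no_ca, collapse = ", "))
    drop <- a$resno %in% no_ca
    a <- a[!drop, ]; aa <- aa[!drop]
  }
  backbone_model(data.frame(resno = a$resno, aa = unname(aa), atom = a$elety,
                            x = a$x, y = a$y, z = a$z,
                            stringsAsFactors = FALSE))
}

#' Write a backbone model as PDB ATOM records
#'
#' @param model A [backbone_model].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(model, path) {
  stopifnot(inherits(model, "backbone_model"))
  if (nrow(model) == 0L) {
    writeLines("END", path)
    return(invisible(path))
  }
  xyz <- as.vector(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = model$resno,
                   resid = unname(AA1_TO_3[model$aa]),
                   eleno = seq_len(nrow(model)),
                   elety = model$atom,
                   chain = "A")
  invisible(path)
}
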