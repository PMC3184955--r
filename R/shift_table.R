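#' Construct a per-residue chemical-shift table
#'
#' A `shift_table` holds assigned backbone chemical shifts for one
#' expression construct: one row per residue, with columns for each atom
#' kind (`CA`, `HA`, `N`, `HN`, `CB`) in ppm and `NA` where a resonance was
#' not assigned. Residue indices are construct-local and strictly
#' increasing; His-tag residues carry indices <= 0 and are dropped from
#' analyses unless explicitly requested. `offset` maps construct positions
#' into full-length numbering (full-length index = index + offset).
#'
#' @param index Integer residue indices (construct numbering).
#' @param aa One-letter amino-acid codes, same length as `index`.
#' @param shifts Named list or data.frame of numeric ppm vectors, names
#'   from `CA`, `HA`, `N`, `HN`, `CB`. Missing atoms may be omitted.
#' @param construct Construct name (free text, e.g. `"Amel-M"`).
#' @param offset Integer offset into full-length numbering.
#' @return Object of class `shift_table`: a list with elements `construct`,
#'   `offset` and `data` (data.frame `index`, `aa`, then atom columns).
#' @export
#' @examples
#' st <- shift_table(1:3, c("M", "P", "L"),
#'                   list(CA = c(55.4, 63.3, 55.1), HA = c(4.48, 4.42, 4.34)))
#' st$data
shift_table <- function(index, aa, shifts = list(), construct = "construct",
                        offset = 0L) {
  index <- as.integer(index)
  aa <- as.character(aa)
  if (length(index) != length(aa)) {
    stopf("`index` and `aa` lengths differ (%d vs %d)", length(index), length(aa))
  }
  if (length(index) > 1L && any(diff(index) <= 0L)) {
    stopf("residue indices must be strictly increasing")
  }
  bad <- aa[!is_aa1(aa)]
  if (length(bad)) stopf("unknown amino-acid code(s): %s", paste(unique(bad), collapse = ", "))
  dat <- data.frame(index = index, aa = aa, stringsAsFactors = FALSE)
  for (k in ATOM_KINDS) {
    v <- if (k %in% names(shifts)) as.numeric(shifts[[k]]) else rep(NA_real_, length(index))
    if (length(v) != length(index)) stopf("shift vector `%s` has wrong length", k)
    if (any(!is.na(v) & !is.finite(v))) stopf("non-finite shift value in `%s`", k)
    dat[[k]] <- v
  }
  extra <- setdiff(names(shifts), ATOM_KINDS)
  if (length(extra)) stopf("unsupported atom kind(s): %s", paste(extra, collapse = ", "))
  structure(
    list(construct = as.character(construct), offset = as.integer(offset), data = dat),
    class = "shift_table"
  )
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf(
    "shift_table '%s': %d residues (offset %+d), %s\n",
    x$construct, nrow(x$data), x$offset,
    paste(sprintf("%s:%d", ATOM_KINDS, colSums(!is.na(x$data[ATOM_KINDS]))),
          collapse = " ")
  ))
  invisible(x)
}

#' Drop or keep tag residues of a shift table
#'
#' @param x A `shift_table`.
#' @param include_tag Keep residues with index <= 0 (His-tag leader)?
#' @return `shift_table` restricted accordingly.
#' @export
construct_residues <- function(x, include_tag = FALSE) {
  stopifnot(inherits(x, "shift_table"))
  if (!include_tag) x$data <- x$data[x$data$index >= 1L, , drop = FALSE]
  rownames(x$data) <- NULL
  x
}

#' Read a chemical-shift table
#'
#' Two dialects are supported. `"tsv"` is a tab-separated table with a
#' header row, columns `residue_index`, `aa`, then any of `CA`, `HA`, `N`,
#' `HN`, `CB`; empty cells are unassigned shifts. `"nmrstar-lite"` is a
#' minimal NMR-STAR v3 `_Atom_chem_shift` loop: the reader locates the
#' first loop whose tags start with `_Atom_chem_shift.` and uses the
#' `Comp_index_ID`, `Comp_ID`, `Atom_ID` and `Val` tags (atom `H` is
#' accepted as `HN`).
#'
#' @param path File path.
#' @param format `"tsv"` or `"nmrstar-lite"`.
#' @param construct Construct name stored on the result.
#' @param offset Offset into full-length numbering.
#' @return A [shift_table].
#' @export
read_shift_table <- function(path, format = c("tsv", "nmrstar-lite"),
                             construct = NULL, offset = 0L) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(construct)) construct <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
    "tsv" = read_shift_tsv(path, construct, offset),
    "nmrstar-lite" = read_shift_star(path, construct, offset)
  )
}

read_shift_tsv <- function(path, construct, offset) {
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(nonblank)) stopf("%s: empty shift table", path)
  header <- strsplit(lines[nonblank[1]], "\t", fixed = TRUE)[[1]]
  if (!all(c("residue_index", "aa") %in% header)) {
    stopf("%s: header must contain residue_index and aa", path)
  }
  atom_cols <- intersect(header, ATOM_KINDS)
  rows <- nonblank[-1]
  n <- length(rows)
  idx <- integer(n); aa <- character(n)
  shifts <- lapply(atom_cols, function(k) rep(NA_real_, n))
  names(shifts) <- atom_cols
  for (r in seq_len(n)) {
    ln <- rows[r]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    length(f) <- length(header) # right-pad short rows with NA
    rec <- stats::setNames(f, header)
    i <- suppressWarnings(as.integer(rec[["residue_index"]]))
    if (is.na(i)) stopf("%s line %d: non-integer residue_index '%s'",
                        path, ln, rec[["residue_index"]])
    idx[r] <- i
    aa[r] <- rec[["aa"]]
    for (k in atom_cols) {
      cell <- rec[[k]]
      if (is.na(cell) || !nzchar(trimws(cell))) next
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v)) stopf("%s line %d: non-numeric ppm value '%s' in column %s",
                          path, ln, cell, k)
      shifts[[k]][r] <- v
    }
  }
  if (anyDuplicated(idx)) stopf("%s: duplicate residue_index %s", path,
                                idx[duplicated(idx)][1])
  o <- order(idx)
  shift_table(idx[o], aa[o], lapply(shifts, function(v) v[o]),
              construct = construct, offset = offset)
}

read_shift_star <- function(path, construct, offset) {
  lines <- trimws(readLines(path))
  li <- which(lines == "loop_")
  if (!length(li)) stopf("%s: no loop_ found", path)
  for (start in li) {
    j <- start + 1L
    tags <- character()
    while (j <= length(lines) && startsWith(lines[j], "_")) {
      tags <- c(tags, lines[j]); j <- j + 1L
    }
    if (!length(tags) || !all(startsWith(tags, "_Atom_chem_shift."))) next
    want <- c("Comp_index_ID", "Comp_ID", "Atom_ID", "Val")
    pos <- match(paste0("_Atom_chem_shift.", want), tags)
    if (anyNA(pos)) stopf("%s: Atom_chem_shift loop lacks tag(s): %s", path,
                          paste(want[is.na(pos)], collapse = ", "))
    recs <- list()
    while (j <= length(lines) && !(lines[j] %in% c("stop_", "loop_"))) {
      if (nzchar(lines[j]) && !startsWith(lines[j], "#")) {
        f <- strsplit(lines[j], "[[:space:]]+")[[1]]
        if (length(f) < length(tags)) {
          stopf("%s line ~%d: loop row has %d fields, expected %d",
                path, j, length(f), length(tags))
        }
        recs[[length(recs) + 1L]] <- f[pos]
      }
      j <- j + 1L
    }
    if (!length(recs)) stopf("%s: empty Atom_chem_shift loop", path)
    m <- do.call(rbind, recs)
    idx <- suppressWarnings(as.integer(m[, 1]))
    if (anyNA(idx)) stopf("%s: non-integer Comp_index_ID", path)
    aa3 <- toupper(m[, 2])
    aa1 <- AA3_TO_1[aa3]
    if (anyNA(aa1)) stopf("%s: unknown residue type '%s'", path, aa3[is.na(aa1)][1])
    atom <- toupper(m[, 3])
    atom[atom == "H"] <- "HN"
    val <- suppressWarnings(as.numeric(m[, 4]))
    if (anyNA(val)) stopf("%s: non-numeric Val '%s'", path, m[is.na(val), 4][1])
    keep <- atom %in% ATOM_KINDS
    idx <- idx[keep]; aa1 <- unname(aa1[keep]); atom <- atom[keep]; val <- val[keep]
    key <- paste(idx, atom)
    if (anyDuplicated(key)) stopf("%s: duplicate shift entry for residue %s atom %s",
                                  path, idx[duplicated(key)][1],
                                  atom[duplicated(key)][1])
    uidx <- sort(unique(idx))
    uaa <- aa1[match(uidx, idx)]
    shifts <- lapply(ATOM_KINDS, function(k) {
      v <- rep(NA_real_, length(uidx))
      sel <- atom == k
      v[match(idx[sel], uidx)] <- val[sel]
      v
    })
    names(shifts) <- ATOM_KINDS
    return(shift_table(uidx, uaa, shifts, construct = construct, offset = offset))
  }
  stopf("%s: no _Atom_chem_shift loop found", path)
}

#' Write a shift table in the package TSV dialect
#'
#' @param x A [shift_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(x, path) {
  stopifnot(inherits(x, "shift_table"))
  d <- x$data
  cells <- lapply(ATOM_KINDS, function(k) {
    ifelse(is.na(d[[k]]), "", formatC(d[[k]], format = "g", digits = 15))
  })
  out <- c(
    paste(c("residue_index", "aa", ATOM_KINDS), collapse = "\t"),
    do.call(paste, c(list(d$index, d$aa), cells, sep = "\t"))
  )
  writeLines(out, path)
  invisible(path)
}
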