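#' Classify 3J(HN-HA) scalar couplings
#'
#' Small three-bond HN-HA couplings are consistent with helical phi
#' angles; values at or above the threshold indicate extended
#' conformations. The boundary value is assigned to `extended`.
#'
#' @param values data.frame with `index` and `value` (Hz), as returned by
#'   [read_value_table]; missing values allowed.
#' @param threshold_hz Classification threshold in Hz (default 7).
#' @return data.frame with `index` and `j_class` in
#'   `helix_compatible` / `extended` / `unclassified`.
#' @export
#' @examples
#' classify_jcoupling(data.frame(index = 1:3, value = c(6.5, 7.0, NA)))
classify_jcoupling <- function(values, threshold_hz = 7.0) {
  v <- values$value
  if (any(!is.na(v) & v < 0)) stopf("negative J coupling value")
  cls <- ifelse(is.na(v), "unclassified",
                ifelse(v < threshold_hz, "helix_compatible", "extended"))
  data.frame(index = as.integer(values$index), j_class = cls,
             stringsAsFactors = FALSE)
}

#' Classify heteronuclear NOE rigidity
#'
#' Steady-state 1H-15N NOE values near 0.6 and above indicate a rigid
#' backbone; values near 0.3 and below indicate flexibility. The default
#' cutoff 0.45 is the midpoint of those two regimes; the boundary value is
#' assigned to `rigid`.
#'
#' @param values data.frame with `index` and `value` (dimensionless, must
#'   lie in \[-1.5, 1.1\]).
#' @param rigid_min Rigidity cutoff (default 0.45).
#' @return data.frame with `index` and `rigidity` in
#'   `rigid` / `flexible` / `unclassified`.
#' @export
classify_hnoe <- function(values, rigid_min = 0.45) {
  v <- values$value
  if (any(!is.na(v) & (v < -1.5 | v > 1.1))) {
    stopf("heteronuclear NOE value outside [-1.5, 1.1]")
  }
  cls <- ifelse(is.na(v), "unclassified",
                ifelse(v >= rigid_min, "rigid", "flexible"))
  data.frame(index = as.integer(values$index), rigidity = cls,
             stringsAsFactors = FALSE)
}

#' Distance upper bound for an NOE intensity bin
#'
#' Restraint classification used when converting NOE intensities to
#' distance bounds: strong 2 A, medium 4 A, weak 6 A.
#'
#' @param intensity_bin `"strong"`, `"medium"` or `"weak"` (vectorised).
#' @return Numeric distance bound(s) in Angstrom.
#' @export
bin_noe_distance <- function(intensity_bin) {
  map <- c(strong = 2.0, medium = 4.0, weak = 6.0)
  bad <- setdiff(unique(intensity_bin), names(map))
  if (length(bad)) stopf("unknown NOE intensity bin: %s", paste(bad, collapse = ", "))
  unname(map[intensity_bin])
}

NOE_SEPS <- c("i+1", "i+2", "i+3", "long")

noe_sep_label <- function(i, j) {
  d <- abs(j - i)
  ifelse(d == 1L, "i+1", ifelse(d == 2L, "i+2", ifelse(d == 3L, "i+3", "long")))
}

#' Tabulate inter-residue NOE connectivities
#'
#' Assigns each record to a sequence-separation category by `|j - i|`
#' (1, 2, 3, or >= 4 = long range) within its class (`dNN`, `daN`,
#' `dbN`), accumulating counts at the lower residue index. Symmetric
#' duplicates (i,j)/(j,i) collapse to one record; duplicates of the same
#' pair and class keep the strongest intensity bin (shortest distance
#' bound). Records with `i == j` are rejected with a warning.
#'
#' @param records A [noe_records] data.frame.
#' @return List with `counts` (data.frame `index`, `class`, `separation`,
#'   `n` — the per-residue diagram data) and `records` (the accepted,
#'   de-duplicated records with a `separation` column).
#' @export
tabulate_connectivities <- function(records) {
  stopifnot(inherits(records, "noe_records") || is.data.frame(records))
  r <- as.data.frame(records)
  self <- r$i == r$j
  if (any(self)) {
    warnf("rejecting %d NOE record(s) with i == j", sum(self))
    r <- r[!self, , drop = FALSE]
  }
  lo <- pmin(r$i, r$j); hi <- pmax(r$i, r$j)
  r$i <- lo; r$j <- hi
  # collapse duplicates of (pair, class): keep strongest (shortest) bin
  strength <- match(r$bin, c("strong", "medium", "weak"))
  o <- order(r$i, r$j, r$class, strength)
  r <- r[o, , drop = FALSE]
  key <- paste(r$i, r$j, r$class)
  r <- r[!duplicated(key), , drop = FALSE]
  rownames(r) <- NULL
  r$separation <- noe_sep_label(r$i, r$j)
  if (nrow(r)) {
    tab <- stats::aggregate(list(n = rep(1L, nrow(r))),
                            by = list(index = r$i, class = r$class,
                                      separation = r$separation),
                            FUN = sum)
    tab <- tab[order(tab$index, tab$class, tab$separation), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(index = integer(), class = character(),
                      separation = character(), n = integer())
  }
  list(counts = tab, records = r)
}

#' Combine per-residue dynamics evidence channels
#'
#' Joins J-coupling classes, heteronuclear-NOE rigidity and NOE
#' connectivity counts on residue index into a single evidence table
#' consumed by [call_secondary_structure].
#'
#' @param jclass Output of [classify_jcoupling] (or `NULL`).
#' @param rigidity Output of [classify_hnoe] (or `NULL`).
#' @param connectivities Output of [tabulate_connectivities] (or `NULL`).
#' @param indices Residue indices the table must cover (defaults to the
#'   union of inputs).
#' @return Object of class `residue_evidence`: data.frame with `index`,
#'   `j_class`, `rigidity`, `noe_i3` (count of (i,i+3) contacts starting
#'   at the residue), `noe_i2`, `noe_long`.
#' @export
residue_evidence <- function(jclass = NULL, rigidity = NULL,
                             connectivities = NULL, indices = NULL) {
  if (is.null(indices)) {
    indices <- sort(unique(c(jclass$index, rigidity$index,
                             connectivities$counts$index)))
  }
  ev <- data.frame(index = as.integer(indices))
  ev$j_class <- if (is.null(jclass)) "unclassified" else {
    out <- jclass$j_class[match(ev$index, jclass$index)]
    ifelse(is.na(out), "unclassified", out)
  }
  ev$rigidity <- if (is.null(rigidity)) "unclassified" else {
    out <- rigidity$rigidity[match(ev$index, rigidity$index)]
    ifelse(is.na(out), "unclassified", out)
  }
  count_at <- function(sep) {
    if (is.null(connectivities)) return(rep(0L, nrow(ev)))
    cc <- connectivities$counts
    cc <- cc[cc$separation == sep, , drop = FALSE]
    if (nrow(cc) == 0L) return(rep(0L, nrow(ev)))
    agg <- tapply(cc$n, cc$index, sum)
    out <- as.integer(agg[as.character(ev$index)])
    out[is.na(out)] <- 0L
    out
  }
  ev$noe_i2 <- count_at("i+2")
  ev$noe_i3 <- count_at("i+3")
  ev$noe_long <- count_at("long")
  structure(ev, class = c("residue_evidence", "data.frame"))
}
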