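#' Load a random-coil / database-average reference shift table
#'
#' Secondary chemical shifts are computed against per-amino-acid average
#' reference shifts. The packaged `"bmrb-average"` table is a static
#' snapshot of database-average CA/HA/N/HN values in ppm; database
#' statistics drift across releases, so the exact values are configuration
#' rather than fact, and a user-supplied table (same TSV layout: columns
#' `aa`, `CA`, `HA`, `N`, `HN`) can be passed instead.
#'
#' @param name `"bmrb-average"` or a path to a user TSV.
#' @param override Optional named list of per-amino-acid overrides, e.g.
#'   `list(Q = c(CA = 55.9))`.
#' @return Object of class `reference_shifts`: data.frame with rownames
#'   the 20 one-letter codes and columns `CA`, `HA`, `N`, `HN`.
#' @export
#' @examples
#' ref <- load_reference_shifts()
#' ref["Q", "CA"]
load_reference_shifts <- function(name = "bmrb-average", override = NULL) {
  path <- if (identical(name, "bmrb-average")) {
    system.file("extdata", "reference_shifts_bmrb_average.tsv",
                package = "amelnmr", mustWork = TRUE)
  } else {
    if (!file.exists(name)) stopf("reference table not found: %s", name)
    name
  }
  d <- utils::read.delim(path)
  need <- c("aa", "CA", "HA", "N", "HN")
  if (!all(need %in% names(d))) {
    stopf("reference table needs columns %s", paste(need, collapse = ", "))
  }
  rownames(d) <- d$aa
  d <- d[, c("CA", "HA", "N", "HN")]
  missing_aa <- setdiff(AA1, rownames(d))
  if (length(missing_aa)) {
    stopf("reference table missing amino acid(s): %s", paste(missing_aa, collapse = ", "))
  }
  d <- d[AA1, ]
  if (!is.null(override)) {
    for (a in names(override)) {
      if (!a %in% AA1) stopf("override for unknown amino acid '%s'", a)
      v <- override[[a]]
      d[a, names(v)] <- as.numeric(v)
    }
  }
  if (any(!is.finite(as.matrix(d))) || any(as.matrix(d) <= 0)) {
    stopf("reference shifts must all be finite and positive")
  }
  structure(d, class = c("reference_shifts", "data.frame"))
}

#' Build a reference_shifts object from vectors (used by generators/tests)
#'
#' @param CA,HA,N,HN Named numeric vectors over the 20 one-letter codes.
#' @return A `reference_shifts` object.
#' @export
reference_shifts <- function(CA, HA, N, HN) {
  d <- data.frame(CA = CA[AA1], HA = HA[AA1], N = N[AA1], HN = HN[AA1],
                  row.names = AA1)
  if (any(!is.finite(as.matrix(d))) || any(as.matrix(d) <= 0)) {
    stopf("reference shifts must all be finite and positive")
  }
  structure(d, class = c("reference_shifts", "data.frame"))
}
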