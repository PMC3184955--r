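#' Secondary chemical shifts relative to reference averages
#'
#' Computes per-residue secondary shifts delta = observed - reference for
#' the CA and HA nuclei. Positive delta-CA together with negative delta-HA
#' is the canonical helix signature; strongly negative delta-CA at a
#' residue immediately preceding a proline is a sequence effect rather
#' than a conformational signal and is flagged separately (see
#' [flag_preproline]). Missing observed shifts propagate as missing
#' deltas, never as zero.
#'
#' @param shifts A [shift_table].
#' @param reference A [reference_shifts] table covering every amino acid
#'   present.
#' @param include_tag Include His-tag residues (index <= 0)?
#' @return Object of class `secondary_shift_profile`: data.frame with
#'   columns `index`, `aa`, `delta_ca`, `delta_ha`, `preceding_proline`
#'   (next residue is P), `preproline_flag` (set by [flag_preproline],
#'   initially `FALSE`).
#' @export
#' @examples
#' ref <- load_reference_shifts()
#' st <- shift_table(1:3, c("Q", "P", "L"),
#'                   list(CA = c(ref["Q", "CA"] - 2.5, 63.3, 55.6)))
#' compute_delta_shifts(st, ref)
compute_delta_shifts <- function(shifts, reference, include_tag = FALSE) {
  stopifnot(inherits(shifts, "shift_table"))
  stopifnot(inherits(reference, "reference_shifts"))
  d <- construct_residues(shifts, include_tag = include_tag)$data
  bad <- setdiff(unique(d$aa), rownames(reference))
  if (length(bad)) {
    stopf("no reference entry for residue type(s): %s (first at residue %d)",
          paste(bad, collapse = ", "), d$index[d$aa %in% bad][1])
  }
  # successor looked up by index so assignment gaps cannot shift the frame
  next_aa <- d$aa[match(d$index + 1L, d$index)]
  prof <- data.frame(
    index = d$index,
    aa = d$aa,
    delta_ca = d$CA - reference[d$aa, "CA"],
    delta_ha = d$HA - reference[d$aa, "HA"],
    preceding_proline = !is.na(next_aa) & next_aa == "P",
    preproline_flag = FALSE,
    stringsAsFactors = FALSE
  )
  structure(prof, class = c("secondary_shift_profile", "data.frame"))
}

#' Flag pre-proline residues with strongly negative delta-CA
#'
#' A residue immediately preceding a proline whose delta-CA falls below
#' `threshold_ppm` is flagged: such shifts are dominated by the proline
#' sequence effect and must not be read as conformational. The summary
#' reports (a) how many residues fall below the threshold, (b) how many of
#' those precede a proline, and (c) how many pre-proline residues pass the
#' threshold.
#'
#' @param profile A `secondary_shift_profile`.
#' @param sequence Optional character vector of one-letter codes for
#'   positions `1..max(index)`; when supplied, the preceding-proline
#'   column is recomputed from it (useful when the shift table itself has
#'   assignment gaps at prolines).
#' @param threshold_ppm Flagging threshold on delta-CA in ppm (default
#'   -1.5).
#' @return The profile with `preproline_flag` set and a `preproline_summary`
#'   attribute (named integer vector `below_threshold`,
#'   `below_threshold_pre_proline`, `pre_proline_flagged`,
#'   `pre_proline_total`).
#' @export
flag_preproline <- function(profile, sequence = NULL, threshold_ppm = -1.5) {
  stopifnot(inherits(profile, "secondary_shift_profile"))
  if (!is.null(sequence)) {
    nxt <- profile$index + 1L
    profile$preceding_proline <- nxt >= 1L & nxt <= length(sequence) &
      sequence[pmax(nxt, 1L)] == "P"
  }
  below <- !is.na(profile$delta_ca) & profile$delta_ca < threshold_ppm
  profile$preproline_flag <- below & profile$preceding_proline
  pre_assigned <- profile$preceding_proline & !is.na(profile$delta_ca)
  attr(profile, "preproline_summary") <- c(
    below_threshold = sum(below),
    below_threshold_pre_proline = sum(below & profile$preceding_proline),
    pre_proline_flagged = sum(profile$preproline_flag),
    pre_proline_total = sum(pre_assigned)
  )
  profile
}

#' Detect helix-indicative secondary-shift plateaus
#'
#' Finds maximal runs of at least `min_length` residues whose delta-CA is
#' at or above `ca_min` and delta-HA at or below `ha_max` — the
#' simultaneous positive-CA / negative-HA plateau that marks helix-like
#' structure. At most one interior residue per run may fail either cutoff
#' (tolerating single-residue interruptions such as an internal proline),
#' and residues carrying a pre-proline flag are exempted from the delta-CA
#' cutoff, since the proline sequence effect drives their delta-CA
#' negative regardless of conformation. Missing deltas fail the cutoffs.
#'
#' @param profile A `secondary_shift_profile` (pre-proline flags applied).
#' @param min_length Minimum run length in residues.
#' @param ca_min Lower cutoff for delta-CA (ppm).
#' @param ha_max Upper cutoff for delta-HA (ppm).
#' @return data.frame of segments with columns `start`, `end` (full
#'   residue indices, inclusive) and `length`.
#' @export
detect_shift_plateaus <- function(profile, min_length = 4L, ca_min = 0.7,
                                  ha_max = -0.05) {
  stopifnot(inherits(profile, "secondary_shift_profile"))
  if (nrow(profile) == 0L) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  # work on a dense index grid so runs cannot jump assignment gaps
  idx <- seq(min(profile$index), max(profile$index))
  m <- match(idx, profile$index)
  ca_ok <- !is.na(m) &
    ((!is.na(profile$delta_ca[m]) & profile$delta_ca[m] >= ca_min) |
       profile$preproline_flag[m] %in% TRUE)
  ha_ok <- !is.na(m) & !is.na(profile$delta_ha[m]) & profile$delta_ha[m] <= ha_max
  pass <- ca_ok & ha_ok
  runs <- true_runs(pass)
  if (nrow(runs) == 0L) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  # merge pairs of runs separated by exactly one failing interior residue;
  # each merged segment tolerates at most one such residue (greedy, left
  # to right, deterministic)
  merged <- list()
  k <- 1L
  while (k <= nrow(runs)) {
    s <- runs$start[k]; e <- runs$end[k]
    if (k < nrow(runs) && runs$start[k + 1L] == e + 2L) {
      e <- runs$end[k + 1L]
      k <- k + 2L
    } else {
      k <- k + 1L
    }
    merged[[length(merged) + 1L]] <- c(s, e)
  }
  seg <- do.call(rbind, merged)
  out <- data.frame(start = idx[seg[, 1]], end = idx[seg[, 2]])
  out$length <- out$end - out$start + 1L
  out[out$length >= min_length, , drop = FALSE]
}

#' Composite chemical-shift deviation
#'
#' Scalar deviation combining amide-proton, alpha-carbon and amide-nitrogen
#' shift differences, each weighted by a nucleus-specific scale:
#' `xi = sqrt((d_hn^2 + d_ca^2/4 + d_n^2/25) / 3)`. It is zero iff all
#' three inputs are zero, symmetric under sign flips, and monotone in the
#' magnitude of each input.
#'
#' @param d_hn,d_ca,d_n Shift differences in ppm (vectorised).
#' @return Non-negative numeric vector.
#' @export
#' @examples
#' composite_deviation(1, 2, 5) # == 1
composite_deviation <- function(d_hn, d_ca, d_n) {
  n <- max(length(d_hn), length(d_ca), length(d_n))
  d_hn <- rep_len(as.numeric(d_hn), n)
  d_ca <- rep_len(as.numeric(d_ca), n)
  d_n <- rep_len(as.numeric(d_n), n)
  if (any(!is.finite(d_hn)) || any(!is.finite(d_ca)) || any(!is.finite(d_n))) {
    stopf("composite_deviation requires finite inputs")
  }
  sqrt((d_hn^2 + d_ca^2 / 4 + d_n^2 / 25) / 3)
}
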