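#' Match HSQC peaks between a fragment and the full-length protein
#'
#' Each assigned fragment peak is matched to the nearest full-length peak
#' inside a tolerance box of `tol_n15` ppm in the 15N dimension and
#' `tol_h1` ppm in 1H. The distance metric is the larger of the two
#' tolerance-normalised offsets (`max(|d15N|/tol_n15, |d1H|/tol_h1)`), and
#' one-to-one matching is enforced greedily in ascending distance — peak
#' lists of well-resolved amides are sparse enough that this equals the
#' optimal assignment in practice. Fragment peaks with no counterpart in
#' the box are `lost`; the intensity ratio (full / fragment) is carried
#' where both lists record heights.
#'
#' @param fragment A [peak_list] with assigned peaks (the monomeric
#'   reference spectrum).
#' @param full A [peak_list] (the assembled / full-length spectrum); may
#'   contain unassigned peaks.
#' @param tol_n15,tol_h1 Matching tolerances in ppm.
#' @return data.frame of class `peak_matches`: `index`, `aa`,
#'   `delta_n15`, `delta_h1`, `intensity_ratio`, `status`
#'   (`retained` / `lost`).
#' @export
match_peaks <- function(fragment, full, tol_n15 = 0.2, tol_h1 = 0.02) {
  stopifnot(inherits(fragment, "peak_list"), inherits(full, "peak_list"))
  fp <- fragment$peaks[!is.na(fragment$peaks$index), , drop = FALSE]
  if (anyDuplicated(fp$index)) stopf("duplicate assignment in fragment list")
  lp <- full$peaks
  nf <- nrow(fp); nl <- nrow(lp)
  # normalized distances, nf x nl
  if (nf && nl) {
    dn <- abs(outer(fp$n15, lp$n15, `-`)) / tol_n15
    dh <- abs(outer(fp$h1, lp$h1, `-`)) / tol_h1
    dist <- pmax(dn, dh)
  } else {
    dist <- matrix(numeric(), nf, nl)
  }
  match_of <- rep(NA_integer_, nf)
  if (nf && nl) {
    cand <- which(dist <= 1, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dist[cand])
      used_f <- rep(FALSE, nf); used_l <- rep(FALSE, nl)
      for (k in ord) {
        fi <- cand[k, 1]; li <- cand[k, 2]
        if (used_f[fi] || used_l[li]) next
        match_of[fi] <- li
        used_f[fi] <- TRUE; used_l[li] <- TRUE
      }
    }
  }
  ratio <- rep(NA_real_, nf)
  d15 <- rep(NA_real_, nf); d1 <- rep(NA_real_, nf)
  hit <- !is.na(match_of)
  d15[hit] <- lp$n15[match_of[hit]] - fp$n15[hit]
  d1[hit] <- lp$h1[match_of[hit]] - fp$h1[hit]
  both_h <- hit & !is.na(fp$height) & fp$height > 0 &
    !is.na(lp$height[ifelse(hit, match_of, 1L)])
  ratio[both_h] <- lp$height[match_of[both_h]] / fp$height[both_h]
  structure(
    data.frame(index = fp$index, aa = fp$aa,
               delta_n15 = d15, delta_h1 = d1,
               intensity_ratio = ratio,
               status = ifelse(hit, "retained", "lost"),
               stringsAsFactors = FALSE),
    class = c("peak_matches", "data.frame"),
    tolerances = c(n15 = tol_n15, h1 = tol_h1)
  )
}

#' Classify residues as monomeric-in-assembly or assembly-involved
#'
#' Residues whose fragment peak is lost in the assembled spectrum, or
#' retained with an intensity ratio below `reduced_ratio_max`
#' ("dramatically reduced"), are classified `assembly_involved`; retained
#' residues are `monomeric`. Where no intensity is available, retained
#' presence alone decides. Contiguous runs of each label are reported as
#' regions.
#'
#' @param matches Output of [match_peaks].
#' @param reduced_ratio_max Intensity-ratio cutoff below which a retained
#'   peak still counts as assembly-involved (default 0.3).
#' @return List of class `involvement_map`: `residues` (data.frame
#'   `index`, `involvement`) and `regions` (data.frame `start`, `end`,
#'   `involvement` over contiguous index runs).
#' @export
classify_involvement <- function(matches, reduced_ratio_max = 0.3) {
  stopifnot(inherits(matches, "peak_matches"))
  inv <- ifelse(
    matches$status == "lost" |
      (matches$status == "retained" & !is.na(matches$intensity_ratio) &
         matches$intensity_ratio < reduced_ratio_max),
    "assembly_involved", "monomeric"
  )
  o <- order(matches$index)
  res <- data.frame(index = matches$index[o], involvement = inv[o],
                    stringsAsFactors = FALSE)
  regions <- list()
  if (nrow(res)) {
    brk <- c(TRUE, res$involvement[-1] != res$involvement[-nrow(res)])
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      sel <- grp == g
      regions[[g]] <- data.frame(start = min(res$index[sel]),
                                 end = max(res$index[sel]),
                                 involvement = res$involvement[sel][1],
                                 stringsAsFactors = FALSE)
    }
  }
  structure(
    list(residues = res,
         regions = if (length(regions)) do.call(rbind, regions) else
           data.frame(start = integer(), end = integer(),
                      involvement = character())),
    class = "involvement_map"
  )
}

#' Test two spectra of the same construct for interaction
#'
#' Compares an HSQC recorded alone with one recorded in the presence of a
#' potential partner. Residues whose peak moves beyond tolerance or
#' vanishes are reported; an empty list means no interaction.
#'
#' @param spectrum_alone,spectrum_with_partner Assigned [peak_list]s of
#'   the same construct.
#' @param tol_n15,tol_h1 Matching tolerances in ppm.
#' @return List with `verdict` (`"no_interaction"` or `"interaction"`)
#'   and `interaction_at` (integer residue indices).
#' @export
interaction_test <- function(spectrum_alone, spectrum_with_partner,
                             tol_n15 = 0.2, tol_h1 = 0.02) {
  if (!identical(spectrum_alone$construct, spectrum_with_partner$construct)) {
    stopf("spectra are from different constructs (%s vs %s)",
          spectrum_alone$construct, spectrum_with_partner$construct)
  }
  m <- match_peaks(spectrum_alone, spectrum_with_partner,
                   tol_n15 = tol_n15, tol_h1 = tol_h1)
  moved <- m$index[m$status == "lost"]
  list(verdict = if (length(moved)) "interaction" else "no_interaction",
       interaction_at = sort(moved))
}
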