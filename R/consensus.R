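#' Stitch overlapping fragment shift tables into a full-length table
#'
#' Each fragment maps into full-length numbering through its `offset`.
#' Where fragments overlap, every residue/atom pair is compared: values
#' agreeing within the per-atom tolerance are averaged; disagreements are
#' flagged in the consistency report and resolved by keeping the value
#' from the fragment in which the residue lies farther from a construct
#' terminus (terminal residues are the most perturbed by tags and
#' truncation). Overlapping residues with different amino-acid identity
#' indicate misaligned offsets and are a hard error.
#'
#' @param fragments List of [shift_table] objects with offsets set.
#' @param tol_ppm Named numeric vector of per-atom tolerances in ppm.
#' @return List with `merged` (a full-length [shift_table], offset 0) and
#'   `report` (data.frame of all overlap comparisons: `index`, `atom`,
#'   `value_a`, `value_b`, `construct_a`, `construct_b`, `difference`,
#'   `consistent`, `resolved`).
#' @export
stitch_fragments <- function(fragments,
                             tol_ppm = c(CA = 0.2, CB = 0.2, N = 0.2,
                                         HA = 0.02, HN = 0.02)) {
  stopifnot(length(fragments) >= 1L,
            all(vapply(fragments, inherits, TRUE, "shift_table")))
  # per-fragment full-length frames, tag residues excluded
  frames <- lapply(fragments, function(f) {
    d <- construct_residues(f)$data
    d$full <- d$index + f$offset
    d$construct <- f$construct
    # distance of each residue from its nearer construct terminus
    d$interiority <- pmin(d$index - min(d$index), max(d$index) - d$index)
    d
  })
  all_full <- sort(unique(unlist(lapply(frames, `[[`, "full"))))
  aa_of <- rep(NA_character_, length(all_full))
  for (fr in frames) {
    m <- match(fr$full, all_full)
    clash <- !is.na(aa_of[m]) & aa_of[m] != fr$aa
    if (any(clash)) {
      stopf("amino-acid mismatch at full-length residue %d (%s vs %s): misaligned offsets?",
            fr$full[clash][1], aa_of[m][clash][1], fr$aa[clash][1])
    }
    aa_of[m] <- fr$aa
  }
  merged <- lapply(ATOM_KINDS, function(k) rep(NA_real_, length(all_full)))
  names(merged) <- ATOM_KINDS
  rep_rows <- list()
  for (k in ATOM_KINDS) {
    tol <- if (k %in% names(tol_ppm)) tol_ppm[[k]] else 0.2
    for (pos in seq_along(all_full)) {
      obs <- list()
      for (fr in frames) {
        row <- which(fr$full == all_full[pos])
        if (length(row) && !is.na(fr[[k]][row])) {
          obs[[length(obs) + 1L]] <- list(v = fr[[k]][row],
                                          construct = fr$construct[row],
                                          interiority = fr$interiority[row])
        }
      }
      if (!length(obs)) next
      if (length(obs) == 1L) {
        merged[[k]][pos] <- obs[[1]]$v
        next
      }
      vs <- vapply(obs, `[[`, 0, "v")
      spread <- max(vs) - min(vs)
      consistent <- spread <= tol
      merged[[k]][pos] <- if (consistent) {
        mean(vs)
      } else {
        vs[which.max(vapply(obs, `[[`, 0, "interiority"))]
      }
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        index = all_full[pos], atom = k,
        value_a = vs[1], value_b = vs[2],
        construct_a = obs[[1]]$construct, construct_b = obs[[2]]$construct,
        difference = spread, consistent = consistent,
        resolved = merged[[k]][pos], stringsAsFactors = FALSE
      )
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else {
    data.frame(index = integer(), atom = character(), value_a = numeric(),
               value_b = numeric(), construct_a = character(),
               construct_b = character(), difference = numeric(),
               consistent = logical(), resolved = numeric())
  }
  list(
    merged = shift_table(all_full, aa_of, merged, construct = "merged",
                         offset = 0L),
    report = report
  )
}

SS_STATES <- c("alpha", "three_ten", "ppii", "turn", "coil")

#' Call per-residue secondary structure from fused evidence
#'
#' Applies a transparent rule cascade over four evidence channels
#' (secondary shifts, scalar couplings, NOE connectivities, rigidity):
#'
#' 1. a residue inside a secondary-shift plateau that also has a
#'    helix-compatible J coupling or an (i,i+3) NOE is `alpha`;
#' 2. a short (2-3 residue) run with helix-like shifts but no (i,i+3)
#'    support, flanked by coil, is `three_ten` (a heuristic surrogate for
#'    3-10 helix, which strictly requires calculated structure);
#' 3. a residue in a proline-rich window (at least one P per 3 residues
#'    over >= 5 residues) with pre-proline flags nearby and no helix
#'    evidence is `ppii`;
#' 4. a 3-5 residue gap between two alpha segments with (i,i+2) NOE
#'    support is `turn`;
#' 5. everything else is `coil`.
#'
#' Confidence counts the evidence channels that independently agree with
#' the call (shift plateau, J class, NOE pattern, rigidity), 0-4.
#'
#' @param profile A `secondary_shift_profile` with pre-proline flags set.
#' @param evidence A [residue_evidence] table on the same residue indices.
#' @param sequence Character vector of one-letter codes for positions
#'   `1..L` (full-length numbering).
#' @param plateau_args Optional list of overrides for
#'   [detect_shift_plateaus].
#' @return Object of class `ss_annotation`: list with `residues`
#'   (data.frame `index`, `aa`, `state`, `confidence`) and `segments`
#'   (data.frame `start`, `end`, `state`).
#' @export
call_secondary_structure <- function(profile, evidence, sequence,
                                     plateau_args = list()) {
  stopifnot(inherits(profile, "secondary_shift_profile"))
  idx <- sort(unique(c(profile$index, evidence$index)))
  if (length(idx) && (min(idx) < 1L || max(idx) > length(sequence))) {
    stopf("evidence indices extend outside the sequence (1..%d)", length(sequence))
  }
  n <- length(idx)
  pm <- match(idx, profile$index)
  em <- match(idx, evidence$index)
  delta_ca <- profile$delta_ca[pm]
  preflag <- profile$preproline_flag[pm] %in% TRUE
  j_class <- ifelse(is.na(em), "unclassified", evidence$j_class[em])
  rigidity <- ifelse(is.na(em), "unclassified", evidence$rigidity[em])
  noe_i2 <- ifelse(is.na(em), 0L, evidence$noe_i2[em])
  noe_i3 <- ifelse(is.na(em), 0L, evidence$noe_i3[em])

  plateaus <- do.call(detect_shift_plateaus, c(list(profile), plateau_args))
  in_plateau <- rep(FALSE, n)
  for (k in seq_len(nrow(plateaus))) {
    in_plateau[idx >= plateaus$start[k] & idx <= plateaus$end[k]] <- TRUE
  }
  # an (i,i+3) contact starting at i supports residues i..i+3
  i3_support <- rep(FALSE, n)
  for (r in idx[noe_i3 > 0]) i3_support[idx >= r & idx <= r + 3L] <- TRUE
  i2_support <- rep(FALSE, n)
  for (r in idx[noe_i2 > 0]) i2_support[idx >= r & idx <= r + 2L] <- TRUE

  state <- rep("coil", n)

  # rule 1: plateau + coupling or medium-range NOE support; never alpha on
  # a missing delta-CA unless NOE contacts vouch for the residue
  state[in_plateau & (j_class == "helix_compatible" | i3_support) &
          (!is.na(delta_ca) | i3_support)] <- "alpha"

  # rule 2: 2-3 residue helix-like runs without (i,i+3) support
  helix_like <- !is.na(delta_ca) & delta_ca >= 0.7 & !i3_support &
    state != "alpha"
  runs <- true_runs(helix_like)
  for (k in seq_len(nrow(runs))) {
    len <- runs$end[k] - runs$start[k] + 1L
    contiguous <- idx[runs$end[k]] - idx[runs$start[k]] + 1L == len
    if (len >= 2L && len <= 3L && contiguous) {
      lo <- runs$start[k] - 1L; hi <- runs$end[k] + 1L
      flank_ok <- (lo < 1L || state[lo] == "coil") &&
        (hi > n || state[hi] == "coil")
      if (flank_ok) state[runs$start[k]:runs$end[k]] <- "three_ten"
    }
  }

  # rule 3: proline-rich windows with pre-proline flags, no helix evidence
  is_p <- sequence == "P"
  prich <- rep(FALSE, length(sequence))
  w <- 5L # proline-rich: >= 1 P per 3 residues over a 5-residue window
  if (length(sequence) >= w) {
    cnt <- stats::filter(as.numeric(is_p), rep(1, w), sides = 1)
    hit <- which(!is.na(cnt) & cnt >= 2)
    for (h in hit) prich[(h - w + 1L):h] <- TRUE
  }
  near_flag <- rep(FALSE, n)
  for (r in idx[preflag]) near_flag[abs(idx - r) <= 3L] <- TRUE
  # "no helix evidence" means no shift plateau and no medium-range NOEs;
  # small J couplings alone are not counted against PPII, which shows
  # poorly dispersed couplings
  state[state == "coil" & prich[idx] & near_flag & !in_plateau &
          !i3_support] <- "ppii"

  # rule 4: short gaps between alpha segments with (i,i+2) support
  aruns <- true_runs(state == "alpha")
  if (nrow(aruns) >= 2L) {
    for (k in seq_len(nrow(aruns) - 1L)) {
      gap <- (aruns$end[k] + 1L):(aruns$start[k + 1L] - 1L)
      glen <- idx[aruns$start[k + 1L]] - idx[aruns$end[k]] - 1L
      if (glen >= 3L && glen <= 5L && any(i2_support[gap]) &&
          all(state[gap] %in% c("coil", "three_ten"))) {
        state[gap] <- "turn"
      }
    }
  }

  confidence <- (in_plateau & state %in% c("alpha", "three_ten")) +
    (j_class == "helix_compatible" & state %in% c("alpha", "three_ten", "turn")) +
    ((i3_support & state == "alpha") | (i2_support & state == "turn") |
       (near_flag & state == "ppii")) +
    (rigidity == "rigid" & state %in% c("alpha", "three_ten", "turn"))
  confidence[state == "coil"] <- 0L

  segments <- annotation_segments(idx, state)
  structure(
    list(residues = data.frame(index = idx, aa = sequence[idx], state = state,
                               confidence = as.integer(confidence),
                               stringsAsFactors = FALSE),
         segments = segments),
    class = "ss_annotation"
  )
}

annotation_segments <- function(idx, state) {
  out <- list()
  for (st in setdiff(SS_STATES, "coil")) {
    runs <- true_runs(state == st)
    for (k in seq_len(nrow(runs))) {
      out[[length(out) + 1L]] <- data.frame(
        start = idx[runs$start[k]], end = idx[runs$end[k]], state = st,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), state = character()))
  }
  seg <- do.call(rbind, out)
  seg[order(seg$start), , drop = FALSE]
}

#' @export
print.ss_annotation <- function(x, ...) {
  tab <- table(factor(x$residues$state, levels = SS_STATES))
  cat(sprintf("ss_annotation: %d residues (%s); %d segment(s)\n",
              nrow(x$residues),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$segments)))
  invisible(x)
}

#' Summarise an annotation over functional domains
#'
#' @param annotation An `ss_annotation`.
#' @param domains data.frame with `domain`, `start`, `end` (defaults to
#'   [amelogenin_domains]); domains must not overlap.
#' @return data.frame with one row per domain: residue count, percentage
#'   of each state, and the majority state.
#' @export
summarize_domains <- function(annotation, domains = amelogenin_domains()) {
  stopifnot(inherits(annotation, "ss_annotation"))
  if (any(domains$start > domains$end)) stopf("domain start > end")
  o <- order(domains$start)
  d <- domains[o, ]
  if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)])) {
    stopf("domain definitions overlap")
  }
  res <- annotation$residues
  rows <- lapply(seq_len(nrow(d)), function(k) {
    sel <- res$index >= d$start[k] & res$index <= d$end[k]
    states <- factor(res$state[sel], levels = SS_STATES)
    n <- sum(sel)
    pct <- if (n) 100 * as.vector(table(states)) / n else rep(NA_real_, length(SS_STATES))
    data.frame(domain = d$domain[k], start = d$start[k], end = d$end[k],
               n_residues = n,
               stats::setNames(as.list(pct), paste0("pct_", SS_STATES)),
               majority = if (n) SS_STATES[which.max(table(states))] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
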