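#' Write a per-residue annotation report
#'
#' Joins the secondary-shift profile, the evidence table and the state
#' calls into one per-residue TSV.
#'
#' @param annotation An `ss_annotation`.
#' @param path Output path.
#' @param profile Optional `secondary_shift_profile` to merge in.
#' @param evidence Optional `residue_evidence` to merge in.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path, profile = NULL,
                                 evidence = NULL) {
  stopifnot(inherits(annotation, "ss_annotation"))
  out <- annotation$residues
  if (!is.null(profile)) {
    m <- match(out$index, profile$index)
    out$delta_ca <- profile$delta_ca[m]
    out$delta_ha <- profile$delta_ha[m]
    out$preproline_flag <- profile$preproline_flag[m]
  }
  if (!is.null(evidence)) {
    m <- match(out$index, evidence$index)
    out$j_class <- evidence$j_class[m]
    out$rigidity <- evidence$rigidity[m]
    out$noe_i3 <- evidence$noe_i3[m]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a JSON run summary
#'
#' @param x Named list of scalar results and small tables.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
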