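#' Construct an HSQC peak list
#'
#' One row per cross-peak of a 2D 1H-15N HSQC: assignment (residue index +
#' one-letter code, or unassigned), 15N and 1H chemical shifts in ppm, and
#' an optional intensity. At most one assigned peak per residue is allowed
#' (one backbone amide per residue).
#'
#' @param index Integer residue indices; `NA` for unassigned peaks.
#' @param aa One-letter codes (`NA` for unassigned).
#' @param n15,h1 Chemical shifts in ppm.
#' @param height Peak intensities (>= 0); `NA` if not recorded.
#' @param construct Construct name.
#' @return Object of class `peak_list` with elements `construct` and
#'   `peaks` (data.frame `index`, `aa`, `n15`, `h1`, `height`).
#' @export
peak_list <- function(index, aa, n15, h1, height = NA_real_,
                      construct = "construct") {
  n <- length(n15)
  index <- as.integer(rep_len(index, n))
  aa <- as.character(rep_len(aa, n))
  height <- as.numeric(rep_len(height, n))
  n15 <- as.numeric(n15); h1 <- as.numeric(h1)
  if (length(h1) != n) stopf("n15 and h1 lengths differ")
  if (any(!is.finite(n15)) || any(!is.finite(h1))) stopf("ppm values must be finite")
  if (any(!is.na(height) & height < 0)) stopf("peak heights must be >= 0")
  assigned <- !is.na(index)
  if (anyDuplicated(index[assigned])) {
    stopf("duplicate assigned peak for residue %s",
          index[assigned][duplicated(index[assigned])][1])
  }
  if (any(assigned & !is_aa1(aa))) stopf("assigned peaks need a valid one-letter code")
  structure(
    list(construct = as.character(construct),
         peaks = data.frame(index = index, aa = aa, n15 = n15, h1 = h1,
                            height = height, stringsAsFactors = FALSE)),
    class = "peak_list"
  )
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("peak_list '%s': %d peaks (%d assigned)\n", x$construct,
              nrow(x$peaks), sum(!is.na(x$peaks$index))))
  invisible(x)
}

# "T63N-H" -> list(aa = "T", index = 63); "?" or "?-?" -> unassigned
parse_sparky_label <- function(label) {
  if (grepl("^\\?+(-\\?+)?$", label)) return(list(aa = NA_character_, index = NA_integer_))
  m <- regmatches(label, regexec("^([A-Za-z])(-?[0-9]+)N?-?H?N?$", label))[[1]]
  if (length(m) == 3L && is_aa1(toupper(m[2]))) {
    return(list(aa = toupper(m[2]), index = as.integer(m[3])))
  }
  NULL
}

#' Read a Sparky-style HSQC peak list
#'
#' Whitespace-delimited text, one peak per line: an assignment label (such
#' as `T63N-H`, or `?` / `?-?` for unassigned), the 15N shift, the 1H
#' shift, and an optional height. A header line starting with `Assignment`
#' is skipped.
#'
#' @param path File path.
#' @param construct Construct name stored on the result.
#' @return A [peak_list].
#' @export
read_peak_list <- function(path, construct = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(construct)) construct <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#") &
    !grepl("^\\s*Assignment", lines)
  idx <- integer(); aa <- character(); n15 <- numeric(); h1 <- numeric()
  ht <- numeric()
  for (ln in which(keep)) {
    f <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(f) < 3L) stopf("%s line %d: expected assignment + 2 ppm columns", path, ln)
    lab <- parse_sparky_label(f[1])
    if (is.null(lab)) stopf("%s line %d: unparseable assignment '%s'", path, ln, f[1])
    v <- suppressWarnings(as.numeric(f[2:3]))
    if (anyNA(v)) stopf("%s line %d: non-numeric ppm column", path, ln)
    h <- if (length(f) >= 4L) suppressWarnings(as.numeric(f[4])) else NA_real_
    idx <- c(idx, lab$index); aa <- c(aa, lab$aa)
    n15 <- c(n15, v[1]); h1 <- c(h1, v[2]); ht <- c(ht, h)
  }
  peak_list(idx, aa, n15, h1, ht, construct = construct)
}

#' Write a peak list in Sparky-style text
#'
#' @param x A [peak_list].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(x, path) {
  stopifnot(inherits(x, "peak_list"))
  p <- x$peaks
  lab <- ifelse(is.na(p$index), "?-?", paste0(p$aa, p$index, "N-H"))
  ht <- ifelse(is.na(p$height), "", formatC(p$height, format = "g", digits = 15))
  out <- paste(lab,
               formatC(p$n15, format = "g", digits = 15),
               formatC(p$h1, format = "g", digits = 15),
               ht)
  writeLines(c("Assignment w1 w2 Height", trimws(out)), path)
  invisible(path)
}
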