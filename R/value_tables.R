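#' Read a per-residue value table
#'
#' TSV with header `residue_index` and one value column (e.g. `j_hna` in
#' Hz or `hnoe`, dimensionless). Empty cells are missing values.
#'
#' @param path File path.
#' @param value_col Name of the value column; defaults to the first
#'   non-index column.
#' @return data.frame with columns `index` and `value`.
#' @export
read_value_table <- function(path, value_col = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.delim(path, check.names = FALSE)
  if (!"residue_index" %in% names(d)) stopf("%s: missing residue_index column", path)
  if (is.null(value_col)) value_col <- setdiff(names(d), "residue_index")[1]
  if (is.na(value_col) || !value_col %in% names(d)) {
    stopf("%s: no value column found", path)
  }
  v <- d[[value_col]]
  if (is.character(v)) {
    v <- suppressWarnings(as.numeric(ifelse(nzchar(trimws(v)), v, NA)))
    if (any(is.na(v) & nzchar(trimws(d[[value_col]])))) {
      stopf("%s: non-numeric value in column %s", path, value_col)
    }
  }
  data.frame(index = as.integer(d$residue_index), value = as.numeric(v))
}

#' Write a per-residue value table
#' @param x data.frame with `index` and `value`.
#' @param path Output path.
#' @param value_col Column name used in the header.
#' @return `path`, invisibly.
#' @export
write_value_table <- function(x, path, value_col = "value") {
  out <- data.frame(residue_index = x$index, v = x$value)
  names(out)[2] <- value_col
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Construct a set of inter-residue NOE records
#'
#' @param i,j Residue indices of the contact partners (`i != j`).
#' @param class NOE class: `dNN`, `daN` or `dbN`.
#' @param bin Intensity bin: `strong`, `medium` or `weak`.
#' @return data.frame of class `noe_records`.
#' @export
noe_records <- function(i, j, class, bin) {
  i <- as.integer(i); j <- as.integer(j)
  class <- as.character(class); bin <- as.character(bin)
  n <- length(i)
  if (!all(lengths(list(j, class, bin)) == n)) stopf("NOE record columns differ in length")
  if (!all(class %in% c("dNN", "daN", "dbN"))) stopf("NOE class must be dNN, daN or dbN")
  if (!all(bin %in% c("strong", "medium", "weak"))) stopf("NOE bin must be strong, medium or weak")
  structure(data.frame(i = i, j = j, class = class, bin = bin,
                       stringsAsFactors = FALSE),
            class = c("noe_records", "data.frame"))
}

#' Read NOE records from TSV
#'
#' Columns `i`, `j`, `class` (`dNN`/`daN`/`dbN`) and `bin`
#' (`strong`/`medium`/`weak`).
#'
#' @param path File path.
#' @return A [noe_records] data.frame.
#' @export
read_noe_records <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.delim(path)
  need <- c("i", "j", "class", "bin")
  if (!all(need %in% names(d))) {
    stopf("%s: missing column(s) %s", path, paste(setdiff(need, names(d)), collapse = ", "))
  }
  noe_records(d$i, d$j, d$class, d$bin)
}

#' Write NOE records to TSV
#' @param x A [noe_records] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_noe_records <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an AUC c(s) peak summary
#'
#' TSV with columns `mass_kda` (> 0) and `fraction` (in \[0, 1\], summing
#' to <= 1 over the file).
#'
#' @param path File path.
#' @return data.frame with `mass_kda` and `fraction`.
#' @export
read_auc_peaks <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.delim(path)
  if (!all(c("mass_kda", "fraction") %in% names(d))) {
    stopf("%s: need columns mass_kda and fraction", path)
  }
  validate_auc_peaks(d[c("mass_kda", "fraction")])
}

validate_auc_peaks <- function(d) {
  if (any(!is.finite(d$mass_kda)) || any(d$mass_kda <= 0)) stopf("mass_kda must be > 0")
  if (any(!is.finite(d$fraction)) || any(d$fraction < 0 | d$fraction > 1)) {
    stopf("fractions must lie in [0, 1]")
  }
  if (sum(d$fraction) > 1 + 1e-8) stopf("fractions sum to more than 1")
  d
}
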