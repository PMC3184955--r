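#' Amelogenin construct offsets and domain layout
#'
#' The three overlapping expression constructs map into full-length (M180)
#' numbering through fixed offsets: Amel-N covers residues 1-92 (offset 0),
#' Amel-M covers 34-154 (offset 33), Amel-C covers 86-180 (offset 85).
#' Full-length position = construct position + offset.
#'
#' @return Named integer vector of offsets.
#' @export
#' @examples
#' construct_offsets()
construct_offsets <- function() {
  c(`Amel-N` = 0L, `Amel-M` = 33L, `Amel-C` = 85L, M180 = 0L)
}

#' Default amelogenin domain boundaries
#'
#' Four functional domains of the 180-residue mouse amelogenin: the
#' tyrosine-rich TRAP domain (1-45), the histidine-rich coil domain
#' (46-125), the proline-rich PXX tripeptide-repeat domain (126-164) and
#' the charged hydrophilic C-terminus (165-180).
#'
#' @return data.frame with columns `domain`, `start`, `end`.
#' @export
amelogenin_domains <- function() {
  data.frame(
    domain = c("TRAP", "coil", "PXX", "C-term"),
    start = c(1L, 46L, 126L, 165L),
    end = c(45L, 125L, 164L, 180L),
    stringsAsFactors = FALSE
  )
}

#' His-tag leader sequence used by the expression constructs
#'
#' Tag residues are stored at indices <= 0 (the tag's C-terminal residue at
#' index 0) and excluded from analyses by default.
#'
#' @return Single string, one-letter codes.
#' @export
his_tag_sequence <- function() "MRGSHHHHHHGAGDRGPE"

#' Synthetic amelogenin-like 180-mer test sequence
#'
#' A synthetic sequence with the domain architecture of mouse amelogenin:
#' a tyrosine/tryptophan-bearing helix-prone N-terminus, a His/Gln-rich
#' central region, a PXQ/PXX tripeptide repeat region spanning the PXX
#' domain, and a charged hydrophilic tail. It is used by the generators and
#' tests; it is not the real amelogenin sequence.
#'
#' @return Character vector of 180 one-letter codes.
#' @export
#' @examples
#' seq <- amelogenin_like_sequence()
#' length(seq)
amelogenin_like_sequence <- function() {
  trap <- "MPLPPHPGSPGYINLSYEVLTPLKWYQSMIRQPYPSYGYEPMGGW" # 1-45
  coil <- paste0(
    "LHHQIIPVVSQQHPPSHTLQPHHHIPVVPAQQPVAPQQPMMPVPGHHSMTPTQHHQPNLP"
  ) # 46-105 (60)
  coil2 <- "QPAQQPFQPQPVQPQPHQPL" # 106-125 (20)
  s <- strsplit(paste0(trap, coil, coil2), "")[[1]]
  stopifnot(length(s) == 125L)
  # PXX domain 126-164: thirteen P-X-Q style triplets (X cycling)
  xs <- c("L", "M", "F", "S", "A", "V", "H", "L", "M", "F", "S", "A", "V")
  pxx <- unlist(lapply(xs, function(x) c("P", x, "Q")))
  stopifnot(length(pxx) == 39L)
  tail16 <- strsplit("KREEVDSDKTKREEVD", "")[[1]] # 165-180
  out <- c(s, pxx, tail16)
  stopifnot(length(out) == 180L)
  out
}
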