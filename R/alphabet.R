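#' The 21-symbol window alphabet
#'
#' The twenty standard amino acids ordered alphabetically by their three-letter
#' code (Ala, Arg, Asn, Asp, Cys, Gln, Glu, Gly, His, Ile, Leu, Lys, Met, Phe,
#' Pro, Ser, Thr, Trp, Tyr, Val) followed by the end-of-sequence symbol `"-"`,
#' which pads windows that overhang a sequence terminal. Each window symbol is
#' one-hot encoded over this alphabet, so every symbol occupies a block of 21
#' binary features. The ordering is a fixed convention: any permutation gives
#' an equivalent feature space, but a declared order makes encodings
#' reproducible and decodable.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' og_alphabet()
og_alphabet <- function() {
  c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
    "-"
  )
}

#' @rdname og_alphabet
#' @export
og_eos <- function() "-"

# amino-acid letters only (no end-of-sequence symbol)
og_aa <- function() og_alphabet()[1:20]

# letters accepted only under permissive reading; all map to X
og_nonstandard <- function() c("B", "Z", "X", "U", "O", "J", "*")
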