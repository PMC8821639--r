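#' The residue alphabet shared by all encoders
#'
#' Every encoder in the package works over a fixed, ordered 28-symbol
#' alphabet: the 20 canonical amino acids, the six extended IUPAC ambiguity
#' or rare-residue codes (B, J, O, U, X, Z), the translation-stop artifact
#' `*`, and one designated padding symbol. The padding symbol gets its own
#' indicator channel, which is what makes the one-hot feature space
#' 28-dimensional.
#'
#' @param symbols Character vector of distinct single characters. The 20
#'   canonical residues must all be present and `pad_symbol` must be a
#'   member.
#' @param pad_symbol The padding character; must not be a residue code.
#'
#' @return An object of class `residue_alphabet`: a character vector of
#'   symbols with attributes `pad_symbol` and a named `index` lookup.
#' @examples
#' ab <- residue_alphabet()
#' length(ab)            # 28
#' alphabet_index(ab, "A")
#' @export
residue_alphabet <- function(symbols = c(CANONICAL_RESIDUES,
                                         c("B", "J", "O", "U", "X", "Z"),
                                         "*", "-"),
                             pad_symbol = "-") {
  symbols <- as.character(symbols)
  if (any(nchar(symbols) != 1L)) {
    stop("alphabet symbols must be single characters", call. = FALSE)
  }
  if (anyDuplicated(symbols)) {
    stop("alphabet symbols must be distinct", call. = FALSE)
  }
  if (!all(CANONICAL_RESIDUES %in% symbols)) {
    stop("all 20 canonical amino acids must be in the alphabet", call. = FALSE)
  }
  if (!pad_symbol %in% symbols) {
    stop("pad_symbol must be a member of the alphabet", call. = FALSE)
  }
  if (pad_symbol %in% CANONICAL_RESIDUES) {
    stop("pad_symbol must be distinct from residue characters", call. = FALSE)
  }
  idx <- stats::setNames(seq_along(symbols), symbols)
  structure(symbols, pad_symbol = pad_symbol, index = idx,
            class = "residue_alphabet")
}

#' @rdname residue_alphabet
#' @format NULL
#' @export
CANONICAL_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname residue_alphabet
#' @param alphabet A `residue_alphabet`.
#' @param symbol Character vector of symbols to look up.
#' @export
alphabet_index <- function(alphabet, symbol) {
  idx <- attr(alphabet, "index")[symbol]
  if (anyNA(idx)) {
    stop("symbol(s) not in alphabet: ",
         paste(symbol[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  unname(idx)
}

#' @rdname residue_alphabet
#' @export
pad_symbol <- function(alphabet = residue_alphabet()) {
  attr(alphabet, "pad_symbol")
}

#' @export
print.residue_alphabet <- function(x, ...) {
  cat("<residue_alphabet> ", length(x), " symbols: ",
      paste(unclass(x), collapse = ""), "\n",
      "pad symbol: '", pad_symbol(x), "'\n", sep = "")
  invisible(x)
}

# residue symbols allowed inside sequences (everything but the pad)
sequence_symbols <- function(alphabet = residue_alphabet()) {
  setdiff(unclass(alphabet), pad_symbol(alphabet))
}
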