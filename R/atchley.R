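#' The Atchley five-factor physicochemical table
#'
#' Atchley and colleagues reduced 54 amino-acid attributes to five factor
#' scores per residue: (1) accessibility/polarity/hydrophobicity,
#' (2) secondary-structure propensity, (3) molecular size, (4) codon
#' composition and (5) electrostatic charge. Residues with similar scores
#' along a factor are similar in that property. The table ships with the
#' package as a TSV file and is the single source of truth for the Atchley
#' encoder; values are never hard-coded elsewhere.
#'
#' Non-canonical residues are resolved from the canonical 20 by standard
#' ambiguity semantics: B = mean(D, N), Z = mean(E, Q), J = mean(I, L),
#' X = mean of all 20, U (selenocysteine) = C, O (pyrrolysine) = K, and the
#' stop artifact `*` = all zeros.
#'
#' @param path Path to the factor TSV (residue, f1..f5). Defaults to the
#'   shipped file.
#' @return A 20 x 5 numeric matrix with canonical residues as rownames and
#'   columns `f1`..`f5`.
#' @examples
#' tab <- atchley_table()
#' tab["A", ]
#' @export
atchley_table <- function(path = system.file("extdata", "atchley_factors.tsv",
                                             package = "poreformer")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(raw), c("residue", "f1", "f2", "f3", "f4", "f5")))
  m <- as.matrix(raw[, -1L])
  rownames(m) <- raw$residue
  if (!setequal(rownames(m), CANONICAL_RESIDUES) || nrow(m) != 20L) {
    stop("Atchley table must have exactly the 20 canonical residues",
         call. = FALSE)
  }
  if (!all(is.finite(m))) stop("non-finite Atchley factor value", call. = FALSE)
  m[CANONICAL_RESIDUES, , drop = FALSE]
}

# Per-symbol 5-factor rows for the full 27 non-pad alphabet, derived from
# the canonical table by the ambiguity policy above. Pad rows are all-zero
# and handled by the encoder, not here.
atchley_rows <- function(alphabet = residue_alphabet(),
                         table = atchley_table()) {
  syms <- sequence_symbols(alphabet)
  rows <- matrix(0, nrow = length(syms), ncol = 5L,
                 dimnames = list(syms, colnames(table)))
  canon <- intersect(syms, rownames(table))
  rows[canon, ] <- table[canon, ]
  amb <- list(B = c("D", "N"), Z = c("E", "Q"), J = c("I", "L"),
              X = CANONICAL_RESIDUES, U = "C", O = "K")
  for (s in names(amb)) {
    if (s %in% syms) rows[s, ] <- colMeans(table[amb[[s]], , drop = FALSE])
  }
  if ("*" %in% syms) rows["*", ] <- 0
  rows
}
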