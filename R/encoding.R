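#' Encode protein sequences as fixed-length numeric tensors
#'
#' Three per-residue encoding schemes turn a variable-length sequence into
#' a fixed `pad_length x channels` matrix:
#'
#' * `one_hot` — 28 channels, one indicator per alphabet symbol. Each real
#'   position carries a single 1 in its residue's channel; padded positions
#'   carry a 1 in the dedicated pad channel (the 28th dimension of the
#'   feature space).
#' * `atchley` — 5 channels, the Atchley physicochemical factor scores of
#'   the residue (see [atchley_table()]); padded positions are all-zero.
#' * `combined` — 33 channels, the columnwise concatenation of the two.
#'
#' @param sequence A single residue string (no pad characters).
#' @param pad_length Common output length `L`; must be at least the
#'   sequence length. All sequences are zero-padded to `L` so a batch forms
#'   a rectangular array.
#' @param alphabet The [residue_alphabet()] fixing channel order.
#' @param table Atchley factor matrix, from [atchley_table()].
#' @return A `pad_length x channels` numeric matrix with attribute
#'   `true_length`.
#' @examples
#' m <- encode_one_hot("ACD", pad_length = 5)
#' dim(m)          # 5 x 28
#' rowSums(m)      # all 1: real rows mark the residue, pad rows the pad
#' @name encoding
NULL

#' @rdname encoding
#' @export
encode_one_hot <- function(sequence, pad_length,
                           alphabet = residue_alphabet()) {
  chars <- check_encodable(sequence, pad_length, alphabet)
  n <- length(chars)
  C <- length(alphabet)
  m <- matrix(0, nrow = pad_length, ncol = C,
              dimnames = list(NULL, unclass(alphabet)))
  if (n > 0L) m[cbind(seq_len(n), alphabet_index(alphabet, chars))] <- 1
  if (n < pad_length) {
    m[(n + 1L):pad_length, alphabet_index(alphabet, pad_symbol(alphabet))] <- 1
  }
  structure(m, true_length = n)
}

#' @rdname encoding
#' @export
encode_atchley <- function(sequence, pad_length,
                           alphabet = residue_alphabet(),
                           table = atchley_table()) {
  chars <- check_encodable(sequence, pad_length, alphabet)
  rows <- atchley_rows(alphabet, table)
  m <- matrix(0, nrow = pad_length, ncol = 5L,
              dimnames = list(NULL, colnames(rows)))
  if (length(chars) > 0L) m[seq_along(chars), ] <- rows[chars, ]
  structure(m, true_length = length(chars))
}

#' @rdname encoding
#' @export
encode_combined <- function(sequence, pad_length,
                            alphabet = residue_alphabet(),
                            table = atchley_table()) {
  oh <- encode_one_hot(sequence, pad_length, alphabet)
  at <- encode_atchley(sequence, pad_length, alphabet, table)
  structure(cbind(oh, at), true_length = attr(oh, "true_length"))
}

check_encodable <- function(sequence, pad_length, alphabet) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  n <- nchar(sequence)
  if (n > pad_length) {
    stop("sequence length ", n, " exceeds pad_length ", pad_length,
         call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (pad_symbol(alphabet) %in% chars) {
    stop("sequence contains the pad symbol '", pad_symbol(alphabet), "'",
         call. = FALSE)
  }
  chars
}

#' Number of channels a scheme produces
#' @param scheme `"one_hot"`, `"atchley"` or `"combined"`.
#' @param alphabet The alphabet in force (sets the one-hot width).
#' @return Integer channel count (28, 5 or 33 for the default alphabet).
#' @export
scheme_channels <- function(scheme, alphabet = residue_alphabet()) {
  scheme <- match.arg(scheme, c("one_hot", "atchley", "combined"))
  switch(scheme,
         one_hot = length(alphabet),
         atchley = 5L,
         combined = length(alphabet) + 5L)
}

#' Encode a whole sequence table as a tensor batch
#'
#' Maps the chosen single-sequence encoder over every row of a sequence
#' tibble, preserving order, and stacks the results into one numeric array
#' together with an aligned 0/1 label vector (`positive` = 1, `negative` =
#' 0, `unknown` = `NA`).
#'
#' @param data A `pf_sequences` tibble (see [sequence_tbl()]).
#' @param scheme Encoding scheme, see [encoding].
#' @param pad_length Common padded length; defaults to the longest sequence
#'   in `data`.
#' @inheritParams encoding
#' @return A `pf_tensors` object: list with `x` (array `L x C x N`), `ids`,
#'   `labels`, `family`, `true_length`, `scheme`, `pad_length`.
#' @examples
#' d <- sequence_tbl(c("a", "b"), c("MKV", "GG"), label = "positive")
#' tn <- encode_sequences(d, "combined", pad_length = 10)
#' dim(tn$x)    # 10 x 33 x 2
#' @export
encode_sequences <- function(data, scheme = c("combined", "one_hot", "atchley"),
                             pad_length = NULL,
                             alphabet = residue_alphabet(),
                             table = atchley_table()) {
  scheme <- match.arg(scheme)
  data <- validate_sequences(data)
  C <- scheme_channels(scheme, alphabet)
  n <- nrow(data)
  if (is.null(pad_length)) pad_length <- if (n) max(nchar(data$sequence)) else 0L
  enc <- switch(scheme,
                one_hot = function(s) encode_one_hot(s, pad_length, alphabet),
                atchley = function(s) encode_atchley(s, pad_length, alphabet, table),
                combined = function(s) encode_combined(s, pad_length, alphabet, table))
  x <- array(0, dim = c(pad_length, C, n))
  for (i in seq_len(n)) {
    x[, , i] <- tryCatch(enc(data$sequence[i]), error = function(e) {
      stop("record '", data$id[i], "': ", conditionMessage(e), call. = FALSE)
    })
  }
  labels <- c(positive = 1, negative = 0, unknown = NA_real_)[data$label]
  structure(
    list(x = x, ids = data$id, labels = unname(labels), family = data$family,
         true_length = nchar(data$sequence), scheme = scheme,
         pad_length = as.integer(pad_length), channels = C),
    class = "pf_tensors"
  )
}

#' @export
print.pf_tensors <- function(x, ...) {
  cat("<pf_tensors> ", dim(x$x)[3L], " sequences, scheme '", x$scheme,
      "', ", x$pad_length, " positions x ", x$channels, " channels\n", sep = "")
  invisible(x)
}

#' Subset a tensor batch by sequence index
#' @param x A `pf_tensors` object.
#' @param i Integer or logical index over sequences.
#' @param ... Unused.
#' @export
`[.pf_tensors` <- function(x, i, ...) {
  i <- seq_len(dim(x$x)[3L])[i]
  structure(
    list(x = x$x[, , i, drop = FALSE], ids = x$ids[i], labels = x$labels[i],
         family = x$family[i], true_length = x$true_length[i],
         scheme = x$scheme, pad_length = x$pad_length, channels = x$channels),
    class = "pf_tensors"
  )
}
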