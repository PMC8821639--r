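#' Build a sequence table
#'
#' All pipeline stages exchange protein sequences as a tibble with one row
#' per record and columns `id`, `description`, `sequence`, `label`
#' (`"positive"`, `"negative"` or `"unknown"`) and `family` (an optional
#' tag such as `"alpha"` or `"beta"`; `NA` when untagged).
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of uppercase residue strings.
#' @param label Record label, recycled; one of `"positive"`, `"negative"`,
#'   `"unknown"`.
#' @param family Optional family tag, recycled.
#' @param description Full FASTA header text, recycled; defaults to `id`.
#' @return A tibble of class `pf_sequences`.
#' @examples
#' sequence_tbl(c("a", "b"), c("MKV", "GGA"), label = "positive",
#'              family = "alpha")
#' @export
sequence_tbl <- function(id, sequence, label = "unknown", family = NA_character_,
                         description = id) {
  out <- tibble::tibble(
    id = as.character(id),
    description = as.character(description),
    sequence = as.character(sequence),
    label = vctrs_recycle(as.character(label), length(id)),
    family = vctrs_recycle(as.character(family), length(id))
  )
  validate_sequences(out)
}

vctrs_recycle <- function(x, n) {
  if (length(x) == 1L) rep(x, n) else {
    stopifnot(length(x) == n)
    x
  }
}

#' Validate a sequence table
#'
#' Checks the invariants every downstream stage relies on: unique ids,
#' nonempty sequences, no whitespace or pad characters, and all characters
#' drawn from the 27 non-pad alphabet symbols.
#'
#' @param data A sequence tibble (see [sequence_tbl()]).
#' @param alphabet The [residue_alphabet()] to validate against.
#' @return `data`, invisibly classed `pf_sequences`, or an error.
#' @export
validate_sequences <- function(data, alphabet = residue_alphabet()) {
  stopifnot(is.data.frame(data))
  required <- c("id", "sequence", "label")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop("sequence table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"family" %in% names(data)) data$family <- NA_character_
  if (!"description" %in% names(data)) data$description <- data$id
  if (anyDuplicated(data$id)) {
    stop("duplicate sequence ids: ",
         paste(unique(data$id[duplicated(data$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_label <- setdiff(unique(data$label), c("positive", "negative", "unknown"))
  if (length(bad_label)) {
    stop("invalid label(s): ", paste(bad_label, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(data$sequence) | is.na(data$sequence))) {
    stop("empty sequence for id(s): ",
         paste(data$id[!nzchar(data$sequence) | is.na(data$sequence)],
               collapse = ", "), call. = FALSE)
  }
  allowed <- sequence_symbols(alphabet)
  chars <- unique(unlist(strsplit(data$sequence, "", fixed = TRUE)))
  outside <- setdiff(chars, allowed)
  if (length(outside)) {
    stop("sequence characters outside the alphabet: ",
         paste(outside, collapse = " "), call. = FALSE)
  }
  class(data) <- unique(c("pf_sequences", class(data)))
  invisible(data)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a sequence tibble.
#' Sequences are uppercased; gap characters `-` and `.` are stripped; any
#' remaining character outside the 27 non-pad alphabet symbols is replaced
#' by `X` with a warning, or rejected with an error in strict mode. The id
#' is the header token up to the first whitespace; the full header is kept
#' as `description`. File order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param label Label applied to every record: `"positive"`, `"negative"`
#'   or `"unknown"`.
#' @param family Optional family tag applied to every record.
#' @param strict If `TRUE`, characters outside the alphabet are an error
#'   naming the record and position instead of being mapped to `X`.
#' @param alphabet The [residue_alphabet()] in force.
#' @return A `pf_sequences` tibble.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a toxin", "MKV", ">b", "GG"), fa)
#' read_fasta(fa, label = "positive", family = "alpha")
#' @export
read_fasta <- function(path, label = "unknown", family = NA_character_,
                       strict = FALSE, alphabet = residue_alphabet()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", headers)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("header(s) with empty sequence: ",
         paste(headers[empty], collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(gsub("[-.[:space:]]", "", seqs))
  allowed <- sequence_symbols(alphabet)
  # bracket expression: allowed symbols are letters and '*', all literal
  # inside [] for TRE; a custom alphabet must avoid ']', '^' and '-'
  pat <- paste0("[^", paste(allowed, collapse = ""), "]")
  has_bad <- grepl(pat, seqs)
  if (any(has_bad)) {
    if (strict) {
      i <- which(has_bad)[1L]
      p <- regexpr(pat, seqs[i])
      stop("record '", ids[i], "' has character '",
           substr(seqs[i], p, p), "' outside the alphabet at position ",
           as.integer(p), call. = FALSE)
    }
    warning(sum(has_bad), " record(s) contained characters outside the ",
            "alphabet; replaced with 'X'", call. = FALSE)
    seqs[has_bad] <- gsub(pat, "X", seqs[has_bad])
  }
  sequence_tbl(id = ids, sequence = seqs, label = label, family = family,
               description = headers)
}

#' Write a sequence table to FASTA
#'
#' Round-trip property: reading back a written file reproduces the
#' `(id, sequence)` pairs exactly.
#'
#' @param data A `pf_sequences` tibble.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60L) {
  if (nrow(data) == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write to ", path, call. = FALSE)
    return(invisible(path))
  }
  data <- validate_sequences(data)
  set <- Biostrings::BStringSet(data$sequence)
  names(set) <- data$id
  tryCatch(
    Biostrings::writeXStringSet(set, path, width = as.integer(width)),
    error = function(e) stop("cannot write FASTA to ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}
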