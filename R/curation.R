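#' Curation configuration
#'
#' Parameters of the dataset-assembly rules: sequences outside a length
#' window are dropped, positives are de-redundified by greedy identity
#' clustering, and negatives resembling any positive are purged by a local
#' alignment screen.
#'
#' @param min_length,max_length Length window in residues, inclusive
#'   (defaults 50 and 2000).
#' @param cluster_identity Identity threshold for collapsing positives
#'   (default 0.70).
#' @param purge_evalue E-value cutoff for discarding a negative with a
#'   significant local-alignment hit to a positive (default 0.01).
#' @param substitution_matrix,gap_opening,gap_extension Alignment scoring:
#'   substitution matrix name available in \pkg{Biostrings} and affine gap
#'   penalties (a gap of length g costs `gap_opening + g * gap_extension`).
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(min_length = 50L, max_length = 2000L,
                            cluster_identity = 0.70, purge_evalue = 0.01,
                            substitution_matrix = "BLOSUM62",
                            gap_opening = 10, gap_extension = 1) {
  stopifnot(min_length > 0, min_length <= max_length,
            cluster_identity > 0, cluster_identity <= 1,
            purge_evalue > 0)
  structure(list(min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 cluster_identity = cluster_identity,
                 purge_evalue = purge_evalue,
                 substitution_matrix = substitution_matrix,
                 gap_opening = gap_opening,
                 gap_extension = gap_extension),
            class = "curation_config")
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Keep sequences within a length window
#'
#' Retains exactly the records with `min_length <= nchar <= max_length`
#' (boundaries inclusive: only strictly shorter or strictly longer
#' sequences are eliminated). Order-preserving and idempotent.
#'
#' @param data A `pf_sequences` tibble.
#' @param min_length,max_length Inclusive bounds in residues.
#' @return The filtered tibble.
#' @export
filter_by_length <- function(data, min_length = 50L, max_length = 2000L) {
  stopifnot(min_length > 0, min_length <= max_length)
  dplyr::filter(data, nchar(.data$sequence) >= min_length,
                nchar(.data$sequence) <= max_length)
}

#' Global pairwise sequence identity
#'
#' Identity between two sequences under optimal global (Needleman-Wunsch)
#' alignment with affine gaps: identical columns divided by alignment
#' length including gaps. Symmetric, and 1 for identical sequences.
#'
#' @param a,b Residue strings.
#' @param config A [curation_config()] supplying the scoring scheme.
#' @return A fraction in \[0, 1\].
#' @examples
#' pairwise_identity("MKVLA", "MKVIA")  # 0.8
#' @export
pairwise_identity <- function(a, b, config = curation_config()) {
  stopifnot(nzchar(a), nzchar(b))
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = get_submat(config$substitution_matrix),
    gapOpening = config$gap_opening, gapExtension = config$gap_extension)
  Biostrings::pid(pa, type = "PID1") / 100
}

# Identity of one query against many subjects in a single vectorised call.
identity_to_set <- function(query, subjects, config = curation_config()) {
  if (!length(subjects)) return(numeric(0))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects), query, type = "global",
    substitutionMatrix = get_submat(config$substitution_matrix),
    gapOpening = config$gap_opening, gapExtension = config$gap_extension)
  Biostrings::pid(pa, type = "PID1") / 100
}

#' Greedy identity clustering of sequences
#'
#' CD-HIT-style incremental clustering, longest sequence first (ties broken
#' by id): each record either joins the first existing representative with
#' identity at or above the threshold, or founds a new cluster.
#' Deterministic given the input.
#'
#' @param data A `pf_sequences` tibble.
#' @param threshold Identity threshold in (0, 1\].
#' @param config Alignment scoring, see [curation_config()].
#' @return A list with `representatives` (tibble, original row order
#'   restricted to representatives) and `assignment` (tibble: `id`,
#'   `representative`, `identity`; representatives map to themselves with
#'   identity 1).
#' @export
cluster_by_identity <- function(data, threshold = 0.70,
                                config = curation_config()) {
  data <- validate_sequences(data)
  ord <- order(-nchar(data$sequence), data$id)
  rep_ids <- character(0)
  rep_seqs <- character(0)
  assign_rep <- character(nrow(data))
  assign_idy <- numeric(nrow(data))
  names(assign_rep) <- names(assign_idy) <- data$id
  for (i in ord) {
    id <- data$id[i]
    s <- data$sequence[i]
    hit <- NA_integer_
    if (length(rep_seqs)) {
      ids <- identity_to_set(s, rep_seqs, config)
      ok <- which(ids >= threshold)
      if (length(ok)) hit <- ok[1L]   # first (earliest-founded) representative
    }
    if (is.na(hit)) {
      rep_ids <- c(rep_ids, id)
      rep_seqs <- c(rep_seqs, s)
      assign_rep[id] <- id
      assign_idy[id] <- 1
    } else {
      assign_rep[id] <- rep_ids[hit]
      assign_idy[id] <- ids[hit]
    }
  }
  list(
    representatives = dplyr::filter(data, .data$id %in% rep_ids),
    assignment = tibble::tibble(id = data$id,
                                representative = unname(assign_rep[data$id]),
                                identity = unname(assign_idy[data$id]))
  )
}

# Karlin-Altschul E-value approximation for a gapped Smith-Waterman score
# under BLOSUM62 (lambda = 0.267, K = 0.041, the standard gapped values).
# An approximation to BLASTP's statistics, not a BLASTP reimplementation.
karlin_altschul_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

#' Purge negatives that resemble any positive
#'
#' Screens every negative against every positive with local
#' (Smith-Waterman) alignment and removes negatives whose best hit is
#' significant at the configured E-value, mirroring a BLASTP similarity
#' purge. Significance uses the Karlin-Altschul approximation
#' `E = K m n exp(-lambda S)` with the standard gapped BLOSUM62 parameters
#' (lambda 0.267, K 0.041). Retained negatives keep their order.
#'
#' @param negatives,positives `pf_sequences` tibbles.
#' @param config A [curation_config()].
#' @return A list with `negatives` (the retained tibble) and `audit`
#'   (tibble: `id`, `action`, `best_hit`, `score`, `evalue`).
#' @export
purge_positive_like <- function(negatives, positives,
                                config = curation_config()) {
  negatives <- validate_sequences(negatives)
  positives <- validate_sequences(positives)
  submat <- get_submat(config$substitution_matrix)
  pos_set <- Biostrings::AAStringSet(positives$sequence)
  n_neg <- nrow(negatives)
  best_score <- numeric(n_neg)
  best_hit <- character(n_neg)
  for (i in seq_len(n_neg)) {
    sc <- Biostrings::pairwiseAlignment(
      pos_set, negatives$sequence[i], type = "local",
      substitutionMatrix = submat, gapOpening = config$gap_opening,
      gapExtension = config$gap_extension, scoreOnly = TRUE)
    j <- which.max(sc)
    best_score[i] <- sc[j]
    best_hit[i] <- positives$id[j]
  }
  ev <- karlin_altschul_evalue(best_score,
                               m = nchar(negatives$sequence),
                               n = nchar(positives$sequence[match(best_hit, positives$id)]))
  removed <- ev <= config$purge_evalue
  audit <- tibble::tibble(id = negatives$id,
                          action = ifelse(removed, "removed", "retained"),
                          best_hit = best_hit, score = best_score,
                          evalue = ev)
  list(negatives = negatives[!removed, , drop = FALSE], audit = audit)
}

#' Assemble a curated dataset
#'
#' Applies the three curation rules in sequence: length filtering of both
#' sets, greedy identity clustering of the positives (representatives
#' kept), and alignment-based purging of the negatives. Returns the
#' curated sets together with a per-record audit trail recording which
#' step removed what.
#'
#' @param positives,negatives `pf_sequences` tibbles; positives should be
#'   family-tagged.
#' @param config A [curation_config()].
#' @return A list of class `curated_dataset`: `positives`, `negatives`,
#'   `audit` (tibble: `id`, `step`, `action`, `detail`), `config`.
#' @export
assemble_dataset <- function(positives, negatives,
                             config = curation_config()) {
  positives <- validate_sequences(positives)
  negatives <- validate_sequences(negatives)
  if (length(intersect(positives$id, negatives$id))) {
    stop("positive and negative ids overlap", call. = FALSE)
  }
  audit <- list()
  note <- function(ids, step, action, detail = "") {
    if (length(ids)) {
      audit[[length(audit) + 1L]] <<- tibble::tibble(
        id = ids, step = step, action = action, detail = detail)
    }
  }

  pos_f <- filter_by_length(positives, config$min_length, config$max_length)
  note(setdiff(positives$id, pos_f$id), "length_filter", "removed",
       "length outside window")
  neg_f <- filter_by_length(negatives, config$min_length, config$max_length)
  note(setdiff(negatives$id, neg_f$id), "length_filter", "removed",
       "length outside window")
  if (nrow(pos_f) == 0L) stop("no positives survive length filtering",
                              call. = FALSE)
  if (nrow(neg_f) == 0L) stop("no negatives survive length filtering",
                              call. = FALSE)

  cl <- cluster_by_identity(pos_f, config$cluster_identity, config)
  dropped <- dplyr::filter(cl$assignment, .data$id != .data$representative)
  note(dropped$id, "identity_cluster", "removed",
       paste0("merged into ", dropped$representative))

  pg <- purge_positive_like(neg_f, cl$representatives, config)
  rem <- dplyr::filter(pg$audit, .data$action == "removed")
  note(rem$id, "similarity_purge", "removed",
       paste0("hit ", rem$best_hit, " E=", signif(rem$evalue, 3)))

  if (nrow(pg$negatives) == 0L) stop("no negatives survive similarity purge",
                                     call. = FALSE)
  structure(list(positives = cl$representatives, negatives = pg$negatives,
                 audit = dplyr::bind_rows(audit), config = config),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("<curated_dataset> ", nrow(x$positives), " positives (",
      paste(names(table(x$positives$family)), collapse = "/"), "), ",
      nrow(x$negatives), " negatives; ", nrow(x$audit),
      " records removed during curation\n", sep = "")
  invisible(x)
}
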