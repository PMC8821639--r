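#' Synthetic benchmark configuration
#'
#' The generator emulates, at desk scale, the structure of a curated
#' pore-former dataset: two positive pseudo-families that share a
#' physicochemical property bias (a hydrophobic composition shift, the
#' kind of signal the Atchley encoding can see) but differ in motif
#' content (short family-specific sequence blocks, the kind of signal
#' one-hot convolution filters can see), a diverse i.i.d. background
#' negative set, and a "novel" holdout family that shares the property
#' bias but none of the motifs. Both signal components scale linearly
#' with `signal_strength`; at 0 every class is distributionally identical
#' to background.
#'
#' @param n_per_family Positive sequences generated per family.
#' @param n_negative Background sequences.
#' @param n_holdout Sequences in the novel holdout family.
#' @param min_length,max_length Uniform sequence-length window, within
#'   \[50, 2000\].
#' @param signal_strength Signal scale in \[0, 1\]: motif insertion
#'   probability per slot and the weight of the composition shift.
#' @param n_motifs_per_family Motifs drawn per family (8-15 residues
#'   each).
#' @param motif_slots Insertion attempts per positive sequence; each slot
#'   plants one motif with probability `signal_strength`.
#' @param bias_weight Maximum mixing weight of the hydrophobic target
#'   composition at full signal.
#' @param background Length-20 residue frequency vector over
#'   [CANONICAL_RESIDUES] (default uniform).
#' @param families Names of the training pseudo-families.
#' @param seed Integer seed; all generation is deterministic given the
#'   config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_family = 100L, n_negative = 200L,
                             n_holdout = 50L, min_length = 100L,
                             max_length = 400L, signal_strength = 1,
                             n_motifs_per_family = 3L, motif_slots = 3L,
                             bias_weight = 0.35,
                             background = rep(1 / 20, 20L),
                             families = c("alpha", "beta"),
                             seed = 1L) {
  stopifnot(signal_strength >= 0, signal_strength <= 1,
            min_length >= 50, max_length <= 2000, min_length <= max_length,
            length(background) == 20L, all(background >= 0),
            abs(sum(background) - 1) < 1e-8,
            bias_weight >= 0, bias_weight <= 1)
  structure(list(n_per_family = as.integer(n_per_family),
                 n_negative = as.integer(n_negative),
                 n_holdout = as.integer(n_holdout),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 signal_strength = signal_strength,
                 n_motifs_per_family = as.integer(n_motifs_per_family),
                 motif_slots = as.integer(motif_slots),
                 bias_weight = bias_weight,
                 background = stats::setNames(background, CANONICAL_RESIDUES),
                 families = families,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Hydrophobic/amphipathic target composition for the property bias:
# mass concentrated on A, C, F, I, L, M, V, W (membrane-insertion-prone
# residues), a caricature of the composition shift of pore-forming
# segments.
hydrophobic_target <- function() {
  w <- stats::setNames(rep(0.2, 20L), CANONICAL_RESIDUES)
  w[c("A", "C", "F", "I", "L", "M", "V", "W")] <- 1
  w / sum(w)
}

random_sequences <- function(n, min_length, max_length, composition) {
  lens <- sample(seq.int(min_length, max_length), n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(CANONICAL_RESIDUES, L, replace = TRUE, prob = composition),
          collapse = "")
  }, character(1L))
}

#' Draw a family motif set
#'
#' Motifs are 8-15 canonical residues, drawn once per family from the
#' seeded generator.
#'
#' @param n Number of motifs.
#' @param seed Integer seed.
#' @return Character vector of motif strings.
#' @export
draw_motifs <- function(n, seed) {
  rng <- local_rng(seed)
  on.exit(rng())
  vapply(seq_len(n), function(i) {
    L <- sample(8:15, 1L)
    paste(sample(CANONICAL_RESIDUES, L, replace = TRUE), collapse = "")
  }, character(1L))
}

#' Generate background (negative) sequences
#'
#' I.i.d. residues from the background composition, lengths uniform in
#' the configured window. Deterministic per seed.
#'
#' @param config A [synthetic_config()].
#' @param n Number of sequences (defaults to `config$n_negative`).
#' @param prefix Id prefix.
#' @return A `pf_sequences` tibble labelled `"negative"`.
#' @export
generate_background <- function(config, n = config$n_negative,
                                prefix = "neg") {
  rng <- local_rng(config$seed + 1L)
  on.exit(rng())
  seqs <- random_sequences(n, config$min_length, config$max_length,
                           config$background)
  sequence_tbl(sprintf("%s%04d", prefix, seq_len(n)), seqs,
               label = "negative")
}

# Insert motif blocks into a sequence by in-place substring replacement
# (length-preserving), at non-overlapping random positions.
plant_motifs <- function(sequence, motifs, slots, prob) {
  taken <- integer(0)
  for (k in seq_len(slots)) {
    if (stats::runif(1L) >= prob) next
    m <- motifs[[sample.int(length(motifs), 1L)]]
    w <- nchar(m)
    L <- nchar(sequence)
    if (w > L) stop("motif longer than sequence", call. = FALSE)
    for (try in 1:50) {
      at <- sample.int(L - w + 1L, 1L)
      if (!any(abs(at - taken) < w + 15L)) break
      at <- NA_integer_
    }
    if (is.na(at)) next
    taken <- c(taken, at)
    substr(sequence, at, at + w - 1L) <- m
  }
  sequence
}

#' Generate a positive pseudo-family
#'
#' Each sequence is a background chain with (a) up to `motif_slots`
#' family motifs planted at random non-overlapping positions, each slot
#' firing with probability `signal_strength`, and (b) residues drawn from
#' a composition shifted toward the hydrophobic target with weight
#' `signal_strength * bias_weight`. At `signal_strength = 0` the output
#' is distributionally identical to background. At `signal_strength = 1`
#' every sequence contains at least one exact motif copy (the slots are
#' forced).
#'
#' @param config A [synthetic_config()].
#' @param family Family name (used in ids and the `family` column).
#' @param motifs Motif set for this family, e.g. from [draw_motifs()].
#' @param n Number of sequences (defaults to `config$n_per_family`).
#' @param label Record label, default `"positive"`.
#' @return A `pf_sequences` tibble.
#' @export
generate_family <- function(config, family, motifs,
                            n = config$n_per_family, label = "positive") {
  stopifnot(length(motifs) >= 1L,
            all(grepl("^[A-Z]+$", motifs)))
  rng <- local_rng(config$seed + 1000L + sum(utf8ToInt(family)))
  on.exit(rng())
  s <- config$signal_strength
  comp <- (1 - s * config$bias_weight) * config$background +
    s * config$bias_weight * hydrophobic_target()
  seqs <- random_sequences(n, config$min_length, config$max_length, comp)
  seqs <- vapply(seqs, plant_motifs, character(1L), motifs = motifs,
                 slots = config$motif_slots, prob = s, USE.NAMES = FALSE)
  sequence_tbl(sprintf("%s%04d", family, seq_len(n)), seqs,
               label = label, family = family)
}

#' Generate a motif-disjoint novel family
#'
#' The holdout family for the generalization experiment: same property
#' bias as the training families, but a freshly drawn motif set sharing
#' no motif string with any training family ("same physics, different
#' sequence"). Errors if a drawn motif collides with a training motif.
#'
#' @param config A [synthetic_config()].
#' @param training_motifs Character vector of all motifs used by the
#'   training families.
#' @param family Holdout family name.
#' @return A `pf_sequences` tibble labelled `"positive"`.
#' @export
generate_novel_family <- function(config, training_motifs,
                                  family = "novel") {
  motifs <- draw_motifs(config$n_motifs_per_family, config$seed + 5000L)
  if (length(intersect(motifs, training_motifs))) {
    stop("novel-family motif collides with a training motif", call. = FALSE)
  }
  generate_family(config, family, motifs, n = config$n_holdout)
}

#' Build the full synthetic benchmark
#'
#' Generates the training dataset (two positive families plus background
#' negatives) and the novel holdout family, together with a manifest
#' sufficient to regenerate the benchmark bit-identically. Optionally
#' writes FASTA files and the JSON manifest to a directory.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory for FASTA + manifest files.
#' @return A list of class `pf_benchmark`: `dataset` (positives +
#'   negatives, one tibble), `holdout`, `motifs` (named list per family),
#'   `manifest` (list: config, seed, per-file md5 checksums when written).
#' @examples
#' bench <- make_benchmark(synthetic_config(n_per_family = 5,
#'                                          n_negative = 10, n_holdout = 3))
#' table(bench$dataset$label)
#' @export
make_benchmark <- function(config = synthetic_config(), dir = NULL) {
  motifs <- lapply(seq_along(config$families), function(i) {
    draw_motifs(config$n_motifs_per_family, config$seed + 100L * i)
  })
  names(motifs) <- config$families
  if (anyDuplicated(unlist(motifs))) {
    stop("motif collision between training families; change the seed",
         call. = FALSE)
  }
  pos <- dplyr::bind_rows(lapply(config$families, function(f) {
    generate_family(config, f, motifs[[f]])
  }))
  neg <- generate_background(config)
  holdout <- generate_novel_family(config, unlist(motifs))
  dataset <- dplyr::bind_rows(pos, neg)
  manifest <- list(generator = "poreformer::make_benchmark", version = 1L,
                   config = unclass(config), motifs = motifs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(positives = file.path(dir, "positives.fa"),
               negatives = file.path(dir, "negatives.fa"),
               holdout = file.path(dir, "holdout.fa"))
    write_fasta(pos, files[["positives"]])
    write_fasta(neg, files[["negatives"]])
    write_fasta(holdout, files[["holdout"]])
    manifest$checksums <- vapply(files, function(f) unname(tools::md5sum(f)),
                                 character(1L))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(dataset = dataset, holdout = holdout, motifs = motifs,
                 manifest = manifest),
            class = "pf_benchmark")
}

#' Regenerate a benchmark from its manifest
#' @param manifest A manifest list (or path to a `manifest.json`).
#' @return The regenerated `pf_benchmark`.
#' @export
benchmark_from_manifest <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  cfg <- manifest$config
  make_benchmark(synthetic_config(
    n_per_family = cfg$n_per_family, n_negative = cfg$n_negative,
    n_holdout = cfg$n_holdout, min_length = cfg$min_length,
    max_length = cfg$max_length, signal_strength = cfg$signal_strength,
    n_motifs_per_family = cfg$n_motifs_per_family,
    motif_slots = cfg$motif_slots, bias_weight = cfg$bias_weight,
    background = unlist(cfg$background), families = cfg$families,
    seed = cfg$seed))
}
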