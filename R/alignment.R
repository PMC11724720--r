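# Protein similarity descriptors: local alignment of a query receptor against
# an ordered reference panel, one normalized score per panel member.

canonical_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
ambiguity_aa <- c("B", "Z", "X")

#' Read protein sequences from a FASTA file
#'
#' Reads one record per sequence; the identifier is the header line up to the
#' first whitespace and residues are upper-cased. Sequences are validated
#' against the canonical 20-letter amino-acid alphabet.
#'
#' @param path Path to a FASTA file.
#' @param allow_ambiguity If `TRUE`, the ambiguity codes B, Z and X are
#'   accepted (they are scored by the corresponding rows of the substitution
#'   matrix when it defines them). Defaults to `FALSE`: ambiguity codes are a
#'   parse error, so silent low-similarity artifacts cannot enter a panel.
#' @return A tibble with columns `id` and `sequence`, in file order. A
#'   reference panel is simply such a tibble; its row order defines the
#'   descriptor axes and must be kept with any trained model.
#' @export
read_fasta <- function(path, allow_ambiguity = FALSE) {
  check_string(path, "path")
  check_flag(allow_ambiguity, "allow_ambiguity")
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("cannot parse FASTA '", path, "': ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0) abort(paste0("FASTA file is empty: ", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence ids in '", path, "': ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out <- tibble(id = ids, sequence = seqs)
  validate_sequences(out, allow_ambiguity = allow_ambiguity)
  out
}

# Validates a sequence tibble; errors name the offending record.
validate_sequences <- function(seqs, allow_ambiguity = FALSE) {
  alphabet <- canonical_aa
  if (allow_ambiguity) alphabet <- c(alphabet, ambiguity_aa)
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$sequence[i]
    if (is.na(s) || !nzchar(s)) {
      abort(paste0("record '", seqs$id[i], "' has an empty sequence"))
    }
    chars <- unique(strsplit(s, "")[[1]])
    bad <- setdiff(chars, alphabet)
    if (length(bad) > 0) {
      abort(paste0("record '", seqs$id[i], "' contains illegal residue(s): ",
                   paste(bad, collapse = ", "),
                   if (!allow_ambiguity && any(bad %in% ambiguity_aa))
                     " (set allow_ambiguity = TRUE to accept B/Z/X)" else ""))
    }
  }
  invisible(seqs)
}

#' Alignment parameters for the protein similarity descriptor
#'
#' Affine-gap local (Smith-Waterman) alignment parameters. A gap of length L
#' is penalized `gap_open + L * gap_extend`. Defaults follow common protein
#' local-alignment practice: BLOSUM62 with gap open 10 and gap extend 0.5.
#'
#' @param substitution_matrix Either the name of a matrix shipped with
#'   Biostrings (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`) or a numeric
#'   residue-pair score matrix with matching dimnames.
#' @param gap_open Non-negative gap opening penalty.
#' @param gap_extend Non-negative per-residue gap extension penalty; must not
#'   exceed `gap_open`.
#' @param normalization Either `"geometric"` (default) — normalize a raw score
#'   by the geometric mean of the two self-alignment scores, which is
#'   symmetric, bounded in \[0, 1\] and equal to 1 exactly at identity — or
#'   `"query"` — divide by the query self-score only.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 10, gap_extend = 0.5,
                             normalization = c("geometric", "query")) {
  normalization <- match.arg(normalization)
  check_number(gap_open, "gap_open", min = 0)
  check_number(gap_extend, "gap_extend", min = 0)
  if (gap_extend > gap_open) abort("gap_extend must not exceed gap_open")
  if (is.character(substitution_matrix)) {
    check_string(substitution_matrix, "substitution_matrix")
    matrix_name <- substitution_matrix
    env <- new.env()
    ok <- tryCatch({
      utils::data(list = matrix_name, package = "Biostrings", envir = env)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !exists(matrix_name, envir = env)) {
      abort(paste0("unknown substitution matrix: ", matrix_name))
    }
    substitution_matrix <- get(matrix_name, envir = env)
  } else {
    if (!is.matrix(substitution_matrix) || !is.numeric(substitution_matrix)) {
      abort("substitution_matrix must be a name or a numeric matrix")
    }
    matrix_name <- "custom"
  }
  structure(
    list(substitution_matrix = substitution_matrix,
         matrix_name = matrix_name,
         gap_open = gap_open, gap_extend = gap_extend,
         normalization = normalization),
    class = "alignment_params"
  )
}

#' @export
print.alignment_params <- function(x, ...) {
  cat("<alignment_params> matrix:", x$matrix_name,
      " gap_open:", x$gap_open, " gap_extend:", x$gap_extend,
      " normalization:", x$normalization, "\n")
  invisible(x)
}

as_alignment_params <- function(params) {
  if (inherits(params, "alignment_params")) return(params)
  abort("params must be created with alignment_params()")
}

check_sequence_string <- function(x, what, params) {
  check_string(x, what)
  x <- toupper(x)
  allowed <- rownames(params$substitution_matrix)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), allowed)
  if (length(bad) > 0) {
    abort(paste0(what, " contains residues absent from the substitution ",
                 "matrix: ", paste(bad, collapse = ", ")))
  }
  x
}

#' Smith-Waterman local alignment score
#'
#' Maximum local-alignment score between two protein sequences under affine
#' gap penalties. The score is symmetric in its arguments and never negative
#' (the empty alignment scores 0).
#'
#' @param a,b Protein sequence strings (upper-case residues).
#' @param params An [alignment_params()] object.
#' @return A single non-negative numeric score.
#' @export
sw_score <- function(a, b, params = alignment_params()) {
  params <- as_alignment_params(params)
  a <- check_sequence_string(a, "a", params)
  b <- check_sequence_string(b, "b", params)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE
  )
  # the empty local alignment is always admissible
  max(0, s)
}

#' Normalized local-alignment similarity
#'
#' Normalizes the raw local-alignment score into \[0, 1\]. With the default
#' geometric normalization, `sim(a, b) = SW(a, b) / sqrt(SW(a, a) * SW(b, b))`:
#' symmetric, 1 exactly when the sequences are identical (under a matrix whose
#' diagonal dominates), and 0 when no residue pair scores positively.
#'
#' @inheritParams sw_score
#' @return A similarity value in \[0, 1\].
#' @export
normalized_similarity <- function(a, b, params = alignment_params()) {
  params <- as_alignment_params(params)
  saa <- sw_score(a, a, params)
  sbb <- sw_score(b, b, params)
  if (saa <= 0 || sbb <= 0) {
    abort("degenerate sequence: self-alignment score is 0 under this matrix")
  }
  sab <- sw_score(a, b, params)
  denom <- switch(params$normalization,
                  geometric = sqrt(saa * sbb),
                  query = saa)
  min(1, sab / denom)
}

#' Protein similarity descriptors against a reference panel
#'
#' Computes, for each query sequence, the normalized local-alignment
#' similarity to every member of the reference panel. With the default
#' 30-member panel this is the 30-dimensional protein block of the PCM
#' feature vector; column order follows panel row order.
#'
#' @param queries A tibble with columns `id` and `sequence` (as returned by
#'   [read_fasta()]), or a single sequence string.
#' @param panel The reference panel: a tibble with columns `id` and
#'   `sequence` whose row order defines the descriptor axes.
#' @param params An [alignment_params()] object.
#' @return A tibble with one row per query: `target_id` followed by one
#'   `P_<panel id>` column per panel member, each value in \[0, 1\].
#' @export
protein_descriptors <- function(queries, panel, params = alignment_params()) {
  params <- as_alignment_params(params)
  if (is.character(queries) && length(queries) == 1) {
    queries <- tibble(id = "query", sequence = queries)
  }
  if (!is.data.frame(queries) || !all(c("id", "sequence") %in% names(queries))) {
    abort("queries must be a data frame with columns 'id' and 'sequence'")
  }
  if (!is.data.frame(panel) || !all(c("id", "sequence") %in% names(panel))) {
    abort("panel must be a data frame with columns 'id' and 'sequence'")
  }
  if (nrow(panel) == 0) abort("panel must be non-empty")
  if (anyDuplicated(panel$id)) abort("panel ids must be unique")

  panel_self <- vapply(seq_len(nrow(panel)), function(i) {
    s <- tryCatch(sw_score(panel$sequence[i], panel$sequence[i], params),
                  error = function(e) abort(paste0(
                    "panel member '", panel$id[i], "': ", conditionMessage(e))))
    if (s <= 0) abort(paste0("panel member '", panel$id[i],
                             "' has a zero self-alignment score"))
    s
  }, numeric(1))

  rows <- lapply(seq_len(nrow(queries)), function(q) {
    qseq <- queries$sequence[q]
    sqq <- tryCatch(sw_score(qseq, qseq, params),
                    error = function(e) abort(paste0(
                      "query '", queries$id[q], "': ", conditionMessage(e))))
    if (sqq <= 0) abort(paste0("query '", queries$id[q],
                               "' has a zero self-alignment score"))
    vals <- vapply(seq_len(nrow(panel)), function(i) {
      sab <- tryCatch(sw_score(qseq, panel$sequence[i], params),
                      error = function(e) abort(paste0(
                        "aligning query '", queries$id[q], "' to panel member '",
                        panel$id[i], "': ", conditionMessage(e))))
      denom <- switch(params$normalization,
                      geometric = sqrt(sqq * panel_self[i]),
                      query = sqq)
      min(1, sab / denom)
    }, numeric(1))
    c(list(target_id = queries$id[q]),
      setNames(as.list(vals), protein_feature_names(panel$id)))
  })
  dplyr::bind_rows(rows)
}
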