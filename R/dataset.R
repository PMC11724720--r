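# Bioactivity records: EC50 dichotomization, assembly of 217-D PCM feature
# vectors (protein block then ligand block) and stratified train/validation
# splitting.

#' Convert EC50 potency values to activity labels
#'
#' Dichotomizes half-maximal effective concentrations at a potency threshold:
#' a compound is `"active"` when its EC50 is at or below the threshold
#' (boundary inclusive), `"inactive"` otherwise. The default threshold is
#' 1 micromolar.
#'
#' @param ec50 Numeric vector of EC50 values in micromolar; all values must
#'   be positive.
#' @param threshold Potency threshold in micromolar (default 1).
#' @return Character vector of `"active"` / `"inactive"`.
#' @export
label_from_ec50 <- function(ec50, threshold = 1) {
  check_number(threshold, "threshold", min = 0)
  if (!is.numeric(ec50) || length(ec50) == 0) {
    abort("ec50 must be a non-empty numeric vector")
  }
  if (anyNA(ec50) || any(ec50 <= 0)) {
    abort("ec50 values must be positive and non-missing")
  }
  ifelse(ec50 <= threshold, "active", "inactive")
}

#' Read bioactivity records from a CSV file
#'
#' Expects columns `compound_id` and `target_id`, plus `ec50` (with optional
#' `ec50_units` of `uM`, `nM` or `M`, converted to micromolar) and/or
#' `label`. When both are present the label must agree with the dichotomized
#' EC50. A `smiles` column, if present, is carried through.
#'
#' @param path CSV file path.
#' @param threshold Potency threshold in micromolar passed to
#'   [label_from_ec50()].
#' @return A tibble of bioactivity records with a `label` column.
#' @export
read_bioactivity <- function(path, threshold = 1) {
  check_string(path, "path")
  if (!file.exists(path)) abort(paste0("bioactivity file not found: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("compound_id", "target_id")
  missing <- setdiff(req, names(d))
  if (length(missing) > 0) {
    abort(paste0("bioactivity CSV is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!("ec50" %in% names(d)) && !("label" %in% names(d))) {
    abort("bioactivity CSV needs an 'ec50' or a 'label' column")
  }
  if ("ec50" %in% names(d)) {
    ec50 <- as.numeric(d$ec50)
    if ("ec50_units" %in% names(d)) {
      unit <- tolower(trimws(as.character(d$ec50_units)))
      unit[is.na(unit) | !nzchar(unit)] <- "um"
      mult <- dplyr::case_match(unit, "nm" ~ 1e-3, "um" ~ 1, "µm" ~ 1,
                                "m" ~ 1e6, .default = NA_real_)
      if (anyNA(mult)) {
        abort(paste0("unrecognized ec50_units: ",
                     paste(unique(unit[is.na(mult)]), collapse = ", ")))
      }
      ec50 <- ec50 * mult
    }
    d$ec50 <- ec50
    derived <- label_from_ec50(ec50, threshold)
    if ("label" %in% names(d)) {
      clash <- which(!is.na(d$label) & as.character(d$label) != derived)
      if (length(clash) > 0) {
        abort(paste0("label disagrees with dichotomized EC50 for ",
                     length(clash), " record(s), first at row ", clash[1]))
      }
    }
    d$label <- derived
  }
  d$label <- as.character(d$label)
  invisible(as_activity_factor(d$label))  # validates values
  as_tibble(d)
}

#' Assemble PCM feature vectors from bioactivity records
#'
#' Joins each record's target to its protein similarity descriptor against
#' the reference panel and its compound to the ligand descriptor vector,
#' producing the concatenated PCM feature (protein block first). With the
#' default 30-member panel and 187-descriptor manifest each example carries
#' 217 features.
#'
#' @param records Bioactivity records: a tibble with `compound_id`,
#'   `target_id` and `label` (or `ec50`).
#' @param targets Tibble with `id` and `sequence` for every distinct
#'   `target_id` (targets may be, but need not be, panel members).
#' @param compounds Tibble with `id` and `smiles` for every distinct
#'   `compound_id`.
#' @param panel Reference panel tibble (`id`, `sequence`); row order defines
#'   the protein-block axes.
#' @param params An [alignment_params()] object.
#' @param manifest Ligand descriptor manifest; defaults to
#'   [default_manifest()].
#' @param threshold Potency threshold (micromolar) used when `label` is
#'   absent but `ec50` is present.
#' @return A tibble with `compound_id`, `target_id`, `label`, `origin`
#'   (`"original"`) and the feature columns `P_*` then `L_*`. Records whose
#'   ids cannot be resolved are excluded and reported in the `problems`
#'   attribute plus a warning; an empty result is an error.
#' @export
assemble_examples <- function(records, targets, compounds, panel,
                              params = alignment_params(),
                              manifest = default_manifest(),
                              threshold = 1) {
  if (!is.data.frame(records) ||
      !all(c("compound_id", "target_id") %in% names(records))) {
    abort("records must have columns 'compound_id' and 'target_id'")
  }
  if (!("label" %in% names(records))) {
    if (!("ec50" %in% names(records))) {
      abort("records need a 'label' or an 'ec50' column")
    }
    records$label <- label_from_ec50(records$ec50, threshold)
  }
  records$label <- as.character(records$label)
  invisible(as_activity_factor(records$label))

  bad_target <- !(records$target_id %in% targets$id)
  bad_compound <- !(records$compound_id %in% compounds$id)
  problems <- tibble(
    row = which(bad_target | bad_compound),
    compound_id = records$compound_id[bad_target | bad_compound],
    target_id = records$target_id[bad_target | bad_compound],
    reason = dplyr::case_when(
      bad_target[bad_target | bad_compound] &
        bad_compound[bad_target | bad_compound] ~ "unknown target and compound",
      bad_target[bad_target | bad_compound] ~ "unknown target id",
      TRUE ~ "unknown compound id"
    )
  )
  keep <- !(bad_target | bad_compound)
  if (nrow(problems) > 0) {
    warn(paste0(nrow(problems), " record(s) with unresolvable ids were ",
                "excluded (see attr(., 'problems'))"))
  }
  if (!any(keep)) abort("no records survived id resolution")
  records <- records[keep, , drop = FALSE]

  used_targets <- targets[targets$id %in% unique(records$target_id), ,
                          drop = FALSE]
  used_compounds <- compounds[compounds$id %in% unique(records$compound_id), ,
                              drop = FALSE]
  pdesc <- protein_descriptors(used_targets, panel, params)
  ldesc <- ligand_descriptors(used_compounds, manifest)

  out <- records[, c("compound_id", "target_id", "label")]
  out$origin <- "original"
  out <- dplyr::left_join(out, pdesc, by = "target_id")
  out <- dplyr::left_join(out, ldesc, by = "compound_id")
  out <- as_tibble(out)
  attr(out, "problems") <- problems
  attr(out, "panel_ids") <- panel$id
  attr(out, "manifest") <- manifest
  out
}

#' Split examples into training and validation sets
#'
#' Seeded, reproducible partition with stratification (by default within
#' target and label jointly, so every target keeps both activity classes on
#' both sides whenever its strata allow it).
#'
#' @param examples Assembled examples from [assemble_examples()].
#' @param train_fraction Fraction assigned to training; the classical grid
#'   uses 0.50 to 0.90 in steps of 0.05, with 0.85 the default.
#' @param seed Integer seed.
#' @param stratify_by `"both"` (target x label), `"label"`, `"target"` or
#'   `"none"`.
#' @return A list with tibbles `train` and `validation`; together they are a
#'   disjoint, exhaustive partition of the input rows.
#' @export
split_examples <- function(examples, train_fraction = 0.85, seed = 42,
                           stratify_by = c("both", "label", "target", "none")) {
  stratify_by <- match.arg(stratify_by)
  check_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be strictly between 0 and 1")
  }
  check_number(seed, "seed")
  n <- nrow(examples)
  if (n < 2) abort("need at least 2 examples to split")
  stratum <- switch(stratify_by,
    both = paste(examples$target_id, examples$label, sep = "/"),
    label = as.character(examples$label),
    target = as.character(examples$target_id),
    none = rep("all", n)
  )
  counts <- table(stratum)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    abort(paste0("stratum too small to split (need >= 2 examples): ",
                 paste(small, collapse = ", ")))
  }
  idx_train <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (s in sort(unique(stratum))) {
      rows <- which(stratum == s)
      n_tr <- round(train_fraction * length(rows))
      n_tr <- max(1L, min(length(rows) - 1L, n_tr))
      idx_train <- c(idx_train, sample(rows, n_tr))
    }
  })
  idx_train <- sort(idx_train)
  list(train = examples[idx_train, , drop = FALSE],
       validation = examples[-idx_train, , drop = FALSE])
}
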