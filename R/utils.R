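# Internal helpers shared across modules.

# Names of the protein-block feature columns for a panel.
protein_feature_names <- function(panel_ids) paste0("P_", panel_ids)

# Names of the ligand-block feature columns for a manifest.
ligand_feature_names <- function(manifest) paste0("L_", manifest)

# All feature columns of an example tibble, protein block first.
feature_names_of <- function(examples) {
  nms <- names(examples)
  c(nms[startsWith(nms, "P_")], nms[startsWith(nms, "L_")])
}

# Extract the feature matrix (rows = examples) in a fixed column order.
feature_matrix <- function(examples, feature_names = feature_names_of(examples)) {
  missing <- setdiff(feature_names, names(examples))
  if (length(missing) > 0) {
    abort(paste0("examples are missing feature columns: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  as.matrix(examples[, feature_names, drop = FALSE])
}

# Validate a single-string scalar argument.
check_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1 || is.na(x) || !nzchar(x)) {
    abort(paste0(what, " must be a single non-empty string"))
  }
  x
}

check_number <- function(x, what, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(paste0(what, " must be a single number in [", min, ", ", max, "]"))
  }
  x
}

check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    abort(paste0(what, " must be TRUE or FALSE"))
  }
  x
}

# Two-class label vector used throughout: "active" / "inactive".
activity_levels <- c("inactive", "active")

as_activity_factor <- function(label) {
  bad <- setdiff(unique(as.character(label)), activity_levels)
  if (length(bad) > 0) {
    abort(paste0("labels must be 'active' or 'inactive', found: ",
                 paste(bad, collapse = ", ")))
  }
  factor(as.character(label), levels = activity_levels)
}

# 0/1 encoding with active = 1.
label_to_binary <- function(label) as.integer(as.character(label) == "active")
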