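# Compound input: SMILES lists, CSV columns and SDF files, validated and
# canonicalized through Open Babel. Invalid records are reported, never
# silently dropped.

# Parse a single SMILES; returns the canonical SMILES or NA (with a reason
# attribute) when the string does not describe a valid molecule with at least
# one heavy atom.
canonicalize_smiles <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) NA_character_
  )
  if (is.na(out) || !nzchar(out)) {
    return(structure(NA_character_, reason = "unparseable SMILES"))
  }
  can <- strsplit(sub("\n$", "", out), "\t")[[1]][1]
  if (is.na(can) || !nzchar(can)) {
    return(structure(NA_character_, reason = "unparseable SMILES"))
  }
  can
}

#' Read compounds from a SMILES list, CSV or SDF file
#'
#' Every structure is validated and canonicalized. Records that do not parse
#' are excluded and reported as a single warning plus a `problems` attribute
#' (a tibble with `id` and `reason`), mirroring how readr reports bad rows.
#'
#' @param path Path to the input file.
#' @param format `"smiles"` (one SMILES per line, optionally followed by
#'   whitespace and an id), `"csv"` (columns named by `smiles_col` /
#'   `id_col`), `"sdf"` (ids from the molecule title field), or `"auto"`
#'   (by file extension: .csv, .sdf/.mol, else smiles list).
#' @param smiles_col,id_col Column names used for `format = "csv"`.
#' @return A tibble with columns `id`, `smiles` (canonical) and `source`
#'   (the input path). Attribute `problems` holds the excluded records.
#' @export
read_compounds <- function(path, format = c("auto", "smiles", "csv", "sdf"),
                           smiles_col = "smiles", id_col = "compound_id") {
  format <- match.arg(format)
  check_string(path, "path")
  if (!file.exists(path)) abort(paste0("compound file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv"
      else if (ext %in% c("sdf", "mol")) "sdf"
      else "smiles"
  }
  raw <- switch(format,
    smiles = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      if (length(lines) == 0) abort(paste0("no SMILES records in: ", path))
      parts <- stringr::str_split_fixed(trimws(lines), "\\s+", 2)
      ids <- ifelse(nzchar(parts[, 2]), parts[, 2],
                    paste0("cpd", seq_along(lines)))
      tibble(id = ids, smiles_in = parts[, 1])
    },
    csv = {
      d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
      if (!smiles_col %in% names(d)) {
        abort(paste0("CSV is missing the SMILES column '", smiles_col, "'"))
      }
      ids <- if (id_col %in% names(d)) as.character(d[[id_col]])
             else paste0("cpd", seq_len(nrow(d)))
      tibble(id = ids, smiles_in = as.character(d[[smiles_col]]))
    },
    sdf = {
      sdfs <- tryCatch(ChemmineR::read.SDFset(path),
                       error = function(e) abort(paste0(
                         "cannot read SDF '", path, "': ", conditionMessage(e))))
      ids <- vapply(ChemmineR::SDFset2list(sdfs), function(x) {
        h <- x$header[["Molecule_Name"]]
        if (is.null(h) || is.na(h) || !nzchar(h)) NA_character_ else h
      }, character(1))
      ids[is.na(ids)] <- paste0("cpd", which(is.na(ids)))
      smi <- tryCatch(
        as.character(ChemmineR::sdf2smiles(sdfs)),
        error = function(e) abort(paste0("cannot convert SDF to SMILES: ",
                                         conditionMessage(e))))
      tibble(id = ids, smiles_in = smi)
    })

  if (anyDuplicated(raw$id)) {
    abort(paste0("duplicate compound ids in '", path, "': ",
                 paste(unique(raw$id[duplicated(raw$id)]), collapse = ", ")))
  }
  canon <- vapply(raw$smiles_in, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    as.character(canonicalize_smiles(s))
  }, character(1), USE.NAMES = FALSE)
  bad <- is.na(canon)
  problems <- tibble(id = raw$id[bad],
                     reason = rep("unparseable SMILES", sum(bad)))
  if (any(bad)) {
    warn(paste0(sum(bad), " compound record(s) failed to parse and were ",
                "excluded: ", paste(head(raw$id[bad], 5), collapse = ", "),
                if (sum(bad) > 5) ", ..." else ""))
  }
  out <- tibble(id = raw$id[!bad], smiles = canon[!bad], source = path)
  if (nrow(out) == 0) abort(paste0("no valid compound records in: ", path))
  attr(out, "problems") <- problems
  out
}

# Parse a SMILES into a heavy-atom molecular graph via an Open Babel V2000
# molblock round trip:
#   elements  character vector of atomic symbols
#   bonds     tibble(a1, a2, order) with kekulized bond orders
# Hydrogens are implicit throughout. `sdf` is filled in lazily by callers
# that need ChemmineR ring perception.
parse_molecule_ob <- function(smiles) {
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", smiles)),
    error = function(e) abort(paste0("invalid SMILES: ", smiles))
  )
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 5) abort(paste0("invalid SMILES: ", smiles))
  na <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nb <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(na) || na < 1 || is.na(nb)) {
    abort(paste0("molecule has no heavy atoms: ", smiles))
  }
  atom_lines <- lines[4 + seq_len(na)]
  elements <- trimws(substr(atom_lines, 32, 34))
  bonds <- if (nb == 0) {
    tibble(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bl <- lines[4 + na + seq_len(nb)]
    tibble(a1 = as.integer(substr(bl, 1, 3)),
           a2 = as.integer(substr(bl, 4, 6)),
           order = as.integer(substr(bl, 7, 9)))
  }
  list(smiles = smiles, elements = elements, n_atoms = na,
       bonds = bonds, sdf = NULL, molblock = txt)
}

# igraph of the heavy-atom skeleton (unweighted, undirected).
molecule_graph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds) > 0) mol$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(0), a2 = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(mol$n_atoms))
  )
}
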