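# Matched molecular pairs: single-cut fragmentation of every acyclic single
# bond, fragment canonicalization with a dummy-atom attachment marker, and
# core-indexed pair discovery; plus the chemical-space network with
# per-compound best-target annotation.

# Write a V2000 molblock for a subset of atoms plus one dummy (*) atom
# bonded to the attachment atom, and return its canonical SMILES.
fragment_smiles <- function(mol, atom_idx, attach_atom) {
  els <- c(mol$elements[atom_idx], "*")
  n_at <- length(els)
  map <- setNames(seq_along(atom_idx), atom_idx)
  keep <- mol$bonds$a1 %in% atom_idx & mol$bonds$a2 %in% atom_idx
  bonds <- mol$bonds[keep, , drop = FALSE]
  bl <- rbind(
    cbind(map[as.character(bonds$a1)], map[as.character(bonds$a2)],
          bonds$order),
    c(map[as.character(attach_atom)], n_at, 1L)
  )
  mb <- paste0(
    "fragment\n  pcmscreen\n\n",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000\n", n_at, nrow(bl)),
    paste0(sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   els), collapse = "\n"), "\n",
    paste0(sprintf("%3d%3d%3d  0", bl[, 1], bl[, 2], bl[, 3]),
           collapse = "\n"), "\n",
    "M  END\n"
  )
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("MOL", "CAN", mb)),
    error = function(e) NA_character_
  )
  if (is.na(out) || !nzchar(out)) return(NA_character_)
  strsplit(sub("\n$", "", out), "\t")[[1]][1]
}

#' Enumerate single-cut fragmentations of a compound
#'
#' Cuts every acyclic (bridge) single bond between heavy atoms, producing a
#' core and a substituent fragment, each canonicalized with a single
#' dummy-atom (`*`) attachment marker. The core is the fragment with the
#' larger heavy-atom count (ties broken by the lexicographically smaller
#' canonical string). Cuts whose substituent exceeds the size constraints
#' are filtered out.
#'
#' @param smiles A single SMILES string.
#' @param max_substituent_fraction Maximal substituent size as a fraction of
#'   the parent's heavy atoms (default 1/3).
#' @param max_substituent_atoms Absolute cap on substituent heavy atoms
#'   (default 13).
#' @return A tibble with one row per eligible cut: `cut_bond` (bond index),
#'   `core`, `substituent` (canonical fragment SMILES with `*`),
#'   `core_atoms`, `substituent_atoms`. Molecules with no acyclic single
#'   bond (e.g. benzene) return zero rows.
#' @export
enumerate_cuts <- function(smiles, max_substituent_fraction = 1 / 3,
                           max_substituent_atoms = 13) {
  check_string(smiles, "smiles")
  check_number(max_substituent_fraction, "max_substituent_fraction", min = 0,
               max = 1)
  check_number(max_substituent_atoms, "max_substituent_atoms", min = 1)
  mol <- parse_molecule_ob(smiles)
  empty <- tibble(cut_bond = integer(0), core = character(0),
                  substituent = character(0), core_atoms = integer(0),
                  substituent_atoms = integer(0))
  if (nrow(mol$bonds) == 0) return(empty)
  g <- molecule_graph(mol)
  bridge_idx <- as.integer(igraph::bridges(g))
  cuts <- bridge_idx[mol$bonds$order[bridge_idx] == 1]
  if (length(cuts) == 0) return(empty)

  rows <- lapply(cuts, function(bi) {
    g_cut <- igraph::delete_edges(g, bi)
    comp <- igraph::components(g_cut)$membership
    a1 <- mol$bonds$a1[bi]; a2 <- mol$bonds$a2[bi]
    side1 <- which(comp == comp[a1])
    side2 <- which(comp == comp[a2])
    n1 <- length(side1); n2 <- length(side2)
    # smaller side is the substituent candidate
    if (n2 < n1 || (n1 == n2 && a2 > a1)) {
      core_atoms <- side1; sub_atoms <- side2
      core_attach <- a1; sub_attach <- a2
    } else {
      core_atoms <- side2; sub_atoms <- side1
      core_attach <- a2; sub_attach <- a1
    }
    n_sub <- length(sub_atoms)
    if (n_sub > max_substituent_atoms ||
        n_sub > max_substituent_fraction * mol$n_atoms) {
      return(NULL)
    }
    core <- fragment_smiles(mol, core_atoms, core_attach)
    sub <- fragment_smiles(mol, sub_atoms, sub_attach)
    if (is.na(core) || is.na(sub)) return(NULL)
    # canonical tie-break when the halves are the same size
    if (length(core_atoms) == length(sub_atoms) && sub < core) {
      tmp <- core; core <- sub; sub <- tmp
      tmp_n <- core_atoms; core_atoms <- sub_atoms; sub_atoms <- tmp_n
    }
    tibble(cut_bond = bi, core = core, substituent = sub,
           core_atoms = length(core_atoms),
           substituent_atoms = length(sub_atoms))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Find all matched molecular pairs in a compound library
#'
#' Indexes every compound's single-cut fragmentations by canonical core;
#' every unordered pair of distinct compounds sharing a core with different
#' substituents yields exactly one pair per shared core. The output is
#' deterministic under permutation of the input (sorted by id pair, then
#' core).
#'
#' @param compounds Tibble with `id` and `smiles`.
#' @inheritParams enumerate_cuts
#' @return A tibble: `compound_a`, `compound_b` (with `compound_a` <
#'   `compound_b`), `core`, `substituent_a`, `substituent_b`.
#' @export
find_mmps <- function(compounds, max_substituent_fraction = 1 / 3,
                      max_substituent_atoms = 13) {
  if (!is.data.frame(compounds) ||
      !all(c("id", "smiles") %in% names(compounds))) {
    abort("compounds must have columns 'id' and 'smiles'")
  }
  if (nrow(compounds) < 2) abort("need at least 2 compounds")
  if (anyDuplicated(compounds$id)) abort("compound ids must be unique")

  cuts <- purrr::map_dfr(seq_len(nrow(compounds)), function(i) {
    ct <- enumerate_cuts(compounds$smiles[i],
                         max_substituent_fraction = max_substituent_fraction,
                         max_substituent_atoms = max_substituent_atoms)
    if (nrow(ct) == 0) return(ct)
    dplyr::mutate(ct, compound_id = compounds$id[i])
  })
  empty <- tibble(compound_a = character(0), compound_b = character(0),
                  core = character(0), substituent_a = character(0),
                  substituent_b = character(0))
  if (nrow(cuts) == 0) return(empty)
  # one (compound, core) entry per distinct substituent
  cuts <- dplyr::distinct(cuts, .data$compound_id, .data$core,
                          .data$substituent)

  pairs <- dplyr::inner_join(cuts, cuts, by = "core",
                             suffix = c("_a", "_b"),
                             relationship = "many-to-many")
  pairs <- dplyr::filter(pairs,
                         .data$compound_id_a < .data$compound_id_b,
                         .data$substituent_a != .data$substituent_b)
  if (nrow(pairs) == 0) return(empty)
  # exactly one pair per (a, b, core): deterministic representative
  pairs <- dplyr::arrange(pairs, .data$compound_id_a, .data$compound_id_b,
                          .data$core, .data$substituent_a,
                          .data$substituent_b)
  pairs <- dplyr::distinct(pairs, .data$compound_id_a, .data$compound_id_b,
                           .data$core, .keep_all = TRUE)
  dplyr::select(pairs, compound_a = "compound_id_a",
                compound_b = "compound_id_b", core = "core",
                substituent_a = "substituent_a",
                substituent_b = "substituent_b")
}

# Rejoin a core and substituent at their attachment markers; returns the
# canonical SMILES of the reassembled molecule. Used to verify that cuts
# are information-preserving.
mmp_join <- function(core, substituent) {
  m1 <- parse_molecule_ob(core)
  m2 <- parse_molecule_ob(substituent)
  star1 <- which(m1$elements == "*")
  star2 <- which(m2$elements == "*")
  if (length(star1) != 1 || length(star2) != 1) {
    abort("fragments must each carry exactly one * attachment marker")
  }
  nb1 <- c(m1$bonds$a2[m1$bonds$a1 == star1], m1$bonds$a1[m1$bonds$a2 == star1])
  nb2 <- c(m2$bonds$a2[m2$bonds$a1 == star2], m2$bonds$a1[m2$bonds$a2 == star2])
  if (length(nb1) != 1 || length(nb2) != 1) {
    abort("attachment marker must have exactly one neighbor")
  }
  keep1 <- setdiff(seq_len(m1$n_atoms), star1)
  keep2 <- setdiff(seq_len(m2$n_atoms), star2)
  map1 <- setNames(seq_along(keep1), keep1)
  map2 <- setNames(seq_along(keep2) + length(keep1), keep2)
  els <- c(m1$elements[keep1], m2$elements[keep2])
  b1 <- m1$bonds[m1$bonds$a1 != star1 & m1$bonds$a2 != star1, , drop = FALSE]
  b2 <- m2$bonds[m2$bonds$a1 != star2 & m2$bonds$a2 != star2, , drop = FALSE]
  bl <- rbind(
    cbind(map1[as.character(b1$a1)], map1[as.character(b1$a2)], b1$order),
    cbind(map2[as.character(b2$a1)], map2[as.character(b2$a2)], b2$order),
    c(map1[as.character(nb1)], map2[as.character(nb2)], 1L)
  )
  mb <- paste0(
    "joined\n  pcmscreen\n\n",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000\n",
            length(els), nrow(bl)),
    paste0(sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   els), collapse = "\n"), "\n",
    paste0(sprintf("%3d%3d%3d  0", bl[, 1], bl[, 2], bl[, 3]),
           collapse = "\n"), "\n",
    "M  END\n"
  )
  out <- suppressWarnings(ChemmineOB::convertFormat("MOL", "CAN", mb))
  strsplit(sub("\n$", "", out), "\t")[[1]][1]
}

#' Build the chemical-space network of a screened library
#'
#' Nodes are compounds annotated with their best-scoring target (argmax over
#' the screening table, ties broken by first appearance in target order) and
#' best score; edges are matched molecular pairs; connected components label
#' the scaffold clusters.
#'
#' @param pairs MMP tibble from [find_mmps()].
#' @param compounds Tibble with `id` and `smiles`.
#' @param screening A screening table covering every compound, with
#'   `compound_id`, `target_id` and `score` (e.g. from
#'   [screen_compounds()]).
#' @return A `csn_network` list with `nodes` (tibble `id`, `smiles`,
#'   `best_target`, `best_score`, `component`), `edges` (the pairs tibble)
#'   and `graph` (an igraph object).
#' @export
build_network <- function(pairs, compounds, screening) {
  req <- c("compound_id", "target_id", "score")
  if (!all(req %in% names(screening))) {
    abort("screening must have columns compound_id, target_id, score")
  }
  target_order <- unique(screening$target_id)
  seen <- table(factor(screening$compound_id, levels = compounds$id))
  missing <- names(seen)[seen < length(target_order)]
  if (length(missing) > 0) {
    abort(paste0("compound(s) missing from the screening table (need every ",
                 "compound x target pair): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  best <- screening |>
    dplyr::mutate(.t_ord = match(.data$target_id, target_order)) |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$.t_ord,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("compound_id", best_target = "target_id",
                  best_score = "score")

  nodes <- dplyr::left_join(compounds[, c("id", "smiles")], best,
                            by = c(id = "compound_id"))
  g <- igraph::graph_from_data_frame(
    d = if (nrow(pairs) > 0) pairs[, c("compound_a", "compound_b")] else
      data.frame(a = character(0), b = character(0)),
    directed = FALSE,
    vertices = data.frame(name = nodes$id)
  )
  comp <- igraph::components(g)$membership
  nodes$component <- unname(comp[nodes$id])
  igraph::V(g)$best_target <- nodes$best_target[match(igraph::V(g)$name,
                                                      nodes$id)]
  igraph::V(g)$best_score <- nodes$best_score[match(igraph::V(g)$name,
                                                    nodes$id)]
  igraph::V(g)$smiles <- nodes$smiles[match(igraph::V(g)$name, nodes$id)]
  structure(list(nodes = nodes, edges = pairs, graph = g),
            class = "csn_network")
}

#' @export
print.csn_network <- function(x, ...) {
  cat("<csn_network>", nrow(x$nodes), "compounds,", nrow(x$edges),
      "matched pairs,", max(x$nodes$component), "components\n")
  invisible(x)
}

#' Export a chemical-space network
#'
#' Writes the network as GraphML (primary exchange format, node attributes
#' included) and optionally the edge list as CSV.
#'
#' @param network A `csn_network` from [build_network()].
#' @param path Output GraphML path.
#' @param edges_path Optional CSV path for the edge list.
#' @export
write_network_graphml <- function(network, path, edges_path = NULL) {
  if (!inherits(network, "csn_network")) abort("not a csn_network")
  igraph::write_graph(network$graph, path, format = "graphml")
  if (!is.null(edges_path)) {
    readr::write_csv(network$edges, edges_path)
  }
  invisible(path)
}
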