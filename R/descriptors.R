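# Ligand descriptors: a fixed registry of 187 two-dimensional physicochemical
# and topological descriptors computed on the implicit-hydrogen heavy-atom
# graph, plus a handful of Open Babel bulk properties. The registry order is
# frozen by the manifest, which is serialized with every trained model.

# Atomic property tables (heavy atoms only; hydrogens are implicit).
.atom_props <- local({
  sym <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si")
  list(
    mass  = setNames(c(12.011, 14.007, 15.999, 32.06, 30.974, 18.998,
                       35.45, 79.904, 126.904, 10.81, 28.085), sym),
    # Pauling electronegativity
    en    = setNames(c(2.55, 3.04, 3.44, 2.58, 2.19, 3.98,
                       3.16, 2.96, 2.66, 2.04, 1.90), sym),
    # atomic polarizability, A^3
    pol   = setNames(c(1.76, 1.10, 0.80, 2.90, 3.63, 0.56,
                       2.18, 3.05, 5.35, 3.03, 5.38), sym),
    # van der Waals volume, A^3
    vdw   = setNames(c(20.58, 15.60, 14.71, 24.43, 24.43, 13.31,
                       22.45, 26.52, 32.52, 18.0, 38.8), sym),
    # valence electrons
    zv    = setNames(c(4, 5, 6, 6, 5, 7, 7, 7, 7, 3, 4), sym),
    # atomic number
    z     = setNames(c(6, 7, 8, 16, 15, 9, 17, 35, 53, 5, 14), sym),
    # usual valence, used to infer implicit hydrogens
    stdval = setNames(c(4, 3, 2, 2, 3, 1, 1, 1, 1, 3, 4), sym),
    # principal quantum number
    pqn   = setNames(c(2, 2, 2, 3, 3, 2, 3, 4, 5, 2, 3), sym)
  )
})

atom_prop <- function(tab, elements, default) {
  v <- unname(tab[elements])
  v[is.na(v)] <- default
  v
}

#' The default ligand descriptor manifest
#'
#' Returns the 187 descriptor names computed by [ligand_descriptors()], in
#' the frozen (alphabetical) order that defines the ligand block of the PCM
#' feature vector. The registry covers Open Babel bulk properties (`OB_*`),
#' atom/bond/ring counts, functional-group counts, connectivity (chi) and
#' shape (kappa) indices, electrotopological-state summaries, distance-based
#' topological indices, and Moreau-Broto / Moran / Geary autocorrelations of
#' atomic mass, electronegativity, polarizability and van der Waals volume
#' at topological lags 1-8.
#'
#' @return A character vector of length 187.
#' @export
default_manifest <- function() {
  ac <- as.vector(outer(c("ATS", "MATS", "GATS"),
                        as.vector(outer(c("m", "e", "p", "v"), 1:8, paste0)),
                        paste0))
  nms <- c(
    paste0("OB_", c("HBA1", "HBA2", "HBD", "MR", "MW", "TPSA", "logP", "nF")),
    "nHeavyAtoms", "nAtomC", "nAtomN", "nAtomO", "nAtomS", "nAtomP",
    "nAtomF", "nAtomCl", "nAtomBr", "nAtomI", "nHalogen", "nHetero",
    "nImplicitH", "totalValence", "nTerminalAtoms",
    "fracC", "fracN", "fracO", "fracHetero", "fracRingAtoms",
    "nBonds", "nBondsSingle", "nBondsDouble", "nBondsTriple", "nBondsRing",
    "nBondsRotatable", "nBondsBridge", "meanBondOrder",
    "nDeg1", "nDeg2", "nDeg3", "nDeg4", "meanDegree",
    "nRingsSSSR", "nAromaticRings", "nAromaticAtoms", "nRingAtoms",
    "graphDensity", "PetitjeanIndex",
    "WienerIndex", "WienerPolarity", "HararyIndex", "graphDiameter",
    "graphRadius", "meanEccentricity", "meanDistance", "ZagrebM1",
    "ZagrebM2", "PlattIndex",
    paste0("Chi", 0:4), paste0("Chi", 0:4, "v"),
    paste0("Kappa", 1:3),
    "EStateSum", "EStateMax", "EStateMin", "EStateMean",
    "nCarboxyl", "nCarbonyl", "nHydroxyl", "nEther", "nMethoxy", "nAmide",
    "nPrimaryAmine", "nNitrile",
    "longestCarbonChain", "nAcyclicAtoms", "MolecularFlexibility",
    "avgAtomicMass", "totalPolarizability",
    "TotalWalkCount2", "TotalWalkCount3", "BalabanJ",
    "EccentricConnectivity",
    ac
  )
  # radix sort = C-locale byte order, identical on every platform
  sort(unique(nms), method = "radix")
}

#' Read or write a descriptor manifest file
#'
#' A manifest is a plain-text file with one descriptor name per line; its
#' order is the ligand-block column order and is serialized with any model.
#'
#' @param path File path.
#' @return `read_manifest()` returns a character vector of descriptor names.
#' @export
read_manifest <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) abort(paste0("manifest file not found: ", path))
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0) abort("manifest file contains no descriptor names")
  if (anyDuplicated(x)) abort("manifest contains duplicate descriptor names")
  x
}

#' @rdname read_manifest
#' @param manifest Character vector of descriptor names.
#' @export
write_manifest <- function(manifest, path) {
  writeLines(manifest, path)
  invisible(path)
}

# ---- per-molecule graph descriptor engine ------------------------------

# Enumerate simple paths with k edges; returns count and the sum of
# prod(delta)^(-1/2) over paths for the given per-atom delta vector.
path_stats <- function(adj, delta, k) {
  if (k == 0) {
    ok <- delta > 0
    return(list(count = sum(ok), chi = sum(1 / sqrt(delta[ok]))))
  }
  count <- 0L
  chi <- 0
  n <- length(adj)
  # DFS from every atom; keep paths whose endpoints satisfy first < last
  walk <- function(path_atoms, prod_delta) {
    last <- path_atoms[length(path_atoms)]
    if (length(path_atoms) == k + 1) {
      if (path_atoms[1] < last) {
        count <<- count + 1L
        if (prod_delta > 0) chi <<- chi + 1 / sqrt(prod_delta)
      }
      return(invisible())
    }
    for (nb in adj[[last]]) {
      if (!(nb %in% path_atoms)) {
        walk(c(path_atoms, nb), prod_delta * delta[nb])
      }
    }
  }
  for (a in seq_len(n)) walk(a, delta[a])
  list(count = count, chi = chi)
}

# All graph-derived descriptors for one parsed molecule.
graph_descriptors <- function(mol) {
  el <- mol$elements
  n <- mol$n_atoms
  bonds <- mol$bonds
  nb <- nrow(bonds)
  g <- molecule_graph(mol)

  deg <- rep(0L, n)
  if (nb > 0) {
    t1 <- tabulate(bonds$a1, nbins = n)
    t2 <- tabulate(bonds$a2, nbins = n)
    deg <- t1 + t2
  }
  adj <- lapply(seq_len(n), function(i) {
    c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
  })
  bond_order_sum <- rep(0, n)
  if (nb > 0) {
    for (i in seq_len(nb)) {
      bond_order_sum[bonds$a1[i]] <- bond_order_sum[bonds$a1[i]] + bonds$order[i]
      bond_order_sum[bonds$a2[i]] <- bond_order_sum[bonds$a2[i]] + bonds$order[i]
    }
  }
  stdval <- atom_prop(.atom_props$stdval, el, 4)
  n_h <- pmax(0, stdval - bond_order_sum)
  zv <- atom_prop(.atom_props$zv, el, 4)
  z <- atom_prop(.atom_props$z, el, 6)
  pqn <- atom_prop(.atom_props$pqn, el, 2)

  # ring membership via bridges
  is_bridge <- rep(FALSE, nb)
  if (nb > 0) {
    br <- igraph::bridges(g)
    if (length(br) > 0) is_bridge[as.integer(br)] <- TRUE
  }
  ring_bond <- !is_bridge
  ring_atoms <- unique(c(bonds$a1[ring_bond], bonds$a2[ring_bond]))
  n_ring_atoms <- length(ring_atoms)
  comps <- igraph::components(g)$no
  n_rings <- nb - n + comps

  # aromatic rings (size <= 8) via ring perception on the SDF
  n_arom_rings <- 0L
  n_arom_atoms <- 0L
  if (n_rings > 0 && !is.null(mol$sdf)) {
    arom <- tryCatch(
      suppressWarnings(ChemmineR::rings(mol$sdf, upper = 8, type = "all",
                                        arom = TRUE)),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    n_arom_rings <- sum(arom$AROMATIC %in% TRUE)
    arom_atoms <- unique(unlist(arom$RINGS[arom$AROMATIC %in% TRUE]))
    n_arom_atoms <- length(arom_atoms)
  }

  # distances
  D <- igraph::distances(g)
  finite_upper <- function(M) {
    v <- M[upper.tri(M)]
    v[is.finite(v) & v > 0]
  }
  dv <- finite_upper(D)
  ecc <- apply(D, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0) 0 else max(r)
  })
  diam <- if (length(dv) > 0) max(dv) else 0
  radius <- if (n > 1) min(ecc[ecc > 0 | n == 1]) else 0
  if (!is.finite(radius) || length(radius) == 0) radius <- 0

  # rotatable: acyclic single bonds between non-terminal atoms
  rot <- nb > 0 & is_bridge & bonds$order == 1 &
    deg[bonds$a1] >= 2 & deg[bonds$a2] >= 2

  # chi / kappa
  delta_v <- ifelse(pqn <= 2, zv - n_h, (zv - n_h) / pmax(1, z - zv - 1))
  chi <- numeric(5); chiv <- numeric(5); pcounts <- numeric(4)
  for (k in 0:4) {
    st <- path_stats(adj, deg, k)
    chi[k + 1] <- st$chi
    if (k >= 1) pcounts[k] <- st$count
    stv <- path_stats(adj, pmax(delta_v, 0), k)
    chiv[k + 1] <- stv$chi
  }
  p1 <- nb; p2 <- pcounts[2]; p3 <- pcounts[3]
  kappa1 <- if (p1 > 0) n * (n - 1)^2 / p1^2 else 0
  kappa2 <- if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else 0
  kappa3 <- if (p3 > 0) {
    if (n %% 2 == 0) (n - 3) * (n - 2)^2 / p3^2
    else (n - 1) * (n - 3)^2 / p3^2
  } else 0

  # electrotopological state
  istate <- ifelse(deg > 0, ((2 / pqn)^2 * delta_v + 1) / deg,
                   (2 / pqn)^2 * delta_v + 1)
  estate <- istate
  if (n > 1) {
    for (i in seq_len(n)) {
      d_i <- D[i, ]
      ok <- is.finite(d_i) & seq_len(n) != i
      estate[i] <- istate[i] +
        sum((istate[i] - istate[ok]) / (d_i[ok] + 1)^2)
    }
  }

  # functional groups (kekulized bond orders, implicit hydrogens)
  bond_between <- function(i, j) {
    hit <- (bonds$a1 == i & bonds$a2 == j) | (bonds$a1 == j & bonds$a2 == i)
    if (any(hit)) bonds$order[which(hit)[1]] else 0L
  }
  is_carbonyl_c <- vapply(seq_len(n), function(i) {
    el[i] == "C" && any(vapply(adj[[i]], function(j)
      el[j] == "O" && bond_between(i, j) == 2, logical(1)))
  }, logical(1))
  n_carboxyl <- sum(vapply(seq_len(n), function(i) {
    is_carbonyl_c[i] && any(vapply(adj[[i]], function(j)
      el[j] == "O" && deg[j] == 1 && bond_between(i, j) == 1, logical(1)))
  }, logical(1)))
  n_hydroxyl <- sum(el == "O" & deg == 1 & vapply(seq_len(n), function(i)
    el[i] == "O" && deg[i] == 1 && bond_order_sum[i] == 1, logical(1)))
  n_ether <- sum(vapply(seq_len(n), function(i)
    el[i] == "O" && deg[i] == 2 && bond_order_sum[i] == 2, logical(1)))
  n_methoxy <- sum(vapply(seq_len(n), function(i) {
    el[i] == "O" && deg[i] == 2 && bond_order_sum[i] == 2 &&
      any(vapply(adj[[i]], function(j)
        el[j] == "C" && deg[j] == 1, logical(1)))
  }, logical(1)))
  n_amide <- sum(vapply(seq_len(n), function(i) {
    el[i] == "N" && any(vapply(adj[[i]], function(j)
      is_carbonyl_c[j] && bond_between(i, j) == 1, logical(1)))
  }, logical(1)))
  n_prim_amine <- sum(vapply(seq_len(n), function(i) {
    el[i] == "N" && deg[i] == 1 && bond_order_sum[i] == 1 &&
      !any(vapply(adj[[i]], function(j) is_carbonyl_c[j], logical(1)))
  }, logical(1)))
  n_nitrile <- sum(vapply(seq_len(n), function(i)
    el[i] == "N" && any(vapply(adj[[i]], function(j)
      bond_between(i, j) == 3, logical(1))), logical(1)))

  # longest carbon chain: diameter (in atoms) of the carbon-only subgraph
  c_idx <- which(el == "C")
  longest_chain <- 0
  if (length(c_idx) == 1) longest_chain <- 1
  if (length(c_idx) > 1) {
    gc <- igraph::induced_subgraph(g, c_idx)
    Dc <- igraph::distances(gc)
    fin <- Dc[is.finite(Dc)]
    longest_chain <- max(fin) + 1
  }

  # walk counts and Balaban J
  A <- matrix(0, n, n)
  if (nb > 0) {
    A[cbind(bonds$a1, bonds$a2)] <- 1
    A[cbind(bonds$a2, bonds$a1)] <- 1
  }
  A2 <- A %*% A
  twc2 <- sum(A2) / 2
  twc3 <- sum(A2 %*% A) / 2
  Dfin <- D; Dfin[!is.finite(Dfin)] <- 0
  srow <- rowSums(Dfin)
  balaban <- 0
  if (nb > 0 && all(srow[c(bonds$a1, bonds$a2)] > 0)) {
    mu <- n_rings
    balaban <- (nb / (mu + 1)) *
      sum(1 / sqrt(srow[bonds$a1] * srow[bonds$a2]))
  }

  mass <- atom_prop(.atom_props$mass, el, 12.011)
  pol <- atom_prop(.atom_props$pol, el, 1.76)

  halogens <- c("F", "Cl", "Br", "I")
  out <- c(
    nHeavyAtoms = n,
    nAtomC = sum(el == "C"), nAtomN = sum(el == "N"), nAtomO = sum(el == "O"),
    nAtomS = sum(el == "S"), nAtomP = sum(el == "P"), nAtomF = sum(el == "F"),
    nAtomCl = sum(el == "Cl"), nAtomBr = sum(el == "Br"),
    nAtomI = sum(el == "I"),
    nHalogen = sum(el %in% halogens),
    nHetero = sum(el != "C"),
    nImplicitH = sum(n_h), totalValence = sum(bond_order_sum + n_h),
    nTerminalAtoms = sum(deg <= 1),
    fracC = sum(el == "C") / n, fracN = sum(el == "N") / n,
    fracO = sum(el == "O") / n, fracHetero = sum(el != "C") / n,
    fracRingAtoms = n_ring_atoms / n,
    nBonds = nb, nBondsSingle = sum(bonds$order == 1),
    nBondsDouble = sum(bonds$order == 2),
    nBondsTriple = sum(bonds$order == 3),
    nBondsRing = sum(ring_bond), nBondsRotatable = sum(rot),
    nBondsBridge = sum(is_bridge),
    meanBondOrder = if (nb > 0) mean(bonds$order) else 0,
    nDeg1 = sum(deg == 1), nDeg2 = sum(deg == 2), nDeg3 = sum(deg == 3),
    nDeg4 = sum(deg >= 4), meanDegree = mean(deg),
    nRingsSSSR = n_rings, nAromaticRings = n_arom_rings,
    nAromaticAtoms = n_arom_atoms, nRingAtoms = n_ring_atoms,
    graphDensity = if (n > 1) 2 * nb / (n * (n - 1)) else 0,
    PetitjeanIndex = if (radius > 0) (diam - radius) / radius else 0,
    WienerIndex = sum(dv), WienerPolarity = sum(dv == 3),
    HararyIndex = sum(1 / dv),
    graphDiameter = diam, graphRadius = radius,
    meanEccentricity = mean(ecc),
    meanDistance = if (length(dv) > 0) mean(dv) else 0,
    ZagrebM1 = sum(deg^2),
    ZagrebM2 = if (nb > 0) sum(deg[bonds$a1] * deg[bonds$a2]) else 0,
    PlattIndex = if (nb > 0) sum(deg[bonds$a1] + deg[bonds$a2] - 2) else 0,
    setNames(chi, paste0("Chi", 0:4)),
    setNames(chiv, paste0("Chi", 0:4, "v")),
    Kappa1 = kappa1, Kappa2 = kappa2, Kappa3 = kappa3,
    EStateSum = sum(estate), EStateMax = max(estate),
    EStateMin = min(estate), EStateMean = mean(estate),
    nCarboxyl = n_carboxyl, nCarbonyl = sum(is_carbonyl_c),
    nHydroxyl = n_hydroxyl, nEther = n_ether, nMethoxy = n_methoxy,
    nAmide = n_amide, nPrimaryAmine = n_prim_amine, nNitrile = n_nitrile,
    longestCarbonChain = longest_chain,
    nAcyclicAtoms = n - n_ring_atoms,
    MolecularFlexibility = kappa1 * kappa2 / n,
    avgAtomicMass = mean(mass), totalPolarizability = sum(pol),
    TotalWalkCount2 = twc2, TotalWalkCount3 = twc3,
    BalabanJ = balaban, EccentricConnectivity = sum(ecc * deg)
  )

  # autocorrelations over topological lags 1..8
  props <- list(m = mass / 12.011, e = atom_prop(.atom_props$en, el, 2.55),
                p = pol, v = atom_prop(.atom_props$vdw, el, 20.58))
  ac <- numeric(0)
  for (pn in names(props)) {
    p <- props[[pn]]
    pbar <- mean(p)
    varp <- sum((p - pbar)^2)
    for (lag in 1:8) {
      pairs <- which(D == lag & upper.tri(D), arr.ind = TRUE)
      npair <- nrow(pairs)
      ats <- if (npair > 0) sum(p[pairs[, 1]] * p[pairs[, 2]]) else 0
      if (npair > 0 && varp > 0) {
        num_m <- sum((p[pairs[, 1]] - pbar) * (p[pairs[, 2]] - pbar)) / npair
        mats <- num_m / (varp / n)
        gats <- (sum((p[pairs[, 1]] - p[pairs[, 2]])^2) / (2 * npair)) /
          (varp / (n - 1))
      } else {
        mats <- 0; gats <- 0
      }
      ac <- c(ac, setNames(c(ats, mats, gats),
                           paste0(c("ATS", "MATS", "GATS"), pn, lag)))
    }
  }
  c(out, ac)
}

#' Compute ligand descriptors for a set of compounds
#'
#' Computes the descriptor vector named by the manifest for each compound.
#' With the default manifest this is the 187-dimensional ligand block of the
#' PCM feature vector. Identical molecules (equal canonical SMILES) always
#' receive identical vectors; descriptors that are undefined for a molecule
#' (for example autocorrelations at lags beyond its diameter) are imputed as
#' 0 and counted in a message.
#'
#' @param compounds A tibble with columns `id` and `smiles` (as returned by
#'   [read_compounds()] or [simulate_compounds()]).
#' @param manifest Character vector of descriptor names; defaults to
#'   [default_manifest()].
#' @return A tibble with `compound_id` followed by one `L_<name>` column per
#'   manifest entry, all values finite.
#' @export
ligand_descriptors <- function(compounds, manifest = default_manifest()) {
  if (!is.data.frame(compounds) ||
      !all(c("id", "smiles") %in% names(compounds))) {
    abort("compounds must be a data frame with columns 'id' and 'smiles'")
  }
  if (nrow(compounds) == 0) abort("no compounds to featurize")
  unknown <- setdiff(manifest, default_manifest())
  if (length(unknown) > 0) {
    abort(paste0("manifest names not in the descriptor registry: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }

  canon <- vapply(compounds$smiles, function(s) {
    cs <- canonicalize_smiles(s)
    if (is.na(cs)) abort(paste0("invalid SMILES for descriptor computation: ", s))
    cs
  }, character(1), USE.NAMES = FALSE)

  mols <- lapply(canon, parse_molecule_ob)
  multi <- vapply(mols, function(m) m$n_atoms > 1, logical(1))

  # Open Babel bulk properties; single-heavy-atom molecules fall outside the
  # SDF round trip and get a formula-level fallback (the rest imputed as 0).
  ob_tab <- matrix(NA_real_, nrow(compounds), 8,
                   dimnames = list(NULL, c("OB_HBA1", "OB_HBA2", "OB_HBD",
                                           "OB_MR", "OB_MW", "OB_TPSA",
                                           "OB_logP", "OB_nF")))
  if (any(multi)) {
    sdfset <- ChemmineR::smiles2sdf(setNames(canon[multi],
                                             compounds$id[multi]))
    ob <- suppressWarnings(ChemmineR::propOB(sdfset))
    ob_num <- function(col) suppressWarnings(as.numeric(ob[[col]]))
    ob_tab[multi, ] <- cbind(ob_num("HBA1"), ob_num("HBA2"), ob_num("HBD"),
                             ob_num("MR"), ob_num("MW"), ob_num("TPSA"),
                             ob_num("logP"), ob_num("nF"))
    kept <- which(multi)
    for (j in seq_along(kept)) mols[[kept[j]]]$sdf <- sdfset[[j]]
  }
  if (any(!multi)) {
    for (i in which(!multi)) {
      el <- mols[[i]]$elements[1]
      mass <- atom_prop(.atom_props$mass, el, 12.011)
      nh <- atom_prop(.atom_props$stdval, el, 4)
      ob_tab[i, ] <- c(as.numeric(el %in% c("N", "O")),
                       as.numeric(el %in% c("N", "O")),
                       as.numeric(el %in% c("N", "O") && nh > 0),
                       0, mass + 1.008 * nh, 0, 0,
                       as.numeric(el == "F"))
    }
  }

  n_imputed <- 0L
  rows <- lapply(seq_len(nrow(compounds)), function(i) {
    mol <- mols[[i]]
    vals <- c(graph_descriptors(mol), ob_tab[i, ])
    v <- vals[manifest]
    names(v) <- manifest
    bad <- !is.finite(v)
    if (any(bad)) {
      n_imputed <<- n_imputed + sum(bad)
      v[bad] <- 0
    }
    v
  })
  if (n_imputed > 0) {
    inform(paste0("imputed ", n_imputed,
                  " undefined descriptor value(s) as 0"))
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- ligand_feature_names(manifest)
  dplyr::bind_cols(tibble(compound_id = compounds$id), as_tibble(mat))
}
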