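# Deterministic synthetic-data generator: a family-structured receptor
# panel, a small-grammar compound library and bioactivity labels from a
# planted rule that couples ligand features to target family. The generator
# plants exactly the statistical structure the PCM pipeline assumes —
# within-family sequence similarity and a family-conditional ligand rule —
# and nothing more; it is not a realistic receptor or chemistry simulator.

#' Simulate a family-structured reference panel
#'
#' Draws one random ancestor sequence per family and derives each panel
#' member from its family ancestor by independent per-site substitutions.
#' Within-family similarity therefore exceeds between-family similarity in
#' expectation, which is the signal the protein descriptor block carries.
#'
#' @param panel_size Number of panel members (default 30, the size of the
#'   reference panel the protein descriptor is built against).
#' @param n_families Number of sequence families (default 4).
#' @param seq_length Sequence length in residues (default 120).
#' @param mutation_rate Per-site substitution probability between ancestor
#'   and member (default 0.1).
#' @param seed Integer seed.
#' @return A list with `panel` (tibble `id`, `sequence`, `family`) and
#'   `ancestors` (tibble `family`, `sequence`).
#' @export
simulate_panel <- function(panel_size = 30, n_families = 4, seq_length = 120,
                           mutation_rate = 0.1, seed = 42) {
  check_number(panel_size, "panel_size", min = 1)
  check_number(n_families, "n_families", min = 1)
  if (panel_size < n_families) abort("panel_size must be >= n_families")
  check_number(seq_length, "seq_length", min = 1)
  check_number(mutation_rate, "mutation_rate", min = 0)
  if (mutation_rate >= 1) abort("mutation_rate must be in [0, 1)")
  check_number(seed, "seed")

  withr::with_seed(as.integer(seed), {
    ancestors <- vapply(seq_len(n_families), function(f) {
      paste(sample(canonical_aa, seq_length, replace = TRUE), collapse = "")
    }, character(1))
    family <- rep(seq_len(n_families), length.out = panel_size)
    members <- vapply(seq_len(panel_size), function(i) {
      res <- strsplit(ancestors[family[i]], "")[[1]]
      mut <- runif(seq_length) < mutation_rate
      if (any(mut)) {
        res[mut] <- vapply(res[mut], function(a) {
          sample(setdiff(canonical_aa, a), 1)
        }, character(1))
      }
      paste(res, collapse = "")
    }, character(1))
    list(
      panel = tibble(
        id = sprintf("NRF%d_%02d", family, seq_len(panel_size)),
        sequence = members, family = family),
      ancestors = tibble(family = seq_len(n_families), sequence = ancestors)
    )
  })
}

# Grammar pieces: an alkyl chain, an optional benzene ring, an optional
# terminal functional group. All emitted SMILES are valid by construction.
.group_smiles <- c(none = "", carboxyl = "C(=O)O", amide = "C(N)=O",
                   methoxy = "OC")

#' Simulate a compound library from a small structural grammar
#'
#' Each compound is an alkyl chain of 2-12 carbons, with probability 1/2
#' attached to a benzene ring, and with a terminal functional group drawn
#' from none / carboxyl / amide / methoxy. The grammar spans the structural
#' motifs the screen is meant to separate — long-chain carboxylic acids
#' versus small aromatics — while staying trivially valid SMILES.
#'
#' @param n_compounds Library size (default 300).
#' @param seed Integer seed.
#' @return A tibble with `id`, `smiles` and the latent generative features
#'   `chain_length`, `has_ring`, `group` (used by the planted activity
#'   rule and convenient for tests).
#' @export
simulate_compounds <- function(n_compounds = 300, seed = 42) {
  check_number(n_compounds, "n_compounds", min = 1)
  check_number(seed, "seed")
  withr::with_seed(as.integer(seed), {
    chain_length <- sample(2:12, n_compounds, replace = TRUE)
    has_ring <- runif(n_compounds) < 0.5
    group <- sample(names(.group_smiles), n_compounds, replace = TRUE,
                    prob = c(0.3, 0.4, 0.15, 0.15))
    smiles <- paste0(ifelse(has_ring, "c1ccccc1", ""),
                     strrep("C", chain_length),
                     unname(.group_smiles[group]))
    tibble(
      id = sprintf("CPD%04d", seq_len(n_compounds)),
      smiles = smiles,
      chain_length = chain_length, has_ring = has_ring, group = group
    )
  })
}

# The planted interaction rule: families alternate between two ligand
# predicates, so activity depends on BOTH the compound and the target
# family and the protein block is informative.
planted_rule_active <- function(compounds, family) {
  long_acid <- compounds$chain_length >= 7 & compounds$group == "carboxyl"
  aromatic <- compounds$has_ring
  if (family %% 2 == 1) long_acid else aromatic
}

planted_rule_description <- paste(
  "odd families: active iff chain_length >= 7 and a carboxyl group;",
  "even families: active iff the compound carries a benzene ring")

#' Simulate bioactivity records from the planted interaction rule
#'
#' Picks training targets among the panel members (covering both rule
#' groups) plus fully held-out external targets from families seen in
#' training, then labels every (compound, target) pair by the planted
#' family-conditional rule with independent label flips at rate
#' `activity_noise`. EC50 values are sampled consistently with the labels
#' around the 1 micromolar potency threshold: actives log-uniform in
#' \[0.001, 1\], inactives log-uniform in (1, 100\].
#'
#' @param panel_sim Output of [simulate_panel()] (or a panel tibble with a
#'   `family` column).
#' @param compounds Output of [simulate_compounds()].
#' @param n_train_targets Number of panel members with training bioactivity
#'   data (default 5).
#' @param held_out_targets Number of additional targets excluded from
#'   training to emulate external validation on receptors without
#'   bioactivity data (default 2).
#' @param activity_noise Label-flip probability (default 0.05).
#' @param seed Integer seed.
#' @return A list with `records` (training bioactivity tibble), `external`
#'   (held-out-target records), `targets` (tibble `id`, `family`, `rule`,
#'   `held_out`) and `rule` (a description string).
#' @export
simulate_bioactivity <- function(panel_sim, compounds, n_train_targets = 5,
                                 held_out_targets = 2, activity_noise = 0.05,
                                 seed = 42) {
  panel <- if (is.data.frame(panel_sim)) panel_sim else panel_sim$panel
  if (!all(c("id", "family") %in% names(panel))) {
    abort("panel must carry 'id' and 'family' columns")
  }
  check_number(n_train_targets, "n_train_targets", min = 2)
  check_number(held_out_targets, "held_out_targets", min = 0)
  check_number(activity_noise, "activity_noise", min = 0)
  if (activity_noise >= 1) abort("activity_noise must be in [0, 1)")
  check_number(seed, "seed")
  if (n_train_targets + held_out_targets > nrow(panel)) {
    abort("not enough panel members for the requested target counts")
  }

  withr::with_seed(as.integer(seed), {
    # interleave rule groups so training covers both predicates
    odd <- panel$id[panel$family %% 2 == 1]
    even <- panel$id[panel$family %% 2 == 0]
    if (length(odd) == 0 || length(even) == 0) {
      abort("panel must contain both odd and even families")
    }
    take <- function(pool, k) pool[seq_len(min(k, length(pool)))]
    n_odd <- ceiling(n_train_targets / 2)
    train_ids <- c(take(sample(odd), n_odd),
                   take(sample(even), n_train_targets - n_odd))
    remaining <- setdiff(panel$id, train_ids)
    train_fams <- panel$family[match(train_ids, panel$id)]
    eligible <- remaining[panel$family[match(remaining, panel$id)] %in%
                            train_fams]
    external_ids <- take(sample(eligible), held_out_targets)

    make_records <- function(target_ids) {
      purrr::map_dfr(target_ids, function(tg) {
        fam <- panel$family[panel$id == tg]
        active <- planted_rule_active(compounds, fam)
        flip <- runif(nrow(compounds)) < activity_noise
        lab <- xor(active, flip)
        ec50 <- ifelse(lab,
                       10^runif(nrow(compounds), -3, 0),
                       10^runif(nrow(compounds), log10(1.0001), 2))
        tibble(compound_id = compounds$id, target_id = tg,
               ec50 = ec50, ec50_units = "uM",
               label = ifelse(lab, "active", "inactive"))
      })
    }
    records <- make_records(train_ids)
    external <- if (held_out_targets > 0) make_records(external_ids) else
      records[0, ]

    both <- all(tapply(records$label, records$target_id,
                       function(l) length(unique(l)) == 2))
    if (!both) {
      abort(paste0("a training target lost one activity class; use a ",
                   "larger compound library or a different seed"))
    }
    list(
      records = records, external = external,
      targets = tibble(
        id = c(train_ids, external_ids),
        family = panel$family[match(c(train_ids, external_ids), panel$id)],
        rule = ifelse(panel$family[match(c(train_ids, external_ids),
                                         panel$id)] %% 2 == 1,
                      "long_acid", "aromatic"),
        held_out = c(rep(FALSE, length(train_ids)),
                     rep(TRUE, length(external_ids)))),
      rule = planted_rule_description
    )
  })
}

#' Simulate a complete synthetic PCM study
#'
#' Convenience wrapper producing the panel, the compound library and the
#' bioactivity records (training and held-out external) in one call, all
#' driven by a single seed.
#'
#' @inheritParams simulate_panel
#' @inheritParams simulate_compounds
#' @inheritParams simulate_bioactivity
#' @return A list: `panel` (tibble), `ancestors`, `compounds`, `records`,
#'   `external`, `targets`, `rule`.
#' @export
simulate_pcm_data <- function(panel_size = 30, n_families = 4,
                              seq_length = 120, mutation_rate = 0.1,
                              n_compounds = 300, n_train_targets = 5,
                              held_out_targets = 2, activity_noise = 0.05,
                              seed = 42) {
  ps <- simulate_panel(panel_size = panel_size, n_families = n_families,
                       seq_length = seq_length,
                       mutation_rate = mutation_rate, seed = seed)
  compounds <- simulate_compounds(n_compounds = n_compounds, seed = seed + 1)
  bio <- simulate_bioactivity(ps, compounds,
                              n_train_targets = n_train_targets,
                              held_out_targets = held_out_targets,
                              activity_noise = activity_noise,
                              seed = seed + 2)
  c(list(panel = ps$panel, ancestors = ps$ancestors, compounds = compounds),
    bio)
}
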