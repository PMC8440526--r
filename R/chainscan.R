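#' Coarse-grained chain model from a protein sequence
#'
#' One bead per residue on a fixed-bond-length backbone (3.8 A, the
#' C-alpha--C-alpha distance). Beads carry the residue charge (+1 for K/R,
#' -1 for D/E, 0 otherwise) and a Kyte-Doolittle hydropathy normalized to
#' `[0, 1]`, which scales the attractive well of the pairwise
#' Lennard-Jones term.
#'
#' @param sequence Amino-acid string.
#' @param bond_length Bond length in Angstrom.
#' @param bead_diameter Lennard-Jones bead diameter (sigma) in Angstrom.
#' @param eps0 Maximum attraction depth (kT) for a fully hydrophobic pair.
#' @param contact_eps Energy scale (kT) of one unit of solution repulsion
#'   per contact: `W_solv = -lambda * contact_eps * n_contacts`. Matched to
#'   `eps0` by default so the solution axis perturbs on the same scale as
#'   the intrinsic attractions and the compaction response is graded rather
#'   than an all-or-none collapse at the first non-zero lambda.
#'
#' @return A `chain_model` list.
#' @export
chain_model <- function(sequence, bond_length = 3.8, bead_diameter = 4.5,
                        eps0 = 0.2, contact_eps = 0.2) {
  residues <- assert_protein_sequence(sequence, min_length = 3L)
  structure(
    list(sequence = sequence,
         charges = as.numeric(residue_charges(residues)),
         hydropathy = unname((KYTE_DOOLITTLE[residues] + 4.5) / 9),
         bond_length = bond_length, bead_diameter = bead_diameter,
         eps0 = eps0, contact_eps = contact_eps, n_beads = length(residues)),
    class = "chain_model"
  )
}

#' Solution condition for a chain scan
#'
#' `lambda_repulsion` is the dimensionless strength with which the solution
#' repels the chain from itself — operationally, every non-bonded bead
#' contact (distance < 1.5 bead diameters) is rewarded by `-lambda` kT, so
#' stronger solution repulsion of the chain drives compaction. `lambda = 0`
#' is the reference, most-expanding condition. Electrostatics are screened
#' Debye-Hueckel with Bjerrum length 7.1 A (water, 298 K) and a default
#' Debye length of 10 A (about 150 mM monovalent salt).
#'
#' @param lambda_repulsion Non-negative contact reward in kT.
#' @param debye_length Debye screening length in Angstrom.
#' @param bjerrum_length Bjerrum length in Angstrom.
#'
#' @return A `solution_condition` list.
#' @export
solution_condition <- function(lambda_repulsion = 0, debye_length = 10,
                               bjerrum_length = 7.1) {
  assert_scalar_number(lambda_repulsion, "lambda_repulsion", lower = 0)
  assert_scalar_number(debye_length, "debye_length", lower = 0, strict_lower = TRUE)
  structure(
    list(lambda_repulsion = lambda_repulsion, debye_length = debye_length,
         bjerrum_length = bjerrum_length, temperature = 1),
    class = "solution_condition"
  )
}

#' Energy breakdown of a chain conformation
#'
#' Evaluates `E_total = W_solv + U_lj + W_el` (kT units) for one
#' conformation: `U_lj` the excluded-volume core plus hydropathy-scaled
#' Lennard-Jones attraction over non-bonded pairs, `W_el` the
#' Debye-Hueckel energy `q_i q_j l_B exp(-r/kappa_D)/r` over charged
#' pairs, and `W_solv = -lambda * contact_eps * n_contacts` the
#' solution-repulsion stand-in (a contact is a non-bonded pair closer than
#' 1.5 bead diameters).
#'
#' @param conformation Numeric n x 3 matrix of bead coordinates (A).
#' @param model A [chain_model()].
#' @param condition A [solution_condition()].
#'
#' @return A one-row tibble with `total`, `w_solv`, `u_lj`, `w_el`,
#'   `n_contacts`.
#' @export
chain_energy <- function(conformation, model, condition) {
  stopifnot(inherits(model, "chain_model"), inherits(condition, "solution_condition"))
  conformation <- as.matrix(conformation)
  if (nrow(conformation) != model$n_beads || ncol(conformation) != 3L) {
    abort("conformation must be an n_beads x 3 coordinate matrix.",
          class = "osmofret_geometry_error")
  }
  bond_r <- sqrt(rowSums((conformation[-1, , drop = FALSE] -
                            conformation[-nrow(conformation), , drop = FALSE])^2))
  if (any(bond_r < 1e-6)) {
    abort("bonded beads overlap; invalid conformation.",
          class = "osmofret_geometry_error")
  }
  e <- chain_energy_cpp(conformation, model$charges, model$hydropathy,
                        condition$lambda_repulsion * model$contact_eps,
                        condition$debye_length,
                        condition$bjerrum_length, model$eps0,
                        model$bead_diameter)
  tibble(total = e$total, w_solv = e$w_solv, u_lj = e$u_lj, w_el = e$w_el,
         n_contacts = e$n_contacts)
}

#' Radius of gyration of a conformation
#'
#' Root-mean-square distance of beads from their centroid, uniform masses.
#'
#' @param conformation Numeric n x 3 coordinate matrix (n >= 2).
#' @return Rg in the units of the coordinates.
#' @export
radius_of_gyration <- function(conformation) {
  conformation <- as.matrix(conformation)
  if (nrow(conformation) < 2L) {
    abort("at least 2 beads are required.", class = "osmofret_domain_error")
  }
  rg_cpp(conformation)
}

#' Freely jointed chain conformation
#'
#' Random-walk reference chain: `n` beads joined by bonds of fixed length
#' in uniformly random directions. Used as the ideal-chain baseline whose
#' ensemble obeys `<Rg^2> = (b^2/6) (n^2 - 1)/n`.
#'
#' @param n Number of beads.
#' @param bond_length Bond length.
#' @param seed Integer seed.
#'
#' @return An n x 3 coordinate matrix.
#' @export
fjc_chain <- function(n, bond_length = 3.8, seed = 1L) {
  n <- assert_count(n, "n", lower = 2L)
  with_local_seed(seed, {
    z <- runif(n - 1L, -1, 1)
    phi <- runif(n - 1L, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    steps <- bond_length * cbind(r * cos(phi), r * sin(phi), z)
    rbind(0, apply(steps, 2, cumsum))
  })
}

#' Metropolis Monte Carlo sampling of a chain ensemble
#'
#' Samples conformations at kT = 1 with pivot and crankshaft moves (both
#' bond-length preserving), starting each of `n_repeats` independent
#' repeats from a distinct random freely jointed conformation. Snapshots
#' of the radius of gyration are recorded every `snapshot_every` proposals
#' after `equil` equilibration steps. The incremental energy bookkeeping is
#' checked against full recomputation every 1000 steps and the maximum
#' drift reported.
#'
#' @param model A [chain_model()].
#' @param condition A [solution_condition()].
#' @param steps Monte Carlo proposals per repeat (after which sampling stops).
#' @param equil Equilibration proposals discarded before snapshots.
#' @param snapshot_every Proposal interval between Rg snapshots.
#' @param n_repeats Independent repeats (5 by convention).
#' @param seed Integer seed; repeat seeds are derived from it.
#'
#' @return A list of class `chain_ensemble`: `rg` (tibble with `repeat_id`,
#'   `snapshot`, `rg`), `repeat_means`, `acceptance_rates`,
#'   `max_energy_drift`, `final_conformations`.
#' @export
mc_sample_ensemble <- function(model, condition, steps = 1e5, equil = 2e4,
                               snapshot_every = 125, n_repeats = 5, seed = 1L) {
  stopifnot(inherits(model, "chain_model"), inherits(condition, "solution_condition"))
  steps <- assert_count(steps, "steps", lower = 1L)
  equil <- assert_count(equil, "equil", lower = 0L)
  if (steps <= equil) {
    abort("`steps` must exceed `equil`.", class = "osmofret_invalid_parameter")
  }
  n_repeats <- assert_count(n_repeats, "n_repeats", lower = 1L)
  seed <- assert_count(seed, "seed")

  runs <- purrr::map(seq_len(n_repeats), function(rep) {
    rep_seed <- (seed * 1009L + rep * 7919L) %% .Machine$integer.max
    mc_run_cpp(model$charges, model$hydropathy,
               condition$lambda_repulsion * model$contact_eps,
               condition$debye_length,
               condition$bjerrum_length, model$eps0, model$bead_diameter,
               model$bond_length, steps, equil, snapshot_every, 1000L,
               as.integer(rep_seed))
  })
  rg <- purrr::imap_dfr(runs, function(run, rep) {
    tibble(repeat_id = rep, snapshot = seq_along(run$rg), rg = run$rg)
  })
  structure(
    list(
      rg = rg,
      repeat_means = vapply(runs, function(r) mean(r$rg), 0),
      acceptance_rates = vapply(runs, function(r) r$acceptance_rate, 0),
      max_energy_drift = max(vapply(runs, function(r) r$max_energy_drift, 0)),
      final_conformations = purrr::map(runs, "final_coords"),
      condition = condition, model = model
    ),
    class = "chain_ensemble"
  )
}

#' Solution-space scan of a chain's compaction sensitivity
#'
#' Samples the chain ensemble at every solution-repulsion level in
#' `lambda_grid` (which must include the reference 0), summarizes the mean
#' and SD of Rg over the independent repeats (SD across repeat means), and
#' normalizes each condition's mean Rg by the most expanding condition so
#' `normalized_rg <= 1` with equality where the chain is most expanded.
#' The scalar sensitivity is `1 - min(normalized_rg)`: the fractional Rg
#' compression the solution scan can induce.
#'
#' @param model A [chain_model()].
#' @param lambda_grid Solution-repulsion levels; must contain 0.
#' @param debye_length Debye length passed to every condition.
#' @param steps,equil,snapshot_every,n_repeats,seed Sampling protocol, as
#'   in [mc_sample_ensemble()].
#'
#' @return A tibble of class `scan_result` with one row per condition:
#'   `lambda`, `mean_rg`, `sd_rg`, `normalized_rg`; the scalar
#'   `sensitivity` and the protocol are attached as attributes.
#' @export
solution_scan <- function(model, lambda_grid = c(0, 1, 2, 4, 8),
                          debye_length = 10, steps = 1e5, equil = 2e4,
                          snapshot_every = 125, n_repeats = 5, seed = 1L) {
  if (length(lambda_grid) < 2L) {
    abort("a single condition cannot define a sensitivity; provide a grid.",
          class = "osmofret_invalid_parameter")
  }
  if (!0 %in% lambda_grid) {
    abort("`lambda_grid` must include the reference condition 0.",
          class = "osmofret_invalid_parameter")
  }
  lambda_grid <- sort(unique(lambda_grid))
  rows <- purrr::map_dfr(seq_along(lambda_grid), function(i) {
    ens <- mc_sample_ensemble(
      model, solution_condition(lambda_grid[i], debye_length),
      steps = steps, equil = equil, snapshot_every = snapshot_every,
      n_repeats = n_repeats, seed = seed + i - 1L)
    tibble(lambda = lambda_grid[i],
           mean_rg = mean(ens$repeat_means),
           sd_rg = sd(ens$repeat_means))
  })
  rows <- dplyr::mutate(rows, normalized_rg = .data$mean_rg / max(.data$mean_rg))
  out <- structure(rows, class = c("scan_result", class(tibble())))
  attr(out, "sensitivity") <- 1 - min(rows$normalized_rg)
  attr(out, "protocol") <- list(steps = steps, equil = equil,
                                snapshot_every = snapshot_every,
                                n_repeats = n_repeats, seed = seed)
  out
}

#' Sensitivity of a finished scan
#'
#' @param scan A [solution_scan()] result.
#' @return `1 - min(normalized_rg)`.
#' @export
scan_sensitivity <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  attr(scan, "sensitivity")
}
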