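#' Energy weights for the coarse-grained tail score
#'
#' The sampling score is a documented coarse-grained surrogate combining a
#' soft-sphere clash penalty, Debye-screened electrostatics between charged
#' residue classes, and flat-harmonic crosslink restraints:
#' `E = w_clash sum_{d<dmin, |i-j|>1} (dmin-d)^2
#'    + w_elec sum q_i q_j exp(-d/lambda)/d + w_xl sum f(d)`.
#' The selection cascade treats the energy only as a sortable score.
#'
#' @param w_clash,w_elec,w_xl non-negative term weights (defaults 1)
#' @param clash_dmin clash onset distance, Angstrom (default 4)
#' @param screening_length Debye screening length lambda, Angstrom
#'   (default 10)
#' @return list of class `energy_weights`
#' @export
energy_weights <- function(w_clash = 1, w_elec = 1, w_xl = 1,
                           clash_dmin = 4, screening_length = 10) {
  if (any(c(w_clash, w_elec, w_xl) < 0)) stop("weights must be non-negative")
  structure(list(w_clash = w_clash, w_elec = w_elec, w_xl = w_xl,
                 clash_dmin = clash_dmin,
                 screening_length = screening_length),
            class = "energy_weights")
}

#' Two-stage annealing schedule for tail sampling
#'
#' Stage 1 applies large pivot rotations under geometric cooling from
#' `T_start` to `T_end` (the coarse collapse phase); stage 2 applies small
#' pivots at `T_end` followed by greedy per-pivot line-search minimization
#' (the refinement phase).
#'
#' @param stage1_steps,stage2_steps Monte-Carlo steps per stage
#' @param T_start,T_end dimensionless temperatures (T_start >= T_end > 0)
#' @param stage1_max_angle,stage2_max_angle pivot amplitude, degrees
#' @param n_scramble forced random pivots applied before stage 1 so that
#'   sampling does not remember the start conformation
#' @param minimize_sweeps greedy minimization sweeps after stage 2
#' @return list of class `anneal_schedule`
#' @export
anneal_schedule <- function(stage1_steps = 2000, stage2_steps = 1000,
                            T_start = 5, T_end = 0.2,
                            stage1_max_angle = 60, stage2_max_angle = 10,
                            n_scramble = 50, minimize_sweeps = 2) {
  if (!(T_start >= T_end && T_end > 0))
    stop("need T_start >= T_end > 0")
  structure(list(stage1_steps = as.integer(stage1_steps),
                 stage2_steps = as.integer(stage2_steps),
                 T_start = T_start, T_end = T_end,
                 stage1_max_angle = stage1_max_angle,
                 stage2_max_angle = stage2_max_angle,
                 n_scramble = as.integer(n_scramble),
                 minimize_sweeps = as.integer(minimize_sweeps)),
            class = "anneal_schedule")
}

# resolve crosslinks + params into 0-based CA row indices and per-link
# flat-harmonic parameters
.link_spec <- function(structure, restraints,
                       params = flat_harmonic_params()) {
  ca <- ca_coords(structure)
  if (is.null(restraints) || nrow(restraints) == 0L)
    return(list(idx = matrix(integer(0), 0, 2), edge = numeric(0),
                sigma = numeric(0)))
  k1 <- paste0(restraints$chain1, ":", restraints$res1)
  k2 <- paste0(restraints$chain2, ":", restraints$res2)
  missing <- setdiff(unique(c(k1, k2)), rownames(ca))
  if (length(missing))
    stop("restraint to missing residue: ", paste(missing, collapse = ", "))
  list(idx = cbind(match(k1, rownames(ca)), match(k2, rownames(ca))) - 1L,
       edge = rep(params$x0 + params$tolerance, length(k1)),
       sigma = rep(params$sigma, length(k1)))
}

#' Coarse-grained tail energy with per-term breakdown
#'
#' Evaluates the sampling score of a conformation (see
#' [energy_weights()]): soft-sphere clashes over nonadjacent Ca pairs,
#' screened electrostatics between charged residue classes, and
#' flat-harmonic crosslink restraints.
#'
#' @param structure structure3d (Ca sites, single chain)
#' @param restraints `crosslinks` table (targets only) or NULL
#' @param weights [energy_weights()]
#' @param xl_params [flat_harmonic_params()]
#' @param charges per-residue charges; default [residue_charges()]
#' @return list: `clash`, `elec`, `xl`, `total`
#' @export
tail_energy <- function(structure, restraints = NULL,
                        weights = energy_weights(),
                        xl_params = flat_harmonic_params(),
                        charges = residue_charges(structure)) {
  ca <- ca_coords(structure)
  ls <- .link_spec(structure, restraints, xl_params)
  .tail_energy_cpp(ca, as.numeric(charges[rownames(ca)]),
                   ls$idx, ls$edge, ls$sigma,
                   weights$w_clash, weights$w_elec, weights$w_xl,
                   weights$clash_dmin, weights$screening_length)
}

# candidate pivot rows (0-based) for a tail on a rigid core: the core
# anchor residue and every tail residue except the last, excluding the
# interiors of rigid helix segments
.pivot_rows <- function(structure, tail_res, helix_ranges) {
  ca <- ca_coords(structure)
  res <- as.integer(sub("^.*:", "", rownames(ca)))
  tail_rows <- which(res %in% tail_res)
  if (length(tail_rows) < 3L) stop("tail length must be >= 3")
  anchor <- min(tail_rows) - 1L
  cand <- c(anchor, tail_rows[-length(tail_rows)])
  in_helix_interior <- rep(FALSE, length(cand))
  for (h in helix_ranges) {
    hr <- range(h)
    in_helix_interior <- in_helix_interior |
      (res[cand] >= hr[1] & res[cand] < hr[2])
  }
  sort(cand[!in_helix_interior]) - 1L
}

#' Sample tail conformations under crosslink restraints
#'
#' Generates `n_models` independent conformations of a flexible tail
#' attached to a rigid core, each by two-stage simulated annealing of pivot
#' moves (see [anneal_schedule()]) under the coarse-grained energy (see
#' [energy_weights()]). Model `m` uses seed `base_seed + m`, so any single
#' model is bitwise reproducible in isolation. Pivot moves preserve virtual
#' bond lengths exactly, the core never moves, and helix segments move only
#' as rigid bodies.
#'
#' @param start structure3d: core plus tail in its start conformation
#' @param tail_res integer residue numbers of the movable tail
#' @param restraints `crosslinks` table used as flat-harmonic restraints
#' @param n_models number of models
#' @param base_seed integer base seed
#' @param schedule [anneal_schedule()]
#' @param weights [energy_weights()]
#' @param xl_params [flat_harmonic_params()]
#' @param helix_ranges list of residue-number ranges kept rigidly helical
#' @return list of `sample_result`: each has `model_id`, `structure`,
#'   `energy`, `accepted_moves`, `seed_used`
#' @export
sample_tail <- function(start, tail_res, restraints = NULL, n_models = 200,
                        base_seed = 1, schedule = anneal_schedule(),
                        weights = energy_weights(),
                        xl_params = flat_harmonic_params(),
                        helix_ranges = list()) {
  if (n_models < 1) stop("n_models must be >= 1")
  ca <- ca_coords(start)
  charges <- residue_charges(start)[rownames(ca)]
  ls <- .link_spec(start, restraints, xl_params)
  pivots <- .pivot_rows(start, tail_res, helix_ranges)
  ca_atom_rows <- which(start$atoms$name == "CA")
  lapply(seq_len(n_models), function(m) {
    seed <- base_seed + m
    res <- .with_seed(seed, {
      .sample_tail_cpp(ca, pivots, as.numeric(charges), ls$idx, ls$edge,
                       ls$sigma, weights$w_clash, weights$w_elec,
                       weights$w_xl, weights$clash_dmin,
                       weights$screening_length,
                       schedule$stage1_steps, schedule$stage2_steps,
                       schedule$T_start, schedule$T_end,
                       schedule$stage1_max_angle * pi / 180,
                       schedule$stage2_max_angle * pi / 180,
                       schedule$n_scramble, schedule$minimize_sweeps)
    })
    s <- start
    s$atoms[ca_atom_rows, c("x", "y", "z")] <- res$coords
    s$title <- sprintf("sampled tail model %d", m)
    structure(list(model_id = as.integer(m), structure = s,
                   energy = res$energy,
                   accepted_moves = as.integer(res$accepted),
                   seed_used = as.integer(seed)),
              class = "sample_result")
  })
}
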