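# Synthetic-data generators: every input class the pipeline consumes, with
# known ground truth. All generators are pure functions of their parameters
# and seed (RNG state is saved and restored around each call).

.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.unit <- function(v) v / sqrt(sum(v^2))

# virtual-bond helix: rise 1.5 A and 100 deg per residue about the axis;
# the radius is fixed so that consecutive Ca-Ca chords are exactly 3.8 A
.helix_radius <- function(bond = 3.8, rise = 1.5, omega = 100 * pi / 180) {
  sqrt(bond^2 - rise^2) / (2 * sin(omega / 2))
}

# n points of an ideal helix whose first point is `first`, axis `axis`
# (unit), phase phi measured in the (e1, e2) plane perpendicular to axis
.helix_points <- function(n, first, axis, phi = 0, rise = 1.5,
                          omega = 100 * pi / 180) {
  a <- .unit(axis)
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(ref - sum(ref * a) * a)
  e2 <- .crossp(a, e1)
  r <- .helix_radius()
  k <- seq_len(n) - 1
  local <- cbind(r * cos(omega * k + phi), r * sin(omega * k + phi),
                 rise * k)
  pts <- local[, 1, drop = FALSE] %*% t(e1) +
    local[, 2, drop = FALSE] %*% t(e2) +
    local[, 3, drop = FALSE] %*% t(a)
  sweep(pts, 2, pts[1, ] - first, "-")
}

.crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.rot_about <- function(axis, theta) {
  a <- .unit(axis)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# equal-length chain bridge (inverse kinematics): n chords of length 3.8
# from `from` to exactly `to`, with the elbow pushed along `hint`;
# returns an n x 3 chord matrix (deterministic)
.bridge_chords <- function(from, to, n, hint, bond = 3.8) {
  gap <- to - from
  d <- sqrt(sum(gap^2))
  if (d > n * bond + 1e-9)
    stop(sprintf("bridge of %d chords cannot span %.2f A", n, d))
  if (n == 1L) {
    if (abs(d - bond) > 1e-6) stop("1-chord bridge must span exactly 3.8 A")
    return(matrix(gap, 1, 3))
  }
  perp <- hint - sum(hint * gap) / sum(gap^2) * gap
  if (sqrt(sum(perp^2)) < 1e-8) perp <- .crossp(gap, c(0, 0, 1))
  perp <- .unit(perp)
  if (n == 2L) {
    h <- sqrt(max(bond^2 - (d / 2)^2, 0))
    apex <- from + gap / 2 + h * perp
    return(rbind(apex - from, to - apex))
  }
  # n == 3: take one step biased along the elbow hint, then a 2-chord bridge
  for (w in seq(1.2, 0, by = -0.05)) {
    dir <- .unit(.unit(gap) + w * perp)
    t1 <- from + bond * dir
    d2 <- sqrt(sum((to - t1)^2))
    if (d2 <= 2 * bond - 1e-6 && d2 > 0.3)
      return(rbind(t1 - from, .bridge_chords(t1, to, 2L, hint, bond)))
  }
  stop("3-chord bridge construction failed")
}

# chord directions (unit step vectors scaled to 3.8) of one repeat template:
# an 8-residue helix h1 running perpendicular to an antiparallel helical
# hairpin (h2 up, h3 down), with hairpin turn and inter-repeat linker
# residues bridging exactly. Returns a 32 x 3 chord matrix; chord k leads
# from residue k to residue k+1 (chord 32 to the next repeat's residue 1).
.repeat_template <- function(advance = c(12.2, 5.6, 0)) {
  bond <- 3.8
  chord <- function(pts) diff(pts)
  p0 <- c(0, 0, -5.5)
  h1 <- .helix_points(8, p0, axis = c(1, 0, 0), phi = 1.8)
  e1 <- h1[8, ]
  h2_first <- e1 + bond * .unit(c(0.55, 0.15, 1.15))
  h2 <- .helix_points(11, h2_first, axis = c(0, 0, 1), phi = pi)
  e2 <- h2[11, ]
  h3_first <- e2 + c(0, 8.0, -0.5)
  turn <- .bridge_chords(e2, h3_first, 3L, hint = c(0, 1.2, 1))
  h3 <- .helix_points(9, h3_first, axis = c(0, 0, -1), phi = 0.6)
  e3 <- h3[9, ]
  closure <- .bridge_chords(e3, p0 + advance, 3L, hint = c(-1.2, 0.2, -0.3))
  rbind(chord(h1),   # 7 chords, residues 1-8
        h2_first - e1,
        chord(h2),   # 10 chords, residues 9-19
        turn,        # 3 chords, turn residues 20-21
        chord(h3),   # 8 chords, residues 22-30
        closure)     # 3 chords, linker residues 31-32 -> next repeat
}

#' Build a rigid helical-repeat core
#'
#' A Ca-only model of a solenoid of `n_repeats` repeats, each one an
#' 8-residue helix (h1) running perpendicular to a 12+12-residue
#' antiparallel helical hairpin (h2, h3), stacked along a right-handed
#' superhelical path. Helix geometry is ideal (1.5 A rise, 100 deg per
#' residue about the axis) and every consecutive Ca-Ca virtual bond is
#' exactly 3.8 A. Every 6th residue is a designated lysine-surrogate
#' crosslinking site; the surrogates on the last repeat form the charged
#' basic patch (ARG residue name) and all other residues are neutral ALA.
#' The construction is deterministic; the seed is recorded but does not
#' influence coordinates.
#'
#' @param n_repeats number of repeats (>= 1)
#' @param seed recorded for provenance
#' @return structure3d with `32 * n_repeats` residues in chain A
#' @export
build_core <- function(n_repeats = 8, seed = 1) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  template <- .repeat_template()
  # right-handed superhelical screw: advance along +x with a twist about x
  R <- .rot_about(c(1, 0, 0), 16 * pi / 180)
  n_res <- 32L * n_repeats
  pts <- matrix(0, n_res, 3)
  dirs <- template
  pos <- c(0, 0, 0)
  k <- 1L
  pts[1, ] <- pos
  for (rep_i in seq_len(n_repeats)) {
    for (j in seq_len(32L)) {
      if (k == n_res) break
      pos <- pos + dirs[j, ]
      k <- k + 1L
      pts[k, ] <- pos
    }
    dirs <- dirs %*% t(R)
  }
  res_num <- seq_len(n_res)
  # crosslinkable lysine surrogates sit at every 6th residue; the basic
  # patch is a spatially compact Arg cluster near the C-terminal end of
  # the solenoid (surrogates within 12 A of the one closest to the
  # C-terminus), mimicking a coherent charged surface patch rather than a
  # diffuse ring of charges
  res_name <- rep("ALA", n_res)
  surr <- which(res_num %% 6L == 0L & res_num > n_res - 64L)
  if (length(surr)) {
    seedr <- surr[length(surr)]
    d2seed <- sqrt(rowSums(sweep(pts[surr, , drop = FALSE], 2,
                                 pts[seedr, ])^2))
    res_name[surr[order(d2seed)][seq_len(min(4L, length(surr)))]] <- "ARG"
  }
  atoms <- data.frame(serial = res_num, name = "CA", element = "C",
                      res_name = res_name, chain_id = "A",
                      res_num = res_num,
                      x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      stringsAsFactors = FALSE)
  out <- structure3d(atoms, title = sprintf("synthetic %d-repeat core",
                                            n_repeats))
  attr(out, "seed") <- seed
  out
}

.aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")

#' Per-residue charge classes of a structure
#'
#' +1 for Arg/Lys, -1 for Asp/Glu, 0 otherwise, taken per CA site.
#'
#' @param structure structure3d
#' @return named numeric vector (addresses as in [ca_coords()])
#' @export
residue_charges <- function(structure) {
  a <- structure$atoms[structure$atoms$name == "CA", ]
  q <- ifelse(a$res_name %in% c("ARG", "LYS"), 1,
              ifelse(a$res_name %in% c("ASP", "GLU"), -1, 0))
  stats::setNames(q, paste0(a$chain_id, ":", a$res_num))
}

#' Default flexible-tail sequence used by the packaged synthetic system
#'
#' 30 residues with an acidic stretch (EDEDTDTDE-like) in its first half
#' and lysines in the distal half, mimicking a charged disordered tail.
#' @return character scalar of 1-letter codes
#' @export
default_tail_sequence <- function() {
  "SGSAGAEDEDTDTDEGSGKSAGAGKGSGAL"
}

# smallest distance between nonadjacent Ca pairs (chain order = row order)
.min_nonadjacent <- function(pts) {
  D <- as.matrix(stats::dist(pts))
  n <- nrow(D)
  diag(D) <- Inf
  D[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- Inf
  D[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- Inf
  min(D)
}

# pivot-space minimization of the grown tail under clash + electrostatics
# (no restraints); clash onset padded to 4.3 A so settled pairs stay >= 4
.relax_truth <- function(core, tail_pts, seq1, helix_ranges, n_core) {
  tail_res <- n_core + seq_along(seq1)
  atoms_tail <- data.frame(serial = tail_res, name = "CA", element = "C",
                           res_name = unname(.aa3[seq1]),
                           chain_id = "A", res_num = tail_res,
                           x = tail_pts[, 1], y = tail_pts[, 2],
                           z = tail_pts[, 3], stringsAsFactors = FALSE)
  s <- structure3d(rbind(core$atoms, atoms_tail))
  ca <- ca_coords(s)
  charges <- residue_charges(s)[rownames(ca)]
  hr <- lapply(helix_ranges, function(h) n_core + h[1]:h[2])
  pivots <- .pivot_rows(s, tail_res, hr)
  res <- .sample_tail_cpp(ca, pivots, as.numeric(charges),
                          matrix(integer(0), 0, 2), numeric(0), numeric(0),
                          1, 1, 0, 4.3, 10,
                          0L, 0L, 1, 0.2, 0, 10 * pi / 180, 0L, 4L)
  res$coords
}

#' Attach a flexible tail in a known ("truth") docked conformation
#'
#' Grows a Ca tail residue-by-residue from the core C-terminus with 3.8 A
#' virtual bonds and clash avoidance (no nonadjacent Ca pair under 4 A),
#' biasing the acidic stretch of the sequence toward the core's basic
#' surface patch so that, in the recorded truth conformation, the acidic
#' stretch docks on the patch (centroid within 12 A). Helix ranges are
#' placed as rigid ideal helices. The grown conformation is then settled
#' into a nearby local minimum of the coarse-grained clash+electrostatics
#' energy (pivot-space line-search minimization), so that the recorded
#' truth is consistent with the energy model used for sampling, as a
#' native conformation would be.
#'
#' @param core structure3d from [build_core()]
#' @param tail_sequence 1-letter codes (default [default_tail_sequence()])
#' @param helix_ranges list of `c(from, to)` positions within the tail kept
#'   helical (1-based along the tail); NULL for fully coil
#' @param seed integer seed
#' @param max_attempts growth restarts before giving up
#' @return list of class `synthetic_system`: `core`, `tail_truth`
#'   (core+tail structure3d), `basic_patch` (addresses), `acidic_stretch`
#'   (addresses), `tail_res` (residue numbers of the tail), `helix_ranges`
#'   (residue numbers), `truth_params`
#' @export
attach_truth_tail <- function(core, tail_sequence = default_tail_sequence(),
                              helix_ranges = NULL, seed = 1,
                              max_attempts = 40) {
  seq1 <- strsplit(tail_sequence, "")[[1]]
  n_tail <- length(seq1)
  if (n_tail < 3L) stop("tail must have >= 3 residues")
  core_xyz <- ca_coords(core)
  n_core <- nrow(core_xyz)
  core_centroid <- colMeans(core_xyz)
  # basic patch: the charged (Arg) surface cluster defined by the core
  core_ca <- core$atoms[core$atoms$name == "CA", ]
  patch_res <- core_ca$res_num[core_ca$res_name %in% c("ARG", "LYS")]
  if (length(patch_res) == 0L)
    stop("core carries no basic patch (no Arg/Lys residues)")
  patch_centroid <- colMeans(core_xyz[paste0("A:", patch_res), , drop = FALSE])
  # dock target sits just outside the patch, away from the core interior
  outward <- .unit(patch_centroid - core_centroid)
  target <- patch_centroid + 5 * outward
  acidic_pos <- which(seq1 %in% c("D", "E"))
  helix_mask <- rep(FALSE, n_tail)
  for (h in helix_ranges) helix_mask[h[1]:h[2]] <- TRUE
  bond <- 3.8
  grown <- .with_seed(seed, {
    result <- NULL
    for (attempt in seq_len(max_attempts)) {
      pts <- matrix(NA_real_, n_tail, 3)
      prev <- core_xyz[n_core, ]
      prev_dir <- .unit(prev - core_xyz[n_core - 1, ])
      all_pts <- core_xyz
      ok <- TRUE
      i <- 1L
      while (i <= n_tail) {
        if (helix_mask[i]) {
          j <- i
          while (j < n_tail && helix_mask[j + 1L]) j <- j + 1L
          placed <- FALSE
          for (try in 1:60) {
            axis <- .unit(prev_dir + 0.7 * matrix(stats::rnorm(3), 1)[1, ])
            first <- prev + bond * .unit(axis + 0.3 * stats::rnorm(3))
            hp <- .helix_points(j - i + 1L, first, axis,
                                phi = stats::runif(1, 0, 2 * pi))
            cand <- rbind(all_pts, pts[seq_len(i - 1L), , drop = FALSE])
            cand <- cand[stats::complete.cases(cand), , drop = FALSE]
            # first helix residue is bonded to `prev`: exclude that pair
            cand_np <- cand[-nrow(cand), , drop = FALSE]
            d1 <- if (nrow(cand_np)) min(rowSums(sweep(cand_np, 2,
                                                       hp[1, ])^2)) else Inf
            drest <- if (nrow(hp) > 1L)
              min(apply(hp[-1, , drop = FALSE], 1, function(p)
                min(rowSums(sweep(cand, 2, p)^2))))
            else Inf
            if (min(d1, drest) >= 16) { placed <- TRUE; break }
          }
          if (!placed) { ok <- FALSE; break }
          pts[i:j, ] <- hp
          prev <- hp[nrow(hp), ]
          prev_dir <- .unit(hp[nrow(hp), ] - hp[max(nrow(hp) - 1, 1), ])
          i <- j + 1L
          next
        }
        # coil residue: persistent direction plus docking bias
        bias_w <- if (length(acidic_pos) && i <= max(acidic_pos)) 1.2 else 0.15
        placed <- FALSE
        for (try in 1:80) {
          noise <- stats::rnorm(3, sd = 0.8)
          dir <- .unit(0.8 * prev_dir + bias_w * .unit(target - prev) + noise)
          cand_pt <- prev + bond * dir
          prior <- rbind(all_pts, pts[seq_len(i - 1L), , drop = FALSE])
          prior <- prior[stats::complete.cases(prior), , drop = FALSE]
          # exclude the bonded neighbor (the immediately previous residue)
          d2 <- rowSums(sweep(prior, 2, cand_pt)^2)
          d2 <- d2[-length(d2)]
          if (length(d2) == 0L || min(d2) >= 16) {
            pts[i, ] <- cand_pt
            prev_dir <- dir
            prev <- cand_pt
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
        i <- i + 1L
      }
      if (!ok) next
      # settle into a nearby local minimum of the clash+elec energy; the
      # clash onset is padded so minimized pairs stay clear of 4 A
      relaxed <- .relax_truth(core, pts, seq1, helix_ranges, n_core)
      if (length(acidic_pos)) {
        ac_centroid <- colMeans(relaxed[n_core + acidic_pos, , drop = FALSE])
        if (sqrt(sum((ac_centroid - patch_centroid)^2)) >= 12) next
      }
      if (.min_nonadjacent(relaxed) < 4) next
      result <- relaxed[n_core + seq_len(n_tail), , drop = FALSE]
      break
    }
    result
  })
  if (is.null(grown))
    stop("tail growth failed after ", max_attempts,
         " attempts; try a different seed")
  tail_res <- n_core + seq_len(n_tail)
  atoms_tail <- data.frame(serial = tail_res, name = "CA", element = "C",
                           res_name = unname(.aa3[seq1]),
                           chain_id = "A", res_num = tail_res,
                           x = grown[, 1], y = grown[, 2], z = grown[, 3],
                           stringsAsFactors = FALSE)
  tail_truth <- structure3d(rbind(core$atoms, atoms_tail),
                            title = paste0(core$title, " + tail (truth)"))
  out <- list(core = core, tail_truth = tail_truth,
              basic_patch = paste0("A:", patch_res),
              acidic_stretch = paste0("A:", n_core + acidic_pos),
              tail_res = tail_res,
              helix_ranges = lapply(helix_ranges, function(h)
                n_core + h[1]:h[2]),
              truth_params = list(seed = seed,
                                  tail_sequence = tail_sequence,
                                  helix_ranges = helix_ranges,
                                  n_core = n_core))
  class(out) <- "synthetic_system"
  out
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat(sprintf("synthetic_system: %d core + %d tail residues, patch {%s}\n",
              x$truth_params$n_core, length(x$tail_res),
              paste(x$basic_patch, collapse = ",")))
  invisible(x)
}

#' Replace the truth tail with an extended, undocked conformation
#'
#' A deterministic tail pointing away from the core centroid (straight
#' virtual-bond chain, with any helix ranges placed as ideal helices along
#' the same direction), used as the sampling start so that sampling does
#' not begin at the truth.
#'
#' @param system `synthetic_system`
#' @return structure3d (core + extended tail)
#' @export
extended_start <- function(system) {
  core_xyz <- ca_coords(system$core)
  n_core <- nrow(core_xyz)
  anchor <- core_xyz[n_core, ]
  dir <- .unit(anchor - colMeans(core_xyz))
  n_tail <- length(system$tail_res)
  helix_mask <- rep(FALSE, n_tail)
  for (h in system$helix_ranges)
    helix_mask[match(h, system$tail_res)] <- TRUE
  pts <- matrix(NA_real_, n_tail, 3)
  prev <- anchor
  i <- 1L
  while (i <= n_tail) {
    if (helix_mask[i]) {
      j <- i
      while (j < n_tail && helix_mask[j + 1L]) j <- j + 1L
      hp <- .helix_points(j - i + 1L, prev + 3.8 * dir, axis = dir)
      pts[i:j, ] <- hp
      prev <- hp[nrow(hp), ]
      i <- j + 1L
    } else {
      pts[i, ] <- prev + 3.8 * dir
      prev <- pts[i, ]
      i <- i + 1L
    }
  }
  s <- system$tail_truth
  idx <- which(s$atoms$res_num %in% system$tail_res)
  s$atoms[idx, c("x", "y", "z")] <- pts
  s$title <- paste0(system$core$title, " + tail (extended start)")
  s
}

#' Simulate DSS crosslink identifications on a synthetic system
#'
#' True links are sampled among designated lysine-surrogate pairs whose
#' truth-conformation Ca-Ca distance is at most `max_true_dist` and that
#' bridge the core and the tail (so each link restrains the tail position);
#' decoys among pairs farther apart than 40 A. True scores are
#' Uniform(20, 40) and decoy scores Uniform(0, 20): disjoint by default.
#'
#' @param system `synthetic_system`
#' @param n_true number of true (target) records
#' @param n_decoy number of decoy records
#' @param max_true_dist geometric cap for true links, Angstrom (default 24,
#'   the DSS spacer plus two lysine side chains)
#' @param seed integer seed
#' @return `crosslinks` table
#' @export
simulate_crosslinks <- function(system, n_true, n_decoy = 0,
                                max_true_dist = 24, seed = 1) {
  s <- system$tail_truth
  ca <- ca_coords(s)
  res <- s$atoms$res_num[s$atoms$name == "CA"]
  is_lys <- s$atoms$res_name[s$atoms$name == "CA"] == "LYS" |
    res %% 6L == 0L
  sites <- which(is_lys)
  if (length(sites) < 2L) stop("not enough lysine-surrogate sites")
  pr <- t(utils::combn(sites, 2L))
  d <- sqrt(rowSums((ca[pr[, 1], , drop = FALSE] -
                       ca[pr[, 2], , drop = FALSE])^2))
  in_tail <- matrix(res[pr] %in% system$tail_res, ncol = 2)
  # informative links bridge the rigid core and the flexible tail (as the
  # modeled lysine pairs in real tail studies do); tail-internal pairs are
  # nearly always satisfied and carry little positional information
  true_cand <- which(d <= max_true_dist & xor(in_tail[, 1], in_tail[, 2]))
  decoy_cand <- which(d > 40)
  if (length(true_cand) < n_true)
    stop("only ", length(true_cand),
         " qualifying true pairs available (need ", n_true, ")")
  if (n_decoy > 0 && length(decoy_cand) < n_decoy)
    stop("only ", length(decoy_cand), " qualifying decoy pairs available")
  .with_seed(seed, {
    # spread true links over distinct tail sites (real crosslink sets report
    # several different lysines): greedily require a new tail residue at
    # least 5 positions from those already used, falling back when exhausted
    shuffled <- sample(true_cand)
    tail_site <- ifelse(in_tail[shuffled, 1], res[pr[shuffled, 1]],
                        res[pr[shuffled, 2]])
    ti <- integer(0); used <- integer(0)
    for (ii in seq_along(shuffled)) {
      if (length(ti) == n_true) break
      if (all(abs(tail_site[ii] - used) >= 5)) {
        ti <- c(ti, shuffled[ii]); used <- c(used, tail_site[ii])
      }
    }
    if (length(ti) < n_true)
      ti <- c(ti, setdiff(shuffled, ti)[seq_len(n_true - length(ti))])
    di <- if (n_decoy > 0) sample(decoy_cand, n_decoy) else integer(0)
    idx <- c(ti, di)
    crosslinks(chain1 = "A", res1 = res[pr[idx, 1]],
               chain2 = "A", res2 = res[pr[idx, 2]],
               score = c(stats::runif(n_true, 20, 40),
                         stats::runif(n_decoy, 0, 20)),
               is_decoy = rep(c(FALSE, TRUE), c(n_true, n_decoy)))
  })
}

#' Noise specification for synthetic observables
#' @param saxs_rel_sigma relative SAXS uncertainty (default 0.02)
#' @param trace_sd additive trace noise, signal units (default 0.02)
#' @param seed integer seed
#' @return list of class `noise_spec`
#' @export
noise_spec <- function(saxs_rel_sigma = 0.02, trace_sd = 0.02, seed = 1) {
  if (saxs_rel_sigma < 0 || trace_sd < 0) stop("noise must be non-negative")
  structure(list(saxs_rel_sigma = saxs_rel_sigma, trace_sd = trace_sd,
                 seed = seed), class = "noise_spec")
}

#' Default instrument-like q grid
#' @param n number of points
#' @param q_min,q_max range, 1/Angstrom (defaults 0.004-0.388)
#' @return ascending numeric vector
#' @export
default_q_grid <- function(n = 120, q_min = 0.004, q_max = 0.388) {
  seq(q_min, q_max, length.out = n)
}

#' Simulate a SAXS curve from coordinates
#'
#' The intensity is the Debye profile of the structure; the uncertainty is
#' multiplicative, `sigma_i = saxs_rel_sigma * I_i`, and the observed
#' intensity is Gaussian around the exact profile. With zero noise the
#' exact profile is returned (with a tiny nominal sigma so the curve
#' remains valid for chi-square weighting).
#'
#' @param structure structure3d
#' @param q_grid ascending q values (default [default_q_grid()])
#' @param noise [noise_spec()]
#' @return `saxs_curve`
#' @export
simulate_saxs <- function(structure, q_grid = default_q_grid(),
                          noise = noise_spec()) {
  I0 <- debye_profile(structure, q_grid)
  eps <- noise$saxs_rel_sigma
  if (eps == 0) return(saxs_curve(q_grid, I0, 1e-6 * I0))
  sig <- eps * I0
  I <- .with_seed(noise$seed, stats::rnorm(length(I0), I0, sig))
  saxs_curve(q_grid, I, sig)
}

#' Simulate 1:1-model biolayer interferometry traces
#'
#' Per analyte concentration C the association response is
#' `R(t) = R_eq (1 - exp(-k_obs t))` with `k_obs = k_a C + k_d` and
#' `R_eq = Bmax C / (C + k_d / k_a)`; the dissociation phase decays from
#' the association endpoint with rate `k_d`. Gaussian noise of sd
#' `trace_sd` is added.
#'
#' @param k_a association rate constant, 1/M/s
#' @param k_d dissociation rate constant, 1/s
#' @param Bmax maximal response
#' @param concentrations analyte concentrations, M
#' @param t_assoc association-phase duration, s
#' @param t_dissoc dissociation-phase duration, s (0 for association only)
#' @param noise [noise_spec()]
#' @param dt sampling interval, s
#' @return `trace_table` with one column per concentration; the generator
#'   record (true `k_obs`, `R_eq` per concentration) is in the `truth`
#'   attribute
#' @export
simulate_bli <- function(k_a, k_d, Bmax, concentrations,
                         t_assoc = 120, t_dissoc = 120,
                         noise = noise_spec(), dt = 0.2) {
  if (k_a <= 0 || k_d <= 0) stop("rate constants must be positive")
  t <- seq(0, t_assoc + t_dissoc, by = dt)
  KD <- k_d / k_a
  cols <- list()
  truth <- list()
  for (C in concentrations) {
    k_obs <- k_a * C + k_d
    R_eq <- Bmax * C / (C + KD)
    R <- ifelse(t <= t_assoc,
                R_eq * (1 - exp(-k_obs * t)),
                R_eq * (1 - exp(-k_obs * t_assoc)) *
                  exp(-k_d * (t - t_assoc)))
    nm <- sprintf("C_%.3g", C)
    cols[[nm]] <- R
    truth[[nm]] <- list(conc = C, k_obs = k_obs, R_eq = R_eq)
  }
  if (noise$trace_sd > 0)
    cols <- .with_seed(noise$seed, lapply(cols, function(y)
      y + stats::rnorm(length(y), 0, noise$trace_sd)))
  out <- trace_table(t, as.data.frame(cols, check.names = FALSE),
                     conc = stats::setNames(concentrations, names(cols)))
  attr(out, "truth") <- truth
  attr(out, "t_assoc") <- t_assoc
  out
}

#' Simulate a thermal-melt (DSF-like) curve
#'
#' Boltzmann sigmoid
#' `F(T) = F_low + (F_high - F_low) / (1 + exp((Tm - T)/slope))` with
#' additive Gaussian noise.
#'
#' @param Tm midpoint, degrees C
#' @param slope transition width, degrees C (> 0)
#' @param F_low,F_high baseline and plateau fluorescence
#' @param T_grid ascending temperatures, degrees C
#' @param noise [noise_spec()]
#' @return `trace_table` with column `F` (temperature in `t`)
#' @export
simulate_melt <- function(Tm, slope, F_low = 0, F_high = 1,
                          T_grid = seq(25, 95, by = 0.5),
                          noise = noise_spec()) {
  if (slope <= 0) stop("slope must be > 0")
  F <- F_low + (F_high - F_low) / (1 + exp((Tm - T_grid) / slope))
  if (noise$trace_sd > 0)
    F <- .with_seed(noise$seed,
                    F + stats::rnorm(length(F), 0, noise$trace_sd))
  trace_table(T_grid, F = F)
}
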