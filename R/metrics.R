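#' Parameters for solvent-accessible surface area
#'
#' Shrake-Rupley quadrature settings: probe radius, number of quasi-uniform
#' sphere points, and the per-element van der Waals radii table. Structures
#' containing only CA sites use the pseudo-residue radius.
#'
#' @param probe_radius solvent probe, Angstrom (default 1.4)
#' @param n_sphere_points quadrature points per atom (default 960)
#' @param radii named per-element radii, Angstrom
#' @param ca_radius pseudo-residue radius for Ca-only models (default 3.0)
#' @return list of class `sasa_params`
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        radii = c(C = 1.7, N = 1.55, O = 1.52, S = 1.8,
                                  H = 1.2, P = 1.8),
                        ca_radius = 3.0) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_sphere_points < 60) stop("n_sphere_points must be >= 60")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points,
                 radii = radii, ca_radius = ca_radius),
            class = "sasa_params")
}

# quasi-uniform points on the unit sphere (golden-section spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atom_radii <- function(structure, params) {
  a <- structure$atoms
  if (all(a$name == "CA")) return(rep(params$ca_radius, nrow(a)))
  r <- params$radii[toupper(a$element)]
  r[is.na(r)] <- 1.7
  as.numeric(r)
}

#' Euclidean distance between two C-alpha atoms
#' @param structure structure3d
#' @param chain_a,res_a first residue address (author numbering)
#' @param chain_b,res_b second residue address
#' @return distance in Angstrom
#' @export
ca_distance <- function(structure, chain_a, res_a, chain_b, res_b) {
  sqrt(sum((ca_site(structure, chain_a, res_a) -
              ca_site(structure, chain_b, res_b))^2))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, the fraction of quasi-uniform sphere points at radius
#' `r + probe` that fall inside no neighboring expanded sphere, times
#' `4 pi (r + probe)^2`.
#'
#' @param structure structure3d
#' @param params [sasa_params()]
#' @return list: `per_atom` (Angstrom^2 per atom), `total`
#' @export
sasa <- function(structure, params = sasa_params()) {
  xyz <- as.matrix(structure$atoms[c("x", "y", "z")])
  n <- nrow(xyz)
  r <- .atom_radii(structure, params) + params$probe_radius
  sp <- .sphere_points(params$n_sphere_points)
  maxr <- max(r)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    pts <- sp * r[i] + matrix(xyz[i, ], params$n_sphere_points, 3,
                              byrow = TRUE)
    if (length(nb)) {
      free <- rep(TRUE, nrow(pts))
      for (j in nb) {
        dj2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
        free <- free & dj2 > r[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    per_atom[i] <- frac * 4 * pi * r[i]^2
  }
  list(per_atom = per_atom, total = sum(per_atom))
}

#' Buried interface area between two atom groups
#'
#' `(SASA(A alone) + SASA(B alone) - SASA(A union B)) / 2`, the standard
#' per-side burial.
#'
#' @param structure structure3d containing both groups
#' @param group_a,group_b logical or integer atom indices (disjoint,
#'   non-empty), or chain id character vectors
#' @param params [sasa_params()]
#' @return buried area in Angstrom^2
#' @export
interface_area <- function(structure, group_a, group_b,
                           params = sasa_params()) {
  idx <- function(g) {
    if (is.character(g)) which(structure$atoms$chain_id %in% g)
    else if (is.logical(g)) which(g)
    else as.integer(g)
  }
  ia <- idx(group_a); ib <- idx(group_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("both groups must be non-empty")
  if (length(intersect(ia, ib))) stop("groups overlap")
  sub <- function(i) {
    s <- structure
    s$atoms <- s$atoms[i, , drop = FALSE]
    rownames(s$atoms) <- NULL
    s
  }
  sa <- sasa(sub(ia), params)$total
  sb <- sasa(sub(ib), params)$total
  sab <- sasa(sub(sort(c(ia, ib))), params)$total
  (sa + sb - sab) / 2
}

#' Per-residue RMSF across an aligned ensemble
#'
#' Frames are superposed on the Ca atoms of `align_range` onto the
#' iteratively refined Procrustes mean (initialized from the first frame
#' and re-estimated until convergence, which makes the result independent
#' of frame order); the fluctuation of each reported residue is
#' `sqrt(mean_t |x_i(t) - <x_i>|^2)`.
#'
#' @param ensemble list of structure3d sharing residue addressing
#' @param align_range addresses (rownames as in [ca_coords()]) used for
#'   superposition; default all shared addresses
#' @param report_selection addresses reported; default `align_range` plus
#'   all shared addresses
#' @return list of class `rmsf_profile`: `rmsf` (named per-residue,
#'   Angstrom), `align_range`
#' @export
rmsf <- function(ensemble, align_range = NULL, report_selection = NULL) {
  if (length(ensemble) < 2L) stop("need >= 2 conformations")
  coords <- lapply(ensemble, ca_coords)
  shared <- Reduce(intersect, lapply(coords, rownames))
  if (length(shared) == 0L) stop("mismatched residue addressing")
  if (is.null(align_range)) align_range <- shared
  if (is.null(report_selection)) report_selection <- shared
  if (!all(align_range %in% shared) || !all(report_selection %in% shared))
    stop("mismatched residue addressing in selection")
  ref <- coords[[1]][align_range, , drop = FALSE]
  ref <- sweep(ref, 2, colMeans(ref))
  for (iter in 1:25) {
    al <- lapply(coords, function(m) {
      fit <- superpose(m[align_range, , drop = FALSE], ref)
      apply_transform(m[align_range, , drop = FALSE], fit)
    })
    new_ref <- Reduce(`+`, al) / length(al)
    new_ref <- sweep(new_ref, 2, colMeans(new_ref))
    if (max(abs(new_ref - ref)) < 1e-10) { ref <- new_ref; break }
    ref <- new_ref
  }
  aligned <- lapply(coords, function(m) {
    fit <- superpose(m[align_range, , drop = FALSE], ref)
    apply_transform(m[report_selection, , drop = FALSE], fit)
  })
  arr <- simplify2array(aligned)              # nres x 3 x nframes
  mu <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), mu)^2
  # per frame: sum squared deviation over xyz; then mean over frames
  msd <- rowMeans(apply(dev2, 3, rowSums))
  structure(list(rmsf = stats::setNames(sqrt(msd), report_selection),
                 align_range = align_range),
            class = "rmsf_profile")
}
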