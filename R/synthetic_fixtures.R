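# Synthetic pseudo-all-atom trajectories with prescribed bonded
# distributions, and particle configurations with planted aggregation
# structure.  These generators make every test input reproducible in code:
# no reference trajectory is ever downloaded.
#
# Construction: the two ring triangles are built from their (possibly
# rigid) edge lengths; the acceptor ring is attached by sequential
# internal-to-Cartesian (NeRF) placement using the sampled inter-monomer
# bond, two sampled junction angles and the sampled dihedral.  The two
# remaining junction angles are not independent degrees of freedom once the
# rings are rigid: the free azimuth and spin are solved once, at mean
# geometry, so those angles hit their target means, and their spread is
# induced by the sampled terms rather than prescribed.  Every bead is then
# decorated with its mapped atoms at fixed zero-mean offsets, so the
# centre-of-geometry projection inverts the decoration exactly.

#' Generator specification for a pseudo-all-atom trajectory
#'
#' @param spec A [disaccharide_spec()] (default: trehalose, `1GA_0GA`).
#' @param distances Named list `bond0`..`bond6` of `c(mean, sd)` in nm.
#'   Defaults are the trehalose CG values (rings rigid, sd 0; the
#'   inter-monomer `bond3` 0.48 +/- 0.02 nm).
#' @param angles Named list `angle0`..`angle3` of `c(mean, sd)` in degrees.
#'   `angle0` and `angle2` are sampled; `angle1` and `angle3` are honoured
#'   in the mean via the solved azimuth/spin.
#' @param dihedral `c(mean, sd)` in degrees.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param box Orthorhombic box edges (nm).
#' @param dt_ps Frame spacing (ps).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(spec = NULL,
                           distances = list(bond0 = c(0.32, 0), bond1 = c(0.36, 0),
                                            bond2 = c(0.45, 0), bond3 = c(0.48, 0.02),
                                            bond4 = c(0.33, 0), bond5 = c(0.36, 0),
                                            bond6 = c(0.47, 0)),
                           angles = list(angle0 = c(120, 5), angle1 = c(100, NA),
                                         angle2 = c(110, 5), angle3 = c(80, NA)),
                           dihedral = c(-60, 10),
                           n_frames = 1000L, seed = 1L,
                           box = c(10, 10, 10), dt_ps = 100) {
  if (is.null(spec))
    spec <- disaccharide_spec("GLC", "GLC", linkage_spec(1L, "ALPHA", "ALPHA"))
  stopifnot(all(paste0("bond", 0:6) %in% names(distances)),
            all(paste0("angle", 0:3) %in% names(angles)))
  sds <- vapply(distances, `[[`, 0, 2L)
  if (any(sds[!is.na(sds)] < 0)) stop("distance sds must be >= 0")
  structure(list(spec = spec, distances = distances, angles = angles,
                 dihedral = dihedral, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), box = box, dt_ps = dt_ps),
            class = "generator_spec")
}

sample_term <- function(target, n) {
  m <- target[[1L]]; s <- target[[2L]]
  if (is.na(s) || s == 0) rep(m, n) else rnorm(n, m, s)
}

# azimuth (deg) giving angle(ref, apex, placed) == target at mean geometry;
# solved on a fine grid. `place` maps an azimuth to the placed point.
solve_azimuth <- function(place, ref, apex, target, what) {
  grid <- seq(-180, 180, by = 0.1)
  ang <- vapply(grid, function(phi) angle_deg(ref, apex, place(phi)), 0)
  best <- which.min(abs(ang - target))
  if (abs(ang[best] - target) > 1)
    stop("generator targets are geometrically inconsistent: cannot reach ",
         what, " = ", target, " deg (closest attainable ",
         round(ang[best], 1), " deg)")
  grid[best]
}

#' Generate a pseudo-all-atom trajectory with prescribed bonded terms
#'
#' See the construction notes at the top of this file.  The returned
#' trajectory carries atoms (not beads): projecting it with the molecule's
#' own mapping recovers the generated bead positions to machine precision,
#' and measuring/fitting it recovers the prescribed means.
#'
#' @param gspec A [generator_spec()].
#' @return List of class `pseudo_aa_traj`: `coords` array
#'   `[atoms, 3, frames]` (atom ids as dimnames), `atoms`, `box`, `times`,
#'   plus `graph`, `mapping`, `connectivity`, `bead_coords` (the generated
#'   bead array) and `manifest` (targets, sampled-vs-implied status, solved
#'   azimuth/spin).
#' @export
gen_pseudo_aa_traj <- function(gspec) {
  stopifnot(inherits(gspec, "generator_spec"))
  set.seed(gspec$seed)
  n <- gspec$n_frames
  graph <- build_atom_graph(gspec$spec)
  mapping <- assign_beads(graph)
  conn <- build_connectivity(mapping, graph)
  d <- conn$distances
  an <- conn$angles
  # bead roles
  a <- conn$inter_beads[["a"]]; b <- conn$inter_beads[["b"]]
  r1 <- unique(c(d$i[1:3], d$j[1:3]))
  r2 <- unique(c(d$i[5:7], d$j[5:7]))
  x <- setdiff(r1, a); y <- setdiff(r2, b)

  ds <- lapply(gspec$distances, sample_term, n = n)
  a0 <- sample_term(gspec$angles$angle0, n)
  a2 <- sample_term(gspec$angles$angle2, n)
  dih <- sample_term(gspec$dihedral, n)

  # donor ring triangle: vertices in (r1[1], r1[2], r1[3]) order with side
  # lengths bond0 = (1,2), bond1 = (2,3), bond2 = (1,3)
  tri1 <- place_triangle(ds$bond0, ds$bond1, ds$bond2)
  pos <- list()
  pos[[r1[1L]]] <- tri1$p1; pos[[r1[2L]]] <- tri1$p2; pos[[r1[3L]]] <- tri1$p3

  means <- function(v) mean(v)
  mean_pos <- lapply(pos, colMeans)
  place_b <- function(phi, th = means(a0), r = means(ds$bond3))
    nerf_place(rbind(mean_pos[[x[2L]]]), rbind(mean_pos[[x[1L]]]),
               rbind(mean_pos[[a]]), r, th, phi)
  phi_az <- solve_azimuth(place_b, rbind(mean_pos[[x[2L]]]),
                          rbind(mean_pos[[a]]),
                          gspec$angles$angle1[[1L]], "angle1")
  pos[[b]] <- nerf_place(pos[[x[2L]]], pos[[x[1L]]], pos[[a]],
                         ds$bond3, a0, phi_az)

  # acceptor ring side lengths by bead pair
  side <- function(p, q) {
    for (k in 5:7) {
      if ((d$i[k] == p && d$j[k] == q) || (d$i[k] == q && d$j[k] == p))
        return(ds[[d$label[k]]])
    }
    stop("no ring edge between ", p, " and ", q)
  }
  d_by1 <- side(b, y[1L]); d_by2 <- side(b, y[2L]); d_y12 <- side(y[1L], y[2L])
  pos[[y[1L]]] <- nerf_place(pos[[x[1L]]], pos[[a]], pos[[b]], d_by1, a2, dih)
  # interior angle at y1 of the acceptor triangle (law of cosines)
  cosb <- (d_by1^2 + d_y12^2 - d_by2^2) / (2 * d_by1 * d_y12)
  if (any(abs(cosb) >= 1))
    stop("acceptor ring edge lengths violate the triangle inequality")
  beta <- acos(cosb) * 180 / pi
  mean_pos <- lapply(pos, colMeans)
  place_y2 <- function(psi)
    nerf_place(rbind(mean_pos[[a]]), rbind(mean_pos[[b]]),
               rbind(mean_pos[[y[1L]]]), means(d_y12), means(beta), psi)
  psi_spin <- solve_azimuth(place_y2, rbind(mean_pos[[a]]),
                            rbind(mean_pos[[b]]),
                            gspec$angles$angle3[[1L]], "angle3")
  pos[[y[2L]]] <- nerf_place(pos[[a]], pos[[b]], pos[[y[1L]]],
                             d_y12, beta, psi_spin)

  bead_names <- vapply(mapping$beads, `[[`, "", "name")
  beads <- array(NA_real_, dim = c(length(bead_names), 3L, n),
                 dimnames = list(bead_names, NULL, NULL))
  for (nm in c(r1, r2)) beads[nm, , ] <- t(pos[[nm]])
  for (vn in names(mapping$virtual_sites))
    beads[vn, , ] <- colMeans(beads[mapping$virtual_sites[[vn]], , ,
                                    drop = FALSE], dims = 1L)
  # centre in the box
  for (k in 1:3) beads[, k, ] <- beads[, k, ] + gspec$box[[k]] / 2

  # decorate beads with atoms at fixed zero-mean offsets (COG-invertible)
  atoms <- graph$atoms
  arr <- array(NA_real_, dim = c(nrow(atoms), 3L, n),
               dimnames = list(atoms$id, NULL, NULL))
  offsets <- list()
  for (bd in mapping$beads) {
    if (bd$is_virtual) next
    m <- length(bd$atom_names)
    off <- matrix(rnorm(3L * m, sd = 0.05), nrow = m)
    off <- sweep(off, 2L, colMeans(off))
    offsets[[bd$name]] <- off
    for (ai in seq_len(m))
      arr[bd$atom_names[[ai]], , ] <- beads[bd$name, , ] + off[ai, ]
  }
  manifest <- list(
    molecule = gspec$spec$name, n_frames = n, seed = gspec$seed,
    targets = c(gspec$distances,
                gspec$angles[c("angle0", "angle2")],
                list(dihedral0 = gspec$dihedral)),
    implied_means = list(angle1 = gspec$angles$angle1[[1L]],
                         angle3 = gspec$angles$angle3[[1L]]),
    solved = list(azimuth = phi_az, spin = psi_spin))
  structure(list(coords = arr, atoms = atoms, box = gspec$box,
                 times = seq_len(n) * gspec$dt_ps - gspec$dt_ps,
                 graph = graph, mapping = mapping, connectivity = conn,
                 bead_coords = beads, manifest = manifest),
            class = "pseudo_aa_traj")
}

#' Write fixture files for a generated trajectory
#'
#' Emits `<prefix>.gro` (multi-frame GRO trajectory), `<prefix>.map`
#' (manual mapping file) and `<prefix>_manifest.json` (ground-truth
#' targets).
#'
#' @param traj A `pseudo_aa_traj`.
#' @param prefix Output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_fixture_files <- function(traj, prefix) {
  stopifnot(inherits(traj, "pseudo_aa_traj"))
  gro <- paste0(prefix, ".gro")
  nm <- traj$manifest$molecule
  res_names <- c(sub("^.*_", "", nm), sub("_.*$", "", nm))
  if (file.exists(gro)) file.remove(gro)
  for (k in seq_len(dim(traj$coords)[[3L]])) {
    write_gro(traj$coords[, , k], traj$box, gro,
              atom_names = traj$atoms$name,
              res_ids = traj$atoms$residue,
              res_names = res_names[traj$atoms$residue],
              title = paste("pseudo-AA", nm), time = traj$times[[k]],
              append = k > 1L)
  }
  map <- paste0(prefix, ".map")
  write_mapping_file(traj$mapping, map)
  man <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(traj$manifest, man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(gro, map, man))
}

#' Particle configuration with planted aggregation structure
#'
#' Places `n_mol` single-bead molecules so that molecules within each
#' planted cluster are chained at `spacing` (below the network cutoff) and
#' distinct clusters are separated by more than `gap`.
#'
#' @param n_mol Total molecule count; must equal `sum(planted_sizes)`.
#' @param planted_sizes Integer vector of intended component sizes.
#' @param gap Minimum separation between clusters (nm); must exceed the
#'   network cutoff for the plant to be recovered.
#' @param box Orthorhombic box edges (nm).
#' @param seed RNG seed for the small positional jitter.
#' @param spacing Chain spacing within a cluster (nm).
#' @return A frame (list with `coords`, `box`, `mol_index`, `time = 0`)
#'   suitable for [aggregate_sizes()].
#' @export
gen_clustered_config <- function(n_mol, planted_sizes, gap = 1.0,
                                 box = c(12, 12, 12), seed = 1L,
                                 spacing = 0.3) {
  if (sum(planted_sizes) != n_mol)
    stop("planted_sizes must sum to n_mol")
  stopifnot(gap > 0, spacing > 0)
  set.seed(seed)
  jit <- 0.02
  chain_len <- (max(planted_sizes) - 1L) * spacing
  pitch_y <- gap + 2 * jit + 0.01
  need_y <- length(planted_sizes) * pitch_y + gap
  need_x <- chain_len + gap + 2 * jit
  if (need_x > box[[1L]] || need_y > box[[2L]])
    stop("box too small for the requested cluster separation (need ",
         round(need_x, 2), " x ", round(need_y, 2), " nm)")
  coords <- matrix(NA_real_, nrow = n_mol, ncol = 3L)
  mol <- 0L
  for (ci in seq_along(planted_sizes)) {
    yc <- 0.5 + (ci - 1L) * pitch_y
    for (mi in seq_len(planted_sizes[[ci]])) {
      mol <- mol + 1L
      coords[mol, ] <- c(0.5 + (mi - 1L) * spacing, yc, box[[3L]] / 2) +
        runif(3L, -jit, jit)
    }
  }
  rownames(coords) <- paste0("M", seq_len(n_mol))
  list(coords = coords, box = box, mol_index = seq_len(n_mol), time = 0)
}
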