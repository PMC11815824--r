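# Aggregation analysis: system composition at a target concentration,
# per-frame minimum-distance molecular networks, cutoff filtering,
# connected-component aggregate sizes, and windowed size distributions.
#
# The distance network has one node per disaccharide; an edge exists when
# the minimum bead-bead distance between two molecules (minimum image,
# orthorhombic box) does not exceed the cutoff, 0.47 nm (4.7 Angstrom) by
# default, edges at exactly the cutoff included.

#' All-atom waters required for a target disaccharide concentration
#'
#' The solution volume is approximated by the water mass at 1.000 g/cm^3,
#' i.e. the solute-to-water ratio is computed from molecular weights alone.
#' Note the inversion residual: 20 trehalose in 7609 waters evaluates to
#' 49.9 g/L, which rounds to the nominal 50 g/L, but inverting 50 g/L
#' exactly yields 7600 waters.
#'
#' @param n_solute Number of solute molecules.
#' @param mw_solute Solute molecular weight (g/mol); trehalose 342.30.
#' @param concentration Target concentration (g/L).
#' @param mw_water Water molecular weight (g/mol).
#' @return Rounded number of all-atom water molecules.
#' @examples
#' waters_for_concentration(20, 342.30, 50)  # 7600
#' @export
waters_for_concentration <- function(n_solute, mw_solute, concentration,
                                     mw_water = 18.015) {
  stopifnot(n_solute > 0, mw_solute > 0, concentration > 0, mw_water > 0)
  round(n_solute * mw_solute * 1000 / (concentration * mw_water))
}

#' Concentration of a solute/water composition
#'
#' @param n_solute,mw_solute Solute count and molecular weight (g/mol).
#' @param aa_waters Number of all-atom water molecules.
#' @param mw_water Water molecular weight (g/mol).
#' @return Concentration in g/L (water volume at 1.000 g/cm^3).
#' @examples
#' round(concentration_of(20, 342.30, 7609))  # 50
#' @export
concentration_of <- function(n_solute, mw_solute, aa_waters,
                             mw_water = 18.015) {
  stopifnot(n_solute > 0, mw_solute > 0, aa_waters > 0, mw_water > 0)
  1000 * n_solute * mw_solute / (aa_waters * mw_water)
}

#' Martini water beads for an all-atom water count
#'
#' Standard 4:1 mapping of all-atom waters to CG water beads.
#'
#' @param aa_waters Number of all-atom water molecules (>= 0).
#' @return `floor(aa_waters / 4)` beads.
#' @examples
#' cg_water_beads(7609)  # 1902
#' @export
cg_water_beads <- function(aa_waters) {
  stopifnot(aa_waters >= 0)
  as.integer(floor(aa_waters / 4))
}

check_box <- function(box) {
  if (is.matrix(box) || length(box) != 3L)
    stop("only orthorhombic boxes (length-3 edge vector) are supported; ",
         "triclinic boxes are rejected")
  if (any(box <= 0)) stop("box edges must be positive")
  box
}

#' Minimum intermolecular bead distance under periodic boundaries
#'
#' Minimum over all bead pairs of the minimum-image distance in an
#' orthorhombic box.
#'
#' @param mol_i,mol_j Coordinate matrices (beads x 3, nm) of two molecules.
#' @param box Orthorhombic box edge lengths (nm).
#' @return Minimum distance in nm.
#' @export
min_intermolecular_distance <- function(mol_i, mol_j, box) {
  box <- check_box(box)
  mol_i <- as_mat3(mol_i); mol_j <- as_mat3(mol_j)
  if (!nrow(mol_i) || !nrow(mol_j)) stop("empty molecule")
  d2 <- 0
  for (k in 1:3) {
    d <- outer(mol_i[, k], mol_j[, k], "-")
    d <- d - box[[k]] * round(d / box[[k]])
    d2 <- d2 + d * d
  }
  sqrt(min(d2))
}

#' Aggregate sizes of one frame
#'
#' Builds the cutoff-filtered minimum-distance network and returns the
#' connected-component sizes, sorted descending.  The cutoff is inclusive
#' (an edge at exactly the cutoff is kept).
#'
#' @param frame List with `coords` (beads x 3 matrix), `box`, `mol_index`
#'   (integer molecule id per bead row) and optional `time`.
#' @param cutoff Distance cutoff in nm (default 0.47 nm = 4.7 Angstrom).
#' @return An `aggregate_record`: list with `time`, `sizes` (descending)
#'   and `members` (list of molecule-id vectors per component).
#' @export
aggregate_sizes <- function(frame, cutoff = 0.47) {
  box <- check_box(frame$box)
  mols <- sort(unique(frame$mol_index))
  n <- length(mols)
  if (n < 1L) stop("frame contains no molecules")
  per_mol <- lapply(mols, function(m)
    frame$coords[frame$mol_index == m, , drop = FALSE])
  edges <- integer()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (min_intermolecular_distance(per_mol[[i]], per_mol[[j]], box) <= cutoff)
          edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  members <- split(mols, comp$membership)
  ord <- order(comp$csize, decreasing = TRUE)
  structure(list(time = frame$time,
                 sizes = as.integer(comp$csize[ord]),
                 members = unname(members[ord])),
            class = "aggregate_record")
}

#' Aggregate records for every frame of a trajectory
#'
#' @param traj List of frames (each as in [aggregate_sizes()]), or a list
#'   with elements `frames`.
#' @param cutoff Distance cutoff (nm).
#' @return List of `aggregate_record`s.
#' @export
aggregate_series <- function(traj, cutoff = 0.47) {
  frames <- if (!is.null(traj$frames)) traj$frames else traj
  lapply(frames, aggregate_sizes, cutoff = cutoff)
}

record_times <- function(records)
  vapply(records, function(r) if (is.null(r$time) || is.na(r$time)) NA_real_
         else r$time, 0)

#' Pooled aggregate-size distribution over a trailing window
#'
#' Pools the component sizes of frames selected every `stride_ps` within
#' the final `window_ps` of each replicate and tabulates them over sizes
#' `1..n_mol`.
#'
#' @param records A list of `aggregate_record`s (one replicate) or a list
#'   of such lists (several replicates, pooled).
#' @param window_ps Trailing window length (ps); `Inf` keeps all frames.
#' @param stride_ps Frame selection stride (ps); frames at times that are
#'   multiples of the stride (within the window) are used.
#' @param n_mol Total number of molecules (defaults to the size sum of the
#'   first record).
#' @return Data frame with `size` (1..n_mol) and `count`.
#' @export
size_distribution <- function(records, window_ps = Inf, stride_ps = NULL,
                              n_mol = NULL) {
  if (length(records) && inherits(records[[1L]], "aggregate_record"))
    records <- list(records)
  if (is.null(n_mol)) n_mol <- sum(records[[1L]][[1L]]$sizes)
  counts <- integer(n_mol)
  for (rep in records) {
    times <- record_times(rep)
    keep <- rep_len(TRUE, length(rep))
    if (is.finite(window_ps)) {
      if (anyNA(times)) stop("window selection requires frame times")
      span <- max(times) - min(times)
      if (window_ps > span)
        stop("window (", window_ps, " ps) exceeds trajectory span (",
             span, " ps)")
      keep <- keep & times >= max(times) - window_ps
    }
    if (!is.null(stride_ps)) {
      if (anyNA(times)) stop("stride selection requires frame times")
      keep <- keep & (times %% stride_ps < 1e-9 |
                      stride_ps - times %% stride_ps < 1e-9)
    }
    for (r in rep[keep]) {
      tab <- tabulate(r$sizes, nbins = n_mol)
      counts <- counts + tab
    }
  }
  data.frame(size = seq_len(n_mol), count = counts)
}

#' Time evolution of the aggregate-size record
#'
#' @param records List of `aggregate_record`s over the full trajectory.
#' @return Data frame with `time`, `n_aggregates`, `largest`, `mean_size`
#'   per frame.
#' @export
time_evolution <- function(records) {
  data.frame(time = record_times(records),
             n_aggregates = vapply(records, function(r) length(r$sizes), 0L),
             largest = vapply(records, function(r) max(r$sizes), 0L),
             mean_size = vapply(records, function(r) mean(r$sizes), 0))
}
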