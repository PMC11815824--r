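# Projection of all-atom coordinates onto bead centres of geometry, bonded
# connectivity construction, and measurement of bonded terms.
#
# Units follow the coordinate-file native convention: lengths in nm, angles
# and dihedrals in degrees (dihedrals wrapped to (-180, 180]).

#' Project one frame onto bead coordinates
#'
#' Each real bead sits at the unweighted mean (centre of geometry) of its
#' mapped atoms' positions; each ring virtual site at the centre of geometry
#' of its ring's three beads.
#'
#' @param frame Either an atom coordinate matrix (rows named by atom id) or
#'   a list with element `coords` (such a matrix) plus optional `box`,
#'   `time`.
#' @param mapping A `cg_mapping`.
#' @return A numeric matrix (beads x 3) with bead names as row names.
#' @export
project_frame <- function(frame, mapping) {
  coords <- if (is.list(frame)) frame$coords else frame
  out <- matrix(NA_real_, nrow = length(mapping$beads), ncol = 3L,
                dimnames = list(vapply(mapping$beads, `[[`, "", "name"), NULL))
  for (b in mapping$beads) {
    if (b$is_virtual) next
    miss <- setdiff(b$atom_names, rownames(coords))
    if (length(miss))
      stop("frame is missing mapped atom(s): ", paste(miss, collapse = ", "))
    out[b$name, ] <- colMeans(coords[b$atom_names, , drop = FALSE])
  }
  for (vn in names(mapping$virtual_sites))
    out[vn, ] <- colMeans(out[mapping$virtual_sites[[vn]], , drop = FALSE])
  out
}

#' Project an atom trajectory onto bead coordinates
#'
#' @param traj A trajectory: list with `coords`, an array
#'   `[atoms, 3, frames]` with atom ids as first dimnames, plus optional
#'   `box`, `times`.
#' @param mapping A `cg_mapping`.
#' @return A list of class `cg_traj`: `coords` array `[beads, 3, frames]`,
#'   `box`, `times`.
#' @export
project_traj <- function(traj, mapping) {
  arr <- traj$coords
  stopifnot(length(dim(arr)) == 3L)
  ids <- dimnames(arr)[[1L]]
  bead_names <- vapply(mapping$beads, `[[`, "", "name")
  nf <- dim(arr)[[3L]]
  out <- array(NA_real_, dim = c(length(bead_names), 3L, nf),
               dimnames = list(bead_names, NULL, NULL))
  for (b in mapping$beads) {
    if (b$is_virtual) next
    idx <- match(b$atom_names, ids)
    if (anyNA(idx))
      stop("trajectory is missing mapped atom(s): ",
           paste(b$atom_names[is.na(idx)], collapse = ", "))
    out[b$name, , ] <- colMeans(arr[idx, , , drop = FALSE], dims = 1L)
  }
  for (vn in names(mapping$virtual_sites))
    out[vn, , ] <- colMeans(out[mapping$virtual_sites[[vn]], , , drop = FALSE],
                            dims = 1L)
  structure(list(coords = out, box = traj$box, times = traj$times),
            class = "cg_traj")
}

#' Make molecules whole across periodic boundaries
#'
#' Rebuilds each frame by walking the bond graph breadth-first from the
#' first atom and placing every atom at the minimum-image position relative
#' to its parent.  Required before intramolecular measurements whenever a
#' molecule may be wrapped; a no-op for already-whole molecules.
#'
#' @param traj Atom trajectory (see [project_traj()]) with an orthorhombic
#'   `box` (length-3 edge vector, nm).
#' @param graph The molecule's `atom_graph`.
#' @return The trajectory with unwrapped coordinates.
#' @export
unwrap_traj <- function(traj, graph) {
  box <- traj$box
  if (is.null(box)) return(traj)
  stopifnot(length(box) == 3L, all(box > 0))
  arr <- traj$coords
  ids <- dimnames(arr)[[1L]]
  ig <- graph_of(graph)
  bfs <- igraph::bfs(ig, root = 1, father = TRUE)
  ord <- as.integer(bfs$order)
  father <- as.integer(bfs$father)
  for (v in ord[-1L]) {
    pa <- father[v]
    i <- match(igraph::V(ig)$name[v], ids)
    j <- match(igraph::V(ig)$name[pa], ids)
    d <- arr[i, , , drop = FALSE] - arr[j, , , drop = FALSE]
    for (k in 1:3)
      d[1L, k, ] <- d[1L, k, ] - box[[k]] * round(d[1L, k, ] / box[[k]])
    arr[i, , ] <- arr[j, , , drop = FALSE] + d
  }
  traj$coords <- arr
  traj
}

#' Build the CG bonded connectivity of a mapped disaccharide
#'
#' Seven distance terms in topology order: `bond0`-`bond2` are the donor
#' ring triangle (constraints), `bond3` the single harmonic bond joining the
#' beads that flank the glycosidic linkage (donor C1 bead to acceptor
#' link-carbon bead), `bond4`-`bond6` the acceptor ring triangle.  Four
#' angles combine each inter-bonded bead with its two ring partners
#' (`x1-a-b`, `x2-a-b`, `a-b-y1`, `a-b-y2`) and the unique dihedral is
#' `x1-a-b-y1` with partners chosen by lowest bead index.
#'
#' @param mapping A `cg_mapping`.
#' @param graph The matching `atom_graph`.
#' @return An object of class `cg_connectivity`: data frames `distances`
#'   (label, i, j, kind), `angles` (label, i, j, k), `dihedrals`
#'   (label, i, j, k, l), plus `inter_beads` and `virtual_sites`.
#' @export
build_connectivity <- function(mapping, graph) {
  stopifnot(inherits(mapping, "cg_mapping"), inherits(graph, "atom_graph"))
  assignment <- bead_assignment(mapping)
  p <- graph$spec$linkage$position
  a <- unname(assignment[["1:C1"]])
  link_c <- paste0("2:", sub("^O", "C",
                             graph$atoms[graph$glycosidic_oxygen, "name"]))
  b <- unname(assignment[[link_c]])
  ring_beads <- function(r) {
    nm <- vapply(mapping$beads, `[[`, "", "name")
    virt <- vapply(mapping$beads, `[[`, TRUE, "is_virtual")
    res <- vapply(mapping$beads, `[[`, 1L, "residue")
    nm[!virt & res == r]
  }
  r1 <- ring_beads(1L); r2 <- ring_beads(2L)
  tri <- function(bd) rbind(bd[c(1L, 2L)], bd[c(2L, 3L)], bd[c(1L, 3L)])
  dist_pairs <- rbind(tri(r1), c(a, b), tri(r2))
  distances <- data.frame(label = paste0("bond", 0:6),
                          i = dist_pairs[, 1L], j = dist_pairs[, 2L],
                          kind = c(rep("constraint", 3L), "bond",
                                   rep("constraint", 3L)),
                          stringsAsFactors = FALSE)
  x <- setdiff(r1, a); y <- setdiff(r2, b)  # ring partners, index order
  angles <- data.frame(label = paste0("angle", 0:3),
                       i = c(x[1L], x[2L], a, a),
                       j = c(a, a, b, b),
                       k = c(b, b, y[1L], y[2L]),
                       stringsAsFactors = FALSE)
  dihedrals <- data.frame(label = "dihedral0", i = x[1L], j = a, k = b,
                          l = y[1L], stringsAsFactors = FALSE)
  structure(list(distances = distances, angles = angles,
                 dihedrals = dihedrals, inter_beads = c(a = a, b = b),
                 virtual_sites = mapping$virtual_sites),
            class = "cg_connectivity")
}

#' Measure bonded terms over a trajectory
#'
#' Computes every distance, angle and dihedral term of the CG connectivity
#' on bead coordinates.  Distances are Euclidean norms (molecules are made
#' whole first when a graph and box are available, so no minimum-image is
#' applied within the molecule); angles use the arccosine of the normalised
#' dot product; dihedrals the signed atan2 convention.  Degenerate frames
#' (zero-length vector in an angle) are excluded from that term's samples
#' with a message.
#'
#' @param traj Either a `cg_traj` from [project_traj()] or an atom
#'   trajectory (projected internally; requires `mapping`).
#' @param mapping A `cg_mapping` (needed when `traj` holds atoms).
#' @param connectivity A `cg_connectivity`.
#' @param graph Optional `atom_graph`, used to unwrap an atom trajectory.
#' @return An object of class `term_samples`: `samples` (named list of
#'   numeric vectors; nm for bonds, degrees otherwise), `kind` (named
#'   character), `times`.
#' @export
measure_terms <- function(traj, mapping = NULL, connectivity, graph = NULL) {
  if (!inherits(traj, "cg_traj")) {
    if (is.null(mapping))
      stop("mapping is required to project an atom trajectory")
    if (!is.null(graph) && !is.null(traj$box)) traj <- unwrap_traj(traj, graph)
    traj <- project_traj(traj, mapping)
  }
  arr <- traj$coords
  P <- function(name) t(arr[name, , , drop = TRUE])  # frames x 3
  nf <- dim(arr)[[3L]]
  at <- function(name) if (nf == 1L) matrix(arr[name, , 1L], ncol = 3L) else P(name)
  samples <- list(); kind <- character()
  d <- connectivity$distances
  for (r in seq_len(nrow(d))) {
    samples[[d$label[r]]] <- vnorm3(at(d$i[r]) - at(d$j[r]))
    kind[d$label[r]] <- d$kind[r]
  }
  an <- connectivity$angles
  for (r in seq_len(nrow(an))) {
    v <- angle_deg(at(an$i[r]), at(an$j[r]), at(an$k[r]))
    if (anyNA(v)) {
      message("term ", an$label[r], ": excluded ", sum(is.na(v)),
              " degenerate frame(s)")
      v <- v[!is.na(v)]
    }
    samples[[an$label[r]]] <- v
    kind[an$label[r]] <- "angle"
  }
  dh <- connectivity$dihedrals
  for (r in seq_len(nrow(dh))) {
    samples[[dh$label[r]]] <- dihedral_deg(at(dh$i[r]), at(dh$j[r]),
                                           at(dh$k[r]), at(dh$l[r]))
    kind[dh$label[r]] <- "dihedral"
  }
  structure(list(samples = samples, kind = kind, times = traj$times),
            class = "term_samples")
}

#' @export
print.term_samples <- function(x, ...) {
  cat("<term_samples>", length(x$samples), "terms,",
      length(x$samples[[1L]]), "frames\n")
  for (lab in names(x$samples)) {
    s <- x$samples[[lab]]
    cat(sprintf("  %-9s %-10s mean %8.3f sd %7.4f\n", lab, x$kind[[lab]],
                mean(s), stats::sd(s)))
  }
  invisible(x)
}
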