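# Atom-to-bead assignment for Martini 3 disaccharides.
#
# Each pyranose ring is mapped to three "small" beads grown from consecutive
# ring-carbon pairs (A = C1/C2, B = C3/C4, C = C5/C6) plus one massless
# virtual site at the ring centre.  Exocyclic heavy atoms join the bead of
# the ring carbon they are bonded to (ring O5 joins bead C) and every
# hydrogen follows its heavy atom, so a bead collects 3-5 heavy atoms plus
# their hydrogens.  The glycosidic oxygen is the one atom whose bead is
# linkage-dependent: for 1->1/2/3/4 linkages it joins the donor A bead
# (anomeric-carbon group), for 1->6 it stays with the acceptor C6/O6
# exocyclic group in the acceptor C bead.  These rules live in an editable
# rules list so other mapping conventions can be expressed without code
# changes.

#' Default mapping rules table
#'
#' @param virtual_type Bead-type label written for ring virtual sites.  The
#'   site is massless and apolar; the label is configurable because
#'   published topologies are free to choose their own.
#' @return A named list consumed by [assign_beads()] and [bead_type_of()]:
#'   ring-carbon pairs per bead letter, the bead taking the ring oxygen,
#'   the glycosidic-bead side per linkage position, ring bead types and the
#'   glycosidic bead types (`SN6`, with the `SN6r` variant for 1->6 mannose
#'   junctions), plus heavy-atom count limits.
#' @export
default_mapping_rules <- function(virtual_type = "TC4") {
  list(
    bead_letters = c("A", "B", "C"),
    ring_pairs = list(A = c("C1", "C2"), B = c("C3", "C4"), C = c("C5", "C6")),
    ring_oxygen_bead = "C",
    glycosidic_bead_side = c(`1` = "donor", `2` = "donor", `3` = "donor",
                             `4` = "donor", `6` = "acceptor"),
    ring_bead_types = c(A = "SP4r", B = "SP4r", C = "SP1r"),
    glycosidic_types = c(default = "SN6", man16 = "SN6r"),
    virtual_type = virtual_type,
    min_heavy = 3L, max_heavy = 5L
  )
}

mapping_error <- function(msg) {
  stop(structure(class = c("cgsugar_mapping_error", "error", "condition"),
                 list(message = paste0(msg,
                   "; falling back to a manual mapping file (see",
                   " read_mapping_file) is recommended"), call = sys.call(-1))))
}

#' Bead type lookup
#'
#' Resolves a bead's Martini 3 type from the rules table.  Ring beads take
#' the per-letter default (SP4r/SP4r/SP1r); the bead containing the
#' glycosidic oxygen becomes SN6, or SN6r for a 1->6 mannose junction;
#' virtual sites take the configured virtual type.  Unknown keys raise an
#' error rather than silently defaulting.
#'
#' @param bead A bead definition (element of `cg_mapping$beads`) carrying
#'   `letter`, `is_virtual`, `contains_glycosidic`, `sugar_id`, `position`.
#' @param rules A rules list from [default_mapping_rules()].
#' @return A bead type string.
#' @export
bead_type_of <- function(bead, rules = default_mapping_rules()) {
  if (isTRUE(bead$is_virtual)) return(rules$virtual_type)
  if (isTRUE(bead$contains_glycosidic)) {
    key <- if (identical(bead$position, 6L) && identical(bead$sugar_id, "MAN"))
      "man16" else "default"
    ty <- rules$glycosidic_types[key]
    if (is.na(ty)) stop("no glycosidic bead type for key '", key, "'")
    return(unname(ty))
  }
  ty <- rules$ring_bead_types[bead$letter]
  if (is.na(ty)) stop("no ring bead type for bead letter '", bead$letter, "'")
  unname(ty)
}

#' Assign every atom of a disaccharide to a Martini 3 bead
#'
#' Deterministically partitions the atom graph into six real beads (three
#' per ring, grown in fixed ring order C1->C2->...) plus one virtual site per
#' ring constructed from that ring's three beads.  The partition is
#' validated: every atom in exactly one bead, every bead connected in the
#' molecular graph, heavy-atom counts within the configured 3-5 range.
#' Violations raise a `cgsugar_mapping_error` naming the offending atoms,
#' pointing the caller at the manual mapping-file route.
#'
#' @param graph An `atom_graph` from [build_atom_graph()].
#' @param rules Rules list from [default_mapping_rules()].
#' @return An object of class `cg_mapping`: `beads` is an ordered list of
#'   bead definitions (`name`, `bead_type`, `residue`, `letter`,
#'   `atom_names`, `is_virtual`, ...), `virtual_sites` maps each site name
#'   to its three constructing beads, `molecule` is the GLYCAM-style name.
#' @export
assign_beads <- function(graph, rules = default_mapping_rules()) {
  stopifnot(inherits(graph, "atom_graph"))
  spec <- graph$spec
  p <- spec$linkage$position
  atoms <- graph$atoms
  adj <- adjacency_of(graph)
  assignment <- setNames(rep(NA_character_, nrow(atoms)), atoms$id)

  bead_names <- unlist(lapply(1:2, function(r) paste0("R", r, rules$bead_letters)))
  # (i)+(ii) grow beads from ring-carbon pairs in ring order
  for (r in 1:2) {
    for (letter in rules$bead_letters) {
      bname <- paste0("R", r, letter)
      for (cn in rules$ring_pairs[[letter]]) {
        id <- paste0(r, ":", cn)
        if (id %in% atoms$id) assignment[id] <- bname
      }
    }
    # exocyclic heavy atoms join the bead of their bonded ring carbon
    o5 <- paste0(r, ":O5")
    assignment[o5] <- paste0("R", r, rules$ring_oxygen_bead)
    res_heavy <- atoms$id[atoms$residue == r & atoms$heavy]
    for (id in res_heavy) {
      if (!is.na(assignment[id]) || id == graph$glycosidic_oxygen) next
      nb <- adj[[id]]
      carbon_nb <- nb[!is.na(assignment[nb])]
      carbon_nb <- carbon_nb[atoms[carbon_nb, "residue"] == r]
      if (length(carbon_nb) == 0L)
        mapping_error(paste0("atom ", id, " could not be reached from the ",
                             "ring atoms during bead growth"))
      assignment[id] <- assignment[carbon_nb[[1L]]]
    }
  }
  # glycosidic oxygen placed by linkage class
  side <- rules$glycosidic_bead_side[as.character(p)]
  if (is.na(side)) mapping_error(paste0("no glycosidic-bead rule for 1->", p))
  glyc_bead <- if (side == "donor") {
    assignment[["1:C1"]]
  } else {
    link_c <- paste0("2:", sub("^O", "C", atoms[graph$glycosidic_oxygen, "name"]))
    assignment[[link_c]]
  }
  assignment[graph$glycosidic_oxygen] <- glyc_bead
  # (iii) hydrogens follow their heavy atom
  for (id in atoms$id[!atoms$heavy]) {
    nb <- adj[[id]]
    heavy_nb <- nb[atoms[nb, "heavy"]]
    if (length(heavy_nb) == 0L || is.na(assignment[heavy_nb[[1L]]]))
      mapping_error(paste0("hydrogen ", id, " has no mapped heavy neighbour"))
    assignment[id] <- assignment[[heavy_nb[[1L]]]]
  }

  un <- names(assignment)[is.na(assignment)]
  if (length(un))
    mapping_error(paste0("atoms not assigned to any bead: ",
                         paste(un, collapse = ", ")))

  ig <- graph_of(graph)
  beads <- lapply(bead_names, function(bname) {
    ids <- names(assignment)[assignment == bname]
    # beads must be contiguous pieces of the molecule
    sub <- igraph::induced_subgraph(ig, ids)
    if (igraph::components(sub)$no != 1L)
      mapping_error(paste0("bead ", bname, " is split (non-contiguous atoms: ",
                           paste(ids, collapse = ", "), ")"))
    nh <- sum(atoms[ids, "heavy"])
    if (nh < rules$min_heavy || nh > rules$max_heavy)
      mapping_error(paste0("bead ", bname, " maps ", nh, " heavy atoms (",
                           "allowed ", rules$min_heavy, "-", rules$max_heavy,
                           "): ", paste(ids, collapse = ", ")))
    res <- as.integer(substr(bname, 2L, 2L))
    list(name = bname, letter = substr(bname, 3L, 3L), residue = res,
         atom_names = ids[order(match(ids, atoms$id))], is_virtual = FALSE,
         contains_glycosidic = graph$glycosidic_oxygen %in% ids,
         sugar_id = if (res == 1L) spec$donor$sugar_id else spec$acceptor$sugar_id,
         position = p)
  })
  for (k in seq_along(beads))
    beads[[k]]$bead_type <- bead_type_of(beads[[k]], rules)
  vs <- lapply(1:2, function(r) {
    list(name = paste0("VS", r), letter = "V", residue = r,
         atom_names = character(), is_virtual = TRUE,
         contains_glycosidic = FALSE, sugar_id = NA_character_, position = p,
         bead_type = rules$virtual_type,
         constructed_from = paste0("R", r, rules$bead_letters))
  })
  structure(list(beads = c(beads, vs),
                 virtual_sites = setNames(lapply(vs, `[[`, "constructed_from"),
                                          vapply(vs, `[[`, "", "name")),
                 molecule = spec$name, rules = rules),
            class = "cg_mapping")
}

bead_by_name <- function(mapping, name) {
  for (b in mapping$beads) if (b$name == name) return(b)
  stop("no bead named ", name)
}

# named vector atom id -> bead name over the real beads
bead_assignment <- function(mapping) {
  out <- character()
  for (b in mapping$beads) {
    if (b$is_virtual) next
    out[b$atom_names] <- b$name
  }
  out
}

#' @export
print.cg_mapping <- function(x, ...) {
  cat("<cg_mapping>", x$molecule, "-",
      sum(!vapply(x$beads, `[[`, TRUE, "is_virtual")), "beads +",
      length(x$virtual_sites), "virtual sites\n")
  for (b in x$beads) {
    if (b$is_virtual) {
      cat(sprintf("  %-4s %-5s VS(%s)\n", b$name, b$bead_type,
                  paste(b$constructed_from, collapse = " ")))
    } else {
      cat(sprintf("  %-4s %-5s %s\n", b$name, b$bead_type,
                  paste(b$atom_names, collapse = " ")))
    }
  }
  invisible(x)
}

# ---- manual mapping-file dialect ------------------------------------------
# One bead per line: <residue_index> <bead_name> <bead_type> <atom names...>
# Virtual sites:     VS <residue_index> <bead1> <bead2> <bead3>
# '#' comments, whitespace separated, UTF-8.  Atom names default to the
# bead's residue; atoms borrowed from the other residue are written with an
# explicit "<residue>:" prefix (the glycosidic oxygen in 1->1/2/3/4 beads).

#' Read a manual bead-mapping file
#'
#' Parses the dialect described above.  Errors (unknown atom when a graph is
#' supplied, duplicated atom, missing residue or virtual site) report the
#' offending line number.
#'
#' @param path File path.
#' @param graph Optional `atom_graph` used to validate atom names and the
#'   partition property.
#' @param rules Rules list (for the glycosidic/type metadata of the result).
#' @return A `cg_mapping` in canonical form (beads ordered by residue and
#'   name, atoms in template order when a graph is given, else sorted).
#' @export
read_mapping_file <- function(path, graph = NULL,
                              rules = default_mapping_rules()) {
  raw <- readLines(path, warn = FALSE)
  seen <- character()
  beads <- list(); vsites <- list()
  for (ln in seq_along(raw)) {
    line <- trimws(sub("#.*$", "", raw[ln]))
    if (!nzchar(line)) next
    tok <- strsplit(line, "[[:space:]]+")[[1L]]
    if (tok[[1L]] == "VS") {
      if (length(tok) != 5L)
        stop("line ", ln, ": VS lines need <residue> <bead1> <bead2> <bead3>")
      vsites[[length(vsites) + 1L]] <-
        list(residue = as.integer(tok[[2L]]), from = tok[3:5], line = ln)
      next
    }
    if (length(tok) < 4L)
      stop("line ", ln, ": expected <residue> <name> <type> <atoms...>")
    res <- suppressWarnings(as.integer(tok[[1L]]))
    if (is.na(res)) stop("line ", ln, ": residue index '", tok[[1L]],
                         "' is not an integer")
    ids <- vapply(tok[-(1:3)], function(a) {
      if (grepl(":", a, fixed = TRUE)) a else paste0(res, ":", a)
    }, "", USE.NAMES = FALSE)
    dup <- ids[ids %in% seen]
    if (length(dup))
      stop("line ", ln, ": atom(s) assigned twice: ", paste(dup, collapse = ", "))
    seen <- c(seen, ids)
    if (!is.null(graph)) {
      bad <- setdiff(ids, graph$atoms$id)
      if (length(bad))
        stop("line ", ln, ": unknown atom name(s): ", paste(bad, collapse = ", "))
    }
    beads[[length(beads) + 1L]] <-
      list(name = tok[[2L]], bead_type = tok[[3L]], residue = res, ids = ids)
  }
  resids <- vapply(beads, `[[`, 1L, "residue")
  for (r in 1:2) {
    if (!r %in% resids) stop("mapping file lacks beads for residue ", r)
    if (!r %in% vapply(vsites, `[[`, 1L, "residue"))
      stop("mapping file lacks a VS line for residue ", r)
  }
  if (!is.null(graph)) {
    missing <- setdiff(graph$atoms$id, seen)
    if (length(missing))
      stop("mapping file leaves atoms unassigned: ",
           paste(missing, collapse = ", "))
  }
  p <- if (!is.null(graph)) graph$spec$linkage$position else NA_integer_
  glyc_o <- if (!is.null(graph)) graph$glycosidic_oxygen else NA_character_
  ord <- order(resids, vapply(beads, `[[`, "", "name"))
  beads <- lapply(beads[ord], function(b) {
    ids <- if (!is.null(graph)) {
      b$ids[order(match(b$ids, graph$atoms$id))]
    } else sort(b$ids)
    list(name = b$name, letter = substr(b$name, nchar(b$name), nchar(b$name)),
         residue = b$residue, atom_names = ids, is_virtual = FALSE,
         contains_glycosidic = !is.na(glyc_o) && glyc_o %in% ids,
         sugar_id = NA_character_, position = p, bead_type = b$bead_type)
  })
  vord <- order(vapply(vsites, `[[`, 1L, "residue"))
  vs <- lapply(vsites[vord], function(v) {
    list(name = paste0("VS", v$residue), letter = "V", residue = v$residue,
         atom_names = character(), is_virtual = TRUE,
         contains_glycosidic = FALSE, sugar_id = NA_character_, position = p,
         bead_type = rules$virtual_type, constructed_from = v$from)
  })
  structure(list(beads = c(beads, vs),
                 virtual_sites = setNames(lapply(vs, `[[`, "constructed_from"),
                                          vapply(vs, `[[`, "", "name")),
                 molecule = if (!is.null(graph)) graph$spec$name else NA_character_,
                 rules = rules),
            class = "cg_mapping")
}

#' Write a bead mapping in the manual-file dialect
#'
#' Writes the canonical form (beads ordered by residue then name); reading
#' the result back yields an identical canonical mapping.
#'
#' @param mapping A `cg_mapping`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mapping_file <- function(mapping, path) {
  stopifnot(inherits(mapping, "cg_mapping"))
  real <- Filter(function(b) !b$is_virtual, mapping$beads)
  ord <- order(vapply(real, `[[`, 1L, "residue"), vapply(real, `[[`, "", "name"))
  lines <- c(sprintf("# bead mapping for %s", mapping$molecule))
  for (b in real[ord]) {
    disp <- vapply(b$atom_names, function(id) {
      parts <- strsplit(id, ":", fixed = TRUE)[[1L]]
      if (as.integer(parts[[1L]]) == b$residue) parts[[2L]] else id
    }, "", USE.NAMES = FALSE)
    lines <- c(lines, paste(b$residue, b$name, b$bead_type,
                            paste(disp, collapse = " ")))
  }
  for (vn in names(mapping$virtual_sites)) {
    r <- as.integer(sub("^VS", "", vn))
    lines <- c(lines, paste("VS", r,
                            paste(mapping$virtual_sites[[vn]], collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}
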