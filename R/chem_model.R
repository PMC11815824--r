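# Monosaccharide templates, disaccharide enumeration and atom-graph assembly.
#
# Templates are editable plain-text files under inst/extdata/templates/ using
# GLYCAM/Amber atom names (C1..C6, O1..O6, ring O5, hydroxyl hydrogens HOx).
# GLC and MAN share one graph topology; they differ only in the C2 hydroxyl
# stereo descriptor, which is carried as metadata (the 2D graph is what the
# bead mapping consumes; geometry enters only through trajectories).

SUGAR_LETTER <- c(GLC = "G", MAN = "M")
ANOMER_LETTER <- c(ALPHA = "A", BETA = "B")
LINK_POSITIONS <- c(1L, 2L, 3L, 4L, 6L)

.template_cache <- new.env(parent = emptyenv())

#' Read a monosaccharide template file
#'
#' Parses the whitespace-separated template dialect shipped under
#' `inst/extdata/templates/`.  Recognised directives: `sugar <id>`,
#' `stereo <free text>`, `atom <name> <element>`, `bond <a> <b>`,
#' `ring <six atom names>`, `hydroxyl <position> <oxygen name>`.
#' Lines starting with `#` are comments.
#'
#' @param path Path to a template file.
#' @return An object of class `mono_template` with elements `sugar_id`,
#'   `atoms` (data frame: name, element, heavy), `bonds` (two-column
#'   character matrix), `ring_atoms`, `hydroxyl_map` (named character:
#'   position -> oxygen) and `stereo`.
#' @seealso [load_template()] for the shipped GLC/MAN templates.
#' @export
read_template <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[[:space:]]+")
  sugar <- NULL; stereo <- NA_character_
  atoms <- list(); bonds <- list(); ring <- NULL; hydroxyl <- character()
  for (f in fields) {
    switch(f[[1L]],
      sugar = { sugar <- f[[2L]] },
      stereo = { stereo <- paste(f[-1L], collapse = " ") },
      atom = { atoms[[length(atoms) + 1L]] <- f[2:3] },
      bond = { bonds[[length(bonds) + 1L]] <- f[2:3] },
      ring = { ring <- f[-1L] },
      hydroxyl = { hydroxyl[f[[2L]]] <- f[[3L]] },
      stop("unknown template directive '", f[[1L]], "' in ", path)
    )
  }
  atoms <- data.frame(name = vapply(atoms, `[[`, "", 1L),
                      element = vapply(atoms, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
  atoms$heavy <- atoms$element != "H"
  tpl <- structure(list(sugar_id = sugar, atoms = atoms,
                        bonds = do.call(rbind, bonds), ring_atoms = ring,
                        hydroxyl_map = hydroxyl, stereo = stereo),
                   class = "mono_template")
  validate_template(tpl)
  tpl
}

validate_template <- function(tpl) {
  if (is.null(tpl$sugar_id)) stop("template lacks a 'sugar' directive")
  if (length(tpl$ring_atoms) != 6L)
    stop("ring must list exactly 6 atoms, got ", length(tpl$ring_atoms))
  known <- tpl$atoms$name
  if (anyDuplicated(known)) stop("duplicated atom names in template")
  bad <- setdiff(c(tpl$bonds), known)
  if (length(bad)) stop("bonds reference unknown atoms: ",
                        paste(bad, collapse = ", "))
  # ring atoms must form a cycle in the bond list
  ring <- tpl$ring_atoms
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bondkeys <- key(tpl$bonds[, 1L], tpl$bonds[, 2L])
  ringkeys <- key(ring, c(ring[-1L], ring[1L]))
  if (!all(ringkeys %in% bondkeys))
    stop("ring atoms do not form a closed cycle in the bond list")
  if (!all(tpl$hydroxyl_map %in% known))
    stop("hydroxyl map references unknown oxygens")
  invisible(tpl)
}

#' Load a shipped monosaccharide template
#'
#' @param sugar_id `"GLC"` or `"MAN"`.
#' @return A `mono_template` (see [read_template()]).
#' @export
load_template <- function(sugar_id) {
  sugar_id <- toupper(sugar_id)
  if (!is.null(.template_cache[[sugar_id]])) return(.template_cache[[sugar_id]])
  path <- system.file("extdata", "templates", paste0(sugar_id, ".txt"),
                      package = "cgsugar")
  if (!nzchar(path))
    stop("no shipped template for sugar '", sugar_id,
         "'; available: GLC, MAN (or supply a file via read_template)")
  tpl <- read_template(path)
  .template_cache[[sugar_id]] <- tpl
  tpl
}

#' Glycosidic linkage specification
#'
#' @param position Linkage position on the reducing (acceptor) residue; one
#'   of 1, 2, 3, 4, 6.
#' @param glycosidic_anomer Configuration at the non-reducing C1 taking part
#'   in the glycosidic bond: `"ALPHA"` or `"BETA"`.
#' @param reducing_anomer Anomeric configuration of the free reducing end.
#' @return An object of class `linkage_spec`.
#' @export
linkage_spec <- function(position, glycosidic_anomer, reducing_anomer) {
  position <- as.integer(position)
  if (length(position) != 1L || !position %in% LINK_POSITIONS)
    stop("position must be one of {", paste(LINK_POSITIONS, collapse = ", "),
         "}, got ", position)
  glycosidic_anomer <- match.arg(toupper(glycosidic_anomer), names(ANOMER_LETTER))
  reducing_anomer <- match.arg(toupper(reducing_anomer), names(ANOMER_LETTER))
  structure(list(position = position, glycosidic_anomer = glycosidic_anomer,
                 reducing_anomer = reducing_anomer), class = "linkage_spec")
}

#' Disaccharide specification
#'
#' Joins a non-reducing donor residue (contributing its anomeric C1) to an
#' acceptor (reducing) residue through a glycosidic linkage, and carries the
#' systematic GLYCAM-style name.
#'
#' @param donor,acceptor Sugar identifiers (`"GLC"`/`"MAN"`) or
#'   `mono_template` objects.
#' @param linkage A [linkage_spec()].
#' @return An object of class `disaccharide_spec` with elements `donor`,
#'   `acceptor`, `linkage`, `name`.
#' @export
disaccharide_spec <- function(donor, acceptor, linkage) {
  if (is.character(donor)) donor <- load_template(donor)
  if (is.character(acceptor)) acceptor <- load_template(acceptor)
  stopifnot(inherits(donor, "mono_template"),
            inherits(acceptor, "mono_template"),
            inherits(linkage, "linkage_spec"))
  spec <- structure(list(donor = donor, acceptor = acceptor,
                         linkage = linkage, name = NA_character_),
                    class = "disaccharide_spec")
  spec$name <- glycam_name(spec)
  spec
}

#' @export
print.disaccharide_spec <- function(x, ...) {
  cat(sprintf("<disaccharide_spec> %s: %s%s(1->%d)%s%s\n", x$name,
              x$donor$sugar_id, tolower(substr(x$linkage$glycosidic_anomer, 1, 1)),
              x$linkage$position, x$acceptor$sugar_id,
              tolower(substr(x$linkage$reducing_anomer, 1, 1))))
  invisible(x)
}

#' GLYCAM-style disaccharide name
#'
#' The reducing residue is coded with its linkage position digit, the
#' terminal donor with "0"; letters G/M select the hexose and A/B the
#' anomeric configuration.  For example Glc-alpha-(1->4)-Glc-beta is
#' `"4GB_0GA"` (beta-maltose).
#'
#' @param spec A [disaccharide_spec()].
#' @return A character scalar such as `"4GB_0GA"`.
#' @export
glycam_name <- function(spec) {
  stopifnot(inherits(spec, "disaccharide_spec"))
  lk <- spec$linkage
  paste0(lk$position, SUGAR_LETTER[[spec$acceptor$sugar_id]],
         ANOMER_LETTER[[lk$reducing_anomer]], "_0",
         SUGAR_LETTER[[spec$donor$sugar_id]],
         ANOMER_LETTER[[lk$glycosidic_anomer]])
}

#' Enumerate homodimeric disaccharides
#'
#' Generates every anomeric combination (2 glycosidic x 2 reducing) for each
#' sugar and linkage position: glucose alone over positions 1,2,3,4,6 yields
#' the 20 unique glucose disaccharides, glucose plus mannose the full 40.
#' The two mixed-anomer 1,1 entries (e.g. `1GA_0GB` / `1GB_0GA`) describe the
#' same molecule read from either end; they are counted separately by
#' default and collapsed by `dedupe_symmetric = TRUE`.
#'
#' @param sugars Character vector of sugar identifiers (`"GLC"`, `"MAN"`).
#' @param positions Integer vector of linkage positions, subset of
#'   {1,2,3,4,6}.
#' @param dedupe_symmetric Drop the redundant member of each symmetric
#'   1,1 mixed-anomer pair.
#' @return A list of [disaccharide_spec()] objects in deterministic order
#'   (sugar, then position, then glycosidic anomer, then reducing anomer).
#' @examples
#' length(enumerate_disaccharides("GLC"))          # 20
#' length(enumerate_disaccharides(c("GLC", "MAN"))) # 40
#' @export
enumerate_disaccharides <- function(sugars, positions = LINK_POSITIONS,
                                    dedupe_symmetric = FALSE) {
  if (length(sugars) == 0L) stop("sugars must be non-empty")
  positions <- as.integer(positions)
  bad <- setdiff(positions, LINK_POSITIONS)
  if (length(bad))
    stop("invalid linkage position(s) ", paste(bad, collapse = ", "),
         "; allowed: {", paste(LINK_POSITIONS, collapse = ", "), "}")
  out <- list()
  for (s in sugars) {
    tpl <- if (is.character(s)) load_template(s) else s
    for (p in positions) {
      for (ga in names(ANOMER_LETTER)) {
        for (ra in names(ANOMER_LETTER)) {
          if (dedupe_symmetric && p == 1L && ga == "BETA" && ra == "ALPHA")
            next  # same molecule as 1,1 (ALPHA, BETA) read from the other end
          out[[length(out) + 1L]] <-
            disaccharide_spec(tpl, tpl, linkage_spec(p, ga, ra))
        }
      }
    }
  }
  out
}

#' Build the all-atom graph of a disaccharide
#'
#' Performs the condensation joining the two residue templates: the donor
#' loses its anomeric O1-HO1 group, the acceptor hydroxyl at the linkage
#' position loses its hydrogen, and the retained acceptor oxygen becomes the
#' glycosidic bridge bonded to the donor C1.  Residue 1 is the donor
#' (non-reducing), residue 2 the acceptor (reducing end).  Atom identifiers
#' are `"<residue>:<name>"`.
#'
#' @param spec A [disaccharide_spec()].
#' @return An object of class `atom_graph` with elements `atoms` (data
#'   frame: id, residue, name, element, heavy), `bonds` (two-column id
#'   matrix), `glycosidic_oxygen` (atom id) and `spec`.
#' @export
build_atom_graph <- function(spec) {
  stopifnot(inherits(spec, "disaccharide_spec"))
  p <- spec$linkage$position
  res_atoms <- function(tpl, res) {
    a <- tpl$atoms
    data.frame(id = paste0(res, ":", a$name), residue = res, name = a$name,
               element = a$element, heavy = a$heavy, stringsAsFactors = FALSE)
  }
  res_bonds <- function(tpl, res) {
    matrix(paste0(res, ":", tpl$bonds), ncol = 2L)
  }
  atoms <- rbind(res_atoms(spec$donor, 1L), res_atoms(spec$acceptor, 2L))
  bonds <- rbind(res_bonds(spec$donor, 1L), res_bonds(spec$acceptor, 2L))
  glyc_o_name <- spec$acceptor$hydroxyl_map[[as.character(p)]]
  glyc_o <- paste0("2:", glyc_o_name)
  # hydroxyl hydrogen bonded to the glycosidic oxygen (to be removed)
  partners <- c(bonds[bonds[, 1L] == glyc_o, 2L], bonds[bonds[, 2L] == glyc_o, 1L])
  glyc_oh <- partners[atoms$element[match(partners, atoms$id)] == "H"]
  drop <- c("1:O1", "1:HO1", glyc_oh)
  atoms <- atoms[!atoms$id %in% drop, , drop = FALSE]
  bonds <- bonds[!(bonds[, 1L] %in% drop | bonds[, 2L] %in% drop), , drop = FALSE]
  bonds <- rbind(bonds, c("1:C1", glyc_o))
  rownames(atoms) <- atoms$id
  g <- structure(list(atoms = atoms, bonds = bonds,
                      glycosidic_oxygen = glyc_o, spec = spec),
                 class = "atom_graph")
  ig <- graph_of(g)
  if (igraph::components(ig)$no != 1L)
    stop("assembled atom graph is not connected")
  g
}

# igraph view of an atom_graph (vertex names = atom ids)
graph_of <- function(g) {
  ig <- igraph::make_empty_graph(n = nrow(g$atoms), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$atoms$id)
  igraph::add_edges(ig, t(matrix(match(g$bonds, g$atoms$id), ncol = 2L)))
}

# adjacency list keyed by atom id
adjacency_of <- function(g) {
  adj <- setNames(vector("list", nrow(g$atoms)), g$atoms$id)
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds[k, 1L]; b <- g$bonds[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Automated-parametrization success rate
#'
#' Fraction (percent) of enumerated disaccharides that pass the automated
#' mapping without manual intervention.
#'
#' @param n_total Number of disaccharides attempted.
#' @param n_manual Number requiring a manual mapping file.
#' @return Percentage of fully automated cases.
#' @examples
#' automation_success_rate(40, 12)  # 70
#' @export
automation_success_rate <- function(n_total, n_manual) {
  stopifnot(n_total > 0, n_manual >= 0, n_manual <= n_total)
  100 * (n_total - n_manual) / n_total
}
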