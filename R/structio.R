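#' @importFrom stats runif rnorm rbinom setNames cov
#' @importFrom utils read.csv write.table head
NULL

# Internal atom table columns shared by all constructors.
.atom_cols <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                "x", "y", "z", "o", "b")

#' Construct a structure model from an atom table
#'
#' A structure model is the package's in-memory coordinate container: an
#' ordered atom table in author numbering (chain, residue number, insertion
#' code, residue name, atom name, element, position, occupancy, B-factor).
#' Hydrogens and waters are dropped on construction; deposited models at
#' typical cryo-EM/crystallographic resolutions carry no reliable hydrogen
#' positions.
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{elety}, \code{elesy}, \code{x},
#'   \code{y}, \code{z}, \code{o}, \code{b}. Missing \code{insert},
#'   \code{o}, \code{b}, \code{elesy} columns are filled with defaults.
#' @param title character title.
#' @param source_format one of \code{"pdb"}, \code{"mmcif"}, \code{"memory"}.
#' @return object of class \code{xl_structure}.
#' @export
structure_model <- function(atoms, title = "", source_format = "memory") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$elesy)) atoms$elesy <- .guess_element(atoms$elety)
  atoms$insert[is.na(atoms$insert)] <- ""
  missing <- setdiff(.atom_cols, names(atoms))
  if (length(missing))
    stop("atom table missing columns: ", paste(missing, collapse = ", "))
  atoms <- atoms[, .atom_cols]
  keep <- !(toupper(atoms$resid) %in% c("HOH", "WAT", "DOD")) &
    toupper(atoms$elesy) != "H" & toupper(atoms$elesy) != "D"
  atoms <- atoms[keep, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("empty model: no non-water heavy atoms")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate atom address (chain, resno, insert, atom name): ",
         key[duplicated(key)][1])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title,
                 source_format = source_format),
            class = "xl_structure")
}

.guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", trimws(elety))
  toupper(substr(e, 1, 1))
}

#' @export
print.xl_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<xl_structure> %d atoms, %d chains (%s), %d residues\n",
              nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              length(unique(paste(a$chain, a$resno, a$insert)))))
  if (nzchar(x$title)) cat(" title:", x$title, "\n")
  invisible(x)
}

#' Read a coordinate model from PDB or mmCIF
#'
#' Loads ATOM/HETATM records into a structure model. Multi-model files are
#' reduced to the first model (with a warning); alternate locations are
#' collapsed to the highest-occupancy conformer, ties broken by first
#' occurrence in the file. Hydrogens and waters are dropped.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"}, or
#'   \code{"mmcif"}.
#' @return \code{xl_structure}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      # suppress read.cif's unconditional beta-status warnings
      suppressWarnings(
        bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE,
                        verbose = FALSE))
    },
    error = function(e) stop("unparseable ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model: ", path)
  if (!is.null(pdb$xyz) && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1L)
    warning("multi-model file; using first model only: ", path)
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- ""
  a$o[is.na(a$o)] <- 1
  a$b[is.na(a$b)] <- 0
  atoms <- data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
                      resid = a$resid, elety = a$elety, elesy = a$elesy,
                      x = a$x, y = a$y, z = a$z, o = a$o, b = a$b,
                      stringsAsFactors = FALSE)
  atoms <- .collapse_altloc(atoms, alt = a$alt)
  structure_model(atoms, title = basename(path), source_format = format)
}

# Highest-occupancy conformer per (chain,resno,insert,elety); ties first-seen.
.collapse_altloc <- function(atoms, alt) {
  if (is.null(alt)) alt <- rep(NA_character_, nrow(atoms))
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$o, seq_len(nrow(atoms)), method = "radix")
  keep <- ord[!duplicated(key[ord])]
  atoms[sort(keep), , drop = FALSE]
}

#' Write a coordinate model to PDB or mmCIF
#'
#' PDB output uses fixed-width v3.3 ATOM records (coordinates limited to
#' three decimals by the format); mmCIF output writes a minimal
#' \code{_atom_site} loop. A written model re-read with
#' \code{\link{read_structure}} reproduces atom identities and coordinates
#' to 1e-3 Angstrom.
#'
#' @param model \code{xl_structure}.
#' @param path output file path.
#' @param format \code{"pdb"} or \code{"mmcif"}.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif")) {
  stopifnot(inherits(model, "xl_structure"))
  format <- match.arg(format)
  a <- model$atoms
  if (nrow(a) == 0L) stop("refusing to write empty model")
  if (format == "pdb") {
    xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
    bio3d::write.pdb(file = path, xyz = xyz, resno = a$resno,
                     resid = a$resid, eleno = seq_len(nrow(a)),
                     elety = a$elety, chain = a$chain,
                     insert = ifelse(nzchar(a$insert), a$insert, NA),
                     o = a$o, b = a$b, elesy = a$elesy, verbose = FALSE)
  } else {
    .write_mmcif(a, path, title = model$title)
  }
  invisible(path)
}

# Canonical PDBx/mmCIF _atom_site loop (standard 21-field column order).
.write_mmcif <- function(a, path, title = "model") {
  con <- file(path, "w")
  on.exit(close(con))
  id <- gsub("[^A-Za-z0-9_-]", "_", ifelse(nzchar(title), title, "model"))
  fields <- c("group_PDB", "id", "type_symbol", "label_atom_id",
              "label_alt_id", "label_comp_id", "label_asym_id",
              "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
              "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
              "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
              "auth_comp_id", "auth_asym_id", "auth_atom_id",
              "pdbx_PDB_model_num")
  writeLines(c(paste0("data_", id), "#", "loop_",
               paste0("_atom_site.", fields)), con)
  lines <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    seq_len(nrow(a)), a$elesy, a$elety, a$resid, a$chain, a$resno,
    ifelse(nzchar(a$insert), a$insert, "?"),
    a$x, a$y, a$z, a$o, a$b, a$resno, a$resid, a$chain, a$elety)
  writeLines(lines, con)
  writeLines("#", con)
}

#' Select atoms from a model
#'
#' @param model \code{xl_structure}.
#' @param chains optional character vector of chain ids.
#' @param resno optional integer vector of residue numbers (author
#'   numbering), applied after the chain filter.
#' @param elety optional atom-name filter (e.g., \code{"CA"}).
#' @return integer vector of row indices into \code{model$atoms}.
#' @export
select_atoms <- function(model, chains = NULL, resno = NULL, elety = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) keep <- keep & a$chain %in% chains
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  which(keep)
}

#' Extract a sub-model
#'
#' @param model \code{xl_structure}.
#' @param idx integer row indices (as from \code{\link{select_atoms}}).
#' @return \code{xl_structure} restricted to the selected atoms.
#' @export
subset_structure <- function(model, idx) {
  structure_model(model$atoms[idx, , drop = FALSE], title = model$title,
                  source_format = model$source_format)
}

#' C-alpha coordinates of a model
#'
#' @param model \code{xl_structure}.
#' @param chains optional chain filter.
#' @return numeric matrix (n x 3) of CA positions, with a companion
#'   attribute \code{address} (data.frame chain/resno/insert) in file order.
#' @export
ca_coords <- function(model, chains = NULL) {
  idx <- select_atoms(model, chains = chains, elety = "CA")
  a <- model$atoms[idx, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- NULL
  attr(m, "address") <- data.frame(chain = a$chain, resno = a$resno,
                                   insert = a$insert,
                                   stringsAsFactors = FALSE)
  m
}

# ---- chain mapping -------------------------------------------------------

#' Construct a chain map
#'
#' A chain map relates crosslink protein identities (full-length residue
#' numbering) to model chains (author numbering). Each entry maps a
#' full-length range \code{[first, last]} of \code{protein} onto chain
#' \code{chain} with \code{author_resno = full_length_resno + offset}.
#' Constructs are routinely truncations, and a protein present as a
#' homodimer maps to several chains: \code{\link{map_residue}} then returns
#' several addresses.
#'
#' @param entries data.frame with columns \code{protein}, \code{chain},
#'   \code{offset}, \code{first}, \code{last}.
#' @return object of class \code{xl_chainmap}.
#' @export
chain_map <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("protein", "chain", "offset", "first", "last")
  missing <- setdiff(need, names(entries))
  if (length(missing))
    stop("chain map missing columns: ", paste(missing, collapse = ", "))
  entries$offset <- as.integer(entries$offset)
  entries$first <- as.integer(entries$first)
  entries$last <- as.integer(entries$last)
  if (any(entries$last < entries$first))
    stop("chain map range with last < first")
  # ranges mapped onto one chain must not overlap in author numbering
  for (ch in unique(entries$chain)) {
    e <- entries[entries$chain == ch, , drop = FALSE]
    if (nrow(e) > 1L) {
      lo <- e$first + e$offset
      hi <- e$last + e$offset
      ord <- order(lo)
      if (any(lo[ord][-1] <= hi[ord][-nrow(e)]))
        stop("overlapping author-numbering ranges for chain ", ch)
    }
  }
  structure(list(entries = entries[, need]), class = "xl_chainmap")
}

#' Read a chain map from a YAML config
#'
#' Expected schema: a top-level \code{chains:} list whose elements carry
#' \code{protein}, \code{chain}, \code{offset}, \code{first}, \code{last}.
#'
#' @param path YAML file path.
#' @return \code{xl_chainmap}.
#' @export
read_chain_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$chains
  if (is.null(entries)) stop("chain map YAML lacks a 'chains' key: ", path)
  chain_map(do.call(rbind, lapply(entries, function(e)
    data.frame(protein = e$protein, chain = e$chain,
               offset = as.integer(e$offset %||% 0L),
               first = as.integer(e$first), last = as.integer(e$last),
               stringsAsFactors = FALSE))))
}

#' Write a chain map to YAML
#' @param cmap \code{xl_chainmap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_chain_map <- function(cmap, path) {
  e <- cmap$entries
  yaml::write_yaml(list(chains = lapply(seq_len(nrow(e)), function(i)
    as.list(e[i, ]))), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map a full-length residue to author-numbered model addresses
#'
#' Returns zero, one, or several (chain, resno) addresses. Zero rows means
#' the residue is unmapped (disordered or absent from the deposited
#' construct) -- a status, not an error -- so crosslinks into unresolved
#' regions can be excluded with explicit accounting. Several rows arise for
#' homodimers, where the crosslink names the protein but not the copy.
#'
#' @param cmap \code{xl_chainmap}.
#' @param protein protein name used in the crosslink table.
#' @param resno full-length residue number.
#' @param strict error (rather than return unmapped) when the protein name
#'   has no entry at all.
#' @return data.frame with columns \code{chain}, \code{resno} (author
#'   numbering); zero rows when unmapped.
#' @export
map_residue <- function(cmap, protein, resno, strict = FALSE) {
  e <- cmap$entries[cmap$entries$protein == protein, , drop = FALSE]
  if (nrow(e) == 0L) {
    if (strict) stop("unknown protein in chain map: ", protein)
    return(data.frame(chain = character(), resno = integer(),
                      stringsAsFactors = FALSE))
  }
  hit <- e$first <= resno & resno <= e$last
  data.frame(chain = e$chain[hit], resno = as.integer(resno + e$offset[hit]),
             stringsAsFactors = FALSE)
}
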