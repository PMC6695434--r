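# Structure and table I/O: PDB reading (via bio3d), vdW radius assignment,
# fixture writing, and residue scalar tables.

#' van der Waals radii by element
#'
#' Radius table used throughout the package: C 1.7, N 1.55, O 1.52, S 1.8,
#' H 1.2 Angstrom; any other element falls back to 1.7 Angstrom with a
#' warning at assignment time.
#'
#' @param elements character vector of element symbols (case-insensitive).
#' @param warn_unknown logical; warn once when unknown elements fall back
#'   to 1.7 Angstrom.
#' @return numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdw_radius(c("C", "N", "O", "S", "H", "Se"))
vdw_radius <- function(elements, warn_unknown = TRUE) {
  tab <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2)
  key <- toupper(trimws(elements))
  r <- unname(tab[key])
  unknown <- is.na(r)
  if (any(unknown)) {
    if (warn_unknown) {
      warning(sprintf(
        "unknown element(s) %s assigned fallback vdW radius 1.7 A",
        paste(unique(key[unknown]), collapse = ", ")))
    }
    r[unknown] <- 1.7
  }
  r
}

#' Construct an atom cloud
#'
#' An `atom_cloud` is a data frame of atom records (element, x/y/z in
#' Angstrom, vdW radius, residue index and 3-letter type, chain id, and a
#' C-alpha flag) carrying a source label. It is the universal structural
#' input for shape and mapping operations.
#'
#' @param element character element symbols.
#' @param x,y,z numeric coordinates (Angstrom).
#' @param radius numeric vdW radii (Angstrom); default from [vdw_radius()].
#' @param resno integer residue indices.
#' @param resid character 3-letter residue types.
#' @param chain character chain identifiers.
#' @param calpha logical C-alpha flags.
#' @param source character source label.
#' @return object of class `atom_cloud` (a data frame).
#' @export
atom_cloud <- function(element, x, y, z,
                       radius = vdw_radius(element, warn_unknown = FALSE),
                       resno = seq_along(x),
                       resid = "ALA",
                       chain = "A",
                       calpha = FALSE,
                       source = "synthetic") {
  n <- length(x)
  cl <- data.frame(
    element = rep_len(as.character(element), n),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    radius = rep_len(as.numeric(radius), n),
    resno = rep_len(as.integer(resno), n),
    resid = rep_len(as.character(resid), n),
    chain = rep_len(as.character(chain), n),
    calpha = rep_len(as.logical(calpha), n),
    stringsAsFactors = FALSE)
  attr(cl, "source") <- source
  class(cl) <- c("atom_cloud", "data.frame")
  validate_atom_cloud(cl)
  cl
}

validate_atom_cloud <- function(cl) {
  if (nrow(cl) < 1L) stop("atom_cloud is empty")
  if (!all(is.finite(cl$x) & is.finite(cl$y) & is.finite(cl$z)))
    stop("atom_cloud coordinates must be finite")
  if (!all(cl$radius > 0)) stop("atom_cloud radii must be positive")
  ord <- unlist(tapply(cl$resno, cl$chain, function(v) all(diff(v) >= 0)),
                use.names = FALSE)
  if (!all(ord))
    stop("residue indices must be non-decreasing within each chain")
  invisible(cl)
}

#' @export
print.atom_cloud <- function(x, ...) {
  cat(sprintf("<atom_cloud> %d atoms, %d residues, %d chain(s) [%s]\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              length(unique(x$chain)),
              attr(x, "source") %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records, keeps the first MODEL of multi-model files and the
#' highest-occupancy alternate conformer, excludes HETATM records (waters
#' and ligands), and assigns vdW radii from the element table. Elements are
#' taken from the element column when present, else inferred from the atom
#' name (with a message for every fallback).
#'
#' @param path path to a PDB file.
#' @param include_hydrogens keep hydrogen atoms? Default `FALSE`.
#' @return an [atom_cloud()].
#' @export
read_structure <- function(path, include_hydrogens = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop(sprintf(
      "PDB parse failure in '%s': %s", path, conditionMessage(e))))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L)
    stop(sprintf("no ATOM records in '%s' (line 1 onward scanned)", path))
  # alternate locations: keep the highest-occupancy conformer per atom site
  alt <- at$alt
  if (any(!is.na(alt) & alt != "")) {
    site <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), site), function(idx) {
      if (length(idx) == 1L) return(idx)
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  elem <- at$elesy
  need_guess <- is.na(elem) | trimws(elem) == ""
  if (any(need_guess)) {
    guessed <- guess_element(at$elety[need_guess])
    message(sprintf("inferred element from atom name for %d atom(s)",
                    sum(need_guess)))
    elem[need_guess] <- guessed
  }
  elem <- toupper(trimws(elem))
  if (!include_hydrogens) {
    keep <- !(elem %in% c("H", "D"))
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
  }
  if (nrow(at) == 0L) stop("no atoms left after hydrogen filtering")
  atom_cloud(
    element = elem,
    x = at$x, y = at$y, z = at$z,
    radius = vdw_radius(elem),
    resno = at$resno,
    resid = at$resid,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    calpha = at$elety == "CA" & elem == "C",
    source = basename(path))
}

guess_element <- function(atom_names) {
  nm <- toupper(trimws(atom_names))
  # strip leading digits (e.g. "1HB"), take first letter; two-letter check
  nm <- sub("^[0-9]+", "", nm)
  first <- substr(nm, 1L, 1L)
  ifelse(first %in% c("C", "N", "O", "S", "H"), first, "X")
}

#' Write an atom cloud as a PDB fixture
#'
#' Emits standard ATOM records re-readable by [read_structure()].
#' Coordinates are written at PDB precision (3 decimals).
#'
#' @param cloud an [atom_cloud()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(cloud, path) {
  validate_atom_cloud(cloud)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("unwritable path: %s", path))
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(cloud[, c("x", "y", "z")]))),
      resno = cloud$resno,
      resid = cloud$resid,
      eleno = seq_len(nrow(cloud)),
      elety = ifelse(cloud$calpha, "CA",
                     paste0(cloud$element, seq_len(nrow(cloud)) %% 10)),
      chain = cloud$chain,
      o = rep(1.00, nrow(cloud)), b = rep(0.00, nrow(cloud)),
      elesy = cloud$element)
    TRUE
  }, error = function(e) stop(sprintf(
    "failed writing '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

#' Read a residue scalar table
#'
#' Tab-separated table with header `residue_index<TAB>value`, one finite
#' value per residue (e.g. per-position evolutionary rates normalised to the
#' average of all positions, or surface propensities).
#'
#' @param path TSV file path.
#' @return a `residue_scalar_table`: data frame with columns
#'   `residue_index`, `value`.
#' @export
read_residue_scalars <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("residue_index", "value") %in% names(tb)))
    stop("expected columns 'residue_index' and 'value'")
  residue_scalar_table(tb$residue_index, tb$value)
}

#' Construct a residue scalar table
#'
#' @param residue_index integer residue indices (unique).
#' @param value finite numeric scalars, one per residue.
#' @return a `residue_scalar_table` data frame.
#' @export
residue_scalar_table <- function(residue_index, value) {
  if (anyDuplicated(residue_index))
    stop("one value per residue: duplicated residue_index")
  if (!all(is.finite(value))) stop("scalar values must be finite")
  tb <- data.frame(residue_index = as.integer(residue_index),
                   value = as.numeric(value))
  class(tb) <- c("residue_scalar_table", "data.frame")
  tb
}

#' Write a residue scalar table to TSV
#'
#' @param table a `residue_scalar_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_residue_scalars <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
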