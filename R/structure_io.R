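#' Read a protein structure from a PDB or mmCIF file
#'
#' Parses all `ATOM` records of the first model in the file. `HETATM`
#' records (including waters and ligands) and hydrogen atoms are excluded;
#' alternate locations are resolved by keeping the conformer with the
#' highest occupancy (ties go to the first one encountered). The B-factor
#' column is retained per atom because predicted models (e.g. AlphaFold)
#' store the per-residue pLDDT confidence there.
#'
#' @param path Path to a structure file.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`. With `"auto"` the
#'   format is chosen by file extension (`.cif`/`.mmcif` vs anything else),
#'   falling back to content sniffing for extensionless files.
#' @param id Identifier for the structure; defaults to the file name without
#'   extension.
#' @return An object of class `zd_structure`: a list with `id`, `atoms`
#'   (a data frame with columns `element`, `name`, `x`, `y`, `z`, `chain`,
#'   `resno`, `residue_index`, `bfactor`, `occupancy`) and `n_residues`.
#'   `residue_index` is the 1-based sequential index of the residue within
#'   the file; `resno` is the author-assigned residue number.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
    else if (ext %in% c("pdb", "ent", "")) {
      head_lines <- tryCatch(readLines(path, n = 50L, warn = FALSE),
                             error = function(e) character())
      if (ext == "" && any(grepl("^\\s*(data_|_atom_site\\.)", head_lines)))
        "mmcif" else "pdb"
    } else "pdb"
  }
  obj <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                           verbose = FALSE)
      else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- obj$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  # drop hydrogens (element symbol if present, else leading atom-name letter)
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1L, 1L), at$elesy)))
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  elem <- elem[!(elem %in% c("H", "D"))]
  if (nrow(at) == 0L)
    stop("no protein ATOM records remain after filtering in '", path, "'")

  insert <- if (is.null(at$insert)) rep("", nrow(at)) else ifelse(is.na(at$insert), "", at$insert)
  res_key <- paste(at$chain, at$resno, insert, sep = "|")
  # resolve altlocs: per (residue, atom name) keep the highest occupancy,
  # first encountered on ties
  alt <- if (is.null(at$alt)) rep("", nrow(at)) else ifelse(is.na(at$alt), "", at$alt)
  occ <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
  atom_key <- paste(res_key, trimws(at$elety), sep = "|")
  if (any(alt != "")) {
    # stable: order by occupancy (desc) keeping original order on ties
    ord <- order(-occ, seq_len(nrow(at)))
    first_best <- ord[!duplicated(atom_key[ord])]
    keep <- sort(first_best)
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
    res_key <- res_key[keep]
    occ <- occ[keep]
  }

  residue_index <- match(res_key, unique(res_key))
  atoms <- data.frame(
    element = elem,
    name = trimws(at$elety),
    x = at$x, y = at$y, z = at$z,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    residue_index = residue_index,
    bfactor = at$b,
    occupancy = occ,
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in '", path, "'")

  structure(list(
    id = if (is.null(id)) tools::file_path_sans_ext(basename(path)) else id,
    atoms = atoms,
    n_residues = length(unique(res_key))),
    class = "zd_structure")
}

#' @export
print.zd_structure <- function(x, ...) {
  cat("<zd_structure> ", x$id, ": ", nrow(x$atoms), " atoms, ",
      x$n_residues, " residues\n", sep = "")
  invisible(x)
}

#' Construct a structure object from an atom table
#'
#' Used by the fixture generators and tests; performs the same invariant
#' checks as [parse_structure()].
#'
#' @param atoms Data frame with at least `element`, `name`, `x`, `y`, `z`,
#'   `chain`, `resno`, `bfactor`.
#' @param id Structure identifier.
#' @return A `zd_structure`.
#' @export
as_zd_structure <- function(atoms, id = "structure") {
  stopifnot(is.data.frame(atoms),
            all(c("element", "name", "x", "y", "z", "chain", "resno") %in% names(atoms)))
  if (is.null(atoms$bfactor)) atoms$bfactor <- 0
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  res_key <- paste(atoms$chain, atoms$resno, sep = "|")
  atoms$residue_index <- match(res_key, unique(res_key))
  structure(list(id = id, atoms = atoms, n_residues = length(unique(res_key))),
            class = "zd_structure")
}

#' Write a structure to a PDB file
#'
#' Fixed-column `ATOM` records; used to materialize synthetic fixtures so
#' the command-line tools can consume them unchanged.
#'
#' @param s A `zd_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  stopifnot(inherits(s, "zd_structure"))
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = rep("ALA", nrow(a)),
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain, o = a$occupancy, b = a$bfactor,
                   elesy = a$element)
  invisible(path)
}

#' Select an atom subset for surface generation
#'
#' Full-atom surfaces use every heavy atom; the main-chain representation
#' keeps only the backbone C-alpha, C and N atoms, which was found to give
#' a smoother, better-performing surface for fold retrieval.
#'
#' @param s A `zd_structure`.
#' @param mode `"full_atom"` or `"main_chain"`.
#' @return A data frame of atoms (subset of `s$atoms`).
#' @export
select_atoms <- function(s, mode = c("full_atom", "main_chain")) {
  stopifnot(inherits(s, "zd_structure"))
  mode <- match.arg(mode)
  if (nrow(s$atoms) == 0L) stop("structure has no atoms")
  if (mode == "full_atom") {
    s$atoms[!(s$atoms$element %in% c("H", "D")), , drop = FALSE]
  } else {
    sel <- s$atoms[s$atoms$name %in% c("CA", "C", "N"), , drop = FALSE]
    if (nrow(sel) == 0L)
      stop("no main-chain (CA, C, N) atoms found; not a protein structure?")
    sel
  }
}

#' Per-residue confidence profile (pLDDT)
#'
#' Returns one value per residue taken from the B-factor of the CA atom
#' (falling back to the first atom of the residue). Predicted models store
#' pLDDT on a 0-100 scale in this column; profiles whose maximum is <= 1
#' are assumed to be on a 0-1 scale and are rescaled by 100 so that the
#' canonical internal scale is always 0-100.
#'
#' @param s A `zd_structure`.
#' @return Numeric vector of length `s$n_residues`, class
#'   `zd_confidence_profile`.
#' @export
confidence_profile <- function(s) {
  stopifnot(inherits(s, "zd_structure"))
  a <- s$atoms
  if (all(is.na(a$bfactor))) stop("structure has no B-factor values")
  vals <- vapply(seq_len(s$n_residues), function(i) {
    res <- a[a$residue_index == i, , drop = FALSE]
    ca <- which(res$name == "CA")
    b <- if (length(ca)) res$bfactor[ca[1L]] else res$bfactor[1L]
    if (is.na(b)) stop("residue ", i, " has no B-factor value")
    as.numeric(b)
  }, numeric(1))
  if (max(vals) <= 1.0) vals <- vals * 100
  if (any(vals < 0 | vals > 100))
    stop("confidence values outside [0, 100] after rescaling")
  structure(vals, class = "zd_confidence_profile")
}
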