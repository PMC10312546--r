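## Atomic model and 1D profile input/output.
##
## Atoms are represented as a plain data.frame with columns
##   x, y, z        coordinates, Angstrom
##   element        chemical symbol, resolvable by ff_coeffs()
##   atom_name      PDB atom-name string ("CA", "HB2", ...)
##   residue_name   3-letter residue code
##   resno, chain   residue number and chain id (diagnostics only)
##   b_factor       isotropic B-factor, squared Angstrom, >= 0
##   occupancy      in [0, 1]

#' Assemble an atom table
#'
#' Low-level constructor used by fixtures and parsers; validates the fields
#' required by the density and volume calculations.
#'
#' @param x,y,z Coordinates in Angstrom.
#' @param element Chemical symbols.
#' @param atom_name PDB-style atom names.
#' @param residue_name 3-letter residue codes.
#' @param resno Residue numbers.
#' @param chain Chain identifiers.
#' @param b_factor Isotropic B-factors (squared Angstrom, non-negative).
#' @param occupancy Occupancies in `[0, 1]`.
#' @return A `data.frame` of atoms.
#' @export
atom_table <- function(x, y, z, element, atom_name = element,
                       residue_name = "UNK", resno = 1L, chain = "A",
                       b_factor = 0, occupancy = 1) {
  atoms <- data.frame(x = x, y = y, z = z,
                      element = .norm_element(element),
                      atom_name = trimws(atom_name),
                      residue_name = trimws(residue_name),
                      resno = resno, chain = chain,
                      b_factor = b_factor, occupancy = occupancy,
                      stringsAsFactors = FALSE)
  bad <- !atoms$element %in% names(.cm_table)
  if (any(bad))
    stop("unknown element(s): ", paste(unique(atoms$element[bad]), collapse = ", "),
         call. = FALSE)
  if (any(atoms$b_factor < 0)) stop("negative b_factor", call. = FALSE)
  atoms
}

#' Atom coordinates as a matrix
#'
#' @param atoms Atom data.frame.
#' @return Numeric matrix with columns x, y, z.
#' @export
atom_coords <- function(atoms) cbind(x = atoms$x, y = atoms$y, z = atoms$z)

## element inference from PDB atom names, used only when the element column is
## absent or blank; every fallback is reported
.element_from_name <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  nm <- sub("^[0-9']+", "", nm)        # "1HB2" -> "HB2"
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "NA", "MG", "FE", "ZN", "SE", "CA"),
                two, substr(nm, 1, 1))
  ## bare "CA" as an atom name is a calcium ion only in ion residues; in
  ## proteins it is the alpha carbon, which single-letter truncation handles
  ifelse(nm == "CA", "C", out)
}

#' Read an atomic model from a PDB file
#'
#' Parses ATOM/HETATM records, resolves alternate locations by keeping the
#' highest-occupancy conformer, and optionally drops solvent waters. Models
#' are expected to carry explicit hydrogens; a model without any hydrogen
#' triggers a warning because both the excluded-volume and the scattering
#' calculation would be systematically wrong without them.
#'
#' @param path Path to a PDB file.
#' @param exclude_waters Drop HOH/WAT/DOD residues (default `TRUE`).
#' @return Atom `data.frame` (see [atom_table()]).
#' @export
read_pdb <- function(path, exclude_waters = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) < 1) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  if (exclude_waters) at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (nrow(at) < 1) stop("no atoms left after water removal in ", path, call. = FALSE)

  ## alternate locations: keep the highest-occupancy conformer per atom site
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$resid, trimws(at$elety), sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
      i[which.max(occ[i])]
    }), use.names = FALSE)
    n_drop <- nrow(at) - length(keep)
    if (n_drop > 0)
      message("read_pdb: resolved alternate locations, dropped ", n_drop,
              " lower-occupancy conformer(s)")
    at <- at[sort(keep), , drop = FALSE]
  }

  elem <- toupper(trimws(at$elesy))
  elem[is.na(elem)] <- ""
  miss <- elem == ""
  if (any(miss)) {
    elem[miss] <- .element_from_name(at$elety[miss])
    message("read_pdb: inferred element from atom name for ", sum(miss),
            " atom(s) lacking an element column")
  }
  elem[elem == "D"] <- "H"
  bad <- !elem %in% names(.cm_table)
  if (any(bad))
    stop("unknown element symbol '", elem[which(bad)[1]], "' at atom serial ",
         at$eleno[which(bad)[1]], call. = FALSE)

  occ <- ifelse(is.na(at$o), 1, at$o)
  bfc <- ifelse(is.na(at$b), 0, at$b)
  atoms <- atom_table(at$x, at$y, at$z, elem, at$elety, at$resid,
                      at$resno, ifelse(is.na(at$chain), "A", at$chain),
                      pmax(bfc, 0), occ)
  if (!any(atoms$element == "H"))
    warning("model contains no hydrogen atoms; adjusted volumes and the ",
            "calculated profile will be systematically wrong", call. = FALSE)
  atoms
}

#' Write an atom table as a PDB file
#'
#' Minimal fixed-column ATOM-record writer used to emit synthetic fixtures so
#' the command-line path can be exercised end-to-end.
#'
#' @param atoms Atom data.frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(atoms, path) {
  nm <- atoms$atom_name
  ## PDB column 13-16: element right-justified into cols 13-14 for 1-letter
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4),
                ifelse(nchar(atoms$element) == 1, sprintf(" %-3s", nm),
                       sprintf("%-4s", nm)))
  lines <- sprintf("ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(nrow(atoms)), nm4, atoms$residue_name,
                   substr(atoms$chain, 1, 1), atoms$resno,
                   atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$b_factor,
                   atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Construct a scattering profile
#'
#' @param q Momentum transfer, inverse Angstrom, strictly increasing.
#' @param I Intensities (arbitrary units).
#' @param sigma Experimental errors, same units as `I`; may be `NULL` for
#'   calculated profiles.
#' @return Object of class `swaxs_profile`: a data.frame with columns `q`,
#'   `I` and (if given) `sigma`.
#' @export
swaxs_profile <- function(q, I, sigma = NULL) {
  if (length(q) != length(I)) stop("q and I lengths differ", call. = FALSE)
  if (!is.null(sigma) && length(sigma) != length(q))
    stop("sigma length differs from q", call. = FALSE)
  if (any(diff(q) <= 0)) stop("q must be strictly increasing", call. = FALSE)
  df <- if (is.null(sigma)) data.frame(q = q, I = I)
        else data.frame(q = q, I = I, sigma = sigma)
  class(df) <- c("swaxs_profile", "data.frame")
  df
}

#' @export
print.swaxs_profile <- function(x, ...) {
  cat(sprintf("SWAXS profile: %d points, q in [%.4g, %.4g] 1/A%s\n",
              nrow(x), min(x$q), max(x$q),
              if ("sigma" %in% names(x)) ", with errors" else ""))
  invisible(x)
}

#' Read a 1D scattering profile from a text file
#'
#' Reads whitespace-delimited `q I [sigma]` columns (the SASBDB `.dat`
#' convention). Comment and header lines are tolerated; rows with non-numeric
#' entries or non-positive errors are dropped with a reported count.
#'
#' @param path File path.
#' @param require_sigma If `TRUE`, a missing error column is fatal (needed for
#'   fitting); otherwise errors are filled with 1.0 and a warning is issued.
#' @param q_unit `"A"` (inverse Angstrom, default) or `"nm"` (inverse
#'   nanometer, divided by 10 on input).
#' @return A `swaxs_profile` with `q` sorted ascending.
#' @export
read_profile <- function(path, require_sigma = FALSE, q_unit = c("A", "nm")) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) stop("cannot read profile file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:],]+")
  parsed <- lapply(toks, function(tk) suppressWarnings(as.numeric(tk)))
  ncols <- vapply(parsed, length, integer(1))
  ok <- ncols >= 2 & vapply(parsed, function(v) !anyNA(v[1:2]), logical(1))
  if (!any(ok)) stop("no numeric rows with >= 2 columns in ", path, call. = FALSE)
  rows <- parsed[ok]
  q <- vapply(rows, `[`, numeric(1), 1)
  I <- vapply(rows, `[`, numeric(1), 2)
  s <- vapply(rows, function(v) if (length(v) >= 3) v[3] else NA_real_, numeric(1))
  n_skipped <- sum(!ok)

  if (all(is.na(s))) {
    if (require_sigma)
      stop("profile ", path, " lacks an error column required for fitting", call. = FALSE)
    warning("profile ", path, " lacks an error column; sigma filled with 1.0",
            call. = FALSE)
    s <- rep(1, length(q))
  } else {
    drop_bad <- is.na(s) | s <= 0
    if (any(drop_bad)) {
      n_skipped <- n_skipped + sum(drop_bad)
      q <- q[!drop_bad]; I <- I[!drop_bad]; s <- s[!drop_bad]
    }
  }
  if (n_skipped > 0)
    message("read_profile: dropped ", n_skipped, " malformed or bad-sigma row(s)")
  if (length(q) == 0) stop("profile ", path, " empty after filtering", call. = FALSE)
  if (q_unit == "nm") q <- q / 10
  o <- order(q)
  q <- q[o]; I <- I[o]; s <- s[o]
  keep <- c(TRUE, diff(q) > 0)   # collapse exact duplicates in q
  swaxs_profile(q[keep], I[keep], s[keep])
}

#' Write a scattering profile as ASCII columns
#'
#' @param profile A `swaxs_profile`.
#' @param path Output path.
#' @param header Optional comment lines written with a leading `#`.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if ("sigma" %in% names(profile)) {
    writeLines(sprintf("%.8e %.8e %.8e", profile$q, profile$I, profile$sigma), con)
  } else {
    writeLines(sprintf("%.8e %.8e", profile$q, profile$I), con)
  }
  invisible(path)
}
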