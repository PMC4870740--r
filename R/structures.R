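#' @title Structure container
#' @description An `xbsf_structure` is a plain list with elements
#'   `atoms` (a data frame, one heavy or hydrogen atom per row),
#'   `model_id` (integer, from MODEL records; 1 for single-model files)
#'   and `resolution` (Angstroms, `NA` if the file carries no
#'   REMARK 2 RESOLUTION record). The `atoms` data frame columns are
#'   `serial`, `name`, `altloc`, `resname`, `chain`, `resno`, `x`, `y`,
#'   `z`, `occupancy`, `b`, `element`, `record` (ATOM or HETATM) and
#'   `is_water` (residue name HOH/WAT/H2O).
#' @name xbsf_structure
NULL

WATER_RESNAMES <- c("HOH", "WAT", "H2O")

# AutoDock atom types -> element, for PDBQT files.
AD_TYPE_ELEMENT <- c(
  C = "C", A = "C", N = "N", NA. = "N", NS = "N", O = "O", OA = "O",
  OS = "O", S = "S", SA = "S", H = "H", HD = "H", HS = "H", F = "F",
  CL = "Cl", BR = "Br", I = "I", P = "P", MG = "Mg", MN = "Mn",
  ZN = "Zn", CA = "Ca", FE = "Fe"
)

normalize_element <- function(el) {
  el <- toupper(trimws(el))
  two <- c(CL = "Cl", BR = "Br", SE = "Se", ZN = "Zn", MG = "Mg",
           MN = "Mn", FE = "Fe", CU = "Cu", NI = "Ni", CO = "Co",
           CD = "Cd", HG = "Hg", AS = "As", NA. = "Na", K = "K",
           I = "I", F = "F", C = "C", N = "N", O = "O", S = "S",
           P = "P", H = "H", B = "B", D = "H", CA = "Ca")
  ifelse(el %in% names(two), two[el],
         ifelse(nchar(el) > 0,
                paste0(substr(el, 1, 1),
                       tolower(substr(el, 2, nchar(el)))),
                ""))
}

# Element from an atom name when the element column is absent: strip
# digits/primes, prefer the two-letter halogens, else first letter.
element_from_name <- function(name) {
  alpha <- toupper(gsub("[^A-Za-z]", "", name))
  vapply(alpha, function(a) {
    if (a %in% c("CL", "BR")) return(normalize_element(a))
    if (nchar(a) == 0) return("")
    normalize_element(substr(a, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Parse a PDB or PDBQT structure file
#'
#' Reads ATOM/HETATM records by fixed columns, splitting multi-MODEL
#' files (e.g. docked pose sets written by docking engines) into one
#' structure per MODEL block. A file without MODEL records yields exactly
#' one structure. Waters are retained but flagged; alternate locations
#' other than blank or 'A' are dropped so geometry is deterministic.
#'
#' Element resolution: for PDB, the element column (77-78) when present,
#' else a name-based fallback; for PDBQT, the AutoDock atom type
#' (columns 78-79), else the name-based fallback. Every returned atom has
#' a non-empty element.
#'
#' @param path file to read.
#' @param dialect `"auto"` (by file extension), `"pdb"` or `"pdbqt"`.
#' @return A list of [xbsf_structure] objects, one per MODEL.
#' @export
#' @examples
#' cx <- make_complex(halogen = "I", acceptor = "O",
#'                    distance = 3.354, theta = 177.8)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(cx$ligand, f)
#' parse_structure(f)[[1]]$atoms
parse_structure <- function(path, dialect = c("auto", "pdb", "pdbqt")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE))
      "pdbqt" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty file: ", path)

  resolution <- NA_real_
  res_line <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(res_line) >= 1) {
    m <- regmatches(res_line[1],
                    regexpr("[0-9]+\\.?[0-9]*", sub("RESOLUTION", "", res_line[1])))
    if (length(m) == 1) resolution <- as.numeric(m)
  }

  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  model_of <- cumsum(is_model)
  has_models <- any(is_model)
  if (!has_models) model_of[] <- 1L
  model_ids <- sort(unique(model_of[is_atom]))
  if (length(model_ids) == 0) stop("no ATOM/HETATM records in ", path)

  parse_block <- function(model) {
    idx <- which(is_atom & model_of == model)
    ln <- lines[idx]
    num <- function(from, to, what) {
      v <- suppressWarnings(as.numeric(substr(ln, from, to)))
      bad <- which(!is.finite(v))
      if (what %in% c("x", "y", "z") && length(bad) > 0)
        stop("malformed ", what, " coordinate at line ", idx[bad[1]],
             " of ", path)
      v
    }
    atoms <- data.frame(
      serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
      name = trimws(substr(ln, 13, 16)),
      altloc = substr(ln, 17, 17),
      resname = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      resno = suppressWarnings(as.integer(substr(ln, 23, 26))),
      x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
      occupancy = num(55, 60, "occupancy"),
      b = num(61, 66, "b"),
      record = trimws(substr(ln, 1, 6)),
      stringsAsFactors = FALSE
    )
    atoms$occupancy[!is.finite(atoms$occupancy)] <- 1
    atoms$b[!is.finite(atoms$b)] <- 0

    if (dialect == "pdbqt") {
      ad <- toupper(trimws(substr(ln, 78, 79)))
      ad[ad == "NA"] <- "NA."
      el <- unname(AD_TYPE_ELEMENT[ad])
      el[is.na(el)] <- ""
    } else {
      el <- normalize_element(substr(ln, 77, 78))
    }
    missing <- !nzchar(el)
    el[missing] <- element_from_name(atoms$name[missing])
    if (any(!nzchar(el)))
      stop("could not resolve element at line ", idx[which(!nzchar(el))[1]],
           " of ", path)
    atoms$element <- el
    atoms$is_water <- atoms$resname %in% WATER_RESNAMES

    atoms <- atoms[atoms$altloc %in% c(" ", "", "A"), , drop = FALSE]
    rownames(atoms) <- NULL
    structure(list(atoms = atoms,
                   model_id = if (has_models) model else 1L,
                   resolution = resolution),
              class = "xbsf_structure")
  }

  out <- lapply(model_ids, parse_block)
  n_at <- vapply(out, function(s) nrow(s$atoms), integer(1))
  if (length(unique(n_at)) > 1)
    warning("models of ", path, " differ in atom count")
  out
}

#' @export
print.xbsf_structure <- function(x, ...) {
  cat(sprintf("xbsf_structure: %d atoms (model %d)%s\n",
              nrow(x$atoms), x$model_id,
              if (is.finite(x$resolution))
                sprintf(", resolution %.2f A", x$resolution) else ""))
  tab <- table(x$atoms$element)
  cat("  elements:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

format_atom_line <- function(a, record = NULL) {
  rec <- if (is.null(record)) a$record else record
  name <- a$name
  # PDB name justification: 1-3 char names start in column 14.
  name <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
  el <- toupper(a$element)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial, name, " ", a$resname,
          ifelse(nzchar(trimws(a$chain)), a$chain, "A"),
          a$resno, a$x, a$y, a$z, a$occupancy, a$b, el)
}

#' Write a structure (or a pose set) as PDB
#'
#' A list of structures is written as a multi-MODEL file.
#'
#' @param structure an [xbsf_structure] or a list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  if (inherits(structure, "xbsf_structure")) structure <- list(structure)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(structure) > 1
  for (i in seq_along(structure)) {
    atoms <- structure[[i]]$atoms
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(vapply(seq_len(nrow(atoms)), function(j)
      format_atom_line(atoms[j, ]), character(1)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Element -> AutoDock heavy-atom type (acceptors get their ...A types so
# the element round-trips through the PDBQT dialect).
element_to_ad_type <- function(el) {
  map <- c(C = "C", N = "NA", O = "OA", S = "SA", Cl = "Cl", Br = "Br",
           I = "I", F = "F", H = "HD", P = "P")
  ty <- unname(map[el])
  ty[is.na(ty)] <- toupper(substr(el[is.na(ty)], 1, 2))
  ty
}

#' Write a structure (or pose set) in the PDBQT dialect
#'
#' Emits the Vina-style multi-MODEL layout with zero partial charges and
#' AutoDock atom types derived from the element, so that PDBQT readers
#' (including [parse_structure()]) recover the elements exactly.
#'
#' @inheritParams write_pdb
#' @return `path`, invisibly.
#' @export
write_pdbqt <- function(structure, path) {
  if (inherits(structure, "xbsf_structure")) structure <- list(structure)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(structure) > 1
  for (i in seq_along(structure)) {
    atoms <- structure[[i]]$atoms
    if (multi) writeLines(sprintf("MODEL %d", i), con)
    lines <- vapply(seq_len(nrow(atoms)), function(j) {
      a <- atoms[j, ]
      base <- format_atom_line(a)
      sprintf("%s", paste0(substr(base, 1, 66),
                           sprintf("    %6.3f %-2s", 0,
                                   element_to_ad_type(a$element))))
    }, character(1))
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Find covalently bonded C-X halogen sites in a ligand
#'
#' A halogen-bond donor site is a Cl, Br or I atom with a carbon within
#' the per-halogen covalent cutoff (2.1 / 2.2 / 2.4 A for Cl / Br / I);
#' the nearest such carbon is taken as the bonded partner, ties broken by
#' lowest serial. Fluorine and free halide ions are excluded.
#'
#' @param ligand an [xbsf_structure].
#' @param params an [xbsf_params()] set (carries the covalent cutoffs).
#' @return A data frame with one row per site: `hal_idx`, `carbon_idx`
#'   (row indices into `ligand$atoms`), `hal_serial`, `carbon_serial`,
#'   `element`, `cx_bond_length`.
#' @export
find_halogen_sites <- function(ligand, params = xbsf_params()) {
  atoms <- ligand$atoms
  xi <- which(atoms$element %in% c("Cl", "Br", "I"))
  ci <- which(atoms$element == "C")
  empty <- data.frame(hal_idx = integer(), carbon_idx = integer(),
                      hal_serial = integer(), carbon_serial = integer(),
                      element = character(), cx_bond_length = numeric(),
                      stringsAsFactors = FALSE)
  if (length(xi) == 0 || length(ci) == 0) return(empty)
  cxyz <- as.matrix(atoms[ci, c("x", "y", "z")])
  rows <- lapply(xi, function(i) {
    cutoff <- params$covalent_cutoff[[atoms$element[i]]]
    d <- sqrt(colSums((t(cxyz) - as.numeric(atoms[i, c("x", "y", "z")]))^2))
    ok <- which(d <= cutoff)
    if (length(ok) == 0) return(NULL)
    # nearest carbon; ties by lowest serial
    best <- ok[order(d[ok], atoms$serial[ci[ok]])][1]
    data.frame(hal_idx = i, carbon_idx = ci[best],
               hal_serial = atoms$serial[i],
               carbon_serial = atoms$serial[ci[best]],
               element = atoms$element[i],
               cx_bond_length = d[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Find halogen-bond acceptor atoms in a receptor
#'
#' Acceptors are all O, N and S atoms. Water oxygens (residue HOH, WAT,
#' H2O) are excluded by default, mirroring the usual receptor preparation
#' which strips waters; set `include_waters = TRUE` to keep them. HETATM
#' cofactor atoms count as acceptors (they are part of the prepared
#' receptor file); set `include_hetatm = FALSE` to restrict to ATOM
#' records.
#'
#' @param protein an [xbsf_structure].
#' @param include_waters keep water oxygens?
#' @param include_hetatm keep HETATM O/N/S (cofactors)?
#' @return The acceptor rows of `protein$atoms`, with an `acc_idx` column
#'   giving the row index into the original table.
#' @export
find_acceptors <- function(protein, include_waters = FALSE,
                           include_hetatm = TRUE) {
  atoms <- protein$atoms
  keep <- atoms$element %in% c("O", "N", "S")
  if (!include_waters) keep <- keep & !atoms$is_water
  if (!include_hetatm) keep <- keep & atoms$record == "ATOM"
  out <- atoms[keep, , drop = FALSE]
  out$acc_idx <- which(keep)
  rownames(out) <- NULL
  out
}
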