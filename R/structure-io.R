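# Reading/writing structures, heme macrocycle extraction, geometric measurement.

#' Canonical porphyrin macrocycle atom labels
#'
#' The 24 core atoms of a porphyrin macrocycle in canonical cyclic order:
#' for each pyrrole (A--D) the pyrrole nitrogen, the two alpha carbons
#' bracketing the two beta carbons, then the meso carbon that bridges to the
#' next pyrrole. Labels follow PDB chemical-component naming for HEM.
#'
#' @return Character vector of length 24.
#' @export
macrocycle_atom_labels <- function() {
  unlist(lapply(c("A", "B", "C", "D"), function(p) {
    nxt <- c(A = "B", B = "C", C = "D", D = "A")[[p]]
    c(paste0("N", p),
      paste0("C", 1:4, p),
      paste0("CH", nxt))
  }), use.names = FALSE)
}

# Normalize PDB atom-name variants ("N A", " NA ", quotes) to canonical form.
normalize_atom_name <- function(x) {
  gsub("[ '\"]", "", toupper(x))
}

new_structure_model <- function(structure_id, atoms, resolution = NA_real_) {
  stopifnot(is.data.frame(atoms))
  structure(list(structure_id = structure_id,
                 resolution = resolution,
                 atoms = atoms),
            class = "structure_model")
}

new_geometry_frame <- function(label, atoms) {
  if (nrow(atoms) < 1L) stop("geometry frame must contain at least one atom")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("geometry frame contains non-finite coordinates")
  structure(list(label = label, atoms = atoms), class = "geometry_frame")
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdb = "pdb", ent = "pdb",
         cif = "mmcif", mmcif = "mmcif",
         xyz = "xyz",
         stop("cannot infer structure format from extension '.", ext,
              "'; pass format explicitly", call. = FALSE))
}

#' Read a molecular structure file
#'
#' Reads PDB (fixed-width v3.3) and mmCIF files into a `structure_model`
#' (atom table in file order), and XYZ files into a `geometry_frame`.
#' PDB/mmCIF parsing is delegated to \pkg{bio3d}; only the first model of a
#' multi-model file is read.
#'
#' @param path Path to the file.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`, `"xyz"`.
#' @return A `structure_model` (PDB/mmCIF) or `geometry_frame` (XYZ).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  if (format == "xyz") return(read_xyz(path))

  empty_atoms <- data.frame(
    atom_name = character(), element = character(),
    residue_name = character(), chain_id = character(),
    residue_number = integer(), altloc = character(),
    model_number = integer(), x = numeric(), y = numeric(), z = numeric(),
    occupancy = numeric(), stringsAsFactors = FALSE)
  if (format == "pdb" &&
      !any(grepl("^(ATOM|HETATM)", readLines(path, warn = FALSE))))
    return(new_structure_model(sub("\\.[^.]*$", "", basename(path)),
                               empty_atoms))

  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("parse error in ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  atoms <- data.frame(
    atom_name = normalize_atom_name(a$elety),
    element = ifelse(is.na(a$elesy) | a$elesy == "", "", toupper(a$elesy)),
    residue_name = toupper(a$resid),
    chain_id = ifelse(is.na(a$chain), "", a$chain),
    residue_number = a$resno,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    model_number = 1L,
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    stringsAsFactors = FALSE)
  ok <- is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)
  if (!all(ok))
    stop("parse error in '", path, "': non-finite coordinates for atom record(s) ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  new_structure_model(structure_id = sub("\\.[^.]*$", "", basename(path)),
                      atoms = atoms)
}

# XYZ: count line, comment line, then "element x y z" records.
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("parse error in '", path, "' at line 1: empty file",
                               call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("parse error in '", path, "' at line 1: expected positive atom count",
         call. = FALSE)
  if (length(lines) < n + 2L)
    stop("parse error in '", path, "': expected ", n + 2L, " lines, found ",
         length(lines), call. = FALSE)
  lab <- character(n); xyz <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
    if (length(tok) < 4L)
      stop("parse error in '", path, "' at line ", ln,
           ": expected 'element x y z'", call. = FALSE)
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(!is.finite(v)))
      stop("parse error in '", path, "' at line ", ln,
           ": non-numeric coordinate", call. = FALSE)
    lab[i] <- tok[1L]; xyz[i, ] <- v
  }
  new_geometry_frame(label = trimws(lines[2L]),
                     atoms = data.frame(label = lab, x = xyz[, 1L],
                                        y = xyz[, 2L], z = xyz[, 3L],
                                        stringsAsFactors = FALSE))
}

new_macrocycle <- function(heme_id, xyz, iron = NULL, axial = NULL) {
  labels <- macrocycle_atom_labels()
  stopifnot(is.matrix(xyz), nrow(xyz) == 24L, ncol(xyz) == 3L,
            identical(rownames(xyz), labels))
  if (!all(is.finite(xyz))) stop("macrocycle coordinates must be finite")
  if (!is.null(axial)) {
    axial <- as.numeric(axial)
    nrm <- sqrt(sum(axial^2))
    if (abs(nrm - 1) > 1e-9) axial <- axial / nrm
  }
  structure(list(heme_id = heme_id, xyz = xyz,
                 iron = if (is.null(iron)) NULL else as.numeric(iron),
                 axial = axial),
            class = "macrocycle_geometry")
}

#' @export
print.macrocycle_geometry <- function(x, ...) {
  cat(sprintf("Porphyrin macrocycle %s %s%d (24 atoms%s%s)\n",
              x$heme_id$resname, x$heme_id$chain, x$heme_id$resnum,
              if (is.null(x$iron)) "" else ", Fe",
              if (is.null(x$axial)) "" else ", axial ligand"))
  invisible(x)
}

# Resolve altlocs within one residue: keep highest occupancy, ties by
# altloc letter order; blank altloc always wins over lettered duplicates.
resolve_altloc <- function(res, policy) {
  if (!policy %in% c("occupancy", "first"))
    stop("unknown altloc_policy '", policy, "'", call. = FALSE)
  split_idx <- split(seq_len(nrow(res)), res$atom_name)
  keep <- vapply(split_idx, function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- res[idx, ]
    if (policy == "first") return(idx[1L])
    o <- order(-sub$occupancy, sub$altloc)
    idx[o[1L]]
  }, integer(1))
  res[sort(keep), , drop = FALSE]
}

#' Extract porphyrin macrocycles from a structure
#'
#' Locates heme-type residues, resolves alternate locations, and returns one
#' [new_macrocycle()] object per heme that carries all 24 canonical macrocycle
#' atoms, in canonical order regardless of file order. Hemes missing any of
#' the 24 atoms are excluded from the result but listed in the completeness
#' report attached as attribute `"report"` (see [macrocycle_report()]).
#'
#' The iron position is captured when an FE atom is present; the axial
#' direction is the unit vector from Fe to the nearest non-heme atom within
#' `axial_cutoff` angstroms (typically the proximal thiolate S or a bound
#' diatomic ligand).
#'
#' @param model A `structure_model` from [read_structure()].
#' @param residue_names Residue names treated as heme groups.
#' @param altloc_policy `"occupancy"` (keep highest occupancy, ties by altloc
#'   letter) or `"first"`.
#' @param model_policy Only `"first"` is supported (files are read first-model).
#' @param axial_cutoff Maximum Fe--ligand distance in angstroms.
#' @return List of `macrocycle_geometry`, with attribute `"report"`.
#' @export
extract_macrocycles <- function(model,
                                residue_names = c("HEM", "HEC", "HEA", "HEB"),
                                altloc_policy = "occupancy",
                                model_policy = "first",
                                axial_cutoff = 3.0) {
  stopifnot(inherits(model, "structure_model"))
  if (!identical(model_policy, "first"))
    stop("unsupported model_policy '", model_policy,
         "'; structures are read first-model only", call. = FALSE)
  labels <- macrocycle_atom_labels()
  atoms <- model$atoms
  heme_rows <- atoms$residue_name %in% toupper(residue_names)
  report <- data.frame(structure_id = character(), chain = character(),
                       resnum = integer(), resname = character(),
                       complete = integer(), missing_atoms = character(),
                       stringsAsFactors = FALSE)
  out <- list()
  if (any(heme_rows)) {
    hm <- atoms[heme_rows, , drop = FALSE]
    key <- paste(hm$chain_id, hm$residue_number, hm$residue_name, sep = "\r")
    for (grp in unique(key)) {
      res <- resolve_altloc(hm[key == grp, , drop = FALSE], altloc_policy)
      id <- list(chain = res$chain_id[1L], resnum = res$residue_number[1L],
                 resname = res$residue_name[1L])
      hit <- match(labels, res$atom_name)
      missing <- labels[is.na(hit)]
      report <- rbind(report, data.frame(
        structure_id = model$structure_id, chain = id$chain,
        resnum = id$resnum, resname = id$resname,
        complete = as.integer(length(missing) == 0L),
        missing_atoms = paste(missing, collapse = ","),
        stringsAsFactors = FALSE))
      if (length(missing) > 0L) next
      xyz <- as.matrix(res[hit, c("x", "y", "z")])
      dimnames(xyz) <- list(labels, c("x", "y", "z"))
      fe_row <- which(res$atom_name == "FE")
      iron <- axial <- NULL
      if (length(fe_row) >= 1L) {
        iron <- as.numeric(res[fe_row[1L], c("x", "y", "z")])
        other <- atoms[!heme_rows, , drop = FALSE]
        if (nrow(other) > 0L) {
          d <- sqrt((other$x - iron[1])^2 + (other$y - iron[2])^2 +
                    (other$z - iron[3])^2)
          j <- which.min(d)
          if (d[j] <= axial_cutoff && d[j] > 1e-6) {
            axial <- (c(other$x[j], other$y[j], other$z[j]) - iron) / d[j]
          }
        }
      }
      out[[length(out) + 1L]] <- new_macrocycle(id, xyz, iron, axial)
    }
  }
  attr(out, "report") <- report
  out
}

#' Heme completeness report
#'
#' @param macrocycles Result of [extract_macrocycles()].
#' @return Data frame with columns structure_id, chain, resnum, resname,
#'   complete (0/1), missing_atoms.
#' @export
macrocycle_report <- function(macrocycles) {
  rep <- attr(macrocycles, "report")
  if (is.null(rep)) stop("object carries no completeness report", call. = FALSE)
  rep
}

#' Write a heme completeness report as TSV
#'
#' @param report Data frame from [macrocycle_report()].
#' @param path Output path.
#' @export
write_macrocycle_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

coords_and_labels <- function(frame) {
  if (inherits(frame, "macrocycle_geometry")) {
    xyz <- frame$xyz; labels <- rownames(xyz)
    if (!is.null(frame$iron)) {
      xyz <- rbind(xyz, FE = frame$iron); labels <- c(labels, "FE")
    }
  } else if (inherits(frame, "geometry_frame")) {
    xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
    labels <- frame$atoms$label
  } else if (inherits(frame, "structure_model")) {
    xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
    labels <- frame$atoms$atom_name
  } else stop("unsupported frame object", call. = FALSE)
  list(xyz = xyz, labels = labels)
}

resolve_selector <- function(sel, labels) {
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1L | idx > length(labels)))
      stop("atom index out of range (1..", length(labels), ")", call. = FALSE)
    return(idx)
  }
  vapply(as.character(sel), function(s) {
    hit <- which(labels == s)
    if (length(hit) == 0L)
      stop("unknown atom identifier '", s, "'", call. = FALSE)
    if (length(hit) > 1L)
      stop("atom identifier '", s, "' is ambiguous (", length(hit),
           " matches); use numeric indices", call. = FALSE)
    hit
  }, integer(1))
}

#' Measure a distance or angle on a coordinate frame
#'
#' Two atom identifiers give the Euclidean distance in angstroms; three give
#' the interior angle at the middle atom, in degrees. Identifiers are atom
#' labels (unique within the frame) or 1-based indices.
#'
#' @param frame A `geometry_frame`, `macrocycle_geometry` or `structure_model`.
#' @param selector Vector of 2 or 3 atom identifiers.
#' @return Distance (angstrom) or angle (degrees).
#' @export
measure <- function(frame, selector) {
  cl <- coords_and_labels(frame)
  idx <- resolve_selector(selector, cl$labels)
  if (length(idx) != length(unique(idx)))
    stop("selected atoms must be distinct", call. = FALSE)
  p <- cl$xyz[idx, , drop = FALSE]
  if (length(idx) == 2L) {
    return(sqrt(sum((p[1L, ] - p[2L, ])^2)))
  }
  if (length(idx) == 3L) {
    v1 <- p[1L, ] - p[2L, ]; v2 <- p[3L, ] - p[2L, ]
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    return(acos(max(-1, min(1, cosang))) * 180 / pi)
  }
  stop("selector must name 2 (distance) or 3 (angle) atoms", call. = FALSE)
}

# PDB %8.3f coordinate field limits.
check_pdb_coords <- function(xyz) {
  if (any(xyz > 9999.999 + 5e-4 | xyz < -999.999 - 5e-4))
    stop("coordinate exceeds the fixed-width PDB field (-999.999..9999.999); ",
         "refusing to write corrupt columns", call. = FALSE)
}

#' Write a structure or macrocycle to PDB or XYZ
#'
#' PDB output follows the fixed-width v3.3 column layout (via \pkg{bio3d});
#' coordinates that overflow the 8.3 field raise an error rather than
#' producing corrupt columns. XYZ output carries full double precision.
#'
#' @param x A `structure_model`, `macrocycle_geometry` or `geometry_frame`.
#' @param path Output path.
#' @param format `"pdb"` or `"xyz"`.
#' @export
write_structure <- function(x, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (inherits(x, "macrocycle_geometry")) {
    labels <- rownames(x$xyz); xyz <- x$xyz
    elem <- substr(labels, 1L, 1L)
    resid <- rep(x$heme_id$resname, 24L)
    chain <- rep(x$heme_id$chain, 24L)
    resno <- rep(x$heme_id$resnum, 24L)
    occ <- rep(1, 24L)
    if (!is.null(x$iron)) {
      labels <- c(labels, "FE"); elem <- c(elem, "FE")
      xyz <- rbind(xyz, x$iron)
      resid <- c(resid, x$heme_id$resname); chain <- c(chain, x$heme_id$chain)
      resno <- c(resno, x$heme_id$resnum); occ <- c(occ, 1)
      if (!is.null(x$axial)) {
        # marker atom 2 A along the axial direction, in a non-heme residue,
        # so extraction recovers the axial-ligand side of the ring
        labels <- c(labels, "AX"); elem <- c(elem, "S")
        xyz <- rbind(xyz, x$iron + 2.0 * x$axial)
        resid <- c(resid, "AXL"); chain <- c(chain, x$heme_id$chain)
        resno <- c(resno, x$heme_id$resnum + 1L); occ <- c(occ, 1)
      }
    }
    atoms <- data.frame(atom_name = labels, element = elem,
                        residue_name = resid, chain_id = chain,
                        residue_number = resno, altloc = "",
                        model_number = 1L, x = xyz[, 1L], y = xyz[, 2L],
                        z = xyz[, 3L], occupancy = occ,
                        stringsAsFactors = FALSE)
  } else if (inherits(x, "geometry_frame")) {
    atoms <- data.frame(atom_name = x$atoms$label, element = x$atoms$label,
                        residue_name = "UNK", chain_id = "A",
                        residue_number = 1L, altloc = "", model_number = 1L,
                        x = x$atoms$x, y = x$atoms$y, z = x$atoms$z,
                        occupancy = 1, stringsAsFactors = FALSE)
  } else if (inherits(x, "structure_model")) {
    atoms <- x$atoms
  } else stop("unsupported object for write_structure", call. = FALSE)

  if (nrow(atoms) > 0L && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("coordinates must be finite", call. = FALSE)

  if (format == "xyz") {
    comment <- if (inherits(x, "geometry_frame")) x$label
               else if (inherits(x, "structure_model")) x$structure_id
               else sprintf("%s %s%d", x$heme_id$resname, x$heme_id$chain,
                            x$heme_id$resnum)
    lab <- if (nrow(atoms) > 0L && any(atoms$element != "")) atoms$element
           else atoms$atom_name
    lines <- c(as.character(nrow(atoms)), comment,
               sprintf("%-4s %18.12f %18.12f %18.12f",
                       lab, atoms$x, atoms$y, atoms$z))
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) stop("cannot write '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
    return(invisible(path))
  }

  if (nrow(atoms) == 0L) {
    writeLines("END", path)
    return(invisible(path))
  }
  check_pdb_coords(as.matrix(atoms[, c("x", "y", "z")]))
  hetero <- atoms$residue_name %in% c("HEM", "HEC", "HEA", "HEB", "UNK", "POR")
  tryCatch(
    bio3d::write.pdb(file = path,
                     type = ifelse(hetero, "HETATM", "ATOM"),
                     xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                     resno = atoms$residue_number,
                     resid = atoms$residue_name,
                     eleno = seq_len(nrow(atoms)),
                     elety = atoms$atom_name,
                     chain = ifelse(atoms$chain_id == "", " ", atoms$chain_id),
                     o = atoms$occupancy, b = rep(0, nrow(atoms)),
                     elesy = atoms$element),
    error = function(e) stop("cannot write '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}
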