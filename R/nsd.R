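# Normal-coordinate decomposition of porphyrin out-of-plane distortion:
# a planar D4h reference macrocycle, six symmetry-adapted out-of-plane
# modes (doming, ruffling, saddling, two waving partners, propellering),
# rigid least-squares alignment, and orthonormal projection.

# Fixed angular offsets (degrees) of the alpha/beta carbons from their
# pyrrole axis. Chosen once from idealized metalloporphine bond lengths;
# kept constant so that scaling the ring radii is a pure homothety.
.ALPHA_OFFSET_DEG <- 22.0
.BETA_OFFSET_DEG <- 9.13

# Per-label angular position (degrees) and atom class for the canonical order.
macrocycle_layout <- function() {
  labels <- macrocycle_atom_labels()
  pyrrole_phi <- c(A = 0, B = 90, C = 180, D = 270)
  theta <- numeric(24L)
  class <- character(24L)
  pyrrole <- character(24L)
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (grepl("^N", lab)) {
      p <- substr(lab, 2L, 2L)
      theta[i] <- pyrrole_phi[[p]]; class[i] <- "N"; pyrrole[i] <- p
    } else if (grepl("^CH", lab)) {
      p <- substr(lab, 3L, 3L)               # meso CHX sits before pyrrole X
      theta[i] <- pyrrole_phi[[p]] - 45
      class[i] <- "Cm"; pyrrole[i] <- p
    } else {
      p <- substr(lab, 3L, 3L)
      k <- as.integer(substr(lab, 2L, 2L))
      off <- switch(k, -.ALPHA_OFFSET_DEG, -.BETA_OFFSET_DEG,
                    .BETA_OFFSET_DEG, .ALPHA_OFFSET_DEG)
      theta[i] <- pyrrole_phi[[p]] + off
      class[i] <- if (k %in% c(1L, 4L)) "Ca" else "Cb"
      pyrrole[i] <- p
    }
  }
  data.frame(label = labels, theta = theta, class = class,
             pyrrole = pyrrole, stringsAsFactors = FALSE)
}

#' Build a planar D4h reference porphyrin
#'
#' Places the 24 macrocycle atoms on concentric rings in the z = 0 plane with
#' exact four-fold symmetry: pyrrole nitrogens on the diagonals at radius
#' `r_N`, alpha/beta carbons at fixed angular offsets at radii `r_Ca`/`r_Cb`,
#' meso carbons on the axes at radius `r_Cm`. Defaults approximate an
#' idealized metalloporphine core.
#'
#' @param ring_radii Numeric of length 4: radii (angstrom) of the N, Calpha,
#'   Cbeta and Cmeso rings.
#' @return A `porphyrin_reference`: list with `positions24` (24 x 3 matrix,
#'   canonical row order) and `ring_radii`.
#' @export
build_reference <- function(ring_radii = c(N = 2.05, Ca = 3.05,
                                           Cb = 4.25, Cm = 3.42)) {
  r <- as.numeric(ring_radii)
  if (length(r) != 4L || any(!is.finite(r)) || any(r <= 0))
    stop("ring_radii must be 4 positive lengths (N, Ca, Cb, Cm)", call. = FALSE)
  lay <- macrocycle_layout()
  rad <- r[match(lay$class, c("N", "Ca", "Cb", "Cm"))]
  th <- lay$theta * pi / 180
  pos <- cbind(x = rad * cos(th), y = rad * sin(th), z = 0)
  rownames(pos) <- lay$label
  # exact centroid at origin: remove the ~1e-16 trigonometric dust
  pos[abs(pos) < 1e-12] <- 0
  pos <- sweep(pos, 2L, colMeans(pos))
  pos[, "z"] <- 0
  structure(list(positions24 = pos, ring_radii = stats::setNames(
    r, c("N", "Ca", "Cb", "Cm"))), class = "porphyrin_reference")
}

# Raw (pre-orthonormalization) symmetry-adapted z-displacement patterns.
raw_mode_patterns <- function(lay) {
  n <- nrow(lay)
  pat <- matrix(0, 6L, n,
                dimnames = list(c("dom", "ruf", "sad", "wav_x", "wav_y", "pro"),
                                lay$label))
  pyr_sign <- c(A = 1, B = -1, C = 1, D = -1)
  meso_sign <- c(CHA = 1, CHB = -1, CHC = 1, CHD = -1)
  # the meso preceding pyrrole X is CHX; the meso following it is CH(next(X))
  nxt <- c(A = "B", B = "C", C = "D", D = "A")
  th <- lay$theta * pi / 180
  for (i in seq_len(n)) {
    lab <- lay$label[i]; cls <- lay$class[i]; p <- lay$pyrrole[i]
    s <- pyr_sign[[p]]
    # doming (A2u): same sign everywhere, class-dependent magnitude
    pat["dom", i] <- switch(cls, N = 1.0, Ca = 0.5, Cb = 0.2, Cm = 0.4)
    # ruffling (B1u): meso alternation; pyrrole carbons twist with their meso
    if (cls == "Cm") pat["ruf", i] <- meso_sign[[lab]]
    if (cls == "Ca") {
      adj <- if (grepl("^C1", lab)) paste0("CH", p) else paste0("CH", nxt[[p]])
      pat["ruf", i] <- 0.5 * meso_sign[[adj]]
    }
    if (cls == "Cb") {
      adj <- if (grepl("^C2", lab)) paste0("CH", p) else paste0("CH", nxt[[p]])
      pat["ruf", i] <- 0.25 * meso_sign[[adj]]
    }
    # saddling (B2u): alternate pyrroles tilt up/down, mesos pinned
    pat["sad", i] <- s * switch(cls, N = 0.15, Ca = 0.4, Cb = 1.0, Cm = 0)
    # waving (Eg pair): azimuthal cos/sin profile with class weights chosen
    # not proportional to the ring radii (those are the rigid rotations)
    w <- switch(cls, N = 1.0, Ca = -0.6, Cb = 0.8, Cm = -1.0)
    pat["wav_x", i] <- w * cos(th[i])
    pat["wav_y", i] <- w * sin(th[i])
    # propellering (A1u): every pyrrole twisted the same way about its axis
    if (cls == "Ca") pat["pro", i] <- if (grepl("^C1", lab)) 0.6 else -0.6
    if (cls == "Cb") pat["pro", i] <- if (grepl("^C2", lab)) 1.0 else -1.0
  }
  pat
}

#' Build the orthonormal out-of-plane mode basis
#'
#' Constructs six symmetry-adapted z-displacement patterns on the 24 reference
#' atoms -- dom (A2u), ruf (B1u), sad (B2u), wav_x/wav_y (Eg), pro (A1u) --
#' projects out the three out-of-plane rigid-body patterns (uniform z
#' translation, rigid rotations about x and y), and Gram-Schmidt
#' orthonormalizes. Each returned mode is a unit-norm 24-vector.
#'
#' @param ref A `porphyrin_reference` from [build_reference()].
#' @return A `mode_basis`: list with `modes` (6 x 24, unit rows), `rigid`
#'   (3 x 24 orthonormal rigid-body patterns) and `ref`.
#' @export
build_mode_basis <- function(ref) {
  stopifnot(inherits(ref, "porphyrin_reference"))
  pos <- ref$positions24
  if (min(stats::dist(pos)) < 1e-6)
    stop("degenerate reference: coincident atoms", call. = FALSE)
  lay <- macrocycle_layout()

  # orthonormal rigid-body out-of-plane patterns: uniform z, z ~ y (rot x),
  # z ~ x (rot y); x and y columns are orthogonal to each other and sum to 0
  rigid <- rbind(tz = rep(1, 24L), rx = pos[, "y"], ry = pos[, "x"])
  for (i in 1:3) {
    v <- rigid[i, ]
    if (i > 1L) for (j in seq_len(i - 1L)) v <- v - sum(v * rigid[j, ]) * rigid[j, ]
    rigid[i, ] <- v / sqrt(sum(v^2))
  }

  modes <- raw_mode_patterns(lay)
  for (i in seq_len(nrow(modes))) {
    v <- modes[i, ]
    for (j in 1:3) v <- v - sum(v * rigid[j, ]) * rigid[j, ]
    if (i > 1L) for (j in seq_len(i - 1L)) v <- v - sum(v * modes[j, ]) * modes[j, ]
    nrm <- sqrt(sum(v^2))
    if (nrm < 1e-8)
      stop("mode pattern '", rownames(modes)[i],
           "' collapsed during orthonormalization", call. = FALSE)
    modes[i, ] <- v / nrm
  }
  colnames(modes) <- rownames(pos)
  colnames(rigid) <- rownames(pos)
  structure(list(modes = modes, rigid = rigid, ref = ref),
            class = "mode_basis")
}

# Kabsch: proper rotation R minimizing || Xc R - Yc ||_F.
kabsch_rotation <- function(Xc, Yc) {
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Align a macrocycle to the reference porphyrin
#'
#' Least-squares rigid superposition (rotation + translation, no scaling)
#' using the canonical label correspondence. If the macrocycle carries an
#' iron position and axial direction, the pose is sign-fixed so the axial
#' ligand lies on +z (when Kabsch places it on -z, the out-of-plane axis is
#' mirrored, i.e. the ring is viewed from the ligand face); otherwise the
#' determinant-positive Kabsch rotation is returned as-is.
#'
#' @param mac A complete `macrocycle_geometry`.
#' @param ref A `porphyrin_reference`.
#' @return List with `macrocycle` (aligned pose), `in_plane_rmsd` (angstrom),
#'   `flipped` (logical: axial sign fix applied) and `unreliable` (in-plane
#'   RMSD > 1 angstrom, projection assumptions doubtful).
#' @export
align_to_reference <- function(mac, ref) {
  stopifnot(inherits(mac, "macrocycle_geometry"),
            inherits(ref, "porphyrin_reference"))
  X <- mac$xyz
  if (nrow(X) != 24L || !identical(rownames(X), macrocycle_atom_labels()))
    stop("macrocycle must carry the 24 canonical atoms", call. = FALSE)
  Y <- ref$positions24
  cX <- colMeans(X)
  Xc <- sweep(X, 2L, cX)
  R <- kabsch_rotation(Xc, Y)      # Y centroid is the origin by construction
  aligned <- Xc %*% R
  iron <- if (is.null(mac$iron)) NULL else (mac$iron - cX) %*% R
  axial <- if (is.null(mac$axial)) NULL else as.numeric(mac$axial %*% R)
  flipped <- FALSE
  if (!is.null(axial) && axial[3L] < 0) {
    aligned[, 3L] <- -aligned[, 3L]
    axial[3L] <- -axial[3L]
    if (!is.null(iron)) iron[3L] <- -iron[3L]
    flipped <- TRUE
  }
  dimnames(aligned) <- dimnames(Y)
  ipr <- sqrt(mean(rowSums((aligned[, 1:2, drop = FALSE] -
                            Y[, 1:2, drop = FALSE])^2)))
  list(macrocycle = new_macrocycle(mac$heme_id, aligned,
                                   iron = if (is.null(iron)) NULL else as.numeric(iron),
                                   axial = axial),
       in_plane_rmsd = ipr, flipped = flipped, unreliable = ipr > 1.0)
}

#' Decompose an aligned macrocycle into out-of-plane mode amplitudes
#'
#' Projects the z-displacement 24-vector of an aligned macrocycle onto the
#' orthonormal mode basis. The rigid-body out-of-plane content (residual
#' translation/tilt left by the finite-displacement alignment) is removed
#' before projection, so the Parseval identity
#' `total_oop_norm^2 = sum(amplitudes^2) + residual_norm^2` holds exactly.
#'
#' @param aligned Result of [align_to_reference()] (or an already-aligned
#'   `macrocycle_geometry`).
#' @param basis A `mode_basis` from [build_mode_basis()].
#' @param per_atom_norm If `TRUE`, report amplitudes and norms divided by
#'   sqrt(24) (per-atom RMS displacement units) instead of unit-norm mode
#'   coefficients.
#' @return An `nsd_result`: list with `heme_id`, `amplitudes` (named: dom,
#'   ruf, sad, wav_x, wav_y, pro; angstrom, signed), `residual_norm`,
#'   `total_oop_norm`, `in_plane_rmsd`, `flipped`, `unreliable`.
#' @export
nsd_project <- function(aligned, basis, per_atom_norm = FALSE) {
  stopifnot(inherits(basis, "mode_basis"))
  if (inherits(aligned, "macrocycle_geometry"))
    aligned <- list(macrocycle = aligned, in_plane_rmsd = NA_real_,
                    flipped = FALSE, unreliable = FALSE)
  mac <- aligned$macrocycle
  dz <- mac$xyz[, 3L] - basis$ref$positions24[, 3L]
  for (j in seq_len(nrow(basis$rigid)))
    dz <- dz - sum(dz * basis$rigid[j, ]) * basis$rigid[j, ]
  amp <- as.numeric(basis$modes %*% dz)
  names(amp) <- rownames(basis$modes)
  recon <- as.numeric(crossprod(basis$modes, amp))
  residual <- sqrt(sum((dz - recon)^2))
  total <- sqrt(sum(dz^2))
  scale <- if (per_atom_norm) 1 / sqrt(24) else 1
  structure(list(heme_id = mac$heme_id,
                 amplitudes = amp * scale,
                 residual_norm = residual * scale,
                 total_oop_norm = total * scale,
                 in_plane_rmsd = aligned$in_plane_rmsd,
                 flipped = aligned$flipped,
                 unreliable = isTRUE(aligned$unreliable)),
            class = "nsd_result")
}

#' @export
print.nsd_result <- function(x, ...) {
  cat(sprintf("NSD result for %s %s%s\n", x$heme_id$resname, x$heme_id$chain,
              x$heme_id$resnum))
  print(round(x$amplitudes, 4))
  cat(sprintf("residual %.4f  total out-of-plane %.4f  in-plane RMSD %s\n",
              x$residual_norm, x$total_oop_norm,
              ifelse(is.na(x$in_plane_rmsd), "NA",
                     sprintf("%.4f", x$in_plane_rmsd))))
  invisible(x)
}

#' Align and decompose a macrocycle in one call
#'
#' @inheritParams align_to_reference
#' @inheritParams nsd_project
#' @return An `nsd_result`; see [nsd_project()].
#' @export
nsd_decompose <- function(mac, ref = build_reference(),
                          basis = build_mode_basis(ref),
                          per_atom_norm = FALSE) {
  nsd_project(align_to_reference(mac, ref), basis, per_atom_norm)
}

#' Per-heme distortion table for a structure
#'
#' Extracts all complete heme macrocycles from a structure (file path or
#' `structure_model`) and decomposes each. Incomplete hemes are excluded and
#' reported via the attached completeness report (attribute `"report"`).
#'
#' @param model A `structure_model` or a path readable by [read_structure()].
#' @param format Passed to [read_structure()] when `model` is a path.
#' @param ring_radii Passed to [build_reference()].
#' @param per_atom_norm Passed to [nsd_project()].
#' @param ... Passed to [extract_macrocycles()].
#' @return Data frame with columns structure_id, chain, resnum, dom, ruf, sad,
#'   wav_x, wav_y, pro, residual, total_oop, in_plane_rmsd.
#' @export
heme_distortion_table <- function(model, format = "auto",
                                  ring_radii = c(2.05, 3.05, 4.25, 3.42),
                                  per_atom_norm = FALSE, ...) {
  if (is.character(model)) model <- read_structure(model, format)
  stopifnot(inherits(model, "structure_model"))
  macs <- extract_macrocycles(model, ...)
  ref <- build_reference(ring_radii)
  basis <- build_mode_basis(ref)
  rows <- lapply(macs, function(m) {
    r <- nsd_decompose(m, ref, basis, per_atom_norm)
    data.frame(structure_id = model$structure_id,
               chain = m$heme_id$chain, resnum = m$heme_id$resnum,
               dom = r$amplitudes[["dom"]], ruf = r$amplitudes[["ruf"]],
               sad = r$amplitudes[["sad"]], wav_x = r$amplitudes[["wav_x"]],
               wav_y = r$amplitudes[["wav_y"]], pro = r$amplitudes[["pro"]],
               residual = r$residual_norm, total_oop = r$total_oop_norm,
               in_plane_rmsd = r$in_plane_rmsd,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure_id = character(), chain = character(),
               resnum = integer(), dom = numeric(), ruf = numeric(),
               sad = numeric(), wav_x = numeric(), wav_y = numeric(),
               pro = numeric(), residual = numeric(), total_oop = numeric(),
               in_plane_rmsd = numeric(), stringsAsFactors = FALSE)
  attr(out, "report") <- attr(macs, "report")
  out
}
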