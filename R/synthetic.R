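# Seeded generators for every input the pipeline consumes: distorted porphyrin
# macrocycles with known mode amplitudes, bimodal distortion feature clouds
# with planted outliers, and the embedded P450nor stationary-point fixture.

# Run expr with a local RNG state; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

euler_rotation <- function(angles) {
  a <- angles[1L]; b <- angles[2L]; c <- angles[3L]
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Recipe for a synthetic distorted porphyrin
#'
#' @param amplitudes Named numeric vector of mode amplitudes in angstrom;
#'   names must be among dom, ruf, sad, wav_x, wav_y, pro.
#' @param noise_sd Isotropic Gaussian coordinate noise, angstrom (>= 0).
#' @param rotation Three Euler angles in radians (intrinsic x, y, z).
#' @param translation 3-vector, angstrom.
#' @param seed Integer seed for the noise draw.
#' @return A `distortion_spec`.
#' @export
distortion_spec <- function(amplitudes = c(ruf = 0.3, dom = -0.1),
                            noise_sd = 0, rotation = c(0, 0, 0),
                            translation = c(0, 0, 0), seed = 1L) {
  known <- c("dom", "ruf", "sad", "wav_x", "wav_y", "pro")
  bad <- setdiff(names(amplitudes), known)
  if (length(bad))
    stop("unknown mode label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(amplitudes = amplitudes, noise_sd = noise_sd,
                 rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 seed = as.integer(seed)),
            class = "distortion_spec")
}

#' Generate a distorted porphyrin macrocycle with known ground truth
#'
#' Builds `pose(ref + sum(amplitude * mode) + noise)`: the reference
#' macrocycle displaced out-of-plane by the requested unit-norm mode
#' amplitudes, perturbed by isotropic Gaussian noise, then rigidly posed. The
#' iron is placed at the ring centroid and the axial direction along the
#' posed +z axis, so the sign convention survives arbitrary poses. The
#' ground-truth amplitudes are attached as attribute `"amplitudes"`.
#'
#' @param spec A [distortion_spec()].
#' @param ref A `porphyrin_reference` (defaults rebuilt on the fly).
#' @param basis A matching `mode_basis`.
#' @return A `macrocycle_geometry` with attribute `"amplitudes"`.
#' @export
make_distorted_porphyrin <- function(spec = distortion_spec(),
                                     ref = build_reference(),
                                     basis = build_mode_basis(ref)) {
  stopifnot(inherits(spec, "distortion_spec"))
  pos <- ref$positions24
  dz <- rep(0, 24L)
  for (m in names(spec$amplitudes))
    dz <- dz + spec$amplitudes[[m]] * basis$modes[m, ]
  pos[, "z"] <- pos[, "z"] + dz
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(72L, sd = spec$noise_sd), 24L, 3L))
    pos <- pos + noise
  }
  R <- euler_rotation(spec$rotation)
  posed <- pos %*% t(R)
  posed <- sweep(posed, 2L, spec$translation, "+")
  dimnames(posed) <- dimnames(ref$positions24)
  iron <- as.numeric(c(0, 0, 0) %*% t(R)) + spec$translation
  axial <- as.numeric(c(0, 0, 1) %*% t(R))
  mac <- new_macrocycle(list(chain = "A", resnum = 1L, resname = "HEM"),
                        posed, iron = iron, axial = axial)
  attr(mac, "amplitudes") <- spec$amplitudes
  mac
}

#' Recipe for a synthetic distortion feature cloud
#'
#' The default emulates the bimodal doming split seen across heme
#' oxidoreductases: a penta-coordinated component domed away from the planar
#' geometry and a hexa-coordinated component near zero doming, with one
#' planted far outlier.
#'
#' @param components List of `list(mean, cov, count)` entries; `cov` must be
#'   symmetric positive semi-definite.
#' @param outliers List of explicit feature vectors to plant.
#' @param feature_names Column names of the feature space.
#' @param seed Integer seed.
#' @return A `cloud_spec`.
#' @export
cloud_spec <- function(components = list(
                         list(mean = c(ruf = 0, dom = -0.60),
                              cov = diag(c(0.15, 0.12)^2), count = 100L),
                         list(mean = c(ruf = 0, dom = -0.05),
                              cov = diag(c(0.15, 0.08)^2), count = 100L)),
                       outliers = list(c(ruf = 1.2, dom = 0.8)),
                       feature_names = c("ruf", "dom"),
                       seed = 1L) {
  for (cmp in components) {
    if (!all(c("mean", "cov", "count") %in% names(cmp)))
      stop("each component needs mean, cov, count", call. = FALSE)
    if (cmp$count < 1L) stop("component counts must be positive", call. = FALSE)
    S <- as.matrix(cmp$cov)
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
      stop("component covariance must be symmetric", call. = FALSE)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("component covariance must be positive semi-definite", call. = FALSE)
  }
  structure(list(components = components, outliers = outliers,
                 feature_names = feature_names, seed = as.integer(seed)),
            class = "cloud_spec")
}

# Multivariate normal draw via eigen decomposition (PSD-safe).
rmvn <- function(n, mean, cov) {
  d <- length(mean)
  e <- eigen(as.matrix(cov), symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), d)
  Z <- matrix(stats::rnorm(n * d), n, d)
  sweep(Z %*% t(L), 2L, mean, "+")
}

#' Generate a feature cloud with planted outliers
#'
#' @param spec A [cloud_spec()].
#' @param standardize Passed to [feature_dataset()].
#' @return A `feature_dataset` whose `labels` record `component` membership
#'   (`"outlier"` for planted points) and `planted_outlier` (0/1).
#' @export
make_feature_cloud <- function(spec = cloud_spec(), standardize = FALSE) {
  stopifnot(inherits(spec, "cloud_spec"))
  with_seed(spec$seed, {
    Xs <- list(); comp <- character(0)
    for (i in seq_along(spec$components)) {
      cmp <- spec$components[[i]]
      Xs[[i]] <- rmvn(cmp$count, cmp$mean, cmp$cov)
      comp <- c(comp, rep(paste0("component", i), cmp$count))
    }
    X <- do.call(rbind, Xs)
    if (length(spec$outliers)) {
      X <- rbind(X, do.call(rbind, lapply(spec$outliers, as.numeric)))
      comp <- c(comp, rep("outlier", length(spec$outliers)))
    }
    colnames(X) <- spec$feature_names
    feature_dataset(X, ids = paste0("p", seq_len(nrow(X))),
                    labels = data.frame(
                      component = comp,
                      planted_outlier = as.integer(comp == "outlier"),
                      stringsAsFactors = FALSE),
                    standardize = standardize)
  })
}

#' Write a feature dataset as TSV
#'
#' @param dataset A `feature_dataset`.
#' @param path Output path.
#' @export
write_feature_tsv <- function(dataset, path) {
  df <- data.frame(id = dataset$ids, dataset$X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(dataset$labels)) df <- cbind(df, dataset$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Embedded stationary-point fixture for the P450nor N2O-forming step
#'
#' Energies (kcal/mol, relative to the encounter complex `1` of the
#' Fe3+-NHO radical-anion intermediate with the second NO) for the reported
#' pathway network: the main N-N coupling route (`1 -> TS2 -> 3`), the
#' metastable H-abstraction route (`1 -> TS2m -> 3m -> TS4m -> 3`), the
#' two-water proton-shuttle branch (`3_2W ... 7_2W`), the late main route
#' (`7 -> TS8 -> 9 -> TS10 -> 11 -> TS12 -> 13`), and the metastable
#' proton-transfer-first rearrangement (`7 -> TS8m -> 9m -> TS10m -> 11`).
#'
#' Stored values are the printed per-step differences anchored at
#' `E(1) = 0`. Two reported placements are textually ambiguous in the source
#' and are flagged `ambiguous = TRUE` with notes: the absolute level of
#' `7_2W` (here anchored 11.8 kcal/mol below `3_2W`), of `7` (set equal to
#' `7_2W`, treating removal of the spectator waters as energy-neutral), and
#' of `11` (28.1 kcal/mol above the product complex `13`). All per-step
#' barriers and stabilizations are independent of these anchor choices.
#'
#' @return A `pathway_graph` with five named routes.
#' @export
p450nor_pathway_fixture <- function() {
  pts <- function(label, kind, energy, ambiguous = FALSE, note = "") {
    data.frame(label = label, kind = kind, energy = energy,
               ambiguous = ambiguous, note = note, stringsAsFactors = FALSE)
  }
  points <- rbind(
    pts("1", "minimum", 0, note = "encounter complex, reference"),
    pts("TS2", "transition_state", 8.5, note = "N-N coupling, barrier 8.5"),
    pts("3", "minimum", -15.4, note = "hyponitrous complex, 15.4 below 1"),
    pts("TS2m", "transition_state", 12.0, note = "H abstraction, barrier 12.0"),
    pts("3m", "minimum", 8.9, note = "HNO + Fe-NO-, 8.9 above 1"),
    pts("TS4m", "transition_state", 10.4, note = "N-N rebound, 1.5 above 3m"),
    pts("3_2W", "minimum", -15.4,
        note = "two-water adduct of 3; branch anchored at E(3)"),
    pts("TS4_2W", "transition_state", -3.0,
        note = "water-mediated proton transfer, barrier 12.4"),
    pts("5_2W", "minimum", -16.5, note = "ONNOH- complex, 1.1 below 3_2W"),
    pts("TS6_2W", "transition_state", -11.0, note = "OH flip, barrier 5.5"),
    pts("7_2W", "minimum", -27.2, ambiguous = TRUE,
        note = "intramolecular H-bond; printed placement garbled, anchored 11.8 below 3_2W"),
    pts("7", "minimum", -27.2, ambiguous = TRUE,
        note = "waters removed, set equal to 7_2W"),
    pts("TS8", "transition_state", -11.6,
        note = "Fe-N to Fe-O rearrangement, barrier 15.6"),
    pts("9", "minimum", -31.6, note = "O-coordinated, 4.4 below 7"),
    pts("TS10", "transition_state", -21.1,
        note = "intramolecular proton transfer, barrier 10.5"),
    pts("11", "minimum", -23.8, ambiguous = TRUE,
        note = "printed placement garbled, anchored 28.1 above 13"),
    pts("TS12", "transition_state", -23.5, note = "N2O release, barrier 0.3"),
    pts("13", "minimum", -51.9,
        note = "Fe-OH- + N2O products, 51.9 below 1"),
    pts("TS8m", "transition_state", -23.0,
        note = "proton transfer first, barrier 4.2 from 7"),
    pts("9m", "minimum", -26.4, note = "OHNNO- species, 0.8 above 7"),
    pts("TS10m", "transition_state", -8.4,
        note = "metastable Fe-N to Fe-O rearrangement, barrier 18.0"))
  edges <- rbind(
    c("1", "TS2"), c("3", "TS2"),
    c("1", "TS2m"), c("3m", "TS2m"), c("3m", "TS4m"), c("3", "TS4m"),
    c("3_2W", "TS4_2W"), c("5_2W", "TS4_2W"),
    c("5_2W", "TS6_2W"), c("7_2W", "TS6_2W"),
    c("7", "TS8"), c("9", "TS8"), c("9", "TS10"), c("11", "TS10"),
    c("11", "TS12"), c("13", "TS12"),
    c("7", "TS8m"), c("9m", "TS8m"), c("9m", "TS10m"), c("11", "TS10m"))
  routes <- list(
    main = c("1", "TS2", "3"),
    metastable_NN = c("1", "TS2m", "3m", "TS4m", "3"),
    two_water = c("3_2W", "TS4_2W", "5_2W", "TS6_2W", "7_2W"),
    main_late = c("7", "TS8", "9", "TS10", "11", "TS12", "13"),
    metastable_rearrangement = c("7", "TS8m", "9m", "TS10m", "11"))
  build_pathway(points, edges, routes, reference = "1")
}

#' Write the sample fixture files used by the CLI docs and tests
#'
#' Emits `pathway.json` (the embedded P450nor fixture), `porphyrin.pdb` (a
#' seeded distorted macrocycle) and `features.tsv` (the default feature
#' cloud) into a directory.
#'
#' @param directory Output directory (created if absent).
#' @param seed Seed forwarded to the generators.
#' @return Named character vector of the paths written.
#' @export
write_fixture_files <- function(directory, seed = 1L) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  paths <- c(pathway = file.path(directory, "pathway.json"),
             porphyrin = file.path(directory, "porphyrin.pdb"),
             features = file.path(directory, "features.tsv"))
  write_pathway_json(p450nor_pathway_fixture(), paths[["pathway"]])
  mac <- make_distorted_porphyrin(
    distortion_spec(amplitudes = c(ruf = 0.3, dom = -0.15),
                    noise_sd = 0.01, seed = seed))
  write_structure(mac, paths[["porphyrin"]], format = "pdb")
  write_feature_tsv(make_feature_cloud(cloud_spec(seed = seed)),
                    paths[["features"]])
  invisible(paths)
}
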