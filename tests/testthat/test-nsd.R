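# Reference geometry, mode basis symmetry, alignment and decomposition.

ref <- build_reference()
basis <- build_mode_basis(ref)

test_that("reference porphyrin is planar, centred and exactly four-fold symmetric", {
  pos <- ref$positions24
  expect_true(all(pos[, "z"] == 0))
  expect_lt(max(abs(colMeans(pos))), 1e-12)

  # 90 degree rotation about z + cyclic pyrrole relabel reproduces the ring
  perm <- c4_relabel_perm()
  Rz <- cbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))
  rotated <- pos %*% t(Rz)
  expect_lt(max(abs(rotated - pos[perm, ])), 1e-12)

  # homothety: doubling all radii doubles every interatomic distance
  big <- build_reference(2 * ref$ring_radii)
  expect_equal(as.matrix(stats::dist(big$positions24)),
               2 * as.matrix(stats::dist(pos)), tolerance = 1e-12)

  expect_error(build_reference(c(2, 3, -4, 3.4)), "positive")
})

test_that("mode basis is orthonormal and free of rigid-body content", {
  G <- basis$modes %*% t(basis$modes)
  expect_lt(max(abs(G - diag(6L))), 1e-12)
  expect_lt(max(abs(basis$modes %*% t(basis$rigid))), 1e-12)
  # uniform z-translation specifically
  expect_lt(max(abs(basis$modes %*% rep(1, 24L))), 1e-11)
})

test_that("modes carry their symmetry characters under the C4 relabel", {
  perm <- c4_relabel_perm()
  # ruffling is B1u: the transported pattern is the negative of itself
  expect_lt(max(abs(basis$modes["ruf", perm] + basis$modes["ruf", ])), 1e-12)
  # doming and propellering keep their sign (A2u / A1u)
  expect_lt(max(abs(basis$modes["dom", perm] - basis$modes["dom", ])), 1e-12)
  expect_lt(max(abs(basis$modes["pro", perm] - basis$modes["pro", ])), 1e-12)
  # the waving pair maps onto itself (Eg): transported wav_x lies along wav_y
  moved <- basis$modes["wav_x", perm]
  expect_equal(abs(sum(moved * basis$modes["wav_y", ])), 1, tolerance = 1e-12)
  expect_lt(abs(sum(moved * basis$modes["wav_x", ])), 1e-12)
})

test_that("alignment recovers arbitrary proper rigid poses", {
  mac0 <- make_distorted_porphyrin(distortion_spec(amplitudes = c(ruf = 0)),
                                   ref, basis)
  self <- align_to_reference(mac0, ref)
  expect_lt(self$in_plane_rmsd, 1e-12)

  for (seed in 1:10) {
    pose <- with_local_seed(seed, list(a = runif(3, -pi, pi),
                                       t = runif(3, -20, 20)))
    moved <- rigid_motion(mac0, pose$a, pose$t)
    al <- align_to_reference(moved, ref)
    expect_lt(al$in_plane_rmsd, 1e-9)
    expect_lt(max(abs(al$macrocycle$xyz - ref$positions24)), 1e-9)
  }
  bad <- mac0; bad$xyz <- bad$xyz[c(2:24, 1L), ]
  expect_error(align_to_reference(bad, ref), "canonical")
})

test_that("decomposition recovers planted amplitudes exactly when noiseless", {
  planar <- make_distorted_porphyrin(
    distortion_spec(amplitudes = c(ruf = 0)), ref, basis)
  r0 <- nsd_decompose(planar, ref, basis)
  expect_lt(max(abs(r0$amplitudes)), 1e-12)
  expect_lt(r0$residual_norm, 1e-12)

  spec <- distortion_spec(amplitudes = c(ruf = 0.30, dom = -0.10),
                          rotation = c(0.4, 1.0, -0.7),
                          translation = c(8, -3, 2))
  r <- nsd_decompose(make_distorted_porphyrin(spec, ref, basis), ref, basis)
  expect_equal(r$amplitudes[["ruf"]], 0.30, tolerance = 1e-9)
  expect_equal(r$amplitudes[["dom"]], -0.10, tolerance = 1e-9)
  expect_lt(max(abs(r$amplitudes[c("sad", "wav_x", "wav_y", "pro")])), 1e-9)
  expect_lt(r$residual_norm, 1e-9)

  # a purely ruffled ring: no in-plane displacement, 0.3 A out-of-plane norm
  pure <- nsd_decompose(make_distorted_porphyrin(
    distortion_spec(amplitudes = c(ruf = 0.3)), ref, basis), ref, basis)
  expect_lt(pure$in_plane_rmsd, 1e-9)
  expect_equal(pure$total_oop_norm, 0.3, tolerance = 1e-9)
})

test_that("decomposition is invariant under proper rigid motions of the input", {
  base <- make_distorted_porphyrin(
    distortion_spec(amplitudes = c(ruf = 0.2, dom = 0.15, sad = -0.1,
                                   wav_x = 0.05, pro = 0.08),
                    noise_sd = 0.03, seed = 21L), ref, basis)
  r_base <- nsd_decompose(base, ref, basis)
  for (seed in 1:8) {
    pose <- with_local_seed(100 + seed, list(a = runif(3, -pi, pi),
                                             t = runif(3, -30, 30)))
    r_moved <- nsd_decompose(rigid_motion(base, pose$a, pose$t), ref, basis)
    expect_equal(r_moved$amplitudes, r_base$amplitudes, tolerance = 1e-9)
    expect_equal(r_moved$residual_norm, r_base$residual_norm, tolerance = 1e-9)
  }
})

test_that("Parseval identity holds for every decomposition", {
  for (seed in 1:20) {
    amp <- with_local_seed(seed, stats::setNames(runif(6, -1, 1),
                                                 rownames(basis$modes)))
    mac <- make_distorted_porphyrin(
      distortion_spec(amplitudes = amp, noise_sd = 0.05, seed = seed,
                      rotation = c(0.2, -0.4, 0.9)), ref, basis)
    r <- nsd_decompose(mac, ref, basis)
    expect_equal(r$total_oop_norm^2,
                 sum(r$amplitudes^2) + r$residual_norm^2, tolerance = 1e-9)
  }
})

test_that("noisy recovery error stays within three noise standard deviations", {
  for (sigma in c(0.01, 0.05)) {
    errs <- vapply(1:30, function(seed) {
      amp <- with_local_seed(seed, stats::setNames(runif(6, -1, 1),
                                                   rownames(basis$modes)))
      mac <- make_distorted_porphyrin(
        distortion_spec(amplitudes = amp, noise_sd = sigma, seed = seed),
        ref, basis)
      max(abs(nsd_decompose(mac, ref, basis)$amplitudes - amp))
    }, numeric(1))
    expect_lt(stats::median(errs), 3 * sigma)
  }
})

test_that("axial sign convention makes the amplitudes face-independent", {
  spec <- distortion_spec(amplitudes = c(dom = -0.2, ruf = 0.25))
  mac <- make_distorted_porphyrin(spec, ref, basis)
  r_up <- nsd_decompose(mac, ref, basis)
  # a rigid motion of the whole ring is undone exactly by the alignment
  r_rot <- nsd_decompose(rigid_motion(mac, c(pi, 0, 0), c(0, 0, 0)),
                         ref, basis)
  expect_false(r_rot$flipped)
  expect_equal(r_rot$amplitudes, r_up$amplitudes, tolerance = 1e-9)
  # moving the ligand to the opposite heme face mirrors the viewing axis:
  # all out-of-plane amplitudes change sign under the +z-toward-ligand rule
  other_face <- mac
  other_face$axial <- -mac$axial
  r_down <- nsd_decompose(other_face, ref, basis)
  expect_true(r_down$flipped)
  expect_equal(r_down$amplitudes, -r_up$amplitudes, tolerance = 1e-9)
})

test_that("per-atom normalisation rescales amplitudes by sqrt(24)", {
  mac <- make_distorted_porphyrin(
    distortion_spec(amplitudes = c(ruf = 0.3)), ref, basis)
  a <- nsd_decompose(mac, ref, basis)
  b <- nsd_decompose(mac, ref, basis, per_atom_norm = TRUE)
  expect_equal(b$amplitudes, a$amplitudes / sqrt(24), tolerance = 1e-12)
  expect_equal(b$total_oop_norm, a$total_oop_norm / sqrt(24),
               tolerance = 1e-12)
})

test_that("heme distortion tables carry one row per complete heme", {
  mac <- make_distorted_porphyrin(
    distortion_spec(amplitudes = c(ruf = 0.3, dom = -0.15), seed = 2L))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(mac, path, "pdb")
  tab <- heme_distortion_table(path)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$ruf, 0.3, tolerance = 0.02)
  expect_equal(tab$dom, -0.15, tolerance = 0.02)
  expect_named(tab, c("structure_id", "chain", "resnum", "dom", "ruf", "sad",
                      "wav_x", "wav_y", "pro", "residual", "total_oop",
                      "in_plane_rmsd"))
})
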