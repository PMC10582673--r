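test_that("decimated icosphere stays within 1% of the source surface (brute-force oracle)", {
  ico <- icosphere(4)                       # 5120 faces
  dec <- clean_and_resample(ico, 2000)
  expect_lte(abs(nrow(dec$faces) - 2000), 200)
  pts <- sample_points(dec, 400, seed = 1)$points
  d1 <- points_to_mesh_dist(pts, ico)
  pts2 <- sample_points(ico, 400, seed = 2)$points
  d2 <- points_to_mesh_dist(pts2, dec)
  expect_lt(max(d1, d2), 0.01)              # 1% of the unit radius
})

test_that("small holes are closed and a mesh at target is (near) untouched", {
  m <- icosphere(2)
  m$faces <- m$faces[-1, , drop = FALSE]    # open a 3-edge hole
  fixed <- clean_and_resample(m, nrow(m$faces) + 1L)
  F <- fixed$faces
  de <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  k <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  expect_true(all(table(k) == 2L))          # watertight

  ico <- icosphere(3)
  same <- clean_and_resample(ico, nrow(ico$faces))
  expect_lte(abs(nrow(same$faces) - nrow(ico$faces)),
             0.1 * nrow(ico$faces))
  expect_lt(max(abs(sqrt(rowSums(same$vertices^2)) - 1)), 1e-6)

  up <- clean_and_resample(icosphere(1), 600)   # upsample path
  expect_lte(abs(nrow(up$faces) - 600), 60)
})

test_that("surface sampling is area-weighted uniform and reproducible", {
  sq <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
  ps <- sample_points(sq, 10000, seed = 2)
  counts <- tabulate(ps$face, 2)
  expect_lt(abs(counts[1] - 5000), 3 * sqrt(2500))   # binomial bound
  expect_identical(ps$points, sample_points(sq, 10000, seed = 2)$points)
  expect_error(sample_points(sq, 50), "at least 100")
  # barycentric residual: points reconstruct from stored coordinates
  A <- sq$vertices[sq$faces[ps$face, 1], ]
  B <- sq$vertices[sq$faces[ps$face, 2], ]
  C <- sq$vertices[sq$faces[ps$face, 3], ]
  rec <- A * ps$bary[, 1] + B * ps$bary[, 2] + C * ps$bary[, 3]
  expect_lt(max(abs(rec - ps$points)), 1e-9)
})

test_that("pose initialization recovers large rotations and flags mirrors", {
  mm <- make_mesh(shape_spec(), 1200, seed = 3, random_pose = FALSE)$mesh
  P <- sample_points(mm, 600, seed = 4)$points
  ang <- 170 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  X <- P %*% t(R)
  ini <- initialize_pose(X, P)
  err <- acos(pmin(1, (sum(diag(ini$transform$R %*% R)) - 1) / 2)) * 180 / pi
  expect_lt(err, 5)
  expect_equal(det(ini$transform$R), 1, tolerance = 1e-9)

  same <- initialize_pose(P, P)
  expect_lt(max(abs(same$transform$R - diag(3))), 1e-6)
  expect_lt(max(abs(same$transform$t)), 1e-6)

  Xm <- P; Xm[, 1] <- -Xm[, 1]
  inim <- initialize_pose(Xm, P)
  expect_equal(det(inim$transform$R), 1, tolerance = 1e-9)
  expect_true(inim$mirror_suspect)
})

test_that("ICP recovers a known rigid+scale pose and has a monotone PSM trace", {
  mm <- make_mesh(shape_spec(), 2000, seed = 5, random_pose = FALSE)$mesh
  P <- sample_points(mm, 1000, seed = 10)$points
  set.seed(8)
  R <- rand_rot3(); tr <- rnorm(3, 0, 2); s <- 1.3
  X <- sweep(P %*% t(R) * s, 2, tr, `+`)
  al <- icp_align(X, P, allow_scale = TRUE)
  rot_err <- acos(pmin(1, (sum(diag(al$transform$R %*% R)) - 1) / 2)) * 180 / pi
  expect_lt(rot_err, 0.5)
  expect_lt(abs(al$transform$s * s - 1), 1e-3)
  expect_lt(al$psm, 1e-6 * bbox_diagonal(P))
  expect_silent_psm_trace(al$psm_trace)
  expect_true(al$converged)

  id <- icp_align(P, P)
  expect_lt(id$psm, 1e-10)
  expect_lt(max(abs(id$transform$R - diag(3))), 1e-6)
})

test_that("PSM satisfies the metric axioms and matches the brute-force oracle", {
  set.seed(21)
  A <- matrix(rnorm(600), 200, 3)
  B <- matrix(rnorm(600), 200, 3) + 0.5
  expect_identical(psm(A, A), 0)
  expect_identical(psm(A, B), psm(B, A))
  dab <- nn_brute(A, B)$dist
  dba <- nn_brute(B, A)$dist
  oracle <- sqrt(sum(dab^2) / (2 * 200) + sum(dba^2) / (2 * 200))
  expect_identical(psm(A, B), oracle)
  expect_lt(psm(A, B, symmetric = FALSE) - sqrt(mean(dab^2)), 1e-15)
})

test_that("PSM of offset dense squares scales linearly with the offset", {
  g <- as.matrix(expand.grid(x = seq(0, 1, length.out = 40),
                             y = seq(0, 1, length.out = 40)))
  sq <- cbind(g, 0)
  # offsets well below the sample spacing (0.026), the delta -> 0 regime
  deltas <- c(0.01, 0.005, 0.002)
  ratios <- vapply(deltas, function(delta) {
    psm(sq, sweep(sq, 2, c(delta, 0, 0), `+`)) / delta
  }, 1.0)
  expect_true(all(ratios > 0 & ratios <= 1 + 1e-9))
  expect_lt(diff(range(ratios)), 0.2)     # approximately constant c
  # brute-force all-pairs oracle at one offset
  B <- sweep(sq, 2, c(0.005, 0, 0), `+`)
  dab <- nn_brute(sq, B)$dist; dba <- nn_brute(B, sq)$dist
  expect_equal(psm(sq, B),
               sqrt(sum(dab^2) / (2 * nrow(sq)) + sum(dba^2) / (2 * nrow(B))),
               tolerance = 1e-12)
})

test_that("generalized alignment collapses an identical-shape cohort", {
  mm <- make_mesh(shape_spec(), 1200, seed = 5, random_pose = FALSE)$mesh
  base <- sample_points(mm, 800, seed = 100)$points
  set.seed(3)
  samples <- lapply(1:5, function(i)
    sweep(base %*% t(rand_rot3()), 2, rnorm(3), `+`))
  names(samples) <- paste0("s", 1:5)
  g <- gpsa(samples, "s1")
  expect_lt(utils::tail(g$mean_psm_trace, 1), 1e-6 * bbox_diagonal(base))
  expect_lt(max(g$morphospace$eigenvalues), 1e-10)
  expect_true(all(diff(g$mean_psm_trace) <= 1e-12))
  expect_lt(max(g$deviation), 1e-8)
  expect_equal(length(g$deviation), 800L)
})

test_that("homologized rows equal the brute-force all-pairs implementation", {
  set.seed(5)
  mm <- make_mesh(shape_spec(coefficient_noise_sd = 0.02), 800,
                  seed = 9, random_pose = FALSE)$mesh
  samples <- lapply(1:5, function(i) sample_points(mm, 200, seed = i)$points)
  names(samples) <- paste0("s", 1:5)
  g <- gpsa(samples, "s1", max_outer = 1L, flag_misaligned = FALSE)
  P <- g$prototype_points
  for (i in 1:5) {
    al <- icp_align(samples[[i]], samples[["s1"]])
    idx <- nn_brute(P, al$aligned)$idx
    expect_identical(g$homologized[i, ],
                     as.numeric(t(al$aligned[idx, , drop = FALSE])))
  }
})

test_that("ordination is invariant to a common rigid motion of all inputs", {
  des <- tiny_design(n_per = 2L)
  coh <- make_cohort(des, tree = NULL, bm_sigma = 0, seed = 6,
                     n_points = 128, target_faces = 800)
  samples <- purrr::imap(setNames(coh$mesh, coh$specimen_id),
                         function(m, id) sample_points(m, 400, seed = 50)$points)
  g1 <- suppressWarnings(gpsa(samples, names(samples)[1], max_outer = 3L))
  set.seed(11); R <- rand_rot3(); tr <- c(3, -2, 5)
  moved <- lapply(samples, function(s) sweep(s %*% t(R), 2, tr, `+`))
  g2 <- suppressWarnings(gpsa(moved, names(samples)[1], max_outer = 3L))
  k <- min(3, ncol(g1$morphospace$scores))
  for (j in seq_len(k)) {
    a <- g1$morphospace$scores[, j]; b <- g2$morphospace$scores[, j]
    if (cor(a, b) < 0) b <- -b
    expect_lt(max(abs(a - b)), 1e-4 * bbox_diagonal(samples[[1]]))
  }
  expect_equal(sum(g1$morphospace$proportions), 1, tolerance = 1e-9)
  expect_lte(sum(g1$morphospace$eigenvalues > 1e-12), length(samples) - 1L)
})

test_that("scale handling: allow_scale absorbs size; without it size separates", {
  mm <- make_mesh(shape_spec(coefficient_noise_sd = 0.01), 900,
                  seed = 13, random_pose = FALSE)$mesh
  base <- lapply(1:6, function(i) sample_points(mm, 400, seed = 20 + i)$points)
  names(base) <- paste0("s", 1:6)
  doubled <- base
  doubled$s6 <- doubled$s6 * 2
  gs <- suppressWarnings(gpsa(doubled, "s1", allow_scale = TRUE, max_outer = 2L))
  expect_equal(unname(gs$alignments$centroid_size[6] /
                        gs$alignments$centroid_size[1]), 2, tolerance = 0.2)
  sc <- gs$morphospace$scores
  spread <- apply(sc, 2, sd)
  expect_lt(abs(sc[6, 1] - mean(sc[-6, 1])),
            1e-3 * bbox_diagonal(base$s1) + 6 * spread[1])

  gn <- suppressWarnings(gpsa(doubled, "s1", allow_scale = FALSE, max_outer = 2L))
  sc2 <- gn$morphospace$scores[, 1]
  expect_gt(abs(sc2[6] - mean(sc2[-6])), 5 * sd(sc2[-6]))
})

test_that("deviation heat export writes PLY point fields of the right shape", {
  mm <- make_mesh(shape_spec(), 800, seed = 2, random_pose = FALSE)$mesh
  base <- sample_points(mm, 300, seed = 1)$points
  samples <- setNames(lapply(1:4, function(i) base), paste0("s", 1:4))
  g <- gpsa(samples, "s1")
  expect_true(all(g$deviation >= 0))
  expect_lt(max(g$deviation), 1e-10)       # identical cohort -> zero field
  f <- file.path(withr::local_tempdir(), "heat.ply")
  paths <- deviation_heat_export(g, f, pcs = 1L)
  expect_true(all(file.exists(paths)))
  lines <- readLines(f)
  expect_true(any(grepl("property float quality", lines)))
  expect_equal(sum(grepl("^element vertex", lines)), 1L)
})
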