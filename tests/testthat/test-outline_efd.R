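test_that("binarization thresholds, keeps the largest blob and fills holes", {
  img <- matrix(10, 20, 20)
  img[5:14, 5:14] <- 200            # 100-px blob
  img[17:19, 17:19] <- 200          # 9-px blob
  img[9:10, 9:10] <- 10             # hole inside the big blob
  mask <- binarize(img)
  expect_equal(sum(mask), 100)      # largest component, hole filled
  expect_false(any(mask[17:19, 17:19]))
  expect_error(binarize(matrix(5, 4, 4)), "constant|empty")
})

test_that("Moore tracing gives closed counterclockwise chain codes", {
  m <- matrix(FALSE, 6, 6); m[3:4, 3:4] <- TRUE
  cc <- trace_chain(m)
  expect_length(cc$codes, 4L)
  ctr <- chain_to_contour(cc)
  expect_equal(nrow(unique(ctr)), 4L)         # visits the 4 boundary pixels
  expect_gte(polygon_area(ctr), 0)            # CCW in math coordinates

  m2 <- matrix(FALSE, 5, 7); m2[3, 3:5] <- TRUE
  cc2 <- trace_chain(m2)                      # closure checked on construction
  expect_s3_class(cc2, "chaincode")

  m3 <- matrix(FALSE, 3, 3); m3[2, 2] <- TRUE
  expect_error(trace_chain(m3), "isolated pixel")
})

test_that("chain-code text files round trip", {
  m <- matrix(FALSE, 8, 8); m[3:6, 3:5] <- TRUE
  cc <- trace_chain(m)
  f <- tempfile(fileext = ".chc")
  write_chain_file(list(spec1 = cc), f)
  back <- read_chain_file(f)
  expect_identical(back$spec1$codes, cc$codes)
  # contour from a chain code feeds efd directly
  e <- efd(back$spec1, 4)
  expect_s3_class(e, "efdset")
})

test_that("EFD matches the analytic circle and the quadrature ellipse oracle", {
  e <- efd(circle_contour(1024), 8)
  expect_lt(abs(e$coef[1, "a"] - 1), 1e-4)
  expect_lt(abs(e$coef[1, "d"] - 1), 1e-4)
  expect_lt(max(abs(e$coef[1, c("b", "c")])), 1e-4)
  expect_lt(max(abs(e$coef[-1, ])), 1e-3)

  orc <- ellipse_efd_oracle(2, 1, harmonics = 1:3)
  # frozen oracle values (quadrature, arc-length parametrization)
  expect_equal(unname(orc[1, c("a", "d")]), c(1.828412, 1.073017),
               tolerance = 1e-5)
  e2 <- efd(ellipse_contour(1024), 8)
  expect_lt(max(abs(e2$coef[1:3, ] - orc)), 1e-4)
})

test_that("a one-harmonic reconstruction is an exact conic (ellipse)", {
  ol <- base_outline(256)
  r1 <- efd_reconstruct(efd(ol, 8), n_use = 1, n_points = 400)
  M <- cbind(r1[, 1]^2, r1[, 1] * r1[, 2], r1[, 2]^2, r1[, 1], r1[, 2], 1)
  expect_lt(min(svd(M)$d) / max(svd(M)$d), 1e-9)
})

test_that("normalized coefficients are invariant to pose, scale and start point", {
  ol <- base_outline(200)
  ref <- normalize_longest_radius(efd(ol, 12))
  set.seed(42)
  for (i in 1:100) {
    ang <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    s <- exp(runif(1, -1.5, 1.5))
    shift <- sample.int(200, 1)
    q <- sweep(ol %*% t(R) * s, 2, rnorm(2, 0, 10), `+`)
    q <- q[c(shift:200, seq_len(shift - 1))[1:200], , drop = FALSE]
    out <- normalize_longest_radius(efd(q, 12))
    expect_lt(max(abs(out$coef - ref$coef)), 1e-6)
  }
  expect_equal(ref$A0, 0, tolerance = 1e-9)
  expect_equal(ref$C0, 0, tolerance = 1e-9)
})

test_that("longest-radius normalization scales the ellipse by its semi-major axis", {
  # the two semi-major vertices tie for the longest radius; the first (at
  # parameter 0) wins deterministically
  expect_warning(en <- normalize_longest_radius(efd(ellipse_contour(1024), 8)),
                 "tied")
  orc_a1 <- ellipse_efd_oracle(2, 1, harmonics = 1)[1, "a"]
  expect_equal(unname(en$coef[1, "a"]), unname(orc_a1) / 2, tolerance = 1e-4)
  expect_lt(abs(en$coef[1, "b"]), 1e-3)
  expect_lt(abs(en$coef[1, "c"]), 1e-3)
})

test_that("a circle triggers the radius tie-break deterministically", {
  expect_warning(en <- normalize_longest_radius(efd(circle_contour(128), 4)),
                 "tied")
  expect_true(en$normalization$radius_tie)
  expect_equal(en$normalization$start_shift, 0L)
})

test_that("reconstruction error is non-increasing in harmonics and small at N = 26", {
  set.seed(7)
  for (i in 1:20) {
    sp <- shape_spec(medial_tip_amplitude = runif(1, 0, 0.3),
                     coefficient_noise_sd = 0.02, process_angle_sd = 8)
    ol <- make_outline(sp, seed = 100 + i, n_points = 256)$contour
    e <- efd(ol, 26)
    errs <- vapply(c(1, 2, 4, 8, 16, 26), function(k) {
      r <- efd_reconstruct(e, k, 256)
      # mean distance from source vertices to reconstruction (dense eval)
      rd <- efd_reconstruct(e, k, 1024)
      mean(vapply(seq_len(256), function(j)
        sqrt(min(colSums((t(rd) - ol[j, ])^2))), 1.0))
    }, 1.0)
    expect_true(all(diff(errs) <= 1e-9))
    expect_lt(errs[length(errs)], 0.01 * e$T)
  }
})

test_that("efd is the exact adjoint of reconstruction under matched parametrization", {
  e <- efd(ellipse_contour(512), 8)
  r <- efd_reconstruct(e, 8, 131072)
  e2 <- efd(r, 8, t = attr(r, "t"))
  expect_lt(max(abs(e2$coef - e$coef)), 1e-9)
  expect_lt(abs(e2$A0 - e$A0), 1e-9)
  # chord reparametrization stays close (curve-level, not discretization)
  e3 <- efd(r, 8)
  expect_lt(max(abs(e3$coef - e$coef)), 5e-3)
})

test_that("round trip through the EFD basis recovers a band-limited source", {
  e0 <- efd(base_outline(256), 26)
  src <- efd_reconstruct(e0, 26, 4096)      # band-limited contour
  e <- efd(src, 26, t = attr(src, "t"))
  rec <- efd_reconstruct(e, 26, 4096)
  expect_lt(max(abs(rec - src)) / e$T, 1e-6)
})

test_that("coefficient PCA has the expected rank structure", {
  ol1 <- base_outline(128)
  ol2 <- make_outline(shape_spec(medial_tip_amplitude = 0.4),
                      n_points = 128)$contour
  same <- lapply(1:5, function(i) normalize_longest_radius(efd(ol1, 8)))
  ms_same <- efd_pca(same)
  expect_lt(max(ms_same$eigenvalues), 1e-12)

  mix <- lapply(1:6, function(i)
    normalize_longest_radius(efd(if (i <= 3) ol1 else ol2, 8)))
  ms_mix <- efd_pca(mix)
  expect_equal(sum(ms_mix$eigenvalues > 1e-12), 1L)
  expect_equal(sum(ms_mix$proportions), 1, tolerance = 1e-9)
  expect_error(efd_pca(mix[1:2]), "at least 3")
})

test_that("planted tips separate on PC1 by more than 3 within-group SDs", {
  des <- tiny_design(n_per = 5L)
  coh <- make_cohort(des, effects = list(
    pelvic_female = shape_spec(medial_tip_amplitude = 0.3,
                               coefficient_noise_sd = 0.012,
                               process_angle_sd = 8),
    pelvic_male = shape_spec(coefficient_noise_sd = 0.012,
                             process_angle_sd = 8),
    transfer_female = shape_spec(coefficient_noise_sd = 0.012,
                                 process_angle_sd = 8),
    transfer_male = shape_spec(coefficient_noise_sd = 0.012,
                               process_angle_sd = 8)),
    tree = NULL, bm_sigma = 0, seed = 17, n_points = 256)
  efds <- lapply(coh$outline, function(o) normalize_longest_radius(efd(o, 26)))
  ms <- efd_pca(efds, ids = coh$specimen_id)
  g <- coh$strategy == "pelvic" & coh$sex == "female"
  sc <- ms$scores[, 1]
  gap <- abs(mean(sc[g]) - mean(sc[!g]))
  wsd <- sqrt(mean(c(var(sc[g]), var(sc[!g]))))
  expect_gt(gap, 3 * wsd)
})

test_that("wireframes and SVG export produce mean and +/- sd outlines per axis", {
  efds <- lapply(1:6, function(i)
    normalize_longest_radius(efd(make_outline(
      shape_spec(coefficient_noise_sd = 0.03), seed = i,
      n_points = 128)$contour, 8)))
  ms <- efd_pca(efds)
  wf <- efd_wireframes(ms, pcs = 1:2, n_points = 64)
  expect_setequal(unique(wf$pose), c("-sd", "mean", "+sd"))
  expect_equal(nrow(wf), 2 * 3 * 64)
  f <- tempfile(fileext = ".svg")
  write_wireframe_svg(wf, f)
  expect_true(any(grepl("polygon", readLines(f))))
})
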