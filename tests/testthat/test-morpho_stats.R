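test_that("broken stick matches closed-form enumeration up to p = 50", {
  expect_equal(broken_stick(c(0.7, 0.2, 0.1)), 1L)
  expect_equal(broken_stick(rep(1, 5)), 0L)
  expect_equal(broken_stick(c(0.99, 0.01)), 1L)
  set.seed(1)
  for (p in c(2, 3, 7, 20, 50)) {
    ev <- sort(rexp(p), decreasing = TRUE)
    props <- ev / sum(ev)
    b <- vapply(seq_len(p), function(k) sum(1 / (k:p)) / p, 1.0)
    exp_k <- 0L
    for (k in seq_len(p)) {
      if (props[k] > b[k]) exp_k <- k else break
    }
    expect_identical(broken_stick(ev), exp_k)
    # cross-check the null expectation against vegan's broken stick
    expect_equal(b * sum(ev), unname(vegan::bstick(p, tot.var = sum(ev))),
                 tolerance = 1e-12)
  }
  expect_error(broken_stick(c(0, 0)), "zero")
  expect_error(broken_stick(3), "at least 2")
})

test_that("z-scoring standardizes axes and drops constants", {
  set.seed(2)
  X <- matrix(rnorm(60, 5, 3), 20, 3)
  Z <- zscore_scores(X)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(zscore_scores(sweep(X * 4.2, 2, c(1, 2, 3), `+`)), Z,
               ignore_attr = TRUE)
  expect_warning(Z2 <- zscore_scores(cbind(X, 7)), "constant")
  expect_equal(ncol(Z2), 3L)
  expect_error(zscore_scores(X[1, , drop = FALSE]), "2 rows")
})

test_that("PERMANOVA keeps the stated term order and decomposes SS exactly", {
  set.seed(3)
  des <- tiny_design(n_per = 5L)
  sc <- matrix(rnorm(40), 20, 2)
  tab <- permanova(sc, des, n_perm = 99, seed = 4)
  expect_identical(tab$term[1:4], c("strategy", "sex", "strategy:sex",
                                    "standard_length"))
  tot <- tab$sum_sq[tab$term == "Total"]
  expect_equal(sum(tab$sum_sq[1:4]) + tab$sum_sq[tab$term == "Residual"],
               tot, tolerance = 1e-9)
  expect_true(all(tab$r_squared[1:4] >= 0 & tab$r_squared[1:4] <= 1))
  expect_true(all(tab$p_value[1:4] >= 1 / 100 & tab$p_value[1:4] <= 1))
  # reproducible under a fixed seed, different otherwise
  expect_identical(tab$p_value,
                   permanova(sc, des, n_perm = 99, seed = 4)$p_value)
  # sequential interaction SS agrees with univariate aov on one axis
  a <- stats::aov(sc[, 1] ~ strategy + sex + strategy:sex,
                  data = as.data.frame(des))
  t1 <- permanova(sc[, 1, drop = FALSE], des,
                  formula = ~ strategy + sex + strategy:sex,
                  n_perm = 49, seed = 1)
  expect_equal(t1$sum_sq[1:3], unname(summary(a)[[1]][["Sum Sq"]][1:3]),
               tolerance = 1e-9)
})

test_that("a fully separated two-group design reaches the attainable p floor", {
  set.seed(5)
  des <- tiny_design(n_per = 5L)
  sc <- matrix(rnorm(40, sd = 0.1), 20, 2)
  sc[des$strategy == "pelvic", 1] <- sc[des$strategy == "pelvic", 1] + 50
  tab <- permanova(sc, des, formula = ~ strategy, n_perm = 9999, seed = 6)
  expect_equal(tab$p_value[1], 1e-4)
})

test_that("aliased term orderings are refused with the offending term named", {
  des <- tiny_design(n_per = 5L)     # species fully determines strategy
  sc <- matrix(rnorm(40), 20, 2)
  expect_error(permanova(sc, des, formula = ~ species + strategy,
                         n_perm = 49), "strategy")
})

test_that("a single-group term explains nothing", {
  set.seed(8)
  des <- tiny_design(n_per = 5L)
  des$strategy <- "pelvic"
  des$species <- "A_sp"              # keep strategy constant within species
  sc <- matrix(rnorm(40), 20, 2)
  tab <- permanova(sc, des, formula = ~ sex, n_perm = 199, seed = 2)
  expect_lt(tab$r_squared[1], 0.2)
  expect_gt(tab$p_value[1], 0.05)
})

test_that("disparity indices reproduce closed forms on square and cube", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  d2 <- disparity_indices(sq, rep("g", 4), n_boot = 10, seed = 1)
  expect_equal(d2$summary$observed[d2$summary$index == "ranges"], 2)
  expect_equal(d2$summary$observed[d2$summary$index == "hull"], 4)

  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  d3 <- disparity_indices(cube, rep("g", 8), n_boot = 10, seed = 1)
  expect_equal(d3$summary$observed[d3$summary$index == "ranges"], 3)
  expect_equal(d3$summary$observed[d3$summary$index == "hull"], 6)
})

test_that("bootstrap medians cannot exceed the full-sample ranges", {
  set.seed(9)
  X <- matrix(rnorm(90), 30, 3)
  d <- disparity_indices(X, rep("g", 30), n_boot = 5000, seed = 10)
  s <- d$summary
  expect_lte(s$boot_median[s$index == "ranges"],
             s$observed[s$index == "ranges"])
  expect_true(all(d$boot[["g"]][, "ranges"] <=
                    s$observed[s$index == "ranges"] + 1e-12))
})

test_that("degenerate and undersized groups are handled as documented", {
  # coplanar 3D points: hull measured in the affine span
  P <- cbind(matrix(rnorm(40), 20, 2), 0)
  hm <- hull_measure(P)
  expect_equal(hm$dim_used, 2L)
  expect_gt(hm$measure, 0)
  # > 3 axes: projected flag set
  h6 <- hull_measure(matrix(rnorm(120), 20, 6))
  expect_true(h6$projected)
  # too-small group: hull flagged as skipped
  d <- disparity_indices(matrix(rnorm(9), 3, 3), rep("g", 3),
                         n_boot = 5, seed = 1)
  expect_true(d$summary$hull_skipped[d$summary$index == "hull"])
})

test_that("disparity t-tests use Welch statistics with Bonferroni over pairs", {
  set.seed(11)
  X <- rbind(matrix(rnorm(100), 50, 2),
             matrix(rnorm(100), 50, 2),
             matrix(rnorm(100, 4), 50, 2))
  g <- rep(c("a", "b", "c"), each = 50)
  d <- disparity_indices(X, g, n_boot = 500, seed = 12)
  tt <- disparity_ttests(d)
  expect_equal(nrow(tt), 6L)                 # 3 pairs x 2 indices
  ab <- tt[tt$group1 == "a" & tt$group2 == "b" & tt$index == "ranges", ]
  expect_gt(ab$p_adjusted, 0.0)
  expect_lte(max(tt$p_adjusted), 1)
  expect_equal(tt$p_adjusted, pmin(1, tt$p_value * 3))
  ac <- tt[tt$group1 == "a" & tt$group2 == "c" & tt$index == "ranges", ]
  expect_lt(ac$p_adjusted, 0.001)            # shifted distributions
})

test_that("PGLS equals OLS on star trees and at lambda 0, and matches nlme", {
  tr <- default_tree()
  set.seed(13)
  dat <- tibble::tibble(
    species = tr$tip.label,
    strategy = ifelse(tr$tip.label %in%
                        c("A_oophorus", "O_eversi", "O_sarasinorum"),
                      "pelvic", "transfer"),
    standard_length = runif(8, 25, 45),
    PC1 = rnorm(8))
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("%s:1", tr$tip.label), collapse = ","), ");"))
  ols <- stats::lm(PC1 ~ strategy + standard_length, dat)
  fs <- pgls_fit(PC1 ~ strategy + standard_length, dat, star, lambda = 0.4)
  expect_lt(max(abs(fs$coefficients$estimate - coef(ols))), 1e-8)
  f0 <- pgls_fit(PC1 ~ strategy + standard_length, dat, tr, lambda = 0)
  expect_lt(max(abs(f0$coefficients$estimate - coef(ols))), 1e-8)
  expect_equal(f0$df, c(2L, 5L))

  skip_if_not_installed("nlme")
  g <- nlme::gls(PC1 ~ strategy + standard_length, data = as.data.frame(dat),
                 correlation = ape::corPagel(0.6, tr, fixed = TRUE,
                                             form = ~species),
                 method = "ML")
  fm <- pgls_fit(PC1 ~ strategy + standard_length, dat, tr, lambda = 0.6)
  expect_lt(max(abs(fm$coefficients$estimate - coef(g))), 1e-8)
  expect_equal(fm$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
})

test_that("the lambda policy optimizes the likelihood and applies the set-to-1 rule", {
  tr <- default_tree()
  dat <- tibble::tibble(
    species = tr$tip.label,
    strategy = ifelse(tr$tip.label %in%
                        c("A_oophorus", "O_eversi", "O_sarasinorum"),
                      "pelvic", "transfer"),
    standard_length = seq(25, 45, length.out = 8))
  ll_of <- function(fit) fit$loglik
  for (i in 1:5) {
    y <- sim_bm_traits(tr, sigma = 1, lambda = 1, seed = 400 + i)
    d2 <- dat; d2$PC1 <- y[dat$species]
    fml <- pgls_fit(PC1 ~ strategy + standard_length, d2, tr, lambda = "ML")
    l0 <- pgls_fit(PC1 ~ strategy + standard_length, d2, tr, lambda = 0)
    l1 <- pgls_fit(PC1 ~ strategy + standard_length, d2, tr, lambda = 1)
    expect_gte(fml$loglik + 1e-8, max(l0$loglik, l1$loglik))
    pol <- pgls_fit(PC1 ~ strategy + standard_length, d2, tr)
    if (pol$lrt_p_vs1 >= 0.05) expect_equal(pol$lambda_used, 1)
    expect_true(pol$lambda_hat >= 0 && pol$lambda_hat <= 1)
  }
})

test_that("species-sex means and the dimorphism contrast feed the PGLS scan", {
  des <- tiny_design(n_per = 4L)
  set.seed(14)
  sc <- matrix(rnorm(nrow(des) * 2), ncol = 2,
               dimnames = list(NULL, c("PC1", "PC2")))
  mm <- species_sex_means(sc, des)
  expect_setequal(unique(mm$sex), c("female", "male", "dimorphism"))
  a_f <- mm$PC1[mm$species == "A_sp" & mm$sex == "female"]
  a_m <- mm$PC1[mm$species == "A_sp" & mm$sex == "male"]
  a_d <- mm$PC1[mm$species == "A_sp" & mm$sex == "dimorphism"]
  expect_equal(a_d, a_m - a_f, tolerance = 1e-12)
  mq <- species_sex_means(sc, des, ratio = TRUE)
  expect_equal(mq$PC1[mq$species == "A_sp" & mq$sex == "dimorphism"],
               a_m / a_f, tolerance = 1e-12)

  # scan needs several species to fit strategy + size
  des4 <- dplyr::bind_rows(
    des,
    dplyr::mutate(des, species = paste0(.data$species, "2"),
                  specimen_id = paste0(.data$specimen_id, "x"),
                  strategy = rev(.data$strategy)))
  des4$strategy <- ifelse(des4$species %in% c("A_sp", "B_sp2"),
                          "pelvic", "transfer")
  des4$standard_length <- des4$standard_length +
    10 * as.integer(factor(des4$species))   # size varies across species
  set.seed(15)
  sc4 <- matrix(rnorm(nrow(des4) * 2), ncol = 2,
                dimnames = list(NULL, c("PC1", "PC2")))
  tr4 <- ape::read.tree(
    text = "((A_sp:1,A_sp2:1):1,(B_sp:1,B_sp2:1):1);")
  scan <- pgls_scan(sc4, des4, tr4, pcs = 1:2)
  expect_equal(nrow(scan), 6L)
  expect_true(all(scan$lambda_used >= 0 & scan$lambda_used <= 1))
})
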