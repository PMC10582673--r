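# Downstream statistics: broken-stick component retention, PERMANOVA on
# retained scores, disparity indices with bootstrap t-tests, z-scoring, and
# phylogenetic generalized least squares with a Pagel's-lambda policy.

#' Broken-stick retention of principal components
#'
#' Compares observed eigenvalue proportions with the broken-stick null
#' expectation `b_k = (1/p) * sum_{i=k..p} 1/i` and retains leading axes
#' while the observed proportion exceeds `b_k`, stopping at the first
#' failure.
#'
#' @param eigenvalues non-negative eigenvalues (at least two).
#' @return Integer count of retained axes (possibly zero).
#' @export
broken_stick <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  if (length(ev) < 2L) abort("broken stick needs at least 2 eigenvalues")
  if (any(ev < 0)) abort("eigenvalues must be non-negative")
  tot <- sum(ev)
  if (tot <= 0) abort("all eigenvalues are zero")
  p <- length(ev)
  props <- ev / tot
  b <- rev(cumsum(rev(1 / seq_len(p)))) / p
  ok <- props > b
  if (!ok[1]) return(0L)
  first_fail <- which(!ok)[1]
  if (is.na(first_fail)) p else first_fail - 1L
}

#' Z-transform score columns
#'
#' Standardizes each axis to mean 0, SD 1. Constant axes are dropped with a
#' warning.
#'
#' @param scores numeric matrix (specimens x axes), at least two rows.
#' @return Standardized matrix.
#' @export
zscore_scores <- function(scores) {
  X <- as.matrix(scores)
  if (nrow(X) < 2L) abort("z-scoring needs at least 2 rows")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d constant axis/axes", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(X) == 0L) abort("no variable axes left")
  scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
}

check_no_aliasing <- function(formula, data) {
  trm <- stats::terms(formula)
  labels <- attr(trm, "term.labels")
  X <- matrix(1, nrow(data), 1)
  for (lab in labels) {
    f1 <- stats::as.formula(paste("~", paste(c("1", lab), collapse = "+")))
    Xt <- stats::model.matrix(stats::as.formula(
      paste("~", paste(labels[seq_len(match(lab, labels))], collapse = "+"))),
      data)
    r_prev <- qr(X)$rank
    r_new <- qr(Xt)$rank
    if (r_new == r_prev)
      abort(sprintf(
        "term '%s' is aliased by the preceding terms; reorder the model",
        lab))
    X <- Xt
  }
  invisible(labels)
}

#' PERMANOVA on retained ordination scores
#'
#' Permutational multivariate analysis of variance on Euclidean distances
#' between retained PC scores, with sequential (Type-I) sums of squares and
#' free row permutation. The default model is
#' `strategy + sex + strategy:sex + standard_length`; a species-centred
#' ordering can be fitted by passing another formula. The permutation
#' p-value is `(1 + #{F* >= F}) / (1 + n_perm)`, so its floor with 9999
#' permutations is 1e-4.
#'
#' @param scores numeric matrix of retained scores (specimens x axes), rows
#'   in design order.
#' @param design design tibble with the model variables.
#' @param formula right-hand-side model formula over design columns.
#' @param n_perm number of permutations (9999 is the conventional choice).
#' @param seed optional seed making the permutation p-values reproducible.
#' @return A `permanova_tbl` tibble: `term`, `df`, `sum_sq`, `r_squared`,
#'   `statistic` (pseudo-F), `p_value`; attributes record `n_perm` and
#'   `seed`.
#' @export
permanova <- function(scores, design,
                      formula = ~ strategy + sex + strategy:sex +
                        standard_length,
                      n_perm = 9999L, seed = NULL) {
  X <- as.matrix(scores)
  dat <- as.data.frame(design)
  if (nrow(X) != nrow(dat)) abort("scores and design row counts differ")
  vars <- all.vars(formula)
  missing <- setdiff(vars, names(dat))
  if (length(missing) > 0)
    abort(sprintf("design lacks model variable(s): %s",
                  paste(missing, collapse = ", ")))
  if (anyNA(dat[vars])) abort("missing values in model variables")
  check_no_aliasing(formula, dat)
  .permanova_dist <- dist(X)
  # interactions become explicit combined factors so the sequential order
  # is exactly the order written (R's canonical expansion would move
  # interactions after all main effects, and the interaction SS is the
  # rank-increment over the preceding terms either way)
  labels <- attr(stats::terms(formula, keep.order = TRUE), "term.labels")
  safe <- labels
  for (i in seq_along(labels)) {
    if (grepl(":", labels[i], fixed = TRUE)) {
      parts <- strsplit(labels[i], ":", fixed = TRUE)[[1]]
      nm <- paste(parts, collapse = "_x_")
      dat[[nm]] <- interaction(dat[parts], drop = TRUE)
      safe[i] <- nm
    }
  }
  f <- stats::as.formula(
    paste(".permanova_dist ~", paste(safe, collapse = " + ")),
    env = environment())
  res <- with_local_seed(seed,
    vegan::adonis2(f, data = dat, permutations = n_perm, by = "terms"))
  term_names <- rownames(res)
  term_names[match(safe, term_names)] <- labels
  out <- tibble(term = term_names, df = res$Df, sum_sq = res$SumOfSqs,
                r_squared = res$R2, statistic = res$F,
                p_value = res$`Pr(>F)`)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("permanova_tbl", class(out))
  out
}

#' Disparity indices per group with bootstrap
#'
#' Sum of per-axis ranges and the convex-hull boundary measure
#' ([hull_measure()]) of each group's scores, with a specimen bootstrap
#' (resampling with replacement within group). Groups smaller than
#' `dim + 1` points get `NA` hull values with a flag.
#'
#' @param scores numeric matrix (specimens x axes).
#' @param groups grouping vector (length = specimens).
#' @param n_boot bootstrap replicates (5000 is the conventional choice).
#' @param seed optional seed.
#' @return A `disparity` object: `summary` tibble (group, index, observed,
#'   median and quartiles of the bootstrap) and `boot` (named list of
#'   matrices `n_boot x 2` with columns `ranges`, `hull`).
#' @export
disparity_indices <- function(scores, groups, n_boot = 5000L, seed = NULL) {
  X <- as.matrix(scores)
  groups <- as.character(groups)
  if (length(groups) != nrow(X)) abort("`groups` must match score rows")
  idx_by_group <- split(seq_len(nrow(X)), groups)

  indices <- function(M) {
    rng <- sum(apply(M, 2, function(v) diff(range(v))))
    # a d-dimensional hull needs at least d+1 points; smaller groups are
    # skipped (flagged), degenerate configurations fall back to their
    # affine span inside hull_measure()
    hull <- if (nrow(M) < ncol(M) + 1L) NA_real_ else
      tryCatch(hull_measure(M)$measure, error = function(e) NA_real_)
    c(ranges = rng, hull = hull)
  }

  with_local_seed(seed, {
    boot <- lapply(idx_by_group, function(ix) {
      out <- matrix(NA_real_, n_boot, 2,
                    dimnames = list(NULL, c("ranges", "hull")))
      for (b in seq_len(n_boot)) {
        take <- sample(ix, length(ix), replace = TRUE)
        out[b, ] <- indices(X[take, , drop = FALSE])
      }
      out
    })
    obs <- lapply(idx_by_group, function(ix) indices(X[ix, , drop = FALSE]))
    summary <- purrr::map_dfr(names(idx_by_group), function(g) {
      purrr::map_dfr(c("ranges", "hull"), function(ind) {
        bb <- boot[[g]][, ind]
        tibble(group = g, index = ind, n = length(idx_by_group[[g]]),
               observed = obs[[g]][[ind]],
               boot_median = median(bb, na.rm = TRUE),
               boot_q25 = quantile(bb, 0.25, na.rm = TRUE, names = FALSE),
               boot_q75 = quantile(bb, 0.75, na.rm = TRUE, names = FALSE),
               hull_skipped = ind == "hull" && all(is.na(bb)))
      })
    })
    structure(list(summary = summary, boot = boot, n_boot = n_boot,
                   seed = seed),
              class = "disparity")
  })
}

#' @export
print.disparity <- function(x, ...) {
  cat(sprintf("<disparity: %d groups, %d bootstrap replicates>\n",
              length(x$boot), x$n_boot))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.disparity <- function(x, ...) x$summary

#' Pairwise bootstrap t-tests between group disparity distributions
#'
#' Welch t-statistics on the bootstrap distributions of each index for every
#' group pair, with Bonferroni correction over the pairs within an index.
#'
#' @param disp a `disparity` object.
#' @return Tibble: `index`, `group1`, `group2`, `statistic`, `df`,
#'   `p_value`, `p_adjusted` (Bonferroni, capped at 1).
#' @export
disparity_ttests <- function(disp) {
  stopifnot(inherits(disp, "disparity"))
  gs <- names(disp$boot)
  if (length(gs) < 2L) abort("need at least 2 groups")
  pairs <- utils::combn(gs, 2)
  m <- ncol(pairs)
  purrr::map_dfr(c("ranges", "hull"), function(ind) {
    purrr::map_dfr(seq_len(m), function(k) {
      a <- disp$boot[[pairs[1, k]]][, ind]
      b <- disp$boot[[pairs[2, k]]][, ind]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2L || length(b) < 2L || (var(a) == 0 && var(b) == 0)) {
        tt <- list(statistic = 0, parameter = NA_real_,
                   p.value = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      } else {
        tt <- stats::t.test(a, b)
      }
      tibble(index = ind, group1 = pairs[1, k], group2 = pairs[2, k],
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value,
             p_adjusted = min(1, tt$p.value * m))
    })
  })
}

# ---- PGLS -----------------------------------------------------------------

gls_profile <- function(y, X, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) abort("phylogenetic covariance is not positive definite")
  logdet <- 2 * sum(log(diag(ch)))
  Xi <- backsolve(ch, X, transpose = TRUE)
  yi <- backsolve(ch, y, transpose = TRUE)
  fit <- stats::lm.fit(Xi, yi)
  beta <- fit$coefficients
  e <- yi - Xi %*% beta
  rss <- sum(e^2)
  sigma2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdet + n)
  list(beta = beta, rss = rss, sigma2_ml = sigma2_ml, loglik = ll,
       chol = ch, Xi = Xi, yi = yi)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' GLS regression of a species-level response with residual covariance
#' `V(lambda)`: the Brownian shared-path matrix of the tree with
#' off-diagonal entries scaled by `lambda`. `lambda` is estimated by
#' maximum likelihood on `[0, 1]` and tested against `lambda = 1` by a
#' likelihood-ratio test with the 50:50 chi-square boundary mixture; if the
#' test is not significant at `alpha` the model is refit with `lambda = 1`
#' (the conservative strong-signal assumption) and that fit is reported.
#' Polytomies enter as true multifurcations of the covariance matrix.
#'
#' @param formula model formula, e.g. `PC1 ~ strategy + standard_length`.
#' @param data species-level data frame with a `species` column matching
#'   the tree's tip labels.
#' @param tree a `phylo` with branch lengths covering the species.
#' @param lambda `"policy"` (default: ML estimate, then the set-to-1 rule),
#'   `"ML"` (always the ML estimate), or a fixed numeric value in `[0, 1]`.
#' @param alpha significance level of the lambda LRT.
#' @return A `pgls_fit` with coefficient table, `lambda_hat`,
#'   `lambda_used`, LRT p-values vs 0 and 1, F, df, R-squared and model p.
#' @export
pgls_fit <- function(formula, data, tree, lambda = "policy", alpha = 0.05) {
  dat <- as.data.frame(data)
  if (!"species" %in% names(dat)) abort("`data` needs a `species` column")
  if (!all(dat$species %in% tree$tip.label))
    abort("tree does not cover all species in `data`")
  tr <- ape::keep.tip(tree, dat$species)
  V <- ape::vcv(tr)[dat$species, dat$species]
  mf <- stats::model.frame(formula, dat)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) abort("singular design matrix")

  ll_of <- function(l) gls_profile(y, X, lambda_transform(V, l))$loglik
  opt <- optimize(ll_of, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll_of(0), ll_of(1))
  lambda_hat <- cand[which.max(lls)]
  ll_hat <- max(lls)

  lrt_p <- function(ll0) {
    D <- 2 * (ll_hat - ll0)
    if (D <= 0) 1 else 0.5 * pchisq(D, df = 1, lower.tail = FALSE)
  }
  p_vs1 <- lrt_p(ll_of(1))
  p_vs0 <- lrt_p(ll_of(0))

  lambda_used <- if (identical(lambda, "policy")) {
    if (p_vs1 >= alpha) 1 else lambda_hat
  } else if (identical(lambda, "ML")) lambda_hat
  else {
    lv <- as.numeric(lambda)
    if (is.na(lv) || lv < 0 || lv > 1) abort("fixed lambda must be in [0, 1]")
    lv
  }

  Vl <- lambda_transform(V, lambda_used)
  fit <- gls_profile(y, X, Vl)
  sigma2 <- fit$rss / (n - p)
  XtX_inv <- chol2inv(chol(crossprod(fit$Xi)))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- fit$beta / se
  pvals <- 2 * pt(abs(tval), df = n - p, lower.tail = FALSE)

  # intercept-only fit in the same covariance metric for F and R-squared
  fit0 <- gls_profile(y, matrix(1, n, 1), Vl)
  tss <- fit0$rss
  q <- p - 1L
  Fstat <- if (q > 0) ((tss - fit$rss) / q) / (fit$rss / (n - p)) else NA_real_
  model_p <- if (q > 0) pf(Fstat, q, n - p, lower.tail = FALSE) else NA_real_
  r2 <- 1 - fit$rss / tss

  structure(list(
    formula = formula, n = n,
    coefficients = tibble(term = colnames(X), estimate = as.numeric(fit$beta),
                          std_error = se, statistic = as.numeric(tval),
                          p_value = as.numeric(pvals)),
    lambda_hat = lambda_hat, lambda_used = lambda_used,
    lrt_p_vs1 = p_vs1, lrt_p_vs0 = p_vs0, loglik = fit$loglik,
    statistic = Fstat, df = c(q, n - p), r_squared = r2,
    p_value = model_p, sigma2 = sigma2),
    class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "<pgls_fit: n = %d, lambda_hat = %.3f (used %.3f), F(%d,%d) = %.3f, p = %.4g, R2 = %.3f>\n",
    x$n, x$lambda_hat, x$lambda_used, x$df[1], x$df[2], x$statistic,
    x$p_value, x$r_squared))
  invisible(x)
}

#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(n = x$n, lambda_hat = x$lambda_hat, lambda_used = x$lambda_used,
         lrt_p_vs1 = x$lrt_p_vs1, lrt_p_vs0 = x$lrt_p_vs0,
         statistic = x$statistic, df = x$df[1], df_residual = x$df[2],
         r_squared = x$r_squared, p_value = x$p_value,
         loglik = x$loglik)
}

#' Species-by-sex mean scores and a dimorphism response
#'
#' Averages retained PC scores per species and sex and derives a
#' male-to-female contrast per species: by default the male minus female
#' mean per axis (robust when scores cross zero); a quotient is available
#' with `ratio = TRUE`.
#'
#' @param scores numeric score matrix, rows in design order.
#' @param design design tibble with `species`, `sex`, `strategy`,
#'   `standard_length`.
#' @param ratio use the male/female quotient instead of the difference.
#' @return A tibble with `species`, `sex` (female, male, or `dimorphism`),
#'   `strategy`, `standard_length` (group mean), and one column per axis.
#' @export
species_sex_means <- function(scores, design, ratio = FALSE) {
  X <- as.matrix(scores)
  axes <- colnames(X) %||% paste0("PC", seq_len(ncol(X)))
  colnames(X) <- axes
  df <- dplyr::bind_cols(
    as_tibble(design[, c("species", "sex", "strategy", "standard_length")]),
    as_tibble(X))
  by_sex <- df |>
    dplyr::group_by(.data$species, .data$sex, .data$strategy) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("standard_length", axes)),
                                   mean), .groups = "drop")
  dim_tbl <- by_sex |>
    tidyr::pivot_longer(dplyr::all_of(axes), names_to = "axis") |>
    tidyr::pivot_wider(names_from = "sex", values_from = c("value", "standard_length")) |>
    dplyr::mutate(value = if (ratio) .data$value_male / .data$value_female
                  else .data$value_male - .data$value_female,
                  standard_length = (.data$standard_length_male +
                                       .data$standard_length_female) / 2,
                  sex = "dimorphism") |>
    dplyr::select("species", "sex", "strategy", "standard_length", "axis",
                  "value") |>
    tidyr::pivot_wider(names_from = "axis", values_from = "value")
  dplyr::bind_rows(by_sex, dim_tbl)
}

#' Fit the standard set of PGLS models over leading axes
#'
#' One model per axis and response set (females, males, dimorphism
#' contrast), regressing the species-level mean score on reproductive
#' strategy and standard length.
#'
#' @param scores retained score matrix (rows in design order).
#' @param design design tibble.
#' @param tree species `phylo`.
#' @param pcs axis numbers to model (default up to 6).
#' @param ratio dimorphism as quotient rather than difference.
#' @inheritParams pgls_fit
#' @return Tibble with one row per (axis, response set): glance columns of
#'   each [pgls_fit()] plus the strategy coefficient and its p-value.
#' @export
pgls_scan <- function(scores, design, tree, pcs = NULL, lambda = "policy",
                      alpha = 0.05, ratio = FALSE) {
  X <- as.matrix(scores)
  axes <- colnames(X) %||% paste0("PC", seq_len(ncol(X)))
  colnames(X) <- axes
  if (is.null(pcs)) pcs <- seq_len(min(6L, ncol(X)))
  means <- species_sex_means(X, design, ratio = ratio)
  purrr::map_dfr(c("female", "male", "dimorphism"), function(sx) {
    sub <- means[means$sex == sx, ]
    purrr::map_dfr(pcs, function(j) {
      f <- stats::as.formula(paste(axes[j], "~ strategy + standard_length"))
      fit <- pgls_fit(f, sub, tree, lambda = lambda, alpha = alpha)
      strat_row <- grepl("^strategy", fit$coefficients$term)
      dplyr::bind_cols(tibble(response = sx, axis = axes[j]),
                       glance(fit),
                       tibble(strategy_estimate =
                                fit$coefficients$estimate[strat_row][1],
                              strategy_p = fit$coefficients$p_value[strat_row][1]))
    })
  })
}
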