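test_that("chi_square_form satisfies the mass and residual identities", {
  set.seed(51)
  inst <- random_instance(8, 5, 2)
  cf <- chi_square_form(inst$s)
  expect_equal(sum(cf$P), 1)
  expect_equal(sum(cf$r), 1)
  expect_equal(sum(cf$c), 1)
  # trivial margins annihilate Qbar
  expect_lt(max(abs(cf$Qbar %*% sqrt(cf$c))), 1e-12)
  expect_lt(max(abs(crossprod(cf$Qbar, sqrt(cf$r)))), 1e-12)
  expect_error(chi_square_form(-inst$s), "shift_nonnegative")
})

test_that("build_environment averages per population", {
  set.seed(52)
  ref <- matrix(rnorm(36), 9, 4,
                dimnames = list(paste0("g", 1:9), paste0("s", 1:4)))
  grp <- c("A", "A", "B", "C")
  Z <- build_environment(ref, grp)
  expect_identical(colnames(Z), c("A", "B", "C"))
  expect_equal(Z[, "A"], rowMeans(ref[, 1:2]))
  expect_equal(Z[, "B"], ref[, 3])
  expect_error(build_environment(ref, grp, populations = c("A", "X")), "X")

  # idempotent mean: duplicated sample leaves the column unchanged
  ref2 <- cbind(ref, s5 = ref[, 3])
  Z2 <- build_environment(ref2, c(grp, "B"))
  expect_equal(Z2[, "B"], ref[, 3])
})

test_that("check_env_collinearity flags duplicates and dependences", {
  set.seed(53)
  Z <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  dup <- cbind(Z, d = Z[, "a"])
  rep_dup <- check_env_collinearity(dup)
  expect_true(any(rep_dup$flagged_pairs$r > 0.999))
  expect_true("a" %in% rep_dup$flagged_vif || "d" %in% rep_dup$flagged_vif)

  orth <- qr.Q(qr(Z))
  colnames(orth) <- colnames(Z)
  expect_lt(max(check_env_collinearity(orth)$vif), 1.5)

  dep <- cbind(Z[, 1:2], c = Z[, 1] + Z[, 2])
  expect_true(any(!is.finite(check_env_collinearity(dep)$vif)))
})

test_that("cca_fit matches the brute-force oracle on a fixed instance", {
  set.seed(54)
  inst <- random_instance(6, 4, 2)
  fit <- cca_fit(inst$s, inst$Z, scaling = 0)
  orc <- oracle_cca(inst$s, inst$Z)
  expect_equal(fit$eigenvalues, orc$eigenvalues, tolerance = 1e-10)
  expect_equal(fit$inertia_total, orc$inertia_total, tolerance = 1e-12)
  expect_equal(abs(unname(fit$sample_scores)), abs(orc$sample_scores),
               tolerance = 1e-8)
  ss <- sign_align(unname(fit$sample_scores), orc$sample_scores)
  expect_equal(ss, orc$sample_scores, tolerance = 1e-8)
  gl <- sign_align(unname(fit$gene_scores_lc), orc$gene_scores_lc)
  expect_equal(gl, orc$gene_scores_lc, tolerance = 1e-8)
  gw <- sign_align(unname(fit$gene_scores_wa), orc$gene_scores_wa)
  expect_equal(gw, orc$gene_scores_wa, tolerance = 1e-8)
  bb <- sign_align(unname(fit$env_biplot), orc$env_biplot)
  expect_equal(bb, orc$env_biplot, tolerance = 1e-8)
})

test_that("cca_fit agrees with vegan on eigenvalues and inertia", {
  skip_if_not_installed("vegan")
  set.seed(55)
  inst <- random_instance(12, 7, 3)
  fit <- cca_fit(inst$s, inst$Z)
  vg <- vegan::cca(X = inst$s, Y = inst$Z)
  expect_equal(unname(fit$eigenvalues), unname(vg$CCA$eig),
               tolerance = 1e-10)
  expect_equal(fit$inertia_total, vg$tot.chi, tolerance = 1e-10)
  expect_equal(fit$inertia_constrained, vg$CCA$tot.chi, tolerance = 1e-10)
})

test_that("degenerate and error contracts of cca_fit", {
  # rank-1 independence table: zero inertia everywhere
  r <- c(1, 2, 3); cc <- c(2, 1, 1, 2)
  s <- outer(r, cc)
  dimnames(s) <- list(paste0("g", 1:3), paste0("s", 1:4))
  Z <- matrix(rnorm(6), 3, 2, dimnames = list(rownames(s), c("a", "b")))
  fit <- cca_fit(s, Z)
  expect_equal(fit$inertia_total, 0, tolerance = 1e-12)
  expect_length(fit$eigenvalues, 0)

  set.seed(56)
  inst <- random_instance(6, 4, 2)
  expect_error(cca_fit(inst$s, inst$Z[, c(1, 1)]), "aliased")
  expect_error(cca_fit(inst$s, cbind(inst$Z, inst$Z, inst$Z)), "overfit")
})

test_that("CCA reduces to CA when the environment spans the gene space", {
  set.seed(57)
  inst <- random_instance(5, 8, 4)
  fit <- cca_fit(inst$s, inst$Z, scaling = 0)
  expect_equal(fit$percent_explained, 100, tolerance = 1e-8)
  cf <- chi_square_form(inst$s)
  ca_eig <- svd(cf$Qbar)$d
  ca_eig <- ca_eig[ca_eig > 1e-12 * ca_eig[1]]^2
  expect_equal(unname(fit$eigenvalues), ca_eig, tolerance = 1e-10)
  dec <- decompose_inertia(fit)
  expect_equal(dec$unconstrained, 0, tolerance = 1e-10)
})

test_that("inertia conservation, monotonicity and scale invariance hold", {
  set.seed(58)
  for (i in 1:20) {
    inst <- random_instance(sample(5:10, 1), sample(4:6, 1), 3)
    fit3 <- cca_fit(inst$s, inst$Z)
    dec <- decompose_inertia(fit3)
    expect_equal(dec$constrained + dec$unconstrained, dec$total,
                 tolerance = 1e-10)
    # nested projections: constrained inertia nondecreasing in columns
    fit1 <- cca_fit(inst$s, inst$Z[, 1, drop = FALSE])
    fit2 <- cca_fit(inst$s, inst$Z[, 1:2])
    expect_lte(fit1$inertia_constrained,
               fit2$inertia_constrained + 1e-12)
    expect_lte(fit2$inertia_constrained,
               fit3$inertia_constrained + 1e-12)
    # scale invariance
    fitk <- cca_fit(inst$s * 7.3, inst$Z)
    expect_equal(fitk$eigenvalues, fit3$eigenvalues, tolerance = 1e-12)
    expect_equal(fitk$sample_scores, fit3$sample_scores, tolerance = 1e-10)
  }
})

test_that("lc scores are the weighted projection of wa scores per axis", {
  set.seed(59)
  inst <- random_instance(9, 6, 3)
  fit <- cca_fit(inst$s, inst$Z, scaling = 0)
  cf <- fit$chi_form
  Zw <- fit$Zstd * sqrt(cf$r)
  H <- Zw %*% solve(crossprod(Zw)) %*% t(Zw)
  for (a in seq_along(fit$lambdas)) {
    proj <- (H %*% (sqrt(cf$r) * fit$gene_scores_wa[, a])) / sqrt(cf$r)
    expect_equal(as.vector(proj), unname(fit$gene_scores_lc[, a]),
                 tolerance = 1e-8)
  }
})

test_that("env arrows are weighted correlations; limits behave", {
  set.seed(60)
  inst <- random_instance(8, 5, 2)
  fit <- cca_fit(inst$s, inst$Z, scaling = 0)
  r <- fit$chi_form$r
  B <- fit$env_biplot
  for (j in 1:2) {
    for (a in seq_along(fit$lambdas)) {
      w <- fit$gene_scores_wa[, a]
      z <- fit$Zstd[, j]
      wmean <- sum(r * w)
      bb <- sum(r * z * (w - wmean)) / sqrt(sum(r * (w - wmean)^2))
      expect_equal(unname(B[j, a]), bb, tolerance = 1e-10)
    }
  }
  expect_lte(max(abs(B)), 1 + 1e-12)
  # environment column proportional to an axis's wa scores: |B| = 1
  Zp <- cbind(inst$Z[, 1, drop = FALSE],
              ax = fit$gene_scores_wa[, 1] * 2 + 1)
  fit2 <- cca_fit(inst$s, Zp, scaling = 0)
  B2 <- env_arrow_scores(fit2, weighted_std(Zp, fit2$chi_form$r))
  # recompute wa of original fit against new Zstd: use correlation directly
  r2 <- fit2$chi_form$r
  z <- weighted_std(Zp, r2)[, "ax"]
  w <- fit$gene_scores_wa[, 1]
  wc <- w - sum(r2 * w)
  expect_equal(abs(sum(r2 * z * wc) / sqrt(sum(r2 * wc^2))), 1,
               tolerance = 1e-10)
})

test_that("percent_visualised follows the eigenvalue arithmetic", {
  set.seed(61)
  inst <- random_instance(8, 6, 3)
  fit <- cca_fit(inst$s, inst$Z)
  k <- length(fit$eigenvalues)
  expect_equal(percent_visualised(fit, k), 100)
  expect_equal(percent_visualised(fit, 1),
               100 * fit$eigenvalues[1] / sum(fit$eigenvalues))
  expect_error(percent_visualised(fit, k + 1), "between")
})
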