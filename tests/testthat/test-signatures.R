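make_groups_matrix <- function(ng = 40, n1 = 4, n2 = 6, seed = 31,
                               effect = 0) {
  set.seed(seed)
  x <- matrix(rnorm(ng * (n1 + n2)), ng,
              dimnames = list(sprintf("g%02d", seq_len(ng)),
                              paste0("s", seq_len(n1 + n2))))
  x[1:5, seq_len(n1)] <- x[1:5, seq_len(n1)] + effect
  list(x = x, group = rep(c("T", "R"), c(n1, n2)))
}

test_that("d0 = 0 reproduces the ordinary two-sample t exactly", {
  d <- make_groups_matrix(effect = 1)
  st <- moderated_t(d$x, d$group, "T", d0 = 0)
  n1 <- sum(d$group == "T"); n2 <- sum(d$group == "R")
  tt <- apply(d$x, 1, function(v) {
    a <- v[d$group == "T"]; b <- v[d$group == "R"]
    sp <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    (mean(a) - mean(b)) / sqrt(sp * (1 / n1 + 1 / n2))
  })
  expect_equal(st$t_mod, unname(tt), tolerance = 1e-12)
})

test_that("d0 -> Inf collapses every posterior variance to s0_sq", {
  d <- make_groups_matrix(effect = 1)
  st_inf <- moderated_t(d$x, d$group, "T", d0 = Inf)
  st_big <- moderated_t(d$x, d$group, "T", d0 = 1e9)
  expect_equal(st_big$t_mod, st_inf$t_mod, tolerance = 1e-6)
  s0 <- attr(st_inf, "s0_sq")
  n1 <- 4; n2 <- 6
  expect_equal(st_inf$t_mod,
               st_inf$mean_diff / sqrt(s0 * (1 / n1 + 1 / n2)),
               tolerance = 1e-12)
})

test_that("moderated_t matches the reference empirical-Bayes fitter", {
  skip_if_not_installed("limma")
  d <- make_groups_matrix(ng = 120, n1 = 5, n2 = 7, seed = 33, effect = 1.5)
  st <- moderated_t(d$x, d$group, "T")
  design <- cbind(Intercept = 1, T = as.numeric(d$group == "T"))
  fit <- limma::eBayes(limma::lmFit(d$x, design))
  expect_equal(attr(st, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(st, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(st$t_mod, unname(fit$t[, "T"]), tolerance = 1e-8)
  expect_equal(st$p_raw, unname(fit$p.value[, "T"]), tolerance = 1e-8)
})

test_that("moderated_t is invariant to gene order and calibrated under null", {
  d <- make_groups_matrix(ng = 60, seed = 35)
  st <- moderated_t(d$x, d$group, "T")
  perm <- sample(nrow(d$x))
  st_p <- moderated_t(d$x[perm, ], d$group, "T")
  expect_equal(st_p$t_mod, st$t_mod[perm])
  expect_error(moderated_t(d$x[, 1:3], rep(c("T", "R"), c(1, 2)), "T"),
               ">=2 samples")

  set.seed(36)
  xn <- matrix(rnorm(200 * 10), 200,
               dimnames = list(sprintf("n%03d", 1:200), paste0("s", 1:10)))
  stn <- moderated_t(xn, rep(c("T", "R"), each = 5), "T")
  frac <- mean(stn$p_raw < 0.05)
  expect_gt(frac, 0.05 - 2.576 * sqrt(0.05 * 0.95 / 200))
  expect_lt(frac, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 200))
})

test_that("select_signature filters, ranks and breaks ties as specified", {
  st <- data.frame(
    gene_id = c("b", "a", "c", "d", "e"),
    t_mod = c(3, 3, 5, -2, 1),
    p_adj = c(1e-6, 1e-6, 1e-7, 1e-8, 0.5),
    stringsAsFactors = FALSE)
  all_pos <- select_signature(st, max_p_adj = 1, top_k = Inf)
  expect_identical(all_pos$gene_ids, c("c", "a", "b", "e"))
  expect_identical(select_signature(st, 1, top_k = 1)$gene_ids, "c")
  # tie at the cut: lexicographically smaller gene retained
  expect_identical(select_signature(st, 1, top_k = 2)$gene_ids, c("c", "a"))
  expect_error(select_signature(st, max_p_adj = 1e-12), "relaxing")
})

test_that("signature_score is the z-scaled Pearson correlation to the profile", {
  set.seed(41)
  prof <- c(g1 = 1, g2 = 3, g3 = 2, g4 = 5)
  x <- cbind(s1 = prof, s2 = -prof, s3 = prof * 2 + 7,
             s4 = rnorm(4), s5 = rnorm(4))
  rownames(x) <- names(prof)
  sig <- structure(list(population = "P", gene_ids = names(prof),
                        threshold_used = 1, mean_profile = prof),
                   class = "ccam_signature")
  raw <- signature_score(x, sig, scale = FALSE)
  expect_equal(unname(raw["s1"]), 1)
  expect_equal(unname(raw["s2"]), -1)
  expect_equal(unname(raw["s3"]), 1)  # affine invariance of correlation
  brute <- apply(x, 2, function(v) cor(v, prof))
  expect_equal(raw, brute)
  z <- signature_score(x, sig)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("cluster_signatures reproduces brute-force average linkage", {
  set.seed(43)
  base <- rnorm(10)
  m <- rbind(p1 = base, p2 = base,              # identical: merge at 0
             p3 = -base,                        # anti-correlated
             p4 = base + rnorm(10, 0, 0.4),
             p5 = rnorm(10),
             p6 = rnorm(10))
  colnames(m) <- paste0("s", 1:10)
  cl <- cluster_signatures(m)
  expect_equal(min(cl$hclust$height), 0, tolerance = 1e-12)

  # 3-row case: the anti-correlated row joins last
  m3 <- rbind(a = base, b = base + rnorm(10, 0, 0.1), c = -base)
  colnames(m3) <- paste0("s", 1:10)
  cl3 <- cluster_signatures(m3, h = 1)
  two <- cutree(cl3$hclust, k = 2)
  expect_equal(sum(two == two["c"]), 1L)

  orc <- oracle_average_linkage(1 - cor(t(m)))
  expect_equal(sort(cl$hclust$height), sort(orc$heights), tolerance = 1e-10)
  # every oracle merge set appears as a flat cluster at its merge height
  for (i in seq_along(orc$members)) {
    cut_i <- cutree(cl$hclust, h = orc$heights[i] + 1e-9)
    grp <- lapply(unname(split(seq_len(6), cut_i)), sort)
    expect_true(any(vapply(grp, identical, logical(1), orc$members[[i]])),
                info = paste("merge", i))
  }
})
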