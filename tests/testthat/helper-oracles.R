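# Independent oracles, deliberately written on a different code path from
# the package (explicit projector + eigendecomposition, direct enumeration).

options(ccam.verbose = FALSE)

# brute-force constrained ordination: forms the n_genes x n_genes projector
# explicitly and eigendecomposes Qc' Qc
oracle_cca <- function(s, Z) {
  P <- s / sum(s)
  r <- rowSums(P)
  cc <- colSums(P)
  E <- outer(r, cc)
  Qbar <- (P - E) / sqrt(E)
  mu <- colSums(Z * r)
  Zc <- sweep(Z, 2, mu)
  v <- colSums(Zc^2 * r)
  Zstd <- sweep(Zc, 2, sqrt(v), "/")
  Zw <- Zstd * sqrt(r)
  H <- Zw %*% solve(crossprod(Zw)) %*% t(Zw)
  Qc <- H %*% Qbar
  eg <- eigen(crossprod(Qc), symmetric = TRUE)
  pos <- eg$values > 1e-12 * max(eg$values, 1e-300)
  lam <- sqrt(pmax(eg$values[pos], 0))
  V <- eg$vectors[, pos, drop = FALSE]
  U <- Qc %*% V %*% diag(1 / lam, length(lam))
  sample_std <- V / sqrt(cc)
  gene_lc <- U / sqrt(r)
  wa <- sweep((P %*% sample_std) / r, 2, lam, "/")
  B <- sapply(seq_along(lam), function(a) {
    w <- wa[, a]
    wc <- w - sum(r * w)
    colSums(Zstd * (r * wc)) / sqrt(sum(r * wc^2))
  })
  B <- matrix(B, ncol = length(lam))
  list(eigenvalues = lam^2, lambdas = lam,
       sample_scores = unname(sample_std),
       gene_scores_lc = unname(gene_lc), gene_scores_wa = unname(wa),
       env_biplot = unname(B),
       inertia_total = sum(Qbar^2), inertia_constrained = sum(lam^2))
}

# r-weighted column standardization (test-side re-implementation)
weighted_std <- function(Z, r) {
  mu <- colSums(Z * r)
  Zc <- sweep(Z, 2, mu)
  sweep(Zc, 2, sqrt(colSums(Zc^2 * r)), "/")
}

# align the column signs of a to those of b (SVD signs are arbitrary)
sign_align <- function(a, b) {
  for (j in seq_len(ncol(a))) {
    if (sum(a[, j] * b[, j]) < 0) a[, j] <- -a[, j]
  }
  a
}

# random small nonnegative instance with no zero rows/columns
random_instance <- function(ng, ns, ne) {
  s <- matrix(stats::rexp(ng * ns) + 0.05, ng, ns,
              dimnames = list(paste0("g", seq_len(ng)),
                              paste0("s", seq_len(ns))))
  Z <- matrix(stats::rnorm(ng * ne), ng, ne,
              dimnames = list(rownames(s), paste0("E", seq_len(ne))))
  list(s = s, Z = Z)
}

# two-group log-rank by direct O-E / V enumeration over event times
oracle_logrank2 <- function(time, event, group) {
  levs <- sort(unique(group))
  stopifnot(length(levs) == 2)
  o <- 0; e <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    n <- sum(time >= tt)
    n1 <- sum(time >= tt & group == levs[1])
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == levs[1])
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# exact Mann-Whitney p by exhaustive enumeration of group assignments
oracle_mw_exact_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, function(i) {
    xx <- all_v[i]; yy <- all_v[-i]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  mu <- nx * (n - nx) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# step-by-step average-linkage agglomeration on a distance matrix
oracle_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i >= j) next
        h <- mean(d[active[[i]], active[[j]]])
        if (h < bh) { bh <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, bh)
    merges[[length(merges) + 1L]] <- sort(c(active[[best[1]]],
                                            active[[best[2]]]))
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1L]] <- merged
  }
  list(heights = heights, members = merges)
}

# default demo world (MDS-like severity continuum)
demo_cfg <- function(seed, ...) synthetic_config(seed = seed, ...)

# leukaemia-like world: near-pure samples, used for arrow recovery
recovery_cfg <- function(seed, ...) {
  synthetic_config(seed = seed, mixture_concentration = 0.1, ...)
}

run_pipe <- function(cfg, ...) {
  ref <- make_reference(cfg)
  dis <- make_disease(cfg)
  pipe <- ccam_pipeline(dis$expr, ref$expr, ref$annotation$group,
                        populations = cfg$population_names, ...)
  list(ref = ref, dis = dis, pipe = pipe)
}
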