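# simulate count profiles directly from the rate-correlation mixture
sim_t1_counts <- function(n, theta, alpha = 0.5, lA = 2, lB = 2) {
  div <- stats::runif(n) < theta
  rA <- stats::rgamma(n, alpha, alpha)
  rB <- ifelse(div, stats::rgamma(n, alpha, alpha), rA)
  list(a = mk_profile(stats::rpois(n, rA * lA)),
       b = mk_profile(stats::rpois(n, rB * lB)),
       divergent = div)
}
mk_profile <- function(x, n_leaves = 6) {
  structure(list(counts = x, n_leaves = n_leaves, tree_length = 1,
                 cluster_leaves = paste0("l", seq_len(n_leaves))),
            class = "site_profile")
}

test_that("parsimony site counts match exhaustive enumeration", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  aln <- c(a = "AAAC", b = "AACC", c = "ARAC", d = "ARCC")
  prof <- parsimony_site_counts(aln, tr, c("a", "b", "c", "d"))
  # column 1 invariant; column 2 single derived state twice (A,A,R,R);
  # columns 3-4 checked against the enumeration oracle
  expect_identical(prof$counts[1], 0L)
  m <- famevol:::.aln_to_matrix(aln)
  for (j in 1:4) {
    expect_identical(prof$counts[j],
                     as.integer(oracle_fitch_site(tr, m[tr$tip.label, j])))
  }
  # single derived state in one leaf -> one change
  aln2 <- c(a = "A", b = "A", c = "A", d = "C")
  expect_identical(parsimony_site_counts(aln2, tr, tr$tip.label)$counts, 1L)

  expect_error(parsimony_site_counts(aln, tr, "a"), "at least 2")
  # random two-state columns on a larger tree
  set.seed(17)
  tr6 <- ape::rtree(6)
  for (r in 1:10) {
    col <- sample(c("A", "S"), 6, replace = TRUE)
    aln6 <- stats::setNames(col, tr6$tip.label)
    prof6 <- parsimony_site_counts(aln6, tr6, tr6$tip.label)
    expect_identical(prof6$counts[1],
                     as.integer(oracle_fitch_site(tr6, col)))
  }
})

test_that("small clusters are refused for divergence analysis", {
  p3 <- mk_profile(c(1, 2, 0), n_leaves = 3)
  p6 <- mk_profile(c(1, 2, 0), n_leaves = 6)
  expect_error(fit_type1_divergence(p3, p6), "less than four sequences")
  a <- matrix("A", 3, 10, dimnames = list(paste0("x", 1:3), NULL))
  b <- matrix("A", 6, 10, dimnames = list(paste0("y", 1:6), NULL))
  expect_error(fit_type2_divergence(a, b), "less than four sequences")
})

test_that("type-I estimates are calibrated under the null", {
  set.seed(2)
  hits <- 0L
  for (r in 1:50) {
    d <- sim_t1_counts(300, theta = 0)
    fit <- fit_type1_divergence(d$a, d$b, n_starts = 2, seed = r)
    if (fit$theta <= 0.1) hits <- hits + 1L
    expect_gte(fit$theta, 0); expect_lte(fit$theta, 1)
    expect_true(all(fit$qk >= 0 & fit$qk <= 1))
    expect_gte(fit$lrt$two_delta_l, -1e-4)
  }
  expect_gte(hits / 50, 0.8)
})

test_that("type-I Qk is a posterior that permutes with the sites", {
  set.seed(3)
  d <- sim_t1_counts(200, theta = 0.5)
  fit <- fit_type1_divergence(d$a, d$b, n_starts = 2)
  perm <- sample(200)
  fit_p <- fit_type1_divergence(mk_profile(d$a$counts[perm]),
                                mk_profile(d$b$counts[perm]), n_starts = 2)
  expect_equal(fit_p$qk, fit$qk[perm], tolerance = 1e-6)
  # divergent sites carry higher Qk on average
  expect_gt(mean(fit$qk[d$divergent]), mean(fit$qk[!d$divergent]))
  expect_error(fit_type1_divergence(mk_profile(rep(0L, 50)),
                                    mk_profile(rep(0L, 50))),
               "inestimable")
})

# cluster alignments with a controlled fraction of radical shifts
sim_t2_alignments <- function(n_sites = 300, shift = 0.3, nA = 6, nB = 6,
                              poly = 0.15) {
  groups <- aa_property_groups()
  res <- names(groups)
  A <- matrix("", nA, n_sites); B <- matrix("", nB, n_sites)
  for (j in seq_len(n_sites)) {
    a <- sample(res, 1)
    b <- if (stats::runif(1) < shift) {
      sample(res[groups != groups[[a]]], 1)   # radical fixed difference
    } else if (stats::runif(1) < 0.5) a
      else sample(res[groups == groups[[a]]], 1) # conservative difference
    acol <- rep(a, nA); bcol <- rep(b, nB)
    if (stats::runif(1) < poly)
      acol[sample(nA, 1)] <- sample(res[groups == groups[[a]]], 1)
    if (stats::runif(1) < poly)
      bcol[sample(nB, 1)] <- sample(res[groups == groups[[b]]], 1)
    A[, j] <- acol; B[, j] <- bcol
  }
  rownames(A) <- paste0("a", seq_len(nA))
  rownames(B) <- paste0("b", seq_len(nB))
  list(a = A, b = B)
}

test_that("type-II estimator responds to radical property shifts", {
  # identical consensus everywhere: no radical signal, theta <= 0
  base <- matrix(rep(c("A", "K", "D", "S", "F"), each = 6), 6,
                 dimnames = list(paste0("a", 1:6), NULL))
  b2 <- base; rownames(b2) <- paste0("b", 1:6)
  b2[1, 1] <- "V" # some conservative within-cluster polymorphism
  fit0 <- fit_type2_divergence(base, b2)
  expect_lte(fit0$theta, 0)
  expect_true(all(fit0$qk == 0))

  set.seed(5)
  positive <- 0L
  for (r in 1:50) {
    d <- sim_t2_alignments(200, shift = 0.3)
    if (fit_type2_divergence(d$a, d$b)$theta > 0) positive <- positive + 1L
  }
  expect_gte(positive / 50, 0.8)

  # entirely gapped column in one cluster is an error
  g <- sim_t2_alignments(5)
  g$a[, 3] <- "-"
  expect_error(fit_type2_divergence(g$a, g$b), "entirely gapped")
})

test_that("negative type-II estimates are passed through unclamped", {
  # many conservative fixed differences, radical within-cluster polymorphism
  set.seed(11)
  groups <- aa_property_groups()
  res <- names(groups)
  nA <- 6; nB <- 6; n_sites <- 150
  A <- matrix("", nA, n_sites); B <- matrix("", nB, n_sites)
  for (j in seq_len(n_sites)) {
    a <- sample(res, 1)
    b <- sample(res[groups == groups[[a]]], 1) # conservative or identical
    acol <- rep(a, nA); bcol <- rep(b, nB)
    u <- stats::runif(1)
    if (u < 0.4) # radical polymorphism, keeping the baseline below 1
      acol[1] <- sample(res[groups != groups[[a]]], 1)
    else if (u < 0.6)
      acol[1] <- sample(setdiff(res[groups == groups[[a]]], a), 1)
    A[, j] <- acol; B[, j] <- bcol
  }
  rownames(A) <- paste0("a", 1:6); rownames(B) <- paste0("b", 1:6)
  fit <- fit_type2_divergence(A, B)
  expect_lt(fit$theta, 0)
  expect_true(is.finite(fit$se))
})

test_that("CAAS calling is strict and intersects correctly", {
  fake <- structure(list(qk = c(0.96, 0.95, 0.50), type = 1L),
                    class = "divergence_fit")
  expect_identical(call_caas(fake, 0.95), 1L)
  expect_identical(intersect_caas(c(3, 7, 9), c(7, 9, 11)), c(7L, 9L))

  # precision at the 0.95 cutoff is at least that at 0.80
  set.seed(8)
  prec <- function(calls, truth) if (length(calls)) mean(truth[calls]) else NA
  p95 <- c(); p80 <- c()
  for (r in 1:10) {
    d <- sim_t1_counts(400, theta = 0.3, alpha = 0.4, lA = 3, lB = 3)
    fit <- fit_type1_divergence(d$a, d$b, n_starts = 2, seed = r)
    p95 <- c(p95, prec(call_caas(fit, 0.95), d$divergent))
    p80 <- c(p80, prec(call_caas(fit, 0.80), d$divergent))
  }
  expect_gt(mean(p95, na.rm = TRUE), mean(p80, na.rm = TRUE))
})
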