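test_that("rate matrix is a proper reversible generator", {
  pi <- equal_codon_freqs()
  Q <- codon_rate_matrix(2.5, 0.4, pi)
  expect_lt(max(abs(rowSums(Q))), 1e-10)
  expect_lt(max(abs(pi %*% Q)), 1e-10)                    # stationarity
  expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-12)          # detailed balance
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)  # unit mean rate
})

test_that("likelihood engine handles degenerate trees in closed form", {
  pi <- equal_codon_freqs()
  aln1 <- c(only = "ATGGCTGGA")
  expect_equal(codon_log_likelihood(aln1, tree = NULL, codon_freqs = pi),
               3 * log(1 / 61))

  # all branch lengths zero, identical sequences: lnL = sum log pi
  tr <- balanced6(0)
  seqs <- stats::setNames(rep("ATGGCTGGAAAA", 6), tr$tip.label)
  expect_equal(
    codon_log_likelihood(seqs, tr, kappa = 2, omega = 0.5, codon_freqs = pi),
    4 * log(1 / 61), tolerance = 1e-10)
})

test_that("pruning equals exhaustive-state enumeration on small trees", {
  skip_if_not_installed("Matrix")
  pi <- equal_codon_freqs()
  # 3 taxa, 5 codons
  tr3 <- ape::read.tree(text = "(a:0.2,b:0.3,c:0.1);")
  s3 <- simulate_codon_alignment(
    tr3, sim_model_spec("M0", kappa = 2, omega = 0.5, seed = 3), 5)
  expect_equal(
    codon_log_likelihood(s3$alignment, tr3, kappa = 1.7, omega = 0.4,
                         codon_freqs = pi),
    oracle_codon_loglik(s3$alignment, tr3, 1.7, 0.4, pi),
    tolerance = 1e-8)

  # 4 taxa (two internal nodes), 10 codons
  tr4 <- ape::read.tree(text = "((a:0.2,b:0.1):0.15,c:0.3,d:0.25);")
  s4 <- simulate_codon_alignment(
    tr4, sim_model_spec("M0", kappa = 3, omega = 0.8, seed = 4), 10)
  expect_equal(
    codon_log_likelihood(s4$alignment, tr4, kappa = 2.2, omega = 1.1,
                         codon_freqs = pi),
    oracle_codon_loglik(s4$alignment, tr4, 2.2, 1.1, pi),
    tolerance = 1e-8)
})

test_that("likelihood ratio test matches its closed-form tail", {
  lrt <- likelihood_ratio_test(-14554.8, -14274.8, df = 4)
  expect_equal(lrt$two_delta_l, 560)
  expect_false(lrt$flagged)

  eq <- likelihood_ratio_test(-100, -100, df = 2)
  expect_equal(eq$two_delta_l, 0)
  expect_equal(eq$p_value, 1)

  neg <- likelihood_ratio_test(-99, -100, df = 1)
  expect_true(neg$flagged)
  expect_equal(neg$p_value, 1)

  # chi-square survival oracle (closed form for even df) at moderate x
  for (x in c(3.2, 9.5, 25)) {
    expect_equal(likelihood_ratio_test(0, x / 2, df = 4)$p_value,
                 oracle_chisq_tail_even_df(x, 4), tolerance = 1e-12)
  }
  # 2*dlnL = 560 on 4 df is below double-precision tail resolution
  expect_lt(likelihood_ratio_test(-14554.8, -14274.8, df = 4)$p_value,
            1e-100)
})

test_that("site models expose the conventional parameter counts", {
  tr <- balanced6(0.2)
  sim <- simulate_codon_alignment(
    tr, sim_model_spec("M0", kappa = 2, omega = 0.3, seed = 21), 60)
  m0 <- fit_site_model(sim$alignment, tr, "M0", n_starts = 1)
  expect_identical(m0$n_free_params, 1L)
  expect_true(is.finite(m0$lnL) && m0$lnL < 0)
  expect_s3_class(m0, "site_model_fit")
  expect_identical(
    vapply(c("M0", "M3", "M7", "M8"),
           function(m) famevol:::.site_model_pars(m, 10)$n_omega_pars,
           integer(1), USE.NAMES = FALSE),
    c(1L, 5L, 2L, 4L))
  # posterior rows sum to 1
  expect_equal(rowSums(m0$posterior), rep(1, 60))
})

test_that("optimizer is stable across starting points", {
  tr <- balanced6(0.25)
  sim <- simulate_codon_alignment(
    tr, sim_model_spec("M0", kappa = 2, omega = 0.4, seed = 31), 100)
  f1 <- fit_site_model(sim$alignment, tr, "M0", n_starts = 2, seed = 1)
  f2 <- fit_site_model(sim$alignment, tr, "M0", n_starts = 2, seed = 99)
  expect_lt(abs(f1$lnL - f2$lnL), 1e-4)
})

test_that("nested site models dominate their null models", {
  tr <- balanced6(0.25)
  sim <- simulate_codon_alignment(
    tr, sim_model_spec("M3", kappa = 2, omega = c(0.05, 0.5, 1.2),
                       proportions = c(0.5, 0.3, 0.2), seed = 41), 150)
  aln <- sim$alignment
  m0 <- fit_site_model(aln, tr, "M0", n_starts = 1)
  m3 <- fit_site_model(aln, tr, "M3", n_starts = 2)
  m7 <- fit_site_model(aln, tr, "M7", n_starts = 1)
  m8 <- fit_site_model(aln, tr, "M8", n_starts = 2)
  expect_gte(m3$lnL, m0$lnL - 1e-4)
  expect_gte(m8$lnL, m7$lnL - 1e-4)
  lrt <- likelihood_ratio_test(m0$lnL, m3$lnL, df = 4)
  expect_gte(lrt$two_delta_l, -1e-4)
})

test_that("positive-site inference is refused for models without omega > 1", {
  tr <- balanced6(0.25)
  sim <- simulate_codon_alignment(
    tr, sim_model_spec("M0", kappa = 2, omega = 0.3, seed = 51), 60)
  m7 <- fit_site_model(sim$alignment, tr, "M7", n_starts = 1)
  expect_error(site_posteriors(m7), "not allowed")
  m0 <- fit_site_model(sim$alignment, tr, "M0", n_starts = 1)
  expect_error(site_posteriors(m0), "not allowed")
})

test_that("NEB posteriors normalize and collapse for degenerate mixtures", {
  cls_ll <- matrix(log(c(0.2, 0.5, 0.1, 0.4, 0.3, 0.2)), nrow = 3)
  post <- famevol:::.neb_posterior(cls_ll, c(0.2, 0.3, 0.5))
  expect_equal(rowSums(post), rep(1, 2))
  # all weight on one class forces posterior 1 on that class
  post1 <- famevol:::.neb_posterior(cls_ll, c(0, 0, 1))
  expect_equal(post1[, 3], rep(1, 2))
})

test_that("M8 empirical Bayes enriches truly selected sites", {
  tr <- balanced6(0.3)
  spec <- sim_model_spec("M8", kappa = 2, beta_params = c(0.5, 2), p0 = 0.9,
                         omega_s = 3, seed = 42)
  sim <- simulate_codon_alignment(tr, spec, 300)
  truth <- sim$site_classes == 11 # the selected class
  fit <- fit_site_model(sim$alignment, tr, "M8", n_starts = 2, seed = 1)
  neb <- site_posteriors(fit, "NEB")
  calls <- neb$sites_0.95
  expect_gt(length(calls), 0)
  precision <- mean(truth[calls])
  expect_gt(precision / mean(truth), 5)
  # gridBEB returns posteriors on the same scale
  grid <- site_posteriors(fit, "gridBEB")
  expect_true(all(grid$posterior_positive >= 0 &
                    grid$posterior_positive <= 1))
})

test_that("branch-site fit has the model-A class structure", {
  tr <- balanced6(0.3)
  fg <- edge_to_tip(tr, "a")
  spec <- sim_model_spec("branch_site_A", kappa = 2, p0 = 0.7, p1 = 0.2,
                         omega0 = 0.2, omega_s = 3,
                         foreground_branches = fg, seed = 61)
  sim <- simulate_codon_alignment(tr, spec, 120)
  bs <- fit_branch_site(sim$alignment, tr, foreground = fg, n_starts = 1)
  cls <- bs$classes
  expect_equal(sum(cls$proportion), 1, tolerance = 1e-9)
  expect_equal(cls$proportion[3] / cls$proportion[4],
               cls$proportion[1] / cls$proportion[2], tolerance = 1e-9)
  expect_gte(bs$params$omega2, 1)
  expect_equal(cls$omega_fg[3], cls$omega_fg[4])
  expect_true(all(bs$posterior_positive >= 0 & bs$posterior_positive <= 1))

  expect_error(fit_branch_site(sim$alignment, tr, integer(0)), "at least one")
  expect_error(
    fit_branch_site(sim$alignment, tr, seq_len(nrow(tr$edge))),
    "background")
})

test_that("branch-site LRT detects strong foreground selection", {
  tr <- balanced6(0.3)
  fg <- edge_to_tip(tr, "a")
  rejections <- 0L
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    spec <- sim_model_spec("branch_site_A", kappa = 2, p0 = 0.80, p1 = 0.10,
                           omega0 = 0.2, omega_s = 4,
                           foreground_branches = fg, seed = 7000 + r)
    sim <- simulate_codon_alignment(tr, spec, 500)
    bs <- fit_branch_site(sim$alignment, tr, foreground = fg,
                          n_starts = 1, seed = r)
    if (bs$lrt$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_rep, 0.6)
})
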