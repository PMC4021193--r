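make_locus <- function(ranks_by_chr) {
  rows <- lapply(names(ranks_by_chr), function(chr) {
    r <- ranks_by_chr[[chr]]
    data.frame(gene_id = paste0("c", chr, "g", r), chromosome = chr,
               rank = r, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("tandem clusters follow the one-intervening-gene rule", {
  locus <- make_locus(list(`1` = 1:10))
  fam <- function(r) paste0("c1g", r)

  # consecutive ranks 1,2,3 -> one cluster of three
  cl <- detect_tandem_clusters(locus, fam(1:3))
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$gene_ids, fam(1:3))

  # ranks 1,2,3,5 (one intervening non-family gene) -> one cluster of four
  cl <- detect_tandem_clusters(locus, fam(c(1, 2, 3, 5)))
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$gene_ids, fam(c(1, 2, 3, 5)))

  # two intervening genes break the chain
  expect_length(detect_tandem_clusters(locus, fam(c(1, 4))), 0L)

  # clusters never span chromosomes
  locus2 <- make_locus(list(`1` = 1:3, `2` = 1:3))
  cl2 <- detect_tandem_clusters(locus2, c("c1g2", "c1g3", "c2g1", "c2g2"))
  expect_length(cl2, 2L)
  expect_true(all(vapply(cl2, function(x) length(x$gene_ids), 1L) == 2L))

  expect_error(detect_tandem_clusters(locus, "nope"), "absent")
})

test_that("tandem detection recovers planted clusters exactly", {
  for (seed in 1:10) {
    fx <- generate_genome_fixture(n_chromosomes = 4, n_genes = 160,
                                  tandem_sizes = c(3, 2, 4, 2),
                                  n_singleton_family = 5,
                                  n_segmental_pairs = 0, seed = seed)
    found <- detect_tandem_clusters(fx$locus_table,
                                    fx$locus_table$gene_id[fx$locus_table$is_family])
    found_sets <- lapply(found, function(x) sort(x$gene_ids))
    planted_sets <- lapply(fx$planted_tandem, sort)
    expect_setequal(found_sets, planted_sets)
  }
})

test_that("NG86 counts match the trivial cases", {
  cds <- "ATGGCTGGAAAATTC"
  r <- compute_ng86(cds, cds)
  expect_equal(r$ka, 0); expect_equal(r$ks, 0)
  expect_true(is.na(r$omega))
  expect_equal(r$N + r$S, 3 * r$n_codons, tolerance = 1e-9)

  # TTT -> TTA is Phe -> Leu: one nonsynonymous difference
  r <- compute_ng86("TTT", "TTA")
  expect_equal(r$Sd, 0); expect_equal(r$Nd, 1)
  expect_equal(r$ks, 0); expect_gt(r$ka, 0)

  expect_error(compute_ng86("TTT", "TTTAAA"), "equal codon counts")
})

test_that("NG86 equals the pathway-enumeration oracle", {
  # 10-codon pair including a double-hit codon (GCT vs GAA), a synonymous
  # change (TTC vs TTT) and a triple-hit codon (ATG vs GCA)
  s1 <- "ATGGCTGGAAAATTCGCTCATCGTACGATG"
  s2 <- "ATGGAAGGAAAATTTGCTCATCGTACGGCA"
  got <- compute_ng86(s1, s2)
  exp <- oracle_ng86(s1, s2)
  expect_equal(got$ks, exp$ks, tolerance = 1e-12)
  expect_equal(got$ka, exp$ka, tolerance = 1e-12)
  expect_equal(got$S, exp$S, tolerance = 1e-12)
  expect_equal(got$Sd, exp$Sd, tolerance = 1e-12)

  # swap invariance, also on gapped random pairs
  set.seed(12)
  tr <- ape::read.tree(text = "(u:0.3,v:0.3);")
  for (r in 1:5) {
    sim <- simulate_codon_alignment(
      tr, sim_model_spec("M0", kappa = 2, omega = 0.4, seed = 300 + r), 50)
    a <- sim$alignment[["u"]]; b <- sim$alignment[["v"]]
    f <- compute_ng86(a, b); g <- compute_ng86(b, a)
    expect_equal(f$ka, g$ka, tolerance = 1e-12)
    expect_equal(f$ks, g$ks, tolerance = 1e-12)
    o <- oracle_ng86(a, b)
    expect_equal(f$ks, o$ks, tolerance = 1e-12)
    expect_equal(f$ka, o$ka, tolerance = 1e-12)
  }
})

test_that("NG86 Ks tracks the simulated synonymous divergence", {
  # kappa = 1 so the equal-pathway NG counting is unbiased; target Ks is
  # branch length x synonymous flux / synonymous sites under the model
  pi <- equal_codon_freqs()
  Q <- codon_rate_matrix(1, 0.3, pi, scale = TRUE)
  syn <- outer(famevol:::SENSE_AA, famevol:::SENSE_AA, "==")
  offd <- Q; diag(offd) <- 0
  syn_flux <- sum(pi * rowSums(offd * syn))
  true_ks <- 0.6 * syn_flux / sum(pi * famevol:::.NG_SYN_SITES)
  tr <- ape::read.tree(text = "(x:0.3,y:0.3);")
  est <- vapply(1:20, function(r) {
    sim <- simulate_codon_alignment(
      tr, sim_model_spec("M0", kappa = 1, omega = 0.3, seed = 2000 + r), 500)
    compute_ng86(sim$alignment[[1]], sim$alignment[[2]])$ks
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - true_ks), 3 * se)
})

test_that("4DTv counts fourfold third-position transversions", {
  expect_equal(compute_4dtv("GGA", "GGT")$value, 1) # A<->T transversion
  expect_equal(compute_4dtv("GGA", "GGG")$value, 0) # transition
  expect_equal(compute_4dtv("GGAGGC", "GGAGGC")$value, 0)
  expect_error(compute_4dtv("TTT", "TTT"), "fourfold")
  # never exceeds 1; zero against itself
  set.seed(4)
  tr <- ape::read.tree(text = "(x:0.5,y:0.5);")
  sim <- simulate_codon_alignment(
    tr, sim_model_spec("M0", kappa = 2, omega = 0.5, seed = 6), 200)
  v <- compute_4dtv(sim$alignment[[1]], sim$alignment[[2]])
  expect_gte(v$value, 0); expect_lte(v$value, 1)
  expect_equal(compute_4dtv(sim$alignment[[1]], sim$alignment[[1]])$value, 0)
})

test_that("segmental dating filters anchors and converts Ks to ages", {
  ev <- date_segmental_event(c("A", "B"), rep(0.100, 6))
  expect_identical(ev$t_my, 8L)
  ev <- date_segmental_event(c("A", "B"), anchors_from_summary(3, 0.817, 0.266))
  expect_identical(ev$t_my, 67L)
  expect_equal(ev$sd_ks, 0.266, tolerance = 1e-9)

  rej <- date_segmental_event(c("A", "B"), c(0.2, 0.3))
  expect_true(rej$rejected)
  expect_match(rej$reason, "fewer than 3")

  # window endpoints are open
  ev2 <- date_segmental_event(c("A", "B"), c(0.2, 0.3, 0.4, 1.0, 0))
  expect_identical(ev2$n_anchors, 3L)

  # dating is linear in the mean Ks before rounding
  ks <- c(0.11, 0.14, 0.20)
  t1 <- date_segmental_event(c("A", "B"), ks)$t_years
  t2 <- date_segmental_event(c("A", "B"), 2 * ks)$t_years
  expect_equal(t2, 2 * t1)
})

test_that("duplication report computes family percentages", {
  ids <- sprintf("m%02d", 1:75)
  clusters <- list(list(gene_ids = ids[1:4]), list(gene_ids = ids[5:8]),
                   list(gene_ids = ids[9:11]))
  events <- lapply(1:26, function(i) list(pair = ids[c(2 * i - 1, 2 * i)],
                                          rejected = FALSE))
  events[[26]]$pair <- ids[c(51, 1)] # 26 events covering 51 distinct genes
  rpt <- duplication_report(ids, clusters, events)
  expect_identical(rpt$n_tandem, 11L)
  expect_equal(rpt$pct_tandem, 14.7)
  expect_identical(rpt$n_segmental, 51L)
  expect_equal(rpt$pct_segmental, 68.0)

  empty <- duplication_report(character(0))
  expect_identical(empty$n_tandem, 0L)
  expect_equal(empty$pct_segmental, 0)
})
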