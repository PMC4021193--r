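## Type-I and type-II functional divergence between paralogous clusters.
## Type I (rate shift after duplication) follows the classic
## rate-correlation mixture: a fraction theta of sites draw independent
## gamma-distributed rates in the two clusters while the rest share one
## rate, with Poisson likelihoods for per-site parsimony substitution
## counts. Type II (property shift) is a moment-style contrast of radical
## between-cluster fixed differences against the within-cluster radical
## polymorphism baseline.

#' Per-site parsimony substitution counts within a cluster subtree
#'
#' Fitch minimum-change counts per alignment column on the subtree spanned
#' by the cluster's leaves.
#'
#' @param alignment Named character vector or matrix of aligned proteins.
#' @param tree `ape::phylo` containing the cluster leaves.
#' @param cluster_leaves Character vector of >= 2 leaf names; a warning is
#'   issued when they are not monophyletic in `tree`.
#' @return A `site_profile` list: `counts` (integer per site), `n_leaves`,
#'   `tree_length` (sum of subtree branch lengths, NA if absent),
#'   `cluster_leaves`.
#' @export
parsimony_site_counts <- function(alignment, tree, cluster_leaves) {
  if (length(cluster_leaves) < 2)
    stop("cluster must contain at least 2 leaves")
  m <- .aln_to_matrix(alignment)
  missing <- setdiff(cluster_leaves, tree$tip.label)
  if (length(missing))
    stop("leaves absent from tree: ", paste(missing, collapse = ", "))
  if (!all(cluster_leaves %in% rownames(m)))
    stop("cluster leaves absent from alignment")
  if (length(setdiff(tree$tip.label, cluster_leaves)) > 0 &&
      !ape::is.monophyletic(tree, cluster_leaves))
    warning("cluster leaves are not monophyletic in the supplied tree")
  sub <- ape::keep.tip(tree, cluster_leaves)
  sm <- m[sub$tip.label, , drop = FALSE]
  pd <- phangorn::phyDat(sm, type = "AA")
  scores <- phangorn::fitch(sub, pd, site = "site")
  counts <- as.integer(scores[attr(pd, "index")])
  structure(list(counts = counts, n_leaves = length(cluster_leaves),
                 tree_length = if (is.null(sub$edge.length)) NA_real_
                               else sum(sub$edge.length),
                 cluster_leaves = cluster_leaves),
            class = "site_profile")
}

## log density of the shared-rate (f0) and independent-rate (f1) components
## for count pairs, gamma(shape a, rate a) site rates (mean 1), Poisson
## means r * lambda.
.t1_log_f0 <- function(xA, xB, a, lA, lB) {
  lgamma(a + xA + xB) - lgamma(a) - lfactorial(xA) - lfactorial(xB) +
    xA * log(lA) + xB * log(lB) + a * log(a) -
    (a + xA + xB) * log(a + lA + lB)
}
.t1_log_nb <- function(x, a, l) {
  lgamma(a + x) - lgamma(a) - lfactorial(x) +
    x * log(l) + a * log(a) - (a + x) * log(a + l)
}
.t1_log_f1 <- function(xA, xB, a, lA, lB)
  .t1_log_nb(xA, a, lA) + .t1_log_nb(xB, a, lB)

.t1_loglik <- function(theta, a, lA, lB, xA, xB) {
  l0 <- .t1_log_f0(xA, xB, a, lA, lB)
  l1 <- .t1_log_f1(xA, xB, a, lA, lB)
  if (theta <= 0) return(sum(l0))
  if (theta >= 1) return(sum(l1))
  m <- pmax(l0, l1)
  sum(m + log((1 - theta) * exp(l0 - m) + theta * exp(l1 - m)))
}

#' Fit type-I functional divergence between two clusters
#'
#' Maximum likelihood for the two-state mixture: with probability theta a
#' site's evolutionary rates in the two clusters are independent
#' gamma(alpha) draws (rate shift after duplication); otherwise the two
#' clusters share a single gamma rate. Per-cluster Poisson means scale the
#' common rate. The LRT contrasts theta = 0 (1 df); Qk is the posterior
#' probability of the divergent class at each site.
#'
#' @param profile_a,profile_b `site_profile` objects from
#'   [parsimony_site_counts()] over the same alignment columns.
#' @param n_starts Optimizer restarts (seeded).
#' @param seed Integer seed for the restarts.
#' @return Object of class `divergence_fit` with `type = 1`, `theta`,
#'   `se`, `lrt` (an `lrt_result`), `qk`, `alpha`, `lambda`,
#'   `boundary` flag.
#' @export
fit_type1_divergence <- function(profile_a, profile_b, n_starts = 4,
                                 seed = 1L) {
  stopifnot(inherits(profile_a, "site_profile"),
            inherits(profile_b, "site_profile"))
  if (profile_a$n_leaves < 4 || profile_b$n_leaves < 4)
    stop("groups with less than four sequences cannot be analyzed")
  xA <- profile_a$counts; xB <- profile_b$counts
  if (length(xA) != length(xB))
    stop("profiles must cover the same alignment columns")
  if (all(xA == 0) && all(xB == 0))
    stop("all-zero substitution counts in both clusters: theta inestimable")

  # par = (logit theta, log alpha, log lambdaA, log lambdaB)
  neg_ll <- function(par) {
    v <- -.t1_loglik(stats::plogis(par[1]), exp(par[2]), exp(par[3]),
                     exp(par[4]), xA, xB)
    if (!is.finite(v)) 1e10 else v
  }
  mA <- max(mean(xA), 0.05); mB <- max(mean(xB), 0.05)
  base <- c(0, log(1), log(mA), log(mB))
  restore_rng <- .rng_snapshot()
  on.exit(restore_rng(), add = TRUE)
  set.seed(as.integer(seed))
  starts <- c(list(base),
              replicate(max(0, n_starts - 1),
                        base + stats::rnorm(4, 0, 0.8), simplify = FALSE))
  best <- NULL
  for (s in starts) {
    opt <- stats::nlminb(s, neg_ll, control = list(iter.max = 300))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  theta <- stats::plogis(best$par[1])
  a <- exp(best$par[2]); lA <- exp(best$par[3]); lB <- exp(best$par[4])
  lnL1 <- -best$objective

  # null model: theta = 0 (shared rates only)
  neg_ll0 <- function(par) {
    v <- -.t1_loglik(0, exp(par[1]), exp(par[2]), exp(par[3]), xA, xB)
    if (!is.finite(v)) 1e10 else v
  }
  opt0 <- stats::nlminb(best$par[2:4], neg_ll0, control = list(iter.max = 300))
  lnL0 <- -opt0$objective
  lrt <- likelihood_ratio_test(lnL0, lnL1, df = 1, mixture = FALSE)

  # delta-method standard error for theta on the probability scale
  se <- NA_real_
  boundary <- theta < 1e-4 || theta > 1 - 1e-4
  if (!boundary) {
    H <- tryCatch(stats::optimHess(best$par, neg_ll), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && V[1, 1] > 0) {
        dtheta <- theta * (1 - theta) # d plogis / d logit
        se <- sqrt(V[1, 1]) * dtheta
      }
    }
  }

  l0 <- .t1_log_f0(xA, xB, a, lA, lB)
  l1 <- .t1_log_f1(xA, xB, a, lA, lB)
  qk <- if (theta <= 0) rep(0, length(xA)) else {
    num <- log(theta) + l1
    den <- mapply(function(p, q) .logsumexp(c(p, q)),
                  log(theta) + l1, log1p(-theta) + l0)
    exp(num - den)
  }
  structure(list(type = 1L, theta = min(max(theta, 0), 1), se = se,
                 lrt = lrt, qk = qk, alpha = a,
                 lambda = c(a = lA, b = lB),
                 boundary = boundary, lnL = lnL1, lnL_null = lnL0),
            class = "divergence_fit")
}

#' Amino-acid physicochemical property groups
#'
#' A coarse charge/polarity partition of the 20 standard residues
#' (positive, negative, polar uncharged, nonpolar) used to classify
#' substitutions as radical (group-changing) or conservative.
#'
#' @return Named character vector mapping residue -> group.
#' @export
aa_property_groups <- function() {
  c(K = "positive", R = "positive", H = "positive",
    D = "negative", E = "negative",
    S = "polar", T = "polar", N = "polar", Q = "polar",
    C = "polar", G = "polar", Y = "polar", W = "polar",
    A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
    M = "nonpolar", F = "nonpolar", P = "nonpolar")
}

#' Fit type-II functional divergence between two clusters
#'
#' Moment-style estimator of the fraction of sites with a radical
#' (property-group changing) shift between clusters. Sites with disjoint
#' residue sets in the two clusters are fixed differences; a fixed
#' difference is radical when the cluster consensus residues fall in
#' different property groups. The baseline probability that an ordinary
#' substitution is radical is estimated from within-cluster polymorphism,
#' and `thetaII = (f_radical - baseline) / (1 - baseline)`; estimates may
#' be negative and are reported unclamped with a delta-method standard
#' error.
#'
#' @param alignment_a,alignment_b Aligned proteins (named vectors or
#'   matrices) of the two clusters over the same columns.
#' @param property_groups Residue -> group mapping (default
#'   [aa_property_groups()]).
#' @return Object of class `divergence_fit` with `type = 2`, `theta`
#'   (unclamped), `se`, `qk`, and the contrast's ingredients
#'   (`n_fixed`, `n_radical_fixed`, `baseline`).
#' @export
fit_type2_divergence <- function(alignment_a, alignment_b,
                                 property_groups = aa_property_groups()) {
  mA <- .aln_to_matrix(alignment_a)
  mB <- .aln_to_matrix(alignment_b)
  if (ncol(mA) != ncol(mB))
    stop("cluster alignments must cover the same columns")
  if (nrow(mA) < 4 || nrow(mB) < 4)
    stop("groups with less than four sequences cannot be analyzed")
  n_sites <- ncol(mA)
  states <- function(col) col[col %in% names(property_groups)]
  consensus <- function(s) names(sort(table(s), decreasing = TRUE))[1]

  fixed <- logical(n_sites); radical <- logical(n_sites)
  polymorphic <- 0L; radical_poly <- 0L
  for (j in seq_len(n_sites)) {
    sA <- states(mA[, j]); sB <- states(mB[, j])
    if (!length(sA) || !length(sB))
      stop("alignment column ", j, " is entirely gapped in one cluster")
    fixed[j] <- length(intersect(unique(sA), unique(sB))) == 0L
    if (fixed[j])
      radical[j] <- property_groups[[consensus(sA)]] !=
        property_groups[[consensus(sB)]]
    for (s in list(sA, sB)) {
      if (length(unique(s)) > 1L) {
        polymorphic <- polymorphic + 1L
        if (length(unique(property_groups[s])) > 1L)
          radical_poly <- radical_poly + 1L
      }
    }
  }
  n_fixed <- sum(fixed); n_rad <- sum(radical)
  baseline <- if (polymorphic > 0) radical_poly / polymorphic else 0
  f_rad <- if (n_fixed > 0) n_rad / n_fixed else 0
  theta <- if (baseline < 1) (f_rad - baseline) / (1 - baseline) else NA_real_

  se <- NA_real_
  if (!is.na(theta) && n_fixed > 0 && polymorphic > 0) {
    vf <- f_rad * (1 - f_rad) / n_fixed
    vp <- baseline * (1 - baseline) / polymorphic
    se <- sqrt(vf / (1 - baseline)^2 +
                 vp * (1 - f_rad)^2 / (1 - baseline)^4)
  }
  qk <- rep(0, n_sites)
  tc <- max(theta, 0, na.rm = TRUE)
  if (tc > 0) {
    denom <- tc + (1 - tc) * baseline
    qk[radical] <- if (denom > 0) tc / denom else 1
  }
  structure(list(type = 2L, theta = theta, se = se, qk = qk,
                 n_fixed = n_fixed, n_radical_fixed = n_rad,
                 baseline = baseline, lrt = NULL),
            class = "divergence_fit")
}

#' @export
print.divergence_fit <- function(x, ...) {
  lab <- if (x$type == 1L) "Type-I" else "Type-II"
  se_txt <- if (is.na(x$se)) "NA" else sprintf("%.3f", x$se)
  cat(sprintf("%s functional divergence: theta = %.3f +/- %s\n",
              lab, x$theta, se_txt))
  if (!is.null(x$lrt)) print(x$lrt)
  cat("  sites with Qk > 0.95:", length(call_caas(x, 0.95)), "\n")
  invisible(x)
}

#' @export
coef.divergence_fit <- function(object, ...) {
  c(theta = object$theta, se = object$se)
}

#' Call critical amino acid sites from a divergence fit
#'
#' Sites whose posterior Qk strictly exceeds the cutoff.
#'
#' @param fit A `divergence_fit` (or any object with a numeric `qk`).
#' @param cutoff Posterior cutoff (default 0.95).
#' @return Integer vector of 1-based alignment-column indices.
#' @export
call_caas <- function(fit, cutoff = 0.95) {
  qk <- if (is.list(fit)) fit$qk else fit
  which(qk > cutoff)
}

#' Intersect critical-site calls from two analyses
#'
#' @param sites_a,sites_b Site index vectors (or `divergence_fit` objects,
#'   called at `cutoff`).
#' @param cutoff Cutoff applied when fits are supplied.
#' @return Sorted intersection of the two site sets.
#' @export
intersect_caas <- function(sites_a, sites_b, cutoff = 0.95) {
  get_sites <- function(x)
    if (inherits(x, "divergence_fit")) call_caas(x, cutoff) else as.integer(x)
  sort(intersect(get_sites(sites_a), get_sites(sites_b)))
}

#' @export
summary.divergence_fit <- function(object, ...) {
  print(object)
  caas <- call_caas(object, 0.95)
  if (length(caas))
    cat("  critical sites (Qk > 0.95):", paste(caas, collapse = ", "), "\n")
  invisible(object)
}
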