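## Maximum-likelihood codon-model machinery: Felsenstein pruning over the
## 61-state GY94 rate matrix, site models M0/M3/M7/M8 as omega-class
## mixtures, the branch-site model A, likelihood-ratio tests and
## empirical-Bayes site identification. Site classes share one rate scale
## (the proportion-weighted mean background rate is 1) so branch lengths
## are expected substitutions per codon, matching the simulator.

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Precompute pattern-compressed alignment data bound to a tree.
.codon_lik_data <- function(alignment, tree, codon_freqs = NULL) {
  stopifnot(inherits(tree, "phylo"))
  states_full <- codon_matrix(alignment)
  if (!setequal(rownames(states_full), tree$tip.label))
    stop("alignment names and tree leaves do not match")
  states_full <- states_full[tree$tip.label, , drop = FALSE]
  pi <- if (is.null(codon_freqs)) f3x4_frequencies(alignment) else codon_freqs
  .check_codon_freqs(pi)
  key <- apply(states_full, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat_index <- match(key, key[first])
  pstates <- states_full[, first, drop = FALSE]
  w <- tabulate(pat_index, nbins = sum(first))
  tree_po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  npat <- ncol(pstates)
  list(tree = tree_po, pi = pi, weights = w, pat_index = pat_index,
       npat = npat, ntip = ntip, tip_states = pstates,
       n_sites = length(pat_index))
}

## Per-class, per-pattern log-likelihood matrix (nclass x npat).
## classes: data frame with omega_bg, omega_fg; fg_children: child node ids
## of foreground edges. Eigendecompositions of the *unscaled* GY94 matrix
## are cached per (kappa, omega) in `cache` (which may persist across
## optimizer evaluations); the mixture rate scale is folded into the
## branch length, since scaling Q only scales its eigenvalues.
.class_pattern_loglik <- function(dat, kappa, classes, scale = 1,
                                  fg_children = integer(0), cache = NULL) {
  pi <- dat$pi
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$eig)) { cache$eig <- list(); cache$rate <- list() }
  get_unit <- function(omega) {
    key <- sprintf("%.17g_%.17g", kappa, omega)
    u <- cache$eig[[key]]
    if (is.null(u)) {
      Q <- codon_rate_matrix(kappa, omega, pi, scale = FALSE)
      u <- codon_eigen(Q, pi)
      cache$eig[[key]] <- u
      cache$rate[[key]] <- -sum(pi * diag(Q))
    }
    u
  }
  rate_of <- function(omega) {
    get_unit(omega)
    cache$rate[[sprintf("%.17g_%.17g", kappa, omega)]]
  }
  mu <- sum(classes$proportion * vapply(classes$omega_bg, rate_of, numeric(1)))
  p_cache <- list()
  get_P <- function(omega, t) {
    key <- sprintf("%.17g_%.17g", omega, t)
    if (is.null(p_cache[[key]]))
      p_cache[[key]] <<- codon_probs(get_unit(omega), t / mu)
    p_cache[[key]]
  }
  tree <- dat$tree
  edges <- tree$edge
  elen <- tree$edge.length * scale
  npat <- dat$npat
  nclass <- nrow(classes)
  out <- matrix(0, nclass, npat)
  for (k in seq_len(nclass)) {
    partial <- vector("list", max(edges))
    logsc <- rep(0, npat)
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; ch <- edges[e, 2]
      omega <- if (ch %in% fg_children) classes$omega_fg[k] else classes$omega_bg[k]
      P <- get_P(omega, elen[e])
      if (ch <= dat$ntip) {
        # tip: P %*% indicator is just column selection; NA = missing codon
        st <- dat$tip_states[ch, ]
        contrib <- matrix(1, N_SENSE, npat)
        obs <- !is.na(st)
        contrib[, obs] <- P[, st[obs], drop = FALSE]
      } else {
        contrib <- P %*% partial[[ch]]
      }
      if (is.null(partial[[par]])) {
        partial[[par]] <- contrib
      } else {
        x <- partial[[par]] * contrib
        # 1-norm column rescaling against underflow (values are nonnegative)
        cs <- .colSums(x, N_SENSE, npat)
        cs[cs == 0] <- 1
        partial[[par]] <- x * rep(1 / cs, each = N_SENSE)
        logsc <- logsc + log(cs)
      }
    }
    root <- edges[nrow(edges), 1]
    lik <- as.vector(pi %*% partial[[root]])
    out[k, ] <- log(lik) + logsc
  }
  out
}

## Column-wise logsumexp for a small-row matrix, loop-free over columns.
.col_logsumexp <- function(x) {
  n <- nrow(x)
  if (n == 1L) return(as.vector(x))
  m <- x[1, ]
  for (i in 2:n) m <- pmax(m, x[i, ])
  m + log(.colSums(exp(x - rep(m, each = n)), n, ncol(x)))
}

## Mix class pattern log-likelihoods into a total log-likelihood.
.mix_loglik <- function(cls_ll, proportions, weights) {
  sum(weights * .col_logsumexp(cls_ll + log(proportions)))
}

#' Codon-model log-likelihood
#'
#' Felsenstein-pruning log-likelihood of a codon alignment on a tree under
#' the GY94 model with an omega-class mixture. With a single sequence and
#' `tree = NULL` the likelihood reduces to the stationary codon
#' frequencies.
#'
#' @param alignment Named character vector of aligned CDS (no stop codons).
#' @param tree `ape::phylo` tree whose leaves match the alignment names.
#' @param kappa Transition/transversion ratio.
#' @param omega Single omega, or use `classes`.
#' @param classes Optional data frame `proportion`, `omega_bg`, `omega_fg`
#'   (as in [sim_model_spec()]'s normalized classes).
#' @param codon_freqs 61-vector of codon frequencies; default F3x4 from the
#'   alignment.
#' @param scale Multiplier applied to all branch lengths.
#' @param foreground Integer indices of foreground edges (rows of
#'   `tree$edge`) for branch-site classes.
#' @return Total log-likelihood (scalar).
#' @export
codon_log_likelihood <- function(alignment, tree = NULL, kappa = 2,
                                 omega = NULL, classes = NULL,
                                 codon_freqs = NULL, scale = 1,
                                 foreground = integer(0)) {
  if (is.null(tree)) {
    if (length(alignment) != 1L)
      stop("tree may be NULL only for a single sequence")
    pi <- if (is.null(codon_freqs)) equal_codon_freqs() else codon_freqs
    idx <- codon_matrix(alignment)[1, ]
    return(sum(log(pi[idx])))
  }
  if (is.null(classes)) {
    if (is.null(omega)) stop("supply either omega or classes")
    classes <- data.frame(proportion = 1, omega_bg = omega, omega_fg = omega)
  }
  fg_children <- if (length(foreground)) tree$edge[foreground, 2] else integer(0)
  dat <- .codon_lik_data(alignment, tree, codon_freqs)
  cls_ll <- .class_pattern_loglik(dat, kappa, classes, scale, fg_children)
  .mix_loglik(cls_ll, classes$proportion, dat$weights)
}

## ---- site models ---------------------------------------------------------

## Parameter transforms per model: R^p -> named parameter list.
.softmax <- function(x) { e <- exp(c(x, 0)); e / sum(e) }

.site_model_pars <- function(model, n_beta_classes) {
  switch(model,
    M0 = list(
      n = 3L,
      init = function() c(log(2), log(0.3), 0),
      unpack = function(par) list(kappa = exp(par[1]), scale = exp(par[3]),
                                  omega = exp(par[2])),
      classes = function(p) data.frame(proportion = 1, omega_bg = p$omega,
                                       omega_fg = p$omega),
      n_omega_pars = 1L),
    M3 = list(
      n = 7L,
      init = function() c(log(2), 0, 0, 0, log(0.05), log(0.3), log(1)),
      unpack = function(par) list(kappa = exp(par[1]), scale = exp(par[2]),
                                  prop = .softmax(par[3:4]),
                                  omega = exp(par[5:7])),
      classes = function(p) data.frame(proportion = p$prop,
                                       omega_bg = p$omega, omega_fg = p$omega),
      n_omega_pars = 5L),
    M7 = list(
      n = 4L,
      init = function() c(log(2), 0, log(0.5), log(2)),
      unpack = function(par) list(kappa = exp(par[1]), scale = exp(par[2]),
                                  p = exp(par[3]), q = exp(par[4])),
      classes = function(p) {
        w <- beta_omega_classes(p$p, p$q, p$k)
        data.frame(proportion = rep(1 / p$k, p$k), omega_bg = w, omega_fg = w)
      },
      n_omega_pars = 2L),
    M8 = list(
      n = 6L,
      init = function() c(log(2), 0, log(0.5), log(2), stats::qlogis(0.9), log(1)),
      unpack = function(par) list(kappa = exp(par[1]), scale = exp(par[2]),
                                  p = exp(par[3]), q = exp(par[4]),
                                  p0 = stats::plogis(par[5]),
                                  omega_s = 1 + exp(par[6])),
      classes = function(p) {
        w <- beta_omega_classes(p$p, p$q, p$k)
        data.frame(proportion = c(rep(p$p0 / p$k, p$k), 1 - p$p0),
                   omega_bg = c(w, p$omega_s), omega_fg = c(w, p$omega_s))
      },
      n_omega_pars = 4L))
}

#' Fit a codon site model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over kappa, a global branch-length
#' scale and the model's omega-distribution parameters. The beta models
#' discretize beta(p, q) into `n_beta_classes` equal-probability
#' categories. Multiple optimizer starts are used; for the alternative
#' models one start is warm-loaded from the matching null fit (M0 for M3,
#' M7 for M8) so that nested-model likelihood dominance holds to optimizer
#' tolerance.
#'
#' @param alignment Named character vector of aligned CDS.
#' @param tree `ape::phylo` tree with branch lengths (relative; a free
#'   scale is estimated).
#' @param model `"M0"`, `"M3"`, `"M7"` or `"M8"`.
#' @param codon_freqs 61-vector or `NULL` (F3x4 from the data; pass
#'   `equal_codon_freqs()` for the equal-frequency variant).
#' @param n_beta_classes Beta discretization size (default 10).
#' @param n_starts Optimizer starts (first deterministic, rest jittered).
#' @param seed Seed for the jittered starts.
#' @return An object of class `site_model_fit`: fitted parameters,
#'   `classes` table, `lnL`, `n_free_params` (omega-distribution parameter
#'   count), per-site class posteriors, and the bound data for
#'   empirical-Bayes refinement.
#' @export
fit_site_model <- function(alignment, tree, model = c("M0", "M3", "M7", "M8"),
                           codon_freqs = NULL, n_beta_classes = 10,
                           n_starts = 3, seed = 1L) {
  model <- match.arg(model)
  dat <- .codon_lik_data(alignment, tree, codon_freqs)
  mp <- .site_model_pars(model, n_beta_classes)
  cache <- new.env(parent = emptyenv())

  objective <- function(par) {
    p <- mp$unpack(par); p$k <- n_beta_classes
    cls <- mp$classes(p)
    ll <- tryCatch(
      .mix_loglik(.class_pattern_loglik(dat, p$kappa, cls, p$scale,
                                        cache = cache),
                  cls$proportion, dat$weights),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- list(mp$init())
  # warm start from the nested null model
  if (model == "M3") {
    m0 <- fit_site_model(alignment, tree, "M0", codon_freqs = dat$pi,
                         n_starts = 1, seed = seed)
    w0 <- max(m0$params$omega, 1e-4)
    starts[[length(starts) + 1L]] <-
      c(log(m0$params$kappa), log(m0$params$scale), 0, 0,
        log(w0 * 0.5), log(w0), log(w0 * 1.5))
  }
  if (model == "M8") {
    m7 <- fit_site_model(alignment, tree, "M7", codon_freqs = dat$pi,
                         n_beta_classes = n_beta_classes,
                         n_starts = 1, seed = seed)
    starts[[length(starts) + 1L]] <-
      c(log(m7$params$kappa), log(m7$params$scale), log(m7$params$p),
        log(m7$params$q), stats::qlogis(1 - 1e-5), log(1 + 1e-6))
  }
  restore_rng <- .rng_snapshot()
  on.exit(restore_rng(), add = TRUE)
  set.seed(as.integer(seed))
  while (length(starts) < n_starts)
    starts[[length(starts) + 1L]] <- mp$init() + stats::rnorm(mp$n, 0, 0.5)

  best <- NULL
  for (s in starts) {
    opt <- stats::nlminb(s, objective,
                         control = list(iter.max = 500, eval.max = 1000,
                                        rel.tol = 1e-10))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  p <- mp$unpack(best$par); p$k <- n_beta_classes
  cls <- mp$classes(p)
  cls_ll <- .class_pattern_loglik(dat, p$kappa, cls, p$scale, cache = cache)
  lnL <- .mix_loglik(cls_ll, cls$proportion, dat$weights)
  post_pat <- .neb_posterior(cls_ll, cls$proportion)
  structure(list(model = model, params = p, classes = cls, lnL = lnL,
                 n_free_params = mp$n_omega_pars,
                 kappa = p$kappa, scale = p$scale,
                 posterior = post_pat[dat$pat_index, , drop = FALSE],
                 converged = best$convergence == 0,
                 data = dat, n_beta_classes = n_beta_classes),
            class = "site_model_fit")
}

## columns of cls_ll are patterns; returns npat x nclass posterior matrix
.neb_posterior <- function(cls_ll, proportions) {
  lp <- log(proportions)
  post <- t(apply(cls_ll + lp, 2, function(x) {
    z <- .logsumexp(x); exp(x - z)
  }))
  if (nrow(cls_ll) == 1L) post <- matrix(1, ncol(cls_ll), 1)
  post
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat("Codon site model", x$model, "  lnL =", sprintf("%.4f", x$lnL), "\n")
  cat("  kappa =", sprintf("%.4f", x$kappa),
      "  branch scale =", sprintf("%.4f", x$scale), "\n")
  if (x$model == "M0") {
    cat("  omega =", sprintf("%.5f", x$params$omega), "\n")
  } else if (x$model == "M3") {
    cat("  proportions:", paste(sprintf("%.5f", x$params$prop), collapse = " "), "\n")
    cat("  omegas:     ", paste(sprintf("%.5f", x$params$omega), collapse = " "), "\n")
  } else {
    cat("  beta p =", sprintf("%.5f", x$params$p),
        " q =", sprintf("%.5f", x$params$q), "\n")
    if (x$model == "M8")
      cat("  p0 =", sprintf("%.5f", x$params$p0),
          " omega_s =", sprintf("%.5f", x$params$omega_s), "\n")
  }
  invisible(x)
}

#' @export
logLik.site_model_fit <- function(object, ...) {
  structure(object$lnL, df = object$n_free_params + 2L, class = "logLik")
}

#' @export
coef.site_model_fit <- function(object, ...) {
  p <- object$params
  out <- c(kappa = p$kappa, scale = p$scale)
  extra <- switch(object$model,
    M0 = c(omega = p$omega),
    M3 = c(stats::setNames(p$prop, paste0("p", seq_along(p$prop) - 1L)),
           stats::setNames(p$omega, paste0("omega", seq_along(p$omega) - 1L))),
    M7 = c(p = p$p, q = p$q),
    M8 = c(p0 = p$p0, p = p$p, q = p$q, omega_s = p$omega_s))
  c(out, extra)
}

#' Likelihood-ratio test between nested codon models
#'
#' @param lnl0,lnl1 Log-likelihoods of the null and alternative models.
#' @param df Degrees of freedom (difference in free parameters, >= 1).
#' @param mixture Use the 50:50 mixture of a point mass at 0 and chi-square
#'   with 1 df (branch-site convention) instead of the plain chi-square?
#' @return List of class `lrt_result`: `two_delta_l`, `df`, `p_value`,
#'   `flagged` (TRUE when 2*delta-lnL is negative, in which case p = 1).
#' @export
likelihood_ratio_test <- function(lnl0, lnl1, df = 1, mixture = FALSE) {
  if (df < 1) stop("df must be >= 1")
  x <- 2 * (lnl1 - lnl0)
  flagged <- x < 0
  p <- if (flagged) 1 else if (mixture) {
    if (x == 0) 1 else 0.5 * stats::pchisq(x, 1, lower.tail = FALSE)
  } else stats::pchisq(x, df, lower.tail = FALSE)
  structure(list(two_delta_l = x, df = df, p_value = p, flagged = flagged),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: 2*dlnL = %.4f  df = %d  p = %.4g%s\n",
              x$two_delta_l, x$df, x$p_value,
              if (x$flagged) "  [flagged: negative 2*dlnL]" else ""))
  invisible(x)
}

#' Empirical-Bayes identification of positively selected sites
#'
#' Naive empirical Bayes (NEB): posterior of class k at a site is
#' proportional to the class proportion times the class's site likelihood,
#' all evaluated at the MLEs. `"gridBEB"` averages the NEB posterior over
#' an 8-point grid of perturbed selection parameters (proportion and omega
#' of the selected class scaled by fixed factors), a documented coarse
#' stand-in for full Bayes empirical Bayes integration.
#'
#' @param fit A `site_model_fit` from a model with at least one omega > 1
#'   class (M3 or M8 with omega_s > 1).
#' @param method `"NEB"` or `"gridBEB"`.
#' @param cutoff Posterior cutoff for calling sites (default 0.95; 0.99
#'   reported alongside).
#' @return List with `method`, `posterior_positive` (per-site posterior of
#'   the omega > 1 classes), `sites_0.95`, `sites_0.99`, `cutoff_sites`.
#' @export
site_posteriors <- function(fit, method = c("NEB", "gridBEB"), cutoff = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "site_model_fit"))
  if (fit$model %in% c("M0", "M7"))
    stop("not allowed: model ", fit$model, " has no omega > 1 class")
  pos_class <- which(fit$classes$omega_bg > 1)
  if (!length(pos_class))
    stop("no fitted class with omega > 1; positive-site inference not allowed")
  dat <- fit$data
  if (method == "NEB") {
    pp <- rowSums(fit$posterior[, pos_class, drop = FALSE])
  } else {
    # 8 grid points: {0.5, 1, 1.5} x {0.75, 1, 1.33} on (selected proportion,
    # selected omega), center excluded; equal prior weights
    grid <- expand.grid(fp = c(0.5, 1, 1.5), fw = c(0.75, 1, 1.33))
    grid <- grid[!(grid$fp == 1 & grid$fw == 1), ]
    acc <- 0
    for (g in seq_len(nrow(grid))) {
      cls <- fit$classes
      sel <- pos_class
      newp <- pmin(cls$proportion[sel] * grid$fp[g], 0.95)
      cls$proportion[sel] <- newp
      cls$proportion[-sel] <- cls$proportion[-sel] *
        (1 - sum(newp)) / sum(cls$proportion[-sel])
      cls$omega_bg[sel] <- cls$omega_fg[sel] <-
        1 + (cls$omega_bg[sel] - 1) * grid$fw[g]
      cll <- .class_pattern_loglik(dat, fit$kappa, cls, fit$scale)
      post <- .neb_posterior(cll, cls$proportion)
      acc <- acc + rowSums(post[, sel, drop = FALSE])
    }
    pp <- (acc / nrow(grid))[dat$pat_index]
  }
  pp <- as.vector(pp)
  list(method = method, posterior_positive = pp,
       sites_0.95 = which(pp > 0.95), sites_0.99 = which(pp > 0.99),
       cutoff_sites = which(pp > cutoff))
}

## ---- branch-site model A -------------------------------------------------

.bs_classes <- function(p0, p1, omega0, omega2) {
  p2 <- 1 - p0 - p1
  data.frame(
    proportion = c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1)),
    omega_bg = c(omega0, 1, omega0, 1),
    omega_fg = c(omega0, 1, omega2, omega2),
    row.names = c("0", "1", "2a", "2b"))
}

#' Fit the branch-site model A and test for foreground positive selection
#'
#' Four site classes: 0 (omega0 everywhere), 1 (neutral everywhere), 2a and
#' 2b (omega0 / 1 on background branches, omega2 on foreground branches),
#' with class 2 split between 2a and 2b in proportion p0 : p1. The null
#' model fixes omega2 = 1; the alternative constrains omega2 >= 1; the LRT
#' has 1 degree of freedom. kappa and the branch-length scale are estimated
#' once under M0 and held fixed for both branch-site fits. Positive sites
#' on the foreground are identified by NEB posteriors of classes 2a + 2b.
#'
#' @param alignment Named character vector of aligned CDS.
#' @param tree `ape::phylo` tree with branch lengths.
#' @param foreground Integer indices of foreground edges (rows of
#'   `tree$edge`); must be a nonempty proper subset.
#' @param codon_freqs 61-vector or `NULL` (F3x4).
#' @param n_starts Optimizer starts per fit.
#' @param seed Seed for jittered starts.
#' @param mixture_null Use the 50:50 chi-square mixture for the LRT p-value
#'   (default FALSE: plain chi-square with 1 df, the conservative
#'   convention).
#' @return Object of class `branch_site_fit`: `classes` (fitted
#'   proportions and omegas, alternative model), `lnL_alt`, `lnL_null`,
#'   `lrt` (an `lrt_result`), `posterior_positive` per site, `sites_0.95`,
#'   `kappa`, `scale`, `params`.
#' @export
fit_branch_site <- function(alignment, tree, foreground,
                            codon_freqs = NULL, n_starts = 2, seed = 1L,
                            mixture_null = FALSE) {
  if (!length(foreground)) stop("foreground must contain at least one edge")
  if (length(foreground) >= nrow(tree$edge))
    stop("foreground cannot include every branch (no background left)")
  fg_children <- tree$edge[foreground, 2]
  dat <- .codon_lik_data(alignment, tree, codon_freqs)
  m0 <- fit_site_model(alignment, tree, "M0", codon_freqs = dat$pi,
                       n_starts = 1, seed = seed)
  kappa <- m0$kappa; scale <- m0$scale
  cache <- new.env(parent = emptyenv())

  make_obj <- function(fix_omega2) function(par) {
    pr <- .softmax(par[1:2])
    p0 <- pr[1]; p1 <- pr[2]
    omega0 <- stats::plogis(par[3])
    omega2 <- if (is.na(fix_omega2)) 1 + exp(par[4]) else fix_omega2
    cls <- .bs_classes(p0, p1, omega0, omega2)
    ll <- tryCatch(
      .mix_loglik(.class_pattern_loglik(dat, kappa, cls, scale, fg_children,
                                        cache = cache),
                  cls$proportion, dat$weights),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  run_fit <- function(obj, npar, inits) {
    best <- NULL
    for (s in inits) {
      opt <- stats::nlminb(s, obj,
                           control = list(iter.max = 400, eval.max = 800,
                                          rel.tol = 1e-9))
      if (is.null(best) || opt$objective < best$objective) best <- opt
    }
    best
  }

  restore_rng <- .rng_snapshot()
  on.exit(restore_rng(), add = TRUE)
  set.seed(as.integer(seed))
  base_null <- c(1.5, -0.5, stats::qlogis(0.15))
  inits_null <- c(list(base_null),
                  replicate(max(0, n_starts - 1),
                            base_null + stats::rnorm(3, 0, 0.7),
                            simplify = FALSE))
  fit_null <- run_fit(make_obj(1), 3, inits_null)
  # alternative warm-started from the null optimum (omega2 ~ 1) plus jitter
  base_alt <- c(fit_null$par, log(1e-4))
  inits_alt <- c(list(base_alt, c(fit_null$par, log(1))),
                 replicate(max(0, n_starts - 1),
                           base_alt + c(stats::rnorm(3, 0, 0.7), log(2)),
                           simplify = FALSE))
  fit_alt <- run_fit(make_obj(NA), 4, inits_alt)

  lnL_null <- -fit_null$objective
  lnL_alt <- -fit_alt$objective
  pr <- .softmax(fit_alt$par[1:2])
  omega0 <- stats::plogis(fit_alt$par[3])
  omega2 <- 1 + exp(fit_alt$par[4])
  cls <- .bs_classes(pr[1], pr[2], omega0, omega2)
  lrt <- likelihood_ratio_test(lnL_null, lnL_alt, df = 1,
                               mixture = mixture_null)
  cls_ll <- .class_pattern_loglik(dat, kappa, cls, scale, fg_children,
                                  cache = cache)
  post <- .neb_posterior(cls_ll, cls$proportion)[dat$pat_index, , drop = FALSE]
  pp <- rowSums(post[, 3:4, drop = FALSE])
  structure(list(classes = cls, lnL_alt = lnL_alt, lnL_null = lnL_null,
                 lrt = lrt, posterior = post, posterior_positive = pp,
                 sites_0.95 = which(pp > 0.95),
                 kappa = kappa, scale = scale,
                 params = list(p0 = pr[1], p1 = pr[2], omega0 = omega0,
                               omega2 = omega2),
                 foreground = foreground),
            class = "branch_site_fit")
}

#' @export
print.branch_site_fit <- function(x, ...) {
  cat("Branch-site model A\n")
  cat(sprintf("  lnL (alt) = %.4f   lnL (null, omega2 = 1) = %.4f\n",
              x$lnL_alt, x$lnL_null))
  print(x$lrt)
  tab <- cbind(proportion = x$classes$proportion,
               background = x$classes$omega_bg,
               foreground = x$classes$omega_fg)
  rownames(tab) <- rownames(x$classes)
  print(round(tab, 5))
  if (length(x$sites_0.95))
    cat("  positively selected sites (posterior > 0.95):",
        paste(x$sites_0.95, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.branch_site_fit <- function(object, ...) {
  structure(object$lnL_alt, df = 4L, class = "logLik")
}

#' @export
coef.branch_site_fit <- function(object, ...) {
  unlist(object$params)
}

#' @export
summary.site_model_fit <- function(object, ...) {
  print(object)
  cat("  site classes:\n")
  tab <- object$classes
  tab$proportion <- round(tab$proportion, 5)
  tab$omega_bg <- round(tab$omega_bg, 5)
  print(tab[, c("proportion", "omega_bg")])
  if (any(object$classes$omega_bg > 1)) {
    pos <- site_posteriors(object, "NEB")
    cat("  sites with P(omega > 1 class) > 0.95:",
        if (length(pos$sites_0.95)) paste(pos$sites_0.95, collapse = ", ")
        else "none", "\n")
  }
  invisible(object)
}

#' @export
summary.branch_site_fit <- function(object, ...) {
  print(object)
  invisible(object)
}
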