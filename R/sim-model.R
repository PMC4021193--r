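## Specification objects for codon-model simulation. A sim_model_spec
## normalizes every supported model (M0, M3, M7, M8, branch-site model A)
## into a common site-class table: per class a proportion, a background
## omega and a foreground omega (identical except under the branch-site
## model). The same normalization is used by the likelihood engine, so the
## simulator is the exact inverse of the inference model.

#' Define a codon-model simulation specification
#'
#' @param model One of `"M0"`, `"M3"`, `"M7"`, `"M8"`, `"branch_site_A"`.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Single omega (M0), or vector of class omegas (M3).
#' @param proportions Class proportions (M3; must sum to 1).
#' @param beta_params Length-2 vector `c(p, q)` for M7/M8.
#' @param p0 Proportion of the beta component under M8, or of the purifying
#'   class under the branch-site model.
#' @param p1 Proportion of the neutral class (branch-site model).
#' @param omega_s Omega of the selected class (M8, >= 1 conventionally;
#'   branch-site foreground omega2).
#' @param omega0 Purifying-class omega for the branch-site model (0 < omega0 < 1).
#' @param n_beta_classes Discretization size for the beta models.
#' @param foreground_branches Integer vector of edge indices (rows of the
#'   tree's edge matrix) treated as foreground (branch-site model only).
#' @param codon_freqs Stationary codon frequencies (61-vector, sums to 1).
#' @param seed Integer seed fully determining all simulator draws.
#' @return An object of class `sim_model_spec` with a normalized
#'   `classes` data frame (`proportion`, `omega_bg`, `omega_fg`).
#' @export
sim_model_spec <- function(model = c("M0", "M3", "M7", "M8", "branch_site_A"),
                           kappa = 2,
                           omega = NULL, proportions = NULL,
                           beta_params = NULL, p0 = NULL, p1 = NULL,
                           omega_s = NULL, omega0 = NULL,
                           n_beta_classes = 10,
                           foreground_branches = integer(0),
                           codon_freqs = equal_codon_freqs(),
                           seed = 1L) {
  model <- match.arg(model)
  stopifnot(kappa > 0)
  .check_codon_freqs(codon_freqs)
  classes <- switch(model,
    M0 = {
      if (is.null(omega)) stop("M0 requires `omega`")
      data.frame(proportion = 1, omega_bg = omega, omega_fg = omega)
    },
    M3 = {
      if (is.null(omega) || is.null(proportions))
        stop("M3 requires `omega` and `proportions` vectors")
      if (length(omega) != length(proportions))
        stop("omega and proportions must have equal length")
      data.frame(proportion = proportions, omega_bg = omega, omega_fg = omega)
    },
    M7 = {
      if (is.null(beta_params)) stop("M7 requires `beta_params`")
      w <- beta_omega_classes(beta_params[1], beta_params[2], n_beta_classes)
      data.frame(proportion = rep(1 / n_beta_classes, n_beta_classes),
                 omega_bg = w, omega_fg = w)
    },
    M8 = {
      if (is.null(beta_params) || is.null(p0) || is.null(omega_s))
        stop("M8 requires `beta_params`, `p0` and `omega_s`")
      stopifnot(p0 >= 0, p0 <= 1)
      w <- beta_omega_classes(beta_params[1], beta_params[2], n_beta_classes)
      data.frame(proportion = c(rep(p0 / n_beta_classes, n_beta_classes), 1 - p0),
                 omega_bg = c(w, omega_s), omega_fg = c(w, omega_s))
    },
    branch_site_A = {
      if (is.null(p0) || is.null(p1) || is.null(omega0) || is.null(omega_s))
        stop("branch_site_A requires `p0`, `p1`, `omega0` and `omega_s`")
      stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1, omega_s >= 1)
      p2 <- 1 - p0 - p1
      # classes 0, 1, 2a, 2b; 2a:2b in proportion p0:p1
      data.frame(
        proportion = c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1)),
        omega_bg = c(omega0, 1, omega0, 1),
        omega_fg = c(omega0, 1, omega_s, omega_s),
        row.names = c("0", "1", "2a", "2b"))
    })
  if (any(classes$omega_bg < 0) || any(classes$omega_fg < 0))
    stop("all omega values must be nonnegative")
  if (abs(sum(classes$proportion) - 1) > 1e-12)
    stop("class proportions must sum to 1 (within 1e-12)")
  structure(list(model = model, kappa = kappa, classes = classes,
                 beta_params = beta_params,
                 foreground_branches = as.integer(foreground_branches),
                 codon_freqs = codon_freqs, seed = as.integer(seed)),
            class = "sim_model_spec")
}

#' @export
print.sim_model_spec <- function(x, ...) {
  cat("Codon simulation model:", x$model, "\n")
  cat("  kappa =", x$kappa, "\n")
  cat("  site classes:\n")
  print(round(x$classes, 5))
  if (length(x$foreground_branches))
    cat("  foreground edges:", paste(x$foreground_branches, collapse = ", "), "\n")
  cat("  seed =", x$seed, "\n")
  invisible(x)
}

#' Simulate a codon alignment under a site or branch-site model
#'
#' Evolves codon sites down a tree under the GY94 model with the site-class
#' structure given by `spec`. Each site draws its class once at the root and
#' keeps it along the whole tree; on foreground edges (branch-site model)
#' the class's foreground omega applies. All class rate matrices share a
#' single scale factor chosen so the proportion-weighted mean background
#' substitution rate is 1, i.e. branch lengths are expected substitutions
#' per codon averaged over site classes.
#'
#' Draw order (fully determined by `spec$seed`): site classes first, then
#' root codons (unless `root_seq` is supplied), then child states edge by
#' edge in the tree's cladewise edge order.
#'
#' @param tree An `ape::phylo` tree with nonnegative branch lengths in
#'   expected substitutions per codon.
#' @param spec A [sim_model_spec()].
#' @param n_codons Number of codon sites (>= 1).
#' @param root_seq Optional root CDS (character string of length
#'   `3 * n_codons`, no stop codons); by default the root is drawn from the
#'   stationary codon frequencies.
#' @return A list with `alignment` (named character vector of CDS, one per
#'   leaf), `site_classes` (integer class index per site) and `spec`.
#' @export
simulate_codon_alignment <- function(tree, spec, n_codons, root_seq = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(spec, "sim_model_spec"))
  if (n_codons < 1) stop("n_codons must be >= 1")
  if (length(tree$tip.label) < 2) stop("tree must have >= 2 leaves")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have nonnegative branch lengths")

  pi <- spec$codon_freqs
  cls <- spec$classes
  # common scale: proportion-weighted mean background rate
  mu <- sum(cls$proportion *
              vapply(cls$omega_bg, function(w) .mean_rate(spec$kappa, w, pi),
                     numeric(1)))
  eig_cache <- new.env(parent = emptyenv())
  get_eig <- function(omega) {
    key <- format(omega, digits = 17)
    if (is.null(eig_cache[[key]])) {
      Q <- codon_rate_matrix(spec$kappa, omega, pi, scale = FALSE) / mu
      eig_cache[[key]] <- codon_eigen(Q, pi)
    }
    eig_cache[[key]]
  }

  restore_rng <- .rng_snapshot()
  on.exit(restore_rng(), add = TRUE)
  set.seed(spec$seed)
  n_class <- nrow(cls)
  site_class <- sample.int(n_class, n_codons, replace = TRUE,
                           prob = cls$proportion)
  if (is.null(root_seq)) {
    root_state <- sample.int(N_SENSE, n_codons, replace = TRUE, prob = pi)
  } else {
    cods <- split_codons(root_seq)
    if (length(cods) != n_codons)
      stop("root_seq must contain exactly n_codons codons")
    if (any(cods %in% STOP_CODONS))
      stop("stop codon in supplied root sequence")
    root_state <- codon_index(cods)
    if (anyNA(root_state)) stop("root_seq contains invalid codons")
  }

  fg <- spec$foreground_branches
  if (length(fg) && any(fg < 1 | fg > nrow(tree$edge)))
    stop("foreground_branches must index rows of tree$edge")
  fg_children <- tree$edge[fg, 2] # stable under edge reordering
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_node <- max(tree$edge)
  states <- matrix(NA_integer_, nrow = n_node, ncol = n_codons)
  root <- tree$edge[1, 1]
  states[root, ] <- root_state

  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    t_e <- tree$edge.length[e]
    omega_col <- if (child %in% fg_children) cls$omega_fg else cls$omega_bg
    child_state <- states[parent, ]
    if (t_e > 0) {
      for (k in seq_len(n_class)) {
        sites_k <- which(site_class == k)
        if (!length(sites_k)) next
        P <- codon_probs(get_eig(omega_col[k]), t_e)
        par_k <- states[parent, sites_k]
        # sample each site's child codon from its parent row of P
        child_state[sites_k] <- vapply(par_k, function(s)
          sample.int(N_SENSE, 1L, prob = P[s, ]), integer(1))
      }
    }
    states[child, ] <- child_state
  }

  leaves <- seq_along(tree$tip.label)
  aln <- vapply(leaves, function(i)
    paste0(SENSE_CODONS[states[i, ]], collapse = ""), character(1))
  names(aln) <- tree$tip.label
  list(alignment = aln, site_classes = site_class, spec = spec)
}
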