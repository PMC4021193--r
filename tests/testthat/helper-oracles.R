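# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route (brute force, enumeration, closed form)
# than the package code.

# matrix exponential transition probabilities via Matrix::expm (Higham's
# algorithm), independent of the package's symmetric eigendecomposition
oracle_probs <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# brute-force codon log-likelihood: sum over all internal-node codon
# assignments, transition probabilities from oracle_probs
oracle_codon_loglik <- function(aln, tree, kappa, omega, pi) {
  Q <- codon_rate_matrix(kappa, omega, pi)
  P <- lapply(tree$edge.length, function(t) oracle_probs(Q, t))
  states <- famevol:::codon_matrix(aln)
  states <- states[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[tree$edge[, 1] > ntip, 1]))
  root <- tree$edge[1, 1]
  n_sites <- ncol(states)
  ll <- 0
  combos <- as.matrix(expand.grid(rep(list(1:61), length(internal))))
  for (s in seq_len(n_sites)) {
    tot <- 0
    for (r in seq_len(nrow(combos))) {
      assign_state <- function(node) {
        if (node <= ntip) states[node, s]
        else combos[r, match(node, internal)]
      }
      pr <- pi[assign_state(root)]
      for (e in seq_len(nrow(tree$edge)))
        pr <- pr * P[[e]][assign_state(tree$edge[e, 1]),
                          assign_state(tree$edge[e, 2])]
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  unname(ll)
}

# independent NG86: recomputes synonymous site fractions and pathway
# averages directly from Biostrings::GENETIC_CODE
oracle_ng86 <- function(seq1, seq2) {
  gc <- Biostrings::GENETIC_CODE
  nucs <- c("T", "C", "A", "G")
  aa <- function(codon) unname(gc[codon])
  syn_frac <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    syn <- 0
    for (p in 1:3) for (nt in setdiff(nucs, ch[p])) {
      mut <- ch; mut[p] <- nt
      if (aa(paste0(mut, collapse = "")) == aa(codon)) syn <- syn + 1
    }
    syn / 3
  }
  all_orders <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_orders(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  path_counts <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    pos <- which(ca != cb)
    if (!length(pos)) return(c(0, 0))
    paths <- list()
    for (ord in all_orders(pos)) {
      cur <- ca; sdc <- 0; ndc <- 0; bad <- FALSE
      for (p in ord) {
        before <- aa(paste0(cur, collapse = ""))
        cur[p] <- cb[p]
        after <- aa(paste0(cur, collapse = ""))
        if (after == "*") { bad <- TRUE; break }
        if (after == before) sdc <- sdc + 1 else ndc <- ndc + 1
      }
      if (!bad) paths <- c(paths, list(c(sdc, ndc)))
    }
    if (!length(paths)) return(c(0, length(pos)))
    colMeans(do.call(rbind, paths))
  }
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- split3(toupper(seq1)); c2 <- split3(toupper(seq2))
  keep <- !grepl("-", c1) & !grepl("-", c2)
  c1 <- c1[keep]; c2 <- c2[keep]
  S <- (sum(vapply(c1, syn_frac, 1)) + sum(vapply(c2, syn_frac, 1))) / 2
  N <- 3 * length(c1) - S
  sd_tot <- 0; nd_tot <- 0
  for (k in seq_along(c1)) {
    pc <- path_counts(c1[k], c2[k])
    sd_tot <- sd_tot + pc[1]; nd_tot <- nd_tot + pc[2]
  }
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  list(ka = jc(nd_tot / N), ks = jc(sd_tot / S), S = S, N = N,
       Sd = sd_tot, Nd = nd_tot)
}

# exhaustive Fitch: minimum changes for one site over all internal-node
# state assignments drawn from the observed states
oracle_fitch_site <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[tree$edge[, 1] > ntip, 1]))
  obs <- unique(tip_states)
  combos <- as.matrix(expand.grid(rep(list(obs), length(internal))))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    st <- function(node) if (node <= ntip) tip_states[node]
                         else combos[r, match(node, internal)]
    changes <- sum(vapply(seq_len(nrow(tree$edge)), function(e)
      st(tree$edge[e, 1]) != st(tree$edge[e, 2]), logical(1)))
    best <- min(best, changes)
  }
  best
}

# brute-force average-linkage agglomeration; returns merge heights in order
oracle_average_linkage <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# fine-grid scan for the zero crossing of the protein net charge
oracle_pi_grid <- function(protein, step = 5e-4) {
  aa <- strsplit(toupper(protein), "")[[1]]
  side <- famevol:::PKA_SIDECHAIN
  nterm <- famevol:::PKA_NTERM
  cterm <- famevol:::PKA_CTERM
  nt <- if (aa[1] %in% names(nterm)) nterm[[aa[1]]] else famevol:::PKA_NTERM_DEFAULT
  last <- aa[length(aa)]
  ct <- if (last %in% names(cterm)) cterm[[last]] else famevol:::PKA_CTERM_DEFAULT
  counts <- table(factor(aa, levels = names(famevol:::AA_MASS)))
  pH <- seq(0, 14, by = step)
  charge <- 1 / (1 + 10^(pH - nt)) - 1 / (1 + 10^(ct - pH))
  for (r in c("K", "R", "H"))
    charge <- charge + counts[[r]] / (1 + 10^(pH - side[[r]]))
  for (r in c("D", "E", "C", "Y"))
    charge <- charge - counts[[r]] / (1 + 10^(side[[r]] - pH))
  i <- which(diff(sign(charge)) != 0)[1]
  (pH[i] + pH[i + 1]) / 2
}

# closed-form chi-square upper tail for even degrees of freedom:
# S(x) = exp(-x/2) * sum_{k<df/2} (x/2)^k / k!
oracle_chisq_tail_even_df <- function(x, df) {
  stopifnot(df %% 2 == 0)
  k <- 0:(df / 2 - 1)
  exp(-x / 2) * sum((x / 2)^k / factorial(k))
}

# shared small fixtures -----------------------------------------------------

balanced6 <- function(bl = 0.3) {
  tr <- ape::read.tree(
    text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr
}

edge_to_tip <- function(tree, tip) which(tree$edge[, 2] == match(tip, tree$tip.label))
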