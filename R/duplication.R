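## Duplication analysis: tandem clusters by the ordinal-rank adjacency rule,
## pairwise Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, the
## transversion rate at fourfold-degenerate sites (4DTv), and Ks-based
## dating of segmental events via T = Ks / (2 * lambda).

#' Detect tandem duplication clusters
#'
#' Family genes on one chromosome form a tandem cluster when consecutive
#' members are separated by at most `max_intervening` non-family genes
#' (i.e. their ordinal ranks differ by at most `max_intervening + 1`).
#' Maximal chains are reported; singletons are discarded; clusters never
#' span chromosomes.
#'
#' @param locus_table Data frame with `gene_id`, `chromosome`, `rank`
#'   (ordinal gene rank, unique per chromosome).
#' @param family_ids Gene ids of the family members.
#' @param max_intervening Maximum intervening non-family genes (default 1).
#' @return List of clusters, each a list with `chromosome`, `gene_ids`,
#'   `ranks`, `max_intervening`.
#' @export
detect_tandem_clusters <- function(locus_table, family_ids, max_intervening = 1) {
  missing <- setdiff(family_ids, locus_table$gene_id)
  if (length(missing))
    stop("family id(s) absent from locus table: ",
         paste(missing, collapse = ", "))
  fam <- locus_table[locus_table$gene_id %in% family_ids, , drop = FALSE]
  clusters <- list()
  for (chr in unique(fam$chromosome)) {
    sub <- fam[fam$chromosome == chr, , drop = FALSE]
    if (anyDuplicated(locus_table$rank[locus_table$chromosome == chr]))
      stop("ordinal ranks are not unique on chromosome ", chr)
    sub <- sub[order(sub$rank), , drop = FALSE]
    if (nrow(sub) < 2) next
    gap <- diff(sub$rank)
    breaks <- which(gap > max_intervening + 1L)
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, nrow(sub))
    for (k in seq_along(starts)) {
      idx <- starts[k]:ends[k]
      if (length(idx) < 2) next
      clusters[[length(clusters) + 1L]] <-
        list(chromosome = chr, gene_ids = sub$gene_id[idx],
             ranks = sub$rank[idx], max_intervening = max_intervening)
    }
  }
  clusters
}

## --- NG86 machinery -------------------------------------------------------

## Fraction of the nine single-nucleotide changes of a codon that are
## synonymous; changes producing stop codons count as nonsynonymous.
.NG_SYN_SITES <- local({
  s <- numeric(N_SENSE)
  for (i in seq_len(N_SENSE)) {
    cod <- strsplit(SENSE_CODONS[i], "")[[1]]
    syn <- 0
    for (p in 1:3) {
      for (nt in setdiff(NUC, cod[p])) {
        mut <- cod; mut[p] <- nt
        mut <- paste0(mut, collapse = "")
        if (CODON_AA[[mut]] == SENSE_AA[i]) syn <- syn + 1
      }
    }
    s[i] <- syn / 3
  }
  names(s) <- SENSE_CODONS
  s
})

## Enumerate minimal substitution pathways between two codons; average the
## synonymous / nonsynonymous step counts over pathways that avoid stop
## codons (all pathways used if every one passes through a stop).
.ng86_path_counts <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- .permutations(pos)
  res <- matrix(NA_real_, nrow = nrow(perms), ncol = 2)
  for (r in seq_len(nrow(perms))) {
    cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in perms[r, ]) {
      prev_aa <- CODON_AA[[paste0(cur, collapse = "")]]
      cur[p] <- b[p]
      nxt <- paste0(cur, collapse = "")
      nxt_aa <- CODON_AA[[nxt]]
      if (nxt_aa == "*") { blocked <- TRUE; break }
      if (nxt_aa == prev_aa) sd <- sd + 1 else nd <- nd + 1
    }
    if (!blocked) res[r, ] <- c(sd, nd)
  }
  ok <- !is.na(res[, 1])
  if (!any(ok)) {
    # all pathways pass through a stop codon: count every step nonsynonymous
    return(c(sd = 0, nd = length(pos)))
  }
  c(sd = mean(res[ok, 1]), nd = mean(res[ok, 2]))
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, 1))
  out <- NULL
  for (i in seq_len(n))
    out <- rbind(out, cbind(x[i], .permutations(x[-i])))
  out
}

#' Nei-Gojobori (1986) Ka/Ks for a pair of coding sequences
#'
#' Counts synonymous and nonsynonymous sites by codon degeneracy (mutations
#' to stop codons counted as nonsynonymous), averages substitution counts
#' for multi-hit codons over equal-weight minimal pathways (pathways
#' through stop codons discarded), and applies the Jukes-Cantor correction
#' `d = -3/4 log(1 - 4p/3)` to both proportions. Codons containing a gap in
#' either sequence are dropped.
#'
#' @param seq1,seq2 Aligned CDS strings of equal length (gaps `-` allowed).
#' @return A `kaks_result` list: `ka`, `ks`, `omega` (NA when Ks = 0),
#'   `N`, `S`, `Nd`, `Sd`, `n_codons`.
#' @export
compute_ng86 <- function(seq1, seq2) {
  c1 <- split_codons(seq1); c2 <- split_codons(seq2)
  if (length(c1) != length(c2)) stop("sequences must have equal codon counts")
  keep <- !grepl("-", c1, fixed = TRUE) & !grepl("-", c2, fixed = TRUE)
  c1 <- toupper(c1[keep]); c2 <- toupper(c2[keep])
  if (!length(c1)) stop("zero comparable codons")
  if (any(c1 %in% STOP_CODONS) || any(c2 %in% STOP_CODONS))
    stop("stop codon in coding sequence")
  i1 <- codon_index(c1); i2 <- codon_index(c2)
  if (anyNA(i1) || anyNA(i2)) stop("invalid codon in coding sequence")

  S <- (sum(.NG_SYN_SITES[i1]) + sum(.NG_SYN_SITES[i2])) / 2
  L <- 3 * length(c1)
  N <- L - S
  sd <- 0; nd <- 0
  for (k in seq_along(c1)) {
    if (c1[k] == c2[k]) next
    cnt <- .ng86_path_counts(c1[k], c2[k])
    sd <- sd + cnt[["sd"]]; nd <- nd + cnt[["nd"]]
  }
  ps <- if (S > 0) sd / S else 0
  pn <- if (N > 0) nd / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) stop("proportion >= 3/4: Jukes-Cantor correction undefined")
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ks <- jc(ps); ka <- jc(pn)
  structure(list(ka = ka, ks = ks,
                 omega = if (ks > 0) ka / ks else NA_real_,
                 N = N, S = S, Nd = nd, Sd = sd, n_codons = length(c1)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: Ka = %.4f  Ks = %.4f  Ka/Ks = %s  (%d codons)\n",
              x$ka, x$ks,
              if (is.na(x$omega)) "NA" else sprintf("%.4f", x$omega),
              x$n_codons))
  cat(sprintf("  sites N = %.2f, S = %.2f; differences Nd = %.2f, Sd = %.2f\n",
              x$N, x$S, x$Nd, x$Sd))
  invisible(x)
}

#' Transversion rate at fourfold-degenerate sites (4DTv)
#'
#' A codon site qualifies when both codons are fourfold degenerate at the
#' third position and identical at positions 1-2; the statistic is the
#' (uncorrected) proportion of qualifying sites whose third positions
#' differ by a transversion.
#'
#' @param seq1,seq2 Aligned CDS strings of equal length (gaps allowed).
#' @return List with `value`, `n_4d_sites`, `n_transversions`.
#' @export
compute_4dtv <- function(seq1, seq2) {
  c1 <- split_codons(seq1); c2 <- split_codons(seq2)
  if (length(c1) != length(c2)) stop("sequences must have equal codon counts")
  keep <- !grepl("-", c1, fixed = TRUE) & !grepl("-", c2, fixed = TRUE)
  c1 <- toupper(c1[keep]); c2 <- toupper(c2[keep])
  qual <- c1 %in% FOURFOLD_CODONS & c2 %in% FOURFOLD_CODONS &
    substr(c1, 1, 2) == substr(c2, 1, 2)
  n4 <- sum(qual)
  if (n4 == 0) stop("no fourfold-degenerate sites shared by the pair")
  t1 <- match(substr(c1[qual], 3, 3), NUC)
  t2 <- match(substr(c2[qual], 3, 3), NUC)
  tv <- sum(t1 != t2 & !is_transition(t1, t2))
  list(value = tv / n4, n_4d_sites = n4, n_transversions = tv)
}

#' Date a segmental duplication event from anchor Ks values
#'
#' Anchor Ks values are filtered to the open window `ks_window`; events
#' with fewer than `min_anchors` surviving anchors are rejected. The age is
#' `T = mean(Ks) / (2 * lambda)` years, reported in million years rounded
#' to the nearest integer.
#'
#' @param pair Length-2 character vector naming the duplicated gene pair.
#' @param anchor_ks Numeric vector of per-anchor Ks values.
#' @param lambda Synonymous substitution rate per site per year
#'   (default 6.1e-9, Fabaceae).
#' @param ks_window Open filtering interval (default (0, 1)).
#' @param min_anchors Minimum surviving anchors (default 3).
#' @return A `segmental_event` list: `pair`, `raw_ks`, `ks` (filtered),
#'   `n_anchors`, `mean_ks`, `sd_ks` (sample s.d.), `t_years`, `t_my`
#'   (rounded), `rejected`, `reason`.
#' @export
date_segmental_event <- function(pair, anchor_ks, lambda = 6.1e-9,
                                 ks_window = c(0, 1), min_anchors = 3) {
  if (!length(anchor_ks)) stop("anchor list is empty")
  keep <- anchor_ks > ks_window[1] & anchor_ks < ks_window[2]
  ks <- anchor_ks[keep]
  if (length(ks) < min_anchors) {
    return(structure(list(pair = pair, raw_ks = anchor_ks, ks = ks,
                          n_anchors = length(ks), mean_ks = NA_real_,
                          sd_ks = NA_real_, t_years = NA_real_,
                          t_my = NA_integer_, rejected = TRUE,
                          reason = sprintf("fewer than %d anchors in (%g, %g)",
                                           min_anchors, ks_window[1],
                                           ks_window[2])),
                     class = "segmental_event"))
  }
  m <- mean(ks)
  t_years <- m / (2 * lambda)
  structure(list(pair = pair, raw_ks = anchor_ks, ks = ks,
                 n_anchors = length(ks), mean_ks = m,
                 sd_ks = stats::sd(ks), t_years = t_years,
                 t_my = as.integer(round(t_years / 1e6)),
                 rejected = FALSE, reason = NA_character_),
            class = "segmental_event")
}

#' @export
print.segmental_event <- function(x, ...) {
  if (x$rejected) {
    cat("Segmental event", paste(x$pair, collapse = " & "),
        "- rejected:", x$reason, "\n")
  } else {
    cat(sprintf("Segmental event %s: %d anchors, Ks = %.3f +/- %.3f, ~%d My\n",
                paste(x$pair, collapse = " & "), x$n_anchors,
                x$mean_ks, x$sd_ks, x$t_my))
  }
  invisible(x)
}

#' Duplication-class report for a gene family
#'
#' @param member_ids All family gene ids.
#' @param clusters Tandem clusters from [detect_tandem_clusters()].
#' @param events Segmental events (list of `segmental_event` or of lists
#'   with a `pair` element); rejected events are ignored.
#' @return List with `n_members`, `n_tandem`, `pct_tandem`, `n_segmental`,
#'   `pct_segmental` (percentages of the family size to one decimal).
#' @export
duplication_report <- function(member_ids, clusters = list(), events = list()) {
  tandem_genes <- unique(unlist(lapply(clusters, `[[`, "gene_ids")))
  seg_genes <- unique(unlist(lapply(events, function(e) {
    if (isTRUE(e$rejected)) NULL else e$pair
  })))
  tandem_genes <- intersect(tandem_genes, member_ids)
  seg_genes <- intersect(seg_genes, member_ids)
  n <- length(member_ids)
  pct <- function(k) if (n == 0) 0 else round(100 * k / n, 1)
  list(n_members = n,
       n_tandem = length(tandem_genes), pct_tandem = pct(length(tandem_genes)),
       n_segmental = length(seg_genes), pct_segmental = pct(length(seg_genes)))
}

#' Reconstruct an anchor-Ks set from published summary statistics
#'
#' Builds a deterministic set of `n` anchor Ks values inside the open
#' interval (0, 1) whose sample mean and sample standard deviation equal
#' the published summary exactly, using a two-point design (`k` anchors at
#' a high value, `n - k` at a low value, with `k` chosen to keep both
#' values as central as possible). Useful for re-dating events from
#' published per-pair summaries when the raw anchor lists are not
#' distributed.
#'
#' @param n Number of anchors (>= 1).
#' @param mean_ks Published mean Ks, in (0, 1).
#' @param sd_ks Published sample standard deviation (>= 0).
#' @return Numeric vector of `n` Ks values in (0, 1).
#' @export
anchors_from_summary <- function(n, mean_ks, sd_ks) {
  stopifnot(n >= 1, mean_ks > 0, mean_ks < 1, sd_ks >= 0)
  if (n == 1 || sd_ks == 0) return(rep(mean_ks, n))
  s_pop <- sd_ks * sqrt((n - 1) / n)
  best <- NULL
  for (k in seq_len(n - 1)) {
    h <- mean_ks + s_pop * sqrt((n - k) / k)
    l <- mean_ks - s_pop * sqrt(k / (n - k))
    if (h < 1 && l > 0) {
      margin <- min(l, 1 - h)
      if (is.null(best) || margin > best$margin)
        best <- list(k = k, h = h, l = l, margin = margin)
    }
  }
  if (is.null(best))
    stop("no anchor set in (0, 1) can reproduce mean ", mean_ks,
         " and sd ", sd_ks, " with n = ", n)
  c(rep(best$h, best$k), rep(best$l, n - best$k))
}
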