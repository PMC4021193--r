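## Seeded fixture generators for the non-sequence stages of the pipeline:
## genome layouts with planted tandem clusters and segmental anchor pairs,
## expression matrices with planted specificity classes, and promoter sets
## with planted motif copies. Each generator plants structure that the
## corresponding detector must recover exactly on noiseless input.

#' Generate a genome layout with planted duplication structure
#'
#' Genes are laid out on `n_chromosomes` chromosomes with unique ordinal
#' ranks. Tandem clusters are planted as runs of family genes occupying
#' consecutive ranks, optionally with a single intervening non-family gene
#' (the "<= 1 intervening gene" adjacency rule holds by construction).
#' Isolated family genes are placed at least `min_separation` ranks away
#' from any other family gene so that planted clusters are exactly the
#' maximal chains a detector should find. Segmental pairs are assigned
#' anchor Ks values drawn i.i.d. from `ks_rfun`.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param n_genes Total number of genes across all chromosomes.
#' @param tandem_sizes Integer vector of planted tandem cluster sizes
#'   (each >= 2).
#' @param n_singleton_family Number of isolated (non-tandem) family genes.
#' @param n_segmental_pairs Number of planted segmental pairs (drawn from
#'   the family genes).
#' @param anchors_per_pair Anchor count per segmental pair; recycled.
#' @param ks_rfun Function `(n)` returning `n` anchor Ks draws.
#' @param truncate_ks Truncate (redraw) anchor Ks into the open interval
#'   (0, 1)?
#' @param gap_prob Probability that a planted cluster carries one
#'   intervening non-family gene.
#' @param min_separation Minimum rank distance between family genes that do
#'   not share a cluster.
#' @param seed Integer seed.
#' @return A list of class `genome_fixture`: `locus_table` (data frame with
#'   `gene_id`, `chromosome`, `rank`, `start`, `end`, `strand`,
#'   `is_family`), `planted_tandem` (list of gene-id vectors),
#'   `planted_segmental` (list of `gene_a`, `gene_b`, `anchor_ks`).
#' @export
generate_genome_fixture <- function(n_chromosomes = 4,
                                    n_genes = 200,
                                    tandem_sizes = c(3, 2),
                                    n_singleton_family = 6,
                                    n_segmental_pairs = 3,
                                    anchors_per_pair = 6,
                                    ks_rfun = function(n) stats::rlnorm(n, log(0.3), 0.5),
                                    truncate_ks = TRUE,
                                    gap_prob = 0.5,
                                    min_separation = 3,
                                    seed = 1L) {
  if (any(tandem_sizes < 2)) stop("tandem cluster sizes must be >= 2")
  restore_rng <- .rng_snapshot()
  on.exit(restore_rng(), add = TRUE)
  set.seed(as.integer(seed))
  # chromosome sizes: roughly even split
  sizes <- rep(n_genes %/% n_chromosomes, n_chromosomes)
  rem <- n_genes - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L

  # footprint of each cluster (members + optional one gap)
  gaps <- stats::runif(length(tandem_sizes)) < gap_prob
  footprints <- tandem_sizes + as.integer(gaps)
  n_family_needed <- sum(tandem_sizes) + n_singleton_family
  if (n_family_needed > n_genes)
    stop("more planted family genes (", n_family_needed,
         ") than n_genes (", n_genes, ")")

  # assign clusters to chromosomes round-robin where they fit
  chrom_of_cluster <- integer(length(tandem_sizes))
  next_chr <- 1L
  for (i in seq_along(tandem_sizes)) {
    tries <- 0L
    while (sizes[next_chr] < footprints[i] + 2L * min_separation) {
      next_chr <- next_chr %% n_chromosomes + 1L
      tries <- tries + 1L
      if (tries > n_chromosomes) stop("chromosomes too small for clusters")
    }
    chrom_of_cluster[i] <- next_chr
    next_chr <- next_chr %% n_chromosomes + 1L
  }

  locus <- data.frame()
  planted <- vector("list", length(tandem_sizes))
  gene_counter <- 0L
  new_ids <- function(n) sprintf("g%04d", gene_counter + seq_len(n))

  family_flags_all <- list()
  for (chr in seq_len(n_chromosomes)) {
    n_chr <- sizes[chr]
    fam <- rep(FALSE, n_chr)
    blocked <- rep(FALSE, n_chr) # ranks unavailable for further family genes
    # place clusters assigned to this chromosome
    for (i in which(chrom_of_cluster == chr)) {
      fp <- footprints[i]
      ok_start <- which(!blocked[seq_len(n_chr - fp + 1L)])
      ok_start <- ok_start[vapply(ok_start, function(s)
        !any(blocked[s:(s + fp - 1L)]), logical(1))]
      if (!length(ok_start)) stop("no room to place cluster on chromosome ", chr)
      s <- ok_start[sample.int(length(ok_start), 1L)]
      member_ranks <- s:(s + fp - 1L)
      if (gaps[i]) {
        # one intervening non-family gene at an interior position
        gap_at <- s + sample.int(fp - 2L, 1L)
        member_ranks <- setdiff(member_ranks, gap_at)
      }
      fam[member_ranks] <- TRUE
      lo <- max(1L, s - min_separation)
      hi <- min(n_chr, s + fp - 1L + min_separation)
      blocked[lo:hi] <- TRUE
      planted[[i]] <- list(chromosome = chr, ranks = member_ranks)
    }
    family_flags_all[[chr]] <- list(fam = fam, blocked = blocked)
  }

  # scatter singleton family genes respecting separation
  singles_left <- n_singleton_family
  guard <- 0L
  while (singles_left > 0L) {
    guard <- guard + 1L
    if (guard > 10000L) stop("cannot place singleton family genes")
    chr <- sample.int(n_chromosomes, 1L)
    st <- family_flags_all[[chr]]
    free <- which(!st$blocked)
    if (!length(free)) next
    r <- free[sample.int(length(free), 1L)]
    st$fam[r] <- TRUE
    lo <- max(1L, r - min_separation)
    hi <- min(sizes[chr], r + min_separation)
    st$blocked[lo:hi] <- TRUE
    family_flags_all[[chr]] <- st
    singles_left <- singles_left - 1L
  }

  # build the locus table
  for (chr in seq_len(n_chromosomes)) {
    n_chr <- sizes[chr]
    ids <- new_ids(n_chr)
    gene_counter <- gene_counter + n_chr
    width <- sample(500:4000, n_chr, replace = TRUE)
    gap_bp <- sample(200:2000, n_chr, replace = TRUE)
    start <- cumsum(gap_bp) + c(0, cumsum(width))[seq_len(n_chr)]
    locus <- rbind(locus, data.frame(
      gene_id = ids, chromosome = chr, rank = seq_len(n_chr),
      start = start, end = start + width - 1L,
      strand = sample(c("+", "-"), n_chr, replace = TRUE),
      is_family = family_flags_all[[chr]]$fam,
      stringsAsFactors = FALSE))
  }

  id_at <- function(chr, ranks)
    locus$gene_id[locus$chromosome == chr][ranks]
  planted_tandem <- lapply(planted, function(p) id_at(p$chromosome, p$ranks))

  fam_ids <- locus$gene_id[locus$is_family]
  planted_segmental <- list()
  if (n_segmental_pairs > 0) {
    if (2L * n_segmental_pairs > length(fam_ids))
      stop("not enough family genes for the requested segmental pairs")
    chosen <- sample(fam_ids, 2L * n_segmental_pairs)
    k <- rep_len(anchors_per_pair, n_segmental_pairs)
    for (i in seq_len(n_segmental_pairs)) {
      ks <- ks_rfun(k[i])
      if (truncate_ks && k[i] > 0) {
        guard <- 0L
        while (any(ks <= 0 | ks >= 1)) {
          bad <- ks <= 0 | ks >= 1
          ks[bad] <- ks_rfun(sum(bad))
          guard <- guard + 1L
          if (guard > 1000L) stop("ks_rfun cannot produce values in (0, 1)")
        }
      }
      planted_segmental[[i]] <- list(gene_a = chosen[2L * i - 1L],
                                     gene_b = chosen[2L * i],
                                     anchor_ks = ks)
    }
  }

  structure(list(locus_table = locus,
                 planted_tandem = planted_tandem,
                 planted_segmental = planted_segmental,
                 seed = as.integer(seed)),
            class = "genome_fixture")
}

#' Generate an expression matrix with planted specificity classes
#'
#' @param n_genes Number of genes; gene `i` takes class
#'   `class_assignments[i]` (recycled).
#' @param tissues Character vector of tissue names.
#' @param class_assignments Classes from `constitutive`,
#'   `single_tissue_exclusive`, `single_tissue_peak`, `silent`.
#' @param seed Integer seed.
#' @return List with `matrix` (genes x tissues, RPKM-like nonnegative
#'   values), `classes` and `peak_tissue` (NA where not applicable).
#' @export
generate_expression_fixture <- function(n_genes,
                                        tissues,
                                        class_assignments = "constitutive",
                                        seed = 1L) {
  if (!length(tissues)) stop("tissues must be nonempty")
  known <- c("constitutive", "single_tissue_exclusive", "single_tissue_peak",
             "silent")
  cls <- rep_len(class_assignments, n_genes)
  if (!all(cls %in% known))
    stop("unknown class label: ", paste(setdiff(cls, known), collapse = ", "))
  restore_rng <- .rng_snapshot()
  on.exit(restore_rng(), add = TRUE)
  set.seed(as.integer(seed))
  nt <- length(tissues)
  mat <- matrix(0, n_genes, nt,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)), tissues))
  peak <- rep(NA_character_, n_genes)
  for (i in seq_len(n_genes)) {
    row <- switch(cls[i],
      constitutive = stats::runif(nt, 1, 50),
      single_tissue_exclusive = {
        j <- sample.int(nt, 1L)
        peak[i] <- tissues[j]
        v <- numeric(nt); v[j] <- stats::runif(1, 1, 50); v
      },
      single_tissue_peak = {
        j <- sample.int(nt, 1L)
        peak[i] <- tissues[j]
        v <- stats::runif(nt, 0, 1)
        if (nt > 1L) v[sample(setdiff(seq_len(nt), j), 1L)] <- 0 # not constitutive
        v[j] <- 3 * sum(v[-j]) + 1 # peak share >= 0.75 of the row total
        v
      },
      silent = numeric(nt))
    mat[i, ] <- row
  }
  list(matrix = mat, classes = cls, peak_tissue = peak,
       seed = as.integer(seed))
}

#' Generate promoter sequences with planted motif copies
#'
#' Each promoter receives exactly its planted number of non-overlapping
#' forward-strand copies of the motif; with `exclude_background = TRUE` the
#' background is redrawn until a both-strand scan of the final sequence
#' reports exactly the planted count (no accidental matches on either
#' strand).
#'
#' @param n_genes Number of promoters.
#' @param length Promoter length in bp.
#' @param motif IUPAC consensus to plant (a concrete instance is drawn per
#'   copy).
#' @param copies Integer vector of planted copy counts (recycled).
#' @param exclude_background Reject backgrounds carrying accidental matches?
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector), `copies` and
#'   `motif`.
#' @export
generate_promoter_fixture <- function(n_genes,
                                      length = 1500,
                                      motif = "CACGTG",
                                      copies = 1,
                                      exclude_background = TRUE,
                                      seed = 1L) {
  w <- nchar(motif)
  if (length < w) stop("promoter length shorter than the motif")
  copies <- rep_len(as.integer(copies), n_genes)
  if (any(copies < 0)) stop("planted copy counts must be >= 0")
  if (any(copies * w > length))
    stop("planted motifs cannot fit without overlap")
  restore_rng <- .rng_snapshot()
  on.exit(restore_rng(), add = TRUE)
  set.seed(as.integer(seed))
  iupac <- Biostrings::IUPAC_CODE_MAP
  motif_chars <- strsplit(toupper(motif), "")[[1]]
  if (!all(motif_chars %in% names(iupac))) stop("invalid IUPAC code in motif")
  draw_instance <- function() paste0(vapply(motif_chars, function(ch) {
    opts <- strsplit(iupac[[ch]], "")[[1]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")

  seqs <- character(n_genes)
  for (i in seq_len(n_genes)) {
    k <- copies[i]
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 2000L)
        stop("could not generate a motif-free background; motif too permissive")
      s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      if (k > 0) {
        # choose k non-overlapping start positions by sampling starts in the
        # "compressed" coordinate system then re-expanding
        slots <- sort(sample.int(length - k * w + k, k))
        starts <- slots + (seq_len(k) - 1L) * (w - 1L)
        for (st in starts)
          s[st:(st + w - 1L)] <- strsplit(draw_instance(), "")[[1]]
      }
      seq_i <- paste0(s, collapse = "")
      if (!exclude_background) break
      found <- .count_motif_both_strands(seq_i, motif)
      if (found == k) break
    }
    seqs[i] <- seq_i
  }
  names(seqs) <- sprintf("g%04d", seq_len(n_genes))
  list(sequences = seqs, copies = copies, motif = motif,
       seed = as.integer(seed))
}
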