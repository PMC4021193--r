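## Expression normalization, Pearson-correlation clustering,
## tissue-specificity classification and IUPAC cis-element scanning.

#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `count / (length / 1000) / (library_size / 1e6)`.
#'
#' @param counts Genes x tissues matrix of raw read counts.
#' @param gene_lengths_bp Per-gene transcript lengths (bp, > 0), recycled
#'   along rows.
#' @param library_sizes Per-tissue mapped-read totals (> 0), recycled
#'   along columns.
#' @return Matrix of RPKM values with the input dimnames.
#' @export
rpkm_normalize <- function(counts, gene_lengths_bp, library_sizes) {
  counts <- as.matrix(counts)
  if (any(gene_lengths_bp <= 0)) stop("gene lengths must be > 0")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  gene_lengths_bp <- rep_len(gene_lengths_bp, nrow(counts))
  library_sizes <- rep_len(library_sizes, ncol(counts))
  out <- counts / (gene_lengths_bp / 1000)
  sweep(out, 2, library_sizes / 1e6, "/")
}

#' Cluster expression profiles by Pearson correlation
#'
#' Distance `1 - r` between gene profiles, agglomerated by average
#' linkage. Genes with zero variance across tissues (including silent,
#' all-zero genes) have undefined correlation and are excluded with a
#' warning.
#'
#' @param mat Genes x tissues expression matrix.
#' @return List with `hclust` (the dendrogram), `order` (gene names in
#'   dendrogram order), `excluded` (constant-profile gene names),
#'   `distance` (the `dist` object).
#' @export
cluster_expression <- function(mat) {
  mat <- as.matrix(mat)
  v <- apply(mat, 1, stats::var)
  excluded <- rownames(mat)[v == 0 | is.na(v)]
  if (length(excluded))
    warning(length(excluded),
            " constant-profile gene(s) excluded from clustering")
  keep <- setdiff(rownames(mat), excluded)
  if (length(keep) < 2) stop("fewer than 2 clusterable genes")
  m <- mat[keep, , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, order = keep[hc$order], excluded = excluded,
       distance = d)
}

#' Classify tissue-specificity of expression profiles
#'
#' Mutually exclusive classes, assigned in order: `silent` (all zero),
#' `single_tissue_exclusive` (exactly one nonzero tissue), `constitutive`
#' (all tissues nonzero), `single_tissue_peak` (maximum tissue holds at
#' least `peak_fraction` of the row total), otherwise `other`.
#'
#' @param mat Genes x tissues expression matrix (nonnegative).
#' @param peak_fraction Share of the row total that defines a marked
#'   single-tissue peak (default 0.5).
#' @return Data frame with `gene_id`, `class`, `peak_tissue` (NA for
#'   silent genes; the maximum tissue otherwise).
#' @export
call_specificity <- function(mat, peak_fraction = 0.5) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("expression values must be nonnegative")
  tissues <- colnames(mat)
  res <- lapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, ]
    nz <- sum(x > 0)
    peak <- if (nz == 0) NA_character_ else tissues[which.max(x)]
    cls <- if (nz == 0) "silent"
      else if (nz == 1) "single_tissue_exclusive"
      else if (nz == length(x)) "constitutive"
      else if (max(x) / sum(x) >= peak_fraction) "single_tissue_peak"
      else "other"
    data.frame(gene_id = rownames(mat)[i], class = cls, peak_tissue = peak,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Packaged cis-acting element consensus motifs
#'
#' A small IUPAC consensus table covering the promoter element families
#' commonly profiled in plant gene-family studies (light-, hormone-,
#' stress-responsive and circadian elements). The consensi are
#' approximate; supply your own table for curated definitions.
#'
#' @return Data frame with `element` and `consensus` (IUPAC) columns.
#' @export
default_cis_elements <- function() {
  data.frame(
    element = c("G-box", "Box4", "TCA-element", "MBS", "ARE", "HSE",
                "GARE-motif", "circadian"),
    consensus = c("CACGTG", "ATTAAT", "CCATCTTTTT", "CAACTG", "AAACCA",
                  "AAAAAATTTC", "TCTGTTG", "CAANNNNATC"),
    stringsAsFactors = FALSE)
}

## Count motif occurrences on both strands with same-locus deduplication:
## a start position where both the motif and its reverse complement match
## (palindromes) is counted once. Overlapping occurrences all count.
.count_motif_both_strands <- function(seq, consensus) {
  subject <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(consensus)
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, subject,
                                                    fixed = FALSE))
  rev <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::reverseComplement(pat), subject,
                             fixed = FALSE))
  length(union(fwd, rev))
}

#' Scan promoter sequences for cis-acting elements
#'
#' Counts IUPAC consensus matches on both strands (a match and its reverse
#' complement at the same locus are counted once; overlapping occurrences
#' all count) and reports per-family mean copy numbers to three decimals.
#'
#' @param promoters Named character vector of promoter sequences
#'   (A/C/G/T/N).
#' @param motifs Data frame with `element` and `consensus` columns
#'   (default [default_cis_elements()]).
#' @return List with `counts` (genes x elements integer matrix) and
#'   `mean_copies` (named, rounded to three decimals).
#' @export
scan_cis_elements <- function(promoters, motifs = default_cis_elements()) {
  if (is.null(names(promoters))) stop("promoter sequences must be named")
  ok <- grepl("^[ACGTNacgtn]*$", promoters)
  if (!all(ok))
    stop("promoter sequences must contain only A, C, G, T, N")
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  for (cons in motifs$consensus)
    if (!all(strsplit(toupper(cons), "")[[1]] %in% iupac))
      stop("invalid IUPAC code in consensus ", cons)
  counts <- matrix(0L, length(promoters), nrow(motifs),
                   dimnames = list(names(promoters), motifs$element))
  for (j in seq_len(nrow(motifs))) {
    counts[, j] <- vapply(promoters, .count_motif_both_strands,
                          integer(1), consensus = motifs$consensus[j])
  }
  list(counts = counts,
       mean_copies = round(colMeans(counts), 3))
}
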