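## Family membership filters and per-protein descriptive statistics.
## Candidates are retained when they carry both diagnostic Pfam domains at
## a stringent E-value and their CDS forms an integral open reading frame
## (start ATG, terminal stop, no internal stop, length divisible by 3).

#' Check whether a CDS is an integral open reading frame
#'
#' @param cds Character string of A/C/G/T.
#' @return Logical scalar.
#' @export
is_integral_orf <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 6 || n %% 3L != 0L) return(FALSE)
  cods <- split_codons(cds)
  if (cods[1] != "ATG") return(FALSE)
  last <- cods[length(cods)]
  if (!last %in% STOP_CODONS) return(FALSE)
  internal <- cods[-length(cods)]
  !any(internal %in% STOP_CODONS) && all(strsplit(cds, "")[[1]] %in% c("A", "C", "G", "T"))
}

#' Filter family candidates by domain architecture and ORF integrity
#'
#' A candidate is retained iff it has (a) at least one domain hit at
#' E <= `e_max`, (b) hits (at that threshold) to both required domains, and
#' (c) a CDS passing [is_integral_orf()]. Candidates failing any condition
#' are returned with a reason code.
#'
#' @param candidates Data frame with at least `gene_id` and `cds` columns.
#' @param hits Data frame of domain hits: `gene_id`, `domain`, `e_value`.
#' @param e_max E-value cutoff (default 1e-10).
#' @param required_domains The two diagnostic domain accessions
#'   (default `PF03330` and `PF01357`, expansin domains I and II).
#' @return List with `retained` (subset of `candidates`) and `excluded`
#'   (data frame `gene_id`, `reason` in `no_cds`, `single_domain`,
#'   `no_domain`, `bad_orf`).
#' @export
filter_family_members <- function(candidates, hits, e_max = 1e-10,
                                  required_domains = c("PF03330", "PF01357")) {
  stopifnot(e_max > 0, length(required_domains) == 2L)
  if (!all(c("gene_id", "cds") %in% names(candidates)))
    stop("candidates must have gene_id and cds columns")
  if (!all(c("gene_id", "domain", "e_value") %in% names(hits)))
    stop("hits must have gene_id, domain and e_value columns")
  if (any(hits$e_value < 0)) stop("e_value must be >= 0")

  good_hits <- hits[hits$e_value <= e_max &
                      hits$domain %in% required_domains, , drop = FALSE]
  reasons <- character(0); excluded_ids <- character(0)
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    id <- candidates$gene_id[i]
    cds <- candidates$cds[i]
    doms <- unique(good_hits$domain[good_hits$gene_id == id])
    reason <- NULL
    if (is.na(cds) || !nzchar(cds)) reason <- "no_cds"
    else if (length(doms) == 0L) reason <- "no_domain"
    else if (length(doms) == 1L) reason <- "single_domain"
    else if (!is_integral_orf(cds)) reason <- "bad_orf"
    if (is.null(reason)) keep[i] <- TRUE
    else { excluded_ids <- c(excluded_ids, id); reasons <- c(reasons, reason) }
  }
  list(retained = candidates[keep, , drop = FALSE],
       excluded = data.frame(gene_id = excluded_ids, reason = reasons,
                             stringsAsFactors = FALSE))
}

## Bjellqvist-style pKa set as used by the ExPASy Compute pI/Mw tool:
## side chains plus residue-specific N-terminal and C-terminal values.
PKA_SIDECHAIN <- c(C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00,
                   R = 12.00, Y = 10.00)
PKA_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.70, G = 7.50)
PKA_NTERM_DEFAULT <- 7.50
PKA_CTERM <- c(D = 4.55, E = 4.75)
PKA_CTERM_DEFAULT <- 3.55

AA_STANDARD <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

.check_protein <- function(protein) {
  protein <- toupper(protein)
  if (!nzchar(protein)) return(character(0))
  aa <- strsplit(protein, "")[[1]]
  bad <- setdiff(unique(aa), AA_STANDARD)
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  aa
}

## Henderson-Hasselbalch net charge at a given pH.
protein_net_charge <- function(aa, pH) {
  pos_pka <- c(PKA_SIDECHAIN[c("K", "R", "H")])
  counts <- table(factor(aa, levels = AA_STANDARD))
  nt <- if (aa[1] %in% names(PKA_NTERM)) PKA_NTERM[[aa[1]]] else PKA_NTERM_DEFAULT
  last <- aa[length(aa)]
  ct <- if (last %in% names(PKA_CTERM)) PKA_CTERM[[last]] else PKA_CTERM_DEFAULT
  pos <- 1 / (1 + 10^(pH - nt)) +
    sum(vapply(c("K", "R", "H"), function(r)
      counts[[r]] / (1 + 10^(pH - PKA_SIDECHAIN[[r]])), numeric(1)))
  neg <- 1 / (1 + 10^(ct - pH)) +
    sum(vapply(c("D", "E", "C", "Y"), function(r)
      counts[[r]] / (1 + 10^(PKA_SIDECHAIN[[r]] - pH)), numeric(1)))
  pos - neg
}

#' Theoretical isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge of the protein
#' (termini plus ionizable side chains, Bjellqvist-style pKa set) is zero,
#' located by bisection on (0, 14) to |charge| < 1e-4.
#'
#' @param protein Amino-acid sequence (standard one-letter residues).
#' @return pI in pH units, strictly inside (0, 14).
#' @export
compute_pi <- function(protein) {
  aa <- .check_protein(protein)
  if (!length(aa)) stop("sequence must be nonempty")
  lo <- 0; hi <- 14
  # net charge is strictly decreasing in pH
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    ch <- protein_net_charge(aa, mid)
    if (abs(ch) < 1e-4) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  mid
}

## Average residue masses (Da), ExPASy convention; free water added once.
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water, matching the ExPASy
#' convention. The empty sequence returns the mass of water.
#'
#' @param protein Amino-acid sequence (standard residues; may be empty).
#' @return Mass in Daltons.
#' @export
compute_mw <- function(protein) {
  aa <- .check_protein(protein)
  sum(AA_MASS[aa]) + WATER_MASS
}

#' Subfamily size and duplication-class summary
#'
#' @param subfamilies Character vector of subfamily labels, one per family
#'   member (e.g. `EXPA`, `EXPB`, `EXLA`, `EXLB`).
#' @param tandem_ids,segmental_ids Optional gene-id vectors flagged as
#'   tandem / segmental duplicates; percentages are taken over the family
#'   size and rounded to one decimal.
#' @param member_ids Gene ids matching `subfamilies` (required when
#'   duplication flags are supplied).
#' @return A `family_summary` list: `counts` (named, one per subfamily),
#'   `total`, `n_tandem`, `pct_tandem`, `n_segmental`, `pct_segmental`.
#' @export
family_summary <- function(subfamilies, member_ids = NULL,
                           tandem_ids = NULL, segmental_ids = NULL) {
  counts <- if (length(subfamilies)) table(subfamilies) else table(character(0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  pct <- function(n) if (total == 0) 0 else round(100 * n / total, 1)
  n_tan <- length(intersect(member_ids, tandem_ids))
  n_seg <- length(intersect(member_ids, segmental_ids))
  if (is.null(member_ids)) {
    n_tan <- length(unique(tandem_ids))
    n_seg <- length(unique(segmental_ids))
  }
  structure(list(counts = counts, total = total,
                 n_tandem = n_tan, pct_tandem = pct(n_tan),
                 n_segmental = n_seg, pct_segmental = pct(n_seg)),
            class = "family_summary")
}

#' @export
print.family_summary <- function(x, ...) {
  cat("Family summary:", x$total, "members\n")
  if (length(x$counts)) {
    for (nm in names(x$counts)) cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  }
  cat(sprintf("  tandem: %d (%.1f%%)  segmental: %d (%.1f%%)\n",
              x$n_tandem, x$pct_tandem, x$n_segmental, x$pct_segmental))
  invisible(x)
}
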