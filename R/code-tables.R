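## Codon bookkeeping shared by the simulator, the likelihood engine,
## NG86/4DTv counting and the ORF filter. Everything is derived from the
## standard genetic code as shipped in Biostrings::GENETIC_CODE, restricted
## to the 61 sense codons.

NUC <- c("T", "C", "A", "G")

ALL_CODONS <- {
  g <- expand.grid(p3 = NUC, p2 = NUC, p1 = NUC, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

CODON_AA <- {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[ALL_CODONS])
}
names(CODON_AA) <- ALL_CODONS

STOP_CODONS <- ALL_CODONS[CODON_AA == "*"]
SENSE_CODONS <- ALL_CODONS[CODON_AA != "*"]
SENSE_AA <- CODON_AA[SENSE_CODONS]
N_SENSE <- length(SENSE_CODONS) # 61

## integer [61 x 3] matrix of nucleotide indices (1=T,2=C,3=A,4=G)
SENSE_NT <- t(vapply(strsplit(SENSE_CODONS, ""),
                     function(x) match(x, NUC), integer(3)))
rownames(SENSE_NT) <- SENSE_CODONS

is_transition <- function(a, b) {
  # indices into NUC; transitions are T<->C and A<->G
  (a != b) & ((a <= 2L & b <= 2L) | (a >= 3L & b >= 3L))
}

#' Fourfold-degenerate codons
#'
#' A codon is fourfold degenerate (at its third position) when every
#' third-position nucleotide yields the same amino acid.
#' @return Character vector of fourfold-degenerate sense codons.
#' @keywords internal
.fourfold_codons <- function() {
  pre <- unique(substr(SENSE_CODONS, 1, 2))
  ff <- character(0)
  for (p in pre) {
    cods <- paste0(p, NUC)
    aas <- CODON_AA[cods]
    if (!anyNA(aas) && all(aas != "*") && length(unique(aas)) == 1L)
      ff <- c(ff, cods)
  }
  ff
}
FOURFOLD_CODONS <- .fourfold_codons()

## codon string -> index in SENSE_CODONS (NA for stops / gaps)
codon_index <- function(codons) match(toupper(codons), SENSE_CODONS)

## Split a DNA string into codons (assumes length divisible by 3).
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

## Convert a set of equal-length CDS strings into an integer codon matrix
## (rows = sequences, cols = codon sites). Codons containing gaps are NA;
## stop codons raise an error unless allow_stop.
codon_matrix <- function(seqs, allow_stop = FALSE) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences must be aligned to equal length")
  m <- t(vapply(seqs, function(s) {
    cods <- split_codons(s)
    idx <- codon_index(cods)
    gap <- grepl("-", cods, fixed = TRUE)
    if (!allow_stop && any(!gap & cods %in% STOP_CODONS))
      stop("stop codon in sequence")
    idx[gap] <- NA_integer_
    idx
  }, integer(nchar(seqs[[1]]) / 3L)))
  # vapply drops dims for single-site alignments
  if (is.null(dim(m))) m <- matrix(m, nrow = length(seqs))
  rownames(m) <- names(seqs)
  m
}

#' Uniform codon frequencies
#'
#' Equal frequency (1/61) on each sense codon, the `CodonFreq = 0` setting
#' of codon-model software.
#' @return Named numeric vector of length 61 summing to 1.
#' @export
equal_codon_freqs <- function() {
  structure(rep(1 / N_SENSE, N_SENSE), names = SENSE_CODONS)
}

#' F3x4 codon frequencies
#'
#' Codon frequencies predicted from the empirical nucleotide composition at
#' each codon position of an alignment, renormalized over sense codons
#' (the common `CodonFreq = 2` convention).
#'
#' @param seqs Named character vector of aligned CDS (gaps allowed).
#' @return Named numeric vector of length 61 summing to 1.
#' @export
f3x4_frequencies <- function(seqs) {
  cm <- lapply(seqs, function(s) strsplit(toupper(s), "")[[1]])
  len <- unique(lengths(cm))
  if (length(len) != 1L) stop("sequences must be aligned to equal length")
  pos_freq <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, NUC))
  for (s in cm) {
    pos <- ((seq_along(s) - 1L) %% 3L) + 1L
    keep <- s %in% NUC
    tab <- table(factor(pos[keep], levels = 1:3), factor(s[keep], levels = NUC))
    pos_freq <- pos_freq + as.matrix(tab)
  }
  pos_freq <- pos_freq / rowSums(pos_freq)
  f <- pos_freq[1, SENSE_NT[, 1]] * pos_freq[2, SENSE_NT[, 2]] *
    pos_freq[3, SENSE_NT[, 3]]
  f <- f / sum(f)
  names(f) <- SENSE_CODONS
  f
}

.check_codon_freqs <- function(codon_freqs) {
  if (length(codon_freqs) != N_SENSE)
    stop("codon_freqs must have length ", N_SENSE, " (sense codons only)")
  if (any(codon_freqs < 0))
    stop("codon_freqs must be nonnegative")
  if (abs(sum(codon_freqs) - 1) > 1e-12)
    stop("codon_freqs must sum to 1 (within 1e-12)")
  invisible(codon_freqs)
}

## Capture the caller's RNG state; returns a restorer. Seeded functions use
## this so an explicit `seed` argument never clobbers the caller's stream.
.rng_snapshot <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    function() assign(".Random.seed", old, globalenv())
  } else {
    function() {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }
  }
}
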