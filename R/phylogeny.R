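## Protein distance matrices, neighbor-joining trees and reference-guided
## subfamily assignment. Tree construction itself is delegated to ape's
## Saitou-Nei implementation; this module owns the distance definitions,
## validation/clamping and the clade-based labelling logic.

#' Pairwise protein distances with pairwise gap deletion
#'
#' For each sequence pair, alignment columns where either sequence carries
#' a gap (`-`) or `X` are dropped; `p` is the mismatch proportion over the
#' remaining columns. Under the `poisson` model the distance is
#' `-log(1 - p)`.
#'
#' @param alignment Named character vector of aligned protein sequences of
#'   equal length, or a character matrix (rows = sequences).
#' @param model `"p_distance"` (default) or `"poisson"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
protein_distance <- function(alignment, model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  m <- .aln_to_matrix(alignment)
  n <- nrow(m)
  if (n < 2) stop("need >= 2 aligned sequences")
  ok <- m != "-" & m != "X" & m != "?"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0)
        stop("sequences ", rownames(m)[i], " and ", rownames(m)[j],
             " share no comparable columns")
      p <- sum(m[i, comp] != m[j, comp]) / nc
      if (model == "poisson") {
        if (p >= 1) stop("p >= 1: poisson correction undefined for pair ",
                         rownames(m)[i], "/", rownames(m)[j])
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

.aln_to_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    if (is.null(names(alignment))) stop("alignment sequences must be named")
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- names(alignment)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("alignment rows must carry unique names")
  m
}

#' Build an unrooted neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a validated distance matrix. Negative
#' branch-length estimates (a known NJ artifact) are clamped to zero with
#' a warning.
#'
#' @param dm Symmetric nonnegative distance matrix with zero diagonal.
#' @return An unrooted `ape::phylo` tree.
#' @export
build_nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need >= 3 leaves for neighbor joining")
  if (any(dm < 0)) stop("distance matrix has negative entries")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix diagonal must be zero")
  tr <- ape::nj(dm)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Assign subfamily labels from reference-labelled leaves
#'
#' Each query leaf receives the label of the smallest bipartition side
#' (clade of the unrooted tree) that contains it together with at least one
#' reference leaf, all of whose reference leaves carry a single label. If
#' no such side exists the query takes the label of the topologically
#' nearest reference leaf and is flagged ambiguous.
#'
#' @param tree An `ape::phylo` tree containing both query and reference
#'   leaves.
#' @param reference_labels Named character vector: reference leaf ->
#'   subfamily label.
#' @return Data frame with `query`, `subfamily`, `ambiguous`.
#' @export
assign_subfamilies <- function(tree, reference_labels) {
  stopifnot(inherits(tree, "phylo"))
  refs <- names(reference_labels)
  missing_refs <- setdiff(refs, tree$tip.label)
  if (length(missing_refs))
    stop("reference leaves absent from tree: ",
         paste(missing_refs, collapse = ", "))
  queries <- setdiff(tree$tip.label, refs)
  ntip <- length(tree$tip.label)

  # leaf sets of both sides of every internal edge
  sides <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    below <- .tips_below(tree, child)
    sides[[length(sides) + 1L]] <- below
    sides[[length(sides) + 1L]] <- setdiff(seq_len(ntip), below)
  }
  sides <- unique(sides[lengths(sides) > 0 & lengths(sides) < ntip])

  path_d <- ape::cophenetic.phylo(ape::compute.brlen(tree, 1))
  out <- data.frame(query = character(0), subfamily = character(0),
                    ambiguous = logical(0), stringsAsFactors = FALSE)
  ref_idx <- match(refs, tree$tip.label)
  for (q in queries) {
    qi <- match(q, tree$tip.label)
    best_size <- Inf; best_label <- NA_character_
    for (s in sides) {
      if (!(qi %in% s)) next
      rs <- intersect(s, ref_idx)
      if (!length(rs)) next
      labs <- unique(reference_labels[match(tree$tip.label[rs], refs)])
      if (length(labs) == 1L && length(s) < best_size) {
        best_size <- length(s); best_label <- labs
      }
    }
    ambiguous <- FALSE
    if (is.na(best_label)) {
      ambiguous <- TRUE
      nearest <- refs[which.min(path_d[q, refs])]
      best_label <- unname(reference_labels[nearest])
    }
    out <- rbind(out, data.frame(query = q, subfamily = unname(best_label),
                                 ambiguous = ambiguous,
                                 stringsAsFactors = FALSE))
  }
  out
}

.tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .tips_below, tree = tree))
}

#' Bootstrap support for a neighbor-joining protein tree
#'
#' Resamples alignment columns with replacement (preserving taxon order so
#' that replicated data deterministically reproduce the reference tree),
#' rebuilds the NJ tree and counts how often each clade of the reference
#' tree recurs among the replicates.
#'
#' @param alignment Named character vector or matrix of aligned proteins.
#' @param model Distance model passed to [protein_distance()].
#' @param B Number of replicates (default 1000).
#' @param seed Integer seed.
#' @return List with `tree` (the NJ tree from the full alignment) and
#'   `support` (percentage in \[0, 100\] per internal node; the root node,
#'   whose "clade" is the full leaf set, is reported as 100).
#' @export
nj_bootstrap <- function(alignment, model = "p_distance", B = 1000, seed = 1L) {
  m <- .aln_to_matrix(alignment)
  fun <- function(x)
    suppressWarnings(build_nj_tree(protein_distance(x, model = model)))
  tr <- fun(m)
  restore_rng <- .rng_snapshot()
  on.exit(restore_rng(), add = TRUE)
  set.seed(as.integer(seed))
  boots <- vector("list", B)
  for (b in seq_len(B))
    boots[[b]] <- fun(m[, sample.int(ncol(m), replace = TRUE), drop = FALSE])
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(tr, boots, rooted = FALSE)
  counts[is.na(counts)] <- B
  list(tree = tr, support = 100 * counts / B)
}
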