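#' Code dosage genotypes to character sequences
#'
#' Codes each biallelic marker genotype to one symbol: dosage 0 to `R`
#' (homozygous reference), 1 to `H` (heterozygous), 2 to `A` (homozygous
#' alternative), missing to `?`. Optionally appends an all-`R` outgroup
#' sequence representing the reference genotype (the reference genome is
#' homozygous reference at every marker by construction).
#'
#' @param m samples x markers dosage matrix.
#' @param outgroup name for an appended all-reference outgroup sequence, or
#'   NULL.
#' @return Character matrix (taxa x markers) of single-letter codes, class
#'   `coded_seqs`.
#' @export
code_genotypes <- function(m, outgroup = NULL) {
  if (any(!(m %in% c(0, 1, 2, NA)))) {
    stop_clonediv("dosages must be 0, 1, 2 or NA (biallelic markers only)",
                  "invalid_input")
  }
  code <- matrix("?", nrow(m), ncol(m), dimnames = dimnames(m))
  code[!is.na(m) & m == 0] <- "R"
  code[!is.na(m) & m == 1] <- "H"
  code[!is.na(m) & m == 2] <- "A"
  if (!is.null(outgroup)) {
    code <- rbind(code, rep("R", ncol(code)))
    rownames(code)[nrow(code)] <- outgroup
  }
  structure(code, class = c("coded_seqs", class(matrix())))
}

#' Uncorrected p-distance between two coded sequences
#'
#' Proportion of differing characters over pairwise non-missing sites
#' (missing symbol `?` excluded pairwise). The heterozygous code is a
#' distinct state: `R` vs `A` counts as one difference like any mismatch.
#'
#' @param a,b equal-length character vectors (or strings) of codes.
#' @return Fraction in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  if (length(a) == 1 && nchar(a[1]) > 1) a <- strsplit(a, "")[[1]]
  if (length(b) == 1 && nchar(b[1]) > 1) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) {
    stop_clonediv("sequences differ in length", "invalid_input")
  }
  comp <- a != "?" & b != "?"
  if (!any(comp)) stop_clonediv("no comparable sites", "undefined_distance")
  sum(a[comp] != b[comp]) / sum(comp)
}

#' Pairwise p-distance matrix
#'
#' @param seqs character matrix of coded sequences (taxa x markers).
#' @return Symmetric matrix of p-distances, zero diagonal.
#' @export
p_distance_matrix <- function(seqs) {
  n <- nrow(seqs)
  d <- matrix(0, n, n, dimnames = list(rownames(seqs), rownames(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) d[i, j] <- d[j, i] <- p_distance(seqs[i, ], seqs[j, ])
  }
  d
}

# negative NJ branch lengths are artifacts of the agglomeration; clamp to
# zero and transfer the deficit to the sibling branch so path lengths are
# approximately preserved
clamp_negative_branches <- function(phy) {
  for (e in which(phy$edge.length < 0)) {
    parent <- phy$edge[e, 1]
    sib <- setdiff(which(phy$edge[, 1] == parent), e)
    sib <- sib[phy$edge.length[sib] > 0]
    if (length(sib) > 0) {
      phy$edge.length[sib[1]] <- phy$edge.length[sib[1]] + phy$edge.length[e]
    }
    phy$edge.length[e] <- 0
  }
  # any residue (a sibling driven negative by the transfer) is clamped flat
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (Q-criterion agglomeration, via [ape::nj()]).
#' Negative branch lengths are clamped to zero with the deficit transferred
#' to the sibling branch.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 3 taxa.
#' @return An [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(d) {
  dm <- as.matrix(d)
  if (nrow(dm) < 3) stop_clonediv("need at least 3 taxa", "invalid_input")
  clamp_negative_branches(ape::nj(stats::as.dist(dm)))
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree from coded sequences, then resamples markers
#' (columns) with replacement `n_reps` times, rebuilds the NJ tree for each
#' replicate, and reports for every internal edge of the full-data tree the
#' percentage of replicate trees containing the same bipartition (standard
#' nonparametric bootstrap; supports are attached as internal node labels).
#'
#' @param seqs coded sequence matrix ([code_genotypes()]).
#' @param n_reps bootstrap replicates (default 200).
#' @param seed integer seed (resampling is exactly reproducible).
#' @return An [ape::phylo] tree; `$node.label` holds supports in `[0, 100]`
#'   (the root label is empty).
#' @export
bootstrap_supports <- function(seqs, n_reps = 200, seed = 1L) {
  if (n_reps < 1) stop_clonediv("n_reps must be >= 1", "invalid_argument")
  if (nrow(seqs) < 4) {
    stop_clonediv("need >= 4 taxa for nontrivial supports", "invalid_input")
  }
  build <- function(x) nj_tree(p_distance_matrix(x))
  phy <- build(seqs)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  counts <- ape::boot.phylo(phy, seqs, build, B = n_reps, quiet = TRUE,
                            rooted = FALSE)
  support <- round(100 * counts / n_reps)
  support[1] <- NA                                # root of the unrooted tree
  phy$node.label <- ifelse(is.na(support), "", as.character(support))
  phy
}

#' Root a tree with an outgroup
#'
#' Places the root on the outgroup's pendant edge. Idempotent; preserves all
#' unrooted bipartitions.
#'
#' @param phy an [ape::phylo] tree.
#' @param outgroup leaf name.
#' @return Rooted [ape::phylo] tree.
#' @export
root_with_outgroup <- function(phy, outgroup) {
  if (!outgroup %in% phy$tip.label) {
    stop_clonediv(sprintf("outgroup '%s' is not a leaf", outgroup),
                  "invalid_argument")
  }
  ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
}
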