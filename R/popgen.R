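#' Codominant squared genotypic distance
#'
#' The standard codominant squared distance for biallelic dosage genotypes:
#' per locus, `(dosage_a - dosage_b)^2`, i.e. 0 for identical genotypes, 1
#' between a homozygote and the heterozygote, 4 between opposite homozygotes;
#' the total is the sum over pairwise non-missing loci. This equals the
#' squared Euclidean distance on dosage vectors.
#'
#' @param a,b dosage vectors over the same markers.
#' @return Nonnegative squared distance.
#' @export
codominant_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop_clonediv("profiles cover different marker sets", "invalid_input")
  }
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) stop_clonediv("no comparable loci", "undefined_distance")
  sum((a[both] - b[both])^2)
}

#' Pairwise codominant squared-distance matrix
#'
#' @param m samples (or genotypes) x markers dosage matrix.
#' @return Symmetric matrix of squared distances, zero diagonal.
#' @export
codominant_distance_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) d[i, j] <- d[j, i] <- codominant_distance(m[i, ], m[j, ])
  }
  d
}

#' Principal coordinates analysis of a squared-distance matrix
#'
#' Classical metric PCoA: Gower double-centering of `-d^2 / 2` and
#' eigendecomposition (via [stats::cmdscale()]); coordinates are eigenvectors
#' scaled by the square root of their eigenvalues, axes ordered by
#' decreasing eigenvalue, and percent variance computed over positive
#' eigenvalues only.
#'
#' @param d2 symmetric matrix of *squared* distances (e.g.
#'   [codominant_distance_matrix()]).
#' @return List of class `pcoa_result`: `coordinates` (taxa x axes),
#'   `eigenvalues`, `percent` (variance explained per positive axis).
#' @export
pcoa <- function(d2) {
  d2 <- as.matrix(d2)
  if (!isSymmetric(unname(d2), tol = 1e-8)) {
    stop_clonediv("distance matrix must be symmetric", "invalid_input")
  }
  n <- nrow(d2)
  if (n < 2) stop_clonediv("need at least two taxa", "invalid_input")
  fit <- cmdscale(sqrt(d2), k = n - 1, eig = TRUE)
  eig <- fit$eig
  pos <- eig > 1e-9 * max(abs(eig))
  pct <- rep(0, length(eig))
  pct[pos] <- 100 * eig[pos] / sum(eig[pos])
  coords <- fit$points
  if (!is.null(coords) && ncol(coords) > 0) {
    colnames(coords) <- sprintf("PCo%d", seq_len(ncol(coords)))
  }
  structure(list(coordinates = coords, eigenvalues = eig,
                 percent = pct[seq_len(ncol(coords))]),
            class = "pcoa_result")
}

ss_within <- function(d2, idx_by_group) {
  sum(vapply(idx_by_group, function(idx)
    sum(d2[idx, idx, drop = FALSE]) / 2 / length(idx), numeric(1)))
}

phi_from_ssw <- function(ssw, sst, df_among, df_within, n0) {
  vw <- ssw / df_within
  va <- ((sst - ssw) / df_among - vw) / n0
  va / (va + vw)
}

#' AMOVA with the Phi-PT statistic
#'
#' Analysis of molecular variance for a squared codominant genotypic distance
#' matrix and a two-or-more group assignment. Sums of squares follow the
#' standard AMOVA decomposition: `SS_total = sum(d2) / N` over all pairs,
#' `SS_within = sum_g sum(d2 within g) / n_g`, `SS_among` by difference.
#' Variance components use the method of moments with the average group-size
#' coefficient `n0 = (N - sum(n_g^2) / N) / (G - 1)`; `Phi_PT = Va / (Va +
#' Vw)` is the fraction of total molecular variance among groups (negative
#' estimates are reported raw alongside a zero-clamped value). The p-value is
#' obtained by permuting individuals among groups (group sizes fixed) and
#' counting permutations with `Phi_PT` at least as large as observed, as
#' `(count + 1) / (n_perm + 1)`.
#'
#' @param d2 symmetric matrix of squared distances.
#' @param groups named (or positionally matching) character vector of group
#'   labels, one per row of `d2`; every group needs >= 1 member and at least
#'   two groups are required.
#' @param n_perm number of label permutations (default 900).
#' @param seed integer seed for the permutation stream.
#' @return Object of class `amova_phipt`: SS/df/MS table pieces, `Va`, `Vw`,
#'   `n0`, `phi_pt` (clamped at 0), `phi_pt_raw`, `p_value`, `n_perm`.
#' @export
amova_phipt <- function(d2, groups, n_perm = 900, seed = 1L) {
  d2 <- as.matrix(d2)
  n <- nrow(d2)
  if (n < 3) stop_clonediv("need at least 3 individuals", "invalid_input")
  if (length(groups) != n) {
    stop_clonediv("one group label per individual required",
                  "invalid_grouping")
  }
  if (!is.null(names(groups)) && !is.null(rownames(d2))) {
    if (!setequal(names(groups), rownames(d2))) {
      stop_clonediv("group names do not match distance matrix",
                    "invalid_grouping")
    }
    groups <- groups[rownames(d2)]
  }
  groups <- as.character(groups)
  sizes <- table(groups)
  g <- length(sizes)
  if (g < 2) stop_clonediv("need at least two groups", "invalid_grouping")
  if (any(sizes < 1)) stop_clonediv("empty group", "invalid_grouping")

  sst <- sum(d2) / 2 / n
  idx <- split(seq_len(n), groups)
  ssw <- ss_within(d2, idx)
  ssa <- sst - ssw
  df_among <- g - 1
  df_within <- n - g
  n0 <- (n - sum(sizes^2) / n) / df_among
  vw <- ssw / df_within
  va <- (ssa / df_among - vw) / n0
  phi_raw <- va / (va + vw)
  phi_obs <- max(0, phi_raw)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(groups)
    phi_b <- phi_from_ssw(ss_within(d2, split(seq_len(n), perm)), sst,
                          df_among, df_within, n0)
    if (phi_b >= phi_raw - 1e-12) count <- count + 1L
  }
  p <- (count + 1) / (n_perm + 1)

  structure(list(SS_total = sst, SS_among = ssa, SS_within = ssw,
                 df_among = df_among, df_within = df_within,
                 MS_among = ssa / df_among, MS_within = vw,
                 Va = va, Vw = vw, n0 = n0,
                 phi_pt = phi_obs, phi_pt_raw = phi_raw,
                 p_value = p, n_perm = n_perm),
            class = "amova_phipt")
}

#' @export
print.amova_phipt <- function(x, ...) {
  cat("AMOVA (codominant squared distances)\n")
  tab <- data.frame(
    source = c("Among groups", "Within groups", "Total"),
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    SS = c(x$SS_among, x$SS_within, x$SS_total),
    MS = c(x$MS_among, x$MS_within, NA)
  )
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("Va = %.4f  Vw = %.4f  n0 = %.3f\n", x$Va, x$Vw, x$n0))
  cat(sprintf("Phi_PT = %.3f (raw %.3f), p = %.4g (%d permutations)\n",
              x$phi_pt, x$phi_pt_raw, x$p_value, x$n_perm))
  invisible(x)
}
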