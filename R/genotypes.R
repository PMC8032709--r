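#' Collapse a genotype matrix into multilocus genotypes
#'
#' Samples with identical marker profiles share one multilocus genotype
#' (MLG). Under the default `"match_any"` missing policy a missing entry
#' matches any state: a sample joins a genotype when no non-missing marker
#' conflicts, and the genotype's consensus profile is filled in from the new
#' member (samples are processed in input order; the merge is greedy and
#' deterministic). Under `"strict"`, missing entries only match missing
#' entries. Genotypes are named deterministically: multi-sample genotypes get
#' letters (`A`, `B`, ...) by descending member count (ties broken by the
#' lexicographically smallest member id); singletons are named after their
#' single member.
#'
#' @param m samples x markers dosage matrix (0/1/2, NA missing), rownames =
#'   sample ids.
#' @param missing_policy `"match_any"` or `"strict"`.
#' @return Object of class `mlg_set`: list with `genotypes` (each: `name`,
#'   `profile`, `members`, `singleton`) and `markers`.
#' @export
collapse_genotypes <- function(m, missing_policy = c("match_any", "strict")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%03d", seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) {
    stop_clonediv("duplicate sample ids", "invalid_input")
  }
  if (nrow(m) == 0) stop_clonediv("empty genotype matrix", "invalid_input")

  profiles <- list(); members <- list()
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    if (all(is.na(row))) {
      stop_clonediv(sprintf("sample %s is all-missing", rownames(m)[i]),
                    "unusable_sample")
    }
    hit <- 0L
    for (g in seq_along(profiles)) {
      p <- profiles[[g]]
      if (missing_policy == "match_any") {
        both <- !is.na(p) & !is.na(row)
        if (all(p[both] == row[both])) { hit <- g; break }
      } else {
        if (identical(is.na(p), is.na(row)) &&
            all(p[!is.na(p)] == row[!is.na(row)])) { hit <- g; break }
      }
    }
    if (hit == 0L) {
      profiles[[length(profiles) + 1L]] <- row
      members[[length(members) + 1L]] <- rownames(m)[i]
    } else {
      if (missing_policy == "match_any") {      # consensus fill
        p <- profiles[[hit]]
        p[is.na(p)] <- row[is.na(p)]
        profiles[[hit]] <- p
      }
      members[[hit]] <- c(members[[hit]], rownames(m)[i])
    }
  }

  sizes <- vapply(members, length, 1L)
  first_member <- vapply(members, function(x) sort(x)[1], character(1))
  ord <- order(-sizes, first_member)
  profiles <- profiles[ord]; members <- members[ord]; sizes <- sizes[ord]

  nm <- character(length(sizes))
  multi <- sizes > 1
  nm[multi] <- make.unique(c(LETTERS, paste0("A", LETTERS)))[seq_len(sum(multi))]
  nm[!multi] <- vapply(members[!multi], identity, character(1))

  genotypes <- lapply(seq_along(sizes), function(g) {
    list(name = nm[g], profile = profiles[[g]], members = sort(members[[g]]),
         singleton = sizes[g] == 1L)
  })
  structure(list(genotypes = genotypes, markers = colnames(m)),
            class = "mlg_set")
}

#' Profile matrix of a multilocus genotype set
#'
#' @param mlg an `mlg_set`.
#' @return genotypes x markers matrix, rownames = genotype names.
#' @export
mlg_profiles <- function(mlg) {
  m <- do.call(rbind, lapply(mlg$genotypes, function(g) g$profile))
  rownames(m) <- vapply(mlg$genotypes, function(g) g$name, character(1))
  colnames(m) <- mlg$markers
  m
}

#' Membership table of a multilocus genotype set
#'
#' @param mlg an `mlg_set`.
#' @return Data frame with columns `sample`, `genotype`, `singleton`.
#' @export
mlg_membership <- function(mlg) {
  do.call(rbind, lapply(mlg$genotypes, function(g)
    data.frame(sample = g$members, genotype = g$name,
               singleton = g$singleton)))
}

#' Mutational steps between two marker profiles
#'
#' Number of markers whose non-missing dosages differ. Each marker is one
#' multistate character: a 0 vs 2 difference counts as one step by default
#' (character-state semantics); set `dosage_steps = TRUE` to count it as two.
#'
#' @param a,b dosage vectors over the same markers (NA excluded pairwise).
#' @param dosage_steps count |a - b| instead of 0/1 mismatch.
#' @return Integer step count.
#' @export
hamming_steps <- function(a, b, dosage_steps = FALSE) {
  if (length(a) != length(b)) {
    stop_clonediv("profiles cover different marker sets", "invalid_input")
  }
  both <- !is.na(a) & !is.na(b)
  if (dosage_steps) sum(abs(a[both] - b[both])) else sum(a[both] != b[both])
}

step_matrix <- function(profiles, dosage_steps = FALSE) {
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles),
                                       rownames(profiles)))
  for (j in seq_len(ncol(profiles))) {
    x <- profiles[, j]
    diffs <- if (dosage_steps) abs(outer(x, x, "-")) else
      (outer(x, x, "!=") * 1)
    diffs[is.na(diffs)] <- 0                    # missing excluded pairwise
    d <- d + diffs
  }
  d
}

# epsilon-relaxed minimum spanning network: edge (u,v) is kept iff
# d(u,v) <= minimax-path distance between u and v + epsilon. The minimax
# (bottleneck) distance -- the component-merge level of Kruskal's algorithm
# -- equals the single-linkage cophenetic height.
eps_msn <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n == 2) {
    return(data.frame(from = rownames(d)[1], to = rownames(d)[2],
                      steps = d[1, 2]))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  mm <- as.matrix(stats::cophenetic(hc))
  mm <- mm[rownames(d), rownames(d)]
  edges <- which(upper.tri(d) & d <= mm + epsilon + 1e-9, arr.ind = TRUE)
  data.frame(from = rownames(d)[edges[, 1]], to = rownames(d)[edges[, 2]],
             steps = d[edges])
}

median_profile <- function(u, v, w) {
  # per-marker majority state of a connected triplet; a three-way tie keeps
  # the first node's state (deterministic by node order)
  vapply(seq_along(u), function(j) {
    s <- c(u[j], v[j], w[j])
    tb <- sort(table(s), decreasing = TRUE)
    if (tb[1] >= 2) as.numeric(names(tb)[1]) else u[j]
  }, numeric(1))
}

#' Median-joining network of multilocus genotypes
#'
#' Builds the epsilon-relaxed minimum spanning network over the observed
#' genotypes, then iteratively adds median (Steiner) vectors -- the
#' per-marker majority profile of triplets connected in the current network
#' -- until closure, and prunes obsolete medians (degree <= 2 whose removal
#' does not lengthen any shortest path between observed genotypes). Each
#' marker is treated as one multistate character with states 0/1/2 and
#' distances are Hamming steps ([hamming_steps()]). Ties are broken by node
#' name order, so the network is deterministic.
#'
#' @param mlg an `mlg_set`, or a genotypes x markers profile matrix (no
#'   missing values; collapse first).
#' @param epsilon relaxation parameter (0 = strict minimum spanning network).
#' @param dosage_steps see [hamming_steps()].
#' @param max_medians safety cap on inferred median vectors.
#' @return Object of class `mj_network`: `nodes` (profile matrix),
#'   `is_median` (named logical), `edges` (data frame `from`, `to`, `steps`),
#'   `epsilon`.
#' @export
median_joining <- function(mlg, epsilon = 0, dosage_steps = FALSE,
                           max_medians = 200L) {
  profiles <- if (inherits(mlg, "mlg_set")) mlg_profiles(mlg) else mlg
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- sprintf("G%d", seq_len(nrow(profiles)))
  }
  if (nrow(profiles) < 2) {
    stop_clonediv("need at least two genotypes", "invalid_input")
  }
  if (anyNA(profiles)) {
    stop_clonediv("profiles must be complete (no missing entries)",
                  "invalid_input")
  }
  observed <- rownames(profiles)
  nodes <- profiles[order(rownames(profiles)), , drop = FALSE]
  n_median <- 0L

  repeat {
    d <- step_matrix(nodes, dosage_steps)
    net <- eps_msn(d, epsilon)
    adj <- split(c(net$to, net$from), c(net$from, net$to))
    new_meds <- list()
    for (v in rownames(nodes)) {
      nb <- sort(unique(adj[[v]]))
      if (length(nb) < 2) next
      for (pair in utils::combn(nb, 2, simplify = FALSE)) {
        u <- nodes[pair[1], ]; w <- nodes[pair[2], ]
        med <- unname(median_profile(nodes[v, ], u, w))
        # admit a median only when it shortens the local Steiner connection
        # of its triple (sum of spokes < the two existing network edges)
        spokes <- hamming_steps(med, nodes[v, ], dosage_steps) +
          hamming_steps(med, u, dosage_steps) +
          hamming_steps(med, w, dosage_steps)
        cur <- hamming_steps(nodes[v, ], u, dosage_steps) +
          hamming_steps(nodes[v, ], w, dosage_steps)
        if (spokes >= cur) next
        seen <- any(apply(nodes, 1, function(r) all(r == med))) ||
          any(vapply(new_meds, function(x) all(x == med), logical(1)))
        if (!seen) new_meds[[length(new_meds) + 1L]] <- med
      }
    }
    if (length(new_meds) == 0 || n_median >= max_medians) break
    for (med in new_meds) {
      n_median <- n_median + 1L
      nodes <- rbind(nodes, med)
      rownames(nodes)[nrow(nodes)] <- sprintf("mv%d", n_median)
      if (n_median >= max_medians) break
    }
    nodes <- nodes[order(rownames(nodes)), , drop = FALSE]
  }

  # prune obsolete medians
  repeat {
    d <- step_matrix(nodes, dosage_steps)
    net <- eps_msn(d, epsilon)
    g <- igraph::graph_from_data_frame(net, directed = FALSE,
                                       vertices = rownames(nodes))
    deg <- igraph::degree(g)
    base_sp <- igraph::distances(g, v = observed, to = observed,
                                 weights = igraph::E(g)$weight)
    meds <- setdiff(rownames(nodes), observed)
    removed <- FALSE
    for (x in meds[order(deg[meds])]) {
      if (deg[[x]] > 2) next
      keep <- setdiff(rownames(nodes), x)
      d2 <- d[keep, keep, drop = FALSE]
      net2 <- eps_msn(d2, epsilon)
      g2 <- igraph::graph_from_data_frame(net2, directed = FALSE,
                                          vertices = keep)
      sp2 <- igraph::distances(g2, v = observed, to = observed,
                               weights = igraph::E(g2)$weight)
      if (all(sp2 <= base_sp + 1e-9)) {
        nodes <- nodes[keep, , drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  d <- step_matrix(nodes, dosage_steps)
  net <- eps_msn(d, epsilon)
  structure(list(nodes = nodes,
                 is_median = setNames(!(rownames(nodes) %in% observed),
                                      rownames(nodes)),
                 edges = net, epsilon = epsilon),
            class = "mj_network")
}
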