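# Independent oracles used by the test suite. Each is a deliberately
# different derivation from the implementation it checks.

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration: sum the probabilities of all tables with the same margins
# whose probability does not exceed the observed table's.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumeration of all assignments of the pooled
# observations to the first group (no ties assumed); doubles the smaller tail
# as the standard exact two-sided convention does.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n)])
  combos <- combn(length(pooled), n)
  r_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  lower <- mean(r_all <= r_obs)
  upper <- mean(r_all >= r_obs)
  min(1, 2 * min(lower, upper))
}

# Classification rule table derived independently from the class definitions:
# keyed by the (hom_ref, het, hom_alt) count signature of a 4-clone pattern.
oracle_classify <- function(gts) {
  n_r <- sum(gts == "hom_ref"); n_h <- sum(gts == "het")
  n_a <- sum(gts == "hom_alt")
  key <- paste(n_r, n_h, n_a)
  cls <- switch(key,
    "4 0 0" = "invariant",
    "0 4 0" = "SNP", "0 0 4" = "SNP",
    "3 1 0" = "SC_het",
    "1 3 0" = "SC_ref",
    "3 0 1" = "SC_hom", "0 3 1" = "SC_hom",
    "1 0 3" = "complex", "0 1 3" = "complex",
    "2 2 0" = "Sh_het", "0 2 2" = "Sh_hom", "2 0 2" = "Sh_hom",
    "complex"
  )
  focal <- switch(cls,
    SC_het = names(gts)[gts == "het"],
    SC_ref = names(gts)[gts == "hom_ref"],
    SC_hom = names(gts)[gts == "hom_alt"],
    Sh_het = sort(names(gts)[gts == "het"]),
    Sh_hom = sort(names(gts)[gts == "hom_alt"]),
    character(0)
  )
  list(class = cls, focal = focal)
}

# Kruskal MST total weight over a distance matrix (greedy, union-find).
oracle_mst_weight <- function(d) {
  n <- nrow(d)
  comp <- seq_len(n)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs])
  total <- 0
  for (k in ord) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (comp[i] != comp[j]) {
      total <- total + d[i, j]
      comp[comp == comp[j]] <- comp[i]
    }
  }
  total
}

# Brute-force Steiner search: best single extra profile minimising the MST
# weight of observed profiles plus the candidate (exhaustive over the full
# 0/1/2 state space; keep marker counts tiny).
oracle_steiner_point <- function(profiles) {
  m <- ncol(profiles)
  grid <- as.matrix(expand.grid(rep(list(0:2), m)))
  best <- NULL; best_w <- Inf
  for (i in seq_len(nrow(grid))) {
    cand <- grid[i, ]
    aug <- rbind(profiles, cand)
    d <- outer(seq_len(nrow(aug)), seq_len(nrow(aug)),
               Vectorize(function(a, b) sum(aug[a, ] != aug[b, ])))
    w <- oracle_mst_weight(d)
    if (w < best_w - 1e-9) { best_w <- w; best <- cand }
  }
  list(profile = unname(best), weight = best_w)
}

# Exhaustive AMOVA permutation p for small N: enumerate all distinct
# relabelings with the observed group sizes.
oracle_amova_exhaustive_p <- function(d2, groups) {
  n <- length(groups)
  sizes <- table(groups)
  stopifnot(length(sizes) == 2)
  g1 <- names(sizes)[1]
  phi_of <- function(lab) {
    idx <- split(seq_len(n), lab)
    sst <- sum(d2) / 2 / n
    ssw <- sum(vapply(idx, function(ii)
      sum(d2[ii, ii]) / 2 / length(ii), numeric(1)))
    dfa <- length(idx) - 1; dfw <- n - length(idx)
    n0 <- (n - sum(lengths(idx)^2) / n) / dfa
    vw <- ssw / dfw
    va <- ((sst - ssw) / dfa - vw) / n0
    va / (va + vw)
  }
  phi_obs <- phi_of(groups)
  sel <- combn(n, sizes[[g1]])
  phis <- apply(sel, 2, function(idx) {
    lab <- rep(names(sizes)[2], n)
    lab[idx] <- g1
    phi_of(lab)
  })
  mean(phis >= phi_obs - 1e-12)
}

# Small deterministic builders -------------------------------------------

# a call_set from a calls data frame
make_call_set <- function(calls, clones, caller = "x") {
  structure(list(caller = caller, calls = calls, clones = clones),
            class = "call_set")
}

# a one-row site observation with controllable evidence
make_obs_row <- function(clone, chrom = "chr01", pos = 100L, ref = "A",
                         alt = "G", dp = 30L, alt_count = 15L,
                         alt_fwd = NULL, ref_fwd = NULL,
                         alt_off = NULL, ref_off = NULL) {
  ref_count <- dp - alt_count
  if (is.null(alt_fwd)) alt_fwd <- alt_count %/% 2
  if (is.null(ref_fwd)) ref_fwd <- ref_count %/% 2
  # both read groups spread evenly over the read by default
  if (is.null(alt_off)) alt_off <- (seq_len(alt_count) * 13) %% 125
  if (is.null(ref_off)) ref_off <- (seq_len(ref_count) * 17) %% 125
  out <- data.frame(clone = clone, chrom = chrom, pos = pos, ref = ref,
                    alt = alt, dp = dp, alt_count = alt_count,
                    ref_fwd = ref_fwd, ref_rev = ref_count - ref_fwd,
                    alt_fwd = alt_fwd, alt_rev = alt_count - alt_fwd)
  out$alt_offsets <- list(alt_off)
  out$ref_offsets <- list(ref_off)
  out
}

make_obs <- function(...) {
  rows <- list(...)
  obs <- do.call(rbind, rows)
  attr(obs, "clones") <- unique(obs$clone)
  obs
}

all_gt_patterns4 <- function() {
  g <- expand.grid(c1 = GTL, c2 = GTL, c3 = GTL, c4 = GTL,
                   stringsAsFactors = FALSE)
  g
}
GTL <- c("hom_ref", "het", "hom_alt")
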