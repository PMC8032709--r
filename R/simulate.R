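#' Simulation configuration
#'
#' Parameters controlling the synthetic clone-resequencing generator. The
#' defaults emulate the study design the package targets: four clones
#' resequenced at ~30x mean depth with 125 bp reads, heterozygous de novo
#' somatic mutations with a transition excess (ts/tv about 4.1), a fraction of
#' mutations chimeric for one meristem cell layer (L1 about 40% of somatic
#' tissue, L2 the remainder, so an L2-confined heterozygous mutation has
#' expected variant-allele frequency 0.5 * 0.6 = 0.3 and an L1-confined one
#' 0.5 * 0.4 = 0.2), and three callers with independent error profiles.
#'
#' @param mu de novo mutation rate, mutations per site per branch-year.
#' @param tstv_ratio expected transitions/transversions ratio of planted
#'   mutations; a mutation is drawn as a transition with probability
#'   `tstv_ratio / (1 + tstv_ratio)`.
#' @param chimeric_l1_fraction fraction of planted mutations confined to the
#'   L1 cell layer.
#' @param chimeric_l2_fraction fraction of planted mutations confined to the
#'   L2 cell layer; the remainder are present in both layers.
#' @param l1_tissue_fraction fraction of somatic tissue derived from L1
#'   (default 0.4, so L2 contributes about 0.6).
#' @param depth_mean mean per-site sequencing depth (Poisson).
#' @param seq_error per-base sequencing error rate.
#' @param founder_het_fraction fraction of sites heterozygous in the founder
#'   genotype; these are the cultivar-level SNPs relative to the (assumed
#'   homozygous-reference) reference genome, and the substrate for
#'   loss-of-heterozygosity events.
#' @param loh_mu loss-of-heterozygosity rate per founder-heterozygous site per
#'   branch-year; an event resolves the site to homozygous reference or
#'   homozygous alternative with equal probability.
#' @param read_length read length in bases (read-position offsets are drawn
#'   uniformly on `0:(read_length - 1)`).
#' @param strand_fwd_prob probability that a read is on the forward strand;
#'   0.5 unless a bias is wanted for testing the strand-bias filter.
#' @param caller_profiles named list of exactly three per-caller error
#'   profiles, each a list with elements `fn` (probability a true variant site
#'   is missed) and `fp` (per-site probability of a spurious private call).
#' @param seed integer seed; every stochastic generator operation derives its
#'   random stream from it, so a fixed seed reproduces the whole simulation.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(mu = 1e-4,
                       tstv_ratio = 4.1,
                       chimeric_l1_fraction = 0.1,
                       chimeric_l2_fraction = 0.2,
                       l1_tissue_fraction = 0.4,
                       depth_mean = 30,
                       seq_error = 0.002,
                       founder_het_fraction = 0.05,
                       loh_mu = 2e-4,
                       read_length = 125,
                       strand_fwd_prob = 0.5,
                       caller_profiles = list(
                         callerA = list(fn = 0.05, fp = 0.01),
                         callerB = list(fn = 0.05, fp = 0.01),
                         callerC = list(fn = 0.05, fp = 0.01)
                       ),
                       seed = 1L) {
  cfg <- list(
    mu = mu, tstv_ratio = tstv_ratio,
    chimeric_l1_fraction = chimeric_l1_fraction,
    chimeric_l2_fraction = chimeric_l2_fraction,
    l1_tissue_fraction = l1_tissue_fraction,
    depth_mean = depth_mean, seq_error = seq_error,
    founder_het_fraction = founder_het_fraction, loh_mu = loh_mu,
    read_length = read_length, strand_fwd_prob = strand_fwd_prob,
    caller_profiles = caller_profiles, seed = seed
  )
  rates <- c(
    chimeric_l1_fraction, chimeric_l2_fraction, l1_tissue_fraction,
    seq_error, founder_het_fraction, strand_fwd_prob,
    unlist(lapply(caller_profiles, function(p) c(p$fn, p$fp)))
  )
  if (any(rates < 0 | rates > 1)) {
    stop_clonediv("all rate parameters must lie in [0, 1]", "invalid_argument")
  }
  if (chimeric_l1_fraction + chimeric_l2_fraction > 1) {
    stop_clonediv("chimeric layer fractions must sum to at most 1",
                  "invalid_argument")
  }
  if (depth_mean <= 0) stop_clonediv("depth_mean must be > 0", "invalid_argument")
  if (tstv_ratio <= 0) stop_clonediv("tstv_ratio must be > 0", "invalid_argument")
  if (mu < 0 || loh_mu < 0) stop_clonediv("mutation rates must be >= 0",
                                          "invalid_argument")
  structure(cfg, class = "sim_config")
}

# local RNG scope: runs expr with a seed derived from the config seed and a
# per-operation offset, restoring the caller's RNG state afterwards
with_sim_seed <- function(config, offset, expr) {
  if (is.null(config$seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(config$seed) + as.integer(offset))
  force(expr)
}

#' Simulate a clone genealogy with two lineages
#'
#' Builds the propagation history of a set of clonal accessions: a founder
#' plant, two divergent propagation lineages (labelled `Ar` and `Fr` for the
#' two sides of the historical transfer), and one terminal branch per clone
#' whose length (in years of clonal propagation) governs how many somatic
#' mutations accumulate on it. With `n_clones = 4` the genealogy reproduces
#' the canonical four-accession design: two long-propagated clones (MB53,
#' MB59, > 70 years) in one lineage and two recently transferred or never
#' transferred clones (C225 < 30 years, C143) in the other.
#'
#' @param n_clones number of clones (>= 2).
#' @param config a [sim_config()].
#' @return An object of class `clone_genealogy`: list with `clones`,
#'   `parent_of` (named vector over non-root nodes), `branch_years` (named,
#'   years on the branch above each non-root node), `lineage_label` (named,
#'   over clones), `root`.
#' @export
simulate_genealogy <- function(n_clones, config = sim_config()) {
  if (!is.numeric(n_clones) || n_clones < 2) {
    stop_clonediv("n_clones must be at least 2", "invalid_argument")
  }
  n_clones <- as.integer(n_clones)
  if (n_clones == 4L) {
    clones <- c("MB53", "MB59", "C225", "C143")
    lineage <- c(MB53 = "Ar", MB59 = "Ar", C225 = "Fr", C143 = "Fr")
    years <- c(MB53 = 75, MB59 = 70, C225 = 30, C143 = 100,
               anc_Ar = 20, anc_Fr = 20)
  } else {
    n_ar <- ceiling(n_clones / 2)
    clones <- c(sprintf("Ar%02d", seq_len(n_ar)),
                sprintf("Fr%02d", seq_len(n_clones - n_ar)))
    lineage <- setNames(substr(clones, 1, 2), clones)
    years <- with_sim_seed(config, 0L, {
      setNames(c(sample(20:100, n_clones, replace = TRUE), 20, 20),
               c(clones, "anc_Ar", "anc_Fr"))
    })
  }
  parent <- setNames(paste0("anc_", lineage), clones)
  parent <- c(parent, anc_Ar = "root", anc_Fr = "root")
  gen <- structure(
    list(clones = clones, parent_of = parent,
         branch_years = years[names(parent)],
         lineage_label = lineage, root = "root"),
    class = "clone_genealogy"
  )
  validate_genealogy(gen)
  gen
}

validate_genealogy <- function(gen) {
  nodes <- names(gen$parent_of)
  if (!all(gen$clones %in% nodes)) {
    stop_clonediv("every clone needs a parent link", "invalid_genealogy")
  }
  roots <- setdiff(unique(gen$parent_of), nodes)
  if (!identical(sort(roots), gen$root)) {
    stop_clonediv("genealogy must have exactly one root", "invalid_genealogy")
  }
  for (n in nodes) { # acyclicity: walking up must terminate at the root
    seen <- character(0); cur <- n
    while (cur != gen$root) {
      if (cur %in% seen) stop_clonediv("parent links form a cycle",
                                       "invalid_genealogy")
      seen <- c(seen, cur)
      cur <- unname(gen$parent_of[cur])
      if (is.na(cur)) stop_clonediv("dangling parent link", "invalid_genealogy")
    }
  }
  if (!all(gen$clones %in% names(gen$lineage_label))) {
    stop_clonediv("every clone needs a lineage label", "invalid_genealogy")
  }
  if (any(gen$branch_years < 0)) {
    stop_clonediv("branch years must be nonnegative", "invalid_genealogy")
  }
  invisible(gen)
}

# clones descending from (and including) a node
clones_under <- function(gen, node) {
  if (node %in% gen$clones) return(node)
  kids <- names(gen$parent_of)[gen$parent_of == node]
  unlist(lapply(kids, clones_under, gen = gen))
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

draw_alleles <- function(n, tstv_ratio) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  is_ts <- runif(n) < tstv_ratio / (1 + tstv_ratio)
  alt <- character(n)
  alt[is_ts] <- TRANSITION[ref[is_ts]]
  if (any(!is_ts)) {
    alt[!is_ts] <- vapply(ref[!is_ts], function(r) {
      sample(setdiff(setdiff(c("A", "C", "G", "T"), r), TRANSITION[r]), 1)
    }, character(1))
  }
  data.frame(ref = ref, alt = alt,
             substitution = ifelse(is_ts, "transition", "transversion"))
}

# map a linear site index onto 19 chromosomes with regularly spaced positions
site_coords <- function(idx, n_chrom = 19L, spacing = 137L) {
  data.frame(chrom = sprintf("chr%02d", ((idx - 1L) %% n_chrom) + 1L),
             pos = ((idx - 1L) %/% n_chrom + 1L) * spacing)
}

#' Plant somatic mutations on a clone genealogy
#'
#' Assigns de novo heterozygous somatic mutations to genealogy branches with a
#' clock-like model (Poisson per branch, rate `mu * branch_years * n_sites`),
#' seeds a configurable fraction of sites as heterozygous in the founder
#' (cultivar-level SNPs), and applies loss-of-heterozygosity events to
#' founder-heterozygous sites at rate `loh_mu`. Mutations on a terminal branch
#' are confined to one clone (single-clone SNVs); mutations on a shared
#' lineage branch appear in all descendant clones (shared SNVs). Each planted
#' mutation is tagged with its cell-layer chimerism (`both`, `L1`, `L2`), its
#' substitution type, and the classification it should receive downstream.
#'
#' @param genealogy a [simulate_genealogy()] result.
#' @param config a [sim_config()].
#' @param n_sites size of the simulated site space (> 0).
#' @return A `truth_table`: data frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `origin` (`founder_het`, `mutation`, `loh`), `layer`,
#'   `substitution`, `class_expected`, `focal` (comma-separated clone ids) and
#'   one `gt_<clone>` column per clone; attributes `clones` and `n_sites`.
#' @export
plant_mutations <- function(genealogy, config = sim_config(), n_sites) {
  if (!is.numeric(n_sites) || n_sites <= 0) {
    stop_clonediv("n_sites must be > 0", "invalid_argument")
  }
  n_sites <- as.integer(n_sites)
  clones <- genealogy$clones
  n_cl <- length(clones)
  with_sim_seed(config, 1L, {
    free <- seq_len(n_sites)

    # founder-heterozygous background (SNPs)
    n_bg <- rbinom(1, n_sites, config$founder_het_fraction)
    bg_sites <- sort(sample(free, n_bg))
    free <- setdiff(free, bg_sites)

    rows <- list()
    if (n_bg > 0) {
      gt <- matrix("het", n_bg, n_cl, dimnames = list(NULL, clones))
      rows[[length(rows) + 1L]] <- data.frame(
        site = bg_sites, origin = "founder_het", layer = "both",
        class_expected = "SNP", focal = "", gt
      )
    }

    branches <- names(genealogy$parent_of)
    # de novo mutations, clock-like per branch
    for (b in branches) {
      lam <- config$mu * genealogy$branch_years[[b]] * n_sites
      n_mut <- rpois(1, lam)
      n_mut <- min(n_mut, length(free))
      if (n_mut == 0) next
      sites <- sort(sample(free, n_mut))
      free <- setdiff(free, sites)
      carriers <- clones_under(genealogy, b)
      gt <- matrix("hom_ref", n_mut, n_cl, dimnames = list(NULL, clones))
      gt[, carriers] <- "het"
      layer <- sample(c("L1", "L2", "both"), n_mut, replace = TRUE,
                      prob = c(config$chimeric_l1_fraction,
                               config$chimeric_l2_fraction,
                               1 - config$chimeric_l1_fraction -
                                 config$chimeric_l2_fraction))
      cls <- if (length(carriers) == 1) "SC_het"
             else if (length(carriers) == 2 && n_cl == 4) "Sh_het"
             else "complex"
      rows[[length(rows) + 1L]] <- data.frame(
        site = sites, origin = "mutation", layer = layer,
        class_expected = cls, focal = paste(sort(carriers), collapse = ","), gt
      )
    }

    # loss of heterozygosity on founder-het sites
    loh_pool <- bg_sites
    for (b in branches) {
      lam <- config$loh_mu * genealogy$branch_years[[b]] * length(bg_sites)
      n_loh <- min(rpois(1, lam), length(loh_pool))
      if (n_loh == 0) next
      sites <- sort(sample(loh_pool, n_loh))
      loh_pool <- setdiff(loh_pool, sites)
      carriers <- clones_under(genealogy, b)
      to_hom_alt <- runif(n_loh) < 0.5
      gt <- matrix("het", n_loh, n_cl, dimnames = list(NULL, clones))
      gt[, carriers] <- ifelse(to_hom_alt, "hom_alt", "hom_ref")
      cls <- if (length(carriers) == 1) {
        ifelse(to_hom_alt, "SC_hom", "SC_ref")
      } else if (length(carriers) == 2 && n_cl == 4) {
        # 2+2 split; focal = the pair carrying the alternative-most state
        ifelse(to_hom_alt, "Sh_hom", "Sh_het")
      } else "complex"
      focal <- if (length(carriers) <= 2) {
        ifelse(to_hom_alt, paste(sort(carriers), collapse = ","),
               paste(sort(setdiff(clones, carriers)), collapse = ","))
      } else ""
      rows[[length(rows) + 1L]] <- data.frame(
        site = sites, origin = "loh", layer = "both",
        class_expected = cls, focal = focal, gt
      )
      # drop LOH'd sites from the founder_het rows' SNP bookkeeping
      rows[[1L]] <- rows[[1L]][!(rows[[1L]]$site %in% sites), , drop = FALSE]
    }

    if (length(rows) == 0 || sum(vapply(rows, nrow, 1L)) == 0) {
      out <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        origin = character(0), layer = character(0),
                        substitution = character(0),
                        class_expected = character(0), focal = character(0))
      for (cl in clones) out[[paste0("gt_", cl)]] <- character(0)
      return(structure(out, clones = clones, n_sites = n_sites,
                       class = c("truth_table", "data.frame")))
    }
    tt <- do.call(rbind, rows)
    tt <- tt[order(tt$site), , drop = FALSE]
    coords <- site_coords(tt$site)
    alle <- draw_alleles(nrow(tt), config$tstv_ratio)
    names(tt)[match(clones, names(tt))] <- paste0("gt_", clones)
    out <- cbind(coords, alle[, c("ref", "alt")],
                 tt[, c("origin", "layer"), drop = FALSE],
                 substitution = alle$substitution,
                 tt[, c("class_expected", "focal",
                        paste0("gt_", clones)), drop = FALSE])
    rownames(out) <- NULL
    structure(out, clones = clones, n_sites = n_sites,
              class = c("truth_table", "data.frame"))
  })
}

#' Simulate read-level evidence at every truth-table site
#'
#' Draws per-clone sequencing evidence for each variant site: total depth
#' (Poisson around `depth_mean`), alternative-read counts (binomial at the
#' genotype's expected variant-allele frequency), per-read strand and
#' read-position offsets. Chimeric heterozygous mutations have their expected
#' VAF scaled by the carrier layer's tissue fraction: `0.5 *
#' (1 - l1_tissue_fraction)` for L2-confined and `0.5 * l1_tissue_fraction`
#' for L1-confined mutations, which is what makes L1-chimeric sites fall below
#' the heterozygous VAF window downstream.
#'
#' @param truth a [plant_mutations()] truth table.
#' @param config a [sim_config()].
#' @return A `site_observations` data frame with one row per clone x site:
#'   `clone`, `chrom`, `pos`, `ref`, `alt`, `dp`, `alt_count`, strand counts
#'   (`ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`) and list columns
#'   `alt_offsets`, `ref_offsets` of 0-based read positions.
#' @export
simulate_read_counts <- function(truth, config = sim_config()) {
  if (is.null(truth) || nrow(truth) == 0) {
    stop_clonediv("truth table is empty", "invalid_argument")
  }
  clones <- attr(truth, "clones")
  with_sim_seed(config, 2L, {
    per_clone <- lapply(clones, function(cl) {
      gt <- truth[[paste0("gt_", cl)]]
      p_alt <- ifelse(gt == "hom_ref", config$seq_error,
               ifelse(gt == "hom_alt", 1 - config$seq_error,
               ifelse(truth$layer == "L1", 0.5 * config$l1_tissue_fraction,
               ifelse(truth$layer == "L2",
                      0.5 * (1 - config$l1_tissue_fraction), 0.5))))
      n <- nrow(truth)
      dp <- rpois(n, config$depth_mean)
      alt <- rbinom(n, dp, p_alt)
      ref <- dp - alt
      alt_fwd <- rbinom(n, alt, config$strand_fwd_prob)
      ref_fwd <- rbinom(n, ref, config$strand_fwd_prob)
      alt_off <- lapply(alt, function(k)
        sample.int(config$read_length, k, replace = TRUE) - 1L)
      ref_off <- lapply(ref, function(k)
        sample.int(config$read_length, k, replace = TRUE) - 1L)
      out <- data.frame(clone = cl, chrom = truth$chrom, pos = truth$pos,
                        ref = truth$ref, alt = truth$alt, dp = dp,
                        alt_count = alt, ref_fwd = ref_fwd,
                        ref_rev = ref - ref_fwd, alt_fwd = alt_fwd,
                        alt_rev = alt - alt_fwd)
      out$alt_offsets <- alt_off
      out$ref_offsets <- ref_off
      out
    })
    obs <- do.call(rbind, per_clone)
    obs <- obs[order(obs$chrom, obs$pos, obs$clone), , drop = FALSE]
    rownames(obs) <- NULL
    structure(obs, clones = clones,
              read_length = config$read_length,
              class = c("site_observations", "data.frame"))
  })
}

#' Simulate three imperfect variant callers
#'
#' Emulates three independent callers genotyping the same clones: each caller
#' reports the true genotypes at truth-table sites but independently misses
#' true sites (its false-negative rate) and injects spurious caller-private
#' het calls at non-variant sites (its per-site false-positive rate). Because
#' false positives are drawn independently per caller over a large site space,
#' they are private to one caller with overwhelming probability, which is what
#' the three-caller intersection exploits.
#'
#' @param truth a [plant_mutations()] truth table (carries the site space size
#'   as an attribute).
#' @param config a [sim_config()] with exactly three `caller_profiles`.
#' @return Named list of three `call_set` objects (see [intersect_callers()]).
#' @export
simulate_callers <- function(truth, config = sim_config()) {
  if (length(config$caller_profiles) != 3) {
    stop_clonediv("exactly three caller profiles are required",
                  "invalid_argument")
  }
  clones <- attr(truth, "clones")
  n_sites <- attr(truth, "n_sites")
  gt_cols <- paste0("gt_", clones)
  truth_sites <- (match(truth$chrom, sprintf("chr%02d", 1:19))) +
    (truth$pos / 137L - 1L) * 19L
  free_sites <- setdiff(seq_len(n_sites), truth_sites)
  with_sim_seed(config, 3L, {
    out <- lapply(names(config$caller_profiles), function(nm) {
      prof <- config$caller_profiles[[nm]]
      keep <- runif(nrow(truth)) >= prof$fn
      calls <- truth[keep, c("chrom", "pos", "ref", "alt", gt_cols)]
      n_fp <- rbinom(1, length(free_sites), prof$fp)
      if (n_fp > 0) {
        fp_sites <- sample(free_sites, n_fp)
        fp <- site_coords(fp_sites)
        fp_all <- draw_alleles(n_fp, config$tstv_ratio)
        gt <- matrix("hom_ref", n_fp, length(clones),
                     dimnames = list(NULL, gt_cols))
        gt[cbind(seq_len(n_fp),
                 sample.int(length(clones), n_fp, replace = TRUE))] <- "het"
        calls <- rbind(calls, cbind(fp, fp_all[, c("ref", "alt")], gt))
      }
      calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
      rownames(calls) <- NULL
      structure(list(caller = nm, calls = calls, clones = clones),
                class = "call_set")
    })
    names(out) <- names(config$caller_profiles)
    out
  })
}

#' Simulate a genotyped cohort drawn from two clonal lineages
#'
#' Generates a samples-by-markers codominant genotype matrix (allele dosage 0,
#' 1, 2 with optional missing entries) for a cohort descending from the two
#' lineages of a clone genealogy. Each lineage has a founder multilocus
#' genotype; the lineages differ at `n_diagnostic` markers (the shared-SNV
#' markers that separate them). Within each lineage a small number of derived
#' multilocus genotypes carry extra private marker mutations, and individual
#' samples can acquire rare singleton mutations, emulating the clonal
#' genotype structure a custom genotyping chip reveals.
#'
#' @param genealogy a [simulate_genealogy()] result (provides the two lineage
#'   labels).
#' @param n_samples_per_lineage samples per lineage (>= 1).
#' @param n_markers number of biallelic markers (>= 4).
#' @param missing_rate per-entry missing probability in `[0, 1)`; a rate of 1
#'   (all entries missing) is rejected as unusable.
#' @param seed integer seed.
#' @param n_diagnostic number of lineage-diagnostic markers (dosage 1 in the
#'   `Ar` founder, 0 in the `Fr` founder).
#' @param private_rate controls within-lineage divergence: 0 suppresses all
#'   derived genotypes and singleton mutations (the cohort then contains
#'   exactly two multilocus genotypes); positive values scale the number of
#'   marker differences carried by derived genotypes.
#' @param n_derived_per_lineage derived multilocus genotypes per lineage.
#' @param singleton_rate per-sample probability of a private singleton
#'   mutation.
#' @return A list of class `chip_cohort`: `genotypes` (integer matrix, NA for
#'   missing), `groups` (named character vector of truth lineage labels),
#'   `founders` (2 x markers dosage matrix).
#' @export
simulate_chip_cohort <- function(genealogy, n_samples_per_lineage = 107,
                                 n_markers = 41, missing_rate = 0,
                                 seed = 1L, n_diagnostic = 4,
                                 private_rate = 0.02,
                                 n_derived_per_lineage = 6,
                                 singleton_rate = 0.02) {
  if (n_markers < 4) stop_clonediv("need at least 4 markers", "invalid_argument")
  if (n_samples_per_lineage < 1) {
    stop_clonediv("need at least 1 sample per lineage", "invalid_argument")
  }
  if (missing_rate < 0 || missing_rate > 1) {
    stop_clonediv("missing_rate must lie in [0, 1]", "invalid_argument")
  }
  if (missing_rate >= 1) {
    stop_clonediv("missing_rate = 1 leaves no usable genotypes",
                  "unusable_matrix")
  }
  lineages <- sort(unique(unname(genealogy$lineage_label)))
  if (length(lineages) != 2) {
    stop_clonediv("genealogy must carry exactly two lineages",
                  "invalid_argument")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  markers <- sprintf("snv%02d", seq_len(n_markers))
  founders <- matrix(0L, 2, n_markers, dimnames = list(lineages, markers))
  founders[1, seq_len(min(n_diagnostic, n_markers))] <- 1L

  profiles <- list()
  for (lg in lineages) {
    profiles[[lg]] <- list(founders[lg, ])
    if (private_rate > 0 && n_derived_per_lineage > 0) {
      for (k in seq_len(n_derived_per_lineage)) {
        p <- founders[lg, ]
        n_flip <- 1L + rpois(1, private_rate * n_markers)
        at <- sample.int(n_markers, min(n_flip, n_markers))
        p[at] <- pmin(p[at] + 1L, 2L)
        profiles[[lg]][[k + 1L]] <- p
      }
    }
  }

  samples <- character(0); groups <- character(0)
  rows <- list()
  for (lg in lineages) {
    k <- length(profiles[[lg]])
    w <- 2^-(seq_len(k) - 1)                       # founder-heavy frequencies
    pick <- sample.int(k, n_samples_per_lineage, replace = TRUE, prob = w)
    for (i in seq_len(n_samples_per_lineage)) {
      p <- profiles[[lg]][[pick[i]]]
      if (private_rate > 0 && runif(1) < singleton_rate) {
        at <- sample.int(n_markers, 1)
        p[at] <- pmin(p[at] + 1L, 2L)
      }
      id <- sprintf("%s_%03d", lg, i)
      samples <- c(samples, id); groups <- c(groups, lg)
      rows[[id]] <- p
    }
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(samples, markers)
  if (missing_rate > 0) {
    m[matrix(runif(length(m)) < missing_rate, nrow(m))] <- NA_integer_
  }
  structure(list(genotypes = m, groups = setNames(groups, samples),
                 founders = founders),
            class = "chip_cohort")
}
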