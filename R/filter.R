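#' Variant retention filter configuration
#'
#' Cut-offs for the stringent site-level retention filter applied after the
#' three-caller intersection: a total-depth window, variant-allele-frequency
#' (VAF) windows defining the homozygous-reference, heterozygous and
#' homozygous-alternative genotype classes (the gaps between windows are
#' `ambiguous` and fail the site), significance levels for the strand-bias and
#' read-position (distance) bias tests, and the per-read edit-distance budget.
#' The heterozygous window `[0.25, 0.75]` deliberately admits L2-chimeric
#' heterozygous mutations (expected VAF about 0.3 when the L1 layer is about
#' 40% of tissue) while excluding most L1-confined ones (expected VAF about
#' 0.2).
#'
#' @param dp_min,dp_max total-depth window (inclusive).
#' @param vaf_ref_max maximum VAF called homozygous reference.
#' @param vaf_het_min,vaf_het_max heterozygous VAF window (inclusive).
#' @param vaf_hom_min minimum VAF called homozygous alternative.
#' @param bias_alpha significance level; sites with strand- or distance-bias
#'   p-value at or below it are discarded.
#' @param edit_per_bases one mismatch allowed per this many bases of read.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(dp_min = 15, dp_max = 150, vaf_ref_max = 0.025,
                          vaf_het_min = 0.25, vaf_het_max = 0.75,
                          vaf_hom_min = 0.95, bias_alpha = 1e-4,
                          edit_per_bases = 25) {
  if (!(0 <= vaf_ref_max && vaf_ref_max < vaf_het_min &&
        vaf_het_min <= vaf_het_max && vaf_het_max < vaf_hom_min &&
        vaf_hom_min <= 1)) {
    stop_clonediv("VAF windows must be ordered: ref < het <= het < hom <= 1",
                  "invalid_argument")
  }
  if (dp_min > dp_max) stop_clonediv("dp_min must not exceed dp_max",
                                     "invalid_argument")
  structure(list(dp_min = dp_min, dp_max = dp_max, vaf_ref_max = vaf_ref_max,
                 vaf_het_min = vaf_het_min, vaf_het_max = vaf_het_max,
                 vaf_hom_min = vaf_hom_min, bias_alpha = bias_alpha,
                 edit_per_bases = edit_per_bases),
            class = "filter_config")
}

#' Read edit-distance filter
#'
#' A read passes when its edit distance to the reference does not exceed one
#' mismatch per `edit_per_bases` nucleotides of query sequence, i.e.
#' `edit_distance <= floor(length / edit_per_bases)`. Vectorised.
#'
#' @param length read length(s) in bases.
#' @param edit_distance read edit distance(s).
#' @param config a [filter_config()].
#' @return Logical vector.
#' @export
read_passes_edit_filter <- function(length, edit_distance,
                                    config = filter_config()) {
  if (any(edit_distance < 0) || any(length < 0)) {
    stop_clonediv("lengths and edit distances must be nonnegative",
                  "invalid_argument")
  }
  length > 0 & edit_distance <= floor(length / config$edit_per_bases)
}

#' Genotype from variant allele frequency
#'
#' Assigns the VAF-window genotype: homozygous reference when
#' `VAF <= vaf_ref_max`, heterozygous when `vaf_het_min <= VAF <= vaf_het_max`,
#' homozygous alternative when `VAF >= vaf_hom_min`, and `ambiguous` in the
#' gap zones between the windows. Vectorised over sites.
#'
#' @param dp total depth(s), must be positive.
#' @param alt_count alternative-allele read count(s).
#' @param config a [filter_config()].
#' @return Character vector over
#'   `c("hom_ref", "het", "hom_alt", "ambiguous")`.
#' @export
assign_vaf_genotype <- function(dp, alt_count, config = filter_config()) {
  if (any(dp <= 0)) stop_clonediv("no coverage: DP must be > 0", "no_coverage")
  vaf <- alt_count / dp
  ifelse(vaf <= config$vaf_ref_max, "hom_ref",
  ifelse(vaf >= config$vaf_hom_min, "hom_alt",
  ifelse(vaf >= config$vaf_het_min & vaf <= config$vaf_het_max,
         "het", "ambiguous")))
}

#' Strand-bias p-value
#'
#' Two-sided Fisher exact test on the 2x2 table of reference/alternative read
#' counts by forward/reverse strand.
#'
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev strand counts, or pass a 2x2 matrix
#'   as `ref_fwd` (rows ref/alt, columns forward/reverse).
#' @return p-value in (0, 1].
#' @export
strand_bias_p <- function(ref_fwd, ref_rev = NULL, alt_fwd = NULL,
                          alt_rev = NULL) {
  tab <- if (is.matrix(ref_fwd)) ref_fwd else {
    matrix(c(ref_fwd, alt_fwd, ref_rev, alt_rev), 2, 2)
  }
  if (any(tab < 0)) stop_clonediv("counts must be nonnegative",
                                  "invalid_argument")
  if (sum(tab) == 0) stop_clonediv("all-zero strand table: test undefined",
                                   "undefined_test")
  fisher.test(tab, alternative = "two.sided")$p.value
}

#' Read-position (distance) bias p-value
#'
#' Two-sided Wilcoxon rank-sum test comparing the within-read positions of
#' alternative-supporting reads against reference-supporting reads. An exact
#' p-value is used for small samples without ties; the normal approximation
#' with continuity correction otherwise.
#'
#' @param alt_offsets,ref_offsets numeric vectors of 0-based read positions
#'   (both non-empty).
#' @return p-value in (0, 1].
#' @export
distance_bias_p <- function(alt_offsets, ref_offsets) {
  if (length(alt_offsets) == 0 || length(ref_offsets) == 0) {
    stop_clonediv("both offset lists must be non-empty", "undefined_test")
  }
  # a completely tied pooled sample carries no positional signal
  if (length(unique(c(alt_offsets, ref_offsets))) == 1) return(1)
  p <- suppressWarnings(
    wilcox.test(alt_offsets, ref_offsets, alternative = "two.sided",
                exact = NULL, correct = TRUE)$p.value
  )
  if (is.nan(p)) 1 else p
}

call_set_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Intersect three callers' call sets
#'
#' Retains only variants reported by all three callers with the same site key
#' (chrom, pos, ref, alt) *and* the same genotype in every clone: consensus
#' means the same variant call, not mere positional overlap. Output rows are
#' ordered by (chrom, pos).
#'
#' @param a,b,c `call_set` objects over the same clones (as produced by
#'   [simulate_callers()] or [read_caller_vcf()]).
#' @return A `call_set` named `"consensus"`.
#' @export
intersect_callers <- function(a, b, c) {
  sets <- list(a, b, c)
  clones <- a$clones
  if (!all(vapply(sets, function(s) identical(sort(s$clones), sort(clones)),
                  logical(1)))) {
    stop_clonediv("call sets cover different clones", "inconsistent_input")
  }
  gt_cols <- paste0("gt_", clones)
  full_key <- function(s) {
    do.call(paste, c(list(call_set_key(s$calls)),
                     s$calls[gt_cols], list(sep = "|")))
  }
  keys <- lapply(sets, full_key)
  keep <- keys[[1]] %in% keys[[2]] & keys[[1]] %in% keys[[3]]
  calls <- a$calls[keep, , drop = FALSE]
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(caller = "consensus", calls = calls, clones = clones),
            class = "call_set")
}

#' Apply site-level retention filters
#'
#' For every site, every clone's observation must satisfy the depth window,
#' fall in a VAF genotype window (not `ambiguous`), and show no significant
#' strand or read-position bias (Fisher exact / rank-sum p-value above
#' `bias_alpha`). A site fails if any clone violates any rule; each failed
#' site carries machine-readable reasons. Sites missing an observation for
#' some clone are flagged `incomplete_site`.
#'
#' @param obs a `site_observations` data frame ([simulate_read_counts()]
#'   layout) covering every clone at every site.
#' @param config a [filter_config()].
#' @return List with `sites` (data frame: chrom, pos, ref, alt, pass,
#'   reasons) and `audit` (per clone x site: dp, vaf, vaf_genotype, p-values,
#'   per-observation reasons).
#' @export
apply_site_filters <- function(obs, config = filter_config()) {
  clones <- attr(obs, "clones") %||% sort(unique(obs$clone))
  n <- nrow(obs)
  dp_ok_lo <- obs$dp >= config$dp_min
  dp_ok_hi <- obs$dp <= config$dp_max
  vaf <- ifelse(obs$dp > 0, obs$alt_count / obs$dp, NA_real_)
  gt <- rep(NA_character_, n)
  gt[obs$dp > 0] <- assign_vaf_genotype(obs$dp[obs$dp > 0],
                                        obs$alt_count[obs$dp > 0], config)
  p_strand <- rep(NA_real_, n)
  p_dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (obs$dp[i] > 0) {
      p_strand[i] <- strand_bias_p(obs$ref_fwd[i], obs$ref_rev[i],
                                   obs$alt_fwd[i], obs$alt_rev[i])
    }
    ao <- obs$alt_offsets[[i]]; ro <- obs$ref_offsets[[i]]
    if (length(ao) > 0 && length(ro) > 0) {
      p_dist[i] <- distance_bias_p(ao, ro)
    }
    # a site with no alt (or no ref) reads in a clone carries no positional
    # signal for that clone; the bias test is inapplicable, not failed
  }
  reason <- character(n)
  add <- function(reason, cond, tag) {
    ifelse(cond, ifelse(nzchar(reason), paste(reason, tag, sep = ","), tag),
           reason)
  }
  reason <- add(reason, obs$dp == 0, "no_coverage")
  reason <- add(reason, obs$dp > 0 & !dp_ok_lo, "depth_low")
  reason <- add(reason, !dp_ok_hi, "depth_high")
  reason <- add(reason, !is.na(gt) & gt == "ambiguous", "vaf_ambiguous")
  reason <- add(reason, !is.na(p_strand) & p_strand <= config$bias_alpha,
                "strand_bias")
  reason <- add(reason, !is.na(p_dist) & p_dist <= config$bias_alpha,
                "distance_bias")

  audit <- data.frame(clone = obs$clone, chrom = obs$chrom, pos = obs$pos,
                      ref = obs$ref, alt = obs$alt, dp = obs$dp, vaf = vaf,
                      vaf_genotype = gt, p_strand = p_strand, p_dist = p_dist,
                      reasons = reason)

  key <- paste(obs$chrom, obs$pos, obs$ref, obs$alt, sep = ":")
  sites <- unique(data.frame(key = key, chrom = obs$chrom, pos = obs$pos,
                             ref = obs$ref, alt = obs$alt))
  agg_reason <- vapply(sites$key, function(k) {
    r <- reason[key == k]
    seen_clones <- obs$clone[key == k]
    miss <- setdiff(clones, seen_clones)
    r <- r[nzchar(r)]
    tags <- unique(unlist(strsplit(r, ",")))
    if (length(miss) > 0) tags <- c(tags, "incomplete_site")
    paste(sort(tags), collapse = ",")
  }, character(1))
  sites$pass <- !nzchar(agg_reason)
  sites$reasons <- agg_reason
  sites <- sites[order(sites$chrom, sites$pos), setdiff(names(sites), "key"),
                 drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites, audit = audit)
}

#' Run the full consensus + site filter stage
#'
#' Convenience wrapper: intersects the three call sets, then applies the site
#' filters to the read-level observations at the retained sites.
#'
#' @param callsets list of three `call_set` objects.
#' @param obs `site_observations` covering the candidate sites.
#' @param config a [filter_config()].
#' @return List with the consensus `call_set` restricted to sites passing all
#'   filters (`retained`), plus `sites` and `audit` from
#'   [apply_site_filters()].
#' @export
consensus_filter <- function(callsets, obs, config = filter_config()) {
  stopifnot(length(callsets) == 3)
  cons <- intersect_callers(callsets[[1]], callsets[[2]], callsets[[3]])
  ckey <- call_set_key(cons$calls)
  okey <- paste(obs$chrom, obs$pos, obs$ref, obs$alt, sep = ":")
  obs_cons <- obs[okey %in% ckey, , drop = FALSE]
  attr(obs_cons, "clones") <- attr(obs, "clones")
  filt <- apply_site_filters(obs_cons, config)
  pass_key <- with(filt$sites[filt$sites$pass, , drop = FALSE],
                   paste(chrom, pos, ref, alt, sep = ":"))
  retained <- cons
  retained$calls <- cons$calls[ckey %in% pass_key, , drop = FALSE]
  rownames(retained$calls) <- NULL
  list(retained = retained, sites = filt$sites, audit = filt$audit)
}
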