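test_that("edit-distance budget is floor(length / 25)", {
  expect_true(read_passes_edit_filter(125, 5))
  expect_false(read_passes_edit_filter(125, 6))
  expect_true(read_passes_edit_filter(24, 0))
  expect_false(read_passes_edit_filter(24, 1))
  expect_false(read_passes_edit_filter(0, 0))
  expect_identical(read_passes_edit_filter(c(125, 125, 50), c(5, 6, 2)),
                   c(TRUE, FALSE, TRUE))
})

test_that("VAF windows assign genotypes with ambiguous gap zones", {
  expect_identical(assign_vaf_genotype(100, 50), "het")
  expect_identical(assign_vaf_genotype(100, 2), "hom_ref")
  expect_identical(assign_vaf_genotype(100, 20), "ambiguous")  # L1 signature
  expect_identical(assign_vaf_genotype(100, 96), "hom_alt")
  # window boundaries are inclusive
  expect_identical(
    assign_vaf_genotype(rep(1000, 6), c(25, 250, 750, 950, 26, 751)),
    c("hom_ref", "het", "het", "hom_alt", "ambiguous", "ambiguous"))
  expect_error(assign_vaf_genotype(0, 0), class = "no_coverage")
})

test_that("strand-bias Fisher p matches exhaustive hypergeometric oracle", {
  expect_equal(strand_bias_p(10, 10, 10, 10), 1.0)
  cases <- list(
    matrix(c(20, 15, 20, 0), 2, 2),
    matrix(c(12, 3, 9, 8), 2, 2),
    matrix(c(5, 0, 5, 9), 2, 2),
    matrix(c(30, 14, 28, 16), 2, 2)
  )
  for (tab in cases) {
    expect_equal(strand_bias_p(tab), oracle_fisher_p(tab), tolerance = 1e-8)
  }
  # doubling balanced counts keeps p at 1
  expect_equal(strand_bias_p(20, 20, 20, 20), 1.0)
  expect_error(strand_bias_p(0, 0, 0, 0), class = "undefined_test")
})

test_that("distance-bias rank-sum p matches exact enumeration oracle", {
  expect_equal(distance_bias_p(5, 5), 1.0)
  expect_equal(distance_bias_p(c(3, 8, 1, 40), c(3, 8, 1, 40)), 1.0,
               tolerance = 0.05)
  x <- c(2, 11, 23, 31); y <- c(5, 17, 29, 37)
  expect_equal(distance_bias_p(x, y), oracle_ranksum_p(x, y),
               tolerance = 1e-8)
  x2 <- c(1, 2, 3, 4); y2 <- c(10, 20, 30, 40)
  expect_equal(distance_bias_p(x2, y2), oracle_ranksum_p(x2, y2),
               tolerance = 1e-8)
  # alt reads clustered at the read start vs uniform ref -> tiny p
  expect_lt(distance_bias_p(seq(0, 5, length.out = 20) + (1:20) * 1e-3,
                            seq(6, 124, length.out = 20)), 1e-4)
  expect_error(distance_bias_p(numeric(0), 1), class = "undefined_test")
})

test_that("caller intersection requires identical calls in every clone", {
  clones <- c("w", "x", "y", "z")
  base <- data.frame(chrom = "chr01", pos = c(100L, 200L, 300L),
                     ref = "A", alt = "G",
                     gt_w = c("het", "hom_ref", "het"),
                     gt_x = "hom_ref", gt_y = "hom_ref", gt_z = "hom_ref")
  a <- make_call_set(base, clones, "a")
  b <- make_call_set(base[c(1, 2), ], clones, "b")      # misses site 3
  c_disagree <- base
  c_disagree$gt_w[2] <- "het"                            # genotype conflict
  cc <- make_call_set(c_disagree, clones, "c")

  out <- intersect_callers(a, b, cc)
  expect_equal(out$calls$pos, 100L)   # site 2 dropped: genotype disagreement
                                      # site 3 dropped: absent from b
  # idempotence and subset property
  self <- intersect_callers(a, a, a)
  expect_identical(self$calls, a$calls)
  expect_true(all(paste(out$calls$chrom, out$calls$pos) %in%
                    paste(base$chrom, base$pos)))
  # commutativity on the retained key set
  out2 <- intersect_callers(cc, b, a)
  expect_identical(out$calls, out2$calls)

  bad <- make_call_set(base, c("w", "x", "y", "QQ"), "bad")
  expect_error(intersect_callers(a, b, bad), class = "inconsistent_input")
})

test_that("site filters flag depth, ambiguous VAF, and bias failures", {
  clones <- c("c1", "c2")
  ok1 <- make_obs_row("c1", pos = 100L, dp = 30L, alt_count = 15L)
  ok2 <- make_obs_row("c2", pos = 100L, dp = 30L, alt_count = 0L)
  shallow <- make_obs_row("c1", pos = 200L, dp = 14L, alt_count = 7L)
  ok3 <- make_obs_row("c2", pos = 200L, dp = 30L, alt_count = 15L)
  chimera <- make_obs_row("c1", pos = 300L, dp = 100L, alt_count = 20L)
  ok4 <- make_obs_row("c2", pos = 300L, dp = 100L, alt_count = 50L)
  # alt reads exclusively forward while ref is balanced
  stranded <- make_obs_row("c1", pos = 400L, dp = 60L, alt_count = 20L,
                           alt_fwd = 20L, ref_fwd = 20L)
  ok5 <- make_obs_row("c2", pos = 400L, dp = 60L, alt_count = 30L)
  # alt reads piled at the read start
  edged <- make_obs_row("c1", pos = 500L, dp = 60L, alt_count = 25L,
                        alt_off = seq(0, 4.8, length.out = 25),
                        ref_off = seq(5, 124, length.out = 35))
  ok6 <- make_obs_row("c2", pos = 500L, dp = 60L, alt_count = 30L)

  obs <- make_obs(ok1, ok2, shallow, ok3, chimera, ok4, stranded, ok5,
                  edged, ok6)
  res <- apply_site_filters(obs)
  s <- res$sites[order(res$sites$pos), ]
  expect_true(s$pass[s$pos == 100])
  expect_false(s$pass[s$pos == 200])
  expect_match(s$reasons[s$pos == 200], "depth_low")
  expect_false(s$pass[s$pos == 300])
  expect_match(s$reasons[s$pos == 300], "vaf_ambiguous")
  expect_false(s$pass[s$pos == 400])
  expect_match(s$reasons[s$pos == 400], "strand_bias")
  expect_false(s$pass[s$pos == 500])
  expect_match(s$reasons[s$pos == 500], "distance_bias")
  # pass/fail partitions the input; every failure carries >= 1 reason
  expect_true(all(nzchar(s$reasons[!s$pass])))
  expect_true(all(!nzchar(s$reasons[s$pass])))

  # a site lacking one clone's observation is incomplete
  res2 <- apply_site_filters(make_obs(ok1, ok2, shallow))
  s2 <- res2$sites
  expect_match(s2$reasons[s2$pos == 200], "incomplete_site")
})

test_that("pass set shrinks as cut-offs tighten", {
  gen <- simulate_genealogy(4, sim_config(seed = 23))
  cfg <- sim_config(seed = 23)
  tt <- plant_mutations(gen, cfg, 4000)
  obs <- simulate_read_counts(tt, cfg)
  base <- apply_site_filters(obs, filter_config())
  tight_dp <- apply_site_filters(obs, filter_config(dp_min = 25, dp_max = 40))
  tight_alpha <- apply_site_filters(obs, filter_config(bias_alpha = 0.05))
  key <- function(r) paste(r$sites$chrom, r$sites$pos)[r$sites$pass]
  expect_true(all(key(tight_dp) %in% key(base)))
  expect_true(all(key(tight_alpha) %in% key(base)))
  expect_lt(length(key(tight_alpha)), length(key(base)))
})

test_that("consensus + filters beat any single caller's raw precision", {
  gen <- simulate_genealogy(4, sim_config(seed = 29))
  cfg <- sim_config(seed = 29, caller_profiles = list(
    a = list(fn = 0.05, fp = 0.02), b = list(fn = 0.08, fp = 0.02),
    c = list(fn = 0.05, fp = 0.03)))
  tt <- plant_mutations(gen, cfg, 10000)
  obs <- simulate_read_counts(tt, cfg)
  cs <- simulate_callers(tt, cfg)
  truth_key <- paste(tt$chrom, tt$pos)
  precision <- function(keys) mean(keys %in% truth_key)
  raw_prec <- vapply(cs, function(s)
    precision(paste(s$calls$chrom, s$calls$pos)), numeric(1))
  filt <- consensus_filter(cs, obs)
  cons_prec <- precision(paste(filt$retained$calls$chrom,
                               filt$retained$calls$pos))
  expect_gte(cons_prec, max(raw_prec))
  expect_equal(cons_prec, 1.0)   # FPs are caller-private, so none survive
})
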