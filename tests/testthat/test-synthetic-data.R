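test_that("genealogy has two lineages, one root, and is seed-reproducible", {
  cfg <- sim_config(seed = 5)
  gen <- simulate_genealogy(4, cfg)
  expect_length(gen$clones, 4)
  expect_equal(sort(as.integer(table(gen$lineage_label))), c(2L, 2L))
  nodes <- names(gen$parent_of)
  expect_setequal(setdiff(unique(gen$parent_of), nodes), "root")
  expect_identical(simulate_genealogy(4, cfg), gen)
  gen7 <- simulate_genealogy(7, cfg)
  expect_identical(simulate_genealogy(7, cfg), gen7)
  expect_length(gen7$clones, 7)
  expect_error(simulate_genealogy(1, cfg), class = "invalid_argument")
})

test_that("zero mutation rates leave clones genotypically identical", {
  gen <- simulate_genealogy(4, sim_config(seed = 2))
  empty_cfg <- sim_config(mu = 0, loh_mu = 0, founder_het_fraction = 0,
                          seed = 2)
  tt <- plant_mutations(gen, empty_cfg, 1000)
  expect_equal(nrow(tt), 0)

  snp_cfg <- sim_config(mu = 0, loh_mu = 0, founder_het_fraction = 0.1,
                        seed = 2)
  tt2 <- plant_mutations(gen, snp_cfg, 1000)
  expect_gt(nrow(tt2), 0)
  expect_true(all(tt2$class_expected == "SNP"))
  gt <- as.matrix(tt2[, paste0("gt_", gen$clones)])
  expect_true(all(gt == gt[, 1]))   # no clone differs from any other
})

test_that("planted ts/tv converges to the configured ratio", {
  gen <- simulate_genealogy(4, sim_config(seed = 3))
  cfg <- sim_config(tstv_ratio = 4.1, founder_het_fraction = 0.3, seed = 3)
  tt <- plant_mutations(gen, cfg, 10000)
  expect_gt(nrow(tt), 2000)
  ratio <- sum(tt$substitution == "transition") /
    sum(tt$substitution == "transversion")
  expect_lt(abs(ratio - 4.1), 0.5)
})

test_that("branch placement fixes the expected classification", {
  gen <- simulate_genealogy(4, sim_config(seed = 11))
  cfg <- sim_config(seed = 11)
  tt <- plant_mutations(gen, cfg, 10000)
  clones <- attr(tt, "clones")
  gt <- as.matrix(tt[, paste0("gt_", clones)])
  colnames(gt) <- clones

  # terminal-branch mutations -> SC_het carried by the focal clone only
  sc <- tt$origin == "mutation" & tt$class_expected == "SC_het"
  expect_gt(sum(sc), 0)
  for (i in which(sc)) {
    expect_identical(unname(sum(gt[i, ] == "het")), 1L)
    expect_identical(names(which(gt[i, ] == "het")), tt$focal[i])
  }

  # shared-branch mutations -> Sh_het carried by exactly a lineage pair
  sh <- tt$origin == "mutation" & tt$class_expected == "Sh_het"
  expect_gt(sum(sh), 0)
  for (i in which(sh)) {
    carriers <- sort(names(which(gt[i, ] == "het")))
    expect_identical(paste(carriers, collapse = ","), tt$focal[i])
    lin <- unique(gen$lineage_label[carriers])
    expect_length(lin, 1)         # a shared branch is within one lineage
  }

  expect_identical(plant_mutations(gen, cfg, 10000), tt)
  expect_error(plant_mutations(gen, cfg, 0), class = "invalid_argument")
})

test_that("read evidence matches the chimeric VAF model", {
  gen <- simulate_genealogy(4, sim_config(seed = 13))
  cfg <- sim_config(chimeric_l1_fraction = 0.3, chimeric_l2_fraction = 0.3,
                    seq_error = 0, founder_het_fraction = 0.02, seed = 13)
  tt <- plant_mutations(gen, cfg, 20000)
  obs <- simulate_read_counts(tt, cfg)
  key_t <- paste(tt$chrom, tt$pos)
  key_o <- paste(obs$chrom, obs$pos)
  clones <- attr(tt, "clones")

  mean_vaf_for <- function(layer) {
    idx <- which(tt$layer == layer & tt$origin == "mutation")
    vals <- unlist(lapply(idx, function(i) {
      carriers <- strsplit(tt$focal[i], ",")[[1]]
      rows <- obs[key_o == key_t[i] & obs$clone %in% carriers, ]
      rows$alt_count / rows$dp
    }))
    mean(vals, na.rm = TRUE)
  }
  expect_lt(abs(mean_vaf_for("both") - 0.5), 0.03)
  expect_lt(abs(mean_vaf_for("L2") - 0.3), 0.03)   # 0.5 * (1 - 0.4)
  expect_lt(abs(mean_vaf_for("L1") - 0.2), 0.03)   # 0.5 * 0.4

  # most L1-chimeric observations fall below the het VAF window at 30x
  l1 <- which(tt$layer == "L1" & tt$origin == "mutation")
  frac_below <- mean(unlist(lapply(l1, function(i) {
    carriers <- strsplit(tt$focal[i], ",")[[1]]
    rows <- obs[key_o == key_t[i] & obs$clone %in% carriers, ]
    rows$alt_count / rows$dp < 0.25
  })))
  expect_gt(frac_below, 0.5)

  expect_identical(simulate_read_counts(tt, cfg), obs)
})

test_that("error-free callers reproduce the truth; FPs are caller-private", {
  gen <- simulate_genealogy(4, sim_config(seed = 17))
  perfect <- sim_config(seed = 17, caller_profiles = list(
    a = list(fn = 0, fp = 0), b = list(fn = 0, fp = 0),
    c = list(fn = 0, fp = 0)))
  tt <- plant_mutations(gen, perfect, 10000)
  cs <- simulate_callers(tt, perfect)
  tt_sorted <- tt[order(tt$chrom, tt$pos), ]   # call sets sort by chrom, pos
  for (s in cs) {
    expect_equal(nrow(s$calls), nrow(tt))
    expect_identical(s$calls$pos, tt_sorted$pos)
    expect_identical(unname(as.list(s$calls[paste0("gt_", gen$clones)])),
                     unname(as.list(tt_sorted[paste0("gt_", gen$clones)])))
  }

  fp_only <- sim_config(seed = 18, mu = 0, loh_mu = 0,
                        founder_het_fraction = 0.01,
                        caller_profiles = list(
                          a = list(fn = 0, fp = 0.01),
                          b = list(fn = 0, fp = 0.01),
                          c = list(fn = 0, fp = 0.01)))
  tt2 <- plant_mutations(gen, fp_only, 10000)
  cs2 <- simulate_callers(tt2, fp_only)
  truth_key <- paste(tt2$chrom, tt2$pos)
  fp_keys <- lapply(cs2, function(s) {
    k <- paste(s$calls$chrom, s$calls$pos)
    setdiff(k, truth_key)
  })
  for (k in fp_keys) expect_lt(abs(length(k) - 100), 40)  # ~ fp * site space
  shared_all <- Reduce(intersect, fp_keys)
  expect_lte(length(shared_all), 1)  # (0.01)^3 x 10^4 ~ 0 shared by three

  expect_error(
    simulate_callers(tt2, sim_config(caller_profiles = list(
      a = list(fn = 0, fp = 0), b = list(fn = 0, fp = 0)))),
    class = "invalid_argument")
})

test_that("chip cohort carries two founder genotypes plus planted structure", {
  gen <- simulate_genealogy(4, sim_config(seed = 19))
  pure <- simulate_chip_cohort(gen, 10, 41, missing_rate = 0,
                               seed = 19, private_rate = 0)
  expect_equal(nrow(unique(pure$genotypes)), 2)
  expect_setequal(unique(pure$groups), c("Ar", "Fr"))
  expect_equal(as.integer(table(pure$groups)[c("Ar", "Fr")]), c(10L, 10L))

  co <- simulate_chip_cohort(gen, 107, 41, missing_rate = 0.01, seed = 19)
  expect_identical(simulate_chip_cohort(gen, 107, 41, missing_rate = 0.01,
                                        seed = 19), co)
  expect_equal(dim(co$genotypes), c(214L, 41L))
  expect_gt(nrow(unique(co$genotypes)), 2)

  expect_error(simulate_chip_cohort(gen, 10, 41, missing_rate = 1, seed = 1),
               class = "unusable_matrix")
  expect_error(simulate_chip_cohort(gen, 10, 2, seed = 1),
               class = "invalid_argument")
})
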