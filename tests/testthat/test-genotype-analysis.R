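test_that("identical profiles collapse; naming is frequency-ranked", {
  m <- rbind(a3 = c(0L, 1L, 0L), a1 = c(0L, 1L, 0L), a2 = c(0L, 1L, 0L),
             b1 = c(2L, 1L, 0L), b2 = c(2L, 1L, 0L),
             solo = c(0L, 0L, 2L))
  colnames(m) <- c("m1", "m2", "m3")
  mlg <- collapse_genotypes(m)
  expect_length(mlg$genotypes, 3)
  names_ <- vapply(mlg$genotypes, function(g) g$name, character(1))
  sizes <- vapply(mlg$genotypes, function(g) length(g$members), integer(1))
  expect_identical(names_, c("A", "B", "solo"))
  expect_identical(sizes, c(3L, 2L, 1L))
  expect_true(mlg$genotypes[[3]]$singleton)
  memb <- mlg_membership(mlg)
  expect_equal(nrow(memb), nrow(m))          # no sample lost or duplicated
  expect_setequal(memb$sample, rownames(m))

  expect_error(collapse_genotypes(m[c(1, 1), ]), class = "invalid_input")
})

test_that("missing entries merge under match_any but not strict", {
  m <- rbind(x = c(0L, 1L, 0L), y = c(0L, 1L, NA), z = c(0L, 1L, 2L))
  colnames(m) <- c("m1", "m2", "m3")
  relaxed <- collapse_genotypes(m, "match_any")
  # y matches x first (input order), so z stays apart
  expect_length(relaxed$genotypes, 2)
  strict <- collapse_genotypes(m, "strict")
  expect_length(strict$genotypes, 3)
})

test_that("hamming steps exclude missing and honour the dosage flag", {
  a <- c(0L, 1L, 2L, 0L, NA)
  b <- c(0L, 2L, 0L, 0L, 1L)
  expect_equal(hamming_steps(a, a), 0)
  expect_equal(hamming_steps(a, b), 2)
  expect_equal(hamming_steps(b, a), hamming_steps(a, b))
  expect_equal(hamming_steps(a, b, dosage_steps = TRUE), 3)  # |1-2| + |2-0|
  expect_error(hamming_steps(a, b[1:3]), class = "invalid_input")
})

test_that("two genotypes give a single direct edge", {
  prof <- rbind(G1 = c(0L, 0L, 0L, 0L), G2 = c(1L, 1L, 0L, 0L))
  net <- median_joining(prof)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$steps, 2)
  expect_false(any(net$is_median))
})

test_that("median vector matches brute-force Steiner search on a triple", {
  prof <- rbind(P = c(1L, 0L, 0L), Q = c(0L, 1L, 0L), R = c(0L, 0L, 1L))
  net <- median_joining(prof)
  expect_equal(sum(net$is_median), 1)
  med <- net$nodes[net$is_median, ]
  best <- oracle_steiner_point(prof)
  expect_equal(unname(med), best$profile)          # the 0,0,0 centre
  # median connected to all three observed at one step each
  mname <- rownames(net$nodes)[net$is_median]
  spokes <- net$edges[net$edges$from == mname | net$edges$to == mname, ]
  expect_equal(nrow(spokes), 3)
  expect_true(all(spokes$steps == 1))
  # total network weight equals the Steiner optimum
  expect_equal(sum(net$edges$steps[net$edges$steps > 0]), best$weight)
})

test_that("epsilon-0 network contains a spanning tree of MST weight", {
  set.seed(97)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    prof <- matrix(sample(0:2, n * 10, replace = TRUE), n, 10)
    rownames(prof) <- sprintf("G%02d", seq_len(n))
    prof <- unique(prof)
    if (nrow(prof) < 3) next
    d <- outer(seq_len(nrow(prof)), seq_len(nrow(prof)),
               Vectorize(function(a, b) sum(prof[a, ] != prof[b, ])))
    want <- oracle_mst_weight(d)
    # pure minimum spanning network (medians disabled)
    net <- median_joining(prof, max_medians = 0L)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = rownames(net$nodes))
    expect_true(igraph::is_connected(g))
    got <- sum(igraph::E(igraph::mst(
      g, weights = igraph::E(g)$steps))$steps)
    expect_equal(got, want)
    # every observed genotype is a node; edge count >= nodes - 1
    expect_true(all(rownames(prof) %in% rownames(net$nodes)))
    expect_gte(nrow(net$edges), nrow(net$nodes) - 1)
  }
})

test_that("median joining keeps observed genotypes connected after pruning", {
  gen <- simulate_genealogy(4, sim_config(seed = 41))
  co <- simulate_chip_cohort(gen, 30, 41, missing_rate = 0, seed = 41)
  mlg <- collapse_genotypes(co$genotypes)
  prof <- mlg_profiles(mlg)
  net <- median_joining(prof)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = rownames(net$nodes))
  expect_true(igraph::is_connected(g))
  obs_names <- rownames(prof)
  expect_true(all(obs_names %in% rownames(net$nodes)))
  # determinism
  expect_identical(median_joining(prof), net)
  expect_error(median_joining(prof[1, , drop = FALSE]),
               class = "invalid_input")
})

test_that("two-lineage cohorts separate across the longest network edges", {
  gen <- simulate_genealogy(4, sim_config(seed = 43))
  co <- simulate_chip_cohort(gen, 50, 41, missing_rate = 0, seed = 43)
  mlg <- collapse_genotypes(co$genotypes)
  prof <- mlg_profiles(mlg)
  net <- median_joining(prof)
  # map each observed genotype to its lineage by its members' truth labels
  lineage_of <- vapply(mlg$genotypes, function(g)
    unique(co$groups[g$members])[1], character(1))
  names(lineage_of) <- vapply(mlg$genotypes, function(g) g$name, character(1))
  cross <- net$edges[
    !net$is_median[net$edges$from] & !net$is_median[net$edges$to] &
      lineage_of[net$edges$from] != lineage_of[net$edges$to], , drop = FALSE]
  within <- net$edges[
    !net$is_median[net$edges$from] & !net$is_median[net$edges$to] &
      lineage_of[net$edges$from] == lineage_of[net$edges$to], , drop = FALSE]
  if (nrow(cross) > 0 && nrow(within) > 0) {
    expect_gt(min(cross$steps), max(1, stats::median(within$steps)))
  } else {
    succeed("lineages linked only through median vectors")
  }
})
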