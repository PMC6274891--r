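# Constructed trees: leaves are points on a line, clustered with complete
# linkage, so the top-level structure is controlled by the coordinates.

test_that("grouped_tree validates labels and group count", {
  hc <- tree_from_coords(c(0, 0.1, 5, 5.1), c("a1", "a2", "b1", "b2"))
  expect_error(grouped_tree(hc, c(a1 = "A", a2 = "A", b1 = "B")),
               "without a group")
  expect_error(grouped_tree(hc, stats::setNames(c("A", "B", "C", "A"),
                                                hc$labels)),
               "exactly two groups")
  gt <- grouped_tree(hc, stats::setNames(c("A", "A", "B", "B"), hc$labels))
  expect_s3_class(gt, "grouped_tree")
})

test_that("CS is 0 for perfect separation and 50 for full interleaving", {
  labels <- c(paste0("a", 1:4), paste0("b", 1:4))
  groups <- stats::setNames(rep(c("A", "B"), each = 4), labels)
  sep <- tree_from_coords(c(0, 0.1, 0.2, 0.3, 9, 9.1, 9.2, 9.3), labels)
  expect_equal(contralaterality_score(grouped_tree(sep, groups)), 0)

  # alternating leaf order: first half {A,B,A,B} -> a = 2 -> CS = 50
  expect_equal(cs_of_order(c("A", "B", "A", "B", "A", "B", "A", "B")), 50)

  mix <- tree_from_coords(c(0, 1, 2, 3, 0.1, 1.1, 2.1, 3.1), labels)
  expect_equal(contralaterality_score(grouped_tree(mix, groups)), 50)
})

test_that("CS refuses unequal group sizes and tiny groups", {
  hc <- tree_from_coords(c(0, 0.1, 0.2, 5), paste0("s", 1:4))
  gt <- grouped_tree(hc, stats::setNames(c("A", "A", "A", "B"), hc$labels))
  expect_error(contralaterality_score(gt), "equal size")
  hc2 <- tree_from_coords(c(0, 5), c("x", "y"))
  gt2 <- grouped_tree(hc2, c(x = "A", y = "B"))
  expect_error(contralaterality_score(gt2), "at least 2")
})

test_that("CS is invariant to group-label swap and mirror flip", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(c(4L, 8L), 1)
    ord <- sample(rep(c("A", "B"), each = n))
    expect_equal(cs_of_order(ord), cs_of_order(rev(ord)))
    swapped <- chartr("AB", "BA", ord)
    expect_equal(cs_of_order(ord), cs_of_order(swapped))
  }
})

test_that("mean CS under uniformly random leaf order matches the hypergeometric value", {
  set.seed(42)
  cs <- replicate(20000, cs_of_order(sample(rep(c("A", "B"), each = 8))))
  # exact E[CS] for n = 8 is ~40.48; MC standard error ~0.09
  expect_lt(abs(mean(cs) - oracle_expected_cs(8)), 0.5)
})

test_that("classify_batch_effect grades constructed trees correctly", {
  lab_a <- paste0("a", 1:8); lab_b <- paste0("b", 1:8)
  groups <- stats::setNames(rep(c("A", "B"), each = 8), c(lab_a, lab_b))

  # top-level separation of the two groups -> b1a
  b1a_tree <- tree_from_coords(c(seq(0, 0.7, 0.1), seq(10, 10.7, 0.1)),
                               c(lab_a, lab_b))
  expect_equal(classify_batch_effect(grouped_tree(b1a_tree, groups)), "b1a")

  # one defector (a8 sits among the Bs) -> b1b
  b1b_tree <- tree_from_coords(c(seq(0, 0.6, 0.1), 10.75,
                                 seq(10, 10.7, 0.1)), c(lab_a, lab_b))
  expect_equal(classify_batch_effect(grouped_tree(b1b_tree, groups)), "b1b")

  # fully interleaved pairs -> es
  es_tree <- tree_from_coords(c(0, 1, 2, 3, 4, 5, 6, 7,
                                0.01, 1.01, 2.01, 3.01, 4.01, 5.01, 6.01,
                                7.01), c(lab_a, lab_b))
  expect_equal(classify_batch_effect(grouped_tree(es_tree, groups)), "es")

  # severity ordering along the constructed sequence
  sev <- c(b1a = 1, b1b = 2, b2a = 3, b2b = 4, es = 5)
  expect_true(sev[["b1a"]] < sev[["b1b"]])

  expect_error(classify_batch_effect(
    grouped_tree(tree_from_coords(c(0, 5), c("x", "y")),
                 c(x = "A", y = "B"))), "at least 4")
})

test_that("depth-2 classes b2a and b2b are detected", {
  # entire group A pure at depth 2, root split impure -> b2a
  lab <- c(paste0("a", 1:4), paste0("b", 1:12))
  groups <- stats::setNames(rep(c("A", "B"), c(4, 12)), lab)
  coords <- c(seq(0, 0.3, 0.1),            # A cluster
              2.0, 2.1, 2.2,               # 3 Bs joining the A side
              seq(10, 10.8, 0.1))          # main B cluster
  b2a_tree <- tree_from_coords(coords, lab)
  expect_equal(classify_batch_effect(grouped_tree(b2a_tree, groups)), "b2a")

  # all-but-one of group A pure at depth 2 -> b2b
  lab2 <- c(paste0("a", 1:3), paste0("b", 1:3), paste0("b", 4:12), "a4")
  groups2 <- stats::setNames(c(rep("A", 3), rep("B", 12), "A"), lab2)
  coords2 <- c(0, 0.1, 0.2, 2.0, 2.1, 2.2, seq(10, 10.8, 0.1), 12)
  b2b_tree <- tree_from_coords(coords2, lab2)
  expect_equal(classify_batch_effect(grouped_tree(b2b_tree, groups2)), "b2b")
})

test_that("largest_pure_subtree matches hand-built trees", {
  lab_a <- paste0("a", 1:8); lab_b <- paste0("b", 1:8)
  groups <- stats::setNames(rep(c("A", "B"), each = 8), c(lab_a, lab_b))
  b1a_tree <- tree_from_coords(c(seq(0, 0.7, 0.1), seq(10, 10.7, 0.1)),
                               c(lab_a, lab_b))
  gt <- grouped_tree(b1a_tree, groups)
  expect_equal(largest_pure_subtree(gt, "A"), 8)
  expect_equal(largest_pure_subtree(gt, "B"), 8)

  # one defector: the pure remainder of its group has 7 leaves
  defect_tree <- tree_from_coords(c(seq(0, 0.6, 0.1), 10.75,
                                    seq(10, 10.7, 0.1)), c(lab_a, lab_b))
  gt2 <- grouped_tree(defect_tree, groups)
  expect_equal(largest_pure_subtree(gt2, "A"), 7)

  # singleton group
  hc <- tree_from_coords(c(0, 0.1, 0.2, 5), paste0("s", 1:4))
  gt3 <- grouped_tree(hc, stats::setNames(c("A", "A", "A", "B"), hc$labels))
  expect_equal(largest_pure_subtree(gt3, "B"), 1)
  expect_error(largest_pure_subtree(gt3, "C"), "unknown group")
})

test_that("spectrum comparison is zero on identity and depth-invariant", {
  set.seed(43)
  a <- count_kmers(random_fastq(300, 50), 3, label = "a")
  sc <- spectrum_comparison(a, a)
  expect_equal(sc$diff, rep(0, 64))
  expect_equal(sc$mean_abs_diff, 0)

  b <- kmer_profile(3, a$counts * 2, label = "b")   # depth change only
  sc2 <- spectrum_comparison(a, b)
  expect_equal(sc2$diff, rep(0, 64))

  expect_error(spectrum_comparison(a, random_profile(2, "c")), "share one k")
})

test_that("a spiked motif dominates the spectrum difference", {
  set.seed(44)
  base <- rpois(64, 500) + 100
  a <- kmer_profile(3, base, label = "a")
  spiked <- base
  m <- motif_index("ACG") + 1
  spiked[m] <- spiked[m] + 5000
  b <- kmer_profile(3, spiked, label = "b")
  sc <- spectrum_comparison(b, a, target_total = sum(base))
  expect_gt(sc$diff[m], 0.5)
  expect_true(all(abs(sc$diff[-m]) < 0.1))
})

test_that("contamination-equivalent accumulation follows its closed form", {
  base <- rep(1000, 64)
  a <- kmer_profile(3, base, label = "a")
  # one motif carrying exactly fraction * total_reads excess -> 1 motif
  excess1 <- base; excess1[5] <- excess1[5] + 300
  sc <- spectrum_comparison(kmer_profile(3, excess1, label = "b"), a,
                            target_total = 1)
  # scaling distorts counts, so build the comparison at equal totals instead
  sc$scaled_a <- excess1; sc$scaled_b <- base
  expect_equal(kmers_to_contamination_fraction(sc, 10000, 0.03), 1)

  # uniform excess e per motif -> ceil(fraction * total_reads / e)
  e <- 25
  sc$scaled_a <- base + e
  expect_equal(kmers_to_contamination_fraction(sc, 10000, 0.03),
               ceiling(0.03 * 10000 / e))

  # identical profiles -> unreachable
  sc$scaled_a <- base
  expect_error(kmers_to_contamination_fraction(sc, 10000, 0.03),
               "unreachable")
})

test_that("null CS distribution is seeded-deterministic", {
  cfg <- sim_config(reads_per_file = 300L, read_length = 50L)
  v1 <- cs_null_distribution(4L, cfg, reps = 4L, seed = 99L)
  v2 <- cs_null_distribution(4L, cfg, reps = 4L, seed = 99L)
  expect_identical(v1, v2)
  expect_true(all(v1 >= 0 & v1 <= 50))
})
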