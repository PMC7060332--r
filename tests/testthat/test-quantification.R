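test_that("pair validity follows the four rules with fixed reason order", {
  pairs <- make_pairs(
    chrom1 = c("chr1", "chr1", "chr1", "chr1", "chr1"),
    pos1 = c(100, 100, 100, 100, 100), strand1 = c("+", "+", "+", "+", "+"),
    chrom2 = c("chr1", "chr2", "chr1", "chr1", "chr2"),
    pos2 = c(400, 400, 600100, 400, 400), strand2 = c("-", "-", "-", "+", "+"),
    mapped2 = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  res <- filter_pairs(pairs)
  expect_equal(res$valid$pair_id, "p001")
  r <- res$stats$rejected_by_reason
  expect_equal(unname(r["different_chromosome"]), 1L)
  expect_equal(unname(r["too_far"]), 1L)               # 600,000 >= 500,000
  expect_equal(unname(r["same_orientation"]), 1L)
  # the half-mapped interchromosomal pair is charged to unmapped first
  expect_equal(unname(r["unmapped"]), 1L)
  # but its mapped mate still counts toward the read denominator
  expect_equal(res$stats$mapped_read_total, 9L)
})

test_that("the 500 kb bound is strict and stats partition all pairs", {
  at_bound <- make_pairs("chr1", 100, "+", "chr1", c(500100, 500099), "-")
  res <- filter_pairs(at_bound)
  expect_equal(res$stats$rejected_by_reason[["too_far"]], 1L)  # exactly 500,000
  expect_equal(res$valid$pos2, 500099L)                        # 499,999 < 500,000
  set.seed(11)
  n <- 500
  rnd <- make_pairs(
    chrom1 = sample(c("chr1", "chr2"), n, TRUE), pos1 = sample(1e6, n),
    strand1 = sample(c("+", "-"), n, TRUE),
    chrom2 = sample(c("chr1", "chr2"), n, TRUE), pos2 = sample(1e6, n),
    strand2 = sample(c("+", "-"), n, TRUE),
    mapped1 = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.95, 0.05)))
  st <- filter_pairs(rnd)$stats
  expect_equal(st$valid_pairs + sum(st$rejected_by_reason), st$total_pairs)
  expect_equal(st$fraction_valid, st$valid_pairs / n)
  empty <- filter_pairs(make_pairs(character(), integer(), character(),
                                   character(), integer(), character()))
  expect_equal(empty$stats$total_pairs, 0L)
  expect_equal(empty$stats$fraction_valid, 0)
})

test_that("pairs are counted once per gene by mate-start containment", {
  models <- make_models(c("gA", "gB"), c("chr1", "chr1"), c("+", "+"),
                        c(201, 201), c(300, 400))
  # mate1 at 250 is inside both terminal exons (overlapping genes)
  one <- make_pairs("chr1", 250, "+", "chr1", 500, "-")
  expect_equal(count_terminal_exons(one, models), c(gA = 1L, gB = 1L))
  # both mates inside gA's exon: still one count
  both <- make_pairs("chr1", 210, "+", "chr1", 290, "-")
  expect_equal(count_terminal_exons(both, models)[["gA"]], 1L)
  # a hand-built pileup: 100 pairs in gA's exon, none elsewhere
  many <- make_pairs("chr1", rep(201:250, 2), "+", "chr1",
                     rep(251:300, 2), "-")
  models2 <- make_models(c("gA", "gC"), c("chr1", "chr1"), c("+", "+"),
                         c(201, 5000), c(300, 5999))
  expect_equal(count_terminal_exons(many, models2),
               c(gA = 100L, gC = 0L))
})

test_that("RPK10M instantiates its formula and is scale-invariant", {
  models <- make_models("g1", "chr1", "+", 1, 2000)  # 2 kb exon
  counts <- matrix(100L, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(compute_rpk10m(counts, models, c(s1 = 1e7))[1, 1], 50)
  expect_equal(compute_rpk10m(counts, models, c(s1 = 2e7))[1, 1], 25)
  expect_equal(compute_rpk10m(counts * 0L, models, c(s1 = 1e7))[1, 1], 0)
  expect_error(compute_rpk10m(counts, models, c(s1 = 0)), "zero mapped")
  # scaling counts and the mapped total together changes nothing
  set.seed(2)
  for (i in 1:25) {
    models_i <- make_models("g", "chr1", "+", 1, sample(200:2000, 1))
    cnt <- matrix(sample(0:500, 1), 1, 1, dimnames = list("g", "s"))
    mt <- c(s = sample(1e5:1e7, 1))
    f <- sample(2:10, 1)
    expect_equal(compute_rpk10m(cnt, models_i, mt),
                 compute_rpk10m(cnt * f, models_i, mt * f))
  }
})

test_that("log transform and the expressed filter apply their boundaries", {
  expect_equal(log_transform(matrix(c(0, 7, 15), 1,
                                    dimnames = list("g", NULL))),
               matrix(c(0, 3, 4), 1, dimnames = list("g", NULL)))
  expect_error(log_transform(matrix(-1)), "negative")
  vals <- rbind(rep(2.9, 12),
                c(rep(0, 9), rep(3.1, 3)),
                rep(3.0, 12),
                rep(5, 12))
  rownames(vals) <- c("low", "one_condition_up", "at_threshold", "high")
  em <- make_em(vals)
  kept <- filter_expressed(em, threshold = 3.0)
  # max condition mean must exceed 3 strictly
  expect_setequal(rownames(kept$values), c("one_condition_up", "high"))
  expect_equal(colnames(kept$values), colnames(em$values))
})

test_that("relative expression ratios normalize to reference and baseline", {
  expect_equal(relative_expression_ratio(c(0.2, 0.4), c(1, 1))[2], 2.0)
  expect_equal(relative_expression_ratio(c(5, 5), c(2, 2)), c(1, 1))
  # reference doubling cancels target doubling
  expect_equal(relative_expression_ratio(c(3, 6), c(2, 4))[2], 1.0)
  expect_error(relative_expression_ratio(c(1, 2), c(0, 1)), "positive")
})
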