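small_design <- function(...) {
  sim_design(n_genes = 80, library_size = 8000, seed = 42, ...)
}

test_that("annotation simulation is valid, non-overlapping and byte-deterministic", {
  g1 <- tempfile(fileext = ".gtf"); g2 <- tempfile(fileext = ".gtf")
  m1 <- simulate_annotation(100, seed = 11, gtf_path = g1)
  m2 <- simulate_annotation(100, seed = 11, gtf_path = g2)
  expect_identical(readLines(g1), readLines(g2))
  expect_equal(nrow(m1), 100L)
  expect_gte(length(unique(m1$chrom)), 2L)
  expect_true(all(m1$terminal_length >= 200 & m1$terminal_length <= 2000))
  # pairwise non-overlap, by sweep within each chromosome
  for (ch in unique(m1$chrom)) {
    sub <- m1[m1$chrom == ch, ]
    spans <- t(vapply(sub$exons, function(e) range(e), numeric(2)))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))
  }
  one <- simulate_annotation(1, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$terminal_end - one$terminal_start + 1L,
               one$terminal_length)
})

test_that("truth tables satisfy the planted inequalities exactly", {
  des <- small_design(frac_hyperA = 0.2, frac_hyperB = 0.1)
  truth <- simulate_truth(des)
  expect_identical(truth, simulate_truth(des))  # determinism
  A <- truth[truth$class == "hyperA", ]
  expect_true(all(A$`mean_NMDA-saline` - A$`mean_non-treat` >= des$effect_log2))
  expect_true(all(A$mean_KUS121 - A$`mean_NMDA-saline` <= -des$effect_log2))
  expect_true(all(A$mean_KUS187 - A$`mean_NMDA-saline` <= -des$effect_log2))
  B <- truth[truth$class == "hyperB", ]
  expect_true(all(B$`mean_NMDA-saline` - B$`mean_non-treat` >= des$effect_log2))
  expect_true(all(B$mean_KUS121 - B$`mean_NMDA-saline` >= des$effect_log2))
  nul <- truth[truth$class == "null", ]
  expect_equal(nul$`mean_non-treat`, nul$mean_KUS187)
  # forced classes and degenerate effect
  all_A <- simulate_truth(sim_design(n_genes = 50, frac_hyperA = 1,
                                     frac_hyperB = 0, seed = 1))
  expect_true(all(all_A$class == "hyperA"))
  flat <- simulate_truth(sim_design(n_genes = 50, frac_hyperA = 0.5,
                                    effect_log2 = 0, seed = 1))
  expect_equal(flat$`mean_NMDA-saline`, flat$`mean_non-treat`)
  # class draw reproducible under the design's generator
  des2 <- sim_design(n_genes = 2000, frac_hyperA = 0.03, frac_hyperB = 0.0075,
                     seed = 7)
  t2 <- simulate_truth(des2)
  set.seed(des2$seed + 1L)
  expected_cls <- sample(c("hyperA", "hyperB", "null"), 2000, replace = TRUE,
                         prob = c(0.03, 0.0075, 1 - 0.03 - 0.0075))
  expect_equal(t2$class, expected_cls)
})

test_that("invalid design fractions are rejected", {
  expect_error(sim_design(frac_hyperA = 0.8, frac_hyperB = 0.3), "sum")
  expect_error(sim_design(invalid_pair_fracs = c(interchromosomal = 0.5,
                                                 same_orientation = 0.4,
                                                 too_far = 0.2)), "below 1")
  expect_error(sim_design(replicates = 1), "replicates")
})

test_that("alignment defects match the manifest exactly and only there", {
  des <- small_design()
  models <- simulate_annotation(des$n_genes, seed = des$seed)
  truth <- simulate_truth(des)
  aln <- simulate_alignments(truth, models, des, tempfile("aln"))
  s <- names(aln$sam_paths)[1]
  pairs <- read_sam_pairs(aln$sam_paths[[s]])
  res <- filter_pairs(pairs)
  man <- aln$manifest[aln$manifest$sample == s, ]
  rejected <- setdiff(pairs$pair_id, res$valid$pair_id)
  expect_setequal(rejected, man$pair_id)
  # and each rejection reason matches the injected defect
  reason_of <- function(ids) {
    sub <- pairs[match(ids, pairs$pair_id), ]
    ifelse(sub$chrom1 != sub$chrom2, "interchromosomal",
           ifelse(sub$strand1 == sub$strand2, "same_orientation", "too_far"))
  }
  expect_equal(unname(reason_of(man$pair_id)), man$defect)
  tallied <- table(man$defect)
  expect_equal(unname(res$stats$rejected_by_reason[["different_chromosome"]]),
               unname(tallied[["interchromosomal"]]))
  expect_equal(unname(res$stats$rejected_by_reason[["too_far"]]),
               unname(tallied[["too_far"]]))
})

test_that("a defect-free design passes the filter completely", {
  des <- sim_design(n_genes = 40, library_size = 5000, seed = 3,
                    invalid_pair_fracs = c(interchromosomal = 0,
                                           same_orientation = 0, too_far = 0))
  models <- simulate_annotation(des$n_genes, seed = des$seed)
  truth <- simulate_truth(des)
  aln <- simulate_alignments(truth, models, des, tempfile("clean"))
  res <- filter_pairs(read_sam_pairs(aln$sam_paths[[1]]))
  expect_equal(res$stats$fraction_valid, 1)
  expect_equal(nrow(aln$manifest), 0L)
})

test_that("injected too_far fraction shows up in the retained fraction", {
  des <- sim_design(n_genes = 40, library_size = 10000, seed = 8,
                    invalid_pair_fracs = c(interchromosomal = 0,
                                           same_orientation = 0,
                                           too_far = 0.1))
  models <- simulate_annotation(des$n_genes, seed = des$seed)
  truth <- simulate_truth(des)
  aln <- simulate_alignments(truth, models, des, tempfile("tf"))
  res <- filter_pairs(read_sam_pairs(aln$sam_paths[[1]]))
  expect_lt(abs(res$stats$fraction_valid - 0.9), 0.02)
})

test_that("expected pair counts scale with planted abundance", {
  des <- sim_design(n_genes = 30, library_size = 20000, seed = 5,
                    noise_sd_log2 = 0,
                    invalid_pair_fracs = c(interchromosomal = 0,
                                           same_orientation = 0, too_far = 0))
  models <- simulate_annotation(des$n_genes, seed = des$seed)
  truth <- simulate_truth(des)
  aln <- simulate_alignments(truth, models, des, tempfile("cnt"))
  q <- quantify_samples(aln$sam_paths, models)
  # per condition, mean log2 RPK10M across genes tracks the true means
  nontreat_cols <- grep("nontreat", colnames(q$counts))
  rpk <- compute_rpk10m(q$counts, models, q$mapped_read_total)
  obs <- rowMeans(log2(rpk[, nontreat_cols] + 1))
  expect_gt(cor(obs, truth$`mean_non-treat`), 0.95)
})

test_that("gene sets plant the promised overlap structure", {
  des <- small_design(frac_hyperA = 0.3)
  truth <- simulate_truth(des)
  gmt <- tempfile(fileext = ".gmt")
  sets <- simulate_genesets(truth, n_sets = 12, planted_set_size = 10,
                            planted_overlap = 6, seed = 2, gmt_path = gmt)
  expect_length(sets, 12L)
  hyperA <- truth$gene_id[truth$class == "hyperA"]
  expect_equal(sum(sets$PLANTED %in% hyperA), 6L)
  expect_equal(read_gmt(gmt), sets[names(sets)], ignore_attr = "planted")
  expect_error(simulate_genesets(truth, planted_set_size = 5,
                                 planted_overlap = 6), "exceeds")
  # saturated planted set equals the hyperA set
  full <- simulate_genesets(truth, n_sets = 3,
                            planted_set_size = length(hyperA),
                            planted_overlap = length(hyperA), seed = 2)
  expect_setequal(as.character(full$PLANTED), hyperA)
})

test_that("the full input bundle is reproducible byte-for-byte", {
  des <- small_design()
  d1 <- tempfile("bundle1"); d2 <- tempfile("bundle2")
  b1 <- simulate_inputs(des, d1, n_sets = 10)
  b2 <- simulate_inputs(des, d2, n_sets = 10)
  for (f in c("annotation.gtf", "genesets.gmt", "truth.tsv", "manifest.tsv",
              "design.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  for (s in basename(b1$sam_paths))
    expect_identical(readLines(file.path(d1, "alignments", s)),
                     readLines(file.path(d2, "alignments", s)))
})
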