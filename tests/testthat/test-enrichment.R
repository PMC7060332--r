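test_that("hypergeometric tail probabilities are exact", {
  res <- hypergeom_test(5, 5, 5, 10)
  expect_equal(res$p_value, 1 / choose(10, 5))
  expect_equal(res$over_representation, 2.0)
  expect_equal(hypergeom_test(0, 5, 5, 10)$p_value, 1.0)
  expect_equal(hypergeom_test(0, 5, 5, 10)$over_representation, 0)
  sat <- hypergeom_test(6, 6, 6, 6)
  expect_equal(sat$p_value, 1.0)
  expect_equal(sat$over_representation, 1.0)
  expect_error(hypergeom_test(6, 5, 6, 10), "invalid")
})

test_that("tail probabilities match brute-force enumeration on a small grid", {
  for (N in c(6, 9)) {
    for (n in c(2, N %/% 2)) {
      for (K in c(1, N %/% 2, N - 1)) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeom_test(k, n, K, N)$p_value,
                       hyper_oracle(k, n, K, N),
                       tolerance = 1e-12,
                       label = sprintf("P(X>=%d) N=%d n=%d K=%d", k, N, n, K))
        }
      }
    }
  }
})

test_that("the tail is monotone non-increasing in the overlap", {
  for (cfg in list(c(10, 8, 20), c(5, 5, 12), c(15, 10, 40))) {
    p <- vapply(0:min(cfg[1], cfg[2]), function(k)
      hypergeom_test(k, cfg[1], cfg[2], cfg[3])$p_value, numeric(1))
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("gene-list enrichment ranks a planted set first", {
  set.seed(31)
  universe <- sprintf("g%04d", 1:2000)
  hyperA <- sample(universe, 60)
  query <- hyperA
  planted <- c(sample(hyperA, 10), sample(setdiff(universe, hyperA), 10))
  sets <- c(list(PLANTED = planted),
            setNames(lapply(1:49, function(i) sample(universe, 20)),
                     sprintf("R%02d", 1:49)))
  tab <- enrich_gene_list(query, sets, universe)
  expect_equal(tab$set_id[which.min(tab$p_value)], "PLANTED")
  expect_lt(tab$p_value[tab$set_id == "PLANTED"], 1e-6)
  # ordering: descending over-representation, then ascending p
  expect_true(all(diff(tab$over_representation) <= 1e-12))
  # disjoint query: all p = 1
  flat <- enrich_gene_list(setdiff(universe, unique(unlist(sets)))[1:30],
                           sets, universe)
  expect_true(all(flat$p_value == 1))
  # duplicate query genes are de-duplicated
  dup <- enrich_gene_list(c(query, query), sets, universe)
  expect_equal(dup$n[1], length(query))
  expect_warning(enrich_gene_list(c(query, "not_in_universe"), sets, universe),
                 "outside the universe")
})

test_that("null query p-values are super-uniform and reject at about alpha", {
  set.seed(32)
  universe <- sprintf("g%04d", 1:500)
  one_set <- list(S = sample(universe, 50))
  p <- replicate(2000, {
    suppressWarnings(
      enrich_gene_list(sample(universe, 40), one_set, universe)$p_value)
  })
  # discreteness makes the p distribution stochastically dominate uniform
  for (q in c(0.05, 0.2, 0.5)) expect_lte(mean(p <= q), q + 3 * sqrt(q / 2000))
  expect_lte(mean(p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("pathway screens intersect into restoration reports", {
  universe <- sprintf("g%03d", 1:200)
  # four planted "restored up" pathways share genes with all three lists;
  # one decoy pathway is significant in only two comparisons
  planted <- lapply(1:4, function(i) universe[(i * 10):(i * 10 + 9)])
  names(planted) <- paste0("WP", 1:4)
  decoy <- list(DECOY = universe[151:160])
  pathways <- c(planted, decoy)
  down_inj <- universe[10:60]          # hits all four planted + not decoy
  up_121 <- c(universe[10:60], universe[151:160])
  up_187 <- c(universe[10:60], universe[151:160])
  lists <- list(
    `down_NMDA-saline_vs_non-treat` = down_inj,
    `up_KUS121_vs_NMDA-saline` = up_121,
    `up_KUS187_vs_NMDA-saline` = up_187,
    `up_NMDA-saline_vs_non-treat` = character(0),
    `down_KUS121_vs_NMDA-saline` = character(0),
    `down_KUS187_vs_NMDA-saline` = character(0))
  screens <- pathway_screen(lists, pathways, universe, alpha = 0.05)
  expect_setequal(screens$`down_NMDA-saline_vs_non-treat`$significant,
                  paste0("WP", 1:4))
  rep <- intersect_common_pathways(screens)
  expect_setequal(rep$restored_up$set_id, paste0("WP", 1:4))
  expect_equal(nrow(rep$restored_down), 0L)
  expect_true(all(c("p_K121", "p_K187", "p_injury",
                    "matched_K121", "matched_K187", "matched_injury")
                  %in% colnames(rep$restored_up)))
  # a pathway significant in two of three screens is excluded
  expect_true("DECOY" %in% screens$`up_KUS121_vs_NMDA-saline`$significant)
  expect_false("DECOY" %in% rep$restored_up$set_id)
  # empty gene list yields no significant pathways
  expect_length(screens$`up_NMDA-saline_vs_non-treat`$significant, 0L)
})
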