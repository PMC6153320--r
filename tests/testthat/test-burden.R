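test_that("gene-set enrichment reproduces the enumeration oracle on a toy table", {
  # build gene sets realizing the 2x2 table [[4,1],[2,8]]
  query <- paste0("q", 1:5)
  bg <- paste0("b", 1:10)
  universe <- c(query, bg)
  set <- c(paste0("q", 1:4), paste0("b", 1:2))   # a=4, c=2
  res <- fisher_gene_set_enrichment(query, list(toy = set), universe)
  expect_equal(unlist(res[c("a", "b", "c", "d")], use.names = FALSE),
               c(4L, 1L, 2L, 8L))
  expect_equal(res$odds_ratio, 16)
  expect_equal(res$p_value, fisher_oracle(4, 1, 2, 8), tolerance = 1e-12)
  expect_equal(res$n_overlap, 4L)
})

test_that("enrichment directions behave at the extremes", {
  universe <- paste0("g", 1:200)
  strong <- paste0("g", 1:20)
  res <- fisher_gene_set_enrichment(strong, list(self = strong), universe)
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p_value, 1e-6)
  # under-represented overlap (4 observed vs 8 expected) points below 1
  res2 <- fisher_gene_set_enrichment(paste0("g", 1:40),
                                     list(under = c(paste0("g", 1:4),
                                                    paste0("g", 41:76))),
                                     universe)
  expect_lte(res2$odds_ratio, 1)
  # fully disjoint sets: empty overlap cell triggers the Haldane correction,
  # which is flag-reported through the table cells themselves
  res3 <- fisher_gene_set_enrichment(paste0("g", 1:5),
                                     list(far = paste0("g", 100:104)), universe)
  expect_equal(res3$a, 0L)
  expect_equal(res3$odds_ratio,
               (0.5 * (res3$d + 0.5)) / ((res3$b + 0.5) * (res3$c + 0.5)))
})

test_that("enrichment validates inputs and applies correction across the collection", {
  universe <- paste0("g", 1:100)
  expect_error(fisher_gene_set_enrichment(character(), list(s = "g1"), universe),
               "empty query")
  expect_error(fisher_gene_set_enrichment("g1", list(s = "g1"), character()),
               "empty universe")
  expect_warning(
    res <- fisher_gene_set_enrichment(c("g1", "g2", "NOT_THERE"),
                                      list(s = c("g1", "g3")), universe),
    "outside universe")
  sets <- list(a = paste0("g", 1:10), b = paste0("g", 11:30),
               c = paste0("g", 31:35))
  res <- fisher_gene_set_enrichment(paste0("g", 1:12), sets, universe)
  expect_equal(res$p_corrected, p.adjust(res$p_value, "BH"))
  # corrected p never smaller than raw, monotone with raw p
  expect_true(all(res$p_corrected >= res$p_value - 1e-15))
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_corrected[ord]) >= -1e-15))
  bonf <- fisher_gene_set_enrichment(paste0("g", 1:12), sets, universe,
                                     correction = "bonferroni")
  expect_equal(bonf$p_corrected, pmin(bonf$p_value * 3, 1))
})

test_that("Fisher p is invariant under table transposition; OR is exact cross-product", {
  for (tab in list(c(4, 1, 2, 8), c(3, 7, 5, 2), c(10, 4, 6, 12))) {
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    p1 <- fisher.test(matrix(c(a, c, b, d), 2))$p.value
    p2 <- fisher.test(t(matrix(c(a, c, b, d), 2)))$p.value
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_equal(dnmrisk:::sample_odds_ratio(a, b, c, d), a * d / (b * c))
  }
  # Haldane correction on an empty cell
  expect_equal(dnmrisk:::sample_odds_ratio(0, 5, 3, 7),
               (0.5 * 7.5) / (5.5 * 3.5))
})

test_that("intolerance burden uses the derived flags over the annotated universe", {
  ann <- intolerance_flags(data.frame(
    gene = paste0("g", 1:40),
    rvis_percentile = c(rep(10, 10), rep(80, 30)),
    pli = c(rep(0.99, 10), rep(0.1, 30))))
  # query all hot-zone, background none
  res <- intolerance_burden(paste0("g", 1:10), ann)
  hz <- res[res$set == "hot_zone", ]
  expect_equal(hz$a, 10L)
  expect_equal(hz$c, 0L)
  expect_gt(hz$odds_ratio, 1)
  expect_lt(hz$p_value, 1e-6)
  # unannotated genes are excluded with a message
  expect_message(
    intolerance_burden(c("g1", "g2", "UNKNOWN"), ann),
    "unannotated")
})

test_that("module mutation burden builds the 2x2s per level with M1/M2 orientation", {
  counts <- count_extreme_by_gene(dnm_rows(
    # M1 genes: 30 LoF across 3 genes, 5 DMis
    do.call(rbind, lapply(1:30, function(i)
      dnm_row(sample_id = paste0("sL", i), gene = paste0("m1_", 1 + i %% 3),
              variant_class = "stopgain"))),
    do.call(rbind, lapply(1:5, function(i)
      dnm_row(sample_id = paste0("sD", i), gene = "m1_1",
              variant_class = "missense", damaging_votes = 9L))),
    # M2 genes: 5 LoF, 15 DMis
    do.call(rbind, lapply(1:5, function(i)
      dnm_row(sample_id = paste0("tL", i), gene = paste0("m2_", 1 + i %% 2),
              variant_class = "frameshift_indel"))),
    do.call(rbind, lapply(1:15, function(i)
      dnm_row(sample_id = paste0("tD", i), gene = paste0("m2_", 1 + i %% 2),
              variant_class = "missense", damaging_votes = 10L)))))
  labels <- c(m1_1 = 1L, m1_2 = 1L, m1_3 = 1L, m2_1 = 2L, m2_2 = 2L)
  res <- module_mutation_burden(counts, labels)
  expect_equal(nrow(res), 6)
  dnm_lof <- res[res$level == "dnm" & res$class == "LoF", ]
  expect_equal(dnm_lof$m1_count, 30L)
  expect_equal(dnm_lof$odds_ratio, (30 * 15) / (5 * 5))
  expect_equal(dnm_lof$p_value, fisher_oracle(30, 5, 5, 15), tolerance = 1e-10)
  # DMis odds ratio at the same level is the reciprocal
  dnm_dmis <- res[res$level == "dnm" & res$class == "DMis", ]
  expect_equal(dnm_dmis$odds_ratio, 1 / dnm_lof$odds_ratio)
  # row counts reconcile exactly with the count table restricted to modules
  m1 <- counts[counts$gene %in% names(labels)[labels == 1], ]
  expect_equal(dnm_lof$m1_count, sum(m1$n_lof))
  gene_lof <- res[res$level == "gene" & res$class == "LoF", ]
  expect_equal(gene_lof$m1_count, sum(m1$n_lof > 0))
})

test_that("identical class composition gives OR 1, p 1; samples count once", {
  counts <- count_extreme_by_gene(dnm_rows(
    dnm_row(sample_id = "s1", gene = "a", variant_class = "stopgain"),
    dnm_row(sample_id = "s2", gene = "a", variant_class = "missense",
            damaging_votes = 9L),
    dnm_row(sample_id = "s3", gene = "b", variant_class = "stopgain"),
    dnm_row(sample_id = "s4", gene = "b", variant_class = "missense",
            damaging_votes = 9L)))
  res <- module_mutation_burden(counts, c(a = 1L, b = 2L))
  expect_equal(res$odds_ratio[res$level == "dnm"], c(1, 1))
  expect_equal(res$p_value[res$level == "dnm"], c(1, 1))

  # one sample carrying 3 LoF DNMs in the same module counts once
  counts2 <- count_extreme_by_gene(dnm_rows(
    dnm_row(sample_id = "multi", gene = "a", variant_class = "stopgain", pos = 1L),
    dnm_row(sample_id = "multi", gene = "a", variant_class = "stopgain", pos = 2L),
    dnm_row(sample_id = "multi", gene = "a", variant_class = "stoploss", pos = 3L),
    dnm_row(sample_id = "s9", gene = "b", variant_class = "stopgain")))
  res2 <- module_mutation_burden(counts2, c(a = 1L, b = 2L))
  sample_lof <- res2[res2$level == "sample" & res2$class == "LoF", ]
  expect_equal(sample_lof$m1_count, 1L)
  expect_true(sample_lof$haldane)   # zero DMis margins flagged
})
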