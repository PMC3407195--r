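test_that("common gene set is the sorted intersection", {
  expect_equal(common_gene_set(c("A", "B", "C"), c("D", "C", "B")),
               c("B", "C"))
  expect_equal(common_gene_set(c("b", "a"), c("a", "b")), c("a", "b"))
  expect_error(common_gene_set(c("A"), c("B")), "do not intersect")
})

make_calls <- function(gene_id, expressed, condition = "WT") {
  data.frame(gene_id = gene_id, condition = condition,
             mean_expression = ifelse(expressed, 500, 10),
             expressed = expressed, stringsAsFactors = FALSE)
}

test_that("contingency table counts the four binding/expression cells", {
  prof <- toy_profile(c("a", "b", "c", "d"), n_bound = c(1L, 2L, 0L, 0L))
  calls <- make_calls(c("a", "b", "c", "d"), c(TRUE, FALSE, TRUE, FALSE))
  tab <- bound_by_expressed_table(prof, calls, "WT")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1L, 1L, 1L, 1L))
  expect_equal(tab$n, 4L)

  # all bound and expressed
  prof2 <- toy_profile(c("a", "b"), n_bound = c(1L, 1L))
  tab2 <- bound_by_expressed_table(prof2, make_calls(c("a", "b"), c(TRUE, TRUE)),
                                   "WT")
  expect_equal(c(tab2$a, tab2$b, tab2$c, tab2$d), c(2L, 0L, 0L, 0L))
})

test_that("toy 20-gene contingency equals hand enumeration", {
  set.seed(111)
  genes <- sprintf("g%02d", 1:20)
  bound <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  expressed <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  prof <- toy_profile(genes, n_bound = ifelse(bound, 1L, 0L))
  tab <- bound_by_expressed_table(prof, make_calls(genes, expressed), "WT")
  expect_equal(tab$a, sum(bound & expressed))
  expect_equal(tab$b, sum(bound & !expressed))
  expect_equal(tab$c, sum(!bound & expressed))
  expect_equal(tab$d, sum(!bound & !expressed))
  expect_equal(tab$a + tab$b + tab$c + tab$d, 20L)
})

test_that("odds ratio and Wald CI reproduce the published WT table", {
  res <- odds_ratio_ci(c(4171, 304, 4484, 3860), ci_level = 0.99)
  expect_equal(round(res$odds_ratio, 1), 11.8)
  expect_equal(round(res$ci_low, 1), 10.0)
  expect_equal(round(res$ci_high, 1), 13.9)
  expect_lt(res$p_exact, 2.2e-16)
  expect_false(res$haldane)
})

test_that("odds ratio reproduces the published TG table", {
  res <- odds_ratio_ci(c(2883, 275, 5669, 3962), ci_level = 0.99)
  expect_equal(round(res$odds_ratio, 1), 7.3)
  expect_lt(res$p_exact, 2.2e-16)
})

test_that("symmetric table gives OR 1 and exact p 1", {
  res <- odds_ratio_ci(c(10, 10, 10, 10))
  expect_equal(res$odds_ratio, 1)
  expect_lt(res$ci_low, 1)
  expect_gt(res$ci_high, 1)
  expect_equal(res$p_exact, 1)
  expect_equal(res$p_exact, fisher_oracle(10, 10, 10, 10))
})

test_that("odds-ratio invariants hold", {
  # column swap inverts the OR
  r1 <- odds_ratio_ci(c(12, 5, 7, 20))
  r2 <- odds_ratio_ci(c(5, 12, 20, 7))
  expect_equal(r1$odds_ratio * r2$odds_ratio, 1, tolerance = 1e-12)
  # CI shrinks with lower confidence and always brackets the OR
  for (lvl in c(0.99, 0.95, 0.9)) {
    r <- odds_ratio_ci(c(12, 5, 7, 20), ci_level = lvl)
    expect_lt(r$ci_low, r$odds_ratio)
    expect_gt(r$ci_high, r$odds_ratio)
  }
  w99 <- odds_ratio_ci(c(12, 5, 7, 20), 0.99)
  w90 <- odds_ratio_ci(c(12, 5, 7, 20), 0.90)
  expect_lt(w90$ci_high - w90$ci_low, w99$ci_high - w99$ci_low)
  # zero cell triggers the flagged Haldane correction
  rh <- odds_ratio_ci(c(5, 0, 3, 4))
  expect_true(rh$haldane)
  expect_true(is.finite(rh$odds_ratio))
  # chi-square alternative is available
  rc <- odds_ratio_ci(c(12, 5, 7, 20), method = "chisq")
  expect_equal(rc$odds_ratio, r1$odds_ratio)
  expect_false(identical(rc$p_exact, r1$p_exact))
})

test_that("Fisher p matches exhaustive enumeration on small tables", {
  set.seed(121)
  for (i in 1:40) {
    cells <- as.vector(rmultinom(1, sample(4:12, 1), runif(4, 0.1, 1)))
    res <- odds_ratio_ci(cells)
    expect_equal(res$p_exact,
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("fraction of bound genes expressed reproduces printed percents", {
  wt <- fraction_bound_expressed(c(4171, 304, 4484, 3860))
  expect_equal(wt$display, 93)
  expect_equal(wt$raw, 100 * 4171 / 4475, tolerance = 1e-12)
  tg <- fraction_bound_expressed(c(2883, 275, 5669, 3962))
  expect_equal(tg$display, 91)
  expect_equal(fraction_bound_expressed(c(0, 5, 3, 2))$raw, 0)
  expect_false(fraction_bound_expressed(c(0, 0, 3, 2))$defined)
})

test_that("signature-by-expression cross-tab conserves marginals", {
  prof <- toy_profile("a", n_bound = 1L)
  prof$signature <- "Inside"
  tab <- signature_by_expression(prof, make_calls("a", TRUE), "WT")
  expect_equal(tab$expressed, 1L)
  expect_equal(tab$not_expressed, 0L)

  study <- small_study(seed = 43, n_genes = 150)
  res <- run_pipeline(study$probes, study$annotation, study$expression,
                      run_config(seed = 43))
  sx <- res$signature_by_expression$WT
  cen <- res$signatures$WT
  m <- match(cen$signature, sx$signature)
  expect_equal(sx$expressed[m] + sx$not_expressed[m], cen$n_genes)
  expect_equal(sum(sx$expressed + sx$not_expressed),
               sum(res$profiles$WT$n_bound >= 1L))
})

test_that("DE-by-differential-acetylation counts and aggregate share", {
  de <- data.frame(gene_id = c("a", "b", "c"),
                   fold_change = c(2, 2, 1),
                   direction = c(-1, -1, 0), p_value = c(0.01, 0.01, 0.9),
                   de_status = c("DOWN", "DOWN", "UNCHANGED"),
                   stringsAsFactors = FALSE)
  rec <- data.frame(gene_id = c("a", "b", "c"),
                    n_wt_bound = c(2L, 0L, 0L), n_tg_bound = c(1L, 0L, 0L),
                    score = c(-1, 0, 0),
                    category = c("HYPOACETYLATED_IN_TG", "NOT_ACETYLATED",
                                 "NOT_ACETYLATED"),
                    stringsAsFactors = FALSE)
  tab <- de_by_diffacet(de, rec)
  share <- attr(tab, "decreased_acetylation_share")
  expect_equal(unname(share["DOWN"]), 50)
  down <- tab[tab$de_status == "DOWN", ]
  expect_equal(sum(down$n_genes), 2L)

  # no DE genes: empty result with a warning
  de0 <- de
  de0$de_status <- "UNCHANGED"
  expect_warning(tab0 <- de_by_diffacet(de0, rec), "no differentially")
  expect_equal(nrow(tab0), 0L)
})

test_that("expression changes stay decoupled from acetylation loss", {
  # generator property: among truly DE-down genes, the share with
  # decreased acetylation should match its unconditional share
  study <- simulate_study(sim_params(n_genes = 4000, seed = 53,
                                     de_fraction = 0.2))
  res <- run_pipeline(study$probes, study$annotation, study$expression,
                      run_config(seed = 53))
  rec <- res$diffacet
  dec <- rec$category %in% c("HYPOACETYLATED_IN_TG", "NOT_ACETYLATED_IN_TG")
  # reference population: WT-expressed genes (DE genes are drawn there)
  ec <- res$expression_calls
  expressed_wt <- ec$gene_id[ec$condition == "WT" & ec$expressed]
  p0 <- mean(dec[rec$gene_id %in% expressed_wt])
  down_genes <- res$de_calls$gene_id[res$de_calls$de_status == "DOWN"]
  p_down <- mean(dec[rec$gene_id %in% down_genes])
  n_down <- length(down_genes)
  expect_gt(n_down, 50)
  expect_lt(abs(p_down - p0), 3 * sqrt(p0 * (1 - p0) / n_down))
})
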