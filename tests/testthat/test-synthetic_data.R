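test_that("simulation is deterministic given a seed", {
  s1 <- simulate_study(sim_params(n_genes = 80, seed = 21))
  s2 <- simulate_study(sim_params(n_genes = 80, seed = 21))
  expect_identical(s1, s2)
  s3 <- simulate_study(sim_params(n_genes = 80, seed = 22))
  expect_false(identical(s1$probes, s3$probes))
})

test_that("annotation respects chromosome weights and placement rules", {
  n_chr <- length(acechip:::MOUSE_CHROM_LENGTHS)
  params <- sim_params(
    n_genes = 2000, seed = 13,
    chrom_weights = rep(1 / n_chr, n_chr)
  )
  ann <- simulate_annotation(params)
  expect_equal(nrow(ann), 2000L)
  expect_setequal(unique(ann$strand), c("+", "-"))

  # uniform weights: per-chromosome counts within 3 binomial SD
  counts <- table(factor(ann$chromosome,
                         levels = names(acechip:::MOUSE_CHROM_LENGTHS)))
  expected <- 2000 / n_chr
  sd3 <- 3 * sqrt(2000 * (1 / n_chr) * (1 - 1 / n_chr))
  expect_true(all(abs(counts - expected) <= sd3))

  # transcription orientation: minus-strand genes have tss > tes
  expect_true(all(ann$tss[ann$strand == "+"] < ann$tes[ann$strand == "+"]))
  expect_true(all(ann$tss[ann$strand == "-"] > ann$tes[ann$strand == "-"]))

  # probe windows overlap only for divergent (opposite-strand) neighbours
  win <- acechip:::gene_window(ann, params)
  for (chr in unique(ann$chromosome)) {
    w <- win[ann$chromosome == chr, ]
    st <- ann$strand[ann$chromosome == chr]
    ord <- order(w$start)
    w <- w[ord, ]; st <- st[ord]
    overlapping <- which(w$start[-1] < w$end[-nrow(w)])
    if (length(overlapping) > 0L) {
      expect_true(all(st[overlapping] != st[overlapping + 1L]))
    }
  }

  # single gene on one chromosome fits
  one <- simulate_annotation(sim_params(
    n_genes = 1, seed = 1, chrom_lengths = c(chr1 = 1e6),
    chrom_weights = 1
  ))
  expect_equal(nrow(one), 1L)
  expect_true(one$tss + 5500 <= 1e6)

  # chromosome too short for the density
  expect_error(
    simulate_annotation(sim_params(
      n_genes = 100, seed = 1, chrom_lengths = c(chr1 = 1e5),
      chrom_weights = 1
    )),
    "too short"
  )
})

test_that("probe tiling hits the target density with 60-mer probes", {
  params <- sim_params(n_genes = 400, seed = 17, frac_unknown_probes = 0)
  ann <- simulate_annotation(params)
  probes <- simulate_probes(ann, params)
  expect_true(all(probes$end - probes$start == 60L))
  counts <- table(factor(probes$gene_id, levels = ann$gene_id))
  expect_true(all(counts >= 12 & counts <= 55))
  expect_lt(abs(mean(counts) - params$probes_per_gene),
            0.1 * params$probes_per_gene)
  expect_false(anyDuplicated(probes$probe_id) > 0)
})

test_that("probe types follow the location rules", {
  params <- sim_params(n_genes = 10, seed = 1)
  ann <- data.frame(
    gene_id = c("plus", "minus", "divA", "divB"),
    chromosome = c("chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "-", "-", "+"),
    tss = c(100000L, 300000L, 50000L, 52000L),
    tes = c(110000L, 290000L, 44000L, 60000L),
    stringsAsFactors = FALSE
  )
  probe_at <- function(mid, gene, chr = "chr1") {
    data.frame(probe_id = "p", gene_id = gene, chromosome = chr,
               start = as.integer(mid - 30), end = as.integer(mid + 30),
               stringsAsFactors = FALSE)
  }
  cls <- function(mid, gene, chr = "chr1") {
    classify_probe_type(probe_at(mid, gene, chr), ann, params)
  }
  # plus strand: upstream window (TSS-5500, TSS) is Promoter
  expect_equal(cls(100000 - 100, "plus"), "Promoter")
  # boundary: midpoint exactly at the TSS is Inside (declared tie rule)
  expect_equal(cls(100000, "plus"), "Inside")
  expect_equal(cls(105000, "plus"), "Inside")
  expect_equal(cls(110000 + 1000, "plus"), "Downstream")
  expect_equal(cls(110000 + 2500 + 200, "plus"), "Unknown")
  # beyond the upstream window
  expect_equal(cls(100000 - 6000, "plus"), "Unknown")
  # minus strand: upstream is at higher coordinates
  expect_equal(cls(300000 + 100, "minus"), "Promoter")
  expect_equal(cls(295000, "minus"), "Inside")
  expect_equal(cls(290000 - 1000, "minus"), "Downstream")
  # no gene link
  expect_equal(cls(100, NA_character_), "Unknown")
  # divergent pair: shared upstream region between the two TSSs
  expect_equal(cls(51000, "divA", "chr2"), "DivergentPromoter")
  expect_equal(cls(51000, "divB", "chr2"), "DivergentPromoter")
  # divB promoter probe outside divA's upstream window stays Promoter
  expect_equal(cls(47000, "divB", "chr2"), "Promoter")
})

test_that("joint cell solver reproduces the requested odds ratio", {
  grid <- expand.grid(p_row = c(0.1, 0.296, 0.349, 0.7),
                      p_col = c(0.2, 0.675, 0.9),
                      or = c(0.25, 1, 7.3, 11.81))
  for (i in seq_len(nrow(grid))) {
    cells <- solve_joint_cells(grid$p_row[i], grid$p_col[i], grid$or[i])
    expect_equal(sum(cells), 1, tolerance = 1e-12)
    expect_equal(cells[1] + cells[2], grid$p_row[i], tolerance = 1e-9)
    expect_equal(cells[1] + cells[3], grid$p_col[i], tolerance = 1e-9)
    expect_equal((cells[1] * cells[4]) / (cells[2] * cells[3]), grid$or[i],
                 tolerance = 1e-9)
  }
  # independence case
  cells <- solve_joint_cells(0.3, 0.6, 1)
  expect_equal(cells[1], 0.18, tolerance = 1e-12)
  # invalid parameterizations are rejected
  expect_error(solve_joint_cells(0.9, 0.9, 0))
  expect_error(solve_joint_cells(1.2, 0.5, 2))
})

test_that("realized truth marginals match the targets", {
  params <- sim_params(n_genes = 2000, seed = 31)
  study <- simulate_study(params)
  wt <- study$truth[study$truth$condition == "WT", ]
  tg <- study$truth[study$truth$condition == "TG", ]
  n <- nrow(wt)

  se3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(wt$truly_bound) - params$frac_bound_wt),
            se3(params$frac_bound_wt))
  expect_lt(abs(mean(wt$truly_expressed) - params$frac_expressed),
            se3(params$frac_expressed))
  retained <- mean(tg$truly_bound[wt$truly_bound])
  expect_lt(abs(retained - params$gene_retention_tg),
            3 * sqrt(0.715 * 0.285 / sum(wt$truly_bound)))
})

test_that("no-effect parameterization leaves WT and TG truth identical", {
  params <- sim_params(n_genes = 300, seed = 41, gene_retention_tg = 1,
                       probe_ratio_tg = 1, ectopic_gain = 0, or_tg = NA)
  study <- simulate_study(params)
  wt <- study$truth[study$truth$condition == "WT", ]
  tg <- study$truth[study$truth$condition == "TG", ]
  expect_equal(wt$truly_bound, tg$truly_bound)
  expect_equal(wt$bound_probe_ids, tg$bound_probe_ids)
})

test_that("independent coupling target yields an empirical OR near 1", {
  params <- sim_params(n_genes = 4000, seed = 51, or_wt = 1, or_tg = NA)
  study <- simulate_study(params)
  wt <- study$truth[study$truth$condition == "WT", ]
  tab <- table(bound = wt$truly_bound, expressed = wt$truly_expressed)
  res <- odds_ratio_ci(c(tab["TRUE", "TRUE"], tab["TRUE", "FALSE"],
                         tab["FALSE", "TRUE"], tab["FALSE", "FALSE"]),
                       ci_level = 0.99)
  expect_gt(1, res$ci_low)
  expect_lt(1, res$ci_high)
})

test_that("bound-probe p-values concentrate below the calling threshold", {
  params <- sim_params(n_genes = 500, seed = 61)
  study <- simulate_study(params)
  wt_truth <- study$truth[study$truth$condition == "WT", ]
  bound_ids <- unlist(strsplit(wt_truth$bound_probe_ids[wt_truth$truly_bound], ","))
  p_bound <- study$probes$pvalue_WT[study$probes$probe_id %in% bound_ids]
  expect_gt(mean(p_bound <= 0.005), 0.95)
  p_null <- study$probes$pvalue_WT[!study$probes$probe_id %in% bound_ids]
  expect_equal(sum(p_null <= 0.005), 0L)
})
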