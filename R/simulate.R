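#' @importFrom stats rmultinom runif rnorm rlnorm rgeom rbinom qbeta pbeta
#'   setNames uniroot
NULL

# Approximate mouse chromosome lengths (bp) used as the declared genome
# dictionary for simulated annotation.
MOUSE_CHROM_LENGTHS <- c(
  chr1 = 197e6, chr2 = 182e6, chr3 = 160e6, chr4 = 155e6, chr5 = 152e6,
  chr6 = 149e6, chr7 = 145e6, chr8 = 132e6, chr9 = 124e6, chr10 = 130e6,
  chr11 = 122e6, chr12 = 120e6, chr13 = 120e6, chr14 = 125e6, chr15 = 103e6,
  chr16 = 98e6, chr17 = 95e6, chr18 = 91e6, chr19 = 61e6,
  chrX = 166e6, chrY = 16e6
)

#' Parameters of the synthetic promoter-array study
#'
#' Defines an Agilent-style two-colour promoter tiling array experiment:
#' 60-mer probes tiled from `upstream_bp` before to `downstream_bp` after
#' each transcriptional start site, an average of `probes_per_gene` probes
#' per gene, and two conditions (WT, TG) with genotype-dependent binding
#' loss and a tunable binding-expression coupling imposed as a target odds
#' ratio per condition.
#'
#' Marginal defaults mirror the study structure the generator emulates:
#' 29.6% of genes bound in WT, a TG/WT bound-gene retention of 0.715 and a
#' bound-probe ratio of 0.544, 67.5% of genes expressed, and
#' binding-expression odds ratios of 11.8 (WT) and 7.3 (TG).
#'
#' @param n_genes Number of genes (default 2,000 for fast tests; 12,819
#'   emulates the common gene set, ~18,000 the full array).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param chrom_weights Per-chromosome gene weights; default proportional
#'   to chromosome length.
#' @param probes_per_gene Target mean probes per gene after dropout.
#' @param spacing_min,spacing_max Uniform range (bp) of the gap between
#'   consecutive probes.
#' @param probe_length Probe length in bp (60-mers).
#' @param upstream_bp,downstream_bp Tiled window around the TSS.
#' @param downstream_margin Distance past the TES still classed Downstream.
#' @param frac_divergent Fraction of genes placed as the second member of
#'   a divergent (head-to-head) promoter pair.
#' @param frac_unknown_probes Fraction of probes placed intergenically
#'   with no gene annotation (type Unknown).
#' @param frac_bound_wt Fraction of genes truly bound in WT.
#' @param frac_expressed Fraction of genes truly expressed.
#' @param or_wt,or_tg Target bound-by-expressed odds ratio per condition
#'   (`or_tg = NA` for uniform, expression-independent TG retention).
#' @param gene_retention_tg TG/WT ratio of truly bound genes.
#' @param probe_ratio_tg Target TG/WT ratio of bound probes (per-gene
#'   probe retention is calibrated to meet it).
#' @param ectopic_gain Probability that a WT-unbound gene gains binding in
#'   TG (populates the ectopic/hyper categories).
#' @param mean_bound_probes Mean bound probes per bound gene
#'   (1 + geometric, truncated at the gene's probe count).
#' @param bound_type_weights Sampling weights over probe types when
#'   choosing which probes of a bound gene are bound.
#' @param bound_meanlog,bound_sdlog Log-normal parameters of the bound
#'   probe log2(IP/WCE) ratio (median ~1.3 by default).
#' @param null_sd SD of the centred normal null probe log-ratio.
#' @param replicate_sd SD of per-replicate measurement noise.
#' @param n_replicates Replicates per condition.
#' @param bound_p_cut Binding p-value mass point: bound probes fall below
#'   it with probability `1 - bound_p_miss`.
#' @param bound_p_miss Per-probe miss probability for bound probes.
#' @param null_p_floor Lower bound of the uniform null p-value
#'   distribution, emulating conservative error-model p-values for
#'   unbound probes.
#' @param expr_meanlog_on,expr_meanlog_off,expr_sdlog Log-normal
#'   parameters of per-gene mean expression for expressed / silent genes.
#' @param sample_sdlog Log-scale SD of per-sample expression noise.
#' @param n_samples Expression samples per condition.
#' @param de_fraction Fraction of expressed genes that are truly
#'   differentially expressed between genotypes (decoupled from binding).
#' @param de_fold True fold change of differentially expressed genes.
#' @param seed Master RNG seed; every stage derives its own stream via
#'   [stage_seed()].
#' @return A validated `acechip_sim_params` list.
#' @export
sim_params <- function(n_genes = 2000,
                       chrom_lengths = MOUSE_CHROM_LENGTHS,
                       chrom_weights = NULL,
                       probes_per_gene = 25,
                       spacing_min = 100, spacing_max = 300,
                       probe_length = 60,
                       upstream_bp = 5500, downstream_bp = 2500,
                       downstream_margin = 2500,
                       frac_divergent = 0.10,
                       frac_unknown_probes = 0.01,
                       frac_bound_wt = 0.296,
                       frac_expressed = 8655 / 12819,
                       or_wt = 11.8, or_tg = 7.3,
                       gene_retention_tg = 0.715,
                       probe_ratio_tg = 0.544,
                       ectopic_gain = 0.01,
                       mean_bound_probes = 1.8,
                       bound_type_weights = c(Promoter = 0.2, Inside = 0.7,
                                              Downstream = 1 / 30,
                                              DivergentPromoter = 1 / 30,
                                              Unknown = 1 / 30),
                       bound_meanlog = log(1.3), bound_sdlog = 0.35,
                       null_sd = 0.3,
                       replicate_sd = 0.15,
                       n_replicates = 2,
                       bound_p_cut = 0.005,
                       bound_p_miss = 0.03,
                       null_p_floor = 0.01,
                       expr_meanlog_on = log(600),
                       expr_meanlog_off = log(20),
                       expr_sdlog = 0.5,
                       sample_sdlog = 0.12,
                       n_samples = 3,
                       de_fraction = 0.05,
                       de_fold = 2,
                       seed = 1L) {
  if (is.null(chrom_weights)) chrom_weights <- chrom_lengths / sum(chrom_lengths)
  p <- as.list(environment())
  fracs <- c("frac_divergent", "frac_unknown_probes", "frac_bound_wt",
             "frac_expressed", "gene_retention_tg", "probe_ratio_tg",
             "ectopic_gain", "bound_p_miss", "de_fraction")
  for (f in fracs) {
    v <- p[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must be in [0,1]")
  }
  stopifnot(
    n_genes >= 1, probes_per_gene >= 1,
    spacing_min > 0, spacing_max >= spacing_min,
    upstream_bp > 0, downstream_bp > 0, probe_length > 0,
    or_wt > 0, is.na(or_tg) || or_tg > 0,
    mean_bound_probes >= 1, n_replicates >= 1, n_samples >= 2,
    length(chrom_weights) == length(chrom_lengths),
    all(names(bound_type_weights) %in% PROBE_TYPES)
  )
  p$n_genes <- as.integer(n_genes)
  p$seed <- as.integer(seed)
  structure(p, class = "acechip_sim_params")
}

#' Solve 2x2 cell probabilities with given margins and odds ratio
#'
#' Finds the joint probabilities (a, b, c, d) of a 2x2 table with row
#' margin `p_row`, column margin `p_col` and odds ratio `or`
#' (`a*d / (b*c)`). The solution is the admissible root of the standard
#' one-unknown quadratic in the (1,1) cell, so the coupling is imposed
#' analytically rather than by rejection sampling.
#'
#' @param p_row,p_col Margins in (0,1).
#' @param or Target odds ratio, > 0.
#' @return Numeric vector `c(a, b, c, d)` summing to 1.
#' @export
#' @examples
#' cells <- solve_joint_cells(0.349, 0.675, 11.81)
#' (cells[1] * cells[4]) / (cells[2] * cells[3]) # recovers 11.81
solve_joint_cells <- function(p_row, p_col, or) {
  stopifnot(p_row > 0, p_row < 1, p_col > 0, p_col < 1, or > 0)
  lo <- max(0, p_row + p_col - 1)
  hi <- min(p_row, p_col)
  if (abs(or - 1) < 1e-12) {
    a <- p_row * p_col
  } else {
    A <- or - 1
    B <- -((or - 1) * (p_row + p_col) + 1)
    C <- or * p_row * p_col
    disc <- B^2 - 4 * A * C
    if (disc < 0) {
      stop("no real solution for margins (", p_row, ", ", p_col,
           ") with odds ratio ", or)
    }
    roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    ok <- roots >= lo & roots <= hi
    if (!any(ok)) {
      stop("infeasible parameterization: no cell probability in [",
           signif(lo, 6), ", ", signif(hi, 6), "] for margins (", p_row,
           ", ", p_col, ") and odds ratio ", or)
    }
    a <- roots[ok][1]
  }
  cells <- c(a, p_row - a, p_col - a, 1 - p_row - p_col + a)
  if (any(cells < -1e-12)) {
    stop("infeasible parameterization: negative cell probability")
  }
  pmax(cells, 0)
}

# Solve expression-dependent TG retention rates (r_expressed, r_not) so
# that overall gene retention equals `retention` AND the TG bound-by-
# expressed odds ratio hits `or_tg`, with ectopic gains included.
solve_tg_retention <- function(cells, retention, or_tg, ectopic) {
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  if (is.na(or_tg) || b <= 0 || a <= 0) {
    return(list(r_expressed = retention, r_not = retention))
  }
  r_not_of <- function(r_e) (retention * (a + b) - r_e * a) / b
  or2 <- function(r_e) {
    r_n <- r_not_of(r_e)
    a2 <- r_e * a + ectopic * cc
    b2 <- r_n * b + ectopic * d
    c2 <- (1 - r_e) * a + (1 - ectopic) * cc
    d2 <- (1 - r_n) * b + (1 - ectopic) * d
    (a2 * d2) / (b2 * c2)
  }
  lo <- max(0, (retention * (a + b) - b) / a)
  hi <- min(1, retention * (a + b) / a)
  eps <- 1e-9 * (hi - lo)
  f <- function(r_e) log(or2(r_e)) - log(or_tg)
  flo <- f(lo + eps); fhi <- f(hi - eps)
  if (flo * fhi > 0) {
    pick <- if (abs(flo) < abs(fhi)) lo + eps else hi - eps
    warning("TG odds-ratio target ", or_tg, " unreachable at retention ",
            retention, "; using closest attainable (",
            signif(or2(pick), 4), ")")
    r_e <- pick
  } else {
    r_e <- uniroot(f, c(lo + eps, hi - eps), tol = 1e-12)$root
  }
  list(r_expressed = r_e, r_not = min(1, max(0, r_not_of(r_e))))
}

#' Simulate gene annotation on a promoter array
#'
#' Places `n_genes` genes on the declared chromosomes, counts per
#' chromosome multinomial in the chromosome weights, both strands used.
#' Probe windows of distinct genes never overlap except for deliberately
#' placed divergent (head-to-head) pairs, whose upstream regions are
#' shared by construction. Coordinates are transcription-oriented:
#' `tss > tes` on the minus strand.
#'
#' @param params An `acechip_sim_params` ([sim_params()]).
#' @return Annotation `data.frame` (gene_id, chromosome, strand, tss, tes).
#' @export
simulate_annotation <- function(params) {
  stopifnot(inherits(params, "acechip_sim_params"))
  set.seed(stage_seed(params$seed, "annotation"))
  chroms <- names(params$chrom_lengths)
  counts <- as.vector(rmultinom(1, params$n_genes, params$chrom_weights))
  up <- params$upstream_bp
  down <- params$downstream_bp
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    n_c <- counts[ci]
    if (n_c == 0L) next
    len <- rlnorm(n_c, log(15000), 0.7)
    len <- as.integer(pmin(pmax(len, 500), 2e5))
    pair_with_next <- runif(n_c) < params$frac_divergent
    strand <- sample(c("+", "-"), n_c, replace = TRUE)
    tss <- integer(n_c); tes <- integer(n_c)
    cursor <- 1e4
    i <- 1L
    while (i <= n_c) {
      if (pair_with_next[i] && i < n_c) {
        # divergent pair: minus-strand gene then plus-strand gene,
        # TSSs within one upstream window of each other
        strand[i] <- "-"; strand[i + 1L] <- "+"
        tss[i] <- as.integer(cursor + max(down, len[i]))
        tes[i] <- tss[i] - len[i]
        gap_tss <- runif(1, 500, up - 500)
        tss[i + 1L] <- as.integer(tss[i] + gap_tss)
        tes[i + 1L] <- tss[i + 1L] + len[i + 1L]
        foot_end <- max(tss[i] + up, tss[i + 1L] + down, tes[i + 1L])
        i <- i + 2L
      } else {
        if (strand[i] == "+") {
          tss[i] <- as.integer(cursor + up)
          tes[i] <- tss[i] + len[i]
          foot_end <- max(tss[i] + down, tes[i])
        } else {
          tss[i] <- as.integer(cursor + max(down, len[i]))
          tes[i] <- tss[i] - len[i]
          foot_end <- tss[i] + up
        }
        i <- i + 1L
      }
      if (foot_end > params$chrom_lengths[ci]) {
        stop("chromosome ", chroms[ci], " too short for requested gene density")
      }
      cursor <- foot_end + runif(1, 2000, 20000)
    }
    out[[ci]] <- data.frame(
      chromosome = chroms[ci], strand = strand, tss = tss, tes = tes,
      stringsAsFactors = FALSE
    )
  }
  ann <- do.call(rbind, out)
  ann <- cbind(gene_id = sprintf("g%05d", seq_len(nrow(ann))), ann,
               stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  ann
}

# Tiled window of a gene in genomic coordinates [start, end).
gene_window <- function(annotation, params) {
  up <- params$upstream_bp; down <- params$downstream_bp
  plus <- annotation$strand == "+"
  data.frame(
    start = ifelse(plus, annotation$tss - up, annotation$tss - down),
    end = ifelse(plus, annotation$tss + down, annotation$tss + up)
  )
}

#' Simulate probe layout
#'
#' Tiles each gene's window (`-upstream_bp` to `+downstream_bp` of the
#' TSS) with 60-mer probes separated by independent uniform gaps of
#' `spacing_min`-`spacing_max` bp, then randomly drops probes so the
#' realized mean probes/gene matches `probes_per_gene` (emulating probes
#' skipped over repeat-masked sequence on real arrays). A further
#' `frac_unknown_probes` of probes are placed intergenically with no gene
#' link (type Unknown). Types are assigned with [classify_probe_type()].
#'
#' @param annotation From [simulate_annotation()].
#' @param params An `acechip_sim_params`.
#' @return Probe `data.frame` (positions and types only; see
#'   [simulate_signals()] for signals).
#' @export
simulate_probes <- function(annotation, params) {
  stopifnot(inherits(params, "acechip_sim_params"))
  set.seed(stage_seed(params$seed, "probes"))
  n_g <- nrow(annotation)
  win <- gene_window(annotation, params)
  width <- win$end - win$start
  step_max_n <- ceiling(max(width) / (params$spacing_min + params$probe_length)) + 2L
  steps <- matrix(
    runif(n_g * step_max_n, params$spacing_min, params$spacing_max) +
      params$probe_length,
    nrow = n_g
  )
  offsets <- cbind(0, t(apply(steps, 1, cumsum)))
  keep <- offsets <= (width - params$probe_length)
  gene_idx <- rep(seq_len(n_g), times = rowSums(keep))
  start <- as.integer(win$start[gene_idx] + t(offsets)[t(keep)])
  # calibrated dropout to hit the target mean probes per gene
  implied_mean <- length(start) / n_g
  q <- min(1, params$probes_per_gene / implied_mean)
  if (q < 1) {
    sel <- runif(length(start)) < q
    gene_idx <- gene_idx[sel]
    start <- start[sel]
  }
  probes <- data.frame(
    gene_id = annotation$gene_id[gene_idx],
    chromosome = annotation$chromosome[gene_idx],
    start = start,
    end = start + as.integer(params$probe_length),
    stringsAsFactors = FALSE
  )
  # intergenic probes with no gene annotation
  n_unk <- round(params$frac_unknown_probes * nrow(probes))
  if (n_unk > 0) {
    probes <- rbind(probes, intergenic_probes(annotation, params, n_unk))
  }
  ord <- order(match(probes$chromosome, names(params$chrom_lengths)),
               probes$start)
  probes <- probes[ord, , drop = FALSE]
  probes <- cbind(probe_id = sprintf("p%07d", seq_len(nrow(probes))), probes,
                  stringsAsFactors = FALSE)
  rownames(probes) <- NULL
  probes$probe_type <- classify_probe_type(probes, annotation, params)
  probes
}

# Random intergenic probe positions avoiding every gene window and body.
intergenic_probes <- function(annotation, params, n) {
  win <- gene_window(annotation, params)
  occupied <- split(
    IRanges::IRanges(
      start = pmin(win$start, pmin(annotation$tss, annotation$tes)),
      end = pmax(win$end, pmax(annotation$tss, annotation$tes)) +
        params$downstream_margin
    ),
    annotation$chromosome
  )
  out_chr <- character(0); out_start <- integer(0)
  max_span <- max(vapply(split(win$end, annotation$chromosome), max, 0))
  tries <- 0L
  while (length(out_start) < n && tries < 50L) {
    m <- (n - length(out_start)) * 2L
    chr <- sample(names(occupied), m, replace = TRUE)
    pos <- as.integer(runif(m, 1e4, max_span + 5e4))
    ok <- logical(m)
    for (cc in unique(chr)) {
      sel <- chr == cc
      ok[sel] <- IRanges::countOverlaps(
        IRanges::IRanges(pos[sel], width = params$probe_length),
        occupied[[cc]]) == 0L
    }
    out_chr <- c(out_chr, chr[ok]); out_start <- c(out_start, pos[ok])
    tries <- tries + 1L
  }
  k <- min(n, length(out_start))
  data.frame(
    gene_id = rep(NA_character_, k), chromosome = out_chr[seq_len(k)],
    start = out_start[seq_len(k)],
    end = out_start[seq_len(k)] + as.integer(params$probe_length),
    stringsAsFactors = FALSE
  )
}

#' Classify probe location relative to its gene
#'
#' Assigns each probe the array's location vocabulary from its midpoint in
#' transcription-oriented coordinates: `Promoter` when strictly upstream
#' of the TSS within the upstream window, `Inside` from the TSS (offset 0,
#' a declared tie rule) through the TES, `Downstream` within
#' `downstream_margin` past the TES, and `Unknown` otherwise (including
#' probes with no gene link). A Promoter probe whose midpoint also falls
#' in the upstream window of a second, opposite-strand gene is a
#' `DivergentPromoter`.
#'
#' @param probes Probe table with `gene_id`, `chromosome`, `start`, `end`.
#' @param annotation Gene annotation table.
#' @param params An `acechip_sim_params` (supplies window sizes).
#' @return Character vector of probe types.
#' @export
classify_probe_type <- function(probes, annotation, params) {
  up <- params$upstream_bp
  mid <- probes$start + (probes$end - probes$start) %/% 2L
  idx <- match(probes$gene_id, annotation$gene_id)
  tss <- annotation$tss[idx]
  glen <- abs(annotation$tes[idx] - annotation$tss[idx])
  plus <- annotation$strand[idx] == "+"
  offset <- ifelse(plus, mid - tss, tss - mid)
  type <- rep("Unknown", nrow(probes))
  has_gene <- !is.na(idx)
  type[has_gene & offset > -up & offset < 0] <- "Promoter"
  type[has_gene & offset >= 0 & offset <= glen] <- "Inside"
  type[has_gene & offset > glen &
         offset <= glen + params$downstream_margin] <- "Downstream"
  # divergent promoters: also inside the upstream window of an
  # opposite-strand gene
  prom <- which(type == "Promoter")
  if (length(prom) > 0L) {
    upstream_start <- ifelse(annotation$strand == "+",
                             annotation$tss - up + 1L, annotation$tss + 1L)
    upstream_end <- ifelse(annotation$strand == "+",
                           annotation$tss - 1L, annotation$tss + up - 1L)
    for (chr in unique(probes$chromosome[prom])) {
      gi <- which(annotation$chromosome == chr)
      pi <- prom[probes$chromosome[prom] == chr]
      if (length(gi) == 0L || length(pi) == 0L) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(mid[pi], width = 1L),
        IRanges::IRanges(upstream_start[gi], upstream_end[gi])
      )
      if (length(hits) == 0L) next
      qh <- S4Vectors::queryHits(hits)
      own_strand <- annotation$strand[idx[pi[qh]]]
      other_gene <- gi[S4Vectors::subjectHits(hits)]
      divergent <- annotation$strand[other_gene] != own_strand &
        annotation$gene_id[other_gene] != probes$gene_id[pi[qh]]
      type[pi[unique(qh[divergent])]] <- "DivergentPromoter"
    }
  }
  type
}

#' Simulate probe signals, p-values and ground truth
#'
#' Realizes the study's binding structure on the probe layout:
#' per gene, truly-expressed and truly-bound (WT) flags are drawn jointly
#' from the analytic 2x2 cell solution targeting `or_wt`
#' ([solve_joint_cells()]); TG binding retains WT-bound genes with
#' expression-dependent rates solved so overall retention equals
#' `gene_retention_tg` and the TG table hits `or_tg`, plus ectopic gains.
#' Bound genes receive `1 + Geometric` bound probes biased toward Inside
#' probes; TG per-gene probe retention is calibrated so the TG/WT bound
#' probe ratio hits `probe_ratio_tg`. Bound probes draw log-normal
#' log2(IP/WCE) ratios and p-values with `1 - bound_p_miss` mass below
#' `bound_p_cut`; unbound probes draw centred normal signals and uniform
#' p-values on `(null_p_floor, 1)`.
#'
#' @param probes From [simulate_probes()].
#' @param annotation From [simulate_annotation()].
#' @param params An `acechip_sim_params`.
#' @return List with `probes` (signal and p-value columns added) and
#'   `truth` (per gene x condition: truly_bound, truly_expressed,
#'   bound_probe_ids, true_de placeholder).
#' @export
simulate_signals <- function(probes, annotation, params) {
  stopifnot(inherits(params, "acechip_sim_params"))
  set.seed(stage_seed(params$seed, "truth"))
  genes <- annotation$gene_id
  n <- length(genes)

  cells <- solve_joint_cells(params$frac_bound_wt, params$frac_expressed,
                             params$or_wt)
  joint <- sample.int(4L, n, replace = TRUE, prob = cells)
  bound_wt <- joint %in% c(1L, 2L)
  expressed <- joint %in% c(1L, 3L)

  rates <- solve_tg_retention(cells, params$gene_retention_tg, params$or_tg,
                              params$ectopic_gain)
  keep_p <- ifelse(expressed, rates$r_expressed, rates$r_not)
  u <- runif(n)
  bound_tg <- (bound_wt & u < keep_p) |
    (!bound_wt & u < params$ectopic_gain)

  # ---- choose bound probes per gene -------------------------------------
  probe_gene <- match(probes$gene_id, genes)
  probes_of <- split(seq_len(nrow(probes)), factor(probe_gene, levels = seq_len(n)))
  n_probes_gene <- lengths(probes_of)
  if (any(n_probes_gene == 0L)) {
    stop("gene(s) without probes; increase probes_per_gene")
  }
  geom_p <- 1 / params$mean_bound_probes
  w_type <- params$bound_type_weights[probes$probe_type]
  w_type[is.na(w_type)] <- min(params$bound_type_weights)

  draw_bound <- function(gene_ids_idx) {
    k <- pmin(1L + rgeom(length(gene_ids_idx), geom_p),
              n_probes_gene[gene_ids_idx])
    unlist(lapply(seq_along(gene_ids_idx), function(j) {
      cand <- probes_of[[gene_ids_idx[j]]]
      if (length(cand) == 1L) return(cand)
      sample(cand, k[j], prob = w_type[cand])
    }))
  }

  wt_gene_idx <- which(bound_wt)
  wt_bound_idx <- draw_bound(wt_gene_idx)
  bound_probe_wt <- rep(FALSE, nrow(probes))
  bound_probe_wt[wt_bound_idx] <- TRUE

  ectopic_idx <- which(bound_tg & !bound_wt)
  ect_bound_idx <- draw_bound(ectopic_idx)

  # calibrate per-gene probe retention against the probe-ratio target
  retained_idx <- which(bound_wt & bound_tg)
  k_wt <- vapply(probes_of[wt_gene_idx],
                 function(ix) sum(bound_probe_wt[ix]), integer(1))
  names(k_wt) <- as.character(wt_gene_idx)
  k_ret <- k_wt[as.character(retained_idx)]
  needed <- params$probe_ratio_tg * sum(k_wt) - length(ect_bound_idx)
  r_probe <- calibrate_probe_retention(k_ret, needed)

  tg_bound_idx <- integer(0)
  if (length(retained_idx) > 0L) {
    tg_bound_idx <- unlist(lapply(retained_idx, function(g) {
      cand <- probes_of[[g]]
      cand <- cand[bound_probe_wt[cand]]
      kept <- cand[runif(length(cand)) < r_probe]
      if (length(kept) == 0L) kept <- cand[sample.int(length(cand), 1L)]
      kept
    }))
  }
  tg_bound_idx <- c(tg_bound_idx, ect_bound_idx)
  bound_probe_tg <- rep(FALSE, nrow(probes))
  bound_probe_tg[tg_bound_idx] <- TRUE

  # ---- signals and p-values ---------------------------------------------
  set.seed(stage_seed(params$seed, "signals"))
  bound_by_cond <- list(WT = bound_probe_wt, TG = bound_probe_tg)
  for (cond in CONDITIONS) {
    b <- bound_by_cond[[cond]]
    true_sig <- numeric(nrow(probes))
    true_sig[b] <- rlnorm(sum(b), params$bound_meanlog, params$bound_sdlog)
    true_sig[!b] <- rnorm(sum(!b), 0, params$null_sd)
    for (r in seq_len(params$n_replicates)) {
      probes[[sprintf("signal_%s_%d", cond, r)]] <-
        true_sig + rnorm(nrow(probes), 0, params$replicate_sd)
    }
    p <- runif(nrow(probes), params$null_p_floor, 1)
    nb <- sum(b)
    if (nb > 0L) {
      hit <- runif(nb) >= params$bound_p_miss
      pb <- numeric(nb)
      mass <- pbeta(params$bound_p_cut, 0.05, 10)
      pb[hit] <- qbeta(runif(sum(hit)) * mass, 0.05, 10)
      pb[!hit] <- runif(sum(!hit), params$bound_p_cut, 1)
      p[b] <- pb
    }
    probes[[pvalue_col(cond)]] <- p
  }

  ids_of <- function(flag) {
    sel <- split(probes$probe_id[flag], factor(probe_gene[flag], levels = seq_len(n)))
    vapply(sel, paste, character(1), collapse = ",")
  }
  truth <- data.frame(
    gene_id = rep(genes, 2L),
    condition = rep(CONDITIONS, each = n),
    truly_bound = c(bound_wt, bound_tg),
    truly_expressed = rep(expressed, 2L),
    bound_probe_ids = c(ids_of(bound_probe_wt), ids_of(bound_probe_tg)),
    true_de = NA_character_,
    stringsAsFactors = FALSE
  )
  list(probes = probes, truth = truth)
}

# Solve the per-probe TG retention rate r so that, in expectation, the
# retained bound probes (each retained gene keeps at least one) plus the
# already-drawn ectopic probes hit the bound-probe ratio target.
calibrate_probe_retention <- function(k, needed) {
  if (length(k) == 0L) return(1)
  expected <- function(r) sum(k * r + (1 - r)^k)
  if (needed <= expected(0)) return(0)
  if (needed >= sum(k)) return(1)
  uniroot(function(r) expected(r) - needed, c(0, 1), tol = 1e-10)$root
}

#' Simulate expression sample values
#'
#' Expressed genes draw a persistent log-normal baseline well above the
#' expression threshold, silent genes well below it; the flags are shared
#' between genotypes so that expression changes stay decoupled from
#' binding changes. A `de_fraction` of expressed genes is truly
#' differentially expressed (`de_fold` up or down in TG, equal split).
#' Per-sample values add log-normal measurement noise.
#'
#' @param truth Truth table from [simulate_signals()].
#' @param params An `acechip_sim_params`.
#' @return List with `expression` (long table: gene_id, condition,
#'   value_1..n_samples) and `truth` with `true_de` filled in.
#' @export
simulate_expression <- function(truth, params) {
  stopifnot(inherits(params, "acechip_sim_params"))
  set.seed(stage_seed(params$seed, "expression"))
  wt <- truth[truth$condition == "WT", ]
  genes <- wt$gene_id
  n <- length(genes)
  on <- wt$truly_expressed
  base <- numeric(n)
  base[on] <- rlnorm(sum(on), params$expr_meanlog_on, params$expr_sdlog)
  base[!on] <- rlnorm(sum(!on), params$expr_meanlog_off, params$expr_sdlog)

  de <- rep("NONE", n)
  cand <- which(on)
  n_de <- round(params$de_fraction * length(cand))
  if (n_de > 0L) {
    chosen <- sample(cand, n_de)
    de[chosen] <- sample(rep(c("UP", "DOWN"), length.out = n_de))
  }
  mean_tg <- base
  mean_tg[de == "UP"] <- base[de == "UP"] * params$de_fold
  mean_tg[de == "DOWN"] <- base[de == "DOWN"] / params$de_fold

  sample_block <- function(m) {
    vals <- lapply(seq_len(params$n_samples), function(j) {
      m * rlnorm(n, 0, params$sample_sdlog)
    })
    names(vals) <- sprintf("value_%d", seq_len(params$n_samples))
    vals
  }
  expression <- rbind(
    data.frame(gene_id = genes, condition = "WT", sample_block(base),
               stringsAsFactors = FALSE),
    data.frame(gene_id = genes, condition = "TG", sample_block(mean_tg),
               stringsAsFactors = FALSE)
  )
  truth$true_de <- de[match(truth$gene_id, genes)]
  list(expression = expression, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_annotation()], [simulate_probes()],
#' [simulate_signals()] and [simulate_expression()] under the named
#' per-stage RNG streams of `params$seed`.
#'
#' @param params An `acechip_sim_params`.
#' @return List with `annotation`, `probes`, `expression`, `truth`,
#'   `params`.
#' @export
#' @examples
#' study <- simulate_study(sim_params(n_genes = 50, seed = 1))
#' nrow(study$annotation)
simulate_study <- function(params = sim_params()) {
  annotation <- simulate_annotation(params)
  probes <- simulate_probes(annotation, params)
  sig <- simulate_signals(probes, annotation, params)
  expr <- simulate_expression(sig$truth, params)
  list(annotation = annotation, probes = sig$probes,
       expression = expr$expression, truth = expr$truth, params = params)
}

#' Write a simulated study to a directory
#'
#' @param study From [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param config An `acechip_config`; defaults to one carrying the
#'   study's seed.
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir,
                        config = run_config(seed = study$params$seed)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_annotation_table(study$annotation, file.path(dir, "annotation.tsv"), config)
  write_probe_table(study$probes, file.path(dir, "probes.tsv"), config)
  write_expression_table(study$expression, file.path(dir, "expression.tsv"), config)
  write_truth_table(study$truth, file.path(dir, "truth.tsv"), config)
  invisible(dir)
}
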