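#' Simulate a trio DNM study with planted risk genes
#'
#' Generates per-gene, per-class de novo counts from the Poisson background
#' x_c ~ Poisson(2 N mu_c gamma_c), with gamma = 1 for non-risk genes and
#' elevated relative risks for `n_risk_genes` planted risk genes, then
#' expands counts into variant-level records with distinct random carrier
#' ids. Per-gene class rates mu_c are lognormal with median 1e-5 and
#' log-sd 1. Decoy rows — synonymous, noncoding and common (MAF >= 0.001)
#' variants — are sprinkled in to exercise the filtering rules; they are
#' exactly the rows [filter_coding_rare()] and [classify_extreme()]
#' eliminate, so the planted extreme counts are restored downstream. Four
#' rate tables (GC, SC, MF, DM) are emitted as multiplicative-lognormal
#' noisy copies (log-sd `rate_noise_sd`) of the true rates, so the rate
#' models disagree on marginal genes and the >=3-of-4 consensus rule is
#' exercised.
#'
#' The default scale mirrors a severe neurodevelopmental trio study: 1027
#' case trios and 63 planted risk genes with mean LoF relative risk 20 and
#' damaging-missense relative risk 4.7.
#'
#' @param n_genes Number of genes; default 5000.
#' @param n_trios Number of trios; default 1027.
#' @param n_risk_genes Number of planted risk genes; default 63.
#' @param gamma_lof,gamma_dmis Planted relative risks; defaults 20 and 4.7.
#' @param mu_meanlog,mu_sdlog Lognormal parameters of per-gene class rates;
#'   defaults log(1e-5) and 1.
#' @param rate_noise_sd Inter-source rate-table noise (log scale); default
#'   0.2.
#' @param decoy_rate Expected decoy rows (synonymous / noncoding / common)
#'   per gene per type; default 0.02.
#' @param cohort_label `"case"` or `"control"`.
#' @param seed Seed; all randomness derives from it.
#' @return List with `dnm` (record data frame), `rates` (named list of four
#'   [rate_table()]s), `cohort` ([cohort_spec()]), `truth` (list: data frame
#'   `risk_genes` with per-gene planted relative risks, `counts` with the
#'   planted extreme counts, `seed`).
#' @export
simulate_trio_dnms <- function(n_genes = 5000, n_trios = 1027,
                               n_risk_genes = 63, gamma_lof = 20,
                               gamma_dmis = 4.7, mu_meanlog = log(1e-5),
                               mu_sdlog = 1, rate_noise_sd = 0.2,
                               decoy_rate = 0.02,
                               cohort_label = c("case", "control"), seed = 1) {
  cohort_label <- match.arg(cohort_label)
  stopifnot(n_risk_genes <= n_genes)
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  mu_lof <- stats::rlnorm(n_genes, mu_meanlog, mu_sdlog)
  mu_dmis <- stats::rlnorm(n_genes, mu_meanlog, mu_sdlog)
  risk <- if (n_risk_genes > 0) sample(genes, n_risk_genes) else character()
  g_l <- ifelse(genes %in% risk, gamma_lof, 1)
  g_d <- ifelse(genes %in% risk, gamma_dmis, 1)
  x_lof <- stats::rpois(n_genes, 2 * n_trios * mu_lof * g_l)
  x_dmis <- stats::rpois(n_genes, 2 * n_trios * mu_dmis * g_d)

  samples <- sprintf("%s_%04d", cohort_label, seq_len(n_trios))
  rec <- function(gene, n, class_pool, votes_fun, maf = 0) {
    if (n == 0) return(NULL)
    data.frame(
      sample_id = sample(samples, n, replace = TRUE),
      cohort = cohort_label, gene = gene,
      chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
      pos = sample.int(2e8, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      variant_class = sample(class_pool, n, replace = TRUE),
      damaging_votes = votes_fun(n),
      max_maf = maf, stringsAsFactors = FALSE)
  }
  recs <- vector("list", n_genes * 2L)
  j <- 0L
  for (i in seq_len(n_genes)) {
    if (x_lof[i] > 0) {
      j <- j + 1L
      recs[[j]] <- rec(genes[i], x_lof[i], LOF_CLASSES,
                       function(n) rep(NA_integer_, n))
    }
    if (x_dmis[i] > 0) {
      j <- j + 1L
      recs[[j]] <- rec(genes[i], x_dmis[i], "missense",
                       function(n) sample(8:14, n, replace = TRUE))
    }
  }
  # decoys: sub-threshold missense, synonymous, noncoding, common variants
  n_syn <- stats::rpois(1, decoy_rate * n_genes)
  n_nc <- stats::rpois(1, decoy_rate * n_genes)
  n_common <- stats::rpois(1, decoy_rate * n_genes)
  n_benign_mis <- stats::rpois(1, decoy_rate * n_genes)
  decoys <- list(
    rec(NA, 0, "synonymous", identity),  # placeholder keeps types stable
    if (n_syn > 0) {
      d <- rec("X", n_syn, "synonymous", function(n) rep(NA_integer_, n))
      d$gene <- sample(genes, n_syn, replace = TRUE); d
    },
    if (n_nc > 0) {
      d <- rec("X", n_nc, "noncoding", function(n) rep(NA_integer_, n))
      d$gene <- sample(genes, n_nc, replace = TRUE); d
    },
    if (n_common > 0) {
      d <- rec("X", n_common, c(LOF_CLASSES, "missense"),
               function(n) sample(0:14, n, replace = TRUE),
               maf = stats::runif(n_common, 0.001, 0.05))
      d$gene <- sample(genes, n_common, replace = TRUE); d
    },
    if (n_benign_mis > 0) {
      d <- rec("X", n_benign_mis, "missense", function(n) sample(0:7, n, replace = TRUE))
      d$gene <- sample(genes, n_benign_mis, replace = TRUE); d
    }
  )
  dnm <- do.call(rbind, c(recs[seq_len(j)], decoys[!vapply(decoys, is.null, logical(1))]))
  if (is.null(dnm)) {
    dnm <- rec("X", 0, "missense", identity)
  }
  dnm <- dnm[sample.int(nrow(dnm)), , drop = FALSE]
  rownames(dnm) <- NULL

  true_rates <- data.frame(gene = genes, mu_lof = mu_lof, mu_dmis = mu_dmis,
                           stringsAsFactors = FALSE)
  rates <- lapply(c(GC = "GC", SC = "SC", MF = "MF", DM = "DM"), function(src) {
    noisy <- true_rates
    noisy$mu_lof <- noisy$mu_lof * stats::rlnorm(n_genes, 0, rate_noise_sd)
    noisy$mu_dmis <- noisy$mu_dmis * stats::rlnorm(n_genes, 0, rate_noise_sd)
    rate_table(noisy, src)
  })

  truth <- list(
    risk_genes = data.frame(gene = risk,
                            gamma_lof = rep(gamma_lof, length(risk)),
                            gamma_dmis = rep(gamma_dmis, length(risk)),
                            stringsAsFactors = FALSE),
    counts = data.frame(gene = genes, n_lof = x_lof, n_dmis = x_dmis,
                        stringsAsFactors = FALSE),
    true_rates = rate_table(true_rates, "truth"),
    seed = seed)
  list(dnm = dnm, rates = rates,
       cohort = cohort_spec(cohort_label, n_trios), truth = truth)
}

# trajectory templates over the 15 ordered periods (unit amplitude)
module_templates <- function() {
  n <- length(brain_periods())   # 15
  idx <- seq_len(n)
  # rises from the embryonic period to a peak at 16-19 PCW (index 5), then
  # declines to its low in childhood (indices 10-11) and stays low
  m1 <- c(seq(-1, 1, length.out = 5), seq(0.7, -1, length.out = 6), rep(-0.9, 4))
  # falls through fetal life to a minimum in infancy (indices 8-9), then
  # rises to adolescence and plateaus in adulthood
  m2 <- c(seq(1, -1, length.out = 8), -1, seq(-0.6, 0.8, length.out = 3),
          rep(0.85, 3))
  list(m1 = m1[idx], m2 = m2[idx])
}

#' Simulate a spatiotemporal brain expression matrix with planted modules
#'
#' Emulates a Human-Brain-Transcriptome-like matrix: samples are region x
#' developmental-period combinations; genes of the two planted modules
#' follow characteristic temporal templates plus Gaussian noise, background
#' genes are pure noise. Module 1 rises from the embryonic period to a peak
#' at 16-19 post-conception weeks then declines to a childhood low; module
#' 2 declines through fetal life and infancy then recovers to a stable
#' adult level.
#'
#' @param module_sizes Planted module sizes; default `c(39, 18)`.
#' @param background_genes Number of additional unpatterned (pure noise)
#'   genes; default 0. The default matrix holds exactly the 57 module genes:
#'   risk genes missing from an expression resource are modeled by absence
#'   from the matrix, not by unpatterned profiles. Note that with a fixed
#'   two-module cut, added noise genes form their own branch and distort
#'   module recovery.
#' @param regions Brain region labels; default the six canonical regions.
#' @param samples_per_period_region Replicates per (region, period) cell;
#'   default 1.
#' @param noise_sd Gaussian noise sd around the unit-amplitude template;
#'   default 0.4.
#' @param seed Seed.
#' @return List with `expr` (genes x samples matrix), `sample_info`
#'   (sample_id, region, period, age), `truth` (named module label vector:
#'   1, 2 or 0 for background; peak/trough periods; seed).
#' @export
simulate_expression <- function(module_sizes = c(39, 18), background_genes = 0,
                                regions = c("NCX", "HIP", "AMY", "STR", "MD", "CBC"),
                                samples_per_period_region = 1, noise_sd = 0.4,
                                seed = 1) {
  stopifnot(all(module_sizes >= 2))
  set.seed(seed)
  periods <- brain_periods()
  grid <- expand.grid(rep = seq_len(samples_per_period_region),
                      region = regions, period = periods,
                      stringsAsFactors = FALSE)
  sample_info <- data.frame(
    sample_id = sprintf("S%03d", seq_len(nrow(grid))),
    region = grid$region, period = grid$period,
    age = match(grid$period, periods), stringsAsFactors = FALSE)
  tpl <- module_templates()
  n1 <- module_sizes[1]; n2 <- module_sizes[2]
  genes <- c(sprintf("M1_%03d", seq_len(n1)), sprintf("M2_%03d", seq_len(n2)),
             if (background_genes > 0) sprintf("BG_%03d", seq_len(background_genes)))
  labels <- stats::setNames(c(rep(1L, n1), rep(2L, n2),
                              rep(0L, background_genes)), genes)
  base <- rbind(
    matrix(rep(tpl$m1[match(sample_info$period, periods)], n1),
           nrow = n1, byrow = TRUE),
    matrix(rep(tpl$m2[match(sample_info$period, periods)], n2),
           nrow = n2, byrow = TRUE),
    matrix(0, nrow = background_genes, ncol = nrow(sample_info)))
  expr <- base + matrix(stats::rnorm(length(genes) * nrow(sample_info),
                                     sd = noise_sd),
                        nrow = length(genes))
  dimnames(expr) <- list(genes, sample_info$sample_id)
  list(expr = expr, sample_info = sample_info,
       truth = list(module_labels = labels,
                    m1_peak_period = "16-19 PCW",
                    m2_min_era = "infancy", seed = seed))
}

#' Simulate an interaction network with planted query-partner connectivity
#'
#' Erdos-Renyi background over all unordered pairs of the universe, plus
#' independently planted extra query-partner edges with probability
#' `planted_extra_prob`. With `planted_extra_prob = 0` the graph is
#' exchangeable across gene labels, the regime in which permutation
#' p-values are calibrated.
#'
#' @param universe Character vector of node names.
#' @param background_edge_prob Background edge probability; default 0.01.
#' @param query_set,partner_set Gene sets receiving planted edges.
#' @param planted_extra_prob Extra query-partner edge probability; default 0.
#' @param seed Seed.
#' @return List with `network` (a [gene_network()]) and `truth`
#'   (planted_edges data frame, seed).
#' @export
simulate_network <- function(universe, background_edge_prob = 0.01,
                             query_set = character(),
                             partner_set = character(),
                             planted_extra_prob = 0, seed = 1) {
  set.seed(seed)
  n <- length(universe)
  pairs <- utils::combn(n, 2)
  i <- universe[pairs[1, ]]; j <- universe[pairs[2, ]]
  p <- rep(background_edge_prob, ncol(pairs))
  cross <- (i %in% query_set & j %in% partner_set) |
    (j %in% query_set & i %in% partner_set)
  # planted edges add on top of the background: 1 - (1-p0)(1-p1)
  p[cross] <- 1 - (1 - p[cross]) * (1 - planted_extra_prob)
  keep <- stats::runif(ncol(pairs)) < p
  edges <- data.frame(gene1 = i[keep], gene2 = j[keep], weight = 1,
                      stringsAsFactors = FALSE)
  net <- gene_network(edges, nodes = universe)
  list(network = net,
       truth = list(planted_edges = edges[cross[keep], , drop = FALSE],
                    background_edge_prob = background_edge_prob,
                    planted_extra_prob = planted_extra_prob, seed = seed))
}

#' Simulate gene-set collections with planted query overlap
#'
#' Each set draws the stated fraction of its members from the query set and
#' the remainder uniformly from the rest of the universe.
#'
#' @param universe Gene universe.
#' @param query_set Query genes the overlap is planted against.
#' @param set_sizes Sizes of the simulated sets (recycled against
#'   `planted_overlap_fractions`).
#' @param planted_overlap_fractions Fraction of each set drawn from the
#'   query set, each in `[0, 1]`.
#' @param seed Seed.
#' @return List with `collection` (a [gene_set_collection()] with the
#'   universe attached) and `truth` (per-set planted fraction, seed).
#' @export
simulate_gene_sets <- function(universe, query_set, set_sizes = 200,
                               planted_overlap_fractions = 0.4, seed = 1) {
  if (any(planted_overlap_fractions > 1 | planted_overlap_fractions < 0)) {
    stop("overlap fractions must lie in [0, 1]")
  }
  set.seed(seed)
  n_sets <- max(length(set_sizes), length(planted_overlap_fractions))
  set_sizes <- rep_len(set_sizes, n_sets)
  fr <- rep_len(planted_overlap_fractions, n_sets)
  rest <- setdiff(universe, query_set)
  sets <- lapply(seq_len(n_sets), function(k) {
    n_q <- min(round(fr[k] * set_sizes[k]), length(query_set))
    n_r <- min(set_sizes[k] - n_q, length(rest))
    c(sample(query_set, n_q), sample(rest, n_r))
  })
  names(sets) <- sprintf("set_%02d", seq_len(n_sets))
  list(collection = gene_set_collection(sets, universe = universe),
       truth = list(planted_fraction = stats::setNames(fr, names(sets)),
                    seed = seed))
}

#' Write a complete synthetic demo workspace
#'
#' Generates every input the pipeline consumes (DNM table, four rate
#' tables, expression matrix + sample metadata, PPI edge list, gene sets in
#' GMT, intolerance annotations) into a directory, in the exact dialects
#' the readers expect.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed driving all generators.
#' @param n_genes,n_trios,n_risk_genes Passed to [simulate_trio_dnms()]
#'   (smaller defaults than the generator's, for a quick demo).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_demo_workspace <- function(dir, seed = 1, n_genes = 800, n_trios = 1027,
                                 n_risk_genes = 63) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  sim <- simulate_trio_dnms(n_genes = n_genes, n_trios = n_trios,
                            n_risk_genes = n_risk_genes, seed = seed)
  paths$dnm <- file.path(dir, "dnm.tsv")
  write_dnm_table(sim$dnm, paths$dnm)
  for (src in names(sim$rates)) {
    paths[[paste0("rates_", src)]] <- file.path(dir, paste0("rates_", src, ".tsv"))
    write_rate_table(sim$rates[[src]], paths[[paste0("rates_", src)]])
  }
  ex <- simulate_expression(seed = seed + 1)
  # name planted expression genes after planted risk genes so the stages link up
  risk <- sim$truth$risk_genes$gene
  n_named <- min(length(risk), nrow(ex$expr))
  rownames(ex$expr)[seq_len(n_named)] <- risk[seq_len(n_named)]
  paths$expression <- file.path(dir, "expression.tsv")
  write_expression(ex$expr, paths$expression)
  paths$sample_info <- file.path(dir, "sample_info.tsv")
  write_tsv(ex$sample_info, paths$sample_info)
  net <- simulate_network(sprintf("G%05d", seq_len(n_genes)),
                          background_edge_prob = 0.01,
                          query_set = risk, partner_set = setdiff(
                            sprintf("G%05d", seq_len(min(200, n_genes))), risk),
                          planted_extra_prob = 0.05, seed = seed + 2)
  paths$ppi <- file.path(dir, "ppi.tsv")
  edges <- net$network$edges
  names(edges)[names(edges) == "weight"] <- "score"
  edges$score <- 900
  write_tsv(edges, paths$ppi)
  gs <- simulate_gene_sets(sprintf("G%05d", seq_len(n_genes)), risk,
                           set_sizes = c(150, 150, 100, 100),
                           planted_overlap_fractions = c(0.3, 0.2, 0.1, 0),
                           seed = seed + 3)
  paths$gene_sets <- file.path(dir, "gene_sets.gmt")
  write_gmt(gs$collection, paths$gene_sets)
  set.seed(seed + 4)
  ann <- data.frame(gene = sprintf("G%05d", seq_len(n_genes)),
                    rvis_percentile = stats::runif(n_genes, 0, 100),
                    pli = stats::runif(n_genes), stringsAsFactors = FALSE)
  paths$intolerance <- file.path(dir, "intolerance.tsv")
  write_tsv(ann, paths$intolerance)
  invisible(paths)
}
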