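# Cross-product odds ratio with Haldane-Anscombe 0.5 correction when any
# cell is empty; this is the convention the reported ORs follow (not the
# conditional MLE that fisher.test estimates).
sample_odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

fisher_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}

#' Fisher-exact gene-set enrichment of a query gene set
#'
#' For each set in the collection, builds the 2x2 table (query-in-set,
#' query-not-in-set; background-in-set, background-not-in-set) over the
#' given universe (background = universe minus query), computes the
#' two-sided Fisher exact p, the cross-product odds ratio (Haldane 0.5
#' correction on empty cells) and a multiplicity-corrected p across the
#' collection.
#'
#' @param query Query gene set; genes outside the universe are dropped with
#'   a warning.
#' @param collection A [gene_set_collection()] or named list of gene sets;
#'   each set is intersected with the universe.
#' @param universe Background gene universe.
#' @param correction Multiple-testing method, `"BH"` (default) or
#'   `"bonferroni"` (any `stats::p.adjust` method is accepted).
#' @return Data frame of class `"enrichment_result"`: `set`, `a`, `b`, `c`,
#'   `d`, `n_overlap`, `odds_ratio`, `p_value`, `p_corrected`.
#' @export
fisher_gene_set_enrichment <- function(query, collection, universe,
                                       correction = "BH") {
  if (length(universe) == 0) stop("empty universe")
  if (length(query) == 0) stop("empty query set")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside universe dropped: ",
            paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
    query <- intersect(query, universe)
    if (!length(query)) stop("no query genes left inside the universe")
  }
  if (!is.null(attr(collection, "universe"))) {
    universe <- intersect(universe, attr(collection, "universe"))
  }
  background <- setdiff(universe, query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], universe)
    a <- length(intersect(query, s))
    b <- length(query) - a
    c <- length(intersect(background, s))
    d <- length(background) - c
    data.frame(set = nm, a = a, b = b, c = c, d = d, n_overlap = a,
               odds_ratio = sample_odds_ratio(a, b, c, d),
               p_value = fisher_p(a, b, c, d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  method <- if (toupper(correction) %in% c("BH", "BY")) toupper(correction) else tolower(correction)
  out$p_corrected <- stats::p.adjust(out$p_value, method = method)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Intolerance burden of a gene set (RVIS, pLI, hot zone)
#'
#' Treats the three derived intolerance flags — `intolerant` (RVIS
#' percentile <= 25), `extreme_pli` (pLI > 0.9) and `hot_zone` (both) — as
#' gene sets and runs the same Fisher machinery against the annotated
#' universe. Genes without annotation are excluded from both query and
#' background (reported via a message).
#'
#' @param query Query gene set.
#' @param annotations Data frame from [read_intolerance()] /
#'   [intolerance_flags()].
#' @param universe Gene universe; default all annotated genes.
#' @param correction Multiple-testing method; default `"BH"`.
#' @return An `"enrichment_result"` data frame with rows `intolerant`,
#'   `extreme_pli`, `hot_zone`.
#' @export
intolerance_burden <- function(query, annotations, universe = annotations$gene,
                               correction = "BH") {
  if (!all(c("intolerant", "extreme_pli", "hot_zone") %in% names(annotations))) {
    annotations <- intolerance_flags(annotations)
  }
  annotated <- intersect(universe, annotations$gene)
  dropped <- setdiff(union(universe, query), annotated)
  if (length(dropped)) {
    message(length(dropped), " unannotated gene(s) excluded from intolerance burden")
  }
  sets <- list(
    intolerant = annotations$gene[annotations$intolerant],
    extreme_pli = annotations$gene[annotations$extreme_pli],
    hot_zone = annotations$gene[annotations$hot_zone]
  )
  fisher_gene_set_enrichment(intersect(query, annotated), sets, annotated,
                             correction = correction)
}

#' Mutation-class burden between two co-expression modules
#'
#' Contrasts the prevalence of the two extreme-mutation classes (LoF vs
#' damaging missense) between modules M1 and M2 at three levels: DNMs
#' (mutation count), genes (genes carrying at least one such mutation) and
#' samples (distinct carriers; a sample carrying several DNMs of a class in
#' a module counts once). Each level yields per class a 2x2 table
#' \[class in M1, other class in M1; class in M2, other class in M2\] with
#' the odds ratio oriented M1/M2 and a two-sided Fisher exact p.
#'
#' @param counts An `"extreme_counts"` table (with the `samples_lof` /
#'   `samples_dmis` list columns for the sample level).
#' @param modules A `"coexpression_modules"` object or named label vector.
#' @param m1,m2 Module labels to contrast; defaults 1 and 2.
#' @return Data frame of class `"module_burden"` with 6 rows (2 classes x 3
#'   levels): `level`, `class`, `m1_count`, `m1_other`, `m2_count`,
#'   `m2_other`, `odds_ratio`, `p_value`, `haldane` (flag: a zero margin was
#'   corrected).
#' @export
module_mutation_burden <- function(counts, modules, m1 = 1, m2 = 2) {
  labels <- if (inherits(modules, "coexpression_modules")) modules$labels else modules
  g1 <- names(labels)[labels == m1]
  g2 <- names(labels)[labels == m2]
  if (!length(g1) || !length(g2)) stop("both modules must be nonempty")
  if (!all(c("samples_lof", "samples_dmis") %in% names(counts))) {
    stop("counts must carry samples_lof/samples_dmis (use count_extreme_by_gene)")
  }
  sub <- function(genes) counts[counts$gene %in% genes, , drop = FALSE]
  c1 <- sub(g1); c2 <- sub(g2)
  level_counts <- function(cc) {
    list(
      dnm = c(LoF = sum(cc$n_lof), DMis = sum(cc$n_dmis)),
      gene = c(LoF = sum(cc$n_lof > 0), DMis = sum(cc$n_dmis > 0)),
      sample = c(LoF = length(unique(unlist(cc$samples_lof))),
                 DMis = length(unique(unlist(cc$samples_dmis))))
    )
  }
  l1 <- level_counts(c1); l2 <- level_counts(c2)
  rows <- list()
  for (lev in c("dnm", "gene", "sample")) {
    for (cls in c("LoF", "DMis")) {
      other <- setdiff(c("LoF", "DMis"), cls)
      a <- l1[[lev]][[cls]]; b <- l1[[lev]][[other]]
      c <- l2[[lev]][[cls]]; d <- l2[[lev]][[other]]
      rows[[paste(lev, cls)]] <- data.frame(
        level = lev, class = cls,
        m1_count = a, m1_other = b, m2_count = c, m2_other = d,
        odds_ratio = sample_odds_ratio(a, b, c, d),
        p_value = fisher_p(a, b, c, d),
        haldane = any(c(a, b, c, d) == 0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("module_burden", "data.frame")
  out
}
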