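#' Recognised de novo variant classes
#'
#' The coding classes are everything except `"noncoding"`; the
#' loss-of-function (LoF) classes follow the conventional bracketed
#' definition: frameshift or non-frameshift indel, stop-gain, stop-loss and
#' splicing SNV.
#'
#' @format Character vectors.
#' @name variant_classes
NULL

#' @rdname variant_classes
#' @export
DNM_CLASSES <- c(
  "frameshift_indel", "nonframeshift_indel", "stopgain", "stoploss",
  "splicing_snv", "missense", "synonymous", "noncoding"
)

#' @rdname variant_classes
#' @export
LOF_CLASSES <- c(
  "frameshift_indel", "nonframeshift_indel", "stopgain", "stoploss",
  "splicing_snv"
)

#' Column-name dialect for DNM tables
#'
#' Maps the canonical record fields onto the column names used by a
#' particular file. Any subset of names may be overridden.
#'
#' @param ... named overrides, e.g. `gene = "Gene.refGene"`.
#' @return Named character vector mapping field -> column name.
#' @export
dnm_dialect <- function(...) {
  d <- c(
    sample_id = "sample_id", cohort = "cohort", gene = "gene",
    chrom = "chrom", pos = "pos", ref = "ref", alt = "alt",
    variant_class = "variant_class", damaging_votes = "damaging_votes",
    max_maf = "max_maf"
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    d[names(ov)] <- ov
  }
  d
}

#' Read a trio de novo mutation table
#'
#' Reads a tab-separated DNM table (one row per de novo call in one trio
#' child) into the canonical record data frame. `"."` denotes missing.
#' A missense row with missing `damaging_votes` is treated as 0 votes (and
#' reported via a message); a missing `max_maf` is treated as 0 (unobserved
#' in the population databases).
#'
#' @param path File path to a TSV with a header row.
#' @param dialect Column-name mapping from [dnm_dialect()].
#' @return A `data.frame` with columns `sample_id`, `cohort`, `gene`,
#'   `chrom`, `pos`, `ref`, `alt`, `variant_class`, `damaging_votes`,
#'   `max_maf`, rows in file order.
#' @export
read_dnm_table <- function(path, dialect = dnm_dialect()) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = ".",
                           check.names = FALSE)
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols)) {
    stop("DNM table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    sample_id = raw[[dialect["sample_id"]]],
    cohort = raw[[dialect["cohort"]]],
    gene = trimws(raw[[dialect["gene"]]]),
    chrom = raw[[dialect["chrom"]]],
    pos = suppressWarnings(as.integer(raw[[dialect["pos"]]])),
    ref = raw[[dialect["ref"]]],
    alt = raw[[dialect["alt"]]],
    variant_class = raw[[dialect["variant_class"]]],
    damaging_votes = suppressWarnings(as.integer(raw[[dialect["damaging_votes"]]])),
    max_maf = suppressWarnings(as.numeric(raw[[dialect["max_maf"]]])),
    stringsAsFactors = FALSE
  )
  if (nrow(out)) {
    # line numbers are 1-based data rows + header
    bad_pos <- which(is.na(out$pos) & !is.na(raw[[dialect["pos"]]]))
    if (length(bad_pos)) {
      stop("unparsable pos at line ", bad_pos[1] + 1L, " of ", path)
    }
    bad_maf <- which(is.na(out$max_maf) & !is.na(raw[[dialect["max_maf"]]]))
    if (length(bad_maf)) {
      stop("unparsable max_maf at line ", bad_maf[1] + 1L, " of ", path)
    }
    unknown <- setdiff(unique(out$variant_class), DNM_CLASSES)
    if (length(unknown)) {
      stop("unknown variant class(es) in ", path, ": ",
           paste(unknown, collapse = ", "))
    }
    miss_votes <- is.na(out$damaging_votes) & out$variant_class == "missense"
    if (any(miss_votes)) {
      message(sum(miss_votes), " missense row(s) without damaging_votes treated as 0 votes")
      out$damaging_votes[miss_votes] <- 0L
    }
    out$max_maf[is.na(out$max_maf)] <- 0
  }
  validate_dnm_table(out)
  out
}

validate_dnm_table <- function(dnm) {
  stopifnot(is.data.frame(dnm))
  req <- c("sample_id", "cohort", "gene", "chrom", "pos", "ref", "alt",
           "variant_class", "damaging_votes", "max_maf")
  missing_cols <- setdiff(req, names(dnm))
  if (length(missing_cols)) {
    stop("DNM data frame missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(dnm) == 0) return(invisible(dnm))
  if (any(dnm$pos < 1, na.rm = TRUE)) stop("pos must be >= 1 (1-based coordinates)")
  if (any(dnm$max_maf < 0 | dnm$max_maf > 1, na.rm = TRUE)) stop("max_maf must lie in [0, 1]")
  v <- dnm$damaging_votes[!is.na(dnm$damaging_votes)]
  if (any(v < 0 | v > 14)) stop("damaging_votes must lie in 0..14")
  unknown <- setdiff(unique(dnm$variant_class), DNM_CLASSES)
  if (length(unknown)) stop("unknown variant class(es): ", paste(unknown, collapse = ", "))
  invisible(dnm)
}

#' Write a DNM table as TSV
#'
#' @param dnm DNM record data frame.
#' @param path Output path. Missing values are written as `"."`.
#' @export
write_dnm_table <- function(dnm, path) {
  validate_dnm_table(dnm)
  write_tsv(dnm, path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop exact duplicate DNM reports
#'
#' Optional deduplication of identical (sample, chrom, pos, ref, alt)
#' reports that can arise when overlapping cohorts are pooled. The first
#' occurrence is kept.
#'
#' @param dnm DNM record data frame.
#' @return The data frame without exact duplicates, order preserved.
#' @export
drop_duplicate_dnms <- function(dnm) {
  key <- paste(dnm$sample_id, dnm$chrom, dnm$pos, dnm$ref, dnm$alt, sep = "\r")
  dnm[!duplicated(key), , drop = FALSE]
}

#' Retain rare coding de novo mutations
#'
#' Removes non-exonic calls and common variants. A record is kept iff its
#' class is coding (not `"noncoding"`) and its maximum population minor
#' allele frequency is strictly below `maf_threshold` (a variant observed at
#' exactly the threshold is removed). Synonymous records are coding and are
#' retained at this stage.
#'
#' @param dnm DNM record data frame.
#' @param maf_threshold Frequency cutoff; default 0.001.
#' @return Filtered data frame, row order preserved.
#' @export
filter_coding_rare <- function(dnm, maf_threshold = 0.001) {
  validate_dnm_table(dnm)
  keep <- dnm$variant_class != "noncoding" & dnm$max_maf < maf_threshold
  dnm[keep, , drop = FALSE]
}

#' Classify coding DNMs into extreme-mutation classes
#'
#' LoF classes (see [LOF_CLASSES]) map to `"LoF"`; missense calls judged
#' damaging by at least `min_votes` of the 14 in-silico predictors map to
#' `"DMis"`; everything else (sub-threshold missense, synonymous) is
#' `"other"`. Noncoding input is a precondition violation: records must have
#' passed [filter_coding_rare()].
#'
#' @param variant_class Character vector of variant classes (or a DNM record
#'   data frame, in which case `damaging_votes` is taken from it).
#' @param damaging_votes Integer votes in 0..14 (used for missense only).
#' @param min_votes Damaging-vote threshold, default 8.
#' @param lof_includes_nonframeshift_indels Keep non-frameshift indels in the
#'   LoF class (default `TRUE`, matching the conventional bracketed LoF
#'   definition).
#' @return Character vector in `{"LoF","DMis","other"}`.
#' @export
classify_extreme <- function(variant_class, damaging_votes = NULL, min_votes = 8,
                             lof_includes_nonframeshift_indels = TRUE) {
  if (is.data.frame(variant_class)) {
    damaging_votes <- variant_class$damaging_votes
    variant_class <- variant_class$variant_class
  }
  if (any(variant_class == "noncoding")) {
    stop("noncoding records must be removed by filter_coding_rare() before classification")
  }
  lof <- LOF_CLASSES
  if (!lof_includes_nonframeshift_indels) lof <- setdiff(lof, "nonframeshift_indel")
  out <- rep("other", length(variant_class))
  out[variant_class %in% lof] <- "LoF"
  if (is.null(damaging_votes)) damaging_votes <- rep(0L, length(variant_class))
  damaging_votes[is.na(damaging_votes)] <- 0L
  out[variant_class == "missense" & damaging_votes >= min_votes] <- "DMis"
  out
}

#' Aggregate extreme-mutation counts per gene
#'
#' @param dnm Filtered DNM record data frame (output of
#'   [filter_coding_rare()]).
#' @param min_votes,lof_includes_nonframeshift_indels Passed to
#'   [classify_extreme()].
#' @return A `data.frame` of class `"extreme_counts"` with one row per gene
#'   observed in `dnm`: `gene`, `n_lof`, `n_dmis`, `n_total_dnms` (all coding
#'   DNMs including synonymous), plus list columns `samples_lof` and
#'   `samples_dmis` holding the distinct contributing sample ids.
#' @export
count_extreme_by_gene <- function(dnm, min_votes = 8,
                                  lof_includes_nonframeshift_indels = TRUE) {
  validate_dnm_table(dnm)
  if (nrow(dnm) == 0) {
    out <- data.frame(gene = character(), n_lof = integer(), n_dmis = integer(),
                      n_total_dnms = integer(), stringsAsFactors = FALSE)
    out$samples_lof <- list()
    out$samples_dmis <- list()
    class(out) <- c("extreme_counts", "data.frame")
    return(out)
  }
  cls <- classify_extreme(dnm$variant_class, dnm$damaging_votes, min_votes,
                          lof_includes_nonframeshift_indels)
  genes <- sort(unique(dnm$gene))
  idx <- split(seq_len(nrow(dnm)), factor(dnm$gene, levels = genes))
  n_lof <- vapply(idx, function(i) sum(cls[i] == "LoF"), integer(1))
  n_dmis <- vapply(idx, function(i) sum(cls[i] == "DMis"), integer(1))
  n_tot <- lengths(idx)
  s_lof <- lapply(idx, function(i) unique(dnm$sample_id[i][cls[i] == "LoF"]))
  s_dmis <- lapply(idx, function(i) unique(dnm$sample_id[i][cls[i] == "DMis"]))
  out <- data.frame(gene = genes, n_lof = unname(n_lof), n_dmis = unname(n_dmis),
                    n_total_dnms = unname(as.integer(n_tot)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$samples_lof <- unname(s_lof)
  out$samples_dmis <- unname(s_dmis)
  class(out) <- c("extreme_counts", "data.frame")
  out
}

#' Cohort description
#'
#' @param label `"case"` or `"control"`.
#' @param n_trios Positive number of sequenced trios.
#' @return List of class `"cohort_spec"`.
#' @export
cohort_spec <- function(label = c("case", "control"), n_trios) {
  label <- match.arg(label)
  n_trios <- as.integer(n_trios)
  if (is.na(n_trios) || n_trios <= 0) stop("n_trios must be a positive integer")
  structure(list(label = label, n_trios = n_trios), class = "cohort_spec")
}

# ---- gene sets (GMT) --------------------------------------------------------

#' Gene-set collection
#'
#' A named list of nonempty gene-symbol sets, optionally restricted to a
#' gene universe (enrichment computations intersect each set with the
#' universe when one is attached).
#'
#' @param sets Named list of character vectors.
#' @param universe Optional character vector of eligible genes.
#' @return The list with class `"gene_set_collection"` and a `universe`
#'   attribute.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) stop("every set must be named")
  if (any(lengths(sets) == 0)) stop("every gene set must be nonempty")
  sets <- lapply(sets, function(s) unique(trimws(s)))
  structure(sets, universe = universe, class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' One set per line: name TAB description TAB gene TAB gene ...
#'
#' @param path GMT file path.
#' @param universe Optional gene universe to attach.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("GMT line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  gene_set_collection(sets, universe = universe)
}

#' Write gene sets to a GMT file
#'
#' @param collection A [gene_set_collection()] or plain named list.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(collection))
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], descriptions[i], collection[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- background mutation-rate tables ----------------------------------------

#' Read a per-gene background mutation-rate table
#'
#' The table must carry either per-class rates (`mu_lof`, `mu_dmis`) or a
#' single total rate (`mu_total`), in which case a configurable split is
#' applied (and reported via a message): by default 10% of the total rate to
#' LoF and 30% to damaging missense.
#'
#' @param path TSV path with a `gene` column.
#' @param source Rate-model label, conventionally one of `"GC"`, `"SC"`,
#'   `"MF"`, `"DM"`.
#' @param split Named fractions `c(lof=, dmis=)` used when only `mu_total`
#'   is present.
#' @return A `data.frame` of class `"rate_table"` with columns `gene`,
#'   `mu_lof`, `mu_dmis` and a `source` attribute.
#' @export
read_rate_table <- function(path, source = "GC", split = c(lof = 0.1, dmis = 0.3)) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                           stringsAsFactors = FALSE)
  if (!"gene" %in% names(raw)) stop("rate table ", path, " lacks a 'gene' column")
  if (all(c("mu_lof", "mu_dmis") %in% names(raw))) {
    out <- raw[c("gene", "mu_lof", "mu_dmis")]
  } else if ("mu_total" %in% names(raw)) {
    message("rate table ", path, " provides mu_total only; applying split lof=",
            split[["lof"]], ", dmis=", split[["dmis"]])
    out <- data.frame(gene = raw$gene,
                      mu_lof = raw$mu_total * split[["lof"]],
                      mu_dmis = raw$mu_total * split[["dmis"]],
                      stringsAsFactors = FALSE)
  } else {
    stop("rate table ", path, " needs mu_lof+mu_dmis or mu_total columns")
  }
  rate_table(out, source)
}

#' Construct/validate a rate table
#'
#' @param df Data frame with `gene`, `mu_lof`, `mu_dmis`.
#' @param source Rate-model label.
#' @return Classed `"rate_table"` data frame.
#' @export
rate_table <- function(df, source = "GC") {
  stopifnot(all(c("gene", "mu_lof", "mu_dmis") %in% names(df)))
  if (anyDuplicated(df$gene)) stop("duplicate gene keys in rate table")
  if (any(!is.finite(df$mu_lof)) || any(!is.finite(df$mu_dmis)) ||
      any(df$mu_lof < 0) || any(df$mu_dmis < 0)) {
    stop("mutation rates must be finite and nonnegative")
  }
  df$gene <- trimws(df$gene)
  structure(df[c("gene", "mu_lof", "mu_dmis")], source = source,
            class = c("rate_table", "data.frame"))
}

#' Write a rate table as TSV
#'
#' @param rates A [rate_table()].
#' @param path Output path.
#' @export
write_rate_table <- function(rates, path) {
  write_tsv(as.data.frame(rates)[c("gene", "mu_lof", "mu_dmis")], path)
}

# ---- intolerance annotations ------------------------------------------------

#' Read per-gene intolerance annotations (RVIS percentile and pLI)
#'
#' @param path TSV with columns `gene`, `rvis_percentile` (0..100) and
#'   `pli` (0..1).
#' @return Data frame with the derived flags of [intolerance_flags()].
#' @export
read_intolerance <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "rvis_percentile", "pli") %in% names(df)))
  intolerance_flags(df)
}

#' Derive intolerance flags
#'
#' `intolerant`: RVIS percentile in the most-intolerant top 25%
#' (`rvis_percentile <= 25`); `extreme_pli`: pLI strictly greater than 0.9;
#' `hot_zone`: both.
#'
#' @param df Data frame with `gene`, `rvis_percentile`, `pli`.
#' @return The data frame with logical columns `intolerant`, `extreme_pli`,
#'   `hot_zone` appended.
#' @export
intolerance_flags <- function(df) {
  if (any(df$rvis_percentile < 0 | df$rvis_percentile > 100, na.rm = TRUE)) {
    stop("rvis_percentile must lie in [0, 100]")
  }
  if (any(df$pli < 0 | df$pli > 1, na.rm = TRUE)) stop("pli must lie in [0, 1]")
  df$intolerant <- !is.na(df$rvis_percentile) & df$rvis_percentile <= 25
  df$extreme_pli <- !is.na(df$pli) & df$pli > 0.9
  df$hot_zone <- df$intolerant & df$extreme_pli
  df
}

# ---- expression matrix + metadata -------------------------------------------

#' Read an expression matrix (genes x samples)
#'
#' @param path TSV whose first column holds gene symbols and remaining
#'   columns one sample each.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- trimws(df[[1]])
  if (anyNA(m)) stop("expression matrix contains missing values after preprocessing")
  m
}

#' Write an expression matrix as TSV (gene column first)
#'
#' @param expr Genes x samples numeric matrix.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read sample metadata (region, developmental period, age)
#'
#' @param path TSV with columns `sample_id`, `region`, `period`, `age`.
#' @return Data frame; `period` is validated against [brain_periods()].
#' @export
read_sample_info <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "region", "period", "age") %in% names(df)))
  bad <- setdiff(unique(df$period), brain_periods())
  if (length(bad)) stop("unknown developmental period(s): ", paste(bad, collapse = ", "))
  df
}

# ---- interaction networks ---------------------------------------------------

#' Construct a gene interaction network
#'
#' @param edges Data frame with columns `gene1`, `gene2`, `weight`
#'   (nonnegative). Self-loops are rejected; duplicate unordered pairs are
#'   rejected.
#' @param nodes Node universe (all genes eligible to appear); defaults to
#'   the genes present in `edges`.
#' @return List of class `"gene_network"` with elements `edges` and `nodes`.
#' @export
gene_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("gene1", "gene2", "weight") %in% names(edges)))
  if (any(edges$gene1 == edges$gene2)) stop("self-loops are not allowed")
  if (any(edges$weight < 0)) stop("edge weights must be nonnegative")
  key <- ifelse(edges$gene1 < edges$gene2,
                paste(edges$gene1, edges$gene2, sep = "\r"),
                paste(edges$gene2, edges$gene1, sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate unordered gene pair(s) in edge list")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene1, edges$gene2)))
  outside <- setdiff(unique(c(edges$gene1, edges$gene2)), nodes)
  if (length(outside)) stop("edge endpoint(s) outside node universe: ",
                            paste(utils::head(outside, 5), collapse = ", "))
  structure(list(edges = edges[c("gene1", "gene2", "weight")], nodes = nodes),
            class = "gene_network")
}

#' Read a STRING-style interaction edge list
#'
#' Edges with combined score below `score_min` are dropped at load (the
#' default 400 is the conventional "medium confidence" cutoff).
#'
#' @param path TSV with columns `gene1`, `gene2`, `score`.
#' @param score_min Minimum retained score; default 400.
#' @param nodes Optional node universe.
#' @return A [gene_network()].
#' @export
read_edge_list <- function(path, score_min = 400, nodes = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene1", "gene2", "score") %in% names(df)))
  df <- df[df$score >= score_min, , drop = FALSE]
  names(df)[names(df) == "score"] <- "weight"
  gene_network(df, nodes = nodes)
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}
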