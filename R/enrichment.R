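# Gene-level scoring: node -> gene mapping, normalized group averages,
# permutation tests and correlations with evolutionary properties.

#' Read a node-annotation TSV
#'
#' Four tab-separated columns per gene:
#' `gene<TAB>nodes(semicolon-sep)<TAB>property:value pairs(semicolon-sep)<TAB>groups(semicolon-sep)`,
#' e.g. `RAF1\tRaf;Raf_i\tdnds:0.07;broadness:20\tkinase;oncogene`.
#' Empty third/fourth fields are allowed (missing properties, no group).
#' Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return A tibble with columns `gene`, `nodes` (list of node ids),
#'   `properties` (list of named numeric vectors) and `groups` (list of
#'   character vectors).
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  split_semi <- function(s) {
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
    parts[nzchar(parts)]
  }
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) {
      stop("annotation line ", i, ": expected at least gene and nodes",
           call. = FALSE)
    }
    f <- c(f, rep("", 4L - length(f)))
    props <- split_semi(f[3L])
    pv <- numeric(0)
    for (p in props) {
      kv <- strsplit(p, ":", fixed = TRUE)[[1L]]
      if (length(kv) != 2L || is.na(suppressWarnings(as.numeric(kv[2L])))) {
        stop("annotation line ", i, ": bad property '", p, "'",
             call. = FALSE)
      }
      pv[kv[1L]] <- as.numeric(kv[2L])
    }
    tibble::tibble(gene = trimws(f[1L]), nodes = list(split_semi(f[2L])),
                   properties = list(pv), groups = list(split_semi(f[4L])))
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$gene)) {
    stop("duplicate gene in annotation file", call. = FALSE)
  }
  out
}

#' Map node scores to gene scores
#'
#' A gene's evolvability (robustness) score is the mean of the scores of
#' the nodes that map to it; a node mapping to several genes contributes to
#' each of them, and genes none of whose nodes carry a score are dropped.
#'
#' @param node_scores Tibble from [node_scores()].
#' @param mapping Either a two-column tibble (`node`, `gene`) or an
#'   annotation tibble from [read_annotations()].
#' @return A tibble with `gene`, `n_nodes`, `evolvability`, `robustness`.
#' @export
gene_scores <- function(node_scores, mapping) {
  stopifnot(is.data.frame(node_scores),
            all(c("node", "evolvability", "robustness") %in%
                  names(node_scores)))
  map <- if (all(c("gene", "nodes") %in% names(mapping))) {
    tidyr::unnest(dplyr::select(mapping, "gene", node = "nodes"),
                  cols = "node")
  } else if (all(c("node", "gene") %in% names(mapping))) {
    dplyr::select(mapping, "gene", "node")
  } else {
    stop("mapping must have columns gene/nodes or node/gene", call. = FALSE)
  }
  if (nrow(map) == 0L) stop("empty node-gene mapping", call. = FALSE)
  joined <- dplyr::inner_join(map, node_scores, by = "node")
  if (nrow(joined) == 0L) {
    stop("mapping covers no scored node", call. = FALSE)
  }
  dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(joined, .data$gene),
      n_nodes = dplyr::n(),
      evolvability = mean(.data$evolvability),
      robustness = mean(.data$robustness),
      .groups = "drop"
    ),
    .data$gene
  )
}

#' Normalized average group score
#'
#' Mean score of a gene group divided by the mean score over the whole gene
#' universe: values above 1 mark groups enriched in the chosen score.
#' Scale-invariant by construction.
#'
#' @param table Gene-score tibble from [gene_scores()].
#' @param group Character vector of gene ids (intersected with the
#'   universe).
#' @param which `"evolvability"` or `"robustness"`.
#' @return A single ratio.
#' @export
normalized_group_score <- function(table, group,
                                   which = c("evolvability", "robustness")) {
  which <- match.arg(which)
  scores <- setNames(table[[which]], table$gene)
  members <- intersect(group, table$gene)
  if (length(members) == 0L) stop("empty group", call. = FALSE)
  u <- mean(scores)
  if (u == 0) stop("universe mean score is 0", call. = FALSE)
  mean(scores[members]) / u
}

#' Permutation test for group-score enrichment
#'
#' Tests whether the mean score of a gene group exceeds (one-sided,
#' `alternative = "greater"`) what random groups of the same size achieve:
#' each permutation draws `|group|` genes from the universe without
#' replacement, and the p-value uses the finite-sample correction
#' `p = (1 + #(permuted mean >= observed)) / (n_perm + 1)`, so `p` is never
#' below `1/(n_perm + 1)`.
#'
#' @inheritParams normalized_group_score
#' @param n_perm Number of permutations (default 100,000).
#' @param seed Optional integer seed.
#' @param alternative `"greater"` or `"less"`.
#' @return A one-row tibble with `group_size`, `universe_size`,
#'   `observed_mean`, `normalized_score`, `n_perm` and `p_value`.
#' @export
permutation_test <- function(table, group,
                             which = c("evolvability", "robustness"),
                             n_perm = 100000L, seed = NULL,
                             alternative = c("greater", "less")) {
  which <- match.arg(which)
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 1L)
  scores <- setNames(table[[which]], table$gene)
  members <- intersect(group, table$gene)
  m <- length(members)
  if (m == 0L) stop("empty group", call. = FALSE)
  if (m > length(scores)) stop("group larger than universe", call. = FALSE)
  observed <- mean(scores[members])
  exceed <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      pm <- mean(sample(scores, m))
      hit <- if (alternative == "greater") pm >= observed else pm <= observed
      if (hit) hits <- hits + 1L
    }
    hits
  })
  tibble::tibble(
    which = which, group_size = m, universe_size = length(scores),
    observed_mean = observed,
    normalized_score = observed / mean(scores),
    n_perm = n_perm, alternative = alternative,
    p_value = (1 + exceed) / (n_perm + 1)
  )
}

#' Pearson correlation between gene scores and a numeric property
#'
#' Correlates the chosen score with a per-gene numeric property (e.g.
#' dN/dS evolutionary rate or species broadness).  Genes missing the
#' property are dropped pairwise and the effective `n` is reported.
#'
#' @inheritParams normalized_group_score
#' @param annotations Annotation tibble from [read_annotations()], or a
#'   tibble with columns `gene` and `value`.
#' @param property Property name to extract from the annotations (ignored
#'   when a `value` column is supplied directly).
#' @return A one-row tibble with `property`, `r`, `p_value` (two-sided,
#'   t-distributed) and `n`.
#' @export
correlate_scores <- function(table, annotations, property = NULL,
                             which = c("evolvability", "robustness")) {
  which <- match.arg(which)
  vals <- if ("value" %in% names(annotations)) {
    dplyr::select(annotations, "gene", "value")
  } else {
    stopifnot(!is.null(property), "properties" %in% names(annotations))
    tibble::tibble(
      gene = annotations$gene,
      value = vapply(annotations$properties, function(p) {
        if (property %in% names(p)) p[[property]] else NA_real_
      }, numeric(1))
    )
  }
  joined <- dplyr::inner_join(table, vals, by = "gene")
  joined <- joined[!is.na(joined$value), , drop = FALSE]
  if (nrow(joined) < 3L) {
    stop("fewer than 3 genes with both values", call. = FALSE)
  }
  x <- joined[[which]]
  y <- joined$value
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in scores or property", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(property = property %||% "value",
                 which = which,
                 r = unname(ct$estimate),
                 p_value = ct$p.value,
                 n = nrow(joined))
}

#' Genes belonging to an annotation group
#'
#' @param annotations Annotation tibble from [read_annotations()].
#' @param group Group id, e.g. `"oncogene"`.
#' @return Character vector of gene ids.
#' @export
annotation_group <- function(annotations, group) {
  keep <- vapply(annotations$groups, function(g) group %in% g, logical(1))
  annotations$gene[keep]
}
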