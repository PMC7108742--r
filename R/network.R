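## Interaction-network integration: local STRING-style protein-protein and
## miRNA-target tables, filtered to differentially expressed members, with
## inverse-sign miRNA-gene pairing and a combined strength ranking.

#' Load a local interaction table
#'
#' Dialects: `"string_pp"` is a whitespace/tab table with two identifier
#' columns and an integer combined score 0-1000 (divided by 1000 into
#' \[0, 1\]); `"mirna_targets"` is a table with a mature-miRNA column, a
#' target-gene column and an optional support-type column. Duplicate
#' undirected edges are collapsed keeping the maximum score; rows with a
#' malformed score are skipped and counted. Identifiers may be remapped via
#' an alias table (`alias` -> `canonical`).
#'
#' @param path file path.
#' @param dialect `"string_pp"` or `"mirna_targets"`.
#' @param alias optional data frame with columns `alias`, `canonical`.
#' @return list `edges` (data frame `id_a`, `id_b`, `score`), `n_skipped`.
#' @export
load_interaction_table <- function(path, dialect = c("string_pp", "mirna_targets"),
                                   alias = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = .missing_tokens, check.names = FALSE)
  if (dialect == "string_pp") {
    id_cols <- intersect(c("protein1", "protein2"), names(df))
    if (length(id_cols) < 2) id_cols <- names(df)[1:2]
    sc_col <- if ("combined_score" %in% names(df)) "combined_score"
              else names(df)[3]
    if (ncol(df) < 3)
      stop("string_pp table needs two identifier columns and a score; header was: ",
           paste(names(df), collapse = ", "))
    score <- suppressWarnings(as.numeric(df[[sc_col]]))
    bad <- is.na(score) | score < 0 | score > 1000
    edges <- data.frame(id_a = as.character(df[[id_cols[1]]][!bad]),
                        id_b = as.character(df[[id_cols[2]]][!bad]),
                        score = score[!bad] / 1000,
                        stringsAsFactors = FALSE)
  } else {
    if (ncol(df) < 2)
      stop("mirna_targets table needs miRNA and target columns; header was: ",
           paste(names(df), collapse = ", "))
    mir_col <- intersect(c("mirna", "miRNA", "mature_mirna_id"), names(df))
    gene_col <- intersect(c("target", "target_symbol", "gene"), names(df))
    mir_col <- if (length(mir_col)) mir_col[1] else names(df)[1]
    gene_col <- if (length(gene_col)) gene_col[1] else names(df)[2]
    sc_col <- intersect(c("score", "combined_score"), names(df))
    score <- if (length(sc_col)) suppressWarnings(as.numeric(df[[sc_col[1]]]))
             else rep(1, nrow(df))
    bad <- is.na(score)
    score[score > 1] <- score[score > 1] / 1000   # accept 0-1000 exports too
    edges <- data.frame(id_a = as.character(df[[mir_col]][!bad]),
                        id_b = as.character(df[[gene_col]][!bad]),
                        score = score[!bad],
                        stringsAsFactors = FALSE)
  }
  if (!is.null(alias)) {
    map <- stats::setNames(as.character(alias$canonical), as.character(alias$alias))
    hit_a <- edges$id_a %in% names(map)
    hit_b <- edges$id_b %in% names(map)
    edges$id_a[hit_a] <- map[edges$id_a[hit_a]]
    edges$id_b[hit_b] <- map[edges$id_b[hit_b]]
  }
  ## collapse duplicate undirected edges, keeping the maximum score
  key <- ifelse(edges$id_a <= edges$id_b,
                paste(edges$id_a, edges$id_b, sep = "\r"),
                paste(edges$id_b, edges$id_a, sep = "\r"))
  ord <- order(key, -edges$score)
  edges <- edges[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, n_skipped = sum(bad))
}

.annotate_nodes <- function(edges, dea_a, dea_b = dea_a) {
  ia <- match(edges$id_a, dea_a$id)
  ib <- match(edges$id_b, dea_b$id)
  edges$logFC_a <- dea_a$logFC[ia]; edges$FDR_a <- dea_a$FDR[ia]
  edges$logFC_b <- dea_b$logFC[ib]; edges$FDR_b <- dea_b$FDR[ib]
  edges
}

#' Protein-protein edges between differentially expressed members
#'
#' @param edges edge data frame from [load_interaction_table()].
#' @param dea a [dea_table()] for annotation.
#' @param sig_ids IDs called significant (both endpoints must be in it).
#' @return data frame of class `interaction_set`, type `"pp"`.
#' @export
extract_de_pairs <- function(edges, dea, sig_ids) {
  keep <- edges$id_a %in% sig_ids & edges$id_b %in% sig_ids
  out <- .annotate_nodes(edges[keep, , drop = FALSE], dea)
  out$type <- rep("pp", nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("interaction_set", "data.frame"))
}

#' miRNA-gene pairs with inverse fold changes
#'
#' Keeps a pair only when both members are significant in their own DEA and
#' their log-fold-changes have strictly opposite signs.
#'
#' @param mirna_edges edge list (`id_a` = miRNA, `id_b` = gene).
#' @param mirna_dea,gene_dea [dea_table()]s from the same cohort.
#' @param mirna_sig,gene_sig significant ID sets.
#' @return data frame of class `interaction_set`, type `"mirna_gene"`.
#' @export
integrate_inverse_pairs <- function(mirna_edges, mirna_dea, gene_dea,
                                    mirna_sig, gene_sig) {
  keep <- mirna_edges$id_a %in% mirna_sig & mirna_edges$id_b %in% gene_sig
  out <- .annotate_nodes(mirna_edges[keep, , drop = FALSE], mirna_dea, gene_dea)
  inv <- !is.na(out$logFC_a) & !is.na(out$logFC_b) &
         sign(out$logFC_a) * sign(out$logFC_b) < 0
  out <- out[inv, , drop = FALSE]
  out$type <- rep("mirna_gene", nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("interaction_set", "data.frame"))
}

#' Rank interaction edges by combined strength
#'
#' Edge strength is `score * (|logFC_a| + |logFC_b|) / 2`; ties break
#' lexicographically by (`id_a`, `id_b`). The full annotated table is always
#' returned alongside the top slice.
#'
#' @param edges an `interaction_set`.
#' @param top_n how many edges to keep in the top slice (default 100).
#' @return list `top` (first `top_n` edges), `all` (full table, ranked).
#' @export
rank_edges <- function(edges, top_n = 100) {
  stopifnot(top_n >= 1)
  strength <- edges$score * (abs(edges$logFC_a) + abs(edges$logFC_b)) / 2
  edges$strength <- strength
  ord <- order(-strength, edges$id_a, edges$id_b)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  list(top = utils::head(edges, top_n), all = edges)
}
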