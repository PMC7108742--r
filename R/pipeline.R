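## End-to-end orchestration: preprocessing by data type, optional
## clustering, DEA, repeated elastic-net selection with consensus, optional
## co-expression, survival screening and interaction networks, written to an
## analysis-organized output tree.

#' Run the full screening pipeline
#'
#' Stages are executed in order, each feeding the next: imputation (any
#' missing cells), data-type-specific normalization (`seq`: low-count
#' filter, TMM, voom; `array`: log2 + quantile; `ms`: log2 + median
#' centering; `other`: used as-is), distributional checks, optional k-means
#' clustering with BIC and MDS, differential expression for every pairwise
#' group contrast, repeated elastic-net selection with the DEA consensus,
#' optional co-expression modules, optional Cox survival screening, and
#' optional interaction-network integration. Results are returned and, when
#' `outdir` is given, written one analysis per subfolder.
#'
#' @param x an [expr_matrix()] or path to a matrix file.
#' @param meta a `sample_metadata` or path to a metadata file.
#' @param datatype data-type tag (used when `x` is a path).
#' @param id_col,group_col metadata column names (when `meta` is a path).
#' @param batch_col optional batch column included in the DEA design.
#' @param covariate_cols optional numeric covariate columns for the design.
#' @param transform,center normalization choices for continuous data
#'   (defaults by datatype).
#' @param log_offset add 1 before the log transform.
#' @param fdr,logfc significance cutoffs.
#' @param alpha elastic-net mixing parameter.
#' @param runs repeated elastic-net runs.
#' @param kmeans run clustering when `TRUE`.
#' @param wgcna `"none"`, `"de"` (modules on DEA-significant variables) or
#'   `"all"`.
#' @param survival run Cox screening (requires survival metadata columns).
#' @param surv_adjust adjustment covariates for the Cox models.
#' @param ppi,mirna optional interaction-table paths.
#' @param distcheck_vars variables to pass through distributional checks
#'   (0 disables).
#' @param outdir optional output directory.
#' @param overwrite allow writing into a non-empty `outdir`.
#' @param seed RNG seed governing every stochastic stage.
#' @return list of class `markerpipe_result` with per-stage results and, if
#'   written, the output `manifest`.
#' @export
run_pipeline <- function(x, meta, datatype = c("array", "seq", "ms", "other"),
                         id_col = "id", group_col = "group",
                         batch_col = NULL, covariate_cols = NULL,
                         transform = NULL, center = NULL, log_offset = FALSE,
                         fdr = 0.05, logfc = 1, alpha = 0.5, runs = 10,
                         kmeans = FALSE, wgcna = c("none", "de", "all"),
                         survival = FALSE, surv_adjust = "age",
                         ppi = NULL, mirna = NULL, distcheck_vars = 10,
                         outdir = NULL, overwrite = FALSE, seed = 1) {
  wgcna <- match.arg(wgcna)
  datatype <- match.arg(datatype)
  if (is.character(x)) x <- read_expression_matrix(x, datatype)
  if (is.character(meta)) meta <- read_metadata(meta, id_col, group_col)
  meta <- check_samples(x, meta)
  results <- list()
  report <- list(datatype = datatype_of(x),
                 n_variables = nrow(x), n_samples = ncol(x))

  ## --- preprocess ---------------------------------------------------------
  imp <- impute_missing(x, "lls")
  x <- imp$matrix
  report$n_imputed <- imp$n_imputed
  weights <- NULL
  if (datatype_of(x) == "seq") {
    flt <- filter_low_counts(x, meta)
    x <- flt$matrix
    report$n_removed <- length(flt$removed)
    factors <- tmm_factors(x)
    spec <- build_design(meta, batch_col, covariate_cols)
    vm <- voom_transform(x, factors, spec$design)
    y <- vm$logcpm
    weights <- vm$weights
    results$preprocess <- list(
      report = data.frame(sample = colnames(x), library_size = colSums(unclass(x)),
                          tmm_factor = factors),
      removed = data.frame(id = flt$removed),
      mean_variance_trend = vm$trend)
  } else {
    tr <- transform %||% switch(datatype_of(x), array = "log2", ms = "log2", "none")
    ce <- center %||% switch(datatype_of(x), array = "quantile", ms = "median", "none")
    y <- normalize_continuous(x, tr, ce, offset = log_offset)
    results$preprocess <- list(
      report = data.frame(transform = tr, center = ce,
                          n_imputed = imp$n_imputed))
  }

  ## --- distributional checks ---------------------------------------------
  if (distcheck_vars > 0) {
    dc <- distcheck_report(y, n_vars = distcheck_vars, replicates = 200,
                           seed = seed)
    results$distcheck <- list(
      moments = do.call(rbind, lapply(dc, function(r)
        data.frame(id = r$id, skewness = r$moments[1], kurtosis = r$moments[2],
                   best_fit = if (is.null(r$qqpp)) NA else r$qqpp$best))))
    report$distcheck <- dc
  }

  ## --- clustering ---------------------------------------------------------
  if (kmeans) {
    cl <- select_k_bic(t(unclass(y)), seed = seed)
    mds <- classical_mds(y)
    meta_aug <- as.data.frame(meta)
    meta_aug$kmeans_cluster <- cl$assignments
    results$cluster <- list(
      bic_curve = cl$per_k,
      assignments = data.frame(id = colnames(y), cluster = cl$assignments),
      mds = data.frame(id = rownames(mds$coords), mds$coords),
      metadata_with_clusters = meta_aug)
    report$cluster <- cl
  }

  ## --- differential expression -------------------------------------------
  dea <- run_dea(y, meta, batch_col, covariate_cols, weights, fdr, logfc)
  results$dea <- list()
  for (cn in names(dea)) {
    results$dea[[cn]] <- dea[[cn]]$table
    results$dea[[paste0(cn, "_up")]] <- data.frame(id = dea[[cn]]$up)
    results$dea[[paste0(cn, "_down")]] <- data.frame(id = dea[[cn]]$down)
  }
  report$dea <- dea
  first <- dea[[1]]
  sig_ids <- c(first$up, first$down)

  ## --- elastic-net selection ---------------------------------------------
  sel <- repeated_selection(y, sample_groups(meta), alpha = alpha,
                            runs = runs, base_seed = seed)
  cons <- consensus_overlap(sig_ids, sel$selected)
  results$select <- list(
    frequency = sel$frequency,
    runs = data.frame(run = seq_len(runs),
                      auc = sel$auc,
                      chosen_lambda = vapply(sel$runs, `[[`, 0, "chosen_lambda"),
                      split = vapply(sel$runs, `[[`, "", "split")),
    consensus = {
      tab <- first$table
      data.frame(id = cons$consensus,
                 logFC = tab$logFC[match(cons$consensus, tab$id)],
                 FDR = tab$FDR[match(cons$consensus, tab$id)])
    },
    venn = data.frame(region = names(cons$venn), count = as.integer(cons$venn)))
  report$select <- sel
  report$consensus <- cons

  ## --- co-expression ------------------------------------------------------
  if (wgcna != "none") {
    ids <- if (wgcna == "de") sig_ids else rownames(y)
    if (length(ids) >= 10) {
      sub <- y[rownames(y) %in% ids, , drop = FALSE]
      sft <- pick_soft_threshold(sub)
      adj <- adjacency_matrix(sub, sft$power)
      tom <- tom_from_adjacency(adj)
      mods <- detect_and_merge_modules(1 - tom, sub,
                                       min_size = min(20, max(3, nrow(sub) %/% 4)))
      conn <- intramodular_connectivity(adj, mods)
      top_tables <- if (length(conn$top))
        stats::setNames(conn$top, paste0("top_", names(conn$top))) else list()
      results$coexpr <- c(list(
        soft_threshold = sft$fit,
        modules = data.frame(id = rownames(sub), module = mods$labels,
                             kwithin = unname(conn$kwithin))),
        top_tables)
      if (!is.null(mods$eigengenes))
        results$coexpr$eigengenes <- data.frame(id = colnames(sub),
                                                mods$eigengenes)
      report$coexpr <- list(power = sft$power, modules = mods)
    } else {
      warning("too few variables for co-expression analysis; skipped")
    }
  }

  ## --- survival -----------------------------------------------------------
  if (survival) {
    adj_cols <- intersect(surv_adjust, names(meta))
    scr <- survival_screen(y, meta, adjust_for = adj_cols, fdr_cut = fdr)
    tab <- scr$table
    tab$log2HR <- tab$logHR / log(2)
    tab$log2HR_lo <- tab$ci_lo / log(2)
    tab$log2HR_hi <- tab$ci_hi / log(2)
    results$survival <- list(table = tab,
                             significant = data.frame(id = scr$significant))
    report$survival <- scr
  }

  ## --- interaction networks ----------------------------------------------
  if (!is.null(ppi)) {
    ppi_edges <- load_interaction_table(ppi, "string_pp")
    pp <- extract_de_pairs(ppi_edges$edges, first$table, sig_ids)
    ranked <- rank_edges(pp)
    results$network <- list(pp_all = ranked$all, pp_top = ranked$top)
    report$network_pp <- ranked
  }
  if (!is.null(mirna)) {
    stop("miRNA-gene integration needs a second (miRNA) run; use ",
         "integrate_inverse_pairs() directly with both DEA tables")
  }

  manifest <- NULL
  if (!is.null(outdir)) manifest <- write_output_tree(results, outdir, overwrite)
  structure(list(tables = results, report = report, manifest = manifest,
                 settings = list(fdr = fdr, logfc = logfc, alpha = alpha,
                                 runs = runs, seed = seed)),
            class = "markerpipe_result")
}

#' @export
print.markerpipe_result <- function(x, ...) {
  cat("markerpipe run\n")
  cat(sprintf("  data: %d variables x %d samples (%s)\n",
              x$report$n_variables, x$report$n_samples, x$report$datatype))
  first <- x$report$dea[[1]]
  cat(sprintf("  DEA (%s): %d up, %d down\n", names(x$report$dea)[1],
              length(first$up), length(first$down)))
  cat(sprintf("  elastic net: %d consensus of %d selected (mean AUC %s)\n",
              length(x$report$consensus$consensus),
              length(x$report$consensus$en),
              ifelse(all(is.na(x$report$select$auc)), "n/a",
                     sprintf("%.3f", mean(x$report$select$auc, na.rm = TRUE)))))
  invisible(x)
}
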