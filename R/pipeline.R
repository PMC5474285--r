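# End-to-end orchestration: filter -> target merge -> networks ->
# enrichment -> organ localization -> differential-expression
# intersection, with a JSON run report whose counts are auditable against
# the emitted files.

#' Pipeline configuration
#'
#' Collects all file paths and parameters for [run_pipeline()]. Referenced
#' paths must exist at construction. The enrichment, organ and
#' differential-expression stages are optional and run only when their
#' inputs are supplied.
#'
#' @param compounds Path to the compound ADME TSV.
#' @param targets Path to the target TSV.
#' @param edges Character vector of edge-table TSV paths.
#' @param out_dir Output directory (created if missing).
#' @param rescue Optional path to a rescue-id list (one id per line).
#' @param gmt Optional GMT path for pathway enrichment.
#' @param expression Optional expression-matrix TSV for organ calls.
#' @param organ_panel Optional path to a panel tissue list (one per line);
#'   defaults to all tissues of the expression matrix.
#' @param de_lists Optional character vector of per-dataset gene-list
#'   files (one symbol per line), e.g. exported top-250 tables.
#' @param thresholds A [filter_thresholds()] object.
#' @param top_n Top-list length for reporting (default 250).
#' @param p_cutoff Enrichment raw p-value cutoff in (0, 1), default 0.01.
#' @param seed Integer seed recorded in the report (the pipeline itself
#'   is deterministic; the seed funnels into any generator-produced
#'   inputs upstream).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(compounds, targets, edges, out_dir,
                            rescue = NULL, gmt = NULL, expression = NULL,
                            organ_panel = NULL, de_lists = NULL,
                            thresholds = filter_thresholds(),
                            top_n = 250, p_cutoff = 0.01, seed = 1) {
  stopifnot(top_n >= 1, p_cutoff > 0, p_cutoff < 1,
            inherits(thresholds, "filter_thresholds"))
  paths <- c(compounds, targets, edges, rescue, gmt, expression,
             organ_panel, de_lists)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(compounds = compounds, targets = targets, edges = edges,
                 out_dir = out_dir, rescue = rescue, gmt = gmt,
                 expression = expression, organ_panel = organ_panel,
                 de_lists = de_lists, thresholds = thresholds,
                 top_n = top_n, p_cutoff = p_cutoff, seed = seed),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full network-pharmacology pipeline
#'
#' Executes, in order: ADME filtering, interaction merging, compound-
#' target network construction with centrality, optional pathway
#' enrichment (and target-pathway network), optional organ localization,
#' and optional differential-expression union/intersection. Writes stage
#' outputs (networks as SIF + GraphML + edge TSV with node attributes,
#' tables as TSV) under `config$out_dir` plus a JSON run report, and
#' returns the report invisibly-printable as a `run_report` list. A stage
#' failure aborts with the stage name; files already written are kept and
#' listed in `MANIFEST.txt` with an `INCOMPLETE` marker.
#'
#' Identical configs produce identical reports apart from the `timestamp`
#' field.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list (also written to `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  note <- function(path) outputs <<- c(outputs, path)
  manifest <- file.path(config$out_dir, "MANIFEST.txt")
  on.exit(writeLines(c("INCOMPLETE", outputs), manifest), add = TRUE)

  report <- list(seed = config$seed, timestamp = format(Sys.time()))

  compounds <- run_stage("filter", read_compound_table(config$compounds))
  rescue <- if (is.null(config$rescue)) character(0) else
    readLines(config$rescue, warn = FALSE)
  filt <- run_stage("filter",
                    apply_adme_filter(compounds, config$thresholds, rescue))
  retained <- c(filt$passed, filt$rescued)
  report$compounds_total <- nrow(compounds)
  report$compounds_passed <- length(filt$passed)
  report$compounds_rescued <- length(filt$rescued)
  report$compounds_excluded <- length(filt$excluded)

  targets <- run_stage("map_targets", read_target_table(config$targets))
  edge_tables <- run_stage("map_targets",
                           lapply(config$edges, read_edge_table))
  catalog <- run_stage("map_targets",
                       merge_interactions(edge_tables, retained, targets))
  report$unique_targets <- length(unique(catalog$edges$uniprot_id))
  report$edge_count <- nrow(catalog$edges)
  report$avg_targets_per_compound <-
    if (length(catalog$per_compound_counts))
      average_targets_per_compound(catalog) else NA_real_

  ct <- run_stage("network", {
    if (!nrow(catalog$edges)) stop("no interaction edges after merging")
    build_bipartite(catalog$edges[c("compound_id", "uniprot_id")],
                    left_ids = retained,
                    right_ids = unique(catalog$edges$uniprot_id))
  })
  cent <- run_stage("network", centrality_table(ct))
  for (dialect in c("sif", "graphml", "edge_tsv")) {
    path <- file.path(config$out_dir,
                      paste0("ct_network.", sub("edge_tsv", "edges.tsv", dialect)))
    run_stage("network", write_network(ct, path, dialect, centrality = cent))
    note(path)
    note(node_attr_path(path))
  }
  report$degree_leaders <- list(
    compounds = utils::head(rank_nodes(cent, "degree", "left"), 5),
    targets = utils::head(rank_nodes(cent, "degree", "right"), 5))

  target_symbols <- catalog$targets$gene_symbol
  if (!is.null(config$gmt)) {
    collection <- run_stage("enrich", read_gmt(config$gmt))
    enr <- run_stage("enrich",
                     suppressWarnings(run_enrichment(target_symbols, collection,
                                                     p_cutoff = config$p_cutoff)))
    path <- file.path(config$out_dir, "enrichment.tsv")
    utils::write.table(enr, path, sep = "\t", quote = FALSE, row.names = FALSE)
    note(path)
    report$pathways_passing_cutoff <- nrow(enr)
    if (nrow(enr)) {
      tp_edges <- do.call(rbind, lapply(seq_len(nrow(enr)), function(i) {
        genes <- strsplit(enr$genes[i], ",", fixed = TRUE)[[1]]
        if (!length(genes) || !nzchar(genes[1])) return(NULL)
        data.frame(from = genes, to = enr$set_id[i], stringsAsFactors = FALSE)
      }))
      if (!is.null(tp_edges) && nrow(tp_edges)) {
        tp <- run_stage("network",
                        build_bipartite(tp_edges,
                                        left_ids = unique(tp_edges$from),
                                        right_ids = enr$set_id))
        path <- file.path(config$out_dir, "tp_network.edges.tsv")
        run_stage("network",
                  write_network(tp, path, "edge_tsv",
                                centrality = centrality_table(tp)))
        note(path)
        note(node_attr_path(path))
      }
    }
  }

  if (!is.null(config$expression)) {
    mat <- run_stage("organs", read_expression_matrix(config$expression))
    panel <- if (is.null(config$organ_panel)) colnames(mat) else
      readLines(config$organ_panel, warn = FALSE)
    calls <- run_stage("organs", above_average_calls(mat, panel = panel))
    freq <- run_stage("organs", organ_frequency(calls))
    path <- file.path(config$out_dir, "organ_frequency.tsv")
    utils::write.table(freq, path, sep = "\t", quote = FALSE, row.names = FALSE)
    note(path)
    onet <- run_stage("organs", build_organ_network(calls))
    path <- file.path(config$out_dir, "organ_network.sif")
    run_stage("organs", write_network(onet, path, "sif"))
    note(path)
    note(node_attr_path(path))
    report$organ_frequency <- freq
    report$genes_with_panel_call <-
      length(genes_in_at_least_k_organs(calls, 1))
  }

  if (!is.null(config$de_lists)) {
    lists <- run_stage("de", lapply(config$de_lists, function(p)
      readLines(p, warn = FALSE)))
    de_union <- run_stage("de", union_dedupe(lists))
    common <- run_stage("de",
                        intersect_targets(de_union, target_symbols, targets))
    path <- file.path(config$out_dir, "common_targets.tsv")
    utils::write.table(common, path, sep = "\t", quote = FALSE, row.names = FALSE)
    note(path)
    report$union_de_size <- length(de_union)
    report$intersection_genes <- common$gene_symbol
  }

  report$output_files <- outputs
  path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  note(path)
  on.exit()  # success: replace the INCOMPLETE manifest
  writeLines(c("COMPLETE", outputs), manifest)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("herbnet run report\n")
  cat(sprintf("  compounds: %d total, %d passed, %d rescued, %d excluded\n",
              x$compounds_total, x$compounds_passed, x$compounds_rescued,
              x$compounds_excluded))
  cat(sprintf("  targets: %d unique over %d edges (%.1f per compound)\n",
              x$unique_targets, x$edge_count, x$avg_targets_per_compound))
  if (!is.null(x$pathways_passing_cutoff)) {
    cat(sprintf("  pathways passing cutoff: %d\n", x$pathways_passing_cutoff))
  }
  if (!is.null(x$genes_with_panel_call)) {
    cat(sprintf("  genes with a panel organ call: %d\n", x$genes_with_panel_call))
  }
  if (!is.null(x$union_de_size)) {
    cat(sprintf("  DE union: %d genes; intersection with targets: %d\n",
                x$union_de_size, length(x$intersection_genes)))
  }
  invisible(x)
}
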