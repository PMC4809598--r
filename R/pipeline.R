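#' Default end-to-end run configuration
#'
#' All stage thresholds live in one list so the shipped defaults are the
#' study's settings: 10 M-read sample QC, RPKM >= 0.2 expressed filter,
#' 2/3 tissue-specificity share, 2-SD DE and edge rules, RIF |z| >= 2,
#' enrichment alpha 0.05.
#'
#' @param out_dir output directory (NULL disables file output).
#' @param seed integer seed for the whole run.
#' @param n_genes,animals_per_sire design scale for simulated runs.
#' @return a named list, also writable as YAML.
#' @export
default_config <- function(out_dir = NULL, seed = 1L, n_genes = 2000,
                           animals_per_sire = 8) {
  list(seed = as.integer(seed), out_dir = out_dir,
       simulate = TRUE, input_dir = NULL,
       n_genes = n_genes, animals_per_sire = animals_per_sire,
       min_reads = 1e7, rpkm_threshold = 0.2, ts_threshold = 2 / 3,
       log2_offset = 0.2, de_k = 2, rif_z = 2, pcit_k = 2,
       pcit_stat = "raw", tf_nodes = "all", enrichment_alpha = 0.05,
       exports = c("sif", "tsv"))
}

#' Validate pipeline input tables
#'
#' Schema checks with line-numbered findings for the TSV/CSV inputs of a
#' non-simulated run: counts must be non-negative numbers, lengths
#' positive, and sample metadata consistent (one sire group per animal).
#'
#' @param dir directory holding \code{counts.tsv},
#'   \code{gene_lengths.tsv} and \code{samples.tsv}.
#' @return data frame of findings (file, line, message); zero rows means
#'   the inputs validate.
#' @export
validate_inputs <- function(dir) {
  finding <- function(file, line, message)
    data.frame(file = file, line = line, message = message,
               stringsAsFactors = FALSE)
  out <- list()
  need <- c("counts.tsv", "gene_lengths.tsv", "samples.tsv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      out[[length(out) + 1]] <- finding(f, 0L, "file missing")
  if (length(out)) return(do.call(rbind, out))

  cts <- read_tsv(file.path(dir, "counts.tsv"))
  if (names(cts)[1] != "gene")
    out[[length(out) + 1]] <- finding("counts.tsv", 1L,
                                      "first column must be 'gene'")
  num <- as.matrix(cts[, -1, drop = FALSE])
  bad <- which(!is.finite(num) | num < 0, arr.ind = TRUE)
  for (i in seq_len(min(nrow(bad), 20)))
    out[[length(out) + 1]] <- finding(
      "counts.tsv", bad[i, 1] + 1L,
      sprintf("negative or non-numeric count in column '%s'",
              colnames(num)[bad[i, 2]]))

  len <- read_tsv(file.path(dir, "gene_lengths.tsv"))
  badl <- which(!is.finite(len$length) | len$length <= 0)
  for (i in head(badl, 20))
    out[[length(out) + 1]] <- finding("gene_lengths.tsv", i + 1L,
                                      "non-positive gene length")

  meta <- read_tsv(file.path(dir, "samples.tsv"))
  need_cols <- c("sample", "animal", "sire", "tissue")
  miss <- setdiff(need_cols, names(meta))
  if (length(miss)) {
    out[[length(out) + 1]] <- finding(
      "samples.tsv", 1L, paste("missing column(s):",
                               paste(miss, collapse = ", ")))
  } else {
    sires_per_animal <- tapply(meta$sire, meta$animal,
                               function(s) length(unique(s)))
    for (a in names(sires_per_animal)[sires_per_animal > 1]) {
      ln <- which(meta$animal == a)[1] + 1L
      out[[length(out) + 1]] <- finding(
        "samples.tsv", ln,
        sprintf("animal '%s' appears in more than one sire group", a))
    }
    extra <- setdiff(colnames(num), meta$sample)
    if (ncol(num) && length(extra))
      out[[length(out) + 1]] <- finding(
        "samples.tsv", 1L,
        paste("samples present in counts but not in metadata:",
              paste(head(extra, 5), collapse = ", ")))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(file = character(0), line = integer(0),
               message = character(0), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> sample QC -> RPKM -> expressed
#' filter -> tissue specificity -> log2 -> mixed-model DE -> RIF -> PCIT
#' -> network summaries -> phenotype derivations, writing every stage
#' output and a run report under \code{config$out_dir} (file output is
#' skipped when \code{out_dir} is NULL). Re-running with the same config
#' and seed reproduces identical outputs.
#'
#' @param config a [default_config()]-style list, or the path of a YAML
#'   file holding one.
#' @return the run report (invisible file side effects), a list with
#'   per-stage counts plus the main result objects.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  timing <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }

  ## stage: data
  if (isTRUE(cfg$simulate)) {
    design <- experiment_design(animals_per_sire = cfg$animals_per_sire,
                                n_genes = cfg$n_genes, seed = cfg$seed)
    sim <- simulate_expression(design)
    pheno <- simulate_phenotypes(design)
    truth <- sim$truth
  } else {
    if (is.null(cfg$input_dir)) stop("input_dir required when simulate = FALSE")
    v <- validate_inputs(cfg$input_dir)
    if (nrow(v) > 0) {
      print(v)
      stop("input validation failed (", nrow(v), " finding(s))")
    }
    sim <- read_experiment(cfg$input_dir)
    pheno <- NULL
    truth <- NULL
  }
  meta <- sim$meta
  tick("data")

  ## stage: expression
  cm <- qc_samples(sim$counts, min_reads = cfg$min_reads)
  meta <- meta[meta$sample %in% colnames(cm$counts), , drop = FALSE]
  em <- compute_rpkm(cm, meta)
  expr_filter <- filter_expressed(em, threshold = cfg$rpkm_threshold)
  em <- subset_genes(em, expr_filter$expressed)
  shares <- tissue_share(em)
  ts <- classify_tissue_specific(shares, threshold = cfg$ts_threshold)
  em <- log2_transform(em, offset = cfg$log2_offset)
  tick("expression")

  ## stage: mixed model DE
  fit <- fit_variance_components(em$log2, meta)
  blups <- solve_blups(em$log2, meta, fit)
  de <- call_de(blups, em$log2, meta, k = cfg$de_k)
  ts_genes <- ts$gene[ts$is_ts]
  de_genes <- de$gene[de$is_de]
  tick("mixed_model")

  ## stage: RIF
  ann <- sim$annotation
  tf_all <- intersect(ann$gene[ann$is_tf], rownames(em$log2))
  snp_genes <- intersect(ann$gene[ann$is_snp], rownames(em$log2))
  targets <- union(de_genes, ts_genes)
  rif <- NULL; tf_sel <- character(0)
  if (length(tf_all) > 0 && length(setdiff(targets, tf_all)) > 0) {
    rif <- compute_rif(em$log2, meta, tf_all, targets)
    tf_sel <- select_tf(rif, z_cut = cfg$rif_z)$tf
  }
  tick("rif")

  ## stage: PCIT network
  tf_nodes <- if (identical(cfg$tf_nodes, "selected")) tf_sel else tf_all
  node_set <- Reduce(union, list(ts_genes, de_genes, tf_nodes, snp_genes))
  net <- NULL; edge_tab <- NULL; summ <- NULL; degr <- NULL
  if (length(node_set) >= 3) {
    cs <- correlation_matrix(em$log2, node_set)
    mask <- pcit_significant(cs)
    edge_tab <- threshold_edges(cs, mask, k = cfg$pcit_k,
                                stat = cfg$pcit_stat)
    dom <- setNames(ts$tissue, ts$gene)  # tissue of highest expression
    net <- build_network(edge_tab[edge_tab$accepted, , drop = FALSE],
                         ts_genes, de_genes, tf_nodes, snp_genes,
                         tissue_of = dom,
                         meta = list(seed = cfg$seed, pcit_k = cfg$pcit_k))
    degr <- degree_table(net)
    summ <- tissue_edge_summary(net)
  }
  tick("network")

  ## stage: phenotypes
  ph <- if (!is.null(pheno)) derive_phenotypes(pheno) else NULL
  tick("phenotypes")

  report <- list(
    seed = cfg$seed,
    samples_kept = ncol(cm$counts),
    samples_removed = attr(cm, "removed"),
    genes_expressed = length(expr_filter$expressed),
    genes_not_expressed = length(expr_filter$not_expressed),
    n_ts = length(ts_genes), n_de = length(de_genes),
    n_tf_scored = if (is.null(rif)) 0L else nrow(rif),
    n_tf_selected = length(tf_sel),
    nodes = if (is.null(net)) 0L else nrow(net$nodes),
    edges = if (is.null(net)) 0L else nrow(net$edges),
    within_tissue_fraction = if (is.null(summ)) NA_real_ else
      summ$within_fraction,
    edges_vs_nodes_r2 = if (is.null(summ)) NA_real_ else summ$r2,
    varcomp = fit$varcomp, timing_s = timing,
    r_version = as.character(getRversion()))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (isTRUE(cfg$simulate)) write_simulation(sim, pheno, cfg$out_dir)
    write_tsv(data.frame(gene = rownames(em$rpkm),
                         round(em$rpkm, 4), check.names = FALSE),
              file.path(cfg$out_dir, "rpkm.tsv"))
    write_tsv(ts, file.path(cfg$out_dir, "ts_calls.tsv"))
    jsonlite::write_json(as.list(fit$varcomp),
                         file.path(cfg$out_dir, "varcomp.json"),
                         auto_unbox = TRUE, digits = NA)
    write_tsv(de, file.path(cfg$out_dir, "de_results.tsv"))
    if (!is.null(rif))
      write_tsv(rif, file.path(cfg$out_dir, "rif_scores.tsv"))
    if (!is.null(edge_tab))
      write_tsv(edge_tab, file.path(cfg$out_dir, "edges.tsv"))
    if (!is.null(net)) {
      if ("sif" %in% cfg$exports)
        export_network(net, file.path(cfg$out_dir, "network.sif"), "sif")
      if ("tsv" %in% cfg$exports)
        export_network(net, file.path(cfg$out_dir, "network_edges.tsv"),
                       "tsv")
      if ("graphml" %in% cfg$exports)
        export_network(net, file.path(cfg$out_dir, "network.graphml"),
                       "graphml")
      write_tsv(degr, file.path(cfg$out_dir, "degree.tsv"))
    }
    if (!is.null(ph)) {
      write_csv(ph$table, file.path(cfg$out_dir, "rfi.csv"))
      write_csv(ph$group_differences,
                file.path(cfg$out_dir, "traits_summary.csv"))
    }
    jsonlite::write_json(
      report[setdiff(names(report), "samples_removed")],
      file.path(cfg$out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA)
  }

  c(report, list(ts = ts, de = de, fit = fit, rif = rif,
                 network = net, degree = degr, tissue_summary = summ,
                 phenotypes = ph, truth = truth, config = cfg))
}

#' Command-line entry point
#'
#' Dispatches \code{rfinet <command>} for commands \code{simulate},
#' \code{run}, \code{power} and \code{validate}. Used by the
#' \code{inst/cli/rfinet.R} script:
#' \code{Rscript -e 'rfinet::rfinet_main()' <command> --key value ...}
#'
#' @param args character vector of CLI arguments (default: the
#'   command-line arguments of the session).
#' @return exit status, invisibly.
#' @export
rfinet_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: rfinet <command> [--key value ...]",
    "  simulate --seed 1 --n-genes 2000 --out DIR",
    "  run      --config cfg.yaml | --seed 1 --out DIR",
    "  power    --n 8 --fc 1.8 --cv 0.4 --alpha 0.05 [--depth 2000]",
    "  validate --dir DIR", sep = "\n")
  if (length(args) < 1) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list()
  kv <- args[-1]
  i <- 1
  while (i <= length(kv)) {
    if (startsWith(kv[i], "--")) {
      opt[[sub("^--", "", kv[i])]] <- if (i < length(kv)) kv[i + 1] else ""
      i <- i + 2
    } else i <- i + 1
  }
  num <- function(k, d) if (is.null(opt[[k]])) d else as.numeric(opt[[k]])

  if (cmd == "simulate") {
    design <- experiment_design(n_genes = num("n-genes", 2000),
                                seed = as.integer(num("seed", 1)))
    sim <- simulate_expression(design)
    pheno <- simulate_phenotypes(design)
    write_simulation(sim, pheno, opt[["out"]])
    cat("wrote simulation to", opt[["out"]], "\n")
  } else if (cmd == "run") {
    cfg <- if (!is.null(opt[["config"]])) opt[["config"]] else
      default_config(out_dir = opt[["out"]],
                     seed = as.integer(num("seed", 1)))
    rep <- run_pipeline(cfg)
    cat(sprintf(
      "samples %d | expressed %d | TS %d | DE %d | TF selected %d | nodes %d | edges %d\n",
      rep$samples_kept, rep$genes_expressed, rep$n_ts, rep$n_de,
      rep$n_tf_selected, rep$nodes, rep$edges))
  } else if (cmd == "power") {
    p_an <- de_power(num("n", 8), num("fc", 1.8), num("cv", 0.4),
                     num("alpha", 0.05),
                     if (is.null(opt[["depth"]])) Inf else num("depth", Inf))
    cat(sprintf("analytic power: %.3f\n", p_an))
    if (!is.null(opt[["depth"]])) {
      set.seed(as.integer(num("seed", 1)))
      cat(sprintf("simulated power: %.3f\n",
                  simulate_de_power(num("n", 8), num("fc", 1.8),
                                    num("cv", 0.4), num("alpha", 0.05),
                                    depth = num("depth", 2000))))
    }
  } else if (cmd == "validate") {
    v <- validate_inputs(opt[["dir"]])
    if (nrow(v) == 0) cat("inputs OK\n") else { print(v); return(invisible(1L)) }
  } else {
    cat(usage, "\n"); return(invisible(1L))
  }
  invisible(0L)
}
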