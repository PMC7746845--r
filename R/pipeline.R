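# End-to-end orchestration: simulate/load -> cell-line DEGs -> tissue survival
# screen -> tissue/cell concordance -> candidate genes -> pair signature ->
# validation. Every stage consumes a child seed derived from the master seed,
# all thresholds are echoed in the run report, and all intermediate artifacts
# are written to the run directory with a manifest.

#' Candidate gene selection from tissue lists and the best cell line
#'
#' Intersects the tissue signed lists requiring identical signs across all of
#' them (the cross-tissue reproducible genes), then intersects with the
#' cell-line list requiring sign agreement: a tissue gene positively
#' associated with hazard must be up in resistant cells, and vice versa.
#'
#' @param tissue_lists list of >= 1 signed gene lists.
#' @param best_cell signed gene list of the selected cell-line dataset.
#' @return character vector of candidate gene ids (non-empty, else error).
#' @export
select_candidates <- function(tissue_lists, best_cell) {
  if (!length(tissue_lists)) stop("need >= 1 tissue gene list")
  if (!length(best_cell)) stop("cell-line gene list is empty")
  cross <- tissue_lists[[1]]
  for (other in tissue_lists[-1]) {
    shared <- intersect(names(cross), names(other))
    shared <- shared[cross[shared] == other[shared]]
    cross <- cross[shared]
  }
  if (!length(cross)) stop("empty candidate set: no sign-consistent gene across tissue lists")
  shared <- intersect(names(cross), names(best_cell))
  shared <- shared[cross[shared] == best_cell[shared]]
  if (!length(shared)) stop("empty candidate set: no sign-consistent gene between tissue and cell line")
  sort(shared)
}

#' Assemble a pipeline configuration
#'
#' Each dataset entry is either a simulation config
#' ([tissue_sim_config()] / [cellline_sim_config()]) or a list
#' `list(expr = <path>, pheno = <path>)` pointing at TSV files.
#'
#' @param tissue named list (>= 1) of tissue cohorts used for survival-gene
#'   screening.
#' @param cells named list (>= 1) of cell-line datasets.
#' @param train tissue dataset used for pair screening and signature
#'   optimisation; defaults to the first `tissue` entry.
#' @param validation named list (>= 0) of validation cohorts.
#' @param tissue_fdr,deg_fdr,pair_fdr stage FDR thresholds (defaults 0.2,
#'   0.2, 0.1).
#' @param concordance_alpha adjusted-p cutoff a cell line must pass to be
#'   eligible as the representative model (default 0.05).
#' @param max_signature_size cap passed to [optimize_combination()].
#' @param force_cell optionally name a cell-line dataset to use regardless of
#'   the concordance gate.
#' @param seed master seed; stages derive child seeds from it.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(tissue, cells, train = NULL, validation = list(),
                            tissue_fdr = 0.2, deg_fdr = 0.2, pair_fdr = 0.1,
                            concordance_alpha = 0.05,
                            max_signature_size = Inf, force_cell = NULL,
                            seed = 1L) {
  stopifnot(length(tissue) >= 1, length(cells) >= 1,
            tissue_fdr > 0, tissue_fdr < 1, deg_fdr > 0, deg_fdr < 1,
            pair_fdr > 0, pair_fdr < 1)
  if (is.null(names(tissue))) names(tissue) <- paste0("tissue", seq_along(tissue))
  if (is.null(names(cells))) names(cells) <- paste0("cell", seq_along(cells))
  if (length(validation) && is.null(names(validation))) {
    names(validation) <- paste0("validation", seq_along(validation))
  }
  if (is.null(train)) train <- tissue[[1]]
  structure(list(tissue = tissue, cells = cells, train = train,
                 validation = validation, tissue_fdr = tissue_fdr,
                 deg_fdr = deg_fdr, pair_fdr = pair_fdr,
                 concordance_alpha = concordance_alpha,
                 max_signature_size = max_signature_size,
                 force_cell = force_cell, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Materialise a dataset entry into expr (+ cohort or design), reseeding
# simulation configs from the master seed so runs are reproducible.
load_dataset <- function(entry, kind = c("tissue", "cellline"), seed_offset, master_seed) {
  kind <- match.arg(kind)
  if (inherits(entry, "tissue_sim_config")) {
    entry$seed <- derive_seed(master_seed, seed_offset)
    return(simulate_tissue(entry))
  }
  if (inherits(entry, "cellline_sim_config")) {
    entry$seed <- derive_seed(master_seed, seed_offset)
    return(simulate_cellline(entry))
  }
  if (is.list(entry) && !is.null(entry$expr) && is.character(entry$expr)) {
    expr <- read_expression_matrix(entry$expr)
    ph <- read_phenotype(entry$pheno)
    if (kind == "tissue") return(list(expr = expr, cohort = ph$cohort, truth = NULL))
    if (is.null(ph$design)) stop("cell-line phenotype file lacks a group column")
    return(list(expr = expr, design = ph$design, truth = NULL))
  }
  stop("dataset entry must be a simulation config or list(expr=, pheno=)")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) SAM DEGs per cell-line dataset; (2) univariate Cox
#' survival-gene screen per tissue cohort; (3) cross-tissue sign-consistent
#' genes vs each cell-line DEG list (concordance panel, BH-adjusted); (4) the
#' representative cell line = maximum consistency ratio among datasets with
#' adjusted p below `concordance_alpha` (error if none, unless `force_cell`);
#' (5) candidate genes via [select_candidates()]; (6) pair screening on the
#' training cohort and C-index optimisation; (7) evaluation on training and
#' validation cohorts. All intermediate tables, the signature JSON, a
#' manifest, and a log echoing seeds and thresholds are written to `outdir`.
#'
#' @param config [pipeline_config()].
#' @param outdir run directory (created if needed).
#' @return run report (list), invisibly; also written as `report.json`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  logline <- character(0)
  note <- function(...) logline <<- c(logline, sprintf(...))
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    manifest <<- c(manifest, name)
    path
  }
  note("seed: %d", config$seed)
  note("thresholds: tissue_fdr=%g deg_fdr=%g pair_fdr=%g concordance_alpha=%g",
       config$tissue_fdr, config$deg_fdr, config$pair_fdr, config$concordance_alpha)

  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # (1) cell-line DEGs
  cell_lists <- list()
  cell_data <- list()
  off <- 100L
  for (nm in names(config$cells)) {
    off <- off + 1L
    ds <- stage(paste0("sam:", nm), function()
      load_dataset(config$cells[[nm]], "cellline", off, config$seed))
    cell_data[[nm]] <- ds
    sam <- stage(paste0("sam:", nm), function()
      suppressMessages(sam_fdr(ds$expr, ds$design,
                               seed = derive_seed(config$seed, off + 5000L))))
    degs <- select_degs(sam, config$deg_fdr)
    cell_lists[[nm]] <- degs
    emit(sprintf("sam_%s.tsv", nm), function(p)
      utils::write.table(sam, p, sep = "\t", quote = FALSE, row.names = FALSE))
    note("cell '%s': %d DEG(s) at FDR < %g", nm, length(degs), config$deg_fdr)
  }

  # (2) tissue survival screens
  tissue_lists <- list()
  off <- 200L
  for (nm in names(config$tissue)) {
    off <- off + 1L
    ds <- stage(paste0("coxscreen:", nm), function()
      load_dataset(config$tissue[[nm]], "tissue", off, config$seed))
    scr <- stage(paste0("coxscreen:", nm), function()
      suppressMessages(screen_survival_genes(ds$expr, ds$cohort, config$tissue_fdr)))
    tissue_lists[[nm]] <- scr$genes
    emit(sprintf("coxscreen_%s.tsv", nm), function(p)
      utils::write.table(scr$table, p, sep = "\t", quote = FALSE, row.names = FALSE))
    note("tissue '%s': %d survival gene(s) at FDR < %g", nm, length(scr$genes),
         config$tissue_fdr)
  }

  # (3) cross-tissue consistent genes, concordance panel
  cross <- stage("candidates", function() {
    cr <- tissue_lists[[1]]
    for (other in tissue_lists[-1]) {
      shared <- intersect(names(cr), names(other))
      cr <- cr[shared[cr[shared] == other[shared]]]
    }
    if (!length(cr)) stop("no sign-consistent gene across tissue cohorts")
    cr
  })
  note("cross-tissue consistent genes: %d", length(cross))
  panel <- stage("concordance", function() evaluate_panel(cross, cell_lists))
  emit("concordance_panel.tsv", function(p)
    utils::write.table(panel, p, sep = "\t", quote = FALSE, row.names = FALSE))

  # (4) representative cell line
  best_cell <- stage("concordance", function() {
    if (!is.null(config$force_cell)) {
      if (!config$force_cell %in% names(cell_lists)) {
        stop("force_cell names an unknown dataset: ", config$force_cell)
      }
      return(config$force_cell)
    }
    ok <- !is.na(panel$p_adj) & panel$p_adj < config$concordance_alpha
    if (!any(ok)) {
      stop("no representative cell line: no dataset passes adjusted p < ",
           config$concordance_alpha)
    }
    panel$dataset[ok][which.max(panel$ratio[ok])]
  })
  note("representative cell line: %s", best_cell)

  # (5) candidate genes
  candidates <- stage("candidates", function()
    select_candidates(tissue_lists, cell_lists[[best_cell]]))
  emit("candidates.tsv", function(p)
    writeLines(c("gene", candidates), p))
  note("candidate genes: %d", length(candidates))

  # (6) training cohort, pair screen, optimisation
  train <- stage("signature", function()
    load_dataset(config$train, "tissue", 300L, config$seed))
  screen <- stage("signature", function()
    suppressMessages(screen_pairs(train$expr, train$cohort, candidates,
                                  fdr = config$pair_fdr)))
  note("pair screen: set1=%d tested=%d set2=%d", screen$set1_size,
       screen$n_tested, nrow(screen$set2))
  opt <- stage("signature", function()
    suppressMessages(optimize_combination(screen, train$expr, train$cohort,
                                          max_size = config$max_signature_size)))
  emit("set2.tsv", function(p)
    utils::write.table(screen$set2, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("signature.json", function(p) write_signature(opt$signature, p))
  note("signature: %d rule(s), training C-index %.4f", nrow(opt$signature$rules),
       opt$cindex)

  # (7) evaluation
  evaluations <- list()
  ev_train <- stage("evaluate", function()
    evaluate_signature(opt$signature, train$expr, train$cohort))
  evaluations[["training"]] <- ev_train
  off <- 400L
  for (nm in names(config$validation)) {
    off <- off + 1L
    ds <- stage(paste0("evaluate:", nm), function()
      load_dataset(config$validation[[nm]], "tissue", off, config$seed))
    evaluations[[nm]] <- stage(paste0("evaluate:", nm), function()
      evaluate_signature(opt$signature, ds$expr, ds$cohort))
  }
  ev_tab <- do.call(rbind, lapply(names(evaluations), function(nm) {
    ev <- evaluations[[nm]]
    data.frame(cohort = nm, n_low = as.integer(ev$group_sizes["low"]),
               n_high = as.integer(ev$group_sizes["high"]),
               hr = ev$hr, ci_lo = ev$ci95[1], ci_hi = ev$ci95[2],
               logrank_chi2 = ev$logrank_chi2, p_logrank = ev$p_logrank,
               cindex = ev$cindex, stringsAsFactors = FALSE)
  }))
  emit("evaluation.tsv", function(p)
    utils::write.table(ev_tab, p, sep = "\t", quote = FALSE, row.names = FALSE))
  for (i in seq_len(nrow(ev_tab))) {
    note("evaluation '%s': n_low=%d n_high=%d HR=%.4g logrank p=%.4g",
         ev_tab$cohort[i], ev_tab$n_low[i], ev_tab$n_high[i], ev_tab$hr[i],
         ev_tab$p_logrank[i])
  }

  report <- list(seed = config$seed,
                 thresholds = list(tissue_fdr = config$tissue_fdr,
                                   deg_fdr = config$deg_fdr,
                                   pair_fdr = config$pair_fdr,
                                   concordance_alpha = config$concordance_alpha),
                 cell_degs = lapply(cell_lists, length),
                 tissue_genes = lapply(tissue_lists, length),
                 cross_tissue_genes = length(cross),
                 concordance = panel,
                 best_cell = best_cell,
                 candidates = candidates,
                 set1_size = screen$set1_size,
                 set2 = screen$set2,
                 signature = opt$signature$rules,
                 train_cindex = opt$cindex,
                 evaluation = ev_tab)
  emit("report.json", function(p)
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE))
  emit("run.log", function(p) writeLines(logline, p))
  writeLines(sort(c(manifest, "manifest.txt")), file.path(outdir, "manifest.txt"))
  invisible(report)
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; dataset entries
#' are maps with either `expr`/`pheno` paths or a `sim` block whose `type` is
#' `tissue` or `cellline` and whose remaining keys are the corresponding
#' simulation-config fields (`beta_map` as a gene-to-coefficient map).
#'
#' @param path YAML file path.
#' @return [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  parse_entry <- function(e) {
    if (!is.null(e$sim)) {
      s <- e$sim
      if (identical(s$type, "tissue")) {
        return(tissue_sim_config(
          n_genes = s$n_genes, n_samples = s$n_samples,
          beta_map = unlist(s$beta_map),
          baseline = if (is.null(s$baseline)) list(dist = "exponential", rate = 0.05) else s$baseline,
          censor_horizon = if (is.null(s$censor_horizon)) 60 else s$censor_horizon,
          seed = if (is.null(s$seed)) 1L else s$seed))
      }
      if (identical(s$type, "cellline")) {
        return(cellline_sim_config(
          n_genes = s$n_genes, n_per_group = s$n_per_group, n_de = s$n_de,
          lfc = if (is.null(s$lfc)) 2 else s$lfc,
          noise_sd = if (is.null(s$noise_sd)) 0.5 else s$noise_sd,
          seed = if (is.null(s$seed)) 1L else s$seed))
      }
      stop("sim type must be 'tissue' or 'cellline'")
    }
    list(expr = e$expr, pheno = e$pheno)
  }
  arg <- function(nm, default) if (is.null(y[[nm]])) default else y[[nm]]
  pipeline_config(
    tissue = lapply(y$tissue, parse_entry),
    cells = lapply(y$cells, parse_entry),
    train = if (is.null(y$train)) NULL else parse_entry(y$train),
    validation = if (is.null(y$validation)) list() else lapply(y$validation, parse_entry),
    tissue_fdr = arg("tissue_fdr", 0.2), deg_fdr = arg("deg_fdr", 0.2),
    pair_fdr = arg("pair_fdr", 0.1),
    concordance_alpha = arg("concordance_alpha", 0.05),
    max_signature_size = arg("max_signature_size", Inf),
    force_cell = y$force_cell, seed = arg("seed", 1L))
}
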