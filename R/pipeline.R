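## Stage wrappers tying the modules together on a dataset directory (the
## bundle written by generate_dataset(), or equivalent user files), plus an
## end-to-end driver. Every stage writes TSV and emits one structured log
## line.

#' Load a dataset bundle from disk
#'
#' Reads `tree.nwk`, `matrix.Rtab`, `traits.tsv`, `annotation.tsv` (and
#' `events.tsv` if present) from a directory and cross-validates genome
#' sets.
#'
#' @param dir dataset directory
#' @return list with `tree`, `matrix`, `traits`, `annotation`, `events`
#' @export
load_dataset <- function(dir) {
  tree <- read_newick(file.path(dir, "tree.nwk"))
  pm <- read_presence_matrix(file.path(dir, "matrix.Rtab"), "rtab")
  traits <- read_trait_table(file.path(dir, "traits.tsv"))
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  mat <- match_tree_data(tree, pm$matrix)
  traits <- match_tree_data(tree, traits)
  ev_path <- file.path(dir, "events.tsv")
  events <- if (file.exists(ev_path)) read.delim(ev_path) else NULL
  log_stage("load", dir = dir, n_genomes = nrow(mat), n_families = ncol(mat))
  list(tree = tree, matrix = mat, traits = traits, annotation = ann,
       events = events)
}

#' Run gain/loss inference and write the per-branch table
#'
#' Fits the two-state model, computes per-branch expected events, and
#' writes one aggregated row per branch and family class.
#'
#' @param ds dataset bundle ([load_dataset()] / [generate_dataset()])
#' @param K gamma categories
#' @param out optional output TSV path
#' @return list with `model`, `branch_events`, `table`
#' @export
run_gainloss <- function(ds, K = 4L, out = NULL) {
  model <- fit_gainloss(ds$tree, ds$matrix, K)
  be <- branch_expected_events(ds$tree, ds$matrix, model)
  ann <- ds$annotation
  classes <- c("all", "prophage", "plasmid", "transposon")
  tabs <- lapply(classes, function(cl) {
    fams <- ann$family_id[!ann$singleton & ann$defense_system == "none" &
      (if (cl == "all") TRUE else ann$mge_class == cl)]
    fams <- intersect(fams, colnames(ds$matrix))
    if (!length(fams)) return(NULL)
    agg <- aggregate_branch_events(be, fams)
    agg$family_class <- cl
    agg
  })
  table <- do.call(rbind, tabs)
  table <- table[, c("branch", "expected_gains", "expected_losses",
                     "p_ge1_gain", "p_ge1_loss", "family_class")]
  log_stage("gainloss", gain_rate = model$gain_rate,
            loss_rate = model$loss_rate, gamma_shape = model$gamma_shape,
            loglik = model$loglik)
  if (!is.null(out)) write_table(table, out)
  list(model = model, branch_events = be, table = table)
}

#' Run the PGLMM battery and write the per-model table
#'
#' @param ds dataset bundle
#' @param mode `"single"` or `"joint"` (see [fit_species_battery()])
#' @param cog_categories include per-COG responses
#' @param out optional output TSV path
#' @return the [fit_species_battery()] result
#' @export
run_pglmm <- function(ds, mode = "single", cog_categories = FALSE,
                      out = NULL) {
  C <- brownian_covariance(ds$tree)
  y <- response_vectors(ds$matrix, ds$annotation, cog_categories)
  bat <- fit_species_battery(y, ds$traits, C, mode)
  log_stage("pglmm", n_models = nrow(bat$table),
            n_skipped = nrow(bat$skipped))
  if (!is.null(out)) write_table(bat$table, out)
  bat
}

#' Classify a battery table under both association criteria
#'
#' @param table battery table (a `species` column is added if missing)
#' @param out optional output TSV path prefix (writes `<out>` and a
#'   `<out>.summary.tsv` next to it)
#' @return [associate_battery()] result
#' @export
run_associate <- function(table, out = NULL) {
  tab <- table[table$converged %||% TRUE, , drop = FALSE]
  if (is.null(tab$species)) tab$species <- "species1"
  res <- associate_battery(tab)
  log_stage("associate", n_results = nrow(res$results))
  if (!is.null(out)) {
    write_table(res$results, out)
    write_table(res$summary, paste0(out, ".summary.tsv"))
  }
  res
}

#' Run the sister-clade flux comparison
#'
#' @param ds dataset bundle
#' @param be `"branch_events"` from [run_gainloss()]
#' @param system defense system column of the trait table
#' @param out optional output TSV path prefix
#' @return list with `flux` table and per-stratum `summary`
#' @export
run_clades <- function(ds, be, system = colnames(ds$traits)[1], out = NULL) {
  trait <- setNames(ds$traits[, system], rownames(ds$traits))
  flux <- clade_flux_table(ds$tree, trait, be, ds$annotation)
  summary <- if (nrow(flux)) stratum_summary(flux) else data.frame()
  log_stage("clades", system = system, n_pairs = length(unique(flux$pair)))
  if (!is.null(out)) {
    write_table(flux, out)
    if (nrow(summary)) write_table(summary, paste0(out, ".summary.tsv"))
  }
  list(flux = flux, summary = summary)
}

#' Run the branch-level linkage statistics
#'
#' Events can come from the ground-truth histories (`source = "truth"`,
#' simulated bundles only) or from the inferred posterior event calls
#' (`source = "inferred"`, requires `be`; MGE events are called on the
#' pooled non-singleton MGE-class families, defense events on the defense
#' system's own gene families).
#'
#' @param ds dataset bundle
#' @param be `"branch_events"`, needed when `source = "inferred"`
#' @param source `"truth"` or `"inferred"`
#' @param threshold posterior calling threshold for `"inferred"`
#' @param out optional output TSV path
#' @return list with `table` (branch event table) and `summary`
#' @export
run_linkage <- function(ds, be = NULL, source = c("truth", "inferred"),
                        threshold = 0.5, out = NULL) {
  source <- match.arg(source)
  if (source == "truth") {
    if (is.null(ds$defense_history))
      stop("ground-truth histories unavailable; use source = 'inferred'",
           call. = FALSE)
    tbl <- branch_event_table_from_history(ds$tree, ds$defense_history,
                                           ds$mge_history)
  } else {
    if (is.null(be)) stop("need branch_events for inferred calls",
                          call. = FALSE)
    ann <- ds$annotation
    mge_fams <- ann$family_id[ann$mge_class != "none" & !ann$singleton &
                                ann$defense_system == "none"]
    def_fams <- ann$family_id[ann$defense_system != "none"]
    if (!length(def_fams))
      stop("no defense-system gene families annotated", call. = FALSE)
    mge_calls <- call_branch_events(be, intersect(mge_fams,
                                                  colnames(ds$matrix)),
                                    threshold)
    def_calls <- call_branch_events(be, intersect(def_fams,
                                                  colnames(ds$matrix)),
                                    threshold)
    tbl <- data.frame(branch = mge_calls$branch,
                      def_gain = def_calls$gain, def_loss = def_calls$loss,
                      mge_gain = mge_calls$gain, mge_loss = mge_calls$loss,
                      branch_length = mge_calls$branch_length,
                      is_terminal = mge_calls$is_terminal)
  }
  summary <- linkage_summary(tbl)
  log_stage("linkage", source = source, n_branches = nrow(tbl))
  if (!is.null(out)) write_table(summary, out)
  list(table = tbl, summary = summary)
}

#' End-to-end pipeline on one dataset
#'
#' Simulates (given a config) or loads (given a directory) a dataset, then
#' runs gain/loss inference, the PGLMM battery with association
#' classification, the sister-clade flux comparison with depth
#' stratification, and the linkage statistics, writing all result TSVs to
#' `out_dir`.
#'
#' @param x a [simulation_config()] or a dataset directory path
#' @param out_dir output directory
#' @param cog_categories include per-COG PGLMM responses
#' @return list with all stage results, invisibly
#' @export
run_all <- function(x, out_dir, cog_categories = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- if (inherits(x, "simulation_config"))
    generate_dataset(x, file.path(out_dir, "dataset"))
  else load_dataset(x)
  gl <- run_gainloss(ds, out = file.path(out_dir, "branch_events.tsv"))
  bat <- run_pglmm(ds, cog_categories = cog_categories,
                   out = file.path(out_dir, "pglmm.tsv"))
  assoc <- run_associate(bat$table, out = file.path(out_dir,
                                                    "associations.tsv"))
  clades <- run_clades(ds, gl$branch_events,
                       out = file.path(out_dir, "clade_flux.tsv"))
  link_src <- if (is.null(ds$defense_history)) "inferred" else "truth"
  link <- run_linkage(ds, gl$branch_events, source = link_src,
                      out = file.path(out_dir, "linkage.tsv"))
  invisible(list(dataset = ds, gainloss = gl, battery = bat,
                 associations = assoc, clades = clades, linkage = link))
}
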