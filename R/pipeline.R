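#' Pipeline configuration
#'
#' Bundles the simulation block and the analysis thresholds. The threshold
#' defaults are the published ones: fold change >= 2, adjusted p < 0.05,
#' top 10,000 genes by CV, |Pearson r| > 0.964.
#'
#' @param sim A [sim_config()] describing the synthetic inputs (the
#'   pipeline can also be pointed at files; see [run_pipeline()]).
#' @param fc_threshold,alpha,top_k,corr_threshold Analysis thresholds.
#' @param seed Root seed, forwarded to the simulation.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed),
                            fc_threshold = 2, alpha = 0.05,
                            top_k = 10000, corr_threshold = 0.964,
                            seed = 1L) {
  stopifnot(fc_threshold > 0, alpha > 0, alpha < 1, top_k >= 1,
            corr_threshold > 0, corr_threshold <= 1)
  sim$seed <- as.integer(seed)
  validate_sim_config(sim)
  structure(list(sim = sim, fc_threshold = fc_threshold, alpha = alpha,
                 top_k = as.integer(top_k),
                 corr_threshold = corr_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the full desiccation-tolerance pipeline
#'
#' Executes simulate -> physiology -> differential expression -> per-tissue
#' co-expression networks with state overlays -> metabolite fold changes
#' and PCA -> hormone ANOVA with compact letters, writing every table, the
#' network edge lists and GraphML files, and a JSON run manifest recording
#' the config hash, seed and per-stage row/edge counts. Identical config
#' and seed give byte-identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress stage messages.
#' @return The manifest list, invisibly; written to
#'   `file.path(outdir, "manifest.json")`.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   thresholds = list(fc_threshold = config$fc_threshold,
                                     alpha = config$alpha,
                                     top_k = config$top_k,
                                     corr_threshold = config$corr_threshold),
                   stages = list())

  say("stage simulate")
  sim <- stage("simulate", function() {
    ex <- simulate_expression(config$sim)
    mb <- simulate_metabolites(config$sim)
    hm <- simulate_hormones(config$sim)
    ph <- simulate_physiology(config$sim)
    write_matrix_tsv(ex$expression, file.path(outdir, "expression.tsv"),
                     "gene_id")
    write_matrix_tsv(mb$metabolites, file.path(outdir, "metabolites.tsv"),
                     "metabolite")
    write_sample_sheet(ex$samples, file.path(outdir, "samples.csv"))
    write.csv(hm$hormones, file.path(outdir, "hormones.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(ph$weights, file.path(outdir, "weights.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(ph$viability, file.path(outdir, "viability.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(ph$survival, file.path(outdir, "survival.csv"),
              row.names = FALSE, quote = FALSE)
    truth <- list(
      deg_truth = ex$truth$deg_truth,
      module_truth = as.list(ex$truth$module_truth[
        !is.na(ex$truth$module_truth)]),
      hormone_profile_truth = hm$truth)
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", pretty = TRUE),
               file.path(outdir, "truth.json"))
    list(ex = ex, mb = mb, hm = hm, ph = ph)
  })
  manifest$stages$simulate <- list(
    n_genes = nrow(sim$ex$expression), n_samples = ncol(sim$ex$expression),
    n_metabolites = nrow(sim$mb$metabolites),
    n_planted_degs = nrow(sim$ex$truth$deg_truth))

  say("stage physiology")
  phys <- stage("physiology", function() {
    w <- sim$ph$weights
    w$rwc <- compute_rwc(w$fresh_weight, w$dry_weight, w$turgid_weight)
    write.csv(w, file.path(outdir, "physiology_rwc.csv"),
              row.names = FALSE, quote = FALSE)
    cdi <- cell_death_index(sim$ph$viability)
    write.csv(data.frame(treatment = names(cdi), cell_death_index = cdi),
              file.path(outdir, "cell_death_index.csv"),
              row.names = FALSE, quote = FALSE)
    list(rwc = w, threshold_band = survival_threshold(sim$ph$survival),
         cdi = cdi)
  })
  manifest$stages$physiology <- list(
    n_weight_records = nrow(phys$rwc),
    survival_threshold_band = phys$threshold_band)

  say("stage diffexpr")
  degs <- stage("diffexpr", function() {
    d <- deg_all_contrasts(sim$ex$expression, sim$ex$samples,
                           fc_threshold = config$fc_threshold,
                           alpha = config$alpha)
    write.table(d, file.path(outdir, "degs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    d
  })
  manifest$stages$diffexpr <- list(n_rows = nrow(degs),
                                   n_passing = sum(degs$passes))

  say("stage coexnet")
  nets <- stage("coexnet", function() {
    lapply(setNames(nm = config$sim$tissues), function(ti) {
      net <- tissue_network(sim$ex$expression, sim$ex$samples, ti,
                            top_k = config$top_k,
                            threshold = config$corr_threshold)
      ov <- overlay_deg_states(net, degs[degs$tissue == ti, , drop = FALSE])
      summ <- summarize_states(net, ov)
      export_network(net, ov, file.path(outdir, paste0("network_", ti)))
      write.table(summ$per_state,
                  file.path(outdir, paste0("network_", ti, "_summary.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(network = net, overlay = ov, summary = summ)
    })
  })
  manifest$stages$coexnet <- lapply(nets, function(x)
    list(n_nodes = length(x$network$nodes), n_edges = nrow(x$network$edges)))

  say("stage metabolomics")
  metab <- stage("metabolomics", function() {
    fc <- metabolite_fold_changes(sim$mb$metabolites, sim$mb$samples,
                                  alpha = config$alpha)
    write.table(fc, file.path(outdir, "metabolite_fold_changes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pca <- run_pca(sim$mb$metabolites,
                   n_components = min(3, min(dim(sim$mb$metabolites))))
    ord <- heatmap_order(sim$mb$metabolites)
    list(fc = fc, pca = pca, order = ord)
  })
  manifest$stages$metabolomics <- list(
    n_rows = nrow(metab$fc), n_significant_up = sum(metab$fc$significant_up))

  say("stage phytohormones")
  horm <- stage("phytohormones", function() {
    hs <- unique(sim$hm$hormones$hormone)
    res <- lapply(setNames(nm = hs), function(h) {
      a <- anova_oneway(sim$hm$hormones, h)
      l <- compact_letters(sim$hm$hormones, h, alpha = config$alpha)
      list(F = a$statistic, p = a$p_value, letters = unclass(l)[])
    })
    tab <- do.call(rbind, lapply(names(res), function(h)
      data.frame(hormone = h, state = names(res[[h]]$letters),
                 letters = unname(res[[h]]$letters),
                 F = res[[h]]$F, p = res[[h]]$p)))
    write.csv(tab, file.path(outdir, "hormone_letters.csv"),
              row.names = FALSE, quote = FALSE)
    res
  })
  manifest$stages$phytohormones <- lapply(horm, function(x)
    list(F = x$F, p = x$p, n_letter_groups =
           length(unique(unlist(strsplit(unlist(x$letters), ""))))))

  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(outdir, "manifest.json"))
  say("pipeline complete: %s", file.path(outdir, "manifest.json"))
  invisible(manifest)
}
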