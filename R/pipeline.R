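#' Run the full myeloid-diversity pipeline
#'
#' Orchestrates signature construction, deconvolution, diversity scoring,
#' outcome association, mutation contrasts, co-expression module detection
#' and surrogate-model fitting, in that order, over either a simulated
#' cohort (`simulate = TRUE`) or files declared in the config. Stages whose
#' inputs are absent are skipped with an explicit record; a stage failure
#' halts the run naming the stage, retaining partial outputs. Writes every
#' stage output as TSV/JSON under `out_dir` plus a manifest with config
#' hash, seed and per-file MD5 checksums: deterministic stages reproduce
#' their checksums under the same config and seed.
#'
#' @param config a configuration list from [load_config()] (or a YAML path).
#' @param out_dir output directory.
#' @param simulate generate the cohort with the bundled generator.
#' @param inputs optional named list of file paths (`bulk`, `sc_mtx`,
#'   `labels`, `clinical`, `maf`, `gmt`) when `simulate = FALSE`.
#' @return the run manifest (invisibly also written to `manifest.json`).
#' @export
run_all <- function(config = load_config(), out_dir, simulate = TRUE,
                    inputs = list()) {
  if (is.character(config)) config <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "myelodiv", version = as.character(packageVersion("myelodiv")),
    seed = config$seed, started = format(Sys.time(), usetz = TRUE),
    config_hash = config_hash(config), stages = list())
  outputs <- character()
  stage <- function(name, run) {
    res <- tryCatch(run(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, status = "ok",
           outputs = as.list(res %||% character()))
    outputs <<- c(outputs, res %||% character())
  }
  skip <- function(name, why) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, status = "skipped", reason = why)
  }
  path <- function(...) file.path(out_dir, ...)

  sim_cfg <- do.call(simulation_config,
                     modifyList(config$simulation,
                                list(seed = config$seed)))
  sc <- labels <- bulk <- clin <- mut <- truth <- NULL
  if (simulate) {
    stage("simulate", function() {
      obj <- simulate_cohort(sim_cfg, path("cohort"))
      sc <<- obj$sc$counts; labels <<- obj$sc$labels
      truth <<- obj$sc$truth
      bulk <<- obj$bulk; clin <<- obj$clinical; mut <<- obj$mutations
      file.path("cohort", c("bulk.tsv", "clinical.tsv", "mutations.maf",
                            "ground_truth.json"))
    })
  } else {
    if (!is.null(inputs$bulk)) bulk <- read_expression(inputs$bulk)
    if (!is.null(inputs$sc_mtx)) {
      sc <- read_expression(inputs$sc_mtx, format = "mtx")
      lab <- read.delim(inputs$labels, stringsAsFactors = FALSE)
      labels <- setNames(lab[[2L]], lab[[1L]])
    }
    if (!is.null(inputs$clinical)) clin <- read_clinical(inputs$clinical)
    if (!is.null(inputs$maf)) mut <- read_maf(inputs$maf)
  }
  if (is.null(bulk)) stop("stage 'signature' failed: no bulk expression")

  sig <- NULL
  if (!is.null(sc)) {
    stage("signature", function() {
      mk <- do.call(select_markers, c(list(sc = sc, labels = labels),
                                      config$signature))
      sig <<- build_signature(sc, labels, mk)
      write_signature(sig, path("signature.tsv"))
      "signature.tsv"
    })
  } else skip("signature", "no single-cell input")
  if (is.null(sig)) stop("cannot deconvolve without a signature")

  fr <- NULL
  stage("deconvolve", function() {
    ab <- deconvolve(bulk, sig,
                     min_overlap = config$deconvolution$min_overlap)
    fr <<- to_fractions(ab)
    write_expression(t(ab$abundance), path("abundance.tsv"))
    write_expression(t(fr$fractions[!fr$degenerate, , drop = FALSE]),
                     path("fractions.tsv"))
    c("abundance.tsv", "fractions.tsv")
  })

  dt <- strata <- NULL
  stage("diversity", function() {
    dt <<- diversity_table(fr, pielou_n = config$diversity$pielou_n)
    strata <<- stratify_by_quantile(dt, q = config$diversity$q,
                                    scheme = config$diversity$scheme)
    out <- merge(dt, strata, by = "sample_id", all.x = TRUE)
    write.table(out, path("diversity.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    "diversity.tsv"
  })

  if (!is.null(clin)) {
    stage("associate", function() {
      d <- merge(clin, dt[, c("sample_id", "shannon")], by = "sample_id")
      cox_uni <- fit_cox(d, "shannon")
      covs <- intersect(c("shannon", "age", "subtype"), names(d))
      cox_multi <- if (length(covs) > 1) fit_cox(d, covs) else NULL
      km <- km_logrank(clin, strata)
      logi <- if ("response" %in% names(d))
        fit_logistic_response(d, setNames(d$shannon, d$sample_id)) else NULL
      write.table(rbind(cox_uni, cox_multi), path("cox.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(km$curves, path("km_curves.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      writeLines(jsonlite::toJSON(list(chisq = km$chisq, p = km$p_value),
                                  auto_unbox = TRUE, digits = NA),
                 path("logrank.json"))
      if (!is.null(logi))
        write.table(logi, path("logistic.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
      c("cox.tsv", "km_curves.tsv", "logrank.json",
        if (!is.null(logi)) "logistic.tsv")
    })
  } else skip("associate", "no clinical input")

  if (!is.null(mut)) {
    stage("mutations", function() {
      dp <- differential_prevalence(mut, strata,
                                    min_mutated = config$mutations$min_mutated,
                                    include_silent = config$mutations$include_silent)
      si <- somatic_interactions(
        mut, strata$sample_id[strata$stratum %in% c("high", "low")],
        floor_n = config$mutations$interaction_floor,
        include_silent = config$mutations$include_silent)
      panel <- signature_tmb_panel(
        mut, strata, k = config$mutations$top_k,
        min_mutated = config$mutations$min_mutated,
        floor_n = config$mutations$interaction_floor,
        include_silent = config$mutations$include_silent)
      tmb <- compute_tmb(mut, strata$sample_id,
                         genome_size_mb = config$mutations$genome_size_mb,
                         panel = panel,
                         include_silent = config$mutations$include_silent)
      write.table(dp, path("mutation_contrast.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(si, path("interactions.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(tmb, path("tmb.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      c("mutation_contrast.tsv", "interactions.tsv", "tmb.tsv")
    })
  } else skip("mutations", "no MAF input")

  best_genes <- NULL
  stage("wgcna", function() {
    v <- apply(bulk, 1L, var)
    keep <- head(order(-v), config$wgcna$n_variable_genes)
    sub <- log1p(bulk[keep, , drop = FALSE])
    adj <- build_adjacency(sub, soft_power = config$wgcna$soft_power)
    tom <- topological_overlap(adj)
    mods <- detect_modules(tom, sub,
                           min_module_size = config$wgcna$min_module_size,
                           cut_height = config$wgcna$cut_height)
    if (!length(mods)) {
      best_genes <<- NULL
      return(character())
    }
    mt <- module_trait_correlation(mods, dt)
    if (!is.na(mt$best))
      best_genes <<- mt$modules[[mt$best]]$genes
    member <- do.call(rbind, lapply(mt$modules, function(m)
      data.frame(gene = m$genes, module = m$label)))
    write.table(member, path("modules.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(mt$table, path("module_trait.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    c("modules.tsv", "module_trait.tsv")
  })

  if (!is.null(best_genes) && length(best_genes) >= 2) {
    stage("surrogate", function() {
      imp <- rank_importance(bulk, dt, genes = best_genes,
                             n_trees = config$surrogate$n_trees,
                             train_frac = config$surrogate$train_frac,
                             min_node = config$surrogate$min_node,
                             n_permutations = config$surrogate$n_permutations,
                             seed = config$seed)
      genes <- combine_and_filter(list(imp), bulk,
                                  top_k = config$surrogate$top_k,
                                  r_threshold = config$surrogate$r_threshold)
      model <- fit_surrogate(bulk, dt, genes,
                             r_threshold = config$surrogate$r_threshold)
      scores <- score_samples(model, bulk)
      val <- if (!is.null(clin)) validate_surrogate(scores, clin) else NULL
      write.table(as.data.frame(imp), path("importance.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_surrogate(model, path("surrogate_model.json"))
      write.table(data.frame(sample_id = names(scores),
                             surrogate_index = scores),
                  path("surrogate_scores.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      if (!is.null(val))
        write.table(val$cox, path("surrogate_cox.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      c("importance.tsv", "surrogate_model.json", "surrogate_scores.tsv",
        if (!is.null(val)) "surrogate_cox.tsv")
    })
  } else skip("surrogate", "no diversity-associated module selected")

  files <- unlist(lapply(manifest$stages, function(s)
    if (identical(s$status, "ok")) unlist(s$outputs) else character()))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest$checksums <- as.list(setNames(unname(sums), files))
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

config_hash <- function(config) {
  # order-stable hash of the effective configuration
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  as.character(sum(utf8ToInt(as.character(s)) *
                     (seq_along(utf8ToInt(as.character(s))) %% 97 + 1)) %%
                 2147483647)
}
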