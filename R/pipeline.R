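#' Default pipeline configuration
#'
#' Nested configuration for the full desk-scale pipeline. Reference
#' hyperparameters from the large-scale setting appear as named defaults
#' (localizer q = 0.05, readout lambda = 1e-5 with one-cycle 0.05/0.001/0.3,
#' encoding alpha = 0.1 and NCSNR threshold 0.3, geometry n_comp = 10 and
#' tuning-vector scale 2.5e4); sizes are desk-scale analogs of the
#' originals. Every random stage derives its seed deterministically from
#' the global seed via [derive_seed()].
#'
#' @param seed global integer seed.
#' @return nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  cfg <- list(
    schema_version = "1",
    seed = as.integer(seed),
    stimuli = stimulus_config(),
    model = planted_model_config(),
    localizer = list(q = 0.05, stages = "post", ratio = 2.0),
    readout = readout_config(epochs = 150L, batch_size = 64L, max_lr = 10,
                             initial_lr = 0.2, k = 1L),
    lesion = list(n_top = 2L, n_random_draws = 10L),
    voxels = voxel_config(),
    encoding = list(alpha = 1e-3, ncsnr_threshold = 0.3,
                    noise_grid = c(0, 0.5, 1, 2), n_sim = 200L),
    geometry = geometry_config(),
    output = list(dir = "results")
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration against the schema
#'
#' Unknown keys (at the top level or within plain-list sections) are
#' rejected with the offending key path; a schema-version mismatch is an
#' error.
#'
#' @param config a `pipeline_config`.
#' @return the config, invisibly.
#' @export
validate_pipeline_config <- function(config) {
  template <- default_pipeline_config()
  if (!identical(config$schema_version, template$schema_version))
    stop(sprintf("config schema version '%s' != supported '%s'",
                 config$schema_version, template$schema_version))
  bad <- setdiff(names(config), names(template))
  if (length(bad)) stop(sprintf("unknown config key: %s", bad[1]))
  for (sec in c("localizer", "lesion", "encoding", "output")) {
    bad <- setdiff(names(config[[sec]]), names(template[[sec]]))
    if (length(bad)) stop(sprintf("unknown config key: %s.%s", sec, bad[1]))
  }
  invisible(config)
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Persist an analysis artifact
#'
#' Lossless, versioned round-trip for every domain type: `.rds` for
#' arbitrary objects and matrices, `.json` for selectivity maps / lesion
#' specs / manifests, `.tsv` for tables. A schema-version tag is embedded
#' and checked on load.
#'
#' @param artifact the object.
#' @param path destination; the extension selects the format.
#' @return the path, invisibly.
#' @export
persist_results <- function(artifact, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ext <- tools::file_ext(path)
  if (ext == "tsv") {
    utils::write.table(artifact, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(list(schema_version = "1", payload = artifact), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    saveRDS(list(schema_version = "1", payload = artifact), path)
  }
  invisible(path)
}

#' Load a persisted artifact
#'
#' @param path file written by [persist_results()].
#' @return the artifact; truncated or schema-mismatched files raise an
#'   error rather than returning a partial object.
#' @export
load_results <- function(path) {
  ext <- tools::file_ext(path)
  if (ext == "tsv")
    return(utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE))
  obj <- tryCatch({
    if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
    else readRDS(path)
  }, error = function(e) stop(sprintf("failed to load '%s': %s", path,
                                      conditionMessage(e)), call. = FALSE))
  if (!identical(as.character(obj$schema_version), "1"))
    stop(sprintf("schema-version mismatch in '%s'", path))
  obj$payload
}

pipeline_stages <- c("simulate", "localize", "readout", "lesion", "encode",
                     "geometry")

#' Run the analysis pipeline
#'
#' Executes simulate -> localize -> readout -> lesion -> encode -> geometry
#' in dependency order, writing artifacts and summary tables under the
#' output directory along with a JSON manifest (config hash, per-stage
#' seeds, artifact checksums, wall times). An unchanged stage whose cached
#' artifact carries the same config hash is reused unless `force = TRUE`.
#'
#' @param config a `pipeline_config` (validated first).
#' @param stages subset of stages to run (dependencies must be runnable or
#'   cached).
#' @param out_dir output directory (default from the config).
#' @param force ignore cached artifacts.
#' @param verbose print stage progress.
#' @return the run manifest (named list), invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = pipeline_stages,
                         out_dir = config$output$dir, force = FALSE,
                         verbose = TRUE) {
  validate_pipeline_config(config)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  # output paths do not enter the hash: the same science in a different
  # directory is the same run
  manifest <- list(schema_version = "1",
                   config_hash = config_hash(config[setdiff(names(config), "output")]),
                   seed = config$seed, stages = list())
  art <- new.env(parent = emptyenv())

  stage_file <- function(stage) file.path(out_dir, paste0(stage, ".rds"))
  # per-stage hash covers that stage's config section(s) + the global seed
  stage_cfg <- list(
    simulate = config[c("seed", "stimuli", "model", "voxels")],
    localize = config[c("seed", "stimuli", "model", "localizer")],
    readout  = config[c("seed", "stimuli", "model", "readout")],
    lesion   = config[c("seed", "stimuli", "model", "localizer", "readout", "lesion")],
    encode   = config[c("seed", "stimuli", "model", "localizer", "voxels", "encoding")],
    geometry = config[c("seed", "stimuli", "model", "localizer", "geometry")])

  need <- function(stage) {
    f <- stage_file(stage)
    if (is.null(art[[stage]])) {
      if (!file.exists(f))
        stop(sprintf("stage '%s' requires missing artifact %s", stage, f))
      cached <- load_results(f)
      if (!identical(cached$hash, config_hash(stage_cfg[[stage]])))
        stop(sprintf("cached artifact %s was built from a different config", f))
      art[[stage]] <- cached$value
    }
    art[[stage]]
  }

  run_stage <- function(stage, fn) {
    f <- stage_file(stage)
    h <- config_hash(stage_cfg[[stage]])
    t0 <- proc.time()[["elapsed"]]
    if (!force && file.exists(f)) {
      cached <- tryCatch(load_results(f), error = function(e) NULL)
      if (!is.null(cached) && identical(cached$hash, h)) {
        art[[stage]] <- cached$value
        manifest$stages[[stage]] <<- list(seed = derive_seed(config$seed, stage),
                                          cached = TRUE, hash = h,
                                          file = f, md5 = unname(tools::md5sum(f)),
                                          seconds = 0)
        say("stage %-8s: reused cache", stage)
        return(invisible(NULL))
      }
    }
    value <- fn()
    art[[stage]] <- value
    persist_results(list(hash = h, value = value), f)
    manifest$stages[[stage]] <<- list(seed = derive_seed(config$seed, stage),
                                      cached = FALSE, hash = h,
                                      file = f, md5 = unname(tools::md5sum(f)),
                                      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    say("stage %-8s: done (%.1fs)", stage, proc.time()[["elapsed"]] - t0)
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    stimuli <- generate_stimulus_set(config$stimuli,
                                     derive_seed(config$seed, "stimuli"))
    model <- build_planted_model(stimuli, config$model,
                                 derive_seed(config$seed, "model"))
    store <- forward_activations(model, stimuli)
    voxels <- simulate_voxel_dataset(store, model$planted[[config$voxels$layer]],
                                     config$voxels,
                                     derive_seed(config$seed, "voxels"))
    list(stimuli = stimuli, model = model, store = store, voxels = voxels)
  })

  if ("localize" %in% stages) run_stage("localize", function() {
    sim <- need("simulate")
    design <- localizer_design(sim$model$domains, q = config$localizer$q)
    map <- localize_selective_units(sim$store, design,
                                    stages = config$localizer$stages)
    map_ratio <- ratio_localize(sim$store, design, ratio = config$localizer$ratio)
    overlap <- selectivity_overlap(map, map_ratio)
    gen <- generalization_check(map, sim$store, design)
    summ <- selectivity_summary(map)
    recov <- recovery_scores(map, sim$model)
    persist_results(summ$by_layer, file.path(out_dir, "selectivity_by_layer.tsv"))
    persist_results(overlap, file.path(out_dir, "localizer_method_overlap.tsv"))
    persist_results(gen, file.path(out_dir, "probe_generalization.tsv"))
    persist_results(recov, file.path(out_dir, "planted_recovery.tsv"))
    list(design = design, map = map, map_ratio = map_ratio, overlap = overlap,
         generalization = gen, summary = summ, recovery = recov)
  })

  if ("readout" %in% stages) run_stage("readout", function() {
    sim <- need("simulate")
    rcfg <- config$readout
    rcfg$seed <- derive_seed(config$seed, "readout")
    feats <- activations(sim$store, length(sim$model$layers), "post",
                         split = "readout_train")
    labels <- store_labels(sim$store, "readout_train")
    head <- train_sparse_readout(feats, labels, rcfg)
    acc <- topk_accuracy_per_category(
      head, activations(sim$store, length(sim$model$layers), "post",
                        split = "readout_eval"),
      store_labels(sim$store, "readout_eval"), rcfg$k)
    persist_results(data.frame(category = names(acc), top_k_accuracy = 100 * acc),
                    file.path(out_dir, "readout_baseline_accuracy.tsv"))
    list(head = head, baseline = acc)
  })

  if ("lesion" %in% stages) run_stage("lesion", function() {
    sim <- need("simulate"); loc <- need("localize"); ro <- need("readout")
    domains <- names(sim$model$domains)
    profiles <- lapply(domains, function(dn)
      lesion_cost_profile(sim$model, ro$head, sim$stimuli,
                          domain_lesion(loc$map, dn)))
    names(profiles) <- domains
    D <- t(vapply(profiles, function(p) p$cost, profiles[[1]]$cost))
    ac <- vapply(domains, function(dn) {
      units <- selected_units(loc$map, length(sim$model$layers), dn)
      activation_cost_correlation(sim$store, units, profiles[[dn]],
                                  length(sim$model$layers))$r
    }, numeric(1))
    rnull <- random_lesion_null(sim$model, ro$head, sim$stimuli, loc$map,
                                reference_domain = domains[1],
                                n_draws = config$lesion$n_random_draws,
                                seed = derive_seed(config$seed, "lesion"))
    cv <- crossval_top_affected(sim$model, ro$head, sim$stimuli,
                                domain_lesion(loc$map, domains[1]),
                                n_top = config$lesion$n_top,
                                seed = derive_seed(config$seed, "lesion_cv"))
    persist_results(data.frame(lesion_domain = rownames(D), D,
                               check.names = FALSE),
                    file.path(out_dir, "lesion_cost_matrix.tsv"))
    persist_results(data.frame(domain = domains, activation_cost_r = ac),
                    file.path(out_dir, "activation_cost_correlation.tsv"))
    list(profiles = profiles, deficit_matrix = D, activation_cost_r = ac,
         random_null = rnull, crossval = cv)
  })

  if ("encode" %in% stages) run_stage("encode", function() {
    sim <- need("simulate"); loc <- need("localize")
    vox <- session_zscore(sim$voxels)
    rel <- ncsnr(vox)
    keep <- rel$ncsnr > config$encoding$ncsnr_threshold
    prepared <- average_repeats(vox)
    results <- list()
    for (dn in unique(vox$roi_domain)) {
      cols <- which(vox$roi_domain == dn & keep)
      if (length(cols) < 2) next
      results[[dn]] <- encoding_analysis(sim$store, loc$map,
                                         prepared[, cols, drop = FALSE],
                                         sim$stimuli, unit_domain = dn,
                                         alpha = config$encoding$alpha)
    }
    tab <- do.call(rbind, lapply(names(results), function(dn)
      data.frame(roi = dn, best_layer_uni = results[[dn]]$best[["univariate"]],
                 best_layer_versa = results[[dn]]$best[["versa"]],
                 test_univariate = results[[dn]]$test_univariate,
                 test_versa = results[[dn]]$test_versa)))
    ceilings <- lapply(config$encoding$noise_grid, function(ns)
      noise_ceiling_mc(signal_sd = 1, noise_sd = ns,
                       n_stim = sum(sim$stimuli$split == "enc_test"),
                       n_voxels = 1, n_rep = config$voxels$repeats,
                       n_sim = config$encoding$n_sim,
                       seed = derive_seed(config$seed, "ceiling"))$estimate)
    persist_results(rel, file.path(out_dir, "voxel_reliability.tsv"))
    if (!is.null(tab)) persist_results(tab, file.path(out_dir, "encoding_metrics.tsv"))
    persist_results(data.frame(noise_sd = config$encoding$noise_grid,
                               ceiling = unlist(ceilings)),
                    file.path(out_dir, "noise_ceilings.tsv"))
    list(reliability = rel, kept = keep, metrics = tab, results = results,
         ceilings = unlist(ceilings))
  })

  if ("geometry" %in% stages) run_stage("geometry", function() {
    sim <- need("simulate"); loc <- need("localize")
    traj <- meta_rdm_trajectories(sim$store, config = config$geometry)
    sep <- embedding_separation(traj$coords)
    proj <- pc_projection_map(sim$store, sim$store, loc$map,
                              domains = names(sim$model$domains)[1:2],
                              layer = length(sim$model$layers),
                              config = config$geometry)
    persist_results(sep, file.path(out_dir, "embedding_separation.tsv"))
    persist_results(traj$coords, file.path(out_dir, "mds_trajectories.tsv"))
    list(trajectories = traj, separation = sep, projection = proj)
  })

  manifest$files <- list.files(out_dir, full.names = FALSE)
  persist_results(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
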