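#' Run the end-to-end analysis pipeline
#'
#' Orchestrates a complete run over a synthetic study (or user-supplied
#' tables): study generation, organelle filtering, compositional community
#' tests (ANOSIM/PERMANOVA on Aitchison distance for site, region, vintage;
#' Mantel test of geography against climate), DNA-RNA concordance, and
#' consensus signature extraction.  Stages execute in dependency order; a
#' stage failure aborts the stages depending on it and is recorded.  Every
#' artifact is listed in a JSON manifest with its md5 hash together with all
#' seeds and thresholds, so a rerun with the same config is verifiably
#' identical.
#'
#' @param config a configuration list or the path of a YAML file with
#'   (all optional) entries `scenario` (arguments to [scenario_config()]),
#'   `stages` (subset of `"generate"`, `"filter"`, `"community_tests"`,
#'   `"concordance"`, `"signatures"`), `thresholds`
#'   (`prevalence`, `abundance`, `fdr`, `vita_p`), `n_perm`,
#'   `signature` (`S`, `num_trees`, `scheme`, `target`), `out_dir`, `seed`.
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(list(
    scenario = list(),
    stages = c("generate", "filter", "community_tests", "concordance",
               "signatures"),
    thresholds = list(prevalence = 0.90, abundance = 0.01, fdr = 0.1,
                      vita_p = 0.05),
    n_perm = 999,
    signature = list(S = 20, num_trees = 500, scheme = "split70",
                     target = "site"),
    out_dir = file.path(tempdir(), "mustsig_run"),
    seed = 1
  ), config)
  stages <- match.arg(cfg$stages,
                      c("generate", "filter", "community_tests",
                        "concordance", "signatures"), several.ok = TRUE)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scen <- do.call(scenario_config, modifyList(list(seed = cfg$seed),
                                              cfg$scenario))

  # pre-flight: signatures need transcript features
  if ("signatures" %in% stages && scen$n_genes == 0)
    .stopf("config requests signatures but the scenario has n_genes = 0")

  manifest <- list(package = "mustsig",
                   version = as.character(utils::packageVersion("mustsig")),
                   seed = cfg$seed, thresholds = cfg$thresholds,
                   n_perm = cfg$n_perm, signature = cfg$signature,
                   stages = list(), files = list())
  status <- setNames(rep("skipped", 5),
                     c("generate", "filter", "community_tests",
                       "concordance", "signatures"))
  failed <- FALSE
  study <- NULL
  log_line <- function(...) message(sprintf(...))

  run_stage <- function(name, fun) {
    if (!(name %in% stages) || failed) return(invisible(NULL))
    log_line("[%s] starting", name)
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      status[name] <<- paste("failed:", conditionMessage(res))
      failed <<- TRUE
      log_line("[%s] FAILED: %s", name, conditionMessage(res))
    } else {
      status[name] <<- "ok"
      log_line("[%s] done", name)
    }
    invisible(NULL)
  }

  study <- generate_study(scen)  # always needed as input to any stage
  run_stage("generate", function() {
    write_study(study, file.path(out_dir, "study"))
  })
  filtered <- NULL
  run_stage("filter", function() {
    filtered <<- filter_organelle_asvs(study$bacterial)
    write_count_table(filtered, file.path(out_dir, "bacterial_16S_filtered.tsv"))
  })
  if (is.null(filtered)) filtered <- study$bacterial
  run_stage("community_tests", function() {
    md <- study$metadata
    results <- list()
    for (nm in c("bacterial", "fungal")) {
      tab <- if (nm == "bacterial") filtered else study$fungal
      al <- align_samples(tab, md[md$assay == "DNA", ])
      d <- aitchison_distance(al$table)
      for (grp in c("site", "region", "vintage")) {
        g <- al$metadata[[grp]]
        if (length(unique(g)) < 2) next
        an <- anosim(d, g, n_perm = cfg$n_perm, seed = cfg$seed)
        pe <- permanova(d, g, n_perm = cfg$n_perm, seed = cfg$seed)
        results[[paste(nm, grp, sep = "_")]] <- list(
          table = nm, group = grp,
          anosim_R = an$statistic, anosim_p = an$p_value,
          permanova_F = pe$statistic, permanova_R2 =
            unname(pe$effect_partition["group"]), permanova_p = pe$p_value)
      }
    }
    env <- study$environment
    if (nrow(env$sites) >= 3) {
      geo <- haversine_matrix(env$sites[, c("site", "latitude_deg",
                                            "longitude_deg")])
      v1 <- env$covariates[env$covariates$vintage == scen$vintages[1], ]
      v1 <- v1[match(env$sites$site, v1$site), ]
      clim <- as.matrix(dist(scale_center(
        v1[, c("precipitation_mm", "gdd"), drop = FALSE])))
      rownames(clim) <- colnames(clim) <- env$sites$site
      dp <- dist_matrix(clim, "euclidean")
      mt <- mantel(geo, dp, n_perm = cfg$n_perm, seed = cfg$seed)
      results$geo_climate <- list(mantel_r = mt$statistic,
                                  mantel_p = mt$p_value)
    }
    jsonlite::write_json(results, file.path(out_dir, "community_tests.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  run_stage("concordance", function() {
    tab <- concordance_table(study$fungal, study$transcripts, study$metadata)
    write.table(tab, file.path(out_dir, "concordance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  run_stage("signatures", function() {
    ff <- summarize_timeseries(study$transcripts, study$metadata)
    sc <- cfg$signature
    sig <- consensus_signature(ff, target = sc$target, scheme = sc$scheme,
                               S = sc$S, num_trees = sc$num_trees,
                               seed = cfg$seed)
    rows <- do.call(rbind, lapply(names(sig$signatures), function(cl) {
      df <- sig$signatures[[cl]]
      if (nrow(df) == 0) return(NULL)
      cbind(class = cl, df)
    }))
    if (is.null(rows))
      rows <- data.frame(class = character(0), gene = character(0),
                         attribute = character(0), mean_importance = numeric(0))
    write.table(rows, file.path(out_dir, "signatures.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    one <- classify_samples(ff$x, ff$fermentations[[sc$target]],
                            scheme = "split70", vita = TRUE,
                            num_trees = sc$num_trees, seed = cfg$seed)
    if (!is.null(ff$organism)) {
      att <- organism_attribution(one$global_importance, ff$organism)
      write.table(data.frame(organism = names(att), percent = as.numeric(att)),
                  file.path(out_dir, "organism_attribution.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(accuracy = one$accuracy, kappa = one$kappa,
           n_signature_genes = length(signature_genes(sig))),
      file.path(out_dir, "model_metrics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest$stages <- as.list(status[stages])
  manifest$files <- lapply(files, function(f) {
    list(path = sub(paste0("^", out_dir, "/?"), "", f),
         md5 = unname(tools::md5sum(f)))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
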