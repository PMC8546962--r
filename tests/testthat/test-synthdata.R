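test_that("scenario configs validate their invariants", {
  expect_error(scenario_config(timepoints_hours = c(2, 2, 6)), "increasing")
  expect_error(scenario_config(frac_active_taxa = 1.2), "frac_active_taxa")
  expect_error(scenario_config(dna_rna_r2 = -0.1), "dna_rna_r2")
  expect_error(scenario_config(effect_sd_site = -1), "deviations")
  expect_error(scenario_config(n_regions = 0), "counts")
  expect_error(scenario_config(sites_per_region = c(2, 2)), "length")
  expect_error(scenario_config(rna_vintages = "1999"), "subset")
  expect_s3_class(scenario_null(), "scenario_config")
})

test_that("study generation is deterministic given the seed", {
  cfg <- scenario_null(seed = 5, n_genes = 20)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  s3 <- generate_study(scenario_null(seed = 6, n_genes = 20))
  expect_false(identical(s1$bacterial$counts, s3$bacterial$counts))
})

test_that("table shapes follow the design arithmetic, including dropped tanks", {
  drop <- data.frame(site = "S02", vintage = "2019", tank = "T4")
  cfg <- scenario_config(dropped_tanks = drop)
  st <- generate_study(cfg)
  expect_equal(ncol(st$bacterial$counts), 15 * 4 * 3 - 1)
  expect_equal(ncol(st$fungal$counts), 15 * 4 * 3 - 1)
  expect_equal(length(st$transcripts), 5)
  expect_equal(ncol(st$transcripts[[1]]$counts), 15 * 2 * 2)
  expect_equal(nrow(st$transcripts[[1]]$counts), 200)
  expect_false("dna_S02_2019_T4" %in% st$metadata$sample_id)
  # every count-table sample is described in the metadata
  expect_true(all(colnames(st$fungal$counts) %in% st$metadata$sample_id))
  expect_true(all(colnames(st$transcripts[[3]]$counts) %in%
                    st$metadata$sample_id))
  # truth lists are subsets of the feature ids
  expect_true(all(st$truth$site_genes %in%
                    rownames(st$transcripts[[1]]$counts)))
  expect_true(all(st$truth$active_taxa$feature_id %in%
                    rownames(st$fungal$counts)))
})

test_that("the dominance boost makes the designated taxon top-ranked", {
  cfg <- scenario_config(n_regions = 2, sites_per_region = 2,
                         tanks_per_site = 2, vintages = "2017",
                         rna_vintages = "2017", n_fungal_taxa = 30,
                         dominance_alpha = 1000, seed = 3)
  tab <- generate_community_counts(cfg, "ITS")
  rel <- relative_abundance(tab)
  expect_true(all(apply(rel, 2, which.max) == 1))
  expect_equal(which.max(rowMeans(rel)), c(fASV0001 = 1L))
})

test_that("no-effect scenarios make samples exchangeable across sites", {
  cfg <- scenario_null(seed = 11)
  tab <- generate_community_counts(cfg, "ITS")
  md <- generate_study(cfg)$metadata
  al <- align_samples(tab, md[md$assay == "DNA", ])
  d <- aitchison_distance(al$table)
  res <- permanova(d, al$metadata$site, n_perm = 199, seed = 1)
  expect_gt(res$p_value, 0.01)
})

test_that("degenerate depths and markers are rejected", {
  expect_error(generate_community_counts(scenario_null(library_size_dna = 0),
                                         "16S"), "all-zero")
  expect_error(generate_community_counts(scenario_null(), "mRNA"),
               "invalid marker")
})

test_that("inactivity and inoculant dominance shape the transcriptome", {
  cfg <- scenario_config(n_regions = 2, sites_per_region = 2,
                         tanks_per_site = 2, vintages = c("2017", "2019"),
                         n_fungal_taxa = 30, n_genes = 60,
                         frac_active_taxa = 0, seed = 4)
  fungal <- generate_community_counts(cfg, "ITS")
  tr <- generate_expression_timeseries(cfg, fungal)
  orgs <- unique(tr[[1]]$organism)
  expect_setequal(orgs, c("Saccharomyces cerevisiae", "Vitis vinifera"))
  # inoculant holds the configured majority of reads at every timepoint
  for (tab in tr) {
    rel <- relative_abundance(tab)
    ino <- colSums(rel[tab$organism == "Saccharomyces cerevisiae", ,
                       drop = FALSE])
    expect_true(all(ino > 0.8))
  }
})

test_that("zero genes yield empty transcript tables that downstream refuses", {
  cfg <- scenario_config(n_genes = 0, n_site_genes = 0, seed = 2)
  st <- generate_study(cfg)
  expect_equal(nrow(st$transcripts[[1]]$counts), 0)
  expect_error(summarize_timeseries(st$transcripts, st$metadata),
               "no transcript features")
})

test_that("climate fields are spatially autocorrelated by construction", {
  hits <- 0
  for (s in 1:50) {
    cfg <- scenario_config(seed = 1000 + s)
    env <- generate_environment(cfg)
    geo <- haversine_matrix(env$sites[, c("site", "latitude_deg", "longitude_deg")])
    v <- env$covariates[env$covariates$vintage == "2017", ]
    v <- v[match(env$sites$site, v$site), ]
    dp <- as.matrix(dist(v$precipitation_mm))
    rownames(dp) <- colnames(dp) <- env$sites$site
    res <- mantel(geo, dist_matrix(dp), n_perm = 199, seed = 1)
    if (!is.na(res$statistic) && res$statistic > 0 && res$p_value < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 45)  # >= 90% of seeds
})

test_that("infinite spatial range collapses climate to a constant field", {
  cfg <- scenario_config(env_spatial_range = Inf, seed = 9)
  env <- generate_environment(cfg)
  v <- env$covariates[env$covariates$vintage == "2017", ]
  expect_lt(diff(range(v$precipitation_mm)), 1e-3)
  geo <- haversine_matrix(env$sites[, c("site", "latitude_deg", "longitude_deg")])
  dp <- as.matrix(dist(v$precipitation_mm))
  rownames(dp) <- colnames(dp) <- env$sites$site
  res <- mantel(geo, dist_matrix(round(dp, 12)), n_perm = 99, seed = 1)
  expect_identical(res$flag, "degenerate")
})

test_that("tiny designs warn that the spatial check is skipped", {
  cfg <- scenario_config(n_regions = 1, sites_per_region = 2,
                         tanks_per_site = 2, vintages = "2017",
                         rna_vintages = "2017", seed = 2)
  expect_warning(generate_environment(cfg), "fewer than 3 sites")
})

test_that("sites at identical coordinates share climate expectations", {
  cfg <- scenario_config(n_regions = 2, sites_per_region = 2,
                         tanks_per_site = 2, vintages = "2017",
                         rna_vintages = "2017", env_spatial_range = 40, seed = 8)
  co <- data.frame(site = c("S01", "S02", "S03", "S04"),
                   latitude_deg = c(44.5, 44.5, 45.2, 45.4),
                   longitude_deg = c(-123.0, -123.0, -122.4, -122.6))
  draws <- sapply(1:40, function(i) {
    cfg$seed <- 8 + i
    env <- generate_environment(cfg, coordinates = co)
    v <- env$covariates[env$covariates$vintage == "2017", ]
    v$precipitation_mm[match(c("S01", "S02"), v$site)]
  })
  expect_gt(cor(draws[1, ], draws[2, ]), 0.99)
})

test_that("written studies round-trip through the text formats", {
  st <- generate_study(scenario_null(seed = 14, n_genes = 10))
  dir <- tempfile()
  paths <- write_study(st, dir)
  back <- read_count_table(paths[["fungal"]], "ITS")
  expect_equal(back$counts, st$fungal$counts + 0)
  md <- read_metadata(paths[["metadata"]])
  expect_setequal(md$sample_id, st$metadata$sample_id)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(truth$active_taxa$feature_id, st$truth$active_taxa$feature_id)
})
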