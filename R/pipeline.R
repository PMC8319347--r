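#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes the pipeline stages in order on synthetic data with known ground
#' truth, writing each stage's outputs and a run manifest to `out_dir`.
#' Stages: `simulate` (all synthetic inputs), `consensus` (multi-caller
#' filter), `gscore` (parallel-evolution test), `cooccur` (permutation test
#' on the most-shared gene pair), `lineage` (single-cell tree), `growth`
#' (plate fits + minimal permissive density) and `synergy` (Excess over
#' Bliss). Each stage derives its own seed deterministically from the
#' config's master seed, so reruns with the same config are identical and
#' stages can be reproduced in isolation. Downstream stages fail fast with
#' the stage name when their inputs are missing.
#'
#' @param config A [sim_config()].
#' @param stages Ordered subset of the stage names above.
#' @param out_dir Output directory (created if needed).
#' @param n_sims Randomizations for the G-score null.
#' @param n_perm Replicates for the permutation test.
#' @return The run manifest (list, also written as `manifest.json`).
#' @export
run_pipeline <- function(config = sim_config(),
                         stages = c("simulate", "consensus", "gscore",
                                    "cooccur", "lineage", "growth",
                                    "synergy"),
                         out_dir = tempfile("syntroph_run_"),
                         n_sims = 1000L, n_perm = 2000L) {
  stopifnot(inherits(config, "sim_config"))
  known <- c("simulate", "consensus", "gscore", "cooccur", "lineage",
             "growth", "synergy")
  stages <- match.arg(stages, known, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  deps <- list(
    consensus = "caller_vcfs", gscore = "consensus.tsv",
    cooccur = "trajectories.tsv", lineage = "sc_matrix.csv",
    growth = "plate.csv", synergy = "pairings.csv"
  )
  path <- function(f) file.path(out_dir, f)
  manifest_stages <- list()

  for (stage in stages) {
    dep <- deps[[stage]]
    if (!is.null(dep) && !file.exists(path(dep)) && !dir.exists(path(dep))) {
      abort(sprintf("stage '%s' requires missing upstream output '%s'.",
                    stage, dep))
    }
    t0 <- Sys.time()
    seed <- derive_seed(config$seed, match(stage, known))
    outputs <- switch(stage,
      simulate = stage_simulate(config, out_dir),
      consensus = stage_consensus(out_dir),
      gscore = stage_gscore(config, out_dir, n_sims, seed),
      cooccur = stage_cooccur(out_dir, n_perm, seed),
      lineage = stage_lineage(config, out_dir, seed),
      growth = stage_growth(out_dir),
      synergy = stage_synergy(out_dir)
    )
    manifest_stages[[stage]] <- list(
      stage = stage, seed = seed, outputs = outputs,
      wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  }

  manifest <- list(
    config_hash = hash(unclass(config)),
    seed = config$seed,
    stages = manifest_stages,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_simulate <- function(config, out_dir) {
  sim <- simulate_lines(config)
  write_trajectories(sim$trajectories, file.path(out_dir, "trajectories.tsv"))
  readr::write_tsv(sim$events, file.path(out_dir, "events.tsv"))
  readr::write_tsv(sim$catalog, file.path(out_dir, "catalog.tsv"))

  # per-caller VCFs from the final-generation variant calls of organism A
  ev <- filter(sim$events, .data$organism == "Dv_like")
  true_calls <- with_seed(derive_seed(config$seed, 10L), tibble(
    chrom = "Dv_like", position = seq_len(nrow(ev)) * 100L,
    ref = ev$ref, alt = ev$alt, frequency = runif(nrow(ev), 0.2, 1),
    locus = ev$gene
  ))
  profiles <- tibble(caller = c("gatk", "varscan", "bcftools"),
                     fp_rate = c(0.01, 0.02, 0.015),
                     fn_rate = c(0.05, 0.1, 0.08))
  calls <- simulate_caller_outputs(true_calls, profiles, decoy_sites = 500L,
                                   seed = derive_seed(config$seed, 11L))
  write_caller_vcfs(calls, file.path(out_dir, "caller_vcfs"))

  tree <- random_mutation_tree(5, seed = derive_seed(config$seed, 12L))
  mat <- simulate_single_cells(tree, n_cells = 90, fd = config$fd,
                               ad = config$ad,
                               missing_rate = config$missing_rate,
                               seed = derive_seed(config$seed, 13L))
  write_mutation_matrix(mat, file.path(out_dir, "sc_matrix.csv"))
  writeLines(as_newick(tree), file.path(out_dir, "true_tree.nwk"))

  plate <- simulate_growth_plate(config)
  write_plate(plate, file.path(out_dir, "plate.csv"))
  readr::write_csv(plate$map, file.path(out_dir, "plate_map.csv"))

  pairings <- simulate_pairings(mode = "synergistic",
                                seed = derive_seed(config$seed, 14L))
  readr::write_csv(pairings, file.path(out_dir, "pairings.csv"))

  jsonlite::write_json(
    list(sweep = sim$truth$sweep, parallel_genes = sim$truth$parallel_genes,
         true_tree = as_newick(tree),
         pairing_truth = attr(pairings, "truth")),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  c("trajectories.tsv", "events.tsv", "catalog.tsv", "caller_vcfs",
    "sc_matrix.csv", "true_tree.nwk", "plate.csv", "plate_map.csv",
    "pairings.csv", "truth.json")
}

stage_consensus <- function(out_dir) {
  paths <- list.files(file.path(out_dir, "caller_vcfs"), full.names = TRUE,
                      pattern = "\\.vcf$")
  calls <- read_caller_vcfs(paths)
  cons <- consensus_calls(calls)
  readr::write_tsv(cons, file.path(out_dir, "consensus.tsv"))
  "consensus.tsv"
}

stage_gscore <- function(config, out_dir, n_sims, seed) {
  events <- readr::read_tsv(file.path(out_dir, "events.tsv"),
                            show_col_types = FALSE)
  catalog <- readr::read_tsv(file.path(out_dir, "catalog.tsv"),
                             show_col_types = FALSE)
  out <- list()
  for (org in unique(catalog$organism)) {
    fit <- gscore_test(filter(events, .data$organism == org),
                       filter(catalog, .data$organism == org),
                       n_sims = n_sims, seed = seed)
    out[[org]] <- glance(fit)
    readr::write_tsv(tidy(fit),
                     file.path(out_dir, sprintf("gscore_%s.tsv", org)))
  }
  jsonlite::write_json(out, file.path(out_dir, "gscore_summary.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  c(sprintf("gscore_%s.tsv", names(out)), "gscore_summary.json")
}

stage_cooccur <- function(out_dir, n_perm, seed) {
  traj <- read_trajectories(file.path(out_dir, "trajectories.tsv"))
  # most-shared detected gene pair as the demo test case
  pres <- traj %>%
    filter(.data$frequency >= 0.05) %>%
    distinct(.data$line, .data$gene)
  top <- pres %>% count(.data$gene, sort = TRUE) %>% head(2)
  if (nrow(top) < 2) abort("stage 'cooccur': fewer than two detected genes.")
  res <- permutation_pvalue(traj, top$gene[1], top$gene[2],
                            mode = "co_occurrence", n = n_perm, seed = seed,
                            k = 1L)
  jsonlite::write_json(as.list(res), file.path(out_dir, "cooccur.json"),
                       auto_unbox = TRUE, digits = NA)
  "cooccur.json"
}

stage_lineage <- function(config, out_dir, seed) {
  mat <- read_mutation_matrix(file.path(out_dir, "sc_matrix.csv"),
                              fd = config$fd, ad = config$ad)
  fit <- if (ncol(mat) <= 5) infer_ml_tree(mat, "exhaustive") else
    infer_ml_tree(mat, "mcmc", seed = seed, chain_length = 2e4)
  writeLines(as_newick(fit$tree), file.path(out_dir, "ml_tree.nwk"))
  jsonlite::write_json(
    list(loglik = fit$loglik, n_ties = fit$n_ties,
         tied_labels = fit$tied_labels, search = fit$search),
    file.path(out_dir, "lineage.json"), auto_unbox = TRUE, digits = NA
  )
  c("ml_tree.nwk", "lineage.json")
}

stage_growth <- function(out_dir) {
  plate <- read_plate(file.path(out_dir, "plate.csv"),
                      file.path(out_dir, "plate_map.csv"))
  fits <- fit_growth_plate(plate)
  readr::write_tsv(fits, file.path(out_dir, "growth_fits.tsv"))
  mpd <- minimal_permissive_density(plate)
  jsonlite::write_json(
    list(minimal_density = mpd$minimal_density, profile = mpd$profile),
    file.path(out_dir, "minimal_density.json"), auto_unbox = TRUE,
    dataframe = "rows", digits = NA
  )
  c("growth_fits.tsv", "minimal_density.json")
}

stage_synergy <- function(out_dir) {
  pairings <- readr::read_csv(file.path(out_dir, "pairings.csv"),
                              show_col_types = FALSE)
  rep_ <- synergy_report(pairings)
  jsonlite::write_json(rep_, file.path(out_dir, "synergy.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  "synergy.json"
}

#' Validate a pipeline input file against its schema
#'
#' Checks column presence, types and value ranges for the pipeline's
#' plain-text formats and reports every violation found.
#'
#' @param path File path.
#' @param schema One of `"trajectory"`, `"matrix"`, `"plate"`, `"pairing"`,
#'   `"consensus"`.
#' @return Tibble of violations (column, problem); zero rows when valid.
#' @export
validate_inputs <- function(path, schema = c("trajectory", "matrix", "plate",
                                             "pairing", "consensus")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  violations <- list()
  note <- function(column, problem) {
    violations[[length(violations) + 1]] <<- tibble(column = column,
                                                    problem = problem)
  }

  if (schema == "trajectory") {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("line", "generation", "gene", "frequency")
    for (col in setdiff(need, names(df))) note(col, "missing column")
    if ("frequency" %in% names(df) &&
        any(df$frequency < 0 | df$frequency > 1, na.rm = TRUE)) {
      note("frequency", "values outside [0, 1]")
    }
    if ("generation" %in% names(df) && any(df$generation < 0, na.rm = TRUE)) {
      note("generation", "negative generations")
    }
  } else if (schema == "matrix") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    if (ncol(df) < 2) note("<matrix>", "no mutation columns")
    vals <- unlist(df[, -1, drop = FALSE])
    bad <- setdiff(unique(vals), c(0, 1, 3))
    if (length(bad)) {
      note("<matrix>", sprintf("states outside {0,1,3}: %s",
                               paste(bad, collapse = ", ")))
    }
  } else if (schema == "plate") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    if (!"time" %in% names(df)) note("time", "missing column")
    if ("time" %in% names(df) && any(diff(df$time) <= 0)) {
      note("time", "not strictly increasing")
    }
    ods <- unlist(df[, setdiff(names(df), "time"), drop = FALSE])
    if (any(ods < 0, na.rm = TRUE)) note("<wells>", "negative OD readings")
  } else if (schema == "pairing") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    need <- c("pairing", "metric", "replicate", "value")
    for (col in setdiff(need, names(df))) note(col, "missing column")
    if ("pairing" %in% names(df)) {
      bad <- setdiff(unique(df$pairing), c("AcAc", "EvAc", "AcEv", "EvEv"))
      if (length(bad)) {
        note("pairing", sprintf("unknown level(s): %s",
                                paste(bad, collapse = ", ")))
      }
    }
  } else if (schema == "consensus") {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("position", "alt", "frequency", "n_callers")
    for (col in setdiff(need, names(df))) note(col, "missing column")
    if ("frequency" %in% names(df) &&
        any(df$frequency < 0 | df$frequency > 1, na.rm = TRUE)) {
      note("frequency", "values outside [0, 1]")
    }
  }

  if (length(violations) == 0) {
    return(tibble(column = character(), problem = character()))
  }
  bind_rows(violations)
}

#' Heatmap-style view of mutation-frequency trajectories
#'
#' @param trajectories Trajectory tibble.
#' @param line Optional line id to restrict to.
#' @return A ggplot.
#' @export
plot_trajectories <- function(trajectories, line = NULL) {
  df <- trajectories
  if (!is.null(line)) df <- filter(df, .data$line == !!line)
  ggplot(df, aes(x = factor(.data$generation), y = .data$gene,
                 fill = .data$frequency)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    facet_grid(stats::reformulate("line", "organism"), scales = "free_y") +
    labs(x = "generation", y = NULL, fill = "frequency")
}
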