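#' Default pipeline configuration
#'
#' A fully synthetic demo configuration exercising every stage: a 60-subject
#' battery cohort (30/30) with an 11-test single-factor battery, covariates
#' tied to the latent factor, and a 90-node / 6-module connectome cohort with
#' weaker within-module correlation in the patient group. All stochastic
#' stages derive sub-seeds from the single `seed`.
#'
#' @param seed Master integer seed.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    alpha = 0.05,
    n_perm = 2000L,
    battery = list(synth = list(
      n_per_group = c(30L, 30L),
      group_shift = -0.85)),
    covariates = list(synth = list(
      education = list(slope = 0.5, type = "pearson"),
      onset_age = list(slope = 0.4, type = "spearman"),
      duration = list(slope = -0.4, type = "spearman"),
      n_asm = list(slope = -0.4, type = "spearman"),
      adi = list(slope = 0.5, type = "t"))),
    connectome = list(
      synth = list(n_nodes = 90L, module_sizes = rep(15L, 6L),
                   within_corr = 0.5, between_corr = 0.1,
                   subject_noise_sd = 0.06, group_delta = 0.1,
                   n_subjects_per_group = c(30L, 30L)),
      densities = c(0.2, 0.3, 0.4),
      pc_density = 0.4,
      k_nulls = 10L,
      mode = "weighted",
      negative_policy = "zero",
      louvain_restarts = 20L,
      n_swaps_per_edge = 10L)
  ), class = "run_config")
}

#' Read or write a pipeline configuration
#'
#' Configurations are plain YAML; [read_config()]/[write_config()] round-trip
#' them unchanged.
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @param config A `run_config` list.
#' @export
write_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

resolve_battery <- function(config) {
  b <- config$battery
  if (!is.null(b$path)) return(read_score_table(b$path))
  s <- b$synth %||% list()
  s$seed <- derive_seed(config$seed, "battery-stage")
  spec <- do.call(battery_spec, s)
  simulate_battery(spec)
}

resolve_connectomes <- function(config) {
  cn <- config$connectome
  if (is.null(cn)) return(NULL)
  if (!is.null(cn$manifest)) {
    cohort <- read_connectome_set(cn$manifest)
    cohort$modules <- read_parcellation(cn$parcellation)
    return(cohort)
  }
  s <- cn$synth
  npg <- s$n_subjects_per_group %||% c(50L, 50L)
  s$n_subjects_per_group <- NULL
  s$seed <- derive_seed(config$seed, "connectome-stage")
  spec <- do.call(network_spec, s)
  simulate_connectomes(spec, npg)
}

#' Validate pipeline inputs
#'
#' Resolves the configured inputs (reading or simulating them exactly as
#' [run_pipeline()] would) and checks matrix symmetry, zero diagonals,
#' parcellation coverage, score completeness and group coding. Returns a
#' machine-readable issue list rather than raising errors.
#'
#' @param config A `run_config`.
#' @return `data.frame` with columns `stage` and `issue`; zero rows when the
#'   inputs are clean.
#' @export
validate_inputs <- function(config) {
  issues <- list()
  add <- function(stage, issue)
    issues[[length(issues) + 1L]] <<- data.frame(stage = stage, issue = issue)
  tab <- tryCatch(resolve_battery(config), error = function(e) {
    add("battery", conditionMessage(e)); NULL
  })
  if (!is.null(tab)) {
    if (!all(tab$group %in% c(0L, 1L)))
      add("battery", "group column not coded 0/1")
    tests <- attr(tab, "tests") %||%
      setdiff(names(tab)[vapply(tab, is.numeric, TRUE)], c("group"))
    nmiss <- sum(!stats::complete.cases(tab[tests]))
    if (nmiss > 0)
      add("battery", paste0(nmiss, " subject(s) with missing test scores"))
  }
  cohort <- tryCatch(resolve_connectomes(config), error = function(e) {
    add("connectome", conditionMessage(e)); NULL
  })
  if (!is.null(cohort)) {
    for (i in seq_along(cohort$z)) {
      msg <- tryCatch({
        validate_connectivity_matrix(cohort$z[[i]], cohort$subject[i])
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(msg)) add("connectome", msg)
    }
    n <- nrow(cohort$z[[1]])
    mods <- cohort$modules
    if (is.null(mods)) {
      add("parcellation", "no parcellation provided")
    } else {
      if (length(mods) != n)
        add("parcellation",
            paste0("parcellation covers ", length(mods), " nodes, matrices have ", n))
      bad <- which(is.na(mods) | mods == "")
      for (b in bad) add("parcellation", paste0("node ", b - 1L, " missing module label"))
      if (length(unique(stats::na.omit(mods))) < 2L)
        add("parcellation", "fewer than 2 modules")
    }
    if (!all(cohort$group %in% c(0L, 1L)))
      add("connectome", "group column not coded 0/1")
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(stage = character(), issue = character())
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: score-table acquisition, g-factor
#' extraction (adequacy diagnostics, MAP factor count, minres EFA, regression
#' scores), group comparison (effect-size table, Fisher discriminant and its
#' correlation with g), covariate associations, and — when a connectome stage
#' is configured — the density sweep with null-normalized global metrics,
#' corrected group tests and per-group PC-g correlations. Deterministic under
#' the config seed.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param quiet Suppress stage log messages.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[gconnect] ", ...)
  t0 <- proc.time()[["elapsed"]]
  seed <- config$seed %||% 1L
  alpha <- config$alpha %||% 0.05
  n_perm <- config$n_perm %||% 10000L

  say("stage: battery (seed ", derive_seed(seed, "battery-stage"), ")")
  tab <- resolve_battery(config)
  tests <- attr(tab, "tests") %||%
    setdiff(names(tab)[vapply(tab, is.numeric, TRUE)], "group")

  say("stage: g-factor extraction")
  fit <- gfactor(tab, tests = tests, n_factors = config$n_factors)

  say("stage: group statistics")
  ld <- lda_fit(as.matrix(tab[tests]), tab$group)
  scored <- fit$data
  scored$lda <- ld$scores / stats::sd(ld$scores)
  eff <- effect_size_table(scored, c("g", "lda", tests), n_perm = n_perm,
                           seed = derive_seed(seed, "effects"))
  comp <- lda_vs_g(ld$scores, fit$g, tab[tests])

  assoc <- NULL
  cov_tab <- NULL
  if (!is.null(config$covariates)) {
    say("stage: covariates")
    cs <- config$covariates$synth
    if (!is.null(cs)) {
      g_true <- attr(tab, "latent") %||% fit$g
      slopes <- vapply(cs, function(x) x$slope, numeric(1))
      cov_tab <- simulate_covariates(g_true, slopes,
                                     seed = derive_seed(seed, "covariate-stage"))
      types <- vapply(cs, function(x) x$type %||% "pearson", character(1))
    } else {
      cov_tab <- tab[config$covariates$columns]
      types <- vapply(config$covariates$types, identity, character(1))
    }
    assoc <- do.call(rbind, lapply(names(cov_tab), function(nm) {
      associate(fit$g, cov_tab[[nm]], type = types[[nm]], covariate = nm)
    }))
  }

  connectome <- NULL
  if (!is.null(config$connectome)) {
    cn <- config$connectome
    say("stage: connectome sweep (seed ", derive_seed(seed, "connectome-stage"), ")")
    cohort <- resolve_connectomes(config)
    profiles <- density_sweep(
      cohort,
      densities = cn$densities %||% c(0.2, 0.3, 0.4),
      k_nulls = cn$k_nulls %||% 20L,
      seed = derive_seed(seed, "sweep"),
      mode = cn$mode %||% "weighted",
      negative_policy = cn$negative_policy %||% "zero",
      louvain_restarts = cn$louvain_restarts %||% 100L,
      n_swaps_per_edge = cn$n_swaps_per_edge %||% 10L)
    say("stage: connectome group tests")
    tests_out <- group_metric_tests(profiles, alpha = alpha, n_perm = n_perm,
                                    seed = derive_seed(seed, "gtests"))
    pcg <- NULL
    pc_density <- cn$pc_density %||% 0.4
    if (length(cohort$z) == nrow(tab)) {
      sub_pc <- profiles$parcel_pc[profiles$parcel_pc$density == pc_density, ]
      if (nrow(sub_pc)) pcg <- pc_g_correlation(sub_pc, fit$g, cohort$group,
                                                alpha = alpha)
    } else {
      say("note: connectome cohort size differs from battery; PC-g stage skipped")
    }
    connectome <- list(profiles = profiles, group_tests = tests_out,
                       pc_g = pcg, pc_density = pc_density)
  }

  say(sprintf("done in %.1f s", proc.time()[["elapsed"]] - t0))
  structure(list(
    config = config,
    manifest = list(config_hash = config_hash(config), seed = seed,
                    stage_seeds = list(
                      battery = derive_seed(seed, "battery-stage"),
                      covariates = derive_seed(seed, "covariate-stage"),
                      connectome = derive_seed(seed, "connectome-stage"),
                      sweep = derive_seed(seed, "sweep"))),
    battery = tab,
    gfactor = fit,
    lda = ld,
    effect_sizes = eff,
    lda_comparison = comp,
    covariates = cov_tab,
    associations = assoc,
    connectome = connectome
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("gconnect pipeline report\n")
  cat("  subjects:", nrow(x$battery), "; tests:", length(x$gfactor$tests), "\n")
  cat(sprintf("  KMO %.2f | MAP factors %d | RMSR %.3f | score validity %.2f\n",
              x$gfactor$adequacy$kmo_overall, x$gfactor$map[["1976"]]$n_factors,
              x$gfactor$model$rmsr, x$gfactor$scores$validity[1]))
  dg <- x$effect_sizes[x$effect_sizes$measure == "g", ]
  cat(sprintf("  g effect size d = %.3f (perm p = %.4g); corr(g, LDA) = %.3f\n",
              dg$cohens_d, dg$perm_p, x$lda_comparison$r_lda_g))
  if (!is.null(x$connectome)) {
    sig <- x$connectome$group_tests$global
    cat("  connectome: ", sum(sig$significant), "/", nrow(sig),
        " global metric x density comparisons significant after Bonferroni\n",
        sep = "")
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the report as stable CSV/JSON files (adequacy and factor model JSON,
#' g scores, effect sizes, LDA summary, associations, connectome tables and a
#' manifest with the config hash and stage seeds). Output is byte-identical
#' across runs with the same config.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wc <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  fit <- report$gfactor
  wj(list(kmo_overall = fit$adequacy$kmo_overall,
          msa_per_item = as.list(fit$adequacy$msa_per_item),
          bartlett_chi2 = fit$adequacy$chi2,
          bartlett_df = fit$adequacy$df,
          bartlett_p = fit$adequacy$p), "adequacy.json")
  wj(list(map_1976 = fit$map[["1976"]]$n_factors,
          map_2000 = fit$map[["2000"]]$n_factors,
          n_factors = fit$model$n_factors,
          loadings = as.list(stats::setNames(as.numeric(fit$model$loadings[, 1]),
                                             fit$tests)),
          uniquenesses = as.list(stats::setNames(fit$model$uniquenesses, fit$tests)),
          rmsr = fit$model$rmsr,
          tli = fit$model$tli,
          score_validity = fit$scores$validity,
          score_r2 = fit$scores$r2), "factor_model.json")
  wc(data.frame(subject = report$battery$subject, group = report$battery$group,
                g = fit$g), "g_scores.csv")
  wc(report$effect_sizes, "effect_sizes.csv")
  wj(list(direction = as.list(report$lda$direction),
          r_lda_g = report$lda_comparison$r_lda_g), "lda.json")
  wc(report$lda_comparison$correlations, "lda_correlations.csv")
  if (!is.null(report$associations)) wc(report$associations, "associations.csv")
  if (!is.null(report$connectome)) {
    wc(report$connectome$profiles$global, "connectome_global.csv")
    wc(report$connectome$profiles$parcel_pc, "connectome_parcel_pc.csv")
    wc(report$connectome$group_tests$global, "connectome_tests_global.csv")
    wc(report$connectome$group_tests$parcel, "connectome_tests_parcel.csv")
    if (!is.null(report$connectome$pc_g))
      wc(report$connectome$pc_g, "pc_g_correlations.csv")
  }
  wj(report$manifest, "manifest.json")
  invisible(dir)
}
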