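#' Run the full philopatry analysis pipeline
#'
#' Config-driven end-to-end run: load or simulate the data, screen scoring
#' quality (per-allele HWE), tabulate diversity, estimate differentiation
#' (global and pairwise theta, permutation significance, MDS), pool the
#' references, self-assign the reference individuals (leave-one-out), run
#' the exclusion test and the assignment of tagged fish, classify migratory
#' behaviour from the tracks, summarise assignment per behavioural group,
#' build the migration x assignment contingency table and test independence
#' (Fisher and Boschloo), and check robustness to reference subsampling.
#' Optional stages degrade gracefully with warnings (e.g. no tracks); every
#' output table is a pure function of (inputs, config, seed), so two runs
#' with the same seed produce byte-identical tables.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   * `synthetic`: list of [sim_config()] arguments (exclusive with
#'     `inputs`),
#'   * `inputs`: list with paths `references` (Genepop), `tagged` (Genepop),
#'     `tracks` (CSV, see [read_track_table()]), optional `metadata` (CSV),
#'   * `pooling`: named label -> pool map (file inputs only),
#'   * `structure_panel` / `assignment_panel`: locus panels (defaults:
#'     first 8 loci for population-structure stages, all loci for
#'     assignment stages),
#'   * `permutation_reps` (199), `exclusion_sims` (1000),
#'     `subsample_reps` (10), `subsample_n` (smallest pool size),
#'   * `boschloo`: list(`sided`, `grid_size`, `orientation`),
#'   * `behaviour`: list(`west_lon`, `boundary_lat`, `boundary_lon`,
#'     `min_liberty`),
#'   * `assignment_method` (`"bayesian"`),
#'   * `seed` (1).
#' @param out_dir Optional output directory; when given, writes
#'   `table2_diversity.tsv`, `tableS2_pairwise_fst.tsv`, `fig1_mds.tsv`,
#'   `table1a_assignment.tsv`, `table1b_contingency.tsv`,
#'   `tableS4_subsample.tsv` (each with a full-precision JSON sidecar) and
#'   `report.json`.
#' @return A `homing_run` list with every stage result and `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$inputs)
  if (has_syn == has_inp) {
    abort("Exactly one of `synthetic` or `inputs` must be present in the config.")
  }
  seed <- as.integer(config$seed %||% 1)
  method <- config$assignment_method %||% "bayesian"
  beh <- utils::modifyList(list(west_lon = 10, boundary_lat = 57.75,
                                boundary_lon = 10, min_liberty = 30),
                           config$behaviour %||% list())
  bos <- utils::modifyList(list(sided = "one", grid_size = 1001,
                                orientation = "columns"),
                           config$boschloo %||% list())

  report <- list(package = "codhoming",
                 version = as.character(utils::packageVersion("codhoming")),
                 config = config, stages = list(), warnings = character(0))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    warns <- character(0)
    value <- withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    report$stages[[name]] <<- list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
                                   warnings = warns)
    if (length(warns) > 0) report$warnings <<- c(report$warnings, paste0(name, ": ", warns))
    inform(sprintf("[%s] done (%.2fs)", name, proc.time()[["elapsed"]] - t0))
    value
  }
  out <- list()

  data <- stage("load", {
    if (has_syn) {
      syn <- config$synthetic
      if (isTRUE(syn)) syn <- list()
      if (is.null(syn$seed)) syn$seed <- seed
      study <- sim_study(do.call(sim_config, syn))
      list(ref_geno = study$ref_geno, pools = study$pools, fish = study$fish,
           fish_geno = study$fish_geno, truth = study$truth)
    } else {
      inp <- config$inputs
      if (is.null(inp$references)) abort("`inputs$references` (Genepop path) is required.")
      ref_geno <- read_genepop(inp$references)
      pooling <- unlist(config$pooling)
      pools <- if (!is.null(pooling)) build_pools(ref_geno, pooling) else build_pools(ref_geno)
      fish_geno <- if (!is.null(inp$tagged)) read_genepop(inp$tagged) else NULL
      fish <- if (!is.null(inp$tracks)) read_track_table(inp$tracks) else NULL
      list(ref_geno = ref_geno, pools = pools, fish = fish,
           fish_geno = fish_geno, truth = NULL)
    }
  })
  ref_geno <- data$ref_geno
  all_loci <- locus_levels(ref_geno)
  structure_panel <- config$structure_panel %||% all_loci[seq_len(min(8, length(all_loci)))]
  assignment_panel <- config$assignment_panel %||% all_loci

  out$hwe <- stage("hwe_screen", {
    hw <- hwe_allele_tests(ref_geno, panel = assignment_panel)
    flagged <- sum(hw$p < 0.001, na.rm = TRUE)
    if (flagged > 0) {
      warn(sprintf("%d per-allele HWE test(s) with p < 0.001 (advisory; no multiple-testing correction applied).",
                   flagged))
    }
    hw
  })

  out$diversity <- stage("diversity", {
    d_struct <- diversity_stats(ref_geno, panel = structure_panel)
    d_full <- diversity_stats(ref_geno, panel = assignment_panel)
    sfx <- function(d, k) dplyr::rename_with(d, function(x) paste0(x, "_", k),
                                             c("He", "Ho", "Na"))
    dplyr::left_join(sfx(d_struct, length(structure_panel)),
                     sfx(d_full, length(assignment_panel))[, -c(2, 3)],
                     by = "sample")
  })

  out$global_fst <- stage("global_theta", {
    fst_permutation_test(ref_geno, panel = structure_panel,
                         reps = config$permutation_reps %||% 199,
                         seed = derive_seed(seed, "global-theta"))
  })
  out$pairwise <- stage("pairwise_theta", pairwise_fst(ref_geno, panel = structure_panel))
  out$mds <- stage("mds", fst_mds(out$pairwise, k = 2))

  pools <- data$pools
  out$pools <- pools
  out$self_assignment <- stage("self_assignment", self_assignment(pools, method = method))

  have_fish <- !is.null(data$fish_geno)
  if (have_fish) {
    fish_geno <- subset_loci(data$fish_geno, intersect(assignment_panel,
                                                       locus_levels(data$fish_geno)))
    out$exclusion <- stage("exclusion", {
      exclusion_test(fish_geno, pools, n_sim = config$exclusion_sims %||% 1000,
                     seed = derive_seed(seed, "exclusion"), method = method)
    })
    out$assignment <- stage("assignment", assign_individuals(fish_geno, pools, method = method))
  } else {
    warn("No tagged-fish genotypes: assignment stages skipped.")
  }

  have_tracks <- !is.null(data$fish) && nrow(data$fish) > 0
  if (have_tracks) {
    out$behaviour <- stage("behaviour", {
      classify_behaviour(data$fish, west_lon = beh$west_lon,
                         boundary_lat = beh$boundary_lat,
                         boundary_lon = beh$boundary_lon,
                         min_liberty = beh$min_liberty)
    })
  } else {
    warn("No tracks: behaviour classification skipped.")
  }

  if (have_fish && have_tracks) {
    records <- dplyr::left_join(out$behaviour,
                                dplyr::rename(out$assignment, fish_id = "individual_id"),
                                by = "fish_id")
    out$records <- records
    out$group_summary <- stage("group_summary", {
      summarise_assignment(records[records$category != "Excluded", ],
                           group = "category", pools = pools$pools)
    })
    out$contingency <- stage("contingency", {
      tryCatch(build_contingency(records, pools = pools$pools), error = function(e) {
        warn(paste("Contingency table unavailable:", conditionMessage(e)))
        NULL
      })
    })
    if (!is.null(out$contingency)) {
      out$fisher <- stage("fisher", fisher_exact(out$contingency, sided = bos$sided))
      out$boschloo <- stage("boschloo", {
        tryCatch(
          boschloo_test(out$contingency, sided = bos$sided,
                        grid_size = bos$grid_size, orientation = bos$orientation),
          error = function(e) {
            warn(paste("Boschloo test degenerate:", conditionMessage(e)))
            NULL
          }
        )
      })
    }
    out$subsample <- stage("subsample_robustness", {
      groups <- setNames(records$category, records$fish_id)
      subsample_assignment(fish_geno, pools, groups = groups,
                           n_target = config$subsample_n %||% min(pools$n),
                           reps = config$subsample_reps %||% 10,
                           seed = derive_seed(seed, "subsample"), method = method)
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table4(out$diversity, file.path(out_dir, "table2_diversity.tsv"))
    write_table4(as_tibble(out$pairwise), file.path(out_dir, "tableS2_pairwise_fst.tsv"))
    write_table4(as_tibble(out$mds), file.path(out_dir, "fig1_mds.tsv"))
    t1a <- dplyr::bind_rows(
      dplyr::mutate(out$self_assignment$summary, block = "reference"),
      if (!is.null(out$group_summary)) dplyr::mutate(out$group_summary, block = "behaviour")
    )
    write_table4(t1a, file.path(out_dir, "table1a_assignment.tsv"))
    if (!is.null(out$contingency)) {
      ct <- as_tibble(as.data.frame.matrix(out$contingency), rownames = "assigned")
      ct$fisher_p <- if (is.null(out$fisher)) NA_real_ else tidy(out$fisher)$p
      ct$boschloo_p <- if (is.null(out$boschloo)) NA_real_ else tidy(out$boschloo)$p
      write_table4(ct, file.path(out_dir, "table1b_contingency.tsv"))
    }
    if (!is.null(out$subsample)) {
      write_table4(out$subsample, file.path(out_dir, "tableS4_subsample.tsv"))
    }
  }

  report$summary <- list(
    n_reference = sum(pools$n), pools = as.list(pools$n),
    global_theta = out$global_fst$theta, global_theta_p = out$global_fst$p,
    n_tagged = if (have_fish) length(unique(data$fish_geno$individual_id)) else 0,
    boschloo_p = if (!is.null(out$boschloo)) out$boschloo$p else NULL,
    fisher_p = if (!is.null(out$fisher)) out$fisher$p else NULL
  )
  out$report <- report
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
  }
  structure(out, class = "homing_run")
}

#' @export
print.homing_run <- function(x, ...) {
  cat("codhoming pipeline run\n")
  cat(sprintf("  reference: %s\n",
              paste(sprintf("%s (n=%d)", x$pools$pools, x$pools$n), collapse = ", ")))
  cat(sprintf("  global theta = %.4f (P = %.4g)\n", x$global_fst$theta, x$global_fst$p))
  if (!is.null(x$boschloo)) {
    cat(sprintf("  philopatry: Boschloo P = %.4g (Fisher statistic %.4g)\n",
                x$boschloo$p, x$boschloo$fisher_p))
  }
  invisible(x)
}
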