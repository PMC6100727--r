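# End-to-end orchestration: fixtures -> scan -> FPR cutoff -> blocks ->
# Ne / s inference -> quantitative-trait grid -> clinal test, with one
# master seed and a reproducible JSON manifest.

#' Default pipeline configuration
#'
#' Returns the demo configuration: a scaled-down but complete run of every
#' stage. All entries can be overridden through the `config` argument of
#' [run_pipeline()] or a YAML file with the same structure.
#'
#' @return Nested list of stage parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "thermoevolve_run",
    stages = c("fixtures", "scan", "blocks", "inference", "qt", "clinal"),
    fixtures = list(n_snps = 2000L, ne = 219, generations = 59L,
                    n_replicates = 5L, coverage = 80,
                    block_snps = 28L, block_p0 = 0.44, block_s = 0.07),
    scan = list(n_neutral_runs = 3L, top_k = 100L),
    blocks = list(min_correlation = 0.95, min_coverage = 20, min_rise = 0.2),
    inference = list(pool_size = 500, s_grid_min = -0.05, s_grid_max = 0.15,
                     s_grid_step = 0.002),
    qt = list(background_counts = c(10L, 100L, 1000L),
              optima = c(0.3, 0.5, 0.7), n_sims = 10L,
              cutoff_n_snps = 50000L),
    clinal = list(n_pops = 4L, n_individuals = 20L, n_snps = 197L,
                  n_candidates = 21L, gradient = 0.3, depth = 1.8,
                  n_draws = 10000L)
  )
}

# internal: derive a stage seed from the master seed (kept below 2^31)
derive_seed <- function(master, stage_index) {
  as.integer((as.numeric(master) * 131L + stage_index * 100003) %% .Machine$integer.max)
}

# internal: recursively check config keys against the defaults
check_config_keys <- function(config, reference, path = "") {
  extra <- setdiff(names(config), names(reference))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  for (k in names(config)) {
    if (is.list(reference[[k]]) && !is.null(names(reference[[k]])))
      check_config_keys(as.list(config[[k]]), reference[[k]],
                        paste0(path, k, "."))
  }
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order: generate fixtures
#' (synthetic scan with a planted haplotype block, and a clinal panel), run
#' the CMH scan with simulation-based FPR calibration, call haplotype
#' blocks, infer Ne and the block's selection coefficient, run the
#' quantitative-trait grid, and run the clinal jackknife test. Every stage
#' receives a seed derived deterministically from the master seed, so any
#' stage can be re-run in isolation and identical configurations give
#' identical outputs.
#'
#' @param config A nested list (see [default_config()]), or the path of a
#'   YAML file holding one; missing entries fall back to the defaults,
#'   unknown keys are rejected before any stage runs.
#' @return The run manifest (also written to `manifest.json` in the output
#'   directory): configuration, per-stage seeds and timings, output files
#'   with MD5 hashes, and headline numbers per stage.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ref <- default_config()
  check_config_keys(config, ref)
  cfg <- utils::modifyList(ref, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "thermoevolve",
                   version = as.character(utils::packageVersion("thermoevolve")),
                   seed = cfg$seed, config = cfg[setdiff(names(cfg), "stages")],
                   stages = list())
  files <- character(0)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    seed <- derive_seed(cfg$seed, match(name, ref$stages))
    t0 <- Sys.time()
    out <- tryCatch(fun(seed), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    manifest$stages[[name]] <<- c(list(seed = seed,
      elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2)), out)
  }

  run_stage("fixtures", function(seed) {
    fx <- cfg$fixtures
    scen <- scan_scenario(n_snps = fx$n_snps, ne = fx$ne,
                          generations = fx$generations,
                          n_replicates = fx$n_replicates,
                          coverage = fx$coverage,
                          blocks = list(planted_block(fx$block_snps,
                                                      fx$block_p0, fx$block_s)))
    scan <- generate_scan(scen, seed = seed)
    state$scan <- scan
    state$scenario <- scen
    f1 <- file.path(cfg$out_dir, "ancestral.sync")
    f2 <- file.path(cfg$out_dir, "evolved.sync")
    f3 <- file.path(cfg$out_dir, "truth.tsv")
    write_sync(scan$ancestral, f1)
    write_sync(scan$evolved, f2)
    fwrite(scan$truth, f3, sep = "\t")
    files <<- c(files, f1, f2, f3)
    list(n_snps = fx$n_snps, n_planted = sum(scan$truth$selected))
  })

  run_stage("scan", function(seed) {
    fx <- cfg$fixtures
    res <- cmh_scan(state$scan$ancestral, state$scan$evolved)
    anc_freq <- res$anc_freq
    calib <- calibrate_fpr(res$p_value, p0 = anc_freq, ne = fx$ne,
                           generations = fx$generations,
                           coverage = fx$coverage,
                           n_replicates = fx$n_replicates,
                           n_runs = cfg$scan$n_neutral_runs, seed = seed)
    k <- min(cfg$scan$top_k, nrow(res))
    cutoff <- top_k_cutoff(res$p_value, k)
    fpr_at <- calibrate_fpr(res$p_value, anc_freq, fx$ne, fx$generations,
                            fx$coverage, fx$n_replicates,
                            cfg$scan$n_neutral_runs,
                            thresholds = cutoff, seed = seed)$fpr
    state$scan_result <- res
    state$cutoff <- cutoff
    f1 <- file.path(cfg$out_dir, "cmh_scan.tsv")
    f2 <- file.path(cfg$out_dir, "fpr_calibration.tsv")
    fwrite(res, f1, sep = "\t")
    fwrite(calib, f2, sep = "\t")
    files <<- c(files, f1, f2)
    list(n_tested = nrow(res), top_k = k, cutoff = cutoff,
         fpr_at_cutoff = fpr_at)
  })

  run_stage("blocks", function(seed) {
    bp <- block_params(cfg$blocks$min_correlation, cfg$blocks$min_coverage,
                       cfg$blocks$min_rise)
    er <- er_dataset(state$scan$ancestral, state$scan$evolved)
    blocks <- cluster_trajectories(filter_candidates(er, bp), bp)
    state$blocks <- blocks
    f1 <- file.path(cfg$out_dir, "blocks.tsv")
    f2 <- file.path(cfg$out_dir, "blocks.bed")
    fwrite(blocks_as_table(blocks), f1, sep = "\t")
    fwrite(blocks_to_bed(blocks), f2, sep = "\t", col.names = FALSE)
    files <<- c(files, f1, f2)
    list(n_blocks = length(blocks),
         largest_block = if (length(blocks)) max(vapply(blocks, function(b)
           length(b$pos), 0L)) else 0L)
  })

  run_stage("inference", function(seed) {
    fx <- cfg$fixtures
    inf <- cfg$inference
    er <- er_dataset(state$scan$ancestral, state$scan$evolved)
    neutral <- !state$scan$truth$selected
    # drift is per replicate, so Ne is estimated replicate by replicate and
    # averaged
    ne_reps <- vapply(seq_len(fx$n_replicates), function(r)
      estimate_ne(er$anc_freq[neutral, r], er$evo_freq[neutral, r],
                  coverage_start = fx$coverage, coverage_end = fx$coverage,
                  pool_size = inf$pool_size,
                  generations = fx$generations)$ne, 0)
    ne_est <- list(ne = mean(ne_reps))
    s_hat <- NA_real_
    if (length(state$blocks)) {
      b <- state$blocks[[which.max(vapply(state$blocks, function(b)
        length(b$pos), 0L))]]
      idx <- match(b$pos, state$scan$truth$pos)
      anc <- colMeans(er$anc_freq[idx, , drop = FALSE])
      evo <- colMeans(er$evo_freq[idx, , drop = FALSE])
      if (mean(evo - anc) < 0) {   # polarise to the rising variant
        anc <- 1 - anc; evo <- 1 - evo
      }
      traj <- trajectory(cbind(anc, evo),
                         generations = c(0, fx$generations))
      s_hat <- estimate_s(traj, ne = round(ne_est$ne),
                          s_grid = seq(inf$s_grid_min, inf$s_grid_max,
                                       by = inf$s_grid_step))$s_hat
    }
    list(ne = ne_est$ne, s_hat = s_hat)
  })

  run_stage("qt", function(seed) {
    qt <- cfg$qt
    cutoff <- calibrate_detection_cutoff(n_snps = qt$cutoff_n_snps,
                                         seed = seed)
    grid <- run_qt_grid(qt$background_counts, qt$optima, n_sims = qt$n_sims,
                        cmh_cutoff = cutoff, seed = derive_seed(seed, 1L))
    f1 <- file.path(cfg$out_dir, "qt_grid.tsv")
    fwrite(grid, f1, sep = "\t")
    files <<- c(files, f1)
    list(cmh_cutoff = cutoff,
         min_explained_consistent = grid_min_explained(grid))
  })

  run_stage("clinal", function(seed) {
    cl <- cfg$clinal
    cline <- generate_cline(cl$n_pops, cl$n_individuals, cl$n_snps,
                            cl$gradient, cl$depth, seed = seed)
    freq <- clinal_frequency(cline$panel)
    diffs <- freq[, 1] - freq[, ncol(freq)]     # south minus north
    cand <- sample(names(diffs), min(cl$n_candidates, length(diffs)))
    jk <- jackknife_clinal_test(diffs, cand, n_draws = cl$n_draws,
                                seed = derive_seed(seed, 2L))
    f1 <- file.path(cfg$out_dir, "clinal_jackknife.json")
    jsonlite::write_json(list(observed = jk$observed, p_value = jk$p_value,
                              n_draws = jk$n_draws), f1, auto_unbox = TRUE)
    files <<- c(files, f1)
    list(n_snps_retained = nrow(freq), jackknife_p = jk$p_value)
  })

  manifest$files <- lapply(files, function(f)
    list(path = f, md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
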