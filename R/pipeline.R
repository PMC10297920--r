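#' Default pipeline configuration
#'
#' One declarative list with a section per analysis stage. The defaults are
#' the published analysis parameters: fiber areas 1400-80,000 px and
#' circularity 0.2-1.0, DE significance at adjusted p <= 0.05, module merge
#' threshold 0.25, hub thresholds kME > 0.6 and GS > 0.8, six trend
#' clusters, and 95% confidence intervals for the bias calls.
#'
#' @param seed Global seed recorded in the config.
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    morphometry = unclass(morphometry_config()),
    de = list(alpha = 0.05, lfc_min = 0, min_total_count = 10,
              dispersion_shrink = 0.8),
    coexpression = unclass(coexpression_config()),
    hub = list(kme_min = 0.6, gs_min = 0.8, ns_weight_min = NULL),
    trend = list(n_clusters = 6, fuzzifier = 2),
    bias = list(level = 0.95, mode = "two_ci")
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every invariant of every embedded section and returns the
#' violations found, each naming the offending field(s). Accepts a config
#' list or a path to a YAML file with the same structure.
#'
#' @param config A `pipeline_config` list or a YAML file path.
#' @return Character vector of violations; `character(0)` (invisibly, with a
#'   message) when the config is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    abort_if(!file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  v <- character()
  if (!is_scalar_number(config$seed %||% NA))
    v <- c(v, "seed must be a single number")
  if (!is.null(config$morphometry))
    v <- c(v, validate_morphometry_config(config$morphometry))
  if (!is.null(config$coexpression))
    v <- c(v, validate_coexpression_config(config$coexpression))
  de <- config$de
  if (!is.null(de)) {
    if (!is_scalar_number(de$alpha %||% NA) || de$alpha <= 0 || de$alpha > 1)
      v <- c(v, "de$alpha must lie in (0, 1]")
    if (!is_scalar_number(de$lfc_min %||% NA) || de$lfc_min < 0)
      v <- c(v, "de$lfc_min must be >= 0")
  }
  hub <- config$hub
  if (!is.null(hub)) {
    if (!is_scalar_number(hub$kme_min %||% NA) || hub$kme_min < 0 || hub$kme_min > 1 ||
        !is_scalar_number(hub$gs_min %||% NA) || hub$gs_min < 0 || hub$gs_min > 1)
      v <- c(v, "hub$kme_min and hub$gs_min must lie in [0, 1]")
  }
  tr <- config$trend
  if (!is.null(tr)) {
    if (!is_scalar_number(tr$n_clusters %||% NA) || tr$n_clusters < 2)
      v <- c(v, "trend$n_clusters must be >= 2")
    if (!is_scalar_number(tr$fuzzifier %||% NA) || tr$fuzzifier <= 1)
      v <- c(v, "trend$fuzzifier must be > 1")
  }
  bias <- config$bias
  if (!is.null(bias)) {
    if (!is_scalar_number(bias$level %||% NA) || bias$level <= 0 || bias$level >= 1)
      v <- c(v, "bias$level must lie in (0, 1)")
    if (!is.null(bias$mode) && !bias$mode %in% c("two_ci", "pooled_ci"))
      v <- c(v, "bias$mode must be 'two_ci' or 'pooled_ci'")
  }
  if (length(v) == 0) {
    message("config ok")
    return(invisible(character(0)))
  }
  v
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A `pipeline_config` list.
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   parsed list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass_recursive(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

unclass_recursive <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  x
}

demo_seed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 2147483647L

#' Run the full synthetic demonstration pipeline
#'
#' Generates synthetic data for both tracks, runs every analysis stage, and
#' scores each output against the generator's ground truth. The report is a
#' machine-readable list of named checks, each with the measured value and a
#' pass flag; the whole run is a deterministic function of `seed`.
#'
#' Stages and checks (sizes chosen to run in well under two minutes):
#' segmentation recall and median per-fiber area error on noiseless mosaics;
#' binary-mask disagreement on a noisy mosaic; ATPase slow-twitch proportion
#' recovery; size-factor recovery of planted depths; DE type-I rate on a
#' null simulation and power on planted fold changes; the closed-form
#' hypergeometric enrichment p; module recovery (adjusted Rand index);
#' FCM membership sanity and two-trend separation; discordant-trend
#' sensitivity; bias-call recall and false-bias rate on planted scenarios.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Optional directory; when given, the report is written as
#'   `report.json` plus per-stage TSV tables.
#' @param config A [default_config()]-style configuration.
#' @return A list of class `demo_report` with elements `checks` (tibble:
#'   `check`, `value`, `target`, `pass`), `seed`, and the stage outputs.
#' @export
run_demo <- function(seed = 1, out_dir = NULL, config = default_config(seed)) {
  checks <- list()
  add_check <- function(name, value, target, pass) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = name, value = as.numeric(value), target = target, pass = pass)
  }

  ## -- morphometry track ---------------------------------------------------
  mcfg <- do.call(morphometry_config, config$morphometry)
  recalls <- med_errs <- numeric(3)
  for (i in 1:3) {
    mos <- simulate_fiber_mosaic(n_fibers = 100, mean_area_px = 5000,
                                 noise_sd = 0, seed = demo_seed(seed, i))
    regions <- segment_fibers(preprocess_image(mos$image, mcfg), mcfg)
    acc <- regions[regions$status == "accepted", ]
    recalls[i] <- nrow(acc) / nrow(mos$fibers)
    matched <- match_regions(acc, mos$fibers)
    med_errs[i] <- median(abs(matched$area_px - matched$true_area) /
                            matched$true_area)
  }
  add_check("segmentation_recall", mean(recalls), "== 1", all(recalls == 1))
  add_check("median_area_rel_error", mean(med_errs), "< 0.05",
            all(med_errs < 0.05))

  noisy <- simulate_fiber_mosaic(n_fibers = 60, mean_area_px = 5000,
                                 noise_sd = 10, seed = demo_seed(seed, 4))
  bin <- preprocess_image(noisy$image, mcfg)
  disagree <- mean((bin$pixels > 0) != (noisy$label_map > 0))
  add_check("noisy_mask_disagreement", disagree, "< 0.02", disagree < 0.02)

  atp <- simulate_atpase_image(0.4, n_fibers = 50, seed = demo_seed(seed, 5))
  ft <- fiber_typing(atp$image, mcfg)
  add_check("slow_twitch_proportion_error", abs(ft$proportion_slow - 0.4),
            "== 0", ft$proportion_slow == 0.4)

  ## -- expression core -----------------------------------------------------
  sheet_sf <- sheep_sample_sheet(1, 1, 1, stages = c("D3", "M3", "M6"))
  depths <- rep(c(1, 1.5, 3), 3)[seq_len(nrow(sheet_sf))]
  sim_sf <- simulate_counts(n_genes = 1200, sheet = sheet_sf,
                            depth_factors = depths, nb_dispersion = 0.02,
                            seed = demo_seed(seed, 6))
  sf <- size_factors(sim_sf$counts)
  sf_err <- max(abs(sf * geo_mean(depths) / depths - 1))
  add_check("size_factor_max_rel_error", sf_err, "< 0.05", sf_err < 0.05)

  sheet_de <- sheep_sample_sheet(5, 2, 5, stages = "M3")
  sim_null <- simulate_counts(n_genes = 1500, sheet = sheet_de,
                              nb_dispersion = 0.05, seed = demo_seed(seed, 7))
  de_null <- de_test(sim_null$counts, sim_null$sheet, c("H", "D"))
  t1 <- mean(de_null$p_value[de_null$tested] < 0.05, na.rm = TRUE)
  add_check("de_null_rejection_rate", t1, "in [0.03, 0.07]",
            t1 >= 0.03 && t1 <= 0.07)

  sheet_pw <- sheep_sample_sheet(6, 2, 6, stages = "M3")
  planted <- tibble::tibble(gene = 1:100, group = "D", log2fc = 2)
  sim_pw <- simulate_counts(n_genes = 600, sheet = sheet_pw,
                            baseline = rep(200, 600), nb_dispersion = 0.05,
                            planted_de = planted, seed = demo_seed(seed, 8))
  de_pw <- de_test(sim_pw$counts, sim_pw$sheet, c("H", "D"))
  power <- mean(sim_pw$truth$de$gene_id %in% significant_genes(de_pw))
  add_check("de_power_lfc2", power, "> 0.9", power > 0.9)

  u <- paste0("g", 1:10)
  enr <- enrich_hypergeometric(u[1:4], list(s1 = u[1:5]), u)
  add_check("enrichment_closed_form_error", abs(enr$p_value[1] - 5 / 210),
            "< 1e-12", abs(enr$p_value[1] - 5 / 210) < 1e-12)

  ## -- co-expression -------------------------------------------------------
  simm <- simulate_module_expression(n_modules = 3, module_size = 50,
                                     n_background = 30, n_samples = 12,
                                     noise_sd = 0.3, seed = demo_seed(seed, 9))
  trait <- simm$profiles[1, ] + withr::with_seed(demo_seed(seed, 10),
                                                 rnorm(12, sd = 0.2))
  fit <- build_modules(simm$expr, do.call(coexpression_config,
                                          config$coexpression), trait = trait)
  planted_lab <- simm$truth$module[simm$truth$module != "none"]
  found_lab <- fit$genes$module[match(simm$truth$gene_id[simm$truth$module != "none"],
                                      fit$genes$gene_id)]
  ari <- adjusted_rand_index(planted_lab, found_lab)
  add_check("module_recovery_ari", ari, "> 0.8", ari > 0.8)

  ## -- trends and bias -----------------------------------------------------
  two <- rbind(matrix(rep(c(-1, -0.3, 0.3, 1), each = 40), 40),
               matrix(rep(c(1, 0.3, -0.3, -1), each = 40), 40))
  two <- two + withr::with_seed(demo_seed(seed, 11),
                                matrix(rnorm(320, sd = 0.05), 80, 4))
  fcm <- fcm_cluster(two, c = 2, m = 2, seed = demo_seed(seed, 12))
  row_sum_err <- max(abs(rowSums(fcm$membership) - 1))
  hard_ok <- length(unique(fcm$cluster[1:40])) == 1 &&
    length(unique(fcm$cluster[41:80])) == 1 &&
    fcm$cluster[1] != fcm$cluster[41]
  add_check("fcm_membership_rowsum_error", row_sum_err, "< 1e-9",
            row_sum_err < 1e-9)
  add_check("fcm_two_trend_separation", as.numeric(hard_ok), "== 1", hard_ok)

  # sparse planting: biased genes are a small minority of the transcriptome,
  # so normalization is not distorted by the planted breed effects
  scen <- c(rep("toward_D", 60), rep("toward_H", 60), rep("unbiased", 120))
  sim_b <- simulate_counts(
    n_genes = 1600, sheet = sheep_sample_sheet(6, 5, 3),
    nb_dispersion = 0.05,
    planted_bias = tibble::tibble(gene = seq_along(scen), scenario = scen),
    bias_lfc = 2, seed = demo_seed(seed, 13))
  corrected <- normalize_to_normal(sim_b$counts)
  calls <- call_bias_table(corrected, sim_b$sheet,
                           genes = sim_b$truth$bias$gene_id,
                           level = config$bias$level, mode = config$bias$mode)
  joined <- dplyr::left_join(calls$overall, sim_b$truth$bias,
                             by = "gene_id")
  recall_D <- mean(joined$call[joined$scenario == "toward_D"] == "toward_D")
  recall_H <- mean(joined$call[joined$scenario == "toward_H"] == "toward_H")
  false_bias <- mean(joined$call[joined$scenario == "unbiased"] %in%
                       c("toward_D", "toward_H"))
  add_check("bias_toward_D_recall", recall_D, ">= 0.8", recall_D >= 0.8)
  add_check("bias_toward_H_recall", recall_H, ">= 0.8", recall_H >= 0.8)
  add_check("bias_false_rate_unbiased", false_bias,
            sprintf("<= %g", 2 * (1 - config$bias$level)),
            false_bias <= 2 * (1 - config$bias$level))

  checks <- dplyr::bind_rows(checks)
  report <- structure(list(seed = seed, checks = checks,
                           all_pass = all(checks$pass)),
                      class = "demo_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(seed = seed, all_pass = report$all_pass, checks = checks),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(checks, file.path(out_dir, "checks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  report
}

# greedy centroid matching of accepted regions to ground-truth fibers
match_regions <- function(accepted, truth) {
  idx <- vapply(seq_len(nrow(accepted)), function(i) {
    which.min((truth$centroid_row - accepted$centroid_row[i])^2 +
                (truth$centroid_col - accepted$centroid_col[i])^2)
  }, integer(1))
  dplyr::mutate(accepted, true_area = truth$area_px[idx],
                true_id = truth$fiber_id[idx])
}

#' @export
print.demo_report <- function(x, ...) {
  cat(sprintf("<demo_report> seed %d: %d/%d checks pass\n",
              x$seed, sum(x$checks$pass), nrow(x$checks)))
  print(as.data.frame(x$checks), digits = 4)
  invisible(x)
}
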