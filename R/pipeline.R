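#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: exactly one input source
#' (a phantom specification or a slice-stack directory), preprocessing
#' parameters, Monte Carlo settings, key-section overrides, and the
#' analysed slice range.
#'
#' @param input_dir directory containing a slice stack (see
#'   [read_stack()]), or `NULL`.
#' @param phantom a [phantom_spec()] (or named list of arguments for one),
#'   or `NULL`.
#' @param params a [preprocess_params()].
#' @param mc_n random points per slice.
#' @param seed master seed.
#' @param slice_range optional `c(start, end)` restriction.
#' @param trochanter_window,trochanter_override key-section controls, see
#'   [find_trochanter_section()].
#' @param lh optional externally measured femur length (mm).
#' @param use_traversal report traversal areas instead of Monte Carlo
#'   estimates in the morphometry.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, phantom = NULL,
                            params = preprocess_params(),
                            mc_n = 230400L, seed = 1L,
                            slice_range = NULL,
                            trochanter_window = NULL,
                            trochanter_override = NULL,
                            lh = NULL, use_traversal = FALSE) {
  if (is.null(input_dir) == is.null(phantom)) {
    stop("exactly one input source (input_dir or phantom) is required")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  if (!is.null(phantom) && !inherits(phantom, "phantom_spec")) {
    phantom <- do.call(phantom_spec, as.list(phantom))
  }
  structure(list(input_dir = input_dir, phantom = phantom,
                 params = params, mc_n = as.integer(mc_n),
                 seed = as.integer(seed), slice_range = slice_range,
                 trochanter_window = trochanter_window,
                 trochanter_override = trochanter_override,
                 lh = lh, use_traversal = use_traversal),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Recognised keys mirror the [pipeline_config()] arguments; `params` and
#' `phantom` are nested objects of [preprocess_params()] /
#' [phantom_spec()] arguments.
#'
#' @param path JSON file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- if (is.null(cfg$params)) preprocess_params() else {
    do.call(preprocess_params, as.list(cfg$params))
  }
  pipeline_config(
    input_dir = cfg$input_dir,
    phantom = cfg$phantom,
    params = params,
    mc_n = if (is.null(cfg$mc_n)) 230400L else cfg$mc_n,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed,
    slice_range = cfg$slice_range,
    trochanter_window = cfg$trochanter_window,
    trochanter_override = cfg$trochanter_override,
    lh = cfg$lh,
    use_traversal = isTRUE(cfg$use_traversal)
  )
}

#' Run the full analysis pipeline
#'
#' Executes extraction, Monte Carlo and traversal area estimation,
#' morphometry, and method-agreement validation, writing the complete
#' artifact set under `out_dir`: per-slice mask images and flags
#' (`masks/`), the per-slice area table (`areas.csv`), the morphometry
#' report (`morphometry.json` + `per_slice.csv`), the agreement report
#' (`validation.json`), and a run log with every parameter and seed.
#' Outputs are deterministic given the configuration.
#'
#' @param config a [pipeline_config()] or path to a JSON config file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`stack`, `masks`,
#'   `mc`, `morphometry`, `agreement`, and `truth` for phantom input) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(sprintf("canalmorph pipeline run"),
                 sprintf("seed: %d", config$seed),
                 sprintf("mc_n: %d", config$mc_n),
                 sprintf("sigma: %g  window: %d  t0: %g",
                         config$params$sigma, config$params$window,
                         config$params$t0))

  truth <- NULL
  if (!is.null(config$phantom)) {
    gen <- generate_phantom(config$phantom)
    stack <- gen$stack
    truth <- gen$truth
    log_lines <- c(log_lines,
                   sprintf("input: phantom (%d slices, noise_sd %g, seed %d)",
                           config$phantom$n_slices, config$phantom$noise_sd,
                           config$phantom$seed))
  } else {
    stack <- read_stack(config$input_dir)
    log_lines <- c(log_lines,
                   sprintf("input: %s (%d slices)", config$input_dir,
                           length(stack$images)))
  }
  if (length(stack$images) == 0L) stop("no slices in input")

  masks <- extract_masks_stack(stack, config$params,
                               slice_range = config$slice_range)
  n_acc <- sum(masks$accepted)
  log_lines <- c(log_lines,
                 sprintf("slices analysed: %d, accepted: %d",
                         length(masks$masks), n_acc))
  if (n_acc == 0L) stop("no accepted slices: nothing to analyse")
  write_masks(masks, file.path(out_dir, "masks"))

  mc <- mc_area_stack(masks, n = config$mc_n, seed = config$seed)
  tab <- mc_area_table(mc)
  utils::write.csv(tab, file.path(out_dir, "areas.csv"), row.names = FALSE)

  morph <- compute_morphometry(
    masks, mc, use_traversal = config$use_traversal,
    trochanter_window = config$trochanter_window,
    trochanter_override = config$trochanter_override,
    lh = config$lh)
  utils::write.csv(morph$per_slice, file.path(out_dir, "per_slice.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(schema_version = "1.0",
         key_sections = unclass(morph$key),
         diameters_mm = morph$diameters,
         lengths_mm = morph$lengths,
         ratios = morph$ratios[c("cfi", "mcfi", "dcfi", "ci", "ih_lh",
                                 "r1", "r2")],
         ratios_rounded = morph$ratios$rounded,
         canal_class = morph$canal_class),
    file.path(out_dir, "morphometry.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  agr <- agreement_report(
    alpha_mm = tab$alpha_m, alpha_mt = tab$alpha_mt,
    alpha_cm = tab$alpha_c, alpha_ct = tab$alpha_ct)
  jsonlite::write_json(
    list(schema_version = "1.0",
         summaries = lapply(agr$summaries, unclass),
         anova_medullary = agr$anova_medullary[c("f", "p")],
         anova_cortical = agr$anova_cortical[c("f", "p")],
         max_abs_diff_medullary = agr$max_abs_diff_medullary,
         max_abs_diff_cortical = agr$max_abs_diff_cortical,
         level = agr$level,
         verdict = agr$verdict),
    file.path(out_dir, "validation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_lines <- c(log_lines,
                 sprintf("key sections: c_m0+20=%d c_m0=%d c_m0-20=%d c_m1=%d",
                         morph$key$c_m0_plus20, morph$key$c_m0,
                         morph$key$c_m0_minus20, morph$key$c_m1),
                 sprintf("CFI=%.4f (%s)", morph$ratios$cfi,
                         morph$canal_class),
                 sprintf("agreement: %s", agr$verdict))
  writeLines(log_lines, log_path)

  invisible(list(stack = stack, truth = truth, masks = masks, mc = mc,
                 morphometry = morph, agreement = agr, out_dir = out_dir))
}
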