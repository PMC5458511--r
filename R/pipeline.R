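#' Run configuration for the landscape pipeline
#'
#' A validated nested list controlling the align -> pca -> landscape
#' pipeline. Configurations serialise to/from a single YAML file; unknown
#' keys are rejected so typos fail loudly. All randomness in a run flows
#' from the single `seed`.
#'
#' @param x a YAML file path, or a (possibly partial) nested list; missing
#'   entries take the documented defaults.
#' @return An object of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  defaults <- list(
    paths = list(manifest = NULL, reference = NULL, cp_mask = NULL,
                 rp_mask = NULL, outdir = "volscape_out"),
    align = list(ang_range = 6, ang_step = 2, shift_range = 8),
    pca = list(K = 2),
    landscape = list(components = c(1, 2), bins = c(32, 32),
                     smoothing_sigma = 1, cap_empty = FALSE),
    seed = 1L
  )
  bad <- setdiff(names(x), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (sec in intersect(names(x), c("paths", "align", "pca", "landscape"))) {
    bad <- setdiff(names(x[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      stop("unknown config key(s) in '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    defaults[[sec]][names(x[[sec]])] <- x[[sec]]
  }
  if (!is.null(x$seed)) defaults$seed <- as.integer(x$seed)
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Short, stable fingerprint of a configuration (used to stamp artifacts
# and keep runs from different configs apart in one outdir).
config_hash <- function(config) substr(rlang::hash(unclass(config)), 1, 8)

#' Run the full conformational-landscape pipeline
#'
#' Executes align_ensemble -> fit_pca -> build_landscape ->
#' find_minima_and_barrier from a [run_config()], writing every artifact
#' (transforms, coefficients, eigenvalues, eigenvolumes, landscape grid and
#' heat map, barrier report, machine-readable summary) into
#' `<outdir>/run-<confighash>/`. Re-running with the same configuration
#' and seed reproduces the TSV/JSON outputs byte for byte. A stage failure
#' is reported with the stage name; artifacts from completed stages are
#' retained.
#'
#' @param config a [run_config()] (or list/path coercible to one).
#' @return Invisibly, a list: `outdir`, `summary` (also written as
#'   `summary.json`), `pca`, `landscape`, `barrier`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  p <- config$paths
  for (f in c("manifest", "reference", "cp_mask", "rp_mask")) {
    if (is.null(p[[f]])) stop("config paths$", f, " is required", call. = FALSE)
    if (!file.exists(p[[f]])) stop("config paths$", f, " not found: ",
                                   p[[f]], call. = FALSE)
  }
  hash <- config_hash(config)
  outdir <- file.path(p$outdir, paste0("run-", hash))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[volscape] stage %-10s %6.1f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  inputs <- stage("load", {
    list(manifest = read_manifest(p$manifest),
         reference = read_map(p$reference),
         cp_mask = read_mask(p$cp_mask),
         rp_mask = read_mask(p$rp_mask))
  })
  aligned <- stage("align", {
    al <- align_ensemble(inputs$manifest, inputs$reference, inputs$cp_mask,
                         rp_mask = inputs$rp_mask,
                         ang_range = config$align$ang_range,
                         ang_step = config$align$ang_step,
                         shift_range = config$align$shift_range)
    readr::write_tsv(al$transforms, file.path(outdir, "transforms.tsv"))
    al
  })
  decomposition <- stage("pca", {
    d <- fit_pca(aligned, inputs$rp_mask, K = config$pca$K)
    write_pca(d, outdir)
    d
  })
  landscape <- stage("landscape", {
    l <- build_landscape(decomposition,
                         components = config$landscape$components,
                         bins = config$landscape$bins,
                         smoothing_sigma = config$landscape$smoothing_sigma,
                         cap_empty = config$landscape$cap_empty)
    write_landscape(l, outdir)
    l
  })
  barrier <- stage("barrier", {
    b <- find_minima_and_barrier(landscape)
    jsonlite::write_json(
      list(minima = b$minima, barrier_height = b$barrier_height,
           barrier_level = b$barrier_level, disconnected = b$disconnected),
      file.path(outdir, "barrier.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
    b
  })
  summary <- list(
    config_hash = hash, seed = config$seed,
    n_classes = length(aligned$volumes),
    total_particles = sum(aligned$counts),
    mean_alignment_score = mean(aligned$transforms$score),
    explained_variance = explained_variance(decomposition),
    n_minima = nrow(barrier$minima),
    barrier_height = barrier$barrier_height
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(outdir = outdir, summary = summary, pca = decomposition,
                 landscape = landscape, barrier = barrier,
                 aligned = aligned))
}

#' Generate a named synthetic fixture tree
#'
#' Writes a ready-to-analyse synthetic dataset. Ensemble presets (`flat`,
#' `harmonic`, `double_well`) write class maps, a manifest, a reference
#' map (mobile body at 0 degrees) and CP/RP masks. Mixture presets
#' (`two_state_mixture_dmso`, `two_state_mixture_oprozomib`,
#' `two_state_mixture_epoxomicin`) write a particle stack, a ground-truth
#' table and the two reference maps; their rotated-state fractions are the
#' three measured conditions (41%, 13% and 25% rotated) and the state
#' separation is 25 degrees.
#'
#' @param preset one of the six preset names.
#' @param outdir output directory (created).
#' @param seed integer seed.
#' @param n_classes,total_particles ensemble-preset sizes.
#' @param n_particles,snr mixture-preset sizes.
#' @return Invisibly, a list describing the files written (and the truth
#'   objects used).
#' @export
make_fixtures <- function(preset, outdir, seed = 1L,
                          n_classes = 346, total_particles = 1e5,
                          n_particles = 400, snr = 2) {
  presets <- c("flat", "harmonic", "double_well",
               "two_state_mixture_dmso", "two_state_mixture_oprozomib",
               "two_state_mixture_epoxomicin")
  if (!preset %in% presets)
    stop("unknown preset '", preset, "'; available: ",
         paste(presets, collapse = ", "), call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- phantom_spec(seed = seed)
  masks <- phantom_masks(spec)
  if (preset %in% c("flat", "harmonic", "double_well")) {
    efun <- switch(preset,
      flat = energy_function("flat", domain = c(-25, 25)),
      harmonic = energy_function("harmonic", domain = c(-25, 25),
                                 kappa = 0.02, center = 0),
      double_well = energy_function("double_well_barrier",
                                    domain = c(-25, 25),
                                    well_centers = c(-15, 15),
                                    barrier_height = 3))
    ens <- make_class_ensemble(spec, efun, n_classes, total_particles,
                               seed = seed)
    manifest <- write_ensemble(ens, outdir)
    write_map(render_phantom(spec, 0), file.path(outdir, "reference.mrc"))
    write_map(masks$cp, file.path(outdir, "cp_mask.mrc"))
    write_map(masks$rp, file.path(outdir, "rp_mask.mrc"))
    invisible(list(preset = preset, dir = outdir, manifest = manifest,
                   truth = ens$truth))
  } else {
    f_rot <- switch(preset,
      two_state_mixture_dmso = 0.41,
      two_state_mixture_oprozomib = 0.13,
      two_state_mixture_epoxomicin = 0.25)
    ps <- make_two_state_particles(spec, theta_states = c(25, 0),
                                   fractions = c(f_rot, 1 - f_rot),
                                   n_particles = n_particles, snr = snr,
                                   seed = seed)
    paths <- write_particles(ps, outdir)
    write_map(render_phantom(spec, 25), file.path(outdir, "ref_rotated.mrc"))
    write_map(render_phantom(spec, 0), file.path(outdir, "ref_nonrotated.mrc"))
    invisible(list(preset = preset, dir = outdir, paths = paths,
                   truth = ps$truth))
  }
}
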