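# End-to-end orchestration: one config (list or YAML file) drives model
# building, ensemble generation, the projection, ion and pair analytics and
# the free-energy profile, writing every artifact plus a hashed manifest.

#' Default pipeline configuration (bundled toy-hairpin demo)
#'
#' Morph ensemble over the synthetic 12-nt hairpin with a scripted ion
#' bridge, all analysis stages on, and a small umbrella/WHAM block.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "results/demo",
    stages = c("model", "ensemble", "elvim", "ions", "pairs", "wham"),
    structure = list(synthetic = "hairpin", annotations = "synthetic"),
    model = list(cutoff = 7.0, min_sep = 3L),
    ensemble = list(kind = "morph", n_frames = 200L, unfold_fraction = 1.0,
                    noise = 0.3, n_ions = 8L, box_edge = 150,
                    bridge = list(pair = c(1L, 12L), fraction = 0.7)),
    elvim = list(sigma0 = 3, eps = 0.15, n_iter = 60L,
                 step_fraction = 0.125),
    ions = list(cutoff = 8, q_bin = 0.05, min_sep = 4L),
    pairs = list(lambda = 1.2, q_bin = 0.05),
    wham = list(q0 = seq(0.1, 0.9, by = 0.1), k_q = 20,
                n_steps = 8000L, equil_steps = 2000L, n_bins = 25L,
                temperature = NULL)
  )
}

.merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]) &&
        !is.null(names(user[[k]])))
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Load a pipeline configuration from YAML (merged over the defaults)
#' @param path YAML file.
#' @export
read_config <- function(path) {
  .merge_config(default_config(), yaml::read_yaml(path))
}

.validate_config <- function(config) {
  st <- config$structure
  has_pdb <- !is.null(st$pdb)
  has_syn <- !is.null(st$synthetic)
  if (has_pdb == has_syn)
    stop("config must specify exactly one of structure$pdb or ",
         "structure$synthetic")
  invisible(config)
}

.load_input_structure <- function(st) {
  if (!is.null(st$pdb)) {
    load_structure(readLines(st$pdb), st$chain %||% "A",
                   source_id = basename(st$pdb))
  } else {
    switch(st$synthetic,
           hairpin = synthetic_hairpin(),
           riboswitch = synthetic_riboswitch(),
           stop("unknown synthetic structure: ", st$synthetic))
  }
}

.load_input_annotations <- function(st, n_residues) {
  if (identical(st$annotations, "synthetic")) {
    if (identical(st$synthetic, "hairpin")) synthetic_hairpin_annotations()
    else synthetic_riboswitch_annotations()
  } else if (!is.null(st$annotations)) {
    read_annotations(st$annotations, n_residues = n_residues)
  } else NULL
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order (model -> ensemble ->
#' elvim / ions / pairs -> wham), writes every artifact under
#' \code{config$out_dir}, and finishes with \code{manifest.json} listing
#' each output file with its MD5 content hash, the seed and the config
#' hash. Identical config + seed reproduce identical hashes for all
#' deterministic outputs. On a stage failure the manifest (marking the
#' completed stages) is still written before the error propagates.
#'
#' @param config Configuration list (see \code{\link{default_config}}) or a
#'   YAML file path.
#' @param seed Optional override of \code{config$seed}.
#' @param out_dir Optional override of \code{config$out_dir}.
#' @return Invisibly, a list with the computed objects and the manifest.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- .merge_config(default_config(), config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  .validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed0 <- as.integer(config$seed)
  outputs <- character(0)
  completed <- character(0)
  state <- new.env(parent = emptyenv())
  log_line <- function(...) {
    message(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
  }
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL       # hashes must not depend on placement
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA)
  emit("config.json", function(p) writeLines(cfg_json, p))
  config_hash <- unname(tools::md5sum(file.path(config$out_dir,
                                                "config.json")))
  finish <- function(error = NULL) {
    manifest <- list(
      seed = seed0, config_hash = config_hash,
      completed_stages = completed,
      error = if (is.null(error)) NULL else conditionMessage(error),
      files = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    log_line("stage=", name, " seed=", seed0)
    tryCatch(fun(), error = function(e) {
      finish(error = e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    completed <<- c(completed, name)
  }

  run_stage("model", function() {
    s <- .load_input_structure(config$structure)
    state$cg <- coarse_grain(s)
    state$nc <- native_contacts(state$cg, cutoff = config$model$cutoff,
                                min_sep = config$model$min_sep)
    state$ann <- .load_input_annotations(config$structure,
                                         state$cg$n_residues)
    emit("cg_structure.pdb", function(p) write_cg_pdb(state$cg, p))
    emit("native_contacts.tsv", function(p) write_contacts_tsv(state$nc, p))
  })

  run_stage("ensemble", function() {
    en <- config$ensemble
    if (identical(en$kind, "morph")) {
      state$traj <- morph_ensemble(
        state$cg, n_frames = en$n_frames,
        unfold_fraction = en$unfold_fraction, noise = en$noise,
        seed = seed0, n_ions = en$n_ions, box_edge = en$box_edge,
        bridge = en$bridge)
    } else if (identical(en$kind, "langevin")) {
      cfg <- sim_config(n_steps = en$n_steps, temperature = en$temperature,
                        n_mg = en$n_ions, seed = seed0,
                        save_interval = en$save_interval %||% 500L)
      state$top <- build_topology(state$cg, state$nc, cfg)
      state$traj <- run_langevin(state$top, cfg)
    } else stop("unknown ensemble kind: ", en$kind)
    state$q <- q_trajectory(state$traj, state$nc)
    emit("q_series.tsv", function(p) write_q_series(state$q, p))
    emit("trajectory.bin", function(p) write_traj_bin(state$traj, p))
  })

  run_stage("elvim", function() {
    el <- config$elvim
    D <- dissimilarity_matrix(state$traj, state$cg$residue_index,
                              sigma0 = el$sigma0, eps = el$eps)
    emb <- force_scheme(D, n_iter = el$n_iter,
                        step_fraction = el$step_fraction, seed = seed0)
    dens <- kde_density(emb)
    basin <- region_density(dens, 0.75)
    lcs <- local_signature(basin, state$traj)
    state$embedding <- emb
    emit("dissimilarity.tsv", function(p) write_dissimilarity_tsv(D, p))
    emit("embedding.tsv", function(p)
      write_embedding_tsv(emb, p, density = dens, q = state$q))
    emit("lcs.json", function(p)
      jsonlite::write_json(list(centroid = lcs$centroid,
                                neighbors = lcs$neighbors,
                                mean_drmsd = lcs$mean_drmsd,
                                region_size = length(basin$idx)),
                           p, auto_unbox = TRUE, digits = NA))
  })

  run_stage("ions", function() {
    io <- config$ions
    counts <- occupancy(state$traj, cutoff = io$cutoff)
    hm <- occupancy_vs_q(counts, state$q, bin_width = io$q_bin)
    bm <- bridging_map(state$traj, cutoff = io$cutoff, min_sep = io$min_sep)
    if (!is.null(state$traj$ions) && dim(state$traj$ions)[2] > 0) {
      rdf <- rdf_mg_phosphate(state$traj)
      emit("rdf.tsv", function(p) write_rdf_tsv(rdf, p))
    }
    emit("occupancy_vs_q.tsv", function(p) write_matrix_tsv(hm, p))
    emit("bridge_map.tsv", function(p) write_matrix_tsv(bm, p))
  })

  run_stage("pairs", function() {
    if (is.null(state$ann)) return(invisible(NULL))
    pr <- config$pairs
    st <- interaction_states(state$traj, state$cg, state$ann,
                             lambda = pr$lambda)
    fq <- frequency_vs_q(st, state$q, bin_width = pr$q_bin)
    em <- ensemble_map(st, n_residues = state$cg$n_residues)
    emit("frequency_vs_q.tsv", function(p) write_matrix_tsv(fq, p))
    emit("ensemble_map.tsv", function(p) write_matrix_tsv(em, p))
  })

  run_stage("wham", function() {
    wh <- config$wham
    cfg <- sim_config(n_steps = wh$n_steps,
                      temperature = wh$temperature %||% temperature_folded(),
                      n_mg = 0L, seed = seed0)
    if (is.null(state$top)) state$top <- build_topology(state$cg, state$nc,
                                                        cfg)
    wins <- umbrella_series(state$top, cfg, q0 = wh$q0, k_q = wh$k_q,
                            equil_steps = wh$equil_steps)
    qbw <- lapply(wins, function(tr) as.numeric(q_trajectory(tr, state$nc)))
    hist <- make_q_histograms(qbw, n_bins = wh$n_bins)
    bias <- umbrella_bias_matrix(hist$centers, wh$q0, wh$k_q)
    fep <- wham_solve(hist$counts, bias, hist$centers,
                      temperature = cfg$temperature)
    state$profile <- fep
    emit("free_energy_profile.tsv", function(p)
      write_profile_tsv(fep, p,
                        windows = list(q0 = wh$q0, k_q = wh$k_q,
                                       n_steps = wh$n_steps, seed = seed0)))
    outputs <<- c(outputs, file.path(config$out_dir,
                                     "free_energy_profile.tsv.windows.json"))
  })

  manifest <- finish()
  log_line("pipeline complete: ", length(outputs), " artifacts in ",
           config$out_dir)
  invisible(list(state = as.list(state), manifest = manifest,
                 config = config))
}
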