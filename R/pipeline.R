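#' Default pipeline configuration
#'
#' All defaults match the published parameter set: 100-member ensembles with
#' C = 1, 2 kb feature windows at 25 bp, top-2% binarization, a 15-state
#' HMM, and 25 bp output resolution. World parameters control the synthetic
#' input only.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param ... Overrides for any default field.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(out_dir = "chromscore_run", seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    world = list(n_chroms = 2L, chrom_length = 4e5, n_elements = 60L,
                 n_cell_types = 2L, n_marks = 12L, K_states = 25L,
                 noise_sd = 0.1),
    expert = list(n_models = 100L, C = 1),
    features = list(window_bp = 2000, step_bp = 25),
    hmm = list(K = 15L, top_fraction = 0.02, max_iter = 50L,
               batch_size = NULL),
    assay = "starr_peaks"
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks ranges and types; errors are violations that would break a run,
#' warnings flag deviations from the published defaults (C = 1, 100
#' members, K = 15, top 2%).
#'
#' @param config A [default_config()] list.
#' @return Tibble report with `level` (`"error"`/`"warning"`), `field`,
#'   `message`; zero rows when the config is clean.
#' @export
validate_config <- function(config) {
  rep <- list()
  add <- function(level, field, message) {
    rep[[length(rep) + 1]] <<- tibble::tibble(level = level, field = field,
                                              message = message)
  }
  tf <- config$hmm$top_fraction
  if (!is.numeric(tf) || tf <= 0 || tf >= 1) {
    add("error", "hmm.top_fraction", "must lie strictly between 0 and 1")
  }
  if (config$expert$C <= 0) add("error", "expert.C", "must be positive")
  if (config$expert$n_models < 1) add("error", "expert.n_models", "must be >= 1")
  if (config$hmm$K < 2) add("error", "hmm.K", "must be >= 2")
  if (config$world$chrom_length < 10 * config$features$window_bp) {
    add("error", "world.chrom_length", "must cover at least 10 feature windows")
  }
  if (!is.null(tf) && is.numeric(tf) && tf > 0 && tf < 1 && tf != 0.02) {
    add("warning", "hmm.top_fraction", "differs from the default 0.02")
  }
  if (config$hmm$K >= 2 && config$hmm$K != 15) {
    add("warning", "hmm.K", "differs from the default 15")
  }
  if (config$expert$n_models >= 1 && config$expert$n_models != 100) {
    add("warning", "expert.n_models", "differs from the default 100")
  }
  if (config$expert$C > 0 && config$expert$C != 1) {
    add("warning", "expert.C", "differs from the default 1")
  }
  if (length(rep) == 0) {
    return(tibble::tibble(level = character(), field = character(),
                          message = character()))
  }
  dplyr::bind_rows(rep)
}

config_hash <- function(config) {
  # stable short hash of the resolved config for provenance headers;
  # the output path is location metadata, not part of the analysis identity
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- yaml::as.yaml(cfg)
  v <- utils::head(utils::tail(strtoi(charToRaw(s), 16L), 512), 512)
  sprintf("%08x", sum(v * seq_along(v)) %% .Machine$integer.max)
}

provenance <- function(config, stage) {
  sprintf("chromscore stage=%s config=%s seed=%d", stage,
          config_hash(config), config$seed)
}

#' Run the full pipeline on a synthetic world
#'
#' Executes the stages in order -- simulate, label, train, score,
#' chromscore, binarize, hmm, segment, enrich -- writing every artifact
#' under `config$out_dir` with a provenance header (stage, config hash,
#' seed). Stages whose outputs already exist are skipped when
#' `resume = TRUE`, so interrupted runs are resumable; a rerun with the same
#' config reproduces identical outputs.
#'
#' @param config A [default_config()] list.
#' @param resume Skip stages whose outputs already exist (default TRUE).
#' @return The output directory, invisibly. Side effects: a resolved config
#'   copy (`config.yaml`), per-cell-type track/peak/segmentation files,
#'   label BEDs, expert score and ChromScore bedGraphs, binarized calls, the
#'   fitted HMM, the output segmentation and an enrichment TSV.
#' @export
run_pipeline <- function(config = default_config(), resume = TRUE) {
  errs <- validate_config(config)
  if (any(errs$level == "error")) {
    stop("invalid config: ",
         paste(errs$field[errs$level == "error"], collapse = ", "))
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(out, "config.yaml"))
  done <- function(...) all(file.exists(file.path(out, c(...))))

  w <- config$world
  world <- make_world(n_chroms = w$n_chroms, chrom_length = w$chrom_length,
                      n_elements = w$n_elements,
                      n_cell_types = w$n_cell_types, n_marks = w$n_marks,
                      K_states = w$K_states, noise_sd = w$noise_sd,
                      seed = config$seed)

  # stage: simulate -----------------------------------------------------
  rendered <- lapply(world$cell_types, function(ct) render_tracks(world, ct))
  names(rendered) <- world$cell_types
  if (!resume || !done("truth_elements.tsv")) {
    readr::write_tsv(world$elements, file.path(out, "truth_elements.tsv"))
    for (ct in world$cell_types) {
      write_segmentation(rendered[[ct]]$ann,
                         file.path(out, paste0(ct, "_states.bed")),
                         header = provenance(config, "simulate"))
      write_score_track(rendered[[ct]]$tracks[[1]],
                        file.path(out, paste0(ct, "_mark1.bedgraph")),
                        header = provenance(config, "simulate"))
    }
  }

  # stage: label ---------------------------------------------------------
  labels_by_ct <- lapply(world$cell_types, function(ct) {
    assay <- render_assay(world, ct, assay = config$assay,
                          seed = config$seed + match(ct, world$cell_types))
    act <- label_threshold_peaks(assay, threshold = 0,
                                 dataset_id = paste0(config$assay, "_", ct),
                                 cell_type = ct)
    neu <- sample_neutral_background(world$assembly, nrow(act), 3,
                                     seed = config$seed + 100 +
                                       match(ct, world$cell_types),
                                     dataset_id = paste0(config$assay, "_", ct),
                                     cell_type = ct)
    dplyr::bind_rows(act, neu)
  })
  names(labels_by_ct) <- world$cell_types
  if (!resume || !done(paste0(world$cell_types[1], "_labels.bed"))) {
    for (ct in world$cell_types) {
      write_labels(labels_by_ct[[ct]],
                   file.path(out, paste0(ct, "_labels.bed")),
                   manifest_path = file.path(out, paste0(ct, "_labels_manifest.tsv")),
                   header = provenance(config, "label"))
    }
  }

  # stage: train + score + chromscore ------------------------------------
  score_paths <- file.path(out, paste0(world$cell_types, "_chromscore.bedgraph"))
  expert_tracks_by_ct <- list()
  for (i in seq_along(world$cell_types)) {
    ct <- world$cell_types[i]
    experts <- lapply(world$cell_types, function(train_ct) {
      fit_expert(labels_by_ct[[train_ct]],
                 rendered[[train_ct]]$tracks, rendered[[train_ct]]$peaks,
                 rendered[[train_ct]]$ann,
                 n_models = config$expert$n_models, C = config$expert$C,
                 seed = config$seed + 1000 + match(train_ct, world$cell_types),
                 window_bp = config$features$window_bp,
                 step_bp = config$features$step_bp)
    })
    tracks_e <- lapply(experts, function(e)
      score_genome(e, rendered[[ct]]$tracks, rendered[[ct]]$peaks,
                   rendered[[ct]]$ann))
    names(tracks_e) <- vapply(experts, `[[`, "", "dataset_id")
    expert_tracks_by_ct[[ct]] <- tracks_e
    cs <- chromscore(tracks_e)
    if (!resume || !file.exists(score_paths[i])) {
      write_score_track(cs, score_paths[i],
                        header = provenance(config, "chromscore"))
      for (e in names(tracks_e)) {
        write_score_track(tracks_e[[e]],
                          file.path(out, paste0(ct, "_", e, ".bedgraph")),
                          header = provenance(config, "score"))
      }
    }
  }

  # stage: binarize + hmm + segment --------------------------------------
  calls_by_ct <- lapply(world$cell_types, function(ct)
    binarize_tracks(expert_tracks_by_ct[[ct]],
                    top_fraction = config$hmm$top_fraction))
  names(calls_by_ct) <- world$cell_types
  sequences <- unlist(lapply(calls_by_ct, function(c) c$calls),
                      recursive = FALSE)
  model <- fit_hmm(sequences, K = config$hmm$K,
                   max_iter = config$hmm$max_iter,
                   batch_size = config$hmm$batch_size, seed = config$seed,
                   track_names = calls_by_ct[[1]]$experts)
  model <- order_states(model)
  if (!resume || !done("hmm_model.tsv")) {
    write_hmm_model(model, file.path(out, "hmm_model.tsv"))
    readr::write_tsv(classify_states(model),
                     file.path(out, "state_groups.tsv"))
  }
  seg_paths <- file.path(out, paste0(world$cell_types, "_segmentation.bed"))
  segs <- list()
  for (i in seq_along(world$cell_types)) {
    ct <- world$cell_types[i]
    segs[[ct]] <- segment_genome(model, calls_by_ct[[ct]])
    if (!resume || !file.exists(seg_paths[i])) {
      write_segmentation(segs[[ct]], seg_paths[i],
                         header = provenance(config, "segment"))
    }
  }

  # stage: enrich ---------------------------------------------------------
  if (!resume || !done("enrichment.tsv")) {
    el <- world$elements
    planted <- tibble::tibble(chrom = el$chrom,
                              start = pmax(el$pos - 500L, 0L),
                              end = el$pos + 500L)
    enr <- overlap_fold_enrichment(segs[[1]], planted, "planted_elements")
    readr::write_tsv(enr, file.path(out, "enrichment.tsv"))
  }
  invisible(out)
}
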