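# Pipeline driver: validated run configuration, subcommands, provenance.

VARIANTS <- c("original", "rescaled", "voxelwise", "within_seed")
METHODS <- c("LE", "DE", "PCA")
MEASURES <- c("cosine", "eta2", "pearson_fc")

#' Validated pipeline run configuration
#'
#' Holds every tunable of the gradient pipeline with the conventional
#' defaults (sparsity 0.9, first three gradients, cosine measure) plus
#' paths and the master seed. All enums are validated here, before any
#' computation, and the full configuration is serialized into every
#' output's provenance file.
#'
#' @param variant fingerprint variant.
#' @param measure similarity measure (`within_seed` implies
#'   `"pearson_fc"`).
#' @param method manifold method.
#' @param sparsity row sparsification (default 0.9).
#' @param g gradients to keep (default 3).
#' @param align run Hungarian + Procrustes alignment in `group`.
#' @param seed master seed for all randomness.
#' @param data_dir cohort directory (inputs).
#' @param out_dir output directory.
#' @param overwrite allow clobbering existing outputs.
#' @param n_perm permutations for `rsa`/`classify`.
#' @param k_folds,repetitions,outer,inner CV shape for `classify`/`predict`.
#' @param synth optional [synth_config()] for `simulate` (default built
#'   from `seed`).
#' @return `congradr_config` list.
#' @export
run_config <- function(variant = "rescaled", measure = "cosine",
                       method = "DE", sparsity = 0.9, g = 3L,
                       align = TRUE, seed = 1L,
                       data_dir = "cohort", out_dir = "out",
                       overwrite = FALSE, n_perm = 99L,
                       k_folds = 5L, repetitions = 20L,
                       outer = 10L, inner = 10L, synth = NULL) {
  if (!variant %in% VARIANTS) {
    stop("variant must be one of ", paste(VARIANTS, collapse = ", "),
         call. = FALSE)
  }
  if (variant == "within_seed") measure <- "pearson_fc"
  if (!measure %in% MEASURES) {
    stop("measure must be one of ", paste(MEASURES, collapse = ", "),
         call. = FALSE)
  }
  if (!method %in% METHODS) {
    stop("method must be one of ", paste(METHODS, collapse = ", "),
         call. = FALSE)
  }
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)",
                                          call. = FALSE)
  structure(
    list(variant = variant, measure = measure, method = method,
         sparsity = sparsity, g = as.integer(g), align = isTRUE(align),
         seed = as.integer(seed), data_dir = data_dir, out_dir = out_dir,
         overwrite = isTRUE(overwrite), n_perm = as.integer(n_perm),
         k_folds = as.integer(k_folds), repetitions = as.integer(repetitions),
         outer = as.integer(outer), inner = as.integer(inner),
         synth = synth),
    class = "congradr_config"
  )
}

out_path <- function(config, name) {
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  p <- file.path(config$out_dir, name)
  if (file.exists(p) && !config$overwrite) {
    stop("output exists: ", p, " (set overwrite = TRUE to replace)",
         call. = FALSE)
  }
  p
}

write_provenance <- function(config, command, path, extra = list()) {
  keep <- config[setdiff(names(config), "synth")]
  prov <- c(list(package = "congradr",
                 version = as.character(utils::packageVersion("congradr")),
                 command = command, timestamp = format(Sys.time(), "%FT%T")),
            keep, extra)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

read_cohort_dir <- function(data_dir) {
  meta <- jsonlite::read_json(file.path(data_dir, "cohort.json"),
                              simplifyVector = TRUE)
  n <- meta$n_subjects
  subjects <- lapply(seq_len(n), function(s) {
    list(seed = read_timeseries_tsv(
           file.path(data_dir, sprintf("sub%03d_seed.tsv", s)), "seed"),
         target = read_timeseries_tsv(
           file.path(data_dir, sprintf("sub%03d_target.tsv", s)), "target"))
  })
  lab <- read_voxel_matrix_tsv(file.path(data_dir, "labels.tsv"))
  geo <- read_voxel_matrix_tsv(file.path(data_dir, "geometry.tsv"))
  phen <- data.table::fread(file.path(data_dir, "phenotypes.tsv"), sep = "\t")
  list(subjects = subjects, labels = as.integer(lab$data[, 1L]),
       geometry = geo$data, phenotypes = as.data.frame(phen), meta = meta)
}

subject_similarity <- function(subj, config) {
  build_similarity(subj$seed, subj$target, variant = config$variant,
                   measure = if (config$variant == "within_seed") NULL
                             else config$measure)
}

cohort_gradient_sets <- function(cohort, config, variant = config$variant,
                                 method = config$method) {
  lapply(cohort$subjects, function(subj) {
    S <- build_similarity(subj$seed, subj$target, variant = variant,
                          measure = if (variant == "within_seed") NULL
                                    else config$measure)
    embed_gradients(S, method = method, g = config$g,
                    sparsity = config$sparsity)
  })
}

#' Run a pipeline subcommand
#'
#' Commands: `simulate` (write a synthetic cohort to `data_dir`),
#' `gradients` (per-subject similarity + embedding), `group` (template,
#' alignment, stability), `compare` (cross-variant unaligned-gradient
#' similarity and local-minus-global difference maps), `rsa` (geometry
#' RSA per subject), `classify` (group-gradient nucleus prediction with
#' permutation chance), `predict` (nested-CV LASSO phenotype prediction).
#' All outputs are TSV/JSON in `out_dir` with a provenance JSON recording
#' the full configuration, package version, and master seed.
#'
#' @param command subcommand name.
#' @param config a [run_config()].
#' @return invisibly, a list of the objects written (command-specific).
#' @export
run_pipeline <- function(command = c("simulate", "gradients", "group",
                                     "compare", "rsa", "classify", "predict"),
                         config = run_config()) {
  command <- match.arg(command)
  stopifnot(inherits(config, "congradr_config"))
  switch(command,
         simulate = pipeline_simulate(config),
         gradients = pipeline_gradients(config),
         group = pipeline_group(config),
         compare = pipeline_compare(config),
         rsa = pipeline_rsa(config),
         classify = pipeline_classify(config),
         predict = pipeline_predict(config))
}

pipeline_simulate <- function(config) {
  cfg <- config$synth %||% synth_config(master_seed = config$seed)
  cohort <- generate_cohort(cfg)
  dd <- config$data_dir
  if (!dir.exists(dd)) dir.create(dd, recursive = TRUE)
  guard <- function(name) {
    p <- file.path(dd, name)
    if (file.exists(p) && !config$overwrite) {
      stop("output exists: ", p, " (set overwrite = TRUE to replace)",
           call. = FALSE)
    }
    p
  }
  for (s in seq_along(cohort$subjects)) {
    write_timeseries_tsv(cohort$subjects[[s]]$seed,
                         guard(sprintf("sub%03d_seed.tsv", s)))
    write_timeseries_tsv(cohort$subjects[[s]]$target,
                         guard(sprintf("sub%03d_target.tsv", s)))
  }
  ids <- cohort$subjects[[1L]]$seed$voxel_ids
  write_voxel_matrix_tsv(matrix(cohort$labels), guard("labels.tsv"),
                         voxel_ids = ids, col_names = "label")
  write_voxel_matrix_tsv(cohort$geometry, guard("geometry.tsv"),
                         voxel_ids = ids, col_names = c("x", "y", "z"))
  write_voxel_matrix_tsv(cohort$truth$coord, guard("truth_coord.tsv"),
                         voxel_ids = ids,
                         col_names = paste0("axis", seq_len(ncol(cohort$truth$coord))))
  data.table::fwrite(cohort$phenotypes, guard("phenotypes.tsv"), sep = "\t")
  jsonlite::write_json(
    list(n_subjects = length(cohort$subjects), t = cfg$t,
         m = length(ids), n = n_voxels(cohort$subjects[[1L]]$target),
         master_seed = cfg$master_seed, noise_sd = cfg$noise_sd),
    guard("cohort.json"), auto_unbox = TRUE)
  write_provenance(config, "simulate", guard("provenance.json"))
  invisible(cohort)
}

pipeline_gradients <- function(config) {
  cohort <- read_cohort_dir(config$data_dir)
  out <- vector("list", length(cohort$subjects))
  for (s in seq_along(cohort$subjects)) {
    S <- subject_similarity(cohort$subjects[[s]], config)
    G <- embed_gradients(S, method = config$method, g = config$g,
                         sparsity = config$sparsity)
    write_voxel_matrix_tsv(
      G$gradients, out_path(config, sprintf("sub%03d_gradients.tsv", s)),
      voxel_ids = G$voxel_ids, col_names = paste0("G", seq_len(config$g)))
    out[[s]] <- G
  }
  write_provenance(config, "gradients",
                   out_path(config, "gradients_provenance.json"),
                   list(n_subjects = length(out)))
  invisible(out)
}

pipeline_group <- function(config) {
  cohort <- read_cohort_dir(config$data_dir)
  sims <- lapply(cohort$subjects, subject_similarity, config = config)
  tmpl <- group_template(sims, method = config$method, g = config$g,
                         sparsity = config$sparsity)
  gg <- tmpl$group_gradients
  write_voxel_matrix_tsv(gg$gradients, out_path(config, "group_gradients.tsv"),
                         voxel_ids = gg$voxel_ids,
                         col_names = paste0("G", seq_len(config$g)))
  aligned <- NULL
  if (config$align) {
    report <- list()
    aligned <- vector("list", length(cohort$subjects))
    for (s in seq_along(cohort$subjects)) {
      Gi <- embed_gradients(sims[[s]], method = config$method, g = config$g,
                            sparsity = config$sparsity)
      mt <- match_hungarian(Gi, gg)
      Ga <- procrustes_align(Gi, gg, match = mt)
      aligned[[s]] <- Ga
      write_voxel_matrix_tsv(
        Ga$gradients, out_path(config, sprintf("sub%03d_aligned.tsv", s)),
        voxel_ids = Ga$voxel_ids, col_names = paste0("G", seq_len(config$g)))
      report[[s]] <- data.frame(
        subject = s, component = seq_len(config$g),
        group_component = mt$permutation, sign = mt$signs,
        match_score = mt$match_scores)
    }
    data.table::fwrite(data.table::rbindlist(report),
                       out_path(config, "alignment_report.tsv"), sep = "\t")
    stab <- gradient_stability(aligned, gg)
    data.table::fwrite(
      data.table::data.table(gradient = seq_along(stab), stability = stab,
                             retained = retain_gradients(stab)),
      out_path(config, "stability.tsv"), sep = "\t")
  }
  write_provenance(config, "group", out_path(config, "group_provenance.json"))
  invisible(list(template = tmpl, aligned = aligned))
}

pipeline_compare <- function(config) {
  cohort <- read_cohort_dir(config$data_dir)
  per_method <- list()
  for (method in METHODS) {
    gsets <- lapply(cohort$subjects, function(subj) {
      setNames(lapply(VARIANTS, function(v) {
        S <- build_similarity(subj$seed, subj$target, variant = v,
                              measure = if (v == "within_seed") NULL
                                        else config$measure)
        embed_gradients(S, method = method, g = config$g,
                        sparsity = config$sparsity)
      }), VARIANTS)
    })
    per_method[[method]] <- unaligned_cross_variant_similarity(gsets)
  }
  avg <- Reduce(`+`, per_method) / length(per_method)
  rows <- do.call(rbind, lapply(names(per_method), function(mm) {
    df <- as.data.frame(as.table(per_method[[mm]]))
    names(df) <- c("variant_a", "variant_b", "similarity")
    cbind(method = mm, df)
  }))
  df_avg <- as.data.frame(as.table(avg))
  names(df_avg) <- c("variant_a", "variant_b", "similarity")
  rows <- rbind(rows, cbind(method = "avg", df_avg))
  data.table::fwrite(rows, out_path(config, "compare_similarity.tsv"),
                     sep = "\t")

  # group-level local (original) minus global (rescaled) difference maps
  sims_local <- lapply(cohort$subjects, function(subj) {
    build_similarity(subj$seed, subj$target, "original",
                     measure = config$measure)
  })
  sims_global <- lapply(cohort$subjects, function(subj) {
    build_similarity(subj$seed, subj$target, "rescaled",
                     measure = config$measure)
  })
  gl <- group_template(sims_local, method = config$method, g = config$g,
                       sparsity = config$sparsity)$group_gradients
  gr <- group_template(sims_global, method = config$method, g = config$g,
                       sparsity = config$sparsity)$group_gradients
  mt <- match_hungarian(gl, gr)
  diff <- zscore_and_difference(apply_match(gl, mt), gr)
  write_voxel_matrix_tsv(diff, out_path(config, "local_global_difference.tsv"),
                         voxel_ids = gl$voxel_ids,
                         col_names = paste0("G", seq_len(config$g)))
  write_provenance(config, "compare",
                   out_path(config, "compare_provenance.json"))
  invisible(list(per_method = per_method, average = avg, difference = diff))
}

pipeline_rsa <- function(config) {
  cohort <- read_cohort_dir(config$data_dir)
  gsets <- cohort_gradient_sets(cohort, config)
  rows <- lapply(seq_along(gsets), function(s) {
    r <- rsa_geometry(gsets[[s]], cohort$geometry, n_perm = config$n_perm,
                      seed = spawn_seed(config$seed, paste0("rsa/sub", s)))
    data.frame(subject = s, observed_r = r$observed_r, p_value = r$p_value)
  })
  df <- do.call(rbind, rows)
  data.table::fwrite(df, out_path(config, "rsa.tsv"), sep = "\t")
  write_provenance(config, "rsa", out_path(config, "rsa_provenance.json"))
  invisible(df)
}

pipeline_classify <- function(config) {
  cohort <- read_cohort_dir(config$data_dir)
  sims <- lapply(cohort$subjects, subject_similarity, config = config)
  gg <- group_template(sims, method = config$method, g = config$g,
                       sparsity = config$sparsity)$group_gradients
  cls <- classify_nuclei(gg, cohort$labels, k_folds = config$k_folds,
                         repetitions = config$repetitions, seed = config$seed)
  ch <- chance_accuracy(cohort$labels, gg, n_perm = config$n_perm,
                        seed = config$seed, k_folds = config$k_folds)
  data.table::fwrite(
    data.table::data.table(repetition = seq_along(cls$per_rep_accuracy),
                           accuracy = cls$per_rep_accuracy),
    out_path(config, "classify.tsv"), sep = "\t")
  jsonlite::write_json(
    list(mean_accuracy = mean(cls$per_rep_accuracy), chance = ch$chance,
         n_perm = config$n_perm),
    out_path(config, "classify_summary.json"), auto_unbox = TRUE, digits = NA)
  write_provenance(config, "classify",
                   out_path(config, "classify_provenance.json"))
  invisible(list(classification = cls, chance = ch))
}

pipeline_predict <- function(config) {
  cohort <- read_cohort_dir(config$data_dir)
  sims <- lapply(cohort$subjects, subject_similarity, config = config)
  tmpl <- group_template(sims, method = config$method, g = config$g,
                         sparsity = config$sparsity)
  gg <- tmpl$group_gradients
  feats <- t(vapply(seq_along(sims), function(s) {
    Gi <- embed_gradients(sims[[s]], method = config$method, g = config$g,
                          sparsity = config$sparsity)
    Ga <- procrustes_align(Gi, gg, match = match_hungarian(Gi, gg))
    as.numeric(Ga$gradients)
  }, numeric(nrow(gg$gradients) * config$g)))
  metrics <- setdiff(names(cohort$phenotypes), "subject")
  rows <- list()
  weights <- list()
  for (mt in metrics) {
    fit <- lasso_predict(feats, cohort$phenotypes[[mt]],
                         outer = config$outer, inner = config$inner,
                         repetitions = config$repetitions,
                         seed = spawn_seed(config$seed, paste0("predict/", mt)))
    frac <- significance_summary(fit$per_rep_rho, fit$n_subjects,
                                 n_comparisons = length(metrics))
    rows[[mt]] <- data.frame(metric = mt,
                             repetition = seq_along(fit$per_rep_rho),
                             rho = fit$per_rep_rho,
                             significant_fraction = frac)
    weights[[mt]] <- fit$weight_map
  }
  df <- do.call(rbind, rows)
  data.table::fwrite(df, out_path(config, "predict.tsv"), sep = "\t")
  W <- do.call(cbind, weights)
  write_voxel_matrix_tsv(W, out_path(config, "predict_weights.tsv"),
                         voxel_ids = seq_len(nrow(W)),
                         col_names = metrics)
  write_provenance(config, "predict",
                   out_path(config, "predict_provenance.json"))
  invisible(list(results = df, weights = weights))
}
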