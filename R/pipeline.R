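#' Pipeline run configuration
#'
#' All tunable parameters of the end-to-end demonstration pipeline, with
#' defaults sized for a quick deterministic run (24 subjects on a 12^3 grid).
#' One global `seed` fans out to fixed per-stage offsets so that each stage
#' is independently reproducible.
#'
#' @param n_subjects cohort size.
#' @param grid BOLD voxel grid.
#' @param n_volumes,tr acquisition length and repetition time.
#' @param noise_sd,nuisance_amplitude session noise levels (BOLD a.u.).
#' @param coupling_base baseline source-coupling amplitude; each subject's
#'   planted connectivity offsets this value.
#' @param coupling_gain amplitude change per unit of true connectivity; sets
#'   how much between-subject contrast the sessions carry.
#' @param band,filter_order analysis passband (Hz) and Butterworth order; the
#'   default is the wide resting-state band (the narrow `c(0.08, 0.1)` preset
#'   leaves too few in-band dimensions for nuisance removal to spare signal
#'   at 120 volumes — see the methods vignette).
#' @param tbr_var_keep fraction of data variance kept as the TBR
#'   dimensionality (see [tbr_timecourses()]).
#' @param mask_fraction network-mask threshold fraction of the map maximum.
#' @param pib_cutoff fixed amyloid positivity cutoff (DVR); set
#'   `fit_cutoff = TRUE` to derive it from the sample by [gmm_cutoff()]
#'   instead (needs >= 20 subjects).
#' @param fit_cutoff derive the cutoff from the sample.
#' @param atlas_replicates number of replicate label volumes entering the
#'   modal atlas.
#' @param target_voxel composite-resampling target resolution (mm).
#' @param vertex_radius vertex labelling radius (mm).
#' @param n_vertices surface vertices generated per network.
#' @param fixed_effects generative coefficients passed to [cohort_config()];
#'   the demo default plants a strong negative FC x PiB x time interaction so
#'   that sign recovery is decisive at 24 subjects.
#' @param residual_sd,random_sd cohort noise levels (mm, mm/year).
#' @param seed global integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 24L, grid = c(12L, 12L, 12L),
                            n_volumes = 120L, tr = 3,
                            noise_sd = 0.5, nuisance_amplitude = 0.5,
                            coupling_base = 0.6, coupling_gain = 2,
                            band = c(0.008, 0.1), filter_order = 4L,
                            tbr_var_keep = 0.99, mask_fraction = 0.4,
                            pib_cutoff = 1.186, fit_cutoff = FALSE,
                            atlas_replicates = 9L, target_voxel = 1.5,
                            vertex_radius = 2, n_vertices = 120L,
                            fixed_effects = list(fc_pib_time = -1.8,
                                                 fc_time = 0.1),
                            residual_sd = 0.04,
                            random_sd = c(intercept = 0.08, slope = 0.008),
                            seed = 42L) {
  structure(as.list(environment()), class = c("pipeline_config", "list"))
}

# Stage seed offsets (global seed + offset), fixed so stages never collide.
stage_seed <- function(seed, stage)
  seed + c(simulate = 101L, sessions = 1000L, composites = 305L,
           pet = 407L, vertices = 509L)[[stage]]

#' Run the full pipeline
#'
#' Executes simulate -> preproc -> connect -> composites -> pet -> fit in
#' dependency order on a synthetic cohort with known ground truth:
#'
#' 1. **simulate** — cohort trajectories, template maps, per-subject BOLD
#'    sessions (source coupling tied to each subject's true connectivity),
#'    PET ROI uptake tables, and surface vertices with per-visit thickness.
#' 2. **preproc** — per-session filtering, 33-regressor nuisance reduction
#'    and removal; QC covariates (mean FD, retained PCs).
#' 3. **connect** — TBR time courses, network masks, whole-network
#'    connectivity, bilateral FPCN averaging, between-subject adjustment.
#' 4. **composites** — modal label atlas from replicate label volumes,
#'    resampling to the fine grid, vertex labelling, per-visit composite
#'    thickness.
#' 5. **pet** — FLR DVR, IT tau SUVR, amyloid group assignment.
#' 6. **fit** — the primary mixed model (plus stratified fits when both
#'    groups are large enough) on the measured quantities.
#'
#' @param config a [pipeline_config()] (or YAML-loaded equivalent).
#' @param output_dir optional directory; when given, tables, templates and the
#'   manifest are written there and checksummed.
#' @param stages character subset of the stage names, in any order;
#'   dependencies are validated.
#' @return A list of class `pipeline_run`: `manifest`, `truth`, `qc`,
#'   `connectivity`, `composites`, `pet`, `table` (the modelling table) and
#'   `fits` (named list of [fit_thinning_lme()] objects), populated for the
#'   stages run.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         stages = c("simulate", "preproc", "connect",
                                    "composites", "pet", "fit")) {
  all_stages <- c("simulate", "preproc", "connect", "composites", "pet", "fit")
  bad <- setdiff(stages, all_stages)
  fail_if(length(bad) > 0, "run_pipeline: unknown stage(s): %s", paste(bad, collapse = ", "))
  deps <- list(preproc = "simulate", connect = c("simulate", "preproc"),
               composites = "simulate", pet = "simulate",
               fit = c("connect", "composites", "pet"))
  for (s in intersect(names(deps), stages)) {
    missing <- setdiff(deps[[s]], stages)
    fail_if(length(missing) > 0, "run_pipeline: stage '%s' requires stage '%s'",
            s, missing[1])
  }
  run <- list(config = config)
  seed <- config$seed

  ## simulate ---------------------------------------------------------------
  cc <- cohort_config(n_subjects = config$n_subjects,
                      fixed_effects = config$fixed_effects,
                      residual_sd = config$residual_sd,
                      random_sd = config$random_sd,
                      seed = stage_seed(seed, "simulate"))
  cohort <- generate_cohort(cc)
  truth <- cohort$truth
  sc <- session_config(grid = config$grid, n_volumes = config$n_volumes,
                       tr = config$tr, n_sources = 3L,
                       noise_sd = config$noise_sd,
                       nuisance_amplitude = config$nuisance_amplitude,
                       seed = stage_seed(seed, "simulate"))
  templates <- generate_templates(sc)
  sessions <- lapply(seq_len(config$n_subjects), function(i) {
    sci <- sc; sci$seed <- stage_seed(seed, "sessions") + i
    coupling <- config$coupling_base + config$coupling_gain *
      c(truth$fc[i], truth$fpcn_fc[i], truth$fpcn_fc[i])
    generate_session(templates, sci, coupling = pmax(coupling, 0.05))
  })
  pet_tables <- with_local_seed(stage_seed(seed, "pet"), {
    amy <- do.call(rbind, lapply(seq_len(config$n_subjects), function(i) {
      data.frame(subject = i,
                 region = c(flr_regions(), "cerebellum_cortex"),
                 uptake = c(truth$pib[i] * (1 + rnorm(16, 0, 0.01)), 1))
    }))
    tau <- do.call(rbind, lapply(seq_len(config$n_subjects), function(i) {
      data.frame(subject = i,
                 region = c("lh_inferiortemporal", "rh_inferiortemporal",
                            "cerebellum_cortex"),
                 uptake = c(truth$it_tau[i] * (1 + rnorm(2, 0, 0.01)), 1))
    }))
    list(amyloid = amy, tau = tau)
  })
  vertices <- with_local_seed(stage_seed(seed, "vertices"), {
    masks <- lapply(templates$names, function(nm)
      which(as.logical(network_mask(templates, nm, config$mask_fraction))))
    vx <- voxel_centers(config$grid, sc$voxel_size)
    do.call(rbind, lapply(seq_along(masks), function(li) {
      pick <- sample(masks[[li]], config$n_vertices, replace = TRUE)
      data.frame(x = vx[pick, 1] + runif(config$n_vertices, -1, 1),
                 y = vx[pick, 2] + runif(config$n_vertices, -1, 1),
                 z = vx[pick, 3] + runif(config$n_vertices, -1, 1),
                 true_network = templates$names[li])
    }))
  })
  # per-subject per-visit vertex thickness: DMN vertices carry the DMN
  # trajectory, FPCN vertices the FPCN trajectory
  vertex_thickness <- with_local_seed(stage_seed(seed, "vertices") + 1L, {
    lapply(seq_len(config$n_subjects), function(i) {
      rows <- cohort$table[cohort$table$subject == i, ]
      vapply(seq_len(nrow(rows)), function(j) {
        base <- ifelse(vertices$true_network == "DMN", rows$thickness[j],
                       rows$fpcn_thickness[j])
        base + rnorm(nrow(vertices), 0, 0.05)
      }, numeric(nrow(vertices)))
    })
  })
  run$truth <- truth
  run$templates <- templates
  run$cohort <- cohort$table
  if (identical(stages, "simulate") || !any(c("preproc", "connect",
                                              "composites", "pet") %in% stages)) {
    run$manifest <- build_manifest(run, output_dir)
    return(structure(run, class = "pipeline_run"))
  }

  ## preproc ----------------------------------------------------------------
  qc <- NULL; cleaned <- NULL
  if ("preproc" %in% stages) {
    pre <- lapply(sessions, function(s)
      preprocess_session(s$bold, s$motion, s$tissues, band = config$band,
                         order = config$filter_order))
    cleaned <- lapply(pre, `[[`, "bold")
    qc <- data.frame(subject = seq_along(pre),
                     mean_fd = vapply(pre, `[[`, numeric(1), "mean_fd"),
                     n_retained = vapply(pre, `[[`, numeric(1), "n_retained"))
    run$qc <- qc
  }

  ## connect ----------------------------------------------------------------
  if ("connect" %in% stages) {
    masks <- lapply(setNames(templates$names, templates$names), function(nm)
      network_mask(templates, nm, config$mask_fraction))
    raw <- t(vapply(seq_along(cleaned), function(i) {
      tc <- tbr_timecourses(cleaned[[i]], templates,
                            var_keep = config$tbr_var_keep)
      c(DMN = as.numeric(network_connectivity(cleaned[[i]], tc, masks$DMN)),
        FPCN = bilateral_average(
          network_connectivity(cleaned[[i]], tc, masks$FPCN_L),
          network_connectivity(cleaned[[i]], tc, masks$FPCN_R)))
    }, numeric(2)))
    conn <- rbind(
      data.frame(subject = qc$subject, network = "DMN", raw = raw[, "DMN"]),
      data.frame(subject = qc$subject, network = "FPCN", raw = raw[, "FPCN"]))
    conn$adjusted <- c(
      residualize_between_subject(raw[, "DMN"], qc$mean_fd, qc$n_retained),
      residualize_between_subject(raw[, "FPCN"], qc$mean_fd, qc$n_retained))
    conn$mean_fd <- rep(qc$mean_fd, 2)
    conn$n_pcs <- rep(qc$n_retained, 2)
    run$connectivity <- conn
  }

  ## composites -------------------------------------------------------------
  if ("composites" %in% stages) {
    dict <- setNames(seq_along(templates$names), templates$names)
    map_max <- apply(templates$maps, 2, max)
    base_labels <- apply(templates$maps, 1, function(v) {
      over <- v > config$mask_fraction * map_max
      if (!any(over)) 0L else unname(dict[which.max(ifelse(over, v, -Inf))])
    })
    reps <- with_local_seed(stage_seed(seed, "composites"), {
      lapply(seq_len(config$atlas_replicates), function(r) {
        lab <- base_labels
        drop <- runif(length(lab)) < 0.05
        lab[drop] <- 0L
        label_volume(array(lab, dim = config$grid), voxel_size = sc$voxel_size,
                     dictionary = dict)
      })
    })
    atlas <- modal_label_atlas(reps)
    node_masks <- lapply(dict, function(id) (atlas$labels == id) * 1)
    td <- floor((config$grid - 1) * sc$voxel_size / config$target_voxel) + 1L
    gray <- label_volume(array(1L, dim = td), voxel_size = config$target_voxel)
    highres <- resample_node_mask(node_masks, voxel_size = sc$voxel_size,
                                  target_voxel = config$target_voxel,
                                  gray_partition = gray, labels = dict)
    labelled <- map_labels_to_vertices(highres, vertices,
                                       radius = config$vertex_radius)
    comp <- do.call(rbind, lapply(seq_len(config$n_subjects), function(i) {
      rows <- cohort$table[cohort$table$subject == i, ]
      th <- vertex_thickness[[i]]
      do.call(rbind, lapply(seq_len(nrow(rows)), function(j) {
        dmn <- composite_thickness(labelled, "DMN", th[, j], dictionary = dict)
        fp_l <- composite_thickness(labelled, "FPCN_L", th[, j], dictionary = dict)
        fp_r <- composite_thickness(labelled, "FPCN_R", th[, j], dictionary = dict)
        data.frame(subject = i, visit = rows$visit[j], time = rows$time[j],
                   dmn_thickness = dmn$mean, n_dmn = dmn$n_vertices,
                   fpcn_thickness = (fp_l$mean * fp_l$n_vertices +
                                       fp_r$mean * fp_r$n_vertices) /
                     (fp_l$n_vertices + fp_r$n_vertices))
      }))
    }))
    run$atlas <- highres
    run$composites <- comp
  }

  ## pet --------------------------------------------------------------------
  if ("pet" %in% stages) {
    amy <- flr_dvr(pet_tables$amyloid)
    amy$subject <- as.integer(amy$subject)
    cutoff <- if (isTRUE(config$fit_cutoff))
      as.numeric(gmm_cutoff(amy$dvr, seed = stage_seed(seed, "pet")))
    else config$pib_cutoff
    amy$group <- classify_amyloid(amy$dvr, cutoff)
    tau <- it_suvr(pet_tables$tau)
    tau$subject <- as.integer(tau$subject)
    run$pet <- list(amyloid = amy, tau = tau, cutoff = cutoff)
  }

  ## fit --------------------------------------------------------------------
  if ("fit" %in% stages) {
    base <- cohort$table[, c("subject", "visit", "time", "age", "sex", "edu")]
    tab <- merge(base, run$composites[, c("subject", "visit", "dmn_thickness",
                                          "fpcn_thickness")],
                 by = c("subject", "visit"))
    names(tab)[names(tab) == "dmn_thickness"] <- "thickness"
    wide_fc <- run$connectivity
    fc_d <- wide_fc[wide_fc$network == "DMN", c("subject", "adjusted")]
    names(fc_d)[2] <- "fc"
    fc_f <- wide_fc[wide_fc$network == "FPCN", c("subject", "adjusted")]
    names(fc_f)[2] <- "fpcn_fc"
    tab <- merge(merge(tab, fc_d, by = "subject"), fc_f, by = "subject")
    tab <- merge(tab, run$pet$amyloid[, c("subject", "dvr", "group")], by = "subject")
    names(tab)[names(tab) == "dvr"] <- "pib"
    tab <- merge(tab, setNames(run$pet$tau[, c("subject", "suvr")],
                               c("subject", "it_tau")), by = "subject")
    tab <- tab[order(tab$subject, tab$visit), ]
    run$table <- tab
    fits <- list(primary = fit_thinning_lme(tab, model = "primary"))
    subj_group <- tab$group[!duplicated(tab$subject)]
    for (g in c("high", "low")) {
      if (sum(subj_group == g) >= 5)
        fits[[paste0("stratified_", g)]] <-
          fit_thinning_lme(tab, model = "stratified", group = g)
    }
    run$fits <- fits
  }

  run$manifest <- build_manifest(run, output_dir)
  structure(run, class = "pipeline_run")
}

# Internal: assemble (and optionally write) the run manifest.
build_manifest <- function(run, output_dir) {
  cfg <- run$config
  man <- list(package = "netthin",
              version = as.character(utils::packageVersion("netthin")),
              seed = cfg$seed,
              parameters = cfg[setdiff(names(cfg), "fixed_effects")],
              fixed_effects = cfg$fixed_effects,
              n_subjects = cfg$n_subjects)
  if (!is.null(run$fits))
    man$primary_fit <- run$fits$primary$coefficients
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    wr <- function(obj, name) {
      p <- file.path(output_dir, name)
      write.csv(obj, p, row.names = FALSE)
      paths <<- c(paths, p)
    }
    if (!is.null(run$cohort)) wr(run$cohort, "cohort.csv")
    if (!is.null(run$qc)) wr(run$qc, "session_qc.csv")
    if (!is.null(run$connectivity)) wr(run$connectivity, "connectivity.csv")
    if (!is.null(run$composites)) wr(run$composites, "composites.csv")
    if (!is.null(run$pet)) wr(run$pet$amyloid, "amyloid.csv")
    if (!is.null(run$table)) wr(run$table, "model_table.csv")
    if (!is.null(run$fits))
      wr(run$fits$primary$coefficients, "primary_fit.csv")
    if (!is.null(run$templates)) {
      p <- file.path(output_dir, "templates.nii.gz")
      write_volume(run$templates, p)
      paths <- c(paths, p, paste0(p, ".json"))
    }
    man$files <- as.list(tools::md5sum(paths))
    jsonlite::write_json(man, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  man
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d subjects, seed %d\n",
              x$config$n_subjects, x$config$seed))
  done <- intersect(c("cohort", "qc", "connectivity", "composites", "pet",
                      "table", "fits"), names(x))
  cat("  components:", paste(done, collapse = ", "), "\n")
  if (!is.null(x$fits)) {
    pr <- x$fits$primary
    cf <- pr$coefficients[pr$coefficients$term == pr$primary_term, ]
    cat(sprintf("  primary fc:pib:time: est %.3f, t(%d) = %.2f, p = %.3g\n",
                cf$estimate, cf$df, cf$t, cf$p))
  }
  invisible(x)
}

#' Model report across fits
#'
#' Collates fixed-effect inference from several [fit_thinning_lme()] objects
#' into one long table (model, term, estimate, t, df, p, d), the layout used
#' to compare the primary fit with stratified and augmented fits.
#'
#' @param fits a single fit or named list of `thinning_lme` fits.
#' @return data.frame of class `thinning_report`.
#' @export
make_report <- function(fits) {
  if (inherits(fits, "thinning_lme")) fits <- list(model = fits)
  fail_if(length(fits) < 1, "make_report: need at least one fit")
  stopifnot(all(vapply(fits, inherits, logical(1), "thinning_lme")))
  nms <- names(fits) %||% sprintf("model%d", seq_along(fits))
  out <- do.call(rbind, lapply(seq_along(fits), function(i) {
    cf <- fits[[i]]$coefficients
    cbind(model = nms[i], cf,
          primary = cf$term == fits[[i]]$primary_term)
  }))
  rownames(out) <- NULL
  class(out) <- c("thinning_report", "data.frame")
  out
}

#' @export
print.thinning_report <- function(x, ...) {
  for (m in unique(x$model)) {
    cat(sprintf("== %s ==\n", m))
    cf <- x[x$model == m, c("term", "estimate", "t", "df", "p", "d", "primary")]
    cf$estimate <- signif(cf$estimate, 4); cf$t <- round(cf$t, 2)
    cf$p <- signif(cf$p, 3); cf$d <- round(cf$d, 2)
    cf$primary <- ifelse(cf$primary, "*", "")
    print(as.data.frame(cf), row.names = FALSE)
  }
  invisible(x)
}
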