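#' Subject-level ROI connectivity from annotated trials
#'
#' Runs the per-subject preprocessing chain for one condition: per trial,
#' zero-phase bandpass in the theta and gamma bands, artifact excision into
#' continuous clean segments, analytic transform per segment (edge-trimmed),
#' concatenation of all clean segments, and finally the three connectivity
#' matrices (dPLI theta, dPLI gamma, theta-to-gamma nMI). Both bands are
#' trimmed by the same number of samples — one cycle of the lowest band
#' edge — so theta phase and gamma amplitude stay sample-aligned for the
#' cross-frequency measure.
#'
#' @param samples Samples-by-ROI matrix for the whole recording (trials
#'   concatenated).
#' @param annotations Annotation data frame (`kind`, `start`, `stop`,
#'   `label` in seconds): `trial` rows delimit trials, `artifact` rows mark
#'   segments to exclude.
#' @param fs Sampling rate (Hz).
#' @param theta_band,gamma_band Passbands (Hz).
#' @param order Butterworth design order.
#' @return List `dpli_theta`, `dpli_gamma`, `nmi` (see
#'   [connectivity_matrices()]).
#' @export
subject_connectivity <- function(samples, annotations, fs,
                                 theta_band = c(7, 10),
                                 gamma_band = c(30, 80), order = 4) {
  samples <- as.matrix(samples)
  trials <- annotations[annotations$kind == "trial", , drop = FALSE]
  artifacts <- annotations[annotations$kind == "artifact", , drop = FALSE]
  if (!nrow(trials)) stop("no trial annotations")
  low <- min(theta_band[1], gamma_band[1])
  trim <- ceiling(fs / low)
  min_samp <- 3 * trim
  th_segs <- list()
  ga_segs <- list()
  for (tr in seq_len(nrow(trials))) {
    i0 <- floor(trials$start[tr] * fs) + 1L
    i1 <- min(nrow(samples), round(trials$stop[tr] * fs))
    x <- samples[i0:i1, , drop = FALSE]
    art <- artifacts[artifacts$start < trials$stop[tr] &
                       artifacts$stop > trials$start[tr], , drop = FALSE]
    if (nrow(art)) {
      art$start <- pmax(0, art$start - trials$start[tr])
      art$stop <- pmin(trials$stop[tr] - trials$start[tr],
                       art$stop - trials$start[tr])
    }
    th <- bandpass(x, theta_band, fs, order)
    ga <- bandpass(x, gamma_band, fs, order)
    sth <- clean_segments(th$samples, art, fs, min_samples = min_samp)
    sga <- clean_segments(ga$samples, art, fs, min_samples = min_samp)
    for (k in seq_along(sth)) {
      th_segs[[length(th_segs) + 1L]] <-
        analytic(band_signal(sth[[k]], fs, theta_band),
                 trim_samples = trim)
      ga_segs[[length(ga_segs) + 1L]] <-
        analytic(band_signal(sga[[k]], fs, gamma_band),
                 trim_samples = trim)
    }
  }
  connectivity_matrices(concatenate_clean(th_segs),
                        concatenate_clean(ga_segs))
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis into one validated
#' object: band definitions, filter order, the three significance
#' thresholds (per-source cluster-forming `alpha_init_cluster`, per-link
#' network-forming `alpha_init_nbs`, and the final permutation threshold
#' `alpha_final`), the permutation count, the master seed, and paths.
#' Defaults follow common practice for this analysis family: cluster
#' forming at p < 0.0005, link forming at p < 0.005, final p < 0.05 with
#' 5000 permutations.
#'
#' @param data_dir Directory holding per-subject matrices and annotations
#'   (as written by [write_dataset()]).
#' @param out_dir Output directory for all artifacts.
#' @param theta_band,gamma_band Passbands in Hz.
#' @param filter_order Butterworth design order.
#' @param alpha_init_cluster,alpha_init_nbs,alpha_final Thresholds in
#'   (0, 1).
#' @param n_perm Permutations for all permutation tests.
#' @param seed Master seed.
#' @param inverse_matrix,inverse_coords Optional paths to an inverse
#'   operator (see [read_inverse_operator()]); when given, data are treated
#'   as sensor-level and projected to ROI series first.
#' @param roi_table_path Optional ROI table path (default: bundled
#'   synthetic table).
#' @param simulation Optional named list of [sim_config()] arguments for
#'   the `simulate` stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            theta_band = c(7, 10), gamma_band = c(30, 80),
                            filter_order = 4, alpha_init_cluster = 5e-4,
                            alpha_init_nbs = 0.005, alpha_final = 0.05,
                            n_perm = 5000, seed = 1,
                            inverse_matrix = NULL, inverse_coords = NULL,
                            roi_table_path = NULL, simulation = NULL) {
  for (a in c(alpha_init_cluster, alpha_init_nbs, alpha_final))
    if (a <= 0 || a >= 1) stop("alpha thresholds must be in (0, 1)")
  if (n_perm < 1) stop("n_perm must be >= 1")
  structure(list(data_dir = data_dir, out_dir = out_dir,
                 theta_band = theta_band, gamma_band = gamma_band,
                 filter_order = filter_order,
                 alpha_init_cluster = alpha_init_cluster,
                 alpha_init_nbs = alpha_init_nbs,
                 alpha_final = alpha_final, n_perm = n_perm,
                 seed = as.integer(seed), inverse_matrix = inverse_matrix,
                 inverse_coords = inverse_coords,
                 roi_table_path = roi_table_path, simulation = simulation),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every printed parameter of the analysis is a named, overridable key;
#' unknown keys are rejected so typos fail before any computation.
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

plog <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

list_dataset_files <- function(data_dir) {
  mats <- list.files(data_dir, "^sub[0-9]+_(memory|control)\\.tsv$")
  if (!length(mats)) stop("no subject matrices found in ", data_dir)
  info <- do.call(rbind, strsplit(sub("\\.tsv$", "", mats), "_"))
  data.frame(file = file.path(data_dir, mats), subject = info[, 1],
             condition = info[, 2],
             annotations = file.path(data_dir,
                                     sub("\\.tsv$", "_annotations.tsv",
                                         mats)))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order:
#' `simulate` (synthetic dataset written to `data_dir`), `connectivity`
#' (per-subject preprocessing and the three connectivity matrices, written
#' with a manifest), `power` (band power per ROI/source with cluster-based
#' permutation contrast), `nbs` (directed network statistics: paired nMI
#' contrast, one-sample dPLI per band and condition, plus the
#' between-condition overlap of significant dPLI link sets), and
#' `distances` (link-distance ANOVA across the significant networks).
#' `all` runs everything. Reruns with the same configuration and seed
#' reproduce identical outputs; every stage is logged with its parameters
#' and seed to `out_dir/run_log.txt`.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stage names, or `"all"`.
#' @return Invisible list of stage results.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "connectivity", "power", "nbs", "distances")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  plog(log_path, "run started; seed = %d; n_perm = %d; stages: %s",
       config$seed, config$n_perm, paste(stages, collapse = ", "))
  res <- list()

  if ("simulate" %in% stages) {
    sim_args <- config$simulation %||% list()
    sim_args$seed <- sim_args$seed %||% config$seed
    sc <- do.call(sim_config, sim_args)
    ds <- gen_dataset(sc)
    write_dataset(ds, config$data_dir)
    plog(log_path, "simulate: %d subjects, %d ROIs -> %s",
         sc$n_subjects, sc$n_rois, config$data_dir)
    res$dataset <- ds
  }

  roi_table <- read_roi_table(config$roi_table_path %||%
                                system.file("extdata", "roi84_synthetic.tsv",
                                            package = "dirconn"))
  needs_data <- any(c("connectivity", "power", "nbs", "distances") %in%
                      stages)
  if (!needs_data) return(invisible(res))
  if (!dir.exists(config$data_dir))
    stop("stage input missing: data_dir '", config$data_dir,
         "' not found (run the simulate stage or point to existing data)")
  files <- list_dataset_files(config$data_dir)
  fs_probe <- NULL

  inv <- NULL
  if (!is.null(config$inverse_matrix)) {
    if (!file.exists(config$inverse_matrix) ||
        !file.exists(config$inverse_coords))
      stop("stage 'connectivity' requires the inverse operator files; not found: ",
           config$inverse_matrix)
    inv <- read_inverse_operator(config$inverse_matrix,
                                 config$inverse_coords)
  }

  if (any(c("connectivity", "power", "nbs", "distances") %in% stages)) {
    conn_dir <- file.path(config$out_dir, "connectivity")
    dir.create(conn_dir, showWarnings = FALSE)
    conn <- list()
    power_rows <- list()
    manifest <- NULL
    fs <- NULL
    for (i in seq_len(nrow(files))) {
      x <- read_num_matrix(files$file[i])
      ann <- read_annotations(files$annotations[i])
      if (is.null(fs)) {
        # sampling rate recovered from the first trial annotation
        tr1 <- ann[ann$kind == "trial", ][1, ]
        ntr <- sum(ann$kind == "trial")
        fs <- round(nrow(x) / sum(ann$stop[ann$kind == "trial"] -
                                    ann$start[ann$kind == "trial"]))
        plog(log_path, "data: %d channels at %g Hz, %d trials", ncol(x),
             fs, ntr)
      }
      if (!is.null(inv)) {
        x <- rereference_common_average(x)
        membership <- assign_sources_to_rois(inv$coords, roi_table)
        x <- project_to_rois(x, inv, membership, config, fs)
      }
      cm <- subject_connectivity(x, ann, fs, config$theta_band,
                                 config$gamma_band, config$filter_order)
      key <- paste(files$subject[i], files$condition[i], sep = "_")
      conn[[key]] <- cm
      for (ms in names(cm)) {
        f <- file.path(conn_dir, sprintf("%s_%s.tsv", key, ms))
        write_num_matrix(cm[[ms]], f,
                         col_names = utils::head(roi_table$abbrev, ncol(cm[[ms]])))
        manifest <- rbind(manifest,
                          data.frame(subject = files$subject[i],
                                     condition = files$condition[i],
                                     measure = ms, file = basename(f)))
      }
      # band power per ROI: standardized theta power averaged over time
      th <- analytic(bandpass(x, config$theta_band, fs,
                              config$filter_order))
      pw <- standardize_power(th$amplitude^2)
      power_rows[[key]] <- colMeans(pw, na.rm = TRUE)
    }
    utils::write.table(manifest, file.path(conn_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    plog(log_path, "connectivity: %d subject x condition sets -> %s",
         length(conn), conn_dir)
    res$connectivity <- conn
    res$power <- power_rows
  }

  subjects <- sort(unique(files$subject))
  get_mats <- function(cond, ms)
    lapply(subjects, function(s) res$connectivity[[paste(s, cond,
                                                         sep = "_")]][[ms]])

  if ("power" %in% stages) {
    pa <- do.call(rbind, lapply(subjects, function(s)
      res$power[[paste(s, "memory", sep = "_")]]))
    pb <- do.call(rbind, lapply(subjects, function(s)
      res$power[[paste(s, "control", sep = "_")]]))
    cent <- as.matrix(roi_table[seq_len(ncol(pa)), c("x", "y", "z")])
    adj <- adjacency_from_coords(cent)
    cr <- cluster_perm_power(pa, pb, adj,
                             alpha_init = config$alpha_init_cluster,
                             alpha_cluster = config$alpha_final,
                             n_perm = config$n_perm, seed = config$seed,
                             coords = cent)
    utils::write.table(cr$summary,
                       file.path(config$out_dir, "power_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    plog(log_path, "power: %d candidate cluster(s), %d significant",
         nrow(cr$summary), length(cr$clusters))
    res$power_clusters <- cr
  }

  if (any(c("nbs", "distances") %in% stages)) {
    net_dir <- file.path(config$out_dir, "networks")
    dir.create(net_dir, showWarnings = FALSE)
    labels <- utils::head(roi_table$abbrev,
                          nrow(res$connectivity[[1]]$nmi))
    lg <- function(m) logit_connectivity(m)
    nets <- list()
    nmi_res <- nbs_paired(lapply(get_mats("memory", "nmi"), lg),
                          lapply(get_mats("control", "nmi"), lg),
                          alpha_init = config$alpha_init_nbs,
                          alpha_comp = config$alpha_final,
                          n_perm = config$n_perm, seed = config$seed,
                          measure = "nMI", labels = labels)
    res$nbs_nmi <- nmi_res
    if (length(nmi_res$networks)) nets$nmi <- nmi_res$networks[[1]]
    dpli_links <- list()
    for (band in c("dpli_theta", "dpli_gamma")) {
      for (cond in c("memory", "control")) {
        r <- nbs_onesample_dpli(lapply(get_mats(cond, band), lg),
                                alpha_init = config$alpha_init_nbs,
                                alpha_comp = config$alpha_final,
                                n_perm = config$n_perm,
                                seed = config$seed,
                                measure = paste(band, cond, sep = "_"),
                                labels = labels)
        res[[paste("nbs", band, cond, sep = "_")]] <- r
        if (length(r$networks)) {
          lk <- do.call(rbind, lapply(r$networks, `[[`, "links"))
          dpli_links[[paste(band, cond, sep = "_")]] <- lk
          if (cond == "memory") nets[[band]] <- r$networks[[1]]
        }
        plog(log_path, "nbs %s %s: %d significant component(s)", band,
             cond, length(r$networks))
      }
      a <- dpli_links[[paste(band, "memory", sep = "_")]]
      b <- dpli_links[[paste(band, "control", sep = "_")]]
      if (!is.null(a) && !is.null(b)) {
        ov <- merge(a[, c("src", "dst")], b[, c("src", "dst")])
        plog(log_path, "%s: %d link(s) shared between conditions", band,
             nrow(ov))
        res[[paste("overlap", band, sep = "_")]] <- ov
      }
    }
    for (nm in names(nets))
      write_network(nets[[nm]], file.path(net_dir, nm))
    res$networks <- nets
  }

  if ("distances" %in% stages) {
    da <- tryCatch(link_distance_anova(res$networks, roi_table),
                   error = function(e) conditionMessage(e),
                   warning = function(w) conditionMessage(w))
    if (is.character(da)) {
      plog(log_path, "distances: skipped (%s)", da)
    } else {
      utils::write.table(da$posthoc,
                         file.path(config$out_dir,
                                   "distance_posthoc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      plog(log_path, "distances: F = %.3f, p = %.3g", da$anova$F,
           da$anova$p)
      res$distances <- da
    }
  }
  plog(log_path, "run finished")
  invisible(res)
}

# Sensor -> ROI path: project each band-agnostic sensor matrix through the
# inverse operator (real linear map), then reduce each ROI's member-source
# dipole series to one representative course by SVD.
project_to_rois <- function(x, inv, membership, config, fs) {
  s <- x %*% t(inv$K)
  roi_ids <- sort(unique(membership[!is.na(membership)]))
  roi_reduce(s, membership, roi_ids = roi_ids)
}
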