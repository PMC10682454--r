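# Session serialization and end-to-end orchestration.
#
# Sessions are stored as a plain-text directory: one CSV per activity
# matrix, CSVs for behaviour and masks, optional CSVs for LFP traces, and
# a JSON metadata file. Ground truth goes to a single JSON file. The text
# layout keeps sessions diffable and readable from any language.

#' Write a session bundle to a directory
#'
#' Layout: `rest1.csv`, `run.csv`, `rest2.csv` (frames x neurons),
#' `behaviour.csv` (position_cm, velocity), `movement_mask.csv`,
#' `lfp_rest1.csv`/`lfp_rest2.csv` when present, and `meta.json`.
#'
#' @param session A `"session_bundle"`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wm <- function(M, f) utils::write.csv(as.data.frame(M),
                                        file.path(path, f), row.names = FALSE)
  wm(session$rest1, "rest1.csv")
  wm(session$run, "run.csv")
  wm(session$rest2, "rest2.csv")
  wm(data.frame(position_cm = session$position_cm,
                velocity = session$velocity), "behaviour.csv")
  wm(data.frame(rest1 = session$movement_mask$rest1,
                rest2 = session$movement_mask$rest2), "movement_mask.csv")
  if (!is.null(session$lfp)) {
    wm(data.frame(v = session$lfp$rest1), "lfp_rest1.csv")
    wm(data.frame(v = session$lfp$rest2), "lfp_rest2.csv")
  }
  meta <- unclass(session$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session bundle from a directory
#'
#' @param path Directory written by [write_session()].
#' @return A `"session_bundle"`.
#' @export
read_session <- function(path) {
  rm_ <- function(f) as.matrix(utils::read.csv(file.path(path, f)))
  beh <- utils::read.csv(file.path(path, "behaviour.csv"))
  mm <- utils::read.csv(file.path(path, "movement_mask.csv"))
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  meta$seed <- as.integer(meta$seed)
  class(meta) <- "sim_config"
  lfp <- NULL
  if (file.exists(file.path(path, "lfp_rest1.csv"))) {
    lfp <- list(rest1 = utils::read.csv(file.path(path, "lfp_rest1.csv"))$v,
                rest2 = utils::read.csv(file.path(path, "lfp_rest2.csv"))$v)
  }
  structure(list(
    rest1 = unname(rm_("rest1.csv")),
    run = unname(rm_("run.csv")),
    rest2 = unname(rm_("rest2.csv")),
    position_cm = beh$position_cm,
    velocity = beh$velocity,
    movement_mask = list(rest1 = as.logical(mm$rest1),
                         rest2 = as.logical(mm$rest2)),
    lfp = lfp,
    meta = meta
  ), class = "session_bundle")
}

#' Write ground truth to JSON
#'
#' @param truth A `"ground_truth"` object.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read ground truth from JSON
#'
#' @param path JSON file written by [write_ground_truth()].
#' @return A `"ground_truth"` object.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$ensemble_members <- lapply(x$ensemble_members, as.integer)
  x$reactivation_times_s <- lapply(x$reactivation_times_s,
                                   function(b) lapply(b, as.numeric))
  x$reactivation_coupled <- lapply(x$reactivation_coupled,
                                   function(b) lapply(b, as.logical))
  x$swr_times_s <- lapply(x$swr_times_s, as.numeric)
  class(x) <- "ground_truth"
  x
}

#' Validate a session bundle against the pipeline's requirements
#'
#' Checks non-negativity of activity, position bounds, consistent neuron
#' counts, mask alignment, and the session-inclusion rule of at least 10
#' completed laps during RUN.
#'
#' @param session A `"session_bundle"`.
#' @return Character vector of violations (empty when the session is
#'   valid).
#' @export
validate_session <- function(session) {
  v <- character(0)
  add <- function(v, ok, msg) if (!ok) c(v, msg) else v
  v <- add(v, inherits(session, "session_bundle"), "not a session_bundle")
  if (length(v)) return(v)
  ncols <- c(ncol(session$rest1), ncol(session$run), ncol(session$rest2))
  v <- add(v, length(unique(ncols)) == 1,
           "blocks disagree on the number of neurons")
  v <- add(v, min(session$rest1, session$run, session$rest2) >= 0,
           "negative activity values")
  L <- session$meta$belt_length_cm
  v <- add(v, all(session$position_cm >= 0) && all(session$position_cm < L),
           "positions outside [0, belt_length)")
  v <- add(v, length(session$position_cm) == nrow(session$run),
           "position trace does not align with RUN frames")
  v <- add(v, length(session$movement_mask$rest1) == nrow(session$rest1) &&
             length(session$movement_mask$rest2) == nrow(session$rest2),
           "movement masks do not align with rest frames")
  n_laps <- max(lap_index(session$position_cm, L))
  v <- add(v, n_laps >= 10,
           sprintf("only %d laps in RUN (>= 10 required)", n_laps))
  v
}

#' Run the full analysis pipeline on a session
#'
#' Executes, in order: spatial-cell classification on RUN, ensemble
#' detection and classification in both rest blocks, the seeded PCA-ICA
#' reactivation model on REST2 (and REST1 when it has ensembles), SWR
#' detection on the LFP when present, coupling analyses (peri-SWR
#' averages, coupled cue-trajectory pairs, SWR association, explained
#' variance, REST1-REST2 persistence), and the Hopfield coupled-retrieval
#' experiment when the session yields both coupled and uncoupled pairs.
#'
#' @param session A `"session_bundle"` (e.g. from
#'   [simulate_full_experiment()] or [read_session()]).
#' @param n_shuffles Shuffles for the spatial-information null.
#' @param seed Seed for all stochastic stages.
#' @param out_dir Optional directory; when given, per-stage tables are
#'   written as CSV/JSON and a manifest with file checksums is saved.
#' @return A list of class `"pipeline_result"` with one element per stage
#'   and a `manifest`.
#' @export
run_pipeline <- function(session, n_shuffles = 300, seed = 1L,
                         out_dir = NULL) {
  t0 <- Sys.time()
  violations <- validate_session(session)
  if (length(violations)) {
    stop("invalid session: ", paste(violations, collapse = "; "))
  }
  cfg <- session$meta
  fr <- cfg$frame_rate_hz

  spatial <- classify_spatial_cells(session$run, session$position_cm,
                                    n_shuffles = n_shuffles,
                                    frame_rate_hz = fr,
                                    belt_length_cm = cfg$belt_length_cm,
                                    seed = seed)

  ens <- list()
  models <- list()
  for (block in c("rest1", "rest2")) {
    dm <- correlation_distance(session[[block]],
                               session$movement_mask[[block]],
                               frame_rate_hz = fr)
    es <- detect_ensembles(dm, block = block)
    es <- classify_ensembles(es, spatial, cfg$cue_centers_cm)
    ens[[block]] <- es
    models[[block]] <- if (length(es) > 0) {
      fit_reactivation(session[[block]], es,
                       movement_mask = session$movement_mask[[block]],
                       frame_rate_hz = fr)
    } else NULL
  }

  ripples <- NULL
  if (!is.null(session$lfp)) {
    ripples <- lapply(session$lfp, find_ripples, rate_hz = cfg$lfp_rate_hz)
  }

  coupling <- NULL
  hopfield <- NULL
  m2 <- models$rest2
  if (!is.null(m2)) {
    labs <- vapply(ens$rest2$ensembles, function(e) e$label, character(1))
    cue_idx <- which(labs == "cue")
    traj_idx <- which(labs == "trajectory")
    feats <- extract_run_features(m2, session$run, session$position_cm,
                                  belt_length_cm = cfg$belt_length_cm)
    ev_frac <- explained_variance(session$rest1, session$run, session$rest2,
                                  session$movement_mask$rest1,
                                  session$movement_mask$rest2)
    coupling <- list(features = feats, explained_variance = ev_frac)
    if (!is.null(ripples)) {
      swr2 <- ripples$rest2$onset_s
      if (length(swr2) >= 1) {
        coupling$peri_swr <- lapply(seq_along(m2$members), function(m)
          peri_event_average(m2$strength[, m], swr2, fr))
        coupling$swr_assoc <- vapply(seq_along(m2$members), function(m)
          swr_association_fraction(m2$events[[m]]$onset_s, swr2), numeric(1))
      }
    }
    if (length(cue_idx) >= 1 && length(traj_idx) >= 1) {
      pairs <- find_coupled_pairs(
        m2$strength[, cue_idx, drop = FALSE],
        m2$strength[, traj_idx, drop = FALSE],
        frame_rate_hz = fr, seed = seed,
        features_cue = feats[cue_idx, , drop = FALSE],
        features_traj = feats[traj_idx, , drop = FALSE])
      coupling$pairs <- pairs
      if (any(pairs$coupled) && any(!pairs$coupled)) {
        hopfield <- coupled_retrieval_experiment(
          feats[cue_idx, , drop = FALSE],
          feats[traj_idx, , drop = FALSE], pairs)
      }
    }
    # REST1 -> REST2 persistence
    if (!is.null(models$rest1)) {
      r1_members <- ensemble_members(ens$rest1)
      coupling$persistence <- vapply(ensemble_members(ens$rest2),
                                     max_jaccard, numeric(1),
                                     member_sets = r1_members)
    }
  }

  result <- structure(list(
    spatial = spatial,
    ensembles = ens,
    models = models,
    ripples = ripples,
    coupling = coupling,
    hopfield = hopfield,
    manifest = list(
      seed = seed,
      n_shuffles = n_shuffles,
      started = format(t0),
      finished = format(Sys.time()),
      stages = c("spatial", "ensembles", "reactivation",
                 if (!is.null(ripples)) "ripples",
                 if (!is.null(coupling)) "coupling",
                 if (!is.null(hopfield)) "hopfield")
    )
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(spatial$summary, file.path(out_dir, "spatial.csv"),
                     row.names = FALSE)
    ens_json <- lapply(ens, function(es) lapply(es$ensembles, function(e)
      list(members = e$members, label = e$label, segments = e$segments)))
    jsonlite::write_json(ens_json, file.path(out_dir, "ensembles.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(ripples)) {
      utils::write.csv(do.call(rbind, lapply(names(ripples), function(b)
        cbind(block = b, as.data.frame(ripples[[b]])))),
        file.path(out_dir, "swr.csv"), row.names = FALSE)
    }
    if (!is.null(coupling$pairs)) {
      utils::write.csv(as.data.frame(coupling$pairs),
                       file.path(out_dir, "coupled_pairs.csv"),
                       row.names = FALSE)
    }
    files <- list.files(out_dir, full.names = TRUE)
    result$manifest$checksums <- tools::md5sum(files)
    jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  spatial cells: %d / %d\n", sum(x$spatial$summary$is_spatial),
              nrow(x$spatial$summary)))
  for (b in names(x$ensembles)) {
    labs <- vapply(x$ensembles[[b]]$ensembles, function(e) e$label, character(1))
    cat(sprintf("  %s: %d ensemble(s) [%s]\n", b, length(labs),
                paste(labs, collapse = ", ")))
  }
  if (!is.null(x$ripples)) {
    cat(sprintf("  SWRs: %s\n", paste(vapply(x$ripples, nrow, integer(1)),
                                      collapse = " / ")))
  }
  if (!is.null(x$coupling$explained_variance)) {
    cat(sprintf("  ev = %.1f%%, rev = %.1f%%\n",
                x$coupling$explained_variance$ev_percent,
                x$coupling$explained_variance$rev_percent))
  }
  invisible(x)
}
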